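# memoised fixtures: tiny cohorts and models shared across test files
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

tiny_cohort <- function() memo("tiny_cohort", cohort_fixture(seed = 42424242))

tiny_train_config <- function(loss = "edl_sos", ...) {
  train_config(loss = loss, epochs = 15, hidden = c(32, 16), embed_dim = 16,
               img_channels = c(4, 8), img_embed_dim = 16, seed = 7, ...)
}

tiny_models <- function(loss = "edl_sos") {
  memo(paste0("tiny_models_", loss), {
    tr <- dplyr::filter(tiny_cohort(), split == "train")
    list(f = train_unimodal(tr, tiny_train_config(loss)),
         h = train_multimodal(tr, tiny_train_config(loss)),
         train = tr,
         test = dplyr::filter(tiny_cohort(), split == "test"))
  })
}

# a small linearly separable tabular set (two informative regions)
separable_records <- function(n_per_class = 4, jitter = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    tibble::tibble(
      label = factor(rep(c("cn", "ad"), each = n_per_class),
                     levels = c("cn", "ad")),
      region_001 = rep(c(1, 3), each = n_per_class) + stats::runif(n, -jitter, jitter),
      region_002 = rep(c(5, 2), each = n_per_class) + stats::runif(n, -jitter, jitter)
    )
  })
}

# Monte-Carlo oracle for the Dirichlet expectation of ||y - p||^2
mc_dirichlet_sos <- function(alpha, y, n_draws = 1e5) {
  K <- length(alpha)
  G <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
              n_draws, K)
  P <- G / rowSums(G)
  sq <- (matrix(y, n_draws, K, byrow = TRUE) - P)^2
  vals <- rowSums(sq)
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(n_draws))
}
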