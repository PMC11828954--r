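test_that("the simple gate refers exactly when uncertainty exceeds the threshold", {
  expect_equal(simple_gate(0.6, 0.5), "multi")
  expect_equal(simple_gate(0.4, 0.5), "uni")
  expect_equal(simple_gate(0.5, 0.5), "uni")  # ties take the cheaper path
  expect_equal(simple_gate(c(0, 0.5, 0.50001, 1), 0.5),
               c("uni", "uni", "multi", "multi"))
  expect_error(simple_gate(-0.1, 0.5), "non-negative")
  expect_error(simple_gate(0.2, 1.5), "0, 1")
})

test_that("cosine similarity matches its geometric special cases", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("centroids average the lowest- and highest-uncertainty embeddings", {
  E <- rbind(c(1, 0), c(3, 0), c(0, 2), c(0, 4))
  cp <- build_centroids(E, c(0.1, 0.2, 0.8, 0.9), cutoff_fraction = 0.5)
  expect_equal(cp$g_low, c(2, 0))
  expect_equal(cp$g_high, c(0, 3))
  cp1 <- build_centroids(E, c(0.1, 0.2, 0.8, 0.9), cutoff_fraction = 0.25)
  expect_equal(cp1$g_low, c(1, 0))   # single lowest embedding
  expect_equal(cp1$g_high, c(0, 4))  # single highest embedding
  expect_warning(build_centroids(E, rep(0.3, 4), 0.5), "stable input order")
  expect_error(build_centroids(E, c(0.1, 0.2, 0.8, 0.9), 0.1), "empty")
  expect_error(build_centroids(E, c(0.1, 0.2, 0.8, 0.9), 0.6), "0, 0.5")
})

test_that("ties in uncertainty are broken by stable input order", {
  E <- diag(4)
  cp <- suppressWarnings(build_centroids(E, rep(0.5, 4), 0.25))
  expect_equal(cp$g_low, E[1, ])   # first input
  expect_equal(cp$g_high, E[4, ])  # last input
})

test_that("the distance gate keeps instances near the low-uncertainty centroid", {
  cp <- structure(list(g_low = c(1, 0), g_high = c(0, 1),
                       cutoff_fraction = 0.5, n_low = 1, n_high = 1),
                  class = "centroid_pair")
  expect_equal(distance_gate(c(1, 0), cp), "uni")
  expect_equal(distance_gate(c(0, 1), cp), "multi")
  expect_equal(distance_gate(c(1, 1), cp), "uni")  # equidistant tie
  # the literal similarity orientation flips the rule
  expect_equal(distance_gate(c(1, 0), cp, orientation = "similarity"), "multi")
  expect_error(distance_gate(c(0, 0), cp), "zero vector")
})

test_that("ensemble decisions honour the threshold extremes", {
  m <- tiny_models()
  pol_hi <- gate_policy("simple", tau = 1, uncertainty = "edl")
  dec_hi <- ensemble_predict(m$test, m$f, m$h, pol_hi)
  expect_true(all(dec_hi$used_model == "uni"))
  expect_equal(dec_hi$predicted_label,
               predict(m$f, m$test, type = "class")$.pred_class)
  expect_equal(attr(dec_hi, "n_x2_fetches"), 0L)

  pol_lo <- gate_policy("simple", tau = 0, uncertainty = "edl")
  dec_lo <- ensemble_predict(m$test, m$f, m$h, pol_lo)
  expect_true(all(dec_lo$uncertainty > 0))  # Dirichlet uncertainty mass is positive
  expect_true(all(dec_lo$used_model == "multi"))
  expect_equal(dec_lo$predicted_label,
               predict(m$h, m$test, type = "class")$.pred_class)
})

test_that("the second modality is fetched lazily, once per referral", {
  m <- tiny_models()
  calls <- 0L
  provider <- function(recs, i) {
    calls <<- calls + 1L
    list(image_left = recs$image_left[[i]], image_right = recs$image_right[[i]])
  }
  pol <- gate_policy("simple", tau = stats::median(
    predict(m$f, m$test, type = "opinion")$.uncertainty), uncertainty = "edl")
  dec <- ensemble_predict(m$test, m$f, m$h, pol, x2_provider = provider)
  expect_equal(calls, sum(dec$used_model == "multi"))
  expect_equal(attr(dec, "n_x2_fetches"), calls)
  expect_gt(calls, 0)
  expect_lt(calls, nrow(m$test))
})

test_that("a referral without the second modality is an error", {
  m <- tiny_models()
  te <- m$test
  te$image_left <- vector("list", nrow(te))
  te$image_right <- vector("list", nrow(te))
  pol <- gate_policy("simple", tau = 0, uncertainty = "edl")
  expect_error(ensemble_predict(te, m$f, m$h, pol), "unavailable")
})

test_that("gating is deterministic and referral sets nest as the threshold falls", {
  m <- tiny_models()
  u <- predict(m$f, m$test, type = "opinion")$.uncertainty
  taus <- sort(unique(c(0.2, stats::quantile(u, c(0.3, 0.7)))))
  prev <- NULL
  for (tau in rev(taus)) {  # descending tau
    dec <- ensemble_predict(m$test, m$f, m$h,
                            gate_policy("simple", tau = tau, uncertainty = "edl"))
    dec2 <- ensemble_predict(m$test, m$f, m$h,
                             gate_policy("simple", tau = tau, uncertainty = "edl"))
    expect_identical(dec, dec2)
    referred <- dec$subject_id[dec$used_model == "multi"]
    if (!is.null(prev)) expect_true(all(prev %in% referred))
    prev <- referred
  }
})

test_that("distance-mode decisions record similarities to both centroids", {
  m <- tiny_models()
  u_tr <- predict(m$f, m$train, type = "opinion")$.uncertainty
  cp <- build_centroids(embed(m$f, m$train), u_tr, 0.3)
  pol <- gate_policy("distance", centroids = cp, uncertainty = "edl")
  dec <- ensemble_predict(m$test, m$f, m$h, pol)
  expect_true(all(is.finite(dec$sim_low)))
  expect_true(all(is.finite(dec$sim_high)))
  expect_equal(dec$used_model == "uni", dec$sim_low >= dec$sim_high)
})

test_that("cutoff calibration maximises accuracy and prefers cheaper ties", {
  m <- tiny_models()
  single <- calibrate_cutoff(0.3, m$f, m$h, m$train, m$test, uncertainty = "edl")
  expect_equal(as.numeric(single), 0.3)
  multi <- calibrate_cutoff(c(0.2, 0.4), m$f, m$h, m$train, m$test,
                            uncertainty = "edl")
  res <- attr(multi, "results")
  expect_equal(nrow(res), 2)
  best <- res[order(-res$accuracy, res$referral_fraction), ][1, ]
  expect_equal(as.numeric(multi), best$cutoff_fraction)
  expect_error(calibrate_cutoff(numeric(0), m$f, m$h, m$train, m$test), "non-empty")
})
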