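#' Monte-Carlo dropout prediction
#'
#' Runs `passes` stochastic forward passes with the model's dropout layers
#' active (normalisation-free layers stay deterministic) and collects the
#' per-pass class probabilities. The scalar per-instance uncertainty is the
#' population standard deviation, across passes, of the probability of the
#' second class (for the binary task; for K > 2 the mean of the per-class
#' standard deviations).
#'
#' @param model A fitted `unimodal_model` or `multimodal_model` containing at
#'   least one dropout layer.
#' @param newdata Tibble of subjects to predict.
#' @param passes Number of stochastic forward passes (>= 2; default 100).
#' @param seed Integer seed; fixed seed reproduces the samples exactly.
#' @return An `mc_prediction` object: list with `samples` (passes x n x K
#'   array), `mean_probs` (n x K matrix), `raw_uncertainty` (length-n
#'   vector), `passes`.
#' @export
mc_predict <- function(model, newdata, passes = 100, seed = 1) {
  stopifnot(inherits(model, "mg_model"))
  if (passes < 2) stop("`passes` must be >= 2", call. = FALSE)
  layers <- if (inherits(model, "unimodal_model")) model$net$trunk
            else c(model$net$tab, model$net$img)
  if (!stack_has_dropout(layers)) {
    stop("model has no dropout layers; Monte-Carlo dropout is not applicable",
         call. = FALSE)
  }
  n <- nrow(newdata)
  K <- length(model$classes)
  samples <- array(0, c(passes, n, K))
  withr::with_seed(seed, {
    for (t in seq_len(passes)) {
      z <- forward_logits(model, newdata, stochastic = TRUE)
      samples[t, , ] <- logits_to_probs(model, z)$prob
    }
  })
  mean_probs <- apply(samples, c(2, 3), mean)
  # population SD (divide by T) per class, per instance
  sq <- apply(samples^2, c(2, 3), mean)
  sds <- sqrt(pmax(sq - mean_probs^2, 0))
  raw <- if (K == 2) sds[, 2] else rowMeans(sds)
  structure(list(samples = samples, mean_probs = mean_probs,
                 raw_uncertainty = as.numeric(raw), passes = passes),
            class = "mc_prediction")
}

#' @export
print.mc_prediction <- function(x, ...) {
  cat(sprintf("<mc_prediction> %d passes x %d instances x %d classes\n",
              x$passes, dim(x$samples)[2], dim(x$samples)[3]))
  invisible(x)
}

#' @describeIn mc_predict one row per instance with mean probabilities and
#'   raw uncertainty.
#' @param x An `mc_prediction`.
#' @param ... Unused.
#' @export
tidy.mc_prediction <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$mean_probs))
  names(out) <- paste0(".mean_prob_", seq_len(ncol(out)))
  out$.raw_uncertainty <- x$raw_uncertainty
  out
}

#' Max-normalize raw uncertainties
#'
#' Divides each raw uncertainty by the largest value in the set, mapping the
#' set into [0, 1], so estimates from one model are comparable on a common
#' per-set scale. The reference maximum is attached as
#' `attr(, "reference_max")`. An all-zero input is returned unchanged.
#'
#' @param values Non-empty numeric vector of raw uncertainties, all >= 0.
#' @return Numeric vector in [0, 1] of the same length and order.
#' @export
normalize_uncertainties <- function(values) {
  if (!is.numeric(values) || length(values) == 0) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and non-negative", call. = FALSE)
  }
  mx <- max(values)
  out <- if (mx > 0) values / mx else values
  attr(out, "reference_max") <- mx
  out
}
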