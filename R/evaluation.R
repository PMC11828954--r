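#' Cost reduction of a set of gate decisions
#'
#' The fraction of decisions made without requesting the second modality:
#' `(number of uni decisions) / (total decisions)`. This is the method's cost
#' metric; 132 referred out of 228 test decisions corresponds to a cost
#' reduction of 96/228, printed as 42%.
#'
#' @param decisions A [`gate_decisions`][ensemble_predict] tibble (or any
#'   data frame with a `used_model` column of `"uni"`/`"multi"`).
#' @return Fraction in [0, 1].
#' @export
cost_reduction <- function(decisions) {
  if (is.null(decisions$used_model) || nrow(decisions) == 0) {
    stop("`decisions` must be a non-empty gate-decision table", call. = FALSE)
  }
  mean(decisions$used_model == "uni")
}

#' Accuracy/cost frontier over uncertainty thresholds
#'
#' Evaluates the simple-thresholding ensemble at each threshold of a grid:
#' for every test instance the uni-modal model's uncertainty is compared to
#' the threshold, the gate-selected prediction is scored against the true
#' label, and the referral fraction and its complement (the cost reduction)
#' are recorded. The pure uni-modal and pure multi-modal test accuracies are
#' attached as the curve's endpoints.
#'
#' @param records Labelled test records.
#' @param f,h Fitted uni-modal and multi-modal models.
#' @param thresholds Numeric grid (default 0.1 to 0.9 in steps of 0.1).
#' @param uncertainty `"edl"` or `"mc"`.
#' @param passes Monte-Carlo passes for `"mc"`.
#' @param seed Seed for Monte-Carlo passes.
#' @return A `cost_accuracy_curve` tibble with columns `threshold`,
#'   `accuracy`, `referral_fraction`, `cost_reduction`, and attributes
#'   `uni_accuracy` / `multi_accuracy`.
#' @export
sweep_thresholds <- function(records, f, h, thresholds = seq(0.1, 0.9, by = 0.1),
                             uncertainty = c("edl", "mc"), passes = 100,
                             seed = 1) {
  if (length(thresholds) == 0) stop("`thresholds` must be non-empty", call. = FALSE)
  uncertainty <- match.arg(uncertainty)
  if (is.null(records$label)) stop("records must be labelled", call. = FALSE)
  probe <- gate_policy("simple", uncertainty = uncertainty, passes = passes)
  u <- as.numeric(gate_uncertainties(f, records, probe, seed = seed))
  truth <- records$label
  uni_pred <- predict(f, records, type = "class")$.pred_class
  multi_pred <- predict(h, records, type = "class")$.pred_class
  pts <- purrr::map_dfr(sort(thresholds), function(tau) {
    refer <- u > tau
    pred <- uni_pred
    pred[refer] <- multi_pred[refer]
    tibble::tibble(threshold = tau,
                   accuracy = mean(pred == truth),
                   referral_fraction = mean(refer),
                   cost_reduction = 1 - mean(refer))
  })
  attr(pts, "uni_accuracy") <- mean(uni_pred == truth)
  attr(pts, "multi_accuracy") <- mean(multi_pred == truth)
  attr(pts, "uncertainty_method") <- uncertainty
  class(pts) <- c("cost_accuracy_curve", class(pts))
  pts
}

#' @export
print.cost_accuracy_curve <- function(x, ...) {
  cat(sprintf("<cost_accuracy_curve> %s uncertainty | pure uni %.3f | pure multi %.3f\n",
              attr(x, "uncertainty_method"), attr(x, "uni_accuracy"),
              attr(x, "multi_accuracy")))
  NextMethod()
}

#' Plot an accuracy/cost frontier
#'
#' Accuracy against uncertainty threshold, each point annotated with its
#' cost reduction; dashed lines mark the pure uni-modal and multi-modal
#' accuracies.
#'
#' @param object A `cost_accuracy_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_accuracy_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = attr(object, "uni_accuracy"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = attr(object, "multi_accuracy"),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$cost_reduction)),
      vjust = -1, size = 3) +
    ggplot2::labs(x = "uncertainty threshold", y = "ensemble accuracy",
                  title = "Accuracy vs. referral threshold",
                  subtitle = "labels: cost reduction (fraction of second-modality scans avoided)") +
    ggplot2::theme_minimal()
}

#' Zero-mask volumetric regions
#'
#' Sets selected region columns (or entries of a feature vector) to zero,
#' emulating missing/occluded regions for out-of-distribution probing. When
#' a count `k` is given the masked subset is drawn uniformly with the stated
#' seed; all other entries are returned bit-identical.
#'
#' @param features Numeric vector, or a data frame with `region_*` columns.
#' @param regions Explicit integer indices (1-based, into the region
#'   columns) to mask; mutually exclusive with `k`.
#' @param k Number of regions to mask, drawn uniformly at random.
#' @param seed Seed for the random draw when `k` is given.
#' @return Perturbed copy of `features`; the masked indices are attached as
#'   `attr(, "masked_regions")`.
#' @export
mask_regions <- function(features, regions = NULL, k = NULL, seed = 1) {
  is_df <- is.data.frame(features)
  cols <- if (is_df) feature_columns(features) else NULL
  p <- if (is_df) length(cols) else length(features)
  if (is.null(regions)) {
    if (is.null(k)) stop("give either `regions` or `k`", call. = FALSE)
    if (k < 0 || k > p) stop("`k` must be in [0, ", p, "]", call. = FALSE)
    regions <- if (k == 0) integer(0)
               else withr::with_seed(seed, sort(sample.int(p, k)))
  } else {
    regions <- as.integer(regions)
    if (length(regions) > 0 && (min(regions) < 1 || max(regions) > p)) {
      stop("region index out of range", call. = FALSE)
    }
  }
  out <- features
  if (is_df) {
    for (j in regions) out[[cols[j]]] <- 0
  } else {
    out[regions] <- 0
  }
  attr(out, "masked_regions") <- regions
  out
}

#' Rotate an image clockwise about its centre
#'
#' Bilinear rotation in the row-major, origin-top-left convention: positive
#' degrees rotate the image clockwise (a pixel at (r, c) maps under a 90
#' degree clockwise turn to (c, H-1-r) for square images, 0-based). Pixels
#' sampled from outside the frame are 0; `degrees = 0` bypasses resampling
#' and returns the input bit-exactly.
#'
#' @param image H x W x 3 numeric array.
#' @param degrees Finite rotation angle in degrees.
#' @return Rotated H x W x 3 array.
#' @export
rotate_image <- function(image, degrees) {
  if (length(degrees) != 1 || !is.finite(degrees)) {
    stop("`degrees` must be a single finite number", call. = FALSE)
  }
  if (degrees == 0) return(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  th <- degrees * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  # output pixel grid, 0-based centred coordinates (x = col, y = row, y down)
  rr <- rep(seq_len(H) - 1, times = W)
  cc <- rep(seq_len(W) - 1, each = H)
  up <- cc - cx
  vp <- rr - cy
  # inverse map of the clockwise (y-down) rotation
  us <- up * cos(th) + vp * sin(th) + cx
  vs <- -up * sin(th) + vp * cos(th) + cy
  x0 <- floor(us); y0 <- floor(vs)
  fx <- us - x0; fy <- vs - y0
  out <- array(0, d)
  pixel_at <- function(ch, y, x) {
    ok <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    v <- numeric(length(x))
    v[ok] <- ch[cbind(y[ok] + 1, x[ok] + 1)]
    v
  }
  for (k in seq_len(d[3])) {
    ch <- image[, , k]
    v <- (1 - fx) * (1 - fy) * pixel_at(ch, y0, x0) +
      fx * (1 - fy) * pixel_at(ch, y0, x0 + 1) +
      (1 - fx) * fy * pixel_at(ch, y0 + 1, x0) +
      fx * fy * pixel_at(ch, y0 + 1, x0 + 1)
    out[, , k] <- matrix(v, H, W)
  }
  out
}

#' Out-of-distribution uncertainty report
#'
#' Derives, per perturbation level, an OOD copy of every in-distribution
#' instance (zero-masking `k` regions drawn once per level; for multi-modal
#' models additionally rotating both lateral images clockwise), computes the
#' per-instance uncertainty of the model on both sets, and records the mean
#' uncertainties. The OOD set is instance-paired with the InD set.
#'
#' @param model Fitted `unimodal_model` or `multimodal_model`.
#' @param records InD records (typically the test split).
#' @param method `"edl"` (Dirichlet uncertainty mass; requires an evidential
#'   model) or `"mc"` (raw Monte-Carlo dropout standard deviation).
#' @param levels Perturbation levels: a numeric vector of masking counts
#'   `k`, or a data frame / list of `(k, degrees)` pairs for multi-modal
#'   perturbation.
#' @param passes Monte-Carlo passes for `"mc"`.
#' @param seed Seed (drives both the masked-region draws and the
#'   Monte-Carlo passes; the same passes seed is used for InD and OOD so a
#'   no-op perturbation yields identical uncertainties).
#' @return An `ood_report` tibble: one row per level with `k_masked`,
#'   `rotation_deg`, `mu_ind`, `mu_ood` and list-columns `u_ind`, `u_ood`.
#' @export
ood_report <- function(model, records, method = c("edl", "mc"), levels,
                       passes = 100, seed = 1) {
  method <- match.arg(method)
  if (length(levels) == 0) stop("`levels` must be non-empty", call. = FALSE)
  if (is.data.frame(levels)) {
    lv <- lapply(seq_len(nrow(levels)),
                 function(i) c(k = levels$k[i], degrees = levels$degrees[i]))
  } else if (is.list(levels)) {
    lv <- lapply(levels, function(x) c(k = x[[1]], degrees = x[[2]]))
  } else {
    lv <- lapply(levels, function(k) c(k = k, degrees = 0))
  }
  p <- length(feature_columns(records))
  for (l in lv) if (l[["k"]] < 0 || l[["k"]] > p) {
    stop("masking count outside [0, ", p, "]", call. = FALSE)
  }

  u_of <- function(recs) {
    if (method == "edl") {
      predict(model, recs, type = "opinion")$.uncertainty
    } else {
      mc_predict(model, recs, passes = passes, seed = seed)$raw_uncertainty
    }
  }
  u_ind <- u_of(records)
  multimodal <- inherits(model, "multimodal_model")
  out <- purrr::map_dfr(seq_along(lv), function(i) {
    k <- lv[[i]][["k"]]; deg <- lv[[i]][["degrees"]]
    pert <- mask_regions(records, k = k, seed = seed + i)
    if (multimodal && deg != 0) {
      pert$image_left <- lapply(pert$image_left, rotate_image, degrees = deg)
      pert$image_right <- lapply(pert$image_right, rotate_image, degrees = deg)
    }
    u_ood <- u_of(pert)
    tibble::tibble(k_masked = k, rotation_deg = deg,
                   mu_ind = mean(u_ind), mu_ood = mean(u_ood),
                   u_ind = list(u_ind), u_ood = list(u_ood))
  })
  attr(out, "method") <- method
  class(out) <- c("ood_report", class(out))
  out
}

#' Plot an out-of-distribution uncertainty report
#'
#' Overlaid InD/OOD uncertainty histograms per perturbation level with mean
#' annotations.
#'
#' @param object An `ood_report`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ood_report <- function(object, bins = 30, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    lab <- sprintf("k=%d, rot=%g deg", object$k_masked[i], object$rotation_deg[i])
    dplyr::bind_rows(
      tibble::tibble(level = lab, set = "InD", u = object$u_ind[[i]]),
      tibble::tibble(level = lab, set = "OOD", u = object$u_ood[[i]])
    )
  })
  mu <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    tibble::tibble(level = sprintf("k=%d, rot=%g deg", object$k_masked[i],
                                   object$rotation_deg[i]),
                   label = sprintf("mu_InD=%.3f  mu_OOD=%.3f",
                                   object$mu_ind[i], object$mu_ood[i]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55, position = "identity") +
    ggplot2::facet_wrap(~level, scales = "free_y") +
    ggplot2::geom_text(data = mu, ggplot2::aes(x = Inf, y = Inf, label = .data$label),
                       inherit.aes = FALSE, hjust = 1.05, vjust = 1.5, size = 3) +
    ggplot2::labs(x = "uncertainty", y = "count",
                  title = "InD vs OOD uncertainty by perturbation level") +
    ggplot2::theme_minimal()
}
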