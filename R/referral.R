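# majority vote with a deterministic tie-break (randomForest's own class
# prediction breaks vote ties at random)
rf_predict_class <- function(forest, X) {
  prob <- stats::predict(forest, X, type = "prob")
  factor(colnames(prob)[max.col(prob, ties.method = "first")],
         levels = colnames(prob))
}

#' Label test instances as referral / non-referral
#'
#' Maps gate decisions to the binary explanation target: instances routed to
#' the multi-modal model are the *referral* category (1), instances whose
#' uni-modal prediction stood are *non-referral* (0). Order is preserved.
#'
#' @param decisions A [`gate_decisions`][ensemble_predict] tibble.
#' @return The decisions tibble with an added `referral` integer column;
#'   category counts are attached as `attr(, "counts")`.
#' @export
label_referrals <- function(decisions) {
  if (is.null(decisions$used_model) || nrow(decisions) == 0) {
    stop("`decisions` must be a non-empty gate-decision table", call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(decisions),
                       referral = as.integer(.data$used_model == "multi"))
  attr(out, "counts") <- c(referral = sum(out$referral),
                           non_referral = sum(1 - out$referral))
  out
}

#' Train a random-forest referral classifier
#'
#' Trains a random forest to separate the referral and non-referral
#' categories from the volumetric features alone, using a seeded random
#' subsample of `n_per_class` instances per category (20 by default);
#' the held-out remainder measures accuracy and feeds the explainer.
#'
#' @param features Data frame of `region_*` columns (plus any extra columns,
#'   which are ignored), one row per instance.
#' @param referral Binary vector (0 = non-referral, 1 = referral) aligned
#'   with the rows.
#' @param n_per_class Training instances drawn per category.
#' @param num_trees Forest size.
#' @param mtry Candidate features per split; defaults to one third of the
#'   features, which keeps sparse referral signals discoverable from a small
#'   training subsample.
#' @param seed Seed for the subsample and forest.
#' @return A `referral_classifier` list: `forest`, `train_idx`,
#'   `heldout_idx`, `heldout_accuracy`, `feature_cols`.
#' @export
train_referral_classifier <- function(features, referral, n_per_class = 20,
                                      num_trees = 500, mtry = NULL, seed = 1) {
  cols <- feature_columns(features)
  if (is.null(mtry)) mtry <- max(1, floor(length(cols) / 3))
  referral <- as.integer(referral)
  if (length(referral) != nrow(features)) {
    stop("`referral` must align with `features` rows", call. = FALSE)
  }
  idx0 <- which(referral == 0)
  idx1 <- which(referral == 1)
  if (length(idx0) < n_per_class + 1 || length(idx1) < n_per_class + 1) {
    stop("need more than `n_per_class` instances in each category", call. = FALSE)
  }
  withr::with_seed(seed, {
    train_idx <- sort(c(sample(idx0, n_per_class), sample(idx1, n_per_class)))
    heldout_idx <- setdiff(seq_len(nrow(features)), train_idx)
    X <- as.data.frame(features[cols])
    yf <- factor(referral, levels = c(0, 1),
                 labels = c("non_referral", "referral"))
    forest <- randomForest::randomForest(X[train_idx, , drop = FALSE],
                                         yf[train_idx], ntree = num_trees,
                                         mtry = mtry)
    pred <- rf_predict_class(forest, X[heldout_idx, , drop = FALSE])
    structure(list(forest = forest,
                   train_idx = train_idx,
                   heldout_idx = heldout_idx,
                   heldout_accuracy = mean(pred == yf[heldout_idx]),
                   feature_cols = cols),
              class = "referral_classifier")
  })
}

#' @export
print.referral_classifier <- function(x, ...) {
  cat(sprintf("<referral_classifier> %d trees | train n=%d | held-out accuracy %.3f\n",
              x$forest$ntree, length(x$train_idx), x$heldout_accuracy))
  invisible(x)
}

#' @describeIn train_referral_classifier one-row summary.
#' @param x A `referral_classifier`.
#' @param ... Unused.
#' @export
glance.referral_classifier <- function(x, ...) {
  tibble::tibble(n_trees = x$forest$ntree,
                 n_train = length(x$train_idx),
                 n_heldout = length(x$heldout_idx),
                 heldout_accuracy = x$heldout_accuracy)
}

#' Signed feature attribution for referral decisions
#'
#' Ranks regions by permutation importance on the held-out set: each
#' feature column is permuted `n_perm` times and the mean drop in held-out
#' accuracy is its importance magnitude. Direction is the sign of the
#' Spearman rank correlation between the feature's held-out values and the
#' forest's referral probability (positive: larger volumes push toward
#' referral). A plug-in `explainer` function can replace the built-in
#' statistic (e.g. an external Shapley-value implementation); it receives
#' `(forest, X_heldout)` and must return a numeric vector of signed
#' per-feature attributions.
#'
#' @param classifier A [train_referral_classifier()] result.
#' @param features The same feature table the classifier was built from.
#' @param referral The aligned binary labels.
#' @param n_perm Permutations per feature.
#' @param top_k Size of the reported top subset.
#' @param seed Seed for the permutations.
#' @param explainer Optional plug-in explainer function.
#' @return An `attribution_report` tibble: `feature`, `importance`,
#'   `direction` (+1/-1/0), `rank`; the top-k subset is attached as
#'   `attr(, "top_k")`.
#' @export
feature_attribution <- function(classifier, features, referral, n_perm = 20,
                                top_k = 10, seed = 1, explainer = NULL) {
  stopifnot(inherits(classifier, "referral_classifier"))
  cols <- classifier$feature_cols
  hi <- classifier$heldout_idx
  if (length(hi) < 20) stop("need at least 20 held-out instances", call. = FALSE)
  X <- as.data.frame(features[cols])[hi, , drop = FALSE]
  y <- factor(as.integer(referral)[hi], levels = c(0, 1),
              labels = c("non_referral", "referral"))

  if (!is.null(explainer)) {
    signed <- explainer(classifier$forest, X)
    importance <- abs(signed)
    direction <- sign(signed)
  } else {
    base_acc <- mean(rf_predict_class(classifier$forest, X) == y)
    prob_ref <- stats::predict(classifier$forest, X, type = "prob")[, "referral"]
    n <- nrow(X)
    withr::with_seed(seed, {
      importance <- vapply(seq_along(cols), function(j) {
        # stack all permuted copies so the forest predicts once per feature
        perm <- do.call(rbind, lapply(seq_len(n_perm), function(r) {
          Xp <- X
          Xp[[j]] <- Xp[[j]][sample.int(n)]
          Xp
        }))
        acc <- mean(rf_predict_class(classifier$forest, perm) == rep(y, n_perm))
        base_acc - acc
      }, numeric(1))
    })
    direction <- vapply(seq_along(cols), function(j) {
      if (length(unique(X[[j]])) == 1 || stats::sd(prob_ref) == 0) return(0)
      s <- suppressWarnings(stats::cor(X[[j]], prob_ref, method = "spearman"))
      if (is.na(s)) 0 else sign(s)
    }, numeric(1))
  }

  out <- tibble::tibble(feature = cols,
                        importance = as.numeric(importance),
                        direction = as.numeric(direction))
  out$rank <- rank(-out$importance, ties.method = "first")
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "top_k") <- utils::head(out, top_k)
  class(out) <- c("attribution_report", class(out))
  out
}

#' Plot an attribution report
#'
#' Signed bar chart of the top-k most important regions: bar length is the
#' permutation importance, colour the direction of effect on referral.
#'
#' @param object An `attribution_report`.
#' @param top_k Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_report <- function(object, top_k = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top_k)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$effect <- factor(ifelse(df$direction >= 0, "toward referral",
                             "toward non-referral"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature,
                                   fill = .data$effect)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permutation importance (held-out accuracy drop)",
                  y = NULL, fill = NULL,
                  title = sprintf("Top %d regions driving referral", nrow(df))) +
    ggplot2::theme_minimal()
}
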