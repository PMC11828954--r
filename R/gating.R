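#' Simple uncertainty-threshold gate
#'
#' The instance is referred to the multi-modal model exactly when the
#' uni-modal model's (normalized) uncertainty exceeds the threshold; ties
#' stay uni-modal (the cheaper path wins).
#'
#' @param u Numeric vector of non-negative uncertainties.
#' @param tau Threshold in [0, 1].
#' @return Character vector of `"uni"` / `"multi"`.
#' @examples
#' simple_gate(c(0.4, 0.5, 0.6), tau = 0.5)  # uni, uni, multi
#' @export
simple_gate <- function(u, tau) {
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("`u` must be finite and non-negative", call. = FALSE)
  }
  if (length(tau) != 1 || tau < 0 || tau > 1) {
    stop("`tau` must be a single value in [0, 1]", call. = FALSE)
  }
  ifelse(u > tau, "multi", "uni")
}

#' Cosine similarity of two vectors
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return The cosine of the angle between `a` and `b`, in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  s <- sum(a * b) / (na * nb)
  min(1, max(-1, s))
}

#' Low/high-uncertainty embedding centroids
#'
#' Splits the training instances into a lowest-uncertainty and a
#' highest-uncertainty category (each the bottom/top `cutoff_fraction` of the
#' uncertainty distribution, ties broken by stable input order) and averages
#' the penultimate-layer embeddings of each category.
#'
#' @param embeddings Numeric matrix (one embedding per row) or list of
#'   vectors.
#' @param uncertainties Numeric vector aligned with the rows.
#' @param cutoff_fraction Fraction in (0, 0.5] defining both categories.
#' @return A `centroid_pair` list: `g_low`, `g_high`, `cutoff_fraction`,
#'   `n_low`, `n_high`.
#' @export
build_centroids <- function(embeddings, uncertainties, cutoff_fraction = 0.2) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  n <- nrow(embeddings)
  if (n < 2 || length(uncertainties) != n) {
    stop("need >= 2 embeddings aligned with uncertainties", call. = FALSE)
  }
  if (cutoff_fraction <= 0 || cutoff_fraction > 0.5) {
    stop("`cutoff_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  k <- floor(cutoff_fraction * n)
  if (k < 1) stop("cutoff_fraction leaves an empty category", call. = FALSE)
  if (length(unique(uncertainties)) == 1) {
    warning("all uncertainties equal; categories chosen by stable input order")
  }
  ord <- order(uncertainties)  # radix sort: stable for ties
  low <- ord[seq_len(k)]
  high <- rev(ord)[seq_len(k)]
  structure(list(g_low = colMeans(embeddings[low, , drop = FALSE]),
                 g_high = colMeans(embeddings[high, , drop = FALSE]),
                 cutoff_fraction = cutoff_fraction,
                 n_low = k, n_high = k),
            class = "centroid_pair")
}

#' Distance-based gate
#'
#' Compares the cosine distance of a test embedding to the low- and
#' high-uncertainty centroids: instances at least as close to the
#' low-uncertainty centroid keep the uni-modal prediction, others are
#' referred. The published comparison writes the rule with a "similarity" d
#' but selects the uni-modal branch on the `<=` side, which only matches the
#' stated intent when d is a distance; the distance reading is the default
#' and `orientation = "similarity"` gives the literal reading.
#'
#' @param g_x Numeric embedding vector (non-zero).
#' @param centroids A [build_centroids()] result.
#' @param orientation `"distance"` (default) or `"similarity"`.
#' @return `"uni"` or `"multi"`.
#' @export
distance_gate <- function(g_x, centroids, orientation = c("distance", "similarity")) {
  orientation <- match.arg(orientation)
  sim_low <- cosine_similarity(centroids$g_low, g_x)
  sim_high <- cosine_similarity(centroids$g_high, g_x)
  if (orientation == "distance") {
    if (sim_low >= sim_high) "uni" else "multi"
  } else {
    if (sim_low <= sim_high) "uni" else "multi"
  }
}

#' Gate policy
#'
#' Bundles the per-instance referral rule: either simple thresholding of the
#' uni-modal uncertainty at `tau`, or the embedding-distance rule against a
#' [build_centroids()] pair. The uncertainty source (`"edl"`: the evidential
#' head's Dirichlet uncertainty mass; `"mc"`: max-normalized Monte-Carlo
#' dropout standard deviations) is explicit configuration.
#'
#' @param mode `"simple"` or `"distance"`.
#' @param tau Threshold in [0, 1] (simple mode).
#' @param centroids A `centroid_pair` (distance mode).
#' @param uncertainty `"edl"` or `"mc"`.
#' @param passes Monte-Carlo passes when `uncertainty = "mc"`.
#' @param orientation Distance-rule orientation, see [distance_gate()].
#' @return A `gate_policy` list.
#' @export
gate_policy <- function(mode = c("simple", "distance"), tau = 0.5,
                        centroids = NULL,
                        uncertainty = c("edl", "mc"), passes = 100,
                        orientation = c("distance", "similarity")) {
  mode <- match.arg(mode)
  uncertainty <- match.arg(uncertainty)
  orientation <- match.arg(orientation)
  if (mode == "simple" && (tau < 0 || tau > 1)) {
    stop("`tau` must be in [0, 1]", call. = FALSE)
  }
  if (mode == "distance" && !inherits(centroids, "centroid_pair")) {
    stop("distance mode requires `centroids` from build_centroids()", call. = FALSE)
  }
  structure(list(mode = mode, tau = tau, centroids = centroids,
                 uncertainty = uncertainty, passes = passes,
                 orientation = orientation),
            class = "gate_policy")
}

# uncertainties of the uni-modal model on a record set, per the policy's
# configured source; MC values are max-normalized over this set.
gate_uncertainties <- function(f, records, policy, seed = 1) {
  if (policy$uncertainty == "edl") {
    if (f$config$loss != "edl_sos") {
      stop("policy uses EDL uncertainty but `f` is not an evidential model",
           call. = FALSE)
    }
    u <- predict(f, records, type = "opinion")$.uncertainty
    attr(u, "reference_max") <- NA_real_
    u
  } else {
    raw <- mc_predict(f, records, passes = policy$passes, seed = seed)$raw_uncertainty
    normalize_uncertainties(raw)
  }
}

#' Uncertainty-gated ensemble prediction
#'
#' Runs the full referral cascade on a set of test subjects: the uni-modal
#' model `f` predicts from the tabular features alone; per instance, the gate
#' policy decides from `f`'s uncertainty (or embedding) whether the second
#' modality is requested, and only then is `x2` fetched and the multi-modal
#' model `h` invoked. The second modality is fetched lazily: the number of
#' `x2_provider` calls equals the number of `multi` decisions, which is the
#' exact cost accounting of the method.
#'
#' @param records Tibble of test subjects. Image list-columns are only
#'   touched for referred instances.
#' @param f Fitted `unimodal_model`.
#' @param h Fitted `multimodal_model`.
#' @param policy A [gate_policy()].
#' @param seed Seed for the Monte-Carlo uncertainty passes.
#' @param x2_provider Optional function(records, i) returning
#'   `list(image_left = , image_right = )` for row `i`; defaults to reading
#'   the record's own image columns. Called once per referred instance.
#' @return A `gate_decisions` tibble: `subject_id`, `used_model`,
#'   `predicted_label`, `uncertainty`, `sim_low`, `sim_high` (distance mode),
#'   plus `label` when truth is present. Attributes record the fetch count
#'   and the uncertainty normalisation reference.
#' @export
ensemble_predict <- function(records, f, h, policy, seed = 1,
                             x2_provider = NULL) {
  stopifnot(inherits(f, "unimodal_model"), inherits(h, "multimodal_model"),
            inherits(policy, "gate_policy"))
  n <- nrow(records)
  u <- gate_uncertainties(f, records, policy, seed = seed)
  uni_pred <- predict(f, records, type = "class")$.pred_class

  sim_low <- sim_high <- rep(NA_real_, n)
  if (policy$mode == "simple") {
    used <- simple_gate(as.numeric(u), policy$tau)
  } else {
    G <- embed(f, records)
    used <- character(n)
    for (i in seq_len(n)) {
      sim_low[i] <- cosine_similarity(policy$centroids$g_low, G[i, ])
      sim_high[i] <- cosine_similarity(policy$centroids$g_high, G[i, ])
      used[i] <- distance_gate(G[i, ], policy$centroids, policy$orientation)
    }
  }

  fetches <- 0L
  predicted <- uni_pred
  multi_idx <- which(used == "multi")
  if (length(multi_idx) > 0) {
    fetch_one <- if (is.null(x2_provider)) {
      function(recs, i) {
        li <- recs$image_left[[i]]; ri <- recs$image_right[[i]]
        if (is.null(li) || is.null(ri)) {
          stop("second modality unavailable for subject ", recs$subject_id[i],
               call. = FALSE)
        }
        list(image_left = li, image_right = ri)
      }
    } else x2_provider
    imgs <- vector("list", length(multi_idx))
    for (j in seq_along(multi_idx)) {
      imgs[[j]] <- fetch_one(records, multi_idx[j])
      fetches <- fetches + 1L
    }
    sub <- records[multi_idx, setdiff(names(records), c("image_left", "image_right"))]
    sub$image_left <- lapply(imgs, `[[`, "image_left")
    sub$image_right <- lapply(imgs, `[[`, "image_right")
    predicted[multi_idx] <- predict(h, sub, type = "class")$.pred_class
  }

  out <- tibble::tibble(
    subject_id = if (!is.null(records$subject_id)) records$subject_id
                 else sprintf("row_%d", seq_len(n)),
    used_model = used,
    predicted_label = predicted,
    uncertainty = as.numeric(u),
    sim_low = sim_low,
    sim_high = sim_high
  )
  if (!is.null(records$label)) out$label <- records$label
  attr(out, "n_x2_fetches") <- fetches
  attr(out, "uncertainty_method") <- policy$uncertainty
  attr(out, "reference_max") <- attr(u, "reference_max")
  class(out) <- c("gate_decisions", class(out))
  out
}

#' Calibrate the distance-gate uncertainty cutoff
#'
#' The uncertainty cutoff that forms the low/high-uncertainty embedding
#' categories is found empirically: each candidate fraction is used to build
#' centroids from the training instances, the distance-gated ensemble is
#' evaluated on the validation records, and the candidate with the highest
#' ensemble accuracy wins; ties go to the candidate with the lower referral
#' fraction (the cheaper policy).
#'
#' @param candidate_fractions Non-empty numeric vector of fractions in
#'   (0, 0.5].
#' @param f,h Fitted uni-modal and multi-modal models.
#' @param train_records Records whose embeddings/uncertainties form the
#'   centroids.
#' @param val_records Labelled records on which candidates are scored.
#' @param uncertainty,passes,orientation Passed to [gate_policy()].
#' @param seed Seed for Monte-Carlo passes.
#' @return The best fraction (scalar), with the per-candidate accuracy /
#'   referral table attached as `attr(, "results")`.
#' @export
calibrate_cutoff <- function(candidate_fractions, f, h, train_records,
                             val_records, uncertainty = c("edl", "mc"),
                             passes = 100, orientation = "distance", seed = 1) {
  if (length(candidate_fractions) == 0) {
    stop("`candidate_fractions` must be non-empty", call. = FALSE)
  }
  uncertainty <- match.arg(uncertainty)
  probe <- gate_policy("simple", uncertainty = uncertainty, passes = passes)
  u_train <- gate_uncertainties(f, train_records, probe, seed = seed)
  G_train <- embed(f, train_records)
  res <- purrr::map_dfr(candidate_fractions, function(fr) {
    cen <- build_centroids(G_train, as.numeric(u_train), fr)
    pol <- gate_policy("distance", centroids = cen, uncertainty = uncertainty,
                       passes = passes, orientation = orientation)
    dec <- ensemble_predict(val_records, f, h, pol, seed = seed)
    tibble::tibble(cutoff_fraction = fr,
                   accuracy = mean(dec$predicted_label == dec$label),
                   referral_fraction = mean(dec$used_model == "multi"))
  })
  best <- res[order(-res$accuracy, res$referral_fraction), ][1, ]
  out <- best$cutoff_fraction
  attr(out, "results") <- res
  out
}
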