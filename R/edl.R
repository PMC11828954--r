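#' Build a Dirichlet subjective-logic opinion from class evidence
#'
#' In evidential classification the network head emits a non-negative
#' evidence value \eqn{e_k} for each of the \eqn{K} classes. The evidence
#' induces a Dirichlet distribution with parameters \eqn{\alpha_k = e_k + 1}
#' and total strength \eqn{S = \sum_k \alpha_k}, and a subjective-logic
#' opinion with belief masses \eqn{b_k = e_k / S} and uncertainty mass
#' \eqn{u = K / S}. Beliefs and uncertainty always sum to one; zero total
#' evidence assigns no belief to any class and total uncertainty \eqn{u = 1}.
#'
#' @param evidence Numeric vector of non-negative, finite per-class evidence
#'   values; length \eqn{K \ge 2}.
#' @return An object of class `dirichlet_opinion`: a list with elements
#'   `evidence`, `alpha`, `strength`, `belief`, `uncertainty`, `n_classes`.
#' @examples
#' op <- opinion_from_evidence(c(9, 0))
#' op$belief       # 9/11, 0
#' op$uncertainty  # 2/11
#' @seealso [expected_probability()], [edl_sos_loss()]
#' @export
opinion_from_evidence <- function(evidence) {
  if (!is.numeric(evidence) || length(evidence) < 2) {
    stop("`evidence` must be a numeric vector of length K >= 2", call. = FALSE)
  }
  if (any(!is.finite(evidence)) || any(evidence < 0)) {
    stop("`evidence` must be finite and non-negative", call. = FALSE)
  }
  evidence <- as.numeric(evidence)
  K <- length(evidence)
  alpha <- evidence + 1
  S <- sum(alpha)
  structure(
    list(evidence = evidence,
         alpha = alpha,
         strength = S,
         belief = evidence / S,
         uncertainty = K / S,
         n_classes = K),
    class = "dirichlet_opinion"
  )
}

#' @export
print.dirichlet_opinion <- function(x, ...) {
  cat("<dirichlet_opinion> K =", x$n_classes, "\n")
  cat("  evidence:   ", paste(signif(x$evidence, 4), collapse = ", "), "\n")
  cat("  belief:     ", paste(signif(x$belief, 4), collapse = ", "), "\n")
  cat("  uncertainty:", signif(x$uncertainty, 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn opinion_from_evidence one row per class with evidence, alpha,
#'   belief and expected probability; the scalar uncertainty mass is repeated.
#' @param x A `dirichlet_opinion`.
#' @param ... Unused.
#' @export
tidy.dirichlet_opinion <- function(x, ...) {
  tibble::tibble(
    class = seq_len(x$n_classes),
    evidence = x$evidence,
    alpha = x$alpha,
    belief = x$belief,
    expected_probability = x$alpha / x$strength,
    uncertainty = x$uncertainty
  )
}

#' Expected class probabilities of a Dirichlet opinion
#'
#' The mean of the Dirichlet distribution induced by the evidence,
#' \eqn{\hat p_k = \alpha_k / S}; this is the probability vector used for
#' class prediction by an evidential head.
#'
#' @param opinion A [`dirichlet_opinion`][opinion_from_evidence] object.
#' @return Numeric probability vector of length `n_classes`, summing to 1.
#' @export
expected_probability <- function(opinion) {
  stopifnot(inherits(opinion, "dirichlet_opinion"))
  opinion$alpha / opinion$strength
}

#' Evidential sum-of-squares loss
#'
#' The Dirichlet expectation of the squared error between a one-hot label and
#' the class probability vector, in closed form:
#' \deqn{\sum_j (y_j - \alpha_j/S)^2 + \frac{(\alpha_j/S)(1 - \alpha_j/S)}{S + 1}}
#' with \eqn{S = \sum_j \alpha_j}. It equals the average of
#' \eqn{\|y - p\|_2^2} over \eqn{p \sim \mathrm{Dirichlet}(\alpha)} and is the
#' training criterion of the evidential head. An optional KL regulariser
#' toward the uniform Dirichlet (annealed in some of the evidential
#' literature) is available but off by default.
#'
#' @param alpha Numeric vector of Dirichlet parameters, all \eqn{\ge 1}
#'   (equivalently non-negative evidence).
#' @param y One-hot numeric vector of the same length.
#' @param kl_weight Non-negative weight of the optional KL(Dirichlet(
#'   \eqn{\tilde\alpha}) || Dirichlet(1)) regulariser applied to the
#'   off-target evidence; default 0 (plain sum-of-squares loss).
#' @return Non-negative scalar loss.
#' @examples
#' edl_sos_loss(c(1, 1), c(1, 0))    # 2/3: uniform Dirichlet, maximal spread
#' edl_sos_loss(c(101, 1), c(1, 0))  # ~ 3.8e-4: confident and correct
#' @export
edl_sos_loss <- function(alpha, y, kl_weight = 0) {
  if (!is.numeric(alpha) || !is.numeric(y) || length(alpha) != length(y)) {
    stop("`alpha` and `y` must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha < 1)) {
    stop("all `alpha` must be finite and >= 1 (non-negative evidence)", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    stop("`y` must be one-hot", call. = FALSE)
  }
  S <- sum(alpha)
  p <- alpha / S
  loss <- sum((y - p)^2 + p * (1 - p) / (S + 1))
  if (kl_weight > 0) {
    # evidence on the true class is removed before regularising
    a_tilde <- y + (1 - y) * alpha
    K <- length(alpha)
    S_t <- sum(a_tilde)
    kl <- lgamma(S_t) - lgamma(K) - sum(lgamma(a_tilde)) +
      sum((a_tilde - 1) * (digamma(a_tilde) - digamma(S_t)))
    loss <- loss + kl_weight * kl
  }
  loss
}

# Vectorised opinion summaries for an evidence matrix (rows = instances).
# Used internally by model predict methods.
opinion_summary <- function(evidence) {
  alpha <- evidence + 1
  S <- rowSums(alpha)
  list(prob = alpha / S, uncertainty = ncol(evidence) / S, strength = S)
}
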