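#' Objective functions
#'
#' The classification heads are supervised by the softmax categorical
#' cross-entropy (CCE), optionally combined with a centre loss (sequence
#' branch) or replaced by its label-smoothing-regularized (LSR) form
#' (subtype variant):
#' \describe{
#'   \item{`softmax_probs(logits)`}{`p(k) = exp(z_k) / sum_i exp(z_i)`,
#'     computed with max-subtraction for numerical stability.}
#'   \item{`cce_loss(p, y)`}{`-log p(y)`, the cross-entropy against the
#'     one-hot target.}
#'   \item{`lsr_loss(p, y, epsilon)`}{cross-entropy against the smoothed
#'     target that puts `epsilon / K` on every class and
#'     `1 - epsilon + epsilon / K` on the true class:
#'     `-(1 - epsilon) log p(y) - (epsilon / K) sum_k log p(k)`. With
#'     `epsilon = 0` this is exactly `cce_loss`.}
#'   \item{`joint_loss(p, y, x, centres, lambda)`}{`-log p(y) +
#'     lambda * ||x - c_y||^2`: CCE plus the squared Euclidean distance
#'     between the sample's feature vector and its class centre, which
#'     pushes features of one class together while softmax keeps classes
#'     apart.}
#' }
#' Probabilities are floored at `1e-12` before logs so losses stay
#' finite.
#'
#' @param logits Numeric vector of `K >= 2` finite real scores.
#' @param p Probability vector (nonnegative, sums to 1 within `1e-6`).
#' @param y 1-based index of the true class.
#' @param epsilon Smoothing weight in `[0, 1)`; the subtype variant uses
#'   0.2.
#' @param x Feature vector of the sample.
#' @param centres `K x d` matrix of class centres (row `k` is `c_k`), `d`
#'   matching `length(x)`.
#' @param lambda Nonnegative centre-loss weight (default 0.01).
#' @return `softmax_probs`: a probability vector; the losses: a single
#'   nonnegative number.
#' @examples
#' p <- softmax_probs(c(2, 0))
#' cce_loss(p, 1)
#' lsr_loss(p, 1, epsilon = 0.2)
#' joint_loss(p, 1, x = c(1, 2), centres = rbind(c(0, 0), c(5, 5)),
#'            lambda = 0.01)
#' @name losses
NULL

PROB_FLOOR <- 1e-12

#' @rdname losses
#' @export
softmax_probs <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 2L || !all(is.finite(logits))) {
    abort("logits must be a finite numeric vector of length >= 2")
  }
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

#' @rdname losses
#' @export
cce_loss <- function(p, y) {
  check_probs(p, y)
  -log(max(p[y], PROB_FLOOR))
}

#' @rdname losses
#' @export
lsr_loss <- function(p, y, epsilon = 0.2) {
  check_probs(p, y)
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must lie in [0, 1)")
  K <- length(p)
  lp <- log(pmax(p, PROB_FLOOR))
  -(1 - epsilon) * lp[y] - (epsilon / K) * sum(lp)
}

#' Smoothed label distribution
#'
#' The target distribution used by [lsr_loss()]: `epsilon / K` off the
#' true class and `1 - epsilon + epsilon / K` at it. `epsilon = 0`
#' recovers the one-hot target.
#'
#' @inheritParams losses
#' @param K Number of classes.
#' @return Probability vector of length `K`.
#' @examples
#' label_distribution(2, K = 2, epsilon = 0.2)  # 0.1, 0.9
#' @export
label_distribution <- function(y, K, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must lie in [0, 1)")
  if (y < 1L || y > K) abort("true class index outside 1..K")
  q <- rep(epsilon / K, K)
  q[y] <- 1 - epsilon + epsilon / K
  q
}

#' @rdname losses
#' @export
joint_loss <- function(p, y, x, centres, lambda = 0.01) {
  check_probs(p, y)
  if (lambda < 0) abort("lambda must be nonnegative")
  centres <- as.matrix(centres)
  if (nrow(centres) != length(p)) {
    abort("centres must have one row per class")
  }
  if (ncol(centres) != length(x)) {
    abort(paste0("centre dimensionality (", ncol(centres),
                 ") does not match feature dimensionality (", length(x), ")"))
  }
  cce_loss(p, y) + lambda * sum((x - centres[y, ])^2)
}

check_probs <- function(p, y) {
  if (!is.numeric(p) || length(p) < 2L) abort("p must be a probability vector, K >= 2")
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    abort("p must be nonnegative and sum to 1 (within 1e-6)")
  }
  if (length(y) != 1L || is.na(y) || y < 1L || y > length(p)) {
    abort("y must be a single class index in 1..K")
  }
  invisible(TRUE)
}
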