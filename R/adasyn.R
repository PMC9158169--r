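#' ADASYN: adaptive synthetic oversampling in feature space
#'
#' ADASYN rebalances a binary dataset by synthesizing new minority-class
#' samples, generating more of them where minority points are hardest to
#' learn. For each minority sample `i`, the difficulty
#' `r_i = (# majority points among its k nearest neighbours) / k` is
#' computed in the full data; the normalized weights
#' `rhat_i = r_i / sum(r)` distribute the synthesis budget
#' `G = (n_majority - n_minority) * balance_level` over the minority
#' points (`sum(counts) = round(G)` exactly, via largest-remainder
#' allocation). When all difficulties are zero (perfect separation) the
#' budget is spread uniformly. Each synthetic point is a convex
#' combination `x_i + u (x_z - x_i)`, `u ~ U(0, 1)`, of a minority
#' sample and one of its k nearest minority neighbours.
#'
#' Distances are Euclidean in a z-scored copy of the feature space
#' (learned features have mixed scales); synthesis happens in the same
#' standardized space and is mapped back, which preserves convexity
#' coordinate-wise. A minority class too small to have distinct
#' neighbours falls back to duplication, with a warning.
#'
#' @param features Numeric `n x d` matrix (or data frame) of feature
#'   vectors.
#' @param labels Vector of class labels, length `n`, with exactly two
#'   distinct values for `plan_adasyn()`.
#' @param k Neighbourhood size (default 5).
#' @param balance_level Target fraction of the majority/minority gap to
#'   close, in `(0, 1]`; 1 balances the classes fully.
#' @param majority_count Reference majority size used for the budget
#'   `G`; defaults to the number of non-minority rows. In multi-class
#'   use the size of the largest class is passed instead, so every
#'   minority is balanced towards it.
#' @return `plan_adasyn()`: a tibble of class `adasyn_plan` with one row
#'   per minority sample (`index`, `difficulty`, `weight`,
#'   `synth_count`) and attributes `k`, `balance_level`, `G`,
#'   `minority_class`, `neighbours` (minority kNN index matrix) and the
#'   standardization constants.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(8, mean = 2), 4))
#' y <- rep(c("maj", "min"), c(20, 4))
#' plan <- plan_adasyn(x, y, k = 3)
#' sum(plan$synth_count)   # 16 = (20 - 4) * 1
#' aug <- synthesize_adasyn(x, y, plan, seed = 1)
#' table(aug$labels)
#' @export
plan_adasyn <- function(features, labels, k = 5L, balance_level = 1.0,
                        majority_count = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(labels) != n) abort("labels must match the number of feature rows")
  if (length(unique(labels)) != 2L) {
    abort("plan_adasyn() is binary; use adasyn_augment() for several classes")
  }
  if (k < 1L) abort("k must be >= 1")
  if (balance_level <= 0 || balance_level > 1) {
    abort("balance_level must lie in (0, 1]")
  }
  counts <- table(labels)
  minority_class <- names(counts)[which.min(counts)]
  min_idx <- which(labels == minority_class)
  m <- length(min_idx)
  n_maj <- majority_count %||% (n - m)
  G <- max(0, (n_maj - m) * balance_level)
  total <- round(G)

  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, s, "/")
  Zm <- Z[min_idx, , drop = FALSE]

  # squared distances minority -> all
  d2 <- outer(rowSums(Zm^2), rowSums(Z^2), "+") - 2 * tcrossprod(Zm, Z)
  is_maj <- labels != minority_class
  kk <- min(k, n - 1L)
  difficulty <- vapply(seq_len(m), function(i) {
    ord <- order(d2[i, ])
    ord <- ord[ord != min_idx[i]][seq_len(kk)]
    sum(is_maj[ord]) / k
  }, numeric(1))
  weight <- if (sum(difficulty) > 0) difficulty / sum(difficulty) else rep(1 / m, m)

  raw <- weight * total
  cnt <- floor(raw)
  rem <- total - sum(cnt)
  if (rem > 0) {
    top <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[top] <- cnt[top] + 1L
  }

  # k nearest minority neighbours of each minority point (excluding self)
  duplication <- m < 2L
  neighbours <- if (duplication) {
    warn("minority class has no distinct neighbours; falling back to duplication")
    matrix(rep(min_idx, each = 1L), nrow = m)
  } else {
    km <- min(k, m - 1L)
    d2m <- d2[, min_idx, drop = FALSE]
    res <- vapply(seq_len(m), function(i) {
      ord <- order(d2m[i, ])
      min_idx[ord[ord != i][seq_len(km)]]
    }, integer(km))
    if (km == 1L) matrix(res, ncol = 1L) else t(res)
  }

  out <- tibble(index = min_idx, difficulty = difficulty,
                weight = weight, synth_count = as.integer(cnt))
  attr(out, "k") <- as.integer(k)
  attr(out, "balance_level") <- balance_level
  attr(out, "G") <- G
  attr(out, "minority_class") <- minority_class
  attr(out, "neighbours") <- neighbours
  attr(out, "standardize") <- list(mu = mu, s = s)
  attr(out, "duplication") <- duplication
  class(out) <- c("adasyn_plan", class(out))
  out
}

#' @rdname plan_adasyn
#' @param plan An `adasyn_plan`.
#' @param seed Integer seed; synthesis is bit-reproducible given it.
#' @return `synthesize_adasyn()`: list with `features` (originals first,
#'   then synthetic rows), `labels`, and logical `synthetic` flags.
#' @export
synthesize_adasyn <- function(features, labels, plan, seed) {
  stopifnot(inherits(plan, "adasyn_plan"))
  X <- as.matrix(features)
  std <- attr(plan, "standardize")
  nb <- attr(plan, "neighbours")
  minority_class <- attr(plan, "minority_class")
  total <- sum(plan$synth_count)
  if (total == 0L) {
    return(list(features = X, labels = labels,
                synthetic = rep(FALSE, nrow(X))))
  }
  Z <- sweep(sweep(X, 2L, std$mu), 2L, std$s, "/")
  synth <- with_seed(seed, {
    rows <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      g <- plan$synth_count[i]
      if (g == 0L) next
      xi <- Z[plan$index[i], ]
      zi <- nb[i, , drop = TRUE]
      pick <- if (length(zi) == 1L) rep(zi, g) else sample(zi, g, replace = TRUE)
      u <- runif(g)
      rows[[i]] <- matrix(xi, g, ncol(Z), byrow = TRUE) +
        u * (Z[pick, , drop = FALSE] - matrix(xi, g, ncol(Z), byrow = TRUE))
    }
    do.call(rbind, rows)
  })
  synth <- sweep(sweep(synth, 2L, std$s, "*"), 2L, std$mu, "+")
  list(
    features = rbind(X, synth),
    labels = c(labels, rep(minority_class, nrow(synth))),
    synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(synth)))
  )
}

#' Multi-class ADASYN augmentation
#'
#' Applies ADASYN once per minority class (every class smaller than the
#' largest), each against the union of all other classes, accumulating
#' the synthetic rows. This is the resampling step of the HMPIat subtype
#' variant, performed in transferred feature space.
#'
#' @inheritParams plan_adasyn
#' @param seed Integer seed.
#' @return List with `features`, `labels`, `synthetic` as in
#'   [synthesize_adasyn()].
#' @export
adasyn_augment <- function(features, labels, k = 5L, balance_level = 1.0, seed = 1L) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  majority <- names(counts)[which.max(counts)]
  out_feat <- list(X)
  out_lab <- list(labels)
  out_syn <- list(rep(FALSE, nrow(X)))
  offset <- 0L
  for (cl in setdiff(names(counts), majority)) {
    if (counts[[cl]] >= counts[[majority]]) next
    bin <- ifelse(labels == cl, cl, ".rest")
    plan <- plan_adasyn(X, bin, k = k, balance_level = balance_level,
                        majority_count = counts[[majority]])
    res <- synthesize_adasyn(X, bin, plan, seed = seed + offset)
    new <- res$synthetic
    if (any(new)) {
      out_feat[[length(out_feat) + 1L]] <- res$features[new, , drop = FALSE]
      out_lab[[length(out_lab) + 1L]] <- rep(cl, sum(new))
      out_syn[[length(out_syn) + 1L]] <- rep(TRUE, sum(new))
    }
    offset <- offset + 1L
  }
  list(features = do.call(rbind, out_feat),
       labels = unlist(out_lab, use.names = FALSE),
       synthetic = unlist(out_syn, use.names = FALSE))
}
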