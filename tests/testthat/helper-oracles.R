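# Independent oracles used across test files. These deliberately avoid the
# package's own vectorized code paths.

# Per-position dictionary-lookup one-hot encoding.
oracle_one_hot <- function(sequence) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(sequence, "")[[1]]
  m <- matrix(0L, 4, length(ch), dimnames = list(bases, NULL))
  for (j in seq_along(ch)) m[match(ch[j], bases), j] <- 1L
  m
}

# Per-window lookup structural-profile encoding against a given table.
oracle_sp <- function(sequence, table) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  out <- matrix(NA_real_, 12, L - 1)
  for (j in seq_len(L - 1)) {
    out[, j] <- table$std[, paste0(ch[j], ch[j + 1])]
  }
  out
}

# Brute-force confusion metrics from the standard formulas.
oracle_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / total,
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  )
}

random_seq <- function(L) {
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Between-class centroid distance over mean within-class distance.
separation_ratio <- function(feats, y) {
  mu <- rowsum(feats, y) / as.vector(table(y))
  between <- sqrt(sum((mu[1, ] - mu[2, ])^2))
  within <- mean(sqrt(rowSums((feats - mu[y, ])^2)))
  between / within
}

# Small specs used by several model tests (kept tiny for speed).
tiny_psfn_spec <- function(L = 20, ...) {
  psfn_spec(L, feature_dim = 8L, epochs = 2L, batch_size = 16L, seed = 5L, ...)
}
tiny_dspn_spec <- function(L = 20, ...) {
  dspn_spec(L, block_sizes = c(12L, 24L, 12L, 16L, 24L, 24L, 8L),
            epochs = 2L, batch_size = 16L, seed = 5L, ...)
}
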