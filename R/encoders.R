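#' One-hot (quadrature) encoding of a DNA sequence
#'
#' Encodes a length-`L` sequence as a binary `4 x L` matrix with rows
#' ordered `(A, C, G, T)`: entry `(i, j)` is 1 exactly when base `j` is
#' the i-th item of that tuple. Every column sums to 1, so no sequence
#' information is lost.
#'
#' @param sequence A single DNA string over `{A, C, G, T}` (uppercase).
#' @return A `4 x L` integer matrix with rownames `A, C, G, T`.
#' @examples
#' one_hot_encode("ACGT")   # the 4 x 4 identity matrix
#' @export
one_hot_encode <- function(sequence) {
  codes <- base_codes(sequence)
  L <- length(codes)
  m <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(codes, seq_len(L))] <- 1L
  m
}

#' Structural-profile encoding of a DNA sequence
#'
#' Slides a 2 bp window (stride 1) over the sequence and replaces each
#' dinucleotide with its 12 standardized structural property values,
#' giving a `12 x (L - 1)` real matrix: entry `(i, j)` is the
#' standardized value of property `i` for dinucleotide
#' `B_j B_{j+1}`.
#'
#' @inheritParams one_hot_encode
#' @param table An [sp_table()] with standardized values.
#' @return A `12 x (L - 1)` numeric matrix, one row per property.
#' @examples
#' tab <- sp_table()
#' sp_encode("AAT", tab)   # columns: std values for AA, then AT
#' @export
sp_encode <- function(sequence, table = sp_table()) {
  stopifnot(inherits(table, "sp_table"))
  if (is.null(table$std)) table <- standardize_sp_table(table)
  codes <- base_codes(sequence)
  L <- length(codes)
  if (L < 2L) abort("sequence must have length >= 2 for dinucleotide encoding")
  d <- (codes[-L] - 1L) * 4L + codes[-1L]
  table$std[, d, drop = FALSE]
}

#' Encode a dataset of records for model input
#'
#' Produces the tensors consumed by the PSFN (one-hot, `4 x L x n`) and
#' the DSPN (structural profile, `12 x (L-1) x n`) for all records at
#' once. All sequences must share one length.
#'
#' @param records Tibble with `id`, `sequence` and (for training) `label`
#'   columns.
#' @param table An [sp_table()]; used for the structural encoding.
#' @param which Which encodings to compute (`"both"`, `"onehot"`, `"sp"`).
#' @param classes Optional explicit class-level ordering; defaults to the
#'   sorted unique labels.
#' @return An object of class `encoded_dataset`: list with `onehot`
#'   and/or `sp` arrays, integer `labels` (1-based class indices, or
#'   `NULL` when unlabelled), `classes`, `ids` and `length`.
#' @examples
#' recs <- simulate_promoters(n_per_class = 5, length = 30, seed = 1)
#' enc <- encode_records(recs)
#' dim(enc$onehot); dim(enc$sp)
#' @export
encode_records <- function(records, table = sp_table(),
                           which = c("both", "onehot", "sp"),
                           classes = NULL) {
  check_records(records)
  which <- match.arg(which)
  n <- nrow(records)
  if (n == 0L) abort("no records to encode")
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    abort("all sequences in a dataset must share one length; run validate_records() first")
  }
  L <- lens[1L]
  codes <- matrix(0L, nrow = L, ncol = n)
  for (j in seq_len(n)) {
    codes[, j] <- base_codes(records$sequence[j], id = records$id[j])
  }
  out <- list(onehot = NULL, sp = NULL, labels = NULL, classes = NULL,
              ids = records$id, length = L)
  if (which %in% c("both", "onehot")) {
    arr <- array(0, dim = c(4L, L, n))
    idx <- as.vector(codes) +
      rep.int((seq_len(L) - 1L) * 4L, n) +
      rep((seq_len(n) - 1L) * 4L * L, each = L)
    arr[idx] <- 1
    out$onehot <- arr
  }
  if (which %in% c("both", "sp")) {
    if (is.null(table$std)) table <- standardize_sp_table(table)
    if (L < 2L) abort("structural encoding needs length >= 2")
    d <- (codes[-L, , drop = FALSE] - 1L) * 4L + codes[-1L, , drop = FALSE]
    sp <- table$std[, as.vector(d), drop = FALSE]
    dim(sp) <- c(12L, L - 1L, n)
    out$sp <- sp
  }
  if ("label" %in% names(records) && !all(is.na(records$label))) {
    lab <- as.character(records$label)
    out$classes <- classes %||% sort(unique(lab))
    li <- match(lab, out$classes)
    if (anyNA(li)) abort("labels outside the declared class set")
    out$labels <- li
  }
  structure(out, class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  n <- length(x$ids)
  cat("<encoded_dataset> ", n, " sequence(s) of length ", x$length, "\n", sep = "")
  if (!is.null(x$onehot)) cat("  one-hot: 4 x ", x$length, " x ", n, "\n", sep = "")
  if (!is.null(x$sp)) cat("  structural profile: 12 x ", x$length - 1L, " x ", n, "\n", sep = "")
  if (!is.null(x$labels)) {
    cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Positional structural-profile statistics
#'
#' Averages the standardized structural-profile matrix position-wise over
#' a set of equal-length sequences, one curve per property. Promoter sets
#' show localized deviations (e.g. around core elements near the TSS)
#' that background sequences lack, which is the signal the structural
#' branch exploits.
#'
#' @inheritParams encode_records
#' @param group Optional label describing the sequence set (e.g.
#'   `"promoter"`).
#' @return A tibble of class `positional_profile` with columns
#'   `property`, `position` (index of the dinucleotide window start) and
#'   `mean`, plus attributes `group`, `n` and `matrix` (the
#'   `12 x (L-1)` mean matrix).
#' @examples
#' recs <- simulate_promoters(n_per_class = 20, length = 40, seed = 1)
#' prof <- positional_profile(dplyr::filter(recs, label == "promoter"))
#' head(prof)
#' @export
positional_profile <- function(records, table = sp_table(), group = NULL) {
  enc <- encode_records(records, table = table, which = "sp")
  m <- rowMeans(enc$sp, dims = 2L)
  rownames(m) <- rownames(table$raw)
  out <- tibble(
    property = rep(rownames(m), times = ncol(m)),
    position = rep(seq_len(ncol(m)), each = nrow(m)),
    mean = as.vector(m)
  )
  attr(out, "group") <- group %||% paste(unique(records$label), collapse = "+")
  attr(out, "n") <- nrow(records)
  attr(out, "matrix") <- m
  class(out) <- c("positional_profile", class(out))
  out
}

#' @export
#' @rdname positional_profile
#' @param object A `positional_profile`.
#' @param ... Unused.
#' @method autoplot positional_profile
autoplot.positional_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(
      x = "dinucleotide window position",
      y = "mean standardized property value",
      title = paste0("Positional structural profile (n = ", attr(object, "n"),
                     ", ", attr(object, "group"), ")")
    ) +
    ggplot2::theme_minimal(base_size = 9)
}

# Map one sequence to integer base codes (A=1, C=2, G=3, T=4),
# erroring with the offending position (and record id when known).
base_codes <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("sequence must be a single character string")
  }
  ints <- utf8ToInt(sequence)
  codes <- code_lookup[ints + 1L]
  if (anyNA(codes) || length(codes) == 0L) {
    pos <- if (length(codes) == 0L) 0L else which(is.na(codes))[1L]
    abort(paste0("non-ACGT symbol",
                 if (!is.null(id)) paste0(" in record '", id, "'") else "",
                 " at position ", pos))
  }
  codes
}

code_lookup <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L
  v[utf8ToInt("T") + 1L] <- 4L
  v
})
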