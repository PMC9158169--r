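#' Read labelled DNA sequences from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a tibble of
#' sequence records. Sequences are uppercased on ingest. Header lines are
#' parsed as `>id` or `>id|label`; the first whitespace-delimited token is
#' used. Promoter windows are assumed to be pre-extracted fixed-length
#' spans around the TSS (251 bp `[-200, +50]` eukaryotic convention,
#' 81 bp `[-60, +20]` prokaryotic convention); the reader itself imposes
#' no length.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label attached to every record (overrides
#'   any `|label` parsed from headers). Typical binary labels are
#'   `"promoter"` / `"non-promoter"`; subtype mode uses sigma-factor
#'   labels such as `"sigma70"`.
#' @param policy Non-ACGT handling: `"strict"` (default) errors naming the
#'   offending record and position, `"skip"` drops such records with a
#'   reported count. Both one-hot and structural-profile encodings are
#'   undefined outside `{A, C, G, T}`, so ambiguity codes are never kept.
#'
#' @return A tibble with columns `id`, `sequence`, `label` (record order
#'   preserved).
#' @seealso [validate_records()], [write_fasta()], [split_train_test()]
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "ACGTACGT", ">p2", "ttttacgt"), tf)
#' read_fasta(tf, label = "promoter")
#' @export
read_fasta <- function(path, label = NULL, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty FASTA file: ", path))
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort(paste0("malformed FASTA: sequence data before any header in ", path))
  }
  grp <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste0, character(1), collapse = "")
  # entries with no sequence lines are absent from seqs
  seq_full <- setNames(rep("", length(headers)), as.character(seq_along(headers)))
  seq_full[names(seqs)] <- seqs
  empty <- !nzchar(seq_full)
  if (any(empty)) {
    abort(paste0("malformed FASTA: no sequence for header '>",
                 headers[which(empty)[1L]], "'"))
  }
  token <- vapply(strsplit(headers, "[ \t]"), `[[`, character(1), 1L)
  parts <- strsplit(token, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  parsed_label <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                         character(1))
  out <- tibble(
    id = ids,
    sequence = toupper(unname(seq_full)),
    label = if (is.null(label)) parsed_label else as.character(label)
  )
  bad <- regexpr("[^ACGT]", out$sequence)
  offending <- which(bad > 0L)
  if (length(offending) > 0L) {
    if (policy == "strict") {
      i <- offending[1L]
      abort(paste0("non-ACGT symbol in record '", out$id[i],
                   "' at position ", bad[i],
                   " ('", substr(out$sequence[i], bad[i], bad[i]), "')"))
    }
    rlang::inform(paste0("read_fasta: dropped ", length(offending),
                         " record(s) with non-ACGT symbols"))
    out <- out[-offending, , drop = FALSE]
  }
  out
}

#' Write sequence records to FASTA
#'
#' Headers are written as `>id|label` when a label is present (and
#' `write_label = TRUE`), so that labels round-trip through
#' [read_fasta()].
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `label`.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 70).
#' @param write_label Encode labels into headers (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L, write_label = TRUE) {
  check_records(records)
  if (nrow(records) == 0L) abort("no records to write")
  has_label <- write_label && "label" %in% names(records) &&
    !all(is.na(records$label))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (has_label && !is.na(records$label[i])) {
      paste0(">", records$id[i], "|", records$label[i])
    } else {
      paste0(">", records$id[i])
    }
    s <- records$sequence[i]
    chunks <- substring(s, seq(1L, nchar(s), by = width),
                        pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    writeLines(c(hdr, chunks), con)
  }
  invisible(path)
}

#' Validate a sequence dataset
#'
#' Keeps records that have exactly the expected length and contain only
#' `A`/`C`/`G`/`T`; everything else is rejected with a reason. Within one
#' dataset all model inputs must share a single length because both
#' encodings are fixed-shape.
#'
#' @param records Tibble of records (see [read_fasta()]).
#' @param expected_length Required sequence length (e.g. 251 or 81).
#' @param quiet Suppress the rejection-count message.
#' @return The surviving records; the rejected rows (with a `reason`
#'   column) are attached as attribute `"rejected"`.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACG"),
#'                        label = "promoter")
#' validate_records(recs, expected_length = 4)
#' @export
validate_records <- function(records, expected_length, quiet = FALSE) {
  check_records(records)
  len <- nchar(records$sequence)
  reason <- rep(NA_character_, nrow(records))
  reason[len != expected_length] <- "wrong-length"
  bad_alpha <- grepl("[^ACGT]", records$sequence) & is.na(reason)
  reason[bad_alpha] <- "non-ACGT"
  keep <- is.na(reason)
  if (!any(keep)) {
    abort(paste0("no records of length ", expected_length,
                 " over {A,C,G,T} survive validation"))
  }
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  if (!quiet && nrow(rejected) > 0L) {
    rlang::inform(paste0("validate_records: rejected ", nrow(rejected),
                         " of ", nrow(records), " record(s)"))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Stratified train/test split
#'
#' Partitions records into a training set (4/5) and a test set (1/5),
#' stratified by class label so per-class proportions are preserved to
#' within one record. The split is deterministic given `seed`.
#'
#' @param records Tibble of labelled records.
#' @param seed Integer seed (required: splits must be reproducible).
#' @param test_fraction Held-out fraction (default 1/5).
#' @return An object of class `dataset_split`: list with tibbles `train`
#'   and `test`, plus `seed` and `fractions`.
#' @examples
#' recs <- simulate_promoters(n_per_class = 10, length = 20, seed = 1)
#' sp <- split_train_test(recs, seed = 7)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_train_test <- function(records, seed, test_fraction = 1 / 5) {
  check_records(records)
  if (missing(seed)) abort("split_train_test requires an explicit seed")
  if (!"label" %in% names(records) || anyNA(records$label)) {
    abort("split_train_test requires labelled records")
  }
  counts <- table(records$label)
  if (any(counts < 5L)) {
    abort(paste0(
      "class(es) with fewer than 5 records: ",
      paste(names(counts)[counts < 5L], collapse = ", "),
      "; too small to split 4/5-1/5 (consider the subtype-mode handling ",
      "with merged or duplicated minority classes)"
    ))
  }
  test_idx <- with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(records)), records$label), function(idx) {
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  structure(
    list(
      train = records[-test_idx, , drop = FALSE],
      test = records[test_idx, , drop = FALSE],
      seed = as.integer(seed),
      fractions = c(train = 1 - test_fraction, test = test_fraction)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> seed ", x$seed, ": ", nrow(x$train), " train / ",
      nrow(x$test), " test\n", sep = "")
  print(rbind(train = table(x$train$label), test = table(x$test$label)))
  invisible(x)
}

check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records))) {
    abort("records must be a data frame with columns 'id' and 'sequence'")
  }
  invisible(records)
}
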