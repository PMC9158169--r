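#' Confusion-matrix evaluation: Sn, Sp, Acc, Mcc
#'
#' Computes the four standard promoter-identification measures from
#' predicted and true class labels:
#' sensitivity `Sn = TP / (TP + FN)`, specificity `Sp = TN / (TN + FP)`,
#' accuracy `Acc = (TP + TN) / N` and the Matthews correlation
#' coefficient
#' `Mcc = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the Mcc denominator is zero the coefficient is
#' reported as 0 (with `mcc_degenerate = TRUE`), a common convention for
#' the undefined case.
#'
#' With more than two classes the report is one-vs-rest: each class in
#' turn is treated as positive and a binary report is produced per class
#' (the layout used for sigma-factor subtype results).
#'
#' @param predictions Vector of predicted class labels (or 1-based
#'   indices).
#' @param truths Vector of true class labels, same length.
#' @param positive_class For binary data, which label is the positive
#'   (promoter) class; defaults to the last sorted level.
#' @return A tibble of class `evaluation_report` with columns `class`,
#'   `tp`, `fn`, `tn`, `fp`, `sn`, `sp`, `acc`, `mcc`,
#'   `mcc_degenerate` — a single row in binary mode, one row per class
#'   in one-vs-rest mode.
#' @examples
#' evaluate_predictions(c(1, 1, 2, 2), c(1, 2, 2, 2), positive_class = 2)
#' @export
evaluate_predictions <- function(predictions, truths, positive_class = NULL) {
  if (length(predictions) != length(truths) || length(truths) == 0L) {
    abort("predictions and truths must be equal-length, nonempty vectors")
  }
  classes <- sort(unique(c(as.character(predictions), as.character(truths))))
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (!is.null(positive_class) && !as.character(positive_class) %in% classes) {
    abort(paste0("positive_class '", positive_class, "' not among observed labels"))
  }
  one_vs_rest <- function(pos) {
    tp <- sum(predictions == pos & truths == pos)
    fn <- sum(predictions != pos & truths == pos)
    fp <- sum(predictions == pos & truths != pos)
    tn <- sum(predictions != pos & truths != pos)
    binary_report(pos, tp, fn, tn, fp)
  }
  if (length(classes) <= 2L) {
    pos <- as.character(positive_class %||% classes[length(classes)])
    out <- one_vs_rest(pos)
  } else {
    out <- dplyr::bind_rows(lapply(classes, one_vs_rest))
  }
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Evaluation report from explicit confusion counts
#'
#' @param class Label reported as positive.
#' @param tp,fn,tn,fp Confusion counts.
#' @return One-row tibble as in [evaluate_predictions()].
#' @examples
#' binary_report("promoter", tp = 9, fn = 1, tn = 8, fp = 2)
#' @export
binary_report <- function(class, tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  total <- tp + fn + tn + fp
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom2 <- as.numeric(tp + fp) * as.numeric(tp + fn) *
    as.numeric(tn + fp) * as.numeric(tn + fn)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble(
    class = as.character(class),
    tp = as.integer(tp), fn = as.integer(fn),
    tn = as.integer(tn), fp = as.integer(fp),
    sn = sn, sp = sp, acc = (tp + tn) / total,
    mcc = mcc, mcc_degenerate = degenerate
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  df <- as.data.frame(x)
  for (col in c("sn", "sp", "acc", "mcc")) df[[col]] <- sprintf("%.4f", df[[col]])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Numbers are printed to 4 decimals.
#'
#' @param report An `evaluation_report`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  for (col in c("sn", "sp", "acc", "mcc")) df[[col]] <- sprintf("%.4f", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
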