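#' Dinucleotide structural property tables
#'
#' A structural property (SP) table assigns each of the 16 dinucleotides
#' (lexicographic order `AA, AC, ..., TT`) a value for each of twelve
#' physicochemical/conformational properties: A-philicity, base stacking,
#' B-DNA twist, bendability, bending stiffness, DNA denaturation, duplex
#' disrupt energy, duplex free energy, propeller twist, protein
#' deformation, protein-DNA twist and Z-DNA forming energy. The bundled
#' table is a representative compilation from the primary literature;
#' published tabulations differ slightly between sources, and a
#' user-supplied table in the same format can be used everywhere instead.
#'
#' Raw values are standardized per property across the 16 dinucleotides
#' (population form, denominator 16, since the dinucleotide alphabet is
#' exhaustive): `std = (raw - mean) / sd_pop`.
#'
#' @param path Path to a tab-delimited property table: a header row naming
#'   the 16 dinucleotides, then one row per property (`property` label
#'   followed by 16 numeric values). Lines starting with `#` are ignored.
#' @param standardize Standardize rows on load (default `TRUE`).
#'
#' @return An object of class `sp_table`: a list with
#'   \describe{
#'     \item{properties}{character vector of 12 property labels}
#'     \item{raw}{12 x 16 numeric matrix of raw values}
#'     \item{std}{12 x 16 numeric matrix of standardized values (or `NULL`)}
#'   }
#'   Columns are always the dinucleotides `AA..TT` in lexicographic order.
#'
#' @examples
#' tab <- sp_table()
#' rowMeans(tab$std)       # ~0 for every property
#' tab$std["propeller_twist", "AA"]
#' @export
sp_table <- function() {
  path <- system.file("extdata", "structural_properties.tsv", package = "hmpi")
  read_sp_table(path)
}

#' @rdname sp_table
#' @export
read_sp_table <- function(path, standardize = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("structural property table not found: ", path))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 17L) {
    abort(paste0("property table must have 17 columns (property + 16 dinucleotides), got ",
                 ncol(df)))
  }
  dinucs <- colnames(df)[-1L]
  if (!identical(sort(dinucs), sort(dinucleotides()))) {
    abort("property table header must name the 16 dinucleotides AA..TT")
  }
  raw <- as.matrix(df[, dinucleotides(), drop = FALSE])
  if (!is.numeric(raw) || anyNA(raw)) {
    abort("property table contains non-numeric or missing values")
  }
  rownames(raw) <- df[[1L]]
  tab <- structure(
    list(properties = df[[1L]], raw = raw, std = NULL),
    class = "sp_table"
  )
  if (standardize) tab <- standardize_sp_table(tab)
  tab
}

#' @rdname sp_table
#' @param table An `sp_table` object with raw values.
#' @export
standardize_sp_table <- function(table) {
  stopifnot(inherits(table, "sp_table"))
  raw <- table$raw
  mu <- rowMeans(raw)
  # population standard deviation: the 16 dinucleotides are the whole population
  sd_pop <- sqrt(rowMeans((raw - mu)^2))
  zero <- sd_pop <= 0
  if (any(zero)) {
    abort(paste0("property row(s) with zero variance cannot be standardized: ",
                 paste(table$properties[zero], collapse = ", ")))
  }
  table$std <- (raw - mu) / sd_pop
  table
}

#' @export
print.sp_table <- function(x, ...) {
  cat("<sp_table> ", nrow(x$raw), " properties x ", ncol(x$raw),
      " dinucleotides", if (is.null(x$std)) " (raw only)" else " (standardized)",
      "\n", sep = "")
  cat("  ", paste(x$properties, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy sp_table
tidy.sp_table <- function(x, ...) {
  long <- function(m, which) {
    tibble(
      property = rep(rownames(m), times = ncol(m)),
      dinucleotide = rep(colnames(m), each = nrow(m)),
      value = as.vector(m),
      scale = which
    )
  }
  out <- long(x$raw, "raw")
  if (!is.null(x$std)) out <- dplyr::bind_rows(out, long(x$std, "std"))
  out
}

dinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}
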