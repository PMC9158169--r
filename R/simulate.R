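#' Simulate labelled promoter-vs-background sequence datasets
#'
#' Generates synthetic DNA datasets carrying the two kinds of signal the
#' model branches exploit, so the whole pipeline is testable without any
#' external download:
#' \itemize{
#'   \item a *sequence-level* signal: a consensus motif (default
#'     `TATAAT`, the canonical -10 element) planted in each positive at
#'     a jittered offset, with independent per-position mutation;
#'   \item a *structure-level* signal: positives are drawn from a
#'     first-order Markov background whose transition probabilities are
#'     tilted towards preferred successor bases
#'     (`A->A, C->G, G->C, T->T`), enriching AA/TT/CG/GC steps the way
#'     CpG-island-like and poly(A)-tract-like promoter context does.
#'     The tilt magnitude is `composition_shift`: the preferred
#'     successor has probability `0.25 + 0.75 * shift`. Because the
#'     structural-profile encoding is a dinucleotide lookup, this signal
#'     is exactly what the structural branch must recover.
#' }
#' Negatives are i.i.d. uniform over `{A, C, G, T}`. With
#' `mutation_prob = 1` and `composition_shift = 0`, positives are
#' statistically indistinguishable from negatives (a null calibration).
#'
#' In subtype layout there are no negatives; each subtype class plants
#' its own motif variant on its own tilted background — the
#' preferred-successor map is rotated per class, giving every subtype a
#' distinct dinucleotide enrichment the way promoter classes carry
#' distinct structural signatures — with class counts that default to
#' the sigma-factor imbalance profile `484:134:291:163:94:1694` scaled
#' to the requested total.
#'
#' @param n_per_class Sequences per class (binary layout), or the total
#'   used to scale the default subtype profile.
#' @param length Sequence length (presets: 81 prokaryotic, 251
#'   eukaryotic windows; any length >= motif works).
#' @param motif Consensus motif planted in positives.
#' @param mutation_prob Per-position probability that a planted motif
#'   base is replaced by a uniform random base.
#' @param motif_position Leftmost motif offset before jitter; defaults
#'   to a TSS-proximal location (about 30% of the window upstream of
#'   the 3' end).
#' @param jitter Uniform positional jitter, `+- jitter` positions.
#' @param composition_shift Magnitude of the dinucleotide-frequency tilt
#'   in `[0, 1]`.
#' @param class_layout `"binary"` (promoter vs non-promoter) or
#'   `"subtypes"`.
#' @param subtype_counts Optional integer vector of per-subtype counts
#'   (named or not); overrides the default profile.
#' @param subtype_motifs Optional character vector of per-subtype motifs
#'   (recycled/truncated to the number of subtypes).
#' @param seed Integer seed; output is byte-identical given it.
#' @return A tibble of records (`id`, `sequence`, `label`).
#' @examples
#' recs <- simulate_promoters(n_per_class = 5, length = 40, seed = 1)
#' table(recs$label)
#' @export
simulate_promoters <- function(n_per_class = 1000L,
                               length = 81L,
                               motif = "TATAAT",
                               mutation_prob = 0.1,
                               motif_position = NULL,
                               jitter = 2L,
                               composition_shift = 0.25,
                               class_layout = c("binary", "subtypes"),
                               subtype_counts = NULL,
                               subtype_motifs = NULL,
                               seed = 1L) {
  class_layout <- match.arg(class_layout)
  L <- as.integer(length)
  m <- nchar(motif)
  if (m > L) abort("motif is longer than the requested sequence length")
  if (mutation_prob < 0 || mutation_prob > 1) abort("mutation_prob must be in [0, 1]")
  if (composition_shift < 0 || composition_shift > 1) {
    abort("composition_shift must be in [0, 1]")
  }
  if (n_per_class < 1L && (class_layout == "binary" || is.null(subtype_counts))) {
    abort("n_per_class must be >= 1")
  }
  pos0 <- motif_position %||% max(1L, L - m + 1L - round(0.3 * L))
  pos0 <- min(max(1L, pos0), L - m + 1L)

  with_seed(seed, {
    if (class_layout == "binary") {
      neg <- random_codes(n_per_class, L, shift = 0)
      pos <- random_codes(n_per_class, L, shift = composition_shift)
      pos <- plant_motif(pos, motif, mutation_prob, pos0, jitter)
      tibble(
        id = c(sprintf("pos_%04d", seq_len(n_per_class)),
               sprintf("neg_%04d", seq_len(n_per_class))),
        sequence = c(codes_to_strings(pos), codes_to_strings(neg)),
        label = rep(c("promoter", "non-promoter"), each = n_per_class)
      )
    } else {
      profile <- c(sigma24 = 484, sigma28 = 134, sigma32 = 291,
                   sigma38 = 163, sigma54 = 94, sigma70 = 1694)
      if (is.null(subtype_counts)) {
        counts <- pmax(1L, round(profile / sum(profile) * n_per_class * 6))
        names(counts) <- names(profile)
      } else {
        counts <- as.integer(subtype_counts)
        names(counts) <- names(subtype_counts) %||%
          paste0("class", seq_along(counts))
      }
      motifs <- subtype_motifs %||% default_subtype_motifs(length(counts), motif)
      motifs <- rep_len(motifs, length(counts))
      rows <- lapply(seq_along(counts), function(ci) {
        nc <- counts[ci]
        partner_ci <- ((c(1L, 3L, 2L, 4L) - 1L + (ci - 1L)) %% 4L) + 1L
        codes <- random_codes(nc, L, shift = composition_shift,
                              partner = partner_ci)
        codes <- plant_motif(codes, motifs[ci], mutation_prob, pos0, jitter)
        tibble(
          id = sprintf("%s_%04d", names(counts)[ci], seq_len(nc)),
          sequence = codes_to_strings(codes),
          label = names(counts)[ci]
        )
      })
      dplyr::bind_rows(rows)
    }
  })
}

#' Write simulated records as a FASTA fixture
#'
#' Headers carry the label as `>id|label`, so the fixture round-trips
#' through [read_fasta()].
#'
#' @param records Tibble of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(records, path) {
  write_fasta(records, path, write_label = TRUE)
}

# Base codes matrix (L x n). shift = 0: i.i.d. uniform; otherwise a
# first-order Markov chain whose preferred successor (default
# A->A, C->G, G->C, T->T) has probability 0.25 + 0.75 * shift.
random_codes <- function(n, L, shift = 0, partner = c(1L, 3L, 2L, 4L)) {
  if (shift == 0) {
    return(matrix(sample.int(4L, n * L, replace = TRUE), L, n))
  }
  others <- t(vapply(1:4, function(b) setdiff(1:4, partner[b]), integer(3)))
  p1 <- 0.25 + 0.75 * shift
  p0 <- (1 - p1) / 3
  codes <- matrix(0L, L, n)
  codes[1L, ] <- sample.int(4L, n, replace = TRUE)
  for (j in 2L:L) {
    cur <- codes[j - 1L, ]
    r <- runif(n)
    take_partner <- r < p1
    alt <- pmin(3L, 1L + floor((r - p1) / p0))
    nxt <- integer(n)
    nxt[take_partner] <- partner[cur[take_partner]]
    if (any(!take_partner)) {
      nxt[!take_partner] <- others[cbind(cur[!take_partner], alt[!take_partner])]
    }
    codes[j, ] <- nxt
  }
  codes
}

plant_motif <- function(codes, motif, mutation_prob, pos0, jitter) {
  n <- ncol(codes)
  L <- nrow(codes)
  mc <- base_codes(toupper(motif))
  m <- length(mc)
  offs <- pos0 + (if (jitter > 0) sample(seq(-jitter, jitter), n, replace = TRUE)
                  else integer(n))
  offs <- pmin(pmax(offs, 1L), L - m + 1L)
  for (i in seq_len(n)) {
    planted <- mc
    if (mutation_prob > 0) {
      hit <- runif(m) < mutation_prob
      if (any(hit)) planted[hit] <- sample.int(4L, sum(hit), replace = TRUE)
    }
    codes[offs[i]:(offs[i] + m - 1L), i] <- planted
  }
  codes
}

codes_to_strings <- function(codes) {
  bases <- c("A", "C", "G", "T")
  apply(codes, 2L, function(col) paste0(bases[col], collapse = ""))
}

# Distinct, fixed motif variants for subtype classes; the first class
# keeps the consensus.
default_subtype_motifs <- function(n, motif) {
  pool <- c(motif, "TTGACA", "CTGGCA", "GAACTT", "TGGCAC", "CCGATC",
            "GGTACC", "AAGCTT")
  rep_len(pool, n)
}
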