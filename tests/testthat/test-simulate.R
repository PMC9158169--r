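test_that("with no mutation and no jitter every positive carries the exact motif", {
  recs <- simulate_promoters(n_per_class = 30, length = 40, seed = 1,
                             mutation_prob = 0, jitter = 0, motif_position = 12)
  pos <- recs$sequence[recs$label == "promoter"]
  expect_true(all(substr(pos, 12, 17) == "TATAAT"))
  neg <- recs$sequence[recs$label == "non-promoter"]
  expect_lt(mean(grepl("TATAAT", neg, fixed = TRUE)), 0.2)
})

test_that("jitter moves the motif within the declared window", {
  recs <- simulate_promoters(n_per_class = 100, length = 40, seed = 2,
                             mutation_prob = 0, jitter = 2, motif_position = 12)
  pos <- recs$sequence[recs$label == "promoter"]
  at <- regexpr("TATAAT", pos, fixed = TRUE)
  expect_true(all(at >= 10 & at <= 14))
  expect_gt(length(unique(at)), 1)
})

test_that("generation is byte-identical given the seed", {
  a <- simulate_promoters(n_per_class = 25, length = 30, seed = 33)
  b <- simulate_promoters(n_per_class = 25, length = 30, seed = 33)
  expect_identical(a, b)
  c <- simulate_promoters(n_per_class = 25, length = 30, seed = 34)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("the composition shift tilts dinucleotide frequencies of positives only", {
  recs <- simulate_promoters(n_per_class = 400, length = 81, seed = 3,
                             mutation_prob = 1)   # no motif signal left
  din_freq <- function(seqs, d) {
    mean(vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      mean(paste0(ch[-length(ch)], ch[-1]) == d)
    }, numeric(1)))
  }
  pos <- recs$sequence[recs$label == "promoter"]
  neg <- recs$sequence[recs$label == "non-promoter"]
  # preferred steps AA and CG are enriched in positives
  expect_gt(din_freq(pos, "AA"), din_freq(neg, "AA") + 0.02)
  expect_gt(din_freq(pos, "CG"), din_freq(neg, "CG") + 0.02)
  expect_lt(abs(din_freq(neg, "AA") - 1 / 16), 0.005)
})

test_that("null configuration produces positives indistinguishable from negatives", {
  recs <- simulate_promoters(n_per_class = 300, length = 41, seed = 4,
                             mutation_prob = 1, composition_shift = 0)
  base_counts <- function(seqs) {
    table(factor(unlist(strsplit(seqs, "")), levels = c("A", "C", "G", "T")))
  }
  pos <- base_counts(recs$sequence[recs$label == "promoter"])
  neg <- base_counts(recs$sequence[recs$label == "non-promoter"])
  expect_gt(suppressWarnings(chisq.test(rbind(pos, neg))$p.value), 0.01)
})

test_that("subtype layout mirrors the sigma imbalance profile and plants distinct motifs", {
  recs <- simulate_promoters(n_per_class = 100, length = 40, seed = 5,
                             class_layout = "subtypes", mutation_prob = 0,
                             jitter = 0, motif_position = 10)
  counts <- table(recs$label)
  expect_identical(names(which.max(counts)), "sigma70")
  expect_identical(names(which.min(counts)), "sigma54")
  expect_equal(unname(counts["sigma70"] / counts["sigma54"]), 1694 / 94,
               tolerance = 0.05)
  s24 <- substr(recs$sequence[recs$label == "sigma24"][1], 10, 15)
  s28 <- substr(recs$sequence[recs$label == "sigma28"][1], 10, 15)
  expect_false(identical(s24, s28))
})

test_that("motifs longer than the sequence are rejected", {
  expect_error(simulate_promoters(n_per_class = 2, length = 4, seed = 1),
               "longer")
})

test_that("fixtures round-trip through FASTA with labels intact", {
  recs <- simulate_promoters(n_per_class = 10, length = 25, seed = 6)
  tf <- tempfile(fileext = ".fa")
  write_fixture(recs, tf)
  expect_identical(sum(startsWith(readLines(tf), ">")), 20L)
  back <- read_fasta(tf)
  expect_identical(back$id, recs$id)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$label, recs$label)
  expect_error(write_fixture(recs[0, ], tempfile()), "no records")
})

test_that("weaker motif corruption never hurts a simple k-mer baseline", {
  # monotone signal check with a motif-match score as the Bayes proxy
  score <- function(mp) {
    recs <- simulate_promoters(n_per_class = 200, length = 41, seed = 7,
                               mutation_prob = mp, composition_shift = 0)
    hit <- grepl("TATAAT", recs$sequence, fixed = TRUE)
    mean(hit[recs$label == "promoter"]) - mean(hit[recs$label == "non-promoter"])
  }
  expect_gt(score(0), score(0.3))
  expect_gt(score(0.3), score(0.9) - 0.05)
})
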