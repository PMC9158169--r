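test_that("one_hot_encode matches its definition on canonical cases", {
  expect_equal(unname(one_hot_encode("ACGT")), diag(4), ignore_attr = TRUE)
  m <- one_hot_encode("AAAA")
  expect_equal(m["A", ], rep(1L, 4))
  expect_equal(sum(m[-1, ]), 0L)
})

test_that("one_hot_encode agrees with the per-position lookup oracle on random sequences", {
  set.seed(42)
  for (rep in 1:20) {
    s <- random_seq(251)
    m <- one_hot_encode(s)
    expect_identical(m, oracle_one_hot(s))
    expect_true(all(colSums(m) == 1))
    counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    expect_equal(rowSums(m), as.vector(counts), ignore_attr = TRUE)
  }
})

test_that("one_hot_encode errors on non-ACGT symbols, naming the position", {
  expect_error(one_hot_encode("ACNT"), "position 3")
})

test_that("sp_encode is the dinucleotide lookup of standardized values", {
  tab <- sp_table()
  m <- sp_encode("AAT", tab)
  expect_equal(m[, 1], tab$std[, "AA"], ignore_attr = TRUE)
  expect_equal(m[, 2], tab$std[, "AT"], ignore_attr = TRUE)
  expect_equal(sp_encode("AA", tab), tab$std[, "AA", drop = FALSE],
               ignore_attr = TRUE)
  set.seed(7)
  for (rep in 1:10) {
    s <- random_seq(81)
    expect_equal(unname(sp_encode(s, tab)), oracle_sp(s, tab))
  }
})

test_that("reversing a sequence does not simply reverse its SP matrix", {
  tab <- sp_table()
  set.seed(9)
  found_counterexample <- FALSE
  for (rep in 1:50) {
    s <- random_seq(10)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    if (!isTRUE(all.equal(sp_encode(r, tab),
                          sp_encode(s, tab)[, 9:1, drop = FALSE]))) {
      found_counterexample <- TRUE
      break
    }
  }
  expect_true(found_counterexample)
})

test_that("every SP entry lies within the property's standardized range", {
  tab <- sp_table()
  lo <- apply(tab$std, 1, min)
  hi <- apply(tab$std, 1, max)
  set.seed(11)
  m <- sp_encode(random_seq(200), tab)
  expect_true(all(m >= lo - 1e-12 & m <= hi + 1e-12))
})

test_that("encode_records reproduces the single-sequence encoders for every record", {
  recs <- simulate_promoters(n_per_class = 10, length = 30, seed = 5)
  tab <- sp_table()
  enc <- encode_records(recs, tab)
  expect_identical(dim(enc$onehot), c(4L, 30L, 20L))
  expect_identical(dim(enc$sp), c(12L, 29L, 20L))
  for (i in c(1, 7, 20)) {
    expect_equal(enc$onehot[, , i], unname(one_hot_encode(recs$sequence[i])))
    expect_equal(enc$sp[, , i], unname(sp_encode(recs$sequence[i], tab)))
  }
  expect_identical(enc$classes, c("non-promoter", "promoter"))
  expect_identical(enc$labels[1], 2L)
})

test_that("encode_records refuses mixed lengths and names offending records", {
  recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACGTA"),
                         label = "x")
  expect_error(encode_records(recs), "share one length")
  recs2 <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "ACNT"),
                          label = "x")
  expect_error(encode_records(recs2), "'b'")
})

test_that("positional_profile averages SP matrices position-wise", {
  tab <- sp_table()
  one <- tibble::tibble(id = "a", sequence = "ACGTT", label = "promoter")
  prof <- positional_profile(one, tab)
  expect_equal(attr(prof, "matrix"), sp_encode("ACGTT", tab),
               ignore_attr = TRUE)
  two <- tibble::tibble(id = c("a", "b"), sequence = c("AA", "AA"), label = "p")
  prof2 <- positional_profile(two, tab)
  expect_equal(as.vector(attr(prof2, "matrix")), unname(tab$std[, "AA"]))
  expect_identical(attr(prof2, "n"), 2L)
})

test_that("profile of uniform random sequences stays within Monte-Carlo bounds of zero", {
  tab <- sp_table()
  set.seed(20)
  recs <- tibble::tibble(
    id = sprintf("r%04d", 1:1000),
    sequence = vapply(1:1000, function(i) random_seq(81), character(1)),
    label = "bg"
  )
  prof <- positional_profile(recs, tab)
  # each entry is a mean of 1000 draws from a distribution with sd 1
  expect_lt(max(abs(prof$mean)), 3 / sqrt(1000) * 1.5)
})

test_that("positional profile of planted-motif positives deviates at the motif locus", {
  recs <- simulate_promoters(n_per_class = 200, length = 41, seed = 8,
                             mutation_prob = 0, jitter = 0,
                             motif_position = 20, composition_shift = 0.25)
  pos <- dplyr::filter(recs, label == "promoter")
  prof <- positional_profile(pos)
  m <- attr(prof, "matrix")
  motif_cols <- 20:24          # dinucleotide windows inside TATAAT
  flank_cols <- setdiff(seq_len(ncol(m)), 18:27)
  motif_dev <- mean(abs(m[, motif_cols]))
  flank_dev <- mean(abs(m[, flank_cols]))
  expect_gt(motif_dev, 2 * flank_dev)
})
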