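test_that("softmax is symmetric, shift-invariant, and overflow-safe", {
  expect_equal(softmax_probs(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_probs(rep(3.7, 5)), rep(0.2, 5))
  p <- softmax_probs(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_error(softmax_probs(c(Inf, 0)), "finite")
})

test_that("cross-entropy: sum form over the one-hot target equals the -log p(y) shortcut", {
  set.seed(1)
  for (rep in 1:200) {
    K <- sample(2:6, 1)
    p <- softmax_probs(rnorm(K))
    y <- sample(K, 1)
    q <- label_distribution(y, K)
    expect_equal(cce_loss(p, y), -sum(q * log(p)), tolerance = 1e-12)
  }
  expect_equal(cce_loss(c(1, 0), 1), 0)
  expect_equal(cce_loss(c(0.5, 0.5), 2), log(2))
})

test_that("label smoothing reduces to CCE at epsilon = 0 and is flat on uniform p", {
  set.seed(2)
  for (rep in 1:200) {
    K <- sample(2:6, 1)
    p <- softmax_probs(rnorm(K))
    y <- sample(K, 1)
    expect_identical(lsr_loss(p, y, epsilon = 0), cce_loss(p, y))
    u <- rep(1 / K, K)
    for (eps in c(0, 0.1, 0.2, 0.5)) {
      expect_equal(lsr_loss(u, y, eps), log(K), tolerance = 1e-12)
    }
  }
  # the smoothed target for K = 2, eps = 0.2 puts 0.9 on the true class
  expect_equal(label_distribution(1, 2, 0.2), c(0.9, 0.1))
  # lsr equals CCE against the smoothed target
  p <- c(0.7, 0.3)
  q <- label_distribution(1, 2, 0.2)
  expect_equal(lsr_loss(p, 1, 0.2), -sum(q * log(p)), tolerance = 1e-12)
})

test_that("joint loss adds the squared centre distance and degenerates correctly", {
  centres <- rbind(c(0, 0), c(5, 5))
  p <- c(1, 0)
  expect_equal(joint_loss(p, 1, x = c(0, 0), centres = centres, lambda = 1), 0)
  expect_equal(joint_loss(p, 1, x = c(3, 4), centres = centres, lambda = 0.01),
               0.25)
  pr <- c(0.6, 0.4)
  expect_equal(joint_loss(pr, 1, x = c(9, 9), centres = centres, lambda = 0),
               cce_loss(pr, 1))
  # joint >= cce whenever lambda >= 0
  set.seed(3)
  for (rep in 1:50) {
    x <- rnorm(2)
    expect_gte(joint_loss(pr, 1, x, centres, lambda = 0.01), cce_loss(pr, 1))
  }
  expect_error(joint_loss(pr, 1, x = c(1, 2, 3), centres = centres),
               "dimensionality")
})

test_that("evaluate_predictions matches the formula oracle on small tables", {
  for (tp in 0:3) for (fn in 0:3) for (tn in 0:3) for (fp in 0:3) {
    if (tp + fn + tn + fp == 0) next
    r <- binary_report("pos", tp, fn, tn, fp)
    o <- oracle_metrics(tp, fn, tn, fp)
    expect_equal(r$sn, o$sn)
    expect_equal(r$sp, o$sp)
    expect_equal(r$acc, o$acc)
    expect_equal(r$mcc, o$mcc)
  }
})

test_that("evaluate_predictions builds the confusion table from labels", {
  pred <- c("p", "p", "p", "p", "p", "p", "p", "p", "p", "n",
            "p", "p", "n", "n", "n", "n", "n", "n", "n", "n")
  truth <- c(rep("p", 10), rep("n", 10))
  r <- evaluate_predictions(pred, truth, positive_class = "p")
  expect_identical(c(r$tp, r$fn, r$tn, r$fp), c(9L, 1L, 8L, 2L))
  expect_equal(r$sn, 0.9)
  expect_equal(r$sp, 0.8)
  expect_equal(r$acc, 0.85)
  expect_equal(r$mcc, oracle_metrics(9, 1, 8, 2)$mcc)
})

test_that("perfect and inverted predictions give Mcc of +1 and -1", {
  y <- rep(c("a", "b"), each = 5)
  perfect <- evaluate_predictions(y, y, positive_class = "b")
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$acc, 1)
  inverted <- evaluate_predictions(ifelse(y == "a", "b", "a"), y,
                                   positive_class = "b")
  expect_equal(inverted$mcc, -1)
})

test_that("degenerate Mcc denominators report 0 with a flag", {
  r <- binary_report("pos", tp = 0, fn = 0, tn = 5, fp = 0)
  expect_equal(r$mcc, 0)
  expect_true(r$mcc_degenerate)
})

test_that("Mcc is invariant under swapping class roles", {
  set.seed(4)
  for (rep in 1:20) {
    pred <- sample(c("a", "b"), 30, replace = TRUE)
    truth <- sample(c("a", "b"), 30, replace = TRUE)
    m1 <- evaluate_predictions(pred, truth, positive_class = "b")$mcc
    m2 <- evaluate_predictions(pred, truth, positive_class = "a")$mcc
    expect_equal(m1, m2)
    expect_true(m1 >= -1 && m1 <= 1)
  }
})

test_that("multi-class evaluation yields one one-vs-rest row per class", {
  truth <- rep(c("s24", "s32", "s70"), times = c(4, 6, 10))
  pred <- truth
  pred[c(1, 5, 11)] <- c("s32", "s70", "s24")
  r <- evaluate_predictions(pred, truth)
  expect_identical(nrow(r), 3L)
  expect_setequal(r$class, c("s24", "s32", "s70"))
  row <- r[r$class == "s24", ]
  expect_identical(c(row$tp, row$fn, row$fp), c(3L, 1L, 1L))
})

test_that("evaluation reports serialize with 4-decimal formatting", {
  r <- evaluate_predictions(c("a", "b"), c("a", "b"), positive_class = "b")
  tf <- tempfile(fileext = ".tsv")
  write_report(r, tf)
  out <- read.delim(tf)
  expect_identical(sprintf("%.4f", out$acc), "1.0000")
})
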