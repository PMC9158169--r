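test_that("the default PSFN has the prescribed three-block architecture", {
  model <- build_psfn(psfn_spec(251))
  convs <- Filter(function(l) l$type == "conv1d", model$stack)
  expect_length(convs, 3L)
  expect_identical(vapply(convs, `[[`, integer(1), "out_ch"), c(32L, 64L, 128L))
  expect_identical(vapply(convs, `[[`, integer(1), "kernel"), c(3L, 4L, 5L))
  expect_identical(convs[[1]]$in_ch, 4L)
  # block composition: conv -> LeakyReLU(0.2) -> Dropout(0.25)
  types <- vapply(model$stack, `[[`, character(1), "type")
  expect_identical(types[1:9],
                   rep(c("conv1d", "leaky_relu", "dropout"), 3))
  lrelus <- Filter(function(l) l$type == "leaky_relu", model$stack)
  expect_true(all(vapply(lrelus, `[[`, numeric(1), "alpha") == 0.2))
  drops <- Filter(function(l) l$type == "dropout", model$stack)
  expect_true(all(vapply(drops, `[[`, numeric(1), "rate") == 0.25))
  # flatten -> Dense(feature) -> ReLU, then a K-way head
  expect_identical(types[10:12], c("flatten", "dense", "relu"))
  expect_identical(model$stack[[11]]$in_dim, 128L * 251L)
  expect_identical(model$stack[[11]]$out_dim, 128L)
  expect_identical(model$head$out_dim, 2L)
})

test_that("centre embedding dimensions follow feature_dim and K", {
  model <- build_psfn(psfn_spec(30, feature_dim = 8, num_classes = 2))
  expect_identical(dim(model$centres), c(8L, 2L))
})

test_that("too-short inputs are rejected with the minimal length", {
  expect_error(build_psfn(psfn_spec(4)), "minimal supported length is 5")
})

test_that("evaluation-mode forward passes are deterministic and probabilistic", {
  recs <- simulate_promoters(n_per_class = 12, length = 20, seed = 5)
  enc <- encode_records(recs)
  model <- train_psfn(build_psfn(tiny_psfn_spec()), enc)
  p1 <- predict(model, enc)
  p2 <- predict(model, enc)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 24), tolerance = 1e-9)
  expect_identical(colnames(p1), c("non-promoter", "promoter"))
})

test_that("extract_features returns the documented shapes, identically for identical samples", {
  recs <- simulate_promoters(n_per_class = 6, length = 20, seed = 5)
  recs$sequence[2] <- recs$sequence[1]
  enc <- encode_records(recs)
  model <- train_psfn(build_psfn(tiny_psfn_spec()), enc)
  f <- extract_features(model, enc, "feature_layer")
  expect_identical(dim(f), c(12L, 8L))
  expect_equal(f[1, ], f[2, ])
  b2 <- extract_features(model, enc, "second_block")
  expect_identical(dim(b2), c(12L, 64L))
  expect_error(extract_features(model, enc, "third_block"))
})

test_that("training with lambda = 0 reproduces the pure-CCE trace exactly", {
  recs <- simulate_promoters(n_per_class = 20, length = 20, seed = 6)
  enc <- encode_records(recs)
  m0 <- train_psfn(build_psfn(tiny_psfn_spec(lambda_centre = 0)), enc)
  m0b <- train_psfn(build_psfn(tiny_psfn_spec(lambda_centre = 0)), enc)
  expect_identical(m0$log$loss, m0b$log$loss)
  # the joint loss with lambda > 0 upper-bounds the CCE part at matched seed
  m1 <- train_psfn(build_psfn(tiny_psfn_spec(lambda_centre = 0.01)), enc)
  expect_true(all(m1$log$loss >= m0$log$loss - 1e-8))
})

test_that("classes compact around their centres as centre-loss training progresses", {
  recs <- simulate_promoters(n_per_class = 60, length = 30, seed = 7)
  enc <- encode_records(recs)
  # within-class distance to the centre, relative to centre separation
  rel_compact <- function(m) {
    f <- t(extract_features(m, enc))
    within <- mean(sqrt(colSums((f - m$centres[, enc$labels])^2)))
    within / sqrt(sum((m$centres[, 1] - m$centres[, 2])^2))
  }
  fit_at <- function(ep) {
    train_psfn(build_psfn(psfn_spec(30, feature_dim = 8, epochs = ep,
                                    batch_size = 16, seed = 5)), enc)
  }
  r1 <- rel_compact(fit_at(1))
  r4 <- rel_compact(fit_at(4))
  r12 <- rel_compact(fit_at(12))
  expect_lt(r4, r1)
  expect_lt(r12, r4)
})

test_that("tidy and glance summarize a trained model", {
  recs <- simulate_promoters(n_per_class = 12, length = 20, seed = 5)
  enc <- encode_records(recs)
  model <- train_psfn(build_psfn(tiny_psfn_spec()), enc)
  expect_s3_class(tidy(model), "tbl_df")
  g <- glance(model)
  expect_identical(g$epochs_run, 2L)
  expect_gt(g$n_parameters, 0)
})
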