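# The end-to-end synthetic benchmark is expensive, so it is computed once
# per test run and shared by the acceptance tests that consume different
# facets of it (accuracies, separation ratios, imbalance comparison).

.bench_cache <- new.env(parent = emptyenv())

# Planted-motif + composition-shift identification task at the study
# scale: 2500 sequences of length 81, split 2000 train (1600 fit + 400
# early-stopping validation) / 500 test.
benchmark_identification <- function() {
  if (!is.null(.bench_cache$ident)) return(.bench_cache$ident)
  recs <- simulate_promoters(n_per_class = 1250, length = 81, seed = 11)
  sp <- split_train_test(recs, seed = 11)
  spv <- split_train_test(sp$train, seed = 12)
  enc_tr <- encode_records(spv$train)
  enc_va <- encode_records(spv$test, classes = enc_tr$classes)
  enc_te <- encode_records(sp$test, classes = enc_tr$classes)
  y_test <- sp$test$label

  ps <- psfn_spec(81, epochs = 20, seed = 11)
  ds <- dspn_spec(81, preset = "prokaryote", epochs = 20, seed = 11)
  pm <- train_psfn(build_psfn(ps), enc_tr, enc_va)
  dm <- train_dspn(build_dspn(ds), enc_tr, enc_va)
  acc <- function(m) mean(predicted_classes(predict(m, enc_te)) == y_test)

  hm <- build_hmpi(hmpi_spec(ps, ds, seed = 11))
  hm$psfn <- pm
  hm$dspn <- dm
  hm <- train_hmpi(hm, enc_tr, enc_va, reuse_branches = TRUE)

  # centre-loss ablation at matched seed
  pm0 <- train_psfn(build_psfn(psfn_spec(81, epochs = 20, seed = 11,
                                         lambda_centre = 0)), enc_tr, enc_va)
  y_te_idx <- match(y_test, enc_tr$classes)
  sep_cl <- separation_ratio(extract_features(pm, enc_te), y_te_idx)
  sep_cce <- separation_ratio(extract_features(pm0, enc_te), y_te_idx)

  # label-shuffled control (structural branch, fast)
  enc_sh <- enc_tr
  enc_sh$labels <- with_seed_for_tests(13, sample(enc_sh$labels))
  dm_sh <- train_dspn(build_dspn(dspn_spec(81, preset = "prokaryote",
                                           epochs = 10, seed = 11)), enc_sh)
  res <- list(
    acc_psfn = acc(pm), acc_dspn = acc(dm), acc_hmpi = acc(hm),
    acc_shuffled = acc(dm_sh),
    sep_centre = sep_cl, sep_cce = sep_cce,
    n_train = nrow(sp$train), n_test = nrow(sp$test),
    psfn = pm, dspn = dm, hmpi = hm,
    enc_tr = enc_tr, enc_te = enc_te, y_test = y_test
  )
  .bench_cache$ident <- res
  res
}

# Imbalanced (10:1) subtype task: two sigma-like classes whose motifs
# differ by one base, own structural tilt per class.
benchmark_imbalance <- function() {
  if (!is.null(.bench_cache$imb)) return(.bench_cache$imb)
  recs <- simulate_promoters(length = 81, seed = 21, class_layout = "subtypes",
                             subtype_counts = c(sigma70 = 600, sigma54 = 60),
                             subtype_motifs = c("TATAAT", "TACAAT"))
  sp <- split_train_test(recs, seed = 21)
  spv <- split_train_test(sp$train, seed = 22)
  enc_tr <- encode_records(spv$train)
  enc_va <- encode_records(spv$test, classes = enc_tr$classes)
  enc_te <- encode_records(sp$test, classes = enc_tr$classes)
  ps <- psfn_spec(81, epochs = 15, seed = 21)
  ds <- dspn_spec(81, preset = "prokaryote", epochs = 15, seed = 21)
  base <- train_hmpi(build_hmpi(hmpi_spec(ps, ds, seed = 21)), enc_tr, enc_va)
  at <- run_hmpiat(build_hmpi(hmpi_spec(ps, ds, variant = "at", seed = 21)),
                   enc_tr, enc_va)
  minority_mcc <- function(m) {
    r <- evaluate_predictions(predicted_classes(predict(m, enc_te)),
                              sp$test$label, positive_class = "sigma54")
    r$mcc[r$class == "sigma54"]
  }
  res <- list(mcc_base = minority_mcc(base), mcc_at = minority_mcc(at),
              n_synthetic = attr(at$log, "n_synthetic"))
  .bench_cache$imb <- res
  res
}

# Seeded evaluation that restores the RNG state (tests should not leak
# RNG changes into each other).
with_seed_for_tests <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
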