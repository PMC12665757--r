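test_that("stratification keys enumerate the label states", {
  rec <- toy_records(
    c("ACDEF", "GHIKL", "MNPQR"),
    ec50 = matrix(c(10, 10, NA,
                    2000, 10, 500,
                    NA, NA, NA), 3, 3, byrow = TRUE)
  )
  expect_identical(make_strat_key(rec), c("1|1|m", "0|1|1", "m|m|m"))
  # 3 receptors x 3 states span 27 possible keys
  states <- c("1", "0", "m")
  expect_equal(nrow(expand.grid(states, states, states)), 27)
})

test_that("stratified folds partition the data and balance keys", {
  set.seed(1)
  rec <- toy_records(
    vapply(1:100, function(i) pep_detokenize(random_tokens(10, 0)),
           character(1)),
    ec50 = matrix(100, 100, 3)
  )
  fold <- stratified_kfold(rec, k = 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 20))  # one key -> equal folds
  # mixed keys: per-key counts differ by at most one across folds
  ec <- matrix(100, 60, 3)
  ec[31:60, 1] <- 5000
  rec2 <- toy_records(
    vapply(1:60, function(i) pep_detokenize(random_tokens(10, 0)),
           character(1)),
    ec50 = ec
  )
  fold2 <- stratified_kfold(rec2, k = 5, seed = 3)
  keys <- make_strat_key(rec2)
  for (key in unique(keys)) {
    counts <- table(factor(fold2[keys == key], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_error(stratified_kfold(rec2[1:3, ], k = 5), "at least k")
})

test_that("metric computation agrees with the exhaustive pair oracle", {
  set.seed(4)
  for (i in 1:25) {
    n <- 30
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    scores <- round(runif(n), 2)  # rounded to force ties
    m <- evaluate_predictions(
      matrix(scores, ncol = 1, dimnames = list(NULL, "GCGR")),
      matrix(y, ncol = 1)
    )
    expect_equal(m$auc_roc, pair_count_auc(scores, y), tolerance = 1e-9)
  }
})

test_that("metrics handle separable, constant and single-class inputs", {
  y <- c(rep(1, 5), rep(0, 5))
  sep <- c(seq(0.9, 0.98, length.out = 5), seq(0.1, 0.2, length.out = 5))
  m <- evaluate_predictions(matrix(sep, ncol = 1,
                                   dimnames = list(NULL, "GCGR")),
                            matrix(y, ncol = 1))
  expect_equal(m$auc_roc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc_pr, 1)
  m2 <- evaluate_predictions(matrix(rep(0.7, 10), ncol = 1,
                                    dimnames = list(NULL, "GCGR")),
                             matrix(y, ncol = 1))
  expect_equal(m2$auc_roc, 0.5)
  m3 <- evaluate_predictions(matrix(runif(5), ncol = 1,
                                    dimnames = list(NULL, "GCGR")),
                             matrix(rep(1, 5), ncol = 1))
  expect_true(is.na(m3$auc_roc))
})

test_that("auc agrees with an established implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60)
  m <- evaluate_predictions(matrix(s, ncol = 1,
                                   dimnames = list(NULL, "GCGR")),
                            matrix(y, ncol = 1))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(m$auc_roc, ref, tolerance = 1e-9)
})

test_that("ensembles average probabilities and check fingerprints", {
  ns <- fit_norm_stats(lapply(c("HSQGTFTSDY", "ACDEFGHIK"), pep_tokenize))
  m1 <- gat_init(tiny_gat_config(), ns, seed = 1)
  m2 <- gat_init(tiny_gat_config(), ns, seed = 2)
  single <- predict(m1, "ACDEFGH")
  ens_same <- ensemble_predict(list(m1, m1), "ACDEFGH")
  expect_equal(as.matrix(ens_same[, -1]), as.matrix(single[, -1]))
  ens <- ensemble_predict(list(m1, m2), "ACDEFGH")
  by_hand <- (as.matrix(predict(m1, "ACDEFGH")[, -1]) +
                as.matrix(predict(m2, "ACDEFGH")[, -1])) / 2
  expect_equal(as.matrix(ens[, -1]), by_hand)
  ns2 <- fit_norm_stats(lapply(c("WWWWW", "PPPPP"), pep_tokenize))
  m3 <- gat_init(tiny_gat_config(), ns2, seed = 1)
  expect_error(ensemble_predict(list(m1, m3), "ACDEF"), "statistics")
})

test_that("similarity filtering removes exact matches and flags novelty", {
  train <- toy_records(c("ACDEFGHIKL", "WWWWWWWWWW", "PPPPPPPPPP"))
  val <- toy_records(c("ACDEFGHIKL", "ACWWWWWWWW", "KKKKKKKKKK"),
                     ids = c("v1", "v2", "v3"))
  expect_message(
    out <- similarity_filter(val, train),
    "exact"
  )
  expect_equal(nrow(out$full), 2)       # exact match removed
  expect_false("v1" %in% out$full$id)
  expect_equal(out$similarity$max_similarity[1], 1)
  expect_equal(out$similarity$best_match_id[1], "P01")
  # brute-force check of the reported similarities
  for (i in 1:3) {
    sims <- vapply(train$tokens, function(tt) {
      1 - dp_levenshtein(val$tokens[[i]], tt) /
        max(length(val$tokens[[i]]), length(tt))
    }, numeric(1))
    expect_equal(out$similarity$max_similarity[i], max(sims))
  }
  # novel subset = similarity <= 0.8
  expect_true(all(out$similarity$max_similarity[
    out$similarity$id %in% out$novel$id] <= 0.8))
})

test_that("transfer learning freezes the encoder bit-exactly in stage 2", {
  ds <- generate_dataset(synth_config(n_sequences = 48, seed = 4,
                                      nsaa_prob = 0))
  rec <- ds$records
  tc <- train_config(stage1_epochs = 3L, stage2_epochs = 3L,
                     stage3_epochs = 2L, batch_size = 16L, seed = 2)
  fit <- run_transfer_learning(rec[1:36, ], rec[37:48, ],
                               tiny_gat_config(), tc)
  groups <- triagonist:::param_groups(fit)
  s1 <- fit$stage_snapshots$stage1
  s2 <- fit$stage_snapshots$stage2
  for (nm in groups$encoder) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  for (nm in groups$GCGR) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  # the GIPR head did train in stage 2
  expect_false(identical(s1[["head_GIPR_W1"]], s2[["head_GIPR_W1"]]))
  # per-stage logs exist and early stopping never returns a loss above the
  # best seen
  for (st in names(fit$history)) {
    log <- fit$history[[st]]
    expect_true(all(min(log[, 2]) <= log[, 2]))
  }
})

test_that("stage-1 training reduces the training loss", {
  ds <- generate_dataset(synth_config(n_sequences = 40, seed = 9,
                                      nsaa_prob = 0))
  rec <- ds$records
  tc <- train_config(stage1_epochs = 12L, stage2_epochs = 1L,
                     stage3_epochs = 1L, batch_size = 20L, seed = 3)
  fit <- run_transfer_learning(rec[1:30, ], rec[31:40, ],
                               tiny_gat_config(), tc)
  log <- fit$history$stage1
  expect_lt(log[nrow(log), 1], log[1, 1])
})
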