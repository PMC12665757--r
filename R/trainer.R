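# Training protocol: three-stage transfer learning with Adam, gradient
# clipping and per-stage early stopping; stratified k-fold cross-validation
# over multi-receptor activity patterns; masked multi-label metrics.

#' Training configuration
#'
#' @param stage1_epochs,stage2_epochs,stage3_epochs Epoch budgets: stage 1
#'   trains the encoder and the GCGR/GLP1R heads on records labelled for
#'   either receptor; stage 2 freezes the encoder and trains only the GIPR
#'   head on GIPR-labelled records; stage 3 fine-tunes everything at a
#'   reduced learning rate.
#' @param lr_stage12,lr_stage3 Adam learning rates.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement), applied per stage.
#' @param grad_clip_norm Global gradient-norm clip.
#' @param k_folds Cross-validation folds.
#' @param inner_split Fraction of training data used for fitting inside each
#'   fold (the rest monitors early stopping).
#' @param batch_size Minibatch size.
#' @param warmup_steps Optimizer steps over which the learning rate ramps
#'   linearly from zero (stabilizes the attention/batch-norm cold start).
#' @param seed Integer seed controlling shuffling, dropout and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(stage1_epochs = 80L, stage2_epochs = 100L,
                         stage3_epochs = 60L, lr_stage12 = 1e-3,
                         lr_stage3 = 1e-4, patience = 15L,
                         grad_clip_norm = 1.0, k_folds = 5L,
                         inner_split = 0.8, batch_size = 32L,
                         warmup_steps = 30L, seed = 1L) {
  stopifnot(stage1_epochs > 0, stage2_epochs > 0, stage3_epochs > 0,
            inner_split > 0, inner_split < 1)
  structure(as.list(environment()), class = "train_config")
}

# --- stratification --------------------------------------------------------

#' Stratification key of a record
#'
#' Concatenates the per-receptor activity state (1, 0 or `m` for missing)
#' into keys like `"1|0|m"`, giving 27 possible strata for three receptors.
#'
#' @param records Activity tibble.
#' @return Character vector of keys.
#' @export
make_strat_key <- function(records) {
  cols <- paste0("label_", RECEPTORS)
  apply(records[, cols], 1, function(x) {
    paste(ifelse(is.na(x), "m", x), collapse = "|")
  })
}

#' Stratified k-fold assignment
#'
#' Members of each stratification key are dealt round-robin (after
#' shuffling, with a random starting fold per key) so per-key counts differ
#' by at most one across folds; keys rarer than `k` are spread the same way.
#'
#' @param records Activity tibble.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k).
#' @export
stratified_kfold <- function(records, k = 5L, seed = 1L) {
  n <- nrow(records)
  if (n < k) stop("need at least k records", call. = FALSE)
  set.seed(seed)
  keys <- make_strat_key(records)
  fold <- integer(n)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    idx <- idx[sample.int(length(idx))]  # sample(x) on a scalar is a range
    start <- sample.int(k, 1)
    fold[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1
  }
  fold
}

# Stratified inner train/monitor split, same keys as the outer folds
inner_split_idx <- function(records, frac, seed) {
  set.seed(seed)
  keys <- make_strat_key(records)
  train_idx <- integer(0)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    idx <- idx[sample.int(length(idx))]
    n_tr <- max(1L, round(frac * length(idx)))
    train_idx <- c(train_idx, idx[seq_len(n_tr)])
  }
  # rare strata can swallow every record; keep at least one for monitoring
  if (length(train_idx) >= nrow(records)) {
    train_idx <- train_idx[-length(train_idx)]
  }
  sort(train_idx)
}

# --- optimizer -------------------------------------------------------------

adam_new <- function(params, trainable) {
  list(m = lapply(params[trainable], function(x) x * 0),
       v = lapply(params[trainable], function(x) x * 0),
       t = 0L)
}

deep_copy <- function(params) lapply(params, function(x) x + 0)

# In-place Adam step over the trainable tensors (C++ kernel); `params`,
# and the optimizer moment buffers are modified directly, so callers hold
# unshared copies.
adam_step <- function(params, grads, state, trainable, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 1.0) {
  state$t <- state$t + 1L
  adam_step_cpp(params, grads, state$m, state$v, trainable, lr, beta1,
                beta2, eps, clip_norm, state$t)
  list(params = params, state = state)
}

# --- stage runner ----------------------------------------------------------

label_matrix <- function(records) {
  m <- as.matrix(records[, paste0("label_", RECEPTORS)])
  colnames(m) <- RECEPTORS
  m
}

eval_loss <- function(model, graphs, labels, weights, cfg) {
  batch <- batch_graphs(graphs)
  out <- gat_forward(model, batch, active = names(weights)[weights > 0])
  suppressWarnings(
    multitask_loss(out$probs, labels, weights, cfg$focal_alpha,
                   cfg$focal_gamma)$loss
  )
}

run_stage <- function(model, graphs, labels, val_graphs, val_labels,
                      sample_idx, weights, training_flags, trainable,
                      lr, epochs, tc) {
  cfg <- model$config
  if (length(sample_idx) == 0) return(list(model = model, log = NULL))
  # the optimizer updates parameter buffers in place: give this stage its
  # own copies so caller-held snapshots stay untouched
  model$params <- deep_copy(model$params)
  opt <- adam_new(model$params, trainable)
  active <- names(weights)[weights > 0]
  best <- list(loss = Inf, params = deep_copy(model$params), bn = model$bn)
  wait <- 0L
  log <- list()
  for (epoch in seq_len(epochs)) {
    idx <- sample_idx[sample.int(length(sample_idx))]
    splits <- split(idx, ceiling(seq_along(idx) / tc$batch_size))
    if (length(splits) > 1 && length(splits[[length(splits)]]) < 2) {
      # avoid a size-1 batch (degenerate batch-norm statistics)
      splits[[length(splits) - 1]] <-
        c(splits[[length(splits) - 1]], splits[[length(splits)]])
      splits[[length(splits)]] <- NULL
    }
    epoch_loss <- 0
    for (b in splits) {
      batch <- batch_graphs(graphs[b])
      out <- gat_forward(model, batch, training_flags, active = active)
      model <- out$model  # batch-norm running stats
      ml <- suppressWarnings(
        multitask_loss(out$probs, labels[b, , drop = FALSE], weights,
                       cfg$focal_alpha, cfg$focal_gamma)
      )
      epoch_loss <- epoch_loss + ml$loss * length(b)
      grads <- gat_backward(model, batch, out$cache, ml$grad_logits)
      wu <- if (tc$warmup_steps > 0) min(1, (opt$t + 1) / tc$warmup_steps) else 1
      upd <- adam_step(model$params, grads, opt, trainable, lr * wu,
                       clip_norm = tc$grad_clip_norm)
      model$params <- upd$params
      opt <- upd$state
    }
    vl <- eval_loss(model, val_graphs, val_labels, weights, cfg)
    log[[epoch]] <- c(train = unname(epoch_loss) / length(idx),
                      val = unname(vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = deep_copy(model$params), bn = model$bn)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, log = do.call(rbind, log), best_val = best$loss)
}

#' Three-stage transfer learning
#'
#' Stage 1 trains the shared encoder with the GCGR and GLP1R heads on all
#' records labelled for either receptor. Stage 2 freezes every encoder
#' parameter and trains only the GIPR head on GIPR-labelled records (the
#' frozen modules also run in evaluation mode, so their batch-norm state is
#' untouched). Stage 3 unfreezes everything and fine-tunes at a reduced
#' learning rate on all tasks. Each stage early-stops on validation loss and
#' restores its best weights.
#'
#' @param train_records,val_records Activity tibbles (validation monitors
#'   early stopping).
#' @param model_config A [gat_config()].
#' @param tc A [train_config()].
#' @param stats Optional pre-fitted [fit_norm_stats()]; default fits on
#'   `train_records`.
#' @param overrides Optional NSAA override tibble.
#' @return A trained `gat_model` with a `history` element (per-stage loss
#'   logs) and `stage_snapshots` (parameter snapshots at each stage end).
#' @export
run_transfer_learning <- function(train_records, val_records,
                                  model_config = gat_config(),
                                  tc = train_config(), stats = NULL,
                                  overrides = NULL) {
  set.seed(tc$seed)
  if (is.null(stats)) stats <- fit_norm_stats(train_records, overrides)
  model <- gat_init(model_config, stats, seed = tc$seed)
  graphs <- lapply(train_records$tokens, build_graph, stats = stats,
                   overrides = overrides)
  val_graphs <- lapply(val_records$tokens, build_graph, stats = stats,
                       overrides = overrides)
  labels <- label_matrix(train_records)
  val_labels <- label_matrix(val_records)
  groups <- param_groups(model)
  rs <- model_config$receptors
  w <- model_config$task_weight
  has_gipr <- sum(!is.na(labels[, "GIPR"])) > 0
  history <- list()
  snapshots <- list()

  # stage 1: encoder + GCGR/GLP1R heads on records with either label
  idx1 <- which(!is.na(labels[, "GCGR"]) | !is.na(labels[, "GLP1R"]))
  st1 <- run_stage(
    model, graphs, labels, val_graphs, val_labels, idx1,
    weights = c(GCGR = w, GLP1R = w, GIPR = 0),
    training_flags = list(encoder = TRUE,
                          heads = c(GCGR = TRUE, GLP1R = TRUE, GIPR = FALSE)),
    trainable = c(groups$encoder, groups$GCGR, groups$GLP1R),
    lr = tc$lr_stage12, epochs = tc$stage1_epochs, tc = tc
  )
  model <- st1$model
  history$stage1 <- st1$log
  snapshots$stage1 <- model$params

  # stage 2: frozen encoder, GIPR head only
  if (has_gipr) {
    idx2 <- which(!is.na(labels[, "GIPR"]))
    st2 <- run_stage(
      model, graphs, labels, val_graphs, val_labels, idx2,
      weights = c(GCGR = 0, GLP1R = 0, GIPR = 1),
      training_flags = list(encoder = FALSE,
                            heads = c(GCGR = FALSE, GLP1R = FALSE, GIPR = TRUE)),
      trainable = groups$GIPR,
      lr = tc$lr_stage12, epochs = tc$stage2_epochs, tc = tc
    )
    model <- st2$model
    history$stage2 <- st2$log
  } else {
    warning("no GIPR-labelled records; stage 2 skipped", call. = FALSE)
  }
  snapshots$stage2 <- model$params

  # stage 3: unified fine-tuning, all tasks, reduced learning rate
  idx3 <- which(rowSums(!is.na(labels)) > 0)
  gipr_w <- if (has_gipr) w else 0
  st3 <- run_stage(
    model, graphs, labels, val_graphs, val_labels, idx3,
    weights = c(GCGR = w, GLP1R = w, GIPR = gipr_w),
    training_flags = list(encoder = TRUE,
                          heads = c(GCGR = TRUE, GLP1R = TRUE, GIPR = has_gipr)),
    trainable = unlist(groups, use.names = FALSE),
    lr = tc$lr_stage3, epochs = tc$stage3_epochs, tc = tc
  )
  model <- st3$model
  history$stage3 <- st3$log

  model$history <- history
  model$stage_snapshots <- snapshots
  model
}

# --- metrics ---------------------------------------------------------------

metric_row <- function(scores, y) {
  keep <- !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- auc_pr <- NA_real_
  if (n1 > 0 && n0 > 0) {
    # Mann-Whitney form (ties counted half)
    r <- rank(scores)
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # average-precision integration of the PR curve
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]
    tp <- cumsum(ys)
    prec <- tp / seq_along(ys)
    auc_pr <- sum(prec[ys == 1]) / n1
  }
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (n1 > 0) tp / n1 else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  spec <- if (n0 > 0) tn / n0 else NA_real_
  bal_acc <- mean(c(recall, spec))
  tibble::tibble(auc_roc = auc, auc_pr = auc_pr, f1 = f1,
                 precision = precision, recall = recall,
                 balanced_accuracy = bal_acc, n_pos = n1, n_neg = n0)
}

#' Classification metrics per receptor
#'
#' AUC-ROC via the Mann-Whitney statistic, AUC-PR by average-precision
#' integration, and threshold-0.5 class metrics (F1, precision, recall,
#' balanced accuracy). Missing labels are excluded; single-class receptors
#' report `NA` AUCs.
#'
#' @param probs n x R probability matrix (columns = receptors).
#' @param labels n x R matrix of 1/0/`NA`.
#' @return Tibble with one row per receptor.
#' @export
evaluate_predictions <- function(probs, labels) {
  rows <- lapply(seq_len(ncol(probs)), function(r) {
    dplyr::bind_cols(tibble::tibble(receptor = colnames(probs)[r]),
                     metric_row(probs[, r], labels[, r]))
  })
  dplyr::bind_rows(rows)
}

#' Ensemble prediction across fold models
#'
#' Arithmetic mean of per-model sigmoid probabilities. By default the models
#' must carry identical normalization statistics; cross-validation fold
#' models legitimately differ (each fold refits its statistics and each
#' model normalizes its own inputs), so `check_stats = FALSE` permits them.
#'
#' @param models List of `gat_model`s.
#' @param newdata Sequences (see [predict.gat_model()]).
#' @param check_stats Require identical normalization statistics.
#' @return Tibble of averaged probabilities.
#' @export
ensemble_predict <- function(models, newdata, check_stats = TRUE) {
  stopifnot(length(models) >= 1)
  fps <- vapply(models, `[[`, character(1), "fingerprint")
  if (check_stats && length(unique(fps)) != 1) {
    stop("fold models carry different normalization statistics", call. = FALSE)
  }
  preds <- lapply(models, predict, newdata = newdata)
  probs <- Reduce(`+`, lapply(preds, function(p) {
    as.matrix(p[, paste0("prob_", RECEPTORS)])
  })) / length(models)
  dplyr::bind_cols(preds[[1]]["sequence"], tibble::as_tibble(probs))
}

#' Similarity-based validation filtering
#'
#' Computes each validation record's maximum token-level similarity to any
#' training sequence, removes exact matches, and splits off the novel subset
#' (maximum similarity at or below `threshold`).
#'
#' @param validation_records,training_records Activity tibbles.
#' @param threshold Novelty cut-off on similarity.
#' @return List: `novel` (tibble), `full` (exact matches removed),
#'   `similarity` (per-record `id`, `max_similarity`, `best_match_id`).
#' @export
similarity_filter <- function(validation_records, training_records,
                              threshold = 0.8) {
  stopifnot(nrow(validation_records) > 0, nrow(training_records) > 0)
  sims <- purrr::map(validation_records$tokens, similarity_to_set,
                     set_tokens = training_records$tokens)
  max_sim <- vapply(sims, max, numeric(1))
  best <- vapply(sims, which.max, integer(1))
  sim_tbl <- tibble::tibble(
    id = validation_records$id,
    max_similarity = max_sim,
    best_match_id = training_records$id[best]
  )
  keep <- max_sim < 1
  if (any(!keep)) {
    message(sum(!keep), " validation sequence(s) removed as exact training matches")
  }
  full <- validation_records[keep, ]
  novel <- validation_records[keep & max_sim <= threshold, ]
  if (nrow(novel) == 0) message("no novel sequences below similarity threshold")
  list(novel = novel, full = full, similarity = sim_tbl)
}

# --- cross-validation ------------------------------------------------------

#' Stratified k-fold cross-validation of the transfer-learning protocol
#'
#' Each fold trains a full three-stage model on the remaining folds (with an
#' inner stratified split for early stopping) and is evaluated on the
#' held-out fold. Normalization statistics are refitted on each fold's
#' training portion.
#'
#' @param records Activity tibble.
#' @param model_config A [gat_config()].
#' @param tc A [train_config()].
#' @param overrides Optional NSAA override tibble.
#' @param keep_models Keep the fold models (needed for ensembling).
#' @return A `gat_cv` object: per-fold metric tibble, fold assignment, and
#'   optionally the models.
#' @export
crossval <- function(records, model_config = gat_config(),
                     tc = train_config(), overrides = NULL,
                     keep_models = TRUE) {
  fold <- stratified_kfold(records, tc$k_folds, tc$seed)
  metrics <- list()
  models <- list()
  for (f in seq_len(tc$k_folds)) {
    tr <- records[fold != f, ]
    te <- records[fold == f, ]
    ii <- inner_split_idx(tr, tc$inner_split, tc$seed + f)
    fit <- run_transfer_learning(tr[ii, ], tr[-ii, ], model_config, tc,
                                 overrides = overrides)
    pr <- predict(fit, te)
    m <- evaluate_predictions(as.matrix(pr[, paste0("prob_", RECEPTORS)]) |>
                                `colnames<-`(RECEPTORS),
                              label_matrix(te))
    metrics[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), m)
    if (keep_models) models[[f]] <- fit
  }
  structure(list(metrics = dplyr::bind_rows(metrics), fold = fold,
                 models = if (keep_models) models,
                 config = model_config, tc = tc),
            class = "gat_cv")
}

#' @export
print.gat_cv <- function(x, ...) {
  cat("<gat_cv>", x$tc$k_folds, "folds\n")
  print(glance(x))
  invisible(x)
}

# --- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint directory
#'
#' The directory holds the configuration as JSON, the weights and batch-norm
#' state as an RDS, and the normalization-statistics fingerprint as plain
#' text. Loading verifies the fingerprint and refuses mismatched weights.
#'
#' @param model A `gat_model`.
#' @param dir Checkpoint directory (created if needed).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(params = model$params, bn = model$bn, stats = model$stats),
          file.path(dir, "weights.rds"))
  writeLines(model$fingerprint, file.path(dir, "stats_fingerprint.txt"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$receptors <- as.character(cfg$receptors)
  cfg <- do.call(gat_config, cfg[setdiff(names(cfg), "in_dim")])
  w <- readRDS(file.path(dir, "weights.rds"))
  fp <- readLines(file.path(dir, "stats_fingerprint.txt"))
  if (!identical(fp, stats_fingerprint(w$stats))) {
    stop("checkpoint statistics fingerprint mismatch", call. = FALSE)
  }
  model <- gat_init(cfg, w$stats, seed = 0L)
  model$params <- w$params
  model$bn <- w$bn
  model
}
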