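make_tiny_model <- function(seed = 3) {
  ns <- fit_norm_stats(lapply(c("HSQGTFTSDY", "ACDEFGHIK", "YYYWWW"),
                              pep_tokenize))
  list(ns = ns, model = gat_init(tiny_gat_config(), ns, seed = seed))
}

test_that("configuration is validated", {
  expect_error(gat_config(hidden_dim = 95L, n_heads = 6L), "divisible")
  expect_error(gat_config(dropout = 1), "dropout")
  cfg <- gat_config()
  expect_equal(cfg$n_layers, 4L)
  expect_equal(cfg$hidden_dim, 96L)
  expect_equal(cfg$set2set_steps, 3L)
})

test_that("initialization is seed-deterministic", {
  tm1 <- make_tiny_model(seed = 5)
  tm2 <- make_tiny_model(seed = 5)
  expect_identical(tm1$model$params, tm2$model$params)
  tm3 <- make_tiny_model(seed = 6)
  expect_equal(sum(vapply(tm1$model$params, length, integer(1))),
               sum(vapply(tm3$model$params, length, integer(1))))
  expect_false(identical(tm1$model$params$rep_W, tm3$model$params$rep_W))
})

test_that("forward pass yields finite probabilities, even for 1-node graphs", {
  tm <- make_tiny_model()
  pr <- predict(tm$model, c("A", "HSQGTFTSDY"))
  expect_true(all(is.finite(as.matrix(pr[, -1]))))
  expect_true(all(as.matrix(pr[, -1]) > 0 & as.matrix(pr[, -1]) < 1))
})

test_that("graph-level logits are invariant to node relabelling", {
  tm <- make_tiny_model()
  g <- build_graph("ACDEFGHIK", tm$ns)
  b1 <- triagonist:::batch_graphs(list(g))
  out1 <- triagonist:::gat_forward(tm$model, b1)
  perm <- sample(9)
  inv <- order(perm)
  b2 <- b1
  b2$X <- b1$X[inv, ]
  b2$src <- perm[b1$src]
  b2$dst <- perm[b1$dst]
  out2 <- triagonist:::gat_forward(tm$model, b2)
  expect_equal(out1$logits, out2$logits, tolerance = 1e-5)
})

test_that("analytic gradients match finite differences everywhere", {
  tm <- make_tiny_model()
  graphs <- lapply(c("HSQGTFTSDY", "ACDEFGHIK", "YYYWWW"), build_graph,
                   stats = tm$ns)
  batch <- triagonist:::batch_graphs(graphs)
  labels <- matrix(c(1, 0, NA, 0, 1, 1, 1, NA, 0), 3, 3, byrow = TRUE,
                   dimnames = list(NULL, RECEPTORS))
  flags <- list(encoder = TRUE,
                heads = c(GCGR = TRUE, GLP1R = TRUE, GIPR = TRUE))
  loss_fn <- function(m) {
    out <- triagonist:::gat_forward(m, batch, flags)
    multitask_loss(out$probs, labels, c(0.5, 0.5, 0.5))$loss
  }
  model <- tm$model
  out <- triagonist:::gat_forward(model, batch, flags)
  ml <- multitask_loss(out$probs, labels, c(0.5, 0.5, 0.5))
  grads <- triagonist:::gat_backward(model, batch, out$cache, ml$grad_logits)
  set.seed(9)
  eps <- 1e-6
  for (nm in names(model$params)) {
    ks <- sample(length(model$params[[nm]]),
                 min(3, length(model$params[[nm]])))
    for (k in ks) {
      m2 <- model; m2$params[[nm]][k] <- m2$params[[nm]][k] + eps
      m3 <- model; m3$params[[nm]][k] <- m3$params[[nm]][k] - eps
      fd <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      expect_lt(abs(fd - as.numeric(grads[[nm]])[k]), 1e-6)
    }
  }
})

test_that("evaluation-mode forward is deterministic", {
  tm <- make_tiny_model()
  p1 <- predict(tm$model, "HSQGTFTSDY")
  p2 <- predict(tm$model, "HSQGTFTSDY")
  expect_identical(p1, p2)
})

test_that("loss decreases on a 10-graph overfit problem", {
  set.seed(2)
  seqs <- vapply(1:10, function(i) {
    pep_detokenize(random_tokens(12, nsaa_prob = 0))
  }, character(1))
  toks <- lapply(seqs, pep_tokenize)
  ns <- fit_norm_stats(toks)
  model <- gat_init(tiny_gat_config(), ns, seed = 1)
  graphs <- lapply(toks, build_graph, stats = ns)
  batch <- triagonist:::batch_graphs(graphs)
  labels <- matrix(rep(c(1, 0), 15), 10, 3, dimnames = list(NULL, RECEPTORS))
  flags <- list(encoder = TRUE,
                heads = c(GCGR = TRUE, GLP1R = TRUE, GIPR = TRUE))
  opt <- triagonist:::adam_new(model$params, names(model$params))
  losses <- numeric(50)
  for (i in 1:50) {
    out <- triagonist:::gat_forward(model, batch, flags)
    model <- out$model
    ml <- multitask_loss(out$probs, labels, c(0.5, 0.5, 0.5))
    losses[i] <- ml$loss
    g <- triagonist:::gat_backward(model, batch, out$cache, ml$grad_logits)
    upd <- triagonist:::adam_step(model$params, g, opt, names(model$params),
                                  1e-3)
    model$params <- upd$params
    opt <- upd$state
  }
  expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
})

test_that("checkpoints round-trip and verify the stats fingerprint", {
  tm <- make_tiny_model()
  dir <- withr::local_tempdir()
  save_checkpoint(tm$model, dir)
  back <- load_checkpoint(dir)
  expect_equal(back$params, tm$model$params)
  p1 <- predict(tm$model, "ACDEF")
  p2 <- predict(back, "ACDEF")
  expect_equal(p1, p2)
  # corrupt the fingerprint
  writeLines("0|0|0|0|0|0", file.path(dir, "stats_fingerprint.txt"))
  expect_error(load_checkpoint(dir), "fingerprint")
})
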