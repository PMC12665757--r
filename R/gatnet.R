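# Multi-task graph-attention classifier.
#
# Architecture: four GATv2-style multi-head attention layers (ReLU, batch
# normalization, dropout after each; identity residual connections after
# layers 2 and 4), a Set2Set readout (LSTM-driven attention pooling, three
# processing steps, output 2 x hidden), a representation layer (linear
# 2h -> h, ReLU, batch norm, dropout) and three task heads (h -> 48 -> 24 ->
# 1 with ReLU/batch norm/dropout between layers) ending in one logit per
# receptor. Implemented in vectorized base R with an explicit backward pass;
# gradients are verified against finite differences in the test suite.

# fast column-wise scale/shift (avoids sweep's aperm copies)
colscale <- function(x, v) x * rep(v, each = nrow(x))
colshift <- function(x, v) x + rep(v, each = nrow(x))
lrelu_mask <- function(x) LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LRELU_SLOPE <- 0.2
ATT_CLAMP <- 50

#' Model configuration
#'
#' Hyperparameters of the graph-attention classifier. `hidden_dim` must be
#' divisible by `n_heads` (heads are concatenated).
#'
#' @param n_layers Number of attention layers.
#' @param n_heads Attention heads per layer.
#' @param hidden_dim Hidden width (concatenated across heads).
#' @param dropout Dropout probability in \[0, 1).
#' @param set2set_steps Processing steps of the Set2Set readout.
#' @param head_dims Widths of the task-head hidden layers.
#' @param receptors Task names.
#' @param task_weight Per-task loss weight for active receptors.
#' @param focal_alpha,focal_gamma Focal-loss parameters (`focal_gamma = 0`,
#'   `focal_alpha = 0.5` reduces the per-sample term to 0.5 x binary
#'   cross-entropy).
#' @return A `gat_config` list.
#' @export
gat_config <- function(n_layers = 4L, n_heads = 6L, hidden_dim = 96L,
                       dropout = 0.2, set2set_steps = 3L,
                       head_dims = c(48L, 24L), receptors = RECEPTORS,
                       task_weight = 0.5, focal_alpha = 0.25,
                       focal_gamma = 2.0) {
  if (hidden_dim %% n_heads != 0) {
    stop("hidden_dim must be divisible by n_heads", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    hidden_dim = as.integer(hidden_dim), dropout = dropout,
    set2set_steps = as.integer(set2set_steps),
    head_dims = as.integer(head_dims), receptors = receptors,
    task_weight = task_weight, focal_alpha = focal_alpha,
    focal_gamma = focal_gamma, in_dim = 7L
  ), class = "gat_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize a graph-attention model
#'
#' @param config A [gat_config()].
#' @param stats Fitted [fit_norm_stats()] statistics (frozen into the model;
#'   prediction refuses inputs normalized with different statistics).
#' @param seed Integer seed for weight initialization.
#' @return A `gat_model` object.
#' @export
gat_init <- function(config, stats, seed = 1L) {
  set.seed(seed)
  h <- config$hidden_dim
  p <- list()
  bn <- list()
  new_bn <- function(dim) list(mean = rep(0, dim), var = rep(1, dim))
  in_dim <- config$in_dim
  for (l in seq_len(config$n_layers)) {
    p[[paste0("gat", l, "_Wsrc")]] <- glorot(in_dim, h)
    p[[paste0("gat", l, "_Wdst")]] <- glorot(in_dim, h)
    p[[paste0("gat", l, "_att")]] <- stats::runif(h, -0.1, 0.1)
    p[[paste0("gat", l, "_bias")]] <- rep(0, h)
    p[[paste0("bn_gat", l, "_gamma")]] <- rep(1, h)
    p[[paste0("bn_gat", l, "_beta")]] <- rep(0, h)
    bn[[paste0("bn_gat", l)]] <- new_bn(h)
    in_dim <- h
  }
  p$lstm_Wi <- glorot(2L * h, 4L * h)
  p$lstm_Wh <- glorot(h, 4L * h)
  p$lstm_b <- rep(0, 4L * h)
  p$rep_W <- glorot(2L * h, h)
  p$rep_b <- rep(0, h)
  p$bn_rep_gamma <- rep(1, h)
  p$bn_rep_beta <- rep(0, h)
  bn$bn_rep <- new_bn(h)
  dims <- c(h, config$head_dims, 1L)
  for (r in config$receptors) {
    for (k in seq_len(length(dims) - 1L)) {
      p[[paste0("head_", r, "_W", k)]] <- glorot(dims[k], dims[k + 1])
      p[[paste0("head_", r, "_b", k)]] <- rep(0, dims[k + 1])
      if (k < length(dims) - 1L) {
        p[[paste0("bn_head_", r, "_", k, "_gamma")]] <- rep(1, dims[k + 1])
        p[[paste0("bn_head_", r, "_", k, "_beta")]] <- rep(0, dims[k + 1])
        bn[[paste0("bn_head_", r, "_", k)]] <- new_bn(dims[k + 1])
      }
    }
  }
  structure(list(config = config, params = p, bn = bn, stats = stats,
                 fingerprint = stats_fingerprint(stats)),
            class = "gat_model")
}

#' @export
print.gat_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("<gat_model>", x$config$n_layers, "attention layers,",
      x$config$n_heads, "heads, hidden", x$config$hidden_dim,
      "|", n_par, "parameters\n")
  invisible(x)
}

# Parameter names grouped by module (used for stage-wise freezing)
param_groups <- function(model) {
  nm <- names(model$params)
  enc <- nm[grepl("^(gat|bn_gat|lstm|rep_|bn_rep)", nm)]
  heads <- lapply(model$config$receptors, function(r) {
    nm[grepl(paste0("^(head_", r, "_|bn_head_", r, "_)"), nm)]
  })
  names(heads) <- model$config$receptors
  c(list(encoder = enc), heads)
}

# --- layer primitives ------------------------------------------------------

bn_forward <- function(x, gamma, beta, running, training) {
  if (training) {
    o <- bn_fwd_train_cpp(x, gamma, beta, BN_EPS)
    n <- nrow(x)
    v <- as.numeric(o$var)
    unb <- if (n > 1) v * n / (n - 1) else v
    new_running <- list(
      mean = (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * as.numeric(o$mu),
      var = (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * unb
    )
    list(y = o$y, cache = list(xhat = o$xhat, inv = as.numeric(o$inv),
                               gamma = gamma, training = TRUE),
         running = new_running)
  } else {
    o <- bn_fwd_eval_cpp(x, gamma, beta, running$mean, running$var, BN_EPS)
    list(y = o$y, cache = list(xhat = o$xhat, inv = as.numeric(o$inv),
                               gamma = gamma, training = FALSE),
         running = running)
  }
}

bn_backward <- function(dy, cache) {
  o <- bn_bwd_cpp(dy, cache$xhat, cache$inv, cache$gamma, cache$training)
  list(dx = o$dx, dgamma = as.numeric(o$dgamma), dbeta = as.numeric(o$dbeta))
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x))
  list(y = x * mask, mask = mask)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- GATv2 attention layer -------------------------------------------------

gat_layer_forward <- function(X, src, dst, Wsrc, Wdst, att, bias, n_heads) {
  out <- gat_layer_fwd_cpp(X, src - 1L, dst - 1L, Wsrc, Wdst, att, bias,
                           n_heads)
  list(y = out$y,
       cache = list(X = X, src = src, dst = dst, Wsrc = Wsrc, Wdst = Wdst,
                    att = att, GsT = out$GsT, SmaskT = out$SmaskT,
                    ZT = out$ZT, LgT = out$LgT, AT = out$AT,
                    n_heads = n_heads))
}

gat_layer_backward <- function(dOut, cache) {
  g <- gat_layer_bwd_cpp(dOut, cache$X, cache$src - 1L, cache$dst - 1L,
                         cache$Wsrc, cache$Wdst, cache$att, cache$GsT,
                         cache$SmaskT, cache$ZT, cache$LgT, cache$AT,
                         cache$n_heads)
  list(dX = g$dX, dWsrc = g$dWsrc, dWdst = g$dWdst, datt = as.numeric(g$datt),
       dbias = as.numeric(g$dbias))
}

# --- Set2Set readout -------------------------------------------------------

set2set_forward <- function(M, graph_id, n_graphs, Wi, Wh, b, steps) {
  h <- ncol(M)
  B <- n_graphs
  qstar <- matrix(0, B, 2L * h)
  hs <- matrix(0, B, h)
  cs <- matrix(0, B, h)
  step_caches <- vector("list", steps)
  for (t in seq_len(steps)) {
    zpre <- colshift(qstar %*% Wi + hs %*% Wh, b)
    ig <- sigmoid(zpre[, 1:h, drop = FALSE])
    fg <- sigmoid(zpre[, (h + 1):(2 * h), drop = FALSE])
    gg <- tanh(zpre[, (2 * h + 1):(3 * h), drop = FALSE])
    og <- sigmoid(zpre[, (3 * h + 1):(4 * h), drop = FALSE])
    c_new <- fg * cs + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    q <- h_new
    at <- s2s_attend_cpp(M, graph_id - 1L, q, B)
    alpha <- as.numeric(at$alpha)
    r <- at$r
    step_caches[[t]] <- list(qstar_prev = qstar, h_prev = hs, c_prev = cs,
                             ig = ig, fg = fg, gg = gg, og = og,
                             c_new = c_new, tc = tc, q = q,
                             alpha = alpha)
    qstar <- cbind(q, r)
    hs <- h_new
    cs <- c_new
  }
  list(y = qstar, cache = list(M = M, graph_id = graph_id, steps = steps,
                               step_caches = step_caches, Wi = Wi, Wh = Wh))
}

set2set_backward <- function(dqstar, cache) {
  M <- cache$M
  gid <- cache$graph_id
  h <- ncol(M)
  Wi <- cache$Wi; Wh <- cache$Wh
  dM <- matrix(0, nrow(M), h)
  dWi <- matrix(0, nrow(Wi), ncol(Wi))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4L * h)
  dh_next <- matrix(0, nrow(dqstar), h)
  dc_next <- matrix(0, nrow(dqstar), h)
  for (t in rev(seq_len(cache$steps))) {
    sc <- cache$step_caches[[t]]
    dq <- dqstar[, 1:h, drop = FALSE]
    dr <- dqstar[, (h + 1):(2 * h), drop = FALSE]
    ab <- s2s_attend_bwd_cpp(M, gid - 1L, sc$q, sc$alpha, dr,
                             nrow(dqstar))
    dM <- dM + ab$dM
    dh <- dq + ab$dq + dh_next
    # LSTM cell backward
    do <- dh * sc$tc
    dc <- dh * sc$og * (1 - sc$tc^2) + dc_next
    df <- dc * sc$c_prev
    di <- dc * sc$gg
    dg <- dc * sc$ig
    dc_next <- dc * sc$fg
    dz <- cbind(di * sc$ig * (1 - sc$ig),
                df * sc$fg * (1 - sc$fg),
                dg * (1 - sc$gg^2),
                do * sc$og * (1 - sc$og))
    dWi <- dWi + crossprod(sc$qstar_prev, dz)
    dWh <- dWh + crossprod(sc$h_prev, dz)
    db <- db + colSums(dz)
    dqstar <- dz %*% t(Wi)
    dh_next <- dz %*% t(Wh)
  }
  list(dM = dM, dWi = dWi, dWh = dWh, db = db)
}

# --- full forward / backward ----------------------------------------------

# training: list(encoder = flag, heads = named logical per receptor).
# A FALSE flag runs that module in eval mode (running BN stats, no dropout),
# which keeps frozen modules bit-identical during later stages.
gat_forward <- function(model, batch, training = NULL,
                        active = NULL) {
  cfg <- model$config
  p <- model$params
  if (is.null(training)) {
    training <- list(encoder = FALSE,
                     heads = stats::setNames(rep(FALSE, length(cfg$receptors)),
                                             cfg$receptors))
  }
  if (is.null(active)) active <- cfg$receptors
  enc_tr <- isTRUE(training$encoder)
  cache <- list(layers = list(), training = training)
  Xcur <- batch$X
  res_anchor <- NULL
  for (l in seq_len(cfg$n_layers)) {
    lc <- list()
    att_out <- gat_layer_forward(
      Xcur, batch$src, batch$dst,
      p[[paste0("gat", l, "_Wsrc")]], p[[paste0("gat", l, "_Wdst")]],
      p[[paste0("gat", l, "_att")]], p[[paste0("gat", l, "_bias")]],
      cfg$n_heads
    )
    lc$att <- att_out$cache
    a <- att_out$y
    lc$relu_in <- a
    a <- pmax(a, 0)
    bno <- bn_forward(a, p[[paste0("bn_gat", l, "_gamma")]],
                      p[[paste0("bn_gat", l, "_beta")]],
                      model$bn[[paste0("bn_gat", l)]], enc_tr)
    if (enc_tr) model$bn[[paste0("bn_gat", l)]] <- bno$running
    lc$bn <- bno$cache
    a <- bno$y
    dr <- dropout_forward(a, cfg$dropout, enc_tr)
    lc$drop_mask <- dr$mask
    a <- dr$y
    # identity residual after every second layer
    if (l %% 2 == 0 && !is.null(res_anchor)) {
      a <- a + res_anchor
      lc$residual <- TRUE
    } else {
      lc$residual <- FALSE
    }
    if (l %% 2 == 1) res_anchor <- a
    cache$layers[[l]] <- lc
    Xcur <- a
  }
  cache$node_repr <- Xcur
  s2s <- set2set_forward(Xcur, batch$graph_id, batch$n_graphs,
                         p$lstm_Wi, p$lstm_Wh, p$lstm_b, cfg$set2set_steps)
  cache$s2s <- s2s$cache
  g <- s2s$y
  cache$rep_in <- g
  r0 <- colshift(g %*% p$rep_W, p$rep_b)
  cache$rep_relu_in <- r0
  r1 <- pmax(r0, 0)
  bno <- bn_forward(r1, p$bn_rep_gamma, p$bn_rep_beta, model$bn$bn_rep, enc_tr)
  if (enc_tr) model$bn$bn_rep <- bno$running
  cache$rep_bn <- bno$cache
  r2 <- bno$y
  dr <- dropout_forward(r2, cfg$dropout, enc_tr)
  cache$rep_drop <- dr$mask
  repr <- dr$y
  cache$repr <- repr
  logits <- matrix(NA_real_, batch$n_graphs, length(cfg$receptors),
                   dimnames = list(NULL, cfg$receptors))
  cache$heads <- list()
  cache$active <- active
  for (r in active) {
    htr <- isTRUE(training$heads[[r]])
    hc <- list(layers = list())
    x <- repr
    n_hidden <- length(cfg$head_dims)
    for (k in seq_len(n_hidden)) {
      kc <- list(x_in = x)
      z <- colshift(x %*% p[[paste0("head_", r, "_W", k)]],
                    p[[paste0("head_", r, "_b", k)]])
      kc$relu_in <- z
      z <- pmax(z, 0)
      bno <- bn_forward(z, p[[paste0("bn_head_", r, "_", k, "_gamma")]],
                        p[[paste0("bn_head_", r, "_", k, "_beta")]],
                        model$bn[[paste0("bn_head_", r, "_", k)]], htr)
      if (htr) model$bn[[paste0("bn_head_", r, "_", k)]] <- bno$running
      kc$bn <- bno$cache
      z <- bno$y
      drh <- dropout_forward(z, cfg$dropout, htr)
      kc$drop_mask <- drh$mask
      x <- drh$y
      hc$layers[[k]] <- kc
    }
    hc$final_in <- x
    kfin <- n_hidden + 1L
    z <- x %*% p[[paste0("head_", r, "_W", kfin)]] +
      p[[paste0("head_", r, "_b", kfin)]]
    logits[, r] <- z
    cache$heads[[r]] <- hc
  }
  list(logits = logits, probs = sigmoid(logits), cache = cache, model = model)
}

gat_backward <- function(model, batch, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  drepr_total <- matrix(0, nrow(cache$repr), ncol(cache$repr))
  n_hidden <- length(cfg$head_dims)
  for (r in cache$active) {
    hc <- cache$heads[[r]]
    kfin <- n_hidden + 1L
    dz <- matrix(dlogits[, r], ncol = 1)
    grads[[paste0("head_", r, "_W", kfin)]] <- crossprod(hc$final_in, dz)
    grads[[paste0("head_", r, "_b", kfin)]] <- colSums(dz)
    dx <- dz %*% t(p[[paste0("head_", r, "_W", kfin)]])
    for (k in rev(seq_len(n_hidden))) {
      kc <- hc$layers[[k]]
      if (!is.null(kc$drop_mask)) dx <- dx * kc$drop_mask
      bnb <- bn_backward(dx, kc$bn)
      grads[[paste0("bn_head_", r, "_", k, "_gamma")]] <- bnb$dgamma
      grads[[paste0("bn_head_", r, "_", k, "_beta")]] <- bnb$dbeta
      dx <- bnb$dx * (kc$relu_in > 0)
      grads[[paste0("head_", r, "_W", k)]] <- crossprod(kc$x_in, dx)
      grads[[paste0("head_", r, "_b", k)]] <- colSums(dx)
      dx <- dx %*% t(p[[paste0("head_", r, "_W", k)]])
    }
    drepr_total <- drepr_total + dx
  }
  dx <- drepr_total
  if (!is.null(cache$rep_drop)) dx <- dx * cache$rep_drop
  bnb <- bn_backward(dx, cache$rep_bn)
  grads$bn_rep_gamma <- bnb$dgamma
  grads$bn_rep_beta <- bnb$dbeta
  dx <- bnb$dx * (cache$rep_relu_in > 0)
  grads$rep_W <- crossprod(cache$rep_in, dx)
  grads$rep_b <- colSums(dx)
  dg <- dx %*% t(p$rep_W)
  s2sb <- set2set_backward(dg, cache$s2s)
  grads$lstm_Wi <- s2sb$dWi
  grads$lstm_Wh <- s2sb$dWh
  grads$lstm_b <- s2sb$db
  dX <- s2sb$dM
  res_grad <- NULL
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    # gradient arriving at this layer's output; odd layers also received the
    # residual anchor gradient from the following even layer
    if (l %% 2 == 1 && !is.null(res_grad)) {
      dX <- dX + res_grad
      res_grad <- NULL
    }
    if (lc$residual) res_grad <- dX
    dxl <- dX
    if (!is.null(lc$drop_mask)) dxl <- dxl * lc$drop_mask
    bnb <- bn_backward(dxl, lc$bn)
    grads[[paste0("bn_gat", l, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn_gat", l, "_beta")]] <- bnb$dbeta
    dxl <- bnb$dx * (lc$relu_in > 0)
    gb <- gat_layer_backward(dxl, lc$att)
    grads[[paste0("gat", l, "_Wsrc")]] <- gb$dWsrc
    grads[[paste0("gat", l, "_Wdst")]] <- gb$dWdst
    grads[[paste0("gat", l, "_att")]] <- gb$datt
    grads[[paste0("gat", l, "_bias")]] <- gb$dbias
    dX <- gb$dX
  }
  grads
}

#' Predict receptor activation probabilities
#'
#' @param object A trained `gat_model`.
#' @param newdata Character vector of sequences, list of `pep_tokens`, or an
#'   activity tibble with a `tokens` column.
#' @param ... Unused.
#' @return Tibble with `sequence` and one probability column per receptor.
#' @export
predict.gat_model <- function(object, newdata, ...) {
  token_lists <- if (is.data.frame(newdata)) {
    newdata$tokens
  } else if (is.character(newdata)) {
    tokenize_all(newdata)
  } else if (inherits(newdata, "pep_tokens")) {
    list(newdata)
  } else {
    newdata
  }
  graphs <- lapply(token_lists, build_graph, stats = object$stats)
  batch <- batch_graphs(graphs)
  out <- gat_forward(object, batch)
  probs <- tibble::as_tibble(out$probs)
  names(probs) <- paste0("prob_", object$config$receptors)
  dplyr::bind_cols(
    tibble::tibble(sequence = vapply(token_lists, pep_detokenize, character(1))),
    probs
  )
}
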