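# Independent oracles and fixture builders used across the suite.

# Quadratic dynamic-programming Levenshtein over token vectors (the
# reference implementation for the similarity tests).
dp_levenshtein <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# Exhaustive pair-counting AUC (Mann-Whitney by definition)
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Random token sequence; with probability nsaa_prob each position becomes a
# bracketed NSAA token
random_tokens <- function(len, nsaa_prob = 0.1) {
  base <- sample(triagonist:::AA_STANDARD, len, replace = TRUE)
  tok <- base
  for (i in seq_along(tok)) {
    if (runif(1) < nsaa_prob) {
      tok[i] <- if (runif(1) < 0.5) paste0("[d", base[i], "]")
                else "[K (yE-C16)]"
    }
  }
  structure(tok, class = "pep_tokens")
}

# Small activity tibble built in code
toy_records <- function(seqs, ec50 = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  df <- tibble::tibble(id = ids, sequence = seqs)
  if (is.null(ec50)) {
    ec50 <- matrix(100, n, 3)
  }
  for (k in seq_along(RECEPTORS)) {
    df[[paste0("EC50_", RECEPTORS[k])]] <- ec50[, k]
  }
  triagonist:::validate_records(df)
}

# Tiny model/train configuration for fast learning tests
tiny_gat_config <- function(...) {
  gat_config(n_layers = 4L, n_heads = 2L, hidden_dim = 12L, dropout = 0,
             set2set_steps = 2L, head_dims = c(8L, 6L), ...)
}

ref_panel <- reference_candidates()
ref_standard <- ref_panel[!grepl("[", ref_panel$sequence, fixed = TRUE), ]
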