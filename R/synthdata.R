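# Synthetic sequence-activity data with the statistical shape of the curated
# triple-agonist dataset and a planted, recoverable structure-activity rule.
# The generator mutates native-hormone templates (the real dataset consists
# of incretin-scaffold variants), plants or removes per-receptor sequence
# determinants to hit target positive fractions, and draws EC50 values from
# two log-normal components so that thresholding at 1000 pM reproduces the
# labels exactly.

#' Synthetic dataset configuration
#'
#' Defaults emulate the curated dataset's shape: 234 sequences, labels
#' available for 206/234 (GCGR), 234/234 (GLP1R) and 56/234 (GIPR), positive
#' fractions 0.490 / 0.748 / 0.571, lengths 25-40, occasional NSAA tokens.
#'
#' @param n_sequences Number of records.
#' @param avail Named per-receptor label-availability fractions.
#' @param pos_frac Named per-receptor positive fractions among labelled
#'   records.
#' @param len_range Sequence length range.
#' @param nsaa_prob Probability that a record carries one NSAA token
#'   (D-residue or lipidated lysine).
#' @param noise Label-flip probability applied after the planted rule.
#' @param template_mut_rate Per-position mutation rate applied to the native
#'   hormone templates.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sequences = 234L,
                         avail = c(GCGR = 206 / 234, GLP1R = 1.0,
                                   GIPR = 56 / 234),
                         pos_frac = c(GCGR = 0.490, GLP1R = 0.748,
                                      GIPR = 0.571),
                         len_range = c(25L, 40L), nsaa_prob = 0.08,
                         noise = 0.05, template_mut_rate = 0.15,
                         seed = 1L) {
  stopifnot(all(avail >= 0 & avail <= 1), all(pos_frac >= 0 & pos_frac <= 1),
            noise >= 0, noise < 0.5)
  structure(as.list(environment()), class = "synth_config")
}

# Planted per-receptor determinants:
#   GCGR : H at position 1 and W at position 8 (both required; chosen inside
#          the 4-hop receptive field of the attention encoder so a correct
#          learner can resolve the conjunction, and distinct from the
#          residues of the GLP1R core so neither rule decoys the other)
#   GLP1R: EGTF core in the N-terminal window, graded credit per matching
#          position (quadratic, so only the complete core crosses 0.5 but
#          partial matches still provide an optimization gradient)
#   GIPR : overall polar-residue enrichment (compositional determinant;
#          positives planted at fraction >= 0.65, negatives at <= 0.25)
# A small hydropathy term spreads the GCGR/GLP1R scores continuously without
# ever crossing the class boundary; margins are wide enough that a correct
# learner separates the classes.
oracle_margins <- function(base) {
  L <- length(base)
  kd_c <- mean(AA_KD[base]) / 4.5  # in [-1, 1]
  g_gcgr <- 1.6 * (base[1] == "H" && L >= 8 && base[8] == "W") - 0.8 +
    0.3 * kd_c
  core <- c("E", "G", "T", "F")
  m <- 0L
  if (L >= 5) {
    for (s in 1:(min(L, 8) - 3)) {
      m <- max(m, sum(base[s:(s + 3)] == core))
    }
  }
  g_glp1r <- 3.6 * (m / 4)^2 - 2.4 + 0.3 * kd_c
  polar_frac <- mean(base %in% AA_POLAR)
  g_gipr <- 7 * (polar_frac - 0.45)
  c(GCGR = g_gcgr, GLP1R = g_glp1r, GIPR = g_gipr)
}

#' Planted structure-activity oracle
#'
#' A deterministic map from token sequences to per-receptor activation
#' probabilities, built from interpretable positional rules (see
#' [synth_config()]). It stands in for a trained predictor and for the true
#' assay when testing the learning pipeline and the genetic algorithm
#' offline.
#'
#' @param seed Unused by the rules themselves (they are fixed); kept so oracle
#'   identity across calls with equal seeds is explicit.
#' @return A function: list of `pep_tokens` (or character vector) ->
#'   n x 3 probability matrix with receptor columns.
#' @export
planted_oracle <- function(seed = 1L) {
  force(seed)
  function(seqs) {
    if (is.character(seqs)) seqs <- tokenize_all(seqs)
    if (inherits(seqs, "pep_tokens")) seqs <- list(seqs)
    out <- t(vapply(seqs, function(tok) {
      sigmoid(oracle_margins(token_base(tok)))
    }, numeric(3)))
    colnames(out) <- RECEPTORS
    out
  }
}

# Mutate a template, trim/extend to length L
random_backbone <- function(L, comp, mut_rate) {
  tmpl <- strsplit(sample(native_hormones(), 1), "")[[1]]
  if (length(tmpl) >= L) {
    s <- tmpl[seq_len(L)]
  } else {
    s <- c(tmpl, sample(AA_STANDARD, L - length(tmpl), replace = TRUE,
                        prob = comp))
  }
  mut <- stats::runif(L) < mut_rate
  s[mut] <- sample(AA_STANDARD, sum(mut), replace = TRUE, prob = comp)
  s
}

# Plant or remove the per-receptor determinants for target labels y (0/1)
plant_labels <- function(s, y, comp) {
  L <- length(s)
  core <- c("E", "G", "T", "F")
  # GCGR first: its anchors (1 and 8) are protected by the later edits
  if (y[["GCGR"]] == 1) {
    s[1] <- "H"
    s[8] <- "W"
  } else if (s[1] == "H" && s[8] == "W") {
    s[1] <- sample(setdiff(AA_STANDARD, "H"), 1)
  }
  if (y[["GLP1R"]] == 1) {
    s[2:5] <- core
  } else {
    # break every EGTF window without touching the GCGR anchor positions
    repeat {
      str <- paste0(s, collapse = "")
      hit <- regexpr("EGTF", str, fixed = TRUE)
      if (hit < 0) break
      pos <- setdiff(as.integer(hit) + 0:3, c(1L, 8L))
      pos <- pos[sample.int(length(pos), 1)]
      s[pos] <- sample(setdiff(AA_STANDARD, core), 1)
    }
  }
  # the whole N-terminal determinant block stays untouched so compositional
  # edits can never create or destroy a positional determinant; 8 fixed
  # positions cannot push the polar fraction across the 0.45 boundary
  editable <- setdiff(seq_len(L), 1:8)
  nonpolar_pool <- c("A", "L", "V", "G", "F", "I")
  if (y[["GIPR"]] == 1) {
    while (mean(s %in% AA_POLAR) < 0.65) {
      cand <- editable[!(s[editable] %in% AA_POLAR)]
      if (length(cand) == 0) break
      s[cand[sample.int(length(cand), 1)]] <- sample(AA_POLAR, 1)
    }
  } else {
    while (mean(s %in% AA_POLAR) > 0.25) {
      cand <- editable[s[editable] %in% AA_POLAR]
      if (length(cand) == 0) break
      s[cand[sample.int(length(cand), 1)]] <- sample(nonpolar_pool, 1)
    }
  }
  s
}

draw_ec50 <- function(label) {
  # positives: log-normal around 30 pM; negatives: around 30,000 pM;
  # truncated at the 1000 pM threshold so labels round-trip exactly
  n <- length(label)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(label[i])) { out[i] <- NA_real_; next }
    repeat {
      v <- if (label[i] == 1) 10^stats::rnorm(1, log10(30), 0.5)
           else 10^stats::rnorm(1, log10(30000), 0.5)
      if ((label[i] == 1 && v < 1000) || (label[i] == 0 && v >= 1000)) break
    }
    out[i] <- v
  }
  round(out, 3)
}

#' Generate a synthetic activity dataset
#'
#' @param config A [synth_config()].
#' @return List: `records` (activity tibble as returned by
#'   [read_activity_table()]), and `manifest` (config echo, per-receptor
#'   planted/observed label summaries, true pre-noise labels and oracle
#'   probabilities).
#' @export
generate_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_sequences
  comp <- native_composition()
  oracle <- planted_oracle(config$seed)
  # Exact-count design: availability is an exact subset per receptor, and the
  # planted positive rate is adjusted for the label-flip noise so observed
  # positive fractions land on the config targets in expectation.
  avail_m <- matrix(FALSE, n, 3, dimnames = list(NULL, RECEPTORS))
  true_labels <- matrix(0L, n, 3, dimnames = list(NULL, RECEPTORS))
  for (r in RECEPTORS) {
    n_avail <- round(n * config$avail[[r]])
    av <- sample.int(n, n_avail)
    avail_m[av, r] <- TRUE
    p_adj <- (config$pos_frac[[r]] - config$noise) / (1 - 2 * config$noise)
    p_adj <- min(max(p_adj, 0), 1)
    pos_av <- sample(av, round(n_avail * p_adj))
    true_labels[pos_av, r] <- 1L
    not_av <- setdiff(seq_len(n), av)
    if (length(not_av) > 0) {
      pos_not <- sample(not_av, round(length(not_av) * p_adj))
      true_labels[pos_not, r] <- 1L
    }
  }
  rows <- vector("list", n)
  obs_labels <- matrix(NA_integer_, n, 3, dimnames = list(NULL, RECEPTORS))
  for (i in seq_len(n)) {
    L <- config$len_range[1] +
      sample.int(config$len_range[2] - config$len_range[1] + 1L, 1L) - 1L
    y <- stats::setNames(true_labels[i, ], RECEPTORS)
    s <- random_backbone(L, comp, config$template_mut_rate)
    s <- plant_labels(s, y, comp)
    flip <- stats::runif(3) < config$noise
    obs <- ifelse(flip, 1L - y, y)
    obs[!avail_m[i, ]] <- NA_integer_
    obs_labels[i, ] <- obs
    tokens <- s
    if (stats::runif(1) < config$nsaa_prob) {
      # keep NSAA insertions away from the planted determinant region
      j <- sample(9:L, 1)
      tokens[j] <- if (stats::runif(1) < 0.5) {
        paste0("[d", s[j], "]")
      } else {
        "[K (yE-C16)]"
      }
    }
    rows[[i]] <- tibble::tibble(
      id = sprintf("SYN%04d", i),
      sequence = paste0(tokens, collapse = "")
    )
  }
  df <- dplyr::bind_rows(rows)
  for (r in RECEPTORS) {
    df[[paste0("EC50_", r)]] <- draw_ec50(obs_labels[, r])
  }
  records <- validate_records(df)
  seq_probs <- oracle(records$tokens)
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    n = n,
    labels_available = colSums(!is.na(obs_labels)),
    positive_fraction = colMeans(obs_labels == 1, na.rm = TRUE),
    true_labels = true_labels,
    oracle_probs = seq_probs
  )
  list(records = records, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' Emits the activity CSV plus a `manifest.json` holding the seed, the
#' configuration and the true (pre-noise) labels and oracle probabilities.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_activity_table(dataset$records, file.path(dir, "activity.csv"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
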