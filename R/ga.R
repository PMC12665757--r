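# Evolutionary optimizer over token sequences: tournament selection,
# single-point crossover with independent cut points, adaptive mutation with
# a point/conservative/modified-residue event mix, elitism, motif-preserving
# repair, and convergence detection on fitness improvement and population
# diversity.

#' Genetic algorithm configuration
#'
#' @param pop_size Population size.
#' @param len_min,len_max Allowed sequence length range.
#' @param max_generations Generation budget.
#' @param tournament_k Tournament size for parent selection.
#' @param crossover_rate Probability a parent pair undergoes crossover.
#' @param mutation_rate Per-offspring mutation probability (doubled when mean
#'   population diversity drops below `low_diversity`, capped at
#'   `mutation_rate_cap`).
#' @param mutation_mix Probabilities of point / conservative / modified-
#'   residue mutation events (must sum to 1).
#' @param elite_fraction Fraction of top individuals copied unchanged.
#' @param convergence_eps Convergence threshold on the moving average of
#'   best-fitness improvement.
#' @param convergence_window Generations in the moving average.
#' @param stagnation_window Consecutive generations of flat diversity that
#'   trigger a stagnation stop.
#' @param stagnation_eps Diversity change considered flat.
#' @param fitness_weights Named weights of the six fitness components
#'   (`H`, `P`, `Pmin`, `B`, `N`, `D`).
#' @param fitness_threshold Optional early-stop fitness target.
#' @param low_diversity,mutation_rate_cap Adaptive-mutation parameters.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100L, len_min = 25L, len_max = 35L,
                      max_generations = 50L, tournament_k = 3L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_mix = c(point = 0.7, conservative = 0.2,
                                       modified = 0.1),
                      elite_fraction = 0.1, convergence_eps = 0.1,
                      convergence_window = 3L, stagnation_window = 10L,
                      stagnation_eps = 1e-3,
                      fitness_weights = c(H = 1, P = 1, Pmin = 1, B = 1,
                                          N = 1, D = 1),
                      fitness_threshold = NULL, low_diversity = 0.2,
                      mutation_rate_cap = 0.3, seed = 1L) {
  stopifnot(abs(sum(mutation_mix) - 1) < 1e-9,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            len_min >= 2, len_max >= len_min)
  if (floor(pop_size * elite_fraction) < 1) {
    stop("elite_fraction must keep at least one individual", call. = FALSE)
  }
  structure(as.list(environment()), class = "ga_config")
}

#' Scoring context for the genetic algorithm
#'
#' Bundles everything the fitness function needs besides the predictor:
#' the training sequences (novelty reference), the motif anchor sets, and
#' the residue composition used for random initialization.
#'
#' @param training_tokens List of `pep_tokens` (the novelty reference set).
#' @param motifs Motif tibble from [binding_motifs()].
#' @return A `ga_context` list.
#' @export
ga_context <- function(training_tokens, motifs = binding_motifs()) {
  stopifnot(length(training_tokens) > 0)
  structure(list(training_tokens = training_tokens, motifs = motifs,
                 comp = native_composition()),
            class = "ga_context")
}

#' Fitness components of one candidate
#'
#' `F = w_H H + w_P P + w_Pmin Pmin + w_B B + w_N N + w_D D` where `H` is the
#' number of receptors with predicted probability at or above 0.5, `P` the
#' mean and `Pmin` the minimum predicted probability, `B` the biological
#' plausibility total, `N` the novelty against the training set and `D` the
#' population diversity contribution. Default weights are 1.
#'
#' @param tokens Candidate `pep_tokens`.
#' @param probs Numeric vector of three receptor probabilities.
#' @param context A [ga_context()].
#' @param population Current population (for `D`); `NULL` gives `D = 0`.
#' @param weights Component weights.
#' @return One-row tibble of components and `total`.
#' @export
ga_fitness <- function(tokens, probs, context, population = NULL,
                       weights = c(H = 1, P = 1, Pmin = 1, B = 1, N = 1, D = 1)) {
  stopifnot(length(probs) == 3, all(probs > 0 & probs < 1))
  b <- plausibility(tokens, context$motifs)
  comp <- c(
    H = sum(probs >= 0.5),
    P = mean(probs),
    Pmin = min(probs),
    B = b$B_total,
    N = novelty_score(tokens, context$training_tokens),
    D = if (is.null(population)) 0 else diversity_score(tokens, population)
  )
  tibble::tibble(
    H = comp[["H"]], P = comp[["P"]], Pmin = comp[["Pmin"]], B = comp[["B"]],
    N = comp[["N"]], D = comp[["D"]],
    total = sum(weights[names(comp)] * comp),
    pass = b$pass
  )
}

# sample() treats a scalar first argument as a range, so draw explicitly
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Random plausibility-filtered individual
random_individual <- function(config, context) {
  for (attempt in seq_len(100L)) {
    L <- sample_range(config$len_min, config$len_max)
    s <- sample(AA_STANDARD, L, replace = TRUE, prob = context$comp)
    tok <- structure(s, class = "pep_tokens")
    if (plausibility(tok, context$motifs)$pass) return(tok)
  }
  NULL
}

#' Initialize a plausibility-filtered random population
#'
#' Residues are drawn from the native-hormone composition distribution and
#' candidates failing the plausibility filter are rejected.
#'
#' @param config A [ga_config()].
#' @param context A [ga_context()].
#' @return List of `pep_tokens` of length `pop_size`.
#' @export
initialize_population <- function(config, context) {
  pop <- vector("list", config$pop_size)
  for (i in seq_len(config$pop_size)) {
    ind <- random_individual(config, context)
    if (is.null(ind)) {
      stop("could not generate enough plausible sequences; ",
           "consider seeding the population with template sequences",
           call. = FALSE)
    }
    pop[[i]] <- ind
  }
  pop
}

#' Tournament selection
#'
#' Draws `k` members uniformly and returns the index of the fittest; ties go
#' to the earliest drawn index.
#'
#' @param fitness Numeric fitness vector of the population.
#' @param k Tournament size.
#' @return Selected index.
#' @export
tournament_select <- function(fitness, k = 3L) {
  if (length(fitness) < k) stop("population smaller than tournament", call. = FALSE)
  cand <- sample.int(length(fitness), k)
  cand[which.max(fitness[cand])]
}

#' Single-point crossover
#'
#' Independent cut points are drawn in each parent and suffixes exchanged,
#' so offspring lengths vary while the total token count is conserved.
#'
#' @param a,b Parent `pep_tokens` (length >= 2).
#' @return List of two offspring `pep_tokens`.
#' @export
ga_crossover <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ca <- sample.int(length(a) - 1L, 1)
  cb <- sample.int(length(b) - 1L, 1)
  c1 <- structure(c(unclass(a)[1:ca], unclass(b)[(cb + 1):length(b)]),
                  class = "pep_tokens")
  c2 <- structure(c(unclass(b)[1:cb], unclass(a)[(ca + 1):length(a)]),
                  class = "pep_tokens")
  list(c1, c2)
}

#' Adaptive mutation
#'
#' With probability `mutation_rate` (doubled under low population diversity,
#' capped) one mutation event is applied, drawn from the configured mix:
#' point substitution to a different standard residue, conservative
#' substitution within the residue's physicochemical group, or introduction
#' of a modified residue (D-form token, or a lipidated-lysine token when the
#' site is a lysine).
#'
#' @param tokens Candidate `pep_tokens`.
#' @param config A [ga_config()].
#' @param population_diversity Mean population diversity (drives adaptation).
#' @return Possibly mutated `pep_tokens`.
#' @export
ga_mutate <- function(tokens, config, population_diversity = 1.0) {
  rate <- config$mutation_rate
  if (population_diversity < config$low_diversity) {
    rate <- min(2 * rate, config$mutation_rate_cap)
  }
  if (stats::runif(1) >= rate) return(tokens)
  s <- unclass(tokens)
  type <- sample(names(config$mutation_mix), 1, prob = config$mutation_mix)
  pos <- sample.int(length(s), 1)
  base <- token_base(structure(s[pos], class = "pep_tokens"))
  if (type == "point") {
    s[pos] <- sample(setdiff(AA_STANDARD, s[pos]), 1)
  } else if (type == "conservative") {
    grp <- purrr::detect(AA_GROUPS, function(g) base %in% g)
    alt <- setdiff(grp, base)
    if (length(alt) == 0) {
      s[pos] <- sample(setdiff(AA_STANDARD, s[pos]), 1)
    } else {
      s[pos] <- sample(alt, 1)
    }
  } else {
    s[pos] <- if (base == "K" && stats::runif(1) < 0.5) {
      "[K (yE-C16)]"
    } else {
      paste0("[d", base, "]")
    }
  }
  structure(s, class = "pep_tokens")
}

#' Repair an offspring
#'
#' Clamps the length into the configured range (C-terminal trim, or extension
#' with the fitter parent's C-terminal tokens), then, while the candidate
#' fails the plausibility filter, re-instates the anchor residues of the
#' worst-scoring motif for up to five rounds. A candidate that still fails is
#' replaced by a copy of the fitter parent.
#'
#' @param tokens Offspring `pep_tokens`.
#' @param parents List of the two parent `pep_tokens`, fitter first.
#' @param config A [ga_config()].
#' @param context A [ga_context()].
#' @return A valid `pep_tokens`.
#' @export
ga_repair <- function(tokens, parents, config, context) {
  s <- unclass(tokens)
  if (length(s) > config$len_max) {
    s <- s[seq_len(config$len_max)]
  } else if (length(s) < config$len_min) {
    donor <- unclass(parents[[1]])
    need <- config$len_min - length(s)
    s <- c(s, utils::tail(donor, need))
    if (length(s) < config$len_min) {
      s <- c(s, sample(AA_STANDARD, config$len_min - length(s), replace = TRUE,
                       prob = context$comp))
    }
  }
  tok <- structure(s, class = "pep_tokens")
  for (round in seq_len(5L)) {
    pl <- plausibility(tok, context$motifs)
    if (pl$pass) return(tok)
    scores <- vapply(seq_len(nrow(context$motifs)), function(i) {
      score_one_motif(token_base(tok), context$motifs[i, ])
    }, numeric(1))
    worst <- context$motifs[which.min(scores), ]
    anchors <- worst$anchors[[1]]
    pos <- as.integer(names(anchors))
    if (worst$frame == "C") pos <- length(tok) - pos
    keep <- pos >= 1 & pos <= length(tok)
    s <- unclass(tok)
    s[pos[keep]] <- anchors[keep]
    tok <- structure(s, class = "pep_tokens")
  }
  if (plausibility(tok, context$motifs)$pass) tok else parents[[1]]
}

#' Convergence check
#'
#' Stops with reason `"converged"` when the moving average of best-fitness
#' improvement over `convergence_window` generations falls below
#' `convergence_eps`; `"stagnated"` when diversity changes stay below
#' `stagnation_eps` for `stagnation_window` consecutive generations;
#' `"max_gen"` at the generation budget; `"threshold"` when an optional
#' fitness target is reached.
#'
#' @param best_history Numeric vector of per-generation best fitness.
#' @param diversity_history Numeric vector of per-generation mean diversity.
#' @param config A [ga_config()].
#' @return List `stop` (logical) and `reason` (character or `NA`).
#' @export
check_convergence <- function(best_history, diversity_history, config) {
  g <- length(best_history)
  if (!is.null(config$fitness_threshold) &&
      g > 0 && best_history[g] >= config$fitness_threshold) {
    return(list(stop = TRUE, reason = "threshold"))
  }
  if (g > config$max_generations) {
    return(list(stop = TRUE, reason = "max_gen"))
  }
  w <- config$convergence_window
  if (g >= w + 1) {
    imp <- diff(best_history)
    if (mean(utils::tail(imp, w)) < config$convergence_eps) {
      return(list(stop = TRUE, reason = "converged"))
    }
  }
  sw <- config$stagnation_window
  if (length(diversity_history) >= sw + 1) {
    dd <- abs(diff(diversity_history))
    if (all(utils::tail(dd, sw) < config$stagnation_eps)) {
      return(list(stop = TRUE, reason = "stagnated"))
    }
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Run the evolutionary optimization
#'
#' Per generation: fitness evaluation with the supplied predictor, elitism
#' (top `elite_fraction` copied unchanged), tournament selection, crossover,
#' adaptive mutation, repair, and replacement at constant population size.
#'
#' @param config A [ga_config()].
#' @param predictor Function mapping a list of `pep_tokens` to an n x 3
#'   probability matrix (e.g. [planted_oracle()] or
#'   [predictor_from_models()]).
#' @param context A [ga_context()].
#' @return A `ga_result`: best sequence and fitness, per-generation history
#'   tibble, initial and final populations with fitness, and the stop reason.
#' @export
ga_evolve <- function(config, predictor, context) {
  set.seed(config$seed)
  pop <- initialize_population(config, context)
  n <- config$pop_size
  n_elite <- max(1L, floor(n * config$elite_fraction))
  # fitness rows are assigned when an individual is first evaluated and carried
  # forward by elitism, so the best recorded fitness is non-decreasing
  fits <- vector("list", n)
  best_hist <- numeric(0)
  div_hist <- numeric(0)
  history <- list()
  initial_pop <- pop
  reason <- "max_gen"
  gen <- 0L
  repeat {
    need <- which(vapply(fits, is.null, logical(1)))
    if (length(need) > 0) {
      probs <- predictor(pop[need])
      probs <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
      for (j in seq_along(need)) {
        i <- need[j]
        fits[[i]] <- ga_fitness(pop[[i]], probs[j, ], context,
                                population = pop[-i],
                                weights = config$fitness_weights)
      }
    }
    fit_tot <- vapply(fits, `[[`, numeric(1), "total")
    div <- vapply(fits, `[[`, numeric(1), "D")
    best_i <- which.max(fit_tot)
    best_hist <- c(best_hist, fit_tot[best_i])
    div_hist <- c(div_hist, mean(div))
    history[[gen + 1L]] <- tibble::tibble(
      generation = gen,
      best_fitness = fit_tot[best_i],
      mean_fitness = mean(fit_tot),
      sd_fitness = stats::sd(fit_tot),
      mean_diversity = mean(div),
      n_high_affinity = sum(vapply(fits, `[[`, numeric(1), "H") == 3)
    )
    if (gen >= config$max_generations) { reason <- "max_gen"; break }
    conv <- check_convergence(best_hist, div_hist, config)
    if (conv$stop) { reason <- conv$reason; break }
    # next generation
    elite_idx <- order(fit_tot, decreasing = TRUE)[seq_len(n_elite)]
    new_pop <- pop[elite_idx]
    new_fits <- fits[elite_idx]
    mean_div <- mean(div)
    while (length(new_pop) < n) {
      i1 <- tournament_select(fit_tot, config$tournament_k)
      i2 <- tournament_select(fit_tot, config$tournament_k)
      p1 <- pop[[i1]]; p2 <- pop[[i2]]
      parents <- if (fit_tot[i1] >= fit_tot[i2]) list(p1, p2) else list(p2, p1)
      if (stats::runif(1) < config$crossover_rate) {
        kids <- ga_crossover(p1, p2)
      } else {
        kids <- list(p1, p2)
      }
      for (kid in kids) {
        if (length(new_pop) >= n) break
        kid <- ga_mutate(kid, config, mean_div)
        kid <- ga_repair(kid, parents, config, context)
        new_pop[[length(new_pop) + 1L]] <- kid
        new_fits[length(new_pop)] <- list(NULL)
      }
    }
    pop <- new_pop
    fits <- new_fits
    length(fits) <- n
    gen <- gen + 1L
  }
  best_i <- which.max(fit_tot)
  structure(list(
    best_tokens = pop[[best_i]],
    best_sequence = pep_detokenize(pop[[best_i]]),
    best_fitness = max(best_hist),
    history = dplyr::bind_rows(history),
    initial_population = initial_pop,
    final_population = pop,
    final_fitness = fit_tot,
    stop_reason = reason,
    config = config
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result>", nrow(x$history), "generations, stop:", x$stop_reason, "\n")
  cat("best fitness", round(x$best_fitness, 4), "\n")
  cat("best sequence", x$best_sequence, "\n")
  invisible(x)
}

#' Wrap fold models into a GA predictor
#'
#' @param models List of trained `gat_model`s.
#' @return Function: list of `pep_tokens` -> n x 3 probability matrix.
#' @export
predictor_from_models <- function(models) {
  function(seqs) {
    pr <- ensemble_predict(models, seqs, check_stats = FALSE)
    m <- as.matrix(pr[, paste0("prob_", RECEPTORS)])
    colnames(m) <- RECEPTORS
    m
  }
}
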