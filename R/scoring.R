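# Candidate scoring components used by the genetic algorithm and by the
# validation filter: token-level sequence similarity, novelty against a
# training set, motif preservation against literature-derived anchor sets,
# and the weighted biological plausibility score.

# Map token vectors to single-character strings over a shared alphabet so the
# C-level Levenshtein in utils::adist can do the dynamic programming. NSAA
# bracket tokens compare as atomic symbols.
encode_token_strings <- function(token_lists) {
  vocab <- unique(unlist(lapply(token_lists, unclass), use.names = FALSE))
  alphabet <- intToUtf8(seq(256L, 255L + length(vocab)), multiple = TRUE)
  vapply(token_lists, function(tok) {
    paste0(alphabet[match(unclass(tok), vocab)], collapse = "")
  }, character(1))
}

#' Token-level sequence similarity
#'
#' Normalized Levenshtein similarity between two token sequences:
#' `1 - d(a, b) / max(|a|, |b|)`, where `d` is the edit distance over whole
#' residue tokens (an NSAA bracket token is a single symbol).
#'
#' @param a,b Sequence strings or `pep_tokens`.
#' @return Similarity in \[0, 1\]; 1 for identical token sequences.
#' @examples
#' pep_similarity("HSQGTF", "HSEGTF")
#' @export
pep_similarity <- function(a, b) {
  a <- as_tokens(a); b <- as_tokens(b)
  enc <- encode_token_strings(list(a, b))
  d <- utils::adist(enc[1], enc[2])[1, 1]
  1 - d / max(length(a), length(b))
}

# Similarity of one sequence against a list of sequences (shared encoding)
similarity_to_set <- function(x, set_tokens) {
  x <- as_tokens(x)
  enc <- encode_token_strings(c(list(x), set_tokens))
  d <- utils::adist(enc[1], enc[-1])[1, ]
  lens <- pmax(length(x), vapply(set_tokens, length, integer(1)))
  1 - d / lens
}

#' Novelty of a candidate against the training set
#'
#' `1 - max similarity` to any training sequence, with an additional 0.2
#' penalty (floored at 0) when the maximum similarity exceeds
#' `penalty_threshold`, discouraging near-duplicates of training peptides.
#'
#' @param x Sequence string or `pep_tokens`.
#' @param training_tokens List of training `pep_tokens`.
#' @param penalty_threshold Similarity above which the extra penalty applies.
#' @param penalty Size of the extra penalty.
#' @return Novelty score in \[0, 1\].
#' @export
novelty_score <- function(x, training_tokens, penalty_threshold = 0.8,
                          penalty = 0.2) {
  stopifnot(length(training_tokens) > 0)
  max_sim <- max(similarity_to_set(x, training_tokens))
  n <- 1 - max_sim
  if (max_sim > penalty_threshold) n <- max(0, n - penalty)
  n
}

#' Load the packaged binding-motif anchor sets
#'
#' Position-specific residue anchors for receptor binding, compiled from
#' structure-activity relationships and ortholog/paralog conservation of the
#' three native hormones. Each motif is expressed in its native hormone's own
#' coordinate frame; `frame = "N"` anchors count from the N-terminus (1-based)
#' and `frame = "C"` from the C-terminus (0 = last residue).
#'
#' @param path CSV path; `NULL` loads the packaged set.
#' @return Tibble with columns `motif`, `frame`, and a list-column `anchors`
#'   (named character vectors, names = positions).
#' @export
binding_motifs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "binding_motifs.csv", package = "triagonist")
  }
  df <- readr::read_csv(path, col_types = "ccc")
  df$anchors <- lapply(df$anchors, function(s) {
    parts <- strsplit(strsplit(s, ";")[[1]], "=")
    res <- vapply(parts, `[`, character(1), 2)
    names(res) <- vapply(parts, `[`, character(1), 1)
    res
  })
  tibble::as_tibble(df)
}

# Score one motif against a sequence's base residues
score_one_motif <- function(base, motif_row, wildcard = 1L, cons_credit = 0.5) {
  anchors <- motif_row$anchors[[1]]
  pos <- as.integer(names(anchors))
  if (motif_row$frame == "C") pos <- length(base) - pos
  keep <- pos >= 1 & pos <= length(base)
  if (!any(keep)) return(0)
  pos <- pos[keep]; expected <- anchors[keep]
  found <- base[pos]
  exact <- found == expected
  conservative <- !exact & vapply(seq_along(pos), function(i) {
    grp <- purrr::detect(AA_GROUPS, function(g) expected[i] %in% g)
    found[i] %in% grp
  }, logical(1))
  credit <- ifelse(exact, 1, ifelse(conservative, cons_credit, 0))
  # forgive up to `wildcard` outright mismatches per motif
  miss <- which(credit == 0)
  forgiven <- head(miss, wildcard)
  credit[forgiven] <- 1
  mean(credit)
}

#' Motif preservation score
#'
#' For each motif: the fraction of anchored positions matched, where an exact
#' match counts 1, a substitution within the same conservative group counts
#' `cons_credit`, and up to `wildcard` outright mismatches per motif are
#' forgiven. The overall score is the mean over the motif set.
#'
#' @param x Sequence string or `pep_tokens`.
#' @param motifs Motif tibble from [binding_motifs()].
#' @param wildcard Number of forgiven mismatches per motif.
#' @param cons_credit Credit for a conservative-group substitution.
#' @return Score in \[0, 1\].
#' @export
motif_score <- function(x, motifs = binding_motifs(), wildcard = 1L,
                        cons_credit = 0.5) {
  base <- token_base(as_tokens(x))
  scores <- vapply(seq_len(nrow(motifs)), function(i) {
    score_one_motif(base, motifs[i, ], wildcard, cons_credit)
  }, numeric(1))
  mean(scores)
}

#' Chemical constraint score
#'
#' Mean of three rule passes: net charge at pH 7 within \[-6, +2\], longest
#' run of strongly hydrophobic residues (KD > 1.8) at most 5, and no single
#' residue exceeding 30% of the composition.
#'
#' @param x Sequence string or `pep_tokens`.
#' @return Score in \[0, 1\].
#' @export
chemical_constraint_score <- function(x) {
  tok <- as_tokens(x)
  base <- token_base(tok)
  charge_ok <- {
    q <- pep_charge(tok, 7.0)
    q >= -6 && q <= 2
  }
  hydro <- AA_KD[base] > 1.8
  runs <- rle(hydro)
  patch_ok <- !any(runs$values & runs$lengths > 5)
  comp_ok <- max(table(base)) / length(base) <= 0.30
  mean(c(charge_ok, patch_ok, comp_ok))
}

#' Proteolytic stability score
#'
#' `1 - (#cleavage sites) / (L - 1)`. A trypsin site is K or R not followed by
#' P; a chymotrypsin site is F, Y or W not followed by P. Only positions with
#' a following residue can be sites.
#'
#' @param x Sequence string or `pep_tokens`.
#' @return Score in \[0, 1\]; 1 means no predicted cleavage sites.
#' @export
proteolytic_stability_score <- function(x) {
  base <- token_base(as_tokens(x))
  L <- length(base)
  if (L < 2) return(1)
  first <- base[-L]; nxt <- base[-1]
  sites <- (first %in% c("K", "R", "F", "Y", "W")) & nxt != "P"
  1 - sum(sites) / (L - 1)
}

#' Composition similarity to natural hormones
#'
#' One minus the total-variation distance between the sequence's residue
#' frequency vector and the pooled residue frequencies of the three native
#' hormones.
#'
#' @param x Sequence string or `pep_tokens`.
#' @return Score in \[0, 1\].
#' @export
composition_score <- function(x) {
  base <- token_base(as_tokens(x))
  freq <- as.numeric(table(factor(base, levels = AA_STANDARD))) / length(base)
  1 - sum(abs(freq - native_composition())) / 2
}

#' Biological plausibility score
#'
#' The weighted combination `B = 0.3 C + 0.35 M + 0.2 P + 0.15 A` of the
#' chemical constraint score `C`, motif preservation `M`, proteolytic
#' stability `P` and composition similarity `A`. Candidates with `B >= 0.3`
#' pass the plausibility filter.
#'
#' @param x Sequence string or `pep_tokens`.
#' @param motifs Motif tibble for the `M` component.
#' @param weights Numeric vector of the four component weights.
#' @param pass_threshold Minimum `B` for the pass flag.
#' @return One-row tibble: `C_chem`, `M_motif`, `P_stab`, `A_comp`, `B_total`,
#'   `pass`.
#' @export
plausibility <- function(x, motifs = binding_motifs(),
                         weights = c(C = 0.3, M = 0.35, P = 0.2, A = 0.15),
                         pass_threshold = 0.3) {
  tok <- as_tokens(x)
  comps <- c(
    C = chemical_constraint_score(tok),
    M = motif_score(tok, motifs),
    P = proteolytic_stability_score(tok),
    A = composition_score(tok)
  )
  b <- sum(weights[names(comps)] * comps)
  tibble::tibble(
    C_chem = comps[["C"]], M_motif = comps[["M"]], P_stab = comps[["P"]],
    A_comp = comps[["A"]], B_total = b, pass = b >= pass_threshold
  )
}

#' Population diversity score of one sequence
#'
#' Mean dissimilarity `1 - similarity` between a sequence and a sample of up
#' to `sample_size` other population members.
#'
#' Uses the session RNG when subsampling; seed upstream with `set.seed()` for
#' reproducibility.
#'
#' @param x Sequence string or `pep_tokens`.
#' @param population List of `pep_tokens`.
#' @param sample_size Maximum number of members compared; larger populations
#'   are subsampled.
#' @return Score in \[0, 1\].
#' @export
diversity_score <- function(x, population, sample_size = 20L) {
  stopifnot(length(population) > 0)
  idx <- seq_along(population)
  if (length(idx) > sample_size) idx <- sample(idx, sample_size)
  mean(1 - similarity_to_set(x, population[idx]))
}

#' Count sequences containing a contiguous motif
#'
#' Presence/absence per sequence (a sequence with two occurrences counts
#' once), matched on base residue letters.
#'
#' @param seqs Character vector of sequences or list of `pep_tokens`.
#' @param motif Contiguous residue string, length >= 1.
#' @return Integer count.
#' @examples
#' count_motif_occurrences(c("HAEGTFTSD", "AAAA"), "EGTF")
#' @export
count_motif_occurrences <- function(seqs, motif) {
  stopifnot(nchar(motif) >= 1)
  if (is.character(seqs)) seqs <- tokenize_all(seqs)
  sum(vapply(seqs, function(tok) {
    grepl(motif, paste0(token_base(tok), collapse = ""), fixed = TRUE)
  }, logical(1)))
}
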