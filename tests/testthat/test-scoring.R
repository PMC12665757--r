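test_that("token-level similarity agrees with the DP oracle", {
  expect_equal(pep_similarity("ACDEF", "ACDEF"), 1)
  expect_equal(pep_similarity("AAAA", "CCCC"), 0)
  set.seed(21)
  for (i in 1:1000) {
    a <- random_tokens(sample(4:12, 1), nsaa_prob = 0.15)
    b <- random_tokens(sample(4:12, 1), nsaa_prob = 0.15)
    d <- dp_levenshtein(a, b)
    expect_identical(pep_similarity(a, b),
                     1 - d / max(length(a), length(b)))
  }
})

test_that("similarity satisfies the edit-metric triangle-type bound", {
  set.seed(22)
  for (i in 1:50) {
    a <- random_tokens(8); b <- random_tokens(8); c <- random_tokens(8)
    expect_gte(pep_similarity(a, c) + 1e-12,
               pep_similarity(a, b) + pep_similarity(b, c) - 1)
  }
})

test_that("novelty penalizes near-duplicates of the training set", {
  train <- lapply(c("ACDEFGHIKL", "YYYYYYYYYY"), pep_tokenize)
  expect_equal(novelty_score(pep_tokenize("ACDEFGHIKL"), train), 0)
  # max similarity 0.5 -> novelty 0.5
  expect_equal(novelty_score(pep_tokenize("ACDEFWWWWW"), train), 0.5)
  # max similarity 0.9 -> 0.1 - 0.2 penalty, floored at 0
  expect_equal(novelty_score(pep_tokenize("ACDEFGHIKW"), train), 0)
})

test_that("motif scoring honours anchors, frames and substitutions", {
  motifs <- binding_motifs()
  glucagon <- native_hormones()[["glucagon"]]
  paralog <- motifs[motifs$motif == "glucagon_paralog", ]
  expect_equal(motif_score(glucagon, paralog), 1)
  # the full literature set scores natives high, poly-alanine low
  expect_gt(motif_score(glucagon), 0.6)
  ala <- paste(rep("A", 30), collapse = "")
  expect_lt(motif_score(ala), motif_score(glucagon))
  # C-terminal frame anchors from the end: GLP-1 matches its own C-motif
  glp1 <- native_hormones()[["glp1"]]
  cterm <- motifs[motifs$motif == "glp1_cterm_core", ]
  expect_equal(motif_score(glp1, cterm), 1)
  # conservative substitution earns partial credit: R -> K at the C-terminus
  glp1_k <- sub("R$", "K", glp1)
  expect_lt(motif_score(glp1_k, cterm, wildcard = 0), 1)
  expect_gte(motif_score(glp1_k, cterm, wildcard = 0), 0.5)
  # intact core beats a scrambled one
  intact <- "HAEGTFTSDVAAAAAAAAAAAAAAAAAAAA"
  scram <- "HTAGEFTSDVAAAAAAAAAAAAAAAAAAAA"
  expect_gt(motif_score(intact), motif_score(scram))
})

test_that("plausibility components follow their stated formulas", {
  expect_equal(proteolytic_stability_score("KKKKKKKKKK"), 0)
  expect_equal(proteolytic_stability_score("PPPPP"), 1)
  # trypsin/chymotrypsin sites only when not followed by proline
  expect_equal(proteolytic_stability_score("AKAA"), 1 - 1 / 3)
  expect_equal(proteolytic_stability_score("AKPA"), 1)
  glucagon <- native_hormones()[["glucagon"]]
  polyA <- paste(rep("A", 29), collapse = "")
  expect_gt(composition_score(glucagon), composition_score(polyA))
  expect_true(chemical_constraint_score(glucagon) >= 2 / 3)
  # hydrophobic patch rule: six consecutive strongly hydrophobic residues
  expect_lt(chemical_constraint_score("ILIVLIAAAADDDDKKKKSSSS"),
            chemical_constraint_score("ILIVAAAAAADDDDKKKKSSSS"))
})

test_that("plausibility total is the stated weighted combination", {
  pl <- plausibility(native_hormones()[["glucagon"]])
  expect_equal(pl$B_total,
               0.3 * pl$C_chem + 0.35 * pl$M_motif + 0.2 * pl$P_stab +
                 0.15 * pl$A_comp,
               tolerance = 1e-9)
  expect_true(pl$pass)
  # monotone in each component: a better motif score cannot lower B
  s1 <- plausibility("HAEGTFTSDVSSYLEGQAAKEFIAWLVKGR")
  s2 <- plausibility("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA")
  expect_gt(s1$B_total, s2$B_total)
})

test_that("diversity is 0 for clones, 1 for disjoint sets", {
  clone <- pep_tokenize("ACDEFGHIKL")
  pop <- rep(list(clone), 10)
  expect_equal(diversity_score(clone, pop), 0)
  other <- lapply(rep("WWWWWWWWWW", 5), pep_tokenize)
  expect_equal(diversity_score(clone, other), 1)
  # invariant to sample order below the subsampling threshold
  mixed <- lapply(c("ACDEFGHIKL", "WWWWWWWWWW", "ACDEFWWWWW"), pep_tokenize)
  expect_equal(diversity_score(clone, mixed),
               diversity_score(clone, rev(mixed)))
})

test_that("contiguous motif counting is per-sequence presence", {
  expect_equal(count_motif_occurrences(ref_panel$sequence, "EGTF"), 13L)
  expect_equal(count_motif_occurrences(c("AAEGTFEGTFAA"), "EGTF"), 1L)
  expect_equal(count_motif_occurrences(c("ACD", "DEF"), "ACDEFGH"), 0L)
})
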