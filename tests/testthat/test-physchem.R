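test_that("property panel reproduces published values for standard rows", {
  for (i in seq_len(nrow(ref_standard))) {
    row <- ref_standard[i, ]
    tok <- pep_tokenize(row$sequence)
    expect_equal(pep_mw(tok), row$mol_weight, tolerance = 1e-5)
    expect_lt(abs(pep_pi(tok) - row$isoelectric), 1e-4)
    expect_lt(abs(pep_instability(tok) - row$instability_index), 5e-4)
    expect_lt(abs(pep_gravy(tok) - row$gravy), 1e-4)
    expect_identical(pep_psa(tok), row$estimated_PSA)
    expect_identical(pep_logp(tok), pep_gravy(tok))
  }
})

test_that("hydropathy and PSA behave at their extremes", {
  expect_equal(pep_gravy("II"), 4.5)
  expect_equal(pep_logp("GG"), -0.4)
  expect_equal(pep_psa("AAAA"), 0)
  expect_equal(pep_psa("STNQDEHKR"), 450)
})

test_that("molecular weight matches free amino acids plus water", {
  expect_equal(pep_mw("G"), 75.07, tolerance = 1e-3)
  # additivity: MW(AB) = MW(A) + MW(B) - water
  expect_equal(pep_mw("AG"), pep_mw("A") + pep_mw("G") - 18.0153,
               tolerance = 1e-9)
})

test_that("PSA equals a brute-force polar-residue count times 50", {
  polar <- c("S", "T", "N", "Q", "D", "E", "H", "K", "R")
  set.seed(7)
  for (i in 1:20) {
    tok <- random_tokens(sample(5:35, 1), nsaa_prob = 0)
    expect_identical(pep_psa(tok), 50 * sum(unclass(tok) %in% polar))
  }
})

test_that("isoelectric point reflects ionizable composition", {
  expect_gt(pep_pi("KKAA"), 7)
  expect_lt(pep_pi("DDAA"), 7)
  # charge is monotone decreasing in pH
  tok <- pep_tokenize("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
  charges <- vapply(seq(2, 12, by = 0.5), function(ph) pep_charge(tok, ph),
                    numeric(1))
  expect_true(all(diff(charges) < 0))
  expect_lt(abs(pep_charge(tok, pep_pi(tok))), 1e-3)
})

test_that("pI is composition-only but the instability index is not", {
  set.seed(11)
  tok <- random_tokens(20, nsaa_prob = 0)
  perm <- structure(sample(unclass(tok)), class = "pep_tokens")
  # same first/last residue so the terminal pKa assignment matches
  perm[c(1, 20)] <- tok[c(1, 20)]
  mid <- sample(unclass(tok)[2:19])
  perm <- structure(c(unclass(tok)[1], mid, unclass(tok)[20]),
                    class = "pep_tokens")
  expect_equal(pep_pi(tok), pep_pi(perm), tolerance = 1e-9)
  # a sequence and its reversal generally differ in dipeptide weights
  expect_false(isTRUE(all.equal(
    pep_instability("KAPEW"), pep_instability("WEPAK")
  )))
})

test_that("instability index follows the dipeptide-weight formula", {
  # (10/L) * sum of DIWV over consecutive pairs, L = 2 here
  expect_equal(pep_instability("AA"),
               (10 / 2) * triagonist:::DIWV["A", "A"])
  expect_equal(pep_instability("KP"),
               (10 / 2) * triagonist:::DIWV["K", "P"])
  expect_error(pep_instability("A"), "at least 2")
})

test_that("NSAA overrides change mass and hydropathy, defaults fall back", {
  ov <- nsaa_overrides()
  tok <- pep_tokenize("A[K (yE-C16)]G")
  base <- pep_tokenize("AKG")
  expect_equal(pep_mw(tok, NULL), pep_mw(base))  # no override: base values
  expect_gt(pep_mw(tok, ov), pep_mw(base) + 300) # acyl chain adds mass
  expect_gt(pep_gravy(tok, ov), pep_gravy(base)) # lipid is hydrophobic
})

test_that("pep_properties bundles the panel and appends to data frames", {
  prof <- pep_properties("YAEGTFFTSDYSKLHKEAAEAFINWLIQTKITD")
  expect_s3_class(prof, "tbl_df")
  expect_equal(prof$est_logP, prof$gravy)
  expect_equal(prof$length, 33)
  df <- tibble::tibble(sequence = c("ACDEF", "GGGGG"))
  out <- pep_properties(df)
  expect_equal(nrow(out), 2)
  expect_true(all(c("mol_weight", "isoelectric", "net_charge_ph7")
                  %in% names(out)))
})
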