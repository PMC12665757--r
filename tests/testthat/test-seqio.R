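test_that("tokenizer splits standard and bracketed NSAA tokens", {
  t1 <- pep_tokenize("YAEGTFFTSDYSKLHKEAAEAFINWLIQTKITD")
  expect_length(t1, 33)
  expect_true(all(unclass(t1) %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

  t2 <- pep_tokenize("YAEGTFSDDDWTGIKMYNLWQRT [K (eK-eK-yE-C20DA)]YVIFQ")
  expect_length(t2, 29)
  expect_identical(unclass(t2)[24], "[K (eK-eK-yE-C20DA)]")
  expect_identical(token_base(t2)[24], "K")

  # whitespace between tokens ignored; base letter folded into a following
  # side-chain-only bracket
  t3 <- pep_tokenize("A K [(yE-C16)] C")
  expect_identical(unclass(t3), c("A", "[K (yE-C16)]", "C"))

  expect_error(pep_tokenize(""), "empty")
  expect_error(pep_tokenize("AC[dS"), "unbalanced")
  expect_error(pep_tokenize("AC]X"), "unbalanced")
  expect_error(pep_tokenize("ABZ"), "position 2")
  expect_error(pep_tokenize("[(yE-C16)]A"), "preceding")
})

test_that("tokenize/detokenize round-trips, including the candidate panel", {
  set.seed(42)
  for (i in 1:50) {
    tok <- random_tokens(sample(5:40, 1))
    expect_identical(unclass(pep_tokenize(pep_detokenize(tok))), unclass(tok))
  }
  for (s in ref_panel$sequence) {
    tok <- pep_tokenize(s)
    expect_identical(unclass(pep_tokenize(pep_detokenize(tok))), unclass(tok))
  }
  # token length statistics of the panel
  lens <- vapply(lapply(ref_panel$sequence, pep_tokenize), length, integer(1))
  expect_equal(mean(lens), 32.7, tolerance = 1e-6)
})

test_that("token classifiers recognize D-residues and lipidation", {
  tok <- pep_tokenize("A[dS][K (yE-C16)]G")
  expect_identical(token_is_d(tok), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(token_is_lipidated(tok), c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(token_base(tok), c("A", "S", "K", "G"))
})

test_that("EC50 labelling follows the strict 1000 pM threshold", {
  expect_identical(label_from_ec50(c(22.6, 999, 1000, 1500, NA)),
                   c(1L, 1L, 0L, 0L, NA))
  expect_error(label_from_ec50(-5), "non-negative")
  # changing the threshold relabels consistently
  ec <- c(5, 9.99, 10, 11, 500)
  expect_identical(label_from_ec50(ec, threshold = 10),
                   as.integer(ec < 10))
  expect_identical(label_from_ec50(ec, threshold = 10, strict = FALSE),
                   as.integer(ec <= 10))
})

test_that("activity tables read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,sequence,EC50_GCGR,EC50_GLP1R,EC50_GIPR",
    "a,HSQGTFTSDY,12,1500,",
    "b,YAEGTFISDY,900,22.6,469.5",
    "c,ACDEF,,5000,1000"
  ), path)
  rec <- read_activity_table(path, quiet = TRUE)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$label_GCGR, c(1L, 1L, NA))
  expect_identical(rec$label_GIPR, c(NA, 1L, 0L))
  expect_equal(sum(is.na(rec$label_GIPR)), 1)
  expect_s3_class(rec$tokens[[1]], "pep_tokens")

  out <- withr::local_tempfile(fileext = ".csv")
  write_activity_table(rec, out)
  rec2 <- read_activity_table(out, quiet = TRUE)
  expect_equal(rec2$EC50_GLP1R, rec$EC50_GLP1R)
  expect_identical(rec2$label_GCGR, rec$label_GCGR)

  writeLines(c(
    "id,sequence,EC50_GCGR,EC50_GLP1R,EC50_GIPR",
    "a,HSQGTFTSDY,12,15,",
    "a,YAEGTFISDY,900,22.6,469.5"
  ), path)
  expect_error(read_activity_table(path, quiet = TRUE), "duplicated")

  writeLines(c(
    "id,sequence,EC50_GCGR,EC50_GLP1R,EC50_GIPR",
    "a,HSQGTF1SDY,12,15,"
  ), path)
  expect_error(read_activity_table(path, quiet = TRUE), "row 1")
})

test_that("FASTA io preserves NSAA tokens inline", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c("HSQGTFTSDY", "YAEG[K (yE-C16)]TFISDY")
  write_sequences_fasta(c("s1", "s2"), seqs, path)
  back <- read_sequences_fasta(path)
  expect_identical(back$sequence, seqs)
  expect_identical(back$id, c("s1", "s2"))
})
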