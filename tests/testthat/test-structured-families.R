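make_chh_precursor <- function(cprp_len = 37, mature_len = 72,
                               n_cys = 6, gly12 = FALSE, aiaxx = FALSE,
                               with_cprp = TRUE, amidated = TRUE,
                               seed = 1) {
  set.seed(seed)
  spec <- synthetic_spec(seed = seed)
  sig <- pepminer:::syn_signal(26, 1.0)
  mat <- pepminer:::syn_cys_domain(mature_len, n_cys, gly12 = gly12,
                                   aiaxx = aiaxx)
  body <- if (with_cprp) {
    cprp <- paste(sample(c("D", "E", "N", "H", "Y"), cprp_len,
                         replace = TRUE), collapse = "")
    paste0(cprp, "KR", mat)
  } else mat
  list(protein = paste0(sig, body, if (amidated) "G" else ""),
       signal_end = 26, mature = mat)
}

test_that("CHH typing follows the structural call table", {
  # signal + CPRP + KR + 6-Cys mature -> type-I
  t1 <- make_chh_precursor(cprp_len = 37, mature_len = 72, seed = 2)
  a1 <- classify_chh(t1$protein, t1$signal_end)
  expect_identical(a1$call, "type-I-CHH")
  expect_true(a1$has_cprp)
  expect_equal(a1$cprp_span[2] - a1$cprp_span[1] + 1, 37)
  expect_equal(nchar(a1$mature), 72)
  expect_equal(a1$n_cys_mature, 6)
  expect_true(a1$amidated)

  # no CPRP + Gly12 -> type-II
  t2 <- make_chh_precursor(mature_len = 75, gly12 = TRUE,
                           with_cprp = FALSE, seed = 3)
  a2 <- classify_chh(t2$protein, t2$signal_end)
  expect_identical(a2$call, "type-II-MIH/GIH")
  expect_true(a2$gly12)
  expect_equal(nchar(a2$mature), 75)

  # no CPRP, no Gly12, 6-Cys -> CHH-MIH-like
  t3 <- make_chh_precursor(mature_len = 104, with_cprp = FALSE,
                           amidated = FALSE, seed = 4)
  a3 <- classify_chh(t3$protein, t3$signal_end)
  expect_identical(a3$call, "CHH-MIH-like")

  # CPRP wins even with an aberrant cysteine count (partial-like mature)
  t4 <- make_chh_precursor(mature_len = 40, n_cys = 1, seed = 5)
  a4 <- classify_chh(t4$protein, t4$signal_end)
  expect_identical(a4$call, "type-I-CHH")

  # nothing CHH-like
  a5 <- classify_chh(paste0(strrep("D", 40)), 0)
  expect_identical(a5$call, "not-CHH")
})

test_that("AIAXX detection matches its definition", {
  expect_true(check_aiaxx("DDDDAIAQL"))
  expect_false(check_aiaxx("DDDDDDAIA"))   # needs two trailing residues
  expect_warning(flag <- check_aiaxx("AIA"), "shorter")
  expect_false(flag)

  # agrees with a direct substring oracle on random 20-mers
  set.seed(3)
  for (i in 1:200) {
    s <- random_protein(20, alphabet = c("A", "I", "L", "Q"))
    expect_identical(check_aiaxx(s),
                     substr(s, 16, 18) == "AIA")
  }
})

test_that("insulin-like precursors parse into B, C, A chains", {
  set.seed(29)
  spec <- synthetic_spec(seed = 29)
  for (i in 1:10) {
    g <- generate_precursor(spec, "IAG", id = "iag")
    tr <- g$truth
    sig_end <- tr$end[tr$element_type == "signal"]
    ic <- parse_insulin_chains(g$protein, sig_end)
    expect_equal(ic$b_span,
                 c(tr$start[tr$element_type == "b_chain"],
                   tr$end[tr$element_type == "b_chain"]))
    expect_equal(ic$c_span,
                 c(tr$start[tr$element_type == "c_peptide"],
                   tr$end[tr$element_type == "c_peptide"]))
    expect_equal(ic$a_span,
                 c(tr$start[tr$element_type == "a_chain"],
                   tr$end[tr$element_type == "a_chain"]))
    expect_equal(ic$n_cys_b + ic$n_cys_a, 8)
    # spans partition the post-signal proprotein minus the site residues
    expect_equal((ic$b_span[2] - ic$b_span[1] + 1) +
                   (ic$c_span[2] - ic$c_span[1] + 1) +
                   (ic$a_span[2] - ic$a_span[1] + 1) + 4,
                 nchar(g$protein) - sig_end)
  }

  # fewer than two internal sites is not insulin-like
  p <- paste0(strrep("D", 30), "KR", strrep("E", 30))
  expect_error(parse_insulin_chains(p, 0), "not insulin-like")
})

test_that("CFSH architecture separates PRP from the cysteine-rich mature", {
  set.seed(31)
  spec <- synthetic_spec(seed = 31)
  for (i in 1:5) {
    g <- generate_precursor(spec, "CFSH", id = "cfsh")
    tr <- g$truth
    sig_end <- tr$end[tr$element_type == "signal"]
    cf <- parse_cfsh(g$protein, sig_end)
    expect_true(cf$has_prp)
    expect_equal(cf$prp_span,
                 c(tr$start[tr$element_type == "prp"],
                   tr$end[tr$element_type == "prp"]))
    expect_equal(cf$mature_span,
                 c(tr$start[tr$element_type == "mature"],
                   tr$end[tr$element_type == "mature"]))
    expect_equal(cf$n_cys_mature, 8)
  }

  # no internal site: flagged, mature is the whole proprotein
  p <- paste0(strrep("D", 20), strrep("E", 30))
  cf0 <- parse_cfsh(p, 0)
  expect_false(cf0$has_prp)
  expect_equal(cf0$mature_span, c(1, 50))
})

test_that("architecture calls equal generator truth across a mixed set", {
  set.seed(43)
  spec <- synthetic_spec(seed = 43)
  expected <- c("CHH-type-I" = "type-I-CHH",
                "CHH-type-II" = "type-II-MIH/GIH",
                "CHH-MIH-like" = "CHH-MIH-like")
  for (fam in names(expected)) {
    for (i in 1:5) {
      g <- generate_precursor(spec, fam, id = fam)
      sig_end <- g$truth$end[g$truth$element_type == "signal"]
      ann <- classify_chh(g$protein, sig_end)
      expect_identical(ann$call, unname(expected[fam]), label = fam)
      mat <- g$truth[g$truth$element_type == "mature", ]
      expect_identical(ann$mature, mat$sequence)
    }
  }
})
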