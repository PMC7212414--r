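test_that("cleavage examples follow the stated rules", {
  s <- find_cleavage_sites("AAAKRAAA")
  expect_equal(s$position, 5)
  expect_identical(s$pattern, "KR")

  # proline immediately after the site blocks cleavage
  expect_equal(nrow(find_cleavage_sites("AAPKRPAA")), 0)
  # cysteine flanking the scissile bond blocks cleavage
  expect_equal(nrow(find_cleavage_sites("AAAKRCAA")), 0)

  # monobasic R requires a supporting basic at -3/-5/-7
  expect_equal(find_cleavage_sites("AAKAARAA")$position, 6)   # K at -3
  expect_equal(nrow(find_cleavage_sites("AAAAARAA")), 0)      # no support
  # lone K is not cleaved by default, but can be enabled
  expect_equal(nrow(find_cleavage_sites("AAKAAKAA")), 0)
  sK <- find_cleavage_sites("AAKAAKAA", cleavage_rules(monobasic_K = TRUE))
  expect_identical(sK$pattern, "monobasic-K")   # only the K with support
  expect_equal(sK$position, 6)

  # overlapping dibasics resolve to the downstream one (KKR -> KR)
  s2 <- find_cleavage_sites("AAKKRAA")
  expect_equal(s2$position, 5)
  expect_identical(s2$pattern, "KR")

  # extended dibasics obey their toggles
  off <- cleavage_rules(enable_KK = FALSE, enable_RK = FALSE)
  expect_equal(nrow(find_cleavage_sites("AAAKKAAARKAA", off)), 0)
  on <- find_cleavage_sites("AAAKKAAARKAA")
  expect_identical(on$pattern, c("KK", "RK"))
})

test_that("site scanner equals the exhaustive rule checker on random 100-mers", {
  set.seed(23)
  configs <- list(
    cleavage_rules(),
    cleavage_rules(enable_KK = FALSE),
    cleavage_rules(enable_RK = FALSE, enable_monobasic = FALSE),
    cleavage_rules(monobasic_K = TRUE),
    cleavage_rules(block_P = FALSE, block_C = FALSE)
  )
  for (i in 1:1000) {
    p <- random_protein(100)
    rules <- configs[[(i %% length(configs)) + 1]]
    got <- find_cleavage_sites(p, rules)
    want <- oracle_sites(p, rules)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("excision conserves the proprotein exactly", {
  frags <- excise_peptides("AAKRNN", data.frame(
    position = 4, pattern = "KR", confidence = "canonical"))
  expect_identical(frags$sequence, c("AAKR", "NN"))

  # no sites: identity
  f0 <- excise_peptides("MNPQ", find_cleavage_sites("MNPQ"))
  expect_identical(f0$sequence, "MNPQ")

  # many-site synthetic proprotein: fragments partition the input
  set.seed(101)
  for (i in 1:25) {
    p <- random_protein(120)
    sites <- find_cleavage_sites(p)
    frags <- excise_peptides(p, sites)
    expect_identical(paste(frags$sequence, collapse = ""), p)
    expect_equal(sum(nchar(frags$sequence)), nchar(p))
    expect_equal(nrow(frags), nrow(sites) + (utils::tail(c(0, sites$position), 1) != nchar(p)))
  }
})

test_that("maturation applies trimming, amidation, pyroGlu, disulfide in order", {
  rpch <- maturate("QLNFSPGWGKR", 1, 11, "KR")
  expect_identical(rpch$sequence, "QLNFSPGW")
  expect_true(rpch$amidated)
  expect_true(rpch$pyroglu)
  expect_identical(render_peptide(rpch$sequence, rpch$amidated,
                                  rpch$pyroglu), "pQLNFSPGWamide")

  # terminal fragment with no trailing G: no flags
  proc <- maturate("RYLPT", 10, 14, NA_character_, at_true_end = TRUE)
  expect_identical(proc$sequence, "RYLPT")
  expect_false(proc$amidated)
  expect_false(proc$pyroglu)

  # two cysteines imply one bridge
  ccap <- maturate("PFCNAFTGCGKR", 1, 12, "KR")
  expect_identical(ccap$sequence, "PFCNAFTGC")
  expect_true(ccap$amidated)
  expect_equal(ccap$n_cys, 2)
  expect_identical(ccap$disulfide, "3-9")

  # monobasic site leaves a single basic to trim
  mono <- maturate("AAFGLGR", 1, 7, "monobasic-R")
  expect_identical(mono$sequence, "AAFGL")
  expect_true(mono$amidated)

  # a peptide genuinely ending in R keeps it (trim is at most the site's)
  keepr <- maturate("AAFR" , 1, 4, NA_character_, at_true_end = TRUE)
  expect_identical(keepr$sequence, "AAFR")

  # empty after trimming is dropped with a log message
  expect_message(res <- maturate("KR", 1, 2, "KR"), "dropped")
  expect_null(res)

  # pyroGlu from E only when enabled
  e_off <- maturate("EDAAA", 1, 5, NA_character_)
  expect_false(e_off$pyroglu)
  e_on <- maturate("EDAAA", 1, 5, NA_character_,
                   rules = cleavage_rules(pyroglu_E = TRUE))
  expect_true(e_on$pyroglu)
})

test_that("amidation requires a following site or the true precursor end", {
  # truncated precursor: terminal G is not evidence of amidation
  part <- maturate("AAFGLG", 1, 6, NA_character_, at_true_end = FALSE,
                   partial_c = TRUE)
  expect_false(part$amidated)
  expect_identical(part$sequence, "AAFGLG")
})

test_that("sulfation is flagged only in the sulfakinin context", {
  p1 <- maturate("QFDEYGHMRFG", 1, 11, "KR", at_true_end = FALSE)
  p1 <- flag_sulfation(p1)
  expect_identical(p1$sulfo_tyr, "5")
  expect_identical(render_peptide(p1$sequence, p1$amidated, p1$pyroglu,
                                  p1$sulfo_tyr), "pQFDEY(SO3H)GHMRFamide")

  p2 <- maturate("AGGDYDDYGHLRFG", 1, 14, "KR")
  p2 <- flag_sulfation(p2)
  expect_identical(p2$sulfo_tyr, "8")   # only the Y preceding GHLRF

  p3 <- maturate("AYAAA", 1, 5, NA_character_)
  p3 <- flag_sulfation(p3)
  expect_identical(p3$sulfo_tyr, "")
})

test_that("processing conserves residues and never amidates mid-sequence", {
  set.seed(31)
  for (i in 1:25) {
    p <- random_protein(150)
    sites <- find_cleavage_sites(p)
    frags <- excise_peptides(p, sites)
    peps <- process_proprotein(p)
    # every mature sequence is a prefix of its source fragment
    for (j in seq_len(nrow(peps))) {
      frag <- frags[frags$start <= peps$start[j] &
                      frags$end >= peps$start[j], ]
      expect_identical(substr(frag$sequence[1], 1,
                              nchar(peps$sequence[j])),
                       peps$sequence[j])
    }
    # amidated peptides had a G immediately after their retained span
    am <- peps[peps$amidated, , drop = FALSE]
    for (j in seq_len(nrow(am))) {
      expect_identical(substr(p, am$end[j] + 1, am$end[j] + 1), "G")
    }
  }
})
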