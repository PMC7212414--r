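test_that("FASTA round-trip is lossless for ids and sequences", {
  seqs <- c(p1 = "MKTAYIAKQR", p2 = "ACDEFGHIKLMNPQRSTVWY", p3 = "MKT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  back <- read_fasta(path, "protein")
  expect_identical(back, seqs)
})

test_that("read_fasta validates ids and alphabets", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), path)
  expect_error(read_fasta(path, "nt"), "duplicate ids.*a")

  writeLines(c(">x", "MKT"), path)
  expect_identical(unname(read_fasta(path, "protein")), "MKT")
  # case-normalised to upper
  writeLines(c(">x", "mkt"), path)
  expect_identical(unname(read_fasta(path, "protein")), "MKT")
  # illegal character named with record and offset
  writeLines(c(">bad", "MK7T"), path)
  expect_error(read_fasta(path, "protein"), "'7'.*'bad'.*offset 3")
  # nucleotide alphabet rejects amino-acid letters
  writeLines(c(">nt1", "ACGTMKT"), path)
  expect_error(read_fasta(path, "nt"), "illegal character")
})

test_that("translate_orfs finds forward and reverse ORFs with coordinates", {
  # M + K + 20xA, complete ORF in frame +1
  nt <- paste0("ATGAAA", strrep("GCT", 20), "TAA")
  orfs <- translate_orfs("t", nt, min_protein_len = 10)
  fwd <- orfs[orfs$frame == 1, ]
  expect_equal(fwd$protein, paste0("MK", strrep("A", 20)))
  expect_false(fwd$partial_n)
  expect_false(fwd$partial_c)
  expect_equal(c(fwd$nt_start, fwd$nt_end), c(1, 66))
  expect_true((fwd$nt_end - fwd$nt_start + 1) == 3 * nchar(fwd$protein))

  # reverse complement embedded in Ns finds the same protein on strand -
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
  nt2 <- paste0("NNNN", rc, "NNNNN")
  orfs2 <- translate_orfs("t2", nt2, min_protein_len = 10)
  rev_hit <- orfs2[orfs2$strand == "-" & !orfs2$partial_n &
                     !orfs2$partial_c, ]
  expect_equal(rev_hit$protein[1], paste0("MK", strrep("A", 20)))

  # N codons translate to X and the ORF is flagged
  nt3 <- paste0("ATG", strrep("GCT", 6), "AANTCT", strrep("GCT", 6), "TAA")
  orfs3 <- translate_orfs("t3", nt3, min_protein_len = 10)
  full <- orfs3[orfs3$frame == 1, ]
  expect_true(grepl("X", full$protein[1]))
  expect_true(full$has_x[1])
})

test_that("translate_orfs agrees with a brute-force six-frame oracle", {
  skip_if_not_installed("seqinr")
  set.seed(17)
  for (i in 1:60) {
    nt <- random_transcript(sample(150:600, 1))
    got <- sort(translate_orfs("t", nt, min_protein_len = 10)$protein)
    expect_identical(got, oracle_orfs(nt, 10))
  }
})

test_that("report rendering follows conventional PTM notation", {
  expect_identical(render_peptide("QLNFSPGW", amidated = TRUE,
                                  pyroglu = TRUE), "pQLNFSPGWamide")
  expect_identical(render_peptide("RYLPT"), "RYLPT")
  expect_identical(render_peptide("QFDEYGHMRF", amidated = TRUE,
                                  pyroglu = TRUE, sulfo_tyr = 5L),
                   "pQFDEY(SO3H)GHMRFamide")
})

test_that("rendering is injective over PTM flags and invertible", {
  seqs <- c("QLNFSPGW", "RYLPT", "QFDEYGHMRF")
  seen <- character()
  for (s in seqs) {
    for (am in c(TRUE, FALSE)) {
      for (pg in c(TRUE, FALSE)) {
        if (pg && substr(s, 1, 1) != "Q") next
        r <- render_peptide(s, am, pg)
        expect_false(r %in% seen)
        seen <- c(seen, r)
        back <- parse_rendered(r)
        expect_identical(back$sequence, s)
        expect_identical(back$amidated, am)
        expect_identical(back$pyroglu, pg)
      }
    }
  }
})

test_that("write_report produces deterministic TSV/JSON, empty-safe", {
  spec <- synthetic_spec(seed = 5, n_precursors = 4)
  ds <- generate_dataset(spec)
  res <- mine_peptides(ds$records)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, tsv, "tsv")
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(names(tab)[1:6],
                   c("precursor_id", "peptide_start", "peptide_end",
                     "sequence", "rendered", "family"))
  expect_equal(nrow(tab), nrow(res$peptides))
  json <- withr::local_tempfile(fileext = ".json")
  write_report(res, json, "json")
  parsed <- jsonlite::read_json(json)
  expect_length(parsed, nrow(res$precursors))

  # empty result set: header-only file
  empty <- mine_peptides(character())
  write_report(empty, tsv, "tsv")
  expect_equal(nrow(read.delim(tsv)), 0)
})
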