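# pepminer

Annotation of neuropeptide precursors (prepropeptides) from transcriptome
or protein sequences, in R.

Crustacean and insect neuropeptides are made as precursor proteins: a
signal peptide, sometimes a precursor-related peptide, and one to dozens
of peptide copies flanked by prohormone-convertase cleavage sites. After
cleavage, carboxypeptidase trimming and C-terminal amidation via a glycine
donor produce the mature hormones — e.g. `pQLNFSPGWamide` (red
pigment-concentrating hormone) or `APSGFLGMRamide` (tachykinin). This
package implements that processing logic as an auditable pipeline for
peptide mining in non-model species (it was built around the peptide
repertoire of a caridean shrimp), plus the structural typing used for the
CHH superfamily, insulin-like (IAG) and CFSH precursors, and a
hydropathy-based 7-transmembrane screen for candidate peptide GPCRs.

## What it does

* **Sequence I/O and ORF mining** — FASTA in/out; six-frame
  ORF translation with partial-ORF flags (`read_fasta`, `translate_orfs`).
* **Signal peptides** — a documented heuristic combining Kyte–Doolittle
  h-region hydropathy with the von Heijne (−3,−1) small-residue rule
  (`predict_signal`), or imported external predictor calls, which always
  win (`import_signal_annotations`).
* **Prohormone processing** — convertase site prediction
  (`find_cleavage_sites`): canonical `KR`/`RR`, extended `KK`/`RK`,
  monobasic `R` with a basic residue at −3/−5/−7; proline or cysteine at
  the scissile bond blocks cleavage. Excision (`excise_peptides`),
  carboxypeptidase trimming, amidation, pyroglutamate, disulfide and
  sulfotyrosine annotation (`maturate`, `flag_sulfation`).
* **Family classification** — an editable motif library
  (`inst/extdata/motif_library.tsv`, 31 decapod families) in conventional
  X-notation (`YXFGLamide`, `NF[LI]RFamide`, …) plus exact-sequence rules
  for single-sequence families (`classify_peptide`).
* **Structural typing** — CHH superfamily call table (CPRP ⇒ type-I;
  Gly12 ⇒ type-II MIH/GIH; 6-Cys, no CPRP/Gly12 ⇒ CHH-MIH-like;
  `classify_chh`, `check_aiaxx`), insulin-like B–C–A chain parsing
  (`parse_insulin_chains`), CFSH PRP+mature parsing (`parse_cfsh`).
* **GPCR screen** — sliding-window Kyte–Doolittle profile and
  transmembrane-run counting; 6–8 segments flag a 7TM candidate
  (`screen_gpcr`).
* **Synthetic data** — a seeded generator that emits precursors with full
  ground truth for every element (`synthetic_spec`, `generate_dataset`),
  so each pipeline stage has a recovery test without any downloads.

## Worked example

```r
library(pepminer)
p <- c(demo1 = paste0("M", "KR", strrep("L", 14), "AGA",
       "QLNFSPGWG", "KR", "APSGFLGMRG", "KR", "QFDEYGHMRFG", "KR", "DNHEY"))
res <- mine_peptides(p)
res
#> pepminer result: 1 precursor(s), 4 mature peptide(s)
#>   families: RPCH (1), sulfakinin (1), tachykinin (1), unassigned (1)
res$peptides[, c("peptide_start", "peptide_end", "rendered", "family")]
#>   peptide_start peptide_end               rendered     family
#> 1            21          28         pQLNFSPGWamide       RPCH
#> 2            32          40         APSGFLGMRamide tachykinin
#> 3            44          53 pQFDEY(SO3H)GHMRFamide sulfakinin
#> 4            57          61                  DNHEY unassigned
```

Reading the output: the heuristic called a 20-residue signal peptide
(the `...AGA` junction); three `KR` sites released three fragments; each
lost its `KR` to carboxypeptidase trimming and its terminal `G` to
amidation; `Q` starts became pyroglutamate (`pQ`); the tyrosine before
`GHMRF` was flagged sulfated; and the motif library named the families.
The C-terminal leftover `DNHEY` stays unassigned. `write_report()` emits
the same rows as TSV or nested JSON.

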