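---
title: "Annotating neuropeptide precursors with pepminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating neuropeptide precursors with pepminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepminer)
```

## The processing model

A neuropeptide precursor (prepropeptide) is processed in a fixed order
that this package makes explicit and testable:

1. **Signal peptide removal.** The signal peptidase cleaves after a short
   N-terminal signal (18–35 residues in the decapod precursors this
   package was designed around).
2. **Convertase cleavage.** Prohormone convertases cut after basic-residue
   sites in the proprotein. We commit to a concrete rule set in the
   tradition of Veenstra's processing standards: `KR` and `RR` are always
   cleaved; `KK` and `RK` are cleaved when enabled (default on); a lone
   `R` is cleaved only when another basic residue sits at offset −3, −5 or
   −7. A proline immediately after the scissile bond blocks cleavage, as
   does a cysteine flanking the bond (a disulfide-constrained region is
   not processed). Every sub-rule is a `cleavage_rules()` toggle, because
   published mining studies rarely restate which variant they used.
3. **Carboxypeptidase trimming.** The basic residues a site leaves on the
   upstream fragment are removed — exactly the site's own residues (2 for
   a dibasic, 1 for a monobasic), never more, so a peptide that genuinely
   ends in `R` keeps it.
4. **Amidation.** A now-terminal glycine donates the C-terminal amide,
   but only when the fragment was actually followed by a cleavage site or
   the true precursor end — a glycine at a truncation edge is not
   evidence.
5. **Pyroglutamate.** An N-terminal `Q` cyclizes (rendered `pQ`).
   Glutamate cyclization exists in some lineages and is available as
   `pyroglu_E`, but is off by default because every `pQ` peptide in the
   compiled reference set begins with Q.
6. **Cysteines.** Counted per peptide; exactly two imply one disulfide
   bridge. More than two (the 6- and 8-Cys frameworks of the structured
   families) are counted but connectivity is not predicted.
7. **Sulfation.** The only sulfotyrosine the pipeline ever emits is the
   sulfakinin context: a `Y` directly preceding a C-terminal `GH[ML]RF`
   on an amidated peptide.

The processing engine conserves residues: concatenating the raw fragments
restores the proprotein exactly, and every mature peptide is a prefix of
its fragment. These are tested properties, not aspirations.

## Signal peptides

The package's own predictor is deliberately simple and fully documented:
for each candidate cleavage position $c$ (last signal residue) in
$[15, 40]$,

$$\mathrm{score}(c) = w_h \cdot \overline{\mathrm{KD}}[c-12, c-3] +
  w_c \cdot \#\{\text{small residues at } c-2, c\}$$

with the Kyte–Doolittle scale, small $= \{A, G, S, C, T\}$ (the
(−3,−1) rule), defaults $w_h = 1$, $w_c = 0.5$ and call threshold 1.2.
The search window $[15, 40]$ brackets the 18–35aa signals seen across
the reference decapod precursors. This heuristic is a stand-in for
dedicated predictors, which is why `import_signal_annotations()` exists:
external calls always override the heuristic. Precursors with no call
(N-terminally truncated assemblies are common; kinin- and trissin-type
precursors in the reference repertoire lack signals entirely) are still
processed — the whole protein is treated as proprotein and the first
fragment is flagged `partial_n`, mirroring how published studies report
"the first peptide lacks its N-terminus".

## The motif library

`inst/extdata/motif_library.tsv` compiles the family signatures of the
decapod neuropeptide literature in conventional X-notation (`X` = any
residue, brackets = single-position alternatives, `amide` = a PTM flag,
not sequence). Slash alternations in printed motifs (`NFL/IRFamide`,
`PXXRLRF/Yamide`) are interpreted as single-position alternatives
(`NF[LI]RF`, `PXXRLR[FY]`), consistent with every printed example.
Single-sequence families identified by identity rather than motif
(proctolin `RYLPT`, CCAP `PFCNAFTGCamide`, RPCH `pQLNFSPGWamide`, …) are
exact-anchor rows in the same file. Two documented quirks:

* The C-type allatostatin motif is usually quoted as `XCXFNXXSCFX`, but
  two of the three printed AST-C peptides *end* at the final `F`. Since
  `X` never matches the empty string, the shipped row is `CXFNXXSCF`
  (anchor `anywhere`), which accepts all printed isoforms.
* The AST-B/W(X6)Wamide family is printed both with and without a
  trailing `G` (`ADWSSMRGTWGamide` vs `ADWSSMRGTWamide`); the library
  carries both variants rather than resolving the discrepancy.

A peptide may match several families (signatures overlap); all matches
are returned ordered by matched span then library order, and the pipeline
keeps the best. `requires_amide` motifs never match non-amidated
peptides.

## Structural typing

The CHH-superfamily call table operates on processed fragments: the
mature peptide is the longest fragment; any fragment between signal and
mature is a CHH precursor-related peptide (CPRP). CPRP present ⇒ type-I
CHH (even with an aberrant cysteine count — partial precursors occur);
no CPRP but glycine at mature position 12 ⇒ type-II MIH/GIH; neither,
with a 6-cysteine mature ⇒ CHH-MIH-like. `check_aiaxx()` tests the
conserved caridean type-I C-terminus (`AIAXX`, i.e. positions
end−4..end−2 equal `A,I,A`). `classify_chh()` applies the table as
stated, for use on CHH candidates; the pipeline report additionally
gates the call on structural plausibility (a ≥4-cysteine mature, or a
CPRP ahead of a ≥60aa mature) so arbitrary multi-copy precursors are not
reported as CHHs. The cost is that heavily truncated CHH fragments
(e.g. a 20aa partial mature with one cysteine) are only typed when
called directly — such records are recognized by homology in practice,
which is out of scope here.

Insulin-like precursors are parsed strictly as signal–B–C–A with dibasic
separators, reporting chain spans after trimming, the B/A cysteine
counts and the gap between the 4th and 5th cysteine of the combined B+A
framework. Published chain lengths do not always sum to the precursor
length (site residues are assigned ambiguously in print); the parser
reports its own consistent spans and leaves reconciliation to the user.
CFSH-type precursors are parsed as PRP (first post-signal fragment) plus
a cysteine-rich mature remainder; with no internal site the record is
flagged and the whole proprotein taken as mature.

## The 7TM screen

`hydropathy_profile()` is a centered moving average (window 19) of
Kyte–Doolittle values with no-call (`NA`) ends; `count_tm_segments()`
takes maximal runs above threshold 1.6, merges runs separated by fewer
than 3 residues, discards runs under 15 residues, and flags 6–8
surviving segments as a 7TM candidate. These are the classical
sliding-window settings; all are arguments. Two practical notes. With a
19-residue window, a transmembrane helix flanked by strongly charged
loops yields a run shorter than the helix itself — mildly polar loops
(S/T/N-rich), as in real receptors' short loops, are detected cleanly.
And raising the threshold can only erode or remove runs, so the segment
count never increases with threshold *provided* inter-segment dips
already sit below the working threshold; below that regime two segments
can merge and the count is not monotone. The screen stops at 7TM
flagging: family-level receptor assignment needs phylogeny with
reference GPCRs and is out of scope.

## The synthetic generator

Every stage is validated against `generate_dataset()`, which emits
precursors with per-element ground truth. Design choices that make the
truth unambiguous, and what they imply about the tests:

* Motif instantiation draws `X` positions from the 20 amino acids
  excluding `K`, `R` (no spurious cleavage sites), `C` (deliberate
  cysteine frameworks only), `G` (no fake amidation donors), `P` (no
  accidental cleavage blocking) and `Q` at peptide starts (no fake
  pyroglutamate).
* Each copy carries a 7–12 residue N-terminal spacer drawn from
  hydrophilic, non-small residues (`D,E,N,H,Y`). The length ≥ 7
  guarantees no basic residue of one element can serve as monobasic
  support (offsets −3/−5/−7) for a residue of the next; the composition
  keeps the mature side of the signal junction from out-scoring the true
  cleavage position.
* Signals are tripartite by construction — `M` + 2–4 charged residues +
  a hydrophobic h-region (`L,I,V,F` with probability `h_strength`, else
  weak residues) + an `A-x-A` c-region. At `h_strength = 1` the
  heuristic recovers essentially every cleavage site exactly;
  `h_strength` exists to test graceful degradation.
* Copy counts default to the repertoire sizes of the reference data (up
  to 38 FGLamide copies, up to 12 tachykinin copies); cleavage sites are
  drawn from a `KR/RR/KK/RK/monobasic` mix, canonical-heavy and with no
  monobasic by default. A monobasic site is engineered by overwriting
  the residue at offset −5 with `K`, which may fall inside a motif; with
  monobasic sites enabled, sequence recovery still holds but family
  recovery is below 100% by design.
* Every precursor is at least 46 residues, the minimum the signal
  search window can operate on.

Passing recovery tests therefore show that the pipeline inverts its own
generative model exactly under canonical conditions — they do not show
robustness to real assembly noise: sequencing error, fragmented
assemblies with arbitrary truncation points, non-tripartite signals,
atypical processing (convertase-specific site preferences, partial
processing, N-terminal trimming) are all outside what the generator
emulates.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere; a cleavage site's
  position is its last basic residue; nucleotide spans are reported in
  forward-strand coordinates with the strand recorded.
* Overlapping dibasic candidates (`KKR`) resolve to the dibasic ending
  furthest downstream; output sites are strictly increasing and never
  share residues. Ties in signal scoring resolve to the smallest
  cleavage position. Both choices are for deterministic output.
* `N` in transcripts translates to `X`; ORFs containing `X` are kept but
  flagged. The longest ORF is the default precursor candidate (one
  precursor per transcript), with all ORFs available behind a flag.
* Empty fragments after trimming are dropped with a log message;
  fail-soft runs record per-record errors rather than aborting, so every
  input id appears in the result or the error table.
* Test and acceptance problem sizes (1,000 random 100-mers for the
  cleavage oracle, 40–50 precursor datasets for recovery, 60 random
  transcripts for the ORF oracle) were chosen so the whole suite runs in
  well under a minute while exercising every rule combination; they are
  ordinary desk-scale sizes for this kind of validation, not tuned
  quantities.
* The command-line front end (`inst/exec/pepminer`) is a thin wrapper
  over the exported functions; the functions are the interface of
  record.

## Known limitations

* The signal heuristic is not a trained predictor; on real data, import
  external calls.
* Monobasic cleavage in vivo is idiosyncratic; the −3/−5/−7 rule is a
  reproducible commitment, not a claim of completeness. Where published
  peptides are said to be separated by "carboxypeptidase sites" without
  printed residues, we treat the boundary as a monobasic site plus
  trimming and say so.
* Family assignment is motif identity, not homology: no HMMs, no
  alignment, no phylogeny. Headline repertoire counts of a transcriptome
  study (total transcripts, N50, family totals) depend on sequencing and
  assembly and cannot be reproduced by this package from printed data.
* Disulfide connectivity beyond the 2-cysteine case, alternative
  splicing reconstruction, and expression quantification are out of
  scope.
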