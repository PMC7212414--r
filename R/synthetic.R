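# Residue alphabets used by the generator.
# X positions and linker/pad residues exclude K and R (would create spurious
# cleavage sites), C (cysteine frameworks must be deliberate), G (would fake
# amidation signals), P (would block an adjacent site) and Q (would fake
# pyroglutamate at a peptide start).
SYN_X_ALPHABET <- c("A", "D", "E", "F", "H", "I", "L", "M", "N", "S", "T",
                    "V", "W", "Y")
# pads additionally avoid hydrophobic and small residues so that the mature
# side of a synthetic junction never out-scores the true signal cleavage
# position under the (-3,-1)/hydropathy heuristic
SYN_PAD_ALPHABET <- c("D", "E", "N", "H", "Y")

# family -> motif pattern used for copy instantiation (C-terminally
# amidated families only; exact-sequence families are listed separately)
SYN_MOTIF_PATTERNS <- c(
  "AST-A" = "YXFGL",
  "AST-B" = "XWXXXXGXW",
  "FLRFamide" = "NF[LI]RF",
  "kinin" = "XFX[AP]WA",
  "pyrokinin" = "PRL",
  "sNPF" = "PXXRLR[FY]",
  "natalisin" = "WXXR",
  "EFLamide" = "GSEFL",
  "RYamide" = "RY",
  "NPF" = "RPRF",
  "sulfakinin" = "YGH[ML]RF"
)
SYN_EXACT_PEPTIDES <- list(
  tachykinin = list(sequence = "APSGFLGMR", pyroglu = FALSE),
  RPCH = list(sequence = "QLNFSPGW", pyroglu = TRUE)
)
SYN_ARCHITECTURES <- c("CHH-type-I", "CHH-type-II", "CHH-MIH-like",
                       "IAG", "CFSH")

#' Specification for the synthetic precursor generator
#'
#' Defaults emulate the precursor architectures of decapod neuropeptide
#' transcriptomes: an 18-35 residue signal peptide, 1-40 peptide copies per
#' precursor flanked by mono-/dibasic cleavage sites, amidation glycines,
#' N-terminal glutamines, and (for the structured families) CHH-type,
#' insulin-like B-C-A and CFSH-type domain layouts with 2, 6 or 8 cysteine
#' frameworks.
#'
#' @param seed Integer seed; mandatory (no hidden global randomness).
#' @param n_precursors Number of precursors for [generate_dataset()].
#' @param family_mix Named numeric vector of family proportions (must sum
#'   to 1). Families are the motif families, `tachykinin`/`RPCH`
#'   (exact-sequence) or the architectures `CHH-type-I`, `CHH-type-II`,
#'   `CHH-MIH-like`, `IAG`, `CFSH`.
#' @param signal_len_range Signal-peptide length range, residues.
#' @param copies Named list family -> `c(min, max)` copy counts; families
#'   not listed use `default_copies`. Defaults mirror observed repertoires
#'   (up to 38 FGLamide copies, up to 12 tachykinin copies).
#' @param default_copies Fallback copy-count range.
#' @param site_mix Proportions of cleavage-site patterns placed after each
#'   copy: `KR`, `RR`, `KK`, `RK`, `monobasic`. The default is
#'   canonical/extended dibasics only; a nonzero `monobasic` fraction
#'   engineers a supporting basic residue at offset -5, which may overwrite
#'   a motif residue (family recovery is then below 100% by design).
#' @param pyroglu_rate Probability that a motif-family copy starts with Q.
#' @param h_strength Probability that each h-region residue is drawn from
#'   the strongly hydrophobic set (L,I,V,F) rather than a weak set; lower
#'   values make signal recovery harder.
#' @param tail_len_range Length range of the unprocessed C-terminal tail.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_precursors = 20L,
                           family_mix = NULL,
                           signal_len_range = c(18L, 35L),
                           copies = list("AST-A" = c(2L, 38L),
                                         "AST-B" = c(2L, 12L),
                                         tachykinin = c(2L, 12L)),
                           default_copies = c(1L, 6L),
                           site_mix = c(KR = 0.7, RR = 0.1, KK = 0.1,
                                        RK = 0.1, monobasic = 0),
                           pyroglu_rate = 0.2,
                           h_strength = 1.0,
                           tail_len_range = c(0L, 10L)) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(family_mix)) {
    fams <- c(names(SYN_MOTIF_PATTERNS), names(SYN_EXACT_PEPTIDES))
    family_mix <- stats::setNames(rep(1 / length(fams), length(fams)), fams)
  }
  if (abs(sum(family_mix) - 1) > 1e-8) stop("family_mix must sum to 1")
  if (abs(sum(site_mix) - 1) > 1e-8) stop("site_mix must sum to 1")
  stopifnot(signal_len_range[1L] >= 15L, signal_len_range[2L] <= 40L)
  structure(list(seed = as.integer(seed), n_precursors = n_precursors,
                 family_mix = family_mix,
                 signal_len_range = signal_len_range,
                 copies = copies, default_copies = default_copies,
                 site_mix = site_mix, pyroglu_rate = pyroglu_rate,
                 h_strength = h_strength, tail_len_range = tail_len_range),
            class = "synthetic_spec")
}

r_int <- function(range) {
  if (range[1L] >= range[2L]) return(as.integer(range[1L]))
  sample(seq.int(range[1L], range[2L]), 1L)
}

# tripartite signal: M + charged n-region + hydrophobic h-region +
# small-residue c-region ending A-x-A (small at the -3/-1 positions)
syn_signal <- function(len, h_strength) {
  n_len <- min(4L, max(2L, len - 16L))
  h_len <- len - 1L - n_len - 3L
  strong <- c("L", "I", "V", "F")
  weak <- c("A", "S", "T", "G")
  h <- ifelse(stats::runif(h_len) < h_strength,
              sample(strong, h_len, replace = TRUE),
              sample(weak, h_len, replace = TRUE))
  paste0("M",
         paste(sample(c("K", "R", "D", "E"), n_len, replace = TRUE),
               collapse = ""),
         paste(h, collapse = ""),
         "A", sample(c("N", "E", "H", "D", "Y"), 1L), "A")
}

syn_instantiate_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  out <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      alts <- character()
      while (chars[j] != "]") { alts <- c(alts, chars[j]); j <- j + 1L }
      out <- c(out, sample(alts, 1L))
      i <- j + 1L
    } else if (ch == "X") {
      out <- c(out, sample(SYN_X_ALPHABET, 1L))
      i <- i + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# cysteine-framework domain for the structured families; position 1 is
# never C (a cysteine flanking the upstream scissile bond blocks cleavage)
syn_cys_domain <- function(len, n_cys, gly12 = FALSE, aiaxx = FALSE) {
  body <- sample(SYN_X_ALPHABET, len, replace = TRUE)
  reserved <- 1L
  if (gly12) { body[12L] <- "G"; reserved <- c(reserved, 12L) }
  if (aiaxx) {
    body[(len - 4L):(len - 2L)] <- c("A", "I", "A")
    reserved <- c(reserved, (len - 4L):(len - 2L))
  } else if (len >= 5L && identical(body[(len - 4L):(len - 2L)],
                                    c("A", "I", "A"))) {
    body[len - 3L] <- "L"   # avoid accidental AIAXX
  }
  free <- setdiff(seq_len(len), reserved)
  body[sample(free, n_cys)] <- "C"
  paste(body, collapse = "")
}

syn_draw_site <- function(site_mix) {
  sample(names(site_mix), 1L, prob = site_mix)
}

# one peptide copy for a motif or exact family: mature sequence (without
# the amidation G), PTM flags
syn_peptide <- function(family, spec) {
  if (family %in% names(SYN_EXACT_PEPTIDES)) {
    e <- SYN_EXACT_PEPTIDES[[family]]
    return(list(sequence = e$sequence, amidated = TRUE,
                pyroglu = e$pyroglu))
  }
  pattern <- SYN_MOTIF_PATTERNS[[family]]
  if (is.null(pattern)) stop("unknown family: ", family)
  pad_len <- r_int(c(7L, 12L))
  pad <- sample(SYN_PAD_ALPHABET, pad_len, replace = TRUE)
  pyroglu <- stats::runif(1L) < spec$pyroglu_rate
  if (pyroglu) pad[1L] <- "Q"
  list(sequence = paste0(paste(pad, collapse = ""),
                         syn_instantiate_motif(pattern)),
       amidated = TRUE, pyroglu = pyroglu)
}

#' Generate one synthetic precursor with ground truth
#'
#' Builds `signal (+ optional precursor-related peptide) + [peptide copy +
#' amidation G + cleavage site] x k + tail` for repeat-copy families, or
#' the CHH / insulin-like / CFSH domain layout for architecture families,
#' and records the intended truth for every element.
#'
#' Call [set.seed()] first, pass `seed`, or use [generate_dataset()] which
#' seeds from the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param family Family name (see [synthetic_spec()]).
#' @param id Precursor id.
#' @param copies Copy count override (`NULL`: drawn from the spec ranges).
#' @param seed Optional integer seed for this single precursor.
#' @return List with `id`, `protein`, and `truth` (data.frame with columns
#'   `precursor_id`, `element_type`, `start`, `end`, `sequence`, `family`,
#'   `amidated`, `pyroglu`).
#' @export
generate_precursor <- function(spec, family, id = "syn1", copies = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- c(names(SYN_MOTIF_PATTERNS), names(SYN_EXACT_PEPTIDES),
             SYN_ARCHITECTURES)
  if (!family %in% known) stop("unknown family: ", family)
  sig_len <- r_int(spec$signal_len_range)
  sig <- syn_signal(sig_len, spec$h_strength)
  truth <- list()
  add <- function(type, start, end, sequence, fam = family,
                  amidated = FALSE, pyroglu = FALSE) {
    truth[[length(truth) + 1L]] <<- data.frame(
      precursor_id = id, element_type = type, start = start, end = end,
      sequence = sequence, family = fam, amidated = amidated,
      pyroglu = pyroglu, stringsAsFactors = FALSE)
  }
  add("signal", 1L, sig_len, sig, fam = "")
  pos <- sig_len
  parts <- sig

  append_part <- function(s) {
    parts <<- paste0(parts, s)
    pos <<- pos + nchar(s)
  }

  if (family %in% SYN_ARCHITECTURES) {
    arch <- switch(family,
      "CHH-type-I" = {
        cprp <- paste(sample(SYN_PAD_ALPHABET, 37L, replace = TRUE),
                      collapse = "")
        add("cprp", pos + 1L, pos + nchar(cprp), cprp)
        append_part(cprp)
        append_part("KR")
        mat <- syn_cys_domain(72L, 6L, aiaxx = TRUE)
        add("mature", pos + 1L, pos + nchar(mat), mat, amidated = TRUE)
        append_part(mat)
        append_part("G")
      },
      "CHH-type-II" = {
        mat <- syn_cys_domain(75L, 6L, gly12 = TRUE)
        add("mature", pos + 1L, pos + nchar(mat), mat, amidated = TRUE)
        append_part(mat)
        append_part("G")
      },
      "CHH-MIH-like" = {
        mat <- syn_cys_domain(104L, 6L)
        add("mature", pos + 1L, pos + nchar(mat), mat)
        append_part(mat)
      },
      "IAG" = {
        b <- syn_cys_domain(30L, 2L)
        add("b_chain", pos + 1L, pos + nchar(b), b)
        append_part(b); append_part("KR")
        cp <- paste(sample(SYN_X_ALPHABET, 42L, replace = TRUE),
                    collapse = "")
        add("c_peptide", pos + 1L, pos + nchar(cp), cp)
        append_part(cp); append_part("KR")
        a <- syn_cys_domain(45L, 6L)
        add("a_chain", pos + 1L, pos + nchar(a), a)
        append_part(a)
      },
      "CFSH" = {
        prp <- paste(sample(SYN_PAD_ALPHABET, 30L, replace = TRUE),
                     collapse = "")
        add("prp", pos + 1L, pos + nchar(prp), prp)
        append_part(prp); append_part("KR")
        mat <- syn_cys_domain(163L, 8L)
        add("mature", pos + 1L, pos + nchar(mat), mat)
        append_part(mat)
      })
  } else {
    k <- if (!is.null(copies)) copies else {
      rng <- spec$copies[[family]]
      if (is.null(rng)) rng <- spec$default_copies
      r_int(rng)
    }
    for (j in seq_len(k)) {
      p <- syn_peptide(family, spec)
      chunk <- paste0(p$sequence, if (p$amidated) "G" else "")
      site <- syn_draw_site(spec$site_mix)
      if (site == "monobasic") {
        cv <- strsplit(chunk, "")[[1L]]
        cv[length(cv) - 4L] <- "K"   # support basic at offset -5 from the R
        chunk <- paste(cv, collapse = "")
        p$sequence <- substr(chunk, 1L,
                             nchar(p$sequence))
        site_res <- "R"
      } else {
        site_res <- site
      }
      add("peptide", pos + 1L, pos + nchar(p$sequence), p$sequence,
          amidated = p$amidated, pyroglu = p$pyroglu)
      append_part(chunk)
      append_part(site_res)
    }
    # keep every precursor inside the signal search window (the heuristic
    # needs > max_len + 5 residues to make a call)
    tail_len <- max(r_int(spec$tail_len_range), 46L - pos)
    if (tail_len > 0L) {
      tail <- paste(sample(SYN_PAD_ALPHABET, tail_len, replace = TRUE),
                    collapse = "")
      add("tail", pos + 1L, pos + tail_len, tail, fam = "")
      append_part(tail)
    }
  }
  list(id = id, protein = parts,
       truth = do.call(rbind, truth))
}

#' Generate a synthetic precursor dataset with ground truth
#'
#' Draws `n_precursors` families from `family_mix`, generates each
#' precursor, and (optionally) writes a protein FASTA plus a truth TSV.
#' Identical `(seed, spec)` give byte-identical outputs.
#'
#' @param spec A [synthetic_spec()].
#' @param fasta,truth Optional output paths; written when non-`NULL`.
#' @return List with `records` (named character vector of proteins),
#'   `truth` (data.frame), and the paths written (or `NULL`).
#' @export
generate_dataset <- function(spec, fasta = NULL, truth = NULL) {
  set.seed(spec$seed)
  fams <- sample(names(spec$family_mix), spec$n_precursors, replace = TRUE,
                 prob = spec$family_mix)
  out <- vector("list", spec$n_precursors)
  for (i in seq_len(spec$n_precursors)) {
    out[[i]] <- generate_precursor(
      spec, fams[i],
      id = sprintf("syn%03d_%s", i, gsub("[^A-Za-z0-9]", "", fams[i])))
  }
  records <- stats::setNames(vapply(out, `[[`, character(1), "protein"),
                             vapply(out, `[[`, character(1), "id"))
  truth_df <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(truth_df) <- NULL
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(truth)) {
    utils::write.table(truth_df, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(records = records, truth = truth_df, fasta = fasta,
       truth_path = truth)
}
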