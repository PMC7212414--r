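#' Translate one nucleotide string in a single frame
#'
#' Codons containing `N` translate to `X`; trailing partial codons are
#' dropped. The standard genetic code (from [Biostrings::GENETIC_CODE]) is
#' used, with `*` for stop.
#'
#' @param nt Nucleotide string over `A,C,G,T,N`.
#' @param offset 0-based offset into `nt` (0, 1 or 2).
#' @return Amino-acid string possibly containing `*` and `X`.
#' @keywords internal
translate_frame <- function(nt, offset = 0L) {
  n <- nchar(nt)
  usable <- n - offset
  n_codon <- usable %/% 3L
  if (n_codon < 1L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # any codon containing N (or other ambiguity)
  paste0(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#' @keywords internal
revcomp <- function(nt) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Six-frame open reading frame translation
#'
#' Finds ORFs (start codon `ATG` to stop) in all six frames of a transcript.
#' Within each stop-delimited region the ORF runs from the first `M` to the
#' region end. Regions truncated by the sequence edge yield partial ORFs:
#' missing stop (`partial_c`) and, for the first region of a frame with no
#' internal start, missing start (`partial_n`). ORFs whose protein contains
#' `X` (from assembly `N`s) are kept but flagged.
#'
#' @param id Transcript id.
#' @param nt Nucleotide sequence over `A,C,G,T,N`.
#' @param min_protein_len Minimum protein length to report (>= 10).
#' @param longest_only If `TRUE` return only the longest ORF (the default
#'   precursor candidate: one precursor per transcript).
#' @param include_partial Include ORFs lacking a start and/or stop at the
#'   sequence edge.
#' @return data.frame with columns `id`, `protein`, `frame` (+1..+3, -1..-3),
#'   `strand`, `nt_start`, `nt_end` (1-based inclusive, forward-strand
#'   coordinates of the translated span), `partial_n`, `partial_c`, `has_x`;
#'   sorted longest protein first.
#' @export
translate_orfs <- function(id, nt, min_protein_len = 30L,
                           longest_only = FALSE, include_partial = TRUE) {
  stopifnot(min_protein_len >= 10L)
  nt <- toupper(nt)
  n <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") nt else revcomp(nt)
    for (off in 0:2) {
      pep <- translate_frame(seq_s, off)
      if (nchar(pep) == 0L) next
      frame <- (off + 1L) * (if (strand == "+") 1L else -1L)
      # stop-delimited regions: (start, end, has_stop_after)
      stops <- gregexpr("\\*", pep)[[1L]]
      stops <- stops[stops > 0L]
      bounds <- c(0L, stops, nchar(pep) + 1L)
      for (k in seq_len(length(bounds) - 1L)) {
        rs <- bounds[k] + 1L
        re <- bounds[k + 1L] - 1L
        if (re < rs) next
        region <- substr(pep, rs, re)
        has_stop <- bounds[k + 1L] <= nchar(pep)
        m <- regexpr("M", region)
        cands <- list()
        if (m > 0L) {
          cands[[1L]] <- c(rs + m - 1L, re, 0L)          # started ORF
        }
        if (k == 1L && (m != 1L) && include_partial) {
          cands[[length(cands) + 1L]] <- c(rs, re, 1L)    # edge, no start
        }
        for (cc in cands) {
          ps <- cc[1L]; pe <- cc[2L]
          prot <- substr(pep, ps, pe)
          if (nchar(prot) < min_protein_len) next
          partial_c <- !has_stop
          partial_n <- cc[3L] == 1L
          if (!include_partial && (partial_c || partial_n)) next
          s_nt <- off + 1L + 3L * (ps - 1L)
          e_nt <- off + 3L * pe
          if (strand == "-") {
            tmp <- c(n - e_nt + 1L, n - s_nt + 1L)
            s_nt <- tmp[1L]; e_nt <- tmp[2L]
          }
          out[[length(out) + 1L]] <- data.frame(
            id = id, protein = prot, frame = frame, strand = strand,
            nt_start = s_nt, nt_end = e_nt,
            partial_n = partial_n, partial_c = partial_c,
            has_x = grepl("X", prot, fixed = TRUE),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), protein = character(),
                      frame = integer(), strand = character(),
                      nt_start = integer(), nt_end = integer(),
                      partial_n = logical(), partial_c = logical(),
                      has_x = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$protein), res$frame, res$nt_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  if (longest_only && nrow(res) > 0L) res <- res[1L, , drop = FALSE]
  res
}
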