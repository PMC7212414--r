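#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices. This is the single hydropathy scale used
#' anywhere in the package (signal-peptide scoring and transmembrane
#' detection), so the two screens are directly comparable.
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Per-residue hydropathy values for a protein
#'
#' Unknown residues (e.g. `X`) get hydropathy 0.
#'
#' @param protein Amino-acid string.
#' @return Numeric vector, one value per residue.
#' @keywords internal
residue_hydropathy <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  h <- unname(kyte_doolittle[aa])
  h[is.na(h)] <- 0
  h
}

#' Sliding-window hydropathy profile
#'
#' Centered moving average of Kyte-Doolittle values. The `(window - 1) / 2`
#' residues at each end, where the window does not fit, are `NA` (no call).
#'
#' @param protein Amino-acid string, length at least `window`.
#' @param window Odd window width in residues (default 19, the classical
#'   transmembrane setting).
#' @return Numeric vector of length `nchar(protein)` with `NA` ends.
#' @examples
#' hydropathy_profile(strrep("I", 19))[10]  # 4.5, the scale maximum
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- nchar(protein)
  if (n < window) {
    stop("protein shorter than the smoothing window (", n, " < ", window, ")")
  }
  h <- residue_hydropathy(protein)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, h))
  centre <- (half + 1L):(n - half)
  prof <- rep(NA_real_, n)
  prof[centre] <- (cs[centre + half + 1L] - cs[centre - half]) / window
  prof
}

#' Count transmembrane segments in a hydropathy profile
#'
#' Maximal runs of profile values above `threshold` are candidate
#' transmembrane segments; runs separated by fewer than `merge_gap` residues
#' are merged, then runs shorter than `min_tm_len` are discarded. A protein
#' with 6-8 surviving segments is flagged as a candidate 7TM receptor.
#'
#' @param profile Numeric vector from [hydropathy_profile()] (`NA` ends allowed).
#' @param threshold Hydropathy cutoff for membrane-spanning character.
#' @param min_tm_len Minimum segment length in residues.
#' @param merge_gap Runs separated by fewer than this many residues are merged.
#' @return Object of class `tm_annotation`: list with `segments`
#'   (data.frame `start`, `end`), `n_tm`, `candidate_7tm`, and the input
#'   `profile`.
#' @export
count_tm_segments <- function(profile, threshold = 1.6, min_tm_len = 15L,
                              merge_gap = 3L) {
  above <- !is.na(profile) & profile > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  if (nrow(seg) > 1L) {
    keep_start <- seg$start[1L]
    merged <- list()
    for (i in seq_len(nrow(seg) - 1L)) {
      gap <- seg$start[i + 1L] - seg$end[i] - 1L
      if (gap >= merge_gap) {
        merged[[length(merged) + 1L]] <- c(keep_start, seg$end[i])
        keep_start <- seg$start[i + 1L]
      }
    }
    merged[[length(merged) + 1L]] <- c(keep_start, seg$end[nrow(seg)])
    m <- do.call(rbind, merged)
    seg <- data.frame(start = m[, 1L], end = m[, 2L])
  }
  seg <- seg[seg$end - seg$start + 1L >= min_tm_len, , drop = FALSE]
  rownames(seg) <- NULL
  n_tm <- nrow(seg)
  structure(
    list(profile = profile, segments = seg, n_tm = n_tm,
         candidate_7tm = n_tm >= 6L && n_tm <= 8L),
    class = "tm_annotation"
  )
}

#' Screen a protein for seven-transmembrane (GPCR-like) architecture
#'
#' Convenience wrapper: hydropathy profile plus segment counting.
#'
#' @inheritParams hydropathy_profile
#' @inheritParams count_tm_segments
#' @return See [count_tm_segments()].
#' @export
screen_gpcr <- function(protein, window = 19L, threshold = 1.6,
                        min_tm_len = 15L, merge_gap = 3L) {
  count_tm_segments(hydropathy_profile(protein, window),
                    threshold = threshold, min_tm_len = min_tm_len,
                    merge_gap = merge_gap)
}

#' @export
print.tm_annotation <- function(x, ...) {
  cat("Transmembrane screen:", x$n_tm, "segment(s);",
      if (x$candidate_7tm) "candidate 7TM receptor" else "not a 7TM candidate",
      "\n")
  if (x$n_tm > 0L) {
    spans <- paste0(x$segments$start, "-", x$segments$end, collapse = ", ")
    cat("  segments:", spans, "\n")
  }
  invisible(x)
}
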