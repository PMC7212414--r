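#' Predict the signal-peptide cleavage position of a precursor
#'
#' A deliberately simple, fully documented stand-in for a dedicated
#' signal-peptide predictor, built from the two classical features of a
#' cleaved signal: a hydrophobic h-region just upstream of the junction and
#' small residues at the -3 and -1 positions of the cleavage site (the
#' von Heijne (-3,-1) rule). External predictor output can be imported with
#' [import_signal_annotations()] and always overrides this heuristic.
#'
#' For each candidate cleavage position `c` (the last residue of the signal,
#' 1-based) in `[min_len, max_len]` the score is
#' `w_h * mean(KD[c-12 .. c-3]) + w_c * (#small residues at c-2 and c)`
#' where KD is the Kyte-Doolittle hydropathy and "small" is `A,G,S,C,T`.
#' The best-scoring position is called if its score reaches `threshold`;
#' ties resolve to the smallest `c`.
#'
#' @param protein Precursor amino-acid string; must be longer than
#'   `max_len + 5` residues.
#' @param min_len,max_len Search window for the signal length (defaults 15
#'   and 40 bracket the signal lengths seen in decapod precursors, 18-35aa).
#' @param w_h,w_c Weights of the hydropathy and small-residue terms.
#' @param threshold Minimum score for a call.
#' @return A list of class `signal_call` with `cleavage_after` (`NA` for
#'   no-call), `score`, `source` (`"heuristic"` or `"none"`) and `reason`
#'   when no call is made.
#' @examples
#' p <- paste0("MKR", strrep("L", 14), "AQA", "DEQFNRSPT", strrep("E", 20))
#' predict_signal(p)$cleavage_after  # 20: the second A of ...AQA
#' @export
predict_signal <- function(protein, min_len = 15L, max_len = 40L,
                           w_h = 1.0, w_c = 0.5, threshold = 1.2) {
  n <- nchar(protein)
  if (n < max_len + 5L) {
    return(structure(list(cleavage_after = NA_integer_, score = NA_real_,
                          source = "none",
                          reason = "protein too short for signal search"),
                     class = "signal_call"))
  }
  small <- c("A", "G", "S", "C", "T")
  h <- residue_hydropathy(protein)
  aa <- strsplit(protein, "")[[1]]
  cand <- min_len:min(max_len, n - 1L)
  cand <- cand[cand - 12L >= 1L]
  scores <- vapply(cand, function(cc) {
    hyd <- mean(h[(cc - 12L):(cc - 3L)])
    bonus <- sum(aa[c(cc - 2L, cc)] %in% small)
    w_h * hyd + w_c * bonus
  }, numeric(1))
  best <- which.max(scores)
  if (length(best) == 0L || scores[best] < threshold) {
    return(structure(list(cleavage_after = NA_integer_, score = NA_real_,
                          source = "none", reason = "no position above threshold"),
                     class = "signal_call"))
  }
  structure(list(cleavage_after = cand[best], score = scores[best],
                 source = "heuristic", reason = NULL),
            class = "signal_call")
}

#' @export
print.signal_call <- function(x, ...) {
  if (is.na(x$cleavage_after)) {
    cat("Signal peptide: no call (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Signal peptide: residues 1-%d (%s, score %.2f)\n",
                x$cleavage_after, x$source, x$score))
  }
  invisible(x)
}

#' Import external signal-peptide annotations
#'
#' Reads a two-column TSV (`id`, `cleavage_after`) as produced from an
#' external signal-peptide predictor. Imported calls override the built-in
#' heuristic downstream.
#'
#' @param path TSV file with a header row naming at least `id` and
#'   `cleavage_after`.
#' @param known_ids Optional character vector; ids in the file but not in
#'   `known_ids` trigger a warning listing them.
#' @return Named list of `signal_call` objects (`source = "external"`),
#'   keyed by id.
#' @export
import_signal_annotations <- function(path, known_ids = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  if (!all(c("id", "cleavage_after") %in% names(tab))) {
    stop("annotation TSV must have columns 'id' and 'cleavage_after'")
  }
  pos <- suppressWarnings(as.integer(tab$cleavage_after))
  bad <- is.na(pos) | pos < 1L
  if (any(bad)) {
    stop("malformed cleavage_after in row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (!is.null(known_ids)) {
    unknown <- setdiff(tab$id, known_ids)
    if (length(unknown) > 0L) {
      warning("annotations for unknown id(s): ",
              paste(unknown, collapse = ", "))
    }
  }
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(cleavage_after = pos[i], score = 1.0, source = "external",
                   reason = NULL), class = "signal_call")
  })
  names(calls) <- tab$id
  calls
}
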