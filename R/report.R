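#' Write an annotation report
#'
#' TSV: one row per mature peptide with a fixed, deterministic column
#' order (`precursor_id`, `peptide_start`, `peptide_end`, `sequence`,
#' `rendered`, `family`, `motif`, `amidated`, `pyroglu`, `sulfoTyr`,
#' `n_cys`, `flags`); PTMs appear in the `rendered` column in conventional
#' notation (`pQ` prefix, `amide` suffix, `(SO3H)` on sulfated
#' tyrosines). JSON: one object per precursor with its peptides nested.
#' An empty result yields a header-only TSV (or empty JSON array).
#'
#' @param result A `pepmine_result` from [mine_peptides()], or a plain
#'   data.frame of peptide rows.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  is_result <- inherits(result, "pepmine_result")
  peptides <- if (is_result) result$peptides else result
  tsv_cols <- c("precursor_id", "peptide_start", "peptide_end", "sequence",
                "rendered", "family", "motif", "amidated", "pyroglu",
                "sulfoTyr", "n_cys", "flags")
  if (format == "tsv") {
    cols <- intersect(tsv_cols, names(peptides))
    ok <- tryCatch({
      utils::write.table(peptides[, cols, drop = FALSE], path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) {
      stop("cannot write report to '", path, "': ", conditionMessage(e))
    })
  } else {
    obj <- if (is_result) {
      lapply(seq_len(nrow(result$precursors)), function(i) {
        p <- result$precursors[i, ]
        peps <- peptides[peptides$precursor_id == p$precursor_id, ,
                         drop = FALSE]
        cols <- intersect(tsv_cols, names(peps))
        c(as.list(p), list(peptides = peps[, cols, drop = FALSE]))
      })
    } else {
      peptides
    }
    tryCatch(
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE),
      error = function(e) {
        stop("cannot write report to '", path, "': ", conditionMessage(e))
      })
  }
  invisible(path)
}
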