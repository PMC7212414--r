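#' Compile a family motif pattern
#'
#' Patterns use the conventional peptide-motif notation: `X` for any
#' residue, brackets for single-position alternatives (`[LI]`), literal
#' amino-acid letters otherwise. The `amide` suffix is not part of the
#' sequence pattern; C-terminal amidation is a PTM flag and is matched via
#' the library's `requires_amide` column. Anchors: `C-terminal`,
#' `N-terminal`, `anywhere`, or `exact` (whole-sequence identity, used for
#' single-sequence families identified by identity rather than motif).
#'
#' @param pattern Motif string.
#' @param anchor One of `"C-terminal"`, `"N-terminal"`, `"anywhere"`,
#'   `"exact"`.
#' @return A regular expression string.
#' @keywords internal
compile_motif <- function(pattern, anchor) {
  pat <- sub("amide$", "", pattern)
  chars <- strsplit(pat, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% c(LETTERS, "[", "]"))) {
    stop("uncompilable motif pattern: '", pattern, "'")
  }
  # brackets must be balanced, non-nested, non-empty
  depth <- 0L
  prev <- ""
  for (ch in chars) {
    if (ch == "[") {
      if (depth > 0L) stop("uncompilable motif pattern: '", pattern, "'")
      depth <- depth + 1L
    } else if (ch == "]") {
      if (depth == 0L || prev == "[") {
        stop("uncompilable motif pattern: '", pattern, "'")
      }
      depth <- depth - 1L
    }
    prev <- ch
  }
  if (depth != 0L) stop("uncompilable motif pattern: '", pattern, "'")
  re <- gsub("X", ".", pat)
  switch(anchor,
         "C-terminal" = paste0(re, "$"),
         "N-terminal" = paste0("^", re),
         "anywhere" = re,
         "exact" = paste0("^", re, "$"),
         stop("unknown anchor: ", anchor))
}

#' Load a peptide-family motif library
#'
#' Reads a TSV with columns `family`, `pattern`, `anchor`, `requires_amide`
#' (yes/no) and optional `min_len`, `max_len`, `note`. Each row is compiled
#' into a matcher; a row that fails to compile is an error naming the row.
#'
#' @param path TSV file; default is the library shipped with the package
#'   (signatures of the decapod neuropeptide families).
#' @return data.frame of class `motif_library` with an added `regex` column.
#' @export
load_motif_library <- function(path = system.file("extdata",
                                                  "motif_library.tsv",
                                                  package = "pepminer")) {
  lib <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("family", "pattern", "anchor", "requires_amide")
  if (nrow(lib) == 0L) {
    lib <- data.frame(family = character(), pattern = character(),
                      anchor = character(), requires_amide = character(),
                      stringsAsFactors = FALSE)
  }
  if (!all(need %in% names(lib))) {
    stop("motif library must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(lib$min_len)) lib$min_len <- rep(NA_integer_, nrow(lib))
  if (is.null(lib$max_len)) lib$max_len <- rep(NA_integer_, nrow(lib))
  lib$min_len <- suppressWarnings(as.integer(lib$min_len))
  lib$max_len <- suppressWarnings(as.integer(lib$max_len))
  lib$requires_amide <- tolower(as.character(lib$requires_amide)) %in%
    c("yes", "true", "1")
  lib$regex <- vapply(seq_len(nrow(lib)), function(i) {
    tryCatch(compile_motif(lib$pattern[i], lib$anchor[i]),
             error = function(e) {
               stop("row ", i, " (", lib$family[i], "): ",
                    conditionMessage(e), call. = FALSE)
             })
  }, character(1))
  class(lib) <- c("motif_library", "data.frame")
  lib
}

#' Classify one mature peptide against a motif library
#'
#' Returns every matching family, best first (longest matched span, ties
#' broken by library order). Motifs with `requires_amide` never match a
#' non-amidated peptide. An unmatched peptide yields a single
#' `"unassigned"` row.
#'
#' @param sequence Peptide string (without rendering decorations).
#' @param amidated Is the peptide C-terminally amidated?
#' @param lib A [load_motif_library()] object.
#' @return data.frame with `family`, `matched_pattern`, `match_start`,
#'   `match_end`.
#' @export
classify_peptide <- function(sequence, amidated = FALSE,
                             lib = load_motif_library()) {
  n <- nchar(sequence)
  hits <- list()
  for (i in seq_len(nrow(lib))) {
    if (lib$requires_amide[i] && !amidated) next
    if (!is.na(lib$min_len[i]) && n < lib$min_len[i]) next
    if (!is.na(lib$max_len[i]) && n > lib$max_len[i]) next
    m <- regexpr(lib$regex[i], sequence)
    if (m < 0L) next
    len <- attr(m, "match.length")
    hits[[length(hits) + 1L]] <- data.frame(
      family = lib$family[i], matched_pattern = lib$pattern[i],
      match_start = as.integer(m), match_end = as.integer(m) + len - 1L,
      lib_row = i, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) {
    return(data.frame(family = "unassigned", matched_pattern = NA_character_,
                      match_start = NA_integer_, match_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  span <- res$match_end - res$match_start + 1L
  res <- res[order(-span, res$lib_row), , drop = FALSE]
  res$lib_row <- NULL
  rownames(res) <- NULL
  res
}

#' Classify a table of mature peptides
#'
#' Adds the best family assignment (and its matched pattern) to a peptide
#' table from [process_proprotein()]. Classification is a pure function of
#' each (peptide, library) pair; row order never changes results. Edge
#' fragments of partial precursors are classified but can be excluded from
#' family counting downstream.
#'
#' @param peptides data.frame with at least `sequence` and `amidated`.
#' @param lib A [load_motif_library()] object.
#' @return `peptides` with `family` and `matched_pattern` columns added.
#' @export
classify_peptides <- function(peptides, lib = load_motif_library()) {
  if (nrow(peptides) == 0L) {
    peptides$family <- character(0)
    peptides$matched_pattern <- character(0)
    return(peptides)
  }
  best <- lapply(seq_len(nrow(peptides)), function(i) {
    classify_peptide(peptides$sequence[i], peptides$amidated[i], lib)[1L, ]
  })
  best <- do.call(rbind, best)
  peptides$family <- best$family
  peptides$matched_pattern <- best$matched_pattern
  peptides
}

#' Summarise family assignments
#'
#' @param assignments data.frame with columns `family` and (optionally)
#'   `precursor_id`.
#' @param count_partial Include edge fragments of partial precursors
#'   (columns `partial_n`/`partial_c`) in the counts; excluded by default.
#' @return data.frame `family`, `n_peptides`, `n_precursors`, ordered by
#'   decreasing peptide count then family name.
#' @export
summarize_families <- function(assignments, count_partial = FALSE) {
  a <- assignments
  if (!count_partial && all(c("partial_n", "partial_c") %in% names(a))) {
    a <- a[!(a$partial_n | a$partial_c), , drop = FALSE]
  }
  if (nrow(a) == 0L) {
    return(data.frame(family = character(), n_peptides = integer(),
                      n_precursors = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(a$precursor_id)) a$precursor_id <- ""
  fam <- sort(unique(a$family))
  out <- data.frame(
    family = fam,
    n_peptides = vapply(fam, function(f) sum(a$family == f), integer(1)),
    n_precursors = vapply(fam, function(f) {
      length(unique(a$precursor_id[a$family == f]))
    }, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_peptides, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
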