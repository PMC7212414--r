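#' Mine neuropeptide precursors end-to-end
#'
#' Full pipeline: (optional) six-frame ORF translation, signal-peptide
#' assignment, convertase cleavage-site prediction, peptide excision and
#' maturation (carboxypeptidase trimming, amidation, pyroglutamate,
#' sulfotyrosine), motif-based family classification and CHH-superfamily
#' structural typing.
#'
#' Precursors with no signal call (e.g. N-terminally truncated assemblies)
#' are still processed: the whole protein is treated as proprotein and the
#' first fragment is flagged `partial_n`.
#'
#' @param input Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param type `"protein"` (precursors) or `"nt"` (transcripts; the
#'   longest ORF of each transcript becomes its precursor candidate unless
#'   `longest_only = FALSE`).
#' @param signal_annotations Optional path to a TSV of external signal
#'   calls (`id`, `cleavage_after`) or a list from
#'   [import_signal_annotations()]; external calls override the heuristic.
#' @param lib Motif library from [load_motif_library()].
#' @param rules A [cleavage_rules()] object.
#' @param min_protein_len Minimum ORF protein length for `type = "nt"`.
#' @param longest_only For `type = "nt"`: keep only the longest ORF per
#'   transcript.
#' @param strict Stop on the first per-record error instead of recording
#'   it and continuing (fail-soft default: every input id ends up either
#'   annotated or in `$errors`).
#' @return Object of class `pepmine_result`: list with `peptides` (one row
#'   per mature peptide; columns `precursor_id`, `peptide_start`,
#'   `peptide_end`, `sequence`, `rendered`, `family`, `motif`, `amidated`,
#'   `pyroglu`, `sulfoTyr`, `n_cys`, `flags`), `precursors` (one row per
#'   precursor with signal and CHH-typing columns), `errors` (id,
#'   stage, message), and `families` (the [summarize_families()] table).
#' @export
mine_peptides <- function(input, type = c("protein", "nt"),
                          signal_annotations = NULL,
                          lib = load_motif_library(),
                          rules = cleavage_rules(),
                          min_protein_len = 30L, longest_only = TRUE,
                          strict = FALSE) {
  type <- match.arg(type)
  seqs <- if (is.character(input) && length(input) == 1L &&
              file.exists(input)) {
    read_fasta(input, type = type)
  } else input
  if (type == "nt") {
    prot <- character()
    for (id in names(seqs)) {
      orfs <- translate_orfs(id, seqs[[id]], min_protein_len,
                             longest_only = longest_only)
      if (nrow(orfs) > 0L) {
        ids <- if (nrow(orfs) == 1L) id else {
          paste0(id, "_orf", seq_len(nrow(orfs)))
        }
        prot[ids] <- orfs$protein
      }
    }
    seqs <- prot
  }
  ext <- NULL
  if (!is.null(signal_annotations)) {
    ext <- if (is.character(signal_annotations)) {
      import_signal_annotations(signal_annotations, known_ids = names(seqs))
    } else signal_annotations
  }

  pep_rows <- list()
  prec_rows <- list()
  errors <- data.frame(id = character(), stage = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (id in names(seqs)) {
    res <- tryCatch({
      protein <- seqs[[id]]
      sig <- if (!is.null(ext) && id %in% names(ext)) ext[[id]]
             else predict_signal(protein)
      no_signal <- is.na(sig$cleavage_after)
      signal_end <- if (no_signal) 0L else sig$cleavage_after
      proprotein <- substr(protein, signal_end + 1L, nchar(protein))
      peps <- process_proprotein(proprotein, rules = rules,
                                 partial_n = no_signal,
                                 offset = signal_end)
      peps <- classify_peptides(peps, lib)
      chh <- classify_chh(protein, signal_end, rules)
      # report CHH typing only for structurally plausible candidates: a
      # cysteine-framework mature domain, or a CPRP ahead of a long mature
      # (the call table itself is in classify_chh, for use on candidates)
      plausible <- chh$n_cys_mature >= 4L ||
        (chh$has_cprp && !is.null(chh$mature) && nchar(chh$mature) >= 60L)
      if (!plausible) {
        chh <- structure(list(call = "not-CHH", has_cprp = FALSE,
                              cprp_span = NULL, mature_span = NULL,
                              mature = NULL, gly12 = FALSE,
                              n_cys_mature = chh$n_cys_mature,
                              cys_positions = integer(), aiaxx = FALSE,
                              amidated = FALSE),
                         class = "chh_annotation")
      }
      list(protein = protein, sig = sig, peps = peps, chh = chh)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("record '", id, "': ", conditionMessage(res))
      errors <- rbind(errors, data.frame(
        id = id, stage = "process", message = conditionMessage(res),
        stringsAsFactors = FALSE))
      next
    }
    peps <- res$peps
    if (nrow(peps) > 0L) {
      flags <- apply(peps[, c("partial_n", "partial_c")], 1L, function(r) {
        paste(c(if (r[[1L]]) "partial_n", if (r[[2L]]) "partial_c"),
              collapse = ",")
      })
      pep_rows[[id]] <- data.frame(
        precursor_id = id, peptide_start = peps$start,
        peptide_end = peps$end, sequence = peps$sequence,
        rendered = vapply(seq_len(nrow(peps)), function(i) {
          render_peptide(peps$sequence[i], peps$amidated[i],
                         peps$pyroglu[i], peps$sulfo_tyr[i])
        }, character(1)),
        family = peps$family, motif = peps$matched_pattern,
        amidated = peps$amidated, pyroglu = peps$pyroglu,
        sulfoTyr = peps$sulfo_tyr, n_cys = peps$n_cys,
        disulfide = peps$disulfide, flags = flags,
        partial_n = peps$partial_n, partial_c = peps$partial_c,
        stringsAsFactors = FALSE)
    }
    chh <- res$chh
    prec_rows[[id]] <- data.frame(
      precursor_id = id, length = nchar(res$protein),
      signal_end = if (is.na(res$sig$cleavage_after)) NA_integer_
                   else res$sig$cleavage_after,
      signal_source = res$sig$source,
      n_peptides = nrow(peps),
      chh_call = chh$call,
      cprp_len = if (chh$has_cprp) {
        chh$cprp_span[2L] - chh$cprp_span[1L] + 1L
      } else NA_integer_,
      gly12 = chh$gly12, aiaxx = chh$aiaxx,
      n_cys_mature = chh$n_cys_mature,
      stringsAsFactors = FALSE)
  }
  peptides <- if (length(pep_rows) > 0L) {
    out <- do.call(rbind, pep_rows); rownames(out) <- NULL; out
  } else {
    data.frame(precursor_id = character(), peptide_start = integer(),
               peptide_end = integer(), sequence = character(),
               rendered = character(), family = character(),
               motif = character(), amidated = logical(),
               pyroglu = logical(), sulfoTyr = character(),
               n_cys = integer(), disulfide = character(),
               flags = character(), partial_n = logical(),
               partial_c = logical(), stringsAsFactors = FALSE)
  }
  precursors <- if (length(prec_rows) > 0L) {
    out <- do.call(rbind, prec_rows); rownames(out) <- NULL; out
  } else {
    data.frame(precursor_id = character(), length = integer(),
               signal_end = integer(), signal_source = character(),
               n_peptides = integer(), chh_call = character(),
               cprp_len = integer(), gly12 = logical(), aiaxx = logical(),
               n_cys_mature = integer(), stringsAsFactors = FALSE)
  }
  structure(list(peptides = peptides, precursors = precursors,
                 errors = errors,
                 families = summarize_families(peptides)),
            class = "pepmine_result")
}

#' @export
print.pepmine_result <- function(x, ...) {
  cat("pepminer result:", nrow(x$precursors), "precursor(s),",
      nrow(x$peptides), "mature peptide(s)\n")
  if (nrow(x$errors) > 0L) {
    cat("  ", nrow(x$errors), "record(s) failed (see $errors)\n")
  }
  if (nrow(x$families) > 0L) {
    top <- utils::head(x$families, 8L)
    cat("  families:",
        paste0(top$family, " (", top$n_peptides, ")", collapse = ", "),
        if (nrow(x$families) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.pepmine_result <- function(object, ...) {
  cat("Precursors:", nrow(object$precursors), "\n")
  cat("Mature peptides:", nrow(object$peptides),
      sprintf("(%d amidated, %d pyroGlu, %d with sulfoTyr)\n",
              sum(object$peptides$amidated),
              sum(object$peptides$pyroglu),
              sum(nzchar(object$peptides$sulfoTyr))))
  chh <- object$precursors$chh_call
  if (any(chh != "not-CHH")) {
    cat("CHH-superfamily calls:\n")
    print(table(chh[chh != "not-CHH"]))
  }
  cat("Family counts (partial fragments excluded):\n")
  print(object$families)
  invisible(object$families)
}

#' Classify pre-cleaved mature peptides
#'
#' Takes mature peptides written in conventional rendering (`pQ` prefix,
#' `amide` suffix, `(SO3H)` on sulfated tyrosines) — e.g. peptides
#' transcribed from the literature — parses the notation back into PTM
#' flags, and classifies each against the motif library. Malformed
#' renderings become row-level errors (`family = NA`, `error` column).
#'
#' @param peptides Named character vector of rendered peptides, or a FASTA
#'   path whose sequences are rendered peptides.
#' @param lib Motif library.
#' @return data.frame: `id`, `rendered`, `sequence`, `length`, `amidated`,
#'   `pyroglu`, `sulfo_tyr`, `n_cys`, `disulfide`, `family`,
#'   `matched_pattern`, `error`.
#' @export
run_precleaved <- function(peptides, lib = load_motif_library()) {
  if (is.character(peptides) && length(peptides) == 1L &&
      file.exists(peptides)) {
    set <- Biostrings::readBStringSet(peptides)
    peptides <- stats::setNames(as.character(set),
                                sub("\\s.*$", "", names(set)))
  }
  rows <- lapply(names(peptides), function(id) {
    rendered <- unname(peptides[[id]])
    parsed <- tryCatch(parse_rendered(rendered), error = function(e) e)
    if (inherits(parsed, "error")) {
      return(data.frame(id = id, rendered = rendered,
                        sequence = NA_character_, length = NA_integer_,
                        amidated = NA, pyroglu = NA, sulfo_tyr = "",
                        n_cys = NA_integer_, disulfide = NA_character_,
                        family = NA_character_,
                        matched_pattern = NA_character_,
                        error = conditionMessage(parsed),
                        stringsAsFactors = FALSE))
    }
    cys <- gregexpr("C", parsed$sequence, fixed = TRUE)[[1L]]
    cys <- cys[cys > 0L]
    fam <- classify_peptide(parsed$sequence, parsed$amidated, lib)[1L, ]
    data.frame(id = id, rendered = rendered, sequence = parsed$sequence,
               length = nchar(parsed$sequence),
               amidated = parsed$amidated, pyroglu = parsed$pyroglu,
               sulfo_tyr = paste(parsed$sulfo_tyr, collapse = ","),
               n_cys = length(cys),
               disulfide = if (length(cys) == 2L) {
                 paste(cys, collapse = "-")
               } else "",
               family = fam$family, matched_pattern = fam$matched_pattern,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
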