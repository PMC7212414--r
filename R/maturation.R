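#' Mature a raw fragment into a processed peptide
#'
#' Applies the established propeptide processing steps, in order:
#' \enumerate{
#'   \item carboxypeptidase trimming: the basic residues left on the
#'     fragment by its terminating cleavage site are removed (2 for a
#'     dibasic, 1 for a monobasic site, never more than 2);
#'   \item amidation: if the trimmed fragment ends in glycine and the
#'     fragment was followed by a cleavage site or the true precursor end,
#'     the glycine is removed and the peptide flagged amidated;
#'   \item pyroglutamate: an N-terminal glutamine (optionally glutamate) is
#'     flagged `pyroglu` (the residue is retained, rendered as `pQ`);
#'   \item cysteines are counted; exactly two imply one disulfide bridge.
#' }
#'
#' @param sequence Raw fragment string from [excise_peptides()].
#' @param start,end Fragment coordinates in the proprotein (1-based).
#' @param site_pattern Pattern of the terminating site (`NA` for the final
#'   fragment).
#' @param at_true_end Does the fragment end at a genuine precursor
#'   C-terminus (not a truncation)?
#' @param partial_n,partial_c Edge-fragment flags for partial precursors.
#' @param rules A [cleavage_rules()] object (for `pyroglu_E`).
#' @return A one-row data.frame with columns `sequence`, `start`, `end`,
#'   `amidated`, `pyroglu`, `sulfo_tyr` (comma-separated Y positions, `""`
#'   if none), `n_cys`, `disulfide` (`"i-j"` or `""`), `partial_n`,
#'   `partial_c`; or `NULL` if nothing remains after trimming (logged via
#'   message).
#' @examples
#' maturate("QLNFSPGWGKR", 1, 11, "KR")  # pQLNFSPGWamide
#' @export
maturate <- function(sequence, start, end, site_pattern = NA_character_,
                     at_true_end = TRUE, partial_n = FALSE, partial_c = FALSE,
                     rules = cleavage_rules()) {
  seq <- sequence
  # (1) carboxypeptidase: strip the site's own basics (at most 2)
  n_trim <- if (is.na(site_pattern)) 0L
            else if (startsWith(site_pattern, "monobasic")) 1L else 2L
  while (n_trim > 0L && nchar(seq) > 0L &&
         substr(seq, nchar(seq), nchar(seq)) %in% c("K", "R")) {
    seq <- substr(seq, 1L, nchar(seq) - 1L)
    n_trim <- n_trim - 1L
  }
  # (2) amidation from a C-terminal glycine
  followed <- !is.na(site_pattern) || at_true_end
  amidated <- FALSE
  if (followed && nchar(seq) > 0L &&
      substr(seq, nchar(seq), nchar(seq)) == "G" && !partial_c) {
    seq <- substr(seq, 1L, nchar(seq) - 1L)
    amidated <- TRUE
  }
  if (nchar(seq) == 0L) {
    message("fragment at ", start, "-", end, " empty after trimming; dropped")
    return(NULL)
  }
  # (3) pyroglutamate
  first <- substr(seq, 1L, 1L)
  pyro_set <- if (isTRUE(rules$pyroglu_E)) c("Q", "E") else "Q"
  pyroglu <- !partial_n && first %in% pyro_set
  # (4) cysteines
  cys <- gregexpr("C", seq, fixed = TRUE)[[1L]]
  cys <- cys[cys > 0L]
  n_cys <- length(cys)
  disulfide <- if (n_cys == 2L) paste(cys, collapse = "-") else ""
  data.frame(sequence = seq, start = start, end = start + nchar(seq) - 1L,
             amidated = amidated, pyroglu = pyroglu, sulfo_tyr = "",
             n_cys = n_cys, disulfide = disulfide,
             partial_n = partial_n, partial_c = partial_c,
             stringsAsFactors = FALSE)
}

#' Flag sulfated tyrosines in a sulfakinin-context peptide
#'
#' The only sulfation the pipeline ever emits is the sulfakinin signature:
#' a tyrosine directly preceding a C-terminal `GH[ML]RF` on an amidated
#' peptide is flagged sulfotyrosine.
#'
#' @param peptide One-row peptide data.frame from [maturate()].
#' @return The peptide with `sulfo_tyr` set to the flagged Y position(s).
#' @export
flag_sulfation <- function(peptide) {
  if (!isTRUE(peptide$amidated)) return(peptide)
  m <- regexpr("YGH[ML]RF$", peptide$sequence)
  if (m > 0L) peptide$sulfo_tyr <- as.character(m)
  peptide
}

#' Render a peptide in conventional notation
#'
#' `pQ` prefix for pyroglutamate, `(SO3H)` after each sulfated tyrosine,
#' `amide` suffix for C-terminal amidation. Rendering is injective over
#' (sequence, PTM flags).
#'
#' @param sequence Peptide string.
#' @param amidated,pyroglu Logical flags.
#' @param sulfo_tyr Integer vector of sulfated Y positions (or the
#'   comma-separated string stored in peptide tables).
#' @return Rendered string, e.g. `"pQLNFSPGWamide"`.
#' @export
render_peptide <- function(sequence, amidated = FALSE, pyroglu = FALSE,
                           sulfo_tyr = integer()) {
  if (is.character(sulfo_tyr)) {
    sulfo_tyr <- if (nzchar(sulfo_tyr)) {
      as.integer(strsplit(sulfo_tyr, ",")[[1L]])
    } else integer()
  }
  out <- sequence
  for (p in sort(sulfo_tyr, decreasing = TRUE)) {
    out <- paste0(substr(out, 1L, p), "(SO3H)",
                  substr(out, p + 1L, nchar(out)))
  }
  if (pyroglu) out <- paste0("p", out)
  if (amidated) out <- paste0(out, "amide")
  out
}

#' Parse conventional peptide notation back into sequence and PTM flags
#'
#' Inverse of [render_peptide()]; used to load mature peptides written in
#' the usual `pQ...amide` notation (e.g. peptides transcribed from the
#' literature) without their precursors.
#'
#' @param rendered Rendered peptide string.
#' @return List with `sequence`, `amidated`, `pyroglu`, `sulfo_tyr`
#'   (integer positions).
#' @export
parse_rendered <- function(rendered) {
  s <- rendered
  amidated <- grepl("amide$", s)
  if (amidated) s <- sub("amide$", "", s)
  pyroglu <- grepl("^pQ", s) || grepl("^pE", s)
  if (pyroglu) s <- sub("^p", "", s)
  sulfo <- integer()
  repeat {
    m <- regexpr("\\(SO3H\\)", s)
    if (m < 0L) break
    if (m == 1L || substr(s, m - 1L, m - 1L) != "Y") {
      stop("malformed rendering: (SO3H) not after Y in '", rendered, "'")
    }
    sulfo <- c(sulfo, m - 1L)
    s <- paste0(substr(s, 1L, m - 1L), substr(s, m + 6L, nchar(s)))
  }
  if (grepl("[^A-Z]", s)) stop("malformed rendering: '", rendered, "'")
  list(sequence = s, amidated = amidated, pyroglu = pyroglu,
       sulfo_tyr = sulfo)
}

#' Process a proprotein end-to-end into mature peptides
#'
#' Convenience wrapper chaining [find_cleavage_sites()],
#' [excise_peptides()], [maturate()] and [flag_sulfation()].
#'
#' @param proprotein Post-signal amino-acid string.
#' @param rules A [cleavage_rules()] object.
#' @param partial_n,partial_c Is the precursor truncated at either end?
#' @param offset Coordinate offset to add to peptide positions (residues of
#'   the precursor upstream of the proprotein, i.e. the signal length).
#' @return data.frame of mature peptides (possibly zero rows), columns as
#'   in [maturate()].
#' @export
process_proprotein <- function(proprotein, rules = cleavage_rules(),
                               partial_n = FALSE, partial_c = FALSE,
                               offset = 0L) {
  sites <- find_cleavage_sites(proprotein, rules)
  frags <- excise_peptides(proprotein, sites)
  n <- nrow(frags)
  peps <- vector("list", n)
  for (i in seq_len(n)) {
    p <- maturate(frags$sequence[i], frags$start[i], frags$end[i],
                  site_pattern = frags$site_pattern[i],
                  at_true_end = !partial_c,
                  partial_n = partial_n && i == 1L,
                  partial_c = partial_c && i == n,
                  rules = rules)
    if (!is.null(p)) peps[[i]] <- flag_sulfation(p)
  }
  peps <- peps[!vapply(peps, is.null, logical(1))]
  if (length(peps) == 0L) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), amidated = logical(),
                      pyroglu = logical(), sulfo_tyr = character(),
                      n_cys = integer(), disulfide = character(),
                      partial_n = logical(), partial_c = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, peps)
  if (offset != 0L) {
    out$start <- out$start + offset
    out$end <- out$end + offset
  }
  rownames(out) <- NULL
  out
}
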