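#' Check the conserved caridean CHH C-terminus (AIAXX)
#'
#' True iff the residues at positions `end-4 .. end-2` of the mature
#' peptide are `A`, `I`, `A` — i.e. the C-terminus matches `AIAXX` with two
#' residues after the conserved triplet.
#'
#' @param mature Mature-peptide string.
#' @return Logical flag; sequences shorter than 5 residues return `FALSE`
#'   with a warning.
#' @export
check_aiaxx <- function(mature) {
  n <- nchar(mature)
  if (n < 5L) {
    warning("mature peptide shorter than 5 residues; AIAXX undecidable")
    return(FALSE)
  }
  substr(mature, n - 4L, n - 2L) == "AIA"
}

#' Structural typing of a CHH-superfamily precursor
#'
#' Applies the structural call table for the crustacean hyperglycemic
#' hormone superfamily. The proprotein (precursor after signal removal) is
#' processed into fragments; the mature peptide is the longest fragment
#' after trimming. A CHH precursor-related peptide (CPRP) is any fragment
#' between the signal and the mature peptide, bounded by a cleavage site.
#' The call table:
#' \itemize{
#'   \item CPRP present: type-I CHH;
#'   \item no CPRP, glycine at mature position 12 (Gly12): type-II MIH/GIH;
#'   \item no CPRP, no Gly12, 6-cysteine mature: CHH-MIH-like;
#'   \item otherwise: not-CHH.
#' }
#' CPRP presence alone decides type-I even with an aberrant cysteine count,
#' so partial precursors still type correctly; the 6-cysteine framework is
#' only required for the CHH-MIH-like call.
#'
#' @param protein Precursor amino-acid string.
#' @param signal_end Last residue of the signal peptide (0 or `NA` for
#'   precursors with no signal call; the whole protein is then processed).
#' @param rules A [cleavage_rules()] object.
#' @return List of class `chh_annotation`: `call`, `has_cprp`, `cprp_span`,
#'   `mature_span` (precursor coordinates), `mature`, `gly12`,
#'   `n_cys_mature`, `cys_positions` (within the mature peptide), `aiaxx`,
#'   `amidated`.
#' @export
classify_chh <- function(protein, signal_end = 0L,
                         rules = cleavage_rules()) {
  if (is.na(signal_end)) signal_end <- 0L
  proprotein <- substr(protein, signal_end + 1L, nchar(protein))
  peps <- process_proprotein(proprotein, rules = rules,
                             offset = signal_end)
  not_chh <- structure(
    list(call = "not-CHH", has_cprp = FALSE, cprp_span = NULL,
         mature_span = NULL, mature = NULL, gly12 = FALSE,
         n_cys_mature = 0L, cys_positions = integer(), aiaxx = FALSE,
         amidated = FALSE),
    class = "chh_annotation")
  if (nrow(peps) == 0L) return(not_chh)
  mat_i <- which.max(nchar(peps$sequence))
  mature <- peps$sequence[mat_i]
  cprp_i <- if (mat_i > 1L) mat_i - 1L else NA_integer_
  has_cprp <- !is.na(cprp_i)
  gly12 <- nchar(mature) >= 12L && substr(mature, 12L, 12L) == "G"
  cys <- gregexpr("C", mature, fixed = TRUE)[[1L]]
  cys <- cys[cys > 0L]
  call <- if (has_cprp) "type-I-CHH"
          else if (gly12) "type-II-MIH/GIH"
          else if (length(cys) == 6L) "CHH-MIH-like"
          else "not-CHH"
  aiaxx <- nchar(mature) >= 5L && check_aiaxx(mature)
  structure(
    list(call = call, has_cprp = has_cprp,
         cprp_span = if (has_cprp) c(peps$start[cprp_i], peps$end[cprp_i]),
         mature_span = c(peps$start[mat_i], peps$end[mat_i]),
         mature = mature, gly12 = gly12, n_cys_mature = length(cys),
         cys_positions = cys, aiaxx = aiaxx,
         amidated = peps$amidated[mat_i]),
    class = "chh_annotation")
}

#' @export
print.chh_annotation <- function(x, ...) {
  cat("CHH-superfamily call:", x$call, "\n")
  if (x$has_cprp) {
    cat(sprintf("  CPRP: residues %d-%d (%daa)\n", x$cprp_span[1L],
                x$cprp_span[2L], x$cprp_span[2L] - x$cprp_span[1L] + 1L))
  }
  if (!is.null(x$mature_span)) {
    cat(sprintf("  mature: residues %d-%d (%daa), %d Cys%s%s%s\n",
                x$mature_span[1L], x$mature_span[2L], nchar(x$mature),
                x$n_cys_mature,
                if (x$gly12) ", Gly12" else "",
                if (x$aiaxx) ", AIAXX C-terminus" else "",
                if (x$amidated) ", amidated" else ""))
  }
  invisible(x)
}

#' Parse an insulin-like (B-C-A) precursor into chains
#'
#' Insulin-like androgenic gland hormone precursors are organised
#' signal - B chain - C peptide - A chain, the chains separated by dibasic
#' cleavage sites. The first post-signal fragment is the B chain, the
#' second the C peptide, the third the A chain. Cysteines are counted on
#' the B and A chains and the gap (residue count) between the 4th and 5th
#' cysteine of the combined B+A framework is reported.
#'
#' @inheritParams classify_chh
#' @return List of class `insulin_chains`: `b_span`, `c_span`, `a_span`
#'   (precursor coordinates of the trimmed chains), `b`, `c_pep`, `a`
#'   (sequences), `n_cys_b`, `n_cys_a`, `cys4_cys5_gap` (`NA` if fewer than
#'   5 combined cysteines).
#' @export
parse_insulin_chains <- function(protein, signal_end = 0L,
                                 rules = cleavage_rules()) {
  if (is.na(signal_end)) signal_end <- 0L
  proprotein <- substr(protein, signal_end + 1L, nchar(protein))
  sites <- find_cleavage_sites(proprotein, rules)
  internal <- sites[sites$position < nchar(proprotein), , drop = FALSE]
  if (nrow(internal) < 2L) stop("not insulin-like architecture: fewer than 2 internal cleavage sites")
  peps <- process_proprotein(proprotein, rules = rules, offset = signal_end)
  if (nrow(peps) < 3L) stop("not insulin-like architecture: fewer than 3 fragments")
  b <- peps$sequence[1L]; c_pep <- peps$sequence[2L]; a <- peps$sequence[3L]
  cys_b <- gregexpr("C", b, fixed = TRUE)[[1L]]; cys_b <- cys_b[cys_b > 0L]
  cys_a <- gregexpr("C", a, fixed = TRUE)[[1L]]; cys_a <- cys_a[cys_a > 0L]
  # combined B+A cysteines in precursor order
  comb <- c(peps$start[1L] - 1L + cys_b, peps$start[3L] - 1L + cys_a)
  gap <- if (length(comb) >= 5L) comb[5L] - comb[4L] - 1L else NA_integer_
  structure(
    list(b_span = c(peps$start[1L], peps$end[1L]),
         c_span = c(peps$start[2L], peps$end[2L]),
         a_span = c(peps$start[3L], peps$end[3L]),
         b = b, c_pep = c_pep, a = a,
         n_cys_b = length(cys_b), n_cys_a = length(cys_a),
         cys4_cys5_gap = gap),
    class = "insulin_chains")
}

#' @export
print.insulin_chains <- function(x, ...) {
  cat(sprintf("Insulin-like precursor: B %daa (%d Cys), C %daa, A %daa (%d Cys)\n",
              nchar(x$b), x$n_cys_b, nchar(x$c_pep), nchar(x$a), x$n_cys_a))
  if (!is.na(x$cys4_cys5_gap)) {
    cat("  Cys4-Cys5 gap:", x$cys4_cys5_gap, "residues\n")
  }
  invisible(x)
}

#' Parse a CFSH-type precursor architecture
#'
#' Crustacean female sex hormone precursors carry a precursor-related
#' peptide (PRP) between the signal and a long cysteine-rich mature
#' domain. The first post-signal fragment is the PRP; the mature peptide
#' is everything after the first internal cleavage site. Without any
#' internal site the whole proprotein is taken as mature and the
#' architecture is flagged as lacking a PRP.
#'
#' @inheritParams classify_chh
#' @return List of class `cfsh_architecture`: `prp_span` (or `NULL`),
#'   `mature_span`, `mature`, `n_cys_mature`, `has_prp`.
#' @export
parse_cfsh <- function(protein, signal_end = 0L, rules = cleavage_rules()) {
  if (is.na(signal_end)) signal_end <- 0L
  proprotein <- substr(protein, signal_end + 1L, nchar(protein))
  sites <- find_cleavage_sites(proprotein, rules)
  internal <- sites[sites$position < nchar(proprotein), , drop = FALSE]
  if (nrow(internal) == 0L) {
    cys <- gregexpr("C", proprotein, fixed = TRUE)[[1L]]
    cys <- cys[cys > 0L]
    return(structure(
      list(prp_span = NULL, has_prp = FALSE,
           mature_span = c(signal_end + 1L, nchar(protein)),
           mature = proprotein, n_cys_mature = length(cys)),
      class = "cfsh_architecture"))
  }
  cut <- internal$position[1L]
  prp_frag <- substr(proprotein, 1L, cut)
  prp <- maturate(prp_frag, 1L, cut, site_pattern = internal$pattern[1L])
  mature <- substr(proprotein, cut + 1L, nchar(proprotein))
  cys <- gregexpr("C", mature, fixed = TRUE)[[1L]]
  cys <- cys[cys > 0L]
  structure(
    list(prp_span = c(signal_end + prp$start, signal_end + prp$end),
         has_prp = TRUE,
         mature_span = c(signal_end + cut + 1L, nchar(protein)),
         mature = mature, n_cys_mature = length(cys)),
    class = "cfsh_architecture")
}

#' @export
print.cfsh_architecture <- function(x, ...) {
  cat("CFSH-type architecture:",
      if (x$has_prp) "PRP + mature" else "mature only (no PRP; flagged)",
      "\n")
  cat(sprintf("  mature: residues %d-%d (%daa), %d Cys\n",
              x$mature_span[1L], x$mature_span[2L], nchar(x$mature),
              x$n_cys_mature))
  invisible(x)
}
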