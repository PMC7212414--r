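#' Cleavage rule set for prohormone convertase site prediction
#'
#' Concrete, individually toggleable interpretation of the classical
#' convertase rules for neuropeptide precursors: canonical dibasic sites
#' (`KR`, `RR`) are always cleaved; the extended dibasics (`KK`, `RK`) are
#' cleaved when enabled; a lone arginine is cleaved only when another basic
#' residue sits at offset -3, -5 or -7. Proline immediately after the
#' scissile bond blocks cleavage, as does a cysteine flanking the bond
#' (disulfide-bonded regions are not processed).
#'
#' @param enable_KK,enable_RK Cleave the extended dibasic patterns.
#' @param enable_monobasic Apply the monobasic-arginine rule.
#' @param monobasic_offsets Upstream offsets at which a supporting basic
#'   residue licenses a monobasic site.
#' @param monobasic_K Extend the monobasic rule to lone lysines (off by
#'   default; lone K is essentially never processed).
#' @param block_P,block_C Blocking rules (proline after the site; cysteine
#'   adjacent to the scissile bond).
#' @param pyroglu_E Also form pyroglutamate from N-terminal glutamate
#'   during maturation (default: glutamine only).
#' @return A list of class `cleavage_rules`.
#' @export
cleavage_rules <- function(enable_KK = TRUE, enable_RK = TRUE,
                           enable_monobasic = TRUE,
                           monobasic_offsets = c(3L, 5L, 7L),
                           monobasic_K = FALSE,
                           block_P = TRUE, block_C = TRUE,
                           pyroglu_E = FALSE) {
  structure(list(enable_KK = enable_KK, enable_RK = enable_RK,
                 enable_monobasic = enable_monobasic,
                 monobasic_offsets = as.integer(monobasic_offsets),
                 monobasic_K = monobasic_K,
                 block_P = block_P, block_C = block_C,
                 pyroglu_E = pyroglu_E),
            class = "cleavage_rules")
}

# is the scissile bond after position i blocked?
blocked_after <- function(aa, i, rules) {
  if (i >= length(aa)) return(FALSE)   # precursor end: nothing to block
  nxt <- aa[i + 1L]
  (rules$block_P && nxt == "P") || (rules$block_C && nxt == "C")
}

#' Predict prohormone convertase cleavage sites
#'
#' Scans a proprotein (the precursor after signal-peptide removal) for
#' convertase sites under a [cleavage_rules()] configuration. A site's
#' `position` is the last basic residue of its pattern; cleavage occurs
#' after that residue. Overlapping dibasic candidates (e.g. `KKR`) resolve
#' to the dibasic ending furthest downstream, so output positions are
#' strictly increasing and patterns never share a residue.
#'
#' @param proprotein Amino-acid string (non-empty).
#' @param rules A [cleavage_rules()] object.
#' @return data.frame with columns `position`, `pattern` (`KR`, `RR`, `KK`,
#'   `RK`, `monobasic-R`, `monobasic-K`) and `confidence` (`canonical`,
#'   `extended`, `monobasic`), sorted by position.
#' @examples
#' find_cleavage_sites("AAAKRAAA")   # one canonical KR site at position 5
#' find_cleavage_sites("AAPKRPAA")   # none: P after the site blocks it
#' @export
find_cleavage_sites <- function(proprotein, rules = cleavage_rules()) {
  stopifnot(nchar(proprotein) > 0L)
  aa <- strsplit(proprotein, "")[[1]]
  n <- length(aa)
  basic <- aa %in% c("K", "R")

  empty <- data.frame(position = integer(), pattern = character(),
                      confidence = character(), stringsAsFactors = FALSE)

  dib_ok <- function(pat) {
    switch(pat, KR = TRUE, RR = TRUE,
           KK = rules$enable_KK, RK = rules$enable_RK, FALSE)
  }
  # dibasic candidates, position = second residue
  dib <- list()
  for (i in seq_len(n)[-1L]) {
    if (!basic[i] || !basic[i - 1L]) next
    pat <- paste0(aa[i - 1L], aa[i])
    if (!dib_ok(pat)) next
    if (blocked_after(aa, i, rules)) next
    dib[[length(dib) + 1L]] <- c(i, pat)
  }
  sites <- empty
  if (length(dib) > 0L) {
    pos <- as.integer(vapply(dib, `[`, character(1), 1L))
    pat <- vapply(dib, `[`, character(1), 2L)
    # overlapping dibasics share a residue iff positions differ by 1;
    # keep the downstream one
    keep <- rep(TRUE, length(pos))
    for (j in seq_along(pos)[-1L]) {
      if (pos[j] - pos[j - 1L] == 1L && keep[j - 1L]) keep[j - 1L] <- FALSE
    }
    sites <- data.frame(position = pos[keep], pattern = pat[keep],
                        confidence = ifelse(pat[keep] %in% c("KR", "RR"),
                                            "canonical", "extended"),
                        stringsAsFactors = FALSE)
  }
  # monobasic: lone basic (non-basic neighbours), supporting basic upstream
  if (rules$enable_monobasic) {
    targets <- if (rules$monobasic_K) c("R", "K") else "R"
    mono <- list()
    for (i in seq_len(n)) {
      if (!(aa[i] %in% targets)) next
      if (i > 1L && basic[i - 1L]) next
      if (i < n && basic[i + 1L]) next
      sup <- i - rules$monobasic_offsets
      sup <- sup[sup >= 1L]
      if (!any(basic[sup])) next
      if (blocked_after(aa, i, rules)) next
      mono[[length(mono) + 1L]] <- data.frame(
        position = i, pattern = paste0("monobasic-", aa[i]),
        confidence = "monobasic", stringsAsFactors = FALSE)
    }
    if (length(mono) > 0L) sites <- rbind(sites, do.call(rbind, mono))
  }
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Cut a proprotein into raw fragments at predicted sites
#'
#' Fragments are the maximal substrings between consecutive cleavage sites
#' and the sequence ends; the basic residues of each site stay attached to
#' the upstream fragment (they are removed later by the carboxypeptidase
#' step of [maturate()]). Concatenating the fragments restores the
#' proprotein exactly.
#'
#' @param proprotein Amino-acid string.
#' @param sites data.frame from [find_cleavage_sites()] (sorted, in bounds).
#' @return data.frame with `start`, `end` (1-based inclusive proprotein
#'   coordinates), `sequence`, and `site_pattern` (pattern of the site
#'   terminating the fragment; `NA` for the final fragment).
#' @export
excise_peptides <- function(proprotein, sites) {
  n <- nchar(proprotein)
  if (nrow(sites) > 0L) {
    pos <- sites$position
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("cleavage sites must be strictly increasing")
    }
    if (any(pos < 1L | pos > n)) stop("cleavage site out of bounds")
    # residues covered by each site must not overlap
    width <- ifelse(sites$confidence == "monobasic", 1L, 2L)
    first_res <- pos - width + 1L
    if (any(first_res[-1L] <= pos[-length(pos)])) {
      stop("overlapping cleavage sites")
    }
  }
  bounds <- unique(c(0L, sites$position, n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  pat_at <- structure(sites$pattern, names = sites$position)
  frags <- data.frame(
    start = starts, end = ends,
    sequence = substring(proprotein, starts, ends),
    site_pattern = unname(pat_at[as.character(ends)]),
    stringsAsFactors = FALSE
  )
  rownames(frags) <- NULL
  frags
}
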