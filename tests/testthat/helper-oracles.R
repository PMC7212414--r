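# Independent brute-force oracles, written position-by-position / codon-by-
# codon so that they share no code path with the package implementations.

# exhaustive per-position convertase rule checker
oracle_sites <- function(proprotein, rules = cleavage_rules()) {
  aa <- strsplit(proprotein, "")[[1]]
  n <- length(aa)
  is_basic <- function(i) i >= 1 && i <= n && (aa[i] == "K" || aa[i] == "R")
  blocked <- function(i) {
    if (i >= n) return(FALSE)
    (rules$block_P && aa[i + 1] == "P") || (rules$block_C && aa[i + 1] == "C")
  }
  dib_valid <- function(i) {
    if (i < 2 || !is_basic(i) || !is_basic(i - 1)) return(FALSE)
    pair <- paste0(aa[i - 1], aa[i])
    ok <- pair %in% c("KR", "RR") ||
      (pair == "KK" && rules$enable_KK) ||
      (pair == "RK" && rules$enable_RK)
    ok && !blocked(i)
  }
  out <- NULL
  for (i in seq_len(n)) {
    if (dib_valid(i) && !dib_valid(i + 1)) {
      pair <- paste0(aa[i - 1], aa[i])
      out <- rbind(out, data.frame(
        position = i, pattern = pair,
        confidence = if (pair %in% c("KR", "RR")) "canonical" else "extended",
        stringsAsFactors = FALSE))
    } else if (rules$enable_monobasic) {
      targets <- if (rules$monobasic_K) c("R", "K") else "R"
      if (aa[i] %in% targets && !is_basic(i - 1) && !is_basic(i + 1) &&
          !blocked(i)) {
        support <- FALSE
        for (off in rules$monobasic_offsets) {
          if (is_basic(i - off)) support <- TRUE
        }
        if (support) {
          out <- rbind(out, data.frame(
            position = i, pattern = paste0("monobasic-", aa[i]),
            confidence = "monobasic", stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(position = integer(), pattern = character(),
                      confidence = character(), stringsAsFactors = FALSE)
  }
  out[order(out$position), , drop = FALSE]
}

# brute-force six-frame ORF scanner on top of seqinr's translator
oracle_orfs <- function(nt, min_len) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  prots <- character()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else rc(nt)
    for (off in 0:2) {
      v <- strsplit(s, "")[[1]]
      v <- v[(off + 1):length(v)]
      v <- v[seq_len((length(v) %/% 3) * 3)]
      if (length(v) < 3) next
      pep <- paste(seqinr::translate(v, ambiguous = FALSE), collapse = "")
      pep <- gsub("[^A-Z*]", "X", pep)
      regions <- strsplit(pep, "*", fixed = TRUE)[[1]]
      for (k in seq_along(regions)) {
        region <- regions[k]
        if (nchar(region) == 0) next
        m <- regexpr("M", region)
        if (m > 0) {
          orf <- substr(region, m, nchar(region))
          if (nchar(orf) >= min_len) prots <- c(prots, orf)
        }
        if (k == 1 && m != 1 && nchar(region) >= min_len) {
          prots <- c(prots, region)
        }
      }
    }
  }
  sort(prots)
}

# naive convolution for the hydropathy profile
oracle_profile <- function(protein, window) {
  kd <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
          G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
          H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
          R = -4.5)
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - half < 1 || i + half > n) next
    vals <- kd[aa[(i - half):(i + half)]]
    vals[is.na(vals)] <- 0
    out[i] <- sum(vals) / window
  }
  out
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_transcript <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

fixture_peptides <- function() {
  path <- system.file("extdata", "reference_peptides.tsv",
                      package = "pepminer")
  fix <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  fix$family[is.na(fix$family)] <- ""
  fix
}
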