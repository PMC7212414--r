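#' Read a FASTA file of transcripts or precursor proteins
#'
#' Sequences are upper-cased and validated against the declared alphabet:
#' `A,C,G,T,N` for nucleotide input, the 20 amino-acid letters plus `X` for
#' protein input. Duplicate ids and illegal characters are errors.
#'
#' @param path FASTA file.
#' @param type `"nt"` for transcripts, `"protein"` for precursors.
#' @return A named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, type = c("protein", "nt")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  alphabet <- if (type == "nt") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX"
  bad_re <- paste0("[^", alphabet, "]")
  hit <- regexpr(bad_re, seqs)
  if (any(hit > 0L)) {
    i <- which(hit > 0L)[1L]
    stop("illegal character '", substr(seqs[i], hit[i], hit[i]),
         "' in record '", ids[i], "' at offset ", hit[i])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
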