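#' Read transcripts from a FASTA file
#'
#' Loads target or background transcript sequences. RNA alphabet is accepted
#' on input: any `U` is mapped to `T` so that all downstream probe arithmetic
#' operates on the DNA sense strand. Sequences are upper-cased.
#'
#' @param path path to a FASTA file.
#' @param role `"target"` or `"background"`.
#' @return a named character vector of DNA sequences with attribute `role`.
#' @export
read_transcripts <- function(path, role = c("target", "background")) {
  role <- match.arg(role)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_transcripts(seqs)
  attr(seqs, "role") <- role
  seqs
}

validate_transcripts <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences found")
  if (any(!nzchar(seqs))) stop("empty transcript sequence")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT characters in transcript(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq a single DNA string (A/C/G/T).
#' @return the reverse complement, 5'->3'.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## subsequence by 1-based inclusive transcript coordinates
subseq1 <- function(seq, start, end) {
  stopifnot(start >= 1L, end <= nchar(seq), start <= end)
  substr(seq, start, end)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
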