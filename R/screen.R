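#' Off-target specificity screen for a detection site
#'
#' Rejects a detection site if any stretch of `k` (default 10) contiguous
#' nucleotides of the site occurs exactly in a non-target transcript.
#' The screen runs on the sense strand of the background transcripts (the
#' probes hybridize to RNA); set `both_strands = TRUE` to additionally screen
#' the antisense strand for BLAST-style parity. Implemented as a k-mer
#' dictionary match over the background; equivalent to exhaustive substring
#' search.
#'
#' @param site one row of [find_detection_sites()] output (needs `sequence`,
#'   optionally `transcript_id`), or a plain site sequence string.
#' @param background named character vector of background transcripts.
#' @param k minimum shared exact-match length triggering a failure.
#' @param exempt_ids transcript ids excluded from the screen (the target's
#'   own isoforms).
#' @param both_strands also screen the reverse complement of the background.
#' @return a list with `pass` (logical) and, on failure, `reason` naming the
#'   first offending background transcript and shared k-mer.
#' @export
specificity_screen <- function(site, background, k = 10L,
                               exempt_ids = character(),
                               both_strands = FALSE) {
  if (k < 4L) stop("k must be at least 4")
  site_seq <- if (is.character(site) && length(site) == 1L) site
              else site$sequence
  if (!is.null(attr(site, "transcript_id"))) {
    exempt_ids <- c(exempt_ids, attr(site, "transcript_id"))
  }
  if (is.list(site) && !is.null(site$transcript_id)) {
    exempt_ids <- c(exempt_ids, site$transcript_id)
  }
  bg <- background[!names(background) %in% exempt_ids]
  if (length(bg) == 0L || nchar(site_seq) < k) {
    return(list(pass = TRUE, reason = NA_character_))
  }
  kmers <- unique(substring(site_seq, seq_len(nchar(site_seq) - k + 1L),
                            seq_len(nchar(site_seq) - k + 1L) + k - 1L))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  subjects <- Biostrings::DNAStringSet(unname(bg))
  hits <- Biostrings::vcountPDict(pd, subjects)
  if (both_strands) {
    hits <- hits + Biostrings::vcountPDict(
      pd, Biostrings::reverseComplement(subjects))
  }
  hit_idx <- which(colSums(hits) > 0L)
  if (length(hit_idx) == 0L) {
    return(list(pass = TRUE, reason = NA_character_))
  }
  first_bg <- hit_idx[1L]
  first_kmer <- kmers[which(hits[, first_bg] > 0L)[1L]]
  list(pass = FALSE,
       reason = sprintf("shares %d-mer %s with background transcript '%s'",
                        k, first_kmer, names(bg)[first_bg]))
}

#' Longest exact self-complementary match of an oligonucleotide
#'
#' Length of the longest common substring between a sequence and its reverse
#' complement: the longest stretch that could pair with another copy of the
#' same oligo (or fold back on itself). Panels reject candidate sites whose
#' score exceeds a configurable maximum (default 6).
#'
#' @param seq DNA string.
#' @return integer score (0 when no complementary match of length >= 1
#'   exists).
#' @export
#' @examples
#' self_complementarity("GAATTC")  # a full palindrome: 6
self_complementarity <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("non-ACGT base in sequence")
  a <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- strsplit(revcomp(seq), "", fixed = TRUE)[[1L]]
  n <- length(a)
  best <- 0L
  prev <- integer(n)
  for (i in seq_len(n)) {
    cur <- integer(n)
    j <- which(b == a[i])
    if (length(j)) {
      cur[j] <- ifelse(j == 1L, 1L, prev[pmax(j - 1L, 1L)] + 1L)
      best <- max(best, max(cur))
    }
    prev <- cur
  }
  as.integer(best)
}
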