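#' Enumerate detection sites on a target transcript
#'
#' A detection site is a window of `site_length` nucleotides (default 40)
#' whose two halves abut at a 5'-AG-3' or 5'-TA-3' dinucleotide: the 5' half
#' ends with the first base of that dinucleotide. All coordinates are
#' 1-based inclusive on the transcript. When more non-overlapping windows
#' exist than `max_sites`, sites are tiled to spread coverage along the
#' transcript (deterministic, left-to-right).
#'
#' @param transcript named length-1 character vector (or plain string) of
#'   the target sequence; `names()` supplies `transcript_id`.
#' @param site_length window size in nt; must be even.
#' @param max_sites maximum number of sites to return (1..10).
#' @param transcript_id id used when `transcript` is unnamed.
#' @return a data.frame with columns `transcript_id`, `start`, `end`,
#'   `junction_pos` (first base of the junction dinucleotide),
#'   `dinucleotide`, `sequence`. Zero rows when no valid junction exists.
#' @export
find_detection_sites <- function(transcript, site_length = 40L,
                                 max_sites = 10L,
                                 transcript_id = names(transcript)) {
  seq <- unname(transcript[[1L]])
  if (is.null(transcript_id)) transcript_id <- "target"
  if (site_length %% 2L != 0L) stop("site_length must be even")
  if (max_sites < 1L || max_sites > 10L) stop("max_sites must be in 1..10")
  n <- nchar(seq)
  if (n < site_length) {
    stop(sprintf("transcript '%s' (%d nt) is shorter than site_length %d",
                 transcript_id, n, site_length))
  }
  cand <- enumerate_site_windows(seq, site_length)
  sel <- tile_sites(cand, n, site_length, max_sites)
  if (nrow(sel) == 0L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), junction_pos = integer(),
                      dinucleotide = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    transcript_id = rep(transcript_id, nrow(sel)),
    start = sel$start, end = sel$end,
    junction_pos = sel$junction_pos,
    dinucleotide = sel$dinucleotide,
    sequence = substring(seq, sel$start, sel$end),
    stringsAsFactors = FALSE
  )
}

## all windows of length L whose central dinucleotide (positions
## start+L/2-1, start+L/2) is AG or TA
enumerate_site_windows <- function(seq, L) {
  n <- nchar(seq)
  half <- L %/% 2L
  if (n < L) {
    return(data.frame(start = integer(), end = integer(),
                      junction_pos = integer(), dinucleotide = character()))
  }
  j <- seq_len(n - 1L)                       # first base of each dinucleotide
  di <- substring(seq, j, j + 1L)
  ok <- di %in% c("AG", "TA")
  j <- j[ok]; di <- di[ok]
  start <- j - half + 1L
  inb <- start >= 1L & start + L - 1L <= n
  data.frame(start = start[inb], end = start[inb] + L - 1L,
             junction_pos = j[inb], dinucleotide = di[inb],
             stringsAsFactors = FALSE)
}

## greedy deterministic tiling: take the leftmost-first non-overlapping
## packing; if it still exceeds max_sites, keep the candidates nearest to
## evenly spaced anchors (left-to-right, ties to the left)
tile_sites <- function(cand, n, L, max_sites) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  packed <- cand[keep, , drop = FALSE]
  if (nrow(packed) <= max_sites) return(packed)
  ## members of the packing are already mutually non-overlapping, so anchor
  ## selection below only subsets, never creates overlap
  anchors <- round(seq(1, n - L + 1, length.out = max_sites))
  chosen <- integer(0)
  for (a in anchors) {
    free <- setdiff(seq_len(nrow(packed)), chosen)
    if (length(free) == 0L) break
    d <- abs(packed$start[free] - a)
    chosen <- c(chosen, free[order(d, packed$start[free])[1L]])
  }
  packed[sort(unique(chosen)), , drop = FALSE]
}

#' Adjust H-probe arm lengths to a melting-temperature window
#'
#' Each H probe's binding arm nominally covers 20 nt on its side of the
#' ligation junction. Starting from the nominal length, each arm is extended
#' or trimmed one base at a time at its distal end until the melting
#' temperature of the corresponding DNA duplex falls inside `tm_range`
#' (default 45-65 C). Arm lengths are constrained to 12-30 nt and to the
#' transcript bounds; a site whose arms cannot reach the window is flagged
#' unusable rather than emitted.
#'
#' @param site one row of [find_detection_sites()] output (or a list with
#'   `junction_pos`).
#' @param transcript the target sequence (string).
#' @param tm_range numeric length-2, allowed Tm window in Celsius.
#' @param nominal_len starting arm length in nt.
#' @param len_range allowed arm-length window in nt.
#' @param ... passed to [melting_temperature()].
#' @return a list with `ok`, `reason`, and for usable sites `hl_start`,
#'   `hl_end`, `hr_start`, `hr_end` (arm footprints on the transcript,
#'   1-based inclusive), `hl_tm`, `hr_tm`.
#' @export
adjust_arm_lengths <- function(site, transcript, tm_range = c(45, 65),
                               nominal_len = 20L, len_range = c(12L, 30L),
                               ...) {
  seq <- unname(transcript[[1L]])
  j <- site$junction_pos
  n <- nchar(seq)
  stopifnot(j >= 1L, j < n)

  ## 5' arm ends at the junction base; 3' arm starts just after it
  left <- fit_one_arm(seq, anchor = j, direction = -1L, tm_range,
                      nominal_len, len_range, ...)
  right <- fit_one_arm(seq, anchor = j + 1L, direction = 1L, tm_range,
                       nominal_len, len_range, ...)
  if (!left$ok || !right$ok) {
    which_arm <- c(if (!left$ok) "HL", if (!right$ok) "HR")
    return(list(ok = FALSE,
                reason = sprintf("%s arm cannot reach Tm %.0f-%.0f C within %d-%d nt",
                                 paste(which_arm, collapse = "+"),
                                 tm_range[1], tm_range[2],
                                 len_range[1], len_range[2])))
  }
  list(ok = TRUE, reason = NA_character_,
       hl_start = j - left$len + 1L, hl_end = j,
       hr_start = j + 1L, hr_end = j + right$len,
       hl_tm = left$tm, hr_tm = right$tm)
}

## walk one arm's distal end until Tm enters the window
fit_one_arm <- function(seq, anchor, direction, tm_range, nominal_len,
                        len_range, ...) {
  n <- nchar(seq)
  max_here <- if (direction < 0) anchor else n - anchor + 1L
  len <- min(nominal_len, max_here, len_range[2])
  if (len < len_range[1]) return(list(ok = FALSE))
  arm_tm <- function(len) {
    tgt <- if (direction < 0) subseq1(seq, anchor - len + 1L, anchor)
           else subseq1(seq, anchor, anchor + len - 1L)
    melting_temperature(revcomp(tgt), ...)
  }
  tm <- arm_tm(len)
  for (step in seq_len(len_range[2] - len_range[1] + 1L)) {
    if (tm >= tm_range[1] && tm <= tm_range[2]) {
      return(list(ok = TRUE, len = len, tm = tm))
    }
    move <- if (tm < tm_range[1]) 1L else -1L
    new_len <- len + move
    if (new_len < len_range[1] || new_len > len_range[2] ||
        new_len > max_here) {
      return(list(ok = FALSE))
    }
    len <- new_len
    tm <- arm_tm(len)
  }
  if (tm >= tm_range[1] && tm <= tm_range[2]) {
    list(ok = TRUE, len = len, tm = tm)
  } else {
    list(ok = FALSE)
  }
}
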