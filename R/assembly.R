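## run expr with a temporary RNG state so generators are pure in (args, seed)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  (n - nchar(gsub("[GC]", "", seq))) / n
}

max_homopolymer <- function(seq) {
  runs <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  max(runs$lengths)
}

kmer_set <- function(seq, k) {
  if (nchar(seq) < k) return(character(0))
  i <- seq_len(nchar(seq) - k + 1L)
  unique(substring(seq, i, i + k - 1L))
}

## TRUE when `seq` shares a >= k exact match with any of `others`, on the
## given strand or as a cross-complement
shares_kmer <- function(seq, others, k, cross_complement = TRUE) {
  if (length(others) == 0L) return(FALSE)
  km <- kmer_set(seq, k)
  pool <- unlist(lapply(others, kmer_set, k = k), use.names = FALSE)
  if (cross_complement) {
    pool <- c(pool, vapply(pool, revcomp, ""))
  }
  any(km %in% pool)
}

## rejection-sample n sequences of length len that satisfy composition and
## mutual-orthogonality constraints (GC 40-60%, homopolymers <= 3, no shared
## or cross-complementary >= min_orth-mer against `existing` or each other)
generate_orthogonal_seqs <- function(n, len, seed, min_orth = 8L,
                                     gc_range = c(0.4, 0.6),
                                     homopolymer_max = 3L,
                                     existing = character()) {
  with_seed(seed, {
    out <- character(0)
    attempts <- 0L
    while (length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > 20000L) {
        stop("unable to generate orthogonal sequences under the constraints")
      }
      cand <- random_dna(len)
      if (gc_fraction(cand) < gc_range[1] || gc_fraction(cand) > gc_range[2]) next
      if (max_homopolymer(cand) > homopolymer_max) next
      if (shares_kmer(cand, c(existing, out), min_orth)) next
      out <- c(out, cand)
    }
    out
  })
}

#' Modular H-probe design templates
#'
#' Each template is a pair of single-stranded overhangs: the left overhang
#' is prepended to the 5' end of HL and the right overhang appended to the
#' 3' end of HR (the end that primes rolling-circle replication). Each
#' 22-nt overhang presents an 11-nt bridge-facing segment and an 11-nt
#' circle-facing segment, so that the cognate circle's two terminal 11-mers
#' and the common 31-nt bridge can hybridize across the junction. Eight
#' templates are generated from a fixed internal seed under the package's
#' orthogonality rules; a laboratory's own template table can be supplied
#' as a tab-separated file with columns `template_id`, `l_overhang`,
#' `r_overhang`.
#'
#' @param n number of templates (default 8).
#' @param file optional TSV file overriding the generated table.
#' @return data.frame with columns `template_id`, `l_overhang`,
#'   `r_overhang`.
#' @export
design_templates <- function(n = 8L, file = NULL) {
  if (!is.null(file)) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    stopifnot(all(c("template_id", "l_overhang", "r_overhang") %in%
                    names(tab)))
    return(tab)
  }
  seqs <- generate_orthogonal_seqs(2L * n, 22L, seed = 190711L)
  data.frame(
    template_id = seq_len(n),
    l_overhang = seqs[seq(1L, 2L * n, by = 2L)],
    r_overhang = seqs[seq(2L, 2L * n, by = 2L)],
    stringsAsFactors = FALSE
  )
}

#' Assemble the H-probe pair for one detection site
#'
#' The HL binding sequence is the reverse complement of the site's 5' half
#' (ending at the first base of the AG/TA junction) and the HR binding
#' sequence the reverse complement of the 3' half; written 5'->3', the full
#' HL oligo is `l_overhang + hl_binding` and the full HR oligo
#' `hr_binding + r_overhang`. All probe pairs of one target use the same
#' template, which routes them to the same barcode.
#'
#' @param site one row of [find_detection_sites()] output.
#' @param transcript the target sequence (string).
#' @param template_id template number (1..nrow(templates)).
#' @param templates template table from [design_templates()].
#' @param arms optional precomputed result of [adjust_arm_lengths()]; when
#'   `NULL` the arms are adjusted here.
#' @param ... passed to [adjust_arm_lengths()].
#' @return an object of class `plish_hpair`: a list with the site, arm
#'   coordinates, binding/overhang/full sequences, Tm values and
#'   `template_id`.
#' @export
assemble_h_pair <- function(site, transcript, template_id,
                            templates = design_templates(), arms = NULL,
                            ...) {
  tpl <- templates[templates$template_id == template_id, , drop = FALSE]
  if (nrow(tpl) != 1L) stop("unknown template_id: ", template_id)
  seq <- unname(transcript[[1L]])
  if (is.null(arms)) arms <- adjust_arm_lengths(site, seq, ...)
  if (!isTRUE(arms$ok)) {
    stop("site arms failed Tm adjustment: ", arms$reason)
  }
  half5 <- subseq1(seq, arms$hl_start, arms$hl_end)
  half3 <- subseq1(seq, arms$hr_start, arms$hr_end)
  hl_binding <- revcomp(half5)
  hr_binding <- revcomp(half3)
  structure(list(
    site = site,
    hl_start = arms$hl_start, hl_end = arms$hl_end,
    hr_start = arms$hr_start, hr_end = arms$hr_end,
    hl_binding = hl_binding, hr_binding = hr_binding,
    hl_overhang = tpl$l_overhang, hr_overhang = tpl$r_overhang,
    hl_full = paste0(tpl$l_overhang, hl_binding),
    hr_full = paste0(hr_binding, tpl$r_overhang),
    hl_tm = arms$hl_tm, hr_tm = arms$hr_tm,
    template_id = template_id
  ), class = "plish_hpair")
}

#' @export
print.plish_hpair <- function(x, ...) {
  cat(sprintf("H-probe pair (template %d), site %d-%d junction %s\n",
              x$template_id, x$hl_start, x$hr_end, x$site$dinucleotide))
  cat(sprintf("  HL 5'->3': %s (Tm %.1f C)\n", x$hl_full, x$hl_tm))
  cat(sprintf("  HR 5'->3': %s (Tm %.1f C)\n", x$hr_full, x$hr_tm))
  invisible(x)
}

#' Assemble the circle, bridge and imager set for one barcode channel
#'
#' Builds the barcode-bearing circle oligo (60 nt: two terminal 11-mers
#' complementary to the circle-facing segments of the template's H-probe
#' overhangs, a central 20-nt barcode, and filler), the common 31-nt bridge
#' (complementary to the bridge-facing overhang segments), and one imager
#' oligo per requested mode. The imager hybridizes to the barcode copies in
#' the rolling-circle amplicon, so its sequence is a substring of the
#' circle's barcode.
#'
#' @param barcode_id label for the barcode channel (usually the target id).
#' @param template_id which design template the cognate H probes use.
#' @param modes character vector of imager modes, a subset of
#'   `c("standard", "erasable_dU", "rapid_short")`.
#' @param fluor fluorophore name annotated on the imagers.
#' @param templates template table from [design_templates()].
#' @param barcode_seq optional explicit 20-nt barcode; generated when `NULL`.
#' @param existing_barcodes barcodes already issued in this panel; a new
#'   barcode must not share (or cross-complement) any 8-mer with them.
#' @param seed seed for barcode/filler generation.
#' @return an object of class `plish_barcode_set`.
#' @export
assemble_barcode_set <- function(barcode_id, template_id,
                                 modes = "standard", fluor = "unassigned",
                                 templates = design_templates(),
                                 barcode_seq = NULL,
                                 existing_barcodes = character(),
                                 seed = 1L) {
  tpl <- templates[templates$template_id == template_id, , drop = FALSE]
  if (nrow(tpl) != 1L) stop("unknown template_id: ", template_id)
  if (is.null(barcode_seq)) {
    barcode_seq <- generate_orthogonal_seqs(
      1L, 20L, seed = seed, existing = existing_barcodes)
  } else if (shares_kmer(barcode_seq, existing_barcodes, 8L)) {
    clash <- existing_barcodes[vapply(
      existing_barcodes, function(b) shares_kmer(barcode_seq, b, 8L),
      logical(1))]
    stop("barcode for '", barcode_id,
         "' violates orthogonality against issued barcode(s): ",
         paste(clash, collapse = ", "))
  }
  fillers <- with_seed(seed + 104729L, c(random_dna(9L), random_dna(9L)))
  l_ov <- tpl$l_overhang
  r_ov <- tpl$r_overhang
  ## circle 5'->3': [revcomp of HL overhang's circle-facing 11-mer] -
  ## filler - barcode - filler - [revcomp of HR overhang's circle-facing
  ## 11-mer]; total 60 nt
  circle_seq <- paste0(revcomp(substr(l_ov, 12L, 22L)), fillers[1L],
                       barcode_seq, fillers[2L],
                       revcomp(substr(r_ov, 1L, 11L)))
  ## bridge 5'->3': complements of the two bridge-facing 11-mers around a
  ## 9-nt spacer; 31 nt, shared by all templates built on one spacer seed
  bridge_seq <- paste0(revcomp(substr(r_ov, 12L, 22L)),
                       with_seed(190711L, random_dna(9L)),
                       revcomp(substr(l_ov, 1L, 11L)))
  imagers <- lapply(modes, function(m) {
    make_imager(barcode_seq, mode = m, fluor = fluor)
  })
  names(imagers) <- modes
  structure(list(
    barcode_id = barcode_id, barcode_seq = barcode_seq,
    circle_seq = circle_seq, bridge_seq = bridge_seq,
    template_id = template_id, fluor = fluor, imagers = imagers
  ), class = "plish_barcode_set")
}

#' @export
print.plish_barcode_set <- function(x, ...) {
  cat(sprintf("Barcode set '%s' (template %d, %s)\n", x$barcode_id,
              x$template_id, x$fluor))
  cat("  barcode:", x$barcode_seq, "\n")
  cat("  circle :", x$circle_seq, sprintf("(%d nt)\n", nchar(x$circle_seq)))
  cat("  bridge :", x$bridge_seq, sprintf("(%d nt)\n", nchar(x$bridge_seq)))
  cat("  imagers:", paste(names(x$imagers), collapse = ", "), "\n")
  invisible(x)
}

#' Design an imager oligonucleotide for a barcode
#'
#' The imager hybridizes to the tandem barcode copies in the rolling-circle
#' amplicon. Three modes are supported: `standard` (15-20 nt), `erasable_dU`
#' (the standard imager with every dT replaced by dU so a uracil glycosylase
#' erases the signal between cycles) and `rapid_short` (a 10-11 nt imager
#' that washes off in buffer alone).
#'
#' @param barcode_seq the barcode sequence embedded in the circle.
#' @param mode imager mode.
#' @param fluor fluorophore annotation.
#' @param standard_len length of the standard imager (15-20 nt).
#' @return a list with `sequence`, `mode`, `fluor`, `length`.
#' @export
make_imager <- function(barcode_seq,
                        mode = c("standard", "erasable_dU", "rapid_short"),
                        fluor = "unassigned", standard_len = 18L) {
  mode <- match.arg(mode)
  n <- nchar(barcode_seq)
  if (mode %in% c("standard", "erasable_dU")) {
    if (standard_len < 15L || standard_len > 20L) {
      stop("standard imager length must be 15-20 nt")
    }
    if (n < 15L) stop("barcode too short for a 15-20 nt imager")
    len <- min(standard_len, n)
    seq <- substr(barcode_seq, 1L, len)
    if (mode == "erasable_dU") seq <- gsub("T", "U", seq, fixed = TRUE)
  } else {
    if (n < 10L) stop("barcode too short for a 10-11 nt imager")
    len <- min(11L, n)
    seq <- substr(barcode_seq, 1L, len)
  }
  list(sequence = seq, mode = mode, fluor = fluor, length = nchar(seq))
}

#' Simulate a rolling-circle amplicon and check imager hybridization
#'
#' The amplicon is the tandem repeat of the reverse complement of the
#' circle. An imager hybridizes when its reverse complement occurs in the
#' amplicon (dU is treated as dT for pairing).
#'
#' @param circle_seq circle oligo sequence.
#' @param n_repeats number of tandem repeats to simulate.
#' @return the simulated amplicon string.
#' @export
simulate_amplicon <- function(circle_seq, n_repeats = 3L) {
  paste(rep(revcomp(circle_seq), n_repeats), collapse = "")
}

#' @rdname simulate_amplicon
#' @param imager_seq imager oligo sequence (may contain U).
#' @param amplicon amplicon string from [simulate_amplicon()].
#' @export
imager_hybridizes <- function(imager_seq, amplicon) {
  dna <- gsub("U", "T", imager_seq, fixed = TRUE)
  grepl(revcomp(dna), amplicon, fixed = TRUE)
}
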