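#' Design a complete barcoded probe panel
#'
#' Runs the full design pipeline for every target transcript: detection-site
#' enumeration, off-target k-mer screening against the background
#' transcriptome, self-complementarity filtering, melting-temperature arm
#' adjustment, H-probe assembly, and barcode/circle/bridge/imager assembly.
#' Targets are assigned to (cycle, channel) slots round-robin across the
#' fluorophore palette, and per-oligo working concentrations follow the
#' pro-rating rule: 100 nM per H probe when a target has at most five probe
#' pairs, otherwise `500 / n_pairs` nM each so that the per-target sum is
#' exactly 1000 nM.
#'
#' @param targets named character vector of target transcript sequences, or
#'   a FASTA path.
#' @param background named character vector of background transcripts, or a
#'   FASTA path. Entries whose name matches a target id are exempted from
#'   that target's screen.
#' @param sites_per_target maximum number of detection sites per target
#'   (1..10).
#' @param fluor_palette up to five fluorophore names.
#' @param n_cycles number of label-image-erase cycles.
#' @param site_length nominal detection-site length (nt).
#' @param screen_k minimum shared exact match (nt) that fails the
#'   specificity screen.
#' @param max_self_comp maximum tolerated self-complementarity score of a
#'   site sequence.
#' @param imager_modes imager modes to emit per target.
#' @param tm_range allowed binding-arm melting-temperature window (Celsius).
#' @param templates template table from [design_templates()].
#' @param seed seed for barcode generation (panel output is a pure function
#'   of inputs and seed).
#' @return an object of class `plish_panel`: per-target probe pairs and
#'   barcode sets, slot assignments, an order-sheet data.frame
#'   ([write_order_sheet()]) and a `failures` data.frame listing targets or
#'   sites dropped with reasons.
#' @export
design_panel <- function(targets, background = character(),
                         sites_per_target = 4L,
                         fluor_palette = c("AF488", "Cy3", "Cy5",
                                           "AF750", "PacificBlue"),
                         n_cycles = 1L, site_length = 40L, screen_k = 10L,
                         max_self_comp = 6L, imager_modes = "standard",
                         tm_range = c(45, 65),
                         templates = design_templates(), seed = 1L) {
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    targets <- read_transcripts(targets, "target")
  }
  if (is.character(background) && length(background) == 1L &&
      file.exists(background)) {
    background <- read_transcripts(background, "background")
  }
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  if (length(fluor_palette) > 5L) {
    stop("at most five spectrally distinct fluorophores per cycle")
  }
  n_slots <- n_cycles * length(fluor_palette)
  if (length(targets) > n_slots) {
    stop(sprintf("%d targets exceed %d (cycle, channel) slots",
                 length(targets), n_slots))
  }

  failures <- data.frame(target_id = character(), stage = character(),
                         detail = character(), stringsAsFactors = FALSE)
  add_failure <- function(id, stage, detail) {
    failures <<- rbind(failures, data.frame(
      target_id = id, stage = stage, detail = detail,
      stringsAsFactors = FALSE))
  }

  panel_targets <- list()
  issued_barcodes <- character()
  for (ti in seq_along(targets)) {
    id <- names(targets)[ti]
    seq <- targets[[ti]]
    sites <- tryCatch(
      find_detection_sites(seq, site_length = site_length,
                           max_sites = sites_per_target,
                           transcript_id = id),
      error = function(e) conditionMessage(e))
    if (is.character(sites)) {
      add_failure(id, "sites", sites)
      next
    }
    pairs <- list()
    for (si in seq_len(nrow(sites))) {
      site <- sites[si, ]
      sc <- self_complementarity(site$sequence)
      if (sc > max_self_comp) {
        add_failure(id, "self_complementarity",
                    sprintf("site %d-%d score %d > %d", site$start,
                            site$end, sc, max_self_comp))
        next
      }
      scr <- specificity_screen(site, background, k = screen_k,
                                exempt_ids = id)
      if (!scr$pass) {
        add_failure(id, "specificity", sprintf("site %d-%d: %s",
                                               site$start, site$end,
                                               scr$reason))
        next
      }
      arms <- adjust_arm_lengths(site, seq, tm_range = tm_range)
      if (!arms$ok) {
        add_failure(id, "tm_adjust", sprintf("site %d-%d: %s", site$start,
                                             site$end, arms$reason))
        next
      }
      template_id <- templates$template_id[(ti - 1L) %% nrow(templates) + 1L]
      pairs[[length(pairs) + 1L]] <-
        assemble_h_pair(site, seq, template_id, templates = templates,
                        arms = arms)
    }
    if (length(pairs) == 0L) {
      add_failure(id, "panel", "no surviving detection sites")
      next
    }
    slot <- length(panel_targets)          # 0-based slot index
    cycle <- slot %/% length(fluor_palette) + 1L
    fluor <- fluor_palette[slot %% length(fluor_palette) + 1L]
    bc <- assemble_barcode_set(
      barcode_id = id, template_id = pairs[[1L]]$template_id,
      modes = imager_modes, fluor = fluor, templates = templates,
      existing_barcodes = issued_barcodes, seed = seed + ti)
    issued_barcodes <- c(issued_barcodes, bc$barcode_seq)
    n_pairs <- length(pairs)
    conc <- if (n_pairs <= 5L) 100 else 500 / n_pairs
    panel_targets[[id]] <- list(
      target_id = id, pairs = pairs, barcode = bc, cycle = cycle,
      fluor = fluor, h_conc_nM = conc
    )
  }

  panel <- structure(list(
    targets = panel_targets, failures = failures,
    fluor_palette = fluor_palette, n_cycles = n_cycles,
    params = list(sites_per_target = sites_per_target,
                  site_length = site_length, screen_k = screen_k,
                  max_self_comp = max_self_comp, tm_range = tm_range,
                  imager_modes = imager_modes, seed = seed)
  ), class = "plish_panel")
  panel$order_sheet <- panel_order_sheet(panel)
  panel
}

panel_order_sheet <- function(panel) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (tg in panel$targets) {
    for (pi in seq_along(tg$pairs)) {
      p <- tg$pairs[[pi]]
      add(oligo_name = sprintf("%s_site%d_HL", tg$target_id, pi),
          sequence = p$hl_full, type = "HL", target_id = tg$target_id,
          site_start = p$hl_start, site_end = p$hr_end,
          template_id = p$template_id, fluor = tg$fluor, cycle = tg$cycle,
          concentration_nM = tg$h_conc_nM, tm_C = round(p$hl_tm, 2))
      add(oligo_name = sprintf("%s_site%d_HR", tg$target_id, pi),
          sequence = p$hr_full, type = "HR", target_id = tg$target_id,
          site_start = p$hl_start, site_end = p$hr_end,
          template_id = p$template_id, fluor = tg$fluor, cycle = tg$cycle,
          concentration_nM = tg$h_conc_nM, tm_C = round(p$hr_tm, 2))
    }
    bc <- tg$barcode
    add(oligo_name = sprintf("%s_bridge", tg$target_id),
        sequence = bc$bridge_seq, type = "bridge", target_id = tg$target_id,
        site_start = NA_integer_, site_end = NA_integer_,
        template_id = bc$template_id, fluor = tg$fluor, cycle = tg$cycle,
        concentration_nM = 6000, tm_C = NA_real_)
    add(oligo_name = sprintf("%s_circle", tg$target_id),
        sequence = bc$circle_seq, type = "circle", target_id = tg$target_id,
        site_start = NA_integer_, site_end = NA_integer_,
        template_id = bc$template_id, fluor = tg$fluor, cycle = tg$cycle,
        concentration_nM = 6000, tm_C = NA_real_)
    for (im in bc$imagers) {
      add(oligo_name = sprintf("%s_imager_%s", tg$target_id, im$mode),
          sequence = im$sequence, type = "imager",
          target_id = tg$target_id, site_start = NA_integer_,
          site_end = NA_integer_, template_id = bc$template_id,
          fluor = tg$fluor, cycle = tg$cycle, concentration_nM = 100,
          tm_C = NA_real_)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(oligo_name = character(), sequence = character(),
                      type = character(), target_id = character(),
                      site_start = integer(), site_end = integer(),
                      template_id = integer(), fluor = character(),
                      cycle = integer(), concentration_nM = numeric(),
                      tm_C = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.plish_panel <- function(x, ...) {
  cat(sprintf("PLISH probe panel: %d target(s), %d cycle(s), %d fluor(s)\n",
              length(x$targets), x$n_cycles, length(x$fluor_palette)))
  for (tg in x$targets) {
    cat(sprintf("  %-12s %2d pair(s)  cycle %d  %-12s %.1f nM/H-probe\n",
                tg$target_id, length(tg$pairs), tg$cycle, tg$fluor,
                tg$h_conc_nM))
  }
  if (nrow(x$failures)) {
    cat(sprintf("  %d design failure(s); see $failures\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Write the tab-separated oligo order sheet of a panel
#'
#' @param panel a `plish_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_order_sheet <- function(panel, path) {
  utils::write.table(panel$order_sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the key-value panel manifest (seeds, thresholds, versions)
#'
#' @param panel a `plish_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_manifest <- function(panel, path) {
  p <- panel$params
  lines <- c(
    paste0("plishr_version\t",
           as.character(utils::packageVersion("plishr"))),
    paste0("seed\t", p$seed),
    paste0("site_length\t", p$site_length),
    paste0("sites_per_target\t", p$sites_per_target),
    paste0("screen_k\t", p$screen_k),
    paste0("max_self_comp\t", p$max_self_comp),
    paste0("tm_range_C\t", paste(p$tm_range, collapse = "-")),
    paste0("imager_modes\t", paste(p$imager_modes, collapse = ",")),
    paste0("n_cycles\t", panel$n_cycles),
    paste0("fluor_palette\t", paste(panel$fluor_palette, collapse = ",")),
    paste0("n_targets\t", length(panel$targets)),
    paste0("n_failures\t", nrow(panel$failures))
  )
  writeLines(lines, path)
  invisible(path)
}
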