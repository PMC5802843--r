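#' Generate a synthetic transcriptome with controllable off-target
#' structure
#'
#' Produces random target and background transcript sequences, optionally
#' planting exact 10-mer collisions: for each planted collision a 10-mer
#' spanning a detection-site junction on a target is copied into a named
#' background transcript, so that exactly those sites must fail the
#' specificity screen. Accidental shared 10-mers arising by chance are
#' scrubbed from the background first, making the collision manifest
#' exhaustive. Pure function of its arguments and `seed`.
#'
#' @param n_targets,n_background numbers of transcripts.
#' @param length_range transcript length range in nt (min 200).
#' @param planted_collisions number of target sites to sabotage.
#' @param seed random seed.
#' @param site_length,max_sites site enumeration parameters used to choose
#'   planted sites.
#' @param k collision k-mer length (the screen's `k`).
#' @return list with `targets`, `background` (named character vectors) and
#'   `manifest` (data.frame: `target_id`, `site_start`, `site_end`,
#'   `background_id`, `kmer`, `insert_pos`; zero rows when nothing is
#'   planted).
#' @export
gen_transcriptome <- function(n_targets = 5L, n_background = 20L,
                              length_range = c(1000L, 2000L),
                              planted_collisions = 0L, seed = 1L,
                              site_length = 40L, max_sites = 10L,
                              k = 10L) {
  if (min(length_range) < 200L) stop("transcript lengths must be >= 200")
  with_seed(seed, {
    lens_t <- sample(length_range[1]:length_range[2], n_targets,
                     replace = TRUE)
    lens_b <- sample(length_range[1]:length_range[2], n_background,
                     replace = TRUE)
    targets <- setNames(vapply(lens_t, random_dna, ""),
                        paste0("T", seq_len(n_targets)))
    background <- setNames(vapply(lens_b, random_dna, ""),
                           paste0("BG", seq_len(n_background)))
    background <- scrub_shared_kmers(background, targets, k)

    manifest <- data.frame(target_id = character(), site_start = integer(),
                           site_end = integer(), background_id = character(),
                           kmer = character(), insert_pos = integer(),
                           stringsAsFactors = FALSE)
    if (planted_collisions > 0L) {
      ## enumerate usable sites per target, round-robin through targets
      sites <- do.call(rbind, lapply(names(targets), function(id) {
        find_detection_sites(targets[[id]], site_length = site_length,
                             max_sites = max_sites, transcript_id = id)
      }))
      if (nrow(sites) < planted_collisions) {
        stop("not enough detection sites to plant ", planted_collisions,
             " collisions")
      }
      ord <- order(ave(seq_len(nrow(sites)), sites$transcript_id,
                       FUN = seq_along), sites$transcript_id)
      sites <- sites[ord, , drop = FALSE][seq_len(planted_collisions), ]
      for (i in seq_len(planted_collisions)) {
        st <- sites[i, ]
        ## 10-mer centered on the ligation junction
        off <- st$junction_pos - st$start + 1L    # junction within the site
        kstart <- min(max(off - k %/% 2L + 1L, 1L), nchar(st$sequence) - k + 1L)
        kmer <- substr(st$sequence, kstart, kstart + k - 1L)
        bid <- names(background)[(i - 1L) %% length(background) + 1L]
        pos <- sample.int(nchar(background[[bid]]) - k + 1L, 1L)
        substr(background[[bid]], pos, pos + k - 1L) <- kmer
        manifest <- rbind(manifest, data.frame(
          target_id = st$transcript_id, site_start = st$start,
          site_end = st$end, background_id = bid, kmer = kmer,
          insert_pos = pos, stringsAsFactors = FALSE))
      }
      ## planting may itself have created stray duplicates elsewhere; the
      ## planted copies are the only shared k-mers we keep
      background <- scrub_shared_kmers(background, targets, k,
                                       keep = manifest)
    }
    list(targets = targets, background = background, manifest = manifest)
  })
}

## mutate background bases until no k-mer is shared with any target
## (sense strand), except planted copies listed in `keep`; bases inside a
## planted copy are never touched
scrub_shared_kmers <- function(background, targets, k, keep = NULL) {
  target_kmers <- unique(unlist(lapply(targets, kmer_set, k = k),
                                use.names = FALSE))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:50) {
    dirty <- FALSE
    for (bi in seq_along(background)) {
      bname <- names(background)[bi]
      bseq <- background[[bi]]
      starts <- seq_len(nchar(bseq) - k + 1L)
      km <- substring(bseq, starts, starts + k - 1L)
      bad <- which(km %in% target_kmers)
      planted_starts <- integer(0)
      planted_span <- integer(0)
      if (!is.null(keep)) {
        kept <- keep[keep$background_id == bname, , drop = FALSE]
        planted_starts <- kept$insert_pos
        planted_span <- unique(unlist(lapply(
          kept$insert_pos, function(q) q:(q + k - 1L))))
      }
      bad <- setdiff(bad, planted_starts)
      for (p in bad) {
        span <- p:(p + k - 1L)
        mutable <- setdiff(span, planted_span)
        if (length(mutable) == 0L) next    # only the planted copy itself
        mid <- mutable[ceiling(length(mutable) / 2)]
        substr(bseq, mid, mid) <- rot[[substr(bseq, mid, mid)]]
        dirty <- TRUE
      }
      background[[bi]] <- bseq
    }
    if (!dirty) return(background)
  }
  warning("could not scrub all shared k-mers after 50 passes")
  background
}

#' Simulate a fraction-positive calibration curve
#'
#' Draws, for each FPKM grid point, the number of positive cells among
#' `n_cells` under the Poisson sampling model
#' `P(positive) = 1 - exp(-c * fpkm)`.
#'
#' @param c copies-per-FPKM constant (> 0).
#' @param fpkm_grid FPKM values.
#' @param n_cells cells per grid point.
#' @param seed random seed.
#' @return data.frame with `fpkm`, `n_cells`, `n_positive`.
#' @export
gen_calibration_curve <- function(c = 2.5,
                                  fpkm_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                                  n_cells = 200L, seed = 1L) {
  stopifnot(c > 0)
  with_seed(seed, {
    p <- 1 - exp(-c * fpkm_grid)
    data.frame(fpkm = fpkm_grid, n_cells = n_cells,
               n_positive = rbinom(length(fpkm_grid), n_cells, p))
  })
}

#' Default per-class expression rates for the synthetic tissue
#'
#' Ten cell classes over the eight-gene mouse-lung panel, with
#' marker-specific high/low structure: macrophages (Lyz2/Ftl1/Actb high),
#' two AT2 classes split by Lyz2, two Club classes split by Actb, AT1
#' (Ager high), and four "other" classes defined by housekeeping-gene
#' signatures. Values are expected puncta per cell per gene; they are
#' fixture parameters, not measurements of real lung.
#'
#' @return a 10 x 8 matrix (classes x genes) of Poisson puncta rates.
#' @export
default_class_rates <- function() {
  genes <- c("Actb", "Ager", "Ftl1", "Gapdh", "Lyz2", "Scgb1a1", "Sftpc",
             "Xist")
  rates <- rbind(
    Mac     = c(20, 0.5, 20,  8, 20,  0.5, 0.5, 1),
    AT2_1   = c(4,  2,   4,   8, 18,  0.5, 20,  1),
    AT2_2   = c(4,  2,   4,   8, 0.5, 0.5, 20,  1),
    Club_1  = c(20, 0.5, 12,  8, 0.5, 20,  0.5, 1),
    Club_2  = c(1,  0.5, 12,  8, 0.5, 20,  0.5, 1),
    AT1     = c(16, 20,  2,   8, 0.5, 0.5, 0.5, 1),
    Other_a = c(8,  0.5, 0.5, 20, 0.5, 0.5, 0.5, 1),
    Other_b = c(0.5, 10, 2,   8, 0.5, 0.5, 0.5, 1),
    Other_c = c(0.5, 0.5, 0.5, 8, 0.5, 0.5, 0.5, 15),
    Other_d = c(0.5, 4,  18,  4, 0.5, 0.5, 0.5, 1)
  )
  colnames(rates) <- genes
  rates
}

#' Specify a synthetic multiplexed tissue experiment
#'
#' Captures every knob of the image generator: field geometry, cell
#' placement, class mixture, per-class puncta rates, the negative-binomial
#' puncta-amplitude model (default cv 1.5, mid-range of the 1-2 regime
#' typical of rolling-circle amplicons), autofluorescent background (kept
#' more than 30-fold below the puncta amplitude), and per-cycle planted
#' translation offsets.
#'
#' @param field_px field size in pixels (square).
#' @param pixel_size_um pixel size in micrometers.
#' @param n_cells number of cells to place.
#' @param min_separation_px minimum nucleus center separation.
#' @param margin_px keep-out border for nucleus centers.
#' @param class_proportions per-class mixing proportions (sum 1).
#' @param class_rates classes x genes matrix of Poisson puncta rates.
#' @param puncta_mean,puncta_cv negative-binomial amplitude model.
#' @param spot_sigma_px Gaussian footprint of one punctum.
#' @param puncta_radius_px puncta scatter radius around the nucleus
#'   center (nuclear + peri-nuclear region).
#' @param nucleus_sigma_px,nucleus_amp nuclear-stain blob shape.
#' @param background_level mean autofluorescent background intensity.
#' @param background_sd Gaussian background noise sd.
#' @param cycle_offsets list of per-cycle planted `(dy, dx)` offsets.
#' @param channels_per_cycle data channels imaged per cycle (<= 5 with the
#'   nuclear stain).
#' @param seed random seed.
#' @return an object of class `plish_tissue_spec` (a list).
#' @export
tissue_spec <- function(field_px = 600L, pixel_size_um = 0.5,
                        n_cells = 300L, min_separation_px = 18L,
                        margin_px = 15L,
                        class_proportions = c(0.12, 0.12, 0.12, 0.10, 0.10,
                                              0.12, 0.08, 0.08, 0.08, 0.08),
                        class_rates = default_class_rates(),
                        puncta_mean = 150, puncta_cv = 1.5,
                        spot_sigma_px = 1.5, puncta_radius_px = 8L,
                        nucleus_sigma_px = 3, nucleus_amp = 200,
                        background_level = 2, background_sd = 0.5,
                        cycle_offsets = list(c(0L, 0L), c(3L, -2L)),
                        channels_per_cycle = 4L, seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1")
  }
  if (length(class_proportions) != nrow(class_rates)) {
    stop("one proportion per class required")
  }
  if (any(class_rates < 0)) stop("puncta rates must be non-negative")
  if (channels_per_cycle > 4L) {
    stop("at most 4 data channels + nuclear stain per cycle")
  }
  n_genes <- ncol(class_rates)
  if (length(cycle_offsets) * channels_per_cycle < n_genes) {
    stop("not enough (cycle, channel) slots for ", n_genes, " genes")
  }
  if (background_level >= puncta_mean / 30) {
    stop("background exceeds 1/30 of the puncta amplitude; ",
         "the fixture is meant to mirror the >30-fold regime")
  }
  structure(as.list(environment()), class = "plish_tissue_spec")
}

#' @export
print.plish_tissue_spec <- function(x, ...) {
  cat(sprintf("Synthetic tissue spec: %dx%d px (%.2f um/px), %d cells, %d classes, %d genes, %d cycle(s)\n",
              x$field_px, x$field_px, x$pixel_size_um, x$n_cells,
              nrow(x$class_rates), ncol(x$class_rates),
              length(x$cycle_offsets)))
  invisible(x)
}

## dart-throwing placement with minimum separation
place_nuclei <- function(spec) {
  n <- spec$n_cells
  lo <- spec$margin_px
  hi <- spec$field_px - spec$margin_px
  ys <- numeric(0); xs <- numeric(0)
  attempts <- 0L
  while (length(ys) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) {
      stop("cell density exceeds the packing limit; reduce n_cells or ",
           "min_separation_px")
    }
    y <- runif(1, lo, hi); x <- runif(1, lo, hi)
    if (length(ys) == 0L ||
        min((ys - y)^2 + (xs - x)^2) >= spec$min_separation_px^2) {
      ys <- c(ys, y); xs <- c(xs, x)
    }
  }
  data.frame(y = round(ys), x = round(xs))
}

## add a Gaussian stamp of given peak amplitude at (y, x)
add_spot <- function(img, y, x, amp, sigma) {
  r <- ceiling(3 * sigma)
  ys <- max(1L, y - r):min(nrow(img), y + r)
  xs <- max(1L, x - r):min(ncol(img), x + r)
  g <- outer(ys - y, xs - x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

#' Generate multi-cycle synthetic tissue images with ground truth
#'
#' Renders a field of cells: smooth Gaussian nuclei in the nuclear-stain
#' channel, per-cell per-gene puncta counts drawn from the class's Poisson
#' rate, each punctum a small Gaussian spot with negative-binomially
#' distributed amplitude scattered over the nuclear/peri-nuclear region,
#' plus autofluorescent background. Genes are distributed over
#' label-image-erase cycles and every channel of a cycle (including the
#' nuclear stain) is shifted by that cycle's planted offset. Pure function
#' of `(spec, seed)`.
#'
#' @param spec a [tissue_spec()].
#' @return list with `cycles` (list of [field_image()]), `truth`
#'   (data.frame: `cell`, `class_id`, `class_name`, `y`, `x`, planted
#'   per-gene puncta counts as `n_<gene>`), `puncta` (per-punctum table
#'   with amplitudes), `gene_cycle` (gene -> cycle map), `spec`.
#' @export
gen_tissue_images <- function(spec = tissue_spec()) {
  stopifnot(inherits(spec, "plish_tissue_spec"))
  with_seed(spec$seed, {
    genes <- colnames(spec$class_rates)
    n_genes <- length(genes)
    n_classes <- nrow(spec$class_rates)
    centers <- if (spec$n_cells > 0L) place_nuclei(spec) else
      data.frame(y = numeric(0), x = numeric(0))
    class_id <- if (spec$n_cells > 0L)
      sample.int(n_classes, spec$n_cells, replace = TRUE,
                 prob = spec$class_proportions) else integer(0)

    dim_px <- spec$field_px
    r_nb <- nb_dispersion_for_cv(spec$puncta_mean, spec$puncta_cv)

    ## unshifted truth-frame images
    dapi <- matrix(0, dim_px, dim_px)
    for (i in seq_len(spec$n_cells)) {
      dapi <- add_spot(dapi, centers$y[i], centers$x[i], spec$nucleus_amp,
                       spec$nucleus_sigma_px)
    }
    gene_imgs <- lapply(genes, function(g) matrix(0, dim_px, dim_px))
    names(gene_imgs) <- genes
    counts <- matrix(0L, max(spec$n_cells, 0L), n_genes,
                     dimnames = list(NULL, genes))
    signal <- matrix(0, max(spec$n_cells, 0L), n_genes,
                     dimnames = list(NULL, genes))
    puncta <- list()
    for (i in seq_len(spec$n_cells)) {
      for (gi in seq_len(n_genes)) {
        lam <- spec$class_rates[class_id[i], gi]
        np <- rpois(1L, lam)
        counts[i, gi] <- np
        if (np == 0L) next
        theta <- runif(np, 0, 2 * pi)
        rad <- spec$puncta_radius_px * sqrt(runif(np))
        py <- pmin(pmax(round(centers$y[i] + rad * sin(theta)), 1L), dim_px)
        px <- pmin(pmax(round(centers$x[i] + rad * cos(theta)), 1L), dim_px)
        amp <- rnbinom(np, size = r_nb, mu = spec$puncta_mean)
        signal[i, gi] <- sum(amp)
        for (p in seq_len(np)) {
          gene_imgs[[gi]] <- add_spot(gene_imgs[[gi]], py[p], px[p],
                                      amp[p], spec$spot_sigma_px)
        }
        puncta[[length(puncta) + 1L]] <- data.frame(
          cell = i, gene = genes[gi], y = py, x = px, amplitude = amp)
      }
    }

    ## genes -> (cycle, channel) slots, filling channels first
    n_cycles <- length(spec$cycle_offsets)
    gene_cycle <- (seq_len(n_genes) - 1L) %/% spec$channels_per_cycle + 1L
    names(gene_cycle) <- genes

    cycles <- vector("list", n_cycles)
    for (cy in seq_len(n_cycles)) {
      off <- spec$cycle_offsets[[cy]]
      chans <- list()
      noisy <- function(img) {
        img + spec$background_level +
          matrix(rnorm(dim_px^2, 0, spec$background_sd), dim_px, dim_px)
      }
      chans[["DAPI"]] <- pmax(shift_image(noisy(dapi), off[1], off[2]), 0)
      for (g in genes[gene_cycle == cy]) {
        chans[[g]] <- pmax(shift_image(noisy(gene_imgs[[g]]), off[1],
                                       off[2]), 0)
      }
      cycles[[cy]] <- field_image(chans, cycle = cy,
                                  pixel_size_um = spec$pixel_size_um)
    }

    truth <- data.frame(cell = seq_len(spec$n_cells),
                        class_id = class_id,
                        class_name = rownames(spec$class_rates)[class_id],
                        y = centers$y, x = centers$x)
    cn <- counts
    colnames(cn) <- paste0("n_", genes)
    sg <- signal
    colnames(sg) <- paste0("signal_", genes)
    truth <- cbind(truth, as.data.frame(cn), as.data.frame(sg))
    list(cycles = cycles, truth = truth,
         puncta = if (length(puncta)) do.call(rbind, puncta) else NULL,
         gene_cycle = gene_cycle, spec = spec)
  })
}

#' Write a synthetic tissue simulation to disk
#'
#' Saves each channel of each cycle as 16-bit TIFF plus the ground-truth
#' table and a YAML manifest mapping files to cycle/channel/gene.
#'
#' @param sim output of [gen_tissue_images()].
#' @param outdir output directory (created if missing).
#' @param scale intensity divisor mapping intensities into [0, 1] for
#'   16-bit storage.
#' @return the manifest path, invisibly.
#' @export
write_tissue_images <- function(sim, outdir, scale = 4096) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(pixel_size_um = sim$spec$pixel_size_um,
                   nuclear_channel = "DAPI", cycles = list())
  for (cy in seq_along(sim$cycles)) {
    field <- sim$cycles[[cy]]
    entry <- list()
    for (nm in names(field$channels)) {
      fn <- sprintf("cycle%d_%s.tif", cy, nm)
      img <- pmin(field$channels[[nm]] / scale, 1)
      tiff::writeTIFF(img, file.path(outdir, fn), bits.per.sample = 16L)
      entry[[nm]] <- fn
    }
    manifest$cycles[[paste0("cycle", cy)]] <- entry
  }
  write.csv(sim$truth, file.path(outdir, "ground_truth.csv"),
            row.names = FALSE)
  mpath <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a tissue-image manifest back into field images
#'
#' @param manifest_path path to the YAML manifest written by
#'   [write_tissue_images()] (or hand-written for real data: keys
#'   `pixel_size_um`, `nuclear_channel`, `cycles: {cycle1: {name: file}}`).
#' @param scale intensity multiplier undoing the storage scaling.
#' @return list of [field_image()] objects.
#' @export
read_tissue_images <- function(manifest_path, scale = 4096) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_along(man$cycles), function(cy) {
    entry <- man$cycles[[cy]]
    chans <- lapply(entry, function(fn) {
      tiff::readTIFF(file.path(base, fn)) * scale
    })
    field_image(chans, cycle = cy, pixel_size_um = man$pixel_size_um,
                nuclear_channel = man$nuclear_channel %||% "DAPI")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
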