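#' Bundle the channels of one imaging cycle
#'
#' A field image is the set of co-acquired channels of one
#' label-image-erase cycle: named 2-D intensity matrices (row, col),
#' including the nuclear-stain channel used as the registration fiducial.
#'
#' @param channels named list of numeric matrices with identical
#'   dimensions; names are channel/gene names.
#' @param cycle cycle index (1-based).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param nuclear_channel name of the nuclear-stain channel.
#' @return an object of class `plish_field`.
#' @export
field_image <- function(channels, cycle = 1L, pixel_size_um = 0.5,
                        nuclear_channel = "DAPI") {
  stopifnot(is.list(channels), length(channels) > 0L,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L) {
    stop("all channels of one cycle must share dimensions")
  }
  if (!nuclear_channel %in% names(channels)) {
    stop("nuclear channel '", nuclear_channel, "' not present")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(channels = lapply(channels, as.matrix), cycle = cycle,
                 pixel_size_um = pixel_size_um,
                 nuclear_channel = nuclear_channel),
            class = "plish_field")
}

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack a 3-D array (row, col, plane) or a list of equally sized
#'   matrices.
#' @return the per-pixel maximum across planes (2-D matrix).
#' @export
max_project <- function(zstack) {
  if (is.list(zstack)) {
    dims <- unique(vapply(zstack, function(p) paste(dim(p), collapse = "x"),
                          ""))
    if (length(dims) != 1L) stop("z-planes have mismatched shapes")
    return(Reduce(pmax, lapply(zstack, as.matrix)))
  }
  if (length(dim(zstack)) == 2L) return(as.matrix(zstack))
  if (length(dim(zstack)) != 3L) stop("zstack must be 2-D or 3-D")
  apply(zstack, c(1L, 2L), max)
}

## translate an image by whole pixels, zero-filling uncovered borders:
## out[i + dy, j + dx] = img[i, j]
shift_image <- function(img, dy, dx) {
  out <- matrix(0, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- max(1L, 1L - dy):min(nr, nr - dy)
  src_c <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(src_r) < 1L || length(src_c) < 1L) return(out)
  out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}

## integer-pixel phase correlation: returns c(dy, dx) such that
## moving ~ shift_image(reference, dy, dx), plus the normalized peak height
phase_correlation <- function(reference, moving) {
  if (sd(reference) == 0 || sd(moving) == 0) {
    return(list(dy = 0L, dx = 0L, peak = 0))
  }
  fa <- fft(reference)
  fb <- fft(moving)
  cross <- fb * Conj(fa)
  mag <- Mod(cross)
  mag[mag == 0] <- 1
  corr <- Re(fft(cross / mag, inverse = TRUE)) / length(reference)
  peak <- which.max(corr)
  pr <- (peak - 1L) %% nrow(corr)
  pc <- (peak - 1L) %/% nrow(corr)
  dy <- if (pr > nrow(corr) %/% 2L) pr - nrow(corr) else pr
  dx <- if (pc > ncol(corr) %/% 2L) pc - ncol(corr) else pc
  list(dy = as.integer(dy), dx = as.integer(dx), peak = max(corr))
}

#' Register imaging cycles on the nuclear stain
#'
#' Later cycles are aligned to the first by translation-only registration:
#' integer-pixel phase correlation of the nuclear-stain channels, with the
#' recovered offset applied to every channel of the cycle. A degenerate
#' correlation (blank fiducial or peak below `min_peak`) leaves the cycle
#' unshifted with a warning.
#'
#' @param cycles list of [field_image()] objects (>= 2 for any alignment to
#'   happen; a single cycle passes through).
#' @param min_peak minimum normalized correlation peak accepted.
#' @return a list with `cycles` (aligned fields) and `offsets` (data.frame
#'   of the recovered per-cycle `dy`, `dx`, in pixels; the applied
#'   correction is their negation).
#' @export
register_cycles <- function(cycles, min_peak = 0.03) {
  stopifnot(length(cycles) >= 1L)
  ref <- cycles[[1L]]$channels[[cycles[[1L]]$nuclear_channel]]
  offsets <- data.frame(cycle = seq_along(cycles), dy = 0L, dx = 0L,
                        peak = NA_real_)
  aligned <- cycles
  for (i in seq_along(cycles)) {
    if (i == 1L) next
    nuc <- cycles[[i]]$channels[[cycles[[i]]$nuclear_channel]]
    pc <- phase_correlation(ref, nuc)
    if (pc$peak < min_peak) {
      warning(sprintf("cycle %d: correlation peak %.3f below %.3f; %s",
                      i, pc$peak, min_peak, "keeping identity offset"))
      pc$dy <- 0L; pc$dx <- 0L
    }
    offsets$dy[i] <- pc$dy
    offsets$dx[i] <- pc$dx
    offsets$peak[i] <- pc$peak
    aligned[[i]]$channels <- lapply(cycles[[i]]$channels, shift_image,
                                    dy = -pc$dy, dx = -pc$dx)
  }
  list(cycles = aligned, offsets = offsets)
}

#' Detect nucleus centers as maxima of a filtered nuclear image
#'
#' The nuclear stain is Gaussian-smoothed, thresholded automatically
#' (Otsu), and nucleus seeds are taken as local intensity maxima separated
#' by at least `min_separation_um` (two closer maxima merge into the
#' brighter one).
#'
#' @param dapi 2-D nuclear-stain matrix.
#' @param pixel_size_um pixel size in micrometers.
#' @param smoothing_sigma_um Gaussian smoothing sigma, micrometers.
#' @param min_separation_um minimum seed separation, micrometers.
#' @return data.frame with `y`, `x` (0-based pixel coordinates, row/col)
#'   and `intensity`; zero rows for a blank image.
#' @export
detect_nuclei <- function(dapi, pixel_size_um = 0.5,
                          smoothing_sigma_um = 1,
                          min_separation_um = 4) {
  stopifnot(smoothing_sigma_um > 0, min_separation_um > 0)
  dapi <- as.matrix(dapi)
  if (max(dapi) == 0) {
    return(data.frame(y = integer(), x = integer(), intensity = numeric()))
  }
  sigma_px <- smoothing_sigma_um / pixel_size_um
  sm <- smooth_image(dapi, sigma_px)
  thr <- otsu_threshold(sm)
  r <- max(1L, round(min_separation_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(sm, brush))
  maxima <- (sm >= dil) & (sm > thr)
  if (!any(maxima)) {
    return(data.frame(y = integer(), x = integer(), intensity = numeric()))
  }
  ## plateaus: collapse connected maxima to their centroid
  lab <- EBImage::imageData(EBImage::bwlabel(maxima))
  idx <- which(lab > 0)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  grp <- lab[idx]
  y <- round(tapply(rr, grp, mean))
  x <- round(tapply(cc, grp, mean))
  val <- tapply(sm[idx], grp, max)
  seeds <- data.frame(y = as.integer(y), x = as.integer(x),
                      intensity = as.numeric(val))
  ## greedy suppression: keep brighter seed when two fall within r
  seeds <- seeds[order(-seeds$intensity, seeds$y, seeds$x), ]
  keep <- rep(TRUE, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    if (!keep[i]) next
    if (i < nrow(seeds)) {
      later <- (i + 1L):nrow(seeds)
      d2 <- (seeds$y[later] - seeds$y[i])^2 + (seeds$x[later] - seeds$x[i])^2
      keep[later][d2 <= r^2] <- FALSE
    }
  }
  seeds <- seeds[keep, ]
  seeds <- seeds[order(seeds$y, seeds$x), ]
  rownames(seeds) <- NULL
  seeds$y <- seeds$y - 1L
  seeds$x <- seeds$x - 1L
  seeds
}

smooth_image <- function(img, sigma_px) {
  EBImage::imageData(EBImage::gblur(img, sigma = sigma_px))
}

otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(rng[2])
  EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
}

#' Segment nuclei by seeded propagation
#'
#' Grows each seed outward over the above-background region of the smoothed
#' nuclear image using the Voronoi-style propagation algorithm
#' (intensity-weighted region growing; the same algorithm used by
#' CellProfiler-style pipelines, via `EBImage::propagate`). Every seed
#' yields exactly one label, numbered by seed order; a seed that falls on
#' background keeps a degenerate one-pixel label and raises a warning.
#'
#' @param dapi 2-D nuclear-stain matrix.
#' @param seeds data.frame from [detect_nuclei()].
#' @param pixel_size_um pixel size in micrometers.
#' @param smoothing_sigma_um Gaussian smoothing sigma, micrometers.
#' @param lambda regularization of the propagation metric (0 = pure
#'   intensity, large = pure distance).
#' @return integer label matrix (0 = background, i = nucleus i).
#' @export
segment_nuclei <- function(dapi, seeds, pixel_size_um = 0.5,
                           smoothing_sigma_um = 1, lambda = 1e-4) {
  dapi <- as.matrix(dapi)
  lab0 <- matrix(0L, nrow(dapi), ncol(dapi))
  if (nrow(seeds) == 0L) return(lab0)
  sm <- smooth_image(dapi, smoothing_sigma_um / pixel_size_um)
  mask <- sm > otsu_threshold(sm)
  seed_img <- lab0
  seed_img[cbind(seeds$y + 1L, seeds$x + 1L)] <- seq_len(nrow(seeds))
  on_bg <- which(!mask[cbind(seeds$y + 1L, seeds$x + 1L)])
  if (length(on_bg)) {
    warning("seed(s) on background kept as degenerate 1-px labels: ",
            paste(on_bg, collapse = ", "))
    mask[cbind(seeds$y[on_bg] + 1L, seeds$x[on_bg] + 1L)] <- TRUE
  }
  labels <- EBImage::propagate(EBImage::Image(sm / max(sm)),
                               seeds = seed_img, mask = mask,
                               lambda = lambda)
  out <- EBImage::imageData(labels)
  storage.mode(out) <- "integer"
  out
}

#' Expand nucleus labels into peri-nuclear sampling areas
#'
#' Each label grows outward by `round(radius_um / pixel_size_um)` pixels so
#' that the sampling area covers the nuclear and peri-nuclear region where
#' amplification puncta accumulate. Growth never overwrites an existing
#' label; where two expansions collide, pixels go to the nearest label
#' (chessboard metric, ties to the smaller label index), deterministically.
#'
#' @param labels integer nucleus label matrix.
#' @param radius_um expansion radius in micrometers.
#' @param pixel_size_um pixel size in micrometers.
#' @return integer label matrix of sampling areas.
#' @export
expand_cells <- function(labels, radius_um = 1, pixel_size_um = 0.5) {
  stopifnot(radius_um >= 0)
  r <- round(radius_um / pixel_size_um)
  out <- labels
  storage.mode(out) <- "integer"
  if (r == 0L || max(out) == 0L) return(out)
  nr <- nrow(out); nc <- ncol(out)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  for (step in seq_len(r)) {
    cand <- matrix(NA_integer_, nr, nc)
    for (s in seq_len(nrow(shifts))) {
      sh <- shift_image(out, shifts$dy[s], shifts$dx[s])
      sh[sh == 0] <- NA_integer_
      cand <- pmin(cand, sh, na.rm = TRUE)
    }
    grow <- out == 0L & !is.na(cand)
    out[grow] <- cand[grow]
  }
  out
}

#' Measure per-cell expression profiles
#'
#' Computes the mean intensity of every channel over each cell's sampling
#' area, and attaches the cell's anatomical index (field of view, centroid)
#' and nucleus shape metrics. Labels with zero sampling area are excluded
#' with a warning.
#'
#' @param sampling_map integer sampling-area label matrix
#'   ([expand_cells()]).
#' @param channels named list of aligned intensity matrices, one per gene.
#' @param nucleus_labels optional nucleus label matrix for shape metrics
#'   and centroids (defaults to the sampling map).
#' @param fov field-of-view identifier.
#' @param pixel_size_um pixel size in micrometers.
#' @return a `data.frame` (one row per cell) with columns `cell_id`, `fov`,
#'   `x`, `y` (centroid, 0-based pixels), `area_px`, nucleus shape metrics
#'   (`nuc_area_px`, `nuc_perimeter_px`, `nuc_eccentricity`), then one
#'   column per gene. Gene columns are recorded in `attr(, "genes")`.
#' @export
measure_profiles <- function(sampling_map, channels, nucleus_labels = NULL,
                             fov = "fov1", pixel_size_um = 0.5) {
  if (is.null(nucleus_labels)) nucleus_labels <- sampling_map
  stopifnot(is.list(channels), !is.null(names(channels)))
  for (ch in channels) {
    if (!all(dim(ch) == dim(sampling_map))) {
      stop("channel dimensions differ from the sampling map")
    }
  }
  n_cells <- max(sampling_map)
  if (n_cells == 0L) {
    out <- data.frame(cell_id = integer(), fov = character(), x = numeric(),
                      y = numeric(), area_px = integer(),
                      nuc_area_px = integer(), nuc_perimeter_px = numeric(),
                      nuc_eccentricity = numeric())
    for (g in names(channels)) out[[g]] <- numeric()
    attr(out, "genes") <- names(channels)
    return(out)
  }
  ids <- seq_len(n_cells)
  lab_vec <- as.integer(sampling_map)
  area <- tabulate(lab_vec, nbins = n_cells)
  empty <- which(area == 0L)
  if (length(empty)) {
    warning("label(s) with zero sampling area excluded: ",
            paste(empty, collapse = ", "))
    ids <- setdiff(ids, empty)
  }
  inside <- lab_vec > 0L
  f <- factor(lab_vec[inside], levels = ids)
  means <- vapply(channels, function(ch) {
    as.numeric(tapply(as.numeric(ch)[inside], f, mean))
  }, numeric(length(ids)))
  means <- matrix(means, nrow = length(ids),
                  dimnames = list(NULL, names(channels)))

  ## centroid + shape metrics from the nucleus mask
  nuc_vec <- as.integer(nucleus_labels)
  nuc_in <- nuc_vec > 0L & nuc_vec %in% ids
  fn <- factor(nuc_vec[nuc_in], levels = ids)
  idx <- which(nuc_in)
  rr <- (idx - 1L) %% nrow(nucleus_labels)
  cc <- (idx - 1L) %/% nrow(nucleus_labels)
  cy <- as.numeric(tapply(rr, fn, mean))
  cx <- as.numeric(tapply(cc, fn, mean))
  nuc_area <- as.integer(tabulate(nuc_vec[nuc_in], nbins = n_cells)[ids])
  shp <- tryCatch({
    fs <- EBImage::computeFeatures.shape(nucleus_labels)
    fm <- EBImage::computeFeatures.moment(nucleus_labels)
    list(per = fs[ids, "s.perimeter"], ecc = fm[ids, "m.eccentricity"])
  }, error = function(e) list(per = rep(NA_real_, length(ids)),
                              ecc = rep(NA_real_, length(ids))))
  ## fall back to sampling-area centroid for cells without nucleus pixels
  no_nuc <- is.na(cy)
  if (any(no_nuc)) {
    idx2 <- which(inside)
    fr <- factor(lab_vec[idx2], levels = ids)
    cy2 <- as.numeric(tapply((idx2 - 1L) %% nrow(sampling_map), fr, mean))
    cx2 <- as.numeric(tapply((idx2 - 1L) %/% nrow(sampling_map), fr, mean))
    cy[no_nuc] <- cy2[no_nuc]
    cx[no_nuc] <- cx2[no_nuc]
  }
  out <- data.frame(cell_id = ids, fov = fov, x = cx, y = cy,
                    area_px = area[ids], nuc_area_px = nuc_area,
                    nuc_perimeter_px = as.numeric(shp$per),
                    nuc_eccentricity = as.numeric(shp$ecc),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  attr(out, "genes") <- names(channels)
  out
}

#' Boundary-index image of a label map
#'
#' Produces an image that is zero everywhere except on the boundary pixels
#' of each nucleus, which carry the nucleus's integer index — the format
#' used to join classifications back onto micrographs.
#'
#' @param labels integer label matrix.
#' @return integer matrix of boundary indices.
#' @export
export_boundary_index_image <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  boundary <- (ctr != pad[1:nr, 2:(nc + 1L)]) |
    (ctr != pad[3:(nr + 2L), 2:(nc + 1L)]) |
    (ctr != pad[2:(nr + 1L), 1:nc]) |
    (ctr != pad[2:(nr + 1L), 3:(nc + 2L)])
  out <- matrix(0L, nr, nc)
  sel <- boundary & ctr > 0L
  out[sel] <- ctr[sel]
  out
}

#' Write an integer label image as 16-bit TIFF
#'
#' @param labels integer matrix (values 0..65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Quantify one field of view end to end
#'
#' Convenience wrapper running the full per-field pipeline: cycle
#' registration on the nuclear stain, nuclei detection and propagation
#' segmentation on the first cycle's nuclear channel, peri-nuclear
#' expansion, and per-channel profile measurement over all non-nuclear
#' channels of all cycles.
#'
#' @param cycles list of [field_image()] objects.
#' @param fov field-of-view identifier.
#' @param smoothing_sigma_um,min_separation_um,expansion_um pipeline
#'   parameters in micrometers.
#' @return list with `profiles` (the cell table), `nucleus_labels`,
#'   `sampling_map`, `boundary_index`, `offsets`, `seeds`.
#' @export
quantify_field <- function(cycles, fov = "fov1", smoothing_sigma_um = 1,
                           min_separation_um = 4, expansion_um = 1) {
  reg <- register_cycles(cycles)
  px <- cycles[[1L]]$pixel_size_um
  nuc <- reg$cycles[[1L]]$channels[[reg$cycles[[1L]]$nuclear_channel]]
  seeds <- detect_nuclei(nuc, px, smoothing_sigma_um, min_separation_um)
  labels <- segment_nuclei(nuc, seeds, px, smoothing_sigma_um)
  sampling <- expand_cells(labels, expansion_um, px)
  channels <- list()
  for (cy in reg$cycles) {
    for (nm in names(cy$channels)) {
      if (nm != cy$nuclear_channel) channels[[nm]] <- cy$channels[[nm]]
    }
  }
  profiles <- measure_profiles(sampling, channels, nucleus_labels = labels,
                               fov = fov, pixel_size_um = px)
  list(profiles = profiles, nucleus_labels = labels,
       sampling_map = sampling,
       boundary_index = export_boundary_index_image(labels),
       offsets = reg$offsets, seeds = seeds)
}
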