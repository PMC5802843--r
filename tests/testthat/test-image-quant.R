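test_that("maximum projection equals the elementwise maximum", {
  one <- matrix(runif(100), 10, 10)
  expect_equal(max_project(array(one, c(10, 10, 1))), one)
  set.seed(3)
  planes <- lapply(1:3, function(i) matrix(runif(100), 10, 10))
  expect_equal(max_project(planes), pmax(planes[[1]], planes[[2]],
                                         planes[[3]]))
  stack <- array(unlist(planes), c(10, 10, 3))
  expect_equal(max_project(stack), pmax(planes[[1]], planes[[2]],
                                        planes[[3]]))
  expect_equal(max_project(array(0, c(4, 4, 3))), matrix(0, 4, 4))
  expect_error(max_project(list(matrix(0, 3, 3), matrix(0, 4, 4))),
               "mismatched")
})

make_nuclei_field <- function(n = 12, dim_px = 200, seed = 1, amp = 200,
                              sigma = 3, min_sep = 20) {
  set.seed(seed)
  ys <- numeric(0); xs <- numeric(0)
  while (length(ys) < n) {
    y <- runif(1, 15, dim_px - 15); x <- runif(1, 15, dim_px - 15)
    if (!length(ys) || min((ys - y)^2 + (xs - x)^2) >= min_sep^2) {
      ys <- c(ys, round(y)); xs <- c(xs, round(x))
    }
  }
  img <- matrix(0, dim_px, dim_px)
  for (i in seq_len(n)) img <- plant_blob(img, ys[i], xs[i], amp, sigma)
  list(img = img, y = ys, x = xs)
}

test_that("cycle registration recovers planted integer shifts", {
  f <- make_nuclei_field(seed = 5)
  c1 <- field_image(list(DAPI = f$img, g = f$img * 0.3), cycle = 1)
  shifted <- lapply(c1$channels, plishr:::shift_image, dy = 3, dx = -2)
  c2 <- field_image(shifted, cycle = 2)
  reg <- register_cycles(list(c1, c2))
  expect_equal(reg$offsets$dy, c(0L, 3L))
  expect_equal(reg$offsets$dx, c(0L, -2L))
  ## aligned images match the reference away from the zero-filled border
  inner <- 10:190
  expect_equal(reg$cycles[[2]]$channels$DAPI[inner, inner],
               f$img[inner, inner], tolerance = 1e-10)
  ## identical cycles -> zero offset
  reg0 <- register_cycles(list(c1, c1))
  expect_equal(reg0$offsets$dy[2], 0L)
  expect_equal(reg0$offsets$dx[2], 0L)
})

test_that("a blank fiducial falls back to the identity offset with a warning", {
  f <- make_nuclei_field(seed = 6)
  c1 <- field_image(list(DAPI = f$img), cycle = 1)
  c2 <- field_image(list(DAPI = matrix(0, 200, 200)), cycle = 2)
  expect_warning(reg <- register_cycles(list(c1, c2)), "identity")
  expect_equal(reg$offsets$dy[2], 0L)
})

test_that("nuclei detection finds each planted nucleus once, within 2 px", {
  expect_equal(nrow(detect_nuclei(matrix(0, 50, 50))), 0L)
  f <- make_nuclei_field(n = 40, dim_px = 400, seed = 7)
  seeds <- detect_nuclei(f$img, pixel_size_um = 0.5)
  expect_equal(nrow(seeds), 40L)
  d <- sqrt(outer(seeds$y + 1, f$y, "-")^2 + outer(seeds$x + 1, f$x, "-")^2)
  expect_true(all(apply(d, 2, min) <= 2))
  ## two nuclei closer than the suppression radius merge into one seed
  img <- matrix(0, 80, 80)
  img <- plant_blob(img, 40, 38, 200, 3)
  img <- plant_blob(img, 40, 43, 200, 3)
  close_seeds <- detect_nuclei(img, pixel_size_um = 0.5,
                               min_separation_um = 4)
  expect_equal(nrow(close_seeds), 1L)
})

test_that("propagation segmentation recovers planted disk areas", {
  img <- matrix(0, 120, 120)
  centers <- list(c(30, 30), c(30, 90), c(90, 40), c(85, 95))
  rad <- 8
  for (ct in centers) {
    for (i in (ct[1] - rad):(ct[1] + rad)) {
      for (j in (ct[2] - rad):(ct[2] + rad)) {
        if ((i - ct[1])^2 + (j - ct[2])^2 <= rad^2) img[i, j] <- 150
      }
    }
  }
  seeds <- detect_nuclei(img, pixel_size_um = 0.5)
  expect_equal(nrow(seeds), 4L)
  labels <- segment_nuclei(img, seeds, pixel_size_um = 0.5)
  expect_equal(max(labels), 4L)
  planted_area <- sum((outer(-rad:rad, -rad:rad,
                             function(a, b) a^2 + b^2)) <= rad^2)
  areas <- tabulate(labels[labels > 0], nbins = 4)
  expect_true(all(abs(areas - planted_area) / planted_area <= 0.10))
  ## labels partition the foreground: one label per pixel by construction,
  ## and every seed produced a label
  expect_setequal(sort(unique(as.integer(labels[labels > 0]))), 1:4)
})

test_that("cell expansion matches a square-dilation oracle for one nucleus", {
  labels <- matrix(0L, 40, 40)
  labels[18:22, 18:22] <- 1L
  expect_identical(expand_cells(labels, radius_um = 0), labels)
  grown <- expand_cells(labels, radius_um = 1, pixel_size_um = 0.5)
  oracle <- oracle_box_dilate(labels == 1L, 2L)
  expect_identical(grown == 1L, oracle)
  ## expansion never reassigns original nucleus pixels
  two <- matrix(0L, 30, 30)
  two[10:14, 10:14] <- 1L
  two[10:14, 16:20] <- 2L
  g2 <- expand_cells(two, radius_um = 1, pixel_size_um = 0.5)
  expect_true(all(g2[two == 1L] == 1L))
  expect_true(all(g2[two == 2L] == 2L))
  ## still a partition: expansion only fills background
  expect_true(all(g2[two > 0L] == two[two > 0L]))
})

test_that("profile measurement returns exact means and excludes empty labels", {
  labels <- matrix(0L, 30, 30)
  labels[5:10, 5:10] <- 1L
  labels[20:25, 20:25] <- 2L
  ch <- matrix(0, 30, 30)
  ch[labels == 1L] <- 7.0
  ch[labels == 2L] <- 3.0
  tab <- measure_profiles(labels, list(geneA = ch))
  expect_equal(tab$geneA, c(7, 3))
  expect_equal(attr(tab, "genes"), "geneA")
  ## centroid of cell 1 is the square's center (0-based)
  expect_equal(tab$y[1], 6.5)
  expect_equal(tab$x[1], 6.5)
  ## zero image -> zero means
  tab0 <- measure_profiles(labels, list(g = matrix(0, 30, 30)))
  expect_equal(tab0$g, c(0, 0))
  ## a label index with no pixels is dropped with a warning
  labels2 <- labels
  labels2[labels2 == 2L] <- 3L
  expect_warning(tab2 <- measure_profiles(labels2, list(g = ch)), "excluded")
  expect_equal(tab2$cell_id, c(1L, 3L))
  expect_error(measure_profiles(labels, list(g = matrix(0, 10, 10))),
               "dimensions")
})

test_that("boundary-index image equals the erosion-difference oracle", {
  labels <- matrix(0L, 20, 20)
  labels[5:10, 5:10] <- 5L
  b <- export_boundary_index_image(labels)
  expect_true(all(b[labels == 0L] == 0L))
  expect_true(all(b[b > 0L] == 5L))
  oracle <- oracle_boundary(labels, 5L)
  expect_identical(b == 5L, oracle)
  ## interior is zero
  expect_equal(b[7, 7], 0L)
  ## two adjacent labels both contribute their boundary
  labels[5:10, 11:16] <- 9L
  b2 <- export_boundary_index_image(labels)
  expect_identical(b2 == 5L, oracle_boundary(labels, 5L))
  expect_identical(b2 == 9L, oracle_boundary(labels, 9L))
  expect_identical(export_boundary_index_image(matrix(0L, 8, 8)),
                   matrix(0L, 8, 8))
})

test_that("measurements are invariant to planted shifts after registration", {
  sim <- gen_tissue_images(tissue_spec(
    field_px = 300L, n_cells = 60L, seed = 11,
    cycle_offsets = list(c(0L, 0L), c(4L, -3L))))
  sim0 <- gen_tissue_images(tissue_spec(
    field_px = 300L, n_cells = 60L, seed = 11,
    cycle_offsets = list(c(0L, 0L), c(0L, 0L))))
  q <- quantify_field(sim$cycles)
  q0 <- quantify_field(sim0$cycles)
  expect_equal(q$offsets$dy[2], 4L)
  expect_equal(q$offsets$dx[2], -3L)
  expect_equal(nrow(q$profiles), nrow(q0$profiles))
  genes <- attr(q$profiles, "genes")
  m <- as.matrix(q$profiles[genes])
  m0 <- as.matrix(q0$profiles[genes])
  ## same cells in the same order (same unshifted nuclear stain)
  expect_true(all(abs(m - m0) / pmax(m0, 1) < 0.02))
})
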