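## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## every length-L window whose central dinucleotide is AG or TA
oracle_windows <- function(seq, L) {
  n <- nchar(seq)
  out <- data.frame(start = integer(), end = integer())
  for (start in seq_len(max(n - L + 1L, 0L))) {
    j <- start + L %/% 2L - 1L
    if (substr(seq, j, j + 1L) %in% c("AG", "TA")) {
      out <- rbind(out, data.frame(start = start, end = start + L - 1L,
                                   junction_pos = j))
    }
  }
  out
}

## leftmost-first non-overlapping packing of candidate windows
oracle_pack <- function(windows) {
  keep <- integer(0)
  last_end <- 0L
  for (i in seq_len(nrow(windows))) {
    if (windows$start[i] > last_end) {
      keep <- c(keep, i)
      last_end <- windows$end[i]
    }
  }
  windows[keep, , drop = FALSE]
}

## naive substring screen: does the site share any >= k-nt stretch with a
## non-target transcript? (character-by-character, no k-mer index)
oracle_screen_fails <- function(site_seq, background, k) {
  for (b in background) {
    for (p in seq_len(nchar(site_seq) - k + 1L)) {
      if (grepl(substr(site_seq, p, p + k - 1L), b, fixed = TRUE)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

## longest common substring of a and b by direct enumeration
oracle_lcs <- function(a, b) {
  na <- nchar(a)
  for (len in rev(seq_len(na))) {
    for (p in seq_len(na - len + 1L)) {
      if (grepl(substr(a, p, p + len - 1L), b, fixed = TRUE)) return(len)
    }
  }
  0L
}

## hand-evaluated nearest-neighbor Tm: an independent summation with its own
## copy of the unified parameter table
oracle_tm <- function(seq, oligo_uM = 0.25, na_mM = 50) {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  H <- 0; S <- 0
  for (i in 1:(n - 1)) {
    nn <- paste0(b[i], b[i + 1])
    H <- H + dH[[nn]]
    S <- S + dS[[nn]]
  }
  for (t in b[c(1, n)]) {
    if (t %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  comp <- chartr("ACGT", "TGCA", seq)
  selfc <- identical(paste(rev(strsplit(comp, "")[[1]]), collapse = ""), seq)
  if (selfc) S <- S - 1.4
  S <- S + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- oligo_uM * 1e-6
  H * 1000 / (S + 1.9872 * log(ct / (if (selfc) 1 else 4))) - 273.15
}

## dilate a binary mask with a (2r+1) x (2r+1) square structuring element
oracle_box_dilate <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      out[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)] <- TRUE
    }
  }
  out
}

## boundary of one label: pixels of the label whose 4-neighborhood leaves it
oracle_boundary <- function(labels, id) {
  mask <- labels == id
  nr <- nrow(mask); nc <- ncol(mask)
  er <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
              if (i < nr) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE,
              if (j < nc) mask[i, j + 1] else FALSE)
      er[i, j] <- all(nb)
    }
  }
  mask & !er
}

## draw one Gaussian blob into an image (for planted-nuclei fixtures)
plant_blob <- function(img, y, x, amp, sigma) {
  r <- ceiling(3 * sigma)
  ys <- max(1, y - r):min(nrow(img), y + r)
  xs <- max(1, x - r):min(ncol(img), x + r)
  img[ys, xs] <- img[ys, xs] +
    amp * outer(ys - y, xs - x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  img
}

## average-linkage agglomeration by direct recomputation over point sets
oracle_average_linkage <- function(m) {
  groups <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        d <- mean(as.matrix(stats::dist(m))[groups[[i]], groups[[j]],
                                            drop = FALSE])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}
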