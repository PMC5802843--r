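test_that("a junction-free transcript yields no detection sites", {
  homo <- paste(rep("A", 100), collapse = "")
  expect_equal(nrow(find_detection_sites(homo, transcript_id = "polyA")), 0L)
  expect_error(find_detection_sites("ACGTACGT"), "shorter than")
})

test_that("site enumeration matches the brute-force window oracle", {
  tx <- rand_dna(2000, seed = 42)
  cand <- oracle_windows(tx, 40L)
  ## every emitted site is a legal window; packing matches the oracle when
  ## the non-overlapping packing fits the budget
  packed <- oracle_pack(cand)
  sites10 <- find_detection_sites(tx, max_sites = 10L)
  expect_true(all(paste(sites10$start, sites10$end) %in%
                    paste(cand$start, cand$end)))
  expect_equal(nrow(sites10), min(10L, nrow(packed)))
  ## sparse-junction sequence: packing fits, so the site set is exactly the
  ## greedy packing
  set.seed(7)
  sparse <- paste(sample(c("C", "G"), 900, replace = TRUE), collapse = "")
  for (p in c(100, 350, 600, 850)) substr(sparse, p, p + 1) <- "TA"
  s <- find_detection_sites(sparse, max_sites = 10L)
  o <- oracle_pack(oracle_windows(sparse, 40L))
  expect_equal(s$start, o$start)
  expect_equal(s$end, o$end)
})

test_that("emitted sites are non-overlapping 40-nt windows split at AG/TA", {
  for (seed in 1:5) {
    tx <- rand_dna(1500, seed = 300 + seed)
    s <- find_detection_sites(tx, max_sites = 10L)
    if (nrow(s) == 0) next
    expect_true(all(s$end - s$start + 1L == 40L))
    expect_true(all(s$dinucleotide %in% c("AG", "TA")))
    expect_equal(substring(tx, s$junction_pos, s$junction_pos + 1L),
                 s$dinucleotide)
    ## the junction splits the window at its midpoint
    expect_true(all(s$junction_pos == s$start + 19L))
    if (nrow(s) > 1) {
      expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("arm adjustment walks the distal end into the Tm window", {
  tx <- rand_dna(2000, seed = 42)
  sites <- find_detection_sites(tx, max_sites = 5L)
  a <- adjust_arm_lengths(sites[1, ], tx)
  expect_true(a$ok)
  expect_true(a$hl_tm >= 45 && a$hl_tm <= 65)
  expect_true(a$hr_tm >= 45 && a$hr_tm <= 65)
  ## fixed point: arms already in range stay at the nominal 20 nt
  if (a$hl_end - a$hl_start + 1L == 20L) {
    tm20 <- melting_temperature(revcomp(substring(tx, a$hl_start, a$hl_end)))
    expect_true(tm20 >= 45 && tm20 <= 65)
  }
})

test_that("an AT-rich flank is extended and agrees with a length-scan oracle", {
  ## AT-rich left flank around an AG junction forces extension of HL
  ## (this fixture's nominal 20-nt arm melts at ~42.8 C)
  set.seed(3)
  left <- paste(sample(c("A", "A", "T", "T", "G", "C"), 60, replace = TRUE),
                collapse = "")
  right <- "CGCAGCGTCCAGTTACGGATCCGTAAGCTGACGCATGCTA"
  tx <- paste0(left, "AG", right)
  site <- list(junction_pos = 61L)
  tm_at <- function(L) melting_temperature(
    revcomp(substring(tx, 61L - L + 1L, 61L)))
  expect_lt(tm_at(20L), 45)
  a <- adjust_arm_lengths(site, tx)
  expect_true(a$ok)
  expect_gt(a$hl_end - a$hl_start + 1L, 20L)
  expect_true(a$hl_tm >= 45 && a$hl_tm <= 65)
  ## oracle: the first length at or beyond 20 whose Tm enters the window
  lens <- 20:30
  first_ok <- lens[which(sapply(lens, tm_at) >= 45)[1]]
  expect_equal(a$hl_end - a$hl_start + 1L, first_ok)
})

test_that("arms that cannot reach the window are flagged, not emitted", {
  ## GC-only arms exceed a 45-55 C window even at the 12-nt floor
  gc <- paste(rep("GC", 60), collapse = "")
  a <- adjust_arm_lengths(list(junction_pos = 60L), gc,
                          tm_range = c(45, 55))
  expect_false(a$ok)
  expect_match(a$reason, "cannot reach Tm")
  ## TA-repeat arms stay below 45 C even at the 30-nt ceiling
  ta <- paste(rep("TA", 60), collapse = "")
  b <- adjust_arm_lengths(list(junction_pos = 61L), ta)
  expect_false(b$ok)
  expect_match(b$reason, "cannot reach Tm")
})

test_that("specificity screen agrees with naive substring search", {
  set.seed(99)
  syn <- gen_transcriptome(n_targets = 5, n_background = 20,
                           planted_collisions = 5, seed = 99)
  sites <- do.call(rbind, lapply(names(syn$targets), function(id) {
    find_detection_sites(syn$targets[[id]], max_sites = 10L,
                         transcript_id = id)
  }))
  expect_gte(nrow(sites), 50L)
  sites <- sites[1:50, ]
  verdicts <- logical(50)
  oracle <- logical(50)
  for (i in 1:50) {
    verdicts[i] <- specificity_screen(sites[i, ], syn$background)$pass
    oracle[i] <- !oracle_screen_fails(sites[i, ]$sequence, syn$background, 10L)
  }
  expect_equal(verdicts, oracle)
  ## the planted collisions are among the failing sites
  planted <- paste(syn$manifest$target_id, syn$manifest$site_start)
  screened <- paste(sites$transcript_id, sites$start)
  expect_true(all(!verdicts[screened %in% planted]))
})

test_that("screen edge cases: empty background, planted positive, bad k", {
  tx <- rand_dna(500, seed = 1)
  site <- find_detection_sites(tx, max_sites = 1L)[1, ]
  expect_true(specificity_screen(site, character())$pass)
  planted <- setNames(paste0(rand_dna(100, 2),
                             substr(site$sequence, 10, 19),
                             rand_dna(100, 3)), "decoy")
  res <- specificity_screen(site, planted)
  expect_false(res$pass)
  expect_match(res$reason, "decoy")
  expect_error(specificity_screen(site, planted, k = 3), "at least 4")
  ## the target's own isoforms are exempt
  self_bg <- setNames(tx, site$transcript_id)
  expect_true(specificity_screen(site, self_bg,
                                 exempt_ids = site$transcript_id)$pass)
})

test_that("self-complementarity equals the longest-common-substring oracle", {
  expect_equal(self_complementarity("AAAAAA"), 0L)
  expect_equal(self_complementarity("GAATTC"), 6L)
  for (i in 1:15) {
    s <- rand_dna(60, seed = 400 + i)
    expect_equal(self_complementarity(s),
                 oracle_lcs(s, revcomp(s)))
  }
})

test_that("H-pair assembly reconstructs the detection site exactly", {
  tx <- rand_dna(2000, seed = 42)
  sites <- find_detection_sites(tx, max_sites = 3L)
  tpl <- design_templates()
  for (i in seq_len(nrow(sites))) {
    hp <- assemble_h_pair(sites[i, ], tx, template_id = 2L, templates = tpl)
    reconstructed <- paste0(revcomp(hp$hl_binding), revcomp(hp$hr_binding))
    expect_equal(reconstructed, substring(tx, hp$hl_start, hp$hr_end))
    ## junction legality on the arm footprint
    expect_true(substring(tx, hp$hl_end, hp$hl_end + 1L) %in% c("AG", "TA"))
    ## full oligos carry the overhangs on the correct ends
    expect_equal(hp$hl_full, paste0(tpl$l_overhang[2], hp$hl_binding))
    expect_equal(hp$hr_full, paste0(hp$hr_binding, tpl$r_overhang[2]))
    ## involution
    expect_equal(revcomp(revcomp(hp$hl_binding)), hp$hl_binding)
  }
  ## two sites of one target share one template's overhangs
  hp1 <- assemble_h_pair(sites[1, ], tx, 3L, templates = tpl)
  hp2 <- assemble_h_pair(sites[2, ], tx, 3L, templates = tpl)
  expect_equal(hp1$hl_overhang, hp2$hl_overhang)
  expect_equal(hp1$hr_overhang, hp2$hr_overhang)
  expect_error(assemble_h_pair(sites[1, ], tx, 99L), "unknown template")
})

test_that("barcode sets satisfy the circle/bridge/imager construction identities", {
  tpl <- design_templates()
  for (tid in c(1L, 5L, 8L)) {
    bc <- assemble_barcode_set("tgt", tid,
                               modes = c("standard", "erasable_dU",
                                         "rapid_short"),
                               templates = tpl, seed = tid)
    expect_equal(nchar(bc$bridge_seq), 31L)
    expect_true(abs(nchar(bc$circle_seq) - 60L) <= 2L)
    ## terminal 11-mers of the circle reverse-complement the cognate
    ## overhang segments
    l_ov <- tpl$l_overhang[tid]; r_ov <- tpl$r_overhang[tid]
    expect_equal(revcomp(substr(bc$circle_seq, 1, 11)),
                 substr(l_ov, 12, 22))
    n <- nchar(bc$circle_seq)
    expect_equal(revcomp(substr(bc$circle_seq, n - 10, n)),
                 substr(r_ov, 1, 11))
    ## barcode is embedded in the circle
    expect_true(grepl(bc$barcode_seq, bc$circle_seq, fixed = TRUE))
    ## every imager hybridizes to the simulated amplicon
    amp <- simulate_amplicon(bc$circle_seq)
    for (im in bc$imagers) {
      expect_true(imager_hybridizes(im$sequence, amp))
    }
  }
})

test_that("barcode orthogonality violations are rejected by name", {
  bc1 <- assemble_barcode_set("a", 1L, seed = 1)
  expect_error(
    assemble_barcode_set("b", 2L, barcode_seq = bc1$barcode_seq,
                         existing_barcodes = bc1$barcode_seq),
    "orthogonality")
})

test_that("imager modes follow their length and chemistry rules", {
  bc <- "ACGCATGCACGATCGATCGA"
  std <- make_imager(bc, "standard")
  du <- make_imager(bc, "erasable_dU")
  rs <- make_imager(bc, "rapid_short")
  expect_true(std$length >= 15 && std$length <= 20)
  expect_true(du$length >= 15 && du$length <= 20)
  expect_true(rs$length %in% c(10L, 11L))
  ## dU substitution preserves length; U count equals the standard T count
  expect_equal(du$length, std$length)
  count <- function(s, ch) lengths(regmatches(s, gregexpr(ch, s)))
  expect_equal(count(du$sequence, "U"), count(std$sequence, "T"))
  expect_equal(count(du$sequence, "T"), 0L)
  ## a T-free barcode makes erasable_dU identical to standard
  noT <- "ACGCAGGCACGACCGACCGA"
  expect_equal(make_imager(noT, "erasable_dU")$sequence,
               make_imager(noT, "standard")$sequence)
  expect_error(make_imager("ACGTACGTA", "standard"), "too short")
})

test_that("panel concentrations follow the pro-rating rule", {
  ## a long AT/GC-balanced transcript yields 10 usable sites
  tx <- rand_dna(6000, seed = 77)
  panel <- design_panel(setNames(tx, "big"), sites_per_target = 10L,
                        seed = 3)
  tg <- panel$targets[["big"]]
  n_pairs <- length(tg$pairs)
  sheet <- panel$order_sheet
  h <- sheet[sheet$type %in% c("HL", "HR"), ]
  if (n_pairs > 5) {
    expect_equal(unique(h$concentration_nM), 500 / n_pairs)
    expect_equal(sum(h$concentration_nM), 1000)
  } else {
    expect_equal(unique(h$concentration_nM), 100)
    expect_lte(sum(h$concentration_nM), 1000)
  }
  ## ten pairs exactly -> 50 nM each
  if (n_pairs == 10) expect_equal(unique(h$concentration_nM), 50)
})

test_that("targets are assigned unique (cycle, channel) slots round-robin", {
  set.seed(123)
  txs <- setNames(sapply(1:8, function(i) rand_dna(1200, 500 + i)),
                  paste0("g", 1:8))
  panel <- design_panel(txs, sites_per_target = 2L,
                        fluor_palette = c("f1", "f2", "f3", "f4"),
                        n_cycles = 2L, seed = 4)
  slots <- sapply(panel$targets, function(t) paste(t$cycle, t$fluor))
  expect_equal(length(unique(slots)), length(panel$targets))
  expect_true(all(sapply(panel$targets, function(t) t$cycle) %in% 1:2))
  expect_error(design_panel(txs, fluor_palette = c("f1", "f2"),
                            n_cycles = 1L),
               "exceed")
})

test_that("a minimal one-site panel contains the full oligo complement", {
  tx <- rand_dna(900, seed = 31)
  panel <- design_panel(setNames(tx, "solo"), sites_per_target = 1L,
                        seed = 5)
  sheet <- panel$order_sheet
  expect_equal(sum(sheet$type == "HL"), 1L)
  expect_equal(sum(sheet$type == "HR"), 1L)
  expect_equal(sum(sheet$type == "bridge"), 1L)
  expect_equal(sum(sheet$type == "circle"), 1L)
  expect_gte(sum(sheet$type == "imager"), 1L)
})

test_that("hopeless targets land in failures while the panel is still emitted", {
  good <- rand_dna(1000, seed = 61)
  bad <- paste(rep("A", 500), collapse = "")
  panel <- design_panel(c(ok = good, polyA = bad), seed = 6)
  expect_true("ok" %in% names(panel$targets))
  expect_false("polyA" %in% names(panel$targets))
  expect_true("polyA" %in% panel$failures$target_id)
  expect_gte(nrow(panel$order_sheet), 4L)
})

test_that("every emitted binding arm satisfies the 45-65 C Tm window", {
  set.seed(8)
  txs <- setNames(sapply(1:3, function(i) rand_dna(2000, 600 + i)),
                  paste0("t", 1:3))
  panel <- design_panel(txs, sites_per_target = 5L, seed = 8)
  for (tg in panel$targets) {
    for (p in tg$pairs) {
      expect_true(p$hl_tm >= 45 && p$hl_tm <= 65)
      expect_true(p$hr_tm >= 45 && p$hr_tm <= 65)
    }
  }
})

test_that("identical inputs and seed give a byte-identical order sheet", {
  txs <- setNames(c(rand_dna(1200, 71), rand_dna(1200, 72)), c("a", "b"))
  bg <- setNames(c(rand_dna(2000, 73)), "bg1")
  p1 <- design_panel(txs, bg, seed = 10)
  p2 <- design_panel(txs, bg, seed = 10)
  f1 <- tempfile(); f2 <- tempfile()
  write_order_sheet(p1, f1)
  write_order_sheet(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## manifest records the design parameters
  mf <- tempfile()
  write_panel_manifest(p1, mf)
  expect_true(any(grepl("seed\t10", readLines(mf))))
})
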