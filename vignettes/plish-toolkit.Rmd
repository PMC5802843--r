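---
title: "Methods: probe design and image analysis for proximity ligation in situ hybridization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design and image analysis for proximity ligation in situ hybridization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plishr)
```

## The assay this package models

Proximity ligation in situ hybridization (PLISH) detects single RNA
molecules in tissue. Two DNA "H" probes (HL, HR) hybridize to adjacent
halves of a ~40-nt detection site on the target transcript and abut at a
5'-AG-3' or 5'-TA-3' dinucleotide. Bridge and circle oligonucleotides
hybridize across the probes' single-stranded overhangs; ligation closes
the circle, and rolling-circle amplification (RCA) copies it into a long
tandem repeat that binds many fluorophore-carrying imager
oligonucleotides, producing a bright punctum. Because the barcode read out
by the imager lives in the circle, many probe pairs tiled along one
transcript can share a single readout channel, and imagers can be removed
(label-image-erase cycles) to multiplex beyond the five or so spectrally
separable fluorophores.

`plishr` implements the dry-lab side of this assay: panel design, the
quantitative detection models, the image-to-expression-table pipeline,
unsupervised cell classification with spatial remapping, and a synthetic
data layer that makes the whole loop testable without any microscope.

## Probe design

`find_detection_sites()` enumerates candidate windows (default 40 nt,
1-based inclusive coordinates) whose central dinucleotide is AG or TA.
Two conventions were genuinely open and are now fixed in one place each:

* **Junction split.** The 5' half ends with the *first* base of the
  junction dinucleotide (`...A | G...`, `...T | A...`). Published
  interval arithmetic is consistent with either side; this choice is
  isolated in the window enumeration so the complementary convention is a
  one-line change.
* **Site overlap.** Sites never overlap. Overlapping sites would compete
  for the same RNA footprint, so non-overlap is enforced and tiling is
  deterministic: a leftmost-first non-overlapping packing, thinned toward
  evenly spaced anchors when more sites survive than requested.

`melting_temperature()` is a two-state nearest-neighbor calculation with
the unified DNA/DNA parameter table and an entropic salt correction
(`0.368·(n−1)·ln[Na+]`), evaluated at 0.25 µM oligo and 50 mM monovalent
salt — the defaults of the oligo-analysis tool this emulates. DNA:RNA
hybrid parameters are deliberately **not** used: the design convention
being reproduced evaluated DNA/DNA duplexes, and consistency with that
tool matters more here than hybrid accuracy. Binding arms start at 20 nt
and are extended or trimmed one base at a time at the distal end until
the arm's Tm enters the 45–65 °C window; lengths are constrained to
12–30 nt, keeping the site near its nominal 40 nt. An arm that cannot
reach the window flags the site as unusable rather than emitting an
out-of-specification oligo.

`specificity_screen()` fails a site if any 10 contiguous nucleotides
(configurable, `k >= 4`) occur exactly in a non-target transcript. The
implementation is a k-mer dictionary match (`Biostrings::PDict`) over the
sense strand of the background — probes hybridize to RNA, so the
antisense strand is irrelevant, though a flag adds it for parity with
BLAST-style screens. The test suite holds the screen to exact agreement
with naive substring search. `self_complementarity()` scores the longest
common substring between a sequence and its reverse complement; panels
reject sites scoring above 6 by default (the source procedure says only
"minimize", so the threshold is configurable).

Overhangs, circles, bridges and imagers are assembled from eight modular
design templates. Laboratories typically hold template sequences as
in-house tables, so the shipped table is generated
from a fixed internal seed under explicit orthogonality rules (GC 40–60%,
homopolymers ≤ 3, no shared or cross-complementary 8-mers); a
laboratory's own table loads via `design_templates(file =)`. Geometry per
template: each 22-nt overhang has an 11-nt bridge-facing and an 11-nt
circle-facing segment; the circle (60 nt) carries reverse complements of
the two circle-facing segments at its termini around a 20-nt barcode, and
the bridge (31 nt) carries reverse complements of the two bridge-facing
segments around a 9-nt spacer. The imager must hybridize to the RCA
amplicon — the tandem reverse complement of the circle — which forces the
imager sequence to be a substring of the circle's barcode; this
operational contract is what `simulate_amplicon()`/`imager_hybridizes()`
verify for every emitted set. Imager modes: `standard` (15–20 nt),
`erasable_dU` (every dT replaced by dU so a uracil-DNA-glycosylase
cocktail erases the signal between cycles), `rapid_short` (10–11 nt,
removed by a warm wash).

Working concentrations follow the bench rule: 100 nM per H probe, and
when a target carries more than five probe pairs, `500/n_pairs` nM each so
the per-target total is exactly 1000 nM.

## Detection models

**Calibration.** Under Poisson sampling, a gene at FPKM `f` has `c·f`
copies per cell and is seen in a fraction `1 − exp(−c·f)` of cells. The
reference benchmark value is `c = 2.5` copies/cell/FPKM, which predicts
5 copies per cell at FPKM 2 and detection in ~92% of cells at FPKM 1.
`fit_copies_per_fpkm()` estimates `c` from fraction-positive data by
binomial maximum likelihood (the source analysis says only "fit"; the
binomial likelihood is this package's choice, with least squares on the
fractions available as `method = "ls"` for comparison). The estimate is a
bounded scalar optimization, deterministic given the data; saturated data
(all fractions 0 or 1) are rejected as non-identifiable.

**Efficiency.** With `k` independent probe sites of per-site efficiency
`p`, composite efficiency is `E = 1 − (1−p)^k`; `per_site_efficiency()`
inverts it. The 32%-over-4-sites reference point gives `p = 0.0919`,
reported as 9% under half-up whole-percent rounding
(`percent_round()`), matching how such efficiencies are quoted. The
inversion is exact to numerical precision wherever `1 − E` is
representable; for `(1−p)^k` below ~1e−15 double precision, not algebra,
limits accuracy.

**Puncta intensity.** RCA terminates stochastically and irreversibly, so
punctum intensities are modeled as negative binomial, parameterized by
(mean µ, dispersion r) with variance `µ + µ²/r`, giving
`cv² = 1/µ + 1/r` — a parameterization chosen because the dispersion maps
directly onto the coefficient of variation, the quantity of interest
(typically between 1 and 2 for RCA puncta). Fitting uses a
method-of-moments start refined by maximum likelihood with the mean fixed
at the sample mean and a bounded search on `log r` (tolerance 1e−6);
continuous intensities are binned by rounding. Constant data return
`cv = 0` with the dispersion flagged undefined instead of failing.
`signal_to_background()` is the ratio of median punctum amplitude to
median background intensity.

## Image quantification

The pipeline mirrors a CellProfiler-style workflow on maximum-projected
z-stacks:

1. **Registration.** Later cycles are aligned to the first by
   integer-pixel phase correlation of the nuclear-stain channels; the
   recovered translation is applied to every channel of the cycle.
   Sub-pixel refinement is out of scope; the fiducial is a dense nuclear
   stain and stage drift between cycles is well approximated by whole
   pixels at these magnifications. A degenerate correlation (blank
   fiducial, peak below threshold) warns and keeps the identity offset.
2. **Nuclei.** Seeds are local maxima of the Gaussian-smoothed nuclear
   image (default sigma 1 µm) above an Otsu threshold — parameter-free
   where the source procedure says only "filtered" — separated by at
   least 4 µm (closer maxima merge into the brighter one; this is the
   documented suppression-radius semantics). Boundaries grow from the
   seeds by the Voronoi-style propagation algorithm
   (`EBImage::propagate`, the same algorithm CellProfiler uses for
   secondary objects) restricted to above-threshold pixels.
3. **Sampling areas.** Labels dilate by ~1 µm (`round(radius/pixel)` px)
   to cover the nuclear and peri-nuclear region where amplicons
   accumulate. Growth never overwrites a nucleus pixel; collisions
   resolve to the nearest label under the chessboard metric with ties to
   the smaller index — fully deterministic.
4. **Measurement.** Per cell and channel, the mean pixel intensity over
   the sampling area, plus centroid, area, perimeter and eccentricity of
   the nucleus. Intensities stay on the acquired scale; no background
   subtraction is applied by default. Pixel coordinates are 0-based
   (row, col); physical units enter only through `pixel_size_um`.

`export_boundary_index_image()` emits the zero-background image whose
nucleus-boundary pixels carry the cell index — the join key used to
remap classifications onto micrographs.

## Classification

Per gene, intensities are normalized by the largest value over all cells
and fields of view and scaled to 0:10, then transformed by
`log10(0.1 + x)`, mapping 0 to −1 and 10 to `log10(10.1) ≈ 1.004`. The
log base is 10 by necessity: no other base maps the 0:10 range onto the
stated −1:1 scale. Clustering is k-means in this log space (Euclidean, 50
restarts, fixed seed; `k` is always user-chosen — a silhouette-based
suggestion would be possible but is deliberately not applied silently),
with agglomerative clustering (average linkage, Euclidean; both
configurable) for dendrograms and t-SNE (perplexity 30) strictly for
visualization — embeddings never feed classification, and no spatial
information enters clustering. Whether the original analysis clustered
log-transformed or merely normalized data is stated only for its
hierarchical step; log space is used for both here, on the grounds that a
single feature space should feed every downstream view of the same data.
Marker rules label clusters afterwards; multi-marker (double-positive)
rules take precedence over single-marker rules, so a
Sftpc⁺Scgb1a1⁺ centroid becomes "BASC" rather than "AT2" or "Club", and
unmatched clusters are "other".

## The synthetic data layer

`gen_tissue_images()` renders what the quantification pipeline needs to
see, with full ground truth: Gaussian-blob nuclei placed by dart-throwing
with a minimum separation (default 18 px — placement is kept identifiable
on purpose; segmentation of heavily overlapping nuclei is a
different research problem), ten cell classes drawn from fixed proportions,
per-class per-gene Poisson puncta counts, NB-distributed punctum
amplitudes (mean 150, cv 1.5 — mid-range of the 1–2 regime), a low
autofluorescent background (level 2, more than 30-fold below the median
punctum amplitude by construction), and per-cycle planted integer
translation offsets (default cycle 2: +3 rows, −2 columns). The default
field is 600×600 px at 0.5 µm/px with 300 cells over 8 genes in 2 cycles
— sizes chosen so a full design–simulate–quantify–classify loop runs in
tens of seconds on one core while keeping ≥ 25 cells per class.

The ten class signatures are loosely patterned on mouse-lung cell types
(macrophage; Lyz2⁺ and Lyz2⁻ AT2; Actb-high and Actb-low Club; AT1; four
"other" classes defined by housekeeping-gene signatures). They are
fixture parameters, not claims about real lung. The signatures were
designed against a separability analysis — k-means on the *noiseless
planted counts* must itself resolve the classes, otherwise the fixture
would not be "molecularly distinct" independent of any imaging step — and
therefore use large (≥ 18-fold) rate gaps on splitting markers. The test
suite requires the measured full loop (render → register → segment →
measure → classify) to recover the planted classes at adjusted Rand
index ≥ 0.8 for every seed it runs.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real tissue: optical point-spread functions and
chromatic aberration, spectral bleed-through (the assay handles it by
vendor unmixing upstream), autofluorescent *structures* (the background
here is flat noise), nuclear shape variability and touching nuclei,
z-structure (projections are simulated directly), and any chemistry
kinetics of ligation, amplification or erasure.

`gen_transcriptome()` plants exact 10-mer collisions from chosen
detection sites into named background transcripts and, crucially, scrubs
*accidental* shared 10-mers first (deterministic single-base rotations
outside planted spans), so the collision manifest is exhaustive: exactly
the listed sites fail the screen. `gen_calibration_curve()` draws
binomial fraction-positive data under the Poisson model. All generators
are pure functions of their arguments and a seed.

## Numerical choices and degenerate inputs

* Tm requires ≥ 8 nt (two-state model breaks down shorter) and rejects
  ambiguous bases by position.
* The calibration MLE brackets `c` in `[1e−9, −log(1e−9)/min f]` and
  clamps probabilities to `[1e−12, 1−1e−12]` inside the likelihood.
* Phase correlation normalizes the cross-power spectrum, guarding zero
  magnitude; blank images short-circuit to the identity offset.
* Otsu runs on a 256-level histogram over the image's own range; a
  constant image yields its own value as threshold (nothing detected).
* k-means, t-SNE and all generators run under a temporarily swapped RNG
  state, so library calls never perturb a user's random stream.
* `percent_round()` rounds halves up (`floor(100p + 0.5)`), matching how
  the reference efficiencies are quoted.

## Known limitations

* The specificity screen is exact-match only (that is its definition
  here); it does not model near-matches that BLAST word-extension would
  find, nor RNA secondary structure occluding a site.
* Thermodynamics are DNA/DNA; probe–RNA duplex stability is systematically
  different, which matters if the 45–65 °C window is interpreted as a
  hybrid-duplex property.
* Registration is translation-only and integer-pixel.
* Segmentation assumes separated, roughly convex nuclei; the synthetic
  placement guarantees this, real tissue does not.
* The NB intensity fit fixes the mean at the sample mean; for heavily
  contaminated intensity lists a robust location estimate would be
  preferable.
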