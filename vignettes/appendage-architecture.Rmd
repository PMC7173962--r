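---
title: "Mapping centriolar appendage architecture from dSTORM localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping centriolar appendage architecture from dSTORM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrioleSTORM)
```

## The problem

The mother centriole carries two sets of appendages near its distal end:
nine distal appendages (DAPs — SCLT1, FBF1, CEP83, CEP89, CEP164), which
dock the ciliary membrane, and a variable number of subdistal appendages
(sDAPs — ODF2, CEP128, centriolin, ninein, CEP170), which anchor
microtubules. Two-colour dSTORM resolves this architecture at ~20 nm:
axial views show each protein as a ring whose diameter places it radially,
and lateral views show each protein as one or two thin layers whose signed
position along the centriole axis (relative to the SCLT1 DAP layer) places
it longitudinally. This package implements the quantitative pipeline for
such data — drift and chromatic pre-corrections, ring and layer
estimators, composite averaging, fiber counting, and group statistics —
together with a synthetic localization generator that encodes the measured
geometry, so that every estimator is validated by parameter recovery.

## Data model

A localization table is one row per detected single-fluorophore emission:
0-based `frame`, `channel` (protein label), `x`/`y` in nm, photon count
and optional per-localization uncertainty. CSV files use a
ThunderSTORM-style header. Coordinates are continuous nanometres with an
arbitrary origin; only rendering uses pixels.

## The synthetic generator

`build_model_from_paper()` returns a `ground_truth_model` whose layer
table encodes the measured architecture:

* ring radii — ODF2 at 100 nm (the ~200 nm centriole wall), CEP128 at
  125 nm, centriolin at 140 nm, ninein/CEP170 at 300 nm (the ~600 nm
  sDAP-tip ring), SCLT1 at 225 nm, γ-tubulin as a 200 nm-radius cylinder
  (~400 nm across);
* longitudinal positions relative to SCLT1 (proximal negative) — CEP128
  at −160 nm, dual ODF2 layers at −100 and −200 nm, ninein/CEP170 split
  between the sDAP region (−150 nm) and the proximal end (−500 nm,
  ~350 nm apart), dual CEP89 layers at +30 and −120 nm, CP110 at +80 nm
  as the distal orientation marker;
* knockout presets — `CEP128_KO` keeps a single thinned ODF2 layer
  shifted proximally (−120 nm), drops the proximal CEP89 layer and
  releases γ-tubulin distally; `CEP83_KO` keeps a single ODF2 layer
  (−200 nm) and broadens ninein towards the distal end;
* occupancy presets — `FBS_plus` and `FBS_minus` model the CEP128 ring
  with 50% and 25% of its angular occupancy missing as one contiguous
  arc;
* fiber presets — `fibers_WT` anchors nine α-tubulin fibers at the sDAP
  tips plus four at the DAP level; `fibers_KO` keeps only the DAP subset.

Simulation follows the acquisition physics at the localization level:
emitters are placed on each layer's locus, thinned by labelling
efficiency (default 0.8) and occupancy gaps, and each labelled emitter
produces a geometric number of localizations (mean 5, support ≥ 1 — a
one-parameter stand-in for fluorophore blinking). Each localization is
jittered by an isotropic Gaussian of sd 8.5 nm — a 20 nm FWHM resolution
divided by 2.355 — and assigned a uniformly random frame among the 10,000
acquisition frames. Stage drift (`none`, `linear`, `random_walk`) is
added per frame; the short-wavelength channel is passed through a full
second-order 2D polynomial chromatic distortion; uniform background
(2 µm⁻² per channel) and per-frame fiducial localizations complete the
table. Every stochastic entry point takes an explicit seed and identical
inputs give byte-identical outputs.

Two projection rules matter:

* **Axial views image a focal slab.** 2D dSTORM has a finite depth of
  focus, and axial acquisitions are focused at the appendage level, so
  only layers within `focal_center ± focal_depth/2` (defaults −100 and
  500 nm) appear. Without this, the proximal-end ninein/CEP170
  population — 500 nm out of focus in a real acquisition — would
  contaminate the sDAP ring diameter.
* **Lateral views are orthographic.** A ring seen edge-on projects to
  transverse positions `r·cos(azimuth)`, giving the natural edge-density
  maxima at ±r; fibers are projected with their apparent length scaled
  by the cosine of their azimuth.

What the generator does *not* emulate: detector pixelation and PSF
fitting (we start from localizations), dye photophysics beyond the
geometric blinking law, axial (z) drift, tilted centrioles between the
two canonical views, and biological cell-to-cell variability beyond the
per-layer spreads. Passing tests therefore demonstrate estimator
correctness under the encoded geometry and noise, not robustness to every
artefact of real acquisitions.

## Corrections

Drift is measured from fiducial beads, which are present in essentially
every frame while structural emitters blink only briefly.
`detect_fiducials()` finds persistently occupied regions on a coarse
grid (cell 200 nm, persistence ≥ 50% of frames), attaches neighbouring
localizations so per-frame means are unbiased at cell borders, and
rejects stray structural/background localizations against a rolling
median of the track. `estimate_drift()` averages the per-frame
displacements over tracks and smooths them with a local linear
(Savitzky–Golay order-1) filter over a 100-frame window — unbiased for
linear drift even at the sequence boundaries, unlike a plain moving
average. `apply_drift()` is exactly invertible. Corrections operate at
the localization level rather than on rendered images; this is
equivalent in the noiseless limit and avoids pixel quantization.
`remove_fiducials()` excises the marker localizations before structural
analysis and must be called while the tracks and the table are in the
same correction state.

Chromatic registration fits each long-wavelength axis as a full
second-order polynomial of the short-wavelength coordinates (the
"parabolic mapping" calibrated on multicolour beads): 6 coefficients per
axis, identifiable from ≥ 6 beads, with leave-one-out residuals reported
from 10 beads up. Fitting the *correction* direction inverts the
generative warp only approximately (the inverse of a quadratic is not a
quadratic), which contributes ≪ 1 nm over a 20 µm field at realistic
distortion magnitudes; fitting the forward direction recovers generative
coefficients to machine precision.

## Axial ring analysis

A *punctum* is operationalized as a density-based (DBSCAN) cluster:
radius 20 nm, minimum 5 localizations, with non-core points attached and
unclustered localizations discarded as background. The ring centre is an
algebraic Kåsa circle fit refined by one geometric Gauss–Newton step;
for raw localization input the fit is re-run after discarding radial
outliers beyond 3 sd, which protects the algebraic fit from high-leverage
background. Per-punctum radii are distances to the centre and the mean
diameter is twice the mean radius — the plain definition, with no noise
bias correction by default (the outward bias is `sd²/r` ≈ 0.9 nm for an
ODF2-sized ring; an optional correction flag exists).

Angular occupancy unwraps an annulus (fitted radius ± 3 radial sd) to
polar angle, bins at 10° and marks a bin occupied when its count reaches
`max(3, 10% of the median nonzero-bin count)`. Completeness is the
occupied-bin fraction; contiguous unoccupied runs are reported as gap
arcs. Bin quantization and the smearing of localizations across gap
edges bias the measured missing fraction downward by roughly one bin per
gap edge (~3 percentage points at the preset densities); occupancy
presets therefore use one contiguous gap arc — matching the large
contiguous missing arcs seen in the images — and a ring density at which
a fully occupied ring reads ≥ 97% complete.

Nine-fold symmetry is scored on punctum angles as the mode-9 power ratio
`|Σ exp(i·9θ)|²/n²`: 1 for perfect placement, expectation 1/n for random
angles, and attenuation `ρ² + (1−ρ²)/9` with `ρ = exp(−(9σ)²/2)` for
Gaussian angular jitter σ. Two physical regimes matter: the DAP ring
(SCLT1, radius 225 nm, jitter 3°) has well-separated blades and supports
exact counting of nine puncta, while sDAP blades at 100–125 nm radius
with 5° jitter can physically collide (adjacent blade centres fall
within the clustering radius), so merged counts below nine there reflect
geometry, not estimator failure. The count-nine acceptance check
therefore runs on the complete nine-fold DAP reference ring.

## Lateral longitudinal analysis

The SCLT1 reference appears as a rod transverse to the centriole; the
axis is the perpendicular to the rod's first principal axis through its
centroid, with the distal sign fixed by a marker channel (CP110 when
present) or an explicit flag — without either the sign is refused as
unidentifiable. View classification uses the covariance eigenvalue
ratio (axial < 2, lateral ≥ 3, else ambiguous) after Mahalanobis
trimming of far-field background. In the CEP83 knockout, which lacks
SCLT1, CP110 serves as the reference with ninein as the proximal-side
marker; positions are then in the CP110 frame, which preserves all
within-genotype comparisons and directions.

Longitudinal profiles are 10 nm histograms of axis projections
(mass-conserving). `detect_layers()` smooths with a Gaussian kernel
(sd = the 8.5 nm localization precision), finds local maxima, and accepts
peaks in decreasing height order subject to topographic prominence
≥ 20% of the maximum and separation ≥ 50 nm. Height-fraction prominence
was rejected during development because shoulder bumps on broad layers
pass a height test but fail a valley test; topographic prominence is
what the rule names. Layer position is the density centroid of the
± FWHM window (robust to binning), width the FWHM. Two-Gaussian mixtures
separate into two detected layers exactly when the exact smoothed
mixture density is bimodal under the same rules — verified against a
closed-form oracle over a separation × width sweep; separations below
~2 effective sd, or peaks closer than 50 nm, merge by design.

Composites translate each centriole's reference centroid to the origin,
rotate the axis to +y and sum 10 nm-pixel histograms per channel;
accumulation is order-independent, and a composite of m copies of one
centriole is exactly m times its histogram. Reflection alignment is not
applied. The distal boundary statistic is the signed position below
which 95% of localizations lie, computed on the binned density with
within-bin interpolation — it makes "spreads towards the distal end"
testable (γ-tubulin under CEP128 loss, ninein under CEP83 loss).

## Fibers

Fibers are detected as elongated density clusters: single-linkage
grouping with a 50 nm gap-bridging radius, then a principal-axis gate
(elongation ≥ 4:1, span ≥ 300 nm, support ≥ 30); the segment is the
principal-axis span and its *anchor* is the endpoint nearer the centriole
centre or axis. Counts are reported per radian of surveyed angle for
anchors inside an annulus (axial view) and per longitudinal bin of the
anchor position (lateral view). Anchors sit at the appendage positions:
nine-fold for the sDAP subset (radius 320 nm, −150 nm) and on the
between-blade grid for the DAP subset (radius 200 nm, −20 nm), with
near-radial directions. Crossing or overlapping projected fibers can
merge into one cluster (an X-shaped merge fails the elongation gate; a
collinear merge counts once at the inner anchor), so per-radian rates
slightly undercount dense fields; the wild-type versus knockout contrast
is unaffected because knockout anchors vanish from the sDAP annulus
entirely.

## Statistics

All two-group readouts use a two-sided Mann–Whitney U test — exact when
group sizes permit and ties are absent, tie-corrected normal
approximation otherwise — with the rank-biserial correlation as effect
size; it matches brute-force permutation enumeration for n ≤ 8 per
group. The test is nonparametric because the readouts (per-centriole
radius sd, fiber rates, boundary positions) have no reason to be
Gaussian at n = 5–10; a Welch t-test is available behind a flag. No
multiple-testing correction is applied: comparisons are reported one at
a time, as in the figures they reproduce.

## Problem sizes and determinism

The validation suite simulates 10 centrioles per condition for geometry
recoveries, 8 + 8 for the corrected-versus-clean comparison, 40 paired
simulations for the γ-tubulin boundary direction, and 15 replicate
5 + 5 experiments for fiber-rate power; these sizes give Monte-Carlo
standard errors comfortably inside the stated tolerances while keeping
the full suite to a few minutes. All randomness flows from explicit
seeds; there is no hidden global state, and the end-to-end pipeline
(`run_pipeline()`) regenerates byte-identical JSON reports from a config
and seed.

## Known limitations

* Ring diameters carry the `sd²/r` outward noise bias (sub-nm here) and,
  at punctum level, a small inward chord bias when blades merge.
* The occupancy readout is quantized to 10° bins; missing fractions are
  biased low by ~2–4 percentage points per gap via edge bins and
  localization smear.
* Counting overlapping fibers in projection undercounts dense fields.
* The axis estimate assumes an untilted lateral view; tilted centrioles
  would compress longitudinal distances by the cosine of the tilt.
* Knockout presets encode the reported phenotypes as geometry; they are
  a validation target for the estimators, not a biological model of the
  knockouts.
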