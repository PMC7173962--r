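# centrioleSTORM

Quantitative analysis of two-colour dSTORM single-molecule localization
data from mother-centriole appendages, plus a synthetic-data generator
that validates every estimator by parameter recovery.

The mother centriole carries nine distal appendages (DAPs; SCLT1, CEP83,
CEP89, ...) and a variable set of subdistal appendages (sDAPs; ODF2,
CEP128, centriolin, ninein, CEP170) that anchor microtubules. At ~20 nm
dSTORM resolution each protein appears, in an axial view, as a ring of
characteristic diameter and, in a lateral view, as one or two thin layers
at a signed position along the centriole axis (SCLT1 layer = 0, distal
positive). The package implements the full measurement chain:

* **Corrections** — fiducial-based lateral drift correction
  (`detect_fiducials`, `estimate_drift`, `apply_drift`) and bead-calibrated
  second-order ("parabolic") chromatic registration of the short- onto the
  long-wavelength channel (`fit_chromatic_map`, `apply_chromatic_map`).
* **Axial ring analysis** — density-based puncta (`cluster_puncta`), Kåsa +
  Gauss–Newton circle fit (`fit_ring_center`), mean diameter
  `D = 2·mean(rᵢ)` over per-punctum radii `rᵢ = |pᵢ − c|`
  (`measure_diameter`), polar angular occupancy/completeness with gap arcs
  (`angular_occupancy`), and the nine-fold symmetry score
  `|Σⱼ exp(i·9θⱼ)|²/n²` (`symmetry_score`).
* **Lateral analysis** — view classification and axis estimation from the
  SCLT1 rod (`classify_view`, `estimate_axis`), mass-conserving
  longitudinal profiles and prominence-gated layer detection
  (`longitudinal_profile`, `detect_layers`), composite averaging across
  aligned centrioles (`align_and_composite`), ROI densities and the
  0.95-quantile distal boundary (`roi_density`, `distal_boundary`).
* **Fibers** — elongated-cluster detection of α-tubulin fibers and counts
  per radian / per longitudinal bin of the anchor position
  (`detect_fiber_segments`, `count_per_radian`,
  `count_per_longitudinal_bin`).
* **Statistics** — two-sided Mann–Whitney U with rank-biserial effect size
  (`compare_groups`).
* **Synthetic data** — `build_model_from_paper()` presets (`wild_type`,
  `CEP128_KO`, `CEP83_KO`, `FBS_plus`, `FBS_minus`, `gamma_tubulin`,
  `fibers_WT`, `fibers_KO`) encoding the measured geometry, simulated at
  the localization level with blinking, 8.5 nm precision, drift, chromatic
  warp, background and fiducials (`simulate_centriole`,
  `simulate_bead_field`, `simulate_fibers`); deterministic given a seed.

The methods vignette (`vignettes/appendage-architecture.Rmd`) documents the
model, the estimators, the numerical choices and the known limitations.
The numbered scripts under `analysis/` are thin drivers that run the
package over the presets and write tables under `results/`.

## Worked example

```r
library(centrioleSTORM)

model <- build_model_from_paper("wild_type")      # axial view
sim   <- simulate_centriole(model, seed = 2)
odf2  <- sim$table[sim$table$channel == "ODF2", ]
ring  <- analyze_ring(odf2)
round(ring$ring$mean_diameter, 1)
#> [1] 199.2
nrow(ring$puncta)
#> [1] 8

lat <- simulate_centriole(build_model_from_paper("wild_type",
                                                 view = "lateral"),
                          seed = 2)$table
ax  <- estimate_axis(lat[lat$channel == "SCLT1", ],
                     lat[lat$channel == "CP110", ])
prof <- detect_layers(longitudinal_profile(lat[lat$channel == "CEP128", ],
                                           ax))
round(prof$layers$position, 1)
#> [1] -160.2
```

The ODF2 ring measures ~200 nm across — the centriole wall — and the
CEP128 layer sits ~160 nm proximal to the SCLT1 reference, as encoded in
the wild-type preset. (Eight rather than nine ODF2 puncta is expected:
at a 100 nm radius two adjacent nine-fold blades occasionally merge under
the 20 nm clustering radius.)

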