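#!/usr/bin/env Rscript
# Demonstrate the pre-analysis corrections on a corrupted acquisition:
# linear stage drift measured from three fiducial beads, and a quadratic
# chromatic warp of the short-wavelength channel calibrated from a
# simulated two-colour bead field. Writes summary tables to results/.

suppressMessages(library(centrioleSTORM))
dir.create("results", showWarnings = FALSE)
seed0 <- 20260902L

model <- build_model_from_paper("wild_type")
model$drift <- drift_spec("linear", 0.05)              # ~500 nm over 10k frames
model$fiducials <- rbind(c(-800, -800), c(800, -700), c(-700, 800))
model$chromatic <- chromatic_spec(c(15, 1.002, 1e-5, 3e-7, -1e-7, 2e-7),
                                  c(-12, -1e-5, 0.998, 1e-7, 2e-7, -3e-7))

sim <- simulate_centriole(model, seed = seed0,
                          channels = c("SCLT1", "CEP128"))
tab <- sim$table

tracks <- detect_fiducials(tab)
traj <- estimate_drift(tracks, n_frames = model$n_frames)
structural <- remove_fiducials(tab, tracks)   # markers out, drift still in
clean <- apply_drift(structural, traj)
true_end <- sim$truth$drift[model$n_frames, ]
cat(sprintf("drift endpoint: estimated (%.1f, %.1f) nm, true (%.1f, %.1f) nm\n",
            traj$dx[model$n_frames], traj$dy[model$n_frames],
            true_end[1], true_end[2]))

beads <- simulate_bead_field(50, model$chromatic, noise_sd = 2,
                             seed = seed0 + 1L)
cmap <- fit_chromatic_map(beads$short, beads$long)
cat(sprintf("chromatic map: in-sample RMS %.2f nm, leave-one-out %.2f nm\n",
            cmap$rms, cmap$loo_rms))
registered <- apply_chromatic_map(clean, cmap, channel = "SCLT1")

ring_raw <- analyze_ring(structural[structural$channel == "CEP128", ])
ring_cor <- analyze_ring(registered[registered$channel == "CEP128", ])
summary <- data.frame(
  stage = c("uncorrected", "corrected"),
  cep128_diameter_nm = c(ring_raw$ring$mean_diameter,
                         ring_cor$ring$mean_diameter),
  cep128_radius_sd_nm = c(ring_raw$ring$radius_sd, ring_cor$ring$radius_sd))
print(summary)
write.csv(summary, "results/02_correction_summary.csv", row.names = FALSE)
write.csv(traj, "results/02_drift_trajectory.csv", row.names = FALSE)
cat("drift smears the uncorrected ring; the corrected diameter matches the",
    "drift-free geometry\n")
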