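# drift correction and chromatic registration

fiducial_model <- function(drift = drift_spec("none"), n_frames = 2000L,
                           localization_sd = 8.5,
                           fiducials = rbind(c(-900, -900), c(900, -800),
                                             c(-800, 900))) {
  m <- make_ring_model(radius = 150, radial_sd = 10, n_emitters = 150L,
                       localization_sd = localization_sd)
  m$n_frames <- as.integer(n_frames)
  m$drift <- drift
  m$fiducials <- fiducials
  m
}

test_that("fiducial tracks are recovered at their injected sites", {
  m <- fiducial_model()
  sim <- simulate_centriole(m, seed = 21)
  tracks <- detect_fiducials(sim$table)
  expect_length(tracks, 3L)
  sites <- t(vapply(tracks, function(tr) attr(tr, "site"), numeric(2)))
  sites <- sites[order(sites[, 1L]), ]
  truth <- m$fiducials[order(m$fiducials[, 1L]), ]
  # standard error bound: localization_sd / sqrt(n_frames)
  expect_lt(max(abs(sites - truth)), 3 * 8.5 / sqrt(2000) + 0.5)
})

test_that("a table with only blinking structure has no persistent cluster", {
  m <- make_ring_model(radius = 150, n_emitters = 100L)
  m$n_frames <- 10000L
  sim <- simulate_centriole(m, seed = 22)
  expect_error(detect_fiducials(sim$table), "persistent")
})

test_that("a noiseless fiducial track reproduces the injected random walk", {
  m <- fiducial_model(drift = drift_spec("random_walk", 2),
                      n_frames = 500L, localization_sd = 0,
                      fiducials = rbind(c(-900, -900)))
  sim <- simulate_centriole(m, seed = 23)
  tracks <- detect_fiducials(sim$table)
  traj <- estimate_drift(tracks, n_frames = 500L, window = 1L)
  expect_equal(traj$dx, sim$truth$drift[, 1L], tolerance = 1e-9)
  expect_equal(traj$dy, sim$truth$drift[, 2L], tolerance = 1e-9)
  expect_equal(c(traj$dx[1L], traj$dy[1L]), c(0, 0))
})

test_that("zero drift is estimated as identically zero without noise", {
  m <- fiducial_model(n_frames = 300L, localization_sd = 0,
                      fiducials = rbind(c(-900, -900)))
  sim <- simulate_centriole(m, seed = 24)
  traj <- estimate_drift(detect_fiducials(sim$table), n_frames = 300L)
  expect_lt(max(abs(c(traj$dx, traj$dy))), 1e-9)
})

test_that("linear drift is recovered within the error-propagation bound", {
  m <- fiducial_model(drift = drift_spec("linear", 0.05), n_frames = 10000L)
  sim <- simulate_centriole(m, seed = 25)
  traj <- estimate_drift(detect_fiducials(sim$table), n_frames = 10000L)
  # endpoint displacement 0.05 * 9999 ~ 500 nm
  expect_lt(abs(traj$dx[10000L] - 0.05 * 9999), 3 * 8.5 / sqrt(3 * 100))
})

test_that("drift application is an exact inverse pair and conserves schema", {
  m <- fiducial_model(drift = drift_spec("linear", 0.1), n_frames = 400L)
  tab <- simulate_centriole(m, seed = 26)$table
  zero <- estimate_drift(list(data.frame(frame = 0:399, x = 0, y = 0)),
                         n_frames = 400L)
  expect_equal(apply_drift(tab, zero), tab)
  traj <- estimate_drift(detect_fiducials(tab), n_frames = 400L)
  corrected <- apply_drift(tab, traj)
  expect_equal(nrow(corrected), nrow(tab))
  expect_equal(names(corrected), names(tab))
  expect_equal(apply_drift(corrected, negate_drift(traj)), tab,
               tolerance = 1e-12)
  short <- traj[traj$frame < 10, ]
  expect_error(apply_drift(tab, short), "outside")
})

test_that("corrected fiducial tracks collapse to the localization precision", {
  m <- fiducial_model(drift = drift_spec("linear", 0.05), n_frames = 10000L)
  tab <- simulate_centriole(m, seed = 27)$table
  tracks <- detect_fiducials(tab)
  corrected <- apply_drift(tab, estimate_drift(tracks, n_frames = 10000L))
  tracks2 <- detect_fiducials(corrected)
  rms <- vapply(tracks2, function(tr) {
    sqrt(mean(((tr$x - mean(tr$x))^2 + (tr$y - mean(tr$y))^2) / 2))
  }, 0)
  expect_true(all(rms <= 1.1 * 8.5))
})

test_that("the chromatic polynomial is identified exactly from >= 6 beads", {
  ident <- simulate_bead_field(12, chromatic_spec(), noise_sd = 0, seed = 31)
  map <- fit_chromatic_map(ident$short, ident$long)
  expect_equal(map$coef_x, c(0, 1, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(map$coef_y, c(0, 0, 1, 0, 0, 0), tolerance = 1e-9)
  cs <- chromatic_spec(c(4, 1.002, 3e-5, 3e-7, -2e-7, 1e-7),
                       c(-6, 2e-5, 0.998, -1e-7, 3e-7, 2e-7))
  bf <- simulate_bead_field(12, cs, noise_sd = 0, seed = 32)
  # fitting the distorted channel as a polynomial of the true channel
  # recovers the generative coefficients exactly
  fwd <- fit_chromatic_map(bf$long, bf$short)
  expect_equal(fwd$coef_x, cs$coef_x, tolerance = 1e-8)
  expect_equal(fwd$coef_y, cs$coef_y, tolerance = 1e-8)
  expect_lt(fwd$rms, 1e-8)
})

test_that("bead-noise-limited registration leaves ~noise-level residuals", {
  cs <- chromatic_spec(c(4, 1.002, 3e-5, 3e-7, -2e-7, 1e-7),
                       c(-6, 2e-5, 0.998, -1e-7, 3e-7, 2e-7))
  bf <- simulate_bead_field(100, cs, noise_sd = 2, seed = 33)
  map <- fit_chromatic_map(bf$short, bf$long)
  expect_lt(map$rms, 3)
  expect_lt(map$loo_rms, 3)
  expect_equal(map$n_beads, 100L)
})

test_that("fit residual is non-increasing in polynomial order", {
  cs <- chromatic_spec(c(4, 1.002, 3e-5, 3e-7, -2e-7, 1e-7),
                       c(-6, 2e-5, 0.998, -1e-7, 3e-7, 2e-7))
  bf <- simulate_bead_field(60, cs, noise_sd = 1, seed = 34)
  rms <- vapply(0:2, function(o) fit_chromatic_map(bf$short, bf$long,
                                                   order = o)$rms, 0)
  expect_true(all(diff(rms) <= 1e-9))
})

test_that("degenerate bead designs are refused", {
  line <- data.frame(x = 1:8 * 100, y = 1:8 * 50)  # collinear
  expect_error(fit_chromatic_map(line, line), "degenerate|collinear")
  few <- data.frame(x = 1:5, y = c(2, 4, 1, 5, 3))
  expect_error(fit_chromatic_map(few, few), "6")
})

test_that("chromatic correction transforms only the named channel", {
  cs <- chromatic_spec(c(10, 1.001, 0, 1e-7, 0, 0),
                       c(-10, 0, 0.999, 0, 0, 1e-7))
  bf <- simulate_bead_field(50, cs, noise_sd = 0, seed = 35)
  map <- fit_chromatic_map(bf$short, bf$long)
  tab <- localization_table(frame = 0L, channel = c("561", "647"),
                            x = c(500, 500), y = c(-300, -300))
  out <- apply_chromatic_map(tab, map, channel = "561")
  expect_false(out$x[1L] == tab$x[1L])
  expect_equal(out[2L, ], tab[2L, ])        # other channel untouched
  expect_error(apply_chromatic_map(tab, map), "channel")
  # identity map leaves everything untouched
  imap <- fit_chromatic_map(bf$long, bf$long)
  expect_equal(apply_chromatic_map(tab, imap, channel = "561"), tab,
               tolerance = 1e-9)
})

test_that("registering a distorted ring matches the reference-channel ring", {
  cs <- chromatic_spec(c(15, 1.002, 1e-5, 3e-7, -1e-7, 2e-7),
                       c(-12, -1e-5, 0.998, 1e-7, 2e-7, -3e-7))
  m <- make_ring_model(radius = 150, radial_sd = 10, n_emitters = 200L,
                       protein = "561")
  m$short_channels <- "561"
  m$chromatic <- cs
  distorted <- simulate_centriole(m, seed = 36)$table
  m$chromatic <- chromatic_spec()
  reference <- simulate_centriole(m, seed = 36)$table
  bf <- simulate_bead_field(50, cs, noise_sd = 0, seed = 37)
  map <- fit_chromatic_map(bf$short, bf$long)
  corrected <- apply_chromatic_map(distorted, map, channel = "561")
  c_corr <- fit_ring_center(corrected)$center
  c_ref <- fit_ring_center(reference)$center
  expect_lt(sqrt(sum((c_corr - c_ref)^2)), 3)
})
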