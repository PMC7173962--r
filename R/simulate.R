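# Synthetic two-channel localization data emulating dSTORM acquisition of
# centriolar appendages: emitters on parametric ring/layer loci, geometric
# blinking, isotropic localization noise, uniform background, per-frame
# drift, polynomial chromatic distortion and always-on fiducial markers.

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# draw k gap arcs and k occupied arcs that interleave around the circle;
# returns matrix of gap [start, end) intervals in [0, 2*pi)
draw_gap_arcs <- function(occupancy_fraction, n_arcs) {
  total_gap <- (1 - occupancy_fraction) * 2 * pi
  if (total_gap <= 0) return(matrix(numeric(), ncol = 2L))
  k <- n_arcs
  wg <- stats::runif(k); wg <- wg / sum(wg) * total_gap
  wo <- stats::runif(k); wo <- wo / sum(wo) * (2 * pi - total_gap)
  offset <- stats::runif(1, 0, 2 * pi)
  starts <- offset + cumsum(c(0, wg[-k] + wo[-k]))
  cbind(start = starts %% (2 * pi), end = (starts + wg) %% (2 * pi))
}

angle_in_gap <- function(theta, gaps) {
  if (nrow(gaps) == 0L) return(rep(FALSE, length(theta)))
  theta <- theta %% (2 * pi)
  hit <- rep(FALSE, length(theta))
  for (i in seq_len(nrow(gaps))) {
    s <- gaps[i, 1]; e <- gaps[i, 2]
    hit <- hit | if (s <= e) theta >= s & theta < e else theta >= s | theta < e
  }
  hit
}

# sample emitter angles for one layer, honouring clustering and gaps
sample_layer_angles <- function(layer, gaps) {
  n <- layer$n_emitters
  if (n == 0L) return(numeric())
  if (layer$n_clusters > 0L) {
    k <- layer$n_clusters
    ideal <- 2 * pi * (seq_len(k) - 1L) / k
    centres <- ideal + stats::rnorm(k, 0, layer$cluster_angular_sd)
    keep <- !angle_in_gap(ideal, gaps)
    assignment <- rep(seq_len(k), length.out = n)
    ang <- centres[assignment]
    ang[!keep[assignment]] <- NA_real_
    ang[!is.na(ang)]
  } else {
    # rejection-sample uniform angles on the occupied arcs
    ang <- stats::runif(4L * n + 32L, 0, 2 * pi)
    ang <- ang[!angle_in_gap(ang, gaps)]
    while (length(ang) < n) {
      more <- stats::runif(2L * n, 0, 2 * pi)
      ang <- c(ang, more[!angle_in_gap(more, gaps)])
    }
    ang[seq_len(n)]
  }
}

# per-frame drift displacement matrix (n_frames x 2), frame 0 at (0, 0)
drift_displacement <- function(drift, n_frames) {
  f <- seq_len(n_frames) - 1L
  switch(drift$kind,
    none = matrix(0, n_frames, 2L),
    linear = cbind(f * drift$rate_or_step, f * drift$rate_or_step),
    random_walk = {
      steps <- matrix(stats::rnorm(2L * n_frames, 0, drift$rate_or_step),
                      ncol = 2L)
      steps[1L, ] <- 0
      apply(steps, 2L, cumsum)
    }
  )
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Simulate one centriole acquisition
#'
#' Samples emitters on every in-view protein layer, thins them by labelling
#' efficiency and occupancy gaps, draws a geometric number of localizations
#' per emitter (blinking), jitters each by the isotropic localization
#' precision, assigns frames uniformly, adds drift, applies the chromatic
#' distortion to short-wavelength channels, and appends uniform background
#' and per-frame fiducial localizations.
#'
#' In an axial view only layers whose longitudinal position falls inside the
#' focal slab (`focal_center +/- focal_depth / 2`) contribute; a lateral view
#' projects every layer to (transverse, longitudinal) coordinates with the
#' natural edge-density of an orthographically projected ring.
#'
#' @param model a [ground_truth_model()].
#' @param seed integer seed (mandatory).
#' @param channels optional character vector restricting simulated channels.
#' @param view optional override of `model$view`.
#' @return list with `table` (a [localization_table()]) and `truth`
#'   (ground-truth sidecar: the model, per-layer emitter positions and
#'   localization counts, drift trajectory and row bookkeeping).
#' @export
simulate_centriole <- function(model, seed, channels = NULL, view = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (is.null(view)) view <- model$view
  layers <- model$layers
  if (!is.null(channels)) {
    layers <- Filter(function(l) l$protein_name %in% channels, layers)
  }
  if (view == "axial") {
    lo <- model$focal_center - model$focal_depth / 2
    hi <- model$focal_center + model$focal_depth / 2
    layers <- Filter(function(l) l$longitudinal_position >= lo &
                       l$longitudinal_position <= hi, layers)
  }

  with_seed(seed, {
    disp <- drift_displacement(model$drift, model$n_frames)
    Rm <- rot2(model$rotation)
    parts <- list()
    truth_layers <- list()
    n_signal <- 0L

    for (li in seq_along(layers)) {
      layer <- layers[[li]]
      n_lab <- stats::rbinom(1L, layer$n_emitters, layer$labeling_efficiency)
      if (n_lab == 0L) next
      gaps <- draw_gap_arcs(layer$occupancy_fraction, layer$n_gap_arcs)
      ang <- sample_layer_angles(layer, gaps)
      ang <- ang[seq_len(min(length(ang), n_lab))]
      n_em <- length(ang)
      if (n_em == 0L) next

      dz <- if (layer$axial_profile == "uniform") {
        stats::runif(n_em, -sqrt(3) * layer$axial_sd, sqrt(3) * layer$axial_sd)
      } else {
        stats::rnorm(n_em, 0, layer$axial_sd)
      }
      z <- layer$longitudinal_position + dz

      if (view == "axial") {
        if (layer$n_clusters > 0L) {
          ex <- layer$ring_radius * cos(ang) + stats::rnorm(n_em, 0, layer$radial_sd)
          ey <- layer$ring_radius * sin(ang) + stats::rnorm(n_em, 0, layer$radial_sd)
        } else {
          rr <- layer$ring_radius + stats::rnorm(n_em, 0, layer$radial_sd)
          ex <- rr * cos(ang)
          ey <- rr * sin(ang)
        }
      } else {
        # orthographic lateral projection: transverse = r cos(angle)
        rr <- layer$ring_radius + stats::rnorm(n_em, 0, layer$radial_sd)
        ex <- rr * cos(ang)
        ey <- z
      }
      emitters <- cbind(ex, ey) %*% t(Rm)
      emitters <- sweep(emitters, 2L, model$center, `+`)

      n_locs <- 1L + stats::rgeom(n_em, 1 / model$mean_locs_per_emitter)
      idx <- rep(seq_len(n_em), n_locs)
      n_rows <- length(idx)
      lx <- emitters[idx, 1L] + stats::rnorm(n_rows, 0, model$localization_sd)
      ly <- emitters[idx, 2L] + stats::rnorm(n_rows, 0, model$localization_sd)
      fr <- sample.int(model$n_frames, n_rows, replace = TRUE) - 1L
      parts[[length(parts) + 1L]] <- data.frame(
        frame = fr, channel = layer$protein_name, x = lx, y = ly,
        stringsAsFactors = FALSE)
      n_signal <- n_signal + n_rows
      truth_layers[[length(truth_layers) + 1L]] <- list(
        protein_name = layer$protein_name, layer_index = li,
        emitters = emitters, n_locs = n_locs, gap_arcs = gaps)
    }

    # uniform background per channel over the simulated field
    chans <- unique(vapply(layers, `[[`, "", "protein_name"))
    area_um2 <- (model$field_nm / 1000)^2
    n_bg_total <- 0L
    for (ch in chans) {
      n_bg <- stats::rpois(1L, model$background_density * area_um2)
      if (n_bg > 0L) {
        parts[[length(parts) + 1L]] <- data.frame(
          frame = sample.int(model$n_frames, n_bg, replace = TRUE) - 1L,
          channel = ch,
          x = model$center[1] + stats::runif(n_bg, -0.5, 0.5) * model$field_nm,
          y = model$center[2] + stats::runif(n_bg, -0.5, 0.5) * model$field_nm,
          stringsAsFactors = FALSE)
        n_bg_total <- n_bg_total + n_bg
      }
    }

    # fiducials: one localization per frame per channel, riding the drift
    n_fid_total <- 0L
    if (!is.null(model$fiducials) && nrow(model$fiducials) > 0L) {
      for (fi in seq_len(nrow(model$fiducials))) {
        for (ch in chans) {
          fx <- model$fiducials[fi, 1L] + disp[, 1L] +
            stats::rnorm(model$n_frames, 0, model$localization_sd)
          fy <- model$fiducials[fi, 2L] + disp[, 2L] +
            stats::rnorm(model$n_frames, 0, model$localization_sd)
          parts[[length(parts) + 1L]] <- data.frame(
            frame = seq_len(model$n_frames) - 1L, channel = ch,
            x = fx, y = fy, stringsAsFactors = FALSE)
          n_fid_total <- n_fid_total + model$n_frames
        }
      }
    }

    tab <- do.call(rbind, parts)
    if (is.null(tab)) {
      tab <- data.frame(frame = integer(), channel = character(),
                        x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE)
    }

    # structural rows drift with the stage (fiducials already carry it)
    is_fid <- rep(FALSE, nrow(tab))
    if (n_fid_total > 0L) {
      is_fid[seq.int(nrow(tab) - n_fid_total + 1L, nrow(tab))] <- TRUE
    }
    sel <- !is_fid
    tab$x[sel] <- tab$x[sel] + disp[tab$frame[sel] + 1L, 1L]
    tab$y[sel] <- tab$y[sel] + disp[tab$frame[sel] + 1L, 2L]

    # optical chromatic distortion of the short-wavelength channels
    if (!is_identity_chromatic(model$chromatic) &&
        length(model$short_channels) > 0L) {
      sc <- tab$channel %in% model$short_channels
      if (any(sc)) {
        warped <- poly2_eval(model$chromatic, tab$x[sc], tab$y[sc])
        tab$x[sc] <- warped$x
        tab$y[sc] <- warped$y
      }
    }

    tab <- localization_table(frame = tab$frame, channel = tab$channel,
                              x = tab$x, y = tab$y)
    truth <- list(model = model, view = view, seed = seed,
                  layers = truth_layers, drift = disp,
                  n_signal = n_signal, n_background = n_bg_total,
                  n_fiducial = n_fid_total)
    list(table = tab, truth = truth)
  })
}

#' Simulate a two-colour bead calibration field
#'
#' Matched bead positions in the long-wavelength (true) channel and the
#' short-wavelength channel after the chromatic distortion plus measurement
#' noise.
#'
#' @param n_beads number of beads (>= 6 for an identifiable second-order
#'   mapping).
#' @param chromatic a [chromatic_spec()] mapping true to distorted positions.
#' @param noise_sd per-axis measurement noise sd in nm.
#' @param seed integer seed.
#' @param field_nm side length of the square field covered by beads.
#' @return list with data.frames `long` and `short` (columns `x`, `y`).
#' @export
simulate_bead_field <- function(n_beads, chromatic = chromatic_spec(),
                                noise_sd = 0, seed, field_nm = 20000) {
  if (n_beads < 6L) {
    stop("at least 6 beads are required to identify the 6-coefficient ",
         "second-order chromatic mapping; got ", n_beads)
  }
  with_seed(seed, {
    long <- data.frame(x = stats::runif(n_beads, -0.5, 0.5) * field_nm,
                       y = stats::runif(n_beads, -0.5, 0.5) * field_nm)
    short <- poly2_eval(chromatic, long$x, long$y)
    short$x <- short$x + stats::rnorm(n_beads, 0, noise_sd)
    short$y <- short$y + stats::rnorm(n_beads, 0, noise_sd)
    list(long = long, short = short)
  })
}

#' Simulate microtubule fiber localizations
#'
#' Renders straight fiber segments as localization chains. One endpoint of
#' each fiber (the anchor) lies on the circular anchor locus of `spec`; the
#' fiber extends outward from the centriole with a small angular jitter.
#'
#' @param spec a [fiber_spec()].
#' @param model a [ground_truth_model()] providing pose, view, localization
#'   precision, blinking statistics and frame count.
#' @param seed integer seed.
#' @param direction_jitter_sd sd (radians) of the fiber direction about the
#'   outward direction.
#' @return a [localization_table()] (channel `"aTub"`) with attribute
#'   `fiber_truth`: a data.frame of true segment endpoints.
#' @export
simulate_fibers <- function(spec, model, seed, direction_jitter_sd = 0.05) {
  stopifnot(inherits(spec, "fiber_spec"), inherits(model, "ground_truth_model"))
  with_seed(seed, {
    n <- spec$n_fibers
    if (n == 0L) {
      tab <- localization_table()
      attr(tab, "fiber_truth") <- data.frame(
        x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric())
      return(tab)
    }
    Rm <- rot2(model$rotation)
    if (model$view == "axial") {
      ang <- spec$angular_phase + model$rotation +
        spec$angular_range * (seq_len(n) - 1L) / n +
        stats::rnorm(n, 0, spec$anchor_angular_jitter)
      a0 <- cbind(spec$anchor_radius * cos(ang),
                  spec$anchor_radius * sin(ang))
      dir_ang <- ang + stats::rnorm(n, 0, direction_jitter_sd)
    } else {
      # orthographic lateral projection of fibers leaving the anchor ring
      # at random azimuths: the apparent transverse position and extension
      # scale with cos(azimuth); near-perpendicular fibers appear short
      az <- spec$angular_phase + model$rotation +
        spec$angular_range * (seq_len(n) - 1L) / n +
        stats::rnorm(n, 0, spec$anchor_angular_jitter)
      a0 <- cbind(spec$anchor_radius * cos(az),
                  spec$anchor_longitudinal +
                    stats::rnorm(n, 0, spec$linewidth_sd))
      # outward, tilted slightly towards the proximal side
      tilt <- stats::rnorm(n, -0.15, direction_jitter_sd)
      dir_ang <- ifelse(cos(az) >= 0, 0, pi) + tilt * sign(cos(az))
    }
    len <- stats::runif(n, spec$length_range[1], spec$length_range[2])
    if (model$view == "lateral") len <- len * pmax(abs(cos(az)), 0.05)
    a1 <- a0 + cbind(len * cos(dir_ang), len * sin(dir_ang))

    parts <- vector("list", n)
    for (i in seq_len(n)) {
      n_em <- max(2L, floor(len[i] / spec$emitter_spacing))
      t_em <- seq(0, 1, length.out = n_em)
      ex <- a0[i, 1L] + t_em * (a1[i, 1L] - a0[i, 1L])
      ey <- a0[i, 2L] + t_em * (a1[i, 2L] - a0[i, 2L])
      # transverse linewidth scatter
      perp <- c(-sin(dir_ang[i]), cos(dir_ang[i]))
      off <- stats::rnorm(n_em, 0, spec$linewidth_sd)
      ex <- ex + off * perp[1L]
      ey <- ey + off * perp[2L]
      n_locs <- 1L + stats::rgeom(n_em, 1 / model$mean_locs_per_emitter)
      idx <- rep(seq_len(n_em), n_locs)
      parts[[i]] <- data.frame(
        x = ex[idx] + stats::rnorm(length(idx), 0, model$localization_sd),
        y = ey[idx] + stats::rnorm(length(idx), 0, model$localization_sd))
    }
    pts <- do.call(rbind, parts)
    pts <- as.data.frame(as.matrix(pts) %*% t(Rm))
    names(pts) <- c("x", "y")
    pts$x <- pts$x + model$center[1]
    pts$y <- pts$y + model$center[2]
    ends0 <- sweep(a0 %*% t(Rm), 2L, model$center, `+`)
    ends1 <- sweep(a1 %*% t(Rm), 2L, model$center, `+`)
    tab <- localization_table(
      frame = sample.int(model$n_frames, nrow(pts), replace = TRUE) - 1L,
      channel = "aTub", x = pts$x, y = pts$y)
    attr(tab, "fiber_truth") <- data.frame(
      x0 = ends0[, 1L], y0 = ends0[, 2L],
      x1 = ends1[, 1L], y1 = ends1[, 2L], length = len)
    tab
  })
}
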