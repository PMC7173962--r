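# Pre-analysis corrections: fiducial-based lateral drift correction and
# bead-calibrated second-order chromatic registration of the short-wavelength
# channel onto the long-wavelength channel. Both operate directly on the
# localization table (not on rendered images), which is equivalent in the
# noiseless limit and avoids pixel quantization.

#' Detect fiducial marker tracks
#'
#' Fiducials are bright beads present in (nearly) every frame; structural
#' emitters blink for only a handful of frames. Localizations are grouped
#' into spatially connected regions (coarse grid linkage) and a region is
#' accepted as a fiducial when it is detected in at least
#' `min_frames_fraction` of all frames.
#'
#' @param tab a [localization_table()] (all channels are pooled; the drift is
#'   common to both).
#' @param min_frames_fraction persistence threshold (default 0.5).
#' @param cell_nm linkage grid cell size in nm; regions are unions of
#'   8-connected occupied cells, so tracks may wander by more than one cell
#'   under drift.
#' @return list of tracks; each track is a data.frame with `frame`, `x`, `y`
#'   (per-frame mean position) plus attribute `site` (overall mean).
#' @export
detect_fiducials <- function(tab, min_frames_fraction = 0.5, cell_nm = 200) {
  stopifnot(nrow(tab) > 0L)
  n_frames <- max(tab$frame) + 1L
  ix <- floor(tab$x / cell_nm)
  iy <- floor(tab$y / cell_nm)
  code <- ix * 1e6 + iy               # integer-valued cell code
  ucode <- unique(code)
  cnt <- tabulate(match(code, ucode))
  # keep only cells dense enough to plausibly hold a persistent emitter
  dense <- ucode[cnt >= max(3, 0.05 * n_frames)]
  if (length(dense) == 0L) {
    stop("no persistent localization cluster found; use drift = 'none' or ",
         "supply fiducial coordinates manually")
  }
  # union-find over 8-connected dense cells
  parent <- seq_along(dense)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(dense)) {
    for (dx in -1:1) for (dy in -1:1) {
      j <- match(dense[i] + dx * 1e6 + dy, dense)
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  region_of_cell <- vapply(seq_along(dense), find, 1L)
  # attach every localization whose cell touches a region cell, so that
  # per-frame means are not biased by the dense-cell gate at cell borders
  loc_region <- rep(NA_integer_, nrow(tab))
  for (dx in -1:1) for (dy in -1:1) {
    r <- region_of_cell[match(code + dx * 1e6 + dy, dense)]
    fill <- is.na(loc_region) & !is.na(r)
    loc_region[fill] <- r[fill]
  }
  per_frame_track <- function(rows) {
    sx <- rowsum(cbind(rows$x, rows$y, 1), rows$frame, reorder = TRUE)
    data.frame(frame = as.integer(rownames(sx)),
               x = sx[, 1L] / sx[, 3L], y = sx[, 2L] / sx[, 3L])
  }
  tracks <- list()
  for (r in unique(loc_region[!is.na(loc_region)])) {
    rows <- tab[!is.na(loc_region) & loc_region == r, , drop = FALSE]
    frames_present <- length(unique(rows$frame))
    if (frames_present < min_frames_fraction * n_frames) next
    # reject stray localizations (background or structure swept up by the
    # region) against a rolling-median reference trajectory
    tr <- per_frame_track(rows)
    k <- min(101L, nrow(tr) - (1 - nrow(tr) %% 2L))
    refx <- stats::runmed(tr$x, k)
    refy <- stats::runmed(tr$y, k)
    i <- match(rows$frame, tr$frame)
    res <- sqrt((rows$x - refx[i])^2 + (rows$y - refy[i])^2)
    cut <- max(25, 6 * stats::mad(res))
    rows <- rows[res <= cut, , drop = FALSE]
    if (length(unique(rows$frame)) < min_frames_fraction * n_frames) next
    tr <- per_frame_track(rows)
    attr(tr, "site") <- c(mean(tr$x), mean(tr$y))
    tracks[[length(tracks) + 1L]] <- tr
  }
  if (length(tracks) == 0L) {
    stop("no persistent localization cluster found; use drift = 'none' or ",
         "supply fiducial coordinates manually")
  }
  tracks
}

#' Remove fiducial localizations from a table
#'
#' Drops every localization within `radius` of a detected fiducial site so
#' that the bright, always-on markers do not contaminate the structural
#' analyses downstream of the drift correction.
#'
#' The table and the tracks must be in the same correction state: remove
#' fiducials before applying a drift correction (or re-detect afterwards),
#' since each localization is matched against the track position of its own
#' frame.
#'
#' @param tab a [localization_table()].
#' @param tracks fiducial tracks from [detect_fiducials()] (their per-frame
#'   positions define the exclusion sites).
#' @param radius exclusion radius in nm (default 150).
#' @return the table without fiducial-associated rows.
#' @export
remove_fiducials <- function(tab, tracks, radius = 150) {
  keep <- rep(TRUE, nrow(tab))
  for (tr in tracks) {
    i <- match(tab$frame, tr$frame)
    ok <- !is.na(i)
    d2 <- (tab$x[ok] - tr$x[i[ok]])^2 + (tab$y[ok] - tr$y[i[ok]])^2
    drop <- logical(nrow(tab))
    drop[ok] <- d2 <= radius^2
    keep <- keep & !drop
  }
  tab[keep, , drop = FALSE]
}

#' Estimate the drift trajectory from fiducial tracks
#'
#' The per-frame displacement is the mean over tracks of
#' `position(frame) - position(first frame)`; missing frames are filled by
#' linear interpolation and the result smoothed with a centred local-linear
#' (Savitzky-Golay order 1) filter, which is unbiased for linear drift even
#' at the sequence boundaries.
#'
#' @param tracks list of tracks from [detect_fiducials()].
#' @param n_frames total number of frames (default: inferred from tracks).
#' @param window smoothing window in frames (default 100; 1 = no
#'   smoothing).
#' @return a `drift_trajectory`: data.frame with `frame`, `dx`, `dy`;
#'   frame 0 displacement is (0, 0).
#' @export
estimate_drift <- function(tracks, n_frames = NULL, window = 100L) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(n_frames)) {
    n_frames <- max(vapply(tracks, function(t) max(t$frame), 0L)) + 1L
  }
  frames <- seq_len(n_frames) - 1L
  acc <- matrix(0, n_frames, 2L)
  for (tr in tracks) {
    dx <- stats::approx(tr$frame, tr$x - tr$x[1L], xout = frames,
                        rule = 2L)$y
    dy <- stats::approx(tr$frame, tr$y - tr$y[1L], xout = frames,
                        rule = 2L)$y
    acc <- acc + cbind(dx, dy)
  }
  acc <- acc / length(tracks)
  if (window > 1L) {
    # local linear (Savitzky-Golay order 1) smoothing: unbiased for linear
    # drift everywhere, including the window-truncated boundaries
    half <- floor(window / 2)
    t <- as.numeric(frames)
    lo <- pmax(seq_len(n_frames) - half, 1L)
    hi <- pmin(seq_len(n_frames) + half, n_frames)
    cs1 <- cumsum(c(0, rep(1, n_frames)))
    cst <- cumsum(c(0, t))
    cst2 <- cumsum(c(0, t^2))
    sm <- function(v) {
      csy <- cumsum(c(0, v))
      csty <- cumsum(c(0, t * v))
      n_w <- cs1[hi + 1L] - cs1[lo]
      st <- cst[hi + 1L] - cst[lo]
      st2 <- cst2[hi + 1L] - cst2[lo]
      sy <- csy[hi + 1L] - csy[lo]
      sty <- csty[hi + 1L] - csty[lo]
      det <- n_w * st2 - st^2
      b <- (n_w * sty - st * sy) / det
      a <- (sy - b * st) / n_w
      a + b * t
    }
    acc <- cbind(sm(acc[, 1L]), sm(acc[, 2L]))
  }
  acc <- sweep(acc, 2L, acc[1L, ], `-`)  # re-anchor frame 0 at zero
  structure(data.frame(frame = frames, dx = acc[, 1L], dy = acc[, 2L]),
            class = c("drift_trajectory", "data.frame"), window = window)
}

#' Apply (or undo) a drift correction
#'
#' Each localization is translated by minus the displacement of its frame.
#' All other columns and the row order are unchanged.
#'
#' @param tab a [localization_table()].
#' @param drift a `drift_trajectory` from [estimate_drift()].
#' @return the corrected [localization_table()].
#' @export
apply_drift <- function(tab, drift) {
  tab <- validate_localization_table(tab)
  if (nrow(tab) == 0L) return(tab)
  if (max(tab$frame) > max(drift$frame) || min(tab$frame) < min(drift$frame)) {
    stop("table contains frames outside the drift trajectory (",
         min(tab$frame), "-", max(tab$frame), " vs trajectory ",
         min(drift$frame), "-", max(drift$frame), ")")
  }
  i <- match(tab$frame, drift$frame)
  tab$x <- tab$x - drift$dx[i]
  tab$y <- tab$y - drift$dy[i]
  tab
}

#' Negate a drift trajectory
#' @param drift a `drift_trajectory`.
#' @return the trajectory with both displacement axes negated.
#' @export
negate_drift <- function(drift) {
  drift$dx <- -drift$dx
  drift$dy <- -drift$dy
  drift
}

poly2_design <- function(x, y, order = 2L) {
  switch(as.character(order),
         "0" = matrix(1, length(x), 1L),
         "1" = cbind(1, x, y),
         "2" = cbind(1, x, y, x^2, x * y, y^2),
         stop("order must be 0, 1 or 2"))
}

#' Fit the chromatic registration map from bead pairs
#'
#' Least-squares fit of each long-wavelength axis as a full second-order
#' polynomial in the short-wavelength coordinates (the parabolic mapping
#' used for two-colour bead calibration). With 10 or more beads a
#' leave-one-out residual is reported alongside the in-sample RMS.
#'
#' @param short,long data.frames with `x`, `y` columns: matched bead
#'   positions in the distorted (short) and reference (long) channels.
#' @param order polynomial order (0, 1 or 2; default 2).
#' @return a `chromatic_map`: list with `coef_x`, `coef_y`, `order`,
#'   `rms` (in-sample residual RMS, nm), `loo_rms` (leave-one-out RMS or NA)
#'   and `n_beads`.
#' @export
fit_chromatic_map <- function(short, long, order = 2L) {
  stopifnot(nrow(short) == nrow(long))
  n <- nrow(short)
  if (n < 6L) {
    stop("at least 6 bead pairs are required for the second-order mapping; ",
         "got ", n)
  }
  X <- poly2_design(short$x, short$y, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient bead design (rank ", qrX$rank, " < ", ncol(X),
         "): beads are collinear or otherwise degenerate")
  }
  cx <- qr.coef(qrX, long$x)
  cy <- qr.coef(qrX, long$y)
  res <- cbind(long$x - X %*% cx, long$y - X %*% cy)
  rms <- sqrt(mean(res^2))
  loo_rms <- NA_real_
  if (n >= 10L) {
    loo_sq <- numeric(n)
    for (i in seq_len(n)) {
      Xi <- X[-i, , drop = FALSE]
      cxi <- qr.coef(qr(Xi), long$x[-i])
      cyi <- qr.coef(qr(Xi), long$y[-i])
      loo_sq[i] <- mean((c(X[i, ] %*% cxi, X[i, ] %*% cyi) -
                           c(long$x[i], long$y[i]))^2)
    }
    loo_rms <- sqrt(mean(loo_sq))
  }
  structure(list(coef_x = as.numeric(cx), coef_y = as.numeric(cy),
                 order = order, rms = rms, loo_rms = loo_rms, n_beads = n),
            class = "chromatic_map")
}

#' Apply a chromatic registration map to one channel
#'
#' Only rows of the named channel are transformed (short-to-long channel
#' registration); all other rows, columns and the row order are untouched.
#'
#' @param tab a [localization_table()].
#' @param map a `chromatic_map` from [fit_chromatic_map()].
#' @param channel channel id to transform (mandatory).
#' @return the registered [localization_table()].
#' @export
apply_chromatic_map <- function(tab, map, channel) {
  if (missing(channel)) stop("the channel to register is mandatory")
  tab <- validate_localization_table(tab)
  sel <- tab$channel %in% channel
  if (any(sel)) {
    X <- poly2_design(tab$x[sel], tab$y[sel], map$order)
    tab$x[sel] <- as.numeric(X %*% map$coef_x)
    tab$y[sel] <- as.numeric(X %*% map$coef_y)
  }
  tab
}
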