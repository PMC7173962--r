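# Lateral-view analyses: view classification, centriole-axis estimation from
# the reference channel, longitudinal layer profiling relative to the
# reference (reference centroid = 0, distal positive), cross-centriole
# composite averaging, ROI densities and the distal-boundary statistic.

#' Classify the viewing orientation of a reference point cloud
#'
#' Uses the principal-axis eigenvalue ratio of the reference localizations:
#' a ring (axial view) is isotropic, a rod (lateral view) strongly
#' elongated.
#'
#' @param tab localization table or data.frame with `x`, `y` of the
#'   reference channel.
#' @param lateral_ratio minimum variance ratio for `"lateral"` (default 3).
#' @param axial_ratio maximum variance ratio for `"axial"` (default 2).
#' @return `"axial"`, `"lateral"` or `"ambiguous"`.
#' @export
classify_view <- function(tab, lateral_ratio = 3, axial_ratio = 2) {
  if (nrow(tab) < 50L) {
    stop("at least 50 reference localizations are required; got ", nrow(tab))
  }
  pts <- cbind(tab$x, tab$y)[trim_structure(tab), , drop = FALSE]
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$values
  ratio <- ev[1L] / ev[2L]
  if (ratio < axial_ratio) "axial"
  else if (ratio >= lateral_ratio) "lateral"
  else "ambiguous"
}

# flag localizations belonging to the structure, discarding far-field
# background by iterative Mahalanobis trimming
trim_structure <- function(tab, cutoff = 3.5, iterations = 2L) {
  pts <- cbind(tab$x, tab$y)
  keep <- rep(TRUE, nrow(pts))
  for (it in seq_len(iterations)) {
    mu <- colMeans(pts[keep, , drop = FALSE])
    S <- stats::cov(pts[keep, , drop = FALSE])
    d2 <- stats::mahalanobis(pts, mu, S)
    new_keep <- d2 <= cutoff^2
    if (sum(new_keep) < 10L || all(new_keep == keep)) break
    keep <- new_keep
  }
  keep
}

#' Estimate the centriole axis from the lateral-view reference channel
#'
#' The reference (e.g. the SCLT1 DAP layer) appears as a rod transverse to
#' the centriole; the centriole axis is the perpendicular to the rod's long
#' principal axis through the rod centroid. The distal direction is fixed so
#' that the centroid of a designated marker channel projects positive (when
#' `marker_side = "distal"`, e.g. CP110) or negative
#' (`marker_side = "proximal"`).
#'
#' @param ref_tab reference-channel localizations (lateral view).
#' @param marker_tab localizations of the orientation marker, or NULL.
#' @param marker_side which side of the reference the marker sits on.
#' @param orientation `"+"`/`"-"` manual sign override used when no marker
#'   is available; NULL otherwise.
#' @return a `centriole_axis`: list with `origin` (reference centroid, nm),
#'   `direction` (unit vector, proximal to distal) and `view`.
#' @export
estimate_axis <- function(ref_tab, marker_tab = NULL,
                          marker_side = c("distal", "proximal"),
                          orientation = NULL) {
  marker_side <- match.arg(marker_side)
  view <- classify_view(ref_tab)
  if (view != "lateral") {
    stop("reference channel is not in a lateral (rod) view: ", view)
  }
  pts <- cbind(ref_tab$x, ref_tab$y)[trim_structure(ref_tab), , drop = FALSE]
  origin <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  rod <- ev$vectors[, 1L]          # long axis of the rod (transverse)
  axis <- c(-rod[2L], rod[1L])     # perpendicular: the centriole axis
  if (!is.null(marker_tab) && nrow(marker_tab) > 0L) {
    proj <- mean((marker_tab$x - origin[1L]) * axis[1L] +
                   (marker_tab$y - origin[2L]) * axis[2L])
    want <- if (marker_side == "distal") proj else -proj
    if (want < 0) axis <- -axis
  } else if (!is.null(orientation)) {
    if (orientation == "-") axis <- -axis
  } else {
    stop("axis sign is unidentifiable: supply an orientation marker channel ",
         "or the `orientation` flag")
  }
  structure(list(origin = c(x = unname(origin[1L]), y = unname(origin[2L])),
                 direction = axis / sqrt(sum(axis^2)), view = "lateral"),
            class = "centriole_axis")
}

# signed (longitudinal, transverse) coordinates relative to an axis
axis_coordinates <- function(tab, axis) {
  dx <- tab$x - axis$origin[1L]
  dy <- tab$y - axis$origin[2L]
  u <- dx * axis$direction[1L] + dy * axis$direction[2L]
  v <- -dx * axis$direction[2L] + dy * axis$direction[1L]
  data.frame(longitudinal = u, transverse = v)
}

#' Longitudinal density profile relative to the reference layer
#'
#' Projects target localizations on the centriole axis (reference centroid
#' = 0, distal positive) and bins them. The profile is density-conserving:
#' `sum(density) * bin_width = n`.
#'
#' @param tab target-channel localizations.
#' @param axis a `centriole_axis` from [estimate_axis()].
#' @param bin_width bin width in nm (default 10).
#' @return a `longitudinal_profile`: list with `bin_centers`, `density`
#'   (localizations per nm), `bin_width`, `n`, `projections` (raw signed
#'   positions) and `layers` (NULL until [detect_layers()] is run).
#' @export
longitudinal_profile <- function(tab, axis, bin_width = 10) {
  u <- axis_coordinates(tab, axis)$longitudinal
  if (length(u) == 0L) stop("no localizations to profile")
  lo <- floor(min(u) / bin_width) * bin_width
  hi <- ceiling(max(u) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(findInterval(u, breaks), length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  structure(list(bin_centers = breaks[-length(breaks)] + bin_width / 2,
                 density = counts / bin_width, bin_width = bin_width,
                 n = length(u), projections = u, layers = NULL),
            class = "longitudinal_profile")
}

#' Detect protein layers as peaks of the longitudinal profile
#'
#' The binned profile is smoothed with a Gaussian kernel (sd = the
#' localization precision by default), and local maxima are accepted in
#' decreasing height order subject to a minimum separation and a minimum
#' prominence relative to the global maximum. Each accepted layer's position
#' is the density centroid of its `+/- FWHM` window (robust to binning) and
#' its width the full width at half maximum.
#'
#' @param profile a `longitudinal_profile`.
#' @param min_separation minimum layer separation in nm (default 50).
#' @param min_prominence minimum peak height as a fraction of the maximum
#'   (default 0.2).
#' @param kernel_sd Gaussian smoothing sd in nm (default 8.5).
#' @return the profile with `layers` set: data.frame with `position`,
#'   `width`, `prominence` (height fraction), ordered by position.
#' @export
detect_layers <- function(profile, min_separation = 50,
                          min_prominence = 0.2, kernel_sd = 8.5) {
  d <- profile$density
  bw <- profile$bin_width
  if (kernel_sd > 0) {
    half <- max(1L, ceiling(4 * kernel_sd / bw))
    k <- stats::dnorm(seq(-half, half) * bw, sd = kernel_sd)
    k <- k / sum(k)
    padded <- c(numeric(half), d, numeric(half))
    d <- vapply(seq_along(profile$density),
                function(i) sum(padded[i:(i + 2L * half)] * rev(k)),
                numeric(1))
  }
  n <- length(d)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) d[i - 1L] else -Inf
    right <- if (i < n) d[i + 1L] else -Inf
    d[i] > 0 && d[i] >= left && d[i] > right
  }, logical(1))
  cand <- which(is_max)
  # topographic prominence: height above the deeper of the two valleys
  # separating the peak from the nearest higher ground on each side
  prominence_of <- function(i) {
    base <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- i + dir
      valley <- d[i]
      side_base <- NA_real_
      while (j >= 1L && j <= n) {
        if (d[j] > d[i]) { side_base <- valley; break }
        valley <- min(valley, d[j])
        j <- j + dir
      }
      if (is.na(side_base)) side_base <- valley  # ran off the boundary
      base <- max(base, side_base)
    }
    d[i] - base
  }
  accepted <- integer()
  if (length(cand) > 0L) {
    cand <- cand[order(d[cand], decreasing = TRUE)]
    peak_h <- max(d)
    for (i in cand) {
      if (prominence_of(i) < min_prominence * peak_h) next
      if (length(accepted) > 0L &&
          any(abs(profile$bin_centers[accepted] -
                    profile$bin_centers[i]) < min_separation)) next
      accepted <- c(accepted, i)
    }
  }

  layers <- data.frame(position = numeric(), width = numeric(),
                       prominence = numeric())
  for (i in accepted) {
    half_h <- d[i] / 2
    li <- i; while (li > 1L && d[li - 1L] > half_h) li <- li - 1L
    ri <- i; while (ri < n && d[ri + 1L] > half_h) ri <- ri + 1L
    fwhm <- (ri - li + 1L) * bw
    win <- profile$bin_centers >= profile$bin_centers[i] - fwhm &
      profile$bin_centers <= profile$bin_centers[i] + fwhm
    pos <- sum(profile$bin_centers[win] * d[win]) / sum(d[win])
    layers <- rbind(layers, data.frame(position = pos, width = fwhm,
                                       prominence = d[i] / max(d)))
  }
  layers <- layers[order(layers$position), , drop = FALSE]
  rownames(layers) <- NULL
  profile$layers <- layers
  profile$smoothed_density <- d
  profile
}

#' Align centrioles and accumulate a composite image
#'
#' Each centriole is translated so its reference centroid sits at the
#' origin, rotated so its axis points along +y, and accumulated into a
#' shared 2D histogram (default 10 nm pixels). Channels are stacked
#' separately. Accumulation is order-independent and the total count is the
#' sum of per-centriole in-extent counts.
#'
#' @param centrioles list of entries, each a list with `table` (a
#'   localization table) and `axis` (a `centriole_axis`); views must all be
#'   lateral.
#' @param pixel_nm composite pixel size (default 10).
#' @param xlim,ylim composite extent in aligned (transverse, longitudinal)
#'   nm coordinates.
#' @return a `composite_image`: list with `channels` (named list of
#'   matrices), `n_centrioles`, `pixel_nm`, `xlim`, `ylim` and
#'   `aligned_tables`.
#' @export
align_and_composite <- function(centrioles, pixel_nm = 10,
                                xlim = c(-700, 700), ylim = c(-700, 300)) {
  stopifnot(length(centrioles) >= 1L)
  aligned <- lapply(centrioles, function(ce) {
    if (!inherits(ce$axis, "centriole_axis") || ce$axis$view != "lateral") {
      stop("all centrioles must be lateral views with an estimated axis")
    }
    uv <- axis_coordinates(ce$table, ce$axis)
    data.frame(channel = ce$table$channel, x = uv$transverse,
               y = uv$longitudinal, stringsAsFactors = FALSE)
  })
  all_ch <- unique(unlist(lapply(aligned, function(a) unique(a$channel))))
  nx <- ceiling(diff(xlim) / pixel_nm)
  ny <- ceiling(diff(ylim) / pixel_nm)
  channels <- stats::setNames(
    lapply(all_ch, function(ch) matrix(0, ny, nx)), all_ch)
  for (a in aligned) {
    for (ch in unique(a$channel)) {
      sub <- a[a$channel == ch, , drop = FALSE]
      ix <- floor((sub$x - xlim[1L]) / pixel_nm) + 1L
      iy <- floor((sub$y - ylim[1L]) / pixel_nm) + 1L
      keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
      for (k in which(keep)) {
        channels[[ch]][iy[k], ix[k]] <- channels[[ch]][iy[k], ix[k]] + 1
      }
    }
  }
  structure(list(channels = channels, n_centrioles = length(centrioles),
                 pixel_nm = pixel_nm, xlim = xlim, ylim = ylim,
                 aligned_tables = aligned),
            class = "composite_image")
}

#' Localization count and density in a rectangular ROI
#'
#' The ROI is a rectangle in (longitudinal, |transverse|) coordinates:
#' `longitudinal_range` along the axis and `radial_range` in absolute
#' transverse distance from the axis (both sides counted).
#'
#' @param tab localization table.
#' @param axis a `centriole_axis`.
#' @param longitudinal_range,radial_range length-2 numeric ranges in nm.
#' @return list with `count` and `density` (per nm^2; both transverse bands
#'   contribute to the area).
#' @export
roi_density <- function(tab, axis, longitudinal_range, radial_range) {
  uv <- axis_coordinates(tab, axis)
  sel <- uv$longitudinal >= longitudinal_range[1L] &
    uv$longitudinal <= longitudinal_range[2L] &
    abs(uv$transverse) >= radial_range[1L] &
    abs(uv$transverse) <= radial_range[2L]
  area <- diff(longitudinal_range) * diff(radial_range) * 2
  list(count = sum(sel), density = sum(sel) / area)
}

#' Distal boundary of a longitudinal distribution
#'
#' The signed axis position below which the given quantile of localizations
#' lies — the distal-edge statistic used to compare wild-type and knockout
#' spreading. Computed on the binned density with linear interpolation
#' within the boundary bin.
#'
#' @param profile a `longitudinal_profile`.
#' @param quantile_level quantile (default 0.95).
#' @return position in nm.
#' @export
distal_boundary <- function(profile, quantile_level = 0.95) {
  counts <- profile$density * profile$bin_width
  total <- sum(counts)
  if (total == 0) stop("empty profile")
  target <- quantile_level * total
  cum <- cumsum(counts)
  i <- which(cum >= target)[1L]
  prev <- if (i > 1L) cum[i - 1L] else 0
  frac <- (target - prev) / counts[i]
  left_edge <- profile$bin_centers[i] - profile$bin_width / 2
  left_edge + frac * profile$bin_width
}
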