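# Microtubule fiber detection and counting: elongated density clusters are
# accepted as fibers; counts are reported per radian around a ring centre
# (axial view) or per longitudinal bin along the centriole axis (lateral
# view), always attributed to the fiber's centriole-proximal endpoint (the
# anchor).

#' Detect straight fiber segments in a localization table
#'
#' Localizations are grouped by single-linkage density clustering with a
#' gap-bridging radius; a cluster qualifies as a fiber when it is elongated
#' (principal-axis ratio at least `min_elongation`), long enough and has
#' enough support. The segment is the principal-axis span of the cluster.
#'
#' @param tab single-channel localization table.
#' @param min_length minimum fiber length in nm (default 300).
#' @param min_support minimum localizations per fiber (default 30).
#' @param linewidth expected transverse width (nm); only reported, not used
#'   for gating (default 25).
#' @param bridge_radius linkage radius in nm (default 50); gaps along a
#'   fiber shorter than this are bridged into one segment.
#' @param min_elongation minimum sd ratio of the principal axes (default 4).
#' @return data.frame of segments: endpoints `x0`, `y0`, `x1`, `y1`,
#'   `length`, `orientation` (radians), `support`. Empty when none qualify.
#' @export
detect_fiber_segments <- function(tab, min_length = 300, min_support = 30L,
                                  linewidth = 25, bridge_radius = 50,
                                  min_elongation = 4) {
  empty <- data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), length = numeric(),
                      orientation = numeric(), support = integer())
  if (nrow(tab) == 0L) return(empty)
  groups <- tryCatch(
    cluster_assignments(tab, radius = bridge_radius),
    error = function(e) NULL)
  if (is.null(groups)) return(empty)
  segs <- empty
  for (g in unique(groups)) {
    m <- groups == g
    if (sum(m) < min_support) next
    pts <- cbind(tab$x[m], tab$y[m])
    mu <- colMeans(pts)
    ev <- eigen(stats::cov(pts), symmetric = TRUE)
    if (sqrt(ev$values[1L] / max(ev$values[2L], 1e-12)) < min_elongation) next
    axis1 <- ev$vectors[, 1L]
    proj <- (pts[, 1L] - mu[1L]) * axis1[1L] + (pts[, 2L] - mu[2L]) * axis1[2L]
    span <- range(proj)
    len <- diff(span)
    if (len < min_length) next
    p0 <- mu + span[1L] * axis1
    p1 <- mu + span[2L] * axis1
    segs <- rbind(segs, data.frame(
      x0 = p0[1L], y0 = p0[2L], x1 = p1[1L], y1 = p1[2L], length = len,
      orientation = atan2(axis1[2L], axis1[1L]) %% pi,
      support = sum(m)))
  }
  rownames(segs) <- NULL
  segs
}

# single-linkage cluster labels for every localization (no size filter)
cluster_assignments <- function(tab, radius) {
  pts <- cbind(tab$x, tab$y)
  n <- nrow(pts)
  ix <- floor(pts[, 1L] / radius)
  iy <- floor(pts[, 2L] / radius)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  cell_members <- split(seq_len(n), paste(ix, iy))
  r2 <- radius^2
  for (key in names(cell_members)) {
    members <- cell_members[[key]]
    cc <- as.integer(strsplit(key, " ")[[1L]])
    neigh <- members
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      nb <- cell_members[[paste(cc[1L] + dx, cc[2L] + dy)]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (i in members) {
      d2 <- (pts[neigh, 1L] - pts[i, 1L])^2 + (pts[neigh, 2L] - pts[i, 2L])^2
      for (j in neigh[d2 <= r2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# endpoint of each segment nearer the given point (the anchor)
anchor_endpoints <- function(segments, center) {
  if (nrow(segments) == 0L) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  d0 <- sqrt((segments$x0 - center[1L])^2 + (segments$y0 - center[2L])^2)
  d1 <- sqrt((segments$x1 - center[1L])^2 + (segments$y1 - center[2L])^2)
  swap <- d1 < d0
  data.frame(x = ifelse(swap, segments$x1, segments$x0),
             y = ifelse(swap, segments$y1, segments$y0))
}

#' Fibers per radian around a centre
#'
#' Counts segments whose centriole-proximal endpoint falls inside the given
#' annulus around `center` and divides by the surveyed angular extent.
#'
#' @param segments data.frame from [detect_fiber_segments()].
#' @param center ring centre (x, y) nm.
#' @param annulus length-2 radial range in nm for qualifying anchors.
#' @param angular_extent surveyed extent in radians (default `2 * pi`).
#' @return list with `n_fibers`, `rate_per_radian`.
#' @export
count_per_radian <- function(segments, center, annulus,
                             angular_extent = 2 * pi) {
  anch <- anchor_endpoints(segments, center)
  if (nrow(anch) == 0L) {
    return(list(n_fibers = 0L, rate_per_radian = 0))
  }
  r <- sqrt((anch$x - center[1L])^2 + (anch$y - center[2L])^2)
  n <- sum(r >= annulus[1L] & r <= annulus[2L])
  list(n_fibers = n, rate_per_radian = n / angular_extent)
}

#' Fiber counts per longitudinal bin
#'
#' Each fiber is assigned to the bin containing the longitudinal coordinate
#' of its centriole-proximal endpoint (anchor; the endpoint nearer the
#' axis origin).
#'
#' @param segments data.frame from [detect_fiber_segments()].
#' @param axis a `centriole_axis`.
#' @param breaks longitudinal bin edges in nm (ascending).
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
count_per_longitudinal_bin <- function(segments, axis, breaks) {
  stopifnot(length(breaks) >= 2L)
  out <- data.frame(bin_start = breaks[-length(breaks)],
                    bin_end = breaks[-1L],
                    count = 0L)
  if (nrow(segments) == 0L) return(out)
  anch <- anchor_endpoints(segments, axis$origin)
  u <- axis_coordinates(anch, axis)$longitudinal
  idx <- findInterval(u, breaks)
  idx <- idx[idx >= 1L & idx < length(breaks)]
  if (length(idx) > 0L) {
    tab <- table(idx)
    out$count[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}
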