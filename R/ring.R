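# Axial-view ring quantification: puncta clustering, circle fitting, mean
# diameter, polar angular occupancy / completeness, and nine-fold symmetry.

#' Group localizations into super-resolved puncta
#'
#' Density-based grouping (DBSCAN): a localization is a core point when at
#' least `min_count` localizations (itself included) lie within `radius`;
#' puncta are connected components of core points, with non-core
#' localizations attached to a neighbouring core's punctum. Localizations
#' in no punctum are discarded as background. Two dense clusters whose core
#' regions approach within the grouping radius merge into one punctum
#' (documented behaviour).
#'
#' @param tab a [localization_table()] or data.frame with `x`, `y`
#'   (single channel, axial view).
#' @param radius neighbourhood radius in nm (default 20).
#' @param min_count minimum neighbours for a core point and minimum
#'   localizations per punctum (default 5).
#' @return data.frame of punctum centroids: `x`, `y`, `n` (support).
#' @export
cluster_puncta <- function(tab, radius = 20, min_count = 5L) {
  pts <- cbind(tab$x, tab$y)
  n <- nrow(pts)
  if (n == 0L) stop("no localizations to cluster")
  nb <- neighbor_lists(pts, radius)
  degree <- lengths(nb)                 # neighbour count including self
  core <- degree >= min_count
  if (!any(core)) {
    stop("no punctum with at least ", min_count, " localizations within ",
         radius, " nm; consider changing the clustering thresholds")
  }
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (i in which(core)) {
    for (j in nb[[i]]) {
      if (core[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  labels <- rep(NA_integer_, n)
  labels[core] <- vapply(which(core), find, 1L)
  for (i in which(!core)) {             # border points join a core punctum
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn) > 0L) labels[i] <- find(cn[1L])
  }
  sizes <- table(labels)
  keep <- as.integer(names(sizes)[sizes >= min_count])
  if (length(keep) == 0L) {
    stop("no punctum with at least ", min_count, " localizations within ",
         radius, " nm; consider changing the clustering thresholds")
  }
  cen <- t(vapply(keep, function(r) {
    m <- !is.na(labels) & labels == r
    c(mean(pts[m, 1L]), mean(pts[m, 2L]), sum(m))
  }, numeric(3L)))
  data.frame(x = cen[, 1L], y = cen[, 2L], n = as.integer(cen[, 3L]))
}

# grid-accelerated fixed-radius neighbour lists (self included)
neighbor_lists <- function(pts, radius) {
  n <- nrow(pts)
  ix <- floor(pts[, 1L] / radius)
  iy <- floor(pts[, 2L] / radius)
  cell_members <- split(seq_len(n), paste(ix, iy))
  r2 <- radius^2
  nb <- vector("list", n)
  for (key in names(cell_members)) {
    members <- cell_members[[key]]
    cc <- as.integer(strsplit(key, " ")[[1L]])
    neigh <- members
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      cand <- cell_members[[paste(cc[1L] + dx, cc[2L] + dy)]]
      if (!is.null(cand)) neigh <- c(neigh, cand)
    }
    for (i in members) {
      d2 <- (pts[neigh, 1L] - pts[i, 1L])^2 + (pts[neigh, 2L] - pts[i, 2L])^2
      nb[[i]] <- neigh[d2 <= r2]
    }
  }
  nb
}

#' Fit the centre of a ring of points
#'
#' Algebraic least-squares circle fit (Kasa) refined by one geometric
#' Gauss-Newton pass. Works on partial arcs; at least three non-collinear
#' points are required. With `trim = TRUE` (the default for more than 20
#' points) the fit is re-run after discarding points with radial residuals
#' beyond 3 sd, which protects the algebraic fit against high-leverage
#' background localizations far from the ring.
#'
#' @param pts data.frame with `x`, `y` (puncta centroids or localizations).
#' @param trim logical; iteratively discard gross radial outliers.
#' @return list with `center` (x, y), `radius` and `method`.
#' @export
fit_ring_center <- function(pts, trim = NULL) {
  if (is.null(trim)) trim <- nrow(pts) > 20L
  if (trim) {
    keep <- rep(TRUE, nrow(pts))
    fit <- NULL
    for (it in 1:3) {
      fit <- fit_ring_center(pts[keep, , drop = FALSE], trim = FALSE)
      r <- sqrt((pts$x - fit$center[1L])^2 + (pts$y - fit$center[2L])^2)
      res <- r - fit$radius
      new_keep <- abs(res - stats::median(res[keep])) <=
        3 * stats::sd(res[keep])
      if (sum(new_keep) < 10L || all(new_keep == keep)) break
      keep <- new_keep
    }
    fit$method <- paste0(fit$method, "+trim")
    return(fit)
  }
  x <- pts$x; y <- pts$y
  n <- length(x)
  if (n < 3L) stop("at least 3 points are required to fit a circle")
  X <- cbind(2 * x, 2 * y, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("degenerate (collinear) points: cannot fit a circle")
  # guard against numerically near-collinear input
  if (kappa(qr.R(qrX)) > 1e10) {
    stop("degenerate (collinear) points: cannot fit a circle")
  }
  sol <- qr.coef(qrX, x^2 + y^2)
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt(sol[3L] + cx^2 + cy^2)
  # one Gauss-Newton step on the geometric distance
  for (it in 1L) {
    dx <- x - cx; dy <- y - cy
    ri <- sqrt(dx^2 + dy^2)
    ok <- ri > 1e-9
    J <- cbind(-dx[ok] / ri[ok], -dy[ok] / ri[ok], -1)
    f <- ri[ok] - r
    step <- tryCatch(qr.coef(qr(J), -f), error = function(e) c(0, 0, 0))
    if (all(is.finite(step))) {
      cx <- cx + step[1L]; cy <- cy + step[2L]; r <- r + step[3L]
    }
  }
  list(center = c(x = unname(cx), y = unname(cy)), radius = unname(r),
       method = "kasa+gauss-newton")
}

#' Measure per-punctum radii and the mean ring diameter
#'
#' The radius of each punctum (or localization) is its distance to the ring
#' centre; the mean diameter is twice the mean radius. No noise-bias
#' correction is applied by default (the plain radial definition); with
#' `bias_correction = TRUE` the outward noise bias `sd^2 / r` is subtracted
#' from the mean diameter.
#'
#' @param pts data.frame with `x`, `y`: puncta centroids (default analysis
#'   level) or raw localizations.
#' @param center ring centre (x, y); fitted from `pts` when NULL.
#' @param bias_correction logical (default FALSE).
#' @return a `ring_fit`: list with `center`, `radii`, `mean_diameter`,
#'   `radius_sd`, `n_puncta`, `fit_method`.
#' @export
measure_diameter <- function(pts, center = NULL, bias_correction = FALSE) {
  method <- "given-center"
  if (is.null(center)) {
    fit <- fit_ring_center(pts)
    center <- fit$center
    method <- fit$method
  }
  radii <- sqrt((pts$x - center[1L])^2 + (pts$y - center[2L])^2)
  mean_d <- 2 * mean(radii)
  sd_r <- stats::sd(radii)
  if (bias_correction && mean(radii) > 0) {
    mean_d <- mean_d - 2 * sd_r^2 / (2 * mean(radii))
  }
  structure(list(center = center, radii = radii, mean_diameter = mean_d,
                 radius_sd = sd_r, n_puncta = length(radii),
                 fit_method = method),
            class = "ring_fit")
}

#' Polar angular occupancy of a ring
#'
#' Localizations inside an annulus around the fitted radius are unwrapped to
#' polar angle and binned; a bin is occupied when its count reaches the
#' occupancy threshold. Completeness is the fraction of occupied bins;
#' contiguous unoccupied runs are reported as gap arcs.
#'
#' @param tab localization table or data.frame with `x`, `y`
#'   (single channel).
#' @param center ring centre (x, y).
#' @param bin_width angular bin width in radians (default 10 degrees).
#' @param occupancy_threshold minimum count for an occupied bin; default
#'   `max(3, 0.1 * median nonzero-bin count)`.
#' @param annulus length-2 radial gate in nm; default
#'   `fitted radius +/- 3 * radius sd` computed from the data.
#' @return an `angular_occupancy`: list with `bin_width`, `counts`,
#'   `occupied`, `completeness`, `missing_fraction`, `gap_arcs`
#'   (data.frame of start/end radians and width), `n_localizations`,
#'   `threshold`.
#' @export
angular_occupancy <- function(tab, center, bin_width = 10 * pi / 180,
                              occupancy_threshold = NULL, annulus = NULL) {
  dx <- tab$x - center[1L]
  dy <- tab$y - center[2L]
  r <- sqrt(dx^2 + dy^2)
  if (is.null(annulus)) {
    annulus <- mean(r) + c(-3, 3) * stats::sd(r)
  }
  sel <- r >= annulus[1L] & r <= annulus[2L]
  theta <- atan2(dy[sel], dx[sel]) %% (2 * pi)
  n_bins <- max(1L, round(2 * pi / bin_width))
  bin <- pmin(floor(theta / (2 * pi) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (is.null(occupancy_threshold)) {
    nz <- counts[counts > 0L]
    occupancy_threshold <- if (length(nz) == 0L) 3 else
      max(3, 0.1 * stats::median(nz))
  }
  occupied <- counts >= occupancy_threshold
  completeness <- mean(occupied)
  # contiguous unoccupied runs on the circle
  gaps <- data.frame(start = numeric(), end = numeric(), width = numeric())
  if (!all(occupied) && any(occupied)) {
    occ2 <- rep(occupied, 2L)
    starts <- which(!occ2 & c(TRUE, occ2[-length(occ2)]))
    starts <- starts[starts <= n_bins]
    for (s in starts) {
      len <- 0L
      while (!occ2[s + len]) len <- len + 1L
      gaps <- rbind(gaps, data.frame(
        start = (s - 1L) * 2 * pi / n_bins,
        end = ((s - 1L + len) %% n_bins) * 2 * pi / n_bins,
        width = len * 2 * pi / n_bins))
    }
  } else if (!any(occupied)) {
    gaps <- data.frame(start = 0, end = 0, width = 2 * pi)
  }
  structure(list(bin_width = 2 * pi / n_bins, counts = counts,
                 occupied = occupied, completeness = completeness,
                 missing_fraction = 1 - completeness, gap_arcs = gaps,
                 n_localizations = sum(sel),
                 threshold = occupancy_threshold),
            class = "angular_occupancy")
}

#' Puncta count and nine-fold symmetry score
#'
#' The mode-9 power ratio is `|sum_j exp(i 9 theta_j)|^2 / n^2` over the
#' punctum angles: 1 for perfect nine-fold placement, expectation `1/n`
#' under uniformly random angles.
#'
#' @param puncta data.frame of punctum centroids (`x`, `y`).
#' @param center ring centre (x, y).
#' @param mode harmonic to score (default 9).
#' @return list with `n_puncta` and `mode_ratio`.
#' @export
symmetry_score <- function(puncta, center, mode = 9L) {
  n <- nrow(puncta)
  if (n < 1L) stop("at least one punctum is required")
  theta <- atan2(puncta$y - center[2L], puncta$x - center[1L])
  s <- sum(exp(1i * mode * theta))
  list(n_puncta = n, mode_ratio = as.numeric(Mod(s)^2 / n^2))
}

#' Compare radial spread between two groups of centrioles
#'
#' Two-sided Mann-Whitney U test on per-centriole radial standard
#' deviations (one value per centriole).
#'
#' @param sd_a,sd_b numeric vectors of per-centriole `radius_sd` values.
#' @return a `group_comparison` (see [compare_groups()]).
#' @export
radial_spread_stat <- function(sd_a, sd_b) {
  if (length(sd_a) < 3L || length(sd_b) < 3L) {
    stop("at least 3 centrioles per group are required")
  }
  compare_groups(sd_a, sd_b)
}

#' Full axial-view ring analysis of one channel
#'
#' Convenience pipeline: puncta clustering, circle fit, mean diameter,
#' angular occupancy and nine-fold symmetry in one call.
#'
#' @param tab localization table (single channel; subset first).
#' @param punctum_radius,min_count passed to [cluster_puncta()].
#' @param bin_width passed to [angular_occupancy()].
#' @return list with `puncta`, `ring` (a `ring_fit` on puncta),
#'   `ring_localizations` (a `ring_fit` on raw localizations),
#'   `occupancy`, `symmetry`.
#' @export
analyze_ring <- function(tab, punctum_radius = 20, min_count = 5L,
                         bin_width = 10 * pi / 180) {
  puncta <- cluster_puncta(tab, radius = punctum_radius,
                           min_count = min_count)
  center <- if (nrow(puncta) >= 3L) {
    fit_ring_center(puncta)$center
  } else {
    fit_ring_center(tab)$center
  }
  ring <- measure_diameter(puncta, center)
  ring_loc <- measure_diameter(data.frame(x = tab$x, y = tab$y), center)
  occ <- angular_occupancy(tab, center)
  sym <- symmetry_score(puncta, center)
  list(puncta = puncta, ring = ring, ring_localizations = ring_loc,
       occupancy = occ, symmetry = sym)
}
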