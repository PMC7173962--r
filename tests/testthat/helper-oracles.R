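# independent brute-force oracles shared across test files

# circle-fit oracle: minimize the variance of point radii over a center
# lattice (0.5 nm step) around the centroid
grid_search_center <- function(pts, step = 0.5) {
  search <- function(cx0, cy0, span, by) {
    gx <- seq(cx0 - span, cx0 + span, by = by)
    gy <- seq(cy0 - span, cy0 + span, by = by)
    best <- c(NA, NA); best_v <- Inf
    for (cx in gx) {
      dx2 <- (pts$x - cx)^2
      for (cy in gy) {
        r <- sqrt(dx2 + (pts$y - cy)^2)
        v <- stats::var(r)
        if (v < best_v) { best_v <- v; best <- c(cx, cy) }
      }
    }
    best
  }
  # coarse pass over a wide area (partial arcs put the centroid far from
  # the centre), then the 0.5 nm lattice around the coarse optimum
  coarse <- search(mean(pts$x), mean(pts$y), span = 400, by = 10)
  search(coarse[1], coarse[2], span = 12, by = step)
}

# layer-count oracle: local maxima of the exact two-Gaussian mixture after
# the same kernel/bin smoothing, with the same separation/prominence rules
mixture_layer_count <- function(sep, sd, kernel_sd = 8.5, bin = 10,
                                min_separation = 50, min_prominence = 0.2) {
  s_eff <- sqrt(sd^2 + kernel_sd^2 + bin^2 / 12)
  grid <- seq(-sep, sep, by = 0.1)
  dens <- 0.5 * dnorm(grid, -sep / 2, s_eff) +
    0.5 * dnorm(grid, sep / 2, s_eff)
  n <- length(dens)
  ismax <- c(FALSE, dens[2:(n - 1)] > dens[1:(n - 2)] &
               dens[2:(n - 1)] >= dens[3:n], FALSE)
  peaks <- grid[ismax]
  if (length(peaks) < 2L) return(length(peaks))
  peaks <- range(peaks)
  heights <- stats::approx(grid, dens, peaks)$y
  # the valley between the two exact-mixture peaks sits at zero; the second
  # layer counts only if it clears the prominence and separation rules
  valley <- dens[which.min(abs(grid))]
  if (min(heights) - valley < min_prominence * max(dens)) return(1L)
  if (diff(peaks) < min_separation) return(1L)
  2L
}

# exact two-sided permutation distribution of the Mann-Whitney U statistic
perm_p_value <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
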