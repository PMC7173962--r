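# axial-view ring quantification and its independent oracles

# tiny union-find over an adjacency matrix (oracle for linkage grouping)
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(lab[adj[i, ]])
      if (m < lab[i]) { lab[lab == lab[i]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}


test_that("puncta clustering recovers well-separated clusters exactly", {
  set.seed(41)
  centers <- circle_points(100, 2 * pi * (0:8) / 9)
  pts <- data.frame(
    x = rep(centers$x, each = 50) + rnorm(450, 0, 4),
    y = rep(centers$y, each = 50) + rnorm(450, 0, 4))
  puncta <- cluster_puncta(pts, radius = 20, min_count = 5)
  expect_equal(nrow(puncta), 9L)
  ord <- order(atan2(puncta$y, puncta$x))
  ord_t <- order(atan2(centers$y, centers$x))
  expect_lt(max(abs(puncta$x[ord] - centers$x[ord_t])), 3)
})

test_that("two clusters within the grouping radius merge into one punctum", {
  set.seed(42)
  pts <- data.frame(x = c(rnorm(40, 0, 2), rnorm(40, 15, 2)),
                    y = rnorm(80, 0, 2))
  merged <- cluster_puncta(pts, radius = 20, min_count = 5)
  expect_equal(nrow(merged), 1L)
  # brute-force single-linkage oracle on pairwise distances agrees
  d <- as.matrix(dist(pts))
  g <- igraph_free_components(d <= 20)
  expect_equal(length(unique(g)), 1L)
})

test_that("sparse background below the density threshold is an error", {
  set.seed(43)
  pts <- data.frame(x = runif(30, -1000, 1000), y = runif(30, -1000, 1000))
  expect_error(cluster_puncta(pts, radius = 20, min_count = 5), "threshold")
})

test_that("the circle fit is exact on symmetric points and rejects lines", {
  pts <- data.frame(x = c(100, -100, 0, 0), y = c(0, 0, 100, -100))
  fit <- fit_ring_center(pts)
  expect_equal(unname(fit$center), c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 100, tolerance = 1e-9)
  expect_error(fit_ring_center(data.frame(x = 1:5, y = 2 * (1:5) + 1)),
               "collinear|degenerate")
})

test_that("the circle fit matches the brute-force grid oracle on noisy rings", {
  set.seed(44)
  for (case in 1:6) {
    r0 <- runif(1, 80, 300)
    arc <- runif(1, 0.5, 1) * 2 * pi
    theta <- runif(200, 0, arc)
    pts <- data.frame(x = r0 * cos(theta) + rnorm(200, 0, 8.5),
                      y = r0 * sin(theta) + rnorm(200, 0, 8.5))
    fit <- fit_ring_center(pts, trim = FALSE)
    oracle <- grid_search_center(pts)
    expect_lt(sqrt(sum((fit$center - oracle)^2)), 2)
  }
})

test_that("a noiseless half-ring still yields the exact center", {
  theta <- seq(0, pi, length.out = 100)
  pts <- circle_points(120, theta, center = c(30, -40))
  fit <- fit_ring_center(pts)
  expect_equal(unname(fit$center), c(30, -40), tolerance = 1e-6)
  expect_equal(fit$radius, 120, tolerance = 1e-6)
})

test_that("mean diameter is twice the mean punctum radius, exactly when noiseless", {
  pts <- circle_points(100, 2 * pi * (0:8) / 9)
  ring <- measure_diameter(pts, center = c(0, 0))
  expect_equal(ring$mean_diameter, 200)
  expect_equal(ring$n_puncta, 9L)
  expect_equal(ring$mean_diameter, 2 * mean(ring$radii))
})

test_that("angular occupancy is exact for full rings and clean gaps", {
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  full <- circle_points(150, theta)
  occ <- angular_occupancy(full, center = c(0, 0), annulus = c(140, 160))
  expect_equal(occ$completeness, 1.0)
  # gap aligned with 10-degree bin edges: 40 to 130 degrees
  gap <- circle_points(150, theta[!(theta >= 40 * pi / 180 &
                                      theta < 130 * pi / 180)])
  occ2 <- angular_occupancy(gap, center = c(0, 0), annulus = c(140, 160))
  expect_equal(occ2$completeness, 0.75)
  expect_equal(occ2$missing_fraction, 0.25)
  expect_equal(nrow(occ2$gap_arcs), 1L)
  expect_equal(occ2$gap_arcs$width, pi / 2, tolerance = 1e-9)
})

test_that("completeness is non-increasing in the injected gap measure", {
  missing <- c(0, 0.2, 0.4, 0.6)
  comp <- vapply(missing, function(g) {
    m <- make_ring_model(radius = 150, radial_sd = 0, localization_sd = 0,
                         n_emitters = 1500L, occupancy = 1 - g)
    tab <- simulate_centriole(m, seed = 45)$table
    angular_occupancy(tab, c(0, 0), annulus = c(140, 160))$completeness
  }, 0)
  expect_true(all(diff(comp) <= 0))
})

test_that("nine perfect puncta score count 9 and mode-9 ratio 1", {
  pts <- circle_points(125, 2 * pi * (0:8) / 9 + 0.3)
  sym <- symmetry_score(pts, center = c(0, 0))
  expect_equal(sym$n_puncta, 9L)
  expect_equal(sym$mode_ratio, 1.0, tolerance = 1e-12)
})

test_that("uniform random angles give a mean mode-9 ratio near 1/9", {
  set.seed(46)
  ratios <- replicate(1000, {
    pts <- circle_points(125, runif(9, 0, 2 * pi))
    symmetry_score(pts, center = c(0, 0))$mode_ratio
  })
  expect_lt(abs(mean(ratios) - 1 / 9), 0.02)
})

test_that("5-degree angular jitter attenuates the mode-9 ratio as predicted", {
  # von-Mises/Gaussian attenuation: E[ratio] ~ rho^2 + (1 - rho^2)/9 with
  # rho = exp(-(9 * sd)^2 / 2)
  sd <- 5 * pi / 180
  rho <- exp(-(9 * sd)^2 / 2)
  expected <- rho^2 + (1 - rho^2) / 9
  set.seed(47)
  ratios <- replicate(2000, {
    pts <- circle_points(125, 2 * pi * (0:8) / 9 + rnorm(9, 0, sd))
    symmetry_score(pts, center = c(0, 0))$mode_ratio
  })
  expect_gt(expected, 0.5)
  expect_lt(abs(mean(ratios) - expected), 0.02)
})

test_that("ring statistics are invariant under rigid transforms", {
  m <- build_model_from_paper("wild_type")
  tab <- simulate_centriole(m, seed = 48)$table
  sub <- tab[tab$channel == "CEP128", ]
  a <- analyze_ring(sub)
  phi <- 0.7; shift <- c(350, -120)
  rot <- data.frame(x = cos(phi) * sub$x - sin(phi) * sub$y + shift[1],
                    y = sin(phi) * sub$x + cos(phi) * sub$y + shift[2])
  rot$channel <- sub$channel
  b <- analyze_ring(rot)
  expect_equal(b$ring$mean_diameter, a$ring$mean_diameter, tolerance = 1e-6)
  expect_equal(nrow(b$puncta), nrow(a$puncta))
  expect_equal(b$occupancy$completeness, a$occupancy$completeness)
  expect_equal(b$symmetry$mode_ratio, a$symmetry$mode_ratio,
               tolerance = 1e-6)
})

test_that("radial-spread comparison behaves under identity and label swap", {
  expect_error(radial_spread_stat(c(1, 2), c(1, 2, 3)), "3")
  a <- c(10, 12, 14, 11, 13); b <- c(20, 24, 22, 26, 21)
  r1 <- radial_spread_stat(a, b)
  r2 <- radial_spread_stat(b, a)
  expect_equal(r1$p_value, r2$p_value)
  same <- radial_spread_stat(a, a)
  expect_gt(same$p_value, 0.9)
})

test_that("wider generative radial spread is detected between conditions", {
  diam_sd <- function(preset, seeds) {
    m <- build_model_from_paper(preset)
    vapply(seeds, function(s) {
      tab <- simulate_centriole(m, seed = s)$table
      sub <- tab[tab$channel == "CEP170", ]
      ctr <- fit_ring_center(sub)$center
      r <- sqrt((sub$x - ctr[1])^2 + (sub$y - ctr[2])^2)
      measure_diameter(sub[r < 600, ], ctr)$radius_sd  # drop far background
    }, 0)
  }
  plus <- diam_sd("FBS_plus", 1:10)       # radial sd doubled
  minus <- diam_sd("FBS_minus", 11:20)
  cmp <- radial_spread_stat(plus, minus)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(mean(plus), mean(minus))
})
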