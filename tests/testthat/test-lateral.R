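# lateral-view analyses: view classification, axis estimation, longitudinal
# profiling, layer detection (with its exact-mixture oracle), composites,
# ROI densities and the distal-boundary statistic

lateral_wt <- function(seed) {
  m <- build_model_from_paper("wild_type", view = "lateral")
  simulate_centriole(m, seed = seed)$table
}

wt_axis <- function(tab) {
  estimate_axis(tab[tab$channel == "SCLT1", ],
                tab[tab$channel == "CP110", ])
}

test_that("view classification separates rings, rods and blobs", {
  m <- build_model_from_paper("wild_type")
  tab <- simulate_centriole(m, seed = 51)$table
  sclt1 <- tab[tab$channel == "SCLT1", ]
  expect_equal(classify_view(sclt1), "axial")
  lat <- lateral_wt(51)
  expect_equal(classify_view(lat[lat$channel == "SCLT1", ]), "lateral")
  # constructed cloud with an eigenvalue ratio of exactly 2
  set.seed(52)
  blob <- data.frame(x = rnorm(500, 0, sqrt(2) * 20), y = rnorm(500, 0, 20))
  blob$x <- blob$x * (20 * sqrt(2) / sd(blob$x))
  blob$y <- blob$y * (20 / sd(blob$y))
  expect_equal(classify_view(blob), "ambiguous")
  expect_error(classify_view(blob[1:10, ]), "50")
})

test_that("axis estimation needs an orientation marker or flag", {
  lat <- lateral_wt(53)
  ref <- lat[lat$channel == "SCLT1", ]
  expect_error(estimate_axis(ref), "marker|orientation")
  ax <- estimate_axis(ref, orientation = "+")
  expect_equal(sqrt(sum(ax$direction^2)), 1)
})

test_that("signed longitudinal positions are invariant to pose rotation", {
  m <- build_model_from_paper("wild_type", view = "lateral")
  m$rotation <- 37 * pi / 180
  tab_rot <- simulate_centriole(m, seed = 54)$table
  m$rotation <- 0
  tab <- simulate_centriole(m, seed = 54)$table
  pos <- function(t) {
    ax <- wt_axis(t)
    prof <- detect_layers(longitudinal_profile(t[t$channel == "CEP128", ], ax))
    prof$layers$position
  }
  expect_equal(pos(tab_rot), pos(tab), tolerance = 2)
})

test_that("the CEP128 layer projects ~160 nm proximal to SCLT1", {
  offsets <- vapply(1:5, function(s) {
    tab <- lateral_wt(s)
    ax <- wt_axis(tab)
    prof <- detect_layers(longitudinal_profile(tab[tab$channel == "CEP128", ],
                                               ax))
    prof$layers$position[1L]
  }, 0)
  expect_lt(abs(mean(offsets) - (-160)), 15)
})

test_that("profiles conserve localization mass", {
  tab <- lateral_wt(55)
  ax <- wt_axis(tab)
  sub <- tab[tab$channel == "ODF2", ]
  prof <- longitudinal_profile(sub, ax)
  expect_equal(sum(prof$density) * prof$bin_width, nrow(sub))
  expect_equal(prof$n, nrow(sub))
})

test_that("a target identical to the reference sits in a single layer at 0", {
  tab <- lateral_wt(56)
  ref <- tab[tab$channel == "SCLT1", ]
  ax <- wt_axis(tab)
  prof <- detect_layers(longitudinal_profile(ref, ax))
  expect_equal(nrow(prof$layers), 1L)
  expect_lt(abs(prof$layers$position), 10)
})

test_that("layer detection matches the exact-mixture oracle across a sweep", {
  set.seed(57)
  for (sep in c(40, 80, 100, 140)) {
    for (sd in c(15, 20, 25)) {
      want <- mixture_layer_count(sep, sd)
      u <- c(rnorm(10000, -sep / 2, sd), rnorm(10000, sep / 2, sd))
      ax <- structure(list(origin = c(x = 0, y = 0), direction = c(0, 1),
                           view = "lateral"), class = "centriole_axis")
      tab <- data.frame(x = rnorm(20000, 0, 30), y = u)
      prof <- detect_layers(longitudinal_profile(tab, ax))
      expect_equal(nrow(prof$layers), want,
                   info = sprintf("sep=%d sd=%d", sep, sd))
    }
  }
})

test_that("dual Gaussian layers well apart are localized at their means", {
  set.seed(58)
  u <- c(rnorm(5000, -200, 20), rnorm(5000, -100, 20))
  ax <- structure(list(origin = c(x = 0, y = 0), direction = c(0, 1),
                       view = "lateral"), class = "centriole_axis")
  prof <- detect_layers(longitudinal_profile(data.frame(x = 0, y = u), ax))
  expect_equal(nrow(prof$layers), 2L)
  expect_equal(prof$layers$position, c(-200, -100), tolerance = 3)
})

test_that("composites add counts and reproduce per-centriole layer positions", {
  tab <- lateral_wt(59)
  ax <- wt_axis(tab)
  one <- align_and_composite(list(list(table = tab, axis = ax)))
  expect_equal(one$n_centrioles, 1L)
  # m identical copies scale the histogram exactly
  three <- align_and_composite(rep(list(list(table = tab, axis = ax)), 3L))
  for (ch in names(one$channels)) {
    expect_equal(three$channels[[ch]], 3 * one$channels[[ch]])
  }
  # composite of several seeds: CEP128 layer from the summed histogram
  # matches the mean of per-centriole estimates within 10 nm
  entries <- lapply(1:8, function(s) {
    t <- lateral_wt(s)
    list(table = t, axis = wt_axis(t))
  })
  comp <- align_and_composite(entries)
  img <- comp$channels[["CEP128"]]
  prof_y <- rowSums(img)
  centers <- seq(comp$ylim[1] + comp$pixel_nm / 2, by = comp$pixel_nm,
                 length.out = nrow(img))
  fake_prof <- structure(list(bin_centers = centers,
                              density = prof_y / comp$pixel_nm,
                              bin_width = comp$pixel_nm,
                              n = sum(prof_y), projections = NULL,
                              layers = NULL),
                         class = "longitudinal_profile")
  comp_layer <- detect_layers(fake_prof)$layers$position[1L]
  per_centriole <- vapply(entries, function(e) {
    prof <- detect_layers(longitudinal_profile(
      e$table[e$table$channel == "CEP128", ], e$axis))
    prof$layers$position[1L]
  }, 0)
  expect_lt(abs(comp_layer - mean(per_centriole)), 10)
})

test_that("ROI densities partition and conserve counts", {
  tab <- lateral_wt(60)
  ax <- wt_axis(tab)
  sub <- tab[tab$channel == "CEP128", ]
  all_roi <- roi_density(sub, ax, c(-5000, 5000), c(0, 5000))
  expect_equal(all_roi$count, nrow(sub))
  left <- roi_density(sub, ax, c(-5000, -160), c(0, 5000))
  right <- roi_density(sub, ax, c(-160 + 1e-9, 5000), c(0, 5000))
  expect_equal(left$count + right$count, nrow(sub))  # disjoint ROIs partition
  empty <- roi_density(sub, ax, c(4000, 5000), c(0, 100))
  expect_equal(empty$count, 0L)
  expect_equal(empty$density, 0)
})

test_that("the distal boundary matches the closed-form quantile", {
  # exact uniform density on [-400, -100]: 0.95 quantile at -115
  centers <- seq(-395, -105, by = 10)
  prof <- structure(list(bin_centers = centers,
                         density = rep(1, length(centers)),
                         bin_width = 10, n = 300, projections = NULL,
                         layers = NULL),
                    class = "longitudinal_profile")
  expect_equal(distal_boundary(prof, 0.95), -115)
  expect_equal(distal_boundary(prof, 0.5), -250)
})

test_that("gamma-tubulin is confined distally by the sDAP level in wild type", {
  m <- build_model_from_paper("gamma_tubulin", view = "lateral")
  bounds <- vapply(1:5, function(s) {
    tab <- simulate_centriole(m, seed = s)$table
    ax <- wt_axis(tab)
    distal_boundary(longitudinal_profile(
      tab[tab$channel == "gamma_tubulin", ], ax))
  }, 0)
  expect_true(all(bounds <= -150 + 30))
})
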