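# compact model builders used across the suite

make_ring_model <- function(radius = 150, radial_sd = 12, n_emitters = 300L,
                            occupancy = 1, n_clusters = 0L,
                            cluster_angular_sd = 0, localization_sd = 8.5,
                            protein = "target", view = "axial", z = -150,
                            axial_sd = 15, background = 0, ...) {
  ground_truth_model(
    layers = list(layer_spec(protein, radius, z, axial_sd = axial_sd,
                             radial_sd = radial_sd,
                             occupancy_fraction = occupancy,
                             n_clusters = n_clusters,
                             cluster_angular_sd = cluster_angular_sd,
                             n_emitters = n_emitters,
                             labeling_efficiency = 1)),
    view = view, localization_sd = localization_sd,
    background_density = background, ...
  )
}

noiseless_ring_model <- function(radius = 100, n_emitters = 200L, ...) {
  make_ring_model(radius = radius, radial_sd = 0, n_emitters = n_emitters,
                  localization_sd = 0, axial_sd = 0, background = 0, ...)
}

# circle points at given angles
circle_points <- function(radius, angles, center = c(0, 0)) {
  data.frame(x = center[1] + radius * cos(angles),
             y = center[2] + radius * sin(angles))
}
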