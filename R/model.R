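#' Specify one protein layer of the centriole model
#'
#' A layer is a circular locus of labelled protein: a ring of given radius at
#' a signed longitudinal position along the centriole axis (reference DAP
#' layer = 0, proximal negative, distal positive). Layers may carry partial
#' angular occupancy (contiguous missing arcs) and discrete angular clusters
#' (nine-fold puncta).
#'
#' @param protein_name label, also used as the channel id of simulated rows.
#' @param ring_radius ring radius in nm (>= 0).
#' @param longitudinal_position signed position along the axis in nm.
#' @param axial_sd longitudinal spread (sd, nm) of emitters about the layer.
#' @param radial_sd radial spread (sd, nm) of emitters about the ring.
#' @param occupancy_fraction fraction of the circumference carrying emitters,
#'   in `[0, 1]`; the complement is removed as contiguous arcs.
#' @param n_gap_arcs number of contiguous missing arcs drawn when
#'   `occupancy_fraction < 1` (default 1).
#' @param n_clusters 0 for a continuous ring; k > 0 places emitters in k
#'   evenly spaced angular clusters (9 = nine-fold puncta).
#' @param cluster_angular_sd sd (radians) of each cluster centre about its
#'   ideal angular position.
#' @param n_emitters number of fluorophore-carrying sites on the layer.
#' @param labeling_efficiency fraction of emitters that are actually labelled.
#' @param axial_profile `"gaussian"` (default) or `"uniform"`; uniform spreads
#'   emitters over `longitudinal_position +/- axial_sd * sqrt(3)` (same sd).
#' @return list of class `protein_layer_spec`.
#' @export
layer_spec <- function(protein_name, ring_radius, longitudinal_position = 0,
                       axial_sd = 12, radial_sd = 10,
                       occupancy_fraction = 1, n_gap_arcs = 1L,
                       n_clusters = 0L, cluster_angular_sd = 0,
                       n_emitters = 72L, labeling_efficiency = 0.8,
                       axial_profile = c("gaussian", "uniform")) {
  stopifnot(ring_radius >= 0,
            occupancy_fraction >= 0, occupancy_fraction <= 1,
            n_gap_arcs >= 1L,
            n_clusters >= 0L, n_emitters >= 0L,
            labeling_efficiency >= 0, labeling_efficiency <= 1)
  structure(list(
    protein_name = protein_name,
    ring_radius = ring_radius,
    longitudinal_position = longitudinal_position,
    axial_sd = axial_sd,
    radial_sd = radial_sd,
    occupancy_fraction = occupancy_fraction,
    n_gap_arcs = as.integer(n_gap_arcs),
    n_clusters = as.integer(n_clusters),
    cluster_angular_sd = cluster_angular_sd,
    n_emitters = as.integer(n_emitters),
    labeling_efficiency = labeling_efficiency,
    axial_profile = match.arg(axial_profile)
  ), class = "protein_layer_spec")
}

#' Drift specification
#'
#' @param kind `"none"`, `"linear"` (constant nm/frame on each axis) or
#'   `"random_walk"` (per-frame Gaussian steps of the given sd).
#' @param rate_or_step nm per frame per axis.
#' @return list of class `drift_spec`.
#' @export
drift_spec <- function(kind = c("none", "linear", "random_walk"),
                       rate_or_step = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rate_or_step = rate_or_step),
            class = "drift_spec")
}

#' Chromatic distortion specification
#'
#' Second-order 2D polynomial mapping true coordinates to the distorted
#' short-wavelength channel: for each axis six coefficients ordered as
#' `(1, x, y, x^2, x*y, y^2)`. The identity has x-coefficients
#' `(0,1,0,0,0,0)` and y-coefficients `(0,0,1,0,0,0)`.
#'
#' @param coef_x,coef_y numeric length-6 coefficient vectors.
#' @return list of class `chromatic_spec`.
#' @export
chromatic_spec <- function(coef_x = c(0, 1, 0, 0, 0, 0),
                           coef_y = c(0, 0, 1, 0, 0, 0)) {
  stopifnot(length(coef_x) == 6L, length(coef_y) == 6L)
  structure(list(coef_x = as.numeric(coef_x), coef_y = as.numeric(coef_y)),
            class = "chromatic_spec")
}

#' @rdname chromatic_spec
#' @param spec a `chromatic_spec`.
#' @param x,y coordinates to transform.
#' @return `poly2_eval`: data.frame with transformed `x`, `y`.
#' @export
poly2_eval <- function(spec, x, y) {
  d <- cbind(1, x, y, x^2, x * y, y^2)
  data.frame(x = as.numeric(d %*% spec$coef_x),
             y = as.numeric(d %*% spec$coef_y))
}

is_identity_chromatic <- function(spec) {
  isTRUE(all.equal(spec$coef_x, c(0, 1, 0, 0, 0, 0))) &&
    isTRUE(all.equal(spec$coef_y, c(0, 0, 1, 0, 0, 0)))
}

#' Microtubule fiber bundle specification
#'
#' Straight fiber segments with one endpoint (the anchor) on a circular locus
#' of the centriole: at `anchor_radius` from the centre (axial view) or at
#' `(anchor_longitudinal, +/- anchor_radius)` in a lateral view.
#'
#' @param n_fibers number of fibers (>= 0).
#' @param anchor_radius anchor locus radius in nm.
#' @param anchor_longitudinal anchor longitudinal position in nm (lateral
#'   view only).
#' @param length_range min/max fiber length in nm.
#' @param angular_range total angular extent (radians) over which anchors are
#'   spread (axial view); anchors are evenly spaced over it, emulating
#'   fibers terminating at regularly arranged appendage positions.
#' @param angular_phase angular offset (radians) of the first anchor.
#' @param anchor_angular_jitter sd (radians) of each anchor about its even
#'   position.
#' @param linewidth_sd transverse scatter of fiber localizations (sd, nm).
#' @param emitter_spacing spacing of emitters along the fiber in nm.
#' @return list of class `fiber_spec`.
#' @export
fiber_spec <- function(n_fibers, anchor_radius, anchor_longitudinal = 0,
                       length_range = c(400, 1200), angular_range = 2 * pi,
                       angular_phase = 0, anchor_angular_jitter = 0.03,
                       linewidth_sd = 12, emitter_spacing = 15) {
  stopifnot(n_fibers >= 0L, anchor_radius >= 0,
            length(length_range) == 2L, length_range[1] <= length_range[2])
  structure(list(
    n_fibers = as.integer(n_fibers),
    anchor_radius = anchor_radius,
    anchor_longitudinal = anchor_longitudinal,
    length_range = as.numeric(length_range),
    angular_range = angular_range,
    angular_phase = angular_phase,
    anchor_angular_jitter = anchor_angular_jitter,
    linewidth_sd = linewidth_sd,
    emitter_spacing = emitter_spacing
  ), class = "fiber_spec")
}

#' Ground-truth model of one simulated centriole acquisition
#'
#' Bundles the per-protein layer geometry with the imaging parameters of the
#' emulated acquisition: localization precision, blinking statistics, frames,
#' background, drift, chromatic distortion and fiducial markers.
#'
#' @param layers list of [layer_spec()] objects.
#' @param view `"axial"` (looking down the centriole axis) or `"lateral"`.
#' @param rotation in-plane pose rotation in radians.
#' @param center (x, y) position of the centriole in the field, nm.
#' @param localization_sd isotropic localization precision (sd, nm);
#'   default 8.5 nm (a 20 nm FWHM resolution divided by 2.355).
#' @param mean_locs_per_emitter mean localizations per labelled emitter
#'   (geometric blinking law, support >= 1).
#' @param background_density uniform background localizations per um^2 per
#'   channel over the simulated field.
#' @param field_nm side length of the simulated square field, nm.
#' @param n_frames number of acquisition frames (paper regime 10,000-20,000).
#' @param drift a [drift_spec()].
#' @param chromatic a [chromatic_spec()] applied to short-wavelength channels.
#' @param short_channels channels distorted by `chromatic`.
#' @param fiducials matrix/data.frame of fiducial (x, y) positions in nm, or
#'   NULL.
#' @param fibers optional list of [fiber_spec()] objects.
#' @param focal_center,focal_depth axial-view focal slab: only layers with
#'   `longitudinal_position` within `focal_center +/- focal_depth/2` appear in
#'   an axial image (2D dSTORM images a finite focal slab; axial acquisitions
#'   are focused at the appendage level).
#' @return list of class `ground_truth_model`.
#' @export
ground_truth_model <- function(layers,
                               view = c("axial", "lateral"),
                               rotation = 0, center = c(0, 0),
                               localization_sd = 8.5,
                               mean_locs_per_emitter = 5,
                               background_density = 2,
                               field_nm = 2000,
                               n_frames = 10000L,
                               drift = drift_spec("none"),
                               chromatic = chromatic_spec(),
                               short_channels = character(),
                               fiducials = NULL,
                               fibers = NULL,
                               focal_center = -100,
                               focal_depth = 500) {
  stopifnot(n_frames >= 1L, localization_sd >= 0,
            mean_locs_per_emitter >= 1)
  if (!is.null(fiducials)) {
    fiducials <- as.matrix(fiducials)
    stopifnot(ncol(fiducials) == 2L)
  }
  structure(list(
    layers = layers,
    view = match.arg(view),
    rotation = rotation,
    center = as.numeric(center),
    localization_sd = localization_sd,
    mean_locs_per_emitter = mean_locs_per_emitter,
    background_density = background_density,
    field_nm = field_nm,
    n_frames = as.integer(n_frames),
    drift = drift,
    chromatic = chromatic,
    short_channels = short_channels,
    fiducials = fiducials,
    fibers = fibers,
    focal_center = focal_center,
    focal_depth = focal_depth
  ), class = "ground_truth_model")
}

#' Serialize / restore a ground-truth model as YAML
#'
#' Round-trips losslessly: `read_model_yaml(write_model_yaml(m, f))` restores
#' the model.
#'
#' @param model a [ground_truth_model()].
#' @param path YAML file path.
#' @return `write_model_yaml`: `path` invisibly; `read_model_yaml`: the model.
#' @export
write_model_yaml <- function(model, path) {
  enc <- unclass(model)
  enc$layers <- lapply(model$layers, unclass)
  enc$drift <- unclass(model$drift)
  enc$chromatic <- unclass(model$chromatic)
  if (!is.null(model$fibers)) enc$fibers <- lapply(model$fibers, unclass)
  if (!is.null(model$fiducials)) {
    enc$fiducials <- apply(model$fiducials, 1L, as.numeric, simplify = FALSE)
  }
  yaml::write_yaml(enc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  enc <- yaml::read_yaml(path)
  layers <- lapply(enc$layers, function(l) do.call(layer_spec, l))
  fibers <- if (!is.null(enc$fibers)) {
    lapply(enc$fibers, function(f) do.call(fiber_spec, f))
  }
  fiducials <- if (!is.null(enc$fiducials)) {
    do.call(rbind, lapply(enc$fiducials, as.numeric))
  }
  ground_truth_model(
    layers = layers, view = enc$view, rotation = enc$rotation,
    center = enc$center, localization_sd = enc$localization_sd,
    mean_locs_per_emitter = enc$mean_locs_per_emitter,
    background_density = enc$background_density, field_nm = enc$field_nm,
    n_frames = enc$n_frames,
    drift = do.call(drift_spec, enc$drift),
    chromatic = do.call(chromatic_spec, enc$chromatic),
    short_channels = as.character(unlist(enc$short_channels)),
    fiducials = fiducials, fibers = fibers,
    focal_center = enc$focal_center, focal_depth = enc$focal_depth
  )
}
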