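#' Packaged centriole geometry presets
#'
#' Builds a fully populated [ground_truth_model()] whose layer table encodes
#' the measured architecture of the mother-centriole appendages: ring
#' diameters from axial-view imaging (ODF2 near the ~200 nm centriole wall,
#' CEP128 ~250 nm, ninein/CEP170 at ~600 nm), longitudinal positions relative
#' to the SCLT1 DAP layer (CEP128 at -160 nm; ODF2 dual layers at -100 and
#' -200 nm; ninein/CEP170 split between the sDAP region and the proximal end,
#' ~350 nm apart), and knockout phenotypes (CEP128 loss: single thinned ODF2
#' layer shifted proximally, proximal CEP89 layer absent, gamma-tubulin
#' released distally; CEP83 loss: single ODF2 layer, ninein broadened towards
#' the distal end).
#'
#' @param preset_name one of `"wild_type"`, `"CEP128_KO"`, `"CEP83_KO"`,
#'   `"FBS_plus"`, `"FBS_minus"`, `"gamma_tubulin"`, `"fibers_WT"`,
#'   `"fibers_KO"`.
#' @param view `"axial"` or `"lateral"` pose of the returned model.
#' @return a [ground_truth_model()].
#' @export
build_model_from_paper <- function(preset_name, view = c("axial", "lateral")) {
  view <- match.arg(view)
  presets <- c("wild_type", "CEP128_KO", "CEP83_KO", "FBS_plus", "FBS_minus",
               "gamma_tubulin", "fibers_WT", "fibers_KO")
  if (!is.character(preset_name) || length(preset_name) != 1L ||
      !(preset_name %in% presets)) {
    stop("unknown preset '", paste(preset_name, collapse = ","),
         "'; available presets: ", paste(presets, collapse = ", "))
  }

  deg <- pi / 180

  # reference and orientation markers shared by most presets
  sclt1 <- layer_spec("SCLT1", ring_radius = 225, longitudinal_position = 0,
                      axial_sd = 12, radial_sd = 12,
                      n_clusters = 9L, cluster_angular_sd = 3 * deg,
                      n_emitters = 108L)
  cp110 <- layer_spec("CP110", ring_radius = 75, longitudinal_position = 80,
                      axial_sd = 10, radial_sd = 10, n_emitters = 40L)

  layers <- switch(preset_name,
    wild_type = list(
      sclt1, cp110,
      # dual ODF2 layers flanking the sDAP root, ring at the centriole wall;
      # blades are compact enough for dSTORM to resolve all nine at this
      # small radius
      layer_spec("ODF2", 100, -100, axial_sd = 15, radial_sd = 5,
                 n_clusters = 9L, cluster_angular_sd = 2 * deg,
                 n_emitters = 72L),
      layer_spec("ODF2", 100, -200, axial_sd = 15, radial_sd = 5,
                 n_clusters = 9L, cluster_angular_sd = 2 * deg,
                 n_emitters = 72L),
      # CEP128: one compact layer between the ODF2 layers
      layer_spec("CEP128", 125, -160, axial_sd = 12, radial_sd = 10,
                 n_clusters = 9L, cluster_angular_sd = 5 * deg,
                 n_emitters = 72L),
      layer_spec("centriolin", 140, -130, axial_sd = 18, radial_sd = 12,
                 n_clusters = 9L, cluster_angular_sd = 5 * deg,
                 n_emitters = 72L),
      # ninein: sDAP-tip ring (largest radius) plus proximal-end population
      layer_spec("ninein", 300, -150, axial_sd = 35, radial_sd = 25,
                 n_emitters = 48L),
      layer_spec("ninein", 120, -500, axial_sd = 30, radial_sd = 20,
                 n_emitters = 48L),
      layer_spec("CEP170", 300, -150, axial_sd = 35, radial_sd = 25,
                 n_emitters = 48L),
      layer_spec("CEP170", 120, -500, axial_sd = 30, radial_sd = 20,
                 n_emitters = 48L),
      # CEP89: dual layers, distal (DAP) and proximal (sDAP region)
      layer_spec("CEP89", 190, 30, axial_sd = 12, radial_sd = 12,
                 n_clusters = 9L, cluster_angular_sd = 4 * deg,
                 n_emitters = 60L),
      layer_spec("CEP89", 190, -120, axial_sd = 12, radial_sd = 12,
                 n_clusters = 9L, cluster_angular_sd = 4 * deg,
                 n_emitters = 60L),
      layer_spec("CNAP1", 100, -500, axial_sd = 20, radial_sd = 12,
                 n_emitters = 60L)
    ),
    CEP128_KO = list(
      sclt1, cp110,
      # single thinned ODF2 layer, shifted proximally from the -100 nm layer
      layer_spec("ODF2", 100, -120, axial_sd = 10, radial_sd = 8,
                 n_clusters = 9L, cluster_angular_sd = 5 * deg,
                 n_emitters = 72L),
      # proximal CEP89 layer absent; distal (DAP) layer retained
      layer_spec("CEP89", 190, 30, axial_sd = 12, radial_sd = 12,
                 n_clusters = 9L, cluster_angular_sd = 4 * deg,
                 n_emitters = 60L),
      # sDAP-dependent ninein population lost; proximal-end one retained
      layer_spec("ninein", 120, -500, axial_sd = 30, radial_sd = 20,
                 n_emitters = 48L),
      # gamma-tubulin released from its sDAP distal constraint
      layer_spec("gamma_tubulin", 200, -250, axial_sd = 130, radial_sd = 30,
                 n_emitters = 200L)
    ),
    CEP83_KO = list(
      cp110,  # DAPs (SCLT1) lost; CP110 distal cap remains as reference
      layer_spec("CEP128", 125, -160, axial_sd = 12, radial_sd = 10,
                 n_clusters = 9L, cluster_angular_sd = 5 * deg,
                 n_emitters = 72L),
      # distal (DAP-dependent) ODF2 layer absent
      layer_spec("ODF2", 100, -200, axial_sd = 15, radial_sd = 10,
                 n_clusters = 9L, cluster_angular_sd = 5 * deg,
                 n_emitters = 72L),
      # ninein broadened and shifted towards the distal end
      layer_spec("ninein", 300, -80, axial_sd = 70, radial_sd = 30,
                 n_emitters = 48L),
      layer_spec("ninein", 120, -500, axial_sd = 30, radial_sd = 20,
                 n_emitters = 48L)
    ),
    FBS_plus = list(
      sclt1, cp110,
      # proliferating cells: half the CEP128 ring occupancy missing,
      # CEP170 radial spread doubled
      layer_spec("CEP128", 125, -160, axial_sd = 12, radial_sd = 10,
                 occupancy_fraction = 0.5, n_emitters = 250L),
      layer_spec("CEP170", 300, -150, axial_sd = 35, radial_sd = 50,
                 n_emitters = 48L)
    ),
    FBS_minus = list(
      sclt1, cp110,
      # serum-starved G0: a quarter of the ring occupancy missing
      layer_spec("CEP128", 125, -160, axial_sd = 12, radial_sd = 10,
                 occupancy_fraction = 0.75, n_emitters = 250L),
      layer_spec("CEP170", 300, -150, axial_sd = 35, radial_sd = 25,
                 n_emitters = 48L)
    ),
    gamma_tubulin = list(
      sclt1, cp110,
      # cylindrical cloud, ~400 nm across, longitudinally confined between
      # the proximal end and the sDAP level
      layer_spec("gamma_tubulin", 200, -350, axial_sd = 100, radial_sd = 30,
                 n_emitters = 200L)
    ),
    fibers_WT = list(sclt1, cp110),
    fibers_KO = list(sclt1, cp110)
  )

  fibers <- switch(preset_name,
    fibers_WT = list(
      fiber_spec(9L, anchor_radius = 320, anchor_longitudinal = -150),
      fiber_spec(4L, anchor_radius = 200, anchor_longitudinal = -20,
                 angular_range = 2 * pi * 4 / 9, angular_phase = 20 * deg)
    ),
    fibers_KO = list(
      # sDAP-anchored subset lost; DAP-associated fibers unaffected
      fiber_spec(4L, anchor_radius = 200, anchor_longitudinal = -20,
                 angular_range = 2 * pi * 4 / 9, angular_phase = 20 * deg)
    ),
    NULL
  )

  ground_truth_model(layers = layers, view = view, fibers = fibers,
                     short_channels = "SCLT1")
}
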