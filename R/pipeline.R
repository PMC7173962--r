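# End-to-end pipeline: simulate (or read) -> correct -> classify ->
# ring / lateral analyses -> phenotype flags -> JSON report. Fully
# deterministic given the config and its seed.

#' Phenotype flags from per-channel layer detections
#'
#' Translates layer counts and positions into the qualitative readouts used
#' to describe knockout phenotypes: a single remaining ODF2 layer and the
#' loss of the proximal CEP89 layer.
#'
#' @param layer_positions named list: for each channel, numeric vector of
#'   detected layer positions (nm, reference = 0).
#' @param proximal_limit positions below this count as a proximal CEP89
#'   layer (default -60 nm).
#' @return character vector of flags (possibly empty).
#' @export
phenotype_flags <- function(layer_positions, proximal_limit = -60) {
  flags <- character()
  if ("ODF2" %in% names(layer_positions) &&
      length(layer_positions$ODF2) == 1L) {
    flags <- c(flags, "single ODF2 layer")
  }
  if ("CEP89" %in% names(layer_positions) &&
      !any(layer_positions$CEP89 < proximal_limit)) {
    flags <- c(flags, "proximal CEP89 layer absent")
  }
  flags
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: simulate the configured preset (one or more centrioles), apply
#' drift and chromatic corrections when the model carries them, classify the
#' view, run the axial ring analyses or the lateral longitudinal analyses,
#' derive phenotype flags, and assemble a JSON-serializable report. Any
#' stage error is propagated with its stage name.
#'
#' @param config a named list or path to a YAML file. Mandatory fields:
#'   `seed`, `preset`. Optional: `view` ("axial"/"lateral", default axial),
#'   `n_centrioles` (default 1), `reference_channel` (default "SCLT1"),
#'   `marker_channel` (default "CP110"), `target_channels` (default: all
#'   simulated non-reference channels).
#' @param out_path optional path for the JSON report.
#' @return the report (list), invisibly when `out_path` is given.
#' @export
run_pipeline <- function(config, out_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config is missing the mandatory seed")
  if (is.null(config$preset)) stop("config is missing the preset name")
  view <- config$view %||% "axial"
  n_centrioles <- config$n_centrioles %||% 1L
  ref_ch <- config$reference_channel %||% "SCLT1"
  marker_ch <- config$marker_channel %||% "CP110"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  model <- stage("model", build_model_from_paper(config$preset, view = view))
  per_centriole <- vector("list", n_centrioles)

  for (i in seq_len(n_centrioles)) {
    seed_i <- config$seed + i - 1L
    sim <- stage("simulate", simulate_centriole(model, seed = seed_i))
    tab <- sim$table

    if (model$drift$kind != "none" &&
        !is.null(model$fiducials) && nrow(model$fiducials) > 0L) {
      tab <- stage("drift-correction", {
        tracks <- detect_fiducials(tab)
        traj <- estimate_drift(tracks, n_frames = model$n_frames)
        # excise fiducials while the tracks still match the raw table
        apply_drift(remove_fiducials(tab, tracks), traj)
      })
    }
    channels <- setdiff(unique(tab$channel), c(ref_ch, marker_ch))
    targets <- config$target_channels %||% channels

    result <- list(seed = seed_i)
    if (view == "axial") {
      result$channels <- stage("ring-analysis", {
        out <- list()
        for (ch in intersect(targets, unique(tab$channel))) {
          sub <- tab[tab$channel == ch, , drop = FALSE]
          an <- analyze_ring(sub)
          out[[ch]] <- list(
            mean_diameter = an$ring$mean_diameter,
            radius_sd = an$ring$radius_sd,
            n_puncta = nrow(an$puncta),
            completeness = an$occupancy$completeness,
            missing_fraction = an$occupancy$missing_fraction,
            mode9_ratio = an$symmetry$mode_ratio)
        }
        out
      })
    } else {
      result$channels <- stage("lateral-analysis", {
        ref_tab <- tab[tab$channel == ref_ch, , drop = FALSE]
        marker_tab <- tab[tab$channel == marker_ch, , drop = FALSE]
        axis <- estimate_axis(ref_tab,
                              if (nrow(marker_tab) > 0L) marker_tab)
        out <- list()
        for (ch in intersect(targets, unique(tab$channel))) {
          sub <- tab[tab$channel == ch, , drop = FALSE]
          prof <- detect_layers(longitudinal_profile(sub, axis),
                                kernel_sd = model$localization_sd)
          out[[ch]] <- list(
            layer_positions = prof$layers$position,
            layer_widths = prof$layers$width,
            n_layers = nrow(prof$layers),
            distal_boundary = distal_boundary(prof))
        }
        out
      })
    }
    per_centriole[[i]] <- result
  }

  # summarize across centrioles and derive phenotype flags
  chans <- unique(unlist(lapply(per_centriole,
                                function(r) names(r$channels))))
  summary <- list()
  layer_positions <- list()
  for (ch in chans) {
    vals <- lapply(per_centriole, function(r) r$channels[[ch]])
    vals <- Filter(Negate(is.null), vals)
    if (view == "axial") {
      summary[[ch]] <- list(
        mean_diameter = mean(vapply(vals, `[[`, 0, "mean_diameter")),
        mean_missing_fraction =
          mean(vapply(vals, `[[`, 0, "missing_fraction")),
        mean_mode9_ratio = mean(vapply(vals, `[[`, 0, "mode9_ratio")))
    } else {
      counts <- vapply(vals, `[[`, 0L, "n_layers")
      modal_n <- as.integer(names(sort(table(counts),
                                       decreasing = TRUE))[1L])
      use <- vals[counts == modal_n]
      pos <- if (modal_n > 0L) {
        rowMeans(matrix(unlist(lapply(use, `[[`, "layer_positions")),
                        nrow = modal_n))
      } else numeric()
      summary[[ch]] <- list(
        n_layers = modal_n, layer_positions = pos,
        mean_distal_boundary =
          mean(vapply(vals, `[[`, 0, "distal_boundary")))
      layer_positions[[ch]] <- pos
    }
  }
  flags <- if (view == "lateral") phenotype_flags(layer_positions)
           else character()

  report <- list(
    package = "centrioleSTORM",
    version = as.character(utils::packageVersion("centrioleSTORM")),
    config = config,
    view = view,
    n_centrioles = n_centrioles,
    per_centriole = per_centriole,
    summary = summary,
    flags = flags)
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
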