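# Pipeline configuration: acquisition, per-disease-group population specs,
# detection and analysis parameters. Serializes losslessly to JSON.

#' Analysis parameters
#'
#' @param r_max_um radial-profile outer radius (um).
#' @param bin_um radial shell width (um).
#' @param d_conj_um conjugation distance (um, strict upper bound).
#' @param match_radius_um co-positivity matching radius (um).
#' @param edge_policy radial-profile edge policy.
#' @param n_rois ROIs per tissue block.
#' @param roi_shape_um ROI extents `c(x, y, z)` in um.
#' @param min_gap_um minimum ROI separation in um.
#' @param anchor_marker center T-cell marker for radial profiles.
#' @param neighbor_markers neighbor types profiled around the anchor.
#' @param conjugation_pairs list of `c(type_a, type_b)` pairs.
#' @param copositive_pairs list of `c(numerator, base)` pairs.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(r_max_um = 50, bin_um = 5, d_conj_um = 15,
                            match_radius_um = 5,
                            edge_policy = "interior_only",
                            n_rois = 10L, roi_shape_um = c(150, 150, 150),
                            min_gap_um = 0,
                            anchor_marker = "CD3",
                            neighbor_markers = c("CD20", "FOXP3", "CD68",
                                                 "CD163", "CD14", "CD15"),
                            conjugation_pairs = list(
                              c("CD8", "CD20"), c("CD8", "FOXP3"),
                              c("CD3", "CD68"), c("CD3", "CD163"),
                              c("CD3", "CD14"), c("CD3", "CD15")),
                            copositive_pairs = list(
                              c("Ki67", "CD20"), c("Ki67", "CD8"))) {
  structure(
    list(r_max_um = r_max_um, bin_um = bin_um, d_conj_um = d_conj_um,
         match_radius_um = match_radius_um, edge_policy = edge_policy,
         n_rois = as.integer(n_rois), roi_shape_um = roi_shape_um,
         min_gap_um = min_gap_um, anchor_marker = anchor_marker,
         neighbor_markers = neighbor_markers,
         conjugation_pairs = conjugation_pairs,
         copositive_pairs = copositive_pairs),
    class = "analysis_config"
  )
}

#' Population specs emulating three disease conditions
#'
#' Returns per-group lists of [population_spec()] objects for a reactive
#' (RLN-like), a B-cell-lymphoma (DLBCL-like) and a T-cell-lymphoma
#' (AITL-like) condition. The qualitative structure encoded: B cells are
#' abundant and enriched near T cells in the DLBCL-like condition;
#' regulatory T cells and tumor-associated macrophages are enriched near T
#' cells and neutrophils depleted in the AITL-like condition; CD8 T-cell
#' Ki67 co-positivity is highest in the reactive condition while B-cell
#' Ki67 co-positivity does not differ. Absolute densities are
#' order-of-magnitude choices (1e-5 to 1e-4 cells/um^3), not measurements.
#'
#' @return named list (`RLN`, `DLBCL`, `AITL`) of lists of
#'   [population_spec()].
#' @export
disease_presets <- function() {
  att <- function(anchor, frac) {
    list(anchor = anchor, attached_fraction = frac, max_distance_um = 12)
  }
  ki <- function(frac) list(marker = "Ki67", fraction = frac)
  common <- function(ki67_cd8) list(
    population_spec("CD3", 1.0e-4, "poisson"),
    population_spec("CD8", 0.5e-4, "poisson", copositive_with = ki(ki67_cd8)),
    population_spec("CD68", 0.3e-4, "poisson"),
    population_spec("CD14", 0.3e-4, "poisson")
  )
  list(
    RLN = c(common(ki67_cd8 = 0.45), list(
      population_spec("CD20", 0.8e-4, "poisson", copositive_with = ki(0.3)),
      population_spec("FOXP3", 0.15e-4, "poisson"),
      population_spec("CD163", 0.25e-4, "poisson"),
      population_spec("CD15", 0.4e-4, "poisson")
    )),
    DLBCL = c(common(ki67_cd8 = 0.2), list(
      population_spec("CD20", 1.8e-4, "paired_attraction",
                      attraction_params = att("CD3", 0.6),
                      copositive_with = ki(0.3)),
      population_spec("FOXP3", 0.15e-4, "poisson"),
      population_spec("CD163", 0.25e-4, "poisson"),
      population_spec("CD15", 0.4e-4, "poisson")
    )),
    AITL = c(common(ki67_cd8 = 0.1), list(
      population_spec("CD20", 0.4e-4, "poisson", copositive_with = ki(0.3)),
      population_spec("FOXP3", 0.5e-4, "paired_attraction",
                      attraction_params = att("CD3", 0.5)),
      population_spec("CD163", 0.7e-4, "paired_attraction",
                      attraction_params = att("CD3", 0.5)),
      population_spec("CD15", 0.15e-4, "poisson")
    ))
  )
}

#' Default acquisition configuration with the standard channel set
#'
#' @param markers markers to attach as channels (wavelengths cycle through
#'   488/532/637 nm).
#' @return an [acq_config()].
#' @export
default_acq_config <- function(markers = c("CD3", "CD20")) {
  wl <- c(488, 532, 637)
  channels <- lapply(seq_along(markers), function(i) {
    channel_spec(markers[i], excitation_nm = wl[(i - 1L) %% 3L + 1L])
  })
  acq_config(channels = channels)
}

#' Full pipeline configuration
#'
#' @param domain_um simulation domain extents `c(x, y, z)` in um.
#' @param groups named list of per-group population-spec lists (default
#'   [disease_presets()]).
#' @param acquisition an [acq_config()].
#' @param detection a [detection_params()].
#' @param analysis an [analysis_config()].
#' @param render render volumes and detect spots for the acquisition's
#'   channels (FALSE pipes ground-truth points straight to analysis).
#' @param seed integer seed for the whole run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(domain_um = c(1000, 1000, 500),
                            groups = disease_presets(),
                            acquisition = default_acq_config(),
                            detection = detection_params(),
                            analysis = analysis_config(
                              roi_shape_um = c(200, 200, 200)),
                            render = FALSE,
                            seed = 1L) {
  stopifnot(length(domain_um) == 3L, all(domain_um > 0),
            is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  structure(
    list(domain_um = domain_um, groups = groups, acquisition = acquisition,
         detection = detection, analysis = analysis, render = render,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# ---- JSON (de)serialization ------------------------------------------------

spec_to_list <- function(s) {
  l <- unclass(s)
  l[!vapply(l, is.null, logical(1))]
}

list_to_spec <- function(l) {
  population_spec(
    cell_type = l$cell_type,
    intensity_per_um3 = l$intensity_per_um3,
    pattern = l$pattern,
    cluster_params = l$cluster_params,
    attraction_params = l$attraction_params,
    copositive_with = l$copositive_with
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reconstructs an identical configuration.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  acq <- unclass(config$acquisition)
  acq$channels <- lapply(acq$channels, unclass)
  out <- list(
    domain_um = config$domain_um,
    groups = lapply(config$groups, function(sp) lapply(sp, spec_to_list)),
    acquisition = acq,
    detection = unclass(config$detection),
    analysis = unclass(config$analysis),
    render = config$render,
    seed = config$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  chans <- lapply(l$acquisition$channels, function(ch) {
    channel_spec(ch$name, ch$excitation_nm, ch$attenuation_length_um,
                 ch$psf_sigma_xy_um, ch$psf_sigma_z_um)
  })
  acq <- acq_config(
    lateral_pixel_um = l$acquisition$lateral_pixel_um,
    plane_step_um = l$acquisition$plane_step_um,
    tile_shape_px = unlist(l$acquisition$tile_shape_px),
    section_depth_um = l$acquisition$section_depth_um,
    z_stage_step_um = l$acquisition$z_stage_step_um,
    channels = chans,
    camera_pixel_um = l$acquisition$camera_pixel_um,
    magnification = l$acquisition$magnification,
    bit_depth = l$acquisition$bit_depth
  )
  det <- detection_params(
    expected_diameter_um = l$detection$expected_diameter_um,
    quality_threshold = l$detection$quality_threshold,
    min_separation_um = l$detection$min_separation_um
  )
  ana <- do.call(analysis_config, lapply(l$analysis, function(v) {
    if (is.list(v)) lapply(v, unlist) else v
  }))
  groups <- lapply(l$groups, function(sp) lapply(sp, list_to_spec))
  pipeline_config(domain_um = unlist(l$domain_um), groups = groups,
                  acquisition = acq, detection = det, analysis = ana,
                  render = l$render, seed = l$seed)
}
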