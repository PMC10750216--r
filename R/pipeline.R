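# Pipeline driver: simulate -> (render -> tile -> stitch -> detect) ->
# per-ROI spatial statistics -> group comparison, with a manifest recording
# every artifact, its content hash and the seeds used.

#' Per-ROI spatial statistics for one tissue block
#'
#' Runs the full spatial analysis (densities for every marker present,
#' radial neighbor profiles around the anchor T-cell marker, conjugation
#' counts for the configured pairs, co-positivity ratios) over a list of
#' ROIs.
#'
#' @param points a [cell_points()] object for one tissue block.
#' @param rois list of [roi()] objects.
#' @param analysis an [analysis_config()].
#' @return list of tidy data.frames: `densities`, `radial`, `conjugation`,
#'   `copositivity` (one row per ROI x statistic).
#' @export
analyze_points <- function(points, rois, analysis = analysis_config()) {
  stopifnot(is.data.frame(points), is.list(rois))
  markers <- sort(unique(points$marker))
  by_marker <- lapply(markers, function(m) points_of_type(points, m))
  names(by_marker) <- markers
  dens <- list(); rad <- list(); conj <- list(); copos <- list()
  for (r in rois) {
    for (m in markers) {
      dens[[length(dens) + 1L]] <- data.frame(
        roi = r$label, marker = m,
        n_cells = nrow(points_in_roi(by_marker[[m]], r)),
        density_cells_mm3 = compute_density(points, r, m))
    }
    anchor <- analysis$anchor_marker
    if (anchor %in% markers) {
      for (m in intersect(analysis$neighbor_markers, markers)) {
        pr <- radial_neighbor_profile(
          by_marker[[anchor]], by_marker[[m]], roi = r,
          r_max_um = analysis$r_max_um, bin_um = analysis$bin_um,
          edge_policy = analysis$edge_policy)
        nb <- length(pr$total_count)
        rad[[length(rad) + 1L]] <- data.frame(
          roi = r$label, center_type = anchor, neighbor_type = m,
          bin_lo_um = pr$bin_edges_um[seq_len(nb)],
          bin_hi_um = pr$bin_edges_um[-1L],
          total = pr$total_count,
          mean_per_center = pr$mean_count_per_center,
          n_centers = pr$n_centers)
      }
    }
    for (pair in analysis$conjugation_pairs) {
      if (!all(pair %in% markers)) next
      ce <- conjugation_count(by_marker[[pair[1L]]], by_marker[[pair[2L]]],
                              roi = r, d_max_um = analysis$d_conj_um)
      conj[[length(conj) + 1L]] <- data.frame(
        roi = r$label, type_a = pair[1L], type_b = pair[2L],
        pair_count = ce$pair_count, n_a = ce$n_a, n_b = ce$n_b)
    }
    for (pair in analysis$copositive_pairs) {
      if (!all(pair %in% markers)) next
      cp <- copositivity(points_in_roi(by_marker[[pair[1L]]], r),
                         points_in_roi(by_marker[[pair[2L]]], r),
                         match_radius_um = analysis$match_radius_um)
      copos[[length(copos) + 1L]] <- data.frame(
        roi = r$label, numerator_type = pair[1L], base_type = pair[2L],
        n_double = cp$n_double, n_base = cp$n_base, ratio = cp$ratio)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(densities = bind(dens), radial = bind(rad), conjugation = bind(conj),
       copositivity = bind(copos))
}

#' Kruskal-Wallis comparison of a per-ROI statistic across groups
#'
#' @param df tidy data.frame with one row per ROI.
#' @param value_col column holding the per-ROI statistic.
#' @param group_col column holding the group label.
#' @return one-row data.frame: `statistic_H`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(df, value_col, group_col = "group") {
  kw <- kruskal_wallis(grouped_samples(df[[value_col]], df[[group_col]]))
  data.frame(statistic_H = kw$statistic, df = kw$df, p_value = kw$p_value,
             significant = kw$significant)
}

# detection over an optionally tiled/stitched render of one channel
render_detect_channel <- function(truth, acq, channel, detection, seed) {
  vol <- render_volume(truth, acq, channel, seed = seed)
  depth_um <- volume_extent_um(vol)[["z"]]
  if (depth_um >= acq$section_depth_um &&
      depth_um > acq$z_stage_step_um + acq$plane_step_um) {
    ts <- tile_volume(vol, acq, seed = seed)
    vol <- stitch_tiles(ts)$fused
  }
  detect_spots(vol, detection)
}

#' Run the full pipeline
#'
#' Simulates one tissue block per disease group, optionally renders the
#' configured channels and replaces their ground-truth points with spot
#' detections (tiling and stitching whenever the field is deeper than one
#' optical section), selects ROIs, computes the per-ROI spatial statistics,
#' compares them across groups, and writes everything (point CSVs, tidy
#' statistics CSVs, tests.csv, config echo, manifest with content hashes)
#' under `out_dir`. Rerunning with the same config and seed is
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$seed` when given.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  artifacts <- character(0)
  res <- list(densities = list(), radial = list(), conjugation = list(),
              copositivity = list())
  domain <- domain_box(config$domain_um[1], config$domain_um[2],
                       config$domain_um[3])
  tryCatch({
    for (gi in seq_along(config$groups)) {
      gname <- names(config$groups)[gi]
      stage <- paste0("simulate:", gname)
      truth <- simulate_point_pattern(domain, config$groups[[gi]],
                                      seed = split_seed(seed, 11L, gi))
      pts <- truth$points
      truth_path <- file.path(out_dir, paste0("truth_", gname, ".csv"))
      tp <- pts; tp$block <- gname; tp$seed <- truth$seed
      write_points_csv(tp, truth_path)
      artifacts <- c(artifacts, truth_path)
      if (isTRUE(config$render)) {
        stage <- paste0("detect:", gname)
        for (ch in names(config$acquisition$channels)) {
          det <- render_detect_channel(truth, config$acquisition, ch,
                                       config$detection,
                                       seed = split_seed(seed, 13L, gi))
          pts <- rbind(
            pts[pts$marker != ch, intersect(names(pts), names(det))],
            det[, intersect(names(pts), names(det))])
          det_path <- file.path(out_dir,
                                paste0("detected_", gname, "_", ch, ".csv"))
          write_points_csv(det, det_path)
          artifacts <- c(artifacts, det_path)
        }
        pts <- as_cell_points(pts, validate_markers = FALSE)
      }
      stage <- paste0("analyze:", gname)
      rois <- select_rois(domain, n = config$analysis$n_rois,
                          roi_shape_um = config$analysis$roi_shape_um,
                          seed = split_seed(seed, 17L, gi),
                          min_gap_um = config$analysis$min_gap_um)
      block <- analyze_points(pts, rois, config$analysis)
      for (nm in names(res)) {
        if (!is.null(block[[nm]])) {
          block[[nm]] <- cbind(group = gname, block[[nm]])
          res[[nm]][[gname]] <- block[[nm]]
        }
      }
    }
    stage <- "write-statistics"
    tables <- lapply(res, function(l) if (length(l)) do.call(rbind, l) else NULL)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
    stage <- "compare"
    tests <- list()
    if (!is.null(tables$densities) &&
        length(unique(tables$densities$group)) >= 2L) {
      for (m in unique(tables$densities$marker)) {
        d <- tables$densities[tables$densities$marker == m, ]
        tests[[length(tests) + 1L]] <- cbind(
          metric = paste0("density:", m),
          compare_groups(d, "density_cells_mm3"))
      }
      if (!is.null(tables$conjugation)) {
        cj <- tables$conjugation
        for (key in unique(paste(cj$type_a, cj$type_b))) {
          d <- cj[paste(cj$type_a, cj$type_b) == key, ]
          tests[[length(tests) + 1L]] <- cbind(
            metric = paste0("conjugation:", sub(" ", "-", key)),
            compare_groups(d, "pair_count"))
        }
      }
      if (!is.null(tables$radial)) {
        rd <- tables$radial
        # per-ROI neighbor total within r_max around the anchor
        agg <- stats::aggregate(mean_per_center ~ group + roi + neighbor_type,
                                data = rd, FUN = sum)
        for (m in unique(agg$neighbor_type)) {
          d <- agg[agg$neighbor_type == m, ]
          tests[[length(tests) + 1L]] <- cbind(
            metric = paste0("radial_mean_0_50:", m),
            compare_groups(d, "mean_per_center"))
        }
      }
      if (!is.null(tables$copositivity)) {
        cp <- tables$copositivity
        for (key in unique(paste(cp$numerator_type, cp$base_type))) {
          d <- cp[paste(cp$numerator_type, cp$base_type) == key, ]
          d <- d[is.finite(d$ratio), ]
          if (length(unique(d$group)) >= 2L) {
            tests[[length(tests) + 1L]] <- cbind(
              metric = paste0("copositivity:", sub(" ", "/", key)),
              compare_groups(d, "ratio"))
          }
        }
      }
    }
    if (length(tests)) {
      tests <- do.call(rbind, tests)
      p <- file.path(out_dir, "tests.csv")
      utils::write.csv(tests, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
    stage <- "manifest"
    cfg_path <- file.path(out_dir, "config.json")
    write_pipeline_config(config, cfg_path)
    artifacts <- c(artifacts, cfg_path)
    manifest <- list(
      package = "tme3d",
      version = as.character(utils::packageVersion("tme3d")),
      seed = seed,
      groups = names(config$groups),
      artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                         function(p) list(path = p,
                                          md5 = unname(tools::md5sum(p))))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
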