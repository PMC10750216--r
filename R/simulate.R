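# Ground-truthed synthetic point patterns: homogeneous Poisson, Thomas
# parent-offspring clusters, and anchor-attraction patterns that place a
# fraction of one cell type within conjugation range of another. These
# emulate the spatial structure of immune infiltrates in lymphoid tissue
# (e.g. B-cell enrichment near T cells) with known ground truth.

#' Axis-aligned simulation domain
#'
#' @param x_um,y_um,z_um physical extents in micrometres; the domain is
#'   `[0, x_um) x [0, y_um) x [0, z_um)`.
#' @return an object of class `domain_box`.
#' @export
domain_box <- function(x_um, y_um, z_um) {
  stopifnot(x_um > 0, y_um > 0, z_um > 0)
  structure(list(extent_um = c(x = x_um, y = y_um, z = z_um)),
            class = "domain_box")
}

domain_volume_um3 <- function(domain) prod(domain$extent_um)

#' Specify one simulated cell population
#'
#' @param cell_type marker label from [marker_panel()].
#' @param intensity_per_um3 expected number density in cells/um^3 (tissue
#'   immune densities are of order 1e-5 to 1e-4).
#' @param pattern `"poisson"` (complete spatial randomness),
#'   `"thomas_cluster"` (Poisson parents with Gaussian-dispersed offspring)
#'   or `"paired_attraction"` (a fraction of cells placed within a bounded
#'   distance of an anchor type, the remainder as Poisson background).
#' @param cluster_params for `thomas_cluster`: list with
#'   `parent_intensity_per_um3`, `mean_offspring`, `sigma_um`.
#' @param attraction_params for `paired_attraction`: list with `anchor`
#'   (marker label generated earlier), `attached_fraction` in `[0, 1]`, and
#'   `max_distance_um` strictly below 15 (attached cells are placed
#'   volume-uniformly in a ball of this radius around a random anchor, so
#'   every attached cell is a conjugate of its anchor).
#' @param copositive_with optional list with `marker` and `fraction`: that
#'   fraction of generated cells is re-emitted at identical coordinates
#'   under the second label (double-positive cells, e.g. Ki67+CD8+).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(cell_type, intensity_per_um3,
                            pattern = c("poisson", "thomas_cluster",
                                        "paired_attraction"),
                            cluster_params = NULL,
                            attraction_params = NULL,
                            copositive_with = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(is.character(cell_type), length(cell_type) == 1L)
  if (!cell_type %in% marker_panel()) {
    stop("unknown cell_type '", cell_type, "'")
  }
  if (!is.finite(intensity_per_um3) || intensity_per_um3 < 0) {
    stop("intensity_per_um3 must be >= 0")
  }
  if (pattern == "thomas_cluster") {
    stopifnot(is.list(cluster_params),
              all(c("parent_intensity_per_um3", "mean_offspring",
                    "sigma_um") %in% names(cluster_params)),
              cluster_params$parent_intensity_per_um3 > 0,
              cluster_params$mean_offspring > 0,
              cluster_params$sigma_um > 0)
  }
  if (pattern == "paired_attraction") {
    stopifnot(is.list(attraction_params),
              all(c("anchor", "attached_fraction", "max_distance_um") %in%
                    names(attraction_params)))
    af <- attraction_params$attached_fraction
    if (!is.finite(af) || af < 0 || af > 1) {
      stop("attached_fraction must lie in [0, 1]")
    }
    if (attraction_params$max_distance_um >= 15) {
      stop("attachment max_distance_um must be < 15 um so attached cells ",
           "are conjugates of their anchors")
    }
    stopifnot(attraction_params$max_distance_um > 0)
  }
  if (!is.null(copositive_with)) {
    stopifnot(is.list(copositive_with),
              all(c("marker", "fraction") %in% names(copositive_with)),
              copositive_with$marker %in% marker_panel(),
              copositive_with$fraction >= 0, copositive_with$fraction <= 1)
  }
  structure(
    list(cell_type = cell_type, intensity_per_um3 = intensity_per_um3,
         pattern = pattern, cluster_params = cluster_params,
         attraction_params = attraction_params,
         copositive_with = copositive_with),
    class = "population_spec"
  )
}

# Order specs so every paired_attraction anchor is generated before its
# dependents; cycles are an error.
order_specs <- function(specs) {
  types <- vapply(specs, `[[`, character(1), "cell_type")
  dep <- vapply(specs, function(s) {
    if (s$pattern == "paired_attraction") s$attraction_params$anchor
    else NA_character_
  }, character(1))
  ordered <- integer(0)
  placed <- rep(FALSE, length(specs))
  repeat {
    ready <- which(!placed & (is.na(dep) | dep %in% types[placed]))
    if (!length(ready)) break
    ordered <- c(ordered, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("cyclic or unsatisfiable anchor dependency among: ",
         paste(types[!placed], collapse = ", "))
  }
  ordered
}

runif_in_box <- function(n, domain) {
  e <- domain$extent_um
  cbind(x = stats::runif(n, 0, e[["x"]]),
        y = stats::runif(n, 0, e[["y"]]),
        z = stats::runif(n, 0, e[["z"]]))
}

in_box <- function(xyz, domain) {
  e <- domain$extent_um
  xyz[, 1] >= 0 & xyz[, 1] < e[["x"]] &
    xyz[, 2] >= 0 & xyz[, 2] < e[["y"]] &
    xyz[, 3] >= 0 & xyz[, 3] < e[["z"]]
}

# Uniform directions on the unit sphere.
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Simulate a multi-type 3D point pattern with ground truth
#'
#' Populations are generated in anchor-dependency order under one explicit
#' seed (each population draws from its own derived sub-stream). Points
#' falling outside the domain (cluster offspring, attraction shells near a
#' face) are discarded, so every returned point lies inside the box.
#'
#' @param domain a [domain_box()].
#' @param specs list of [population_spec()] objects.
#' @param seed integer seed; the same `(domain, specs, seed)` regenerates a
#'   bit-identical pattern.
#' @return an object of class `ground_truth`: list with `points`
#'   ([cell_points()]), `specs`, `seed` and `domain`.
#' @export
simulate_point_pattern <- function(domain, specs, seed) {
  stopifnot(inherits(domain, "domain_box"),
            all(vapply(specs, inherits, logical(1), "population_spec")))
  V <- domain_volume_um3(domain)
  ord <- order_specs(specs)
  pts <- list()
  by_type <- list()  # accumulated coordinates per marker, for anchors
  for (i in ord) {
    s <- specs[[i]]
    sseed <- split_seed(seed, i)
    xyz <- with_seed(sseed, {
      if (s$pattern == "poisson") {
        n <- stats::rpois(1L, s$intensity_per_um3 * V)
        runif_in_box(n, domain)
      } else if (s$pattern == "thomas_cluster") {
        cp <- s$cluster_params
        npar <- stats::rpois(1L, cp$parent_intensity_per_um3 * V)
        if (npar == 0L) {
          matrix(numeric(0), ncol = 3)
        } else {
          parents <- runif_in_box(npar, domain)
          noff <- stats::rpois(npar, cp$mean_offspring)
          idx <- rep.int(seq_len(npar), noff)
          off <- parents[idx, , drop = FALSE] +
            matrix(stats::rnorm(3 * length(idx), sd = cp$sigma_um), ncol = 3)
          off[in_box(off, domain), , drop = FALSE]
        }
      } else {  # paired_attraction
        ap <- s$attraction_params
        anchors <- by_type[[ap$anchor]]
        n <- stats::rpois(1L, s$intensity_per_um3 * V)
        n_att <- stats::rbinom(1L, n, ap$attached_fraction)
        if (is.null(anchors) || nrow(anchors) == 0L) {
          if (n_att > 0L) {
            warning("no '", ap$anchor, "' anchors present; placing all '",
                    s$cell_type, "' cells as background")
          }
          n_att <- 0L
        }
        att <- matrix(numeric(0), ncol = 3)
        if (n_att > 0L) {
          ai <- sample.int(nrow(anchors), n_att, replace = TRUE)
          # volume-uniform radius in the attachment ball keeps all attached
          # cells strictly inside conjugation range of their anchor
          r <- ap$max_distance_um * stats::runif(n_att)^(1 / 3)
          att <- anchors[ai, , drop = FALSE] + runif_sphere(n_att) * r
          att <- att[in_box(att, domain), , drop = FALSE]
        }
        bg <- runif_in_box(n - n_att, domain)
        rbind(att, bg)
      }
    })
    colnames(xyz) <- c("x", "y", "z")
    by_type[[s$cell_type]] <- rbind(by_type[[s$cell_type]], xyz)
    p <- cell_points(xyz[, 1], xyz[, 2], xyz[, 3], s$cell_type)
    pts[[length(pts) + 1L]] <- p
    if (!is.null(s$copositive_with) && nrow(xyz) > 0L &&
        s$copositive_with$fraction > 0) {
      co <- with_seed(split_seed(seed, i, 999L), {
        keep <- stats::runif(nrow(xyz)) < s$copositive_with$fraction
        xyz[keep, , drop = FALSE]
      })
      if (nrow(co)) {
        pts[[length(pts) + 1L]] <-
          cell_points(co[, 1], co[, 2], co[, 3], s$copositive_with$marker)
      }
    }
  }
  all_pts <- if (length(pts)) do.call(rbind, pts) else cell_points()
  structure(
    list(points = as_cell_points(all_pts, validate_markers = FALSE),
         specs = specs, seed = seed, domain = domain),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  e <- x$domain$extent_um
  cat(sprintf("<ground_truth> %.0f x %.0f x %.0f um, seed %d\n",
              e[["x"]], e[["y"]], e[["z"]], x$seed))
  print(x$points)
  invisible(x)
}
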