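# The spatial statistics defined on typed 3D cell coordinates: per-ROI cell
# density, radial neighbor profiles in 5-um shells out to 50 um around
# center T cells, cell conjugation (pairs of unlike types closer than
# 15 um), and marker co-positivity. Neighbor queries run on a uniform-grid
# spatial index but are contractually equal to the O(n^2) double loop.

#' Axis-aligned region of interest
#'
#' Membership uses half-open bounds: a point on an upper face is outside.
#'
#' @param x0,x1,y0,y1,z0,z1 bounds in um, upper strictly above lower.
#' @param label identifier.
#' @return an object of class `roi` with derived `volume_mm3`.
#' @export
roi <- function(x0, x1, y0, y1, z0, z1, label = "roi") {
  if (!(x1 > x0 && y1 > y0 && z1 > z0)) {
    stop("ROI must have strictly positive extent on every axis")
  }
  structure(
    list(bounds_um = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1, z0 = z0, z1 = z1),
         volume_mm3 = (x1 - x0) * (y1 - y0) * (z1 - z0) * 1e-9,
         label = label),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  b <- x$bounds_um
  cat(sprintf(
    "<roi> %s: [%g,%g) x [%g,%g) x [%g,%g) um, %.4g mm^3\n",
    x$label, b["x0"], b["x1"], b["y0"], b["y1"], b["z0"], b["z1"],
    x$volume_mm3))
  invisible(x)
}

#' Subset points to an ROI (half-open bounds)
#'
#' @param points a [cell_points()] object.
#' @param roi an [roi()].
#' @return the points inside the ROI.
#' @export
points_in_roi <- function(points, roi) {
  b <- roi$bounds_um
  keep <- points$x_um >= b["x0"] & points$x_um < b["x1"] &
          points$y_um >= b["y0"] & points$y_um < b["y1"] &
          points$z_um >= b["z0"] & points$z_um < b["z1"]
  points[keep, , drop = FALSE]
}

# Uniform-grid neighbor search: all (i, j) pairs with distance below (or at)
# rmax between point sets A and B. Returns data.frame(i, j, d_um).
neighbor_pairs <- function(ax, ay, az, bx, by, bz, rmax,
                          include_equal = FALSE) {
  na <- length(ax); nb <- length(bx)
  empty <- data.frame(i = integer(), j = integer(), d_um = numeric())
  if (na == 0L || nb == 0L) return(empty)
  key3 <- function(x, y, z) paste(x, y, z, sep = "_")
  bi <- floor(bx / rmax); bj <- floor(by / rmax); bk <- floor(bz / rmax)
  bmap <- split(seq_len(nb), key3(bi, bj, bk))
  ai <- floor(ax / rmax); aj <- floor(ay / rmax); ak <- floor(az / rmax)
  out_i <- list(); out_j <- list(); out_d <- list(); nout <- 0L
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    akey <- key3(ai + ox, aj + oy, ak + oz)
    m <- match(akey, names(bmap))
    hit <- which(!is.na(m))
    if (!length(hit)) next
    cand <- bmap[m[hit]]
    lens <- lengths(cand)
    ia <- rep.int(hit, lens)
    ib <- unlist(cand, use.names = FALSE)
    d <- sqrt((ax[ia] - bx[ib])^2 + (ay[ia] - by[ib])^2 +
              (az[ia] - bz[ib])^2)
    keep <- if (include_equal) d <= rmax else d < rmax
    if (any(keep)) {
      nout <- nout + 1L
      out_i[[nout]] <- ia[keep]; out_j[[nout]] <- ib[keep]
      out_d[[nout]] <- d[keep]
    }
  }
  if (!nout) return(empty)
  data.frame(i = unlist(out_i), j = unlist(out_j), d_um = unlist(out_d))
}

#' Cell density within an ROI
#'
#' The count of typed cells inside the ROI's half-open bounds divided by the
#' ROI volume in mm^3.
#'
#' @param points a [cell_points()] object.
#' @param roi an [roi()].
#' @param cell_type marker label to count.
#' @return density in cells/mm^3.
#' @export
compute_density <- function(points, roi, cell_type) {
  stopifnot(inherits(roi, "roi"))
  if (roi$volume_mm3 <= 0) stop("zero-volume ROI")
  p <- points_in_roi(points_of_type(points, cell_type), roi)
  nrow(p) / roi$volume_mm3
}

#' Radial neighbor profile around center cells
#'
#' Counts neighbor-type cells in concentric half-open shells
#' `[k*bin, (k+1)*bin)` um around each center cell, out to `r_max`
#' (defaults: 5-um bins to 50 um, the convention for profiling immune cells
#' around center T cells). Coincident records of the same marker (a center
#' listed among its own neighbors) are excluded. With
#' `edge_policy = "interior_only"` (the default when an ROI is given),
#' centers closer than `r_max` to any ROI face are dropped so shell counts
#' are unbiased and match the closed-form Poisson expectation
#' `lambda * 4/3 * pi * (r2^3 - r1^3)` under complete spatial randomness.
#'
#' @param centers,neighbors [cell_points()] objects (typically one marker
#'   each; the first marker of each is recorded in the profile).
#' @param roi optional [roi()]; when given, both point sets are clipped to
#'   it and the edge policy applies to its faces.
#' @param r_max_um outer radius in um.
#' @param bin_um shell width in um; must divide `r_max_um` exactly.
#' @param edge_policy `"interior_only"` or `"none"`; default
#'   `"interior_only"` with an ROI, `"none"` without.
#' @return an object of class `radial_profile`: `bin_edges_um`,
#'   `total_count` and `mean_count_per_center` per bin, `n_centers`,
#'   `center_type`, `neighbor_type`. `n_centers == 0` yields NaN means with
#'   a warning.
#' @export
radial_neighbor_profile <- function(centers, neighbors, roi = NULL,
                                    r_max_um = 50, bin_um = 5,
                                    edge_policy = NULL) {
  nb <- r_max_um / bin_um
  if (abs(nb - round(nb)) > 1e-9) {
    stop("bin_um must divide r_max_um exactly")
  }
  nb <- as.integer(round(nb))
  if (is.null(edge_policy)) {
    edge_policy <- if (is.null(roi)) "none" else "interior_only"
  }
  edge_policy <- match.arg(edge_policy, c("interior_only", "none"))
  if (edge_policy == "interior_only" && is.null(roi)) {
    stop("edge_policy = \"interior_only\" needs an ROI to define faces")
  }
  if (!is.null(roi)) {
    centers <- points_in_roi(centers, roi)
    neighbors <- points_in_roi(neighbors, roi)
  }
  center_type <- if (nrow(centers)) centers$marker[1L] else NA_character_
  neighbor_type <- if (nrow(neighbors)) neighbors$marker[1L] else NA_character_
  if (edge_policy == "interior_only") {
    b <- roi$bounds_um
    keep <- centers$x_um >= b["x0"] + r_max_um &
            centers$x_um <  b["x1"] - r_max_um &
            centers$y_um >= b["y0"] + r_max_um &
            centers$y_um <  b["y1"] - r_max_um &
            centers$z_um >= b["z0"] + r_max_um &
            centers$z_um <  b["z1"] - r_max_um
    centers <- centers[keep, , drop = FALSE]
  }
  n_centers <- nrow(centers)
  edges <- seq(0, r_max_um, by = bin_um)
  total <- rep(0L, nb)
  if (n_centers > 0L && nrow(neighbors) > 0L) {
    pr <- neighbor_pairs(centers$x_um, centers$y_um, centers$z_um,
                         neighbors$x_um, neighbors$y_um, neighbors$z_um,
                         r_max_um)
    # a coincident same-marker record is the center itself, not a neighbor
    same <- pr$d_um == 0 &
      centers$marker[pr$i] == neighbors$marker[pr$j]
    pr <- pr[!same, , drop = FALSE]
    if (nrow(pr)) {
      binidx <- pmin(nb, floor(pr$d_um / bin_um) + 1L)
      total <- as.integer(tabulate(binidx, nb))
    }
  }
  mean_per_center <- if (n_centers > 0L) total / n_centers else {
    warning("no center cells; per-center means undefined")
    rep(NaN, nb)
  }
  structure(
    list(center_type = center_type, neighbor_type = neighbor_type,
         bin_edges_um = edges, total_count = total,
         mean_count_per_center = mean_per_center, n_centers = n_centers),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s around %s, %d centers\n",
              x$neighbor_type, x$center_type, x$n_centers))
  df <- data.frame(bin_lo = x$bin_edges_um[-length(x$bin_edges_um)],
                   bin_hi = x$bin_edges_um[-1L],
                   total = x$total_count,
                   mean = round(x$mean_count_per_center, 4))
  print(df)
  invisible(x)
}

#' Count cell conjugations between two cell types
#'
#' A conjugation is an unordered pair of cells of different types whose
#' centroids lie strictly closer than `d_max_um` (15 um by definition), both
#' inside the ROI. Computed on a grid spatial index; contractually equal to
#' the O(n^2) double loop.
#'
#' `periodic = TRUE` measures distances on the torus defined by
#' `extent_um` (minimum-image convention). This is a calibration aid: it
#' realizes the interior (edge-free) approximation exactly, so counts under
#' complete spatial randomness can be compared to the closed form
#' `n_a * n_b * 4/3 * pi * d_max^3 / V` without boundary bias. Analyses of
#' real ROIs use the default `periodic = FALSE`.
#'
#' @param points_a,points_b [cell_points()] of two different markers.
#' @param roi optional [roi()]; both sets are clipped to it.
#' @param d_max_um conjugation distance in um (strict upper bound).
#' @param periodic measure distances with periodic boundary conditions.
#' @param extent_um domain extents `c(x=, y=, z=)`, required when periodic.
#' @return an object of class `conjugation_entry`: `type_a`, `type_b`,
#'   `roi_label`, `pair_count`, `n_a`, `n_b`.
#' @export
conjugation_count <- function(points_a, points_b, roi = NULL, d_max_um = 15,
                              periodic = FALSE, extent_um = NULL) {
  ta <- if (nrow(points_a)) points_a$marker[1L] else NA_character_
  tb <- if (nrow(points_b)) points_b$marker[1L] else NA_character_
  if (!is.na(ta) && !is.na(tb) && ta == tb) {
    stop("conjugation is defined between two different cell types")
  }
  if (!is.null(roi)) {
    points_a <- points_in_roi(points_a, roi)
    points_b <- points_in_roi(points_b, roi)
  }
  na <- nrow(points_a); nb <- nrow(points_b)
  if (periodic) {
    if (is.null(extent_um)) stop("periodic counting needs extent_um")
    cnt <- 0L
    if (na > 0L && nb > 0L) {
      wrap <- function(d, L) pmin(abs(d), L - abs(d))
      for (i in seq_len(na)) {
        dx <- wrap(points_a$x_um[i] - points_b$x_um, extent_um[["x"]])
        dy <- wrap(points_a$y_um[i] - points_b$y_um, extent_um[["y"]])
        dz <- wrap(points_a$z_um[i] - points_b$z_um, extent_um[["z"]])
        cnt <- cnt + sum(dx^2 + dy^2 + dz^2 < d_max_um^2)
      }
    }
  } else {
    pr <- neighbor_pairs(points_a$x_um, points_a$y_um, points_a$z_um,
                         points_b$x_um, points_b$y_um, points_b$z_um,
                         d_max_um)
    cnt <- nrow(pr)
  }
  structure(
    list(type_a = ta, type_b = tb,
         roi_label = if (is.null(roi)) NA_character_ else roi$label,
         pair_count = as.integer(cnt), n_a = na, n_b = nb),
    class = "conjugation_entry"
  )
}

#' Marker co-positivity ratio
#'
#' A base cell (e.g. CD8) is double-positive if at least one marker-channel
#' point (e.g. Ki67) lies within `match_radius_um` of it; each marker point
#' may validate at most one base cell, assigned greedily in ascending pair
#' distance. The ratio is double-positive / base count.
#'
#' @param points_marker second-marker detections (e.g. Ki67).
#' @param points_base base-population detections (e.g. CD8).
#' @param match_radius_um matching radius in um (> 0; default 5, about half
#'   a cell diameter).
#' @return an object of class `copositivity_result`: `numerator_type`,
#'   `base_type`, `match_radius_um`, `n_double`, `n_base`, `ratio`. An empty
#'   base set yields ratio NaN with a warning.
#' @export
copositivity <- function(points_marker, points_base, match_radius_um = 5) {
  stopifnot(match_radius_um > 0)
  n_base <- nrow(points_base)
  n_marker <- nrow(points_marker)
  n_double <- 0L
  if (n_base == 0L) {
    warning("empty base set; co-positivity ratio undefined")
  } else if (n_marker > 0L) {
    pr <- neighbor_pairs(points_marker$x_um, points_marker$y_um,
                         points_marker$z_um,
                         points_base$x_um, points_base$y_um,
                         points_base$z_um,
                         match_radius_um, include_equal = TRUE)
    if (nrow(pr)) {
      pr <- pr[order(pr$d_um, pr$i, pr$j), , drop = FALSE]
      used_m <- logical(n_marker); used_b <- logical(n_base)
      for (k in seq_len(nrow(pr))) {
        i <- pr$i[k]; j <- pr$j[k]
        if (used_m[i] || used_b[j]) next
        used_m[i] <- TRUE; used_b[j] <- TRUE
        n_double <- n_double + 1L
      }
    }
  }
  structure(
    list(numerator_type = if (n_marker) points_marker$marker[1L] else NA_character_,
         base_type = if (n_base) points_base$marker[1L] else NA_character_,
         match_radius_um = match_radius_um,
         n_double = n_double, n_base = n_base,
         ratio = if (n_base > 0L) n_double / n_base else NaN),
    class = "copositivity_result"
  )
}

#' Select non-overlapping ROIs inside a domain
#'
#' Seeded rejection sampling of `n` axis-aligned boxes of the given shape,
#' fully inside the domain and pairwise separated by at least `min_gap_um`
#' on some axis.
#'
#' @param domain a [domain_box()].
#' @param n number of ROIs (ten per tissue block is the usual design).
#' @param roi_shape_um extents `c(x, y, z)` of each ROI in um.
#' @param seed integer seed.
#' @param min_gap_um minimum face-to-face separation in um (0 allows
#'   touching, never overlap).
#' @param max_attempts rejection-sampling budget before erroring.
#' @return list of [roi()] objects labelled `roi01, roi02, ...`.
#' @export
select_rois <- function(domain, n = 10L, roi_shape_um = c(150, 150, 150),
                        seed = 1L, min_gap_um = 0, max_attempts = 2000L * n) {
  stopifnot(inherits(domain, "domain_box"), n >= 1L,
            length(roi_shape_um) == 3L, all(roi_shape_um > 0))
  ext <- domain$extent_um
  slack <- c(ext[["x"]], ext[["y"]], ext[["z"]]) - roi_shape_um
  if (any(slack < 0)) {
    stop("ROI shape exceeds the domain extent")
  }
  rois <- list()
  with_seed(split_seed(seed, 4001L), {
    attempts <- 0L
    stalled <- 0L
    while (length(rois) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n, " ROIs of ",
             paste(roi_shape_um, collapse = "x"), " um in the domain after ",
             max_attempts, " attempts (", length(rois), " placed); the ",
             "packing is too tight")
      }
      if (stalled > 500L) {
        # a bad early placement can block the rest; restart the packing
        rois <- list()
        stalled <- 0L
      }
      lo <- stats::runif(3) * slack
      hi <- lo + roi_shape_um
      ok <- TRUE
      for (r in rois) {
        b <- r$bounds_um
        sep <- max(lo[1] - b["x1"], b["x0"] - hi[1],
                   lo[2] - b["y1"], b["y0"] - hi[2],
                   lo[3] - b["z1"], b["z0"] - hi[3])
        if (sep < min_gap_um) { ok <- FALSE; break }
      }
      if (ok) {
        rois[[length(rois) + 1L]] <-
          roi(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3],
              label = sprintf("roi%02d", length(rois) + 1L))
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
      }
    }
  })
  rois
}
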