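# Typed 3D cell coordinates in physical micrometres: the unit analysis
# object shared by detection, simulation and the spatial statistics.

#' Marker panel recognised by the package
#'
#' The immune panel used throughout: T cells (CD3, CD8), B cells (CD20),
#' macrophages (CD68), tumor-associated macrophages (CD163), monocytes
#' (CD14), neutrophils (CD15), regulatory T cells (FOXP3) and the
#' proliferation marker Ki67.
#'
#' @return character vector of marker names.
#' @export
marker_panel <- function() {
  c("CD3", "CD8", "CD20", "CD68", "CD163", "CD14", "CD15", "FOXP3", "Ki67")
}

#' Construct a typed 3D cell point set
#'
#' @param x_um,y_um,z_um numeric coordinates in micrometres (right-handed,
#'   origin at the volume origin).
#' @param marker character vector of marker labels, recycled if length 1;
#'   must come from [marker_panel()] unless `validate_markers = FALSE`.
#' @param quality optional non-negative detection quality score.
#' @param validate_markers check labels against the panel (default TRUE).
#' @return a `data.frame` of class `cell_points` with columns
#'   `x_um, y_um, z_um, marker, quality`.
#' @export
cell_points <- function(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        marker = character(), quality = NULL,
                        validate_markers = TRUE) {
  n <- length(x_um)
  stopifnot(length(y_um) == n, length(z_um) == n)
  if (length(marker) == 1L) marker <- rep(marker, n)
  if (n == 0L) marker <- character()
  stopifnot(length(marker) == n)
  if (is.null(quality)) quality <- rep(NA_real_, n)
  if (length(quality) == 1L) quality <- rep(quality, n)
  stopifnot(length(quality) == n)
  if (!all(is.finite(x_um)) || !all(is.finite(y_um)) || !all(is.finite(z_um))) {
    stop("cell coordinates must be finite")
  }
  if (any(!is.na(quality) & quality < 0)) stop("quality must be >= 0")
  if (validate_markers && n > 0L) {
    bad <- which(!marker %in% marker_panel())
    if (length(bad)) {
      stop("unknown marker '", marker[bad[1L]], "' in row ", bad[1L],
           "; panel is: ", paste(marker_panel(), collapse = ", "))
    }
  }
  structure(
    data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
               z_um = as.numeric(z_um), marker = as.character(marker),
               quality = as.numeric(quality), stringsAsFactors = FALSE),
    class = c("cell_points", "data.frame")
  )
}

as_cell_points <- function(df, validate_markers = TRUE) {
  cell_points(df$x_um, df$y_um, df$z_um, df$marker,
              quality = if ("quality" %in% names(df)) df$quality else NULL,
              validate_markers = validate_markers)
}

#' Subset a point set by marker
#'
#' @param points a [cell_points()] object.
#' @param marker one marker label.
#' @return the rows of `points` carrying `marker`.
#' @export
points_of_type <- function(points, marker) {
  stopifnot(inherits(points, "cell_points") || is.data.frame(points))
  as_cell_points(points[points$marker == marker, , drop = FALSE],
                 validate_markers = FALSE)
}

#' @export
print.cell_points <- function(x, ...) {
  cat(sprintf("<cell_points> %d cells", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$marker)
    cat(": ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "), sep = "")
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write / read cell point sets as CSV
#'
#' The interchange schema is `x_um, y_um, z_um, marker` plus any extra
#' columns present (`quality`, `block`, `seed`). Coordinates survive a
#' round trip to at least 0.001 um.
#'
#' @param points a [cell_points()] object (may carry extra columns).
#' @param path file path.
#' @return `write_points_csv` returns `path` invisibly; `read_points_csv`
#'   returns a `cell_points` data.frame.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(is.data.frame(points),
            all(c("x_um", "y_um", "z_um", "marker") %in% names(points)))
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @param validate_markers check labels against [marker_panel()].
#' @export
read_points_csv <- function(path, validate_markers = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("point CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (validate_markers) {
    bad <- which(!df$marker %in% marker_panel())
    if (length(bad)) {
      stop("unknown marker '", df$marker[bad[1L]], "' in row ", bad[1L],
           " of ", path)
    }
  }
  out <- as_cell_points(df, validate_markers = FALSE)
  extra <- setdiff(names(df), names(out))
  for (cn in extra) out[[cn]] <- df[[cn]]
  out
}
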