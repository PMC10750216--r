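# ImageVolume: one channel's 3D intensity grid with physical voxel spacing.
# Storage convention: `data` is an array of dim (rows = y, cols = x,
# planes = z); the centre of voxel [1, 1, 1] sits at
# origin + 0.5 * (dy, dx, dz) in physical micrometres.

#' Construct an image volume
#'
#' @param data 3D numeric array, dim `(ny, nx, nz)`; non-negative integer
#'   gray levels.
#' @param voxel_size_um named numeric `c(z =, y =, x =)` spacing in um.
#' @param channel marker label of the imaged channel.
#' @param origin_um physical position `c(x =, y =, z =)` of the corner of
#'   voxel `[1, 1, 1]` (default the physical origin).
#' @param bit_depth gray-level bit depth (8 or 16).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_um, channel = "CD3",
                         origin_um = c(x = 0, y = 0, z = 0),
                         bit_depth = 16L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  voxel_size_um <- voxel_size_um[c("z", "y", "x")]
  if (any(is.na(voxel_size_um)) || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be a named vector c(z=, y=, x=) of positive ",
         "spacings")
  }
  origin_um <- origin_um[c("x", "y", "z")]
  stopifnot(!any(is.na(origin_um)), bit_depth %in% c(8L, 16L))
  if (min(data) < 0 || max(data) > 2^bit_depth - 1) {
    stop("intensities outside [0, 2^bit_depth - 1]")
  }
  structure(
    list(data = data, voxel_size_um = voxel_size_um, channel = channel,
         origin_um = origin_um, bit_depth = as.integer(bit_depth)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %s: %d x %d x %d voxels (y,x,z), voxel %g x %g x %g um (z,y,x)\n",
    x$channel, d[1], d[2], d[3],
    x$voxel_size_um[["z"]], x$voxel_size_um[["y"]], x$voxel_size_um[["x"]]))
  invisible(x)
}

#' Physical extent of a volume in micrometres
#'
#' @param volume an [image_volume()].
#' @return named numeric `c(x =, y =, z =)` extents.
#' @export
volume_extent_um <- function(volume) {
  d <- dim(volume$data)
  c(x = d[2] * volume$voxel_size_um[["x"]],
    y = d[1] * volume$voxel_size_um[["y"]],
    z = d[3] * volume$voxel_size_um[["z"]])
}

# physical centre coordinates of voxel indices (1-based)
voxel_centers_um <- function(volume, iy, ix, iz) {
  vs <- volume$voxel_size_um
  o <- volume$origin_um
  cbind(x = o[["x"]] + (ix - 0.5) * vs[["x"]],
        y = o[["y"]] + (iy - 0.5) * vs[["y"]],
        z = o[["z"]] + (iz - 0.5) * vs[["z"]])
}

#' Write / read an image volume as multi-page TIFF
#'
#' One page per z-plane, 16-bit (or 8-bit) grayscale. Because the TIFF
#' writer used here cannot embed description tags, the physical voxel sizes,
#' channel and origin are stored in a JSON sidecar `<path>.json`; reading a
#' TIFF without a sidecar requires an explicit `voxel_size_um` (never a
#' silent isotropy assumption).
#'
#' @param volume an [image_volume()].
#' @param path output `.tif` path.
#' @return `write_volume_tiff` returns `path` invisibly; `read_volume_tiff`
#'   returns an [image_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  maxv <- 2^volume$bit_depth - 1
  pages <- lapply(seq_len(dim(volume$data)[3]), function(k) {
    p <- volume$data[, , k, drop = FALSE] / maxv
    dim(p) <- dim(volume$data)[1:2]
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth,
                  compression = "deflate", reduce = FALSE)
  meta <- list(
    voxel_size_um = as.list(volume$voxel_size_um),
    channel = volume$channel,
    origin_um = as.list(volume$origin_um),
    bit_depth = volume$bit_depth,
    axes = "pages are z-planes; page rows = y, page cols = x",
    unit = "micron"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size_um override / supply voxel sizes `c(z=, y=, x=)` when no
#'   sidecar exists.
#' @param channel override channel label.
#' @export
read_volume_tiff <- function(path, voxel_size_um = NULL, channel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  if (is.null(voxel_size_um)) {
    if (is.null(meta)) {
      stop("no voxel-size metadata for ", path, " (sidecar ", sidecar,
           " missing) and no voxel_size_um supplied; refusing to assume ",
           "isotropic voxels")
    }
    voxel_size_um <- unlist(meta$voxel_size_um)
  }
  bit_depth <- if (!is.null(meta)) meta$bit_depth else 16L
  origin <- if (!is.null(meta)) unlist(meta$origin_um) else c(x = 0, y = 0, z = 0)
  if (is.null(channel)) channel <- if (!is.null(meta)) meta$channel else "CD3"
  maxv <- 2^bit_depth - 1
  d1 <- dim(pages[[1L]])
  data <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- round(pages[[k]] * maxv)
  image_volume(data, voxel_size_um = voxel_size_um, channel = channel,
               origin_um = origin, bit_depth = bit_depth)
}
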