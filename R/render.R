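# Forward model of light-sheet acquisition: cells rendered as anisotropic
# Gaussian blobs, peak amplitude decaying exponentially with imaging depth,
# constant background, Poisson shot noise, integer quantization. Then the
# z-tiler cuts overlapping optical sections the way the stage scan does.

#' Render a ground-truth point pattern into an image volume
#'
#' Each cell of the channel's marker becomes an anisotropic Gaussian blob
#' (sigma from the [channel_spec()]); its peak amplitude is
#' `amplitude * exp(-z / attenuation_length_um)`, emulating depth attenuation
#' in cleared tissue. A constant background offset is added, Poisson shot
#' noise is applied voxel-wise (unless `noise = FALSE`), and the result is
#' quantized to the configured bit depth with saturation.
#'
#' @param truth a [simulate_point_pattern()] result.
#' @param acq an [acq_config()]; the rendering grid uses its lateral pixel
#'   and plane step.
#' @param channel marker label; must name a channel in `acq$channels`.
#' @param seed integer seed for the shot noise.
#' @param amplitude peak signal in gray levels at depth 0.
#' @param background constant background offset in gray levels.
#' @param noise apply Poisson shot noise (default TRUE).
#' @param max_voxels guard against accidental huge fields: rendering more
#'   voxels than this errors instead of silently truncating.
#' @return an [image_volume()] covering the truth domain.
#' @export
render_volume <- function(truth, acq, channel, seed = 1L,
                          amplitude = 150, background = 20,
                          noise = TRUE, max_voxels = 2^27) {
  stopifnot(inherits(truth, "ground_truth"), inherits(acq, "acq_config"))
  if (!channel %in% names(acq$channels)) {
    stop("channel '", channel, "' not present in the acquisition config")
  }
  ch <- acq$channels[[channel]]
  ext <- truth$domain$extent_um
  dx <- acq$lateral_pixel_um
  dz <- acq$plane_step_um
  nx <- ceiling(ext[["x"]] / dx)
  ny <- ceiling(ext[["y"]] / dx)
  nz <- ceiling(ext[["z"]] / dz)
  if (as.numeric(nx) * ny * nz > max_voxels) {
    stop("rendered field would need ", format(as.numeric(nx) * ny * nz,
         big.mark = ","), " voxels, above the max_voxels guard (",
         format(max_voxels, big.mark = ","), "); reduce the domain or raise ",
         "the guard explicitly")
  }
  vol <- array(0, dim = c(ny, nx, nz))
  pts <- points_of_type(truth$points, channel)
  if (nrow(pts)) {
    sx <- ch$psf_sigma_xy_um / dx
    sy <- ch$psf_sigma_xy_um / dx
    sz <- ch$psf_sigma_z_um / dz
    hx <- max(1L, ceiling(4 * sx)); hy <- max(1L, ceiling(4 * sy))
    hz <- max(1L, ceiling(4 * sz))
    for (p in seq_len(nrow(pts))) {
      # fractional voxel position of the cell centre (voxel i spans
      # [(i-1)*d, i*d), centre at (i-0.5)*d)
      cx <- pts$x_um[p] / dx + 0.5
      cy <- pts$y_um[p] / dx + 0.5
      cz <- pts$z_um[p] / dz + 0.5
      a <- amplitude * exp(-pts$z_um[p] / ch$attenuation_length_um)
      ix <- max(1L, floor(cx - hx)):min(nx, ceiling(cx + hx))
      iy <- max(1L, floor(cy - hy)):min(ny, ceiling(cy + hy))
      iz <- max(1L, floor(cz - hz)):min(nz, ceiling(cz + hz))
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-((ix - cx)^2) / (2 * sx^2))
      gy <- exp(-((iy - cy)^2) / (2 * sy^2))
      gz <- exp(-((iz - cz)^2) / (2 * sz^2))
      blob <- a * (gy %o% gx %o% gz)
      vol[iy, ix, iz] <- vol[iy, ix, iz] + blob
    }
  }
  vol <- vol + background
  if (noise) {
    vol[] <- with_seed(split_seed(seed, 7001L),
                       stats::rpois(length(vol), lambda = as.vector(vol)))
  }
  maxv <- 2^acq$bit_depth - 1
  vol[] <- pmin(round(vol), maxv)
  image_volume(vol, voxel_size_um = c(z = dz, y = dx, x = dx),
               channel = channel, bit_depth = acq$bit_depth)
}

#' Cut a volume into overlapping z-sections
#'
#' Emulates the z-stage scan: optical sections of thickness
#' `section_depth_um` are taken every `z_stage_step_um` (16.7% overlap at
#' 300/250 um), the last section anchored so the full depth is covered. An
#' optional seeded jitter of up to `jitter_vox` planes displaces each
#' section's true content position from its nominal offset, to exercise
#' registration; true offsets are recorded.
#'
#' @param volume an [image_volume()] whose depth is at least one section.
#' @param acq an [acq_config()] providing section and step sizes.
#' @param seed integer seed for the jitter.
#' @param jitter_vox maximum |jitter| in planes (0 disables; default 2).
#' @return an object of class `tile_set`: list with `tiles` (each an
#'   `image_tile` with `volume`, `nominal_offset_um`, `tile_index`),
#'   `true_offsets_um`, and the plane spacing.
#' @export
tile_volume <- function(volume, acq, seed = 1L, jitter_vox = 2L) {
  stopifnot(inherits(volume, "image_volume"), inherits(acq, "acq_config"))
  dz <- volume$voxel_size_um[["z"]]
  nz <- dim(volume$data)[3]
  sec_vox <- round(acq$section_depth_um / dz)
  step_vox <- round(acq$z_stage_step_um / dz)
  if (nz < sec_vox) {
    stop("volume depth (", nz * dz, " um) is below one optical section (",
         acq$section_depth_um, " um)")
  }
  n_tiles <- if (nz == sec_vox) 1L else ceiling((nz - sec_vox) / step_vox) + 1L
  starts_nominal <- pmin((seq_len(n_tiles) - 1L) * step_vox, nz - sec_vox)
  jit <- if (jitter_vox > 0 && n_tiles > 1L) {
    j <- with_seed(split_seed(seed, 7002L),
                   sample(-jitter_vox:jitter_vox, n_tiles, replace = TRUE))
    j[1L] <- 0L  # first tile anchors the frame
    j
  } else rep(0L, n_tiles)
  starts_true <- pmax(0L, pmin(starts_nominal + jit, nz - sec_vox))
  tiles <- vector("list", n_tiles)
  for (k in seq_len(n_tiles)) {
    sub <- volume$data[, , (starts_true[k] + 1L):(starts_true[k] + sec_vox),
                       drop = FALSE]
    tiles[[k]] <- structure(
      list(volume = image_volume(sub, volume$voxel_size_um,
                                 channel = volume$channel,
                                 bit_depth = volume$bit_depth),
           nominal_offset_um = starts_nominal[k] * dz,
           tile_index = k),
      class = "image_tile"
    )
  }
  structure(
    list(tiles = tiles,
         true_offsets_um = starts_true * dz,
         plane_step_um = dz),
    class = "tile_set"
  )
}
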