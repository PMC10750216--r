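# Acquisition geometry of the light-sheet microscope: channel optics,
# sampling grid, and the z-tiling scheme used for post-stitching.

#' Specify one fluorescence channel
#'
#' A channel couples a marker label to its excitation wavelength, the depth
#' attenuation of that wavelength in cleared tissue, and the point-spread
#' function (PSF) widths used when rendering synthetic volumes. Defaults for
#' the attenuation length follow measured light-penetration depths in cleared
#' lymphoid tissue: ~660, 780 and 900 um at 488, 532 and 637 nm. The axial
#' PSF sigma defaults to the light-sheet thickness (3.5 um) treated as a
#' FWHM, i.e. 3.5 / (2 * sqrt(2 * log(2))) ~ 1.49 um.
#'
#' @param name marker label, e.g. "CD3".
#' @param excitation_nm excitation wavelength in nm (488, 532 or 637 pick a
#'   default attenuation length).
#' @param attenuation_length_um depth at which signal falls by 1/e, in um.
#' @param psf_sigma_xy_um lateral Gaussian PSF sigma in um.
#' @param psf_sigma_z_um axial Gaussian PSF sigma in um; must be >= the
#'   lateral sigma (light-sheet axial resolution is worse).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name,
                         excitation_nm = 488,
                         attenuation_length_um = NULL,
                         psf_sigma_xy_um = 1.0,
                         psf_sigma_z_um = 3.5 / (2 * sqrt(2 * log(2)))) {
  if (is.null(attenuation_length_um)) {
    attenuation_length_um <- switch(as.character(excitation_nm),
      "488" = 660, "532" = 780, "637" = 900,
      stop("no default attenuation length for ", excitation_nm,
           " nm; supply attenuation_length_um")
    )
  }
  stopifnot(
    is.character(name), length(name) == 1L, nzchar(name),
    attenuation_length_um > 0, psf_sigma_xy_um > 0
  )
  if (psf_sigma_z_um < psf_sigma_xy_um) {
    stop("psf_sigma_z_um must be >= psf_sigma_xy_um (axial resolution of a ",
         "light sheet cannot beat lateral)")
  }
  structure(
    list(name = name, excitation_nm = excitation_nm,
         attenuation_length_um = attenuation_length_um,
         psf_sigma_xy_um = psf_sigma_xy_um,
         psf_sigma_z_um = psf_sigma_z_um),
    class = "channel_spec"
  )
}

#' Acquisition configuration for a light-sheet scan
#'
#' Captures the sampling grid and tiling scheme: 0.59 um lateral pixels
#' (6.5 um camera pitch at x11.1 overall magnification), 2 um plane steps,
#' ~300 um optical sections advanced in 250 um z-stage steps so that
#' consecutive sections overlap by 16.7% for post-stitching.
#'
#' @param lateral_pixel_um object-space pixel size in um.
#' @param plane_step_um spacing between imaged planes in um.
#' @param tile_shape_px camera frame shape `(rows, cols)` per plane.
#' @param section_depth_um thickness of one optical section in um.
#' @param z_stage_step_um z-stage advance between sections in um; must not
#'   exceed `section_depth_um` (a gap between sections is rejected).
#' @param channels list of [channel_spec()] objects.
#' @param camera_pixel_um physical camera pixel pitch in um.
#' @param magnification overall detection magnification.
#' @param bit_depth camera bit depth.
#' @return an object of class `acq_config`.
#' @export
acq_config <- function(lateral_pixel_um = 0.59,
                       plane_step_um = 2.0,
                       tile_shape_px = c(2048L, 1024L),
                       section_depth_um = 300,
                       z_stage_step_um = 250,
                       channels = list(),
                       camera_pixel_um = 6.5,
                       magnification = 11.1,
                       bit_depth = 16L) {
  stopifnot(
    lateral_pixel_um > 0, plane_step_um > 0,
    length(tile_shape_px) == 2L, all(tile_shape_px > 0),
    section_depth_um > 0, z_stage_step_um > 0,
    camera_pixel_um > 0, magnification > 0, bit_depth %in% c(8L, 16L)
  )
  if (z_stage_step_um > section_depth_um) {
    stop("z_stage_step_um > section_depth_um would leave unimaged gaps ",
         "between sections")
  }
  if (length(channels)) {
    stopifnot(all(vapply(channels, inherits, logical(1), "channel_spec")))
    names(channels) <- vapply(channels, `[[`, character(1), "name")
  }
  structure(
    list(lateral_pixel_um = lateral_pixel_um,
         plane_step_um = plane_step_um,
         tile_shape_px = as.integer(tile_shape_px),
         section_depth_um = section_depth_um,
         z_stage_step_um = z_stage_step_um,
         channels = channels,
         camera_pixel_um = camera_pixel_um,
         magnification = magnification,
         bit_depth = as.integer(bit_depth)),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  lateral pixel: %.3g um, plane step: %.3g um\n",
              x$lateral_pixel_um, x$plane_step_um))
  cat(sprintf("  section %g um advanced by %g um (overlap %.1f%%)\n",
              x$section_depth_um, x$z_stage_step_um,
              100 * z_overlap_fraction(x$section_depth_um,
                                       x$z_stage_step_um)))
  cat(sprintf("  channels: %s\n",
              if (length(x$channels)) paste(names(x$channels), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Object-space pixel size from camera pitch and magnification
#'
#' @param camera_pixel_um camera pixel pitch in um (e.g. 6.5 for an sCMOS).
#' @param magnification overall detection magnification.
#' @return pixel size in um in object space.
#' @export
#' @examples
#' object_pixel_size_um(6.5, 11.1)  # ~0.59 um
object_pixel_size_um <- function(camera_pixel_um, magnification) {
  stopifnot(camera_pixel_um > 0, magnification > 0)
  camera_pixel_um / magnification
}

#' Overall magnification from objective and tube-lens focal lengths
#'
#' An infinity-corrected objective's nominal magnification assumes the
#' manufacturer's reference tube lens (180 mm for Olympus); a different tube
#' lens rescales it: M = nominal * f_tube / f_reference. A 10x objective with
#' a 200 mm tube lens gives x11.1.
#'
#' @param objective_mag nominal objective magnification.
#' @param tube_focal_mm tube-lens focal length in mm.
#' @param reference_focal_mm manufacturer reference focal length in mm.
#' @return overall magnification.
#' @export
overall_magnification <- function(objective_mag, tube_focal_mm,
                                  reference_focal_mm = 180) {
  stopifnot(objective_mag > 0, tube_focal_mm > 0, reference_focal_mm > 0)
  objective_mag * tube_focal_mm / reference_focal_mm
}

#' Fractional overlap between consecutive z-sections
#'
#' @param section_depth_um optical-section thickness in um.
#' @param z_stage_step_um z-stage advance in um.
#' @return overlap fraction in `[0, 1)`; 300 um sections at 250 um steps
#'   give 1/6 ~ 16.7%.
#' @export
z_overlap_fraction <- function(section_depth_um, z_stage_step_um) {
  stopifnot(section_depth_um > 0, z_stage_step_um > 0,
            z_stage_step_um <= section_depth_um)
  (section_depth_um - z_stage_step_um) / section_depth_um
}

#' Depth gain of volumetric imaging over thin sections
#'
#' Ratio of the imaged tissue depth to a conventional histology section
#' thickness; ~1000 um imaged depth versus 4-5 um sections exceeds 100x.
#'
#' @param imaged_depth_um total imaged depth in um.
#' @param section_thickness_um conventional section thickness in um.
#' @return the fold expansion (dimensionless).
#' @export
depth_expansion_fold <- function(imaged_depth_um, section_thickness_um) {
  stopifnot(imaged_depth_um > 0, section_thickness_um > 0)
  imaged_depth_um / section_thickness_um
}
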