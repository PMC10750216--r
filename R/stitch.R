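# Registration and fusion of overlapping z-sections. Registration is
# integer-voxel z-translation by normalized cross-correlation over the
# nominal overlap, matching the acquisition's pure z-stage scan pattern.

#' Estimate the z-offset between two overlapping tiles
#'
#' Searches integer plane offsets within `search_radius_um` of the nominal
#' relative offset and returns the one maximizing the normalized
#' cross-correlation (Pearson) over the overlap region; ties and flat
#' (zero-variance) overlaps fall back to the nominal offset (score 0 with a
#' warning for flat overlaps).
#'
#' @param tile_a,tile_b `image_tile` objects from [tile_volume()] (tile_b
#'   deeper than tile_a).
#' @param search_radius_um search half-width around the nominal offset, um.
#' @return list with `offset_um` (refined offset of `tile_b` relative to the
#'   volume origin of `tile_a`), `score` (peak correlation in `[-1, 1]`).
#' @export
estimate_offset <- function(tile_a, tile_b, search_radius_um = 10) {
  stopifnot(inherits(tile_a, "image_tile"), inherits(tile_b, "image_tile"))
  dz <- tile_a$volume$voxel_size_um[["z"]]
  a <- tile_a$volume$data; b <- tile_b$volume$data
  nza <- dim(a)[3]; nzb <- dim(b)[3]
  nominal_vox <- round((tile_b$nominal_offset_um - tile_a$nominal_offset_um) / dz)
  if (nza - nominal_vox < 10L) {
    stop("nominal overlap below 10 planes; cannot register")
  }
  radius_vox <- max(0L, round(search_radius_um / dz))
  cands <- nominal_vox + (-radius_vox):radius_vox
  cands <- cands[cands >= 0L & cands < nza]
  # try candidates nearest-to-nominal first so ties resolve toward nominal
  cands <- cands[order(abs(cands - nominal_vox), cands)]
  best <- list(off = nominal_vox, score = -Inf)
  flat <- TRUE
  for (o in cands) {
    n_ov <- min(nza - o, nzb)
    if (n_ov < 10L) next
    sa <- as.vector(a[, , (o + 1L):(o + n_ov)])
    sb <- as.vector(b[, , 1:n_ov])
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    flat <- FALSE
    sc <- stats::cor(sa, sb)
    if (sc > best$score) best <- list(off = o, score = sc)
  }
  if (flat || !is.finite(best$score)) {
    warning("flat overlap (zero variance); returning nominal offset with ",
            "score 0")
    return(list(offset_um = tile_a$nominal_offset_um + nominal_vox * dz,
                score = 0))
  }
  list(offset_um = tile_a$nominal_offset_um + best$off * dz,
       score = best$score)
}

#' Fuse z-tiles into one volume
#'
#' Tiles are placed at the given integer-voxel offsets; inside each overlap
#' the contributions are blended with a linear ramp (weight proportional to
#' the distance to the tile's z-faces, normalized so weights sum to one at
#' every voxel), which preserves constants and copies voxels verbatim where
#' only one tile contributes.
#'
#' @param tiles list of `image_tile` objects (or a `tile_set`).
#' @param offsets_um numeric vector of per-tile z-offsets in um; must define
#'   a connected chain (each tile overlaps the union of its predecessors).
#' @return the fused [image_volume()].
#' @export
fuse_tiles <- function(tiles, offsets_um) {
  if (inherits(tiles, "tile_set")) tiles <- tiles$tiles
  stopifnot(length(tiles) >= 1L, length(offsets_um) == length(tiles))
  v1 <- tiles[[1L]]$volume
  dz <- v1$voxel_size_um[["z"]]
  off_vox <- round(offsets_um / dz)
  nz_each <- vapply(tiles, function(t) dim(t$volume$data)[3], integer(1))
  ord <- order(off_vox)
  cover_end <- off_vox[ord[1L]] + nz_each[ord[1L]]
  for (k in ord[-1L]) {
    if (off_vox[k] > cover_end) {
      stop("tiles do not form a connected chain in z (gap before tile ",
           tiles[[k]]$tile_index, ")")
    }
    cover_end <- max(cover_end, off_vox[k] + nz_each[k])
  }
  z0 <- min(off_vox)
  nz_out <- max(off_vox + nz_each) - z0
  d <- dim(v1$data)
  acc <- array(0, c(d[1], d[2], nz_out))
  wsum <- rep(0, nz_out)
  for (k in seq_along(tiles)) {
    nz <- nz_each[k]
    # ramp: distance to nearest z-face, in planes (>= 1 at every plane)
    w <- pmin(seq_len(nz), nz + 1L - seq_len(nz))
    idx <- (off_vox[k] - z0) + seq_len(nz)
    for (j in seq_len(nz)) {
      acc[, , idx[j]] <- acc[, , idx[j]] + w[j] * tiles[[k]]$volume$data[, , j]
    }
    wsum[idx] <- wsum[idx] + w
  }
  for (j in seq_len(nz_out)) acc[, , j] <- acc[, , j] / wsum[j]
  maxv <- 2^v1$bit_depth - 1
  acc[] <- pmin(pmax(round(acc), 0), maxv)
  image_volume(acc, v1$voxel_size_um, channel = v1$channel,
               origin_um = c(x = 0, y = 0, z = z0 * dz),
               bit_depth = v1$bit_depth)
}

#' Register and fuse a tile set
#'
#' Chains [estimate_offset()] over consecutive tile pairs and fuses with
#' [fuse_tiles()].
#'
#' @param tile_set a [tile_volume()] result.
#' @param search_radius_um registration search half-width in um.
#' @return an object of class `stitch_result`: `fused` volume,
#'   `refined_offsets_um`, and per-pair `scores`.
#' @export
stitch_tiles <- function(tile_set, search_radius_um = 10) {
  stopifnot(inherits(tile_set, "tile_set"))
  tiles <- tile_set$tiles
  n <- length(tiles)
  offsets <- numeric(n)
  scores <- numeric(max(0L, n - 1L))
  offsets[1L] <- tiles[[1L]]$nominal_offset_um
  if (n > 1L) {
    for (k in 2:n) {
      est <- estimate_offset(tiles[[k - 1L]], tiles[[k]], search_radius_um)
      # estimate is relative to tile k-1's nominal frame; re-anchor on the
      # refined position of tile k-1
      offsets[k] <- offsets[k - 1L] +
        (est$offset_um - tiles[[k - 1L]]$nominal_offset_um)
      scores[k - 1L] <- est$score
    }
  }
  structure(
    list(fused = fuse_tiles(tiles, offsets),
         refined_offsets_um = offsets, scores = scores),
    class = "stitch_result"
  )
}
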