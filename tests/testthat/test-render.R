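test_that("empty point set renders background plus noise only", {
  dom <- domain_box(60, 60, 60)
  gt <- fixed_truth(numeric(0), numeric(0), numeric(0), character(0), dom)
  acq <- test_acq("CD3")
  vol <- render_volume(gt, acq, "CD3", seed = 2L, background = 50)
  m <- mean(vol$data)
  se <- sd(vol$data) / sqrt(length(vol$data))
  expect_lt(abs(m - 50), 3 * max(se, 0.05))
})

test_that("peak amplitude attenuates by e over one attenuation length", {
  acq <- acq_config(channels = list(
    channel_spec("CD3", attenuation_length_um = 100)))
  dom <- domain_box(40, 40, 220)
  gt <- fixed_truth(c(20, 20), c(20, 20), c(10, 110), c("CD3", "CD3"), dom)
  vol <- render_volume(gt, acq, "CD3", noise = FALSE, amplitude = 2000,
                       background = 0)
  plane <- function(z_um) max(vol$data[, , round(z_um / 2)])
  ratio <- plane(10) / plane(110)
  expect_lt(abs(ratio - exp(1)), 0.05 * exp(1))
})

test_that("noise-free blob centroid sits within a quarter voxel of truth", {
  dom <- domain_box(40, 40, 60)
  gt <- fixed_truth(20.3, 19.7, 30.9, "CD3", dom)
  acq <- test_acq("CD3")
  vol <- render_volume(gt, acq, "CD3", noise = FALSE, amplitude = 3000,
                       background = 0)
  w <- vol$data
  iy <- slice.index(w, 1); ix <- slice.index(w, 2); iz <- slice.index(w, 3)
  cx <- (sum(ix * w) / sum(w) - 0.5) * 0.59
  cy <- (sum(iy * w) / sum(w) - 0.5) * 0.59
  cz <- (sum(iz * w) / sum(w) - 0.5) * 2.0
  expect_lt(abs(cx - 20.3), 0.25 * 0.59)
  expect_lt(abs(cy - 19.7), 0.25 * 0.59)
  expect_lt(abs(cz - 30.9), 0.25 * 2.0)
})

test_that("rendering is seed-deterministic and guarded against huge fields", {
  dom <- domain_box(50, 50, 40)
  gt <- fixed_truth(25, 25, 20, "CD3", dom)
  acq <- test_acq("CD3")
  a <- render_volume(gt, acq, "CD3", seed = 9L)
  b <- render_volume(gt, acq, "CD3", seed = 9L)
  expect_identical(a$data, b$data)
  expect_error(render_volume(gt, acq, "CD3", max_voxels = 1000),
               "max_voxels")
  expect_error(render_volume(gt, acq, "CD8"), "not present")
})

test_that("tiling arithmetic covers the depth with the stated overlap", {
  acq <- test_acq("CD3")
  dom <- domain_box(30, 30, 1000)
  gt <- fixed_truth(numeric(0), numeric(0), numeric(0), character(0), dom)
  vol <- render_volume(gt, acq, "CD3", seed = 1L)
  ts <- tile_volume(vol, acq, jitter_vox = 0L)
  # ceil((1000 - 300) / 250) + 1 = 4 sections
  expect_length(ts$tiles, 4L)
  expect_true(all(ts$true_offsets_um[-4L] %% 250 == 0))
  # single section when the volume is exactly one section deep
  dom2 <- domain_box(30, 30, 300)
  gt2 <- fixed_truth(numeric(0), numeric(0), numeric(0), character(0), dom2)
  v2 <- render_volume(gt2, acq, "CD3", seed = 1L)
  ts2 <- tile_volume(v2, acq)
  expect_length(ts2$tiles, 1L)
  expect_equal(ts2$true_offsets_um, 0)
  # too-shallow volume is rejected
  dom3 <- domain_box(30, 30, 100)
  gt3 <- fixed_truth(numeric(0), numeric(0), numeric(0), character(0), dom3)
  v3 <- render_volume(gt3, acq, "CD3", seed = 1L)
  expect_error(tile_volume(v3, acq), "below one optical section")
})

test_that("log peak amplitude is linear in depth with slope -1/L", {
  L <- 150
  acq <- acq_config(channels = list(
    channel_spec("CD3", attenuation_length_um = L)))
  depths <- seq(20, 380, by = 40)
  dom <- domain_box(40, 40, 400)
  gt <- fixed_truth(rep(20, length(depths)), rep(20, length(depths)),
                    depths, "CD3", dom)
  vol <- render_volume(gt, acq, "CD3", noise = FALSE, amplitude = 5000,
                       background = 0)
  peaks <- vapply(depths, function(z) {
    zi <- max(1, round(z / 2) - 2):min(dim(vol$data)[3], round(z / 2) + 2)
    max(vol$data[, , zi])
  }, numeric(1))
  fit <- lm(log(peaks) ~ depths)
  expect_lt(abs(coef(fit)[2] + 1 / L), 0.02 / L)
  expect_gt(summary(fit)$r.squared, 0.999)
})
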