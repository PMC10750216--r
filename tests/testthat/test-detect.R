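# Detection tests run at the matched filter scale: synthetic cells are
# rendered as PSF-sized blobs, so the apparent diameter is ~4 um.
det4 <- function(...) detection_params(expected_diameter_um = 4, ...)

test_that("a single noise-free blob is found within 1 um of truth", {
  dom <- domain_box(40, 40, 60)
  gt <- fixed_truth(20.3, 19.7, 30.9, "CD3", dom)
  vol <- render_volume(gt, test_acq("CD3"), "CD3", noise = FALSE,
                       amplitude = 3000, background = 10)
  det <- detect_spots(vol, det4())
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x_um - 20.3)^2 + (det$y_um - 19.7)^2 +
                 (det$z_um - 30.9)^2), 1)
})

test_that("well-separated cells are each detected exactly once", {
  dom <- domain_box(60, 60, 60)
  gt <- fixed_truth(c(20, 40), c(20, 40), c(20, 40), "CD3", dom)
  vol <- render_volume(gt, test_acq("CD3"), "CD3", noise = FALSE,
                       amplitude = 3000, background = 10)
  det <- detect_spots(vol, det4())
  expect_equal(nrow(det), 2L)
  mr <- match_detections(det, gt$points, tol_um = 2)
  expect_equal(mr$precision, 1.0)
  expect_equal(mr$recall, 1.0)
})

test_that("non-maximum suppression keeps one of two near-coincident blobs", {
  dom <- domain_box(40, 40, 40)
  # separation 1 um, below min_separation 2 um at diameter 4
  gt <- fixed_truth(c(20, 21), c(20, 20), c(20, 20), "CD3", dom)
  vol <- render_volume(gt, test_acq("CD3"), "CD3", noise = FALSE,
                       amplitude = 3000, background = 10)
  det <- detect_spots(vol, det4())
  expect_equal(nrow(det), 1L)
})

test_that("degenerate volumes and unresolvable diameters error or return empty", {
  flat <- image_volume(array(7, c(20, 20, 20)),
                       c(z = 2, y = 0.59, x = 0.59), "CD3")
  expect_equal(nrow(detect_spots(flat, det4())), 0L)
  expect_error(detect_spots(flat, detection_params(expected_diameter_um = 1)),
               "unresolvable|under 2 voxels")
})

test_that("detection is translation-equivariant for interior spots", {
  dom <- domain_box(50, 50, 60)
  gt <- fixed_truth(20, 22, 24, "CD3", dom)
  acq <- test_acq("CD3")
  vol <- render_volume(gt, acq, "CD3", noise = FALSE, amplitude = 3000,
                       background = 10)
  # shift content by 5 voxels in x, 3 in y, 2 planes in z
  sh <- array(10, dim(vol$data))
  d <- dim(vol$data)
  sh[(1 + 3):d[1], (1 + 5):d[2], (1 + 2):d[3]] <-
    vol$data[1:(d[1] - 3), 1:(d[2] - 5), 1:(d[3] - 2)]
  vol2 <- image_volume(sh, vol$voxel_size_um, "CD3")
  d1 <- detect_spots(vol, det4())
  d2 <- detect_spots(vol2, det4())
  expect_equal(nrow(d1), 1L)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$x_um - d1$x_um, 5 * 0.59, tolerance = 1e-6)
  expect_equal(d2$y_um - d1$y_um, 3 * 0.59, tolerance = 1e-6)
  expect_equal(d2$z_um - d1$z_um, 2 * 2.0, tolerance = 1e-6)
})

test_that("raising the quality threshold never increases detections", {
  dom <- domain_box(60, 60, 80)
  pts <- hardcore_points(25, c(60, 60, 80), 8, seed = 21L)
  gt <- fixed_truth(pts[, 1], pts[, 2], pts[, 3], "CD3", dom)
  vol <- render_volume(gt, test_acq("CD3"), "CD3", seed = 4L,
                       amplitude = 80, background = 20)
  base <- detect_spots(vol, det4(quality_threshold = 0))
  thresholds <- quantile(base$quality, c(0, 0.25, 0.5, 0.75, 0.95))
  counts <- vapply(thresholds, function(th) {
    nrow(detect_spots(vol, det4(quality_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy matching equals optimal assignment on small instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    truth <- uniform_points(n, c(100, 100, 100), "CD3", seed)
    jitter <- matrix(rnorm(3 * n, sd = 1), ncol = 3)
    det <- cell_points(truth$x_um + jitter[, 1], truth$y_um + jitter[, 2],
                       truth$z_um + jitter[, 3], "CD3")
    mr <- match_detections(det, truth, tol_um = 50)
    dist <- sqrt(outer(det$x_um, truth$x_um, "-")^2 +
                 outer(det$y_um, truth$y_um, "-")^2 +
                 outer(det$z_um, truth$z_um, "-")^2)
    expect_equal(nrow(mr$matches), oracle_max_matching(dist, 50))
  }
})

test_that("match_detections handles degenerate inputs per contract", {
  p <- uniform_points(9, c(50, 50, 50), "CD3", 3L)
  self <- match_detections(p, p, tol_um = 1)
  expect_equal(self$precision, 1.0)
  expect_equal(self$recall, 1.0)
  extra <- cell_points(c(p$x_um, 500), c(p$y_um, 500), c(p$z_um, 500), "CD3",
                       validate_markers = FALSE)
  mr <- match_detections(extra, p, tol_um = 1)
  expect_equal(mr$precision, 0.9)
  expect_equal(mr$recall, 1.0)
  empty <- cell_points()
  expect_warning(et <- match_detections(p, empty, tol_um = 1), "recall")
  expect_equal(et$precision, 0)
  expect_true(is.nan(et$recall))
})
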