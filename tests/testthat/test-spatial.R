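test_that("density is count over ROI volume with half-open bounds", {
  r <- roi(0, 100, 0, 100, 0, 100)
  expect_equal(compute_density(cell_points(), r, "CD3"), 0)
  set.seed(1)
  p <- uniform_points(100, c(100, 100, 100), "CD3", 2L)
  expect_equal(compute_density(p, r, "CD3"), 100 / 0.001)
  # a point on the upper face is outside
  edge <- cell_points(c(50, 100), c(50, 50), c(50, 50), "CD3")
  expect_equal(compute_density(edge, r, "CD3"), 1 / 0.001)
  expect_error(roi(0, 0, 0, 1, 0, 1), "positive extent")
})

test_that("Poisson density is recovered within sampling error", {
  dom <- domain_box(500, 500, 400)
  gt <- simulate_point_pattern(dom,
    list(population_spec("CD3", 1e-4, "poisson")), seed = 31L)
  r <- roi(50, 450, 50, 450, 50, 350)
  V_um3 <- 400 * 400 * 300
  est <- compute_density(gt$points, r, "CD3")
  lam_mm3 <- 1e-4 * 1e9
  se <- sqrt(1e-4 * V_um3) / (V_um3 * 1e-9)
  expect_lt(abs(est - lam_mm3), 3 * se)
})

test_that("radial profile bins follow the half-open 5-um convention", {
  ctr <- cell_points(0, 0, 0, "CD3")
  nb <- cell_points(c(7, 50, 49.999), c(0, 0, 0), c(0, 0, 0), "CD20")
  pr <- radial_neighbor_profile(ctr, nb)
  expect_equal(length(pr$total_count), 10L)
  expect_equal(pr$total_count[2], 1L)          # 7 um -> [5,10)
  expect_equal(pr$total_count[10], 1L)         # 49.999 -> [45,50)
  expect_equal(sum(pr$total_count), 2L)        # the 50-um point is excluded
  expect_equal(pr$mean_count_per_center, pr$total_count / 1)
  expect_error(radial_neighbor_profile(ctr, nb, bin_um = 7), "divide")
  expect_warning(pr0 <- radial_neighbor_profile(cell_points(), nb),
                 "no center")
  expect_true(all(is.nan(pr0$mean_count_per_center)))
})

test_that("coincident same-marker records are not their own neighbors", {
  p <- cell_points(c(10, 20), c(10, 20), c(10, 10), "CD3")
  pr <- radial_neighbor_profile(p, p)
  # each center sees the other at ~14.1 um but never itself
  expect_equal(sum(pr$total_count), 2L)
  expect_equal(pr$total_count[3], 2L)  # sqrt(200) ~ 14.14 -> [10,15)
})

test_that("conjugation respects the strict 15-um bound", {
  a <- cell_points(0, 0, 0, "CD3")
  b15 <- cell_points(15, 0, 0, "CD20")
  b149 <- cell_points(14.9, 0, 0, "CD20")
  expect_equal(conjugation_count(a, b15)$pair_count, 0L)
  expect_equal(conjugation_count(a, b149)$pair_count, 1L)
  expect_error(conjugation_count(a, cell_points(1, 1, 1, "CD3")),
               "different cell types")
})

test_that("grid-indexed counts equal brute-force loops on seeded instances", {
  for (seed in 1:8) {
    set.seed(seed)
    na <- sample(50:300, 1); nb <- sample(50:300, 1)
    ext <- c(200, 200, 150)
    pa <- uniform_points(na, ext, "CD3", seed * 2L)
    pb <- uniform_points(nb, ext, "CD20", seed * 2L + 1L)
    expect_identical(conjugation_count(pa, pb)$pair_count,
                     oracle_conjugation(pa, pb, 15))
    pr <- radial_neighbor_profile(pa, pb, edge_policy = "none")
    expect_identical(pr$total_count, oracle_radial_bins(pa, pb, 50, 5))
  }
})

test_that("radial bin totals integrate to the 50-um neighbor count", {
  pa <- uniform_points(150, c(300, 300, 200), "CD3", 41L)
  pb <- uniform_points(400, c(300, 300, 200), "CD20", 42L)
  pr <- radial_neighbor_profile(pa, pb, edge_policy = "none")
  direct <- 0L
  for (i in seq_len(nrow(pa))) {
    d <- sqrt((pb$x_um - pa$x_um[i])^2 + (pb$y_um - pa$y_um[i])^2 +
              (pb$z_um - pa$z_um[i])^2)
    direct <- direct + sum(d < 50)
  }
  expect_identical(sum(pr$total_count), direct)
})

test_that("counts are equivariant under joint rescaling of space", {
  pa <- uniform_points(120, c(200, 200, 200), "CD3", 51L)
  pb <- uniform_points(120, c(200, 200, 200), "CD20", 52L)
  for (c_scale in c(0.5, 2, 10)) {
    sa <- cell_points(pa$x_um * c_scale, pa$y_um * c_scale,
                      pa$z_um * c_scale, "CD3")
    sb <- cell_points(pb$x_um * c_scale, pb$y_um * c_scale,
                      pb$z_um * c_scale, "CD20")
    expect_identical(
      conjugation_count(sa, sb, d_max_um = 15 * c_scale)$pair_count,
      conjugation_count(pa, pb, d_max_um = 15)$pair_count)
    expect_identical(
      radial_neighbor_profile(sa, sb, r_max_um = 50 * c_scale,
                              bin_um = 5 * c_scale,
                              edge_policy = "none")$total_count,
      radial_neighbor_profile(pa, pb, edge_policy = "none")$total_count)
  }
})

test_that("interior Poisson shell counts match the closed form", {
  # lambda = 1e-4/um^3 neighbors; centers restricted to the interior so
  # every 50-um ball is fully observed
  ext <- c(500, 500, 400)
  lam <- 1e-4
  dom <- domain_box(ext[1], ext[2], ext[3])
  gt <- simulate_point_pattern(dom, list(
    population_spec("CD20", lam, "poisson"),
    population_spec("CD3", 3e-5, "poisson")), seed = 61L)
  r <- roi(0, ext[1], 0, ext[2], 0, ext[3])
  pr <- radial_neighbor_profile(points_of_type(gt$points, "CD3"),
                                points_of_type(gt$points, "CD20"),
                                roi = r, edge_policy = "interior_only")
  expect_gt(pr$n_centers, 500)
  lo <- pr$bin_edges_um[-11]; hi <- pr$bin_edges_um[-1]
  expected <- lam * 4 / 3 * pi * (hi^3 - lo^3)
  se <- sqrt(expected / pr$n_centers)
  z <- (pr$mean_count_per_center - expected) / se
  expect_true(all(abs(z) < 3))
})

test_that("copositivity is a one-to-one greedy fraction", {
  base <- uniform_points(50, c(200, 200, 200), "CD8", 71L)
  co <- copositivity(base, base)
  expect_equal(co$ratio, 1.0)
  far <- cell_points(base$x_um + 100, base$y_um, base$z_um, "Ki67",
                     validate_markers = FALSE)
  expect_equal(copositivity(far, base)$ratio, 0.0)
  # one marker point cannot validate two base cells
  b2 <- cell_points(c(0, 1), c(0, 0), c(0, 0), "CD8")
  m1 <- cell_points(0.2, 0, 0, "Ki67")
  expect_equal(copositivity(m1, b2)$n_double, 1L)
  expect_warning(e <- copositivity(m1, cell_points()), "empty base")
  expect_true(is.nan(e$ratio))
})

test_that("synthetic co-positive fraction is recovered", {
  dom <- domain_box(400, 400, 300)
  gt <- simulate_point_pattern(dom, list(
    population_spec("CD8", 1000 / (400 * 400 * 300), "poisson",
                    copositive_with = list(marker = "Ki67", fraction = 0.3))
  ), seed = 81L)
  base <- points_of_type(gt$points, "CD8")
  ki <- points_of_type(gt$points, "Ki67")
  co <- copositivity(ki, base)
  expect_lt(abs(co$ratio - 0.3), 3 * sqrt(0.3 * 0.7 / co$n_base))
})

test_that("ROI selection is seeded, disjoint and in-bounds", {
  dom <- domain_box(1000, 1000, 500)
  rois <- select_rois(dom, n = 10, roi_shape_um = c(200, 200, 200),
                      seed = 5L)
  expect_length(rois, 10L)
  for (i in seq_along(rois)) {
    b <- rois[[i]]$bounds_um
    expect_true(b["x0"] >= 0 && b["x1"] <= 1000 && b["y0"] >= 0 &&
                b["y1"] <= 1000 && b["z0"] >= 0 && b["z1"] <= 500)
    for (j in seq_len(i - 1L)) {
      a <- rois[[j]]$bounds_um
      sep <- max(b["x0"] - a["x1"], a["x0"] - b["x1"],
                 b["y0"] - a["y1"], a["y0"] - b["y1"],
                 b["z0"] - a["z1"], a["z0"] - b["z1"])
      expect_gte(sep, 0)
    }
  }
  again <- select_rois(dom, n = 10, roi_shape_um = c(200, 200, 200),
                       seed = 5L)
  expect_identical(rois, again)
  # n = 1 with ROI = domain returns the domain itself
  solo <- select_rois(dom, n = 1, roi_shape_um = c(1000, 1000, 500),
                      seed = 1L)
  b <- solo[[1L]]$bounds_um
  expect_equal(unname(b[c("x1", "y1", "z1")]), c(1000, 1000, 500))
  expect_error(select_rois(dom, n = 500, roi_shape_um = c(200, 200, 200),
                           seed = 1L, max_attempts = 2000L),
               "could not place")
})
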