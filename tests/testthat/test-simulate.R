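test_that("zero-intensity population yields an empty point set", {
  gt <- simulate_point_pattern(domain_box(100, 100, 100),
                               list(population_spec("CD3", 0, "poisson")),
                               seed = 1L)
  expect_equal(nrow(gt$points), 0L)
})

test_that("Poisson counts match the intensity within sampling error", {
  dom <- domain_box(1000, 1000, 500)
  lambdaV <- 1e-4 * 1000 * 1000 * 500  # 50,000
  gt <- simulate_point_pattern(dom,
                               list(population_spec("CD3", 1e-4, "poisson")),
                               seed = 42L)
  expect_lt(abs(nrow(gt$points) - lambdaV), 4 * sqrt(lambdaV))
  expect_true(all(in_bounds <- gt$points$x_um >= 0 & gt$points$x_um < 1000 &
                    gt$points$y_um >= 0 & gt$points$y_um < 1000 &
                    gt$points$z_um >= 0 & gt$points$z_um < 500))
})

test_that("Poisson counts are equidispersed over replicates", {
  dom <- domain_box(100, 100, 100)  # lambda V = 1000 at 1e-3/um^3
  counts <- vapply(1:500, function(k) {
    nrow(simulate_point_pattern(dom,
      list(population_spec("CD3", 1e-3, "poisson")), seed = 1000L + k)$points)
  }, numeric(1))
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)
})

test_that("regeneration with the same seed is bit-identical", {
  dom <- domain_box(300, 300, 150)
  specs <- list(
    population_spec("CD3", 1e-4, "poisson"),
    population_spec("CD20", 1e-4, "thomas_cluster",
                    cluster_params = list(parent_intensity_per_um3 = 5e-6,
                                          mean_offspring = 8, sigma_um = 10)),
    population_spec("FOXP3", 5e-5, "paired_attraction",
                    attraction_params = list(anchor = "CD3",
                                             attached_fraction = 0.5,
                                             max_distance_um = 12))
  )
  a <- simulate_point_pattern(dom, specs, seed = 7L)
  b <- simulate_point_pattern(dom, specs, seed = 7L)
  expect_identical(a$points, b$points)
  c <- simulate_point_pattern(dom, specs, seed = 8L)
  expect_false(identical(a$points, c$points))
})

test_that("fully attached cells are conjugates of their anchors", {
  dom <- domain_box(400, 400, 200)
  specs <- list(
    population_spec("CD3", 200 / (400 * 400 * 200), "poisson"),
    population_spec("CD20", 2e-5, "paired_attraction",
                    attraction_params = list(anchor = "CD3",
                                             attached_fraction = 1.0,
                                             max_distance_um = 12))
  )
  gt <- simulate_point_pattern(dom, specs, seed = 3L)
  anchors <- points_of_type(gt$points, "CD3")
  attached <- points_of_type(gt$points, "CD20")
  expect_gt(nrow(attached), 0L)
  for (i in seq_len(nrow(attached))) {
    dmin <- min(sqrt((anchors$x_um - attached$x_um[i])^2 +
                     (anchors$y_um - attached$y_um[i])^2 +
                     (anchors$z_um - attached$z_um[i])^2))
    expect_lt(dmin, 15)
  }
})

test_that("co-positive duplicates share coordinates under the second label", {
  dom <- domain_box(300, 300, 150)
  gt <- simulate_point_pattern(dom, list(
    population_spec("CD8", 1e-4, "poisson",
                    copositive_with = list(marker = "Ki67", fraction = 0.3))
  ), seed = 5L)
  base <- points_of_type(gt$points, "CD8")
  ki <- points_of_type(gt$points, "Ki67")
  expect_gt(nrow(ki), 0L)
  key <- function(p) paste(p$x_um, p$y_um, p$z_um)
  expect_true(all(key(ki) %in% key(base)))
  frac <- nrow(ki) / nrow(base)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(base)))
})

test_that("anchor dependencies are ordered and cycles rejected", {
  specs <- list(
    population_spec("CD20", 1e-5, "paired_attraction",
                    attraction_params = list(anchor = "CD3",
                                             attached_fraction = 0.5,
                                             max_distance_um = 10)),
    population_spec("CD3", 1e-4, "poisson")
  )
  gt <- simulate_point_pattern(domain_box(200, 200, 100), specs, seed = 1L)
  expect_true(all(c("CD3", "CD20") %in% gt$points$marker))

  cyc <- list(
    population_spec("CD20", 1e-5, "paired_attraction",
                    attraction_params = list(anchor = "CD3",
                                             attached_fraction = 0.5,
                                             max_distance_um = 10)),
    population_spec("CD3", 1e-5, "paired_attraction",
                    attraction_params = list(anchor = "CD20",
                                             attached_fraction = 0.5,
                                             max_distance_um = 10))
  )
  expect_error(simulate_point_pattern(domain_box(100, 100, 100), cyc, 1L),
               "cyclic|unsatisfiable")
})

test_that("invalid population specs are rejected", {
  expect_error(population_spec("CD3", -1, "poisson"), ">= 0")
  expect_error(population_spec("CD20", 1e-5, "paired_attraction",
    attraction_params = list(anchor = "CD3", attached_fraction = 0.5,
                             max_distance_um = 15)), "< 15")
  expect_error(population_spec("CD20", 1e-5, "paired_attraction",
    attraction_params = list(anchor = "CD3", attached_fraction = 1.2,
                             max_distance_um = 10)), "\\[0, 1\\]")
})
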