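# Programmatic fixtures shared across test files.

# ground truth at given coordinates without running the simulator
fixed_truth <- function(x, y, z, marker, domain) {
  structure(
    list(points = cell_points(x, y, z, marker), specs = list(),
         seed = 0L, domain = domain),
    class = "ground_truth"
  )
}

# acquisition config with one channel per marker (defaults as packaged)
test_acq <- function(markers = "CD3") default_acq_config(markers)

# random points with a hard-core minimum spacing (sequential rejection)
hardcore_points <- function(n_target, extent, min_dist, seed,
                            margin = 5) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  while (nrow(pts) < n_target && attempts < 50L * n_target) {
    attempts <- attempts + 1L
    cand <- margin + runif(3) * (extent - 2 * margin)
    if (nrow(pts) == 0L ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_dist) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

# uniform points in a box as a cell_points object
uniform_points <- function(n, extent, marker, seed) {
  set.seed(seed)
  cell_points(runif(n, 0, extent[1]), runif(n, 0, extent[2]),
              runif(n, 0, extent[3]), marker)
}

# per-test scratch directory under the session tempdir
withr_local_tempdir <- function() {
  d <- tempfile("tme3d-test-")
  dir.create(d)
  d
}
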