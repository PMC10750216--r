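# Independent brute-force oracles. These deliberately avoid the package's
# grid index and matrix tricks: plain double loops and direct formulas only.

oracle_conjugation <- function(pa, pb, d_max) {
  cnt <- 0L
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      d <- sqrt((pa$x_um[i] - pb$x_um[j])^2 +
                (pa$y_um[i] - pb$y_um[j])^2 +
                (pa$z_um[i] - pb$z_um[j])^2)
      if (d < d_max) cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_radial_bins <- function(centers, neighbors, r_max, bin) {
  nb <- as.integer(r_max / bin)
  total <- rep(0L, nb)
  for (i in seq_len(nrow(centers))) {
    for (j in seq_len(nrow(neighbors))) {
      d <- sqrt((centers$x_um[i] - neighbors$x_um[j])^2 +
                (centers$y_um[i] - neighbors$y_um[j])^2 +
                (centers$z_um[i] - neighbors$z_um[j])^2)
      if (d == 0 && centers$marker[i] == neighbors$marker[j]) next
      if (d < r_max) {
        k <- floor(d / bin) + 1L
        total[k] <- total[k] + 1L
      }
    }
  }
  total
}

# exhaustive optimal assignment: maximum number of matched pairs under the
# distance tolerance (n small). Recursion over detected points.
oracle_max_matching <- function(dist, tol) {
  n <- nrow(dist); m <- ncol(dist)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (n - i + 1L) <= best) return()
    if (i > n) { best <<- max(best, count); return() }
    recurse(i + 1L, used, count)  # leave detection i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && dist[i, j] <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L)
  best
}

# Kruskal-Wallis H from the definition: explicit mid-ranks and rank sums,
# tie correction from the tie-group sizes.
oracle_kw_H <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    H <- H + sum(r[sel])^2 / sum(sel)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tg <- table(values)
  H / (1 - sum(tg^3 - tg) / (N^3 - N))
}

# O(n^2) oracles with the inner loop vectorized (still index-free and
# independent of the package's grid bucketing); for the many-instance
# parity sweeps.
oracle_conjugation_fast <- function(pa, pb, d_max) {
  cnt <- 0L
  for (i in seq_len(nrow(pa))) {
    d2 <- (pa$x_um[i] - pb$x_um)^2 + (pa$y_um[i] - pb$y_um)^2 +
      (pa$z_um[i] - pb$z_um)^2
    cnt <- cnt + sum(d2 < d_max^2)
  }
  cnt
}

oracle_radial_fast <- function(centers, neighbors, r_max, bin) {
  nb <- as.integer(r_max / bin)
  total <- rep(0L, nb)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((centers$x_um[i] - neighbors$x_um)^2 +
              (centers$y_um[i] - neighbors$y_um)^2 +
              (centers$z_um[i] - neighbors$z_um)^2)
    d <- d[!(d == 0 & centers$marker[i] == neighbors$marker)]
    d <- d[d < r_max]
    if (length(d)) {
      t2 <- tabulate(floor(d / bin) + 1L, nb)
      total <- total + t2
    }
  }
  total
}
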