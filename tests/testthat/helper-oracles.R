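# Independent oracles used across the suite. All are deliberately naive
# (brute force / closed form) and share no code with the implementation paths
# they check.

# Brute-force single-linkage partition: O(N^2) union-find over molecule pairs.
uf_cluster_oracle <- function(config, cutoff) {
  n <- length(config$molecules)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- oracle_min_dist(config$molecules[[i]], config$molecules[[j]],
                             config$box, config$periodic)
        if (d < cutoff) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))   # canonical first-seen labels
}

# scalar minimum inter-atom distance, written loop-wise on purpose
oracle_min_dist <- function(a, b, box, periodic) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      if (periodic) d <- d - box * round(d / box)
      best <- min(best, sqrt(sum(d * d)))
    }
  }
  best
}

# Analytic finite-cylinder-with-caps ("capsule") membership: molecules whose
# centre of mass lies within `radius` of the segment joining the first and
# last ring centres of a straight tube.
capsule_inside_oracle <- function(config, tube, radius) {
  centres <- t(vapply(tube$ring_partition, function(idx)
    colMeans(config$cnt[idx, , drop = FALSE]), numeric(3)))
  A <- centres[1, ]
  B <- centres[nrow(centres), ]
  ab <- B - A
  L <- sqrt(sum(ab^2))
  ab <- ab / L
  coms <- t(mapply(function(m, w) colSums(m * w) / sum(w),
                   config$molecules, config$masses))
  which(vapply(seq_len(nrow(coms)), function(i) {
    p <- coms[i, ]
    d <- p - (A + ab * L / 2)
    if (config$periodic) d <- d - config$box * round(d / config$box)
    p <- A + ab * L / 2 + d
    s <- min(max(sum((p - A) * ab), 0), L)
    sqrt(sum((p - (A + s * ab))^2)) < radius
  }, logical(1)))
}

# Exhaustive grid-search least squares for the power law over (K, n).
grid_power_law_oracle <- function(times, values, k_grid = seq(0, 1.5, 1e-3),
                                  n_grid = seq(0, 1.5, 1e-3)) {
  best <- c(ss = Inf, K = NA, n = NA)
  tn <- outer(times, n_grid, "^")
  for (j in seq_along(n_grid)) {
    ss <- colSums((values - outer(tn[, j], k_grid))^2)
    jm <- which.min(ss)
    if (ss[jm] < best["ss"]) best <- c(ss = ss[jm], K = k_grid[jm],
                                       n = n_grid[j])
  }
  best
}

# Random loose configuration (no carrier): n molecules of 1-3 atoms thrown
# uniformly into a periodic box, dense enough for nontrivial clusters.
random_loose_config <- function(seed, n_range = c(20, 120), box = c(8, 8, 8)) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], 1)
  mols <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    c0 <- stats::runif(3) * box
    sweep(matrix(stats::rnorm(3 * k, 0, 0.15), k, 3), 2, c0, "+")
  })
  configuration(box, molecules = mols, periodic = TRUE)
}

# relative error with absolute fallback for zero-valued truth
rel_err <- function(est, truth) {
  ifelse(truth == 0, abs(est), abs(est - truth) / abs(truth))
}
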