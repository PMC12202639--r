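# Fixture builders shared across the test files. Everything is built in
# code; no data files are read.

# random pressure map with a controllable fraction of zero cells
random_map <- function(seed, nrow = 12L, ncol = 10L, zero_frac = 0.3,
                       interface = "cushion") {
  set.seed(seed)
  g <- matrix(stats::rexp(nrow * ncol, rate = 0.2), nrow, ncol)
  g[stats::runif(nrow * ncol) < zero_frac] <- 0
  pressure_map(g, cell_pitch = c(10, 10), interface = interface)
}

# independent single-pass brute-force oracle for all pressure metrics:
# explicit loops, no reuse of package internals
brute_metrics <- function(map, threshold = 0, bin_width = 4) {
  vals <- c()
  for (i in seq_len(nrow(map$grid)))
    for (j in seq_len(ncol(map$grid)))
      if (map$grid[i, j] > threshold) vals <- c(vals, map$grid[i, j])
  if (!length(vals)) return(NULL)
  n <- length(vals)
  pave <- sum(vals) / n
  spd <- 0
  for (v in vals) spd <- spd + (v - pave)^2
  spd <- spd / (4 * n * pave^2)
  nbins <- floor(max(vals) / bin_width) + 1
  counts <- integer(nbins)
  for (v in vals) {
    k <- floor(v / bin_width) + 1
    counts[k] <- counts[k] + 1
  }
  list(p_max = max(vals), p_ave = pave, n = n,
       area_cm2 = n * map$cell_pitch[1] * map$cell_pitch[2] / 100,
       spd = spd, hist = counts)
}

# small closed box-ish template cloud with well-spread landmarks
template_cloud <- function(n = 300L, seed = 11L, span = 400) {
  set.seed(seed)
  pts <- cbind(stats::runif(n, -span / 4, span / 4),
               stats::runif(n, -span / 4, span / 4),
               stats::runif(n, -span / 2, span / 2))
  point_cloud(pts)
}

template_landmarks <- function(cloud, k = 15L) {
  idx <- round(seq(1L, nrow(cloud$points), length.out = k))
  landmark_set(paste0("lm", seq_along(idx)), cloud$points[idx, ])
}

# n uniformly distributed random rotation matrices (quaternion method),
# returned as a 9 x n matrix of column-major flattened 3x3 matrices
random_rotations_flat <- function(n, seed) {
  set.seed(seed)
  q <- matrix(stats::rnorm(4L * n), 4L)
  q <- q / rep(sqrt(colSums(q^2)), each = 4L)
  w <- q[1L, ]; x <- q[2L, ]; y <- q[3L, ]; z <- q[4L, ]
  rbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

# default convex-ish loading curve used across the foam tests
foam_curve <- function() {
  cbind(c(0, 0.1, 0.25, 0.4, 0.55, 0.7),
        c(0, 0.012, 0.03, 0.055, 0.095, 0.16))
}
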