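# Shared fixtures and independent oracles, built in code at test time.

# coordinate radius of gyration (mass-weighted, unit masses)
coord_rg <- function(pts) {
  ctr <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
}

# brute-force maximum pairwise distance (independent of stats::dist)
brute_dmax <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(pts[(i + 1):n, , drop = FALSE], 2, pts[i, ])^2)
    best <- max(best, d2)
  }
  sqrt(best)
}

# uniform ball point cloud of radius R (rejection sampling)
ball_cloud <- function(n, R, seed) {
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n * 3, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, , drop = FALSE]
  pts[seq_len(n), ] * R
}

# bead model of a uniform cylinder, radius R, length L, lattice spacing sp
cylinder_beads <- function(R, L, sp) {
  xy <- expand.grid(x = seq(-R, R, by = sp), y = seq(-R, R, by = sp))
  xy <- xy[xy$x^2 + xy$y^2 <= R^2, ]
  as.matrix(merge(xy, data.frame(z = seq(0, L, by = sp))))
}

# flat 3%-relative-noise SAXS data from a model curve
noisy_curve <- function(curve, rel = 0.03, seed = 1) {
  simulate_saxs_noise(curve, a = rel, b = 0, seed = seed)
}

# noise-free "data" with nominal uncertainties for chi-square work
nominal_sigma_curve <- function(curve, rel = 0.01) {
  scattering_curve(curve$q, curve$intensity, sigma = rel * curve$intensity)
}
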