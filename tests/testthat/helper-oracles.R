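# Independent oracles and small shared fixtures, built in code.

# weighted-average-of-diagonal-rectangle-areas oracle for bilinear
# interpolation: each corner weighted by the area of the sub-rectangle
# diagonally opposite the query point
bilinear_area_oracle <- function(cell, q) {
  x1 <- cell$x[1]; x2 <- cell$x[2]; y1 <- cell$y[1]; y2 <- cell$y[2]
  A <- (x2 - x1) * (y2 - y1)
  w11 <- (x2 - q[1]) * (y2 - q[2]) / A
  w21 <- (q[1] - x1) * (y2 - q[2]) / A
  w12 <- (x2 - q[1]) * (q[2] - y1) / A
  w22 <- (q[1] - x1) * (q[2] - y1) / A
  w11 * cell$f[1, 1] + w21 * cell$f[2, 1] + w12 * cell$f[1, 2] + w22 * cell$f[2, 2]
}

# brute-force voxel-sort DVH oracles: scan the sorted unique doses for the
# largest dose whose exceedance fraction still reaches p percent
oracle_Dp <- function(d, p) {
  cand <- sort(unique(d), decreasing = TRUE)
  exceed <- vapply(cand, function(t) mean(d >= t), 0)
  cand[max(which(exceed * 100 >= p - 1e-12)[1], 1)]
}
oracle_Vd <- function(d, dval, at_least = TRUE) {
  if (at_least) 100 * sum(d >= dval) / length(d) else 100 * sum(d <= dval) / length(d)
}

# sign-flip permutation test on the mean paired difference
permutation_oracle <- function(a, b, n_perm = 2000, seed = 1) {
  d <- a - b
  t_obs <- mean(d)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  t_perm <- replicate(n_perm, mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  (1 + sum(abs(t_perm) >= abs(t_obs))) / (n_perm + 1)
}

# small shared scene for pipeline tests: 5 mm lattice over the phantom
quick_grid <- function(n = 55, spacing = 5) grid_spec(c(n, n, n), spacing)

quick_scene <- function(seed = 1, n_cp = 8, grid = quick_grid(),
                        heterogeneity = "homogeneous", params = list()) {
  list(grid = grid,
       pdd = make_pdd_table(),
       phantom = make_density_phantom("cylindrical", heterogeneity, grid,
                                      params = params),
       plan = make_plan(n_cp, seed = seed))
}

# square test array at a given pitch spanning +/-130 mm
square_array <- function(pitch_mm) {
  k <- 2 * floor(130 / pitch_mm) + 1
  detector_array_spec(paste0("square", pitch_mm), "square", pitch_mm, k^2,
                      5, 5, 0.125, c(27, 27))
}

# planar measurement with values given by a function f(u, v)
field_measurement <- function(array, f, theta = 0, cp = 1L, rate = NA_real_) {
  pos <- detector_positions(array)
  planar_measurement(theta, f(pos[, 1], pos[, 2]), array, cp, rate)
}
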