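test_that("two-point linear interpolation passes through its nodes", {
  expect_identical(interp_linear(c(0, 0), c(1, 1), 0.5), 0.5)
  expect_identical(interp_linear(c(2, 7), c(5, 13), 2), 7)
  expect_identical(interp_linear(c(2, 7), c(5, 13), 5), 13)
  # line through (0,2) and (4,10), evaluated at 1: least-squares oracle
  fit <- stats::lm(y ~ x, data.frame(x = c(0, 4), y = c(2, 10)))
  expect_equal(interp_linear(c(0, 2), c(4, 10), 1),
               unname(stats::predict(fit, data.frame(x = 1))))
  expect_equal(interp_linear(c(0, 2), c(4, 10), 1), 4)
  expect_error(interp_linear(c(1, 0), c(1, 5), 0.5), "degenerate")
})

test_that("bilinear interpolation equals the weighted-area oracle", {
  cell <- bilinear_cell(0, 1, 0, 1, 1, 3, 5, 7)
  expect_equal(interp_bilinear(cell, c(0.5, 0.5)), 4)     # corner mean
  expect_equal(interp_bilinear(cell, c(0.25, 0.75)), 4.5)
  expect_equal(interp_bilinear(cell, c(0.25, 0.75)),
               bilinear_area_oracle(cell, c(0.25, 0.75)))
  # constant cells are constant everywhere
  cc <- bilinear_cell(-1, 2, 3, 5, 9, 9, 9, 9)
  set.seed(5)
  q <- cbind(runif(20, -1, 2), runif(20, 3, 5))
  expect_true(all(abs(interp_bilinear(cc, q) - 9) < 1e-12))
  expect_error(bilinear_cell(1, 1, 0, 1, 1, 2, 3, 4), "degenerate")
})

test_that("bilinear interpolation is symmetric in the interpolation order", {
  set.seed(6)
  for (i in 1:50) {
    x <- sort(runif(2, -10, 10)); y <- sort(runif(2, -10, 10))
    f <- runif(4)
    cell <- bilinear_cell(x[1], x[2], y[1], y[2], f[1], f[2], f[3], f[4])
    q <- c(runif(1, x[1], x[2]), runif(1, y[1], y[2]))
    # y-then-x: interpolate along y on both x edges, then along x
    s1 <- interp_linear(c(y[1], f[1]), c(y[2], f[3]), q[2])
    s2 <- interp_linear(c(y[1], f[2]), c(y[2], f[4]), q[2])
    yx <- interp_linear(c(x[1], s1), c(x[2], s2), q[1])
    expect_lt(abs(interp_bilinear(cell, q) - yx), 1e-12)
    expect_lt(abs(interp_bilinear(cell, q) - bilinear_area_oracle(cell, q)), 1e-12)
  }
})

test_that("densified planes retain measured chamber values exactly", {
  set.seed(7)
  for (nm in c("octavius729", "octavius1500", "matrixx")) {
    arr <- detector_array(nm)
    pos <- detector_positions(arr)
    m <- field_measurement(arr, function(u, v) runif(length(u), 0, 3))
    f <- plane_interpolant(m)
    expect_lt(max(abs(f(pos) - m$values)), 1e-13)
  }
  # and on the dense lattice itself for the 10 mm array at 2.5 mm
  arr <- detector_array("octavius729")
  pos <- detector_positions(arr)
  m <- field_measurement(arr, function(u, v) runif(length(u), 0, 3))
  dp <- densify_plane(m, 2.5)
  iu <- match(pos[, 1], dp$u); iv <- match(pos[, 2], dp$v)
  expect_false(anyNA(c(iu, iv)))
  expect_lt(max(abs(dp$values[cbind(iu, iv)] - m$values)), 1e-13)
})

test_that("densification reproduces affine fields inside the chamber hull", {
  aff <- function(u, v) 5 + 0.011 * u - 0.007 * v
  for (nm in c("octavius729", "octavius1500", "matrixx")) {
    arr <- detector_array(nm)
    m <- field_measurement(arr, aff)
    dp <- densify_plane(m, if (nm == "matrixx") 2 else 2.5)
    hull <- max(abs(detector_positions(arr)[, 1]))
    su <- abs(dp$u) <= hull; sv <- abs(dp$v) <= hull
    tru <- outer(dp$u[su], dp$v[sv], aff)
    expect_lt(max(abs(dp$values[su, sv] - tru)), 1e-10)
  }
})

test_that("checkerboard gaps fill exactly for linear fields", {
  arr <- detector_array("octavius1500")
  m <- field_measurement(arr, function(u, v) 3 + 0.004 * (u + v))
  f <- plane_interpolant(m)
  # full 5 mm lattice sites, including the unmeasured parity class
  lat <- expand.grid(u = seq(-130, 130, by = 5), v = seq(-130, 130, by = 5))
  expect_lt(max(abs(f(as.matrix(lat)) - (3 + 0.004 * (lat$u + lat$v)))), 1e-10)
})

test_that("extrapolation beyond the outermost chambers clamps", {
  arr <- detector_array("octavius729")
  m <- field_measurement(arr, function(u, v) 3 + 0.01 * u)
  f <- plane_interpolant(m)
  expect_equal(f(c(135, 0)), f(c(130, 0)))
  expect_equal(f(c(-200, 17)), f(c(-130, 17)))
})

test_that("dropout policies bridge or zero missing readings", {
  arr <- detector_array("octavius729")
  aff <- function(u, v) 2 + 0.01 * u + 0.005 * v
  pos <- detector_positions(arr)
  v <- aff(pos[, 1], pos[, 2])
  drop_idx <- c(200, 365, 401)              # interior chambers
  v[drop_idx] <- NA
  m <- planar_measurement(0, v, arr)
  f_int <- plane_interpolant(m, policy = "interpolate")
  # widened interpolation across an affine field restores it exactly
  expect_lt(max(abs(f_int(pos) - aff(pos[, 1], pos[, 2]))), 1e-10)
  f_zero <- plane_interpolant(m, policy = "zero")
  expect_equal(f_zero(pos[drop_idx, , drop = FALSE]), c(0, 0, 0))
  allna <- planar_measurement(0, rep(NA_real_, 729), arr)
  expect_error(plane_interpolant(allna), "empty plane")
  expect_error(densify_plane(m, 12), "target pitch")
})

test_that("angular interpolation is node-exact and wraps full arcs", {
  arr <- detector_array("octavius729")
  angles <- seq(0, 2 * pi, length.out = 9)[-9]
  planes <- lapply(seq_along(angles), function(i)
    densify_plane(field_measurement(arr, function(u, v) i + 0.001 * u,
                                    theta = angles[i], cp = i), 2.5))
  # node exactness
  at_node <- interp_angular(planes, angles[3])
  expect_identical(at_node$values, planes[[3]]$values)
  # two identical neighbouring planes reproduce themselves in between
  twin <- planes; twin[[4]]$values <- twin[[3]]$values
  mid <- interp_angular(twin, (angles[3] + angles[4]) / 2)
  expect_equal(mid$values, twin[[3]]$values)
  # wraparound between last (315 deg) and first (0 deg) control points
  q <- 2 * pi - 0.1
  wrapped <- interp_angular(planes, q)
  gap <- 2 * pi - angles[8]
  wt <- (q - angles[8]) / gap
  oracle <- (1 - wt) * planes[[8]]$values + wt * planes[[1]]$values
  expect_equal(wrapped$values, oracle)
  # a partial arc refuses queries outside its range
  expect_error(interp_angular(planes[1:5], angles[7], periodic = FALSE),
               "outside")
  # per-pixel values linear in angle are reproduced exactly between nodes
  lin <- lapply(seq_along(angles), function(i) {
    p <- planes[[i]]; p$values[] <- 2 + 3 * angles[i]; p
  })
  qq <- (angles[5] + angles[6]) / 2
  expect_equal(unique(as.vector(interp_angular(lin, qq)$values)), 2 + 3 * qq)
})

test_that("depth extension scales by PDD ratios along each ray", {
  pdd <- make_pdd_table()
  arr <- detector_array("octavius729")
  m <- field_measurement(arr, function(u, v) 1 + 0.002 * abs(u))
  dp <- densify_plane(m, 2.5)
  ext <- extend_depth(dp, pdd, 10)
  w <- attr(ext, "w")
  iw0 <- which(w == 0)
  # reference depth: unchanged (rays grazing the rim are zeroed)
  su <- abs(dp$u) <= 130
  expect_equal(ext[su, , iw0], dp$values[su, ])
  # along the central ray the ratio matches the tabulated 10x10 curve
  iu0 <- which(dp$u == 0)
  d0 <- 135 / 10
  ratio <- pdd_eval(pdd, 10, pmin(pmax((135 - w) / 10, 0), 27)) / pdd_eval(pdd, 10, d0)
  expect_equal(ext[iu0, iu0, ], dp$values[iu0, iu0] * ratio, tolerance = 1e-12)
  # non-tabulated field size: linear mix of bracketing curves
  e7 <- extend_depth(dp, pdd, 7)
  ratio7 <- pdd_eval(pdd, 7, pmin(pmax((135 - w) / 10, 0), 27)) / pdd_eval(pdd, 7, d0)
  expect_equal(e7[iu0, iu0, ], dp$values[iu0, iu0] * ratio7, tolerance = 1e-12)
})

test_that("interpolation never overshoots the contributing nodes", {
  set.seed(9)
  for (nm in c("octavius729", "octavius1500")) {
    arr <- detector_array(nm)
    m <- field_measurement(arr, function(u, v) runif(length(u), 0.5, 4))
    dp <- densify_plane(m, 2.5)
    expect_true(all(dp$values <= max(m$values) + 1e-12))
    expect_true(all(dp$values >= min(m$values) - 1e-12))
  }
})

test_that("densification error falls second-order with pitch", {
  sig <- 25
  gauss_err <- function(pitch) {
    arr <- square_array(pitch)
    m <- field_measurement(arr, function(u, v) exp(-(u^2 + v^2) / (2 * sig^2)))
    dp <- densify_plane(m, 2.5)
    hull <- max(abs(detector_positions(arr)[, 1]))
    su <- abs(dp$u) <= hull; sv <- abs(dp$v) <= hull
    tru <- outer(dp$u[su], dp$v[sv],
                 function(a, b) exp(-(a^2 + b^2) / (2 * sig^2)))
    max(abs(dp$values[su, sv] - tru))
  }
  ratio <- gauss_err(10) / gauss_err(5)
  expect_gte(ratio, 3.2)
  expect_lte(ratio, 4.8)
})

test_that("the fused volumetric assembly equals densify + extend + trilinear pull", {
  sc <- quick_scene(seed = 5, n_cp = 3, grid = quick_grid())
  arr <- detector_array("octavius729")
  ms <- measure_plan(sc$plan, sc$phantom, sc$pdd, arr)
  recon <- reconstruct_volume(ms, arr, pdd = sc$pdd, plan = sc$plan,
                              target = sc$grid, mask_to_phantom = FALSE)
  ax <- grid_axes(sc$grid)
  ds <- sc$grid$spacing_mm[1]
  ext <- ceiling(max(abs(ax$x), 135) / ds) * ds
  acc <- array(0, dim = sc$grid$shape)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  for (i in seq_len(sc$plan$n_control_points)) {
    dp <- densify_plane(ms[[i]], ds, extent_mm = ext, v_axis = ax$z)
    cube <- extend_depth(dp, sc$pdd, sc$plan$field_cm[i],
                         w_axis = seq(-ext, ext, by = ds))
    perm <- aperm(cube, c(1, 3, 2))   # (u, w, z)
    cube_grid <- dose_grid(grid_spec(dim(perm), ds, c(-ext, -ext, ax$z[1])),
                           perm)
    uw <- cbind(cos(sc$plan$theta[i]) * pts[, 1] + sin(sc$plan$theta[i]) * pts[, 2],
                -sin(sc$plan$theta[i]) * pts[, 1] + cos(sc$plan$theta[i]) * pts[, 2])
    acc <- acc + array(grid_sample_trilinear(cube_grid,
                                             cbind(uw[, 1], uw[, 2], pts[, 3]),
                                             clamp = TRUE), dim = sc$grid$shape)
  }
  expect_lt(max(abs(acc - recon$values)) / max(recon$values), 1e-10)
})

test_that("reconstruction is exact to in-field tolerance for a single beam", {
  g <- grid_spec(c(109, 109, 109), 2.5)
  pdd <- make_pdd_table()
  phantom <- make_density_phantom("cylindrical", "homogeneous", g)
  plan <- make_plan(2, arc = c(0.3, 0.3 + 1e-9), field_cm = 10,
                    weights = c(0.5, 0.5), seed = 1)
  truth <- ground_truth_dose(plan, phantom, pdd, g)
  arr <- detector_array("octavius729")
  ms <- measure_plan(plan, phantom, pdd, arr)
  recon <- reconstruct_volume(ms, arr, pdd, plan, target = g)
  # in-field: the flattened aperture core (15 mm inside the edges) beyond
  # the buildup region, inside the phantom
  ax <- grid_axes(g)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  u <- cos(0.3) * pts[, 1] + sin(0.3) * pts[, 2]
  w <- -sin(0.3) * pts[, 1] + cos(0.3) * pts[, 2]
  depth <- sqrt(pmax(135^2 - u^2, 0)) - w
  core <- abs(u) < 50 - 20 & abs(pts[, 3]) < 50 - 20 & depth > 20 &
          pts[, 1]^2 + pts[, 2]^2 < 120^2
  err <- abs(recon$values - truth$values)[array(core, dim = g$shape)]
  expect_lt(max(err) / max(truth$values), 0.005)
})

test_that("reconstruction is linear and validates its inputs", {
  sc <- quick_scene(seed = 6, n_cp = 4)
  arr <- detector_array("octavius729")
  ms <- measure_plan(sc$plan, sc$phantom, sc$pdd, arr)
  recon <- reconstruct_volume(ms, arr, pdd = sc$pdd, plan = sc$plan,
                              target = sc$grid)
  ms2 <- lapply(ms, function(m)
    planar_measurement(m$theta, 2 * m$values, m$array,
                       m$control_point_index, m$rate_cgy_min))
  recon2 <- reconstruct_volume(ms2, arr, pdd = sc$pdd, plan = sc$plan,
                               target = sc$grid)
  expect_equal(recon2$values, 2 * recon$values, tolerance = 1e-13)
  expect_error(reconstruct_volume(ms[1:2], arr, sc$pdd, sc$plan,
                                  target = sc$grid), "cover")
  bad <- ms
  bad[[2]] <- planar_measurement(ms[[2]]$theta + 0.2, ms[[2]]$values, arr, 2L)
  expect_error(reconstruct_volume(bad, arr, sc$pdd, sc$plan, target = sc$grid),
               "control point 2")
})

test_that("fully dropped planes are rebuilt along the arc or zeroed by policy", {
  sc <- quick_scene(seed = 8, n_cp = 8)
  arr <- detector_array("octavius729")
  ms <- measure_plan(sc$plan, sc$phantom, sc$pdd, arr)
  full <- reconstruct_volume(ms, arr, pdd = sc$pdd, plan = sc$plan,
                             target = sc$grid)
  drop <- ms
  drop[[3]] <- planar_measurement(ms[[3]]$theta, rep(NA_real_, 729), arr, 3L,
                                  ms[[3]]$rate_cgy_min)
  r_int <- reconstruct_volume(drop, arr, pdd = sc$pdd, plan = sc$plan,
                              target = sc$grid, policy = "interpolate")
  r_zero <- reconstruct_volume(drop, arr, pdd = sc$pdd, plan = sc$plan,
                               target = sc$grid, policy = "zero")
  # zero policy loses that control point's dose; interpolate recovers most
  expect_lt(sum(r_zero$values), sum(full$values))
  expect_lt(abs(sum(r_int$values) - sum(full$values)),
            abs(sum(r_zero$values) - sum(full$values)))
  allna <- lapply(ms, function(m)
    planar_measurement(m$theta, rep(NA_real_, 729), arr,
                       m$control_point_index, m$rate_cgy_min))
  expect_error(reconstruct_volume(allna, arr, pdd = sc$pdd, plan = sc$plan,
                                  target = sc$grid), "no response")
})
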