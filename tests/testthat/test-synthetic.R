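test_that("PDD curves are normalised, monotone beyond buildup, and field-ordered", {
  pdd <- make_pdd_table(field_sizes_cm = c(4, 7, 10, 26))
  expect_equal(apply(pdd$values, 2, max), rep(100, 4), ignore_attr = TRUE)
  dmax_idx <- apply(pdd$values, 2, which.max)
  for (j in 1:4) {
    tail <- pdd$values[dmax_idx[j]:nrow(pdd$values), j]
    expect_true(all(diff(tail) < 0))
  }
  # more scatter for larger fields: higher value at fixed depth beyond buildup
  for (depth in c(5, 10, 20)) {
    v <- vapply(c(4, 7, 10, 26), function(f) pdd_eval(pdd, f, depth), 0)
    expect_true(all(diff(v) > 0))
  }
  expect_error(make_pdd_table(field_sizes_cm = c(4, 10)), "mandatory")
  expect_error(make_pdd_table(mu0_per_cm = 0.01), "positive")
  expect_error(pdd_eval(pdd, 10, 100), "depth")
  expect_error(pdd_eval(pdd, 30, 10), "field size")
})

test_that("PDD evaluation is exact at tabulated fields and linear between them", {
  pdd <- make_pdd_table()
  d <- seq(0, 30, by = 0.25)
  direct <- stats::approx(pdd$depths_cm, pdd$values[, 2], xout = d)$y
  expect_equal(pdd_eval(pdd, 10, d), direct)
  mix <- 0.5 * pdd_eval(pdd, 4, d) + 0.5 * pdd_eval(pdd, 10, d)
  expect_equal(pdd_eval(pdd, 7, d), mix)
})

test_that("density phantoms voxelise water, inserts and air correctly", {
  g <- quick_grid()
  hom <- make_density_phantom("cylindrical", "homogeneous", g)
  ax <- grid_axes(g)
  r2 <- outer(ax$x^2, ax$y^2, "+")
  inside <- array(r2 <= 135^2, dim = g$shape)
  expect_true(all(hom$values[inside] == 1))
  expect_true(all(hom$values[!inside] == 0))

  lung <- make_density_phantom("cylindrical", "lung_insert", g,
                               params = list(insert_rho = 0.01))
  expect_setequal(unique(as.vector(lung$values)), c(0, 0.01, 1))

  two <- make_density_phantom("cylindrical", "custom", g, params = list(
    inserts = list(
      list(shape = "rod", centre_mm = c(40, 0), radius_mm = 20, rho = 0.3),
      list(shape = "sphere", centre_mm = c(-40, 0, 0), radius_mm = 15, rho = 2))))
  counts <- table(two$values)
  expect_setequal(names(counts), c("0", "0.3", "1", "2"))
  # voxel counts per level match the configured insert volumes
  vv <- voxel_volume_cm3(g)
  expect_equal(counts[["0.3"]] * vv, pi * 2^2 * 27.5, tolerance = 0.05)
  expect_equal(counts[["2"]] * vv, 4 / 3 * pi * 1.5^3, tolerance = 0.15)
  expect_error(make_density_phantom("cylindrical", "lung_insert", g,
                                    params = list(insert_rho = 3.5)),
               "\\[0, 3.0\\]")
})

test_that("arc plans have evenly spaced angles and are seed-reproducible", {
  full <- make_plan(178, seed = 5)
  expect_identical(full$n_control_points, 178L)
  expect_true(full$full_arc)
  expect_equal(diff(full$theta), rep(2 * pi / 178, 177))
  expect_equal(max(full$theta) - min(full$theta) + 2 * pi / 178, 2 * pi)

  m120 <- make_plan(120, seed = 5)
  expect_identical(m120$n_control_points, 120L)

  partial <- make_plan(24, arc = c(pi / 6, pi / 6 + 220 * pi / 180), seed = 5)
  expect_false(partial$full_arc)
  expect_equal(range(partial$theta), c(pi / 6, pi / 6 + 220 * pi / 180))

  expect_identical(make_plan(24, seed = 9), make_plan(24, seed = 9))
  expect_false(identical(make_plan(24, seed = 9)$weights,
                         make_plan(24, seed = 10)$weights))
  expect_error(make_plan(1), "at least 2")
  expect_error(make_plan(10, arc = c(1, 1)), "degenerate")
  expect_error(make_plan(10, weights = c(-1, rep(1, 9))), ">= 0")
})

test_that("ROI masks voxelise known volumes and honour the grid", {
  g1 <- grid_spec(c(41, 41, 41), 1)
  rois <- make_roi_set(g1, list(
    list(name = "s", role = "OAR", shape = "sphere", centre_mm = c(0, 0, 0),
         radius_mm = 10)))
  expect_equal(sum(rois$s$mask) * voxel_volume_cm3(g1), 4 / 3 * pi,
               tolerance = 0.02)

  g <- grid_spec(c(109, 109, 109), 2.5)
  rois <- make_roi_set(g, list(
    list(name = "lens", role = "OAR", shape = "sphere",
         centre_mm = c(50, 0, 0), volume_cm3 = 0.2),
    list(name = "ptv", role = "PTV", shape = "sphere",
         centre_mm = c(0, 0, 0), radius_mm = 25)))
  expect_gt(sum(rois$lens$mask), 0)          # lens-scale structure resolvable
  expect_equal((0.2 * 1000 * 3 / (4 * pi))^(1 / 3), 3.628, tolerance = 1e-3)
  expect_identical(sum(rois$lens$mask & rois$ptv$mask), 0L)  # disjoint
  expect_error(make_roi_set(g, list(
    list(name = "out", role = "OAR", shape = "sphere",
         centre_mm = c(500, 0, 0), radius_mm = 5))), "out")
})

test_that("a single static beam reproduces the PDD along its axis", {
  sc <- quick_scene()
  plan <- make_plan(2, arc = c(0, 1e-9), field_cm = 10, weights = c(0.5, 0.5),
                    seed = 1)
  truth <- ground_truth_dose(plan, sc$phantom, sc$pdd, sc$grid)
  ax <- grid_axes(sc$grid)
  mid <- (length(ax$x) + 1) / 2
  # theta = 0: beam travels along -y; depth at (0, y) is 135 - y
  iy1 <- which(ax$y == 50); iy2 <- which(ax$y == -50)
  r_dose <- truth$values[mid, iy1, mid] / truth$values[mid, iy2, mid]
  r_pdd <- pdd_eval(sc$pdd, 10, (135 - 50) / 10) /
           pdd_eval(sc$pdd, 10, (135 + 50) / 10)
  expect_equal(r_dose, r_pdd, tolerance = 1e-10)
})

test_that("opposed beams give a half-turn symmetric dose", {
  sc <- quick_scene()
  plan <- make_plan(2, arc = c(0, pi), field_cm = 10, weights = c(0.5, 0.5),
                    seed = 1)
  truth <- ground_truth_dose(plan, sc$phantom, sc$pdd, sc$grid)
  n <- sc$grid$shape[1]
  rotated <- truth$values[n:1, n:1, ]   # half turn about the z axis
  expect_lt(max(abs(truth$values - rotated)), 1e-10)
})

test_that("a uniform full arc is rotation-invariant on the central plane", {
  g <- grid_spec(c(109, 109, 5), 2.5)
  pdd <- make_pdd_table()
  phantom <- make_density_phantom("cylindrical", "homogeneous", g)
  plan <- make_plan(178, field_cm = 10, weights = rep(2 / 178, 178), seed = 1)
  truth <- ground_truth_dose(plan, phantom, pdd, g)
  ax <- grid_axes(g)
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  for (radius in c(30, 60)) {
    ring <- cbind(radius * cos(phi), radius * sin(phi), 0)
    vals <- grid_sample_trilinear(truth, ring)
    expect_lt(stats::sd(vals) / mean(vals), 0.01)
  }
})

test_that("ground truth dose is linear, non-negative, and vanishes outside apertures", {
  sc <- quick_scene(seed = 3)
  truth <- ground_truth_dose(sc$plan, sc$phantom, sc$pdd, sc$grid)
  expect_true(all(truth$values >= 0))
  doubled <- sc$plan
  doubled$weights <- doubled$weights * 2
  truth2 <- ground_truth_dose(doubled, sc$phantom, sc$pdd, sc$grid)
  expect_equal(truth2$values, 2 * truth$values, tolerance = 1e-12)
  # beyond every aperture's axial edge plus margin, the dose is tail-level
  zmax <- max(sc$plan$field_cm) * 10 / 2
  ax <- grid_axes(sc$grid)
  far <- abs(ax$z) > zmax + 40
  expect_lt(max(truth$values[, , far]) / max(truth$values), 1e-6)
  # bit-reproducible
  sc2 <- quick_scene(seed = 3)
  expect_identical(ground_truth_dose(sc2$plan, sc2$phantom, sc2$pdd, sc2$grid)$values,
                   truth$values)
})

test_that("a low-density insert increases dose beyond it", {
  g <- quick_grid()
  pdd <- make_pdd_table()
  hom <- make_density_phantom("cylindrical", "homogeneous", g)
  lung <- make_density_phantom("cylindrical", "lung_insert", g,
                               params = list(insert_rho = 0.1,
                                             insert_centre_mm = c(0, 60),
                                             insert_radius_mm = 25))
  plan <- make_plan(2, arc = c(0, 1e-9), field_cm = 10, weights = c(0.5, 0.5),
                    seed = 1)
  t_hom <- ground_truth_dose(plan, hom, pdd, g)
  t_lung <- ground_truth_dose(plan, lung, pdd, g)
  ax <- grid_axes(g)
  mid <- (length(ax$x) + 1) / 2
  beyond <- which(ax$y < 20)    # downstream of the insert (beam from +y)
  expect_true(all(t_lung$values[mid, beyond, mid] >
                  t_hom$values[mid, beyond, mid]))
})

test_that("numeric radiological depths agree with the analytic chord integrals", {
  g <- quick_grid()
  pdd <- make_pdd_table()
  lung <- make_density_phantom("cylindrical", "lung_insert", g,
                               params = list(insert_rho = 0.2))
  plan <- make_plan(3, arc = c(0.3, 2.2), field_cm = 8, seed = 2)
  analytic <- ground_truth_dose(plan, lung, pdd, g)
  forced <- lung
  forced$phantom$z_invariant <- FALSE       # force the slice-numeric path
  numeric <- ground_truth_dose(plan, forced, pdd, g)
  # away from the phantom rim, where the buildup gradient amplifies the
  # boundary-voxelisation error of the numeric path
  ax <- grid_axes(g)
  interior <- array(outer(ax$x^2, ax$y^2, "+") < 110^2, dim = g$shape)
  expect_lt(max(abs(analytic$values[interior] - numeric$values[interior])) /
              max(analytic$values), 0.02)
})

test_that("prescription scaling pins the PTV D95 to the prescription", {
  sc <- quick_scene(seed = 4)
  rois <- make_roi_set(sc$grid, list(
    list(name = "ptv", role = "PTV", shape = "sphere",
         centre_mm = c(0, 0, 0), radius_mm = 25)))
  truth <- ground_truth_dose(sc$plan, sc$phantom, sc$pdd, sc$grid)
  f <- scale_to_prescription(truth, rois$ptv$mask, 2)
  expect_equal(dvh_metric(f * truth$values[rois$ptv$mask], "D95"), 2)
})
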