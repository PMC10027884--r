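#' Percent-depth-dose table
#'
#' Builds an analytic family of percent-depth-dose (PDD) curves, one per
#' square field size, of the classical buildup-then-exponential form
#' `raw(d) = (1 - exp(-d/db)) * exp(-mu(F) * d)` with an effective linear
#' attenuation coefficient decreasing with field size,
#' `mu(F) = mu0 - mu_slope * F` (larger fields scatter more, so they fall
#' off more slowly). Each curve is normalised to 100 at its depth of
#' maximum. Field sizes 4, 10 and 26 cm are mandatory.
#'
#' @param field_sizes_cm square field side lengths (cm); must include 4, 10
#'   and 26.
#' @param depths_cm sampled depths (cm), from 0.
#' @param buildup_cm buildup constant `db` (cm); the depth of maximum is
#'   `db * log((1 + mu*db) / (mu*db))`, about 1.4 cm for the defaults
#'   (a 6 MV-like beam).
#' @param mu0_per_cm,mu_slope_per_cm2 attenuation model coefficients.
#' @return object of class `pdd_table` with fields `field_sizes_cm`,
#'   `depths_cm` and a `length(depths) x length(fields)` matrix `values`
#'   (percent, max 100 per column).
#' @export
#' @examples
#' pdd <- make_pdd_table()
#' pdd_eval(pdd, 10, 10)  # ~66 percent at 10 cm depth for a 10 x 10 field
make_pdd_table <- function(field_sizes_cm = c(4, 10, 26),
                           depths_cm = seq(0, 40, by = 0.1),
                           buildup_cm = 0.35,
                           mu0_per_cm = 0.055,
                           mu_slope_per_cm2 = 5e-4) {
  field_sizes_cm <- sort(unique(as.numeric(field_sizes_cm)))
  if (!all(c(4, 10, 26) %in% field_sizes_cm))
    stop("make_pdd_table: field sizes 4, 10 and 26 cm are mandatory")
  mu <- mu0_per_cm - mu_slope_per_cm2 * field_sizes_cm
  if (any(mu <= 0))
    stop("make_pdd_table: attenuation coefficient must stay positive over the field range")
  depths_cm <- sort(unique(as.numeric(depths_cm)))
  if (min(depths_cm) < 0) stop("make_pdd_table: depths must be >= 0")
  raw <- outer(depths_cm, seq_along(field_sizes_cm), function(d, j)
    (1 - exp(-d / buildup_cm)) * exp(-mu[j] * d))
  values <- sweep(raw, 2L, apply(raw, 2L, max), "/") * 100
  structure(list(field_sizes_cm = field_sizes_cm, depths_cm = depths_cm,
                 values = values, buildup_cm = buildup_cm, mu_per_cm = mu),
            class = "pdd_table")
}

#' Evaluate a PDD table
#'
#' Percent depth dose at arbitrary depth and field size: linear
#' interpolation in depth along the stored curves, and linear interpolation
#' between the two bracketing tabulated field sizes (exact at tabulated
#' fields). Depths or fields outside the table raise a range error.
#'
#' @param pdd a `pdd_table`.
#' @param field_cm square field side (cm), scalar.
#' @param depth_cm depth(s) in cm.
#' @return percent depth dose value(s).
#' @export
pdd_eval <- function(pdd, field_cm, depth_cm) {
  stopifnot(inherits(pdd, "pdd_table"), length(field_cm) == 1L)
  fs <- pdd$field_sizes_cm
  if (field_cm < fs[1L] - 1e-9 || field_cm > fs[length(fs)] + 1e-9)
    stop("pdd_eval: field size ", field_cm, " cm outside the tabulated range")
  if (any(depth_cm < min(pdd$depths_cm) - 1e-9 |
          depth_cm > max(pdd$depths_cm) + 1e-9))
    stop("pdd_eval: depth outside the tabulated range")
  j <- findInterval(field_cm, fs, all.inside = TRUE)
  wt <- if (fs[j + 1L] == fs[j]) 0 else (field_cm - fs[j]) / (fs[j + 1L] - fs[j])
  curve <- (1 - wt) * pdd$values[, j] + wt * pdd$values[, j + 1L]
  stats::approx(pdd$depths_cm, curve, xout = pmin(pmax(depth_cm, min(pdd$depths_cm)),
                                                  max(pdd$depths_cm)))$y
}

# ---- density phantoms ------------------------------------------------------

#' Mass-density phantom
#'
#' Voxelises a water-equivalent phantom (density 1.0 g/cm^3 inside, 0
#' outside) with optional lower-density inserts, on a given lattice.
#' `heterogeneity = "lung_insert"` adds a cylindrical lung-like rod
#' parallel to the phantom axis; `"custom"` takes a list of rod or sphere
#' inserts. Densities must lie in [0, 3.0] g/cm^3, the range spanned by
#' human tissue types in clinical CT-to-density tables.
#'
#' Rod inserts keep the density invariant along z, which lets the
#' ground-truth dose engine use exact chord-length radiological depths.
#'
#' @param kind `"cylindrical"` (axis along z) or `"cuboid"`.
#' @param heterogeneity `"homogeneous"`, `"lung_insert"` or `"custom"`.
#' @param grid a `grid_spec` covering the phantom extent.
#' @param params list of optional parameters: `radius_mm` (cylinder radius,
#'   default 135), `half_mm` (cuboid half-extent, default 135),
#'   `insert_rho` (default 0.26), `insert_centre_mm` (transverse, default
#'   `c(45, 0)`), `insert_radius_mm` (default 25), and for `"custom"` an
#'   `inserts` list of `list(shape = "rod"|"sphere", centre_mm, radius_mm,
#'   rho)` entries.
#' @return a `density_volume` (a `dose_grid` in g/cm^3 with phantom
#'   metadata used by the analytic dose engine).
#' @export
make_density_phantom <- function(kind = c("cylindrical", "cuboid"),
                                 heterogeneity = c("homogeneous", "lung_insert", "custom"),
                                 grid, params = list()) {
  kind <- match.arg(kind)
  heterogeneity <- match.arg(heterogeneity)
  stopifnot(inherits(grid, "grid_spec"))
  radius <- params$radius_mm %||% 135
  half <- params$half_mm %||% 135
  inserts <- switch(heterogeneity,
    homogeneous = list(),
    lung_insert = list(list(shape = "rod",
                            centre_mm = params$insert_centre_mm %||% c(45, 0),
                            radius_mm = params$insert_radius_mm %||% 25,
                            rho = params$insert_rho %||% 0.26)),
    custom = params$inserts %||% list())
  for (ins in inserts) {
    if (!is.numeric(ins$rho) || ins$rho < 0 || ins$rho > 3.0)
      stop("make_density_phantom: insert density must lie in [0, 3.0] g/cm3")
  }
  ax <- grid_axes(grid)
  r2 <- outer(ax$x^2, ax$y^2, "+")
  inside <- if (kind == "cylindrical") r2 <= radius^2 else
    outer(abs(ax$x) <= half, abs(ax$y) <= half, "&")
  rho_xy <- ifelse(inside, 1.0, 0.0)
  nz <- grid$shape[3L]
  z_invariant <- TRUE
  rho <- array(rho_xy, dim = grid$shape)
  for (ins in inserts) {
    if (ins$shape == "rod") {
      d2 <- outer((ax$x - ins$centre_mm[1L])^2, (ax$y - ins$centre_mm[2L])^2, "+")
      sel <- d2 <= ins$radius_mm^2 & inside
      for (iz in seq_len(nz)) rho[, , iz][sel] <- ins$rho
    } else if (ins$shape == "sphere") {
      z_invariant <- FALSE
      for (iz in seq_len(nz)) {
        dz2 <- (ax$z[iz] - ins$centre_mm[3L])^2
        if (dz2 > ins$radius_mm^2) next
        d2 <- outer((ax$x - ins$centre_mm[1L])^2, (ax$y - ins$centre_mm[2L])^2, "+")
        sel <- d2 + dz2 <= ins$radius_mm^2 & inside
        rho[, , iz][sel] <- ins$rho
      }
    } else stop("make_density_phantom: unknown insert shape '", ins$shape, "'")
  }
  out <- dose_grid(grid, rho, unit = "g/cm3")
  out$phantom <- list(kind = kind, heterogeneity = heterogeneity,
                      radius_mm = radius, half_mm = half, inserts = inserts,
                      z_invariant = z_invariant)
  class(out) <- c("density_volume", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- arc plans -------------------------------------------------------------

#' Synthetic arc plan
#'
#' Generates a VMAT-like arc plan: control-point gantry angles evenly
#' spaced across the arc, with seeded random per-point beam weights
#' (monitor-unit surrogates) and square field sizes. For a full 360-degree
#' arc the angles cover `[start, end)` so the arc closes periodically
#' without duplicating the first control point. The per-point dose-rate
#' surrogate assumes constant gantry speed (equal time per control point).
#'
#' @param n_control_points number of control points (>= 2).
#' @param arc angular range in radians, length 2; default a full arc
#'   `c(0, 2*pi)`.
#' @param field_cm per-point square field sides (cm), recycled; default
#'   seeded uniform draws in `field_range_cm`.
#' @param weights per-point beam weights (Gy contribution surrogate),
#'   recycled; default seeded uniform modulation of `prescription_gy / n`.
#' @param field_range_cm range for random field sizes (cm).
#' @param prescription_gy prescription dose (Gy), used by
#'   [scale_to_prescription()].
#' @param delivery_time_min total arc delivery time (min), split evenly
#'   over control points.
#' @param seed integer seed; the plan is bit-reproducible given the seed.
#' @return an object of class `arc_plan`.
#' @export
make_plan <- function(n_control_points, arc = c(0, 2 * pi),
                      field_cm = NULL, weights = NULL,
                      field_range_cm = c(6, 14), prescription_gy = 2,
                      delivery_time_min = 2, seed = 1) {
  n <- as.integer(n_control_points)
  if (n < 2L) stop("make_plan: need at least 2 control points")
  span <- arc[2L] - arc[1L]
  if (abs(span) < 1e-12) stop("make_plan: degenerate arc (zero span)")
  full_arc <- isTRUE(all.equal(abs(span), 2 * pi, tolerance = 1e-9))
  theta <- if (full_arc) arc[1L] + span * (seq_len(n) - 1L) / n
           else seq(arc[1L], arc[2L], length.out = n)
  draws <- .local_rng(seed)(list(
    field = stats::runif(n, field_range_cm[1L], field_range_cm[2L]),
    weight = stats::runif(n, 0.5, 1.5)))
  if (is.null(field_cm)) field_cm <- draws$field
  if (is.null(weights)) weights <- draws$weight * prescription_gy / n
  field_cm <- rep_len(field_cm, n)
  weights <- rep_len(weights, n)
  if (any(weights < 0)) stop("make_plan: weights must be >= 0")
  cp_time_min <- rep(delivery_time_min / n, n)
  structure(list(
    theta = theta, field_cm = field_cm, weights = weights,
    cp_time_min = cp_time_min,
    rate_cgy_min = 100 * weights / cp_time_min,
    arc = arc, full_arc = full_arc,
    prescription_gy = prescription_gy, seed = seed,
    n_control_points = n),
    class = "arc_plan")
}

# run `expr` under a private RNG stream without disturbing the global one
.local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf("<arc_plan> %d control points over [%.1f, %.1f] deg%s, fields %.1f-%.1f cm, Rx %g Gy, seed %d\n",
              x$n_control_points, x$arc[1] * 180 / pi, x$arc[2] * 180 / pi,
              if (x$full_arc) " (full arc)" else "",
              min(x$field_cm), max(x$field_cm), x$prescription_gy, x$seed))
  invisible(x)
}

# ---- ROI masks -------------------------------------------------------------

#' ROI mask set
#'
#' Voxelises named regions of interest (PTV / OAR roles) on a lattice.
#' Supported shapes: `sphere` (by `radius_mm` or `volume_cm3`),
#' `ellipsoid` (by `semiaxes_mm`), `shell` (by `radii_mm = c(inner,
#' outer)`). A voxel belongs to the mask when its centre lies inside the
#' shape. The voxelised volume must agree with the nominal analytic volume
#' within one surface voxel layer.
#'
#' @param grid a `grid_spec`.
#' @param config list of ROI descriptors, each a list with `name`, `role`
#'   (`"PTV"` or `"OAR"`), `shape`, `centre_mm`, and the shape's size
#'   fields.
#' @return an object of class `roi_set`: a named list of ROIs, each with
#'   `name`, `role`, logical `mask`, `nominal_volume_cm3`.
#' @export
#' @examples
#' g <- grid_spec(c(41, 41, 41), 2.5)
#' rois <- make_roi_set(g, list(
#'   list(name = "ptv", role = "PTV", shape = "sphere",
#'        centre_mm = c(0, 0, 0), radius_mm = 20),
#'   list(name = "lens", role = "OAR", shape = "sphere",
#'        centre_mm = c(30, 0, 0), volume_cm3 = 0.2)))
make_roi_set <- function(grid, config) {
  stopifnot(inherits(grid, "grid_spec"))
  ax <- grid_axes(grid)
  vv <- voxel_volume_cm3(grid)
  rois <- lapply(config, function(cf) {
    role <- match.arg(cf$role, c("PTV", "OAR"))
    shape <- match.arg(cf$shape, c("sphere", "ellipsoid", "shell"))
    ctr <- cf$centre_mm
    if (shape == "sphere") {
      r <- cf$radius_mm %||% (cf$volume_cm3 * 1000 * 3 / (4 * pi))^(1 / 3)
      if (r <= 0) stop("make_roi_set: non-positive size for ROI '", cf$name, "'")
      semi <- rep(r, 3L)
      vol <- 4 / 3 * pi * r^3 / 1000
      area <- 4 * pi * r^2
    } else if (shape == "ellipsoid") {
      semi <- cf$semiaxes_mm
      stopifnot(length(semi) == 3L, all(semi > 0))
      vol <- 4 / 3 * pi * prod(semi) / 1000
      p <- 1.6075   # Thomsen surface-area approximation
      area <- 4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
                         semi[2]^p * semi[3]^p) / 3)^(1 / p)
    } else {
      ri <- cf$radii_mm[1L]; ro <- cf$radii_mm[2L]
      stopifnot(0 <= ri, ri < ro)
      vol <- 4 / 3 * pi * (ro^3 - ri^3) / 1000
      area <- 4 * pi * (ro^2 + ri^2)
    }
    d2 <- .ellipsoid_norm2(ax, ctr, if (shape == "shell") rep(ro, 3L) else semi)
    mask <- d2 <= 1
    if (shape == "shell") mask <- mask & .ellipsoid_norm2(ax, ctr, rep(ri, 3L)) > 1
    if (!any(mask))
      stop("make_roi_set: ROI '", cf$name, "' has an empty mask (outside the grid?)")
    v_mask <- sum(mask) * vv
    layer_cm3 <- area * max(grid$spacing_mm) / 1000
    if (abs(v_mask - vol) > layer_cm3)
      stop(sprintf("make_roi_set: ROI '%s' voxelised volume %.3f cm3 deviates from nominal %.3f cm3 by more than one voxel layer",
                   cf$name, v_mask, vol))
    list(name = cf$name, role = role, mask = mask, nominal_volume_cm3 = vol)
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  structure(rois, class = "roi_set", grid = grid)
}

.ellipsoid_norm2 <- function(ax, ctr, semi) {
  tx <- ((ax$x - ctr[1L]) / semi[1L])^2
  ty <- ((ax$y - ctr[2L]) / semi[2L])^2
  tz <- ((ax$z - ctr[3L]) / semi[3L])^2
  outer(outer(tx, ty, "+"), tz, "+")
}

# ---- analytic beam model ---------------------------------------------------

# lateral beam profile: flat in-field with logistic penumbra.
# `w8020_mm` is the 80-20 percent penumbra width; the logistic scale is
# w8020 / (2 log 4).
.beam_profile <- function(t_mm, field_cm, w8020_mm = 6) {
  k <- w8020_mm / (2 * log(4))
  stats::plogis((field_cm * 10 / 2 - abs(t_mm)) / k)
}

# Radiological depth (mm of water-equivalent path) at BEV coordinates
# (u, w) for gantry angle theta, for analytic phantoms (cylinder or cuboid
# with rod inserts). u and w are equal-length vectors (or u matrix/w
# matrix of same shape). The beam enters at large w travelling towards -w.
.raddepth_analytic <- function(phantom, theta, u, w) {
  if (phantom$kind == "cylindrical") {
    we <- sqrt(pmax(phantom$radius_mm^2 - u^2, 0))
  } else {
    # cuboid: only exact for axis-aligned beams; callers use the numeric
    # path otherwise
    we <- ifelse(abs(u) <= phantom$half_mm, phantom$half_mm, 0)
  }
  d <- pmin(pmax(we - w, 0), 2 * we)
  for (ins in phantom$inserts) {
    uc <- ins$centre_mm[1L] * cos(theta) + ins$centre_mm[2L] * sin(theta)
    wc <- -ins$centre_mm[1L] * sin(theta) + ins$centre_mm[2L] * cos(theta)
    h <- sqrt(pmax(ins$radius_mm^2 - (u - uc)^2, 0))
    lo <- pmax(pmax(w, -we), wc - h)
    hi <- pmin(we, wc + h)
    d <- d + (ins$rho - 1) * pmax(hi - lo, 0)
  }
  d
}

# Numeric radiological depth for one transverse density slice: bilinear
# sampling of rho on a rotated (u, w) lattice followed by a cumulative
# midpoint sum along the beam direction. Returns a matrix over (u, w).
.raddepth_numeric <- function(rho_xy, xax, yax, theta, u, wseq) {
  pts_u <- rep(u, times = length(wseq))
  pts_w <- rep(wseq, each = length(u))
  # world coords of BEV points: p = u * uhat + w * what
  x <- cos(theta) * pts_u - sin(theta) * pts_w
  y <- sin(theta) * pts_u + cos(theta) * pts_w
  rho <- .bilinear_at(rho_xy, xax, yax, x, y, outside = 0)
  m <- matrix(rho, nrow = length(u))
  ord <- order(wseq, decreasing = TRUE)     # integrate from entry (large w)
  dw <- abs(if (length(wseq) > 1) wseq[2] - wseq[1] else 0)
  cs <- m[, ord, drop = FALSE]
  cs <- t(apply(cs, 1L, cumsum)) * dw
  # midpoint correction: depth at a sample excludes half its own cell
  cs <- cs - m[, ord, drop = FALSE] * dw / 2
  out <- matrix(0, nrow = length(u), ncol = length(wseq))
  out[, ord] <- pmax(cs, 0)
  out
}

# bilinear lookup into matrix m at fractional (1-based) indices
.interp_mat <- function(m, fi, fj) {
  ni <- nrow(m); nj <- ncol(m)
  fi <- pmin(pmax(fi, 1), ni); fj <- pmin(pmax(fj, 1), nj)
  i0 <- pmin(floor(fi), ni - 1L); j0 <- pmin(floor(fj), nj - 1L)
  ai <- fi - i0; aj <- fj - j0
  (1 - aj) * ((1 - ai) * m[cbind(i0, j0)] + ai * m[cbind(i0 + 1, j0)]) +
  aj       * ((1 - ai) * m[cbind(i0, j0 + 1)] + ai * m[cbind(i0 + 1, j0 + 1)])
}

# bilinear lookup into a matrix field sampled at (xax, yax); constant
# `outside` value beyond the hull.
.bilinear_at <- function(m, xax, yax, x, y, outside = 0) {
  nx <- length(xax); ny <- length(yax)
  dx <- xax[2] - xax[1]; dy <- yax[2] - yax[1]
  fx <- (x - xax[1]) / dx + 1
  fy <- (y - yax[1]) / dy + 1
  ok <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny
  fx <- pmin(pmax(fx, 1), nx); fy <- pmin(pmax(fy, 1), ny)
  i0 <- pmin(floor(fx), nx - 1L); j0 <- pmin(floor(fy), ny - 1L)
  ax <- fx - i0; ay <- fy - j0
  v <- (1 - ay) * ((1 - ax) * m[cbind(i0, j0)] + ax * m[cbind(i0 + 1, j0)]) +
       ay       * ((1 - ax) * m[cbind(i0, j0 + 1)] + ax * m[cbind(i0 + 1, j0 + 1)])
  v[!ok] <- outside
  v
}

#' Per-control-point beam dose at arbitrary points
#'
#' Evaluates the analytic parallel-beam dose contribution of one control
#' point at arbitrary world points: flat in-field profile with logistic
#' penumbra in both field directions, times the PDD at the radiological
#' depth along the ray, times the control-point weight. This is the
#' ground-truth model that [ground_truth_dose()] integrates over the arc.
#'
#' @param plan an `arc_plan`.
#' @param cp control-point index.
#' @param points `n x 3` world coordinates (mm).
#' @param density a `density_volume`.
#' @param pdd a `pdd_table`.
#' @param penumbra_mm 80-20 percent penumbra width (mm).
#' @param mask_to_phantom zero the dose outside the phantom.
#' @return numeric vector of doses (Gy).
#' @export
beam_dose_points <- function(plan, cp, points, density, pdd,
                             penumbra_mm = 6, mask_to_phantom = TRUE) {
  stopifnot(inherits(plan, "arc_plan"), inherits(density, "density_volume"))
  p <- .as_points(points, 3L)
  theta <- plan$theta[cp]
  uw <- .bev_uw(p[, 1L], p[, 2L], theta)
  ph <- density$phantom
  rd <- if (ph$z_invariant && ph$kind == "cylindrical") {
    .raddepth_analytic(ph, theta, uw$u, uw$w)
  } else {
    .raddepth_points_numeric(density, theta, uw$u, uw$w, p[, 3L])
  }
  g <- .beam_profile(uw$u, plan$field_cm[cp], penumbra_mm) *
       .beam_profile(p[, 3L], plan$field_cm[cp], penumbra_mm)
  dose <- plan$weights[cp] * g * pdd_eval(pdd, plan$field_cm[cp], rd / 10) / 100
  if (mask_to_phantom) {
    inside <- if (ph$kind == "cylindrical")
      p[, 1L]^2 + p[, 2L]^2 <= ph$radius_mm^2
    else abs(p[, 1L]) <= ph$half_mm & abs(p[, 2L]) <= ph$half_mm
    dose <- dose * inside
  }
  dose
}

# numeric radiological depth at scattered points: per unique z bin, march
# along the ray on the transverse slice
.raddepth_points_numeric <- function(density, theta, u, w, z) {
  ax <- grid_axes(density$grid)
  step <- min(density$grid$spacing_mm[1:2])
  wmax <- max(abs(c(ax$x, ax$y))) * sqrt(2)
  iz <- pmin(pmax(round((z - density$grid$origin_mm[3L]) /
                          density$grid$spacing_mm[3L]) + 1, 1), density$grid$shape[3L])
  out <- numeric(length(u))
  for (slice in unique(iz)) {
    sel <- iz == slice
    wseq <- seq(wmax, -wmax, by = -step)
    rd <- .raddepth_numeric(density$values[, , slice], ax$x, ax$y, theta,
                            u[sel], wseq)
    # linear interp along w for each point
    fi <- (wmax - w[sel]) / step + 1
    fi <- pmin(pmax(fi, 1), length(wseq))
    i0 <- pmin(floor(fi), length(wseq) - 1L)
    fr <- fi - i0
    rows <- seq_len(sum(sel))
    out[sel] <- (1 - fr) * rd[cbind(rows, i0)] + fr * rd[cbind(rows, i0 + 1L)]
  }
  out
}

#' Ground-truth volumetric dose of an arc plan
#'
#' Integrates the analytic per-control-point beam model over all control
#' points of an arc plan on a voxel lattice. For z-invariant cylindrical
#' phantoms (homogeneous or rod inserts) the transverse and axial factors
#' separate and the superposition reduces to one matrix product; general
#' phantoms fall back to per-slice numeric radiological depths.
#'
#' @inheritParams beam_dose_points
#' @param grid target `grid_spec`; defaults to the density lattice.
#' @return a `dose_grid` (Gy), deterministic given the plan.
#' @export
ground_truth_dose <- function(plan, density, pdd, grid = density$grid,
                              penumbra_mm = 6, mask_to_phantom = TRUE) {
  stopifnot(inherits(plan, "arc_plan"), inherits(density, "density_volume"),
            inherits(pdd, "pdd_table"), inherits(grid, "grid_spec"))
  if (any(plan$theta < min(plan$arc) - 1e-9 | plan$theta > max(plan$arc) + 1e-9))
    stop("ground_truth_dose: plan angles lie outside the arc range")
  ax <- grid_axes(grid)
  nx <- grid$shape[1L]; ny <- grid$shape[2L]; nz <- grid$shape[3L]
  X <- rep(ax$x, times = ny)
  Y <- rep(ax$y, each = nx)
  ph <- density$phantom
  inside <- if (ph$kind == "cylindrical") X^2 + Y^2 <= ph$radius_mm^2
            else abs(X) <= ph$half_mm & abs(Y) <= ph$half_mm
  n_cp <- plan$n_control_points
  if (ph$z_invariant && ph$kind == "cylindrical") {
    A <- matrix(0, nrow = nx * ny, ncol = n_cp)
    B <- matrix(0, nrow = n_cp, ncol = nz)
    for (i in seq_len(n_cp)) {
      uw <- .bev_uw(X, Y, plan$theta[i])
      rd <- .raddepth_analytic(ph, plan$theta[i], uw$u, uw$w)
      a <- .beam_profile(uw$u, plan$field_cm[i], penumbra_mm) *
           pdd_eval(pdd, plan$field_cm[i], rd / 10) / 100
      if (mask_to_phantom) a <- a * inside
      A[, i] <- plan$weights[i] * a
      B[i, ] <- .beam_profile(ax$z, plan$field_cm[i], penumbra_mm)
    }
    vals <- array(A %*% B, dim = grid$shape)
  } else {
    vals <- array(0, dim = grid$shape)
    step <- min(density$grid$spacing_mm[1:2])
    dax <- grid_axes(density$grid)
    wmax <- max(abs(c(dax$x, dax$y))) * sqrt(2)
    wseq <- seq(wmax, -wmax, by = -step)
    ulat <- seq(-wmax, wmax, by = step)
    for (i in seq_len(n_cp)) {
      uw <- .bev_uw(X, Y, plan$theta[i])
      gu <- .beam_profile(uw$u, plan$field_cm[i], penumbra_mm)
      gz <- .beam_profile(ax$z, plan$field_cm[i], penumbra_mm)
      fu <- (uw$u - ulat[1]) / step + 1
      fw <- (wmax - uw$w) / step + 1
      for (iz in seq_len(nz)) {
        # rays are transverse, so each z slice is independent; use the
        # nearest density slice to this dose slice
        dz <- which.min(abs(dax$z - ax$z[iz]))
        rd_mat <- .raddepth_numeric(density$values[, , dz], dax$x, dax$y,
                                    plan$theta[i], ulat, wseq)
        rdp <- .interp_mat(rd_mat, fu, fw)
        a <- gu * pdd_eval(pdd, plan$field_cm[i], rdp / 10) / 100
        if (mask_to_phantom) a <- a * inside
        vals[, , iz] <- vals[, , iz] +
          matrix(plan$weights[i] * a * gz[iz], nrow = nx)
      }
    }
  }
  dose_grid(grid, vals, unit = "Gy")
}

#' Scale factor normalising a plan to its prescription
#'
#' Returns the factor `c` such that the PTV D95 of `c * dose` equals the
#' plan prescription (the clinical acceptability rule that 95 percent of
#' the PTV receives the prescribed dose).
#'
#' @param dose a `dose_grid` of the ground truth.
#' @param ptv_mask logical PTV mask.
#' @param prescription_gy prescription dose (Gy).
#' @return scalar scale factor.
#' @export
scale_to_prescription <- function(dose, ptv_mask, prescription_gy) {
  d95 <- dvh_metric(dose$values[ptv_mask], "D95")
  if (d95 <= 0) stop("scale_to_prescription: PTV D95 is not positive")
  prescription_gy / d95
}
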