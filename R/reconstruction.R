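#' Two-point linear interpolation
#'
#' Evaluates the unique line through nodes `(x0, y0)` and `(x1, y1)`:
#' `phi(x) = (x - x1)/(x0 - x1) * y0 + (x - x0)/(x1 - x0) * y1`.
#' The interpolation error at the nodes is exactly 0.
#'
#' @param n0,n1 nodes, numeric `c(x, y)`.
#' @param x query position(s).
#' @return interpolated value(s).
#' @export
#' @examples
#' interp_linear(c(0, 2), c(4, 10), 1)  # 4
interp_linear <- function(n0, n1, x) {
  if (n0[1L] == n1[1L])
    stop("interp_linear: degenerate interval, node positions coincide")
  (x - n1[1L]) / (n0[1L] - n1[1L]) * n0[2L] +
  (x - n0[1L]) / (n1[1L] - n0[1L]) * n1[2L]
}

#' Bilinear interpolation cell
#'
#' A rectangular cell with corner values, for [interp_bilinear()]:
#' corners `P11 = (x1, y1)`, `P21 = (x2, y1)`, `P12 = (x1, y2)`,
#' `P22 = (x2, y2)` carrying values `f11`, `f21`, `f12`, `f22`.
#'
#' @param x1,x2 cell x bounds, `x1 < x2`.
#' @param y1,y2 cell y bounds, `y1 < y2`.
#' @param f11,f21,f12,f22 corner values.
#' @return an object of class `bilinear_cell`.
#' @export
bilinear_cell <- function(x1, x2, y1, y2, f11, f21, f12, f22) {
  if (!(x1 < x2) || !(y1 < y2))
    stop("bilinear_cell: degenerate cell, require x1 < x2 and y1 < y2")
  structure(list(x = c(x1, x2), y = c(y1, y2),
                 f = matrix(c(f11, f21, f12, f22), 2L, 2L)),
            class = "bilinear_cell")
}

#' Bilinear interpolation in a cell
#'
#' Linear interpolation in x along both cell edges (`R1` on the `y1` edge,
#' `R2` on the `y2` edge) followed by linear interpolation in y between
#' `R1` and `R2`. Equal to the weighted average of the four corner values
#' with weights the areas of the diagonally opposite sub-rectangles, and
#' symmetric in the interpolation order (x-then-y equals y-then-x).
#'
#' @param cell a `bilinear_cell`.
#' @param q query point `c(x, y)` or `n x 2` matrix.
#' @return interpolated value(s).
#' @export
#' @examples
#' cell <- bilinear_cell(0, 1, 0, 1, 1, 3, 5, 7)
#' interp_bilinear(cell, c(0.5, 0.5))  # 4, the corner mean
interp_bilinear <- function(cell, q) {
  stopifnot(inherits(cell, "bilinear_cell"))
  q <- .as_points(q, 2L)
  x <- q[, 1L]; y <- q[, 2L]
  x1 <- cell$x[1L]; x2 <- cell$x[2L]; y1 <- cell$y[1L]; y2 <- cell$y[2L]
  r1 <- (x2 - x) / (x2 - x1) * cell$f[1L, 1L] + (x - x1) / (x2 - x1) * cell$f[2L, 1L]
  r2 <- (x2 - x) / (x2 - x1) * cell$f[1L, 2L] + (x - x1) / (x2 - x1) * cell$f[2L, 2L]
  (y2 - y) / (y2 - y1) * r1 + (y - y1) / (y2 - y1) * r2
}

# ---- planar densification --------------------------------------------------

# Map a planar measurement onto its full rectilinear lattice.
# Returns list(u, v, M, measured) where M has NA at structurally
# unmeasured sites (checkerboard gaps, missing corners) and at dropped-out
# chambers, and `measured` flags chamber sites.
.measurement_lattice <- function(m) {
  stopifnot(inherits(m, "planar_measurement"))
  pos <- detector_positions(m$array)
  kind <- m$array$lattice_kind
  if (kind == "checkerboard") {
    a <- m$array$pitch_mm / sqrt(2)
    u <- seq(min(pos[, 1L]), max(pos[, 1L]), by = a)
    v <- seq(min(pos[, 2L]), max(pos[, 2L]), by = a)
  } else {
    u <- sort(unique(pos[, 1L]))
    v <- sort(unique(pos[, 2L]))
  }
  M <- matrix(NA_real_, length(u), length(v))
  iu <- round((pos[, 1L] - u[1L]) / (u[2L] - u[1L])) + 1L
  iv <- round((pos[, 2L] - v[1L]) / (v[2L] - v[1L])) + 1L
  measured <- matrix(FALSE, length(u), length(v))
  measured[cbind(iu, iv)] <- TRUE
  M[cbind(iu, iv)] <- m$values
  list(u = u, v = v, M = M, measured = measured)
}

# Fill structurally unmeasured lattice sites:
#  - checkerboard gaps: mean of the four diagonal measured neighbours
#    (interior), mean of the two in-line lattice-edge neighbours (edges) —
#    both exact for affine fields;
#  - missing corner chambers (MatriXX): parallelogram completion from
#    the two edge-adjacent chambers and their shared diagonal neighbour.
.fill_structural <- function(lat, kind) {
  M <- lat$M
  n <- nrow(M); p <- ncol(M)
  if (kind == "checkerboard") {
    miss <- which(!lat$measured, arr.ind = TRUE)
    i <- miss[, 1L]; j <- miss[, 2L]
    interior <- i > 1L & i < n & j > 1L & j < p
    ii <- i[interior]; jj <- j[interior]
    M[cbind(ii, jj)] <- (M[cbind(ii - 1L, jj - 1L)] + M[cbind(ii - 1L, jj + 1L)] +
                         M[cbind(ii + 1L, jj - 1L)] + M[cbind(ii + 1L, jj + 1L)]) / 4
    edge <- !interior
    ie <- i[edge]; je <- j[edge]
    vert <- ie == 1L | ie == n       # fill along the edge line
    M[cbind(ie[vert], je[vert])] <-
      (M[cbind(ie[vert], je[vert] - 1L)] + M[cbind(ie[vert], je[vert] + 1L)]) / 2
    M[cbind(ie[!vert], je[!vert])] <-
      (M[cbind(ie[!vert] - 1L, je[!vert])] + M[cbind(ie[!vert] + 1L, je[!vert])]) / 2
  } else if (kind == "square_minus_corners") {
    # parallelogram completion from the two edge neighbours and the
    # diagonal neighbour: exact for affine fields
    for (ci in c(1L, n)) for (cj in c(1L, p)) {
      if (!lat$measured[ci, cj]) {
        i2 <- if (ci == 1L) 2L else n - 1L
        j2 <- if (cj == 1L) 2L else p - 1L
        M[ci, cj] <- max(M[ci, j2] + M[i2, cj] - M[i2, j2], 0)
      }
    }
  }
  M
}

# Fill remaining NAs (dropped-out chambers under the interpolate-over
# policy): linear interpolation along rows between the nearest finite
# values (widened interpolation interval), clamped at row ends; columns
# handle rows left entirely empty.
.fill_na_linear <- function(M) {
  fill_dim <- function(M) {
    for (j in seq_len(ncol(M))) {
      col <- M[, j]
      if (anyNA(col) && sum(is.finite(col)) >= 1L) {
        if (sum(is.finite(col)) == 1L) col[is.na(col)] <- col[is.finite(col)]
        else col <- stats::approx(which(is.finite(col)), col[is.finite(col)],
                                  xout = seq_along(col), rule = 2)$y
        M[, j] <- col
      }
    }
    M
  }
  M <- fill_dim(M)      # along u for each v
  if (anyNA(M)) M <- t(fill_dim(t(M)))
  M
}

#' Continuous interpolant of a planar measurement
#'
#' Builds the piecewise-bilinear interpolant of one planar measurement on
#' its chamber lattice: checkerboard gaps and missing corners are filled
#' first (diagonal / in-line averages), dropped-out readings are handled
#' by the chosen policy, and queries beyond the outermost chambers clamp
#' to the nearest lattice node (no extrapolation). Measured chamber
#' positions reproduce their measured values exactly.
#'
#' @param m a `planar_measurement`.
#' @param policy dropout handling: `"interpolate"` treats no-response
#'   readings as missing and widens the interpolation interval across
#'   them; `"zero"` replaces them by 0 Gy (the pathological
#'   no-response-as-zero behaviour).
#' @return an object of class `plane_interpolant`: call it as
#'   `f(points)` with an `n x 2` matrix (or length-2 vector) of in-plane
#'   positions (mm).
#' @export
plane_interpolant <- function(m, policy = c("interpolate", "zero")) {
  policy <- match.arg(policy)
  lat <- .measurement_lattice(m)
  if (all(is.na(lat$M))) stop("plane_interpolant: all chambers report no response (empty plane)")
  if (policy == "zero") lat$M[lat$measured & is.na(lat$M)] <- 0
  M <- .fill_structural(lat, m$array$lattice_kind)
  if (anyNA(M)) M <- .fill_na_linear(M)
  u <- lat$u; v <- lat$v
  f <- function(points) {
    p <- .as_points(points, 2L)
    fu <- (pmin(pmax(p[, 1L], u[1L]), u[length(u)]) - u[1L]) / (u[2L] - u[1L]) + 1
    fv <- (pmin(pmax(p[, 2L], v[1L]), v[length(v)]) - v[1L]) / (v[2L] - v[1L]) + 1
    # snap queries that are numerically at a lattice node, so node
    # exactness is not eroded by floating-point index drift
    fu <- ifelse(abs(fu - round(fu)) < 1e-9, round(fu), fu)
    fv <- ifelse(abs(fv - round(fv)) < 1e-9, round(fv), fv)
    .interp_mat(M, fu, fv)
  }
  structure(f, class = "plane_interpolant", u = u, v = v, values = M)
}

#' Densify a planar measurement onto a fine lattice
#'
#' Resamples one planar measurement onto a square target lattice at
#' `target_pitch` (for example 10 mm chamber pitch to the 2.5 mm
#' reconstruction resolution) through [plane_interpolant()]: unilinear
#' along chamber rows and bilinear across them, with checkerboard lattices
#' first completed from their diagonal neighbours. Values at original
#' chamber positions are retained exactly.
#'
#' @param m a `planar_measurement`.
#' @param target_pitch target lattice spacing (mm), at most the array
#'   pitch.
#' @param policy dropout policy, see [plane_interpolant()].
#' @param extent_mm half-extent of the target lattice (mm); default half
#'   the array's maximum measuring area.
#' @param v_axis optional explicit axial lattice (mm), e.g. a target grid
#'   z axis.
#' @return an object of class `dense_plane` with fields `u`, `v`,
#'   `values` (`length(u) x length(v)`), `theta`, `control_point_index`.
#' @export
densify_plane <- function(m, target_pitch, policy = c("interpolate", "zero"),
                          extent_mm = NULL, v_axis = NULL) {
  stopifnot(inherits(m, "planar_measurement"))
  if (target_pitch > m$array$pitch_mm + 1e-9)
    stop("densify_plane: target pitch exceeds the array pitch")
  ext <- extent_mm %||% (m$array$max_area_cm[1L] * 10 / 2)
  u <- seq(-ext, ext, by = target_pitch)
  v <- v_axis %||% u
  f <- plane_interpolant(m, policy)
  vals <- matrix(f(cbind(rep(u, times = length(v)), rep(v, each = length(u)))),
                 nrow = length(u))
  structure(list(u = u, v = v, values = vals, theta = m$theta,
                 control_point_index = m$control_point_index,
                 array_name = m$array$name),
            class = "dense_plane")
}

#' Angular interpolation between control-point planes
#'
#' Per-pixel linear interpolation in gantry angle between the two control
#' points bracketing a query angle. For full arcs the interpolation wraps
#' periodically across the arc closure (between the last and first control
#' points); for partial arcs a query outside the covered range is a range
#' error. At a control-point angle the stored plane is returned exactly.
#'
#' @param planes list of `dense_plane` objects at increasing angles, or a
#'   3D array (`u x v x angle`).
#' @param phi query angle (radians).
#' @param angles control-point angles; taken from the planes if omitted.
#' @param periodic full-arc wraparound (default TRUE).
#' @return a `dense_plane` at `phi` (when `planes` is a list), else a
#'   matrix.
#' @export
interp_angular <- function(planes, phi, angles = NULL, periodic = TRUE) {
  is_list <- is.list(planes)
  if (is_list) {
    if (is.null(angles)) angles <- vapply(planes, `[[`, 0, "theta")
    arr <- vapply(planes, `[[`, planes[[1L]]$values, "values")
  } else {
    arr <- planes
    if (is.null(angles)) stop("interp_angular: angles required for array input")
  }
  n <- length(angles)
  if (n < 2L) stop("interp_angular: need at least 2 control points")
  if (is.unsorted(angles, strictly = TRUE))
    stop("interp_angular: angles must be strictly increasing")
  if (periodic) {
    period <- 2 * pi
    phi_n <- angles[1L] + (phi - angles[1L]) %% period
    if (phi_n > angles[n]) {      # wrap segment between last and first
      i0 <- n; i1 <- 1L
      gap <- angles[1L] + period - angles[n]
      wt <- (phi_n - angles[n]) / gap
    } else {
      i0 <- findInterval(phi_n, angles, all.inside = TRUE)
      i1 <- i0 + 1L
      wt <- (phi_n - angles[i0]) / (angles[i1] - angles[i0])
    }
  } else {
    if (phi < angles[1L] - 1e-12 || phi > angles[n] + 1e-12)
      stop("interp_angular: query angle outside the partial arc range")
    i0 <- findInterval(phi, angles, all.inside = TRUE)
    i1 <- i0 + 1L
    wt <- (phi - angles[i0]) / (angles[i1] - angles[i0])
  }
  vals <- (1 - wt) * arr[, , i0] + wt * arr[, , i1]
  if (!is_list) return(vals)
  out <- planes[[1L]]
  out$values <- vals
  out$theta <- phi
  out$control_point_index <- NA_integer_
  out
}

# ---- depth extension -------------------------------------------------------

# water-equivalent depth (mm) at BEV coordinates (u, w) assumed by the
# reconstruction: homogeneous cylindrical phantom (entry at
# w = sqrt(R^2 - u^2)) or slab with surface at w = d_surf.
.recon_depth <- function(u, w, geometry, radius_mm) {
  if (geometry == "cylindrical") {
    we <- sqrt(pmax(radius_mm^2 - u^2, 0))
    pmin(pmax(we - w, 0), 2 * we)
  } else {
    pmax(radius_mm - w, 0)
  }
}

# depth-scaling ratio PDD(d(u,w)) / PDD(d(u,0)) on a (u, w) lattice;
# rays whose reference depth is too shallow to normalise (outside the
# phantom rim) contribute 0.
.depth_ratio_matrix <- function(ulat, wlat, pdd, field_cm, geometry, radius_mm,
                                min_ref_depth_mm = 3) {
  d0 <- .recon_depth(ulat, 0, geometry, radius_mm)
  p0 <- pdd_eval(pdd, field_cm, d0 / 10)
  D <- .recon_depth(matrix(ulat, length(ulat), length(wlat)),
                    matrix(wlat, length(ulat), length(wlat), byrow = TRUE),
                    geometry, radius_mm)
  R <- matrix(pdd_eval(pdd, field_cm, as.vector(D) / 10), nrow = length(ulat))
  ok <- d0 >= min_ref_depth_mm & p0 > 0
  R <- R / ifelse(ok, p0, Inf)
  R
}

#' Extend a planar dose in depth with PDD scaling
#'
#' Extends a densified planar dose map along each ray of its (parallel)
#' beam: `dose(u, v, w) = plane(u, v) * PDD(d(u, w)) / PDD(d(u, 0))`,
#' where `d` is the water-equivalent depth from the phantom surface
#' (cylindrical entry surface, or a slab surface for the rectangular
#' geometry) and `w = 0` is the measurement plane through the isocenter.
#' The PDD curve at a non-tabulated field size is the linear mix of the
#' bracketing tabulated curves.
#'
#' @param plane a `dense_plane`.
#' @param pdd a `pdd_table`.
#' @param field_cm square field side (cm) of this control point.
#' @param geometry `"cylindrical"` or `"slab"`.
#' @param radius_mm phantom radius (cylindrical) or surface distance
#'   (slab), mm.
#' @param w_axis sample positions along the beam axis (mm, 0 at the
#'   measurement plane, positive towards the source); default the u
#'   lattice.
#' @return 3D array with dimensions `(u, v, w)` and attributes `u`, `v`,
#'   `w`.
#' @export
extend_depth <- function(plane, pdd, field_cm,
                         geometry = c("cylindrical", "slab"),
                         radius_mm = 135, w_axis = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(plane, "dense_plane"))
  w <- w_axis %||% plane$u
  R <- .depth_ratio_matrix(plane$u, w, pdd, field_cm, geometry, radius_mm)
  nu <- length(plane$u); nv <- length(plane$v); nw <- length(w)
  out <- array(0, dim = c(nu, nv, nw))
  for (k in seq_len(nw)) out[, , k] <- plane$values * R[, k]
  attr(out, "u") <- plane$u; attr(out, "v") <- plane$v; attr(out, "w") <- w
  out
}

# Control points whose whole plane dropped out (no-response at low dose
# rate): under the "interpolate" policy the missing plane is rebuilt by
# chamber-wise linear interpolation in gantry angle between the nearest
# responsive control points (re-interpolation along the rotation
# direction, wrapping across the arc closure for full arcs); under the
# "zero" policy the control point contributes nothing (NULL marker).
.handle_empty_planes <- function(ms, plan, policy) {
  empty <- vapply(ms, function(m) all(is.na(m$values)), TRUE)
  if (!any(empty)) return(ms)
  if (all(empty))
    stop("reconstruct_volume: every control point reports no response")
  n <- length(ms)
  for (i in which(empty)) {
    if (policy == "zero") { ms[i] <- list(NULL); next }
    ok <- which(!empty)
    if (plan$full_arc) {
      span <- 2 * pi
      d <- (plan$theta[ok] - plan$theta[i]) %% span
      nxt <- ok[which.min(ifelse(d == 0, Inf, d))]
      d2 <- (plan$theta[i] - plan$theta[ok]) %% span
      prv <- ok[which.min(ifelse(d2 == 0, Inf, d2))]
      gap <- (plan$theta[nxt] - plan$theta[prv]) %% span
      wt <- ((plan$theta[i] - plan$theta[prv]) %% span) / gap
    } else {
      prv_c <- ok[ok < i]; nxt_c <- ok[ok > i]
      prv <- if (length(prv_c)) max(prv_c) else min(nxt_c)
      nxt <- if (length(nxt_c)) min(nxt_c) else max(prv_c)
      wt <- if (prv == nxt) 0
            else (plan$theta[i] - plan$theta[prv]) /
                 (plan$theta[nxt] - plan$theta[prv])
    }
    v <- (1 - wt) * ms[[prv]]$values + wt * ms[[nxt]]$values
    ms[[i]] <- planar_measurement(ms[[i]]$theta, v, ms[[i]]$array,
                                  ms[[i]]$control_point_index,
                                  ms[[i]]$rate_cgy_min)
  }
  ms
}

# ---- volumetric assembly ---------------------------------------------------

#' Reconstruct a volumetric dose from arc measurements
#'
#' The full reconstruction chain: for every control point the planar
#' measurement is densified to the target resolution
#' ([densify_plane()]), extended in depth along that beam's rays with PDD
#' scaling ([extend_depth()]), and the per-beam lattice (which rotates
#' with the gantry: a cylindrical assembly for the Octavius geometry,
#' rectangular/slab for MatriXX) is resampled onto the fixed world lattice
#' by trilinear pull and summed — dose is additive over beams. On the
#' rotation axis all beam lattices coincide, so the summed contributions
#' average naturally. Deterministic; doubling all measured values doubles
#' the result exactly.
#'
#' @param ms list of `planar_measurement`, one per control point.
#' @param array a `detector_array_spec`; default taken from the
#'   measurements.
#' @param pdd a `pdd_table`.
#' @param plan the `arc_plan` that was delivered (control-point angles and
#'   field sizes).
#' @param target target `grid_spec`; default 2.5 mm over a 27 cm cube for
#'   the Octavius arrays and 2.0 mm over a 24 cm cube for MatriXX.
#' @param geometry assembly geometry, `"cylindrical"` or `"slab"`.
#' @param policy dropout policy, see [plane_interpolant()].
#' @param radius_mm phantom radius (mm).
#' @param mask_to_phantom zero voxels outside the phantom cylinder.
#' @return a `reconstructed_dose`: a `dose_grid` with a `provenance`
#'   field recording the array, interpolation settings and policy.
#' @export
reconstruct_volume <- function(ms, array = ms[[1L]]$array, pdd, plan,
                               target = NULL,
                               geometry = c("cylindrical", "slab"),
                               policy = "interpolate",
                               radius_mm = 135, mask_to_phantom = TRUE) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(pdd, "pdd_table"), inherits(plan, "arc_plan"))
  if (length(ms) != plan$n_control_points)
    stop("reconstruct_volume: measurements do not cover the plan's control points")
  if (is.null(target)) {
    target <- if (array$name == "matrixx") grid_spec(c(121, 121, 121), 2)
              else grid_spec(c(109, 109, 109), 2.5)
  }
  ax <- grid_axes(target)
  ds <- target$spacing_mm[1L]
  if (max(abs(target$spacing_mm - ds)) > 1e-9)
    stop("reconstruct_volume: target grid must be isotropic")
  ext <- max(abs(c(ax$x, ax$y)), radius_mm)
  ext <- ceiling(ext / ds) * ds
  ulat <- seq(-ext, ext, by = ds)
  wlat <- ulat
  nx <- target$shape[1L]; ny <- target$shape[2L]; nz <- target$shape[3L]
  X <- rep(ax$x, times = ny)
  Y <- rep(ax$y, each = nx)
  M <- matrix(0, nrow = nx * ny, ncol = nz)
  ms <- .handle_empty_planes(ms, plan, policy)
  for (i in seq_len(plan$n_control_points)) {
    m <- ms[[i]]
    if (is.null(m)) next                   # dropped plane under zero policy
    if (abs(m$theta - plan$theta[i]) > 1e-9)
      stop("reconstruct_volume: control point ", i,
           ": measurement angle does not match the plan")
    err_tag <- function(e) stop("reconstruct_volume: control point ", i, ": ",
                                conditionMessage(e))
    dp <- tryCatch(densify_plane(m, ds, policy, extent_mm = ext, v_axis = ax$z),
                   error = err_tag)
    R <- tryCatch(.depth_ratio_matrix(ulat, wlat, pdd, plan$field_cm[i],
                                      geometry, radius_mm),
                  error = err_tag)
    uw <- .bev_uw(X, Y, plan$theta[i])
    fu <- (uw$u + ext) / ds + 1
    fw <- (uw$w + ext) / ds + 1
    nlat <- length(ulat)
    fu <- pmin(pmax(fu, 1), nlat); fw <- pmin(pmax(fw, 1), nlat)
    i0u <- pmin(floor(fu), nlat - 1L); i0w <- pmin(floor(fw), nlat - 1L)
    au <- fu - i0u; aw <- fw - i0w
    P <- dp$values                       # (u x z), z lattice = target z
    for (du in 0:1) {
      wu <- if (du == 0L) 1 - au else au
      iu <- i0u + du
      coef <- wu * ((1 - aw) * R[cbind(iu, i0w)] + aw * R[cbind(iu, i0w + 1L)])
      M <- M + coef * P[iu, , drop = FALSE]
    }
  }
  if (mask_to_phantom && geometry == "cylindrical")
    M <- M * (X^2 + Y^2 <= radius_mm^2)
  out <- dose_grid(target, array(M, dim = target$shape), unit = "Gy")
  out$provenance <- list(array = array$name, geometry = geometry,
                         policy = policy, target_pitch_mm = ds,
                         radius_mm = radius_mm, n_control_points = length(ms))
  class(out) <- c("reconstructed_dose", class(out))
  out
}
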