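#' Cartesian to cylindrical coordinates
#'
#' Converts points `(x, y, z)` to cylindrical coordinates `(r, phi, z)` where
#' the cylinder axis is the world z axis (the phantom's long axis, which is
#' also the gantry rotation axis). The azimuth follows the three-branch rule
#' `phi = 0` at the origin of the transverse plane, `phi = asin(y/r)` for
#' `x >= 0` and `phi = pi - asin(y/r)` for `x < 0`, reduced to `[0, 2*pi)`.
#'
#' @param p numeric vector of length 3 or an `n x 3` matrix of `(x, y, z)`
#'   coordinates in mm.
#' @return an `n x 3` matrix with columns `r`, `phi`, `z` (`r` in mm, `phi`
#'   in radians in `[0, 2*pi)`).
#' @seealso [cyl_to_cart()]
#' @export
#' @examples
#' cart_to_cyl(c(0, 2, 1))   # r = 2, phi = pi/2
cart_to_cyl <- function(p) {
  p <- .as_points(p, 3L)
  if (!all(is.finite(p))) stop("cart_to_cyl: coordinates must be finite")
  x <- p[, 1L]; y <- p[, 2L]; z <- p[, 3L]
  r <- sqrt(x^2 + y^2)
  phi <- numeric(length(x))
  nz <- r > 0
  pos <- nz & x >= 0
  neg <- nz & x < 0
  phi[pos] <- asin(y[pos] / r[pos])
  phi[neg] <- pi - asin(y[neg] / r[neg])
  phi <- phi %% (2 * pi)
  cbind(r = r, phi = phi, z = z)
}

#' Cylindrical to cartesian coordinates
#'
#' Inverse of [cart_to_cyl()]: `x = r*cos(phi)`, `y = r*sin(phi)`, `z = z`.
#'
#' @param p numeric vector of length 3 or an `n x 3` matrix of
#'   `(r, phi, z)` coordinates (`r >= 0`, `phi` in radians).
#' @return an `n x 3` matrix with columns `x`, `y`, `z`.
#' @export
cyl_to_cart <- function(p) {
  p <- .as_points(p, 3L)
  if (!all(is.finite(p))) stop("cyl_to_cart: coordinates must be finite")
  if (any(p[, 1L] < 0)) stop("cyl_to_cart: radial coordinate must be >= 0")
  r <- p[, 1L]; phi <- p[, 2L]; z <- p[, 3L]
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.as_points <- function(p, ncol) {
  if (is.null(dim(p))) {
    if (length(p) != ncol) stop("expected a point of length ", ncol)
    p <- matrix(p, nrow = 1L)
  }
  p <- as.matrix(p)
  if (ncol(p) != ncol) stop("expected an n x ", ncol, " matrix of points")
  storage.mode(p) <- "double"
  p
}

# ---- detector arrays --------------------------------------------------------

#' Detector-array specification
#'
#' Constructs the lattice geometry and chamber properties of one planar
#' ion-chamber detector array. Three commercial arrays are built in and
#' loadable by name with [detector_array()]; custom arrays can be declared
#' directly. The triple (`lattice_kind`, `n_detectors`, `pitch_mm`) must be
#' consistent:
#' \describe{
#'   \item{`square`}{`k x k` grid at pitch `p`, so `n = k^2`.}
#'   \item{`checkerboard`}{two interleaved square grids (`k x k` plus
#'     `(k-1) x (k-1)` offset by half a cell); the nearest-neighbour
#'     distance is the lattice diagonal, `n = k^2 + (k-1)^2`.}
#'   \item{`square_minus_corners`}{`k x k` grid with the four corner
#'     chambers absent, `n = k^2 - 4`.}
#' }
#'
#' @param name identifier.
#' @param lattice_kind one of `"square"`, `"checkerboard"`,
#'   `"square_minus_corners"`.
#' @param pitch_mm nearest-neighbour centre spacing in mm.
#' @param n_detectors chamber count.
#' @param chamber_mm lateral extent of one chamber (mm).
#' @param chamber_height_mm chamber height (mm).
#' @param chamber_volume_cm3 chamber volume (cm^3).
#' @param max_area_cm maximum measuring extent, length-2 numeric (cm x cm).
#' @return an object of class `detector_array_spec`.
#' @export
detector_array_spec <- function(name, lattice_kind, pitch_mm, n_detectors,
                                chamber_mm, chamber_height_mm,
                                chamber_volume_cm3, max_area_cm) {
  lattice_kind <- match.arg(lattice_kind,
                            c("square", "checkerboard", "square_minus_corners"))
  if (!is.numeric(pitch_mm) || pitch_mm <= 0)
    stop("detector_array_spec: pitch_mm must be positive")
  k <- switch(lattice_kind,
    square = sqrt(n_detectors),
    checkerboard = (1 + sqrt(2 * n_detectors - 1)) / 2,
    square_minus_corners = sqrt(n_detectors + 4))
  if (abs(k - round(k)) > 1e-9)
    stop("detector_array_spec: n_detectors = ", n_detectors,
         " is inconsistent with lattice_kind '", lattice_kind, "'")
  spec <- structure(list(
    name = name, lattice_kind = lattice_kind, pitch_mm = pitch_mm,
    n_detectors = as.integer(n_detectors), k = as.integer(round(k)),
    chamber_mm = chamber_mm, chamber_height_mm = chamber_height_mm,
    chamber_volume_cm3 = chamber_volume_cm3,
    max_area_cm = as.numeric(max_area_cm)),
    class = "detector_array_spec")
  pos <- detector_positions(spec)
  half <- spec$max_area_cm * 10 / 2
  if (any(abs(pos[, 1L]) > half[1L] + 1e-9) ||
      any(abs(pos[, 2L]) > half[2L] + 1e-9))
    stop("detector_array_spec: lattice exceeds the maximum measuring area")
  spec
}

#' Built-in detector arrays
#'
#' Loads one of the three built-in ion-chamber array specifications:
#' `"octavius729"` (27 x 27 square grid, 10 mm pitch, 729 chambers),
#' `"octavius1500"` (interleaved 27 x 27 + 26 x 26 checkerboard, 7.07 mm
#' nearest-neighbour spacing, 1405 chambers), and `"matrixx"` (32 x 32 grid
#' at 7.62 mm pitch with the four corner chambers removed, 1020 chambers).
#'
#' @param name `"octavius729"`, `"octavius1500"`, or `"matrixx"`.
#' @return a `detector_array_spec`.
#' @export
#' @examples
#' spec <- detector_array("octavius729")
#' nrow(detector_positions(spec))  # 729
detector_array <- function(name = c("octavius729", "octavius1500", "matrixx")) {
  name <- match.arg(name)
  switch(name,
    octavius729 = detector_array_spec(
      "octavius729", "square", pitch_mm = 10, n_detectors = 729,
      chamber_mm = 5, chamber_height_mm = 5, chamber_volume_cm3 = 0.125,
      max_area_cm = c(27, 27)),
    octavius1500 = detector_array_spec(
      "octavius1500", "checkerboard", pitch_mm = 5 * sqrt(2),
      n_detectors = 1405, chamber_mm = 4.4, chamber_height_mm = 3,
      chamber_volume_cm3 = 0.058, max_area_cm = c(27, 27)),
    matrixx = detector_array_spec(
      "matrixx", "square_minus_corners", pitch_mm = 7.62, n_detectors = 1020,
      chamber_mm = 4.4, chamber_height_mm = 5.5, chamber_volume_cm3 = 0.07,
      max_area_cm = c(24, 24)))
}

#' In-plane chamber positions of a detector array
#'
#' Deterministic chamber-centre positions in the detector plane, centred on
#' the array origin. The first column is the lateral (transverse) in-plane
#' coordinate, the second the axial coordinate along the rotation axis.
#'
#' @param spec a `detector_array_spec`.
#' @return an `n_detectors x 2` matrix (mm) with columns `u_mm`, `v_mm`.
#' @export
detector_positions <- function(spec) {
  stopifnot(inherits(spec, "detector_array_spec"))
  k <- spec$k
  pos <- switch(spec$lattice_kind,
    square = {
      ax <- (seq_len(k) - (k + 1) / 2) * spec$pitch_mm
      as.matrix(expand.grid(u_mm = ax, v_mm = ax))
    },
    checkerboard = {
      a <- spec$pitch_mm / sqrt(2)        # axis step of the half lattice
      ax1 <- (seq_len(k) - (k + 1) / 2) * (2 * a)
      ax2 <- (seq_len(k - 1) - k / 2) * (2 * a)
      rbind(as.matrix(expand.grid(u_mm = ax1, v_mm = ax1)),
            as.matrix(expand.grid(u_mm = ax2, v_mm = ax2)))
    },
    square_minus_corners = {
      ax <- (seq_len(k) - (k + 1) / 2) * spec$pitch_mm
      g <- as.matrix(expand.grid(u_mm = ax, v_mm = ax))
      lim <- max(ax)
      corner <- abs(abs(g[, 1L]) - lim) < 1e-9 & abs(abs(g[, 2L]) - lim) < 1e-9
      g[!corner, , drop = FALSE]
    })
  stopifnot(nrow(pos) == spec$n_detectors)
  dimnames(pos) <- list(NULL, c("u_mm", "v_mm"))
  pos
}

#' Rotate the detector plane to a gantry angle
#'
#' Rigid rotation of 3D points about the phantom's long axis (world z). At
#' `theta = 0` the detector plane is the x-z plane, with the in-plane
#' lateral coordinate along +x and the axial coordinate along +z; the beam
#' then travels along -y. Positive angles rotate counter-clockwise when
#' viewed from +z unless `direction = "cw"`.
#'
#' @param points numeric vector of length 3 or `n x 3` matrix (mm).
#' @param theta gantry angle in radians.
#' @param direction `"ccw"` (default) or `"cw"` positive-angle convention.
#' @return rotated `n x 3` matrix.
#' @export
rotate_plane <- function(points, theta, direction = c("ccw", "cw")) {
  direction <- match.arg(direction)
  if (!is.finite(theta)) stop("rotate_plane: theta must be finite")
  if (direction == "cw") theta <- -theta
  p <- .as_points(points, 3L)
  ct <- cos(theta); st <- sin(theta)
  out <- cbind(ct * p[, 1L] - st * p[, 2L],
               st * p[, 1L] + ct * p[, 2L],
               p[, 3L])
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

# Detector-plane frame at gantry angle theta: the plane contains the
# rotation axis (z) and the rotated lateral axis u(theta); the beam travels
# towards decreasing w. Returns orthonormal in-plane/lateral basis vectors.
.gantry_frame <- function(theta) {
  list(u = c(cos(theta), sin(theta), 0),   # lateral in-plane axis
       w = c(-sin(theta), cos(theta), 0))  # beam entry direction (source side)
}

# Beam-eye-view coordinates (u = lateral, w = along source direction) of
# world transverse coordinates (x, y) for gantry angle theta.
.bev_uw <- function(x, y, theta) {
  list(u = cos(theta) * x + sin(theta) * y,
       w = -sin(theta) * x + cos(theta) * y)
}

# ---- array config serialisation --------------------------------------------

#' Write / read a detector-array config
#'
#' Serialises a `detector_array_spec` to a structured-text (YAML) config
#' block, and reads one back. `read_array_config()` re-validates the
#' lattice triple on load.
#'
#' @param spec a `detector_array_spec`.
#' @param path file path.
#' @return `read_array_config()` returns a `detector_array_spec`.
#' @export
write_array_config <- function(spec, path) {
  stopifnot(inherits(spec, "detector_array_spec"))
  fields <- spec[c("name", "lattice_kind", "pitch_mm", "n_detectors",
                   "chamber_mm", "chamber_height_mm", "chamber_volume_cm3",
                   "max_area_cm")]
  yaml::write_yaml(fields, path, precision = 15L)
  invisible(path)
}

#' @rdname write_array_config
#' @export
read_array_config <- function(path) {
  f <- yaml::read_yaml(path)
  detector_array_spec(f$name, f$lattice_kind, f$pitch_mm, f$n_detectors,
                      f$chamber_mm, f$chamber_height_mm,
                      f$chamber_volume_cm3, unlist(f$max_area_cm))
}

#' @export
print.detector_array_spec <- function(x, ...) {
  cat(sprintf("<detector_array_spec> %s: %d chambers, %s lattice, %.2f mm pitch, %g x %g cm2\n",
              x$name, x$n_detectors, x$lattice_kind, x$pitch_mm,
              x$max_area_cm[1], x$max_area_cm[2]))
  invisible(x)
}
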