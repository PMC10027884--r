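#' Regular voxel-lattice specification
#'
#' Defines a regular 3D voxel lattice by voxel counts, edge lengths and the
#' world coordinate of the centre of voxel `(1,1,1)` (voxel-centre
#' convention). All geometry in the package uses millimetres and a world
#' frame with the isocenter at the origin and the phantom/rotation axis
#' along z.
#'
#' @param shape integer vector of length 3, voxel counts per axis (x, y, z).
#' @param spacing_mm numeric, voxel edge lengths per axis (recycled to 3).
#' @param origin_mm world coordinate (mm) of the centre of the first voxel;
#'   default centres the lattice on the origin.
#' @return an object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(c(109, 109, 109), 2.5)
#' range(grid_axes(g)$x)  # -135 .. 135
grid_spec <- function(shape, spacing_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("grid_spec: spacings must be > 0")
  if (is.null(origin_mm)) origin_mm <- -(shape - 1L) / 2 * spacing_mm
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "grid_spec")
}

#' Axis coordinates of a grid
#'
#' @param grid a `grid_spec`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(i)
    grid$origin_mm[i] + (seq_len(grid$shape[i]) - 1L) * grid$spacing_mm[i])
  names(ax) <- c("x", "y", "z")
  ax
}

#' Voxel volume of a grid in cm^3
#' @param grid a `grid_spec`.
#' @return scalar voxel volume (cm^3).
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing_mm) / 1000

#' World to (fractional, 1-based) voxel index and back
#' @param grid a `grid_spec`.
#' @param points `n x 3` world coordinates (mm).
#' @return `n x 3` matrix of fractional indices / world coordinates.
#' @keywords internal
world_to_index <- function(grid, points) {
  p <- .as_points(points, 3L)
  sweep(sweep(p, 2L, grid$origin_mm, "-"), 2L, grid$spacing_mm, "/") + 1
}

#' @rdname world_to_index
#' @keywords internal
index_to_world <- function(grid, points) {
  p <- .as_points(points, 3L)
  sweep(sweep(p - 1, 2L, grid$spacing_mm, "*"), 2L, grid$origin_mm, "+")
}

#' 3D scalar field on a voxel lattice
#'
#' Container pairing a [grid_spec()] with a dense array of per-voxel values
#' (dose in Gy, or mass density in g/cm^3 for [make_density_phantom()]).
#'
#' @param grid a `grid_spec`.
#' @param values numeric array with `dim == grid$shape`.
#' @param unit value unit label (`"Gy"` or `"g/cm3"`).
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values, unit = "Gy") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("dose_grid: values dimension does not match grid shape")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, unit = unit),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, %d x %d x %d voxels at %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              x$unit, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing_mm[1], x$grid$spacing_mm[2], x$grid$spacing_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Trilinear interpolation of a gridded field at world points
#'
#' Evaluates a `dose_grid` at arbitrary world coordinates by trilinear
#' interpolation of the eight surrounding voxel centres. Points outside the
#' voxel-centre hull raise an error unless `clamp = TRUE`, in which case
#' coordinates are clamped to the hull.
#'
#' @param dose a `dose_grid`.
#' @param points `n x 3` matrix of world coordinates (mm).
#' @param clamp clamp out-of-hull coordinates instead of erroring.
#' @return numeric vector of interpolated values.
#' @export
grid_sample_trilinear <- function(dose, points, clamp = FALSE) {
  stopifnot(inherits(dose, "dose_grid"))
  idx <- world_to_index(dose$grid, points)
  shp <- dose$grid$shape
  out_of_hull <- idx < 1 - 1e-9 | sweep(idx, 2L, shp + 1e-9, ">")
  if (any(out_of_hull)) {
    if (!clamp) {
      bad <- which(rowSums(out_of_hull) > 0)[1L]
      stop(sprintf("grid_sample_trilinear: point %d at (%.2f, %.2f, %.2f) mm lies outside the grid",
                   bad, points[bad, 1], points[bad, 2], points[bad, 3]))
    }
  }
  for (j in 1:3) idx[, j] <- pmin(pmax(idx[, j], 1), shp[j])
  i0 <- pmin(floor(idx), matrix(rep(shp - 1L, each = nrow(idx)), ncol = 3L))
  i0 <- pmax(i0, 1)
  f <- idx - i0
  v <- dose$values
  nx <- shp[1L]; nxy <- shp[1L] * shp[2L]
  lin <- function(dx, dy, dz)
    v[(i0[, 1L] + dx) + (i0[, 2L] + dy - 1L) * nx + (i0[, 3L] + dz - 1L) * nxy]
  fx <- f[, 1L]; fy <- f[, 2L]; fz <- f[, 3L]
  (1 - fz) * ((1 - fy) * ((1 - fx) * lin(0, 0, 0) + fx * lin(1, 0, 0)) +
              fy       * ((1 - fx) * lin(0, 1, 0) + fx * lin(1, 1, 0))) +
  fz       * ((1 - fy) * ((1 - fx) * lin(0, 0, 1) + fx * lin(1, 0, 1)) +
              fy       * ((1 - fx) * lin(0, 1, 1) + fx * lin(1, 1, 1)))
}

# ---- grid file format ------------------------------------------------------

#' Write / read a gridded volume
#'
#' One documented, bit-exact on-disk format for `dose_grid` objects: a flat
#' little-endian float64 binary array in x-fastest (column-major) order at
#' `<path>.f64`, plus a JSON sidecar header `<path>.json` recording shape,
#' spacing_mm, origin_mm, unit and dtype.
#'
#' @param dose a `dose_grid`.
#' @param path base path (without extension).
#' @return `read_dose_grid()` returns a `dose_grid`.
#' @export
write_dose_grid <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  hdr <- list(shape = dose$grid$shape, spacing_mm = dose$grid$spacing_mm,
              origin_mm = dose$grid$origin_mm, unit = dose$unit,
              dtype = "float64_le", order = "x_fastest")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  con <- file(paste0(path, ".f64"), "wb")
  on.exit(close(con))
  writeBin(as.vector(dose$values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$shape)
  con <- file(paste0(path, ".f64"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  dose_grid(grid_spec(hdr$shape, hdr$spacing_mm, hdr$origin_mm),
            array(vals, dim = hdr$shape), unit = hdr$unit)
}
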