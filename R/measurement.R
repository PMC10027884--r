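#' Planar measurement container
#'
#' Doses recorded by every chamber of a detector array at one gantry
#' control point. "No response" readings (for example, dropped out at low
#' dose rate) are held as `NA`, an explicit marker distinct from 0 Gy, and
#' flagged on CSV export.
#'
#' @param theta gantry angle (radians).
#' @param values numeric chamber doses (Gy), `NA` = no response; length
#'   must equal the array's chamber count.
#' @param array a `detector_array_spec`.
#' @param control_point_index integer index along the arc.
#' @param rate_cgy_min dose-rate surrogate of this control point (cGy/min,
#'   the machine rate while it was delivered), used for low-dose-rate
#'   dropout.
#' @return an object of class `planar_measurement`.
#' @export
planar_measurement <- function(theta, values, array, control_point_index = 1L,
                               rate_cgy_min = NA_real_) {
  stopifnot(inherits(array, "detector_array_spec"))
  if (length(values) != array$n_detectors)
    stop("planar_measurement: expected ", array$n_detectors, " values")
  if (any(values < 0, na.rm = TRUE))
    stop("planar_measurement: chamber responses must be >= 0")
  structure(list(theta = theta, values = as.numeric(values), array = array,
                 control_point_index = as.integer(control_point_index),
                 rate_cgy_min = rate_cgy_min),
            class = "planar_measurement")
}

#' Sample a dose grid with a detector array
#'
#' Simulates what an ion-chamber array records when held at gantry angle
#' `theta`: the detector plane (containing the rotation axis) is rotated to
#' `theta` and the dose grid is read at every chamber centre. `"point"`
#' mode is a trilinear lookup at the centre; `"volume_averaged"` mode
#' averages a chamber-sized box (lateral extent x lateral extent x chamber
#' height, height along the beam axis) with a fixed 3 x 3 x 3
#' Gauss-Legendre quadrature.
#'
#' @param dose a `dose_grid`.
#' @param array a `detector_array_spec`.
#' @param theta gantry angle (radians).
#' @param mode `"point"` (default) or `"volume_averaged"`.
#' @param control_point_index stored in the measurement.
#' @param rate_cgy_min stored in the measurement (dose-rate surrogate).
#' @return a `planar_measurement`.
#' @export
sample_planar <- function(dose, array, theta, mode = c("point", "volume_averaged"),
                          control_point_index = 1L, rate_cgy_min = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(dose, "dose_grid"), inherits(array, "detector_array_spec"))
  pos <- detector_positions(array)
  ref <- cbind(pos[, 1L], 0, pos[, 2L])   # detector plane at theta = 0 is x-z
  pts <- rotate_plane(ref, theta)
  vals <- tryCatch({
    if (mode == "point") {
      grid_sample_trilinear(dose, pts)
    } else {
      gl <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2
      glw <- c(5, 8, 5) / 18
      acc <- numeric(nrow(pts))
      frame_w <- .gantry_frame(theta)$w
      frame_u <- .gantry_frame(theta)$u
      for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
        off <- gl[a] * array$chamber_mm * frame_u +
               gl[b] * array$chamber_mm * c(0, 0, 1) +
               gl[cc] * array$chamber_height_mm * frame_w
        acc <- acc + glw[a] * glw[b] * glw[cc] *
          grid_sample_trilinear(dose, sweep(pts, 2L, off, "+"))
      }
      acc
    }
  }, error = function(e) {
    stop("sample_planar: detector plane exits the dose grid (", conditionMessage(e), ")")
  })
  planar_measurement(theta, pmax(vals, 0), array, control_point_index, rate_cgy_min)
}

#' Measure every control point of an arc delivery
#'
#' Produces one [planar_measurement()] per control point, ordered along
#' the arc, by sampling each control point's dose contribution with the
#' array rotated to that control point's gantry angle. `dose_per_cp` may
#' be a list of per-control-point `dose_grid` contributions; see
#' [measure_plan()] for the analytic path the experiments use.
#'
#' @param plan an `arc_plan`.
#' @param dose_per_cp list of `dose_grid` objects, one per control point.
#' @param array a `detector_array_spec`.
#' @param mode sampling mode, see [sample_planar()].
#' @return list of `planar_measurement`, one per control point.
#' @export
deliver_plan <- function(plan, dose_per_cp, array, mode = "point") {
  stopifnot(inherits(plan, "arc_plan"))
  if (length(dose_per_cp) != plan$n_control_points)
    stop("deliver_plan: ", length(dose_per_cp), " dose contributions for ",
         plan$n_control_points, " control points")
  lapply(seq_len(plan$n_control_points), function(i)
    sample_planar(dose_per_cp[[i]], array, plan$theta[i], mode = mode,
                  control_point_index = i, rate_cgy_min = plan$rate_cgy_min[i]))
}

#' Analytic per-control-point measurements
#'
#' Evaluates the analytic beam model ([beam_dose_points()]) exactly at the
#' rotated chamber centres of every control point: the noiseless planar
#' dose an ideal point detector would read. This is the measurement path
#' the experiments use (no intermediate voxelisation).
#'
#' @inheritParams beam_dose_points
#' @param array a `detector_array_spec`.
#' @return list of `planar_measurement`, one per control point.
#' @export
measure_plan <- function(plan, density, pdd, array, penumbra_mm = 6) {
  stopifnot(inherits(plan, "arc_plan"), inherits(array, "detector_array_spec"))
  pos <- detector_positions(array)
  ref <- cbind(pos[, 1L], 0, pos[, 2L])
  lapply(seq_len(plan$n_control_points), function(i) {
    pts <- rotate_plane(ref, plan$theta[i])
    vals <- beam_dose_points(plan, i, pts, density, pdd, penumbra_mm)
    planar_measurement(plan$theta[i], vals, array, i, plan$rate_cgy_min[i])
  })
}

#' Detector noise and low-dose-rate dropout
#'
#' Applies multiplicative Gaussian noise (`value * (1 + sigma_rel * eps)`,
#' truncated at zero) to every reading, then marks as no-response every
#' reading whose control point's dose-rate surrogate falls below
#' `dropout_rate_threshold` cGy/min — the low-dose-rate failure mode of
#' rotational deliveries, in which the detector reports no response while
#' the machine output dips. Seeded and reproducible; the global RNG state
#' is left untouched.
#'
#' @param ms list of `planar_measurement`.
#' @param sigma_rel relative noise standard deviation (>= 0).
#' @param dropout_rate_threshold dose-rate threshold in cGy/min (>= 0);
#'   0 disables dropout.
#' @param seed integer seed.
#' @return list of `planar_measurement` with noisy values and `NA`
#'   no-response markers.
#' @export
apply_noise_and_dropout <- function(ms, sigma_rel = 0, dropout_rate_threshold = 0,
                                    seed = 1) {
  if (sigma_rel < 0) stop("apply_noise_and_dropout: sigma_rel must be >= 0")
  if (dropout_rate_threshold < 0)
    stop("apply_noise_and_dropout: dropout threshold must be >= 0")
  .local_rng(seed)(lapply(ms, function(m) {
    stopifnot(inherits(m, "planar_measurement"))
    v <- m$values
    if (sigma_rel > 0)
      v <- pmax(v * (1 + sigma_rel * stats::rnorm(length(v))), 0)
    if (dropout_rate_threshold > 0) {
      if (is.na(m$rate_cgy_min))
        stop("apply_noise_and_dropout: measurements carry no dose-rate surrogate")
      if (m$rate_cgy_min < dropout_rate_threshold) v[] <- NA_real_
    }
    planar_measurement(m$theta, v, m$array, m$control_point_index, m$rate_cgy_min)
  }))
}

#' Export / import measurements as CSV
#'
#' One row per chamber per control point, the package's analogue of vendor
#' planar-dose exports: `chamber_index, u_mm, v_mm, theta_rad,
#' control_point, dose_gy, flag` with flag `ok` or `no_response`.
#'
#' @param ms list of `planar_measurement`.
#' @param path CSV file path.
#' @param array a `detector_array_spec` (for re-import).
#' @return `read_measurements_csv()` returns a list of
#'   `planar_measurement`.
#' @export
write_measurements_csv <- function(ms, path) {
  rows <- lapply(ms, function(m) {
    pos <- detector_positions(m$array)
    data.frame(chamber_index = seq_len(nrow(pos)),
               u_mm = pos[, 1L], v_mm = pos[, 2L],
               theta_rad = m$theta, control_point = m$control_point_index,
               rate_cgy_min = m$rate_cgy_min,
               dose_gy = ifelse(is.na(m$values), 0, m$values),
               flag = ifelse(is.na(m$values), "no_response", "ok"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path, array) {
  df <- utils::read.csv(path)
  lapply(split(df, df$control_point), function(d) {
    d <- d[order(d$chamber_index), ]
    v <- d$dose_gy
    v[d$flag == "no_response"] <- NA_real_
    planar_measurement(d$theta_rad[1L], v, array, d$control_point[1L],
                       d$rate_cgy_min[1L])
  })
}
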