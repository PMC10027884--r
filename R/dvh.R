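#' Cumulative dose-volume histogram
#'
#' Cumulative ("at least") DVH of the masked voxels of a dose grid:
#' uniform dose bins from 0, and at each left bin edge the percent of the
#' ROI volume receiving at least that dose. Voxels have equal volume, so
#' the curve is volume-weighted by construction. The curve starts at 100
#' percent and is monotone non-increasing.
#'
#' @param dose a `dose_grid` or numeric array of voxel doses (Gy).
#' @param mask logical array, same shape; must select at least one voxel.
#' @param bin_width bin width in Gy (default 0.01).
#' @param roi_name used in error messages.
#' @return an object of class `dvh_curve` with fields `dose_gy` (left bin
#'   edges), `volume_pct`, `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01, roi_name = "ROI") {
  vals <- if (inherits(dose, "dose_grid")) dose$values else dose
  if (!any(mask)) stop("compute_dvh: empty mask for '", roi_name, "'")
  if (!identical(dim(vals), dim(mask)) && !is.null(dim(vals)))
    stop("compute_dvh: dose and mask grids are not aligned")
  d <- as.numeric(vals[mask])
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  counts <- graphics::hist(d, breaks = c(edges, max(edges) + bin_width),
                           plot = FALSE, right = FALSE)$counts
  vol <- rev(cumsum(rev(counts))) / length(d) * 100
  structure(list(dose_gy = edges, volume_pct = vol, bin_width = bin_width),
            class = "dvh_curve")
}

#' DVH metric specification
#'
#' The ICRU-83 metric family: `D_p` (minimum dose received by the hottest
#' p percent of the volume), `V_d` (percent volume receiving dose d),
#' `Dmean`, `Dmax`, `Dmin`. The clinical volume convention for `V_d` is
#' `"at_least"` (volume receiving at least d); `"at_most"` is also
#' computable.
#'
#' @param kind `"D"`, `"V"`, `"Dmean"`, `"Dmax"` or `"Dmin"`.
#' @param param p in percent for `D` (in (0, 100]), d in Gy for `V`.
#' @param volume_convention `"at_least"` (default) or `"at_most"`.
#' @return an object of class `metric_spec`.
#' @export
metric_spec <- function(kind = c("D", "V", "Dmean", "Dmax", "Dmin"),
                        param = NULL,
                        volume_convention = c("at_least", "at_most")) {
  kind <- match.arg(kind)
  volume_convention <- match.arg(volume_convention)
  if (kind == "D") {
    if (is.null(param) || param <= 0 || param > 100)
      stop("metric_spec: D_p requires p in (0, 100]")
  } else if (kind == "V") {
    if (is.null(param) || param < 0)
      stop("metric_spec: V_d requires d >= 0")
  }
  structure(list(kind = kind, param = param,
                 volume_convention = volume_convention),
            class = "metric_spec")
}

#' @rdname metric_spec
#' @param s shorthand string, e.g. `"D95"`, `"D2"`, `"V30"`, `"Dmean"`,
#'   `"Dmax"`.
#' @export
parse_metric <- function(s, volume_convention = "at_least") {
  if (inherits(s, "metric_spec")) return(s)
  if (s %in% c("Dmean", "Dmax", "Dmin"))
    return(metric_spec(s, volume_convention = volume_convention))
  kind <- substr(s, 1L, 1L)
  param <- suppressWarnings(as.numeric(substring(s, 2L)))
  if (!kind %in% c("D", "V") || is.na(param))
    stop("parse_metric: cannot parse metric '", s, "'")
  metric_spec(kind, param, volume_convention)
}

#' Evaluate a DVH metric
#'
#' Computes one metric either exactly from raw voxel doses (the pipeline
#' default: `D_p` is the dose exceeded by exactly p percent of the volume
#' with ties broken toward the higher dose, i.e. the
#' `ceiling(n*p/100)`-th largest voxel dose; `Dmax`/`Dmin` are raw voxel
#' extremes) or from a [compute_dvh()] curve (`D_p` by linear
#' interpolation on the cumulative curve, `V_d` by linear interpolation
#' at d). Curve- and voxel-based values agree to within one dose bin.
#'
#' @param x numeric voxel doses, a `dose_grid`-masked vector, or a
#'   `dvh_curve`.
#' @param spec a `metric_spec` or shorthand string (see
#'   [parse_metric()]).
#' @return metric value (Gy for `D` metrics, percent for `V` metrics).
#' @export
#' @examples
#' dvh_metric(c(1, 2, 3, 4), "D50")
dvh_metric <- function(x, spec) {
  spec <- parse_metric(spec)
  if (inherits(x, "dvh_curve")) return(.metric_from_curve(x, spec))
  d <- as.numeric(x)
  if (!length(d)) stop("dvh_metric: no voxel doses")
  switch(spec$kind,
    Dmean = mean(d),
    Dmax = max(d),
    Dmin = min(d),
    D = {
      v <- sort(d, decreasing = TRUE)
      v[max(1L, ceiling(length(d) * spec$param / 100))]
    },
    V = {
      if (spec$volume_convention == "at_least") 100 * mean(d >= spec$param)
      else 100 * mean(d <= spec$param)
    })
}

.metric_from_curve <- function(curve, spec) {
  e <- curve$dose_gy; v <- curve$volume_pct
  switch(spec$kind,
    Dmean = sum(-diff(c(v, 0)) / 100 * e),   # bin-weighted mean (left edges)
    Dmax = e[max(which(v > 0))],
    Dmin = e[max(which(v >= 100 - 1e-9))],
    D = {
      p <- spec$param
      k <- max(which(v >= p))
      if (k == length(e)) e[k]
      else if (v[k] == v[k + 1L]) e[k + 1L]            # ties toward higher dose
      else e[k] + (v[k] - p) / (v[k] - v[k + 1L]) * curve$bin_width
    },
    V = {
      val <- stats::approx(e, v, xout = spec$param, rule = 2)$y
      if (spec$volume_convention == "at_least") val else 100 - val
    })
}

#' DVH metric table for a set of ROIs
#'
#' @param dose a `dose_grid`.
#' @param rois a `roi_set`.
#' @param metrics character vector of metric shorthands.
#' @return data.frame with columns `roi`, `role`, `metric`, `value`.
#' @export
dvh_metrics_table <- function(dose, rois, metrics = c("D98", "D95", "D50", "D2", "Dmean", "Dmax")) {
  stopifnot(inherits(rois, "roi_set"))
  rows <- lapply(rois, function(r) {
    d <- dose$values[r$mask]
    data.frame(roi = r$name, role = r$role, metric = metrics,
               value = vapply(metrics, function(mm) dvh_metric(d, mm), 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a DVH curve as CSV
#'
#' Two columns, `dose_gy` and `volume_pct`.
#'
#' @param curve a `dvh_curve`.
#' @param path file path.
#' @export
write_dvh_csv <- function(curve, path) {
  utils::write.csv(data.frame(dose_gy = curve$dose_gy,
                              volume_pct = curve$volume_pct),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d bins of %.3g Gy, D50 ~ %.3g Gy\n",
              length(x$dose_gy), x$bin_width, .metric_from_curve(x, parse_metric("D50"))))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = "Dose (Gy)", ylab = "Volume (%)",
                           type = "l") {
  graphics::plot(x$dose_gy, x$volume_pct, type = type, xlab = xlab,
                 ylab = ylab, ...)
}
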