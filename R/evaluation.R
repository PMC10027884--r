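#' Absolute percent dose deviation
#'
#' `|(D_reconstruction - D_truth) / D_truth| * 100`, the absolute
#' percentage dose deviation between a reconstructed and a reference
#' (planned) dose metric. Scale-invariant: rescaling both doses by the
#' same positive factor leaves it unchanged.
#'
#' @param recon reconstructed value(s) (Gy).
#' @param truth reference value(s) (Gy), must be > 0.
#' @return absolute percent deviation(s).
#' @export
#' @examples
#' pdd_percent(57, 60)  # 5
pdd_percent <- function(recon, truth) {
  if (any(truth <= 0))
    stop("pdd_percent: reference dose must be positive (undefined deviation)")
  abs((recon - truth) / truth) * 100
}

#' Absolute percent volume deviation
#'
#' `|(V_reconstruction - V_truth) / V_truth| * 100` for volume metrics
#' (V_d), in percent of the reference volume.
#'
#' @param recon_vol reconstructed volume metric(s) (%).
#' @param truth_vol reference volume metric(s) (%), must be > 0.
#' @return absolute percent deviation(s).
#' @export
vd_percent <- function(recon_vol, truth_vol) {
  if (any(truth_vol <= 0))
    stop("vd_percent: reference volume must be positive (undefined deviation)")
  abs((recon_vol - truth_vol) / truth_vol) * 100
}

#' Aggregate deviation statistics
#'
#' Mean, sample SD and a 95 percent confidence interval of a deviation
#' sample. The default CI is a seeded percentile bootstrap of the mean
#' (printed clinical CIs of such deviations are typically asymmetric); a
#' Student-t interval is available. The 2.5-97.5 percentile range of the
#' sample itself is also returned, labelled separately.
#'
#' @param x numeric deviations, length >= 2.
#' @param ci_method `"bootstrap"` (percentile, of the mean) or `"t"`.
#' @param conf confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `n`, `mean`, `sd`, `ci` (of the mean), `ci_method`,
#'   `ci_sample` (sample percentile range).
#' @export
aggregate_deviations <- function(x, ci_method = c("bootstrap", "t"),
                                 conf = 0.95, n_boot = 1e4, seed = 1) {
  ci_method <- match.arg(ci_method)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("aggregate_deviations: need at least 2 values")
  m <- mean(x); s <- stats::sd(x)
  alpha <- (1 - conf) / 2
  ci <- if (ci_method == "bootstrap") {
    means <- .local_rng(seed)({
      idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                    nrow = n_boot)
      rowMeans(matrix(x[idx], nrow = n_boot))
    })
    unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  } else {
    se <- s / sqrt(length(x))
    m + c(-1, 1) * stats::qt(1 - alpha, df = length(x) - 1L) * se
  }
  list(n = length(x), mean = m, sd = s, ci = ci, ci_method = ci_method,
       conf = conf,
       ci_sample = unname(stats::quantile(x, c(alpha, 1 - alpha), type = 7)))
}

#' Normality-gated paired comparison
#'
#' The inference chain used for paired deviation samples: a Shapiro-Wilk
#' test on each sample at the 5 percent level; when both samples are
#' consistent with normality a paired t-test is used, otherwise the
#' Wilcoxon signed-rank test. Significance is declared at `p < alpha`.
#'
#' @param a,b paired numeric samples of equal length (>= 3), matched by
#'   plan/ROI.
#' @param alpha significance level.
#' @return an object of class `paired_comparison`: `test` (name),
#'   `statistic`, `p_value`, `significant`, `shapiro_p` (length 2),
#'   `alpha`, `n`.
#' @export
compare_paired <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b))
    stop("compare_paired: samples are not paired (length mismatch)")
  if (length(a) < 3L) stop("compare_paired: need at least 3 pairs")
  sw <- c(a = stats::shapiro.test(a)$p.value,
          b = stats::shapiro.test(b)$p.value)
  normal <- all(sw > 0.05)
  d <- a - b
  if (all(d == 0)) {
    res <- list(test = if (normal) "paired t-test" else "Wilcoxon signed-rank",
                statistic = 0, p_value = 1)
  } else if (normal) {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    res <- list(test = "Wilcoxon signed-rank",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(c(res, list(significant = res$p_value < alpha, shapiro_p = sw,
                        alpha = alpha, n = length(a))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s on %d pairs: statistic %.4g, p = %.4g (%s at alpha = %g)\n",
              x$test, x$n, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

# ---- Nyquist amplitude recovery --------------------------------------------

#' Amplitude recovery of a sinusoidal planar modulation
#'
#' Samples a planar dose field `base * (1 + depth * cos(2*pi*u/period))`
#' (modulated along the lateral axis, uniform axially) with a detector
#' array, densifies it, and estimates the recovered peak amplitude as
#' half the difference between the densified map's mean value at the
#' modulation's true crest positions and at its true trough positions.
#' Sampling at a pitch above half the modulation period aliases the
#' pattern and destroys the recovered amplitude (Nyquist criterion);
#' sampling below it recovers the amplitude almost exactly.
#'
#' @param period_mm modulation period (mm).
#' @param array a `detector_array_spec` (default the 10 mm pitch array).
#' @param target_pitch_mm densification lattice (mm).
#' @param depth relative modulation depth.
#' @param base_gy baseline dose.
#' @return list with `amplitude_true`, `amplitude_recovered`,
#'   `error_pct` (absolute percent amplitude error).
#' @export
nyquist_amplitude_error <- function(period_mm, array = detector_array("octavius729"),
                                    target_pitch_mm = 2.5, depth = 0.5,
                                    base_gy = 1) {
  pos <- detector_positions(array)
  vals <- base_gy * (1 + depth * cos(2 * pi * pos[, 1L] / period_mm))
  m <- planar_measurement(0, vals, array)
  f <- plane_interpolant(m)
  hull <- max(abs(pos[, 1L]))
  crests <- seq(0, hull, by = period_mm)
  crests <- c(-rev(crests[-1L]), crests)
  troughs <- crests[-length(crests)] + period_mm / 2
  crests <- crests[abs(crests) <= hull]
  troughs <- troughs[abs(troughs) <= hull]
  a_rec <- (mean(f(cbind(crests, 0))) - mean(f(cbind(troughs, 0)))) / 2
  a_true <- base_gy * depth
  list(amplitude_true = a_true, amplitude_recovered = a_rec,
       error_pct = abs(a_rec - a_true) / a_true * 100)
}

# ---- experiments -----------------------------------------------------------

#' Run a scripted reconstruction-accuracy experiment
#'
#' Generates a seeded ensemble of synthetic partial-arc plans, runs the
#' full measurement -> reconstruction -> DVH -> deviation pipeline for
#' each arm of the scenario, and reports per-arm aggregate statistics with
#' a normality-gated paired test between arms. One master seed expands
#' deterministically into per-plan seeds and arc orientations, and all
#' arms share the plan ensemble exactly, so reports are fully
#' reproducible.
#'
#' Scenarios:
#' \describe{
#'   \item{`spacing`}{10 mm square array (Octavius 729) vs 7.07 mm
#'     checkerboard (Octavius 1500); deviation of the PTV mean dose.}
#'   \item{`heterogeneity`}{homogeneous water cylinder vs a lung-like rod
#'     insert (per-plan density drawn in 0.01-0.26 g/cm^3) surrounding a
#'     lesion-type PTV, same plans and array; the reconstruction always
#'     assumes water-equivalent depths, so accuracy degrades in the
#'     low-density region.}
#'   \item{`small_volume`}{deviation of Dmax for a lens-scale 0.2 cm^3
#'     sphere placed off-axis (in the penumbra sweep) vs a >= 50 cm^3
#'     organ-scale sphere, at 10 mm pitch.}
#'   \item{`nyquist`}{sinusoidal modulation of period 15 mm vs 40 mm
#'     sampled at 10 mm pitch (see [nyquist_amplitude_error()]).}
#'   \item{`dropout`}{arcs containing a few low-output control points
#'     whose planes drop out below 5 cGy/min, handled by re-interpolating
#'     the missing planes along the rotation direction vs zero-filling
#'     them.}
#' }
#'
#' @param scenario one of `"spacing"`, `"heterogeneity"`, `"nyquist"`,
#'   `"small_volume"`, `"dropout"`.
#' @param config list of overrides: `n_plans` (default 20, minimum 10 for
#'   statistical scenarios), `n_cp` (control points per arc, default 24),
#'   `grid` (target `grid_spec`, default 2.5 mm over a 27 cm cube),
#'   `arc_span_deg` (default 220, the partial arcs typical of clinical
#'   deliveries), `metric` (default `"Dmean"` on the PTV),
#'   `penumbra_mm`, `field_range_cm`, `prescription_gy`,
#'   scenario-specific entries (`het_insert`, `insert_rho_range`,
#'   `dropout_threshold`, `n_low_rate`, `low_rate_factor`, `periods_mm`,
#'   `sigma_rel`, `ptv`, `small_roi`, `large_roi`).
#' @param seed master seed.
#' @return an object of class `experiment_report`.
#' @export
run_experiment <- function(scenario = c("spacing", "heterogeneity", "nyquist",
                                        "small_volume", "dropout"),
                           config = list(), seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- utils::modifyList(list(
    n_plans = 20L, n_cp = 24L,
    grid = grid_spec(c(109, 109, 109), 2.5),
    arc_span_deg = 220,
    metric = "Dmean", penumbra_mm = 6,
    field_range_cm = c(4, 12), prescription_gy = 2,
    het_insert = list(centre_mm = c(20, 0), radius_mm = 35),
    insert_rho_range = c(0.01, 0.26),
    dropout_threshold = 5, sigma_rel = 0,
    n_low_rate = 3L, low_rate_factor = 0.03,
    periods_mm = c(15, 40),
    ptv = if (scenario == "heterogeneity")
      list(name = "ptv", role = "PTV", shape = "sphere",
           centre_mm = c(20, 0, 0), radius_mm = 20)
    else
      list(name = "ptv", role = "PTV", shape = "sphere",
           centre_mm = c(0, 0, 0), radius_mm = 25),
    small_roi = list(name = "lens_scale", role = "OAR", shape = "sphere",
                     centre_mm = c(50, 0, 0), volume_cm3 = 0.2),
    large_roi = list(name = "organ_scale", role = "OAR", shape = "sphere",
                     centre_mm = c(0, 0, 0), volume_cm3 = 50)),
    config)
  if (scenario == "nyquist") return(.experiment_nyquist(cfg, seed))
  if (cfg$n_plans < 10L)
    stop("run_experiment: statistical scenarios need at least 10 plans")
  draws <- .local_rng(seed)(list(
    plan_seeds = sample.int(2^31 - 1, cfg$n_plans),
    arc_start = stats::runif(cfg$n_plans, 0, 2 * pi)))
  span <- cfg$arc_span_deg * pi / 180
  plans <- lapply(seq_len(cfg$n_plans), function(k)
    make_plan(cfg$n_cp, arc = c(draws$arc_start[k], draws$arc_start[k] + span),
              field_range_cm = cfg$field_range_cm,
              prescription_gy = cfg$prescription_gy,
              seed = draws$plan_seeds[k]))
  pdd <- make_pdd_table()
  runner <- switch(scenario,
    spacing = .experiment_spacing,
    heterogeneity = .experiment_heterogeneity,
    small_volume = .experiment_small_volume,
    dropout = .experiment_dropout)
  runner(cfg, pdd, plans, seed, scenario)
}

# deviation of one DVH metric between truth and reconstruction, after
# normalising the plan to its prescription
.plan_deviation <- function(truth, recon, rois, metric, roi_name,
                            prescription_gy) {
  sc <- scale_to_prescription(truth, rois[[1L]]$mask, prescription_gy)
  d_t <- dvh_metric(sc * truth$values[rois[[roi_name]]$mask], metric)
  d_r <- dvh_metric(sc * recon$values[rois[[roi_name]]$mask], metric)
  data.frame(roi = roi_name, metric = metric, value_truth = d_t,
             value_recon = d_r, pdd_pct = pdd_percent(d_r, d_t))
}

.experiment_arms_report <- function(scenario, records, cfg, seed, settings) {
  arms <- split(records$pdd_pct, records$arm)
  summaries <- lapply(arms, aggregate_deviations, seed = seed)
  test <- if (length(arms) == 2L)
    compare_paired(arms[[1L]], arms[[2L]]) else NULL
  structure(list(scenario = scenario, records = records,
                 arm_names = names(arms), summaries = summaries,
                 test = test, seed = seed, settings = settings),
            class = "experiment_report")
}

.experiment_spacing <- function(cfg, pdd, plans, seed, scenario) {
  phantom <- make_density_phantom("cylindrical", "homogeneous", cfg$grid)
  rois <- make_roi_set(cfg$grid, list(cfg$ptv))
  arrays <- list(octavius729 = detector_array("octavius729"),
                 octavius1500 = detector_array("octavius1500"))
  records <- do.call(rbind, lapply(seq_along(plans), function(k) {
    truth <- ground_truth_dose(plans[[k]], phantom, pdd, cfg$grid,
                               cfg$penumbra_mm)
    do.call(rbind, lapply(names(arrays), function(an) {
      ms <- measure_plan(plans[[k]], phantom, pdd, arrays[[an]],
                         cfg$penumbra_mm)
      recon <- reconstruct_volume(ms, arrays[[an]], pdd, plans[[k]],
                                  target = cfg$grid)
      cbind(plan = k, arm = an,
            .plan_deviation(truth, recon, rois, cfg$metric, "ptv",
                            cfg$prescription_gy))
    }))
  }))
  .experiment_arms_report(scenario, records, cfg, seed,
                          list(arrays = names(arrays), metric = cfg$metric,
                               n_plans = cfg$n_plans, n_cp = cfg$n_cp,
                               arc_span_deg = cfg$arc_span_deg))
}

.experiment_heterogeneity <- function(cfg, pdd, plans, seed, scenario) {
  rois <- make_roi_set(cfg$grid, list(cfg$ptv))
  array <- detector_array("octavius729")
  hom <- make_density_phantom("cylindrical", "homogeneous", cfg$grid)
  rhos <- .local_rng(seed + 1L)(stats::runif(length(plans),
                                             cfg$insert_rho_range[1L],
                                             cfg$insert_rho_range[2L]))
  records <- do.call(rbind, lapply(seq_along(plans), function(k) {
    lung <- make_density_phantom("cylindrical", "lung_insert", cfg$grid,
                                 params = list(insert_rho = rhos[k],
                                               insert_centre_mm = cfg$het_insert$centre_mm,
                                               insert_radius_mm = cfg$het_insert$radius_mm))
    do.call(rbind, lapply(list(list("homogeneous", hom),
                               list("lung_insert", lung)), function(arm) {
      truth <- ground_truth_dose(plans[[k]], arm[[2L]], pdd, cfg$grid,
                                 cfg$penumbra_mm)
      ms <- measure_plan(plans[[k]], arm[[2L]], pdd, array, cfg$penumbra_mm)
      recon <- reconstruct_volume(ms, array, pdd, plans[[k]],
                                  target = cfg$grid)
      cbind(plan = k, arm = arm[[1L]],
            .plan_deviation(truth, recon, rois, cfg$metric, "ptv",
                            cfg$prescription_gy))
    }))
  }))
  .experiment_arms_report(scenario, records, cfg, seed,
                          list(insert_rho = rhos, metric = cfg$metric,
                               insert = cfg$het_insert,
                               n_plans = cfg$n_plans, n_cp = cfg$n_cp,
                               arc_span_deg = cfg$arc_span_deg))
}

.experiment_small_volume <- function(cfg, pdd, plans, seed, scenario) {
  phantom <- make_density_phantom("cylindrical", "homogeneous", cfg$grid)
  rois <- make_roi_set(cfg$grid, list(cfg$ptv, cfg$small_roi, cfg$large_roi))
  array <- detector_array("octavius729")
  records <- do.call(rbind, lapply(seq_along(plans), function(k) {
    truth <- ground_truth_dose(plans[[k]], phantom, pdd, cfg$grid,
                               cfg$penumbra_mm)
    ms <- measure_plan(plans[[k]], phantom, pdd, array, cfg$penumbra_mm)
    recon <- reconstruct_volume(ms, array, pdd, plans[[k]], target = cfg$grid)
    do.call(rbind, lapply(c(cfg$small_roi$name, cfg$large_roi$name),
                          function(rn)
      cbind(plan = k, arm = rn,
            .plan_deviation(truth, recon, rois, "Dmax", rn,
                            cfg$prescription_gy))))
  }))
  .experiment_arms_report(scenario, records, cfg, seed,
                          list(metric = "Dmax", n_plans = cfg$n_plans,
                               n_cp = cfg$n_cp,
                               arc_span_deg = cfg$arc_span_deg))
}

# a few control points are delivered at strongly reduced machine dose
# rate (the gantry slows down, the same monitor units take longer), so
# their rate surrogate falls below the dropout threshold while their dose
# contribution stays full-strength
.with_low_rate_cps <- function(plan, n_low, factor, seed) {
  idx <- .local_rng(seed + 7L)(sample.int(plan$n_control_points, n_low))
  plan$cp_time_min[idx] <- plan$cp_time_min[idx] / factor
  plan$rate_cgy_min <- 100 * plan$weights / plan$cp_time_min
  plan
}

.experiment_dropout <- function(cfg, pdd, plans, seed, scenario) {
  phantom <- make_density_phantom("cylindrical", "homogeneous", cfg$grid)
  rois <- make_roi_set(cfg$grid, list(cfg$ptv))
  array <- detector_array("octavius729")
  records <- do.call(rbind, lapply(seq_along(plans), function(k) {
    plan <- .with_low_rate_cps(plans[[k]], cfg$n_low_rate,
                               cfg$low_rate_factor, plans[[k]]$seed)
    truth <- ground_truth_dose(plan, phantom, pdd, cfg$grid, cfg$penumbra_mm)
    ms <- measure_plan(plan, phantom, pdd, array, cfg$penumbra_mm)
    ms <- apply_noise_and_dropout(ms, cfg$sigma_rel, cfg$dropout_threshold,
                                  seed = plan$seed)
    do.call(rbind, lapply(c("interpolate", "zero"), function(pol) {
      recon <- reconstruct_volume(ms, array, pdd, plan, target = cfg$grid,
                                  policy = pol)
      cbind(plan = k, arm = pol,
            .plan_deviation(truth, recon, rois, cfg$metric, "ptv",
                            cfg$prescription_gy))
    }))
  }))
  .experiment_arms_report(scenario, records, cfg, seed,
                          list(dropout_threshold = cfg$dropout_threshold,
                               n_low_rate = cfg$n_low_rate,
                               metric = cfg$metric, n_plans = cfg$n_plans,
                               n_cp = cfg$n_cp,
                               arc_span_deg = cfg$arc_span_deg))
}

.experiment_nyquist <- function(cfg, seed) {
  res <- lapply(cfg$periods_mm, nyquist_amplitude_error)
  records <- data.frame(
    arm = paste0("period_", cfg$periods_mm, "mm"),
    period_mm = cfg$periods_mm,
    amplitude_true = vapply(res, `[[`, 0, "amplitude_true"),
    amplitude_recovered = vapply(res, `[[`, 0, "amplitude_recovered"),
    error_pct = vapply(res, `[[`, 0, "error_pct"))
  structure(list(scenario = "nyquist", records = records,
                 arm_names = records$arm, summaries = NULL, test = NULL,
                 seed = seed,
                 settings = list(pitch_mm = 10, periods_mm = cfg$periods_mm)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> scenario '%s' (seed %d)\n", x$scenario, x$seed))
  if (x$scenario == "nyquist") {
    print(x$records, row.names = FALSE)
  } else {
    for (an in names(x$summaries)) {
      s <- x$summaries[[an]]
      cat(sprintf("  %-14s mean Pdd%% = %.3f (SD %.3f, 95%% CI %.3f-%.3f, n = %d)\n",
                  an, s$mean, s$sd, s$ci[1], s$ci[2], s$n))
    }
    if (!is.null(x$test)) print(x$test)
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' `report.json` (machine-readable summaries, test result, settings,
#' seeds) and `records.csv` (per-plan deviation records).
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(scenario = report$scenario, seed = report$seed,
               settings = report$settings,
               summaries = report$summaries,
               test = if (!is.null(report$test)) unclass(report$test))
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  invisible(dir)
}
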