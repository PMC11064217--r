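#' SI-TP inversion configuration
#'
#' Bundles everything the steady-state inversion needs: the monitoring
#' calibration window, areal water loading, the focusing strategy and the
#' aggregation grid step.
#'
#' @param calib_start_ce,calib_end_ce Calibration window, calendar years CE
#'   (default 2003-2018, the monitored window the retention coefficient is
#'   anchored to).
#' @param q_s Areal water loading, m yr^-1; give a value or estimate with
#'   [estimate_qs()].
#' @param focusing Strategy tag: `"none"`, `"fixed_factor"` or `"hakanson"`.
#' @param focusing_factors Named numeric vector of per-core focusing factors
#'   (used by `fixed_factor`); unnamed scalar recycled to all cores.
#' @param aggregation_grid_step_yr Grid step for multi-core aggregation, yr.
#' @return Object of class `sitp_config`.
#' @export
sitp_config <- function(calib_start_ce = 2003, calib_end_ce = 2018,
                        q_s = NULL,
                        focusing = c("fixed_factor", "none", "hakanson"),
                        focusing_factors = 1,
                        aggregation_grid_step_yr = 1) {
  focusing <- match.arg(focusing)
  if (calib_start_ce >= calib_end_ce)
    stop("sitp_config: calib_start_ce must precede calib_end_ce")
  if (!is.null(q_s) && (!is.finite(q_s) || q_s <= 0))
    stop("sitp_config: q_s must be strictly positive")
  if (any(!is.finite(focusing_factors)) || any(focusing_factors <= 0))
    stop("sitp_config: focusing factors must be strictly positive")
  structure(list(calib_start_ce = calib_start_ce, calib_end_ce = calib_end_ce,
                 q_s = q_s, focusing = focusing,
                 focusing_factors = focusing_factors,
                 aggregation_grid_step_yr = aggregation_grid_step_yr),
            class = "sitp_config")
}

new_flux_series <- function(core_id, age_ce, l_sed, extra = NULL) {
  o <- order(age_ce)
  pts <- data.frame(age_ce = age_ce[o], l_sed = l_sed[o])
  if (!is.null(extra)) pts <- cbind(pts, extra[o, , drop = FALSE])
  if (any(diff(pts$age_ce) <= 0))
    stop("flux_series '", core_id, "': ages must be strictly increasing")
  if (any(!is.finite(pts$l_sed)) || any(pts$l_sed < 0))
    stop("flux_series '", core_id, "': l_sed must be finite and >= 0")
  rownames(pts) <- NULL
  structure(list(core_id = core_id, points = pts), class = "flux_series")
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("flux_series '%s': %d points, %s-%s CE, L_sed %.3g-%.3g mg/m2/yr\n",
              x$core_id, nrow(x$points),
              format(round(min(x$points$age_ce), 1)),
              format(round(max(x$points$age_ce), 1)),
              min(x$points$l_sed), max(x$points$l_sed)))
  invisible(x)
}

#' Sediment phosphorus burial flux
#'
#' Per-sample areal P burial flux: `l_sed = p_conc * mar * 1e4`, converting
#' (mg P g^-1) x (g cm^-2 yr^-1) = mg P cm^-2 yr^-1 to mg P m^-2 yr^-1.
#' No focusing correction is applied here.
#'
#' @param profile A [core_profile()].
#' @return A `flux_series` (points ordered by increasing age).
#' @export
compute_lsed <- function(profile) {
  stopifnot(inherits(profile, "core_profile"))
  s <- profile$samples
  new_flux_series(profile$core_id, s$age_ce, s$p_conc * s$mar * 1e4)
}

#' Heuristic sediment-focusing factor from lake geometry
#'
#' Dynamic-ratio heuristic: DR = sqrt(lake area, km^2) / mean depth (m);
#' the erosion-plus-transport fraction of the lake bed is approximated as
#' ET% = 25 * DR * 41^(0.061 / DR) (clamped to 5-95%), and a core from the
#' accumulation zone over-represents lake-wide burial by
#' F = 1 / (1 - ET/100) >= 1. This is a geometry-only approximation; when
#' empirical per-core factors are available prefer strategy
#' `"fixed_factor"`.
#'
#' @param lake A [lake_catchment()].
#' @return Focusing factor F >= 1.
#' @export
hakanson_focusing_factor <- function(lake) {
  stopifnot(inherits(lake, "lake_catchment"))
  dr <- sqrt(lake$lake_area_m2 / 1e6) / lake$mean_depth_m
  et <- 25 * dr * 41^(0.061 / dr)
  et <- min(max(et, 5), 95)
  1 / (1 - et / 100)
}

#' Correct burial fluxes for sediment focusing
#'
#' Converts a core-local flux into a lake-wide equivalent flux by dividing
#' by a focusing factor F: `l_sed_lakewide = l_sed_core / F`.
#'
#' @param flux A `flux_series` from [compute_lsed()].
#' @param lake A [lake_catchment()]; required for strategy `"hakanson"`.
#' @param strategy `"none"` (identity, F = 1), `"fixed_factor"` (user
#'   supplied `factor`), or `"hakanson"` (geometry heuristic, see
#'   [hakanson_focusing_factor()]).
#' @param factor Focusing factor for `"fixed_factor"`, must be > 0.
#' @return A `flux_series` of lake-wide equivalent fluxes; the factor used
#'   is attached as attribute `"focusing_factor"`.
#' @export
focusing_correct <- function(flux, lake = NULL,
                             strategy = c("none", "fixed_factor", "hakanson"),
                             factor = 1) {
  stopifnot(inherits(flux, "flux_series"))
  strategy <- match.arg(strategy)
  f <- switch(strategy,
    none = 1,
    fixed_factor = {
      if (!is.finite(factor) || factor <= 0)
        stop("focusing_correct: factor must be strictly positive")
      factor
    },
    hakanson = {
      if (is.null(lake)) stop("focusing_correct: hakanson strategy needs a lake_catchment")
      hakanson_focusing_factor(lake)
    })
  out <- new_flux_series(flux$core_id, flux$points$age_ce, flux$points$l_sed / f)
  attr(out, "focusing_factor") <- f
  out
}

#' Aggregate multi-core fluxes on a common time grid
#'
#' Linearly interpolates each core's flux series to a common grid (default
#' annual) restricted to years covered by at least one core; no
#' extrapolation beyond a core's dated range. The aggregate is the mean of
#' the cores available at each grid year; the per-year spread (min, max)
#' and count of contributing cores are returned alongside.
#'
#' @param fluxes List of `flux_series` (length >= 1).
#' @param grid_step_yr Grid step, yr.
#' @return A `flux_series` with core id `"mean"` and extra point columns
#'   `n_cores`, `l_min`, `l_max`; attribute `"no_overlap"` is TRUE when no
#'   grid year is covered by every core.
#' @export
aggregate_cores <- function(fluxes, grid_step_yr = 1) {
  if (length(fluxes) == 0L) stop("aggregate_cores: empty input")
  for (f in fluxes) stopifnot(inherits(f, "flux_series"))
  lo <- min(vapply(fluxes, function(f) min(f$points$age_ce), 0))
  hi <- max(vapply(fluxes, function(f) max(f$points$age_ce), 0))
  grid <- seq(ceiling(lo / grid_step_yr) * grid_step_yr, hi, by = grid_step_yr)
  vals <- vapply(fluxes, function(f) {
    stats::approx(f$points$age_ce, f$points$l_sed, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  keep <- n > 0
  if (!any(keep)) stop("aggregate_cores: no grid year covered by any core")
  vals <- vals[keep, , drop = FALSE]; grid <- grid[keep]; n <- n[keep]
  agg <- rowMeans(vals, na.rm = TRUE)
  lmin <- apply(vals, 1, min, na.rm = TRUE)
  lmax <- apply(vals, 1, max, na.rm = TRUE)
  out <- new_flux_series("mean", grid, agg,
                         data.frame(n_cores = n, l_min = lmin, l_max = lmax))
  attr(out, "no_overlap") <- !any(n == length(fluxes))
  out
}

#' Estimate areal water loading from a gauged reference record
#'
#' Regresses a short monitored outflow-discharge record on a long gauged
#' reference flow record (ordinary least squares over their overlapping
#' time steps), predicts annual outflow volumes for the requested years,
#' and converts the mean annual volume to areal water loading
#' `q_s = mean(volume) / lake area` (m yr^-1). Negative predicted volumes
#' are floored at zero with a warning.
#'
#' @param outflow_monitored `tp_ts` of monitored outflow discharge,
#'   m^3 yr^-1, on annual time steps.
#' @param reference_gauge `tp_ts` of the gauged reference discharge,
#'   m^3 yr^-1, covering both the overlap and `predict_years`.
#' @param lake A [lake_catchment()].
#' @param predict_years Years to predict outflow for (default: all gauge
#'   years).
#' @return Object of class `qs_estimate`: list with `q_s` (m yr^-1),
#'   `slope`, `intercept`, `predicted` (`tp_ts` of annual volumes) and the
#'   underlying `lm` fit.
#' @export
estimate_qs <- function(outflow_monitored, reference_gauge, lake,
                        predict_years = reference_gauge$when) {
  stopifnot(inherits(outflow_monitored, "tp_ts"),
            inherits(reference_gauge, "tp_ts"),
            inherits(lake, "lake_catchment"))
  m <- match(outflow_monitored$when, reference_gauge$when)
  ok <- !is.na(m)
  if (sum(ok) < 3L)
    stop("estimate_qs: need >= 3 overlapping observations, have ", sum(ok))
  dat <- data.frame(out = outflow_monitored$value[ok],
                    gauge = reference_gauge$value[m[ok]])
  fit <- stats::lm(out ~ gauge, data = dat)
  gp <- reference_gauge$value[match(predict_years, reference_gauge$when)]
  if (anyNA(gp))
    stop("estimate_qs: reference gauge does not cover all predict_years")
  pred <- stats::predict(fit, newdata = data.frame(gauge = gp))
  if (any(pred < 0)) {
    warning("estimate_qs: ", sum(pred < 0),
            " negative predicted volumes floored at 0")
    pred <- pmax(pred, 0)
  }
  structure(list(q_s = mean(pred) / lake$lake_area_m2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 predicted = tp_timeseries(predict_years, pred,
                                           "outflow_m3_yr"),
                 fit = fit),
            class = "qs_estimate")
}

#' @export
print.qs_estimate <- function(x, ...) {
  cat(sprintf("qs_estimate: q_s = %.4g m/yr (slope %.4g, intercept %.4g, %d predicted years)\n",
              x$q_s, x$slope, x$intercept, nrow(x$predicted)))
  invisible(x)
}

#' Outflow phosphorus loading over a monitoring window
#'
#' `l_out = q_s * mean(monitored TP in window)`, with TP in ug L^-1
#' (= mg m^-3) and q_s in m yr^-1, giving mg P m^-2 yr^-1 per unit lake
#' area.
#'
#' @param monitored_tp `tp_ts` of monitored lake-water TP, ug L^-1.
#' @param q_s Areal water loading, m yr^-1.
#' @param window Numeric length-2, inclusive `[start, end]` calendar years.
#' @return Outflow P loading, mg m^-2 yr^-1.
#' @export
compute_lout <- function(monitored_tp, q_s, window) {
  stopifnot(inherits(monitored_tp, "tp_ts"), length(window) == 2L)
  inw <- monitored_tp$when >= window[1] & monitored_tp$when <= window[2]
  if (!any(inw))
    stop("compute_lout: no monitored TP in window [", window[1], ", ",
         window[2], "]")
  q_s * mean(monitored_tp$value[inw])
}

#' Calibrate the phosphorus retention coefficient
#'
#' Anchors the inversion to the monitoring window: the mean lake-wide
#' burial flux over the window (`l_sed_cal`) and the outflow loading give
#' `r_p = l_sed_cal / (l_sed_cal + l_out)`, the fraction of the P supply
#' permanently buried. By construction the inferred TP record then matches
#' the monitored TP mean over the same window.
#'
#' @param flux A `flux_series` (typically the multi-core aggregate).
#' @param l_out Outflow P loading from [compute_lout()], mg m^-2 yr^-1.
#' @param window Numeric length-2, inclusive calibration window (years CE).
#' @return Object of class `retention`: `r_p`, `l_sed_cal`, `l_out_cal`,
#'   `window`.
#' @export
calibrate_rp <- function(flux, l_out, window) {
  stopifnot(inherits(flux, "flux_series"), length(window) == 2L, l_out >= 0)
  inw <- flux$points$age_ce >= window[1] & flux$points$age_ce <= window[2]
  if (!any(inw))
    stop("calibrate_rp: no flux points in window [", window[1], ", ",
         window[2], "]")
  l_sed_cal <- mean(flux$points$l_sed[inw])
  if (l_sed_cal <= 0)
    stop("calibrate_rp: mean flux over the window is not positive; ",
         "retention undefined")
  structure(list(r_p = l_sed_cal / (l_sed_cal + l_out),
                 l_sed_cal = l_sed_cal, l_out_cal = l_out,
                 window = as.numeric(window)),
            class = "retention")
}

#' @export
print.retention <- function(x, ...) {
  cat(sprintf("retention: R_P = %.4f (L_sed_cal %.4g, L_out %.4g mg/m2/yr, window %s-%s)\n",
              x$r_p, x$l_sed_cal, x$l_out_cal, x$window[1], x$window[2]))
  invisible(x)
}

#' Invert the steady-state phosphorus mass balance to lake-water TP
#'
#' At steady state the P supply L_in splits into burial
#' (`L_sed = R_P * L_in`) and outflow export (`L_out = (1 - R_P) * L_in`),
#' and outflow concentration equals lake concentration
#' (`TP = L_out / q_s`). Eliminating L_in:
#' `TP(t) = L_sed(t) * (1 - R_P) / (R_P * q_s)`, ug L^-1.
#'
#' @param flux A `flux_series` of lake-wide burial fluxes.
#' @param retention A `retention` from [calibrate_rp()] (or a list with an
#'   `r_p` element in (0, 1]).
#' @param q_s Areal water loading, m yr^-1, > 0.
#' @param method Method tag for the returned record.
#' @return A [tp_series()] whose aggregate has `when = age_ce`.
#' @export
infer_tp <- function(flux, retention, q_s, method = "SI-TP-raw") {
  stopifnot(inherits(flux, "flux_series"))
  r_p <- retention$r_p
  if (!is.finite(r_p) || r_p <= 0 || r_p > 1)
    stop("infer_tp: r_p must lie in (0, 1]")
  if (!is.finite(q_s) || q_s <= 0) stop("infer_tp: q_s must be > 0")
  tp <- flux$points$l_sed * (1 - r_p) / (r_p * q_s)
  tp_series(method, tp_timeseries(flux$points$age_ce, tp, "TP_ugL"))
}
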