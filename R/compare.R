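#' Penalized-spline smooth of an irregular record
#'
#' Fits a generalized additive model (penalized cubic regression spline,
#' Gaussian response) to an irregularly spaced record, with the smoothing
#' parameter selected by REML (default) or GCV, and evaluates the fit on an
#' annual grid covering exactly the data range (no extrapolation). This is
#' the standard device for comparing paleo records whose native sampling
#' densities differ.
#'
#' @param series A [tp_timeseries()].
#' @param basis_size Spline basis dimension (mgcv `k`); reduced with a
#'   warning when the series has fewer than `basis_size + 2` points.
#' @param selection Smoothness selection criterion, `"REML"` or `"GCV"`.
#' @return Object of class `smooth_fit`: the `mgcv::gam` model, `fitted`
#'   (`tp_ts` on the annual grid, endpoints equal to the data endpoints),
#'   `edf`, `sp`, `basis_size`, `selection`.
#' @export
fit_gam <- function(series, basis_size = 12, selection = c("REML", "GCV")) {
  stopifnot(inherits(series, "tp_ts"))
  selection <- match.arg(selection)
  n <- nrow(series)
  if (n < 4L) stop("fit_gam: need >= 4 points to identify a smooth, have ", n)
  k <- basis_size
  if (n < basis_size + 2L) {
    k <- max(4L, n - 1L)
    warning("fit_gam: only ", n, " points for basis_size ", basis_size,
            "; reducing basis to ", k)
  }
  dat <- data.frame(when = series$when, value = series$value)
  lo <- min(series$when); hi <- max(series$when)
  grid <- seq(lo, hi, by = 1)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  if (stats::sd(dat$value) == 0) {
    # constant response: the smooth is the constant; REML is degenerate here
    model <- stats::lm(value ~ 1, data = dat)
    return(structure(list(model = model,
                          fitted = tp_timeseries(grid,
                                                 rep(dat$value[1],
                                                     length(grid)),
                                                 paste0(ts_label(series),
                                                        "_gam")),
                          edf = 1, sp = Inf,
                          basis_size = k, selection = selection),
                     class = "smooth_fit"))
  }
  model <- mgcv::gam(value ~ s(when, k = k, bs = "cr"), data = dat,
                     method = if (selection == "REML") "REML" else "GCV.Cp")
  fitted <- as.numeric(stats::predict(model, newdata = data.frame(when = grid)))
  structure(list(model = model,
                 fitted = tp_timeseries(grid, fitted,
                                        paste0(ts_label(series), "_gam")),
                 edf = sum(model$edf), sp = unname(model$sp),
                 basis_size = k, selection = selection),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("smooth_fit: basis %d (%s), edf %.2f, grid %s-%s\n",
              x$basis_size, x$selection, x$edf,
              format(round(min(x$fitted$when), 1)),
              format(round(max(x$fitted$when), 1))))
  invisible(x)
}

#' Locate the peak of a smoothed record
#'
#' Argmax of the fitted values on the annual grid; ties are broken to the
#' earliest year and reported. A peak at either grid endpoint is flagged as
#' a boundary peak (the true maximum may lie outside the dated range).
#'
#' @param fit A `smooth_fit` from [fit_gam()].
#' @return List with `peak_year`, `peak_value`, `boundary` (logical),
#'   `tie` (logical).
#' @export
find_peak <- function(fit) {
  stopifnot(inherits(fit, "smooth_fit"))
  f <- fit$fitted
  i <- which(f$value == max(f$value))
  list(peak_year = f$when[i[1]], peak_value = f$value[i[1]],
       boundary = i[1] == 1L || i[1] == nrow(f),
       tie = length(i) > 1L)
}

#' Pair a TP record with reference dates by centered window means
#'
#' For each date of the reference (e.g. diatom-inferred) record, averages
#' all points of the other record (all cores pooled when per-core series
#' are present) falling within +/- `half_window_yr` of that date.
#' Reference dates with no neighbours are dropped and counted.
#'
#' @param sitp A [tp_series()] (per-core points pooled if present,
#'   otherwise the aggregate is used).
#' @param ditp A `tp_ts` (or `tp_series`) providing the reference dates
#'   and values.
#' @param half_window_yr Half window width, yr, > 0 (default 5).
#' @return `data.frame` with columns `ditp_date`, `ditp_value`,
#'   `sitp_mean`, `n_points`; attribute `"n_dropped"` counts unpaired
#'   reference dates.
#' @export
centered_means <- function(sitp, ditp, half_window_yr = 5) {
  stopifnot(inherits(sitp, "tp_series"), half_window_yr > 0)
  if (inherits(ditp, "tp_series")) ditp <- ditp$aggregate
  stopifnot(inherits(ditp, "tp_ts"))
  if (!is.null(sitp$per_core)) {
    pts_when <- unlist(lapply(sitp$per_core, `[[`, "when"), use.names = FALSE)
    pts_val <- unlist(lapply(sitp$per_core, `[[`, "value"), use.names = FALSE)
  } else {
    pts_when <- sitp$aggregate$when
    pts_val <- sitp$aggregate$value
  }
  rows <- lapply(seq_len(nrow(ditp)), function(i) {
    sel <- abs(pts_when - ditp$when[i]) <= half_window_yr
    if (!any(sel)) return(NULL)
    data.frame(ditp_date = ditp$when[i], ditp_value = ditp$value[i],
               sitp_mean = mean(pts_val[sel]), n_points = sum(sel))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("centered_means: no reference date has neighbours within +/-",
         half_window_yr, " yr")
  attr(out, "n_dropped") <- dropped
  out
}

#' Proxy-proxy validation regression
#'
#' Ordinary least squares of the reference record on the paired record
#' (`ditp_value ~ sitp_mean`), with r^2, the two-sided slope p-value, 95%
#' confidence intervals on slope and intercept, per-point 95% prediction
#' intervals, and residual-normality diagnostics (Shapiro-Wilk plus the
#' correlation coefficient of the normal Q-Q plot).
#'
#' @param pairs `data.frame` from [centered_means()] (columns `ditp_value`,
#'   `sitp_mean`), >= 3 rows.
#' @return Object of class `proxy_comparison`: `slope`, `intercept`, `r2`,
#'   `p_value`, `ci95_slope`, `ci95_intercept`, `prediction_band`
#'   (`data.frame` x, fit, lwr, upr), `residuals`, `qq_stats`
#'   (`shapiro_w`, `shapiro_p`, `qq_cor`), `n`, `fit`.
#' @export
regress_proxies <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("ditp_value", "sitp_mean") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) stop("regress_proxies: need >= 3 pairs, have ", n)
  if (stats::sd(pairs$sitp_mean) == 0)
    stop("regress_proxies: zero variance in sitp_mean")
  fit <- stats::lm(ditp_value ~ sitp_mean, data = pairs)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  # in-sample prediction band; predict.lm's "future responses" note is the
  # intended semantics here
  pb <- suppressWarnings(stats::predict(fit, interval = "prediction",
                                        level = 0.95))
  res <- stats::residuals(fit)
  qq_cor <- stats::cor(sort(res), stats::qnorm(stats::ppoints(n)))
  sh <- if (n >= 3 && n <= 5000) stats::shapiro.test(res)
        else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = unname(sm$coefficients["sitp_mean", "Pr(>|t|)"]),
    ci95_slope = unname(ci["sitp_mean", ]),
    ci95_intercept = unname(ci["(Intercept)", ]),
    prediction_band = data.frame(x = pairs$sitp_mean, fit = pb[, "fit"],
                                 lwr = pb[, "lwr"], upr = pb[, "upr"]),
    residuals = unname(res),
    qq_stats = list(shapiro_w = unname(sh$statistic),
                    shapiro_p = sh$p.value, qq_cor = qq_cor),
    n = n, fit = fit),
    class = "proxy_comparison")
}

#' @export
print.proxy_comparison <- function(x, ...) {
  cat(sprintf("proxy_comparison (n=%d): y = %.4g x %s %.4g, r2 = %.4g, p = %.3g\n",
              x$n, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept), x$r2, x$p_value))
  cat(sprintf("  slope 95%% CI [%.4g, %.4g]; Shapiro-Wilk p = %.3g, Q-Q cor = %.4f\n",
              x$ci95_slope[1], x$ci95_slope[2],
              x$qq_stats$shapiro_p, x$qq_stats$qq_cor))
  invisible(x)
}

#' Interval-weighted mean of a dated record
#'
#' Mean of the calendar-aligned bin means (default decadal bins 1900-1909,
#' 1910-1919, ...). Corrects a record mean for variable sampling density:
#' oversampled intervals do not dominate.
#'
#' @param series A `tp_ts`.
#' @param interval_yr Bin width, yr (default 10).
#' @return Scalar: mean of the nonempty bin means.
#' @export
interval_weighted_mean <- function(series, interval_yr = 10) {
  stopifnot(inherits(series, "tp_ts"), interval_yr > 0)
  bins <- floor(series$when / interval_yr)
  mean(tapply(series$value, bins, mean))
}

#' Five-year bin means of a monitored record
#'
#' Non-overlapping calendar-aligned 5-year bin means, timestamped at bin
#' centers — the conventional summary of a monitored TP record plotted
#' against inferred records.
#'
#' @param monitored A `tp_ts`.
#' @return A `tp_ts` of bin means at bin-center times.
#' @export
five_year_means <- function(monitored) {
  stopifnot(inherits(monitored, "tp_ts"))
  bins <- floor(monitored$when / 5) * 5
  m <- tapply(monitored$value, bins, mean)
  tp_timeseries(as.numeric(names(m)) + 2.5, as.numeric(m),
                paste0(ts_label(monitored), "_5yr_mean"))
}
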