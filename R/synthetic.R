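#' Synthetic lake-sediment scenario
#'
#' Defines a fully synthetic lake-sediment system with known ground truth:
#' a smooth multi-century TP trajectory (baseline, logistic-background rise
#' to a peak, partial relaxation to a post-peak level), a set of cores
#' differing in focusing factor, slice thickness and accumulation rate, an
#' optional diagenetic labile-P overprint, multiplicative lognormal noise,
#' a short monitoring window, and a biased noisy diatom-proxy transform.
#'
#' Defaults mirror a small eutrophic lowland lake (area 0.154 km^2, mean
#' depth 6.3 m, q_s 2.79 m yr^-1, monitoring 2003-2018) so magnitudes are
#' realistic; all truth values are synthetic.
#'
#' @param seed Integer seed (mandatory); all noise is drawn from named
#'   substreams derived from it.
#' @param span Length-2 simulated time span, years CE.
#' @param baseline_ugL,peak_ugL,post_peak_ugL TP levels, ug L^-1.
#' @param rise_start_ce,peak_ce Rise onset and peak year, CE.
#' @param lake A [lake_catchment()].
#' @param true_r_p True retention coefficient in (0, 1).
#' @param q_s Areal water loading, m yr^-1.
#' @param n_cores Number of cores.
#' @param focusing Per-core focusing factors (length `n_cores`).
#' @param slice_cm Per-core slice thickness, cm.
#' @param mar Per-core dry-mass accumulation rate, g cm^-2 yr^-1.
#' @param bulk_density Dry bulk density used to convert MAR to linear
#'   sedimentation rate, g cm^-3.
#' @param collection_years Per-core collection years, CE.
#' @param penn List `labile0` (mg g^-1, 0 disables the overprint) and `k`
#'   (yr^-1).
#' @param noise List of coefficients of variation: `flux_cv`,
#'   `monitoring_cv`, `ditp_cv`.
#' @param ditp_bias Multiplicative bias of the diatom proxy.
#' @param monitoring_window Length-2 monitored window, years CE.
#' @return Object of class `lake_scenario`.
#' @export
lake_scenario <- function(seed,
                          span = c(1700, 2018),
                          baseline_ugL = 30, peak_ugL = 180,
                          post_peak_ugL = 80,
                          rise_start_ce = 1800, peak_ce = 1930,
                          lake = lake_catchment(0.154e6, 6.3, 9.3, 1.72e6,
                                                q_s = 2.79),
                          true_r_p = 0.75, q_s = 2.79,
                          n_cores = 4,
                          focusing = c(1, 1.3, 1.6, 2),
                          slice_cm = c(0.5, 1, 1, 2),
                          mar = c(0.047, 0.042, 0.05, 0.045),
                          bulk_density = 0.1,
                          collection_years = c(2018, 2017, 2016, 2018),
                          penn = list(labile0 = 1.5, k = 0.05),
                          noise = list(flux_cv = 0.1, monitoring_cv = 0.1,
                                       ditp_cv = 0.25),
                          ditp_bias = 2,
                          monitoring_window = c(2003, 2018)) {
  if (missing(seed) || !is.finite(seed)) stop("lake_scenario: seed is mandatory")
  stopifnot(span[1] < span[2], true_r_p > 0, true_r_p < 1, q_s > 0,
            baseline_ugL > 0, peak_ugL >= baseline_ugL, post_peak_ugL > 0,
            rise_start_ce < peak_ce, peak_ce < span[2],
            n_cores >= 1, all(focusing > 0), all(slice_cm > 0),
            all(mar > 0), bulk_density > 0,
            penn$labile0 >= 0, penn$k > 0,
            all(unlist(noise) >= 0), ditp_bias > 0,
            monitoring_window[1] < monitoring_window[2])
  rec <- function(x) rep_len(x, n_cores)
  structure(list(seed = as.integer(seed), span = span,
                 baseline_ugL = baseline_ugL, peak_ugL = peak_ugL,
                 post_peak_ugL = post_peak_ugL,
                 rise_start_ce = rise_start_ce, peak_ce = peak_ce,
                 lake = lake, true_r_p = true_r_p, q_s = q_s,
                 n_cores = n_cores, focusing = rec(focusing),
                 slice_cm = rec(slice_cm), mar = rec(mar),
                 bulk_density = bulk_density,
                 collection_years = rec(collection_years),
                 penn = penn, noise = noise, ditp_bias = ditp_bias,
                 monitoring_window = monitoring_window),
            class = "lake_scenario")
}

#' @export
print.lake_scenario <- function(x, ...) {
  cat(sprintf("lake_scenario (seed %d): %s-%s, TP %g->%g->%g ug/L (peak %s), r_p %.2f, q_s %.3g, %d cores, overprint %s\n",
              x$seed, x$span[1], x$span[2], x$baseline_ugL, x$peak_ugL,
              x$post_peak_ugL, x$peak_ce, x$true_r_p, x$q_s, x$n_cores,
              if (x$penn$labile0 > 0) "on" else "off"))
  invisible(x)
}

# Named substreams off one scenario seed: toggling one component never
# perturbs another's draws.
substream_seed <- function(seed, name) {
  off <- c(cores = 101L, monitoring = 211L, ditp = 307L, ditp_dates = 401L)
  (as.integer(seed) + off[[name]]) %% .Machine$integer.max
}

# Closed-form trajectory: logistic background step (baseline -> post-peak,
# centered after the peak so its slope at the peak is negligible) plus an
# asymmetric Gaussian bump whose width blends from a slow rise to a faster
# relaxation. Smooth everywhere; argmax at peak_ce to well under the annual
# grid step.
tp_trajectory <- function(t, sc) {
  s_b <- 7; t_b <- sc$peak_ce + 30
  sigma_r <- (sc$peak_ce - sc$rise_start_ce) / 2.6
  sigma_d <- 22; s_blend <- 8
  bg <- sc$baseline_ugL +
    (sc$post_peak_ugL - sc$baseline_ugL) * stats::plogis((t - t_b) / s_b)
  amp <- max(sc$peak_ugL - (sc$baseline_ugL +
         (sc$post_peak_ugL - sc$baseline_ugL) *
           stats::plogis((sc$peak_ce - t_b) / s_b)), 0)
  sigma <- sigma_r + (sigma_d - sigma_r) *
    stats::plogis((t - sc$peak_ce) / s_blend)
  bg + amp * exp(-((t - sc$peak_ce) / sigma)^2)
}

#' True TP history of a scenario
#'
#' Evaluates the scenario's smooth trajectory on an annual grid over its
#' span: constant baseline into the past, a rise beginning near
#' `rise_start_ce`, peak at `peak_ce`, relaxation toward the post-peak
#' level.
#'
#' @param scenario A [lake_scenario()].
#' @return A `tp_ts` labelled `"TP_true_ugL"`.
#' @export
make_tp_history <- function(scenario) {
  stopifnot(inherits(scenario, "lake_scenario"))
  grid <- seq(scenario$span[1], scenario$span[2], by = 1)
  tp_timeseries(grid, tp_trajectory(grid, scenario), "TP_true_ugL")
}

# inverse of the steady-state inversion: lake-wide burial flux implied by TP
lsed_from_tp <- function(tp, r_p, q_s) tp * q_s * r_p / (1 - r_p)

rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Forward-simulate sediment cores from a TP history
#'
#' Composes the inverse mass balance, per-core focusing, slice-wise
#' sampling, the two-fraction diagenetic overprint and multiplicative
#' lognormal measurement noise: lake-wide flux
#' `L_sed(t) = TP(t) q_s r_p / (1 - r_p)`; core flux `F * L_sed`;
#' deposited concentration `flux / (MAR * 1e4)`; measured concentration
#' adds `labile0 * exp(-k * burial_age)`; slices of the stated thickness
#' carry midpoint ages (linear sedimentation rate `MAR / bulk_density`).
#'
#' @param truth_tp `tp_ts` from [make_tp_history()].
#' @param scenario A [lake_scenario()].
#' @return List: `cores` (list of [core_profile()]), `truth` (list with
#'   `tp`, `lsed` (`tp_ts` of lake-wide flux) and per-core `deposited`
#'   data frames holding the noiseless profile before and after the
#'   overprint), `scenario`.
#' @export
make_cores <- function(truth_tp, scenario) {
  stopifnot(inherits(truth_tp, "tp_ts"), inherits(scenario, "lake_scenario"))
  sc <- scenario
  set.seed(substream_seed(sc$seed, "cores"))
  lsed <- lsed_from_tp(truth_tp$value, sc$true_r_p, sc$q_s)
  cores <- vector("list", sc$n_cores)
  deposited <- vector("list", sc$n_cores)
  for (i in seq_len(sc$n_cores)) {
    coll <- sc$collection_years[i]
    lsr <- sc$mar[i] / sc$bulk_density          # cm yr^-1
    depth_max <- lsr * (coll - sc$span[1])
    edges <- seq(0, depth_max, by = sc$slice_cm[i])
    mid <- utils::head(edges, -1) + sc$slice_cm[i] / 2
    age <- coll - mid / lsr
    keep <- age >= sc$span[1]
    mid <- mid[keep]; age <- age[keep]
    flux_core <- sc$focusing[i] *
      stats::approx(truth_tp$when, lsed, xout = age, rule = 2)$y
    c_dep <- flux_core / (sc$mar[i] * 1e4)
    c_meas <- penn_forward(age, c_dep, sc$penn$labile0, sc$penn$k, coll)
    c_noisy <- c_meas * rlnorm_cv(length(c_meas), sc$noise$flux_cv)
    id <- sprintf("SYN%02d", i)
    cores[[i]] <- core_profile(id, coll,
      data.frame(depth_cm = mid, age_ce = age, p_conc = c_noisy,
                 mar = sc$mar[i]))
    deposited[[i]] <- data.frame(depth_cm = mid, age_ce = age,
                                 p_dep = c_dep, p_overprinted = c_meas)
    names(deposited)[i] <- id
  }
  names(cores) <- vapply(cores, `[[`, "", "core_id")
  list(cores = cores,
       truth = list(tp = truth_tp,
                    lsed = tp_timeseries(truth_tp$when, lsed,
                                         "Lsed_lakewide_mg_m2_yr"),
                    deposited = deposited),
       scenario = sc)
}

#' Simulate a monitored TP record
#'
#' Monthly samples of the true TP over the scenario's monitoring window
#' with multiplicative lognormal noise.
#'
#' @param truth_tp `tp_ts` from [make_tp_history()].
#' @param scenario A [lake_scenario()].
#' @return A `tp_ts` labelled `"TP_monitored_ugL"`.
#' @export
make_monitoring <- function(truth_tp, scenario) {
  stopifnot(inherits(truth_tp, "tp_ts"), inherits(scenario, "lake_scenario"))
  w <- scenario$monitoring_window
  if (w[1] < min(truth_tp$when) || w[2] > max(truth_tp$when))
    stop("make_monitoring: monitoring window [", w[1], ", ", w[2],
         "] outside the simulated span")
  set.seed(substream_seed(scenario$seed, "monitoring"))
  t <- seq(w[1] + 1 / 24, w[2], by = 1 / 12)
  tp <- stats::approx(truth_tp$when, truth_tp$value, xout = t, rule = 2)$y
  tp_timeseries(t, tp * rlnorm_cv(length(t), scenario$noise$monitoring_cv),
                "TP_monitored_ugL")
}

#' Simulate a diatom-inferred TP record
#'
#' A statistical proxy transform of the true TP: multiplicative bias times
#' truth times lognormal noise, at irregular dates (default: a jittered
#' 1850-1990 grid, emulating a proxy core that predates the monitoring
#' record).
#'
#' @param truth_tp `tp_ts` from [make_tp_history()].
#' @param scenario A [lake_scenario()].
#' @param sample_dates Optional dates, CE; must lie within the span.
#' @return A `tp_ts` labelled `"DI-TP_ugL"`.
#' @export
make_ditp <- function(truth_tp, scenario, sample_dates = NULL) {
  stopifnot(inherits(truth_tp, "tp_ts"), inherits(scenario, "lake_scenario"))
  if (is.null(sample_dates)) {
    set.seed(substream_seed(scenario$seed, "ditp_dates"))
    sample_dates <- sort(seq(1850, 1990, length.out = 36) +
                           stats::runif(36, -2, 2))
  }
  if (min(sample_dates) < scenario$span[1] ||
      max(sample_dates) > scenario$span[2])
    stop("make_ditp: sample dates outside the simulated span")
  set.seed(substream_seed(scenario$seed, "ditp"))
  tp <- stats::approx(truth_tp$when, truth_tp$value, xout = sample_dates,
                      rule = 2)$y
  tp_timeseries(sample_dates,
                scenario$ditp_bias * tp *
                  rlnorm_cv(length(tp), scenario$noise$ditp_cv),
                "DI-TP_ugL")
}

#' Simulate a complete synthetic lake-sediment dataset
#'
#' Runs [make_tp_history()], [make_cores()], [make_monitoring()] and
#' [make_ditp()] for one scenario.
#'
#' @param scenario A [lake_scenario()].
#' @return List: `cores`, `truth`, `monitoring`, `ditp`, `scenario`.
#' @export
simulate_lake <- function(scenario) {
  stopifnot(inherits(scenario, "lake_scenario"))
  truth_tp <- make_tp_history(scenario)
  sim <- make_cores(truth_tp, scenario)
  list(cores = sim$cores, truth = sim$truth,
       monitoring = make_monitoring(truth_tp, scenario),
       ditp = make_ditp(truth_tp, scenario),
       scenario = scenario)
}
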