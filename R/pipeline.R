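#' Run the SI-TP inversion on in-memory objects
#'
#' Executes the full inversion twice — once on the raw profiles and once on
#' diagenesis-corrected profiles — so each branch is independently anchored
#' to the monitored window:
#' `compute_lsed` -> `focusing_correct` -> (`penn_fit` + `penn_correct`) ->
#' `aggregate_cores` -> `compute_lout` + `calibrate_rp` -> `infer_tp`.
#'
#' @param cores Named list of [core_profile()].
#' @param monitoring `tp_ts` of monitored TP, ug L^-1.
#' @param config A [sitp_config()]; `q_s` must be set.
#' @param lake Optional [lake_catchment()] (required for the `hakanson`
#'   focusing strategy).
#' @param diagenesis List: `enabled` (default TRUE) and
#'   `fit_max_burial_age_yr` (default 50) — the model is fitted to the
#'   recent, quasi-stationary section of each core (see [penn_fit()]).
#' @param verbose Log calibrated constants with `message()`.
#' @return List of class `sitp_result`: `raw` and `penn` ([tp_series()]
#'   with per-core records), `retention_raw`, `retention_penn`, `l_out`,
#'   `q_s`, `penn_fits`, `flux_raw`, `flux_penn` (aggregates),
#'   `focusing_factors`.
#' @export
sitp_pipeline <- function(cores, monitoring, config, lake = NULL,
                          diagenesis = list(enabled = TRUE,
                                            fit_max_burial_age_yr = 50),
                          verbose = FALSE) {
  stopifnot(inherits(config, "sitp_config"), length(cores) >= 1L)
  for (p in cores) stopifnot(inherits(p, "core_profile"))
  if (is.null(names(cores)))
    names(cores) <- vapply(cores, `[[`, "", "core_id")
  if (is.null(config$q_s))
    stop("sitp_pipeline: config$q_s is not set; supply it or run estimate_qs")
  window <- c(config$calib_start_ce, config$calib_end_ce)
  enabled <- isTRUE(diagenesis$enabled)
  fit_age <- diagenesis$fit_max_burial_age_yr %||% 50

  factor_for <- function(id, i) {
    f <- config$focusing_factors
    if (!is.null(names(f)) && id %in% names(f)) f[[id]]
    else f[[min(i, length(f))]]
  }
  correct_focus <- function(flux, id, i)
    focusing_correct(flux, lake = lake, strategy = config$focusing,
                     factor = factor_for(id, i))

  branch <- function(profiles) {
    fluxes <- vector("list", length(profiles))
    for (i in seq_along(profiles)) {
      fluxes[[i]] <- correct_focus(compute_lsed(profiles[[i]]),
                                   profiles[[i]]$core_id, i)
    }
    names(fluxes) <- names(profiles)
    agg <- aggregate_cores(fluxes, config$aggregation_grid_step_yr)
    l_out <- compute_lout(monitoring, config$q_s, window)
    ret <- calibrate_rp(agg, l_out, window)
    list(fluxes = fluxes, agg = agg, l_out = l_out, ret = ret)
  }

  mk_series <- function(br, method) {
    agg_tp <- infer_tp(br$agg, br$ret, config$q_s, method)$aggregate
    per_core <- lapply(br$fluxes, function(f)
      infer_tp(f, br$ret, config$q_s, method)$aggregate)
    tp_series(method, agg_tp, per_core)
  }

  raw <- branch(cores)
  penn_fits <- NULL
  penn <- NULL
  if (enabled) {
    penn_fits <- lapply(cores, penn_fit, fit_max_burial_age_yr = fit_age)
    corrected <- Map(penn_correct, cores, penn_fits)
    penn <- branch(corrected)
  }
  if (verbose) {
    message(sprintf("sitp_pipeline: q_s = %.4g m/yr, L_out = %.4g mg/m2/yr, window %s-%s",
                    config$q_s, raw$l_out, window[1], window[2]))
    message(sprintf("  raw branch:  R_P = %.4f (L_sed_cal %.4g)",
                    raw$ret$r_p, raw$ret$l_sed_cal))
    if (enabled)
      message(sprintf("  penn branch: R_P = %.4f (L_sed_cal %.4g)",
                      penn$ret$r_p, penn$ret$l_sed_cal))
  }
  structure(list(
    raw = mk_series(raw, "SI-TP-raw"),
    penn = if (enabled) mk_series(penn, "SI-TP-penn"),
    retention_raw = raw$ret,
    retention_penn = if (enabled) penn$ret,
    l_out = raw$l_out, q_s = config$q_s,
    penn_fits = penn_fits,
    flux_raw = raw$agg, flux_penn = if (enabled) penn$agg,
    focusing_factors = vapply(seq_along(cores), function(i)
      factor_for(names(cores)[i], i), 0),
    window = window),
    class = "sitp_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sitp_result <- function(x, ...) {
  cat(sprintf("sitp_result: q_s %.3g m/yr, L_out %.4g; R_P raw %.4f%s\n",
              x$q_s, x$l_out, x$retention_raw$r_p,
              if (is.null(x$retention_penn)) ""
              else sprintf(", R_P penn %.4f", x$retention_penn$r_p)))
  invisible(x)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the SI-TP inversion from a configuration
#'
#' File-based front end to [sitp_pipeline()]. The configuration (YAML path
#' or list) has fields:
#' \describe{
#'   \item{cores}{list of `{path, core_id, collection_year,
#'     focusing_factor}`}
#'   \item{monitoring_path}{CSV of monitored TP (`when,value`)}
#'   \item{sitp}{`{calib_start_ce, calib_end_ce, q_s, focusing,
#'     aggregation_grid_step_yr}`}
#'   \item{lake}{optional `{lake_area_m2, mean_depth_m, max_depth_m,
#'     catchment_area_m2}`}
#'   \item{diagenesis}{`{enabled, fit_max_burial_age_yr}`}
#'   \item{out_dir}{optional output directory}
#' }
#' When `out_dir` is set, writes `sitp_raw.csv`, `sitp_penn.csv` (schema of
#' [write_series_csv()]) and a `sitp_provenance.json` sidecar recording
#' r_p, q_s, l_out, window, focusing strategy and factors, per-core Penn
#' parameters and the package version.
#'
#' @param config YAML path or list.
#' @param verbose Log calibrated constants.
#' @return A `sitp_result` (invisibly when writing files).
#' @export
run_infer <- function(config, verbose = TRUE) {
  cfg <- read_pipeline_config(config)
  for (f in c("cores", "monitoring_path", "sitp"))
    if (is.null(cfg[[f]])) stop("run_infer: config field '", f, "' missing")
  if (!file.exists(cfg$monitoring_path))
    stop("run_infer: monitoring file not found: ", cfg$monitoring_path)
  cores <- lapply(cfg$cores, function(cc) {
    if (!file.exists(cc$path))
      stop("run_infer: core file not found: ", cc$path)
    read_core_csv(cc$path, cc$core_id, cc$collection_year)
  })
  names(cores) <- vapply(cores, `[[`, "", "core_id")
  monitoring <- read_series_csv(cfg$monitoring_path, "TP_monitored_ugL")
  ff <- vapply(cfg$cores, function(cc) cc$focusing_factor %||% 1, 0)
  names(ff) <- names(cores)
  sc <- cfg$sitp
  config_obj <- sitp_config(
    calib_start_ce = sc$calib_start_ce %||% 2003,
    calib_end_ce = sc$calib_end_ce %||% 2018,
    q_s = sc$q_s,
    focusing = sc$focusing %||% "fixed_factor",
    focusing_factors = ff,
    aggregation_grid_step_yr = sc$aggregation_grid_step_yr %||% 1)
  lake <- if (!is.null(cfg$lake))
    lake_catchment(cfg$lake$lake_area_m2, cfg$lake$mean_depth_m,
                   cfg$lake$max_depth_m, cfg$lake$catchment_area_m2)
  dia <- cfg$diagenesis %||% list(enabled = TRUE)
  res <- sitp_pipeline(cores, monitoring, config_obj, lake = lake,
                       diagenesis = dia, verbose = verbose)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series_csv(res$raw, file.path(cfg$out_dir, "sitp_raw.csv"))
    if (!is.null(res$penn))
      write_series_csv(res$penn, file.path(cfg$out_dir, "sitp_penn.csv"))
    prov <- list(
      q_s = res$q_s, l_out = res$l_out, window = res$window,
      focusing = list(strategy = config_obj$focusing,
                      factors = as.list(res$focusing_factors)),
      r_p_raw = res$retention_raw$r_p,
      r_p_penn = if (!is.null(res$retention_penn)) res$retention_penn$r_p,
      penn = lapply(res$penn_fits, function(pf)
        list(a = pf$params$p_stable, b = pf$params$p_unstable0,
             k = pf$params$k, sse = pf$sse,
             identifiable = pf$identifiable, degenerate = pf$degenerate)),
      package_version = as.character(utils::packageVersion("paleotp")))
    jsonlite::write_json(prov,
                         file.path(cfg$out_dir, "sitp_provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Compare two TP records
#'
#' The validation workflow: smooths each record with [fit_gam()], locates
#' the GAM peaks, pairs the records by [centered_means()], regresses the
#' reference record on the paired means ([regress_proxies()]), and
#' computes the interval-weighted (decadal) mean of each record.
#'
#' @param sitp A [tp_series()] (the record paired by windowed means).
#' @param ditp A `tp_ts` or `tp_series` (the reference record, regression
#'   response).
#' @param half_window_yr Pairing half-window, yr.
#' @param basis_size GAM basis dimension.
#' @param interval_yr Bin width of the interval-weighted mean, yr.
#' @param out_dir Optional directory; writes `comparison_pairs.csv` and
#'   `comparison_report.json`.
#' @return List of class `comparison_report`: `gam_sitp`, `gam_ditp`,
#'   `peak_sitp`, `peak_ditp`, `pairs`, `regression`
#'   (`proxy_comparison`), `iwm_sitp`, `iwm_ditp`.
#' @export
run_compare <- function(sitp, ditp, half_window_yr = 5, basis_size = 12,
                        interval_yr = 10, out_dir = NULL) {
  stopifnot(inherits(sitp, "tp_series"))
  ditp_ts <- if (inherits(ditp, "tp_series")) ditp$aggregate else ditp
  gam_sitp <- fit_gam(sitp$aggregate, basis_size)
  gam_ditp <- fit_gam(ditp_ts, basis_size)
  pairs <- centered_means(sitp, ditp_ts, half_window_yr)
  reg <- regress_proxies(pairs)
  rep <- structure(list(
    gam_sitp = gam_sitp, gam_ditp = gam_ditp,
    peak_sitp = find_peak(gam_sitp), peak_ditp = find_peak(gam_ditp),
    pairs = pairs, regression = reg,
    iwm_sitp = interval_weighted_mean(sitp$aggregate, interval_yr),
    iwm_ditp = interval_weighted_mean(ditp_ts, interval_yr)),
    class = "comparison_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pairs, file.path(out_dir, "comparison_pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
      p_value = reg$p_value, ci95_slope = reg$ci95_slope,
      ci95_intercept = reg$ci95_intercept,
      shapiro_p = reg$qq_stats$shapiro_p, qq_cor = reg$qq_stats$qq_cor,
      n_pairs = reg$n,
      peak_year_sitp = rep$peak_sitp$peak_year,
      peak_year_ditp = rep$peak_ditp$peak_year,
      iwm_sitp = rep$iwm_sitp, iwm_ditp = rep$iwm_ditp),
      file.path(out_dir, "comparison_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  r <- x$regression
  cat(sprintf("comparison_report: y = %.4g x %s %.4g, r2 = %.4g, p = %.3g (n = %d)\n",
              r$slope, if (r$intercept < 0) "-" else "+", abs(r$intercept),
              r$r2, r$p_value, r$n))
  cat(sprintf("  GAM peaks: %.0f (paired record) / %.0f (reference); interval-weighted means %.4g / %.4g ug/L\n",
              x$peak_sitp$peak_year, x$peak_ditp$peak_year,
              x$iwm_sitp, x$iwm_ditp))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Simulates a scenario and writes every file the inference pipeline
#' consumes — per-core CSVs, the monitored TP record, the diatom-proxy
#' record — plus the ground truth (`truth_tp.csv`, `truth_lsed.csv`), the
#' scenario (`scenario.yaml`) and a ready-to-run inference configuration
#' (`config.yaml`) pointing at the written files.
#'
#' @param scenario A [lake_scenario()] (or path to a YAML file of
#'   [lake_scenario()] arguments).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [simulate_lake()] result.
#' @export
run_simulate <- function(scenario, out_dir) {
  if (is.character(scenario)) {
    args <- yaml::read_yaml(scenario)
    if (!is.null(args$lake)) args$lake <- do.call(lake_catchment, args$lake)
    for (f in c("span", "focusing", "slice_cm", "mar", "collection_years",
                "monitoring_window"))
      if (!is.null(args[[f]])) args[[f]] <- as.numeric(unlist(args[[f]]))
    scenario <- do.call(lake_scenario, args)
  }
  stopifnot(inherits(scenario, "lake_scenario"))
  sim <- simulate_lake(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  core_entries <- vector("list", length(sim$cores))
  for (i in seq_along(sim$cores)) {
    p <- sim$cores[[i]]
    path <- file.path(out_dir, paste0("core_", p$core_id, ".csv"))
    write_core_csv(p, path)
    core_entries[[i]] <- list(path = path, core_id = p$core_id,
                              collection_year = p$collection_year,
                              focusing_factor = scenario$focusing[i])
  }
  wts <- function(ts, name) {
    utils::write.csv(data.frame(when = ts$when, value = ts$value),
                     file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wts(sim$monitoring, "monitoring.csv")
  wts(sim$ditp, "ditp.csv")
  wts(sim$truth$tp, "truth_tp.csv")
  wts(sim$truth$lsed, "truth_lsed.csv")
  sc <- scenario; sc$lake <- unclass(sc$lake)
  yaml::write_yaml(unclass(sc), file.path(out_dir, "scenario.yaml"))
  cfg <- list(
    cores = core_entries,
    monitoring_path = file.path(out_dir, "monitoring.csv"),
    ditp_path = file.path(out_dir, "ditp.csv"),
    sitp = list(calib_start_ce = scenario$monitoring_window[1],
                calib_end_ce = scenario$monitoring_window[2],
                q_s = scenario$q_s, focusing = "fixed_factor",
                aggregation_grid_step_yr = 1),
    diagenesis = list(enabled = scenario$penn$labile0 > 0,
                      fit_max_burial_age_yr = 50),
    out_dir = out_dir)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(sim)
}
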