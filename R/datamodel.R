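#' Dated sediment-core phosphorus profile
#'
#' Constructs and validates a `core_profile`: one dated sediment core with,
#' per slice, depth below the sediment surface, calibrated calendar age,
#' sediment phosphorus concentration and dry-mass accumulation rate.
#' Sample ages refer to slice midpoints.
#'
#' Units are fixed at this boundary: depth in cm, age in calendar years CE
#' (fractional allowed), P concentration in mg P per g dry sediment, mass
#' accumulation rate (MAR) in g dry sediment per cm^2 per yr.
#'
#' @param core_id Character scalar naming the core.
#' @param collection_year Calendar year CE the core was collected.
#' @param samples `data.frame` with columns `depth_cm`, `age_ce`, `p_conc`,
#'   `mar`. Rows are sorted by depth on construction.
#' @return An object of class `core_profile`: a list with elements
#'   `core_id`, `collection_year` and `samples`.
#' @examples
#' core_profile("demo", 2018,
#'   data.frame(depth_cm = c(1, 2, 3), age_ce = c(2015, 2010, 2005),
#'              p_conc = c(2.1, 1.8, 1.5), mar = c(0.03, 0.03, 0.03)))
#' @export
core_profile <- function(core_id, collection_year, samples) {
  stopifnot(is.character(core_id), length(core_id) == 1L,
            is.numeric(collection_year), length(collection_year) == 1L)
  req <- c("depth_cm", "age_ce", "p_conc", "mar")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("core_profile: missing sample columns: ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[, req]
  if (anyNA(samples))
    stop("core_profile '", core_id, "': missing values are not permitted")
  samples <- samples[order(samples$depth_cm), , drop = FALSE]
  rownames(samples) <- NULL
  x <- structure(list(core_id = core_id,
                      collection_year = as.numeric(collection_year),
                      samples = samples),
                 class = "core_profile")
  validate_core_profile(x)
}

validate_core_profile <- function(x) {
  s <- x$samples
  bad_rows <- function(idx) paste(idx, collapse = ", ")
  if (nrow(s) == 0L) stop("core_profile '", x$core_id, "': no samples")
  if (!all(is.finite(as.matrix(s))))
    stop("core_profile '", x$core_id, "': non-finite values")
  dd <- diff(s$depth_cm)
  if (any(dd <= 0))
    stop("core_profile '", x$core_id, "': depth not strictly increasing at rows ",
         bad_rows(which(dd <= 0) + 1L))
  da <- diff(s$age_ce)
  if (any(da >= 0))
    stop("core_profile '", x$core_id,
         "': age must strictly decrease with depth; violated at rows ",
         bad_rows(which(da >= 0) + 1L))
  if (any(s$age_ce > x$collection_year))
    stop("core_profile '", x$core_id, "': ages exceed collection year at rows ",
         bad_rows(which(s$age_ce > x$collection_year)))
  if (any(s$p_conc < 0))
    stop("core_profile '", x$core_id, "': negative p_conc at rows ",
         bad_rows(which(s$p_conc < 0)))
  if (any(s$mar <= 0))
    stop("core_profile '", x$core_id, "': non-positive mar at rows ",
         bad_rows(which(s$mar <= 0)))
  x
}

#' @export
print.core_profile <- function(x, ...) {
  s <- x$samples
  cat(sprintf("core_profile '%s' (collected %s): %d samples, %.1f-%.1f cm, %s-%s CE\n",
              x$core_id, format(x$collection_year), nrow(s),
              min(s$depth_cm), max(s$depth_cm),
              format(round(min(s$age_ce), 1)), format(round(max(s$age_ce), 1))))
  invisible(x)
}

#' Lake and catchment constants
#'
#' @param lake_area_m2 Lake surface area, m^2.
#' @param mean_depth_m Mean depth, m.
#' @param max_depth_m Maximum depth, m.
#' @param catchment_area_m2 Catchment area, m^2.
#' @param q_s Areal water loading (annual outflow volume / lake area),
#'   m yr^-1. Optional; may be estimated later with [estimate_qs()].
#' @return Object of class `lake_catchment`.
#' @export
lake_catchment <- function(lake_area_m2, mean_depth_m, max_depth_m,
                           catchment_area_m2, q_s = NULL) {
  vals <- c(lake_area_m2, mean_depth_m, max_depth_m, catchment_area_m2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("lake_catchment: all geometry fields must be strictly positive")
  if (mean_depth_m > max_depth_m)
    stop("lake_catchment: mean_depth_m must not exceed max_depth_m")
  if (!is.null(q_s) && (!is.finite(q_s) || q_s <= 0))
    stop("lake_catchment: q_s must be strictly positive")
  structure(list(lake_area_m2 = lake_area_m2, mean_depth_m = mean_depth_m,
                 max_depth_m = max_depth_m,
                 catchment_area_m2 = catchment_area_m2, q_s = q_s),
            class = "lake_catchment")
}

#' @export
print.lake_catchment <- function(x, ...) {
  cat(sprintf("lake_catchment: area %.3g km2, mean depth %.2f m, max depth %.2f m, catchment %.3g km2%s\n",
              x$lake_area_m2 / 1e6, x$mean_depth_m, x$max_depth_m,
              x$catchment_area_m2 / 1e6,
              if (is.null(x$q_s)) "" else sprintf(", q_s %.3g m/yr", x$q_s)))
  invisible(x)
}

#' Dated time series
#'
#' A labelled, strictly time-ordered series of (calendar year CE, value)
#' points. TP values are in ug L^-1 (equivalently mg m^-3); discharge in
#' m^3 yr^-1; the label declares the units.
#'
#' @param when Numeric vector of calendar years CE, strictly increasing
#'   (fractional years allowed).
#' @param value Numeric vector of finite values.
#' @param label Character label declaring variable and units.
#' @return A `data.frame` of class `tp_ts` with columns `when`, `value` and
#'   a `label` attribute.
#' @export
tp_timeseries <- function(when, value, label = "TP_ugL") {
  if (length(when) != length(value))
    stop("tp_timeseries: when and value lengths differ")
  if (length(when) == 0L) stop("tp_timeseries: empty series")
  if (!all(is.finite(when)) || !all(is.finite(value)))
    stop("tp_timeseries: non-finite entries")
  if (any(diff(when) <= 0))
    stop("tp_timeseries: 'when' must be strictly increasing")
  structure(data.frame(when = as.numeric(when), value = as.numeric(value)),
            label = label, class = c("tp_ts", "data.frame"))
}

ts_label <- function(x) attr(x, "label", exact = TRUE)

#' @export
print.tp_ts <- function(x, ...) {
  cat(sprintf("tp_ts '%s': %d points, %s-%s\n", ts_label(x), nrow(x),
              format(round(min(x$when), 2)), format(round(max(x$when), 2))))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Methods recognised for a TP record
#' @keywords internal
TP_METHODS <- c("SI-TP-raw", "SI-TP-penn", "DI-TP", "monitored", "true")

#' Dated total-phosphorus record
#'
#' Carries a TP record produced by one inference method: the aggregate
#' series (ug L^-1) and, optionally, per-core series sharing the method.
#'
#' @param method One of `"SI-TP-raw"`, `"SI-TP-penn"`, `"DI-TP"`,
#'   `"monitored"`, `"true"`.
#' @param aggregate A [tp_timeseries()] in ug L^-1.
#' @param per_core Optional named list of `tp_ts`, one per core.
#' @return Object of class `tp_series`.
#' @export
tp_series <- function(method, aggregate, per_core = NULL) {
  method <- match.arg(method, TP_METHODS)
  if (!inherits(aggregate, "tp_ts")) stop("tp_series: aggregate must be a tp_ts")
  if (any(aggregate$value < 0)) stop("tp_series: negative TP values")
  if (!is.null(per_core)) {
    if (is.null(names(per_core)) || any(!nzchar(names(per_core))))
      stop("tp_series: per_core must be a named list")
    for (s in per_core) {
      if (!inherits(s, "tp_ts")) stop("tp_series: per_core entries must be tp_ts")
      if (any(s$value < 0)) stop("tp_series: negative TP values in per_core")
    }
  }
  structure(list(method = method, aggregate = aggregate, per_core = per_core),
            class = "tp_series")
}

#' @export
print.tp_series <- function(x, ...) {
  cat(sprintf("tp_series [%s]: %d aggregate points%s\n", x$method,
              nrow(x$aggregate),
              if (is.null(x$per_core)) ""
              else sprintf(", %d cores (%s)", length(x$per_core),
                           paste(names(x$per_core), collapse = ", "))))
  invisible(x)
}

#' Read a sediment-core CSV
#'
#' Expects a comma-delimited UTF-8 file with a header row and exact columns
#' `depth_cm`, `age_ce`, `p_conc_mg_g`, `mar_g_cm2_yr`. Rows may be in any
#' order; they are sorted by depth. Missing values are not permitted.
#'
#' @param path Path to the CSV file.
#' @param core_id Core identifier to attach.
#' @param collection_year Calendar year CE the core was collected.
#' @return A validated [core_profile()].
#' @export
read_core_csv <- function(path, core_id, collection_year) {
  if (!file.exists(path)) stop("read_core_csv: file not found: ", path)
  d <- utils::read.csv(path, check.names = TRUE)
  req <- c("depth_cm", "age_ce", "p_conc_mg_g", "mar_g_cm2_yr")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_core_csv: ", path, ": missing required columns: ",
         paste(miss, collapse = ", "))
  core_profile(core_id, collection_year,
               data.frame(depth_cm = d$depth_cm, age_ce = d$age_ce,
                          p_conc = d$p_conc_mg_g, mar = d$mar_g_cm2_yr))
}

#' Write a sediment-core CSV
#'
#' Inverse of [read_core_csv()]: writes the schema that reader expects.
#'
#' @param profile A [core_profile()].
#' @param path Output path.
#' @export
write_core_csv <- function(profile, path) {
  s <- profile$samples
  utils::write.csv(data.frame(depth_cm = s$depth_cm, age_ce = s$age_ce,
                              p_conc_mg_g = s$p_conc, mar_g_cm2_yr = s$mar),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-series CSV
#'
#' Expects columns `when` and `value`; extra columns are read back as
#' per-core series when `as_tp_series` is TRUE.
#'
#' @param path Path to CSV.
#' @param label Label for the series.
#' @param as_tp_series If TRUE return a [tp_series()] (method taken from
#'   `method`), else a bare [tp_timeseries()].
#' @param method Method tag used when `as_tp_series` is TRUE.
#' @return `tp_ts` or `tp_series`.
#' @export
read_series_csv <- function(path, label = "TP_ugL", as_tp_series = FALSE,
                            method = "SI-TP-raw") {
  if (!file.exists(path)) stop("read_series_csv: file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("when", "value") %in% names(d)))
    stop("read_series_csv: ", path, ": columns 'when' and 'value' required")
  agg <- tp_timeseries(d$when, d$value, label)
  if (!as_tp_series) return(agg)
  extra <- setdiff(names(d), c("when", "value"))
  per_core <- NULL
  if (length(extra)) {
    per_core <- lapply(extra, function(cn) {
      keep <- !is.na(d[[cn]])
      tp_timeseries(d$when[keep], d[[cn]][keep], label)
    })
    names(per_core) <- extra
  }
  tp_series(method, agg, per_core)
}

#' Write a TP record to CSV
#'
#' Writes columns `when`, `value` (the aggregate) and, when per-core series
#' are present, one additional column per core aligned on the aggregate time
#' grid (NA where a core does not cover a time step). Values round-trip
#' through [read_series_csv()] to within 1e-9.
#'
#' @param series A [tp_series()].
#' @param path Output path.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "tp_series"))
  agg <- series$aggregate
  out <- data.frame(when = agg$when, value = agg$value, check.names = FALSE)
  for (cn in names(series$per_core)) {
    s <- series$per_core[[cn]]
    out[[cn]] <- s$value[match(out$when, s$when)]
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_series_csv: cannot write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
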