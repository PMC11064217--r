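#' Two-fraction diagenesis parameters
#'
#' Parameters of the two-fraction sediment P model: a stable (permanently
#' buried) concentration, a labile concentration present at deposition, and
#' a first-order decay constant for the labile pool. The sum
#' `p_stable + p_unstable0 * exp(-k * burial_age)` is what a core records;
#' the decaying term is the "stationary peak" seen at the top of recent
#' profiles.
#'
#' @param p_stable Stable P concentration, mg g^-1, >= 0.
#' @param p_unstable0 Labile P concentration at deposition, mg g^-1, >= 0.
#' @param k First-order decay constant of the labile pool, yr^-1, > 0.
#' @return Object of class `penn_params`.
#' @export
penn_params <- function(p_stable, p_unstable0, k) {
  if (any(!is.finite(c(p_stable, p_unstable0, k))))
    stop("penn_params: non-finite parameter")
  if (any(p_stable < 0) || p_unstable0 < 0 || k <= 0)
    stop("penn_params: require p_stable >= 0, p_unstable0 >= 0, k > 0")
  structure(list(p_stable = p_stable, p_unstable0 = p_unstable0, k = k),
            class = "penn_params")
}

#' @export
print.penn_params <- function(x, ...) {
  cat(sprintf("penn_params: stable %s mg/g, labile at deposition %.4g mg/g, k %.4g /yr (half-life %.1f yr)\n",
              if (length(x$p_stable) == 1L) sprintf("%.4g", x$p_stable)
              else sprintf("[per-sample, mean %.4g]", mean(x$p_stable)),
              x$p_unstable0, x$k, log(2) / x$k))
  invisible(x)
}

#' Forward two-fraction diagenesis model
#'
#' The measured concentration a core records for a sample deposited at
#' `age_ce` and observed at `collection_year`:
#' `measured = p_stable + p_unstable0 * exp(-k * (collection_year - age_ce))`.
#' `p_stable` may be per-sample (a stable depositional trajectory) or
#' scalar.
#'
#' @param age_ce Deposition ages, calendar years CE, all <= collection_year.
#' @param p_stable Stable concentration(s), mg g^-1 (scalar or per-sample).
#' @param p_unstable0 Labile concentration at deposition, mg g^-1.
#' @param k Decay constant, yr^-1.
#' @param collection_year Observation year CE.
#' @return Numeric vector of measured concentrations, mg g^-1.
#' @export
penn_forward <- function(age_ce, p_stable, p_unstable0, k, collection_year) {
  if (k <= 0) stop("penn_forward: k must be > 0")
  tau <- collection_year - age_ce
  if (any(tau < 0)) stop("penn_forward: negative burial age (age after collection)")
  p_stable + p_unstable0 * exp(-k * tau)
}

#' Fit the two-fraction diagenesis model to a core profile
#'
#' Bounded nonlinear least squares of
#' `p_conc = a + b * exp(-k * burial_age)` with `a >= 0`, `b >= 0`,
#' `k > 0`, multi-started over `k` in {0.01, 0.03, 0.1, 0.3} yr^-1
#' (constant-plus-exponential fits are multi-modal). `a` estimates the
#' stable concentration, `b` the labile pool at deposition.
#'
#' The model assumes deposition is quasi-stationary over the fitted
#' samples; restrict the window to the recent, post-trend section of a core
#' when the depositional trajectory varies (see `fit_window_depth_cm` /
#' `fit_max_burial_age_yr`).
#'
#' @param profile A [core_profile()].
#' @param fit_window_depth_cm Optional `c(min, max)` depth window, cm.
#' @param fit_max_burial_age_yr Optional maximum burial age to include, yr.
#' @return Object of class `penn_fit`: `params` ([penn_params()] with
#'   scalar `p_stable = a`), `sse`, `n`, `identifiable` (FALSE when the
#'   fitted window spans < 3 fitted half-lives), `degenerate` (TRUE when
#'   `b` is numerically zero: no detectable labile pool; `a` then equals
#'   the window mean), and the fitted window.
#' @export
penn_fit <- function(profile, fit_window_depth_cm = NULL,
                     fit_max_burial_age_yr = NULL) {
  stopifnot(inherits(profile, "core_profile"))
  s <- profile$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(fit_window_depth_cm))
    keep <- keep & s$depth_cm >= fit_window_depth_cm[1] &
      s$depth_cm <= fit_window_depth_cm[2]
  tau <- profile$collection_year - s$age_ce
  if (!is.null(fit_max_burial_age_yr))
    keep <- keep & tau <= fit_max_burial_age_yr
  tau <- tau[keep]; y <- s$p_conc[keep]
  n <- length(y)
  if (n < 4L) stop("penn_fit: need >= 4 samples in the fit window, have ", n)

  # degenerate escape hatch: (numerically) constant profile
  if (stats::sd(y) < 1e-12 * max(mean(y), 1)) {
    warning("penn_fit '", profile$core_id,
            "': constant profile; no detectable labile pool (b = 0)")
    return(structure(list(params = penn_params(mean(y), 0, 0.1),
                          sse = sum((y - mean(y))^2), n = n,
                          identifiable = FALSE, degenerate = TRUE,
                          tau_range = range(tau)),
                     class = "penn_fit"))
  }

  dat <- data.frame(tau = tau, y = y)
  a0 <- max(min(y), 0); b0 <- max(max(y) - min(y), 1e-6)
  best <- NULL
  for (k0 in c(0.01, 0.03, 0.1, 0.3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * exp(-k * tau), data = dat,
                        start = list(a = a0, b = b0, k = k0),
                        lower = c(a = 0, b = 0, k = 1e-8),
                        upper = c(a = Inf, b = Inf, k = 10),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-10 * (1 + best$sse))
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("penn_fit: nonlinear least squares failed for every start")
  co <- stats::coef(best$fit)
  degenerate <- co[["b"]] < 1e-8 * max(mean(y), 1)
  params <- penn_params(co[["a"]], max(co[["b"]], 0), co[["k"]])
  span_hl <- diff(range(tau)) * params$k / log(2)
  identifiable <- span_hl >= 3 && !degenerate
  if (!identifiable)
    warning("penn_fit '", profile$core_id, "': ",
            if (degenerate) "no detectable labile pool (b ~ 0)"
            else sprintf("fit window spans only %.1f half-lives (<3); k weakly identified",
                         span_hl))
  structure(list(params = params, sse = best$sse, n = n,
                 identifiable = identifiable, degenerate = degenerate,
                 tau_range = range(tau)),
            class = "penn_fit")
}

#' @export
print.penn_fit <- function(x, ...) {
  cat(sprintf("penn_fit: a = %.4g, b = %.4g mg/g, k = %.4g /yr; SSE %.4g, n %d%s%s\n",
              x$params$p_stable, x$params$p_unstable0, x$params$k, x$sse, x$n,
              if (x$degenerate) " [degenerate: b ~ 0]" else "",
              if (!x$identifiable && !x$degenerate) " [weakly identified]" else ""))
  invisible(x)
}

#' Remove the transient labile component from a core profile
#'
#' Subtracts the fitted decaying labile component, leaving the
#' ultimately-retained (stable) concentration each sample will hold after
#' full labile decay:
#' `corrected = p_conc - b * exp(-k * burial_age)`.
#' Deep, old samples are essentially unchanged; surface samples lose the
#' full labile amount `b`. Negative results are floored at 0 with a
#' warning.
#'
#' @param profile A [core_profile()].
#' @param params A [penn_params()] (or the `params` of a [penn_fit()]);
#'   `p_unstable0` is the subtracted surface amount.
#' @return A corrected [core_profile()] (same ages, depths and MAR).
#' @export
penn_correct <- function(profile, params) {
  stopifnot(inherits(profile, "core_profile"))
  if (inherits(params, "penn_fit")) params <- params$params
  s <- profile$samples
  tau <- profile$collection_year - s$age_ce
  corr <- s$p_conc - params$p_unstable0 * exp(-params$k * tau)
  if (any(corr < 0)) {
    warning("penn_correct '", profile$core_id, "': ", sum(corr < 0),
            " corrected concentrations negative; floored at 0")
    corr <- pmax(corr, 0)
  }
  core_profile(profile$core_id, profile$collection_year,
               data.frame(depth_cm = s$depth_cm, age_ce = s$age_ce,
                          p_conc = corr, mar = s$mar))
}
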