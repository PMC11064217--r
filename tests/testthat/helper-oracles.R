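# Independent discrete-time lake P box model: dTP/dt = (L_in - L_sed - q_s TP)/z
# with L_in = l_sed / r_p, iterated to steady state. Used as the oracle for
# the closed-form mass-balance inversion; kept deliberately independent of
# infer_tp().
box_model_tp <- function(l_sed, r_p, q_s, z = 6.3, tol = 1e-12) {
  l_in <- l_sed / r_p
  tp <- 0
  dt <- 0.1 * z / q_s
  repeat {
    tp_new <- tp + dt * (l_in - l_sed - q_s * tp) / z
    if (abs(tp_new - tp) < tol * max(1, abs(tp_new))) break
    tp <- tp_new
  }
  tp_new
}

# mean-one multiplicative lognormal noise at a given CV
lnoise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# core whose measured concentrations follow the two-fraction model exactly
# (plus optional noise); stable component may be scalar or per-sample
penn_profile <- function(a, b, k, collection = 2018,
                         ages = seq(1700, 2017.5, by = 2.5),
                         mar = 0.03, noise_cv = 0, lsr = 0.5) {
  p <- penn_forward(ages, a, b, k, collection)
  if (noise_cv > 0) p <- p * lnoise(length(p), noise_cv)
  core_profile("helper", collection,
               data.frame(depth_cm = (collection - ages) * lsr,
                          age_ce = ages, p_conc = p, mar = mar))
}

# random valid core profile for round-trip property tests
random_profile <- function(n = 12) {
  depth <- sort(stats::runif(n, 0.5, 120))
  age <- 2018 - depth * stats::runif(1, 1.5, 3) -
    cumsum(stats::runif(n, 0, 0.2))
  core_profile(paste0("rnd", n), 2018,
               data.frame(depth_cm = depth, age_ce = age,
                          p_conc = stats::runif(n, 0.1, 5),
                          mar = stats::runif(n, 0.01, 0.08)))
}

# small fast scenario for pipeline-level tests
quick_scenario <- function(seed, ...) {
  lake_scenario(seed = seed, n_cores = 2, focusing = c(1, 1.5),
                slice_cm = c(2, 2), mar = c(0.047, 0.045),
                collection_years = c(2018, 2018), ...)
}

run_default_pipeline <- function(sim, diagenesis = list(enabled = TRUE,
                                                        fit_max_burial_age_yr = 50)) {
  sc <- sim$scenario
  cfg <- sitp_config(sc$monitoring_window[1], sc$monitoring_window[2],
                     q_s = sc$q_s, focusing = "fixed_factor",
                     focusing_factors = stats::setNames(sc$focusing,
                                                        names(sim$cores)))
  suppressWarnings(
    sitp_pipeline(sim$cores, sim$monitoring, cfg, diagenesis = diagenesis))
}

window_mean <- function(ts, w) mean(ts$value[ts$when >= w[1] & ts$when <= w[2]])
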