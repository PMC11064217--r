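test_that("burial flux is the dimensional product of concentration and MAR", {
  p <- core_profile("u", 2018,
    data.frame(depth_cm = 1:3, age_ce = c(2010, 2000, 1990),
               p_conc = c(1, 0, 2), mar = 0.01))
  fl <- compute_lsed(p)
  # 1 mg/g * 0.01 g/cm2/yr = 0.01 mg/cm2/yr = 100 mg/m2/yr
  expect_equal(fl$points$l_sed, c(200, 0, 100))  # ordered by increasing age
  p2 <- p; p2$samples$mar <- 0.02
  expect_equal(compute_lsed(p2)$points$l_sed, 2 * fl$points$l_sed)
})

test_that("focusing correction rescales fluxes and the heuristic factor is >= 1", {
  p <- random_profile(6)
  fl <- compute_lsed(p)
  expect_equal(focusing_correct(fl, strategy = "none")$points, fl$points)
  halved <- focusing_correct(fl, strategy = "fixed_factor", factor = 2)
  expect_equal(halved$points$l_sed, fl$points$l_sed / 2)
  expect_error(focusing_correct(fl, strategy = "fixed_factor", factor = 0),
               "positive")
  expect_error(focusing_correct(fl, strategy = "wibble"))
  # deep-coring geometry over-accumulates: F >= 1 always
  for (md in c(2, 6.3, 15, 40)) {
    lake <- lake_catchment(0.154e6, md, md * 1.5, 1.72e6)
    expect_gte(hakanson_focusing_factor(lake), 1)
  }
  lake <- lake_catchment(0.154e6, 6.3, 9.3, 1.72e6)
  corr <- focusing_correct(fl, lake, strategy = "hakanson")
  expect_equal(corr$points$l_sed,
               fl$points$l_sed / attr(corr, "focusing_factor"))
})

test_that("multi-core aggregation interpolates, averages and brackets", {
  set.seed(21)
  f1 <- paleotp:::new_flux_series("a", c(1900, 1910, 1920, 1930, 1940),
                                  c(100, 120, 140, 160, 180))
  # single core: aggregate equals its own interpolation
  agg1 <- aggregate_cores(list(f1))
  expect_equal(agg1$points$l_sed,
               approx(f1$points$age_ce, f1$points$l_sed,
                      xout = agg1$points$age_ce)$y)
  # two identical cores: same values, zero spread
  agg2 <- aggregate_cores(list(f1, f1))
  expect_equal(agg2$points$l_sed, agg1$points$l_sed)
  expect_equal(agg2$points$l_max - agg2$points$l_min,
               rep(0, nrow(agg2$points)))
  # constant offset c: mean offset by c/2 where both contribute
  f2 <- paleotp:::new_flux_series("b", f1$points$age_ce,
                                  f1$points$l_sed + 30)
  agg3 <- aggregate_cores(list(f1, f2))
  both <- agg3$points$n_cores == 2
  expect_equal(agg3$points$l_sed[both], agg1$points$l_sed[both] + 15)
  expect_error(aggregate_cores(list()), "empty")
})

test_that("aggregate flux lies within the contributing cores' envelope", {
  set.seed(22)
  for (rep in 1:5) {
    fluxes <- lapply(1:3, function(i) compute_lsed(random_profile(10)))
    agg <- aggregate_cores(fluxes)
    expect_true(all(agg$points$l_sed >= agg$points$l_min - 1e-12))
    expect_true(all(agg$points$l_sed <= agg$points$l_max + 1e-12))
  }
})

test_that("non-overlapping cores aggregate on the union grid with a flag", {
  f1 <- paleotp:::new_flux_series("a", c(1900, 1910), c(100, 100))
  f2 <- paleotp:::new_flux_series("b", c(1950, 1960), c(200, 200))
  agg <- aggregate_cores(list(f1, f2))
  expect_true(attr(agg, "no_overlap"))
  expect_true(all(agg$points$n_cores == 1))
})

test_that("areal water loading regression reproduces exact linear maps", {
  lake <- lake_catchment(0.154e6, 6.3, 9.3, 1.72e6)
  gauge <- tp_timeseries(2000:2018, seq(4e5, 5e5, length.out = 19),
                         "gauge_m3_yr")
  out_same <- tp_timeseries(2016:2018, gauge$value[17:19], "outflow_m3_yr")
  est <- estimate_qs(out_same, gauge, lake)
  expect_equal(est$slope, 1, tolerance = 1e-9)
  expect_equal(est$intercept, 0, tolerance = 1e-6)
  expect_equal(est$q_s, mean(gauge$value) / lake$lake_area_m2,
               tolerance = 1e-9)
  out_double <- tp_timeseries(2016:2018, 2 * gauge$value[17:19],
                              "outflow_m3_yr")
  est2 <- estimate_qs(out_double, gauge, lake)
  expect_equal(est2$predicted$value, 2 * gauge$value, tolerance = 1e-9)
  expect_error(estimate_qs(tp_timeseries(2017:2018, gauge$value[18:19]),
                           gauge, lake), ">= 3 overlapping")
})

test_that("recovered loading slope falls inside its own 95% CI at nominal rate", {
  lake <- lake_catchment(0.154e6, 6.3, 9.3, 1.72e6)
  gauge_vals <- seq(3e5, 6e5, length.out = 10)
  gauge <- tp_timeseries(2009:2018, gauge_vals, "gauge_m3_yr")
  true_slope <- 1.4; true_int <- 2e4; sigma <- 2e4
  set.seed(314)
  hits <- 0L; n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    out <- tp_timeseries(2009:2018,
                         true_int + true_slope * gauge_vals +
                           stats::rnorm(10, 0, sigma), "outflow_m3_yr")
    est <- estimate_qs(out, gauge, lake)
    ci <- stats::confint(est$fit)["gauge", ]
    if (ci[1] <= true_slope && true_slope <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("outflow P loading is q_s times the window-mean TP", {
  tp <- tp_timeseries(c(2005, 2010), c(80, 120))
  expect_equal(compute_lout(tp, 2.79, c(2003, 2018)), 279)
  expect_equal(compute_lout(tp_timeseries(2005, 0), 2.79, c(2003, 2018)), 0)
  expect_equal(compute_lout(tp_timeseries(2005, 100), 2.79, c(2003, 2018)),
               279)
  expect_error(compute_lout(tp, 2.79, c(1900, 1950)), "1900")
})

test_that("retention calibration follows the flux/outflow partition", {
  fl <- paleotp:::new_flux_series("a", c(2005, 2010, 2015), c(300, 300, 300))
  expect_equal(calibrate_rp(fl, 300, c(2003, 2018))$r_p, 0.5)
  expect_equal(calibrate_rp(fl, 0, c(2003, 2018))$r_p, 1)
  expect_equal(calibrate_rp(fl, 100, c(2003, 2018))$r_p, 0.75)
  ret <- calibrate_rp(fl, 100, c(2003, 2018))
  expect_equal(ret$r_p, ret$l_sed_cal / (ret$l_sed_cal + ret$l_out_cal),
               tolerance = 1e-12)
  expect_error(calibrate_rp(fl, 100, c(1900, 1950)), "window")
})

test_that("mass-balance inversion matches the converged box-model oracle", {
  for (l in c(10, 100, 1000)) for (r in c(0.1, 0.5, 0.9))
    for (q in c(0.5, 5, 20)) {
      fl <- paleotp:::new_flux_series("x", c(2000, 2001), c(l, l))
      tp <- infer_tp(fl, list(r_p = r), q)$aggregate$value[1]
      oracle <- box_model_tp(l, r, q)
      expect_lt(abs(tp - oracle) / oracle, 1e-3)
    }
  # example magnitude: 100 mg/m2/yr at r_p 0.5, q_s 2.79
  fl <- paleotp:::new_flux_series("x", c(2000, 2001), c(100, 100))
  expect_equal(infer_tp(fl, list(r_p = 0.5), 2.79)$aggregate$value[1],
               100 * 0.5 / (0.5 * 2.79), tolerance = 1e-12)
  # total retention: TP identically zero
  expect_equal(infer_tp(fl, list(r_p = 1), 2.79)$aggregate$value,
               c(0, 0))
  expect_error(infer_tp(fl, list(r_p = 0), 2.79), "r_p")
  # linearity in flux
  fl2 <- paleotp:::new_flux_series("x", c(2000, 2001), c(200, 200))
  expect_equal(infer_tp(fl2, list(r_p = 0.5), 2.79)$aggregate$value,
               2 * infer_tp(fl, list(r_p = 0.5), 2.79)$aggregate$value)
})

test_that("inferred TP decreases in both retention and water loading", {
  fl <- paleotp:::new_flux_series("x", c(2000, 2001), c(500, 500))
  tps_r <- vapply(seq(0.1, 0.9, by = 0.1), function(r)
    infer_tp(fl, list(r_p = r), 2.79)$aggregate$value[1], 0)
  expect_true(all(diff(tps_r) < 0))
  tps_q <- vapply(seq(0.5, 20, length.out = 9), function(q)
    infer_tp(fl, list(r_p = 0.5), q)$aggregate$value[1], 0)
  expect_true(all(diff(tps_q) < 0))
})

test_that("anchoring holds: calibration-window SI-TP mean equals monitored mean", {
  for (seed in c(5, 6)) {
    sim <- simulate_lake(quick_scenario(seed))
    res <- run_default_pipeline(sim)
    w <- sim$scenario$monitoring_window
    mon_mean <- window_mean(sim$monitoring, w)
    for (branch in list(res$raw, res$penn)) {
      got <- window_mean(branch$aggregate, w)
      expect_lt(abs(got - mon_mean) / mon_mean, 1e-9)
    }
  }
})
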