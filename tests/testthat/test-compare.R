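test_that("the smoother reproduces functions in and near its null space", {
  set.seed(41)
  w <- sort(stats::runif(40, 1900, 2000))
  lin <- suppressWarnings(fit_gam(tp_timeseries(w, 3 * w - 5000)))
  expect_lt(max(abs(lin$fitted$value - (3 * lin$fitted$when - 5000))), 1e-6)
  cst <- suppressWarnings(fit_gam(tp_timeseries(w, rep(50, 40))))
  expect_lt(max(abs(cst$fitted$value - 50)), 1e-6)
  # irregularly sampled noiseless sine recovered to < 1% of amplitude
  set.seed(42)
  w2 <- sort(stats::runif(80, 1900, 2000))
  y2 <- 100 + 40 * sin(2 * pi * (w2 - 1900) / 50)
  f2 <- fit_gam(tp_timeseries(w2, y2), basis_size = 30)
  truth <- 100 + 40 * sin(2 * pi * (f2$fitted$when - 1900) / 50)
  expect_lt(sqrt(mean((f2$fitted$value - truth)^2)) / 40, 0.01)
})

test_that("the smoother never extrapolates and warns on small samples", {
  set.seed(43)
  w <- sort(stats::runif(25, 1850.3, 1999.7))
  f <- fit_gam(tp_timeseries(w, stats::runif(25, 10, 20)))
  expect_equal(min(f$fitted$when), min(w))
  expect_equal(max(f$fitted$when), max(w))
  expect_warning(fit_gam(tp_timeseries(1:8 + 1900, stats::runif(8)), 12),
                 "reducing basis")
  expect_error(fit_gam(tp_timeseries(1:3 + 1900, 1:3)), ">= 4 points")
})

test_that("peak finding reports boundaries, ties and interior maxima", {
  set.seed(44)
  w <- seq(1900, 2000, by = 2)
  inc <- suppressWarnings(fit_gam(tp_timeseries(w, w - 1800)))
  pk <- find_peak(inc)
  expect_true(pk$boundary)
  expect_equal(pk$peak_year, max(inc$fitted$when))
  # symmetric parabola peaking at 1930
  w2 <- seq(1880, 1980, by = 1)
  par_fit <- suppressWarnings(
    fit_gam(tp_timeseries(w2, 100 - (w2 - 1930)^2 / 50), basis_size = 20))
  expect_equal(find_peak(par_fit)$peak_year, 1930)
  # ties break to the earliest year
  flat <- par_fit; flat$fitted$value <- rep(1, nrow(flat$fitted))
  pk3 <- find_peak(flat)
  expect_true(pk3$tie)
  expect_equal(pk3$peak_year, 1880)
})

test_that("centered means pool cores within the window and drop orphans", {
  agg <- tp_timeseries(c(1900, 1950), c(50, 50))
  per_core <- list(
    A = tp_timeseries(c(1899, 1902, 1948), c(40, 44, 60)),
    B = tp_timeseries(c(1901, 1953), c(48, 70)))
  sitp <- tp_series("SI-TP-raw", agg, per_core)
  ditp <- tp_timeseries(c(1900, 1950, 1990), c(90, 120, 100), "DI-TP")
  pairs <- centered_means(sitp, ditp, half_window_yr = 5)
  # hand arithmetic: 1900 pairs {40,44,48} -> 44; 1950 pairs {60,70} -> 65
  expect_equal(pairs$sitp_mean, c(44, 65))
  expect_equal(pairs$n_points, c(3, 2))
  expect_equal(attr(pairs, "n_dropped"), 1)
  # constant record: every mean is that constant
  cst <- tp_series("SI-TP-raw", tp_timeseries(1895:1955, rep(50, 61)))
  expect_true(all(centered_means(cst, ditp, 5)$sitp_mean == 50))
  # single point inside the window is the degenerate mean
  one <- tp_series("SI-TP-raw", tp_timeseries(c(1899, 1990), c(7, 7)))
  expect_equal(centered_means(one, tp_timeseries(1900, 1), 5)$sitp_mean, 7)
  expect_error(centered_means(one, tp_timeseries(1700, 1), 5), "neighbours")
})

test_that("proxy regression is exact on affine data and r2 is squared Pearson", {
  x <- c(20, 35, 50, 80, 120, 150)
  idem <- regress_proxies(data.frame(sitp_mean = x, ditp_value = x))
  expect_equal(idem$slope, 1, tolerance = 1e-9)
  expect_equal(idem$intercept, 0, tolerance = 1e-9)
  expect_equal(idem$r2, 1, tolerance = 1e-9)
  set.seed(46)
  for (rep in 1:5) {
    a <- stats::runif(1, -3, 3); if (abs(a) < 0.1) a <- 0.5
    b <- stats::runif(1, -50, 50)
    r <- regress_proxies(data.frame(sitp_mean = x, ditp_value = a * x + b))
    expect_equal(r$slope, a, tolerance = 1e-9)
    expect_equal(r$intercept, b, tolerance = 1e-9)
    expect_equal(r$r2, 1, tolerance = 1e-9)
  }
  # shared variance: r2 equals the squared Pearson correlation
  set.seed(47)
  y <- 0.6 * x + 20 + stats::rnorm(6, 0, 5)
  r2 <- regress_proxies(data.frame(sitp_mean = x, ditp_value = y))
  expect_equal(r2$r2, stats::cor(x, y)^2, tolerance = 1e-12)
  expect_lte(r2$ci95_slope[1], r2$slope)
  expect_gte(r2$ci95_slope[2], r2$slope)
  expect_equal(mean(r2$residuals), 0, tolerance = 1e-10)
  expect_error(regress_proxies(data.frame(sitp_mean = rep(1, 5),
                                          ditp_value = 1:5)), "zero variance")
  expect_error(regress_proxies(data.frame(sitp_mean = 1:2,
                                          ditp_value = 1:2)), ">= 3 pairs")
})

test_that("a known noisy slope is recovered within its own interval", {
  set.seed(48)
  x <- stats::runif(40, 20, 200)
  y <- 0.6 * x + 20 + stats::rnorm(40, 0, 10)
  r <- regress_proxies(data.frame(sitp_mean = x, ditp_value = y))
  expect_gte(0.6, r$ci95_slope[1])
  expect_lte(0.6, r$ci95_slope[2])
  expect_lt(r$p_value, 1e-6)
  # prediction band brackets the fit
  expect_true(all(r$prediction_band$lwr < r$prediction_band$fit))
  expect_true(all(r$prediction_band$upr > r$prediction_band$fit))
  expect_gt(r$qq_stats$qq_cor, 0.95)
})

test_that("interval-weighted mean corrects for variable sampling density", {
  toy <- tp_timeseries(c(1901, 1905, 1915), c(10, 20, 30))
  expect_equal(interval_weighted_mean(toy), 22.5)
  cst <- tp_timeseries(seq(1900, 1999, by = 3), rep(7, 34))
  expect_equal(interval_weighted_mean(cst), 7)
  # oversampling a bin whose signal is constant changes nothing...
  base <- tp_timeseries(c(1901, 1905, 1915), c(10, 10, 30))
  dup <- tp_timeseries(c(1901, 1903, 1905, 1915), c(10, 10, 10, 30))
  expect_equal(interval_weighted_mean(dup), interval_weighted_mean(base))
  # ...but an unequal duplicate does
  wrong_dup <- tp_timeseries(c(1901, 1903, 1905, 1915), c(10, 11, 10, 30))
  expect_false(isTRUE(all.equal(interval_weighted_mean(wrong_dup),
                                interval_weighted_mean(base))))
  # the plain mean is not invariant under oversampling: that is the point
  expect_false(isTRUE(all.equal(mean(dup$value), mean(base$value))))
})

test_that("five-year means bin on calendar boundaries at bin centers", {
  cst <- tp_timeseries(2000:2009, rep(12, 10))
  fm <- five_year_means(cst)
  expect_equal(fm$value, c(12, 12))
  expect_equal(fm$when, c(2002.5, 2007.5))
  # hand-built: 2000-2004 -> mean 3, 2005-2009 -> mean 8
  s <- tp_timeseries(2000:2009, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  expect_equal(five_year_means(s)$value, c(3, 8))
  one <- tp_timeseries(c(2001, 2008), c(4, 9))
  expect_equal(five_year_means(one)$value, c(4, 9))
})
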