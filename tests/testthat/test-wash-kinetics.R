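test_that("probe decay estimators use the t = 17 and t = 2 ratios", {
  tp <- c(0, 2, 3, 7, 17)
  flat <- probe_decay_fit(rep(500, 5), timepoints = tp)
  expect_equal(flat$w_inf, 1)
  expect_identical(flat$tau, Inf)
  f <- probe_decay_fit(c(1000, 368, 350, 200, 100), timepoints = tp)
  expect_equal(f$w_inf, 0.1)
  expect_equal(f$tau, -2 / log(0.368))
  expect_equal(f$logI0, 3)
  expect_error(probe_decay_fit(c(10, 5), timepoints = c(0, 3)),
               "missing timepoint")
  # ratios above 1 are clipped and counted
  up <- probe_decay_fit(c(100, 120, 90, 80, 110), timepoints = tp)
  expect_equal(up$w_inf, 1)
  expect_equal(attr(up, "n_clipped"), 2L)
})

test_that("decay fits on a clean sigmoid chip reproduce the planted survival", {
  ser <- chip_sigmoid_clean()
  fits <- probe_decay_fit(ser)
  expect_equal(fits$w_inf, unname(ser$truth$w_S[, "I_t17"]),
               tolerance = 1e-12)
  # two-component least-squares route agrees with the ratio route at the ends
  one <- probe_decay_fit(ser$intensities[17, ], timepoints = ser$timepoints,
                         method = "fit")
  expect_equal(one$w_inf, fits$w_inf[17], tolerance = 0.1)
})

test_that("moving averages extract the mean intensity dependence", {
  f <- data.frame(w_inf = rep(0.5, 30), tau = rep(2, 30), logI0 = rnorm(30))
  ma <- moving_average_vs_logI0(f, window = 10)
  expect_true(all(ma$w_inf == 0.5))
  expect_true(all(ma$tau == 2))
  expect_warning(moving_average_vs_logI0(f, window = 100), "shrinking")
  # PM-only and MM-only trends are indistinguishable by construction
  ser <- chip_sigmoid_clean()
  fits <- probe_decay_fit(ser)
  ma_pm <- moving_average_vs_logI0(fits[fits$probe_type == "PM", ], 1000)
  ma_mm <- moving_average_vs_logI0(fits[fits$probe_type == "MM", ], 1000)
  mid <- approx(ma_mm$logI0, ma_mm$w_inf, xout = ma_pm$logI0, rule = 2)$y
  expect_lt(stats::median(abs(ma_pm$w_inf - mid)), 0.02)
})

test_that("the low-intensity plateau reflects the planted floor", {
  ser <- generate_chip_series(chip_config(
    n_sets = 800, noise_cv = 0, seed = 14,
    washing = list(driver = "sigmoid",
                   params = washing_params(w_min = 0.1, w_max = 0.9))))
  ma <- moving_average_vs_logI0(probe_decay_fit(ser))
  expect_equal(-log10(ma$w_inf[1]), 1, tolerance = 0.05)
})

test_that("sigmoid fits recover planted washing parameters", {
  # direct unit check on synthetic curves, no chip in between
  M <- 10^4.5
  wp <- washing_params(w_min = 0.06, w_max = 0.9, gamma = 1.6,
                       a_prime = 0.1)
  logI0 <- seq(1, log10(M) - 0.01, length.out = 300)
  curve <- data.frame(logI0 = logI0,
                      w_inf = survival_vs_intensity(10^logI0, M, wp))
  sf <- fit_sigmoid(curve, M)
  expect_equal(sf$w_min, 0.06, tolerance = 0.05 * 0.06)
  expect_equal(sf$w_max, 0.9, tolerance = 0.05 * 0.9)
  expect_equal(sf$gamma, 1.6, tolerance = 0.05 * 1.6)
  expect_equal(sf$a_prime, 0.1, tolerance = 0.05 * 0.1)
  expect_equal(sf$I_crit, critical_intensity(M, wp), tolerance = 1)
  # a sharper exponent does not move the critical intensity
  wp4 <- washing_params(w_min = 0.06, w_max = 0.9, gamma = 4, a_prime = 0.1)
  curve4 <- data.frame(logI0 = logI0,
                       w_inf = survival_vs_intensity(10^logI0, M, wp4))
  sf4 <- fit_sigmoid(curve4, M)
  expect_gt(sf4$gamma, sf$gamma)
  expect_equal(sf4$I_crit, sf$I_crit, tolerance = 0.02 * sf$I_crit)
})

test_that("hook-parameter slopes vanish without washing", {
  ser <- generate_chip_series(chip_config(
    n_sets = 800, noise_cv = 0, seed = 15,
    washing = list(driver = "powerlaw", eta = c(N = 0, PM_S = 0, MM_S = 0))))
  hs <- hook_at_timepoints(ser)
  ks <- hook_param_kinetics(hs)
  expect_true(all(abs(ks$slopes[c("sigma_start", "sigma_end", "alpha",
                                  "beta", "R"), "eta"]) < 1e-6))
  we <- invert_washing_exponents(ks)
  expect_equal(c(we$eta_N, we$eta_PM_S, we$eta_MM_S), c(0, 0, 0),
               tolerance = 1e-6)
})

test_that("slope signs on a washed chip match the physical expectation", {
  ser <- chip_powerlaw_clean()
  hs <- hook_series_of(ser, "hs_pl_clean")
  ks <- hook_param_kinetics(hs, O = ser$O)
  eta <- setNames(ks$slopes$eta, rownames(ks$slopes))
  expect_lt(eta[["sigma_start"]], 0)
  expect_lt(eta[["sigma_end"]], 0)
  expect_lt(eta[["O"]], 0)
  expect_gt(eta[["alpha"]], 0)
  expect_gt(eta[["beta"]], 0)
  expect_gt(eta[["R"]], 0)
  expect_error(hook_param_kinetics(structure(
    list(timepoints = c(0, 2), points = list(), fits = list(), snr = list()),
    class = "hook_series")), ">= 3 timepoints")
})

test_that("exponent inversion solves the slope relations", {
  we <- invert_washing_exponents(c(sigma_start = -0.5, sigma_end = -0.125,
                                   alpha = 0.15, R = 0.45))
  expect_equal(we$eta_N, 0.5, tolerance = 1e-12)
  expect_equal(we$eta_PM_S, 0.05, tolerance = 1e-12)
  expect_equal(we$eta_MM_S, 0.2, tolerance = 1e-12)
  expect_lt(we$residual, 1e-12)
  expect_error(invert_washing_exponents(c(sigma_start = -0.5)), "missing")
  # algebraic roundtrip: exponents -> slopes -> exponents
  set.seed(3)
  for (i in 1:20) {
    p <- sort(runif(3, 0, 0.6))           # eta_PM_S <= eta_MM_S <= eta_N
    slopes <- c(sigma_start = -p[3], sigma_end = -(p[1] + p[2]) / 2,
                alpha = p[2] - p[1], delta_end = p[2] - p[1],
                R = p[3] - p[1])
    we <- invert_washing_exponents(slopes)
    expect_equal(c(we$eta_N, we$eta_MM_S, we$eta_PM_S),
                 c(p[3], p[2], p[1]), tolerance = 1e-12)
  }
  # inconsistent slopes: warning, both substitution solutions reported
  expect_warning(
    wi <- invert_washing_exponents(c(sigma_start = -0.5, sigma_end = -0.3,
                                     alpha = 0.15, R = 0.45)),
    "residual")
  expect_equal(wi$via_R[["eta_PM_S"]], 0.05)
  expect_equal(wi$via_endpoint[["eta_PM_S"]], (0.6 - 0.15) / 2)
})
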