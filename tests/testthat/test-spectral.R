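test_that("amplitude spectrum recovers pure tones and zeros constants", {
  n <- 100
  t <- 0:(n - 1)
  s <- make_series(3 * sin(2 * pi * 5 * t / n + 0.7))
  sp <- amplitude_spectrum(s)
  expect_equal(sp$amplitude[sp$k == 5], 3, tolerance = 1e-10)
  expect_lt(max(sp$amplitude[sp$k != 5]), 1e-10)
  expect_equal(sp$phase[sp$k == 5], 0.7, tolerance = 1e-10)
  # constant series: all amplitudes zero
  expect_lt(max(amplitude_spectrum(make_series(rep(4, 50)))$amplitude),
            1e-12)
  # timescales strictly decreasing in k
  expect_true(all(diff(sp$timescale_yr) < 0))
})

test_that("amplitude spectrum equals the direct DFT oracle for all N <= 64", {
  withr::with_seed(11, {
    for (n in 4:64) {
      x <- rnorm(n)
      sp <- amplitude_spectrum(make_series(x))
      expect_equal(sp$amplitude, dft_amplitudes(x), tolerance = 1e-10)
    }
  })
})

test_that("two superposed tones are both recovered exactly", {
  n <- 60
  t <- 0:(n - 1)
  x <- 1 * sin(2 * pi * 3 * t / n + 0.2) + 2 * sin(2 * pi * 10 * t / n - 1)
  sp <- amplitude_spectrum(make_series(x))
  expect_equal(sp$amplitude[sp$k == 3], 1, tolerance = 1e-10)
  expect_equal(sp$amplitude[sp$k == 10], 2, tolerance = 1e-10)
  expect_equal(sp$amplitude, dft_amplitudes(x), tolerance = 1e-10)
})

test_that("zeta and eta are the per-harmonic amplitude ratios", {
  # phase-locked single strong harmonic: eta = 100 GtC/K gives
  # zeta = 2.52 * 100 - 10.9 = 241.1 GtC/K
  n <- 100
  h <- data.frame(k = 4, amp_ca = 10 / 2.12, amp_ta = 0.1, phase = 0.4)
  sys <- gen_harmonic_system(harmonic_spec(n, h, 1.52, -10.9))
  est <- estimates_of(sys)
  row <- est[est$k == 4, ]
  expect_equal(row$eta, 100, tolerance = 1e-8)
  expect_equal(row$zeta, 241.1, tolerance = 1e-8)
  # proportional series: eta = c at every retained harmonic
  ta <- make_series(rnorm(80))
  ca_gtc <- annual_series(series_years(ta), 3 * series_values(ta), "GtC",
                          "co2_concentration")
  est2 <- zeta_eta(NULL, amplitude_spectrum(ca_gtc), amplitude_spectrum(ta))
  expect_equal(est2$eta, rep(3, nrow(est2)), tolerance = 1e-10)
  # mismatched record lengths are rejected
  expect_error(zeta_eta(NULL, amplitude_spectrum(ca_gtc),
                        amplitude_spectrum(make_series(rnorm(50)))),
               class = "ccf_shape_error")
})

test_that("the cross-timescale regression recovers beta and gamma* exactly", {
  sys <- make_locked_system(beta = 1.52, gamma_star = -10.9)
  fit <- fit_beta_gamma_star(estimates_of(sys), band = c(2, 90))
  expect_equal(fit$slope, 2.52, tolerance = 1e-8)
  expect_equal(fit$beta, 1.52, tolerance = 1e-8)
  expect_equal(fit$beta_gtc_per_ppm, 3.2224, tolerance = 1e-8)
  expect_equal(fit$gamma_star, -10.9, tolerance = 1e-8)
  # gamma* = 0 system: intercept ~ 0
  fit0 <- fit_beta_gamma_star(estimates_of(make_locked_system(
    beta = 2, gamma_star = 0)), band = c(2, 90))
  expect_equal(fit0$gamma_star, 0, tolerance = 1e-8)
  expect_error(fit_beta_gamma_star(estimates_of(sys), band = c(2, 2.1)),
               class = "ccf_fit_error")
})

test_that("noisy fits match the closed-form normal equations", {
  withr::with_seed(99, {
    sys <- make_locked_system()
    est <- estimates_of(sys)
    est$zeta <- est$zeta + rnorm(nrow(est), sd = 5)
  })
  d <- est[est$timescale_yr >= 2 & est$timescale_yr <= 90 &
             is.finite(est$zeta) & is.finite(est$eta), ]
  p_hat <- cov(d$zeta, d$eta) / var(d$eta)
  int_hat <- mean(d$zeta) - p_hat * mean(d$eta)
  fit <- fit_beta_gamma_star(est, band = c(2, 90))
  expect_equal(fit$slope, p_hat, tolerance = 1e-10)
  expect_equal(fit$gamma_star, int_hat, tolerance = 1e-10)
})

test_that("per-timescale gamma* inverts the identity and matches the intercept", {
  # arithmetic inverse of the zeta_eta example
  est <- structure(data.frame(k = 1, timescale_yr = 100, zeta = 241.1,
                              eta = 100, af = NA),
                   class = c("timescale_estimates", "data.frame"),
                   n_years = 100, carbon_units = "GtC", n_excluded = 0L)
  expect_equal(gamma_star_by_timescale(est, 1.52)$gamma_star, -10.9,
               tolerance = 1e-10)
  est$zeta <- 2.52 * est$eta
  expect_equal(gamma_star_by_timescale(est, 1.52)$gamma_star, 0,
               tolerance = 1e-12)
  # consistency on a phase-locked system: gamma*_k constant = intercept
  sys <- make_locked_system()
  full <- estimates_of(sys)
  fit <- fit_beta_gamma_star(full, band = c(2, 90))
  gk <- gamma_star_by_timescale(full, fit$beta)$gamma_star
  expect_equal(mean(gk[is.finite(gk)]), fit$gamma_star, tolerance = 1e-8)
})

test_that("preindustrial gamma follows -m (1+beta) eta", {
  expect_equal(preindustrial_gamma(0, 1.52), 0)
  expect_equal(preindustrial_gamma(9, 1.52), -48.0816, tolerance = 1e-10)
  # upper end of the observation-ensemble eta range
  expect_equal(preindustrial_gamma(23, 1.52), -122.8752, tolerance = 1e-10)
})

test_that("band statistics aggregate over the requested timescales", {
  d <- data.frame(timescale_yr = c(100, 95, 50, 20), gamma = c(-50, -50,
                                                               -40, -30))
  bs <- band_statistics(d, c(90, 110))
  expect_equal(bs$mean[bs$quantity == "gamma"], -50)
  expect_equal(bs$sd[bs$quantity == "gamma"], 0)
  expect_equal(bs$n[bs$quantity == "gamma"], 2)
  one <- band_statistics(d, c(45, 55))
  expect_equal(one$n, 1)
  expect_equal(one$sd, 0)
  # monotone input gives band means ordered by band midpoint
  dm <- data.frame(timescale_yr = seq(10, 800, by = 10))
  dm$gamma <- -0.2 * dm$timescale_yr
  m1 <- band_statistics(dm, c(10, 70))$mean
  m2 <- band_statistics(dm, c(200, 800))$mean
  expect_gt(m1, m2)
  expect_error(band_statistics(dm, c(900, 1000)), class = "ccf_band_error")
})

test_that("estimates scale correctly when temperature is rescaled", {
  sys <- make_locked_system()
  c_fac <- 4
  ta2 <- annual_series(series_years(sys$t_a),
                       c_fac * series_values(sys$t_a), "K",
                       "temperature_anomaly")
  # rebuild emissions for the rescaled system so the identity still holds
  ce2 <- annual_series(series_years(sys$c_e),
                       (1 + 1.52) * 2.12 * series_values(sys$c_a) +
                         (-10.9 / c_fac) * series_values(ta2),
                       "GtC", "cumulative_emission")
  est1 <- estimates_of(sys)
  est2 <- zeta_eta(amplitude_spectrum(ce2),
                   amplitude_spectrum(convert_carbon_units(sys$c_a, "GtC")),
                   amplitude_spectrum(ta2))
  expect_equal(est2$eta, est1$eta / c_fac, tolerance = 1e-10)
  fit2 <- fit_beta_gamma_star(est2, band = c(2, 90))
  expect_equal(fit2$beta, 1.52, tolerance = 1e-8)      # beta invariant
  expect_equal(fit2$gamma_star, -10.9 / c_fac, tolerance = 1e-8)
})

test_that("working in ppm then converting beta equals converting series first", {
  sys <- make_locked_system()
  # route 1: all carbon in GtC (the standard pipeline)
  fit_gtc <- fit_beta_gamma_star(estimates_of(sys), band = c(2, 90))
  # route 2: spectra in ppm, slope converted afterwards
  ce_ppm <- convert_carbon_units(sys$c_e, "ppm")
  est_ppm <- zeta_eta(amplitude_spectrum(ce_ppm),
                      amplitude_spectrum(sys$c_a),
                      amplitude_spectrum(sys$t_a))
  d <- est_ppm[est_ppm$timescale_yr >= 2 & est_ppm$timescale_yr <= 90, ]
  slope_ppm <- cov(d$zeta, d$eta) / var(d$eta)
  expect_equal(slope_ppm - 1, fit_gtc$beta, tolerance = 1e-12)
})
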