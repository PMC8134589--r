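test_that("annual_series enforces shape, contiguity and unit/kind legality", {
  expect_s3_class(annual_series(2000:2004, 1:5, "ppm", "co2_concentration"),
                  "annual_series")
  expect_error(annual_series(2000:2004, 1:4, "ppm", "co2_concentration"),
               class = "ccf_shape_error")
  expect_error(annual_series(c(2000, 2002, 2003), 1:3, "ppm",
                             "co2_concentration"),
               class = "ccf_shape_error")
  expect_error(annual_series(2000:2004, 1:5, "ppm", "temperature_anomaly"),
               class = "ccf_unit_error")
})

test_that("carbon unit conversion uses m = 2.12 and round-trips exactly", {
  s <- make_series(c(1, 0, 630, 10), units = "ppm",
                   kind = "co2_concentration")
  g <- convert_carbon_units(s, "GtC")
  expect_equal(series_values(g)[1], 2.12)
  expect_equal(series_values(g)[2], 0)
  back <- convert_carbon_units(make_series(c(630, 1), units = "GtC",
                                           kind = "co2_concentration"), "ppm")
  expect_equal(series_values(back)[1], 297.1698, tolerance = 1e-6)
  # roundtrip identity
  x <- make_series(runif(50, 200, 400), units = "ppm",
                   kind = "co2_concentration")
  rt <- convert_carbon_units(convert_carbon_units(x, "GtC"), "ppm")
  expect_lt(max(abs(series_values(rt) - series_values(x))), 1e-12)
  expect_error(convert_carbon_units(make_series(1:5), "GtC"),
               class = "ccf_unit_error")
})

test_that("cumulative emissions are a running sum, linear, and match a brute-force oracle", {
  mk_flux <- function(v) make_series(v, units = "GtC_per_yr",
                                     kind = "emission_flux")
  zeros <- mk_flux(rep(0, 10))
  expect_equal(series_values(cumulative_emissions(
    emission_record(zeros, zeros))), rep(0, 10))
  ones <- mk_flux(rep(1, 10))
  cum <- cumulative_emissions(emission_record(ones, zeros))
  expect_equal(series_values(cum)[10], 10)
  expect_equal(series_values(cum)[1], 1)
  # exponential flux against a term-by-term summation oracle
  expflux <- 0.27 * exp(0.018 * (0:99)) * 2.12
  got <- series_values(cumulative_emissions(
    emission_record(mk_flux(expflux), mk_flux(rep(0, 100)))))
  oracle <- vapply(1:100, function(i) sum(expflux[1:i]), 1)
  expect_equal(got, oracle, tolerance = 1e-12)
  # linearity: cum(a+b) = cum(a) + cum(b)
  a <- runif(30); b <- runif(30)
  cab <- series_values(cumulative_emissions(
    emission_record(mk_flux(a + b), mk_flux(rep(0, 30)))))
  ca <- series_values(cumulative_emissions(
    emission_record(mk_flux(a), mk_flux(rep(0, 30)))))
  cb <- series_values(cumulative_emissions(
    emission_record(mk_flux(b), mk_flux(rep(0, 30)))))
  expect_equal(cab, ca + cb, tolerance = 1e-12)
  # year mismatch
  expect_error(emission_record(mk_flux(a),
                               make_series(b, units = "GtC_per_yr",
                                           kind = "emission_flux",
                                           start_year = 1900)),
               class = "ccf_alignment_error")
})

test_that("anomaly baselining centres the base period and is idempotent", {
  s <- make_series(rep(3.5, 40))
  expect_equal(series_values(anomaly_relative_to(s, 1860, 1880)),
               rep(0, 40))
  noisy <- make_series(rnorm(100, mean = 7))
  a1 <- anomaly_relative_to(noisy, 1880, 1910)
  base <- series_years(a1) >= 1880 & series_years(a1) <= 1910
  expect_lt(abs(mean(series_values(a1)[base])), 1e-12)
  a2 <- anomaly_relative_to(a1, 1880, 1910)
  expect_equal(series_values(a2), series_values(a1))
  expect_error(anomaly_relative_to(noisy, 1700, 1710),
               class = "ccf_range_error")
})

test_that("nearest-year resampling interpolates to a contiguous grid", {
  out <- resample_to_years(c(1000.2, 1002.9), c(1, 4), "ppm",
                           "co2_concentration")
  expect_equal(series_years(out), 1000:1003)
  expect_equal(series_values(out), c(1, 2, 3, 4))
  # already-annual input is the identity
  ann <- resample_to_years(2000:2010, 11:21, "ppm", "co2_concentration")
  expect_equal(series_values(ann), as.numeric(11:21))
  # irregular samples of a line reproduce the line exactly
  yrs <- c(1000.1, 1003.8, 1006.2, 1009.9, 1015.4, 1020.1, 1024.6, 1030.2,
           1033.9, 1040.3)
  out2 <- resample_to_years(yrs, 2 * round(yrs), "ppm", "co2_concentration")
  expect_equal(series_values(out2), 2 * series_years(out2))
  expect_warning(resample_to_years(c(1000.1, 1000.4, 1005), c(1, 3, 5),
                                   "ppm", "co2_concentration"),
                 "averaged")
})

test_that("N-year spline has the 50% cutoff response and preserves structure", {
  n <- 300
  t <- 1:n
  tone <- function(period) make_series(sin(2 * pi * t / period))
  amp <- function(s, period) {
    mid <- t > n / 4 & t <= 3 * n / 4
    co <- coef(lm(series_values(s)[mid] ~ sin(2 * pi * t[mid] / period) +
                    cos(2 * pi * t[mid] / period)))
    unname(sqrt(co[2]^2 + co[3]^2))
  }
  # constant unchanged
  expect_equal(series_values(spline_smooth(make_series(rep(2, 60)), 10)),
               rep(2, 60), tolerance = 1e-9)
  # response 0.5 at the cutoff period
  expect_equal(amp(spline_smooth(tone(30), 30), 30), 0.5, tolerance = 0.1)
  # response >= 0.95 at 10x the cutoff period
  expect_gte(amp(spline_smooth(tone(300), 30), 300), 0.95)
  # mean preserved
  x <- make_series(rnorm(200, mean = 5))
  expect_equal(mean(series_values(spline_smooth(x, 30))),
               mean(series_values(x)), tolerance = 1e-8)
  # commutes with adding a constant
  s1 <- series_values(spline_smooth(make_series(series_values(x) + 11), 30))
  s2 <- series_values(spline_smooth(x, 30)) + 11
  expect_equal(s1, s2, tolerance = 1e-8)
  expect_error(spline_smooth(x, 1), class = "ccf_param_error")
  expect_error(spline_smooth(make_series(rep(1, 10)), 50),
               class = "ccf_param_error")
})

test_that("alignment restricts all series to the common years", {
  a <- make_series(rnorm(168), start_year = 1850)
  b <- make_series(rnorm(138), start_year = 1880)
  al <- align_series(list(a, b))
  expect_equal(series_years(al[[1]]), 1880:2017)
  expect_equal(series_years(al[[2]]), 1880:2017)
  # identical ranges are the identity
  al2 <- align_series(list(a, a))
  expect_equal(series_values(al2[[1]]), series_values(a))
  # nested ranges give the inner range
  c1 <- make_series(rnorm(851), start_year = 1000)
  c2 <- make_series(rnorm(301), start_year = 1400)
  al3 <- align_series(list(c1, c2))
  expect_equal(range(series_years(al3[[1]])), c(1400, 1700))
  expect_error(align_series(list(make_series(1:5, start_year = 1000),
                                 make_series(1:5, start_year = 2000))),
               class = "ccf_alignment_error")
})

test_that("series round-trip through delimited tables", {
  s <- make_series(rnorm(20), units = "ppm", kind = "co2_concentration")
  f <- withr::local_tempfile(fileext = ".csv")
  write_annual_series(s, f)
  r <- read_annual_series(f, "ppm", "co2_concentration")
  expect_equal(series_values(r), series_values(s), tolerance = 1e-12)
  expect_equal(series_years(r), series_years(s))
})
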