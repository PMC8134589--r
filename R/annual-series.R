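# Canonical annual-series data model: contiguous annual records of carbon and
# temperature quantities, with unit/kind tags enforced at construction.

.ccf_units <- c("ppm", "GtC", "GtC_per_yr", "ppm_per_yr", "K")
.ccf_kinds <- c("co2_concentration", "cumulative_emission", "emission_flux",
                "temperature_anomaly", "carbon_storage", "residual")

# legal units per kind
.ccf_unit_table <- list(
  co2_concentration   = c("ppm", "GtC"),
  cumulative_emission = c("GtC", "ppm"),
  emission_flux       = c("GtC_per_yr", "ppm_per_yr"),
  temperature_anomaly = "K",
  carbon_storage      = c("GtC", "ppm"),
  residual            = c("K", "GtC", "ppm")
)

#' Construct an annual time series
#'
#' The basic container of the package: a contiguous annual record (integer
#' calendar years with step 1) of a tagged physical quantity. All estimators
#' operate on these objects so that unit bookkeeping (ppm vs GtC) and year
#' alignment are checked once, at construction.
#'
#' @param years Integer-valued, strictly increasing, contiguous (step 1).
#' @param values Numeric, same length as `years` (length >= 2).
#' @param units One of `"ppm"`, `"GtC"`, `"GtC_per_yr"`, `"ppm_per_yr"`, `"K"`.
#' @param kind One of `"co2_concentration"`, `"cumulative_emission"`,
#'   `"emission_flux"`, `"temperature_anomaly"`, `"carbon_storage"`,
#'   `"residual"`. The units/kind combination must be physically legal
#'   (e.g. a temperature anomaly must be in K).
#' @return An object of class `annual_series`.
#' @examples
#' co2 <- annual_series(1959:1968, seq(315, 324), "ppm", "co2_concentration")
#' print(co2)
#' @export
annual_series <- function(years, values, units, kind) {
  units <- match.arg(units, .ccf_units)
  kind <- match.arg(kind, .ccf_kinds)
  if (length(years) != length(values)) {
    stop_ccf("years and values must have equal length", class = "ccf_shape_error")
  }
  if (length(years) < 2L) {
    stop_ccf("an annual series needs at least 2 years", class = "ccf_shape_error")
  }
  if (anyNA(years) || any(abs(years - round(years)) > 1e-8)) {
    stop_ccf("years must be integers", class = "ccf_shape_error")
  }
  years <- as.integer(round(years))
  if (any(diff(years) != 1L)) {
    stop_ccf("years must be contiguous with step 1 (align/resample first)",
             class = "ccf_shape_error")
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop_ccf("values must be numeric with no missing entries",
             class = "ccf_shape_error")
  }
  if (!units %in% .ccf_unit_table[[kind]]) {
    stop_ccf("units '", units, "' are not legal for kind '", kind, "'",
             class = "ccf_unit_error")
  }
  structure(list(years = years, values = as.numeric(values),
                 units = units, kind = kind),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %s [%s], %d-%d (n = %d)\n",
              x$kind, x$units, x$years[1], x$years[length(x$years)],
              length(x$years)))
  cat(sprintf("  range of values: %.4g .. %.4g\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}

#' @export
length.annual_series <- function(x) length(x$years)

#' Years and values of an annual series
#' @param s An `annual_series`.
#' @return Integer years, or numeric values.
#' @export
series_years <- function(s) s$years

#' @rdname series_years
#' @export
series_values <- function(s) s$values

#' Restrict an annual series to a year window
#' @param s An `annual_series`.
#' @param from,to First and last year to keep (inclusive).
#' @return An `annual_series` on `from:to`.
#' @export
window_series <- function(s, from, to) {
  stopifnot(inherits(s, "annual_series"))
  if (from > to || from < s$years[1] || to > s$years[length(s$years)]) {
    stop_ccf("window [", from, ", ", to, "] not contained in series years",
             class = "ccf_range_error")
  }
  keep <- s$years >= from & s$years <= to
  annual_series(s$years[keep], s$values[keep], s$units, s$kind)
}

#' Read / write annual series as delimited tables
#'
#' Tables are comma-separated with a header row `year,value` (an optional
#' third `sigma` column is preserved as an attribute on read).
#'
#' @param file Path to a CSV file.
#' @param units,kind Tags for the series being read (see [annual_series()]).
#' @return `read_annual_series()` returns an `annual_series`;
#'   `write_annual_series()` returns the file path, invisibly.
#' @export
read_annual_series <- function(file, units, kind) {
  tab <- utils::read.csv(file)
  if (!all(c("year", "value") %in% names(tab))) {
    stop_ccf("expected columns 'year,value' in ", file, class = "ccf_io_error")
  }
  s <- annual_series(tab$year, tab$value, units, kind)
  if ("sigma" %in% names(tab)) attr(s, "sigma") <- as.numeric(tab$sigma)
  s
}

#' @rdname read_annual_series
#' @param s An `annual_series` to write.
#' @export
write_annual_series <- function(s, file) {
  stopifnot(inherits(s, "annual_series"))
  tab <- as.data.frame(s)
  sig <- attr(s, "sigma")
  if (!is.null(sig)) tab$sigma <- sig
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Anthropogenic emission record with uncertainties
#'
#' Couples the fossil-fuel and land-use-change emission fluxes with their
#' one-sigma uncertainty models: a fractional uncertainty on the fossil-fuel
#' flux (default 5%) and a constant absolute uncertainty on the land-use flux
#' (default 0.7 GtC per year).
#'
#' @param f_ff,f_luc `annual_series` of kind `emission_flux` in GtC per year,
#'   covering identical year ranges.
#' @param sigma_ff_frac Fractional 1-sigma of `f_ff` (default 0.05).
#' @param sigma_luc_abs Absolute 1-sigma of `f_luc` in GtC per year
#'   (default 0.7).
#' @return An object of class `emission_record`.
#' @export
emission_record <- function(f_ff, f_luc, sigma_ff_frac = 0.05,
                            sigma_luc_abs = 0.7) {
  stopifnot(inherits(f_ff, "annual_series"), inherits(f_luc, "annual_series"))
  if (f_ff$kind != "emission_flux" || f_luc$kind != "emission_flux" ||
      f_ff$units != "GtC_per_yr" || f_luc$units != "GtC_per_yr") {
    stop_ccf("f_ff and f_luc must be emission fluxes in GtC_per_yr",
             class = "ccf_unit_error")
  }
  if (!identical(f_ff$years, f_luc$years)) {
    stop_ccf("f_ff and f_luc must cover identical year ranges",
             class = "ccf_alignment_error")
  }
  assert_number(sigma_ff_frac, "sigma_ff_frac", lower = 0)
  assert_number(sigma_luc_abs, "sigma_luc_abs", lower = 0)
  structure(list(f_ff = f_ff, f_luc = f_luc,
                 sigma_ff_frac = sigma_ff_frac,
                 sigma_luc_abs = sigma_luc_abs),
            class = "emission_record")
}

#' Cumulative anthropogenic emissions
#'
#' Running sum of the total annual emission flux (fossil fuel + land use)
#' from the first year of the record; the value at year t is the carbon
#' emitted in all years up to and including t. The rectangle rule is exact
#' for annual totals.
#'
#' @param rec An [emission_record()].
#' @return An `annual_series` of kind `cumulative_emission` in GtC.
#' @export
cumulative_emissions <- function(rec) {
  stopifnot(inherits(rec, "emission_record"))
  total <- rec$f_ff$values + rec$f_luc$values
  annual_series(rec$f_ff$years, cumsum(total), "GtC", "cumulative_emission")
}

#' Convert carbon series between ppm and GtC
#'
#' Stocks convert as GtC = ppm * 2.12; fluxes as GtC/yr = ppm/yr * 2.12.
#' The round trip is the identity to floating tolerance. Temperature series
#' are rejected.
#'
#' @param s An `annual_series` holding a carbon quantity.
#' @param target_units `"ppm"`, `"GtC"`, `"ppm_per_yr"` or `"GtC_per_yr"`.
#' @return The converted `annual_series`.
#' @export
convert_carbon_units <- function(s, target_units) {
  stopifnot(inherits(s, "annual_series"))
  target_units <- match.arg(target_units, c("ppm", "GtC", "ppm_per_yr",
                                            "GtC_per_yr"))
  if (s$units == "K") {
    stop_ccf("cannot carbon-convert a temperature series",
             class = "ccf_unit_error")
  }
  stock_in <- s$units %in% c("ppm", "GtC")
  stock_out <- target_units %in% c("ppm", "GtC")
  if (stock_in != stock_out) {
    stop_ccf("cannot convert between a stock and a flux", class = "ccf_unit_error")
  }
  if (s$units == target_units) return(s)
  to_gtc <- target_units %in% c("GtC", "GtC_per_yr")
  vals <- if (to_gtc) s$values * GTC_PER_PPM else s$values / GTC_PER_PPM
  annual_series(s$years, vals, target_units, s$kind)
}

#' Anomalies relative to a base period
#'
#' Subtracts the mean over `[base_start, base_end]`, so the output averages
#' zero over the base period (the 1961-1990 convention for instrumental
#' temperature records). Idempotent for a fixed base period.
#'
#' @param s An `annual_series`.
#' @param base_start,base_end First and last year of the base period; must lie
#'   within the series.
#' @return An `annual_series` with the base-period mean removed.
#' @export
anomaly_relative_to <- function(s, base_start, base_end) {
  stopifnot(inherits(s, "annual_series"))
  if (base_start > base_end || base_start < s$years[1] ||
      base_end > s$years[length(s$years)]) {
    stop_ccf("base period [", base_start, ", ", base_end,
             "] outside series years", class = "ccf_range_error")
  }
  base <- s$years >= base_start & s$years <= base_end
  annual_series(s$years, s$values - mean(s$values[base]), s$units, s$kind)
}

#' Resample irregular observations to a contiguous annual grid
#'
#' Each observation is assigned to the nearest calendar year (collisions on
#' the same year are averaged, with a warning); gaps are then filled by
#' linear interpolation so the output is a contiguous annual record. This is
#' the standard preparation step for ice-core records whose sampling is
#' irregular in time.
#'
#' @param years Numeric observation times (possibly fractional years).
#' @param values Observed values.
#' @param units,kind Tags for the output series.
#' @return An `annual_series` on the full annual grid spanned by the data.
#' @export
resample_to_years <- function(years, values, units, kind) {
  if (length(years) != length(values) || length(years) < 2L) {
    stop_ccf("need at least 2 (year, value) pairs of equal length",
             class = "ccf_shape_error")
  }
  yr <- round(years)
  if (anyDuplicated(yr)) {
    warning("duplicate nearest-year assignments averaged",
            call. = FALSE)
    agg <- tapply(values, yr, mean)
    yr <- as.numeric(names(agg))
    values <- as.numeric(agg)
  }
  o <- order(yr)
  yr <- yr[o]; values <- values[o]
  grid <- seq(yr[1], yr[length(yr)])
  out <- stats::approx(yr, values, xout = grid, method = "linear")$y
  annual_series(grid, out, units, kind)
}

# Calibrate a cubic smoothing-spline stiffness (smooth.spline's `spar`) so
# that the amplitude response on a pure tone of the given period equals
# `response` (0.5 by convention). Amplitude is measured by harmonic
# regression over the central half of the record to keep natural-boundary
# effects out of the calibration. If even the stiffest admissible spline
# leaves more than the target response (very long cutoffs on short records),
# the stiff endpoint is used.
.spline_spar_for_cutoff <- function(n, cutoff_years, response = 0.5) {
  t <- seq_len(n)
  probe <- sin(2 * pi * t / cutoff_years)
  mid <- t > n / 4 & t <= 3 * n / 4
  amp_of <- function(y) {
    co <- stats::coef(stats::lm(y[mid] ~ sin(2 * pi * t[mid] / cutoff_years) +
                                  cos(2 * pi * t[mid] / cutoff_years)))
    sqrt(co[2]^2 + co[3]^2)
  }
  a0 <- amp_of(probe)
  gap <- function(spar) {
    fit <- stats::smooth.spline(t, probe, spar = spar, cv = FALSE,
                                all.knots = TRUE)
    amp_of(stats::predict(fit, t)$y) / a0 - response
  }
  lo <- -1.5; hi <- 2.5
  if (gap(lo) < 0) return(lo)   # even the loosest spline under-responds
  if (gap(hi) > 0) return(hi)
  stats::uniroot(gap, lower = lo, upper = hi, tol = 1e-4)$root
}

#' Low-pass smooth an annual series with an N-year spline
#'
#' Cubic smoothing spline whose stiffness is calibrated so the amplitude
#' response to a sinusoid of period `cutoff_years` is 0.5 -- the usual
#' dendroclimatology definition of an "N-year spline". Longer periods pass
#' nearly unattenuated, shorter periods are suppressed; constants (and hence
#' the series mean) are preserved.
#'
#' @param s An `annual_series` longer than `cutoff_years`.
#' @param cutoff_years Period (years, >= 2) at which the frequency response
#'   is 0.5.
#' @return The smoothed `annual_series`.
#' @export
spline_smooth <- function(s, cutoff_years) {
  stopifnot(inherits(s, "annual_series"))
  n <- length(s$years)
  assert_number(cutoff_years, "cutoff_years", lower = 2)
  if (cutoff_years >= n) {
    stop_ccf("cutoff_years must be smaller than the series length",
             class = "ccf_param_error")
  }
  spar <- .spline_spar_for_cutoff(n, cutoff_years)
  t <- seq_len(n)
  fit <- stats::smooth.spline(t, s$values, spar = spar, cv = FALSE,
                              all.knots = TRUE)
  annual_series(s$years, stats::predict(fit, t)$y, s$units, s$kind)
}

#' Align several annual series onto their common years
#'
#' @param series_list A list of `annual_series`.
#' @return A list of `annual_series`, all restricted to the intersection of
#'   the year ranges.
#' @export
align_series <- function(series_list) {
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, TRUE, "annual_series")))
  from <- max(vapply(series_list, function(s) s$years[1], 1))
  to <- min(vapply(series_list, function(s) s$years[length(s$years)], 1))
  if (from > to - 1) {
    stop_ccf("series have no overlapping years (or overlap < 2 years)",
             class = "ccf_alignment_error")
  }
  lapply(series_list, window_series, from = from, to = to)
}
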