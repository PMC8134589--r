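# Synthetic-data generators. These produce inputs with exactly the
# statistical structure the estimators assume -- harmonic systems obeying the
# feedback identity with known (beta, gamma*), exponentially growing
# emissions, AR(1) internal variability, ice-core-like smoothing, and
# COU/BGC/RAD experiment triplets with prescribed (beta, gamma, f) -- so each
# stage of the pipeline can be tested against ground truth.

#' Specification of a multi-harmonic feedback system
#'
#' Describes a record of length `n_years` built from sinusoids at integer
#' wavenumbers, whose CO2 and temperature components are tied to cumulative
#' emissions through the feedback identity with prescribed beta and gamma*.
#' In phase-locked mode the CO2 and temperature harmonics share phases, so
#' the per-harmonic amplitude identity a_k = (1+beta) b_k + gamma* c_k is
#' exact; with free phases the identity holds for the complex Fourier
#' coefficients but not necessarily for the amplitudes, which exposes the
#' estimator's phase assumption.
#'
#' @param n_years Record length N (>= 4).
#' @param harmonics Data frame with columns `k` (integer wavenumber,
#'   1 <= k <= N/2), `amp_ca` (ppm), `amp_ta` (K), `phase` (radians) and,
#'   optionally when `phase_locked = FALSE`, `phase_ta` (radians; the
#'   temperature phase, with `phase` then being the CO2 phase).
#' @param beta_true Carbon-concentration feedback, GtC GtC^-1.
#' @param gamma_star_true Combined carbon-climate feedback, GtC K^-1.
#' @param phase_locked Logical; see above (default `TRUE`).
#' @return An object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(n_years, harmonics, beta_true, gamma_star_true,
                          phase_locked = TRUE) {
  assert_number(n_years, "n_years", lower = 4)
  stopifnot(is.data.frame(harmonics),
            all(c("k", "amp_ca", "amp_ta", "phase") %in% names(harmonics)))
  if (any(harmonics$k < 1) || any(harmonics$k > n_years / 2)) {
    stop_ccf("wavenumbers must satisfy 1 <= k <= N/2 (aliasing)",
             class = "ccf_alias_error")
  }
  if (any(harmonics$amp_ca < 0) || any(harmonics$amp_ta < 0)) {
    stop_ccf("amplitudes must be nonnegative", class = "ccf_param_error")
  }
  if (anyDuplicated(harmonics$k)) {
    stop_ccf("duplicate wavenumbers", class = "ccf_param_error")
  }
  assert_number(beta_true, "beta_true")
  assert_number(gamma_star_true, "gamma_star_true")
  if (!"phase_ta" %in% names(harmonics) || isTRUE(phase_locked)) {
    harmonics$phase_ta <- harmonics$phase
  }
  structure(list(n_years = as.integer(n_years), harmonics = harmonics,
                 beta_true = beta_true, gamma_star_true = gamma_star_true,
                 phase_locked = isTRUE(phase_locked)),
            class = "harmonic_spec")
}

#' Generate a harmonic (C_E, C_A, T_A) system with known feedbacks
#'
#' Builds atmospheric CO2 and temperature as the harmonic sums of the spec,
#' then constructs cumulative emissions in the time domain as
#' C_E(t) = (1 + beta) m C_A(t) + gamma* T_A(t) (all in GtC), so the
#' feedback identity holds exactly by construction at every time step and,
#' in phase-locked mode, per harmonic amplitude.
#'
#' @param spec A [harmonic_spec()].
#' @param start_year First calendar year of the record (default 1850).
#' @return List with `annual_series` elements `c_e` (GtC, cumulative
#'   emissions), `c_a` (ppm, CO2 concentration) and `t_a` (K, temperature
#'   anomaly).
#' @export
gen_harmonic_system <- function(spec, start_year = 1850) {
  stopifnot(inherits(spec, "harmonic_spec"))
  n <- spec$n_years
  t <- 0:(n - 1)
  years <- start_year + t
  ca <- rep(0, n)
  ta <- rep(0, n)
  for (i in seq_len(nrow(spec$harmonics))) {
    h <- spec$harmonics[i, ]
    w <- 2 * pi * h$k / n
    ca <- ca + h$amp_ca * sin(w * t + h$phase)
    ta <- ta + h$amp_ta * sin(w * t + h$phase_ta)
  }
  ce <- (1 + spec$beta_true) * GTC_PER_PPM * ca + spec$gamma_star_true * ta
  list(c_e = annual_series(years, ce, "GtC", "cumulative_emission"),
       c_a = annual_series(years, ca, "ppm", "co2_concentration"),
       t_a = annual_series(years, ta, "K", "temperature_anomaly"))
}

#' Exponentially growing emission flux
#'
#' Emission flux A * exp(r * t), t in years since the record start -- the
#' growth law that fits industrial-era anthropogenic emissions (A = 0.27,
#' r = 0.018 per year for 1850-2017). The near-exponential forcing is what
#' makes the ratios of responses, and hence beta and the airborne fraction,
#' nearly constant over the industrial period.
#'
#' @param n_years Record length.
#' @param a Initial flux at t = 0 (default 0.27).
#' @param r Growth rate per year (default 0.018).
#' @param units `"GtC_per_yr"` (default) or `"ppm_per_yr"`.
#' @param start_year First calendar year (default 1850).
#' @return An `annual_series` of kind `emission_flux`.
#' @export
gen_exponential_emissions <- function(n_years, a = 0.27, r = 0.018,
                                      units = "GtC_per_yr",
                                      start_year = 1850) {
  assert_number(n_years, "n_years", lower = 2)
  assert_number(a, "a", lower = 1e-300)
  assert_number(r, "r")
  units <- match.arg(units, c("GtC_per_yr", "ppm_per_yr"))
  t <- 0:(n_years - 1)
  annual_series(start_year + t, a * exp(r * t), units, "emission_flux")
}

#' Stationary AR(1) internal-variability noise
#'
#' First-order autoregressive draw x_t = phi x_{t-1} + innovation, scaled so
#' the stationary marginal standard deviation equals `sigma`. Stands in for
#' the internal climate variability residual epsilon; reproducible for a
#' fixed seed, which is left out of the global RNG state.
#'
#' @param n_years Record length.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param sigma Stationary marginal standard deviation (>= 0).
#' @param seed Integer seed (required).
#' @param units,kind Tags for the output (default a temperature residual
#'   in K).
#' @param start_year First calendar year (default 1850).
#' @return An `annual_series` of kind `residual`.
#' @export
gen_ar1_noise <- function(n_years, phi, sigma, seed, units = "K",
                          kind = "residual", start_year = 1850) {
  assert_number(n_years, "n_years", lower = 2)
  assert_number(phi, "phi")
  if (abs(phi) >= 1) {
    stop_ccf("|phi| must be < 1 for stationarity", class = "ccf_param_error")
  }
  assert_number(sigma, "sigma", lower = 0)
  assert_number(seed, "seed")
  x <- with_seed(seed, {
    innov_sd <- sigma * sqrt(1 - phi^2)
    e <- stats::rnorm(n_years, sd = innov_sd)
    x <- numeric(n_years)
    x[1] <- stats::rnorm(1, sd = sigma)
    for (t in seq_len(n_years)[-1]) x[t] <- phi * x[t - 1] + e[t]
    x
  })
  annual_series(start_year + 0:(n_years - 1), x, units, kind)
}

#' Ice-core-like low-pass smoothing of an annual record
#'
#' Emulates the loss of inter-annual variability in ice-core gas records
#' caused by firn diffusion before bubble close-off, as a spline low-pass
#' with the given cutoff (see [spline_smooth()]).
#'
#' @param s An `annual_series`.
#' @param smooth_years Cutoff period in years (>= 2).
#' @return The smoothed `annual_series`.
#' @export
gen_icecore_like <- function(s, smooth_years) {
  spline_smooth(s, smooth_years)
}

#' Specification of a COU/BGC/RAD experiment triplet
#'
#' Parameters of a bilinear biosphere carbon response
#' Delta C_B = beta m Delta C_A + gamma Delta T_A + f Delta C_A Delta T_A
#' (Delta C_A in ppm, f in GtC ppm^-1 K^-1), together with a logarithmic
#' temperature response of sensitivity `s` K per CO2 doubling, applied to a
#' prescribed CO2 concentration path.
#'
#' @param beta_true Carbon-concentration feedback, GtC GtC^-1.
#' @param gamma_true Carbon-climate feedback, GtC K^-1.
#' @param f_true Bilinear nonlinear coefficient, GtC ppm^-1 K^-1.
#' @param s Warming per CO2 doubling, K (>= 0).
#' @param co2_path `annual_series` of atmospheric CO2 (ppm, positive).
#' @param t_noise_sd Optional sd (K) of white noise added to the BGC-run
#'   temperature (default 0: the BGC run has exactly zero warming).
#' @param seed Seed for the optional noise (required when `t_noise_sd > 0`).
#' @return An object of class `triplet_spec`.
#' @export
triplet_spec <- function(beta_true, gamma_true, f_true, s, co2_path,
                         t_noise_sd = 0, seed = NULL) {
  assert_number(beta_true, "beta_true")
  assert_number(gamma_true, "gamma_true")
  assert_number(f_true, "f_true")
  assert_number(s, "s", lower = 0)
  stopifnot(inherits(co2_path, "annual_series"))
  if (co2_path$units != "ppm") {
    stop_ccf("co2_path must be in ppm", class = "ccf_unit_error")
  }
  if (any(co2_path$values <= 0)) {
    stop_ccf("co2_path must be positive (log forcing)",
             class = "ccf_domain_error")
  }
  assert_number(t_noise_sd, "t_noise_sd", lower = 0)
  if (t_noise_sd > 0 && is.null(seed)) {
    stop_ccf("seed is required when t_noise_sd > 0", class = "ccf_param_error")
  }
  structure(list(beta_true = beta_true, gamma_true = gamma_true,
                 f_true = f_true, s = s, co2_path = co2_path,
                 t_noise_sd = t_noise_sd, seed = seed),
            class = "triplet_spec")
}

#' Generate a fully/biogeochemically/radiatively coupled experiment triplet
#'
#' Builds the three runs of the feedback-analysis design from a
#' [triplet_spec()]. All deltas are relative to the first year of the CO2
#' path. Writing dCA for the CO2 increase (ppm) and dT = (s/ln 2)
#' ln(CO2/CO2_0) for the warming:
#' \describe{
#'   \item{COU}{carbon and radiation both see the CO2 path:
#'     dCB = beta m dCA + gamma dT + f dCA dT.}
#'   \item{BGC}{only carbon sees the CO2 path; warming is zero (plus
#'     optional noise): dCB = beta m dCA.}
#'   \item{RAD}{only radiation sees the CO2 path; dCB = gamma dT.}
#' }
#' The atmospheric CO2 deltas of COU and BGC are identical by construction,
#' as the estimators require, and the construction identity
#' dCB_COU - (dCB_BGC + dCB_RAD) = f dCA dT holds exactly when the BGC
#' warming is exactly zero.
#'
#' @param spec A [triplet_spec()].
#' @return An [experiment_triplet()].
#' @export
gen_experiment_triplet <- function(spec) {
  stopifnot(inherits(spec, "triplet_spec"))
  co2 <- spec$co2_path
  years <- co2$years
  dca <- co2$values - co2$values[1]
  dt <- spec$s / log(2) * log(co2$values / co2$values[1])
  dt_bgc <- if (spec$t_noise_sd > 0) {
    e <- with_seed(spec$seed, stats::rnorm(length(years), sd = spec$t_noise_sd))
    e - e[1]
  } else {
    rep(0, length(years))
  }
  bm <- spec$beta_true * GTC_PER_PPM
  mk <- function(v, units, kind) annual_series(years, v, units, kind)
  run <- function(dcb, dca_run, dta_run) {
    list(delta_cb = mk(dcb, "GtC", "carbon_storage"),
         delta_ca = mk(dca_run, "ppm", "co2_concentration"),
         delta_ta = mk(dta_run, "K", "temperature_anomaly"))
  }
  experiment_triplet(
    cou = run(bm * dca + spec$gamma_true * dt + spec$f_true * dca * dt,
              dca, dt),
    bgc = run(bm * dca + spec$gamma_true * dt_bgc, dca, dt_bgc),
    rad = run(spec$gamma_true * dt, dca, dt)
  )
}
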