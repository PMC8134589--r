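# Airborne fraction, feedback gain g, amplification G = 1/(1-g),
# allowable-emission scaling, and the uncertainty-propagation formulas.

#' Per-timescale airborne fraction from amplitude spectra
#'
#' AF_k = b_k / a_k, the ratio of the CO2 amplitude to the cumulative
#' emission amplitude per harmonic, with band statistics over a timescale
#' band. Harmonics with degenerate emission amplitude are excluded.
#'
#' @param spec_ca Spectrum of atmospheric CO2.
#' @param spec_ce Spectrum of cumulative emissions, same carbon units.
#' @param band Optional timescale band `c(min_yr, max_yr)` for the summary
#'   statistics (default the whole spectrum).
#' @param floor_frac Relative floor on the emission amplitude
#'   (default 1e-9).
#' @return List with `af_k` (data frame `k`, `timescale_yr`, `af`), `mean`,
#'   `sd`, `n`, and `n_excluded`.
#' @export
airborne_fraction_spectrum <- function(spec_ca, spec_ce, band = NULL,
                                       floor_frac = 1e-9) {
  stopifnot(inherits(spec_ca, "amplitude_spectrum"),
            inherits(spec_ce, "amplitude_spectrum"))
  if (attr(spec_ca, "n_years") != attr(spec_ce, "n_years")) {
    stop_ccf("spectra must share the record length N", class = "ccf_shape_error")
  }
  if (attr(spec_ca, "units") != attr(spec_ce, "units")) {
    stop_ccf("spectra must share carbon units", class = "ccf_unit_error")
  }
  keep <- spec_ce$amplitude > floor_frac * max(spec_ce$amplitude) &
    !spec_ce$nyquist
  af <- data.frame(k = spec_ca$k[keep],
                   timescale_yr = spec_ca$timescale_yr[keep],
                   af = spec_ca$amplitude[keep] / spec_ce$amplitude[keep])
  sel <- if (is.null(band)) rep(TRUE, nrow(af)) else
    af$timescale_yr >= band[1] & af$timescale_yr <= band[2]
  v <- af$af[sel]
  list(af_k = af, mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v), n_excluded = sum(!keep))
}

#' Feedback gain from airborne fraction and beta
#'
#' g = 1 - 1 / (AF (1 + beta)), with beta in GtC GtC^-1 (a per-ppm beta is
#' converted via the mandatory unit tag). No rounding is applied; round at
#' the reporting layer.
#'
#' @param af Airborne fraction (> 0).
#' @param beta Carbon-concentration feedback.
#' @param beta_units `"GtC_per_GtC"` or `"GtC_per_ppm"`; mandatory, to
#'   remove the factor-2.12 ambiguity.
#' @return The gain factor g (dimensionless).
#' @export
gain_from_af_beta <- function(af, beta, beta_units) {
  assert_number(af, "af", lower = 1e-12)
  b <- convert_beta_units(beta, beta_units, "GtC_per_GtC")
  if (1 + b <= 0) {
    stop_ccf("1 + beta must be positive", class = "ccf_param_error")
  }
  1 - 1 / (af * (1 + b))
}

#' Feedback gain from gamma*, alpha and beta
#'
#' g = -gamma* alpha / (1 + beta), with alpha = dTA/dCA in K GtC^-1 and
#' gamma* in GtC K^-1. Also returns the diagnostic product alpha * gamma*
#' (GtC GtC^-1).
#'
#' @param gamma_star Combined carbon-climate feedback, GtC K^-1.
#' @param alpha Climate sensitivity to atmospheric CO2, K GtC^-1.
#' @param beta Carbon-concentration feedback.
#' @param beta_units `"GtC_per_GtC"` or `"GtC_per_ppm"`; mandatory.
#' @return List with `g` and `alpha_gamma` (= alpha * gamma*).
#' @export
gain_from_alpha <- function(gamma_star, alpha, beta, beta_units) {
  assert_number(gamma_star, "gamma_star")
  assert_number(alpha, "alpha")
  b <- convert_beta_units(beta, beta_units, "GtC_per_GtC")
  if (1 + b <= 0) {
    stop_ccf("1 + beta must be positive", class = "ccf_param_error")
  }
  list(g = -gamma_star * alpha / (1 + b), alpha_gamma = alpha * gamma_star)
}

#' Feedback amplification
#'
#' G = 1 / (1 - g); a net positive climate-carbon feedback has g > 0 and
#' G > 1. g >= 1 corresponds to runaway feedback and is rejected.
#'
#' @param g Gain factor (< 1).
#' @return The amplification G.
#' @export
amplification <- function(g) {
  if (any(g >= 1)) {
    stop_ccf("g >= 1: runaway feedback, amplification undefined",
             class = "ccf_runaway_error")
  }
  1 / (1 - g)
}

#' Rescale an allowable-emission budget by the ratio of amplifications
#'
#' Given a carbon budget derived under a model amplification G_model, the
#' budget consistent with an observation-based G_obs is
#' base * G_model / G_obs; the percent change is
#' 100 (G_model - G_obs) / G_obs. The 1-sigma of the ratio follows the
#' standard relative-quadrature propagation
#' (G_model/G_obs) sqrt((sigma_model/G_model)^2 + (sigma_obs/G_obs)^2).
#'
#' @param base_budget_gtc Baseline allowable emissions, GtC.
#' @param g_model,sigma_model Model amplification G and its 1-sigma.
#' @param g_obs,sigma_obs Observation-based amplification G and its
#'   1-sigma.
#' @return List with `budget_gtc`, `sigma_budget_gtc`, `percent_change`,
#'   `sigma_percent`.
#' @export
allowable_emissions_scale <- function(base_budget_gtc, g_model, sigma_model,
                                      g_obs, sigma_obs) {
  assert_number(base_budget_gtc, "base_budget_gtc", lower = 0)
  assert_number(g_model, "g_model", lower = 1e-12)
  assert_number(g_obs, "g_obs", lower = 1e-12)
  assert_number(sigma_model, "sigma_model", lower = 0)
  assert_number(sigma_obs, "sigma_obs", lower = 0)
  ratio <- g_model / g_obs
  sigma_ratio <- ratio * sqrt((sigma_model / g_model)^2 +
                                (sigma_obs / g_obs)^2)
  list(budget_gtc = base_budget_gtc * ratio,
       sigma_budget_gtc = base_budget_gtc * sigma_ratio,
       percent_change = 100 * (g_model - g_obs) / g_obs,
       sigma_percent = 100 * sigma_ratio)
}

#' Per-year 1-sigma of the total emission flux
#'
#' Quadrature of the fractional fossil-fuel uncertainty and the absolute
#' land-use uncertainty: sigma = sqrt((frac * F_FF)^2 + sigma_LUC^2).
#'
#' @param rec An [emission_record()].
#' @return Data frame with columns `year`, `sigma` (GtC per year).
#' @export
sigma_emission_flux <- function(rec) {
  stopifnot(inherits(rec, "emission_record"))
  data.frame(year = rec$f_ff$years,
             sigma = sqrt((rec$sigma_ff_frac * rec$f_ff$values)^2 +
                            rec$sigma_luc_abs^2))
}

#' Ensemble mean with propagated uncertainty
#'
#' Mean of n member estimates, with the propagated 1-sigma
#' (1/n) sqrt(sum sigma_i^2) -- the rule used to combine per-dataset
#' regression uncertainties.
#'
#' @param values Member estimates.
#' @param sigmas Member 1-sigmas (same length).
#' @return List with `mean` and `sigma`.
#' @export
ensemble_mean_sigma <- function(values, sigmas) {
  if (length(values) < 1 || length(values) != length(sigmas)) {
    stop_ccf("values and sigmas must be nonempty and of equal length",
             class = "ccf_param_error")
  }
  if (any(sigmas < 0)) {
    stop_ccf("sigmas must be nonnegative", class = "ccf_param_error")
  }
  n <- length(values)
  list(mean = mean(values), sigma = sqrt(sum(sigmas^2)) / n)
}

#' Ensemble spread (sample standard deviation)
#'
#' Plain sample sd across ensemble members, used when the members' own
#' uncertainties are unavailable (e.g. reconstruction x ice-core
#' combinations).
#'
#' @param values At least two member estimates.
#' @return The sample standard deviation.
#' @export
ensemble_sd <- function(values) {
  if (length(values) < 2) {
    stop_ccf("need at least 2 members for a sample sd",
             class = "ccf_param_error")
  }
  stats::sd(values)
}

#' Consistent gain summary
#'
#' Bundles the gain computed from (AF, beta) with, when gamma* and alpha
#' are supplied, the gain from the feedback-parameter route and the implied
#' TCRE. For inputs satisfying the feedback identity
#' 1/AF = (1 + beta) + alpha gamma* the two routes agree exactly.
#'
#' @param af Airborne fraction.
#' @param beta Carbon-concentration feedback.
#' @param beta_units `"GtC_per_GtC"` or `"GtC_per_ppm"`; mandatory.
#' @param gamma_star Optional gamma*, GtC K^-1.
#' @param alpha Optional alpha, K GtC^-1.
#' @return An object of class `gain_result`: list with `af`, `beta`
#'   (GtC GtC^-1), `g`, `G`, and when available `g_alpha`, `alpha_gamma`,
#'   `tcre` (K GtC^-1).
#' @export
gain_summary <- function(af, beta, beta_units, gamma_star = NULL,
                         alpha = NULL) {
  b <- convert_beta_units(beta, beta_units, "GtC_per_GtC")
  g <- gain_from_af_beta(af, b, "GtC_per_GtC")
  out <- list(af = af, beta = b, g = g, G = amplification(g))
  if (!is.null(gamma_star) && !is.null(alpha)) {
    ga <- gain_from_alpha(gamma_star, alpha, b, "GtC_per_GtC")
    out$g_alpha <- ga$g
    out$alpha_gamma <- ga$alpha_gamma
    out$tcre <- alpha / ((1 + b) + ga$alpha_gamma)
  }
  structure(out, class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("<gain_result> AF = %.3f, beta = %.3f GtC GtC^-1\n",
              x$af, x$beta))
  cat(sprintf("  g = %.4f, G = %.4f\n", x$g, x$G))
  if (!is.null(x$g_alpha)) {
    cat(sprintf("  g (from alpha, gamma*) = %.4f; alpha*gamma* = %.4f; TCRE = %.3e K GtC^-1\n",
                x$g_alpha, x$alpha_gamma, x$tcre))
  }
  invisible(x)
}
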