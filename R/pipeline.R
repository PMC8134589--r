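# Configuration-driven orchestration: synthesize or load data, run the
# spectral / box-model / FEA stages, and write report tables plus a run
# manifest. Configs are YAML with a top-level `mode`.

#' Read and validate a pipeline run configuration
#'
#' @param path Path to a YAML file with a top-level `mode` field, one of
#'   `"synth"`, `"industrial_estimate"`, `"pregamma"`, `"boxmodel"`,
#'   `"fea"`, plus the mode's required fields (see [run_pipeline()]).
#' @return The validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_ccf("config file not found: ", path, class = "ccf_io_error")
  }
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A config list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  if (!is.list(config) || is.null(config$mode)) {
    stop_ccf("config must be a list with a 'mode' field",
             class = "ccf_config_error")
  }
  modes <- c("synth", "industrial_estimate", "pregamma", "boxmodel", "fea")
  if (!config$mode %in% modes) {
    stop_ccf("mode must be one of: ", paste(modes, collapse = ", "),
             class = "ccf_config_error")
  }
  required <- switch(config$mode,
    synth = c("n_years", "harmonics", "beta_true", "gamma_star_true"),
    industrial_estimate = c("input_ce", "input_ca", "input_ta"),
    pregamma = c("input_ca", "input_ta", "beta"),
    boxmodel = c("beta", "gamma_star", "s", "c0"),
    fea = c("input_prefix"))
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_ccf("mode '", config$mode, "' config is missing field(s): ",
             paste(missing, collapse = ", "), class = "ccf_config_error")
  }
  stochastic <- (config$mode == "boxmodel" && isTRUE(config$ar1$sigma > 0)) ||
    (config$mode == "synth" && isTRUE(config$phase_random))
  if (stochastic && is.null(config$seed)) {
    stop_ccf("a seed is mandatory for stochastic steps",
             class = "ccf_config_error")
  }
  class(config) <- c("run_config", class(config))
  config
}

.write_kv <- function(kv, file) {
  utils::write.csv(data.frame(key = names(kv),
                              value = unname(vapply(kv, format, ""))),
                   file, row.names = FALSE, quote = FALSE)
}

.write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- list(
    package = "ccfeedback",
    version = as.character(utils::packageVersion("ccfeedback")),
    mode = config$mode,
    config = unclass(config),
    tolerances = list(box_solver_tol_ppm = 1e-10,
                      temperature_amplitude_floor_frac = 1e-9),
    extra = extra
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Run the analysis pipeline for one configuration
#'
#' Modes:
#' \describe{
#'   \item{synth}{generate a phase-locked (or free-phase) harmonic system
#'     with known (beta, gamma*) and write `c_e.csv`, `c_a.csv`,
#'     `t_a.csv`.}
#'   \item{industrial_estimate}{load C_E (GtC), C_A (ppm) and T_A (K)
#'     tables, align them, form spectra, fit (beta, gamma*) over the
#'     configured band (`fit_band`, default 2-90 yr) and report the fit
#'     plus airborne-fraction statistics.}
#'   \item{pregamma}{load preindustrial C_A (ppm) and T_A (K), compute
#'     eta_k, convert to gamma_k with the supplied `beta` (GtC GtC^-1) and
#'     report band statistics (`band`, default 90-110 yr).}
#'   \item{boxmodel}{simulate the box model from `beta`, `gamma_star`,
#'     `s`, `c0` and either an `input_ce` table or an exponential-emission
#'     spec (`emissions: {n_years, a, r}`), optionally with AR(1) noise
#'     (`ar1: {phi, sigma}` plus `seed`); reports the per-year conservation
#'     residual and the round-trip refit.}
#'   \item{fea}{load a triplet from `<input_prefix>_cou.csv` etc. (wide
#'     tables `year,delta_cb,delta_ca,delta_ta`) and report the feedback
#'     decomposition.}
#' }
#' Every run writes its outputs plus a `manifest.yaml` echoing the config,
#' package version and numeric tolerances; identical configs and seeds
#' reproduce identical outputs.
#'
#' @param config A config list or path to a YAML config.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The mode's result object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    stop_ccf("an output directory is required", class = "ccf_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$mode,
    synth = .run_synth(config, out_dir),
    industrial_estimate = .run_industrial(config, out_dir),
    pregamma = .run_pregamma(config, out_dir),
    boxmodel = .run_boxmodel(config, out_dir),
    fea = .run_fea(config, out_dir))
  invisible(res)
}

.run_synth <- function(config, out_dir) {
  h <- do.call(rbind, lapply(config$harmonics, as.data.frame))
  spec <- harmonic_spec(config$n_years, h, config$beta_true,
                        config$gamma_star_true,
                        phase_locked = !isTRUE(config$phase_random))
  sys <- gen_harmonic_system(spec, start_year = config$start_year %||% 1850)
  write_annual_series(sys$c_e, file.path(out_dir, "c_e.csv"))
  write_annual_series(sys$c_a, file.path(out_dir, "c_a.csv"))
  write_annual_series(sys$t_a, file.path(out_dir, "t_a.csv"))
  .write_manifest(config, out_dir)
  sys
}

.run_industrial <- function(config, out_dir) {
  ce <- read_annual_series(config$input_ce, "GtC", "cumulative_emission")
  ca <- read_annual_series(config$input_ca, "ppm", "co2_concentration")
  ta <- read_annual_series(config$input_ta, "K", "temperature_anomaly")
  al <- align_series(list(ce, ca, ta))
  ca_gtc <- convert_carbon_units(al[[2]], "GtC")
  sp_ce <- amplitude_spectrum(al[[1]])
  sp_ca <- amplitude_spectrum(ca_gtc)
  sp_ta <- amplitude_spectrum(al[[3]])
  est <- zeta_eta(sp_ce, sp_ca, sp_ta)
  band <- unlist(config$fit_band %||% c(2, 90))
  fit <- fit_beta_gamma_star(est, band = band)
  af <- airborne_fraction_spectrum(sp_ca, sp_ce, band = band)
  gain <- gain_summary(af$mean, fit$beta, "GtC_per_GtC")
  utils::write.csv(cbind(as.data.frame(est),
                         gamma_star_k = gamma_star_by_timescale(
                           est, fit$beta)$gamma_star),
                   file.path(out_dir, "timescale_estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_kv(list(slope = fit$slope, beta_gtc_per_gtc = fit$beta,
                 beta_gtc_per_ppm = fit$beta_gtc_per_ppm,
                 gamma_star_gtc_per_k = fit$gamma_star,
                 sigma_beta = fit$sigma_beta,
                 sigma_gamma_star = fit$sigma_gamma_star,
                 r_squared = fit$r_squared, n_harmonics = fit$n_harmonics,
                 af_mean = af$mean, af_sd = af$sd,
                 gain_g = gain$g, amplification_G = gain$G),
            file.path(out_dir, "report.csv"))
  .write_manifest(config, out_dir,
                  extra = list(excluded_harmonics = attr(est, "n_excluded")))
  list(fit = fit, af = af, gain = gain, estimates = est)
}

.run_pregamma <- function(config, out_dir) {
  ca <- read_annual_series(config$input_ca, "ppm", "co2_concentration")
  ta <- read_annual_series(config$input_ta, "K", "temperature_anomaly")
  al <- align_series(list(ca, ta))
  est <- zeta_eta(NULL, amplitude_spectrum(al[[1]]),
                  amplitude_spectrum(al[[2]]))
  gam <- data.frame(timescale_yr = est$timescale_yr,
                    eta_ppm_per_k = est$eta,
                    gamma = preindustrial_gamma(est$eta, config$beta))
  band <- unlist(config$band %||% c(90, 110))
  bs <- band_statistics(gam, band)
  utils::write.csv(gam, file.path(out_dir, "gamma_by_timescale.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bs, file.path(out_dir, "band_statistics.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_manifest(config, out_dir)
  list(gamma = gam, band_stats = bs)
}

.run_boxmodel <- function(config, out_dir) {
  ce <- if (!is.null(config$input_ce)) {
    read_annual_series(config$input_ce, "GtC", "cumulative_emission")
  } else {
    em <- config$emissions %||%
      stop_ccf("boxmodel needs input_ce or an emissions spec",
               class = "ccf_config_error")
    flux <- gen_exponential_emissions(em$n_years, em$a %||% 0.27,
                                      em$r %||% 0.018)
    zero <- annual_series(flux$years, rep(0, length(flux$years)),
                          "GtC_per_yr", "emission_flux")
    cumulative_emissions(emission_record(flux, zero))
  }
  eps <- if (!is.null(config$ar1)) {
    gen_ar1_noise(length(ce$years), config$ar1$phi, config$ar1$sigma,
                  seed = config$seed, start_year = ce$years[1])
  } else NULL
  params <- box_model_params(config$beta, config$gamma_star, config$s,
                             config$c0, config$t0 %||% 0, epsilon = eps)
  sim <- simulate_box(params, ce)
  dce <- ce$values - ce$values[1]
  dca <- sim$c_a$values - sim$c_a$values[1]
  dta <- sim$t_a$values - sim$t_a$values[1]
  resid <- dce - (1 + config$beta) * GTC_PER_PPM * dca -
    config$gamma_star * dta
  fit <- self_consistency_recovery(params, ce,
                                   band = unlist(config$fit_band %||% c(2, 90)))
  write_annual_series(sim$c_a, file.path(out_dir, "c_a.csv"))
  write_annual_series(sim$t_a, file.path(out_dir, "t_a.csv"))
  .write_kv(list(max_conservation_residual_gtc = max(abs(resid)),
                 recovered_beta_gtc_per_gtc = fit$beta,
                 recovered_gamma_star = fit$gamma_star),
            file.path(out_dir, "report.csv"))
  .write_manifest(config, out_dir,
                  extra = list(max_iterations = max(sim$iterations)))
  list(simulation = sim, conservation_residual = resid, refit = fit)
}

.read_triplet_run <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("year", "delta_cb", "delta_ca", "delta_ta")
  if (!all(need %in% names(tab))) {
    stop_ccf("expected columns ", paste(need, collapse = ","), " in ", path,
             class = "ccf_io_error")
  }
  list(delta_cb = annual_series(tab$year, tab$delta_cb, "GtC",
                                "carbon_storage"),
       delta_ca = annual_series(tab$year, tab$delta_ca, "ppm",
                                "co2_concentration"),
       delta_ta = annual_series(tab$year, tab$delta_ta, "K",
                                "temperature_anomaly"))
}

.run_fea <- function(config, out_dir) {
  paths <- paste0(config$input_prefix, c("_cou.csv", "_bgc.csv", "_rad.csv"))
  for (p in paths) {
    if (!file.exists(p)) stop_ccf("missing triplet file: ", p,
                                  class = "ccf_io_error")
  }
  tr <- experiment_triplet(.read_triplet_run(paths[1]),
                           .read_triplet_run(paths[2]),
                           .read_triplet_run(paths[3]),
                           reference_year = config$reference_year)
  dec <- feedback_decomposition(tr, horizon_year = config$horizon_year)
  .write_kv(dec[c("beta_bgc", "beta_cou_rad", "gamma_rad", "gamma_cou_bgc",
                  "f_nl", "f_dca", "f_dta", "reference_year",
                  "horizon_year")],
            file.path(out_dir, "decomposition.csv"))
  .write_manifest(config, out_dir)
  dec
}

#' Write an experiment triplet as three delimited tables
#'
#' Writes `<prefix>_cou.csv`, `<prefix>_bgc.csv`, `<prefix>_rad.csv`, each
#' with columns `year,delta_cb,delta_ca,delta_ta`, the schema read back by
#' the `fea` pipeline mode.
#'
#' @param triplet An [experiment_triplet()].
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_triplet <- function(triplet, prefix) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  paths <- paste0(prefix, c("_cou.csv", "_bgc.csv", "_rad.csv"))
  runs <- triplet[c("cou", "bgc", "rad")]
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    utils::write.csv(data.frame(year = r$delta_cb$years,
                                delta_cb = r$delta_cb$values,
                                delta_ca = r$delta_ca$values,
                                delta_ta = r$delta_ta$values),
                     paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
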