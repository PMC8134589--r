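# Shared fixture builders, all generated in code.

make_series <- function(values, units = "K", kind = "temperature_anomaly",
                        start_year = 1850) {
  annual_series(start_year + seq_along(values) - 1, values, units, kind)
}

# A phase-locked multi-harmonic system with known (beta, gamma*).
# Temperature amplitudes are kept small relative to CO2 so every emission
# amplitude stays positive and the amplitude identity has a definite sign.
default_harmonics <- function() {
  data.frame(k = c(3, 7, 12, 20, 31, 45),
             amp_ca = c(8, 5, 3, 2, 1.5, 1),
             amp_ta = c(0.12, 0.08, 0.05, 0.04, 0.03, 0.02),
             phase = c(0.3, 1.1, 2.0, -0.7, 0.5, 1.7))
}

make_locked_system <- function(beta = 1.52, gamma_star = -10.9,
                               n_years = 120, harmonics = default_harmonics()) {
  gen_harmonic_system(harmonic_spec(n_years, harmonics, beta, gamma_star,
                                    phase_locked = TRUE))
}

# Spectral pipeline: series -> timescale estimates with carbon in GtC.
estimates_of <- function(sys) {
  zeta_eta(amplitude_spectrum(sys$c_e),
           amplitude_spectrum(convert_carbon_units(sys$c_a, "GtC")),
           amplitude_spectrum(sys$t_a))
}

# Independent O(N^2) DFT oracle for one-sided amplitudes (sine convention),
# written directly from the definition of the discrete transform.
dft_amplitudes <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  t <- 0:(n - 1)
  vapply(seq_len(floor(n / 2)), function(k) {
    re <- sum(x * cos(2 * pi * k * t / n))
    im <- -sum(x * sin(2 * pi * k * t / n))
    2 / n * sqrt(re^2 + im^2)
  }, 1)
}

# Cumulative emissions from a single flux series (zero land-use part).
cum_from_flux <- function(flux) {
  zero <- annual_series(series_years(flux),
                        rep(0, length(flux)), "GtC_per_yr", "emission_flux")
  cumulative_emissions(emission_record(flux, zero))
}

# A 1%/yr CO2 concentration path, the idealised experiment forcing.
one_pct_co2 <- function(n_years = 140, c0 = 285, start_year = 1880) {
  annual_series(start_year + 0:(n_years - 1), c0 * 1.01^(0:(n_years - 1)),
                "ppm", "co2_concentration")
}
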