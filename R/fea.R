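# Feedback-analysis (FEA) estimators: beta, gamma and the bilinear nonlinear
# term f recovered from differences between fully coupled (COU),
# biogeochemically coupled (BGC) and radiatively coupled (RAD) experiment
# runs at a fixed horizon, all deltas relative to a common reference year.

.valid_run <- function(run, label) {
  need <- c("delta_cb", "delta_ca", "delta_ta")
  if (!is.list(run) || !all(need %in% names(run))) {
    stop_ccf(label, " run must be a list with delta_cb, delta_ca, delta_ta",
             class = "ccf_shape_error")
  }
  for (nm in need) stopifnot(inherits(run[[nm]], "annual_series"))
  if (run$delta_cb$units != "GtC") {
    stop_ccf(label, ": delta_cb must be in GtC", class = "ccf_unit_error")
  }
  if (run$delta_ca$units != "ppm") {
    stop_ccf(label, ": delta_ca must be in ppm", class = "ccf_unit_error")
  }
  if (run$delta_ta$units != "K") {
    stop_ccf(label, ": delta_ta must be in K", class = "ccf_unit_error")
  }
  yrs <- run$delta_cb$years
  if (!identical(run$delta_ca$years, yrs) ||
      !identical(run$delta_ta$years, yrs)) {
    stop_ccf(label, ": run series must share years",
             class = "ccf_alignment_error")
  }
  run
}

#' Bundle of COU/BGC/RAD experiment runs
#'
#' Each run holds annual deltas relative to a common reference year:
#' `delta_cb`, the change in combined land + ocean carbon storage (GtC);
#' `delta_ca`, the change in atmospheric CO2 (ppm); and `delta_ta`, the
#' temperature change (K). A run may additionally carry `delta_cl` and
#' `delta_co` (land and ocean parts of `delta_cb`, GtC) for per-reservoir
#' decompositions. The atmospheric CO2 paths of the COU and BGC runs must
#' agree (checked to 1e-6 relative to the path scale), as the estimators
#' require.
#'
#' @param cou,bgc,rad Lists with elements `delta_cb`, `delta_ca`,
#'   `delta_ta` (each an `annual_series`), and optionally `delta_cl`,
#'   `delta_co`.
#' @param reference_year Reference year of the deltas (default the first
#'   record year).
#' @return An object of class `experiment_triplet`.
#' @export
experiment_triplet <- function(cou, bgc, rad,
                               reference_year = NULL) {
  cou <- .valid_run(cou, "COU")
  bgc <- .valid_run(bgc, "BGC")
  rad <- .valid_run(rad, "RAD")
  yrs <- cou$delta_cb$years
  if (!identical(bgc$delta_cb$years, yrs) ||
      !identical(rad$delta_cb$years, yrs)) {
    stop_ccf("all three runs must share years", class = "ccf_alignment_error")
  }
  scale <- max(1, max(abs(cou$delta_ca$values)))
  if (max(abs(cou$delta_ca$values - bgc$delta_ca$values)) > 1e-6 * scale) {
    stop_ccf("delta_ca of COU and BGC runs must agree",
             class = "ccf_alignment_error")
  }
  structure(list(cou = cou, bgc = bgc, rad = rad,
                 reference_year = reference_year %||% yrs[1]),
            class = "experiment_triplet")
}

#' @export
print.experiment_triplet <- function(x, ...) {
  yrs <- x$cou$delta_cb$years
  cat(sprintf("<experiment_triplet> %d-%d, reference year %d\n",
              yrs[1], yrs[length(yrs)], x$reference_year))
  cat(sprintf("  final deltas (COU): C_B %.2f GtC, C_A %.2f ppm, T_A %.2f K\n",
              x$cou$delta_cb$values[length(yrs)],
              x$cou$delta_ca$values[length(yrs)],
              x$cou$delta_ta$values[length(yrs)]))
  invisible(x)
}

.at_horizon <- function(s, horizon_year) {
  i <- match(horizon_year, s$years)
  if (is.na(i)) {
    stop_ccf("horizon year ", horizon_year, " not in record",
             class = "ccf_range_error")
  }
  s$values[i]
}

.triplet_deltas <- function(triplet, horizon_year) {
  g <- function(run, what) .at_horizon(triplet[[run]][[what]], horizon_year)
  list(cb_cou = g("cou", "delta_cb"), cb_bgc = g("bgc", "delta_cb"),
       cb_rad = g("rad", "delta_cb"),
       ca_cou = g("cou", "delta_ca"), ca_bgc = g("bgc", "delta_ca"),
       ta_cou = g("cou", "delta_ta"), ta_bgc = g("bgc", "delta_ta"),
       ta_rad = g("rad", "delta_ta"))
}

.default_horizon <- function(triplet) {
  yrs <- triplet$cou$delta_cb$years
  yrs[length(yrs)]
}

#' Carbon-concentration feedback from the BGC run
#'
#' Approximate form: beta_BGC = dCB_BGC / dCA_BGC, valid when the BGC run
#' has negligible warming. The exact form uses the COU run to remove the
#' small BGC warming contribution:
#' (dCB_BGC dTA_COU - dCB_COU dTA_BGC) / (dCA_BGC (dTA_COU - dTA_BGC)).
#'
#' @param triplet An [experiment_triplet()].
#' @param horizon_year Year of the deltas (default the final record year).
#' @param exact_form Use the exact quotient (default `FALSE`).
#' @return beta in GtC ppm^-1.
#' @export
beta_bgc <- function(triplet, horizon_year = NULL, exact_form = FALSE) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  d <- .triplet_deltas(triplet, horizon_year)
  if (abs(d$ca_bgc) < 1e-12) {
    stop_ccf("delta_ca^BGC is zero at the horizon", class = "ccf_degenerate_error")
  }
  if (exact_form) {
    den <- d$ca_bgc * (d$ta_cou - d$ta_bgc)
    if (abs(den) < 1e-12) {
      stop_ccf("degenerate denominator in exact beta_bgc",
               class = "ccf_degenerate_error")
    }
    (d$cb_bgc * d$ta_cou - d$cb_cou * d$ta_bgc) / den
  } else {
    d$cb_bgc / d$ca_bgc
  }
}

#' Total carbon-climate feedback from the COU-BGC pair
#'
#' gamma_COU-BGC = (dCB_COU - dCB_BGC) / (dTA_COU - dTA_BGC), which in the
#' presence of a nonlinear term estimates gamma* = gamma + f dCA. The
#' approximate form drops dTA_BGC from the denominator; the form not
#' returned is attached as attribute `other_form`.
#'
#' @inheritParams beta_bgc
#' @param exact_form Use the exact denominator (default `TRUE`).
#' @return gamma in GtC K^-1.
#' @export
gamma_cou_bgc <- function(triplet, horizon_year = NULL, exact_form = TRUE) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  d <- .triplet_deltas(triplet, horizon_year)
  num <- d$cb_cou - d$cb_bgc
  den_exact <- d$ta_cou - d$ta_bgc
  den_apx <- d$ta_cou
  den <- if (exact_form) den_exact else den_apx
  if (abs(den) < 1e-6) {
    stop_ccf("temperature denominator below 1e-6 K",
             class = "ccf_degenerate_error")
  }
  other <- if (abs(if (exact_form) den_apx else den_exact) < 1e-6) {
    NA_real_
  } else {
    num / (if (exact_form) den_apx else den_exact)
  }
  structure(num / den, other_form = other)
}

#' Direct carbon-climate feedback from the RAD run
#'
#' gamma_RAD = dCB_RAD / dTA_RAD.
#'
#' @inheritParams beta_bgc
#' @return gamma in GtC K^-1.
#' @export
gamma_rad <- function(triplet, horizon_year = NULL) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  d <- .triplet_deltas(triplet, horizon_year)
  if (abs(d$ta_rad) < 1e-6) {
    stop_ccf("temperature denominator below 1e-6 K",
             class = "ccf_degenerate_error")
  }
  d$cb_rad / d$ta_rad
}

#' Carbon-concentration feedback from the COU-RAD pair
#'
#' Approximate form: beta_COU-RAD = (dCB_COU - dCB_RAD) / dCA_COU, which in
#' the presence of a nonlinear term estimates beta + f dTA (per ppm). The
#' exact form is
#' (dCB_RAD dTA_COU - dCB_COU dTA_RAD) / (dCA_COU dTA_RAD).
#'
#' @inheritParams beta_bgc
#' @return beta in GtC ppm^-1.
#' @export
beta_cou_rad <- function(triplet, horizon_year = NULL, exact_form = FALSE) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  d <- .triplet_deltas(triplet, horizon_year)
  if (abs(d$ca_cou) < 1e-12) {
    stop_ccf("delta_ca^COU is zero at the horizon",
             class = "ccf_degenerate_error")
  }
  if (exact_form) {
    if (abs(d$ta_rad) < 1e-6) {
      stop_ccf("temperature denominator below 1e-6 K",
               class = "ccf_degenerate_error")
    }
    -(d$cb_rad * d$ta_cou - d$cb_cou * d$ta_rad) / (d$ca_cou * d$ta_rad)
  } else {
    (d$cb_cou - d$cb_rad) / d$ca_cou
  }
}

#' Bilinear nonlinear feedback coefficient f
#'
#' f = [dCB_COU - (dCB_BGC + dCB_RAD)] / [dCA_COU (dTA_COU - dTA_BGC)],
#' with the approximate form using dTA_COU alone in the second factor.
#' Also returns the contributions f dCA_COU (to gamma*, GtC K^-1) and
#' f dTA_COU (to beta, GtC ppm^-1), and their percentage sizes relative to
#' the direct gamma_RAD and beta_BGC estimates.
#'
#' @inheritParams beta_bgc
#' @param exact_form Use the exact denominator (default `TRUE`).
#' @return List with `f_nl` (GtC ppm^-1 K^-1), `f_dca` (GtC K^-1), `f_dta`
#'   (GtC ppm^-1), `pct_of_gamma`, `pct_of_beta`.
#' @export
nonlinear_f <- function(triplet, horizon_year = NULL, exact_form = TRUE) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  d <- .triplet_deltas(triplet, horizon_year)
  dta <- if (exact_form) d$ta_cou - d$ta_bgc else d$ta_cou
  den <- d$ca_cou * dta
  if (abs(den) < 1e-12) {
    stop_ccf("degenerate denominator in nonlinear_f",
             class = "ccf_degenerate_error")
  }
  f <- (d$cb_cou - (d$cb_bgc + d$cb_rad)) / den
  f_dca <- f * d$ca_cou
  f_dta <- f * d$ta_cou
  g_rad <- tryCatch(gamma_rad(triplet, horizon_year), error = function(e) NA)
  b_bgc <- tryCatch(beta_bgc(triplet, horizon_year), error = function(e) NA)
  list(f_nl = f, f_dca = f_dca, f_dta = f_dta,
       pct_of_gamma = if (is.na(g_rad) || g_rad == 0) NA_real_ else
         100 * abs(f_dca / g_rad),
       pct_of_beta = if (is.na(b_bgc) || b_bgc == 0) NA_real_ else
         100 * abs(f_dta / b_bgc))
}

#' Full feedback decomposition of an experiment triplet
#'
#' Convenience wrapper computing all FEA estimators at one horizon. When the
#' runs carry separate land (`delta_cl`) and ocean (`delta_co`) storage
#' series, per-reservoir decompositions are computed by the same formulas
#' and checked to sum to the totals.
#'
#' @inheritParams beta_bgc
#' @return An object of class `feedback_decomposition`: a list with
#'   `beta_bgc`, `beta_cou_rad` (GtC ppm^-1), `gamma_rad`, `gamma_cou_bgc`
#'   (GtC K^-1), `f_nl` (GtC ppm^-1 K^-1), `f_dca`, `f_dta`,
#'   `reference_year`, `horizon_year`, and optionally `land` / `ocean`
#'   sub-decompositions.
#' @export
feedback_decomposition <- function(triplet, horizon_year = NULL) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  horizon_year <- horizon_year %||% .default_horizon(triplet)
  nf <- nonlinear_f(triplet, horizon_year)
  out <- list(beta_bgc = beta_bgc(triplet, horizon_year),
              beta_cou_rad = beta_cou_rad(triplet, horizon_year),
              gamma_rad = gamma_rad(triplet, horizon_year),
              gamma_cou_bgc = as.numeric(gamma_cou_bgc(triplet, horizon_year)),
              f_nl = nf$f_nl, f_dca = nf$f_dca, f_dta = nf$f_dta,
              pct_of_gamma = nf$pct_of_gamma, pct_of_beta = nf$pct_of_beta,
              reference_year = triplet$reference_year,
              horizon_year = horizon_year)
  has_split <- all(vapply(triplet[c("cou", "bgc", "rad")], function(r) {
    all(c("delta_cl", "delta_co") %in% names(r))
  }, TRUE))
  if (has_split) {
    sub <- function(what) {
      runs <- lapply(triplet[c("cou", "bgc", "rad")], function(r) {
        list(delta_cb = r[[what]], delta_ca = r$delta_ca,
             delta_ta = r$delta_ta)
      })
      feedback_decomposition(
        experiment_triplet(runs$cou, runs$bgc, runs$rad,
                           reference_year = triplet$reference_year),
        horizon_year)
    }
    out$land <- sub("delta_cl")
    out$ocean <- sub("delta_co")
    for (q in c("beta_bgc", "gamma_rad", "f_nl")) {
      if (abs(out$land[[q]] + out$ocean[[q]] - out[[q]]) >
          1e-8 * max(1, abs(out[[q]]))) {
        stop_ccf("land + ocean ", q, " do not sum to the total",
                 class = "ccf_consistency_error")
      }
    }
  }
  class(out) <- "feedback_decomposition"
  out
}

#' @export
print.feedback_decomposition <- function(x, ...) {
  cat(sprintf("<feedback_decomposition> horizon %d (reference %d)\n",
              x$horizon_year, x$reference_year))
  cat(sprintf("  beta_BGC     = %8.4f GtC ppm^-1   beta_COU-RAD = %8.4f GtC ppm^-1\n",
              x$beta_bgc, x$beta_cou_rad))
  cat(sprintf("  gamma_RAD    = %8.4f GtC K^-1     gamma_COU-BGC = %8.4f GtC K^-1\n",
              x$gamma_rad, x$gamma_cou_bgc))
  cat(sprintf("  f            = %.4e GtC ppm^-1 K^-1 (f dCA = %.4f GtC K^-1, f dTA = %.4f GtC ppm^-1)\n",
              x$f_nl, x$f_dca, x$f_dta))
  invisible(x)
}

#' Timescale-resolved FEA estimates from sliding windows
#'
#' For each window length, evaluates the approximate BGC beta and RAD gamma
#' ratios over all deltas spanning that window (sliding across the record)
#' and reports their mean and sample standard deviation. The full-record
#' window reproduces the single-horizon estimators.
#'
#' @param triplet An [experiment_triplet()].
#' @param window_lengths Integer vector of window lengths in years
#'   (each <= record span).
#' @return Data frame with columns `window_yr`, `beta_mean`, `beta_sd`,
#'   `gamma_mean`, `gamma_sd`, `n_windows`.
#' @export
fea_by_timescale <- function(triplet, window_lengths) {
  stopifnot(inherits(triplet, "experiment_triplet"))
  if (length(window_lengths) == 0) {
    stop_ccf("window_lengths must be nonempty", class = "ccf_param_error")
  }
  yrs <- triplet$cou$delta_cb$years
  span <- length(yrs) - 1L
  if (any(window_lengths < 1 | window_lengths > span)) {
    stop_ccf("window lengths must be in [1, ", span, "] years",
             class = "ccf_param_error")
  }
  cb_bgc <- triplet$bgc$delta_cb$values
  ca_bgc <- triplet$bgc$delta_ca$values
  cb_rad <- triplet$rad$delta_cb$values
  ta_rad <- triplet$rad$delta_ta$values
  rows <- lapply(as.integer(window_lengths), function(w) {
    i0 <- seq_len(length(yrs) - w)
    i1 <- i0 + w
    dca <- ca_bgc[i1] - ca_bgc[i0]
    dta <- ta_rad[i1] - ta_rad[i0]
    bet <- (cb_bgc[i1] - cb_bgc[i0]) / dca
    gam <- (cb_rad[i1] - cb_rad[i0]) / dta
    bet <- bet[abs(dca) > 1e-12]
    gam <- gam[abs(dta) > 1e-6]
    data.frame(window_yr = w,
               beta_mean = mean(bet), beta_sd = if (length(bet) > 1)
                 stats::sd(bet) else 0,
               gamma_mean = mean(gam), gamma_sd = if (length(gam) > 1)
                 stats::sd(gam) else 0,
               n_windows = length(i0))
  })
  do.call(rbind, rows)
}
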