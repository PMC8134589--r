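#' Carbon unit conversion constant
#'
#' Mass of carbon corresponding to 1 ppm of atmospheric CO2: 2.12 GtC per ppm.
#' Used for every conversion between mixing-ratio (ppm) and mass (GtC) carbon
#' units, including the unit changes of the feedback parameters beta, gamma,
#' alpha and eta.
#'
#' @format A length-one numeric, 2.12.
#' @export
GTC_PER_PPM <- 2.12

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccf <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ccf_error")))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ccf(name, " must be a single finite number", class = "ccf_param_error")
  }
  if (x < lower || x > upper) {
    stop_ccf(name, " must be in [", lower, ", ", upper, "]",
             class = "ccf_param_error")
  }
  invisible(x)
}

# Run code with a private RNG stream; global .Random.seed is left untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Convert a feedback parameter between per-ppm and per-GtC carbon units
#'
#' beta in GtC ppm^-1 equals `GTC_PER_PPM` times beta in GtC GtC^-1; the same
#' factor applies to the nonlinear coefficient f. Supplying the unit tag is
#' mandatory everywhere a beta enters a gain formula, to remove the factor-2.12
#' ambiguity.
#'
#' @param beta Numeric parameter value.
#' @param from,to One of `"GtC_per_GtC"`, `"GtC_per_ppm"`.
#' @return The parameter expressed in `to` units.
#' @export
convert_beta_units <- function(beta, from, to) {
  from <- match.arg(from, c("GtC_per_GtC", "GtC_per_ppm"))
  to <- match.arg(to, c("GtC_per_GtC", "GtC_per_ppm"))
  if (from == to) return(beta)
  if (from == "GtC_per_GtC") beta * GTC_PER_PPM else beta / GTC_PER_PPM
}
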