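#' Acquisition protocol: b-value scheme and effective SNR
#'
#' Bundles the diffusion-weighting scheme (b-values) with the effective
#' signal-to-noise ratio at `b = 0` that together define a measurement
#' design. The effective SNR is a single dimensionless number absorbing
#' sequence settings (TE, TR, repetitions) and ROI averaging.
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2. Must be
#'   finite, non-negative, of length >= 3, and contain at least one zero
#'   (the `b = 0` measurement is required for signal normalisation).
#' @param snr Effective signal-to-noise ratio at `b = 0`; a single finite
#'   value > 0.
#'
#' @return An object of class `acquisition_protocol`: a list with elements
#'   `b_values` and `snr`.
#' @examples
#' acquisition_protocol(c(0, 10, 20, 40, 80, 100, 200, 400, 600), snr = 20)
#' @export
acquisition_protocol <- function(b_values, snr) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 3L) {
    stop("`b_values` must contain at least 3 values", call. = FALSE)
  }
  if (!all(is.finite(b_values)) || any(b_values < 0)) {
    stop("`b_values` must be finite and non-negative", call. = FALSE)
  }
  if (!any(b_values == 0)) {
    stop("`b_values` must include b = 0 (needed for normalisation)",
         call. = FALSE)
  }
  if (length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    stop("`snr` must be a single finite value > 0", call. = FALSE)
  }
  structure(list(b_values = b_values, snr = as.numeric(snr)),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Acquisition protocol:", length(x$b_values), "b-values (s/mm^2):",
      paste(format(x$b_values, trim = TRUE), collapse = ", "),
      "\n  effective SNR at b = 0:", x$snr, "\n")
  invisible(x)
}

#' IVIM model parameters
#'
#' Parameter set for the bi-exponential intravoxel incoherent motion (IVIM)
#' model: perfusion fraction `f`, tissue diffusivity `d_slow`, and
#' pseudo-diffusivity of perfusing water `d_fast`. All diffusivities use
#' the package's canonical unit of mm^2/s (so typical tissue values are of
#' order 1e-3).
#'
#' @param f Perfusion fraction, dimensionless, in \[0, 1\].
#' @param d_slow Diffusivity of non-perfusing water, mm^2/s, >= 0.
#' @param d_fast Pseudo-diffusivity of perfusing water, mm^2/s, >= 0.
#' @return Named numeric vector of class `ivim_params`.
#' @examples
#' ivim_params(f = 0.09, d_slow = 0.35e-3, d_fast = 123e-3)
#' @export
ivim_params <- function(f, d_slow, d_fast) {
  p <- c(f = as.numeric(f), d_slow = as.numeric(d_slow),
         d_fast = as.numeric(d_fast))
  if (!all(is.finite(p))) {
    stop("IVIM parameters must be finite", call. = FALSE)
  }
  if (p[["f"]] < 0 || p[["f"]] > 1) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  if (p[["d_slow"]] < 0 || p[["d_fast"]] < 0) {
    stop("diffusivities must be >= 0", call. = FALSE)
  }
  structure(p, class = "ivim_params")
}

#' ADC model parameters
#'
#' Parameter set for the mono-exponential apparent diffusion coefficient
#' model, in mm^2/s.
#'
#' @param adc Apparent diffusion coefficient, mm^2/s, finite and >= 0.
#' @return Named numeric vector of class `adc_params`.
#' @examples
#' adc_params(1.0e-3)
#' @export
adc_params <- function(adc) {
  adc <- as.numeric(adc)
  if (length(adc) != 1L || !is.finite(adc) || adc < 0) {
    stop("`adc` must be a single finite value >= 0", call. = FALSE)
  }
  structure(c(adc = adc), class = "adc_params")
}

check_b_values <- function(b_values) {
  b_values <- as.numeric(b_values)
  if (!all(is.finite(b_values)) || any(b_values < 0)) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
  b_values
}

#' Noise-free IVIM signal
#'
#' Evaluates the normalised bi-exponential IVIM signal
#' \deqn{S(b)/S_0 = f e^{-b (D_{fast} + D_{slow})} + (1 - f) e^{-b D_{slow}}}
#' at the given b-values. Note that the fast compartment decays at the rate
#' `d_fast + d_slow`, i.e. the pseudo-diffusion is modelled on top of the
#' tissue diffusivity.
#'
#' @param params An [ivim_params] object (or a numeric vector with named
#'   elements `f`, `d_slow`, `d_fast`, validated on the fly).
#' @param b_values Diffusion weightings, s/mm^2, finite and non-negative.
#' @return Numeric vector of normalised signals `S(b)/S0`, one per b-value,
#'   each in (0, 1]; exactly 1 at `b = 0`.
#' @examples
#' p <- ivim_params(f = 0.09, d_slow = 0.35e-3, d_fast = 123e-3)
#' ivim_signal(p, c(0, 100, 600))
#' @export
ivim_signal <- function(params, b_values) {
  if (!inherits(params, "ivim_params")) {
    params <- ivim_params(params[["f"]], params[["d_slow"]],
                          params[["d_fast"]])
  }
  b <- check_b_values(b_values)
  f <- params[["f"]]
  f * exp(-b * (params[["d_fast"]] + params[["d_slow"]])) +
    (1 - f) * exp(-b * params[["d_slow"]])
}

#' Noise-free ADC signal
#'
#' Evaluates the normalised mono-exponential signal
#' \deqn{S(b)/S_0 = e^{-b \cdot ADC}} at the given b-values.
#'
#' @param params An [adc_params] object (or a value coercible to one).
#' @param b_values Diffusion weightings, s/mm^2, finite and non-negative.
#' @return Numeric vector of normalised signals, one per b-value, each in
#'   (0, 1] and non-increasing in b.
#' @examples
#' adc_signal(adc_params(1.91e-3), c(0, 300, 600))
#' @export
adc_signal <- function(params, b_values) {
  if (!inherits(params, "adc_params")) {
    params <- adc_params(if (!is.null(names(params))) params[["adc"]]
                         else params)
  }
  b <- check_b_values(b_values)
  exp(-b * params[["adc"]])
}
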