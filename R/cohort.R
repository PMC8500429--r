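#' @importFrom stats pnorm rnorm
NULL

# physical domain of each model parameter; draws outside are rejected
.param_bounds <- list(
  f      = c(0, 1),
  d_slow = c(0, Inf),
  d_fast = c(0, Inf),
  adc    = c(0, Inf)
)

.model_params <- list(
  IVIM = c("f", "d_slow", "d_fast"),
  ADC  = "adc"
)

#' Tissue characterisation: generative model and parameter distribution
#'
#' Describes one tissue type by a generative signal model (IVIM or ADC) and
#' an independent Gaussian distribution for each of its parameters
#' (mean and standard deviation, in mm^2/s for diffusivities). Draws that
#' violate physical bounds (`f` outside \[0, 1\], negative diffusivities)
#' are rejected and redrawn at sampling time, so the effective per-parameter
#' distribution is a truncated Gaussian.
#'
#' @param label Tissue name, e.g. `"Healthy"` or `"Chronic"`.
#' @param model Generative model identifier: `"IVIM"` or `"ADC"`.
#' @param means Named numeric vector/list of parameter means. Names must be
#'   exactly the model's parameters (`f`, `d_slow`, `d_fast` for IVIM;
#'   `adc` for ADC).
#' @param sds Named numeric vector/list of standard deviations with the same
#'   names; each >= 0. An SD of 0 makes every subject identical to the mean.
#' @return An object of class `tissue_distribution`.
#' @examples
#' tissue_distribution("Healthy", "IVIM",
#'                     means = c(f = 0.09, d_slow = 0.35e-3, d_fast = 123e-3),
#'                     sds   = c(f = 0, d_slow = 0, d_fast = 0))
#' @export
tissue_distribution <- function(label, model, means, sds) {
  model <- match.arg(toupper(model), names(.model_params))
  wanted <- .model_params[[model]]
  means <- unlist(means)[wanted]
  sds <- unlist(sds)[wanted]
  if (anyNA(means) || anyNA(sds)) {
    stop(sprintf("tissue '%s': means and sds must both name exactly: %s",
                 label, paste(wanted, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(means)) || !all(is.finite(sds)) || any(sds < 0)) {
    stop(sprintf("tissue '%s': means must be finite and sds finite, >= 0",
                 label), call. = FALSE)
  }
  structure(list(label = as.character(label), model = model,
                 param_means = means, param_sds = sds),
            class = "tissue_distribution")
}

#' @export
print.tissue_distribution <- function(x, ...) {
  cat(sprintf("Tissue '%s' [%s]:\n", x$label, x$model))
  for (p in names(x$param_means)) {
    cat(sprintf("  %-7s %g +/- %g\n", p, x$param_means[[p]],
                x$param_sds[[p]]))
  }
  invisible(x)
}

#' Cohort specification
#'
#' Combines two tissue characterisations with an acquisition protocol,
#' per-tissue cohort size, and a root RNG seed into a complete recipe for
#' synthesising one two-class cohort.
#'
#' @param tissues List of exactly two [tissue_distribution] objects with
#'   distinct labels.
#' @param n_per_tissue Subjects simulated per tissue, integer >= 2.
#' @param protocol An [acquisition_protocol].
#' @param seed Integer root RNG seed; the cohort is a pure function of the
#'   spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(tissues, n_per_tissue, protocol, seed) {
  if (length(tissues) != 2L ||
      !all(vapply(tissues, inherits, logical(1), "tissue_distribution"))) {
    stop("`tissues` must be a list of exactly two tissue_distribution objects",
         call. = FALSE)
  }
  labels <- vapply(tissues, `[[`, character(1), "label")
  if (labels[1] == labels[2]) {
    stop("the two tissue labels must be distinct", call. = FALSE)
  }
  n_per_tissue <- as.integer(n_per_tissue)
  if (is.na(n_per_tissue) || n_per_tissue < 2L) {
    stop("`n_per_tissue` must be an integer >= 2", call. = FALSE)
  }
  if (!inherits(protocol, "acquisition_protocol")) {
    stop("`protocol` must be an acquisition_protocol", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(tissues = tissues, n_per_tissue = n_per_tissue,
                 protocol = protocol, seed = seed),
            class = "cohort_spec")
}

#' Draw per-subject parameters from a tissue distribution
#'
#' Samples `n` parameter sets from the tissue's independent Gaussians,
#' rejecting and redrawing any value outside its physical domain (truncated
#' Gaussian sampling). If for any parameter the Gaussian places less than
#' 1e-3 of its mass inside the physical domain, the distribution is deemed
#' misconfigured and an error is raised rather than looping.
#'
#' @param dist A [tissue_distribution].
#' @param n Number of subjects to draw, >= 1.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage reproducibility themselves).
#' @return Data frame with `n` rows and one column per model parameter; the
#'   attribute `acceptance_prob` records the per-parameter analytic
#'   probability mass inside the physical bounds.
#' @examples
#' d <- tissue_distribution("Inflamed", "IVIM",
#'                          means = c(f = 0.07, d_slow = 1.91e-3, d_fast = 24.2e-3),
#'                          sds   = c(f = 0.08, d_slow = 0.56e-3, d_fast = 28.5e-3))
#' draw_tissue_parameters(d, 5, seed = 1)
#' @export
draw_tissue_parameters <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "tissue_distribution"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(dist$param_means))
  names(out) <- names(dist$param_means)
  accept <- numeric(length(out))
  names(accept) <- names(out)
  for (p in names(out)) {
    mu <- dist$param_means[[p]]
    sd <- dist$param_sds[[p]]
    lo <- .param_bounds[[p]][1]
    hi <- .param_bounds[[p]][2]
    if (sd == 0) {
      if (mu < lo || mu > hi) {
        stop(sprintf("tissue '%s': mean of '%s' (%g) violates [%g, %g]",
                     dist$label, p, mu, lo, hi), call. = FALSE)
      }
      accept[p] <- 1
      out[[p]] <- rep(mu, n)
      next
    }
    accept[p] <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
    if (accept[p] < 1e-3) {
      stop(sprintf(
        "tissue '%s': distribution of '%s' (%g +/- %g) has mass %.2g inside [%g, %g]; rejection sampling infeasible",
        dist$label, p, mu, sd, accept[p], lo, hi), call. = FALSE)
    }
    x <- rnorm(n, mu, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad) > 0L) {
      x[bad] <- rnorm(length(bad), mu, sd)
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    out[[p]] <- x
  }
  res <- as.data.frame(out)
  attr(res, "acceptance_prob") <- accept
  res
}

#' Corrupt a noise-free signal with Rician noise
#'
#' Applies element-wise independent Rician corruption:
#' \deqn{S_{noisy} = \sqrt{N(S, \sigma^2)^2 + N(0, \sigma^2)^2}}
#' with \eqn{\sigma = S_0 / SNR}. Inputs are normalised signals
#' (\eqn{S_0 = 1}), so \eqn{\sigma = 1/SNR}.
#'
#' @param signal Noise-free normalised signal: numeric vector or matrix,
#'   finite and >= 0.
#' @param snr Effective signal-to-noise ratio at `b = 0`, > 0.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Noisy signal of the same shape; all values >= 0.
#' @examples
#' s <- ivim_signal(ivim_params(0.1, 0.4e-3, 120e-3), c(0, 100, 600))
#' add_rician_noise(s, snr = 20, seed = 1)
#' @export
add_rician_noise <- function(signal, snr, seed = NULL) {
  if (length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    stop("`snr` must be a single finite value > 0", call. = FALSE)
  }
  if (!all(is.finite(signal)) || any(signal < 0)) {
    stop("`signal` must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  n <- length(signal)
  noisy <- sqrt(rnorm(n, as.vector(signal), sigma)^2 + rnorm(n, 0, sigma)^2)
  if (is.matrix(signal)) dim(noisy) <- dim(signal)
  noisy
}

#' Synthesise a two-tissue cohort of noisy normalised dMRI signals
#'
#' Runs the data-synthesis stage end-to-end: per-tissue parameters are drawn
#' from their (truncated) Gaussians, noise-free signals are evaluated under
#' each tissue's generative model at the protocol b-values, every sample --
#' including `b = 0` -- is corrupted with Rician noise at
#' \eqn{\sigma = 1/SNR}, and each subject's signal is divided by its own
#' measured noisy `b = 0` value (the first `b = 0` sample if several),
#' mimicking real-world normalisation where the true \eqn{S_0} is unknown.
#'
#' The root seed deterministically spawns three sub-seeds (parameter draws
#' for each tissue, then noise), so the cohort is a pure function of the
#' spec.
#'
#' @param spec A [cohort_spec].
#' @return An object of class `dmri_cohort`: a list with `protocol`,
#'   `subjects` (data frame: `subject_id`, `tissue`, `model`, and the true
#'   drawn parameters, `NA` for parameters absent from a tissue's model),
#'   and `signals` (numeric matrix, one row per subject, one column per
#'   b-value, named `b_<value>`).
#' @examples
#' prot <- acquisition_protocol(c(0, 100, 300, 600), snr = 50)
#' t1 <- tissue_distribution("Normal", "ADC", c(adc = 0.92e-3), c(adc = 0.26e-3))
#' t2 <- tissue_distribution("Inflamed", "ADC", c(adc = 1.91e-3), c(adc = 0.56e-3))
#' synthesize_cohort(cohort_spec(list(t1, t2), 10, prot, seed = 42))
#' @export
synthesize_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- spec$protocol$b_values
  b0_col <- which(b == 0)[1]
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max, 3L)

  all_params <- vector("list", 2L)
  noisefree <- vector("list", 2L)
  for (i in 1:2) {
    tis <- spec$tissues[[i]]
    pars <- draw_tissue_parameters(tis, spec$n_per_tissue,
                                   seed = sub_seeds[i])
    sig <- matrix(NA_real_, spec$n_per_tissue, length(b))
    for (s in seq_len(spec$n_per_tissue)) {
      sig[s, ] <- if (tis$model == "IVIM") {
        ivim_signal(ivim_params(pars$f[s], pars$d_slow[s], pars$d_fast[s]), b)
      } else {
        adc_signal(adc_params(pars$adc[s]), b)
      }
    }
    all_params[[i]] <- pars
    noisefree[[i]] <- sig
  }

  signals <- do.call(rbind, noisefree)
  signals <- add_rician_noise(signals, spec$protocol$snr,
                              seed = sub_seeds[3])
  signals <- signals / signals[, b0_col]
  colnames(signals) <- paste0("b_", format(b, trim = TRUE,
                                           scientific = FALSE))

  param_cols <- unique(unlist(lapply(all_params, names)))
  subjects <- data.frame(
    subject_id = seq_len(2L * spec$n_per_tissue),
    tissue = rep(vapply(spec$tissues, `[[`, character(1), "label"),
                 each = spec$n_per_tissue),
    model = rep(vapply(spec$tissues, `[[`, character(1), "model"),
                each = spec$n_per_tissue),
    stringsAsFactors = FALSE
  )
  for (p in param_cols) {
    subjects[[p]] <- c(
      if (p %in% names(all_params[[1]])) all_params[[1]][[p]]
      else rep(NA_real_, spec$n_per_tissue),
      if (p %in% names(all_params[[2]])) all_params[[2]][[p]]
      else rep(NA_real_, spec$n_per_tissue)
    )
  }

  structure(list(protocol = spec$protocol, subjects = subjects,
                 signals = signals,
                 acceptance_prob = lapply(all_params, attr,
                                          "acceptance_prob")),
            class = "dmri_cohort")
}

#' @export
print.dmri_cohort <- function(x, ...) {
  tab <- table(x$subjects$tissue)
  cat("dMRI cohort:", nrow(x$signals), "subjects (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      ") x", ncol(x$signals), "b-values; SNR", x$protocol$snr, "\n")
  invisible(x)
}

#' Export a cohort to a flat CSV file
#'
#' One row per subject: tissue label, generative model, true parameters, and
#' the noisy normalised signal values keyed by b-value.
#'
#' @param cohort A `dmri_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "dmri_cohort"))
  utils::write.csv(cbind(cohort$subjects, as.data.frame(cohort$signals)),
                   path, row.names = FALSE)
  invisible(path)
}
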