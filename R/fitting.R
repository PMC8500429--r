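#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

.fit_methods <- c("wLS-ADC", "sNLLS-IVIM", "bcNLLS-IVIM")

#' Fitting configuration
#'
#' Settings for one parameter-estimation method. Three methods are
#' available:
#' \describe{
#'   \item{`wLS-ADC`}{weighted least-squares linear regression of the
#'     log-transformed signal on b; weights are the squared measured
#'     signals (variance-stabilising for log-transformed data); ADC is
#'     minus the slope and the intercept is discarded. Single-shot and
#'     non-iterative.}
#'   \item{`sNLLS-IVIM`}{segmented IVIM fit: a mono-exponential NLLS on
#'     samples with `b >= b_threshold` estimates `d_slow` (its amplitude
#'     is discarded), then `(f, d_fast)` are estimated by bounded NLLS on
#'     all samples with `d_slow` held fixed.}
#'   \item{`bcNLLS-IVIM`}{simultaneous bound-constrained NLLS over
#'     `(f, d_slow, d_fast)` on all samples.}
#' }
#' Iterative fits use a Levenberg-Marquardt trust-region optimiser with box
#' bounds; non-convergence is flagged on the result, never raised, so a
#' whole cohort can be fitted without interruption.
#'
#' @param method One of `"wLS-ADC"`, `"sNLLS-IVIM"`, `"bcNLLS-IVIM"`.
#' @param bounds Named list of closed intervals for the IVIM parameters.
#'   Defaults: `f` in \[0, 1\], `d_fast` in \[0, 0.5\] mm^2/s, `d_slow` in
#'   \[0, 0.01\] mm^2/s.
#' @param b_threshold Segmentation threshold in s/mm^2 (sNLLS only);
#'   must lie strictly between the smallest and largest non-zero protocol
#'   b-values at fit time.
#' @param seed_params Named vector of initial values `(f, d_slow, d_fast)`
#'   for the iterative fits. `NULL` (default) falls back to the midpoint of
#'   the bounds; [run_experiment] replaces this with the arithmetic mean of
#'   the two tissues' distribution means, mimicking experiments in which
#'   individual patient classification is unknown.
#' @param ftol Relative cost-reduction convergence tolerance.
#' @param maxiter Maximum optimiser iterations.
#' @param b_subset Optional numeric vector restricting the fit to a subset
#'   of protocol b-values (e.g. an ADC sub-scheme); `NULL` uses all.
#' @return An object of class `fit_config`.
#' @examples
#' fit_config("sNLLS-IVIM", b_threshold = 50)
#' @export
fit_config <- function(method = c("wLS-ADC", "sNLLS-IVIM", "bcNLLS-IVIM"),
                       bounds = list(f = c(0, 1), d_slow = c(0, 10e-3),
                                     d_fast = c(0, 500e-3)),
                       b_threshold = 200, seed_params = NULL,
                       ftol = 1e-8, maxiter = 200, b_subset = NULL) {
  method <- match.arg(method)
  for (p in c("f", "d_slow", "d_fast")) {
    bi <- bounds[[p]]
    if (is.null(bi) || length(bi) != 2L || !all(is.finite(bi)) ||
        bi[1] >= bi[2]) {
      stop(sprintf("`bounds$%s` must be a non-empty finite interval", p),
           call. = FALSE)
    }
  }
  if (!is.null(seed_params)) {
    seed_params <- unlist(seed_params)[c("f", "d_slow", "d_fast")]
    if (anyNA(seed_params)) {
      stop("`seed_params` must name f, d_slow and d_fast", call. = FALSE)
    }
  }
  structure(list(method = method, bounds = bounds,
                 b_threshold = as.numeric(b_threshold),
                 seed_params = seed_params,
                 ftol = ftol, maxiter = as.integer(maxiter),
                 b_subset = b_subset),
            class = "fit_config")
}

.default_seed <- function(config) {
  if (!is.null(config$seed_params)) return(config$seed_params)
  vapply(config$bounds[c("f", "d_slow", "d_fast")], mean, numeric(1))
}

.fit_result <- function(estimates, converged, residual_norm, method) {
  structure(list(estimates = estimates, converged = converged,
                 residual_norm = residual_norm, method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (%s): ", x$method,
              if (x$converged) "converged" else "NOT converged"))
  cat(paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
            collapse = ", "),
      sprintf("; rss = %.3g\n", x$residual_norm))
  invisible(x)
}

.apply_b_subset <- function(b_values, signal, config) {
  if (is.null(config$b_subset)) return(list(b = b_values, s = signal))
  keep <- b_values %in% config$b_subset
  list(b = b_values[keep], s = signal[keep])
}

#' Weighted least-squares ADC fit on the log-transformed signal
#'
#' Regresses `log(signal)` on `b` with per-point weights equal to the
#' squared measured signal, which stabilises the noise variance after the
#' log transform; the ADC estimate is minus the slope and the intercept is
#' discarded (signals are already normalised; the `b = 0` point
#' participates in the regression). Non-positive signal values, for which
#' the log is undefined, are dropped sample-wise; if fewer than two samples
#' at distinct b-values remain the fit is flagged as failed.
#'
#' @param b_values Protocol b-values, s/mm^2.
#' @param signal Measured normalised signal, one value per b-value.
#' @param config A [fit_config] with method `"wLS-ADC"` (a default one is
#'   built if omitted).
#' @return A `fit_result` with an `adc` estimate (mm^2/s); the residual
#'   norm is the weighted sum of squared log-domain residuals.
#' @examples
#' b <- c(0, 50, 100, 300, 600)
#' fit_wls_adc(b, adc_signal(adc_params(1.2e-3), b))
#' @export
fit_wls_adc <- function(b_values, signal, config = fit_config("wLS-ADC")) {
  sub <- .apply_b_subset(b_values, signal, config)
  b <- sub$b; s <- sub$s
  keep <- is.finite(s) & s > 0
  b <- b[keep]; s <- s[keep]
  if (length(s) < 2L || length(unique(b)) < 2L) {
    return(.fit_result(c(adc = NA_real_), FALSE, NA_real_, "wLS-ADC"))
  }
  y <- log(s)
  w <- s^2
  wsum <- sum(w)
  bbar <- sum(w * b) / wsum
  ybar <- sum(w * y) / wsum
  slope <- sum(w * (b - bbar) * (y - ybar)) / sum(w * (b - bbar)^2)
  intercept <- ybar - slope * bbar
  rss <- sum(w * (y - intercept - slope * b)^2)
  .fit_result(c(adc = -slope), TRUE, rss, "wLS-ADC")
}

.ivim_model <- function(p, b) {
  p[1] * exp(-b * (p[3] + p[2])) + (1 - p[1]) * exp(-b * p[2])
}

.run_nlslm <- function(par, lower, upper, fn, config) {
  tryCatch({
    fit <- nls.lm(par = par, lower = lower, upper = upper, fn = fn,
                  control = nls.lm.control(ftol = config$ftol,
                                           maxiter = config$maxiter))
    list(par = fit$par, converged = fit$info %in% 1:4,
         rss = fit$deviance)
  }, error = function(e) list(par = par, converged = FALSE, rss = NA_real_))
}

#' Segmented NLLS IVIM fit
#'
#' Two-step IVIM estimation. Step 1 fits a mono-exponential
#' `A * exp(-b * d_slow)` by NLLS (linear-domain residuals) to the samples
#' with `b >= b_threshold`, where the perfusion compartment has decayed
#' away; the amplitude `A` is discarded. Step 2 holds `d_slow` fixed and
#' fits `(f, d_fast)` by bounded NLLS on all samples against the full
#' bi-exponential model. The threshold should be chosen from the expected
#' tissue properties (`f`, `d_fast`): too low a threshold leaks perfusion
#' signal into step 1 and biases `d_slow` upwards.
#'
#' @inheritParams fit_wls_adc
#' @param config A [fit_config] with method `"sNLLS-IVIM"`; its
#'   `b_threshold` must lie strictly between the smallest and largest
#'   non-zero b-values.
#' @return A `fit_result` with estimates `(f, d_slow, d_fast)` inside the
#'   configured bounds; `converged` is `TRUE` only if both steps converged.
#' @examples
#' b <- c(0, 10, 20, 40, 80, 100, 200, 400, 600)
#' s <- ivim_signal(ivim_params(0.12, 0.35e-3, 123e-3), b)
#' fit_snlls_ivim(b, s, fit_config("sNLLS-IVIM", b_threshold = 50))
#' @export
fit_snlls_ivim <- function(b_values, signal,
                           config = fit_config("sNLLS-IVIM")) {
  sub <- .apply_b_subset(b_values, signal, config)
  b <- sub$b; s <- sub$s
  bt <- config$b_threshold
  nz <- b[b > 0]
  if (!(bt > min(nz) && bt < max(nz))) {
    stop("`b_threshold` must lie strictly between the smallest and largest non-zero b-values",
         call. = FALSE)
  }
  hi <- b >= bt
  if (sum(hi) < 2L) {
    stop("sNLLS needs >= 2 samples at b >= b_threshold", call. = FALSE)
  }
  seed <- .default_seed(config)
  bd <- config$bounds
  b_hi <- b[hi]; s_hi <- s[hi]
  step1 <- .run_nlslm(
    par = c(1, seed[["d_slow"]]),
    lower = c(0, bd$d_slow[1]), upper = c(Inf, bd$d_slow[2]),
    fn = function(p) p[1] * exp(-b_hi * p[2]) - s_hi,
    config = config
  )
  d_slow <- step1$par[2]
  step2 <- .run_nlslm(
    par = c(seed[["f"]], seed[["d_fast"]]),
    lower = c(bd$f[1], bd$d_fast[1]), upper = c(bd$f[2], bd$d_fast[2]),
    fn = function(p) .ivim_model(c(p[1], d_slow, p[2]), b) - s,
    config = config
  )
  .fit_result(c(f = step2$par[1], d_slow = d_slow, d_fast = step2$par[2]),
              step1$converged && step2$converged, step2$rss, "sNLLS-IVIM")
}

#' Bound-constrained NLLS IVIM fit
#'
#' Simultaneous bounded NLLS over `(f, d_slow, d_fast)` against the
#' bi-exponential IVIM model on all samples, started from
#' `config$seed_params`.
#'
#' @inheritParams fit_wls_adc
#' @param config A [fit_config] with method `"bcNLLS-IVIM"`.
#' @return A `fit_result` with estimates `(f, d_slow, d_fast)` inside the
#'   configured bounds.
#' @examples
#' b <- c(0, 10, 20, 40, 80, 100, 200, 400, 600)
#' s <- ivim_signal(ivim_params(0.09, 0.35e-3, 123e-3), b)
#' fit_bcnlls_ivim(b, s)
#' @export
fit_bcnlls_ivim <- function(b_values, signal,
                            config = fit_config("bcNLLS-IVIM")) {
  sub <- .apply_b_subset(b_values, signal, config)
  b <- sub$b; s <- sub$s
  if (length(s) < 4L) {
    stop("bcNLLS needs >= 4 samples", call. = FALSE)
  }
  seed <- .default_seed(config)
  bd <- config$bounds
  fit <- .run_nlslm(
    par = c(seed[["f"]], seed[["d_slow"]], seed[["d_fast"]]),
    lower = c(bd$f[1], bd$d_slow[1], bd$d_fast[1]),
    upper = c(bd$f[2], bd$d_slow[2], bd$d_fast[2]),
    fn = function(p) .ivim_model(p, b) - s,
    config = config
  )
  .fit_result(c(f = fit$par[1], d_slow = fit$par[2], d_fast = fit$par[3]),
              fit$converged, fit$rss, "bcNLLS-IVIM")
}

.fit_one <- function(b, s, config) {
  switch(config$method,
         "wLS-ADC" = fit_wls_adc(b, s, config),
         "sNLLS-IVIM" = fit_snlls_ivim(b, s, config),
         "bcNLLS-IVIM" = fit_bcnlls_ivim(b, s, config))
}

#' Fit every subject in a cohort
#'
#' Applies one fitting method to each subject's signal, preserving subject
#' order. Failed/non-converged fits are flagged and retained (dropping them
#' would bias downstream ROC curves); a summary count is reported via
#' `message()` when any occur.
#'
#' @param cohort A `dmri_cohort` from [synthesize_cohort].
#' @param config A [fit_config].
#' @param quiet Suppress the non-convergence summary message.
#' @return Data frame with one row per subject: `subject_id`, `tissue`,
#'   `method`, the estimate columns for the fitted model, `converged`, and
#'   `residual_norm`.
#' @examples
#' prot <- acquisition_protocol(c(0, 100, 300, 600), snr = 50)
#' t1 <- tissue_distribution("A", "ADC", c(adc = 1.0e-3), c(adc = 0.1e-3))
#' t2 <- tissue_distribution("B", "ADC", c(adc = 1.4e-3), c(adc = 0.1e-3))
#' coh <- synthesize_cohort(cohort_spec(list(t1, t2), 5, prot, seed = 1))
#' fit_cohort(coh, fit_config("wLS-ADC"))
#' @export
fit_cohort <- function(cohort, config, quiet = FALSE) {
  stopifnot(inherits(cohort, "dmri_cohort"), inherits(config, "fit_config"))
  b <- cohort$protocol$b_values
  n <- nrow(cohort$signals)
  if (n == 0L) {
    return(data.frame(subject_id = integer(), tissue = character(),
                      method = character(), converged = logical(),
                      residual_norm = numeric()))
  }
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- .fit_one(b, cohort$signals[i, ], config)
  }
  est <- do.call(rbind, lapply(fits, `[[`, "estimates"))
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    tissue = cohort$subjects$tissue,
                    method = config$method,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(est))
  out$converged <- vapply(fits, `[[`, logical(1), "converged")
  out$residual_norm <- vapply(fits, `[[`, numeric(1), "residual_norm")
  n_bad <- sum(!out$converged)
  if (n_bad > 0L && !quiet) {
    message(sprintf("fit_cohort [%s]: %d of %d fits did not converge (flagged, retained)",
                    config$method, n_bad, n))
  }
  out
}
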