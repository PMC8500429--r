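b9 <- c(0, 10, 20, 40, 80, 100, 200, 400, 600)

test_that("wLS ADC regression is exact on log-linear data and matches lm", {
  # noise-free mono-exponential data: exact recovery
  for (adc in c(0.3e-3, 1.0e-3, 1.91e-3)) {
    fit <- fit_wls_adc(b9, adc_signal(adc_params(adc), b9))
    expect_true(fit$converged)
    expect_equal(fit$estimates[["adc"]], adc, tolerance = 1e-10)
  }

  # two points interpolate regardless of weights
  fit2 <- fit_wls_adc(c(0, 1000), c(1, exp(-1)))
  expect_equal(fit2$estimates[["adc"]], 1.0e-3, tolerance = 1e-12)

  # noisy data: slope equals the weighted normal-equations solution as
  # computed by stats::lm (independent route) to machine precision
  set.seed(21)
  s <- add_rician_noise(adc_signal(adc_params(1.2e-3), b9), snr = 20)
  fit <- fit_wls_adc(b9, s)
  oracle <- stats::lm(log(s) ~ b9, weights = s^2)
  expect_equal(fit$estimates[["adc"]], -unname(coef(oracle)[2]),
               tolerance = 1e-12)

  # non-positive samples are dropped; too few survivors flags failure
  s_bad <- c(1, 0.9, -0.1, 0.8, 0, 0.6, 0.4, 0.2, 0.1)
  fit <- fit_wls_adc(b9, s_bad)
  expect_true(fit$converged)
  oracle <- stats::lm(log(s_bad[s_bad > 0]) ~ b9[s_bad > 0],
                      weights = s_bad[s_bad > 0]^2)
  expect_equal(fit$estimates[["adc"]], -unname(coef(oracle)[2]),
               tolerance = 1e-12)
  all_bad <- fit_wls_adc(b9, c(1, rep(-1, 8)))
  expect_false(all_bad$converged)
  expect_true(is.na(all_bad$estimates[["adc"]]))
})

test_that("ADC fitted to bi-exponential data is biased above d_slow", {
  # lesion-like parameters: perfusion inflates the apparent diffusivity
  s <- ivim_signal(ivim_params(0.12, 0.60e-3, 123e-3), b9)
  fit <- fit_wls_adc(b9, s)
  expect_gt(fit$estimates[["adc"]], 0.60e-3)
})

test_that("segmented NLLS recovers noise-free IVIM parameters", {
  cfg <- fit_config("sNLLS-IVIM", b_threshold = 50,
                    seed_params = c(f = 0.1, d_slow = 0.5e-3,
                                    d_fast = 100e-3))

  # f = 0: pure mono-exponential
  s0 <- ivim_signal(ivim_params(0, 0.8e-3, 100e-3), b9)
  fit0 <- fit_snlls_ivim(b9, s0, cfg)
  expect_equal(fit0$estimates[["d_slow"]], 0.8e-3, tolerance = 1e-6)
  expect_lt(fit0$estimates[["f"]], 1e-6)

  # lesion-like parameters, threshold 50: all three within 1% of truth
  truth <- c(f = 0.12, d_slow = 0.35e-3, d_fast = 123e-3)
  s <- ivim_signal(ivim_params(truth[1], truth[2], truth[3]), b9)
  fit <- fit_snlls_ivim(b9, s, cfg)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[names(truth)] / truth), rep(1, 3),
               tolerance = 0.01)

  # agrees with the grid-search + simplex oracle at the cost minimum
  oracle <- grid_ivim_fit(b9, s)
  expect_equal(unname(fit$estimates["d_slow"]), unname(oracle["d_slow"]),
               tolerance = 0.01)

  expect_error(fit_snlls_ivim(b9, s, fit_config("sNLLS-IVIM",
                                                b_threshold = 700)),
               "strictly between")
})

test_that("bound-constrained NLLS recovers noise-free IVIM parameters", {
  cfg <- fit_config("bcNLLS-IVIM",
                    seed_params = c(f = 0.105, d_slow = 0.35e-3,
                                    d_fast = 123e-3))
  truth <- c(f = 0.09, d_slow = 0.35e-3, d_fast = 123e-3)
  s <- ivim_signal(ivim_params(truth[1], truth[2], truth[3]), b9)
  fit <- fit_bcnlls_ivim(b9, s, cfg)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates / truth), rep(1, 3), tolerance = 0.01)

  # seed exactly at the truth: stationary point, zero residual
  cfg_t <- fit_config("bcNLLS-IVIM", seed_params = truth)
  fit_t <- fit_bcnlls_ivim(b9, s, cfg_t)
  expect_equal(unname(fit_t$estimates), unname(truth), tolerance = 1e-8)
  expect_lt(fit_t$residual_norm, 1e-20)

  # constant signal: d_slow pinned to ~0 and the curve stays ~1
  fit_c <- fit_bcnlls_ivim(b9, rep(1, 9), cfg)
  expect_lt(fit_c$estimates[["d_slow"]], 1e-6)
  expect_lt(fit_c$residual_norm, 1e-10)
})

test_that("iterative estimates always respect the configured bounds", {
  cfg_s <- fit_config("sNLLS-IVIM", b_threshold = 50)
  cfg_b <- fit_config("bcNLLS-IVIM")
  set.seed(77)
  for (i in 1:50) {
    s <- add_rician_noise(
      ivim_signal(ivim_params(runif(1), runif(1, 0, 3e-3),
                              runif(1, 0, 200e-3)), b9),
      snr = runif(1, 5, 50))
    s <- s / s[1]
    for (fit in list(fit_snlls_ivim(b9, s, cfg_s),
                     fit_bcnlls_ivim(b9, s, cfg_b))) {
      e <- fit$estimates
      expect_true(e[["f"]] >= 0 && e[["f"]] <= 1)
      expect_true(e[["d_slow"]] >= 0 && e[["d_slow"]] <= 10e-3)
      expect_true(e[["d_fast"]] >= 0 && e[["d_fast"]] <= 500e-3)
    }
  }
})

test_that("fit_cohort preserves order, determinism, and flags failures", {
  prot <- acquisition_protocol(b9, snr = 20)
  t1 <- tissue_distribution("Healthy", "IVIM",
                            c(f = 0.09, d_slow = 0.35e-3, d_fast = 123e-3),
                            c(f = 0, d_slow = 0, d_fast = 0))
  t2 <- tissue_distribution("Chronic", "IVIM",
                            c(f = 0.12, d_slow = 0.35e-3, d_fast = 123e-3),
                            c(f = 0, d_slow = 0, d_fast = 0))
  coh <- synthesize_cohort(cohort_spec(list(t1, t2), 25, prot, seed = 9))
  cfg <- fit_config("bcNLLS-IVIM",
                    seed_params = c(f = 0.105, d_slow = 0.35e-3,
                                    d_fast = 123e-3))

  est <- fit_cohort(coh, cfg, quiet = TRUE)
  expect_equal(nrow(est), 50)
  expect_identical(est$subject_id, coh$subjects$subject_id)

  # deterministic: refitting the same cohort reproduces the estimates
  expect_identical(fit_cohort(coh, cfg, quiet = TRUE), est)

  # order invariance: permuting subjects permutes, not changes, results
  perm <- sample(seq_len(50))
  coh_p <- coh
  coh_p$subjects <- coh$subjects[perm, ]
  coh_p$signals <- coh$signals[perm, , drop = FALSE]
  est_p <- fit_cohort(coh_p, cfg, quiet = TRUE)
  reord <- est_p[match(est$subject_id, est_p$subject_id), ]
  rownames(reord) <- NULL
  expect_equal(reord, est, tolerance = 1e-14)

  # empty cohort gives an empty table
  coh0 <- coh
  coh0$subjects <- coh$subjects[0, ]
  coh0$signals <- coh$signals[0, , drop = FALSE]
  expect_equal(nrow(fit_cohort(coh0, cfg, quiet = TRUE)), 0)
})

test_that("bcNLLS yields on-average higher perfusion fractions than sNLLS", {
  cfg <- load_experiment_config(fixture_path("E2_1"))
  res <- run_experiment(cfg, n_per_tissue = 1000, quiet = TRUE)
  est <- res$estimates
  mean_f <- function(m) {
    e <- est[est$method == m, ]
    mean(e$f[!duplicated(e$subject_id)])
  }
  expect_gte(mean_f("bcNLLS-IVIM"), mean_f("sNLLS-IVIM"))
})
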