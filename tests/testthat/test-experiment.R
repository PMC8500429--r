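test_that("bundled fixture configs load with the documented settings", {
  e21 <- load_experiment_config(fixture_path("E2_1"))
  expect_equal(e21$design$protocol$b_values,
               c(0, 10, 20, 40, 80, 100, 200, 400, 600))
  expect_equal(e21$design$protocol$snr, 20)
  expect_equal(e21$design$n_per_tissue, 10000L)
  # diffusivities arrive in canonical mm^2/s
  healthy <- e21$tissues[[which(vapply(e21$tissues, `[[`, character(1),
                                       "label") == "Healthy")]]
  expect_equal(unname(healthy$param_means["d_slow"]), 0.35e-3)
  expect_equal(unname(healthy$param_means["d_fast"]), 123e-3)
  snlls <- e21$design$fits[[1]]
  expect_equal(snlls$b_threshold, 50)

  e11 <- load_experiment_config(fixture_path("E1_1"))
  expect_equal(e11$design$fits[[1]]$b_threshold, 200)
  expect_equal(e11$design$protocol$snr, 150.6)

  e14 <- load_experiment_config(fixture_path("E1_4"))
  expect_equal(e14$design$protocol$b_values, c(0, 50, 100, 300, 600))
  expect_equal(e14$design$protocol$snr, 56.3)
  expect_true("ADC-wLS_adc" %in%
                vapply(e14$design$fits, `[[`, character(1), "id"))
})

test_that("config validation reports the offending field path", {
  raw <- yaml::read_yaml(fixture_path("E2_1"))

  broken <- raw
  broken$design$snr <- NULL
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(broken, p)
  expect_error(load_experiment_config(p), "design\\.snr")

  broken <- raw
  broken$tissues[[1]]$diffusivity_unit <- NULL
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(broken, p)
  expect_error(load_experiment_config(p), "diffusivity_unit")

  broken <- raw
  broken$design$fits[[1]]$method <- "gradientdescent"
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(broken, p)
  expect_error(load_experiment_config(p), "model/method")

  broken <- raw
  broken$design$b_values <- c(10, 100, 600)
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(broken, p)
  expect_error(load_experiment_config(p), "b = 0")

  broken <- raw
  broken$design$fits[[3]]$parameter <- "f"  # f is not an ADC parameter
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(broken, p)
  expect_error(load_experiment_config(p), "not a parameter")
})

test_that("run_experiment is a pure function of the config", {
  cfg <- load_experiment_config(fixture_path("E2_1"))
  r1 <- run_experiment(cfg, n_per_tissue = 60, quiet = TRUE)
  r2 <- run_experiment(cfg, n_per_tissue = 60, quiet = TRUE)
  expect_identical(r1$auc_table, r2$auc_table)
  expect_identical(r1$estimates, r2$estimates)
  # a different seed changes the realisation
  r3 <- run_experiment(cfg, n_per_tissue = 60, seed = 999, quiet = TRUE)
  expect_false(identical(r1$auc_table$auc, r3$auc_table$auc))
})

test_that("identical tissue distributions give chance-level AUC", {
  same <- yaml_tissue("A", f = 0.10, d_slow = 0.5, d_fast = 100,
                      f_sd = 0.02)
  other <- same; other$label <- "B"
  cfg <- make_config("null-task", list(same, other),
                     b_values = c(0, 10, 50, 100, 200, 400, 600),
                     snr = 20, seed = 8, n_per_tissue = 800,
                     positive = "A", negative = "B", parameter = "adc",
                     fits = list(list(model = "ADC", method = "wLS")))
  res <- run_experiment(cfg, quiet = TRUE)
  expect_gt(res$auc_table$auc, 0.47)  # auto-orientation keeps AUC >= 0.5
  expect_lt(res$auc_table$auc, 0.55)
})

test_that("raising SNR does not hurt ADC task performance", {
  t_act <- yaml_tissue("Active", f = 0.12, d_slow = 0.60, d_fast = 123)
  t_chr <- yaml_tissue("Chronic", f = 0.12, d_slow = 0.46, d_fast = 123)
  aucs <- vapply(c(10, 150), function(snr) {
    cfg <- make_config("snr-sweep", list(t_act, t_chr),
                       b_values = c(0, 10, 20, 40, 80, 100, 200, 400, 600),
                       snr = snr, seed = 12, n_per_tissue = 500,
                       positive = "Active", negative = "Chronic",
                       parameter = "adc",
                       fits = list(list(model = "ADC", method = "wLS")))
    run_experiment(cfg, quiet = TRUE)$auc_table$auc
  }, numeric(1))
  expect_gt(aucs[2], aucs[1])
})

test_that("compare_designs ranks by AUC and reports exact ties", {
  t_act <- yaml_tissue("Active", f = 0.12, d_slow = 0.60, d_fast = 123)
  t_chr <- yaml_tissue("Chronic", f = 0.12, d_slow = 0.46, d_fast = 123)
  mk <- function(name, seed) {
    make_config(name, list(t_act, t_chr),
                b_values = c(0, 10, 20, 40, 80, 100, 200, 400, 600),
                snr = 20, seed = seed, n_per_tissue = 200,
                positive = "Active", negative = "Chronic",
                parameter = "adc",
                fits = list(list(model = "ADC", method = "wLS")))
  }
  # duplicate configs with the same seed tie exactly
  cmp <- compare_designs(list(mk("designA", 5), mk("designB", 5)),
                         quiet = TRUE)
  expect_equal(cmp$auc[1], cmp$auc[2])
  expect_true(all(cmp$tied))
  expect_equal(cmp$rank, c(1L, 1L))

  # mismatched tasks are refused
  t_oth <- yaml_tissue("Other", f = 0.12, d_slow = 0.46, d_fast = 123)
  bad <- make_config("bad", list(t_act, t_oth),
                     b_values = c(0, 10, 20, 40, 80, 100, 200, 400, 600),
                     snr = 20, seed = 5, n_per_tissue = 200,
                     positive = "Active", negative = "Other",
                     parameter = "adc",
                     fits = list(list(model = "ADC", method = "wLS")))
  expect_error(compare_designs(list(mk("designA", 5), bad)),
               "share one task")
})

test_that("fixture reruns reproduce output files byte-identically", {
  cfg <- load_experiment_config(fixture_path("E1_4"))
  dirs <- c(tempfile("runA"), tempfile("runB"))
  for (d in dirs) {
    res <- run_experiment(cfg, n_per_tissue = 40, quiet = TRUE)
    write_experiment_result(res, d, dump_cohort = TRUE)
  }
  files <- list.files(dirs[1])
  expect_true(all(c("summary.json", "estimates.csv", "cohort.csv") %in%
                    files))
  expect_setequal(files, list.files(dirs[2]))
  for (f in files) {
    a <- readBin(file.path(dirs[1], f), "raw",
                 file.size(file.path(dirs[1], f)))
    b <- readBin(file.path(dirs[2], f), "raw",
                 file.size(file.path(dirs[2], f)))
    expect_identical(a, b, label = f)
  }
})

test_that("summary quantities are recomputable from the estimate table", {
  cfg <- load_experiment_config(fixture_path("E2_2"))
  res <- run_experiment(cfg, n_per_tissue = 150, quiet = TRUE)
  est <- res$estimates
  for (id in res$auc_table$fit_id) {
    fe <- res$fits[[id]]$entry
    sub <- est[est$fit_id == id, ]
    pos <- sub[[fe$parameter]][sub$tissue == "Active"]
    neg <- sub[[fe$parameter]][sub$tissue == "Chronic"]
    expect_equal(compute_roc_auc(pos, neg)$auc,
                 res$auc_table$auc[res$auc_table$fit_id == id],
                 tolerance = 1e-12)
  }
})
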