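#' Classification task specification
#'
#' Names the two tissue labels of a binary classification task and the
#' fitted-model parameter whose estimates serve as the default
#' classification score.
#'
#' @param positive_label Tissue label treated as "diseased".
#' @param negative_label The other tissue label.
#' @param classification_parameter Name of the estimated parameter used as
#'   the score (`f`, `d_slow`, `d_fast`, or `adc`). Individual fit entries
#'   in an experiment config may override it for models that do not expose
#'   this parameter.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(positive_label, negative_label,
                      classification_parameter) {
  if (positive_label == negative_label) {
    stop("positive and negative labels must differ", call. = FALSE)
  }
  if (!classification_parameter %in% names(.param_bounds)) {
    stop(sprintf("unknown classification parameter '%s'",
                 classification_parameter), call. = FALSE)
  }
  structure(list(positive_label = as.character(positive_label),
                 negative_label = as.character(negative_label),
                 classification_parameter = classification_parameter),
            class = "task_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data frames whose estimate columns differ (ADC vs IVIM fits)
.rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  }))
}

.cfg_fail <- function(path, msg) {
  stop(sprintf("config error at `%s`: %s", path, msg), call. = FALSE)
}

.cfg_get <- function(x, field, path, required = TRUE, default = NULL) {
  if (is.null(x[[field]])) {
    if (required) .cfg_fail(paste0(path, ".", field), "missing")
    return(default)
  }
  x[[field]]
}

.unit_scale <- function(unit, path) {
  switch(unit,
         "mm^2/s" = 1,
         "1e-3 mm^2/s" = 1e-3,
         .cfg_fail(path, sprintf(
           "unknown diffusivity unit '%s' (use 'mm^2/s' or '1e-3 mm^2/s')",
           unit)))
}

.parse_tissue <- function(t, path) {
  label <- .cfg_get(t, "label", path)
  model <- toupper(.cfg_get(t, "model", path))
  if (!model %in% names(.model_params)) {
    .cfg_fail(paste0(path, ".model"),
              sprintf("unknown generative model '%s'", model))
  }
  unit <- .cfg_get(t, "diffusivity_unit", path)
  scale <- .unit_scale(unit, paste0(path, ".diffusivity_unit"))
  means <- unlist(.cfg_get(t, "means", path))
  sds <- unlist(.cfg_get(t, "sds", path))
  diff_pars <- intersect(names(means), c("d_slow", "d_fast", "adc"))
  means[diff_pars] <- means[diff_pars] * scale
  sds[intersect(names(sds), diff_pars)] <-
    sds[intersect(names(sds), diff_pars)] * scale
  tryCatch(tissue_distribution(label, model, means, sds),
           error = function(e) .cfg_fail(path, conditionMessage(e)))
}

.method_table <- data.frame(
  model = c("IVIM", "IVIM", "ADC"),
  method = c("sNLLS", "bcNLLS", "wLS"),
  fit_method = c("sNLLS-IVIM", "bcNLLS-IVIM", "wLS-ADC"),
  stringsAsFactors = FALSE
)

.parse_fit <- function(fe, path, task_param) {
  model <- toupper(.cfg_get(fe, "model", path))
  method <- .cfg_get(fe, "method", path)
  row <- .method_table[.method_table$model == model &
                         .method_table$method == method, ]
  if (nrow(row) != 1L) {
    .cfg_fail(path, sprintf(
      "unknown model/method combination '%s'/'%s'", model, method))
  }
  parameter <- .cfg_get(fe, "parameter", path, required = FALSE)
  if (is.null(parameter)) {
    parameter <- if (model == "ADC") "adc" else task_param
  }
  if (!parameter %in% .model_params[[model]]) {
    .cfg_fail(paste0(path, ".parameter"), sprintf(
      "'%s' is not a parameter of the %s model", parameter, model))
  }
  list(model = model, method = method, fit_method = row$fit_method,
       parameter = parameter,
       b_threshold = .cfg_get(fe, "b_threshold", path, required = FALSE),
       id = sprintf("%s-%s_%s", model, method, parameter))
}

#' Load and validate a declarative experiment configuration
#'
#' Reads a YAML experiment description covering the classification task, the
#' two tissue characterisations, and the candidate experimental design
#' (b-value scheme, effective SNR, fitted models and fitting methods, cohort
#' size, seed), plus optional evaluation settings (orientation mode,
#' clinical-size sub-sampling). Diffusivities are converted to the
#' canonical mm^2/s at load time according to each tissue's mandatory
#' `diffusivity_unit` field (`"mm^2/s"` or `"1e-3 mm^2/s"`), so table-style
#' values such as `0.35` (in 1e-3 mm^2/s) can be written verbatim.
#' Violations are reported with the path of the offending field.
#'
#' Bundled fixture configurations are available via
#' `system.file("extdata", ..., package = "dmriced")`: `E1_1.yaml` ...
#' `E1_4.yaml` (spondyloarthritis tasks with published tissue
#' characterisations) and `E2_1.yaml`, `E2_2.yaml` (illustrative
#' single-parameter-contrast tasks).
#'
#' @param path Path to a YAML config file.
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- load_experiment_config(
#'   system.file("extdata", "E2_1.yaml", package = "dmriced"))
#' cfg$design$protocol
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  name <- .cfg_get(raw, "name", "", required = FALSE,
                   default = tools::file_path_sans_ext(basename(path)))

  tr <- .cfg_get(raw, "task", "")
  task <- tryCatch(
    task_spec(.cfg_get(tr, "positive_label", "task"),
              .cfg_get(tr, "negative_label", "task"),
              .cfg_get(tr, "classification_parameter", "task")),
    error = function(e) .cfg_fail("task", conditionMessage(e)))

  tl <- .cfg_get(raw, "tissues", "")
  if (length(tl) != 2L) .cfg_fail("tissues", "exactly two tissues required")
  tissues <- lapply(seq_along(tl), function(i) {
    .parse_tissue(tl[[i]], sprintf("tissues[%d]", i))
  })
  labels <- vapply(tissues, `[[`, character(1), "label")
  if (!setequal(labels, c(task$positive_label, task$negative_label))) {
    .cfg_fail("task", sprintf(
      "task labels (%s, %s) must match the tissue labels (%s)",
      task$positive_label, task$negative_label,
      paste(labels, collapse = ", ")))
  }

  de <- .cfg_get(raw, "design", "")
  protocol <- tryCatch(
    acquisition_protocol(.cfg_get(de, "b_values", "design"),
                         .cfg_get(de, "snr", "design")),
    error = function(e) .cfg_fail("design", conditionMessage(e)))
  n_per_tissue <- .cfg_get(de, "n_per_tissue", "design",
                           required = FALSE, default = 10000L)
  seed <- .cfg_get(de, "seed", "design")
  fl <- .cfg_get(de, "fits", "design")
  fits <- lapply(seq_along(fl), function(i) {
    .parse_fit(fl[[i]], sprintf("design.fits[%d]", i),
               task$classification_parameter)
  })
  ids <- vapply(fits, `[[`, character(1), "id")
  if (anyDuplicated(ids)) .cfg_fail("design.fits", "duplicate fit entries")

  ev <- .cfg_get(raw, "evaluation", "", required = FALSE, default = list())
  orientation <- .cfg_get(ev, "orientation", "evaluation",
                          required = FALSE, default = "auto")
  if (!orientation %in% c("auto", "fixed")) {
    .cfg_fail("evaluation.orientation", "must be 'auto' or 'fixed'")
  }
  subsample <- .cfg_get(ev, "subsample", "evaluation", required = FALSE)
  if (!is.null(subsample)) {
    for (fld in c("n_pos", "n_neg")) {
      .cfg_get(subsample, fld, "evaluation.subsample")
    }
    subsample$repeats <- .cfg_get(subsample, "repeats",
                                  "evaluation.subsample",
                                  required = FALSE, default = 1000L)
  }

  structure(list(
    name = name, task = task, tissues = tissues,
    design = list(protocol = protocol,
                  n_per_tissue = as.integer(n_per_tissue),
                  seed = as.integer(seed), fits = fits),
    evaluation = list(orientation = orientation, subsample = subsample)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment '%s': %s vs %s on '%s'\n", x$name,
              x$task$positive_label, x$task$negative_label,
              x$task$classification_parameter))
  cat(sprintf("  %d b-values, SNR %g, n = %d per tissue, seed %d\n",
              length(x$design$protocol$b_values), x$design$protocol$snr,
              x$design$n_per_tissue, x$design$seed))
  cat("  fits:", paste(vapply(x$design$fits, `[[`, character(1), "id"),
                       collapse = ", "), "\n")
  invisible(x)
}

# cross-tissue mean of distribution means for IVIM seeding; parameters no
# tissue provides fall back to the midpoint of the fitting bounds
.seed_from_tissues <- function(tissues, bounds) {
  vapply(c("f", "d_slow", "d_fast"), function(p) {
    vals <- unlist(lapply(tissues, function(t) t$param_means[p]))
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean(vals) else mean(bounds[[p]])
  }, numeric(1))
}

#' Run one complete in-silico classification experiment
#'
#' Executes the full assessment pipeline for a declarative design: a
#' two-tissue cohort is synthesised at the design's b-values and SNR
#' (parameter draws, Rician corruption, noisy-S0 normalisation), each
#' configured fitting method is applied to every subject, and each fit
#' entry's classification parameter is scored with an ROC curve, AUC, CNR,
#' and -- when requested -- a clinically sized sub-sampled AUC
#' distribution. Iterative IVIM fits are seeded with the cross-tissue mean
#' of the two tissues' distribution means. The result is a pure function of
#' the config (including its seed).
#'
#' @param config An [experiment_config] from [load_experiment_config].
#' @param n_per_tissue,seed Optional overrides for the config values
#'   (convenience for quick, smaller, or re-seeded runs).
#' @param keep_cohort Retain the synthesised cohort in the result (default
#'   `TRUE`; set `FALSE` to save memory in batch sweeps).
#' @param quiet Suppress per-stage progress and non-convergence messages.
#' @return An object of class `dmri_experiment`: list with `config`,
#'   `cohort` (unless dropped), `estimates` (long table over all fit
#'   entries), `fits` (per-entry list: `roc`, `auc`, `cnr`, `subsample`),
#'   `auc_table` (one row per fit entry), and `diagnostics`.
#' @examples
#' cfg <- load_experiment_config(
#'   system.file("extdata", "E2_1.yaml", package = "dmriced"))
#' res <- run_experiment(cfg, n_per_tissue = 50, quiet = TRUE)
#' res$auc_table
#' @export
run_experiment <- function(config, n_per_tissue = NULL, seed = NULL,
                           keep_cohort = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(n_per_tissue)) {
    config$design$n_per_tissue <- as.integer(n_per_tissue)
  }
  if (!is.null(seed)) config$design$seed <- as.integer(seed)
  t0 <- proc.time()[["elapsed"]]

  spec <- cohort_spec(config$tissues, config$design$n_per_tissue,
                      config$design$protocol, config$design$seed)
  cohort <- synthesize_cohort(spec)
  if (!quiet) {
    message(sprintf("[P1] synthesised %d subjects (%d per tissue), SNR %g",
                    nrow(cohort$signals), config$design$n_per_tissue,
                    config$design$protocol$snr))
  }

  pos_lab <- config$task$positive_label
  neg_lab <- config$task$negative_label
  fits_out <- list()
  est_all <- list()
  auc_rows <- list()
  est_cache <- new.env(parent = emptyenv())
  for (k in seq_along(config$design$fits)) {
    fe <- config$design$fits[[k]]
    fc_args <- list(method = fe$fit_method)
    if (!is.null(fe$b_threshold)) fc_args$b_threshold <- fe$b_threshold
    fc <- do.call(fit_config, fc_args)
    fc$seed_params <- .seed_from_tissues(config$tissues, fc$bounds)
    # several fit entries may reuse one method (different score parameters)
    cache_key <- paste(fe$fit_method, fe$b_threshold %||% "default")
    if (is.null(est_cache[[cache_key]])) {
      est_cache[[cache_key]] <- fit_cohort(cohort, fc, quiet = quiet)
    }
    est <- est_cache[[cache_key]]
    est$fit_id <- fe$id
    n_bad <- sum(!est$converged)
    if (!quiet) {
      message(sprintf("[P2] %-22s %d fits, %d non-converged",
                      fe$id, nrow(est), n_bad))
    }
    scores_pos <- est[[fe$parameter]][est$tissue == pos_lab]
    scores_neg <- est[[fe$parameter]][est$tissue == neg_lab]
    ok <- is.finite(scores_pos)
    scores_pos <- scores_pos[ok]
    scores_neg <- scores_neg[is.finite(scores_neg)]
    roc <- compute_roc_auc(scores_pos, scores_neg,
                           orient = config$evaluation$orientation)
    cnr <- separability_cnr(scores_pos, scores_neg)
    ss <- NULL
    if (!is.null(config$evaluation$subsample)) {
      sub <- config$evaluation$subsample
      ss <- subsample_auc_distribution(
        scores_pos, scores_neg, sub$n_pos, sub$n_neg, sub$repeats,
        seed = (config$design$seed + 104729L + k) %% .Machine$integer.max)
    }
    if (!quiet) {
      message(sprintf("[P3] %-22s AUC = %.4f (%s), CNR = %.3f",
                      fe$id, roc$auc, roc$orientation, cnr))
    }
    fits_out[[fe$id]] <- list(entry = fe, config = fc, roc = roc,
                              auc = roc$auc, cnr = cnr, subsample = ss)
    est_all[[k]] <- est
    auc_rows[[k]] <- data.frame(
      fit_id = fe$id, model = fe$model, method = fe$method,
      parameter = fe$parameter, auc = roc$auc,
      orientation = roc$orientation, cnr = cnr,
      n_nonconverged = n_bad,
      subsample_mean = if (is.null(ss)) NA_real_ else ss$summary[["mean"]],
      subsample_sd = if (is.null(ss)) NA_real_ else ss$summary[["sd"]],
      stringsAsFactors = FALSE)
  }

  structure(list(
    config = config,
    cohort = if (keep_cohort) cohort else NULL,
    estimates = .rbind_fill(est_all),
    fits = fits_out,
    auc_table = do.call(rbind, auc_rows),
    diagnostics = list(
      acceptance_prob = cohort$acceptance_prob,
      runtime_s = proc.time()[["elapsed"]] - t0)
  ), class = "dmri_experiment")
}

#' @export
print.dmri_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%s vs %s), n = %d per tissue:\n",
              x$config$name, x$config$task$positive_label,
              x$config$task$negative_label, x$config$design$n_per_tissue))
  print(x$auc_table[, c("fit_id", "auc", "orientation", "cnr",
                        "n_nonconverged")], row.names = FALSE)
  invisible(x)
}

#' Rank competing experimental designs on predicted task performance
#'
#' Runs every supplied configuration and tabulates the AUC of each design's
#' fit entries, ranked best-first. All configs must describe the same
#' classification task (same positive/negative tissue labels). A config
#' with several fit entries contributes one row per entry, so a single
#' config can also be used to rank fitting methods against each other.
#' Exactly tied AUCs share a rank and are flagged rather than broken.
#'
#' @param configs List of [experiment_config] objects (>= 2 rows overall).
#' @param n_per_tissue,seed Optional overrides applied to every config.
#' @param quiet Suppress stage messages.
#' @return An object of class `design_comparison`: a data frame with one
#'   row per (design, fit entry), columns `design`, `fit_id`, `auc`,
#'   `subsample_sd`, `rank`, `tied`; the full results are attached as the
#'   `results` attribute.
#' @export
compare_designs <- function(configs, n_per_tissue = NULL, seed = NULL,
                            quiet = FALSE) {
  if (!all(vapply(configs, inherits, logical(1), "experiment_config"))) {
    stop("`configs` must be a list of experiment_config objects",
         call. = FALSE)
  }
  tasks <- lapply(configs, function(c) c$task[c("positive_label",
                                                "negative_label")])
  if (length(unique(tasks)) != 1L) {
    stop("all configs must share one task (same positive/negative labels)",
         call. = FALSE)
  }
  results <- lapply(configs, run_experiment, n_per_tissue = n_per_tissue,
                    seed = seed, keep_cohort = FALSE, quiet = quiet)
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    at <- results[[i]]$auc_table
    data.frame(design = configs[[i]]$name, fit_id = at$fit_id,
               auc = at$auc, subsample_sd = at$subsample_sd,
               stringsAsFactors = FALSE)
  }))
  if (nrow(rows) < 2L) {
    stop("need at least two (design, fit) entries to compare",
         call. = FALSE)
  }
  rows <- rows[order(-rows$auc), ]
  rows$rank <- rank(-rows$auc, ties.method = "min")
  rows$tied <- duplicated(rows$auc) | duplicated(rows$auc, fromLast = TRUE)
  rownames(rows) <- NULL
  structure(rows, class = c("design_comparison", "data.frame"),
            results = results)
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Design comparison (best first):\n")
  print.data.frame(x, row.names = FALSE)
  if (any(x$tied)) cat("note: exactly tied AUCs share a rank\n")
  invisible(x)
}

#' Write experiment outputs to disk
#'
#' Writes `summary.json` (config echo, AUC table, diagnostics),
#' `estimates.csv` (per-subject estimates across all fit entries), one
#' `roc_<fit>.csv` per fit entry (threshold, fpr, tpr), per-entry
#' `auc_distribution_<fit>.csv` when sub-sampling was requested, and
#' optionally `cohort.csv` (true parameters plus noisy signals).
#'
#' @param result A `dmri_experiment` from [run_experiment].
#' @param dir Output directory (created if needed).
#' @param dump_cohort Also write the synthesised cohort as CSV (requires
#'   `keep_cohort = TRUE` in [run_experiment]).
#' @return `dir`, invisibly.
#' @export
write_experiment_result <- function(result, dir, dump_cohort = FALSE) {
  stopifnot(inherits(result, "dmri_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  summary <- list(
    name = cfg$name,
    task = cfg$task[c("positive_label", "negative_label",
                      "classification_parameter")],
    design = list(b_values = cfg$design$protocol$b_values,
                  snr = cfg$design$protocol$snr,
                  n_per_tissue = cfg$design$n_per_tissue,
                  seed = cfg$design$seed),
    tissues = lapply(cfg$tissues, function(t) {
      list(label = t$label, model = t$model,
           means = as.list(t$param_means), sds = as.list(t$param_sds))
    }),
    auc_table = result$auc_table,
    # runtime is deliberately omitted so identical reruns are byte-identical
    diagnostics = list(acceptance_prob = result$diagnostics$acceptance_prob)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  for (id in names(result$fits)) {
    f <- result$fits[[id]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    utils::write.csv(
      data.frame(threshold = f$roc$thresholds, fpr = f$roc$fpr,
                 tpr = f$roc$tpr),
      file.path(dir, paste0("roc_", safe, ".csv")), row.names = FALSE)
    if (!is.null(f$subsample)) {
      utils::write.csv(data.frame(auc = f$subsample$samples),
                       file.path(dir, paste0("auc_distribution_", safe,
                                             ".csv")),
                       row.names = FALSE)
    }
  }
  if (dump_cohort) {
    if (is.null(result$cohort)) {
      stop("cohort was not retained in the result; rerun with keep_cohort = TRUE",
           call. = FALSE)
    }
    write_cohort_csv(result$cohort, file.path(dir, "cohort.csv"))
  }
  invisible(dir)
}
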