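#' @importFrom stats quantile sd
NULL

.check_scores <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(scores_pos)) || !all(is.finite(scores_neg))) {
    stop("scores must be finite", call. = FALSE)
  }
}

# rank-based AUC; identical to the trapezoidal area under the empirical ROC
# and to the Mann-Whitney U statistic with half credit for ties
.auc_rank <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

.roc_points <- function(pos, neg) {
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Builds the receiver operating characteristic curve by sweeping a decision
#' threshold across all observed score values (subjects with score >=
#' threshold are called positive) and computes the area under it by the
#' trapezoidal rule. This estimator equals the Mann-Whitney U statistic with
#' half credit for ties. With `orient = "auto"` (clinical convention),
#' scores are negated when the raw AUC falls below 0.5 so that the reported
#' AUC is always >= 0.5, and the `orientation` field records the flip; with
#' `orient = "fixed"` the scores are used as given, so that a method cannot
#' "win" a comparison by flipping sign on noise.
#'
#' @param scores_pos Scores of the positive (diseased) group.
#' @param scores_neg Scores of the negative group.
#' @param orient `"auto"` or `"fixed"`.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (descending, leading `Inf` sentinel), `fpr`, `tpr` (both non-decreasing
#'   from (0,0) to (1,1)), `auc`, and `orientation` (`"original"` or
#'   `"reversed"`).
#' @examples
#' compute_roc_auc(c(1, 3, 5), c(2, 4))$auc   # 4/6
#' @export
compute_roc_auc <- function(scores_pos, scores_neg,
                            orient = c("auto", "fixed")) {
  orient <- match.arg(orient)
  .check_scores(scores_pos, scores_neg)
  pts <- .roc_points(scores_pos, scores_neg)
  orientation <- "original"
  if (orient == "auto" && pts$auc < 0.5) {
    pts <- .roc_points(-scores_pos, -scores_neg)
    orientation <- "reversed"
  }
  structure(c(pts, list(orientation = orientation)), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f (orientation: %s)\n",
              length(x$fpr), x$auc, x$orientation))
  invisible(x)
}

#' Sub-sampled AUC distribution at clinical cohort sizes
#'
#' Repeatedly draws, without replacement, a small cohort (`n_pos` positive
#' and `n_neg` negative subjects) from the large simulated score groups and
#' records the AUC of each draw. This emulates sampling a clinical study
#' from a patient population, so the spread of the returned distribution
#' shows how much task performance measured on a study of that size can
#' deviate from the population value. Each repeat uses the orientation of
#' the full-sample curve, fixed, so sub-samples cannot flip sign
#' independently.
#'
#' @inheritParams compute_roc_auc
#' @param n_pos,n_neg Sub-sample sizes per group; at most the group sizes.
#' @param repeats Number of sub-samples to draw (default 1000).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `auc_distribution`: list with `samples`,
#'   `n_pos`, `n_neg`, `repeats`, `full_auc`, `orientation`, and `summary`
#'   (mean, SD, central 95% interval).
#' @examples
#' set.seed(7)
#' d <- subsample_auc_distribution(rnorm(500, 1), rnorm(500), 14, 14,
#'                                 repeats = 200, seed = 1)
#' d$summary
#' @export
subsample_auc_distribution <- function(scores_pos, scores_neg, n_pos, n_neg,
                                       repeats = 1000, seed = NULL) {
  .check_scores(scores_pos, scores_neg)
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  repeats <- as.integer(repeats)
  if (n_pos > length(scores_pos) || n_neg > length(scores_neg)) {
    stop("sub-sample sizes cannot exceed the group sizes", call. = FALSE)
  }
  if (n_pos < 1L || n_neg < 1L || repeats < 1L) {
    stop("`n_pos`, `n_neg` and `repeats` must be >= 1", call. = FALSE)
  }
  full <- compute_roc_auc(scores_pos, scores_neg, orient = "auto")
  if (full$orientation == "reversed") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- vapply(seq_len(repeats), function(i) {
    .auc_rank(sample(scores_pos, n_pos), sample(scores_neg, n_neg))
  }, numeric(1))
  structure(list(
    samples = samples, n_pos = n_pos, n_neg = n_neg, repeats = repeats,
    full_auc = full$auc, orientation = full$orientation,
    summary = c(mean = mean(samples), sd = sd(samples),
                lower95 = unname(quantile(samples, 0.025)),
                upper95 = unname(quantile(samples, 0.975)))
  ), class = "auc_distribution")
}

#' @export
print.auc_distribution <- function(x, ...) {
  cat(sprintf(
    "Sub-sampled AUC (%d x %d pos / %d neg): mean %.4f, SD %.4f, 95%% [%.4f, %.4f]; full-sample AUC %.4f\n",
    x$repeats, x$n_pos, x$n_neg, x$summary[["mean"]], x$summary[["sd"]],
    x$summary[["lower95"]], x$summary[["upper95"]], x$full_auc))
  invisible(x)
}

#' Contrast-to-noise ratio between two score groups
#'
#' Standardised mean difference
#' \deqn{CNR = |\bar{x}_1 - \bar{x}_2| / \sqrt{SD_1^2 + SD_2^2},}
#' a task-agnostic separability summary that can be contrasted with AUC.
#' This pooled-spread definition is the package's own working definition of
#' CNR.
#'
#' @param scores_pos,scores_neg Numeric score groups, each with >= 2 finite
#'   values.
#' @return Non-negative scalar; 0 iff the means are equal. If both groups
#'   have zero variance but different means, `Inf` is returned with a
#'   warning.
#' @examples
#' separability_cnr(c(0.9, 1.1, 1.0), c(0.1, -0.1, 0.0))
#' @export
separability_cnr <- function(scores_pos, scores_neg) {
  if (length(scores_pos) < 2L || length(scores_neg) < 2L ||
      !all(is.finite(scores_pos)) || !all(is.finite(scores_neg))) {
    stop("each group needs >= 2 finite scores", call. = FALSE)
  }
  dm <- abs(mean(scores_pos) - mean(scores_neg))
  pooled <- sqrt(sd(scores_pos)^2 + sd(scores_neg)^2)
  if (pooled == 0) {
    if (dm == 0) return(0)
    warning("zero variance in both groups with unequal means: CNR is infinite")
    return(Inf)
  }
  dm / pooled
}

#' Closed-form AUC for two Gaussian score distributions
#'
#' For scores distributed N(mu_pos, sd_pos^2) and N(mu_neg, sd_neg^2), the
#' AUC of the ideal ROC is
#' \deqn{\Phi\!\left((\mu_{pos} - \mu_{neg}) / \sqrt{\sigma_{pos}^2 + \sigma_{neg}^2}\right).}
#' Used as the binormal-limit reference when classifying on true (noise- and
#' fitting-free) parameters.
#'
#' @param mu_pos,sd_pos Mean and SD of the positive group's scores.
#' @param mu_neg,sd_neg Mean and SD of the negative group's scores.
#' @return AUC in \[0, 1\]. If both SDs are 0 the limit is 1, 0 or 0.5 by
#'   mean ordering.
#' @examples
#' gaussian_auc_closed_form(0.12, 0.02, 0.09, 0.02)
#' @export
gaussian_auc_closed_form <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (sd_pos < 0 || sd_neg < 0) stop("SDs must be >= 0", call. = FALSE)
  s <- sqrt(sd_pos^2 + sd_neg^2)
  if (s == 0) {
    return(if (mu_pos > mu_neg) 1 else if (mu_pos < mu_neg) 0 else 0.5)
  }
  pnorm((mu_pos - mu_neg) / s)
}
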