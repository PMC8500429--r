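# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# AUC by exhaustive pair counting with half credit for ties
auc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  wins / (length(pos) * length(neg))
}

# mean of a Rice(nu, sigma) variate by numerical quadrature of x * pdf(x);
# exponentially scaled Bessel avoids overflow at high SNR
rice_mean_quadrature <- function(nu, sigma) {
  pdf <- function(x) {
    z <- x * nu / sigma^2
    (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(z, 0, expon.scaled = TRUE)
  }
  stats::integrate(function(x) x * pdf(x), 0, nu + 12 * sigma,
                   rel.tol = 1e-10)$value
}

# empirical mean of a [lo, hi]-truncated Gaussian via a brute-force
# rejection sampler written independently of draw_tissue_parameters
truncnorm_rejection_mean <- function(mu, sd, lo, hi, n, seed) {
  set.seed(seed)
  kept <- numeric(0)
  while (length(kept) < n) {
    x <- rnorm(n)
    x <- mu + sd * x
    kept <- c(kept, x[x >= lo & x <= hi])
  }
  mean(kept[seq_len(n)])
}

# least-squares IVIM parameters by coarse grid search refined with
# Nelder-Mead; an optimiser-independent route to the cost minimum
grid_ivim_fit <- function(b, s,
                          f_grid = seq(0, 0.3, by = 0.01),
                          ds_grid = seq(0.05e-3, 2e-3, by = 0.05e-3),
                          df_grid = seq(10e-3, 250e-3, by = 10e-3)) {
  model <- function(p) {
    p[1] * exp(-b * (p[3] + p[2])) + (1 - p[1]) * exp(-b * p[2])
  }
  cost <- function(p) sum((model(p) - s)^2)
  best <- NULL; best_c <- Inf
  for (f in f_grid) for (ds in ds_grid) for (df in df_grid) {
    cc <- cost(c(f, ds, df))
    if (cc < best_c) { best_c <- cc; best <- c(f, ds, df) }
  }
  ref <- stats::optim(best, cost, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  stats::setNames(ref$par, c("f", "d_slow", "d_fast"))
}

# write an experiment config from R values and load it through the public
# loader, so programmatic fixtures exercise the same code path as files
make_config <- function(name, tissues, b_values, snr, seed, fits,
                        n_per_tissue = 100, positive, negative, parameter,
                        subsample = NULL) {
  cfg <- list(
    name = name,
    task = list(positive_label = positive, negative_label = negative,
                classification_parameter = parameter),
    tissues = tissues,
    design = list(b_values = b_values, snr = snr,
                  n_per_tissue = n_per_tissue, seed = seed, fits = fits),
    evaluation = c(list(orientation = "auto"),
                   if (!is.null(subsample)) list(subsample = subsample))
  )
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  load_experiment_config(path)
}

yaml_tissue <- function(label, f, d_slow, d_fast, f_sd = 0, ds_sd = 0,
                        df_sd = 0) {
  list(label = label, model = "IVIM", diffusivity_unit = "1e-3 mm^2/s",
       means = list(f = f, d_slow = d_slow, d_fast = d_fast),
       sds = list(f = f_sd, d_slow = ds_sd, d_fast = df_sd))
}

fixture_path <- function(name) {
  system.file("extdata", paste0(name, ".yaml"), package = "dmriced")
}
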