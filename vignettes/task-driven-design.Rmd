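---
title: "Task-driven assessment of dMRI experimental designs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-driven assessment of dMRI experimental designs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmriced)
```

## The problem this package addresses

Quantitative diffusion MRI (dMRI) experiments involve many design choices:
the b-value scheme, the signal model, the parameter-estimation method, and
the achievable signal-to-noise ratio. These are conventionally compared on
parameter-estimation fidelity — bias and variance of the recovered
microstructural parameters. For clinical *classification* tasks (is this
tissue healthy or diseased?) that comparison can be misleading: what
matters is the separation between the two groups' estimate distributions,
and a biased but low-variance design can separate groups better than an
unbiased, noisy one.

`dmriced` assesses designs directly on predicted task performance. For
each candidate design it simulates the complete experiment — tissue
parameter draws, signal synthesis, noise corruption, model fitting — and
scores the design with the ROC curve and AUC of the resulting classifier.
Competing designs are then ranked on AUC, optionally with sub-sampled AUC
distributions that show what a clinically sized study would measure.

## Signal models

Two direction-averaged models are supported. The intravoxel incoherent
motion (IVIM) model separates tissue water diffusion from perfusion:

$$\frac{S(b)}{S_0} = f\,e^{-b\,(D_{fast}+D_{slow})} + (1-f)\,e^{-b\,D_{slow}}$$

with perfusion fraction $f \in [0,1]$, tissue diffusivity $D_{slow}$ and
pseudo-diffusivity $D_{fast}$ (both mm²/s; note the fast compartment
decays at the *summed* rate $D_{fast}+D_{slow}$). The apparent diffusion
coefficient (ADC) model is the mono-exponential

$$\frac{S(b)}{S_0} = e^{-b\,\mathrm{ADC}}.$$

All diffusivities are held internally in mm²/s. Config files declare a
`diffusivity_unit` per tissue (`"mm^2/s"` or `"1e-3 mm^2/s"`), converted
once at load time; this makes the common literature convention (values
like 0.35 in 10⁻³ mm²/s) safe to copy verbatim while preventing silent
thousand-fold unit errors.

## Cohort synthesis

Each tissue is characterised by a generative model plus an independent
Gaussian (mean, SD) per parameter. Because literature distributions such
as $f = 0.07 \pm 0.08$ place mass outside the physical domain, draws that
violate the bounds ($f \notin [0,1]$, negative diffusivities) are rejected
and redrawn, i.e. parameters follow *truncated* Gaussians. Rejection keeps
the distribution unimodal and never feeds invalid parameters to the
forward model; if less than 0.1% of the mass is physical the configuration
is refused instead of looping. The per-parameter acceptance probability is
reported in the experiment diagnostics.

Noise is Rician, applied per measurement:

$$S_{noisy}(b) = \sqrt{\,\mathcal{N}(S_{noisefree}(b),\,\sigma^2)^2 +
\mathcal{N}(0,\,\sigma^2)^2\,}, \qquad \sigma = S_0/\mathrm{SNR},$$

with the *effective* SNR a single design input that absorbs sequence
settings and ROI averaging; one simulated subject therefore corresponds
to one mean-ROI signal, not a voxel map. Noise is applied to every sample
including $b=0$, and each subject's signal is then divided by its own
measured noisy $b=0$ value — mimicking real processing, where the true
$S_0$ is unknown. A consequence worth knowing: the normalised $b=0$
sample is exactly 1, and the effective noise on the remaining samples is
slightly non-Gaussian ratio noise.

Reproducibility: a cohort is a pure function of its spec. The root seed
spawns three derived sub-seeds (parameter draws per tissue, then the
noise field), so changing the cohort size changes individual draws but
never silently reuses a stream.

## Parameter estimation

Three fitting methods are provided; all retain and flag non-converged
fits rather than dropping subjects (exclusion would bias the ROC).

* **wLS-ADC** — linear regression of $\log S$ on $b$ with weights $S^2$
  (the measured signal squared), the standard variance-stabilising choice
  for log-transformed data; ADC is minus the slope, the intercept is
  discarded. Non-positive samples, whose log is undefined, are dropped
  sample-wise (the least-informative intervention); fewer than two
  surviving samples flags a failed fit. By default the ADC fit uses all
  protocol b-values including $b=0$; a `b_subset` option restricts it.
* **sNLLS-IVIM** — segmented fit. Step 1 estimates $D_{slow}$ (and an
  amplitude, discarded) by mono-exponential NLLS on samples with
  $b \ge b_{threshold}$; step 2 holds $D_{slow}$ fixed and estimates
  $(f, D_{fast})$ by bounded NLLS on all samples. Both steps run in the
  linear signal domain under one optimiser and one noise model; users
  comparing against log-domain step-1 variants should note this choice,
  as the step-1 variant is the main degree of freedom between published
  segmented fits. $f$ is estimated solely in step 2 (not from the step-1
  intercept). The threshold should reflect expected tissue properties:
  too low a threshold leaks perfusion signal into step 1 and biases
  $D_{slow}$ upward.
* **bcNLLS-IVIM** — simultaneous bound-constrained NLLS over all three
  IVIM parameters.

Defaults and their rationale: bounds $f \in [0,1]$,
$D_{fast} \in [0, 500]\times10^{-3}$, $D_{slow} \in [0, 10]\times10^{-3}$
mm²/s (generous physiological boxes); iterative fits are seeded with the
arithmetic mean of the two tissues' distribution means — mimicking a
real study, where the analyst knows the population but not any subject's
class — and converge when the relative cost change falls below $10^{-8}$
or after 200 iterations. The optimiser is Levenberg–Marquardt with box
constraints (`minpack.lm`); numerical Jacobians are used throughout.

## Task evaluation

Classification uses one estimated parameter as the score. The ROC curve
sweeps the decision threshold across all observed values; AUC is the
trapezoidal area, identical to the Mann–Whitney statistic with half
credit for ties (no binormal smoothing). By default orientation is
automatic — the clinical convention of reporting AUC ≥ 0.5, with the flip
recorded — while `orient = "fixed"` supports method comparisons where a
sign flip on noise must not be rewarded.

Two companions help interpretation: a contrast-to-noise ratio
$|\mu_1-\mu_2|/\sqrt{\sigma_1^2+\sigma_2^2}$ (this package's working
definition of CNR), and the binormal closed form
$\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2})$, which is the AUC limit
when scores are the true drawn parameters and truncation is negligible —
useful as an analytic cross-check of the whole stack.

Sub-sampling draws clinical-size cohorts *without replacement* from the
simulated population (modelling a small study drawn from a population;
1000 repeats by default) and reuses the full-sample orientation.

## Experiment orchestration

A YAML config declares the task (two tissue labels, classification
parameter), the tissue characterisations, and the design (b-values, SNR,
fit entries, cohort size, seed). A fit entry names a model, a method and
optionally its score parameter, so one config can rank IVIM-$f$ against
ADC classifiers on the same cohort; entries sharing a method reuse one
set of fits. `compare_designs()` expands each config into one ranked row
per fit entry and reports exact ties rather than breaking them.

Bundled fixtures encode the published spondyloarthritis classification
settings: four tasks with literature tissue distributions (including
effective SNRs 150.6 and 56.3 and their b-value schemes), and two
illustrative tasks at SNR 20 in which exactly one parameter differs
between tissues — a perfusion-fraction contrast ($f$: 0.09 vs 0.12) and a
diffusivity contrast ($D_{slow}$: 0.46 vs 0.60 ×10⁻³ mm²/s). Default
cohort size is 10,000 per tissue, large enough that sampling error in
AUC is a few 10⁻³. The clinical per-group splits behind the fixture
sub-sample sizes are not published; 14/14 (and 14/13) two-group splits
are used as documented approximations.

## What the simulations do and do not show

The generator emulates mean-ROI magnitude signals with independent
Rician noise, Gaussian (truncated) biological parameter spread, and
noisy-$S_0$ normalisation. It does not simulate voxel-wise images,
spatially correlated noise, partial-volume or ROI-delineation effects,
motion, or the TE/TR/ROI-size physics behind the effective SNR — those
are absorbed into the single SNR input. Passing tests therefore validate
the statistical pipeline under the stated generative assumptions, not
the fidelity of those assumptions to any particular scanner.

Test problem sizes are chosen to exercise the statistics at meaningful
precision while keeping the suite quick: full 10,000-per-tissue cohorts
for the headline chance-level checks, 2,000 per tissue across five seeds
for direction-of-ordering checks, 10⁶ draws for noise moments.

## Known limitations

* The within-IVIM method ranking on diffusivity-contrast tasks is
  sensitive to the segmented fit's step-1 variant. With the linear-domain
  step 1 implemented here, segmented and simultaneous fitting perform
  within statistical error of each other on the bundled diffusivity task,
  so that ranking should not be over-interpreted.
* ADC estimates from wLS are unconstrained and can be negative at very
  low attenuation; they are retained as scores (clamping would create
  artificial ties).
* The $f \cdot D_{fast}$ product is poorly identified when few low-b
  samples exist; constant signals drive $D_{slow}$ to zero while leaving
  an $f$–$D_{fast}$ degeneracy, which the bounds keep finite.
* Rician noise makes the mean measured signal exceed the noise-free
  curve at high b (the noise floor); fits inherit this bias by design,
  since real fits do too.
```{r example, eval = FALSE}
cfg <- load_experiment_config(system.file("extdata", "E2_2.yaml",
                                          package = "dmriced"))
res <- run_experiment(cfg)
res$auc_table
```
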