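# dmriced

Task-driven assessment of quantitative diffusion MRI (dMRI) experimental
designs.

When a dMRI study is planned — which b-values to acquire, which signal
model to fit, which fitting algorithm to use, what SNR to budget for —
the candidates are usually judged on how faithfully they recover
microstructural parameters. For clinical *classification* tasks that
criterion is the wrong one: a biased but precise design can separate
patient groups better than an unbiased noisy one. `dmriced` instead
simulates each candidate experiment end-to-end and scores it on the task
itself.

For a two-tissue classification task the pipeline:

1. **synthesises a cohort** — per-subject tissue parameters are drawn
   from (truncated) Gaussian tissue characterisations, noise-free signals
   are evaluated under the generative model, every sample is corrupted
   with Rician noise
   `S_noisy = sqrt(N(S, σ²)² + N(0, σ²)²)`, `σ = S0/SNR`,
   and each subject is normalised by its own noisy b = 0 measurement;
2. **fits model parameters** — weighted least-squares ADC regression on
   the log signal, segmented IVIM NLLS (`d_slow` from `b ≥ b_threshold`,
   then `(f, d_fast)`), or simultaneous bound-constrained IVIM NLLS
   (`f ∈ [0,1]`, `d_fast ∈ [0,500]·10⁻³`, `d_slow ∈ [0,10]·10⁻³` mm²/s),
   seeded with cross-tissue mean parameters;
3. **evaluates the task** — the chosen parameter estimate is swept as a
   decision threshold to build the empirical ROC curve; the trapezoidal
   AUC (= tie-corrected Mann–Whitney statistic) summarises performance,
   optionally with AUC distributions from repeated clinical-size
   sub-sampling.

The signal models are the bi-exponential intravoxel incoherent motion
(IVIM) model

    S(b)/S0 = f·exp(−b(D_fast + D_slow)) + (1−f)·exp(−b·D_slow)

and the mono-exponential apparent diffusion coefficient (ADC) model
`S(b)/S0 = exp(−b·ADC)`.

## Worked example

Six experiment configurations ship with the package, encoding published
spondyloarthritis lesion-classification settings. `E2_2.yaml` is a
diffusivity-contrast task: "Active" lesions (`D_slow = 0.60·10⁻³ mm²/s`)
vs "Chronic" lesions (`0.46·10⁻³`), identical `f = 0.12` and
`D_fast = 123·10⁻³`, SNR 20, nine b-values from 0 to 600 s/mm², with
three competing analysis designs fitted to the same IVIM-generated
cohort:

```r
library(dmriced)
cfg <- load_experiment_config(system.file("extdata", "E2_2.yaml",
                                          package = "dmriced"))
res <- run_experiment(cfg)
#> [P1] synthesised 20000 subjects (10000 per tissue), SNR 20
#> [P2] IVIM-sNLLS_d_slow      20000 fits, 1 non-converged
#> [P3] IVIM-sNLLS_d_slow      AUC = 0.7268 (original), CNR = 0.600
#> [P2] IVIM-bcNLLS_d_slow     20000 fits, 16 non-converged
#> [P3] IVIM-bcNLLS_d_slow     AUC = 0.7309 (original), CNR = 0.542
#> [P2] ADC-wLS_adc            20000 fits, 0 non-converged
#> [P3] ADC-wLS_adc            AUC = 0.7944 (original), CNR = 0.818
res$auc_table
#>              fit_id       auc orientation       cnr n_nonconverged
#>   IVIM-sNLLS_d_slow 0.7268061    original 0.6002964              1
#>  IVIM-bcNLLS_d_slow 0.7309414    original 0.5422410             16
#>         ADC-wLS_adc 0.7943972    original 0.8183759              0
```

Reading the numbers: every classifier beats chance (AUC 0.5), but the
deliberately mis-specified ADC model — biased upward because perfusion
leaks into its single decay rate — *outperforms* the generative IVIM
model's own `d_slow` estimates (AUC 0.794 vs ≈ 0.73), because its
single-parameter fit has much lower variance and the bias is shared by
both tissues. A task-agnostic bias/variance assessment would have
rejected ADC outright. On the companion perfusion-fraction task
(`E2_1.yaml`) the ranking flips and IVIM wins — design quality is
task-specific, which is the point of the package.

A thin CLI wraps the same functions:

```sh
exec/dmriced run inst/extdata/E2_1.yaml --out out/ --n-subjects 2000
exec/dmriced compare inst/extdata/E2_1.yaml inst/extdata/E2_1.yaml --out cmp/
```

`write_experiment_result()` exports a summary JSON, per-subject estimate
CSV, ROC CSVs, and sub-sampled AUC distributions; reruns with a pinned
seed reproduce all files byte-identically.

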