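# nanocluster

Quantitative analysis of nanoscale membrane-protein clustering, for
researchers working with immunogold electron microscopy of plasma-membrane
sheets and FLIM-FRET imaging — the two standard assays for Ras-family
nanocluster organisation.

Proteins such as H-ras and K-ras concentrate in transient assemblies
("nanoclusters") of <~20 nm radius, and the clustered fraction gates signal
transmission. This package provides the statistical machinery to measure
that organisation:

* **Spatial statistics for immunogold point patterns.** The edge-corrected
  univariate Ripley K-function on gold x/y coordinates inside a 1 µm²
  membrane sheet,

      K̂(r) = A n⁻² Σ_{i≠j} w_ij 1(‖x_i − x_j‖ ≤ r),      L(r) − r = √(K̂(r)/π) − r,

  on a 1–240 nm radius grid, where `w_ij` is Ripley's isotropic weight
  (inverse inside-fraction of the circle centred at `x_i` through `x_j`,
  closed form for a rectangular window). Positive `L(r) − r` means
  clustering at scale `r`.
* **Inference.** Pointwise Monte-Carlo CSR envelopes at a 99% level
  conditioned on the observed gold count; clustered/random/dispersed
  classification over a 5–100 nm report band; per-condition curve
  averaging; and a bootstrap test (integrated squared difference of group
  mean curves, pooled resampling of image-level curves, 1000 resamples)
  for comparing conditions.
* **Frequency-domain FLIM-FRET.** Reference-standard calibration
  (fluorescein, 4.0 ns), phase and modulation lifetimes
  `τ_φ = tan(φ)/ω`, `τ_m = √(1/m² − 1)/ω` at 40 MHz, per-cell means with
  principled invalid-pixel handling, and apparent FRET efficiency
  `E_app = (1 − τ_DA/τ_D) × 100%`.
* **Phenotype scoring.** The deterministic threshold rules behind common
  readouts: neurite outgrowth (> 1.5× soma), tumorsphere counting
  (≥ 50 µm), normalisation to vehicle control, densitometry ratios.
* **Synthetic data.** Generators for binomial CSR, the Thomas cluster
  process, immunogold labelling noise (efficiency, linker jitter,
  hard-core thinning), FLIM frames and FRET experiments — every analysis
  stage is validated against ground truth without any external data.

## Worked example

Fifteen control membrane sheets (spatially random, ~300 golds each)
against fifteen treated sheets with Thomas-process clustering (20 clusters
of ~15 golds, σ = 10 nm):

```r
library(nanocluster)
win <- nc_window(1000, 1000)                     # 1 um^2 sheet, nm units

ctrl  <- lapply(1:15, function(s) simulate_csr(300, win, seed = s,
                                               condition = "control"))
treat <- lapply(1:15, function(s)
  simulate_thomas(thomas_params(2e-5, 15, 10), win, seed = 100 + s,
                  condition = "treated"))

k_ctrl  <- lapply(ctrl, k_function)
k_treat <- lapply(treat, k_function)

average_curves(k_treat)
#> K-function curve: n = 4062, 240 radii in [1, 240] nm (isotropic correction)
#>  max L(r)-r in 5-100 nm band: 99.10 nm at r = 33 nm

env <- csr_envelope(treat[[1]]$n, win, n_simulations = 999,
                    level = 0.99, seed = 7)
exceeds_envelope(k_function(treat[[1]]), env)
#> envelope test: clustered (band 5-100 nm; 240 radii above, 0 below)

bootstrap_compare(k_ctrl, k_treat, n_bootstrap = 1000, seed = 7)
#> bootstrap group comparison: T = 6.233e+05 nm^3, p = 0.000999
#>   (1000 resamples, band 5-100 nm, groups 15 vs 15)
```

The treated group's averaged `L(r) − r` peaks at ~99 nm above zero at
small radii — far outside the CSR envelope, hence "clustered" — and the
bootstrap comparison against the control group is maximally significant
for 1000 resamples (add-one p-value, so p can never reach 0).

A FLIM-FRET run on a simulated experiment with a programmed 20% true
efficiency:

```r
sim <- simulate_fret_experiment(2.4, true_e = 20, n_cells = 30,
                                cell_sd = 0.1, seed = 7)
fret_efficiency(sim$donor_acceptor$tau_ns, mean(sim$donor$tau_ns))
#> apparent FRET efficiency: 21.15% +/- 0.60% (SE), 30 cells, tau_D = 2.43957 ns
```

The recovered mean (21.15%) sits within two standard errors of the
programmed truth.

See `vignettes/nanoclustering-methods.Rmd` for the full account of the
estimator, the envelope and bootstrap constructions, the FLIM physics, and
every tunable default.

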