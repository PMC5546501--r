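---
title: "Quantifying membrane protein nanoclustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane protein nanoclustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocluster)
```

Ras GTPases and many other lipid-anchored signalling proteins are not spread
uniformly over the plasma membrane: a substantial fraction resides in
transient nanoscale assemblies ("nanoclusters") of a few proteins within
radii below ~20 nm, and the clustered fraction controls signal output. Two
assays dominate the quantification of this organisation, and this package
implements the analysis machinery for both:

1. **Immunogold EM spatial mapping.** Intact plasma-membrane sheets are
   labelled with 4.5 nm gold particles against the tagged protein and imaged
   by TEM; the gold x/y coordinates inside a 1 µm² area form a spatial point
   pattern whose second-order structure is summarised by Ripley's
   K-function.
2. **FLIM-FRET.** Clustering of donor- and acceptor-tagged proteins shortens
   the donor fluorescence lifetime; frequency-domain FLIM measures that
   shortening per cell, and the apparent FRET efficiency
   $E_{app} = (1 - \tau_{DA}/\tau_D)\times 100\%$ reads out clustering in
   intact cells.

Alongside these sit deterministic phenotype scoring rules (neurite
outgrowth, tumorsphere counting, densitometry ratios) that turn measured
numbers into the percentages shown in figures. Everything is exercised on
synthetic data with known ground truth; no real micrograph is required
anywhere in the test suite.

## The K-function estimator

For $n$ points $x_1,\dots,x_n$ observed in a window of area $A$, the
estimator is

$$\hat K(r) = \frac{A}{n^2} \sum_{i \neq j} w_{ij}\,
  \mathbf{1}\!\left(\lVert x_i - x_j\rVert \le r\right),$$

evaluated by default on the integer grid $r = 1, 2, \dots, 240$ nm, with
the variance-stabilised display transform

$$L(r) - r = \sqrt{\hat K(r)/\pi} - r.$$

Under complete spatial randomness (CSR), $E[K(r)] = \pi r^2$, so $L(r)-r$
fluctuates around zero; positive excursions indicate clustering at scale
$r$, negative excursions dispersion.

**Edge correction.** $w_{ij}$ is Ripley's isotropic weight: the reciprocal
of the fraction of the circle centred at $x_i$ with radius
$\lVert x_i - x_j\rVert$ that lies inside the window. For a rectangle this
fraction has a closed form by inclusion–exclusion over the edges: each edge
at distance $d < r$ excludes an arc of $2\arccos(d/r)$, and when the circle
reaches past a corner the two adjacent exclusions overlap by
$\pi/2 - \arcsin(d_1/r) - \arcsin(d_2/r)$, which is added back. We restrict
radii to $r \le \min(W, H)/2$; in that regime opposite edges can never both
cut one circle, so the two-edge-plus-corner accounting is provably exact
(the default grid reaches 240 nm, far below the 500 nm bound of the default
window). The test suite checks the closed form against an algorithmically
independent oracle that constructs the excluded angular intervals
explicitly and measures their union, and against blind numeric sampling of
the circle.

**Numerical choices worth knowing.**

* *Pair normalisation.* The estimator divides by $n^2$, matching the form
  above. A `pair_normalisation = "unbiased"` variant divides by $n(n-1)$,
  which makes $\hat K$ exactly unbiased for a binomial process; the two
  differ by the factor $(n-1)/n$ (about −0.5 nm in $L(r)-r$ at
  $r = 200$ nm for $n = 200$). Envelope tests are unaffected by the choice
  as long as envelope and data use the same variant, because the bias
  cancels between the two.
* *Weight capping.* Isotropic weights are capped at `max_weight = 10` by
  default. A point deep in a corner at large $r$ can otherwise receive a
  weight up to 4 at the cap boundary of validity and, for pathological
  geometries, inflate the estimator's variance; the cap bounds that
  inflation and is recorded on every returned curve. Set it to `Inf` to
  reproduce the textbook estimator exactly.
* *Coincident points.* Duplicate coordinates are legal input (weight 1,
  since a circle of radius 0 is entirely interior); `validate_pattern()`
  flags pairs closer than the 4.5 nm gold diameter because physical labels
  exclude each other, but flagged patterns are analysed unchanged.
* *Unbiasedness is a K-scale property.* The suite verifies over 500 CSR
  simulations ($n = 200$) that mean $\hat K(r)$ sits within 2 SE of
  $\pi r^2$ at every grid radius. The same statement cannot hold on the
  per-pattern $L(r)-r$ scale at small $r$: the expected pair count within
  a few nm is far below 1, and the concave square root then produces a
  finite-sample transform bias (about −0.5 nm at $r = 1$ nm) that no
  estimator of this family avoids. The L-scale check is therefore posed on
  the transform of the *mean* curve, with delta-method standard errors —
  the display convention used for group averages anyway.

## Monte-Carlo envelopes

Significance of an individual pattern's $L(r)-r$ curve is judged against a
CSR envelope at confidence level 0.99: `csr_envelope()` simulates
`n_simulations` (default 999) binomial CSR patterns *conditioned on the
observed point count* — the standard practice for a single observed
pattern — computes each simulated curve, and takes pointwise empirical
quantiles at $(1-\text{level})/2$ and $1-(1-\text{level})/2$. At least
$\lceil 2/(1-\text{level})\rceil - 1$ simulations (199 for a 99% envelope)
are required so the tail quantiles are resolvable from order statistics.

The envelope is **pointwise**: it controls the error rate at each radius
separately, and its empirical coverage at a fixed radius matches the
nominal level (the acceptance script measures ~99% at $r = 50$ nm over
2000 fresh CSR patterns). Scanning the whole curve for any excursion
inflates the family-wise rate above 1%, which is why classification is
restricted to a report band (default 5–100 nm, where nanocluster signal
lives) and why a `type = "global"` maximum-deviation envelope is available
for sensitivity analysis. `exceeds_envelope()` calls a curve *clustered*
if it strictly exceeds the upper bound anywhere in the band, *dispersed*
if it strictly undercuts the lower bound, otherwise *random*; a curve
exactly on a bound is not called.

## Group averaging and the bootstrap comparison

Conditions are summarised by averaging per-image curves
(`average_curves()`), by default weighting each image by its gold count:
an image with more particles estimates K with less noise. Equal weighting
is one switch away, since averaging conventions differ between labs. On an
averaged curve `l_minus_r` is the pointwise mean of the member transforms,
not the transform of the mean K; the object records `averaged = TRUE`.

`bootstrap_compare()` tests two conditions against each other. The
observed statistic is the integrated squared difference of the group-mean
$L(r)-r$ curves over the report band (trapezoid rule, units nm³). The null
distribution pools all curves and redraws two groups of the original sizes
with replacement `n_bootstrap` times (default 1000); the p-value follows
the add-one convention $p = (1 + \#\{T^* \ge T_{obs}\})/(1 + B)$, so
$p \ge 1/(1+B)$ always and identical groups give $p = 1$ exactly. The
resampling unit is the *image-level curve*, matching the replicate
structure of the assay (independent membrane sheets); resampling
individual gold particles would ignore the strong within-image
correlation. Calibration measured over 200 replicate CSR-vs-CSR
experiments gives a rejection rate of 0.025 at the 0.05 threshold — the
pooled scheme is mildly conservative, a safe direction for a significance
claim — while CSR-vs-Thomas power at the generator defaults is essentially
100%.

## Frequency-domain FLIM and FRET

Under excitation sinusoidally modulated at $f$ (default 40 MHz,
$\omega = 2\pi f$), a mono-exponential emitter of lifetime $\tau$ responds
with phase shift $\varphi = \arctan(\omega\tau)$ and demodulation
$m = 1/\sqrt{1 + (\omega\tau)^2}$. The instrument adds a phase offset and
a demodulation scale, fixed by imaging a reference standard of known
lifetime (`flim_calibrate()`); fluorescein at 0.01 mM, pH 9 with its
literature lifetime of 4.0 ns is the conventional choice, and the
reference lifetime is an explicit, logged configuration value — never a
hidden constant. After calibration, each pixel yields two estimates,

$$\tau_\varphi = \tan(\varphi)/\omega, \qquad
  \tau_m = \frac{1}{\omega}\sqrt{1/m^2 - 1},$$

equal for mono-exponential decays and ordered
$\tau_\varphi < \tau_m$ for lifetime mixtures. Pixels whose corrected
modulation exceeds 1 or whose corrected phase leaves $[0, \pi/2)$ are
physically impossible for a decay; they are excluded and counted, never
clamped, because clamping would bias cell means toward the boundary.
`cell_mean_lifetime()` averages valid pixels under the chosen estimator —
phase by default, the common convention for FRET readouts; both are always
available, and the choice only matters on heterogeneous fields.
`fret_efficiency()` then applies
$E_{app} = (1 - \tau_{DA}/\tau_D) \times 100\%$ per cell against the mean
donor-only lifetime and reports the mean ± SE over cells.

Raw demodulation of phase-stepped image stacks is upstream of this
package's boundary (vendor software territory): inputs are per-pixel
phase/modulation maps as CSV matrices or single-channel TIFFs.

## Phenotype scoring rules

Three deterministic rules, implemented literally and configurably:

* a cell is differentiated when a neurite is **strictly longer** than 1.5×
  its soma diameter, and the differentiation percentage is taken over
  transfected (GFP-positive) cells only, warning below 100 scored cells;
* spheres count when their size is **at least** 50 µm (inclusive, per the
  assay's wording), and counts are normalised to the vehicle control as a
  percentage that may exceed 100;
* immunoblot bands are reported as band/loading-control and
  phospho/total ratios.

Sphere "size" is treated as a diameter-like scalar; whether it means
diameter or longest axis is an upstream measurement convention the rule
does not depend on. Group-level statistics on these endpoints (t-tests,
ANOVA/Tukey) belong to standard tools — the module emits numbers ready for
`t.test()` or `aov()`, and does not reimplement them.

## What the synthetic generators emulate — and what they do not

`simulate_csr()` produces the binomial null (exactly $n$ uniform points).
`simulate_thomas()` produces the clustered alternative: Poisson parents,
Poisson($\mu$) offspring per parent, isotropic Gaussian scatter $\sigma$;
Thomas rather than Matérn because the Gaussian form gives closed-form
expectations used directly in the tests ($E[N] = \kappa A \mu$; excess
$K(r) = \frac{1}{\kappa}(1 - e^{-r^2/4\sigma^2})$). Defaults — 20 expected
parents per 1 µm², 15 offspring each, $\sigma = 10$ nm, i.e. ~300 golds
per sheet — are synthetic calibration values chosen to exercise the
estimator at realistic gold densities (a few hundred particles per sheet)
and nanocluster scales; published patterns report their curves only as
figures, so these defaults are not fitted to any real dataset.
`apply_labeling()` layers the physical noise of the labelling step on any
pattern: incomplete labelling (independent thinning), antibody-linker
jitter (Gaussian displacement; points jittered out of the window are
discarded and counted), and steric exclusion between the 4.5 nm golds
(deterministic nearest-pair-first hard-core thinning, removing the
higher-index point of each offending pair).

What passing tests on these generators show is that the *pipeline* —
estimator, envelope, bootstrap — detects known structure at the stated
rates and stays calibrated under the null. What they do not show: real
membrane sheets have curvature, non-uniform labelling accessibility, and
spatially varying protein density; none of that is modelled, so agreement
here does not certify any particular biological dataset.

The FLIM generators (`simulate_flim_frame()`,
`simulate_fret_experiment()`) are exact forward models of the homodyne
relations plus Gaussian phase/modulation noise and between-cell lifetime
spread; photon-count (shot-noise) statistics and detector nonlinearity are
deliberately out of scope.

Every generator takes an explicit integer seed and is bit-reproducible
given (seed, parameters); the RNG state of the session is restored
afterwards.

## Validation problem sizes

The shipped validation uses: 50 random patterns against a literal
double-sum oracle; 500 CSR simulations for the unbiasedness check; a
999-simulation envelope scored by 2000 fresh patterns for coverage; 100
seeds for clustered-pattern detection (with 199-simulation envelopes, the
minimum resolvable count for a 99% level); 200 replicate experiments for
null calibration and 50 for power, at $B = 199$ bootstrap resamples
(sufficient resolution for a 5% test; the analysis default stays at 1000).
These sizes are the package's own choices balancing the precision of the
asserted rates against simulation effort.

## Known limitations

* The closed-form isotropic correction is for rectangles only; irregular
  membrane-sheet outlines would need a polygonal correction or toroidal
  wrapping.
* The bootstrap comparison fixes one concrete statistic (band-integrated
  squared mean difference) and resampling unit (curves); other renderings
  of a "bootstrap test between conditions" exist and can give different
  p-values.
* Pointwise envelopes scanned over a band inflate the family-wise error
  rate; use the global envelope when a single curve-level decision at a
  guaranteed level is needed.
* $E_{app}$ from phase lifetimes differs slightly from modulation-based
  values on multi-exponential donors; the estimator choice is surfaced
  precisely because the difference is systematic.
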