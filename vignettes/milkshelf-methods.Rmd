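---
title: "Models and methods behind milkshelf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind milkshelf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkshelf)
```

`milkshelf` analyses storage experiments on pasteurized milk measured by 1D
^1H NMR: which metabolites change with storage time and temperature, and
how fast. This vignette documents the models, the assumptions they rest on,
the tunable parameters, what the synthetic generator does and does not
emulate, and the numerical choices a maintainer would want to know about.

## 1. The experiment the package models

Milk from several pasteurization batches (biological replicates) is stored
at a set of temperatures; bottles are pulled at scheduled collection time
points and measured. The default stated world mirrors a realistic design:

* 4 batches, storage at 4, 10, 15, 20 °C for 78, 17, 6 and 3 days;
* 12–13 collection points per temperature, index 0 being the baseline
  aliquot frozen on the day of pasteurization;
* 2 bottles per batch per collection, giving roughly 376 samples — the
  scale of a full storage study after quality filtering;
* actual pull days jitter around the schedule means (normal, truncated at
  zero), with larger jitter late in the 4 °C arm where sampling follows
  perceived spoilage.

The schedule's means and standard deviations are frozen constants of the
generator (`default_schedule()`); they were chosen to be consistent with the
published anchors of such an experiment (total durations, the late 4 °C
collections at 57 ± 7 and 63 ± 12 days, and collections at 9.97, 12.01,
16.5 d at 10 °C, etc.). They are a stated world, not knobs to retune per
analysis.

## 2. The concentration model

For each batch `b` a baseline `c0_b` is drawn log-normally around the
metabolite's mean (default CV 4%, matching citric acid's 10.3 ± 0.4 mM
between-batch spread). Then:

* **Citric acid** decays linearly, `c(t) = c0_b − r(T)·t`, truncated at 0.
  The rate follows the Arrhenius law with activation energy `citric_Ea`
  (default 143 kJ/mol) anchored at 0.06 mM/d at 4 °C. This reproduces
  per-temperature rates near −0.06/−0.7/−0.8/−1.9 mM/d at 4/10/15/20 °C.
* **Fermentation products** (ethanol, formic, acetic, lactic, succinic
  acid, butyric acid) stay at baseline during a lag
  `L(T) = A0·exp(k·T)` (defaults A0 = 157.3 d, k = −0.254 /°C, i.e.
  L = 56.9/12.4/3.5/1.0 d at 4/10/15/20 °C), then grow exponentially:
  `c(t) = c0_b · min(exp(r(T)·(t − L)), max_fold)`.
* Measurement noise is multiplicative log-normal (`noise_cv`, default 5%),
  keeping concentrations positive.

Two generator choices deserve justification because the underlying
phenomenon only constrains them qualitatively:

* **Post-lag form.** Only "accelerated increase after a lag" is observed;
  any convex increasing form would do. Exponential growth is the most
  parsimonious choice consistent with microbial kinetics, and it makes the
  threshold statistic analytically predictable in tests.
* **Temperature scaling of the production rate (`rate_q10`, default 5;
  reference 20 °C) and a stationary-phase ceiling (`max_fold`,
  default 200).** A temperature-independent per-day rate is untenable: the
  4 °C arm is observed for 21 days past its lag, the 20 °C arm for 2 — a
  shared rate either makes the cold arm explode by e⁹ or the warm arm
  undetectable. Microbial production accelerates strongly with temperature;
  Q10 = 5 puts the per-day rate at 0.15/d at 4 °C versus 2/d at 20 °C and
  yields final fold-changes of roughly 5–50× everywhere, the order of
  magnitude seen in real storage data. Growth saturates (stationary phase),
  hence the ceiling.
* **Butyric acid** is special-cased behind `butyric_temp_inverted`
  (default off): when enabled, its lag and rate use the mirrored
  temperature `T' = Tmin + Tmax − T`, so it surges at low temperatures and
  barely moves when warm — a qualitative emulation of consumption by
  warm-active microbes. No statistical target attaches to it; it is off by
  default because its inverted trajectory otherwise dominates the 4 °C
  untargeted screen, which the default scenario uses to demonstrate the
  monotone temperature ordering of significant bins.

The spectrum generator renders each sample as a sum of Lorentzian
multiplets (singlet/doublet/triplet/quartet/doublet-of-doublets patterns
from the knowledge base, shared linewidth, default 1 Hz at 850 MHz), a
9-proton internal-standard singlet at 0 ppm, and additive Gaussian noise.
**What it does not emulate:** lactose and the dozens of other milk signals
that populate real spectra (so absolute significant-bin counts are far
below the ~1050-bin real case), phase and baseline artefacts, chemical-shift
drift with pH, peak overlap beyond the seven modelled metabolites, and
field inhomogeneity. A green screen test therefore establishes the
statistics, not spectral robustness.

## 3. Untargeted screen

Bins are trapezoidal integrals over half-open 0.01-ppm windows; exclusion
regions (water 4.7–4.9 ppm, reference ±0.05 ppm) are zeroed. Binning is
linear and conserves the spectrum integral over the binned range — both are
tested invariants. Spearman ρ uses average ranks; p-values come from the
t approximation, adequate at the design scale (≥ 40 samples per
temperature) but anti-conservative in the extreme tail below n ≈ 15 — the
null-FDR property test runs at design scale for exactly this reason.
Baseline samples enter every temperature's correlation set, since each
bottle's history starts at collection. Benjamini–Hochberg control defaults
to q\* = 10⁻⁴ ("FDR at the 0.01% level" read literally); the level is a
configuration knob because that phrasing is unusual. Whether spectra should
be total-area normalized before screening is likewise unspecified in the
field's practice; it is a flag (`normalize`, default on in the pipeline).

## 4. Steel's many-one test

Each post-baseline collection point is compared with the baseline control
by Wilcoxon rank sums with tie-corrected variance and no continuity
correction. Under the joint null the standardized statistics have the
one-factor correlation structure `ρ_jk = sqrt(λ_j λ_k)`,
`λ_j = n_j/(n_j + n0)` (0.5 pairwise at equal sizes), so
`P(max_k Z_k ≥ z)` reduces to a one-dimensional integral evaluated by
adaptive quadrature — deterministic and exact to ~1e-10, which is why no
quasi-Monte-Carlo seed is needed. A permutation mode (exact enumeration for
one small treatment, sampled otherwise) is the ground-truth oracle.

Two statistical facts shape the tests:

* The rank statistic is discrete. With a control of 3 and treatments of 3,
  the largest attainable z is 1.96 — below the α = 0.05 critical value of
  the max statistic — so family-wise rejection is *impossible*; the test
  of size therefore uses the design's pooled baseline control (n0 = 16),
  where the attainable size is ≈ 0.042: valid (never above α), close to
  nominal from below.
* The continuous MVN approximation sits within about half a probability
  atom of the discrete permutation law at n = 3; agreement is asserted at
  0.1 absolute with identical orderings.

Sidedness defaults to "greater" (products exceeding baseline); "less" is
available for degrading metabolites.

## 5. Kinetics

`linear_rate` pools batches (one rate per temperature is the quantity of
interest; per-batch slopes are available diagnostically). `arrhenius`
regresses `ln|r|` on `1/(T + 273.15)`; `Ea = −slope·R` in kJ/mol, with the
common sign carried separately so degradation rates have a defined
logarithm.

`threshold_time` runs Steel's test with baseline as control; the threshold
time τ is the mean storage day at the first significant collection
(α = 0.05 by default, matching the convention that all reported threshold
p-values fall below 0.05), its dispersion the standard deviation of those
days. τ is undefined when nothing reaches significance — a real outcome
(slow metabolites at 4 °C) that the fitter must tolerate, which is why
`decay_fit` drops non-finite pairs before checking it still has ≥ 3.

`decay_fit` fits `τ = A·exp(k·T)` by **unweighted NLS on the original
scale**, not log-linear OLS. The two disagree materially (ethanol:
−0.254 vs −0.213 per °C) because the original scale weights the long
low-temperature threshold times most; original-scale NLS is the form that
reproduces the published decay-rate table, validated for all five
metabolites in the acceptance tests. Starting values come from the
log-linear fit; `nls` runs with `scaleOffset = 1` so exact-fit (zero
residual) cases converge; non-convergence falls back to the log-linear
estimate, flagged. The 95% CI of k uses the linearized covariance with a
t quantile at n − 2 df.

**Known limitation (deliberately red acceptance sub-criterion).** The
threshold estimator is censored to the collection grid: detection can only
happen at a scheduled collection at or after the true lag, once growth has
cleared the noise floor. Every τ is therefore right-shifted. Because the
relative delay is roughly constant across temperatures, the decay *rate* k
is nearly unbiased (recovered within ~2 SE of an 8-replicate ensemble
mean), but the *amplitude* A absorbs the delay factor and overshoots the
generating A0 by ~20–30% — beyond 3 SE. This is a property of the
threshold-time statistic in this design (sparse, noisy late 4 °C
collections), not an implementation defect; the corresponding test is left
failing with this analysis rather than loosened.

## 6. Multifactor ANOVA

The model includes time and temperature as continuous covariates,
replicate as a factor, squares of time and temperature, and the three
pairwise interactions. Per-term inference uses partial (drop-one) F tests
— term order is deliberately irrelevant, since no canonical ordering
exists for this design. Backward elimination removes the largest
p ≥ α one at a time; a hierarchy guard (default on, toggleable) refuses to
drop a main effect while a retained square or interaction contains it.
Residual diagnostics: Shapiro–Wilk normality and Brown–Forsythe
homoscedasticity across replicate × temperature cells. Normalization
options are log and Johnson SU; the SU fit uses the classic four-quantile
matching construction (z = 0.524) with a maximum-likelihood fallback when
the quantile discriminant falls outside the SU region, as happens for
near-normal data. A SHASH transform is not provided; log + Johnson SU
cover the normalization role.

## 7. Quantification numerics

Each multiplet is fit on a local window (±`window_ppm` around the
knowledge-base shift) as amplitude × pattern-constrained Lorentzian sum
plus a constant baseline, with amplitude and baseline profiled analytically
(the model is linear in both) and center/log-linewidth optimized by
Nelder–Mead (reltol 1e-12). The baseline term matters: without it, tails
of distant strong peaks bias a clean singlet's area by ~2.5 × 10⁻⁶
relative, just above the forward/inverse identity tolerance; with it the
identity holds to < 10⁻⁶. Quality control rejects fits with local
R² < 0.8 or a fitted shift more than 0.02 ppm from the expected position;
rejected results are flagged with reasons, never dropped silently.
Calibration factors default to 1.0 — instrument-specific values belong in
the knowledge-base file. Concentrations are scale-invariant by
construction (metabolite and reference areas share any overall intensity
factor).

## 8. Reproducibility

Every stochastic routine takes an explicit seed (simulation via
`sim_config(seed=)`, the pipeline via `run_config(seed=)`, permutation
modes via an argument). Pipeline reruns with the same configuration are
byte-identical for deterministic stages, and the run manifest records the
package version, the seed and an MD5 hash of the canonical JSON form of
the configuration. The Steel adjusted p-values are deterministic
(quadrature, not Monte Carlo), to ~1e-10.
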