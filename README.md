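# milkshelf

NMR metabolomics of pasteurized milk storage: spoilage-marker screening and
shelf-life kinetics.

## The problem

Date labels on pasteurized milk are static predictions; actual spoilage
depends on storage temperature and on the microbial load of each
pasteurization batch. Small organic acids and ethanol produced by
post-pasteurization contaminants, and citric acid consumed during storage,
are candidate molecular indicators for real-time shelf-life monitoring.
`milkshelf` implements the full analysis chain for a multi-batch,
multi-temperature storage experiment measured by 1D ^1H NMR:

1. **Untargeted screen** — spectra are integrated into 0.01-ppm bins; for
   each storage temperature every bin is correlated with storage time
   (Spearman ρ, average-rank ties, t-approximation p), with
   Benjamini–Hochberg FDR control (default q\* = 10⁻⁴) and volcano/PCA
   summaries.
2. **Targeted quantification** — a knowledge base of multiplets (chemical
   shift, proton count, multiplicity, coupling constants) drives local
   least-squares fits of pattern-constrained Lorentzian line shapes plus a
   profiled baseline; areas are converted to molar concentrations against
   the 9-proton TSP internal-standard singlet at 0 ppm:
   `c = (A/A_ref) · (9/n_H) · c_ref · calib`.
3. **Multifactor ANOVA** — concentration ~ time + temperature + replicate
   plus square and interaction terms, partial (drop-one) F tests, backward
   elimination at α = 0.05 with a hierarchy guard, and log / Johnson SU
   normalization with residual diagnostics.
4. **Nonparametric confirmation** — Kruskal–Wallis over collection time
   points and Steel's many-one rank test of each time point against the
   baseline, with family-wise control via the exact one-factor multivariate
   normal null (plus a permutation oracle mode).
5. **Kinetics** — two models:
   - citric acid: concentration falls linearly, `c(t) = c0 − r(T)·t`; the
     rates follow the Arrhenius law, `ln|r| = ln A − Ea/(R·T_K)`, giving an
     activation energy `Ea = −slope·R`;
   - fermentation products (ethanol, formic, acetic, lactic, succinic
     acid): flat during a lag, then rapid increase. The *threshold time* τ
     is the mean storage day of the first collection whose concentration
     significantly exceeds baseline (Steel's test); τ shrinks with
     temperature as `τ = A·exp(k·T)`, fit by original-scale nonlinear least
     squares.

A first-class synthetic-data generator (`sim_config()`,
`simulate_concentrations()`, `simulate_spectra()`) reproduces the
statistical structure of such an experiment — four batches, storage at
4/10/15/20 °C for 78/17/6/3 days, batch-varying baselines,
temperature-dependent lags, Arrhenius citric decay, multiplicative noise —
so every stage is testable offline.

## Worked example

Fit the exponential threshold-time decay for ethanol from the shipped
reference table, and the Arrhenius activation energy of citric acid
degradation:

```r
library(milkshelf)

ref <- reference_threshold_times()
d   <- ref[ref$metabolite == "ethanol", ]
decay_fit(d$temperature_C, d$threshold_time_d, metabolite = "ethanol")
#> <threshold_decay_fit ethanol: tau = 157 * exp(-0.254 T), k 95% CI [-0.295, -0.213]>

rates <- reference_citric_rates()
arrhenius(data.frame(temperature = rates$temperature_C, rate = rates$rate_mM_d))
#> <arrhenius_fit: Ea = 136.7 +/- 34.2 kJ/mol over 4 temperatures>
```

The decay constant k = −0.254 /°C means the time until ethanol
significantly exceeds its baseline shrinks by a factor `exp(0.254·ΔT)` —
about 13× between 4 °C and 14 °C. The 136.7 kJ/mol activation energy (from
rates printed to two decimals) is far above the 0–35 kJ/mol typical of
enzyme catalysis, arguing against a purely enzymatic mechanism for citric
acid loss.

A synthetic experiment end to end:

```r
cfg <- sim_config(seed = 42)
s   <- simulate_concentrations(cfg)
head(s, 3)
#>        sample_id batch temperature_C storage_time_d timepoint_index metabolite concentration_M
#> 1 T04_tp00_b1_r1    B1             4              0               0     citric    1.113382e-02
#> 2 T04_tp00_b1_r1    B1             4              0               0    ethanol    4.260940e-05
#> 3 T04_tp00_b1_r1    B1             4              0               0     formic    8.615416e-06

d10 <- s[s$metabolite == "ethanol" & (s$temperature_C == 10 | s$timepoint_index == 0), ]
threshold_time(data.frame(timepoint_index = d10$timepoint_index,
                          storage_time_d  = d10$storage_time_d,
                          concentration   = d10$concentration_M),
               metabolite = "ethanol", temperature = 10)
#> <threshold_time ethanol @ 10 degC: tau = 14.01 +/- 0.13 d (tp 9, p = 0.000)>
```

The configured lag at 10 °C is `157.3·exp(−0.254·10) = 12.4` days; the
first scheduled collection after it (14 d) is correctly detected.

Full pipeline (simulation → spectra → screen → quantify → ANOVA →
kinetics), writing CSV/JSON stage outputs and a run manifest:

```r
run_pipeline(run_config(outdir = "run1", seed = 1,
                        stages = c("simulate", "spectra", "screen",
                                   "quantify", "anova", "kinetics"),
                        simulate_spectra = TRUE))
```

or from the shell via the CLI wrapper:

```sh
Rscript inst/cli/milkshelf.R run-all --seed 1 --outdir run1
```

## Layout

- `R/` — simulator, NMR data model + binning + quantification, screening,
  nonparametric tests, kinetics, ANOVA, pipeline.
- `inst/extdata/` — default multiplet knowledge base and the published
  reference tables (threshold times, citric rates).
- `vignettes/milkshelf-methods.Rmd` — models, assumptions, numerical
  choices, and known limitations.
- `tests/testthat/` — unit, property and acceptance tests.
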