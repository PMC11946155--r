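# oscdyn

Within-task EEG brain dynamics for the equiprobable auditory Go/No-Go
paradigm, exercised end-to-end on synthetic recordings with known ground
truth. The package asks: once pink noise (PN) and white noise (WN) are
validly removed from the immediately-prestimulus EEG spectrum, which
noise-free oscillation components — and which noise levels — predict the
Go/No-Go ERP components and task behaviour?

It is written for EEG/ERP methodologists: everything from the simulator to
the stepwise regressions is a package function with tests, so each claim
("the noise fit never produces negative oscillation power", "planted
couplings are recovered") is checked against constructed oracles and
simulated ground truth.

## The model at the core

Observed prestimulus power at integer bins f = 2..24 Hz is decomposed as

    S(f) = osc(f) + p/f + w,      p, w >= 0,  osc(f) >= 0 for all f.

The fit maximises the total extracted noise `sum_f (p/f + w)` subject to
`p/f + w <= S(f)` at every bin — a two-variable linear program solved
exactly by vertex enumeration (`fit_pink_white()`). The validity constraint
is the point: a free-exponent "aperiodic" background fit can exceed the
observed spectrum and imply negative oscillation power
(`aperiodic_baseline_demo()` shows this on demand). The fitted noise is
evaluated over 1–30 Hz, subtracted in the power domain, and the noise-free
oscillation spectra go to a frequency PCA (covariance input, Varimax +
1.5% variance cutoff, Promax on the retained components). Go and No-Go
ERPs get separate temporal PCAs (covariance, Kaiser, Varimax). Stepwise
regressions (forward p ≤ .05 entry, backward p > .10 removal) link the
per-participant global-mean component amplitudes and the PN/WN amplitudes
at 1 Hz to the ERP components and the six behavioural measures.

## Worked example

Simulate a small cohort with the default planted couplings (alpha → Go
P3b +, beta → Go N2c −, PN → No-Go N1b −, PN → No-Go N1c +) and run the
whole pipeline:

```r
library(oscdyn)

config <- recovery_config()                       # 6 ch, 250 Hz, 75+75 trials
truth  <- ground_truth(couplings = default_couplings(0.5))
res    <- cohort_pipeline(config, truth, n_participants = 47,
                          master_seed = 7, min_trials = 25)

sort(res$fpca$peak_hz)
#> [1]  2  3  4  5  6  8 10 15 25
td <- tidy_stepwise(res$linkage$primary)
td[!is.na(td$predictor) & td$p < 1e-6, c("dependent", "predictor", "beta", "p")]
#>    dependent predictor       beta            p
#> 8    go_T332     F10Hz  0.7290645 1.928790e-10
#> 11   go_T236     F25Hz -0.8049180 9.171913e-12
#> 20 nogo_T100        PN -0.7584378 6.605785e-10
#> 21 nogo_T148        PN  0.7148231 1.660660e-08
```

Reading: the f-PCA recovers the five planted bands (2, 8, 10, 15, 25 Hz;
the 3–6 Hz entries are small residual components from the noise
subtraction). The four strongest regression links are exactly the four
planted couplings, with the planted signs: the Go P3b-like component
(peak 332 ms) depends positively on the 10 Hz (alpha) component, the Go
N2c-like component (236 ms) negatively on the 25 Hz (beta) component, and
the No-Go N1b/N1c-like components (100/148 ms) on the fitted pink-noise
amplitude with opposite signs.

The `analysis/` scripts run the same stages as a narrated workflow
(`01_simulate.R` … `07_linkage_regressions.R`), writing tables under
`results/`; `run_all()` does the same from a YAML config with a
reproducibility manifest.

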