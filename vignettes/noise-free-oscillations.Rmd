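---
title: "Noise-free prestimulus oscillations and their ERP and behaviour linkages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-free prestimulus oscillations and their ERP and behaviour linkages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Scalp EEG mixes rhythmic oscillations with non-oscillatory "noise"
processes: pink noise (PN), whose power falls off as $1/f$, and white noise
(WN), whose power is uniform over frequency. If prestimulus oscillation
amplitudes are to be linked to the event-related potentials (ERPs) and
behaviour that follow each stimulus, the noise must be estimated and removed
first — otherwise apparent "band amplitude" effects may be noise effects in
disguise. The widely used free-exponent ("aperiodic") background fit can
exceed the observed power at some frequencies, which implies *negative*
oscillation power after subtraction — a physical impossibility.

`oscdyn` implements, end-to-end and against synthetic ground truth, a
within-task analysis of this problem for the equiprobable auditory Go/No-Go
paradigm: simulate multichannel EEG sessions with known PN/WN/oscillation/ERP
structure and planted prestimulus-to-ERP couplings; preprocess and epoch;
derive prestimulus amplitude spectra; fit a *validity-constrained* PN + WN
model and subtract it; decompose the noise-free oscillation spectra by
frequency PCA (f-PCA, Promax) and the Go/No-Go ERPs by separate temporal
PCAs (t-PCA, Varimax); and link prestimulus component amplitudes to ERP
components and behaviour by stepwise regression.

# The constrained noise model

Let $S(f)$ be the observed power (squared amplitude) at integer bins
$f = 2..24$ Hz. The noise model is

$$N(f) = p/f + w, \qquad p, w \ge 0,$$

with the **validity constraint** $N(f) \le S(f)$ at every bin, so the
oscillation residual $S - N$ can never be negative. Among all valid $(p, w)$
the fit returns the pair maximising the total extracted noise
$\sum_f N(f)$ — the most conservative attribution of power to oscillations
that is still physically possible. With $x = 1/f$ this is a two-variable
linear program; `fit_pink_white()` solves it exactly by vertex enumeration
(all lines through two spectrum points in $(x, S)$ space plus the two
single-constraint axis candidates), with ties broken toward larger $w$. The
fitted model is evaluated over 1–30 Hz and subtracted in the power domain
(power is what adds across independent processes); amplitudes are recovered
by square root. Within the fit range clipping can never activate; outside it
(1 Hz, 25–30 Hz) clipped bins are counted and reported.

Two properties matter in practice:

* **Validity is structural.** The residual is non-negative at every fit bin
  for *any* non-negative input; the test suite checks this on 1000 random
  spectra and checks exactness against a brute-force lattice maximiser.
* **The maximal-noise objective has a small negative bias on noisy
  spectra.** The constraint surface hugs the *lower envelope* of the
  spectrum; periodogram sampling noise therefore pulls the fit down by
  roughly the envelope dip ($\sim 1.5 \sigma_{bin}$). Averaging many epochs
  shrinks $\sigma_{bin}$; with $\sim$2000 pooled epochs the white level is
  recovered within $\sim$8% and the pink coefficient within $\sim$4%. This
  is why the noise-recovery study uses 1000 trials per condition.

A deliberately *unconstrained* free-exponent fit,
`aperiodic_baseline_demo()`, reproduces the pathology the constrained model
avoids: on bump-dominated spectra it leaves one or more bins with negative
residual power.

## Measurement units

The amplitude-spectrum estimator is tone-calibrated (coherent-gain
correction), so a stochastic process of one-sided PSD $v$ produces an
expected measured bin power of $\kappa v$ with
$\kappa = (\pi/2)\, f_s\, \overline{w^2} / (n\, \bar{w}^2)$
(`noise_measurement_gain()`): the $\pi/4$ factor is the Rayleigh mean of
amplitude averaging, the rest is the window's noise bandwidth over its
squared coherent gain. Recovery studies convert fitted powers back to
generator PSD units with this constant; the linkage analyses never need it
(only between-participant variation matters there).

# Spectral quantification

Prestimulus epochs ($[-500, 0)$ ms) are de-meaned, windowed with a 10%
split-cosine-bell (raised-cosine ramps over the first and last 5% of
samples; the window mean is exactly $1 - 0.10/2 = 0.95$), zero-padded to
twice their length (1 Hz bins), Fourier transformed, and corrected for the
original length and the window's coherent gain. Averaging is done on
amplitude spectra (in $\mu V$), within participant, per channel and
condition; the pooled spectrum is the mean of the Go and No-Go means. The
amplitude-vs-power averaging choice is exposed in the estimator's units (see
above) rather than as a switch; power-domain subtraction is used throughout.

A note on taper leakage: for a tone at bin $f_0$, the negative-frequency
image enters through the taper's transform at $2 f_0$. For the 10%
split-cosine-bell the 25-sample ramps span half a cycle of 20 Hz, so a
10 Hz tone is the worst case: the measured amplitude is
$5.131\,\mu V$ for a 5 $\mu V$ sine (phase-dependent, $\pm 2.6\%$). This is
a property of the stated window, not of the code; the unit tests freeze the
analytic windowed-DFT value, and tones at 15 Hz and above recover within 2%.

# Preprocessing rules

Band-pass 0.1–30 Hz is implemented as exact zero-phase frequency-domain
filtering: a real non-negative transfer function, zero below 0.05 Hz with a
raised-cosine ramp to unity at 0.1 Hz, exactly flat through 30 Hz, and a
ramp to zero at 33 Hz; the DC bin is zeroed exactly. The flat passband is
the point: a 4th-order Butterworth applied forward–backward loses up to
$\sim$26% of the power at 24 Hz (inside the noise-fit range), and a
windowed-sinc FIR sharp enough for a 0.1 Hz edge needs a $\sim$33 s kernel.
The frequency-domain mask is equally non-causal and zero-phase, with the
passband untouched.

Trial validity: valid Go trials have a press in the *closed* $[100, 500]$ ms
window (the boundary semantics are a documented choice); valid No-Go trials
have no press in their interstimulus period; any trial with a response
falling in its 500 ms prestimulus window is invalid. Artifact rejection
applies three rules per epoch in fixed order — extreme amplitude
($>125\,\mu V$), sample-to-sample jump ($>50\,\mu V$, the most literal
reading of "between datapoints", applied per channel on filtered epochs),
and flat line (voltage range $< 0.05\,\mu V$ in any 100 ms window) — and
records the first rule that triggers. Accepted epoch counts are matched
between conditions by seeded subsampling of the larger set; participants
below the inclusion threshold are flagged excluded, not dropped silently.

# PCA and rotations

Both PCAs use the covariance matrix, so loadings scaled by
$\sqrt{\lambda}$ are already in $\mu V$ — these are the "scaled loadings"
that get plotted and that define each component's peak variable.

* **f-PCA** (oscillation spectra; cases = participant $\times$ channel,
  31 variables, 0–30 Hz): all components are extracted and Varimax-rotated;
  components at or above 1.5% variance are retained and then Promax-rotated
  (target $|L|^\kappa\,\mathrm{sign}(L)$ with $\kappa = 3$, the ERP-PCA
  convention; $\kappa$ is configurable). Two design decisions here were
  genuinely open, and both were settled by degeneracies that only appear
  when the input carries many near-noise dimensions:
  1. *Promax is applied to the retained subset, not the full space.*
     Obliquely rotating dozens of near-zero noise directions collapses them
     onto the dominant band (factor correlations $\to 0.99$, duplicated
     factors with inflated structure-SS shares), making oblique variance
     selection meaningless. On well-conditioned inputs the two orderings
     agree.
  2. *Kaiser normalisation is off for the f-PCA Varimax stage* (the t-PCA
     keeps it). Row normalisation gives near-empty frequency bins the same
     criterion weight as the oscillation bands and fragments weak bands
     into sub-threshold pieces; without it, planted-band fixtures select
     exactly the planted components.
* **t-PCA** (mean ERPs per condition; $-100..500$ ms half-sampled): Kaiser
  normalisation, unrestricted Varimax of all rank-supported components,
  1.5% cutoff. Go and No-Go get separate solutions to avoid misallocating
  condition-specific variance.

Oblique explained variance is attributed by structure-loading sums of
squares over the total variance (documented: oblique shares are not
additive). Every component is sign-aligned so its peak scaled loading is
positive, with scores (and $\Phi$) flipped along, so N-type components come
out negative in the data's own units. A component's per-case amplitude is
its factor score times the scaled loading at the peak variable, plus the
centred-out mean at that variable — the mean term keeps polarity and makes
the forward-construction identity exact ("mean" and "peak" amplitude modes
coincide after the sign convention; both are kept for interface fidelity).
Per participant, the global mean averages this over all channels.

# The synthetic cohort

`generate_session()` builds each recording as the exact sum of four parts —
band-limited oscillations (unit-RMS Butterworth-filtered Gaussian latents,
one per band, spread over channels by a smooth topography), pink noise
(spectral synthesis with amplitudes $\propto f^{-1/2}$ and uniform random
phases), white noise, and ERP templates (Gaussian-windowed deflections at
stimulus onsets). Defaults mirror the target paradigm: 30 channels at
1000 Hz, 1100 ms SOA, two blocks of 75 Go + 75 No-Go shuffled tones, RTs
from a normal distribution truncated to $[100, 1000]$ ms, omissions and
commissions at 4.2% and 6.2%. Oscillation bands sit at 2, 8, 10, 15 and
25 Hz (delta/theta through beta) with RMS amplitudes 3, 2.5, 4, 2 and 2
$\mu V$; PN power at 1 Hz is 12 $\mu V^2$/Hz and WN 0.25 $\mu V^2$/Hz —
values chosen once to give spectra of realistic shape and magnitude and a
five-component f-PCA solution. Band amplitudes for the weaker bands were
set so that every band clears the 1.5% selection threshold under the
default between-participant jitter, mirroring the five-component structure
the method is meant to resolve.

**Couplings.** A coupling scales the target ERP template on trial $k$ by
$1 + s_\pm \cdot \mathrm{sign}(A) \cdot \text{strength} \cdot z_k$, where
$z_k$ standardises the prestimulus ($[-500, 0)$ ms) RMS of the source (a
band latent, or the pooled-channel pink part) and $s_\pm$ is the planted
sign of the effect on the *signed* measured amplitude $A$. Critically,
$z_k$ is standardised with *cohort-level* reference moments frozen from the
base (unjittered) truth ($m_{ref}$ from the generator's own shaping
coefficients, $s_{ref} = 0.35\, m_{ref}$, a fixed convention): per-
participant standardisation would cancel exactly the between-participant
covariation that across-participant regressions measure. The default
pattern plants alpha $\to$ Go P3b (+), beta $\to$ Go N2c (−), PN $\to$
No-Go N1b (−), PN $\to$ No-Go N1c (+).

**Participant heterogeneity** is log-normal jitter (SD 0.2 on the log
scale) applied independently to every amplitude-scale quantity. This is a
stand-in, not an inference about any real cohort: real between-participant
structure (correlated band amplitudes, age, skull thickness) is not
modelled, so passing recovery tests show the *pipeline* recovers planted
structure, not that real effects of this size exist.

All randomness flows from one master seed through a documented derivation
(`derive_seed(master, "participant/3")` etc.), so any stage reproduces in
isolation.

# Stepwise linkage regressions

`stepwise_regress()` uses forward entry (smallest entry $p \le 0.05$) and
backward removal (any included $p > 0.10$), iterated to a fixed point —
the thresholds are the common statistical-package defaults and are
exposed as arguments. Standardised $\beta$ comes from
z-scored variables; $t$ and $p$ from the unstandardised fit (identical by
invariance). No multiple-testing correction is applied — the suite is
deliberately exploratory — and the null
calibration quantifies what that costs (with 7 pure-noise predictors and
$n = 47$, at least one false predictor enters in roughly 25–30% of runs).
The suite regresses 6 behavioural + all selected ERP-component dependents
on the prestimulus predictors, then behaviour on the EEG-affected ERP
components.

# Problem sizes and what the studies show

Recovery studies run at deliberately scaled sizes, chosen once:

* **Noise recovery**: 1 channel, 250 Hz, 1000 trials per condition,
  oscillations confined to 6–20 Hz so the 2–5 and 21–24 Hz flanks pin the
  noise line; 20 seeds; medians of fitted/true within 10%.
* **Component recovery**: constructed case matrices at the full
  47 $\times$ 30 = 1410-case geometry (the case count matters: rotation
  allocation of broad late components is unstable at a few hundred cases);
  planted bands recovered within $\pm 1$ bin and deflection latencies
  within $\pm 10$ ms in $\ge 90\%$ of 20 seeds.
* **End-to-end linkage**: 47 participants per cohort at a reduced session
  scale (6 channels, 250 Hz, one 75+75 block; inclusion threshold scaled
  proportionally to 25 of 75), 20 cohort seeds, coupling strength 0.5; each
  planted link must be recovered with the right predictor and sign in
  $\ge 80\%$ of cohorts. At these settings the planted effects come out
  with $|\beta| \approx 0.6$–0.8, so recovery is comfortably powered; the
  stepwise false-selection background is calibrated against an independent
  re-implementation on Gaussian nulls.

Numerical conventions collected in one place: LP feasibility slack
$5 \times 10^{-10}$ absolute (guaranteeing residuals $\ge -10^{-9}$);
out-of-range clip threshold $-10^{-9}$ with clipped-bin counting; PCA rank
guard at $10^{-12} \lambda_{max}$; Kaiser row-norm floor at $10^{-8}$ of
the largest communality; Varimax stop at criterion improvement
$< 10^{-7}$ (tighten to $10^{-10}$ when comparing against the angle
oracle); component sign fixed by the peak loading; stepwise collinearity
guarded by a condition-number warning at $10^8$ and `Inf`-p handling for
degenerate candidates.

# Known limitations

* The generator's topographies are smooth weight profiles over a channel
  index — no head geometry, no volume conduction, no reference physics.
* EOG artifacts, blinks, drift and channel dropout are not simulated, so
  the artifact-rejection rules are exercised by constructed fixtures, not
  by realistic contaminants.
* The maximal-noise fit is negatively biased on poorly averaged spectra
  (see above); single-trial or short-average applications would need a
  bias analysis first.
* Promax with $\kappa = 3$ tends to underestimate strong factor
  correlations; the planted-correlation check (0.5 recovered within 0.1)
  bounds this for the moderate-correlation regime only.
* The 10 Hz tone calibration carries the $\pm 2.6\%$ taper-image leakage
  discussed above.
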