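---
title: "Simulating and analyzing frontal-midline theta neurofeedback studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing frontal-midline theta neurofeedback studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nftheta)
```

## What the package models

`nftheta` is a config-driven simulation and analysis toolkit for closed-loop
frontal-midline theta (Fm&theta;, 4--7 Hz at FCz) neurofeedback protocols
paired with a Go/No-Go shooting task. It covers the complete loop:

1. **Protocol structure** -- five training sessions of six blocks, each block
   six trials of a 10-s rest followed by a 30-s active modulation period
   (180 s active per block, 1080 s per session, 5400 s per subject), with two
   study arms: an *INC* group that up-modulates in every block, and an *ALT*
   group whose six blocks carry three Up and three Down goals with no more
   than two consecutive equal goals.
2. **Closed-loop feedback** -- a streaming theta-power estimator (1-s Hann
   windows of 2048 samples with 1792-sample overlap at 2048 Hz, so exactly
   8 estimates/s), expressed in dB against an adaptive per-session threshold,
   with a &plusmn;75 uV online artifact gate that flat-lines the display at
   the last clean value.
3. **Synthetic subjects** -- 1/f background EEG, a goal-responsive narrowband
   theta component, an alpha component, raised-cosine artifact transients,
   and a virtual shooter whose hit rate follows a logistic psychometric
   function of target exposure time.
4. **Offline spectral analysis** -- zero-phase 1 Hz highpass, 2048 to 512 Hz
   decimation, epoching around modulation onsets (-3 to 30 s) and targets
   (-1 to 2 s), four-criterion artifact rejection on 1-s sub-epochs, Welch
   band power, dB against the pre-trial baseline, and retention accounting.
5. **Multilevel statistics** -- a four-step REML model ladder per outcome,
   with ICC, design effect, fixed-effects pseudo R^2, simple slopes,
   assumption checks and responder classification.

Because no human recordings ship with the package, a synthetic-subject
generator defines the study conditions; every stage is exercised and verified
against analytic and simulation oracles.

## The feedback signal

The online estimator computes, per sliding window, the one-sided Hann-tapered
periodogram with power-spectral-density scaling and averages the PSD bins
with $4 \le f \le 7$ Hz inclusive (`theta_power`, the *band-mean*
convention). The frame rate is $f_s / (\text{window} - \text{overlap})$
exactly. Design choices that the protocol description leaves open are pinned
as follows and tested:

* **Taper**: periodic Hann with PSD scaling. With this normalization the PSD
  integral over frequency estimates signal variance, and a sinusoid of
  amplitude $a$ at a bin frequency integrates to $a^2/2$ exactly -- the
  closed-form oracle used throughout the tests.
* **Band statistic**: the band *mean* of PSD bins ("averaged over 4--7 Hz");
  `welch_band_power()` also exposes the band *integral* for the analytic
  oracles.
* **dB conversion**: $10\log_{10}(P/P_\text{thr})$, floored at -60 dB so zero
  power stays finite while preserving order.
* **Artifact gating**: a frame is gated iff any sample in its window exceeds
  the amplitude limit ("the artifact subsides" = the first window with no
  super-threshold sample, the only window-resolved reading available
  online). Gated frames hold the last clean value; a stream that *starts*
  gated holds 0 dB, the threshold level, as a neutral display.
* **Achievement ties**: frames at exactly 0 dB count as achieved for neither
  goal, so Up- and Down-achievement sum to 100% whenever no frame sits
  exactly on the threshold. Achievement is pooled per block (a per-trial
  variant can be computed by subsetting frames).
* **Threshold schedule**: session 1 uses pre-training resting theta power;
  each later session uses the arithmetic mean of the previous session's six
  block mean powers.

The streaming estimator and the offline Welch estimator share one
periodogram core, so on the same span with the same window and overlap they
agree to floating-point precision -- an invariant the test suite asserts at
1e-6 relative.

## The synthetic EEG generator

The background is spectrally shaped Gaussian noise with a $1/f^a$ spectrum
(default $a = 1$, RMS 5 uV). Theta is synthesized by default as *narrowband
filtered noise* in 4--7 Hz rather than a pure tone, for realistic spectra; a
pure-tone mode is retained because its band power has the closed form
$a^2/2$. Gains act multiplicatively on band *power* (the amplitude envelope
is the square root of the power ratio) and session/block trends act
additively in dB, matching the scale of the analysis stage: during the
modulation period of block $b$ in session $s$,

$$P_\theta = P_\text{base} \cdot g_\text{goal} \cdot
  10^{(\delta_s (s-1) + \delta_b (b-1))/10}.$$

Artifacts are raised-cosine pulses (band-limited, deterministic peak,
default 150 uV over 0.4 s) whose amplitude is adjusted so a &plusmn;75 uV
threshold scan is guaranteed to flag every injected interval. The default
artifact rate of 8 events/min makes roughly a quarter of 1-s analysis
windows artifact-contaminated, the rejection burden a realistic training
session produces. All random streams derive from a counter-based split of
the master seed per (subject, session, stage), so records are reproducible
under reordering.

Two calibration caveats are deliberate and documented rather than corrected:

* The Hann taper smears power across the band edges, so the *absolute*
  measured band-mean power of the narrowband component sits ~20--25% below
  its nominal target; modulation-to-rest *ratios*, the quantity the analysis
  consumes, are unaffected (envelope scaling is exact, as the tests verify
  to 1e-10).
* Background and alpha power leak a small additive component into the theta
  band, diluting measured gain ratios by ~2% at the defaults, with ~2.5%
  Welch sampling error on top per session; the calibration tests therefore
  assert the 5% tolerance on means over several generator seeds.

## The virtual shooter and psychophysics

Enemy hit probability follows the two-parameter logistic constrained through
(`tet50_ms`, 0.5) and (`tet90_ms`, 0.9). Mechanistically, a log-normal shot
latency (median `rt_median_ms`, log-SD `rt_spread`) must beat the exposure
time for a shot to register (otherwise the trial is an omission), and the
hit probability is apportioned conditionally on firing so the *marginal* hit
rate equals the psychometric exactly -- verified by binomial oracles at both
thresholds. Friendly targets draw a commission with probability
`commission_prob`; the commission shot's latency is truncated at the
exposure time. Reaction time is the trigger time of the hitting shot for hit
targets and of the first shot for missed ones; omissions contribute none.

Schedules implement the task composition exactly: 360 targets per condition,
40 per location cell (3 lanes x 3 distances), an exact 324:36
enemy-to-friendly split (4 friendly per cell, which makes the 0.90 enemy
proportion and commission denominators exact), split into 4 blocks of 90.
Inter-target intervals are truncated discrete Gaussians on the
500--1500 ms/100 ms lattice ($\sigma$ = 250 ms, half the stated range, since
the protocol gives a range and a shape but no SD); the familiarization
schedule uses the 1000--3000 ms lattice ($\sigma$ = 500 ms) with exposure
times uniform over the twelve 100-ms bins from 400--1500 ms. Per-target
exposure times in the main task are drawn from a normal distribution
centered on the individualized threshold (`tet50_ms` under High time
stress, `tet90_ms` under Low) with $\sigma$ = 100 ms, rounded to 1 ms and
clipped to [400, 1500] ms -- a documented stand-in, since the mapping from
thresholding results to the full exposure-time distribution is not fully
specified by the protocol. Within a session all subjects share one target
sequence (lanes, identities, intervals) with individualized exposure times,
reshuffled between sessions.

The thresholding procedure (`run_iptp()` + `method_of_limits()`) presents 10
alternating ascending/descending series over 11 exposure levels and fits a
binomial GLM with logit link, pooling series; the 50% and 90% inverses are
the thresholds. At this trial budget a single replicate carries up to ~20%
sampling error on the 90% threshold, so recovery is asserted on the mean
absolute error across 20 replicate experiments (~5%).

## Offline analysis choices

* Highpass: zero-phase linear-phase FIR (FFT convolution with group-delay
  compensation), ~3.3 $f_s$ taps for a 1 Hz transition band; decimation uses
  an anti-alias FIR at 80% of the target Nyquist.
* Epoch windows are half-open and 0-based in samples; events too close to
  the record edges are dropped and counted.
* Rejection criteria: amplitude &plusmn;100 uV; joint probability (mean
  negative log-likelihood under a Gaussian fit to the pooled amplitude
  distribution) more than 5 SD above the across-epoch mean; abnormal trend
  requiring *both* |slope| > 75 uV per 1-s epoch *and* $R^2$ > 0.3
  (conjunctive, mirroring the reference tool's behavior); z-scored sample
  kurtosis > 5 SD. Distribution-based criteria need at least 8 epochs and
  nonzero variance, else they are skipped with a warning. On clean Gaussian
  epochs the false-positive rate stays under 5%.
* The dB reference for task power is the pre-trial baseline period mean
  (-3 to 0 s for modulation trials, -1 to 0 s for shooting trials); with a
  3-s baseline the per-trial dB carries visible small-sample noise, which
  averaging over the six trials per block absorbs.
* Retention percentages are rounded half-up to 2 decimals.

## The statistical stage

Outcomes are analyzed with REML mixed models (`lme4`), with reporting owned
by the package. Coding follows the model equations as printed: Group INC = 0
/ ALT = 1, Modulation Down = 0 / Up = 1, Condition Low = 0 / High = 1,
session and block uncentered at their 1-based values. The four-step ladder
fits the intercepts-only model, adds level-1 predictors, adds session (with
its interaction with the trend-bearing level-1 predictor, plus a random
session slope), then adds group and its interactions. ICC is
$\tau_0 / (\tau_0 + \sigma^2)$; the design effect is $1 + (n-1)\,\text{ICC}$
with the cluster size defaulting to the observations per subject (30 for the
training table: 6 blocks x 5 sessions); the fixed-effects pseudo $R^2$ is
the variance of the fixed-effects-predicted values over the outcome
variance. Fixed-effect p-values use the Wald z reference by default
(switchable to Satterthwaite via `lmerTest`). Singular fits are flagged with
variances floored at zero rather than refused. Simple slopes evaluate
$b(g) = \beta_\text{focal} + g\,\beta_\text{int}$ with delta-method SEs.
Responders are subjects for whom a univariate regression of theta on session
*or* on modulation code is significant at two-sided $\alpha$ = 0.05 (the
union of two screens, so the null responder rate is bounded near 0.10).

One coding consequence matters for power: with uncentered predictors, the
`session:group` coefficient of the *full* three-way model is the group
difference in session slopes extrapolated to block 0, which inflates its
standard error several-fold. The end-to-end detection property is therefore
evaluated on the Group x Session rung
(`y ~ modulation + block + session*group` with a random session slope),
whose coefficient is the effect the simple-slopes contrast reports.

## The generative cohort and what passing tests show

The band-power-level cohort generator (`simulate_cohort_fm_theta()`)
produces the training long table directly in dB:
grand mean -0.18, between-subject intercept variance 6.25 and residual
variance 1.76 (marginal SD 2.83, ICC 0.78 -- the intercepts-only
decomposition of the study-scale data), ALT mean session trend 0.32
dB/session and block trend 0.06 dB/block against INC trends of zero, and a
0.10 dB up-vs-down modulation effect. The between-subject session-slope SD
is set to 0.15 dB/session: an a priori power analysis at 12 + 18 subjects
puts the Group x Session Wald z near 3.8 under this heterogeneity, so the
pattern the cohort encodes is detectable in >= 80 of 100 replicates, which
is the designed property of the study conditions rather than an empirical
claim about human training effects.

`run_study()` exposes two engines. The `"power"` engine generates theta
tables at the band-power level and behavioral tables from the mechanistic
shooter -- this is the study-scale default, and what the 100-replicate
properties use. The `"eeg"` engine synthesizes full waveforms per subject
and session and pushes them through the closed-loop feedback pass (streaming
power, gating, threshold updates, block achievement) and the offline
spectral pipeline; it validates the signal path end to end and is exercised
on small cohorts. Property tests run the waveform generator at 256--512 Hz
and the cadence checks at the native 2048 Hz; statistical recovery suites
use 30 subjects x 30 observations with 100 replicates.

The virtual shooter's parameters are stationary across sessions: the
behavioral tables carry condition effects and between-subject structure but
no session-wise learning, so the behavioral model ladders demonstrate the
machinery on realistic scales rather than reproducing training-related
behavioral gains.

## Known limitations

* Single-channel only; robust referencing, bad-channel interpolation, ICA
  and dipole fitting are out of scope (the four-criterion rejection plus
  filtering stands in for the full multichannel cleaning chain).
* No EDF container I/O; records interchange as plain-text signal CSV, event
  TSV and parameter JSON.
* Narrowband absolute power calibration is approximate at band edges (see
  above); all dB quantities, being ratios, are unaffected.
* The generator does not emulate eye movements, cardiac or respiratory
  physiology, non-stationary artifact topographies, or behavioral learning
  across sessions -- passing tests certify the pipeline's arithmetic and its
  statistical operating characteristics under the generative model, not
  conclusions about human neurofeedback efficacy.
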