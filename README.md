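# nftheta

Simulation and analysis of closed-loop frontal-midline theta (Fmθ)
neurofeedback studies paired with a Go/No-Go shooting task.

## The problem

Neurofeedback protocols that train people to modulate 4–7 Hz power at
fronto-central midline sites couple a streaming EEG band-power estimate to a
visual display, so participants can push their own theta up (or down) against
an adaptive threshold. Evaluating such a protocol end to end involves five
coupled stages — protocol timing, the online feedback computation, the EEG
itself, offline spectral analysis with artifact rejection, and multilevel
statistics over subjects, sessions and blocks — and each stage has enough
numerical conventions (tapers, band definitions, gating rules, coding
schemes) that results are hard to reproduce without executable definitions.

`nftheta` provides those executable definitions as a tested R package, with a
synthetic-subject generator standing in for a human cohort so that every
stage runs and is verified without any recordings:

* **Protocol**: 5 training sessions × 6 blocks × 6 trials (10 s rest + 30 s
  modulation), i.e. 180 s active per block, 1080 s per session, 5400 s per
  subject; an *INC* arm (always up-modulate) and an *ALT* arm (3 Up + 3 Down
  blocks, never three equal goals in a row, uniform over the 14 valid
  arrangements).
* **Feedback engine**: theta power streamed from 1-s Hann windows (2048
  samples at 2048 Hz) with 1792-sample overlap — exactly 8 estimates/s —
  expressed as `10·log10(P / threshold)` dB, with a ±75 µV artifact gate
  that holds the last clean value, per-block goal-achievement percentages,
  and the session-to-session threshold update rule.
* **Synthetic subjects**: 1/f background, narrowband goal-responsive theta
  (power gains multiplicative, session/block trends in dB), alpha,
  raised-cosine artifact pulses, and a virtual shooter whose enemy hit rate
  follows a logistic psychometric through (TET50, 0.5) and (TET90, 0.9).
* **Offline analysis**: zero-phase 1 Hz highpass, 2048→512 Hz decimation,
  epoching, four-criterion artifact rejection (±100 µV amplitude, 5 SD joint
  probability, 75 µV/epoch ∧ R² > 0.3 trend, 5 SD kurtosis), Welch band
  power, pre-trial-baseline dB, retention accounting.
* **Statistics**: four-step REML model ladders (`lme4`) with random
  intercepts and session slopes, ICC = τ₀/(τ₀+σ²), design effect
  `1 + (n−1)·ICC`, fixed-effects pseudo R², delta-method simple slopes,
  assumption checks, and responder classification.

## Worked example

```r
library(nftheta)

study <- run_study(list(master_seed = 1))
study
#> <study_outputs> engine 'power', 30 subjects; NF table 900 rows, behavior 360 rows
#>   training Group x Session: b = 0.215 (SE 0.152), p = 0.158

m0 <- study$ladders$fm_theta_nf$intercepts_only
round(m0$icc, 2)
#> [1] 0.72
round(design_effect(m0$icc, 30), 2)
#> [1] 21.79
```

The simulated cohort (12 INC + 18 ALT subjects, 5 sessions × 6 blocks = 900
rows) shows strong between-subject clustering: 72% of theta variance lies
between subjects, a design effect of ~22, which is why the modeling stage is
multilevel. The full three-way model's `session:group` coefficient is the
slope difference *at block 0* (predictors enter uncentered), so the
group-by-session question is answered on the Group × Session rung with
simple slopes:

```r
fit <- fit_mlm(study$nf_table,
               model_spec(fixed = c("modulation", "block", "session * group"),
                          random_slope = "session"))
simple_slopes(fit, focal = "session", moderator = "group")
#>   level  slope    se    z       p
#> 1     0 0.0064 0.052 0.12 9.0e-01
#> 2     1 0.3726 0.043 8.76 1.9e-18
```

The INC group (level 0) shows no session trend while the ALT group (level 1)
gains ~0.37 dB of Fmθ per session — the qualitative pattern the generative
cohort encodes. Retention accounting works on plain counts:

```r
retention_stats(112794, 154620)$percentage
#> [1] 72.95
```

A full-waveform engine (`engine = "eeg"`) synthesizes per-session EEG
records and pushes them through the streaming feedback pass and the offline
spectral pipeline; see the methods vignette
(`vignettes/nftheta-methods.Rmd`) for the model, conventions, and
limitations. A thin command-line wrapper lives at
`inst/scripts/nftheta-cli.R` (`run`, `simulate`, `feedback`, `shoot`,
`stats` subcommands).

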