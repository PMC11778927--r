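---
title: "Models and methods behind icdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(icdyn)
library(dplyr)
```

icdyn analyses single-unit spike trains recorded while a subject performs an
auditory duration-deviation task, and ships a matched synthetic-session
generator so that every analysis can be exercised against inputs whose ground
truth is known exactly. This vignette explains the underlying models, the
defaults and why they were chosen, the numerical conventions, and what the
synthetic data do and do not establish about real recordings.

## The task and the session model

In the oddball task, each block presents 3–6 repeated 300 ms white-noise
bursts (the *standards*) separated by 600 ms of silence, followed by a final
sound whose duration is `300 × 1.19^n` ms for a deviant level `n` in 0..4;
level 0 is the control, where the final sound equals the standard. The
subject must press a button within 600 ms of the final sound's offset when it
was a deviant (a *hit*, rewarded at the press) and withhold the press on
control blocks (a *correct rejection*, also rewarded). The rounded ladder is
300, 357, 425, 506, 602 ms; `printed_ladder()` additionally provides the
conventional published stimulus list, whose top value is flattened to 600 ms,
so both the formula's output and the conventional set are representable.

A separate *reward protocol* dissociates reward effects from sound-driven
dynamics: a 1000 ms burst repeated 150 times at a 4 s interval, with a water
reward delivered 500 ms after sound offset in trials 51–100 only.

A session (`icdyn_session`) holds one unit's spike times (seconds from
session start) plus the trial tables of whichever protocol was run; window
bounds are always milliseconds, converted to seconds once at the windowing
boundary. Sessions serialise to a documented JSON schema
(`inst/extdata/session.schema.json`) with 17-significant-digit floats, so a
write/read round-trip is bit-exact and byte-identical.

## The synthetic firing-rate model

The generator (`simulate_oddball_session()`, `simulate_reward_session()`)
draws spikes from an inhomogeneous Poisson process by thinning against an
exact rate bound. The instantaneous rate is a sum of interpretable pieces
(`rate_model()`):

| component | default | role |
|---|---|---|
| `baseline_hz` | 10 Hz | spontaneous rate |
| `onset_peak_hz`, `onset_decay_ms` | 80 Hz, 20 ms | exponential onset transient per sound |
| `sustained_hz` | 20 Hz | plateau while the sound is on |
| `climb_slope_max_hz_per_s`, `climb_saturation_order`, `climb_start_ms` | 40 Hz/s, 4, 100 ms | linear late ramp, slope 0 for the first sound, saturating by the fourth |
| `reward_peak_hz`, `reward_decay_ms` | 300 Hz, 300 ms | reward transient |
| `reward_surprise_gain` | 1 | extra fractional amplitude for unpredicted rewards |
| `motor_peak_hz`, `motor_decay_ms` | 0 Hz, 100 ms | press-locked transient, off by default |
| `refractory_ms` | 0 | absolute dead time, applied by deletion |

Shapes were chosen for closed-form window integrals so that every statistic
has an exact oracle: the onset transient is exponential, the climbing effect
is a linear ramp from 100 ms after onset to sound offset (its slope grows
with the sound's order within the block and saturates at order 4 — no climb
on the first sound), and transients are truncated at 8 decay constants,
which makes the generator's stated `rate_max` an exact bound for thinning.
Amplitudes are in the range of strong auditory-midbrain units (onset
transients of ~100 Hz over baseline, instantaneous reward transients of a
few hundred Hz). The reward transient default (300 Hz peak, 300 ms decay)
was fixed by a design requirement on the generator itself: with the surprise
multiplier `1 + gain·exp(−(j−1)/5)` over reward trials `j`, the early-trial
amplitude excess must be reliably detectable in a 15-vs-15 trial contrast in
a 200 ms window, which a closed-form power calculation places at an expected
transient count (peak × effective decay time) of roughly 45 spikes; the
default gives non-centrality ≈ 3.5 for that contrast. The refractory default
is 0 so that spike counts in any window are exactly Poisson with mean equal
to the integral of the rate function — the generator's master invariant,
tested as such; a positive dead time (supported, tested) compresses counts
under strong transients by up to ~25% and would silently bias every
amplitude contrast.

Unpredicted rewards are the correct-rejection ones in the oddball task (the
subject did nothing to earn them) and the early reward-block trials in the
reward protocol; both receive the surprise multiplier. The reward latency
after a correct rejection is not a task constant, so the generator exposes it
(`cr_reward_delay_ms`, default 600 ms = end of the response window).

Choices come from a cumulative-Gaussian psychometric law evaluated at the
duration ratio (`behavior_model()`, defaults a = 1.3, b = 0.15, control
lapse 0.05): a subject that presses on ~5% of controls and >99% at the top
level, i.e. one that passes the behavioural QC below with realistic margins.
Reaction times are normal (300 ± 80 ms), truncated to the response window.
Note what the generator deliberately does *not* do: firing rates are
conditionally independent of the choice given the stimulus, so decision
analyses on simulated sessions have true detection probability 0.5 — a null
construction, which is exactly what makes it useful for calibration.

Blocks are separated by a 2.5 s silent gap (the animal consumes its reward
between blocks), which also guarantees that the truncated reward transient
of one block has fully elapsed before the next block's first standard — so
order profiles are not contaminated by reward tails.

Each session is reproducible from a single master seed; per-block child
seeds are derived by a fixed integer hash so a block's layout and spikes can
be regenerated independently.

## Windowed rates, PSTHs, and the Response Dynamic Index

All windows are half-open `[start, end)` in anchor-relative time, so a spike
on a shared edge is counted exactly once; an edge convention has to be fixed
somewhere, and half-open intervals compose cleanly into PSTH bins. Named presets: onset `[0, 60)` ms from sound onset, after-peak
`[100, 200)` ms from onset, late `[−100, 0)` ms from offset, and the reward
windows `[−200, 0)`, `[0, 100)`, `[0, 200)` ms around reward delivery.

The *Response Dynamic Index* quantifies the climbing effect for one sound:

$$\mathrm{RDI} = \frac{F_{\text{late}} - F_{\text{after-peak}}}{F_{\text{late}} + F_{\text{after-peak}}}$$

with 0/0 defined as 0 (no dynamic change detectable). The two windows do not
overlap only for sounds of at least 300 ms, which `compute_rdi()` enforces.
Across trials the package computes RDI per trial and averages
(`session_rdi()` plus ordinary `dplyr` grouping), rather than forming RDI
from trial-averaged rates: per-trial aggregation keeps unequal trial counts
from biasing level-wise means, at the cost of more small-count noise. Both
conventions are defensible; the per-trial one is the default because its
null distribution is symmetric about zero, which the test-suite exploits.

`compute_psth()` uses 10 ms bins and Gaussian smoothing with sigma 15 ms by
default — fine enough to resolve the 60 ms onset window, wide enough to tame
Poisson noise at tens of trials. Smoothing uses reflected boundaries with a
normalised kernel, which conserves the rate integral exactly (tested to
1e-9). `order_profile()` normalises per-order mean rates by the order-1
rate (a ratio, not a difference), matching how order profiles cluster
around 1 for flat responses.

## Reward analyses

`classify_reward_responsive()` implements the standard criterion: rate in
`[0, 100)` ms after reward vs `[−200, 0)` ms before, paired t-test across
reward trials, responsive iff p < 0.05. `prediction_error_contrast()`
compares the first and last `k = 15` reward trials in the `[0, 200)` ms
post-reward window and, as a specificity control, in the full sound window;
the two reward windows (classification vs contrast) are distinct presets and
never merged. The two-group comparison uses Welch's t-test by default —
equivalent to a one-way two-group ANOVA under equal variances, but robust to
the variance heterogeneity the decaying surprise amplitudes induce — with a
pooled-variance option for strict fidelity. Degenerate inputs (zero variance
everywhere) map to p = 1. `unexpected_reward_response()` applies the same
`[0, 200)` ms window to correct-rejection vs hit rewards in the oddball
session. All contrasts are functions of index-defined trial sets, so
permuting trial order within a set cannot change them (tested).

## Psychometrics and behavioural QC

The psychometric model is the Gaussian integral from 0 to the duration ratio
`r`, i.e. `p(r) = Φ((r−a)/b) − Φ(−a/b)`. The lower limit 0 is implemented
literally rather than renormalising to a CDF: the asymptote is
`1 − Φ(−a/b)`, which differs from 1 negligibly for any sane `a/b` but keeps
the implementation faithful to the printed form; the closed form is verified
against adaptive quadrature of the integrand to 1e-9. `fit_psychometric()`
maximises the binomial log-likelihood over `(a, log b)` with multi-start
Nelder–Mead (least squares on ratios available for comparison); flat or
all-0/all-1 data are reported with `converged = FALSE` and a warning rather
than a silently absurd spread. No lapse/guess parameters are fitted — the
model has none, and the control-level lapse lives in the simulator, not the
fit.

Session-level QC (`session_qc()`) keeps a session only if the control press
ratio is below 0.1 **and** the maximal-level press ratio is above 0.85, both
strict, mirroring standard behavioural inclusion criteria for this task.

## Detection probability

`roc_auc()` is the Mann–Whitney construction — the fraction of
(press, no-press) trial pairs where the press rate is larger, ties counting
half — computed from midranks, which is algebraically the same as exact pair
enumeration (tested for exact equality on random instances, including heavy
ties). `permutation_test_auc()` shuffles class labels preserving class
sizes and reports the two-sided add-one p-value
`(1 + #{|AUC*−0.5| ≥ |AUC−0.5|})/(n_perm + 1)`; when the total number of
label arrangements is at most `n_perm` it enumerates them all exactly
instead. The default 1999 permutations resolves p-values down to 5e-4.
`detection_probability()` applies this to one deviant level at a time —
never pooled across levels — with the late window on the final sound as the
default rate window, configurable because the decision-relevant window is
ultimately a modelling choice.

## Problem sizes and what the tests show

The test suite validates the chain at sizes chosen to make Monte-Carlo
error bars meaningful while keeping a full run in a few minutes: 30–40
blocks per level for single-session checks, 100–500 seeds for calibration
and recovery loops (permutation type-I error over 500 datasets; AUC recovery
against the two-normal closed form `Φ(Δ/(σ√2))` over 500 seeds per shift;
RDI slope recovery over 100 seeds per slope; reward contrasts over 200
seeds). Passing these shows the *estimators* are correct and calibrated
under the generator's assumptions — Poisson spiking, additive rate
components, choice independent of rate. Real recordings violate all three in
interesting ways (non-Poisson variability, adaptation, genuine
choice-related activity), so the suite validates the measurement chain, not
the biology.

## Known limitations

* The generator is phenomenological: no biophysics, no acoustic waveforms,
  no spike sorting; spike trains are (optionally dead-time-thinned) Poisson.
* Rate components are additive; multiplicative gain interactions are not
  representable.
* `fit_psychometric()` fits no lapse parameter, so a subject whose top-level
  press ratio saturates below 1 will bias `b` upward.
* The permutation test treats trials as exchangeable under the null; slow
  drifts in excitability would violate that.
* Reader support covers the package's own JSON schema only, not vendor
  electrophysiology formats.
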