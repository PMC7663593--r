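---
title: "The relative-gamma stress pipeline: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The relative-gamma stress pipeline: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Psychosocial stress leaves a spectral signature in the EEG: under load,
fast (gamma, 25–45 Hz) activity tends to rise relative to the slower
idling rhythms (theta 4–8 Hz and alpha 8–13 Hz). The **relative gamma**

$$ RG = \frac{P_{\gamma}}{P_{\alpha} + P_{\theta}} $$

condenses this into a single per-epoch ratio, usable as a time-resolved
stress biomarker during a structured session: eyes-closed rest (RS1, 2
min), stress induction with the Montreal Imaging Stress Task (3 min
training + 6 min timed arithmetic under social-evaluative pressure), a 5
min relaxation block, and a closing rest (RS2, 2 min). `rgstress`
implements the complete analysis for such sessions — filtering, epoching,
artifact handling, band power, the biomarker, group aggregation and the
survey statistics — together with a synthetic generator that emulates the
statistical structure of the recordings, so every stage is testable
without access to any data.

Two facts shape the design. First, only the central minute of each
resting block is analysed (the ends are contaminated by instructions and
posture changes), giving a 16-minute analysis window and, at 2-second
epochs, exactly 480 biomarker samples per subject:
$480 = 16 \cdot 60 / 2$. Second, the sign of the stress–RG relationship
differs across people: *direct responders*' RG rises with stress,
*inverse responders*' falls. Polarity must be detected and the inverse
series inverted before any group averaging, otherwise the two groups
cancel.

## The processing chain

For each subject, `process_session()` applies, in order:

1. **Concatenation** (`concatenate_blocks`): RS1 central minute | MIST
   training | MIST task | relaxation | RS2 central minute. Block
   boundaries are carried along as a 0-based half-open sample map.
2. **Band-pass** (`bandpass_filter`): order-2 Butterworth, 1–50 Hz,
   applied forward–backward per channel. "Order 2" refers to the
   prototype before the two passes; the magnitude response is effectively
   4th order and the net phase is zero, so no biomarker feature is
   delayed. Edge transients are controlled by odd-symmetric padding of
   three filter orders.
3. **Notch** (`notch_filter`): an RBJ biquad at 50 Hz with quality factor
   30, also zero-phase, removing power-line coupling while leaving 10 Hz
   content attenuated by well under 1 dB.
4. **Epoching** (`epoch_signal`): non-overlapping 2 s epochs. Two seconds
   gives 0.5 Hz spectral resolution — enough to separate the band edges —
   while keeping the biomarker's time resolution useful.
5. **Artifact zeroing** (`reject_artifacts`): any epoch-channel whose
   peak absolute amplitude exceeds 100 µV is set to zero and masked.
   The threshold is evaluated *before* normalization (z-scoring would
   destroy the µV scale the rule is defined on). Masked epoch-channels
   are excluded from the channel average rather than averaged in as
   zeros, which would silently bias power downward; an epoch with all
   channels masked becomes a missing value.
6. **Detrend + z-score** (`detrend_zscore`): per epoch-channel, the
   least-squares linear trend is removed and the residual scaled to unit
   variance. An epoch-channel whose residual is numerically zero
   (relative to its own scale — e.g. a pure ramp) is left at zeros and
   reported rather than amplified into rounding noise.
7. **Band power** (`band_power`): a raw rectangular-window periodogram
   per epoch-channel — in a 2 s segment there is no room for Welch
   averaging at 1 Hz-class resolution — normalized so the one-sided bin
   sum equals the segment's mean square (Parseval). Bins belong to a band
   if $low \le f < high$, so the shared edges of the classical table
   (4, 8, 13, 25 Hz) are never double-counted. Delta and beta are
   computed and exported even though only theta, alpha and gamma feed the
   biomarker.
8. **Relative gamma** (`relative_gamma`), then linear interpolation of
   missing epochs (`interpolate_missing`), 19-point centered moving
   average (`smooth_moving_average`), resampling to 480 points
   (`resample_to_length`), polarity classification
   (`classify_responder`) and orientation (`orient_rg`).

Group curves are pointwise means with SEM (`grand_average_sem`); a
degree-6 polynomial (`fit_poly6`) suppresses residual fluctuation before
the two groups' curves are correlated (`pcc_with_ci`).

### Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| band-pass | 1–50 | Hz | EEG band of interest; order 2 prototype, zero-phase |
| notch | 50, Q = 30 | Hz | mains coupling; narrow enough to spare gamma |
| epoch length | 2 | s | 0.5 Hz resolution vs time resolution trade-off |
| artifact threshold | 100 | µV | amplitude rule on raw scale |
| smoothing span | 19 | epochs | centered window: center + 9 on each side |
| resample length | 480 | epochs | 16 min at 2 s per epoch |
| polynomial degree | 6 | — | smooth, non-monotone session arc |
| CI level / alpha | 0.95 / 0.05 | — | conventional |

The smoothing span deserves a note: a "20-sample" moving average is not
realizable as a *centered* window; the centered form with the 9
preceding and 9 following epochs has 19 points, and that is the form
implemented (even spans are rejected with a hint). The span is the main
lever on the biomarker's latency: a step change is smeared by 9 epochs
(18 s) on each side, so phase-locked features appear shifted by roughly
20 s.

### Statistics

Survey (SPSL) responses are 1–5 integers at four instants (T1 before
RS1, T2 after the MIST, T3 90 s into relaxation, T4 at its end). With
tiny ordinal samples, normality is not tenable: a **Lilliefors** test
(KS against a normal with estimated moments) is computed and reported,
and the **Wilcoxon signed-rank** test is used for all comparisons
regardless of the gate's outcome. The Wilcoxon implementation follows
the classical discard rule for zero differences (the reduction in n is
recorded on the result), midranks ties, and uses the *exact*
sign-assignment null — computed by dynamic programming over doubled
ranks, so midranks stay integral — whenever the effective n is at most
25; beyond that a tie-corrected normal approximation with continuity
correction takes over. Exactness matters here: with n = 10 and many
ties, approximate p-values can cross the 0.05 line in either direction.
The Lilliefors p-value comes from a seeded Monte-Carlo null (10,000
draws by default) rather than critical-value tables, which are coarse at
these sizes; the null depends only on n and can be precomputed and
shared (`lilliefors_null_stats`).

Correlation intervals use the Fisher transformation with n = 480 curve
points. Two caveats are deliberate and documented rather than
"corrected": the 480 points of a smoothed curve are strongly
autocorrelated, so these intervals describe the curves, not an effective
number of independent observations; and the four-point SPSL–RG
correlation is reported without any interval at all. Between-group
Wilcoxon tests pair subjects positionally, which requires equal group
sizes. No multiple-testing correction is applied, and the output says
so.

## The synthetic generator

`generate_session()` emulates exactly the features the pipeline
consumes, no more:

* **Band structure.** Each channel is a sum of five Gaussian components,
  one per classical band, made by filtering white noise forward–backward
  with a 4th-order Butterworth band-pass. The double pass (an |H|⁴
  magnitude) is needed for spectral hygiene: with a single pass, the
  −3 dB skirts of a loud band leak over 20% of a quiet neighbour's
  variance budget (beta into gamma is the worst pair at the default
  amplitudes). Component powers are then calibrated *jointly*: the 5×5
  in-band gain matrix (how much variance each component delivers into
  each band) is solved against the per-band targets
  $\mathrm{ASD}^2 \times \mathrm{bandwidth}$, so each band's in-band
  variance is on target in expectation despite residual cross-talk.
* **Amplitudes.** Default amplitude spectral densities (µV/√Hz): delta
  2.0, theta 1.5, alpha 2.0, beta 0.8, gamma 0.3 — a conventional
  resting-EEG profile chosen once; no published amplitude or SNR figures
  exist for the recordings this generator stands in for, so these are
  field-plausible values, not derived ones. The implied resting relative
  gamma is about 0.07.
* **Stress coupling.** A deterministic latent trajectory $s(t) \in
  [0,1]$ scales the gamma amplitude by $(1 + d\,s(t))$ and theta/alpha
  by $(1 - d\,s(t))$ for direct responders (signs swapped for inverse
  responders), with modulation depth $d = 0.5$ by default. Depths of
  0.3 and above are reliably recoverable by the classifier through the
  full chain.
* **The trajectory** is zero at rest, rises exponentially during the
  MIST (30 s onset constant) to a peak of exactly 1 at the end of the
  task, and decays during relaxation with a 60 s constant toward a small
  *negative* asymptote (clipped at zero, undershoot 0.12). The undershoot
  makes the level cross zero at about 2¼ minutes instead of approaching
  it asymptotically; a gentle rebound (level 0.12, 60 s constant —
  boredom, re-engagement) then lifts the level again, so the group curve
  attains a clear minimum one to three minutes after relaxation onset
  and recovers toward the resting level through RS2. A pure exponential
  with the same constant would place the minimum at the end of the
  block and never below ~0.13 at two minutes, contradicting the shape
  the pipeline is expected to recover.
* **Nuisances.** Optional 50 Hz line coupling (2 µV default) exercises
  the notch; Poisson-placed 200 ms raised-cosine transients of 150–300
  µV on 1–3 random channels (2/min default) guarantee the 100 µV rule
  fires, at a rate that keeps the masked fraction well below 9% of
  epoch-channels per subject.
* **Cohorts.** `make_cohort()` builds 20 subjects, alternating
  control/test assignment, drawing direct polarity with probability
  7/17 — echoing the observed prevalence of direct responders — and
  deriving per-subject seeds from one master seed. Everything is
  bit-reproducible given that seed.

What the generator does **not** emulate: 1/f background beyond the band
mixture, physiological artifact morphology (blinks as dipoles, EMG
bursts), electrode drift, inter-channel correlation structure, or any
mechanism behind responder polarity. Green tests therefore certify the
*pipeline's* behaviour on band-structured signals with known ground
truth — they do not certify biomarker validity on real recordings.

Surveys are simulated as rounded, clipped Gaussians around phase means
(default 2, 4, 2.5, 2 at T1..T4, sd 0.7), which reproduces the expected
significance pattern (rest vs stress significant, no between-group
differences) in essentially every draw.

## Numerical and degenerate-input choices

* Indexing is 0-based half-open everywhere a boundary map appears.
* The central minute of a block of n samples starts at sample
  $\lfloor (n - 60\,r)/2 \rfloor$; a 61 s block at 250 Hz yields samples
  125–15124.
* Resampling is linear interpolation (the method of the original
  resampling being unstated, interpolation is the choice that preserves
  affine sections and endpoints exactly); at the target length it is the
  identity.
* Polynomial fitting rescales the abscissa to $[-1, 1]$; degree-6
  monomials on raw indices 0–479 are numerically hostile.
* Responder ties ($\Delta = 0$) classify as direct; orientation is
  reflection about the series mean, an involution that preserves mean
  and variance so oriented series remain averageable.
* A Wilcoxon sample with all differences zero returns p = 1 with a note,
  not an error; a constant Lilliefors sample is an error.
* Filtering before vs after concatenation: the recordings are
  concatenated first, accepting small transients at block joins (the
  zero-phase filter's padded edges make these brief); this mirrors the
  stated processing order of the study design the pipeline follows.
* Whether z-scoring should precede the PSD at all is moot for the
  biomarker: relative gamma is a ratio of same-epoch band powers and is
  invariant to any common rescaling of the epoch (verified numerically
  in the tests).

## Problem sizes used by the test suite

The suite generates everything it needs at run time: shortened protocols
(e.g. 60/30/120/120/60 s blocks, often at 100 Hz) for I/O and unit
tests, the full 18-minute 250 Hz protocol for end-to-end checks, a
200-subject cohort at depth 0.3 for polarity recovery, 2,000 paired-null
replicates for the Wilcoxon size check, 1,000 replicates for Fisher
interval coverage, and a 10,000-draw Monte-Carlo Lilliefors null shared
across the normality tests. These sizes were chosen to make the
statistical assertions sharp at their stated tolerances.

## Known limitations

* The periodogram is the only PSD estimator wired in; a hook for
  alternatives exists in the configuration but is deliberately untested
  surface.
* Fisher intervals on autocorrelated curves (above) are descriptive.
* EDF support covers the continuous 16-bit EDF+C subset this package
  writes — integer sampling rates, one annotation stream — not the whole
  format family.
* The between-group positional pairing is an assumption; with unequal
  groups the tests refuse to run rather than silently switch to an
  unpaired statistic.
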