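---
title: "Detecting stride-cycle oscillations in behavioural performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stride-cycle oscillations in behavioural performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridecycle)
```

## The problem

During walking, the body passes through a stereotyped cycle — footfall,
double support, swing, footfall — roughly every 0.6 s per step, 1.2 s
per stride. If perception or action is modulated by this cycle, the
modulation is invisible in trial averages: targets appear at arbitrary
moments, and each participant walks at their own cadence. The analysis
implemented here makes the rhythm visible by re-expressing every
behavioural event in *stride time*: the percentile of the concurrent
stride at which the event occurred. Pooling hundreds of events per
participant yields a densely sampled single stride in which accuracy,
reaction time and response likelihood can be examined for periodic
structure.

This vignette documents the models, the tunable parameters, the
synthetic-data generator used for validation, and the design decisions
taken where the method leaves room for choice.

## Gait extraction

Vertical head position oscillates nearly sinusoidally during walking,
with one trough per footfall (the double-support phase) — so a 90 Hz
head trace from a tracked headset is a sufficient gait signal. Per
trial:

1. **Detrend** (`detrend_height()`): a least-squares line is removed so
   slow drift does not bias trough prominence.
2. **Trough detection** (`detect_troughs()`): local minima with
   prominence at least `min_prominence_frac` (default 0.25) of the
   robust (5–95 percentile) height range, separated by at least
   `min_separation_s` (default 0.35 s — below the fastest plausible
   step of ~0.4 s). Candidates are located on a lightly smoothed copy
   of the trace (0.15 s moving average); each accepted trough is then
   refined, either to the raw sample minimum when the trace is
   effectively noise-free (noise estimated from second differences) or
   to the vertex of a local quadratic on the smoothed trace otherwise.
   The two-branch refinement keeps noise-free troughs exact to the
   sample while keeping noisy troughs stable inside the flat bottom of
   the arc.
3. **Stride epoching** (`epoch_strides()`): a stride is a trough to the
   second-next trough (two steps). Strides can be enumerated
   overlapping (advance one trough) or tiling (advance two); both are
   provided because the enumeration is not dictated by the method
   itself. For *event assignment* the tiled enumeration is the coherent
   choice — overlapping strides double-cover every instant, and any
   single-assignment rule over them folds all event phases into half
   the cycle, which would contradict the flat 1–100% target density
   that random probing must produce. Overlapping enumeration remains
   useful for averaging stride-locked head-height curves.
4. **Resampling** (`resample_stride()`): each stride is linearly
   interpolated onto 200 phase points (0.5% steps). At 90 Hz a stride
   contains ≥ 60 raw samples, so higher-order interpolation would
   change nothing material.
5. **QC** (`qc_trials()`): trials are rejected for signal drop-out
   (inter-sample gap > 3 frame intervals, or non-finite heights), flat
   signal, median step duration outside [0.35, 1.0] s, or fewer than 3
   troughs. Rejection reasons are logged.

Phase is trough-anchored: 0% is a footfall, ~25% is mid-swing of the
first step. Left/right foot identity is not distinguished, so a phase
of x and x + 50% differ only by which foot struck first.

## Stride projection

`assign_stride_phase()` places each event in the stride containing it,
with half-open intervals `(start, end]`: an event exactly at a footfall
belongs to the stride that footfall ends (phase 100%). Events before
the first stride, after the last, or in QC gaps are dropped with
counted reasons; rows are conserved.

`bin_series()` averages events in `n_bins` linearly spaced bins over
(0, 100]. The reference analysis uses 40 bins for strides and 20 for
single steps; 100 and 200 are supported for robustness checks. Empty
bins propagate as missing and are dropped by the Fourier fit, never
imputed. Reaction-time series use hits only; accuracy uses all targets;
response likelihood is the density of *response* onsets (normalised to
mean 1), the direct analogue of a response-rate curve. An alternative
target-locked definition (fraction of targets answered, binned by
target phase) is available by binning the hit indicator as a mean — the
wording of the quantity supports both readings; the density reading is
the default because the quantity is about when responses are emitted.

`clocktime_series()` is the control: the same events folded modulo
fixed 1 s epochs of trial time. A genuine stride-locked modulation
survives stride-locking but smears under clock-locking whenever stride
duration varies across trials and participants.

## The oscillation model

At each frequency $w$ (cycles per stride) the binned series $y(x)$,
$x \in (0, 1]$ the stride fraction, is fit with

$$f(x) = a_0 + a_1 \cos(2\pi w x) + b_1 \sin(2\pi w x)
       = a_0 + A\cos(2\pi w x + \varphi),$$

$A = \sqrt{a_1^2 + b_1^2}$, $\varphi = \mathrm{atan2}(-b_1, a_1)$. For
fixed $w$ this is linear least squares, which attains exactly the
optimum that an iterative non-linear fit would; the closed form is used
throughout and is verified in the tests against a brute-force
amplitude/phase grid search. $R^2 = 1 - SS_{res}/SS_{tot}$ (defined 0
for a constant series) is the fit statistic. The sweep covers 0.2–10
cps in 0.2 steps (50 frequencies); the best frequency is the argmax,
ties broken toward the lower frequency.

**Permutation null.** Outcome values are shuffled across events within
each participant — exactly equivalent to shuffling the events' bin
allocations — the binned series are rebuilt, the group average is
re-formed, and the sweep is re-run. Each permutation contributes its
maximum R² across the 50 frequencies; the 95th percentile of these
maxima is the family-wise critical value. For density measures a
shuffle of outcomes is a no-op, so the null instead redraws each
event's bin uniformly, conserving the event count while destroying
phase structure. 1000 permutations is the reference setting; 200 is a
fast setting whose critical value is within Monte-Carlo noise (the
tests check seed-to-seed stability of the criterion).

**Group vs participant level.** Group series are the equal-weight
average of per-participant binned series (participants with an empty
bin drop out of that bin's average); a pooled-events alternative was
considered and rejected as it weights participants by target count.
Participant-level tests compare each participant's own sweep with their
own permutation null. The max-statistic rule is the default at both
levels; a per-frequency 95th-percentile rule is available behind a
flag, because published participant-level analyses are often ambiguous
between the two. Frequency bands: significant participants are classed
as 2 cps (best frequency in [1.5, 2.5]), 4 cps ([3.5, 4.5]) or high
(> 5).

## Population prevalence

A participant-level test with false-positive rate $\alpha$ applied to a
population in which a fraction $\gamma$ truly carries the effect yields
positives at rate $\theta = (1-\gamma)\alpha + \gamma s$, with
sensitivity $s = 1$ by default (no power correction — exposed as a
parameter). With $k$ of $n$ significant and a uniform prior on
$\gamma$, the posterior is
$p(\gamma) \propto \theta(\gamma)^k (1-\theta(\gamma))^{n-k}$,
evaluated on a 2001-point grid and normalised by trapezoid; the MAP has
the closed form $\mathrm{clamp}((k/n - \alpha)/(s - \alpha), 0, 1)$.
The 95% HPDI is found by discrete water-filling: the shortest
contiguous grid interval holding ≥ 95% of the mass, which is robust to
the truncated-Beta shape of the posterior (the density has an atom-like
spike at 0 when $k/n < \alpha$). Coverage is verified by simulation in
the tests (93–97% across 500 binomial draws at $\gamma = 0.5$).

## Phase clustering

For participants with a significant ~2 cps oscillation, the phase of
the 2 cps fit is retained (at exactly 2 cps for every such participant,
even when their best frequency is 1.8 or 2.2, so phases are
comparable). `relative_change()` rescales series to $(x - \bar x)/\bar
x$ for cross-participant display; this divides fitted amplitudes by the
series mean and leaves phases untouched. Rayleigh's test uses
$Z = n\bar r^2$ with the second-order p approximation
$p = e^{-Z}\bigl(1 + \tfrac{2Z - Z^2}{4n} - \tfrac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\bigr)$;
this formula's correction factor turns negative when $Z$ approaches
$n$ (near-perfect clustering), in which case the standard exponential
approximation $p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1+2n))$,
$R = n\bar r$, is substituted — it is positive and monotone in that
regime. Circular variance is reported as $1 - \bar r$.

## QUEST staircase and psychometric fits

The staircase holds detection accuracy near 75% by maintaining a
posterior over the detection threshold on a grayscale grid (0.4–1,
step 0.004; the background is 0.4) in internal dB units
$\mathrm{dB}(c) = 20\log_{10} c$ — a convention recovered from the fact
that published staircase means around −7.1 dB correspond to grayscale
values near the 0.45 starting contrast. The prior is Gaussian in dB
(SD 2) centred at 0.45; the trial likelihood is the classic Weibull
$P(\mathrm{hit}) = \gamma + (1 - \gamma - \delta)\,
\bigl(1 - e^{-10^{\beta (x - x_T + \varepsilon)/20}}\bigr)$ with slope
$\beta = 3.5$, guess $\gamma = 0.5$, lapse $\delta = 0.01$, and
$\varepsilon$ chosen so that the threshold parameter is the 75%-correct
intensity. This offset is the standard QUEST parameterisation; without
it the procedure provably equilibrates at ~81% accuracy (the Weibull's
value at zero offset), not the 75% the staircase is meant to hold.

Each target's contrast is drawn uniformly from the seven posterior
quantiles at percentiles [25, 32.25, 37.5, 50, 62.5, 68.75, 75]
(levels Q−3 … Q+3); the first three familiarisation targets are fixed
at 0.45 and excluded from fits. The resulting spread of tested
contrasts supports an offline maximum-likelihood cumulative-normal fit
(`fit_psychometric()`) with fixed guess 0.5 and free lapse ≤ 0.05,
reporting the 50% threshold ($\mu$), the 5–95% width
($3.29\,\sigma$) and the maximum slope. The staircase's internal
Weibull and the offline cumulative normal are deliberately different
families — the staircase needs only a serviceable trial likelihood,
while the offline fit is the measurement model.

Note one equilibrium subtlety, verified in the tests: feeding the
staircase alternating single hits and misses (50% accuracy) at its own
mean has *no* fixed point — 50% is the guess floor, approached only as
intensity → −∞ — so the posterior escapes upward. The staircase's
actual equilibrium signal is the 75% rate.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which every downstream guarantee is validated. Defaults emulate
the study design the analysis was built for:

- 36 participants; 9 s walking trials at 1.1 m/s sampled at 90 Hz;
  stride duration drawn per participant from Normal(1.18 s, 0.069 s),
  per-step jitter 0.069/√2 s.
- Head height built from per-step raised-cosine arcs (one trough per
  footfall, two per stride) rather than a global sinusoid, so duration
  jitter accumulates realistically; half peak-to-trough amplitude
  0.025 m; measurement noise SD 0.002 m; optional linear drift. Trials
  begin at a uniformly random stride phase, since recording onset is
  independent of footfall timing — without this the target-phase
  distribution would be phase-locked and non-uniform.
- Eight target anchors per trial with ±0.5 s uniform jitter, a 10%
  chance of withholding each target, and a 0.8 s minimum inter-target
  interval enforced after jittering by pushing a violating onset
  forward to `predecessor + 0.8 s`. The stated design implies 7.2
  presented targets per trial in expectation (the reference experiment
  reported an empirical 6.99 — the generator follows the stated
  design). A strict spacing that would make jitter enforcement
  unnecessary (anchors ≥ 1.8 s apart) cannot host 8 targets in 9 s, so
  post-hoc enforcement is the only layout consistent with the design.
- Outcomes: hit ~ Bernoulli(p) with
  p = base ± A·cos(2πfx + φ) at the event's true stride fraction x;
  base hit rate 0.75, oscillation amplitude and frequency
  participant-specific. Hit RTs share the oscillation (anti-phase
  configurable), with Gaussian noise and a 0.15 s floor; each hit emits
  a response event at onset + RT; misses emit nothing. False alarms
  default to none.
- All randomness derives from one master seed through documented
  arithmetic sub-seeding (`derive_seed()`), so cohorts regenerate
  byte-identically.

What the generator does *not* emulate: biomechanics beyond vertical
head oscillation, eye-movement dynamics beyond what the gaze-QC module
needs, attentional drift, fatigue, or any coupling between gait and the
staircase. Passing tests therefore demonstrate that the pipeline
recovers known structure from data shaped like walking-psychophysics
sessions — not that real data meet the generator's assumptions.

## Numerical choices and degenerate inputs

- Frequencies on the sweep grid are exact multiples of 0.2 (rounded),
  so band comparisons like "within ±0.2 cps" are not perturbed by
  binary floating point.
- Constant series: R² is defined 0 (not NaN); the sweep then breaks the
  all-equal tie toward 0.2 cps.
- Rank-deficient designs (a frequency resonant with the bin grid) are
  skipped and reported as missing rather than fitted.
- The HPDI water-filling runs on the trapezoid cumulative integral; the
  MAP is reported from the closed form and cross-checked against the
  grid argmax.
- Blink repair uses modified-Akima (makima) slopes, implemented
  directly from the weight formula; the implementation is cross-checked
  against classic Akima behaviour on uniform nodes. Like MATLAB's
  makima, it weights long-gap secants more than classic Akima, so
  repair error grows with signal frequency × gap length; for
  gaze-pursuit-scale signals and blinks ≤ 300 ms the error is a few
  percent of signal amplitude.
- Blink detection pairs a departure jump with an opposite-signed return
  jump within 0.5 s (a displaced-and-back excursion), then merges
  intervals closer than 100 ms; a lone square discontinuity is thus one
  blink, not two.

## Known limitations

- The sweep's argmax under pure noise is not uniform across the grid
  (neighbouring frequencies share most of their fit and split wins);
  this is irrelevant to inference — which relies on the max-statistic
  null, not on argmax symmetry — but argmax histograms of null data
  should not be over-interpreted.
- Participant-level significance with ~900 events and 40 bins has
  limited power for amplitudes much below ~0.1; prevalence estimates
  inherit that via k.
- The generator's uniform-phase targets make the binned design balanced;
  real data with strong phase-dependent target loss (e.g. gaze
  exclusions clustered at footfall) would unbalance bins, which the
  fitting handles (missing bins) but the tests do not exercise deeply.

## Problem sizes used in the validation suite

Module tests run at reduced but structurally faithful sizes (hundreds
of events, tens of trials). The acceptance-level checks run at the
study's own scale: 900 targets per participant, 36-participant null
cohorts for type-I calibration (200 cohorts, 200 permutations each),
100 seeded recovery runs at 2 and 4 cps, 20 staircase runs of 600
targets, and 500 posterior draws for HPDI coverage — sizes chosen to
make the binomial tolerances on each claim meaningful.
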