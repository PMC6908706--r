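---
title: "Methods: dyadic entrainment analysis of step-onset data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic entrainment analysis of step-onset data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsync)
```

`stepsync` analyses rhythmic entrainment between two walking individuals
from annotated footfall onsets. This vignette documents the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and the limits of what the accompanying tests demonstrate.

## Data model

The unit of observation is a *bout*: one continuous episode of joint
stepping, bounded by its first and last onset. Each onset carries a time
(seconds, non-negative), a subject role (`front` or `hind` — the two
positions in single-file walking), and a bout id. Onsets are re-sorted on
ingestion and validated (strictly increasing per subject per bout; duplicate
timestamps for one subject are rejected as physically impossible). Times are
serialized at millisecond precision, finer than the ~0.04 s frame
resolution of video annotation, so simulator output round-trips exactly.

Annotation reliability between two coders is quantified by greedy
one-to-one nearest-neighbour matching of onsets within a tolerance (default
0.5 s — about half a step period, robust to steps missed by one coder).
Unmatched onsets are counted, not penalized. We summarize the signed
differences by their median absolute value and SD, plus an Anderson–Darling
statistic against a normal with estimated moments; with fewer than 8 pairs
or zero variance the statistic is undefined and reported as `NA`.

## From onsets to tempo and lag

Each subject's step train becomes a 100 Hz *pulse series*: a unit impulse
at the sample nearest each onset. Smoothing uses a third-order Butterworth
low-pass applied forward and backward (zero phase), so an impulse maps to a
symmetric kernel centred on itself and event peaks are never displaced in
time. The cutoff (default 4 Hz) must pass the ~1.1 Hz stepping fundamental
while suppressing sampling shimmer; it is configurable, as is the order.
Edge transients are tamed by odd-reflection padding of `6 * (order + 1)`
samples, capped at the series length.

Tempo is the lag of the maximum of the autocorrelation — Pearson
correlation of the series with itself on the overlapping segment per lag —
restricted to a window of plausible periods (default 0.5–1.5 s). A true
period below the window surfaces through its first harmonic inside it, which
is the desired behaviour for a bounded search. Between-subject lag is the
argmax of the cross-correlation over ±0.5 s; correlation is computed at the
native 10 ms lag resolution and then restricted to a 1/24 s grid (the video
frame grid annotation inherits) by nearest native lag, avoiding resampling
artefacts. Ties at the maximum break toward the smallest absolute lag —
conservative toward the synchrony null. Positive lag means the hind subject
trails the front.

The pipeline's *reference period* is the peak of the per-bout, per-subject
autocorrelation profiles averaged on the common lag grid. When tempo varies
substantially across bouts this pooled peak can sit above the mean step
duration (long-period bouts and in-window harmonics of short-period bouts
both pull it up); the per-bout median is also reported, and when no bout is
long enough for the window the pipeline falls back to the pooled mean step
duration.

## Circular statistics

Step timing is mapped to angles on the reference period T (360° = T) via
`angle = 360 * ((x mod T) / T)`. Two bases are supported:

- **Interval basis (default).** Each inter-step interval is an angle; an
  interval exactly equal to T is 0°. This measures *tempo consistency* and
  is robust to slow tempo drift. It is the basis on which concentrated
  distributions (R̄ well above 0.5) arise for entrained walkers whose tempo
  nevertheless wanders across bouts.
- **Onset basis.** Each onset is an angle relative to the subject's first
  step of the bout. This measures *phase locking to a strict isochronous
  grid*: any tempo drift accumulates, wraps the angle repeatedly, and drives
  R̄ toward zero over long bouts. It is the right tool only when tempo is
  near-constant.

Summaries are the textbook resultant-vector quantities: mean direction,
mean resultant length R̄, circular SD `sqrt(-2 ln R̄)` (one of several
conventions; reported in degrees), and the Rayleigh uniformity p-value from
the standard large-sample approximation. Mean directions are compared
across groups by the Watson–Williams high-concentration F test with the
`1 + 3/(8 kappa)` correction, kappa estimated from the within-group mean
resultant length by Fisher's approximation. The test assumes concentrated
von Mises samples; results carry a `low_concentration` flag when any
group's R̄ falls below 0.45. Perfectly concentrated groups (zero
within-group dispersion) are handled explicitly: F is 0 when the group
means coincide and infinite otherwise. Association between the two
subjects' angles, paired by step index within bout, uses the
Jammalamadaka–Sarma circular correlation; its p-value is the standard
asymptotic normal approximation and its 95% interval a percentile bootstrap
over paired resamples (default 1000, fixed seed, caller RNG untouched).

## Leadership (Granger) analysis

Two formulations are implemented.

**Event domain (default).** The generative observable is the step time, so
the test lives there too. For each direction, the responder's next
inter-step interval is regressed on its own `p` interval lags (default
`p = 1`, the standard first-order linear phase-correction model) plus `p`
lagged step asynchronies to the partner; the partner leads when the
asynchrony terms improve prediction (restricted vs full OLS). Because
entrainment coupling is by construction a *positive corrective* gain, the
default test is one-sided on the signed t of the summed asynchrony
coefficients (`alternative = "two.sided"` switches to the joint F). The
asynchrony integrates the responder's own past — an error-correction
regressor — so under the null the statistic is not F/t distributed;
p-values therefore come from a recursive residual bootstrap under the
restricted model (default 199 replicates). The accompanying calibration
test and the acceptance script verify on hundreds to thousands of
uncoupled simulated bouts that the per-direction rejection rate sits at the
nominal 5% level. Bouts with fewer than about 8 common steps cannot support
the regression and are flagged degenerate (`classification = "none"`).

**Series domain.** The classical alternative fits a bivariate VAR by
equation-wise OLS to the two smoothed 100 Hz pulse series, selects the lag
order by AIC on a common estimation sample over a grid up to 0.3 s (a
single global order, summed AIC across bouts; ties to the smaller order),
and applies the textbook Granger F per direction. This mirrors how such
data have been analysed with standard VAR tooling and is retained for
comparability (`granger_domain = "series"`), but it should be interpreted
with care: the smoothed pulse series is an oversampled, nearly
deterministic signal, its OLS residuals are strongly autocorrelated, and
the nominal F reference is anticonservative there. Moreover own-lags capped
below one step period cannot encode a walker's own phase while the
partner's synchronized series can, which biases tightly entrained dyads
toward a `bidirectional` verdict irrespective of the true coupling
direction. These are properties of the procedure, not of the
implementation; the event-domain default avoids both.

In either domain each bout is classified at `alpha = 0.05` per direction
(`front_leads` / `hind_leads` / `bidirectional` / `none`), without
multiple-testing correction across bouts by default (a Benjamini–Hochberg
option exists, `p_adjust = "BH"`).

## The synthetic coupled-walker generator

`simulate_dyad()` draws, per bout, a duration uniform on 2.6–48 s and a
period `T_b ~ N(0.89, 0.15)` s truncated to [0.5, 1.6] s, then steps both
walkers forward by the phase-correction update

    t_{k+1} = t_k + T_b + N(0, 0.03) - g * (t_k - s_k),

with `s_k` the partner's nearest onset. Defaults (base tempo 0.89 s, drift
0.15 s, motor noise 0.03 s, 28 bouts) were chosen once to emulate reported
synchronized bipedal walking in chimpanzees: they yield pooled step
durations with mean ≈ 0.85–0.9 s and SD ≈ 0.15 s, per-bout mean tempi
inside 0.8–1.5 s, and bout durations averaging ≈ 25 s. Coupling defaults to
symmetric gains of 0.25 (mutual entrainment, asynchrony halved each step —
in phase within a couple of steps, as observed in the behaviour); the
asynchrony recursion `d_{k+1} = (1 - g_f - g_h) d_k` makes gains sum to 1
an exact one-step lock and gains of 1 each a bounded sign-flipping
alternation. A step-duration floor of 0.1 s prevents physically impossible
steps under extreme parameters. `null_dataset()` sets both gains to zero
with independent periods and a random initial phase — the null for
calibration. One seed drives everything; the same seed gives byte-identical
serialized output, and the realized per-bout periods are attached for
parameter-recovery checks.

What the generator does *not* emulate: annotation error (onsets are exact
to 1 ms, whereas human coding has ~0.05 s discrepancies), missed or
spurious steps, pauses and resumptions inside a bout, turning or obstacle
negotiation, and any biomechanics (it is a point-process timing model).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated timing model, not robustness to every artefact
of real video annotation.

## Numerical choices and degenerate inputs

- Impulse placement is nearest-sample; two onsets landing on one sample is
  an error (impossible at real stepping rates and 100 Hz).
- Correlation at a lag returns `NA` on degenerate overlaps (constant
  segment, fewer than 3 points); profiles ignore `NA`s when locating peaks.
- Angles are hard-wrapped into [0, 360); the anchor maps exactly to 0°.
- Rayleigh p is clamped into (0, 1]; kappa estimation clamps R̄ at
  1 − 1e−6.
- VAR designs are solved by QR; rank deficiency (constant series) raises a
  degeneracy error that the pipeline converts into a flagged `none`
  classification, and degenerate bouts are dropped from the AIC sum.
- Bouts with fewer than 2 onsets per subject are excluded and listed;
  aggregate statistics that lose their prerequisites are reported as absent
  and named in the report's `insufficient` field.
- One-sample tempo comparisons against reference gaits (0.81 s wild,
  1.21 s captive — configuration constants, not magic numbers) error on
  zero variance, except the exact-equality case which returns t = 0, p = 1;
  the pipeline skips them when pooled step durations are constant to within
  1e−9 s.
- End-to-end determinism: dataset + configuration + seed fix every number,
  including bootstraps (per-bout seeds derive from the configuration seed),
  so reports are byte-identical across runs and invariant to input row
  order.

## Problem sizes in the test suite

The suite exercises the oracle checks on trains of 14–30 beats, circular
oracles on samples of 15–200 angles with a 10,000-draw permutation check of
the Watson–Williams p, null calibration of the leadership test on 2000
uncoupled bouts, leadership recovery on 200-bout runs (strong one-way
coupling: full correction, motor noise 0.01 s; strong symmetric coupling:
gains 0.5/0.5), and tempo recovery against the realized generative periods
(tolerance 0.02 s). These sizes keep the full suite in the minutes range on
one CPU while leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

- The pooled-autocorrelation reference period is biased upward when tempo
  varies widely across bouts (see above); for such data consider
  `per_bout_period = TRUE` or the interval basis with the per-bout median
  period.
- The Watson–Williams test is a high-concentration approximation; for
  diffuse samples the permutation approach used in the tests is the safer
  inference.
- The event-domain leadership test conditions on the driver's observed
  onsets; it tests corrective coupling, and anticipatory strategies
  (negative mean asynchrony with prediction) are reported only insofar as
  they manifest as corrective structure.
- Bouts shorter than ~8 steps carry no testable leadership information;
  they are flagged, not classified.
- `r_js` pairs steps by ordinal index within bout, which is appropriate for
  near-unison stepping; heavily skipped steps would misalign pairs.
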