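---
title: "Methods: waveform turnover around electrolytic lesions"
author: "perilesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform turnover around electrolytic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilesion)
```

## The problem this package addresses

Electrolytic lesioning through a chronically implanted intracortical
array (a Utah array: 10 x 10 grid, 400 um pitch, 1 mm shanks, 96 wired
channels) makes it possible to kill a small, controlled volume of
cortex while continuing to record from the surviving population with
the same electrodes. Because the probe never moves, activity recorded
before and after the injury can be compared directly. The scientific
question is then: *did the lesion change the recorded population, and
by how much, relative to the array's natural day-to-day turnover?*

This package implements that analysis end to end:

1. **Spike pipeline** -- raw 30 kHz multichannel voltage to accepted
   action-potential snippets and per-electrode event rates.
2. **Turnover statistic** -- per-electrode, per-day-pair change in the
   median radius of waveform clouds projected into the previous day's
   top two principal axes (delta-r), mixture modelling of pooled
   delta-r with BIC component selection, five-way change categories,
   and percent match across the array.
3. **Group statistics** -- pre-pre / pre-post / post-post day-pair
   groups and Mood's median test with Bonferroni correction.
4. **Lesion physics** -- cone/sphere lesion-volume estimation, an
   exponential volume-duration model, and the analytic electrical
   bounds of the constant-current lesioning device.
5. **Synthetic recordings** -- a ground-truth generator emulating the
   array, so every stage is testable without animal data.

## The spike pipeline

Each channel is high-pass filtered with a fourth-order Butterworth at
250 Hz, applied forward and backward (zero phase; the effective
magnitude response is the squared single-pass response). Because
causal IIR passes have start-up transients, the trace is extended at
both ends by odd reflection (up to 1000 samples) before filtering and
the extensions are discarded afterwards; a constant input maps to
essentially zero everywhere, including the edges.

Events are threshold crossings at **-4 x RMS**, where the RMS voltage
is measured over the first minute of the filtered trace (the whole
trace when a session is shorter -- desk-scale simulations are). The
threshold is computed per channel. Each downward crossing is resolved
to the sample of peak depolarisation -- the minimum within the
following 32 samples -- and 48-sample snippets are cut as the 16
points before the trough, the trough, and the 31 points after
(1.6 ms at 30 kHz, trough at index 17). The nominal "16 preceding and
32 proceeding points" sums to 48 only if the trough is counted inside
the 32; this convention makes that explicit. After an accepted event,
crossings within 48 samples are ignored, so one spike cannot yield
overlapping snippets.

Quality control rejects snippets whose peak-to-trough amplitude
exceeds 300 uV (atypical of cortical extracellular recordings with
this probe) or whose width exceeds 1 ms. Width is defined as the
separation between the two prominent peaks of the temporal
derivative; since "prominent" is ambiguous for arbitrary waveforms, it
is made concrete as the distance between the global maximum and global
minimum of the snippet's first difference. Event rates divide accepted
counts by an effective duration that starts at the first accepted
event anywhere on the array (configurable to the full duration), which
excludes inactive lead-in before a session really starts.

## The turnover statistic

For each electrode and day, up to 1000 accepted snippets are sampled
uniformly without replacement, re-aligned so each trough sits at index
17, and standardised per waveform (mean 0, SD 1 across the 48
points). Standardisation deliberately removes amplitude: a pure gain
change is not turnover.

For a day pair (a, b), the basis is the top two principal axes of the
day-a matrix, and both days' waveforms are projected onto it. The
axes are computed from the *uncentred* standardised matrix (its
leading right singular vectors), and radii are measured from the
origin -- the zero waveform. This choice is load-bearing. The first
axis of an uncentred waveform matrix is essentially the dominant
waveform shape itself, so a point's radius measures how much of its
unit-variance energy lies in the previous day's waveform subspace:

- matching multi-unit composition: radius unchanged, delta-r near 0;
- silenced or lost units replaced by noise or unfamiliar shapes:
  projections collapse toward the origin, delta-r strongly negative;
- a cleaner or newly dominant unit aligned with the previous day's
  shapes: delta-r positive.

Had the matrix been column-centred first (the textbook PCA
convention), the top axes would capture *contrasts around the
centroid*; tight matching clouds would then have *small* radii and
noise would have *larger* ones, inverting the sign semantics --
loss would read as a radius increase. We verified this numerically on
controlled simulations; the uncentred construction is the one whose
sign convention matches what the statistic is meant to express
(loss strongly negative, gain strongly positive). Each axis is
oriented so its largest-magnitude loading is positive, making the
projection deterministic.

The median radius uses the lower median for even counts, so a radius
is always an observed norm. `delta_r = r_b - r_a`.

### Mixture model and categories

Delta-r values are pooled per day-pair group across electrodes and
pairs (one distribution per group, not per electrode) and fit with 1-D
Gaussian mixtures, k = 1..5, by EM with 10 restarts per k under a
deterministic seed schedule; restarts initialise component means at
randomly drawn data points, values are sorted first so the fit is
invariant to input order, and component variances are floored at 1e-6
(with a warning) to prevent collapse. The reported k minimises
`BIC = -2 logL + (3k - 1) log n`, ties broken toward smaller k. These
per-group fits carry the cluster-count evidence: does an extra,
negative component appear in the pre-post pool?

The five change categories, by contrast, are defined once, from a
single *global* mixture over all groups' delta-r values. The *match
component* is the component whose mean is nearest zero ("the median
cluster value" is read as that single component's mean). With its
mean mu and SD sigma, categories are: `match` within one sigma,
`small_increase`/`small_decrease` between one and two sigma,
`large_increase`/`large_decrease` beyond two sigma -- five categories
tiling the line with no gaps. Using one reference definition keeps
percent-match values directly comparable across groups; had each
group's own fitted sigma defined its categories, the fit-to-fit
variability of sigma would shift all of a group's pairs coherently
and dominate the between-group comparison. Percent match divides
matching electrodes by the array's fixed 96-electrode denominator.

Electrodes with fewer than 100 accepted snippets on a day (`minEvents`)
cannot support a comparison. If both days are below the floor the
electrode counts as `match` -- nothing observably changed and the
denominator stays fixed. If day a is comparable and day b is
near-silent, the electrode is assigned `large_decrease` (putative
silencing); the mirror case is `large_increase`.

### Groups and test

Ordered day pairs separated by at most 4 days (24/48/72/96 h) form
three groups: `pre_pre` (both pre-lesion), `pre_post` (pre-lesion vs
acute post-lesion, up to 3 days after), and `post_post` (both in the
late window, post-lesion days 4-7). Pairs spanning the acute and late
periods are discarded. The 4-day limit is the default because it
matches the separations actually enumerated for the comparisons; a
3-day switch is provided since both limits appear in descriptions of
this design. The analysis window default is 13 contiguous days (4
pre-lesion, 9 post-lesion), configurable to 11 (4 + 7).

Mood's median test compares two groups' percent-match values: counts
above versus at-or-below the pooled grand median (ties count
at-or-below, a convention fixed for reproducibility) form a 2x2
table whose 1-df chi-square, without continuity correction (a flag
enables it), gives the p-value. Significance is declared at the
Bonferroni-corrected level alpha / 3 = 0.0167 for the three group
comparisons. Degenerate tables (all values identical) report statistic
0, p = 1.

## Lesion physics

Lesion volumes are estimated from histology or photographs with the
geometry observed in the tissue: cones (`V = pi r^2 h / 3`; a
histology slice is assumed to bisect the lesion) or spheres
(`V = 4/3 pi r^3`). Photo-sourced cones with unknown height use
height = radius. The volume-duration relationship for a fixed current
is modelled as `V = a e^{b t}`, fit by nonlinear least squares on the
original scale (a log-linear regression only seeds the optimiser), and
R-squared is likewise computed on the original scale. Durations are
tagged in minutes; the model stores its unit and never converts
silently, because the printed coefficient system for this fit cannot
be dimensionally reconstructed without the underlying volume table
(the bundled `synthetic_lesions.csv` is generated *from* the printed
model and therefore inherits its scale).

Device calculators are Ohm's-law identities: maximum drivable load
`(vcc - vee) / I` (6 MOhm at +/-450 V and 150 uA), maximum output
voltage `vcc - vee` (900 V), the parasitic parallel resistance
implied by excess current `V_supply / I_excess` (1.2-0.6 MOhm for
10-20 uA on a 12 V supply; negative excess indicates a capacitive
regime and is rejected rather than reported as negative resistance),
and the array-diagonal electrode span `sqrt(a^2 + b^2)`.

## The synthetic-recording generator

The generator emulates what the analysis consumes, not cortex. Design
choices, with defaults and reasons:

- **Geometry**: 10 x 10 grid, 400 um pitch, 1 mm shanks, four corners
  unwired -> 96 active channels.
- **Spike template**: difference of two Gaussians in time (sharp
  trough, slower positive rebound), trough-normalised. Two phases give
  the temporal derivative two prominent peaks, so the width QC rule is
  genuinely exercised. Shape parameters (trough SD 0.08-0.14 ms,
  rebound delay 0.3-0.5 ms, rebound fraction 0.35-0.55) vary across
  neurons so electrodes record distinguishable mixtures.
- **Amplitude-distance model**: exponential decay with a 28 um length
  constant, so amplitude at 140 um is ~0.7% of the at-source value;
  against the default 10 uV noise this confines resolvable units to
  roughly 50-140 um from a tip -- the multi-unit "hash" band reported
  for this kind of recording.
- **Population**: 12 neurons per electrode, placed 50-140 um from
  their home tip, parameterised by the trough amplitude *seen at the
  electrode* (uniform 65-185 uV) because that is the quantity real
  recordings constrain; firing rates log-uniform 0.5-20 events/s.
  Twelve per electrode keeps nearly all electrodes above the
  100-event comparability floor in the short desk-scale sessions the
  tests use.
- **Daily drift**: each *electrode's cluster* is independently hit
  with probability 0.05 per day, replacing one of its neurons (new
  shape, rate, and observed amplitude at the same location), and
  surviving amplitudes jitter by +/-5%. Turnover is parameterised at
  the electrode level -- the level the recordings observe -- so that
  natural turnover across the (at most 4-day) pair separations stays
  minimal, which is the premise of the day-pair design; per-neuron
  replacement at the same nominal rate would make nearly every
  12-neuron electrode change over 4 days.
- **Firing**: homogeneous Poisson, thinned to a 1.6 ms minimum
  inter-spike interval so a neuron's snippets never self-overlap.
- **Quantisation**: 0.25 uV per 16-bit code (300 uV = 1200 codes),
  typical acquisition-system resolution.
- **Lesion**: the lesion's volume (from an explicit value or a volume
  model) is inverted to a spherical kill radius centred at the
  midpoint of the anode/cathode tips; neurons inside die, and
  survivors in a 700-um annulus beyond the kill radius have amplitude
  scaled by 0.5 and rate by 0.8 (perturbed survivors: injured but
  recorded). The default simulated kill radius (1.3 mm) silences
  roughly a third of the recorded population; this is deliberately
  larger than the histological volumes the device produces, because
  the recorded perturbation in this preparation extends well beyond
  the histological core, and the simulation targets the *recorded*
  effect.

What the generator does **not** emulate: local field potentials,
pink/line noise, electrode impedance drift, bursting or
rate-nonstationarity, spike sorting into single units, or electrode
micromotion. Passing tests therefore demonstrate that the pipeline
recovers the statistics of this idealised preparation, not that it
would behave identically on real recordings with correlated noise and
non-Poisson firing.

## Numerical choices and degenerate inputs

- Zero-phase filtering pads by odd reflection (1000 samples or trace
  length - 1, whichever is smaller).
- RMS of a constant-zero trace is a degenerate-signal error, not a
  threshold of zero.
- All-identical waveform rows are a degenerate sample for projection.
- Rows whose 48 points have zero variance are dropped before
  standardisation.
- EM: tolerance 1e-8 on the log-likelihood, at most 500 iterations,
  variance floor 1e-6, BIC ties toward smaller k.
- Median radius: lower median. Median test: ties at-or-below; no
  continuity correction by default.
- All randomness flows through named integer seeds; no function draws
  from (or disturbs) the global R random stream.

## Problem sizes used by the test suite

The packaged tests run the full chain at desk scale: 96-channel
arrays, 13 daily sessions of 4 s each, 12 neurons per electrode, and
20 seeded replicates for the null-behaviour and lesion-detection
suites. Session duration is the one dimension scaled down relative to
real experiments (minutes to hours); the comparability floor and all
other analysis parameters are kept at their defaults, which is why
the generator's per-electrode yield is calibrated to clear the floor
in 4 s.

## Known limitations

- The turnover statistic is a population-level proxy; it cannot
  distinguish silenced-but-alive neurons from dead ones, and channels
  silenced outright leave the delta-r pool entirely (they are
  category-forced instead).
- Percent-match comparisons inherit a mild asymmetry from the group
  design itself: pre-post pairs may be separated by up to 4 days while
  pre-pre pairs within a 4-day pre-lesion window cannot exceed 3, so
  natural turnover contributes slightly more to pre-post differences
  even without a lesion.
- The exponential volume model's coefficient units are tied to the
  scale of the data that produced them; predictions are only
  meaningful in that system.
- Mood's median test on the small per-group sample sizes of a single
  13-day experiment has limited power; it is the conservative choice,
  not the most powerful one.
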