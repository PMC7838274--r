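---
title: "Event detection, synchrony and sEPSC clustering: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event detection, synchrony and sEPSC clustering: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibsir)
```

This vignette is the package's account of its methods: the detection model
and its assumptions, the tunable parameters with their defaults and units,
what the synthetic-data generators do and do not emulate, and the design
choices made where the procedure was genuinely open.

## The detection model

A recording is a uniformly sampled trace $y(t_i)$ — fluorescence in
arbitrary units (AU) around 1 frame/s, or membrane current in pA at 2 kHz.
Activity appears as transient deflections on a slowly wandering baseline,
so detection is referenced to the trace itself rather than to a fixed
threshold:

1. **Running median.** $m_i$ is the median of all samples within
   $\pm w/2$ of $t_i$; the window truncates at the recording edges. The
   median follows slow drift but not the (sparser) events.
2. **Traced reference.** The local extrema of $y$ on one side of $m$ —
   troughs below it for calcium, peaks above it for inward currents — are
   connected by linear interpolation into the reference $R(t)$, with both
   endpoints clamped so $R$ spans the recording. Plateaus of equal values
   contribute their first sample; a trace entirely on the wrong side of its
   median degenerates to a flat reference at the global extremum, with a
   warning.
3. **Waveform criterion.** The residual is
   $r_i = \mathrm{polarity}\,(y_i - R(t_i))$. Maximal runs with $r_i > 0$
   are candidates; a run is kept when Ramer-Douglas-Peucker (RDP)
   simplification of the run (plus its flanking baseline samples) at
   tolerance $\varepsilon$ retains an interior point. RDP retains an
   interior point exactly when the maximum deviation from the endpoint
   chord exceeds $\varepsilon$, so detection needs only that first split —
   the recursive simplifier itself, `rdp_simplify()`, is exported and is
   cross-checked against an independent recursive oracle in the tests.
4. **Quantification** uses the raw, unsimplified residual within the run:
   amplitude $\max r$, area under the curve by the trapezoid rule (charge
   transfer $Q$ in pA·ms for currents), duration, rise time
   $t_{peak}-t_{start}$, and peak offset $t_{peak}-(t_{start}+t_{end})/2$
   (negative = peak earlier than the event midpoint, so a *more negative*
   peak offset reads as faster activation). Events touching a recording
   edge are kept but flagged `boundary_truncated` and excluded from
   duration/rise-time means, whose extent is censored.

**Deviation metric.** RDP deviation is measured *vertically* (in signal
units at fixed time) by default rather than perpendicularly. Perpendicular
point-to-chord distance mixes seconds and signal units, so its result
changes under a pure rescaling of the signal axis; vertical deviation makes
detection equivariant — scaling $y$ and $\varepsilon$ by $c$ scales
amplitudes and areas by $c$ and leaves event boundaries unchanged, a
property the test suite asserts. `method = "perpendicular"` is available
for comparison.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `calcium_window_s` | 5 | s | running-median window for fluorescence (5-25 s is sensible) |
| `current_window_s` | 0.05 | s | running-median window for voltage clamp |
| `epsilon` | data-driven | signal units | detection tolerance; default `multiple * robust_noise(residual)` with `robust_noise = 1.4826 * median(|r - median(r)|)` |
| `epsilon_multiple_calcium` | 2 | — | robust-noise multiple for calcium traces |
| `epsilon_multiple_current` | 7 | — | robust-noise multiple for current traces |
| `cutoff_fraction` | 0.10 | — | drop events below this fraction of the cell's largest amplitude before per-neuron means |
| `silent_threshold_au` | 5 | AU | mean amplitude below which a cell is silent |
| `filter_cutoff_hz` | 200 | Hz | zero-phase low-pass for sEPSC detection |
| `filter_order` | 2 | — | Butterworth order per pass (4 poles after filtfilt) |
| `match_tolerance_ms` | 5 | ms | window for re-measuring amplitudes on the raw trace |
| `k_range` | 2-6 | — | candidate cluster counts for PAM |
| `wave_bin_s`, `wave_min_fraction` | 2, 0.5 | s, — | synchronous-wave criterion |

**Why two epsilon multiples.** The tolerance separates genuine waveforms
from noise excursions measured against the traced reference. A calcium
trace has a few hundred samples, and twice the robust noise suffices. A
180 s voltage-clamp trace at 2 kHz contains on the order of $4\times10^3$
noise gaps between traced envelope peaks; the largest of that many
excursions routinely reaches 4-6 robust-noise units, while the smallest
physiological sEPSCs (~10 pA on ~2 pA noise after filtering) sit above 9.
The default multiple of 7 therefore keeps the expected false-event count
per recording near zero without touching genuine events; both multiples
are configuration, not constants.

**Silent threshold.** The silent/active split is bimodal in practice —
noise-scale means (a few AU) against active means an order of magnitude
higher — so any threshold in the gap gives the same answer. The default of
5 AU is an explicit, reported analysis choice, and classification runs on
summaries computed *without* the amplitude cutoff: a cutoff normalizes
every cell to its own maximum, which would let a silent cell's noise
events masquerade as activity.

## Synchrony

The processed (reference-subtracted) recordings, min-max normalized to
$[0,1]$, are correlated pairwise within a culture (never across cultures).
Per cell, the off-diagonal correlations are averaged on the Fisher-Z scale,
$\bar r = \tanh(\mathrm{mean}(\mathrm{arctanh}\, r_{ij}))$, with $|r|$
clipped at $1-10^{-7}$ so perfect correlations stay finite; a zero-variance
trace correlates as 0 with a flag rather than erroring, keeping culture
matrices complete. Correlating the full processed traces (not binarized
event trains) preserves both shared waves and shared sub-threshold
structure. The synchronous-wave annotation — a 2 s bin in which at least
half the co-recorded cells have an event peak — has no published
quantitative definition; the criterion here is the package's own and is
recorded in the output metadata.

## sEPSC analysis

Detection runs on a zero-phase low-passed copy (order-2 Butterworth at
200 Hz applied forward and backward, i.e. 4 poles with no peak shift; a
steeper per-pass order rings on sub-millisecond rise times and creates
spurious side-lobe detections). Amplitudes are then re-measured on the
unfiltered recording as the extreme raw residual within 5 ms of each
filtered peak, matched one-to-one greedily in time order: when two
detections compete for one raw extremum the earlier wins and the later is
flagged `unmatched` (keeping its filtered amplitude) rather than dropped.

Each neuron's events are clustered independently by PAM (`cluster::pam`,
BUILD + SWAP, manhattan distance) on
$[\mathrm{IEI}_{ms}, \mathrm{amplitude}_{pA}, Q_{pA\cdot ms}]$, with
interevent intervals measured peak-to-peak and the first event (undefined
IEI) excluded. The number of clusters maximizes the average silhouette
width over k = 2-6, consistent with the 3-5 optima typical for these data.

**Feature scaling.** By default each feature column is scaled by its mean
absolute deviation (the same rule `pam`'s own `stand` option uses) before
clustering. On raw scales the manhattan distance is dominated by the
interevent-interval axis — thousands of ms against tens of pA — and the
average silhouette then prefers merging the two small-amplitude classes
over separating the long-interval one, even on noiseless ground-truth
features; scale balancing restores comparable influence to the three
physiologically meaningful axes and is what makes the three canonical
clusters (`small;short`, `small;long`, `large`) recoverable. Set
`standardize = FALSE` for raw-scale clustering.

**Labels.** The cluster with the largest medoid amplitude is `large`
(demoted to `medium` when k ≥ 4 and it is under twice the smallest medoid
amplitude); the rest are `small`, graded `short`/`mid`/`long` by medoid
interevent interval.

## The statistical battery

`fisher_exact_2x2()` uses the exact hypergeometric test with the
point-probability two-sided rule (the sum of all tables, at fixed margins,
no more probable than the observed one); an independent enumeration oracle
verifies it exhaustively for every table with total ≤ 30. Welch's ANOVA is
`oneway.test`; the Brown-Forsythe $F^*$ ANOVA (group means weighted by
$(1-n_i/N)s_i^2$, Satterthwaite denominator df) and the Games-Howell and
Dunn post-hoc tests are implemented here with their standard formulas —
Games-Howell on the studentized range with per-pair Welch-Satterthwaite
df, Dunn on rank sums with tie correction and Bonferroni adjustment (the
adjustment choice is documented because conventions differ). The two-way
repeated-measures ANOVA (between factor × pre/post) uses `aov` with an
error stratum per subject, followed by Sidak-adjusted paired contrasts
within each group, $p_{adj} = 1-(1-p)^m$. Degenerate inputs follow fixed
conventions: identical paired vectors give $t=0$, $p=1$; all-zero
differences give Wilcoxon $p=1$ (computed without continuity correction,
so antisymmetric differences also give exactly 1); a zero-variance group
under Welch is nudged by a relative $10^{-9}$ and flagged rather than
fatal. The D'Agostino-Pearson check is advisory only — it never switches a
test automatically.

## The synthetic generators

The calcium generator emulates a dish of co-recorded neurons: per cell, a
baseline (100 AU) plus a slow sinusoidal drift (period 60-180 s, random
phase, amplitude twice the noise sd) plus Gaussian noise (1 AU), with
difference-of-exponential transients (rise 1.5 s, decay 6 s, lognormal
amplitudes of mean 50 and sd 15 AU) at 0.05 Hz per active cell.
Network-wide waves arrive as a Poisson process (0.01 Hz) and each cell
joins each wave independently with probability `coupling_p`; participation
draws are shared uniforms, so lowering the coupling removes participants
without redrawing the rest — decoupling effects are paired at the cell
level. The first `round(frac_silent * n)` cells are silent (drift and
noise only), a deterministic assignment so condition effects can address
"all silent cells" reproducibly. One global seed drives a deterministic
sub-stream per cell; adding cells never perturbs existing ones. Kernel
peaks are renormalized to the realized sample grid, so a planted amplitude
is the amplitude actually present in the trace.

The sEPSC generator draws events sequentially: a mixture component by
weight, an interevent interval and an amplitude from that component's
Gaussians (truncated at one sample and 1 pA), then a bi-exponential kernel
$A(e^{-t/\tau_d}-e^{-t/\tau_r})$ ($\tau_r = 0.5$ ms, $\tau_d = 4$ ms,
peak-normalized) on 2 pA Gaussian noise, inward by convention. The default
mixture plants the three canonical clusters: amplitudes 15/15/80 pA,
intervals 20/2000/200 ms, all sds 20% of the mean, weights 0.4/0.2/0.4 —
the high-frequency small events most numerous, the long-interval class
rarest, as in recordings of this preparation.

**What the generators do not emulate:** photobleaching and indicator
saturation, spatially structured (distance-dependent) coupling,
conductance-based dynamics, event-shape variability beyond the fixed
kernels, and recording artifacts (seal drift, access-resistance changes).
Passing the end-to-end benchmarks therefore shows the pipeline recovers
what it models — Poisson-timed stereotyped events, Bernoulli wave
coupling, a Gaussian three-component sEPSC mixture — not that it is robust
to every failure mode of real data.

## Benchmarks and problem sizes

The `benchmark_*` functions freeze the study conditions used by the tests
and the acceptance script: detection on 20 networks of 20 cells × 300 s at
generator defaults, scored by containment (a truth event is recovered if a
detected event's span, ±2 s, contains its peak; a detection is true if it
contains a truth peak — fair to occasionally merged transients), with
precision computed after the 10% cutoff; the synchrony sweep on 15-cell
networks at coupling 0, 0.3, 0.6, 0.9 (10 seeds each); decoupling at
coupling ×0.25 on a 30-cell network; cluster recovery on ten 180 s
recordings; silent-fraction recovery on ten 100-cell networks with 20%
silent; and a planted interaction in 79 paired recordings (40 affected
cells at amplitude ×1.5). These sizes keep the whole battery within a few
minutes on one CPU while leaving the statistical margins wide; they are
choices of this package, reported here so they can be scaled up.

## Known limitations

- The reference line rides the noise extrema on its side of the median, so
  event amplitudes carry a small positive offset (~1 noise sd) relative to
  the true baseline; comparisons between conditions are unaffected.
- Overlapping transients closer than the kernel decay merge into one run;
  the containment scoring acknowledges this rather than hiding it.
- The running median is computed per window without incremental updates at
  the edges; for very long recordings at high rates the edge recomputation
  is O(window) per edge sample.
- `fold_change_grouping()` classifies an exact zero fold change as
  "decrease" (non-increase) by documented convention, and excludes cells
  with a zero pre-mean.
- k-medoids model selection is limited to the silhouette criterion; gap
  statistics or model-based alternatives are out of scope.
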