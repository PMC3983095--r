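---
title: "Detecting and quantifying spontaneous motor-circuit activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying spontaneous motor-circuit activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorsync)
```

`motorsync` analyses population calcium imaging of developing motor
circuits: 1 Hz fluorescence traces of a few dozen neurons over ten
minutes, in which each neuron fires occasional multi-second
depolarisations ("cycles") whose calcium correlates rise within about a
second and decay over several. This vignette documents the models and
procedures, the parameters that matter, the numerical choices, and what
the simulator-based validation does and does not establish.

## The cycle detector

A trace $s_t$ is optionally smoothed with a centred moving average
(truncated at the edges; default width 1, i.e. none, at the native 1 Hz)
and differenced, $d_t = s_t - s_{t-1}$ with $d_1 = 0$. With $\mu$ and
$\sigma$ the mean and standard deviation of $d$ over the *whole* trace, a
cycle onset is the first frame of each maximal run with
$d_t > \mu + k\sigma$ (default $k = 2$). Scanning forward, the cycle ends
at the first frame where $d$, having gone negative (passed through its
local minimum), returns to $\geq 0$; a cycle still open at the last frame
is closed there. Onsets are never raised inside an open cycle, so cycles
never overlap. Frames are 0-based and cycle intervals half-open.

Assumptions and consequences:

* **Per-trace statistics.** $\mu$ and $\sigma$ include the cycles
  themselves (no baseline-only exclusion is attempted), making detection
  exactly covariant under $s \mapsto a s + b$, $a > 0$ — raw arbitrary
  fluorescence units can be used without $\Delta F/F$ conversion. The
  flip side: the threshold adapts to activity, so a trace with many large
  events has a higher absolute threshold.
* **Amplitude anchoring.** At 1 Hz a ~1 s rise completes within a single
  inter-frame step, so the frame at which the differential first exceeds
  threshold already carries risen fluorescence. Amplitude is therefore
  peak intensity minus the *pre-rise* intensity
  (`min` of the onset frame and the frame before it). Anchoring at the
  onset frame itself would report near-zero amplitudes for fast
  transients and break the SNR definition below.
* **Power at low SNR.** A $2\sigma$ threshold on a differential crosses
  on roughly 2.3% of frames of pure Gaussian noise regardless of scale,
  and a rise that straddles a frame boundary splits its jump across two
  samples of at most $\sim A/2$ each against a threshold of at least
  $2\sqrt{2}$ noise s.d. on the differential. The detector is therefore
  reliable when transients are an order of magnitude above the noise —
  the regime of practical indicator recordings — but cannot reach high
  recall *and* precision near amplitude $= 5\times$ noise s.d.; the test
  suite documents this boundary honestly rather than hiding it.

**SNR and filtering.** A cycle's SNR is its amplitude divided by the
standard deviation of the trace outside all of that ROI's cycles
(`Inf` on noise-free traces, `NA` when no outside frames exist; the
original routine's SNR formula is not public, so this conventional
definition is a documented stand-in). Because of the 2.3% noise-crossing
rate above, raw detections on noisy data — including completely silent
neurons — contain spurious low-SNR cycles; all population statistics are
computed after discarding cycles with SNR < `snr_min` (default 6, midway
on a log scale between the SNR of spurious crossings, about 2–5, and of
genuine transients at realistic indicator SNR, ≥ 10). Note the sampled
peak underestimates the continuous kernel amplitude by up to ~20% when
onsets fall mid-frame, so reported SNR sits slightly below the nominal
amplitude/noise ratio.

## Episodes

An episode is one or more cycles with no intervening return of
fluorescence toward baseline. Successive cycles join one episode when the
minimum intensity between the earlier cycle's *peak* and the frame before
the next onset stays above the episode's primary-cycle pre-rise intensity
plus `baseline_fraction` (default 0.25) of its amplitude. Two choices
deserve note: the trough is sought between the peaks because a detected
cycle's offset can *be* the next cycle's risen onset frame (the
differential only returns to ≥ 0 when the next rise begins); and the 25%
tolerance reflects that chemical indicators decay slowly — a qualitative
"return to baseline" rule needs a quantitative slack. The threshold is
anchored to the episode's first cycle, whose baseline is the one the
trace must revisit.

## Synchrony

Network events are connected components of temporally overlapping cycle
intervals (transitive closure). An event is synchronous when it recruits
strictly more than `sync_threshold` (default 0.6) of the denominator
population **and** at least two neurons co-occur — a lone cycle is not
simultaneous with anything. Two conventions are configurable, and the
choice matters:

* **Denominator** — `"labelled"` (all ROIs; the default) or `"active"`
  (ROIs with ≥ 1 cycle). When fewer than 60% of labelled neurons are
  active at all — the rule at early developmental stages — no cycle can
  ever be synchronous under `"labelled"`; developmental-stage analyses
  therefore use `"active"`, which matches rasters drawn per active
  neuron.
* **Participation** — `"overlap"` (any cycle in the component counts; the
  default) or `"coactive"` (synchrony judged by the event's peak
  instantaneous co-activity). Calcium footprints last ~6 s at the default
  kernel, so chains A–B–C–D in which no two distant members ever coincide
  can span most of a small active set by chance; with few active neurons
  the overlap convention then labels a substantial share of early-stage
  cycles "synchronous" and inverts the developmental trend. Co-activity
  requires genuine simultaneity and coincides with overlap for true
  network events.

Pairwise correlation is Pearson's $r$ between binary occupancy series
(raw-trace correlation is available via `corr_mode = "raw"`; which of the
two the original analysis used is not stated). Zero-variance series have
no defined coefficient: such pairs are flagged invalid and excluded from
per-ROI means, never silently zeroed. Distance–correlation histograms bin
every valid unordered pair by centroid distance (10 equal bins over the
observed range) and coefficient (10 bins on $[0,1]$, negatives clamped
into the lowest bin), normalised to percent over all valid pairs.

## Voltage concordance

Voltage cycles are maximal runs exceeding a running-median baseline by
`depol_threshold_mv` (default 10 mV) for at least `min_duration_s`
(default 1 s — sub-second depolarisations are real but have no calcium
counterpart at 1 Hz and are excluded by construction). The baseline
median uses a 30 s window — much longer than a 2.7 s cycle, much shorter
than the minutes between episodes — and is computed on a decimated trace
and linearly interpolated back, exact for drift slower than the
decimation step (~30 ms) and ~170× faster than the full-rate median.
Matching is greedy one-to-one in time order within ±2 s (one frame of
discretisation either side of the ~1 s rise; events are ~1/min so ties
are practically absent, broken toward the earlier voltage cycle). The
matching window and voltage criteria are exposed because the original
values are not stated.

## Pharmacology comparisons

Each neuron's metric (frequency in cycles/min, or per-cycle length in s)
is divided by the mean baseline value *of its own embryo*; normalised
values are pooled and compared with a two-sided Mann–Whitney rank test
(group sizes differ and normalised ratios are not normal; Welch's t is
available — which test produced the original tables is not stated).
Baseline thus has mean exactly 1 by construction; an embryo with zero
baseline cycles cannot be normalised and its treatment neurons are
excluded with a warning. Complete blockade yields a normalised mean of
exactly 0.

## The simulator

`simulate_events()` draws neuron positions uniformly on a
400 µm × 400 µm field (~25 neurons, the observed field density), assigns
a firing pool of `active_fraction` of them, and generates:

* isolated events per pool neuron as a Poisson process
  (`rate_async_per_min`);
* network events as a field-wide Poisson process (`rate_net_per_min`),
  each seeded at a uniformly chosen pool neuron which always participates
  (the event has to start somewhere); every other pool neuron joins with
  probability $p \cdot \exp(-d^2 / 2\sigma_{rec}^2)$. The Gaussian kernel
  is a modelling choice — only the verbal "neurons recruit their
  neighbours" model is known — with $\sigma_{rec}$ (`recruit_scale_um`)
  controlling locality and $\infty$ giving global recruitment.

Every event instantiates an episode of 1–3 cycles (`p_doublet`,
`p_triplet`); network participants share the episode template, so their
cycles genuinely coincide. Cycle durations are Gaussian
(2.70 ± 0.9 s, truncated at 1.2 s so every cycle outlasts the sub-second
events the voltage detector must reject) and within-episode gaps Gaussian
around 3.2 s, floored at 1.5 s — the measured gap distribution has no
sub-1.5 s mass, and at 1 Hz a shorter gap is unresolvable. Same-neuron
events that overlap, or follow within 2 s, are merged: a neuron cannot
fire two independent cycle onsets within a couple of seconds
(post-episodic depression), and sub-frame-adjacent events are
indistinguishable at the imaging rate even in principle. An explicit
refractory period is available (`refractory_s`) but off by default.

`render_calcium()` gives each cycle a kernel rising linearly over
`kernel_rise_s` (1 s, the observed onset-to-peak) to `amplitude` and
decaying exponentially with constant `kernel_decay_s` (1 s), on a
baseline of 100 a.u. with i.i.d. Gaussian noise. Two numerical choices:
the decay is truncated to exactly zero below 0.5% of amplitude — with an
untruncated exponential the differential never returns to ≥ 0 on
noise-free data and the offset rule would never close a cycle — and the
default decay constant is anchored to the observed optical/electrical
duration ratio (optical cycles roughly twice as long as their ~2.7 s
voltage counterparts) rather than to the reported post-peak return
fractions; the two anchors are not simultaneously satisfiable with this
kernel shape. A consequence worth knowing: at the default fast decay the
trace returns essentially to baseline within a ~3.2 s intra-episode gap,
so doublet structure is under-grouped by the episode criterion; analyses
of episode structure should use a slower, chemical-indicator-like decay
(`kernel_decay_s` ≥ 3), as the episode tests do.

`render_voltage()` renders one neuron's truth at 1 kHz: −48.8 mV baseline
with 1 mV noise, +25 mV plateaus for each cycle, and injected sub-second
(+10 mV, 0.2–0.9 s) depolarisations with no calcium counterpart.

**Stage presets.** `HH23` → `HH30` encode the developmental progression
as increasing `active_fraction` (0.20 → 0.82, the reported range),
shifting weight from asynchronous events (1.45/min, the early-stage
frequency) to network events (~0.4/min, the episode rate implied by
~152 s inter-episode intervals), widening recruitment
($\sigma_{rec}$ 80 µm → ∞) and enabling doublet/triplet episodes at late
stages (cycle counts of ~2.5/episode). Intermediate values interpolate
and are modelling choices; only the qualitative progression is asserted
anywhere.

**What passing the simulator-based tests shows — and does not.** The
generator emulates Poisson timing, Gaussian recruitment, a fixed kernel
and additive white noise. Real recordings add photobleaching and drift,
movement artefacts, indicator nonlinearity and saturation, correlated
noise, irregular non-Poisson timing and heterogeneous per-neuron
kinetics — none of which are modelled. Recovery of generator parameters
therefore validates the *implementation* of each analysis stage and the
internal consistency of the chain, not detector performance on real
tissue; the reported per-stage statistics are properties of the presets,
not measurements of any biological preparation.

## Problem sizes and runtime

All validation runs use desk-scale sizes chosen to keep the full loop
fast while leaving the statistics stable: fields of 25–30 neurons at 1 Hz
for 600 s; 10 seeds per stage preset for trend statistics (pooled over
fields for cycle-level percentages, since per-field percentages are
ill-defined when a field has no cycles); 20 replicates per recruitment
scale for the distance-gradient contrast; 4 paired voltage/calcium
neurons for concordance; 3 embryos × 20 neurons per pharmacology arm. The
whole acceptance computation completes in well under a minute on one CPU.

## Known limitations

* Sub-second events are invisible by design at 1 Hz; the concordance
  module quantifies, not repairs, this.
* The detector's operating point degrades sharply below ~10× amplitude
  to noise; SNR filtering trades recall for precision there but cannot
  recover both.
* Synchrony percentages from fields with very few active neurons are
  unstable under the `"active"` denominator (chance co-activity); pool
  across fields, as the trend analyses do.
* Episode grouping depends on indicator decay; fast-decay data
  under-group, and the `baseline_fraction` default is a convention, not
  a fitted constant.
* No photobleaching correction, ΔF/F conversion, spike inference or ROI
  segmentation is provided; the pipeline starts from extracted traces.
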