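# motorsync

Analysis of spontaneous motor-circuit activity from population calcium
imaging of the developing spinal cord.

In the embryonic spinal cord, limb-innervating motor neurons fire
spontaneous depolarisations ("cycles") grouped into episodes long before
sensory input exists, and this activity reorganises over development from
sparse, asynchronous firing into network-wide synchronous events. Calcium
imaging of retrogradely or genetically labelled motor neuron populations
(typically ~25 neurons per field, 1 Hz, 10 min) records this activity as
fluorescence transients. `motorsync` provides the full analysis chain for
such recordings, plus a ground-truthed simulator so that every stage can
be validated without original recordings:

* **Cycle detection** — the derivative-threshold transient detector: a
  cycle onset is the first frame of each maximal run where the first
  differential of the trace exceeds `mean + 2·sd` of the differential
  (both per trace, so detection is covariant under affine rescaling of raw
  fluorescence), and the cycle lasts until the differential, having passed
  a local minimum below zero, first returns to ≥ 0. Per-cycle amplitude
  and signal-to-noise ratio (amplitude ÷ out-of-cycle s.d.) follow, and an
  SNR filter removes the spurious crossings a per-trace 2 sd threshold
  necessarily produces on noisy traces.
* **Episode grouping** — successive cycles form doublet/triplet episodes
  when the fluorescence fails to return toward baseline (within 25% of
  the primary cycle's amplitude) between them.
* **Synchrony analysis** — network events as maximal sets of temporally
  overlapping cycles; a cycle is synchronous when its event recruits
  > 60% of neurons (strict inequality; "labelled" or "active"
  denominator, overlap or instantaneous-co-activity participation);
  pairwise Pearson correlation of binary occupancy rasters (correlograms);
  per-neuron mean coefficients; 2-D distance-versus-correlation
  histograms.
* **Optical–electrical concordance** — running-median-baseline cycle
  detection on 1 kHz voltage traces, greedy one-to-one onset matching
  against optically detected cycles, onset accuracy and optical/voltage
  duration ratios.
* **Pharmacology comparison** — per-embryo baseline normalisation of
  cycle frequency or length with Mann–Whitney (or Welch) two-sided tests,
  the structure of drug-application tables (baseline mean ≡ 1.000).
* **Simulator** — Poisson asynchronous events per neuron plus network
  events recruiting neighbours with probability
  `p·exp(−d²/2σ²)` around a seed neuron, singlet/doublet/triplet episode
  structure, a linear-rise/exponential-decay calcium kernel, additive
  Gaussian noise, and paired 1 kHz voltage traces with injected
  sub-second depolarisations that calcium imaging cannot see. Stage
  presets `HH23 … HH30` encode the developmental progression.

## Worked example

Simulate a late-stage (HH St. 30-like) field and run the analysis chain:

```r
library(motorsync)

params <- stage_preset("HH30", seed = 42)
truth  <- simulate_events(params)
rec    <- render_calcium(truth)
rec
#> <fluorescence_recording> 600 frames x 25 ROIs at 1 Hz (10.0 min)
#>   stage:      HH30
#>   positions:  present

res <- analyze_recording(rec, sync_denominator = "active",
                         sync_participation = "coactive")
res$summary
#> <activity_summary> 22/25 ROIs active (88.0%)
#>   mean frequency (active ROIs): 0.73 cycles/min
#>   mean cycle duration:          4.75 s
#>   cycles in multi-cycle episodes: 2.5%
res$correlation
#> <correlation_result> 25 ROIs, 231/300 valid pairs, mean coefficient 0.488
res$split
#>     sync_label present n_cycles n_rois frequency_per_min mean_duration_s
#> 1  synchronous    TRUE      110     22         0.5000000        4.718182
#> 2 asynchronous    TRUE       51     14         0.3642857        4.745098
```

88% of neurons are active, the population mean pairwise correlation is
0.49 and 68% of detected cycles are synchronous — against a mean
correlation near 0 and no synchronous cycles for the `"HH23"` preset,
reproducing the developmental emergence of synchrony in direction. The
optical cycle duration (4.75 s) exceeds the underlying 2.7 s
depolarisations because the indicator decays over seconds; the low
multi-cycle share reflects the fast default kernel decay (see the
methods vignette).

File-based workflows use `read_recording()` / `run_pipeline()` (which
writes cycle, network-event, correlation, summary and histogram CSVs with
a seed-stamped manifest), or the CLI at `inst/cli/motorsync`:

```sh
inst/cli/motorsync simulate --preset HH28 --seed 3 --out sim/
inst/cli/motorsync run --trace sim/trace.csv --positions sim/positions.csv --out out/
```

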