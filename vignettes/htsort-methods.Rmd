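---
title: "Sorting dense multi-electrode recordings with htsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting dense multi-electrode recordings with htsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htsort)
```

## The problem

An extracellular probe with tens of contacts at 20–40 µm pitch records every
nearby neuron on several channels at once. Spike sorting recovers, from the
multi-channel voltage traces alone, *which* neuron ("unit") fired *when*.
`htsort` implements a pipeline built around three ideas:

1. **Divide and conquer.** Each detected spike is attributed to the single
   electrode where it is largest, and clustering is then performed per
   electrode group. Grouping by electrode is a spatial pre-clustering: two
   units with near-identical waveforms but different locations are separated
   before any waveform feature is computed.
2. **Density clustering with explicit outliers.** Within a group, snippets
   are projected onto their first two principal components and clustered
   with HDBSCAN. Points in low-density regions — background noise that
   crossed the threshold, and temporally overlapping spikes whose mixed
   waveform fits no cluster — are labeled `-1` rather than forced into a
   cluster.
3. **Template merging and matching pursuit.** Per-cluster mean waveforms
   become templates; redundant templates from neighboring electrodes (a unit
   sitting between two contacts is detected sometimes on one, sometimes on
   the other) are merged. Outlier snippets are then revisited by greedy
   template-matching pursuit, which peels overlapping spikes off one
   template at a time and discards what never matches.

## The model, stage by stage

### Preprocessing

Traces are bandpass filtered to 300–3000 Hz with a 3rd-order Butterworth
applied forward and backward (`bandpass()`). The zero-phase choice is
deliberate: peak alignment downstream is phase sensitive, and a causal filter
would shift every peak by a frequency-dependent delay. High-rate acquisitions
are resampled to a 14 kHz working rate (`resample_recording()`, polyphase
with anti-aliasing), which preserves the spike band while keeping the
threshold scan cheap.

### Detection

The per-channel noise scale is estimated robustly as
$\hat\sigma_n = \mathrm{median}(|X|)/0.6745$, where 0.6745 is the standard
normal inverse CDF at 0.75. Because spikes occupy a small fraction of
samples, the median of absolute values barely moves when they are added,
whereas the plain standard deviation inflates badly — this is the entire
reason the threshold $k\hat\sigma_n$ (default $k = 4$, conventional range
3–5) can be set automatically. A sliding window of `wnd_ms` = 3 ms emits a
snippet wherever the absolute amplitude is the strict maximum of its window
at the alignment position `p` = 0.5 (exact ties keep the earliest index;
windows overhanging the trace ends are dropped). Both polarities are
detected; thresholds are per channel, since noise need not be homogeneous
across a probe.

At 14 kHz a sharp trough spans only a few samples, so the integer peak index
is off by up to half a sample. `align_snippets()` (pipeline default on)
estimates the fractional offset by a three-point parabolic fit and resamples
the waveform by cubic spline so the true extremum lands on the alignment
sample. Without this step, one unit's snippets split into alignment classes
that look like distinct clusters.

### Duplicate suppression and grouping

Snippets whose peaks fall within `delta_t_ms` = 0.5 ms of each other *and*
whose channels are probe neighbors (Euclidean distance below `thres_nb`,
default 40 µm, conventional range 20–50 µm) are the same physical spike; the
relation is closed transitively so an event can chain across a run of
adjacent contacts. Only the member with the largest absolute peak survives
(ties to the lowest channel id), and survivors are grouped by channel.

### Per-group features and clustering

Each group gets its own PCA; only the first two components are kept — they
carry essentially all waveform variance above the noise floor, and a 2-D
space keeps density estimation well conditioned. Clustering is our own
implementation of HDBSCAN (no R implementation was available to build on):
mutual reachability transform with core distance at `min_samples` = 5
neighbors, minimum spanning tree, single-linkage hierarchy, condensation at
`min_cluster_size` = 10, and excess-of-mass cluster extraction. The
implementation agrees point-for-point with scikit-learn's HDBSCAN on
multi-cluster geometries (a test runs both on identical data).

Two extraction details matter at desk scale:

* The condensed root may itself be selected, so a group containing a single
  unit yields one cluster instead of being split or discarded.
* When the root never truly splits (common for a clean blob of ~50–150
  points at `min_cluster_size` = 10), membership of the selected root uses a
  GLOSH-style density cut at half the maximum lambda. The reference rule
  (persist to the maximum lambda) labels only the last dozen points of an
  otherwise clean blob, which starves template estimation.

Defaults `min_cluster_size = 10`, `min_samples = 5` make a unit that fires
at least ~10 times discoverable; both are configurable.

### Template estimation, screening, and merging

Templates are pointwise means (not medians) of cluster members, so that the
later cross-template averaging during merging stays consistent with the
estimation stage.

**Amplitude screen.** With a lenient threshold, chance noise crossings are
frequent enough (~20 per channel per 30 s at $k=4$) to form their own small
dense cluster near the feature-space origin. Averaging such a cluster yields
a "template" peaking near 4.3 $\hat\sigma$. The screen
(`min_template_snr` = 6) keeps a cluster only if its template peak reaches
6 $\hat\sigma$: any unit satisfying the pipeline's working assumption of raw
SNR ≥ 8 keeps a filtered peak of at least ~7.5 $\hat\sigma$ even for the
sharpest troughs the passband permits, while averaged chance crossings stay
below ~5. Rejected members return to the outlier pool.

**Shared comparison space.** Per-group PCA coordinates are mutually
incomparable, so for merging every template is peak-normalized and projected
onto a 5-dimensional PCA basis fit on the normalized template waveforms
themselves; Euclidean distance there is the merge metric, evaluated at the
best sub-sample relative lag (±2 samples in 0.25 steps) so residual
alignment jitter cannot masquerade as a shape difference.

**Merge rule.** Two templates merge iff their distance is below the
threshold *and* they live on the same electrode or neighboring electrodes;
the relation is closed transitively (union-find), which makes the result
independent of template order, and merging is iterated to a fixed point so
re-running it changes nothing. Merged waveforms are spike-count-weighted
means by default (`merge_weighted = FALSE` gives the plain mean), so a
five-spike spur cannot drag a five-hundred-spike template.

The distance threshold defaults to `merge_sigma` = 0.15 in this normalized
space. The conventional dimensionless value 0.05 presumes template SNRs that
half-minute recordings do not reach: a template estimated from $n$ spikes of
peak $A$ carries per-sample noise $\hat\sigma/(\sqrt{n}A)$ after
normalization, which alone contributes ~0.03–0.14 to the distance of a
same-unit pair. Measured across regimes, same-unit pairs fall below ~0.14
and distinct-unit pairs (after the spatial gate) above ~0.26, so 0.15
separates with about a twofold margin. When per-channel noise estimates are
available the threshold additionally widens by the statistically expected
estimation noise of the specific pair,
$\sqrt{\sigma^2 + z^2 k (s_i^2+s_j^2)}$ with $z = 2$ and capped at 0.25, so
a pair of dim, lightly supported clusters that is indistinguishable from one
noisy unit is still merged.

### Overlap resolution by pursuit

Every outlier snippet is revisited: a segment of twice the snippet length
centered on its peak is cut from its channel's filtered trace and pursued
against the *spatially admissible* part of the library — templates homed on
that channel or one of its neighbors. (A spike cannot physically register far
from its unit; without this gate, a distant template with a coincidentally
similar shape occasionally claims the spike.)

Each iteration finds, among all (template, lag) candidates whose normalized
cross-correlation exceeds 0.8, the one whose least-squares subtraction
removes the most residual energy, and subtracts the amplitude-scaled
template. Choosing by energy rather than by raw correlation matters for deep
overlaps: the correlation maximum of a two-spike mixture sits at a
compromise lag between the constituents. Acceptance additionally requires
the fitted amplitude to reach 6 $\hat\sigma$ — the scale-invariant
correlation alone accepts a few percent of pure-noise segments when the best
of ~40 lags × 10 templates is taken, and the fitted amplitude separates
those cleanly (noise ~2 $\hat\sigma$, real spikes ≥ 8 $\hat\sigma$).

The loop stops when the residual peak falls below `dtcTh` (set to the
channel's detection threshold), when no candidate is acceptable, or at
`max_pursuit` = 5 spikes (the result is then flagged truncated). If pursuit
stalls with spike-sized residual remaining, the last subtraction may have
been a compromise across a deep overlap: a rescue step re-fits it jointly
with a second atom (alternating backfit with local lag re-scan), accepting
the pair only if each atom passes the 0.8 rule on the residual the other
leaves. On segments small enough to enumerate, the resulting accepted sets
coincide with an exhaustive two-spike least-squares oracle.

On the matching metric: the normalized squared-difference form
$\sum(T-I)^2/\sqrt{\sum T^2 \sum I^2}$ is *minimal* at a perfect match, which
is incompatible with accepting the *maximum* score above 0.8. We therefore
use normalized cross-correlation (maximal at match, bounded by 1) as the
default and keep the squared-difference form behind `metric = "ssqdiff"`
with acceptance on $1 - R$.

### Evaluation

Sorted spikes are scored against ground truth by greedy one-to-one pairing
within 1 ms per (true unit, sorter unit) pair; sorter units are then
assigned to true units injectively in descending order of the pair's
accuracy. Per unit,
$\mathrm{accuracy} = tp/(tp+fp+fn)$,
$\mathrm{precision} = tp/(tp+fp)$,
$\mathrm{recall} = tp/(tp+fn)$;
accuracy never exceeds the smaller of the other two. Summaries report the
unweighted mean over true units and the detected unit count. All metrics are
invariant to unit relabeling. Greedy injective assignment differs from the
optimal assignment only negligibly at these scales and is deterministic.

## The synthetic ground-truth generator

`simulation_spec()` / `render_recording()` produce recordings with exactly
the statistical structure the pipeline assumes, and nothing more:

* **Biphasic templates** — a sharp negative trough then a slower positive
  overshoot, built from a difference of gamma kernels with randomized width,
  delay and asymmetry spanning the narrow-to-broad variety of cortical cell
  types. Per-channel amplitude decays as $\exp(-d/30\,\mu m)$ from the
  unit's position, scaled so the best (nearest) channel carries exactly
  `snr` × `noise_sigma`; with the default 25 µm pitch each spike is seen on
  2–4 contacts, which is what makes best-channel selection and template
  merging non-trivial.
* **Placement** — `"near-electrode"` (default) spreads units over distinct
  contacts by greedy farthest-point packing with a ≤6 µm jitter: the units a
  sorter can plausibly recover sit close to a recording site, and the
  packing realizes the well-separated-units regime the recovery analyses
  assume. `"midway"` places units halfway between vertically adjacent
  contacts — the best-channel-flipping regime that exercises merging —
  again with farthest-point packing, since random placement essentially
  never achieves the required spacing on a dense probe. `"uniform"` scatters
  freely.
* **Spike trains** — per-unit Poisson (default 5 Hz) with a 2 ms absolute
  dead time. A `collision_fraction` of spikes is re-timed to land within
  half a spike width (±1 ms) of another unit's spike; partners are never
  themselves re-timed, and re-timings violating the unit's own refractory
  period are abandoned, so the collision flags in the ground-truth table are
  exact.
* **Noise** — i.i.d. Gaussian, `noise_sigma` default 10 (arbitrary units,
  int16-compatible). Everything is reproducible from one seed.

What the generator does **not** emulate: electrode drift, bursting amplitude
attenuation, spatially correlated noise, multi-compartment waveform shapes
that change with distance, and non-stationary firing rates. Passing tests on
this generator therefore demonstrates the pipeline's logic — duplicate
suppression, outlier channeling, merging, overlap resolution — not
robustness to every pathology of in-vivo data.

## Problem sizes and numerical choices

The package's own validation runs at desk scale: 32 channels × 30 s at
14 kHz (~1,500 true spikes from 10 units at SNR 10) for end-to-end recovery,
the same scale with 10% collisions for overlap resolution, and 6 midway
units for merging. At these sizes the full pipeline completes in well under
a minute per run and the whole test suite in a few minutes. Scaling down
from hour-long benchmark recordings changes template SNR (hence the
calibrated `merge_sigma` above) but none of the pipeline's structure.

Other numerical choices: exact ties in detection keep the earliest index;
best-channel ties keep the lowest channel id; template-merge candidates are
compared with spline-interpolated sub-sample shifts; degenerate groups
(fewer snippets than `min_cluster_size`) are labeled entirely as outliers
rather than forming an unreliable template; identical-point groups collapse
to a single cluster; pursuit's iteration cap guards against pathological
loops, as collisions of more than five spikes in one window are outside
scope.

## Known limitations

* The merge threshold is calibrated for the package's normalized shared
  space; recordings much longer or shorter than tens of seconds shift
  template SNR and may warrant retuning `merge_sigma`.
* Greedy pursuit resolves two-spike overlaps reliably (and matches an
  exhaustive two-spike oracle on small instances); three-way collisions
  within one window are recovered only partially.
* No drift compensation: a unit that moves across contacts over minutes
  will fragment into multiple templates faster than merging can repair.
* The evaluator's greedy injective assignment can, in principle, differ
  from the optimal assignment when two sorter units tie; ties are broken
  deterministically.

## A worked example

```{r example, eval = FALSE}
library(htsort)

sim <- render_recording(simulation_spec(
  n_channels = 32, n_units = 10, duration_s = 30, snr = 10, seed = 11
))
res <- run_pipeline(sim$recording)
res
#> <ht_sort>
#>   32 channels x 420000 samples @ 14000 Hz
#>   snippets 9051 -> events 2223 -> clustered 1487 + outliers 736
#>   templates 10 -> 10 after merging; pursuit recovered 8
#>   1495 sorted spikes in 10 units

glance(evaluate_sorting(res, sim$truth))
#>   n_gt_units n_sorter_units mean_accuracy mean_precision mean_recall
#> 1         10             10         0.984          0.990       0.993

autoplot(res)          # per-group PC scatter, outliers as crosses
autoplot(res$templates) # merged template waveforms
```
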