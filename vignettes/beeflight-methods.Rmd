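---
title: "Extracting single-unit activity from copter-borne honey bee recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting single-unit activity from copter-borne honey bee recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflight)
```

## The problem

Recording extracellular activity from mushroom body extrinsic neurons of a
honey bee mounted on a quadcopter means fighting interference that is orders
of magnitude stronger than the spikes: rotor electrostatics, motor
electromagnetic fields, and switching noise from the motor controllers, all
varying with flight state. Two electrode channels referenced to a shared
ground see this interference as *common-mode* noise, but with different
effective gains because the electrode impedances differ. The analysis chain
in this package is built around that structure: cancel what is common,
normalize what varies, and only then detect and sort spikes. Downstream, the
sorted unit rates are related to flight behavior: the repetition structure
of the flown trajectory and the copter's turning speed.

## Preprocessing model

Each channel is first normalized as `(x - median(X)) / mad(X)` with the
*unscaled* median absolute deviation. The Gaussian consistency factor
1.4826 is deliberately kept out of the normalization and appears only in the
noise estimate used for thresholding, `n = mad(X) * 1.4826`, which converts
the MAD into an estimate of the background standard deviation that spikes
cannot inflate. (The two formulas are kept separate on purpose; conflating
them would silently scale the detection threshold.)

The subtraction gain `g` minimizing `robust_noise(a - g*b)` is found on a
grid over [0, 4] in steps of 0.01 with golden-section refinement around the
grid minimum; ties go to the smallest gain. Because both channels have
already been MAD-normalized, the optimum is typically near 1 even when the
raw impedance mismatch is large (the normalization itself absorbs most of
the scale difference). The objective is evaluated on a strided subsample of
at most 200k samples: the robust noise is a global scale statistic, so a
deterministic stride changes nothing about the minimizer while keeping the
search inexpensive. The gain is a single constant per recording; a
time-varying `g(t)` is out of scope.

Local renormalization uses a centered 1 s window. Window medians and MADs
are computed every 50 ms and interpolated linearly between centers — a
hop-with-interpolation approximation of a per-sample sliding window that is
indistinguishable at the 20 kHz time scale of spikes (both are configurable).
Windows are truncated at the edges; a window with zero MAD falls back to the
global MAD with a warning.

## Detection and template re-detection

Spikes are negative-going: detection finds local minima below
`-4 * robust_noise(x)` (a `positive_peaks` flag flips the sign convention).
Minima closer than one waveform half-width (14 samples at 20 kHz) are
resolved by keeping the deeper trough. The waveform window is 1.44 ms;
28.8 samples at 20 kHz are rounded up to 29 so the window is symmetric
around the trough.

Waveform extraction re-centers each window on the *continuous* centroid of
the trough lobe (samples below half the trough depth) and resamples at the
fractional shift by linear interpolation. This matters for broad spikes:
the deepest sample alternates between neighbors under noise, and without
alignment one unit's waveforms separate into discrete shape classes several
standard deviations apart, which density clustering happily splits into
spurious units.

Template re-detection computes the sliding Pearson correlation of a unit's
median waveform with the signal and repeats the detection logic on the
correlation series (threshold `4 * robust_noise(c)`, local maxima, same
separation rule). Correlation is amplitude-invariant, so spikes whose shape
survives but whose normalized amplitude dips below threshold in noisy
episodes are recovered. New events within ±2 ms of an existing event — half
the 4 ms refractory period — are discarded; the merged set therefore never
shrinks. Template matching runs one pass per detected unit and pools the
results.

## Sorting

Waveforms are padded 29 → 32 samples by replicating the last sample (zero
padding would inject a spurious step that the coarse wavelet coefficients
would encode) and decomposed with the full-depth orthonormal Haar transform;
all 32 coefficients are kept. PCA retains every component explaining at
least 1% of the variance (never fewer than one). The Local Outlier Factor
(neighborhood 20, threshold 1.5 — scores are ~1 for inliers at any cluster
density) removes anomalous waveforms such as overlap composites before
clustering; flagged spikes are excluded from all downstream analyses.

Clustering is HDBSCAN: mutual-reachability distances with core distance at
`min_samples = min_cluster_size` neighbors, a single-linkage hierarchy,
condensation discarding splits that shed fewer than `min_cluster_size = 100`
points, and excess-of-mass cluster selection. The implementation is
in-package and is validated in the tests against constructed instances with
known structure; on shared feature matrices it reproduces the reference
implementation's labeling. Two design points deserve note:

* `allow_single_cluster` is enabled: a data set whose hierarchy never splits
  into two viable clusters is returned as one cluster rather than all noise.
  In this degenerate case membership follows the reference implementation
  and is restricted to the maximal-density core — the points persisting to
  the cluster's final dissolution — so loosely attached noise events are
  not swept into the unit.
* Cluster labels are renumbered by first spike occurrence, so results are
  deterministic and stable across runs.

Units report their ISI distribution and the fraction of ISIs below 4 ms;
values at 0 indicate clean single-unit isolation, mirroring the refractory
check used for field recordings.

## Rate analysis

Rates are spike counts in half-open 100 ms bins. The 3 s rolling mean exists
for visualization only; all correlations use the raw binned rates. The
behavioral regressor is the bin-averaged *absolute* yaw rate — turning
speed regardless of direction (a signed mode is available). Positive lag
means the neural signal follows the behavior; the peak is the arg-max of
Pearson r over lags on the shared grid, with overlap shrinking at the ends
and lags with fewer than 10 overlapping bins omitted.

Repetition segmentation defines a repetition as the interval between
successive entries into the start region while moving on the initial
bearing; the stretches before the first and after the last entry (lift-off,
landing) are excluded, as are inter-round gaps by construction.

## The synthetic-data generator

The generator produces the study conditions the analysis assumes, not
arbitrary data:

* **Flight**: a trefoil at 5.5 m/s and 15 m altitude, sampled at 100 Hz —
  straight over the feeder, 80 m beyond (default), a clockwise turn back
  onto the feeder from a new bearing, three lobes per round, then a return
  leg. Only waypoints are physically constrained; the joins are circular
  arcs of configurable radius (10 m default), an implementation choice. The
  flight *starts at a turnaround waypoint behind the start corner* so that
  every repetition, including the first, enters the start region on the
  same approach — otherwise the first round would be systematically offset
  from the later ones and the repetition autocorrelation would be biased.
* **Spike trains**: inhomogeneous Poisson by Lewis–Shedler thinning with
  `lambda(t) = baseline + gain * |yaw_rate(t - lag)|` (defaults 10 Hz,
  25 Hz/(rad/s), 0.7 s), an absolute 4 ms refractory period enforced by
  forward deletion, and a relative refractory period (3 ms recovery
  constant) that thins intervals just above the dead time. The relative
  term reflects what real single-unit ISI histograms look like — a single
  mode far above the dead time and almost no mass just above it — and
  avoids an artificial pile-up of intervals exactly at the 4 ms boundary,
  which sampling jitter would otherwise smear across the measurement
  threshold. Spike times are snapped to the 20 kHz recording grid before
  enforcement so refractoriness holds exactly at recording resolution.
* **Recording**: `channel_i = gain_i * common + spike_i + independent_i`,
  with templates injected at half amplitude and opposite polarity across
  channels (so subtraction preserves spikes while cancelling the common
  mode), harmonics plus band-limited broadband noise plus switching-like
  impulses as the common-mode component, all inside the 300 Hz–10 kHz
  hardware band (FFT masking), an amplitude envelope tied to copter speed,
  and 16-bit quantization. The default quantization scale (1000 counts per
  normalized unit) leaves headroom so the worst-case noise stack does not
  clip: clipped samples do not cancel in the differential and masquerade as
  spikes. Templates are negative-going biphasic waveforms (narrow Gaussian
  trough, broader rebound) with three distinct default shapes.
* **Terrain**: blurred-noise height fields with a polygon field mask, or
  flat.

Everything is bit-reproducible from (parameters, seed).

What the generator does *not* emulate: electrode drift, bursting and rate
adaptation, spike waveform nonstationarity, GPS error beyond a constant
clock offset, aerodynamics, or the detailed spectro-temporal structure of
real rotor noise. Passing tests therefore demonstrate that the analysis
recovers known structure under the stated noise model, not that it is
validated on field data.

## Compound-eye model

Viewing directions are a Fibonacci lattice on the sphere restricted to the
field-of-view wedge: 300° horizontally (a 60° rear blind wedge) and 180°
vertically by default, one combined eye of 5000 directions (per-eye anatomy
and per-ommatidium acceptance angles are out of scope). Rays are rotated by
the pose yaw and marched against the height grid at half-cell steps; on a
hit the crossing is refined within the last step, leaving pixel
discretization as the only geometric error (< 1 cell on flat terrain).
Rays exiting the grid or never reaching the surface are class `none`; hits
are `field` or `outside` by the mask. Spike-rate projection assigns each
100 ms bin's rate to every distinct field pixel seen in that bin and
averages per pixel; bins with |yaw rate| above 0.3 rad/s (configurable) are
excluded when turn exclusion is on, so that turn-locked bursts do not
dominate the map.

## Problem sizes and numerical choices

The shipped defaults are the field-analysis values (20 kHz, threshold 4n,
1.44 ms, 1 s window, 1% PCA floor, minimum cluster size 100, 100 ms bins,
3 s smoothing). The test suite and the acceptance script exercise the full
chain on compact trefoils (feeder 55–72 m from the start corner, one to
three repetitions, ~1.5–2 minute recordings, two or three units) — sizes
chosen so the whole validation runs comfortably on one CPU while keeping
>1000 spikes per unit, enough for the 100-member cluster floor and stable
correlation estimates. Degenerate inputs are handled explicitly: constant
signals are a normalization error, zero-variance correlation windows are
defined as r = 0, zero-MAD windows fall back to the global MAD with a
warning, and grid ties in the gain search resolve to the smallest gain.

## Known limitations

* Overlapping spikes are detected as single events; no decomposition is
  attempted, and collisions surviving the outlier screen can contaminate
  clusters at a low rate.
* The subtraction gain is constant per recording; slow impedance drift is
  not tracked.
* The single-cluster path of the density clustering is conservative: only
  the maximal-density core is labeled, so single-unit data sets report
  fewer member spikes than multi-unit ones (see above).
* The eye model ignores per-ommatidium optics; the activity map is a
  visibility-weighted mean, not a retinotopic reconstruction.
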