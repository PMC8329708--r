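# beeflight

Single-unit activity from the brain of a flying honey bee, recorded on a
quadcopter, is buried in strong, time-varying electrical noise from the
copter's motors and rotors. **beeflight** implements the full analysis chain
that turns such two-channel extracellular recordings plus copter telemetry
into sorted single units and links their firing to flight behavior:

1. **Noise-robust preprocessing.** Each monopolar channel is normalized
   robustly, `x_t = (x_t - median(X)) / mad(X)` (unscaled MAD), the channels
   are subtracted with a tuned digital gain `g` that minimizes the robust
   noise of the residual `a - g*b` (common-mode rejection under electrode
   impedance mismatch), and the differential is re-normalized in a 1 s
   sliding window to flatten the time-varying noise floor.
2. **Spike detection.** A robust noise estimate
   `n = median(|x - median(x)|) * 1.4826` sets the threshold `Thr = 4*n`;
   spikes are local minima below `-Thr` (negative-going waveforms). A 1.44 ms
   window (29 samples at 20 kHz) is cut around each trough.
3. **Spike sorting.** Waveforms are transformed to orthonormal Haar wavelet
   coefficients, reduced by PCA keeping every component that explains at
   least 1% of the variance, screened with the Local Outlier Factor, and
   clustered by hierarchical density-based clustering (HDBSCAN, minimum
   cluster size 100). Units report interspike intervals and the fraction
   below the 4 ms refractory bound.
4. **Template re-detection.** Each unit's median waveform is slid along the
   signal as a Pearson correlation; thresholding the correlation series
   recovers spikes whose shape is intact but whose amplitude drops below the
   threshold in high-noise episodes.
5. **Rate analysis.** Spike trains are binned at 100 ms. The rate vector of
   one trefoil repetition is correlated against the whole flight (sliding
   autocorrelation, repetition structure), and rates are cross-correlated
   with the copter's yaw speed `|dyaw/dt|` over lags (positive lag = neural
   activity follows the turn).
6. **Compound-eye back-projection.** A quasi-uniform ray model of the bee
   eye (Fibonacci directions, 300 degrees horizontal field of view) is cast
   against a terrain height grid; each 100 ms bin assigns its spike rate to
   every visible field pixel, and pixels average the rates they collect.

A first-class synthetic-data module (`gen_trefoil_telemetry`,
`gen_spike_trains`, `gen_recording`, `gen_terrain`) generates trefoil
flights at 5.5 m/s and 15 m altitude, yaw-modulated inhomogeneous Poisson
spike trains with a configurable latency, and 16-bit two-channel recordings
with gain-mismatched common-mode noise — so every stage is testable against
ground truth without any field data.

## Worked example

```r
library(beeflight)

cfg <- pipeline_config(seed = 1, n_units = 2, feeder_xy = c(0, 55),
                       leg_beyond_m = 35, turn_radius_m = 8,
                       turnaround_behind_m = 30, n_repetitions = 1)
res <- run_pipeline(cfg)
str(res$metrics[c("detection_f1", "sorting_ari", "peak_lag_s", "peak_r")])
#> List of 4
#>  $ detection_f1: num 0.985
#>  $ sorting_ari : num 1
#>  $ peak_lag_s  : num 0.7
#>  $ peak_r      : num 0.597
```

The run simulates a ~90 s trefoil flight with two units whose firing rate
follows `baseline + gain * |yaw rate|` at a 0.7 s latency, synthesizes and
then analyzes the noisy recording. `detection_f1 = 0.985` scores threshold
detection against the ground-truth spike times (±1 ms); `sorting_ari = 1`
is the adjusted Rand index of cluster labels vs true unit identity;
`peak_lag_s = 0.7` shows the injected neural latency recovered exactly (one
100 ms bin resolution) with peak Pearson correlation `0.597`.

`run_pipeline(cfg, out_dir = "run1")` additionally writes the telemetry CSV,
the 2-channel 16-bit WAV, spike and unit tables, correlation curves, and a
`metrics.json` stamped with the configuration fingerprint.

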