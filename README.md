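# hfoarea

Does the size of an intracranial EEG electrode change the high-frequency
oscillations (HFOs) it measures? HFOs — transient bursts with peak frequency
above 80 Hz, split into ripples (R, 80–250 Hz) and fast ripples (FR,
250–500 Hz) — are a candidate biomarker of epileptogenic brain tissue, yet
they are recorded with contacts spanning three orders of magnitude in
surface area, and rates from different scales are compared as if equivalent.
`hfoarea` is an R package for studying this confound on synthetic data with
known ground truth. It is written for electrophysiology methods researchers
and for anyone evaluating HFO detectors across electrode geometries.

The package chains:

* a **generative measurement model**: HFO pulse trains — gap *s*, duration
  *d*, amplitude *K*, intra-event frequency *f₀* from configurable
  distributions — occur in a tissue patch covering a proportion
  ρ ∈ (0, 3] of the reference contact; the electrode sees the
  coverage-weighted mixture *p*(x_hfo + b₁) + (1 − *p*)b₂ with
  *p* = min(ρ, 1) over independent 1/f backgrounds, measured through a
  lumped platinum electrode–tissue divider
  H(f) = Z_in / (Z_in + Z_e(f, A)), where
  Z_e = R_s(A) + (R_ct/A ∥ 1/(j2πf·C_dl·A)) and
  R_s = ρ_t / (4√(A/π)); interface Johnson noise (PSD 4k_BT·Re Z_e) is added
  at the input. Re-measuring the same source at areas A holds the absolute
  patch fixed: coverage becomes min(ρ·A_ref/A, 1).
* a **two-threshold RMS detector**: 3 ms RMS envelope above mean + 3 SD for
  ≥ 6 ms (stage 1), then ≥ 6 rectified-signal peaks above a second
  mean + 3 SD threshold (stage 2, counted alias-free), per channel in
  one-minute segments, with common-average-reference and transient/DC-shift
  artifact rejection;
* **virtual electrode shorting** on the 8×8 high-density grid (1.08 mm²
  contacts, 3 mm pitch): averaging adjacent contacts in pairs (2.16 mm²) or
  2×2 quads (4.32 mm²) mimics larger electrodes over the same tissue;
* **features and statistics**: per-channel rate, Hilbert-envelope amplitude,
  duration, whitened-spectrum peak frequency, spatial spread S, global rate
  per summed contact area (events counted once across channels), and exact /
  tie-corrected Wilcoxon rank-sum comparisons.

## Worked example

Simulate one HFO-rich fast-ripple channel (2 min at 1000 Hz), detect and
annotate events:

```r
library(hfoarea)
cfg <- simulation_config(duration = 120, seed = 7)
rec <- simulate_recording(cfg)
rec
#> <hfo_recording> 1 channel(s) x 120000 samples @ 1000 Hz (2.0 min), with ground truth
ev <- annotate_features(detect_hfos(rec, "fast_ripple"), rec, "fast_ripple")
head(ev[, c("channel", "start_s", "duration_s", "n_peaks", "amplitude", "peak_freq")], 3)
#>   channel start_s duration_s n_peaks amplitude peak_freq
#> 1    ch01   0.200      0.045      16  21.15720       288
#> 2    ch01   7.272      0.045      13  15.53456       275
#> 3    ch01  24.420      0.091      36  19.37288       317
```

24 events are detected against 23 injected pulses (ρ = 2.44, fully covered
contact): each row gives the event boundaries, the number of supra-threshold
oscillation peaks, the mean Hilbert-envelope amplitude in µV and the
whitened-spectrum peak frequency in Hz.

The headline experiment re-measures 50 source realizations at the three
grid-study contact areas and compares adjacent sizes:

```r
ex <- run_size_experiment(cfg, areas = c(1.08, 2.16, 4.32), n_per_area = 50, seed = 1)
ex
#> <size_experiment> fast_ripple band, 50 records x 3 areas
#>  area rate_per_area med_amplitude med_duration_ms med_peak_freq
#>  1.08     11.111111     17.036808           45.25        360.75
#>  2.16      5.439815     15.268882           44.00        363.00
#>  4.32      2.199074      9.915057           42.00        367.50
```

Rate per unit electrode area falls five-fold from the 1.08 mm² to the
4.32 mm² contact and amplitude drops from ~17 to ~10 µV (both adjacent-pair
rank-sum p < 1e-8), while duration (~45 ms) and peak frequency (~360 Hz)
stay essentially unchanged — the size dependence that makes HFO rates from
different electrode sizes non-comparable. The numbered scripts under
`analysis/` run this experiment plus the ripple-vs-fast-ripple comparison
and the shorting/spatial-spread analysis, writing tables under `results/`.

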