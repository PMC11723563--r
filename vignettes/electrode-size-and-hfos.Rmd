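---
title: "How electrode surface area shapes HFO measurement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How electrode surface area shapes HFO measurement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-frequency oscillations (HFOs) — transient intracranial-EEG bursts with
peak frequency above 80 Hz, split into ripples (80–250 Hz) and fast ripples
(250–500 Hz) — are a candidate biomarker of epileptogenic tissue. They are
recorded with electrodes whose contact areas span three orders of magnitude,
and rates measured at different spatial scales are routinely compared as if
they were the same quantity. `hfoarea` implements a generative measurement
model and detection pipeline for asking, on synthetic data with known ground
truth, how the contact surface area of the measuring electrode changes what
is detected.

This vignette documents the model, its assumptions, the tunable parameters,
and the design decisions behind the numerical choices. It states no result
that the test suite and `scripts/acceptance.R` do not recompute.

## The generative model

Each simulated channel is built in four stages
(`simulate_recording()` composes them):

1. **HFO pulse train.** Pulses are placed by alternating draws of an
   inter-pulse gap $s$ and a pulse $(d, K, f_0)$: duration, peak amplitude
   and intra-event oscillation frequency, all from configurable
   distributions (`sample_hfo_train()`). A pulse that would overrun the
   record is dropped. Each pulse is rendered as
   $K\,w(t)\sin(2\pi f_0 t + \varphi)$ with a raised-cosine (Hann) envelope
   $w$ of length $d$ and uniform random phase (`render_hfo_signal()`). The
   waveform shape is not constrained by the data the model emulates; Hann
   was chosen as the simplest smooth unimodal envelope.

2. **Tissue coverage.** The HFO-generating patch covers a proportion
   $\rho$ of the reference contact area, drawn once per record from
   Uniform(0.05, 3]: from almost no coverage to a patch three times the
   contact. The electrode sees the coverage-weighted mixture
   $p\,(x_{\mathrm{hfo}} + b_1) + (1-p)\,b_2$ with $p = \min(\rho, 1)$
   (`mix_sources()`): coverage saturates once the patch is at least as large
   as the contact, and both the patch and the surrounding tissue contribute
   independent $1/f$ background ($b_1$, $b_2$). Drawing $\rho$ per record
   (rather than per pulse) models a fixed generator geometry under one
   contact.

3. **Scaling with area.** When the same source realization is re-measured at
   several contact areas (`simulate_cohort()`), the absolute patch size is
   held fixed: at area $A$ the effective coverage is
   $\min(\rho\,A_{\mathrm{ref}}/A,\,1)$ with $A_{\mathrm{ref}}$ the
   reference contact (1.08 mm²). Doubling the contact halves the coverage of
   a sub-contact-sized patch — the geometric heart of the size effect.

4. **Electrode–tissue measurement.** The tissue potential passes through a
   lumped voltage divider $H(f) = Z_{\mathrm{in}}/(Z_{\mathrm{in}} + Z_e)$,
   where $Z_e(f, A) = R_s(A) + \left(R_{ct}/A \,\|\, (j 2\pi f\,C_{dl}A)^{-1}\right)$
   is the platinum interface impedance (disc spreading resistance
   $R_s = \rho_t/(4\sqrt{A/\pi})$, double-layer capacitance, charge-transfer
   resistance) and $Z_{\mathrm{in}}$ the amplifier input impedance
   (100 MΩ ∥ 10 pF). Johnson noise of the interface, one-sided PSD
   $4 k_B T\,\mathrm{Re}(Z_e)$, is added at the amplifier input
   (`electrode_transfer()`). Circuit constants are literature-typical
   platinum values, all exposed through `electrode_model()`: double-layer
   capacitance 0.2 µF/mm², charge-transfer resistance large enough that the
   interface is capacitive in-band, tissue resistivity 3 Ω·m. With these
   values $|H| \approx 1$ in the HFO band at all simulated areas, so the
   size effect is carried almost entirely by coverage dilution, with the
   divider and its thermal noise providing the physically correct
   second-order terms.

### Default study conditions

The generator defaults describe an HFO-rich channel sampled at 1000 Hz
(20-minute records at full scale):

| parameter | default | notes |
|---|---|---|
| gap $s$ | Exponential, mean 4 s | ~15 injected events/min |
| duration $d$ | Gamma, mean 55 ms, shape 10 | 5th–95th pct ≈ 29–87 ms, i.e. 30–100 ms events |
| amplitude $K$ | Normal(30, 10) µV, truncated at 0 | symmetric, Gaussian-like |
| $f_0$ | Uniform inside the band | 260–450 Hz (FR), 90–240 Hz (R) |
| $\rho$ | Uniform(0.05, 3] | saturating coverage |
| background | $1/f$, RMS 15 µV | flattened below 1 Hz, RMS exact by rescaling |

The background draw is rescaled to its target RMS exactly; this pins the
in-band noise level that defines burst SNR ($K$ / in-band background RMS,
about $K/4.2$ µV in the fast-ripple band at these defaults).

## Detection

The detector is a two-threshold RMS algorithm applied per channel to
one-minute segments of the band-filtered signal (Butterworth band-pass,
order 6, applied forward–backward; zero-phase notches at the odd 60 Hz
harmonics inside the band):

* **Stage 1** — the RMS envelope in 3 ms sliding windows must exceed
  $T_1 = \mu + 3\sigma$ of the envelope for at least 6 ms; candidates closer
  than 10 ms merge first.
* **Stage 2** — the rectified signal within a candidate must show at least
  six strict local maxima above $T_2 = \mu + 3\sigma$ of the rectified
  segment.

Both thresholds are recomputed per segment, making detection invariant under
uniform gain. A configuration switch (`threshold_reference`) lets $T_1$ be
derived from the rectified signal instead of the envelope, preserving the
alternative literal reading of the published threshold definition.

Three numerical choices deserve comment:

* **Anti-aliased peak counting.** Rectification moves the lobe rate to
  $2 f_0$, which exceeds Nyquist for fast ripples at 1000 Hz; counting
  discrete maxima of the raw rectified samples would silently fail for
  $f_0 \gtrsim 400$ Hz. Stage 2 therefore counts peaks on a band-limited
  (FFT zero-padding) upsampled copy of the segment, recovering the true
  two-peaks-per-cycle count at any sampling rate.
* **Boundary extension.** A threshold crossing at $\mu + 3\sigma$ captures
  only the supra-threshold core of a burst, so the crossing width would
  measure SNR as much as duration. After qualification, event boundaries are
  extended outward to where the envelope falls back to its segment mean
  (sustained for at least one RMS window). This makes measured duration a
  property of the event itself to first order; the residual SNR dependence
  is discussed below.
* **Artifact rejection.** Events overlapping a detection on the
  common-average signal are removed, as are events whose wide-band
  surroundings contain a step between 10 ms mean levels exceeding five times
  the segment's noise scale, or whose band energy would be dominated
  (> 20%) by a lone sample-to-sample jump. The noise scale is estimated
  robustly (MAD of first differences) so that a DC shift cannot inflate the
  reference scale and mask itself. The step/jump constants are approximations
  of published artifact-rejection practice and are config-exposed.

Zero-variance segments are skipped rather than errored. Event coordinates
are 1-based, half-open sample intervals.

## Features and statistics

Amplitude is the mean upper Hilbert (analytic-signal) envelope over the
event, computed with 50 ms padding and cropped back; peak frequency is the
band-restricted argmax of the FFT magnitude after first-difference
whitening, zero-padded to 1 Hz resolution; events shorter than two cycles of
the band's lower edge have undefined peak frequency. Temporally overlapping
events across channels (strictly positive intersection, chained
transitively) form one group; the group's spread $S$ is its number of
distinct channels, and the global rate per area counts groups — unique
events — per minute per summed contact area (69.12 mm² for every grid
configuration). On a single simulated contact this reduces to rate divided
by that contact's area.

`rank_sum_test()` is the two-sided Wilcoxon rank-sum: exact by a tie-safe
counting recursion for pooled samples up to 20, normal approximation with
tie and continuity correction above. The experiment runner compares rate per
area across records (one value per record) and amplitude, duration and peak
frequency across pooled detected events, mirroring per-subject comparisons
on recorded data; no multiplicity correction is applied, matching the
reporting convention the pipeline emulates (stars at 0.05/0.01/0.001).

## Problem sizes

The full-scale conditions (thousands of 20-minute records) are configured
through `simulation_config()`; the packaged experiment, tests and acceptance
script run a reduced design chosen as a desk-scale study: 50 records × 2
minutes per area at areas 1.08/2.16/4.32 mm², 64-channel grids for the
noise-floor, band-comparison and shorting analyses, and six 2-minute records
(~20 bursts each) for recovery measurements. At these sizes all headline
contrasts are decisively resolved.

## What the synthetic data do and do not show

The generator emulates: saturating coverage geometry, $1/f$ background from
covered and surrounding tissue, a platinum interface whose impedance and
thermal noise scale with area, line-harmonic notching, and detection with
per-segment adaptive thresholds. It does not emulate: spatially correlated
background between neighbouring contacts, propagation or shape differences
of real HFO generators, non-stationarity across a recording session,
interictal spikes or other discrete artifacts, or impedance drift. Passing
tests therefore demonstrate internal consistency of the measurement model
and pipeline — that electrode size alone, with sources held fixed,
reproduces the qualitative size dependence — not a quantitative match to any
patient population.

## Known limitations

* **Residual duration truncation.** Any crossing-based duration measure
  truncates low-SNR events slightly more. With boundary extension the effect
  is a few percent (about 2–3 ms at the largest contact against ~45 ms
  medians), but with roughly a thousand pooled events per area it can reach
  nominal significance in one adjacent-size comparison, while rate and
  amplitude change by factors of 2–5. The package reads "duration is
  unaffected" as the absence of a consistent significant ordering across
  both adjacent size pairs, symmetric to how the positive rate/amplitude
  assertions require both pairs.
* **Recovery at threshold SNR.** At burst SNR exactly 5, bursts shorter than
  about three oscillation cycles above $T_2$ are undetectable by
  construction; recovery tests inject bursts away from the notch frequencies
  (where suppression is by design) and report recall there.
* **Coverage model.** $\rho$ is drawn per record and coverage saturates
  sharply at 1; a spatial falloff at patch edges would soften the
  saturation.
* The fast-ripple band's upper edge equals Nyquist at 1000 Hz; the band-pass
  degenerates to a high-pass there, as it must.
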