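---
title: "Mean wavelet power neural features: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean wavelet power neural features: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwpneuro)
```

## The signal model

An intracortical multielectrode array yields, per channel, a raw voltage
trace sampled at 30 kHz that superimposes three physiologically distinct
components: spiking of one or a few nearby units (sub-millisecond
transients, energy concentrated between a few hundred Hz and several kHz),
aggregate multi-unit activity from a larger neighbourhood (same band, but
as a continuous power modulation rather than isolatable events), and the
local field potential (below ~100 Hz, spatially coherent over millimetres).
Movement intent modulates the firing rate of tuned channels, hence the
spike-band power, on the timescale of a cue (seconds).

Mean wavelet power (MWP) summarises this structure without any detection
threshold. Each 100 ms bin (3000 samples) of each channel is decomposed
into 11 levels of the discrete wavelet transform with the `db4` mother
wavelet; the mean absolute detail coefficient of level *k* is the MWP value
of scale *k*. Under the dyadic partition, scale *k* analyses
`[fs/2^(k+1), fs/2^k]` Hz, so at 30 kHz scales 1–2 cover > 3.75 kHz
(hf-MWP), scales 3–6 cover 234 Hz – 3.75 kHz (mf-MWP, the multi-unit band)
and scales 7–11 cover 0–234 Hz (lf-MWP, the LFP band). Because an 11-level
detail pyramid leaves an approximation band below ~7 Hz, the deepest scale
pools its detail and approximation coefficients; the printed band table
(0 Hz lower bound for scale 11) then matches the implementation and the
union of the scale bands covers the whole spectrum.

## The shared post-processing chain

Every feature kind — the per-scale MWP series, threshold-crossing (TC)
counts, LFP bin means, MUA bin RMS — passes through the same chain at
100 ms resolution, in this order:

1. **Causal smoothing** (1 s moving average): bin *k* becomes the mean of
   bins *k−9 … k*; the first nine bins average their shorter history. No
   future bin influences the output, so the chain is implementable in a
   real-time decoder.
2. **Baseline subtraction** (15 s windows): the series is cut into
   consecutive non-overlapping 150-bin windows and each window's own mean
   is removed per channel (and per scale). A final partial window is
   demeaned with its own mean rather than discarded. We read the source
   method's "15-s wide mean subtraction" as block-wise rather than
   sliding; block-wise demeaning is idempotent (each aligned window is
   already mean-zero after one pass), which the tests assert.
3. **Standardization**: mean and *population* standard deviation (divide
   by *n*; the convention is arbitrary and fixed for reproducibility) are
   fitted per channel *and* per scale on the training block (block 1) and
   applied unchanged to the test block. Channels with zero training
   variance are flagged degenerate and map to 0. Standardizing per
   channel-and-scale (rather than per scale only) keeps channels with very
   different gains commensurable; this is one of two readings of the
   method text and is flagged as a choice.
4. **Scale averaging** (MWP only): the standardized scales of the selected
   band (lf/mf/hf) are averaged, unweighted, into one feature per channel
   per bin — 96 features per 100 ms on a full array.

## Extractor parameters

| parameter | default | role |
|---|---|---|
| bin width | 0.1 s | the real-time processing unit |
| smoothing window | 1 s | causal moving average |
| baseline window | 15 s | drift removal |
| wavelet / levels | db4 / 11 | dyadic band partition at 30 kHz |
| TC high-pass | 250 Hz, order 2, causal Butterworth | spike-band front end |
| TC threshold | −4.5 × RMS per 2 s window | event detection |
| TC dead time | 1 ms | one event per spike |
| TC snippet | 0.6 ms pre / 1.0 ms post | peak-to-peak measurement |
| LFP low-pass | 100 Hz, order 3, causal Butterworth | field-potential band |
| MUA band-pass | 300–6000 Hz, causal Butterworth | multi-unit power |

Two deliberate numerical choices deserve a note.

**Wavelet boundary handling.** Decomposing 3000-sample bins through 11
levels exceeds the conventional maximum depth for an 8-tap wavelet, so deep
scales are boundary-dominated. Each bin is decomposed independently with
half-sample symmetric extension (the package's default), preserving the
causal 100 ms processing unit. A periodization mode is also provided; for
this orthonormal filter pair it conserves energy exactly (the test suite
uses it as an oracle: on dyadic-length bins the summed squared coefficients
equal the squared norm of the bin to better than 1e−6).

**TC front-end order.** Only the 250 Hz cutoff is stated by the method;
the filter order and type are open. Run causally, a 4th-order Butterworth
high-pass sags a 0.3–0.4 ms spike trough by 30–37%, which makes spikes of
8× the noise RMS hover at the −4.5×RMS threshold and caps recovery near
80%. A 2nd-order causal Butterworth preserves the trough (attenuation
~18%) and recovers > 99% of injected spikes at 8× noise RMS, so the
package defaults to order 2 (`feature_config(tc = list(hp_order = ...))`
exposes it). For offline amplitude measurements a zero-phase
(forward–backward) mode is available via `feature_config(zero_phase =
TRUE)`; the quality tests use it when asserting absolute peak-to-peak
recovery, since causal filtering biases amplitudes down by design.

## The decoder

One binary RBF-kernel SVM per movement is trained on block 1
(movement-vs-everything-else; rest and other movements pooled as
negatives), per session. Decision values are oriented so positive means
"movement", scaled by the maximum absolute training decision value and
clipped to [−1, 1]. At test time the highest-scoring movement wins if its
score exceeds zero, otherwise the bin is predicted rest. Defaults C = 1
and kernel width 1/n features are unstated in the source method and
exposed in `run_config()`. Metrics are per-bin: overall accuracy over all
bins; per movement, the binary-decision accuracy (a `"precision"`
alternative is provided, since the method text is ambiguous), sensitivity
(cued bins predicted as the movement) and specificity (non-cued bins
predicted rest). Cue labels attach to bins whose start time falls in
`[onset + lag, onset + lag + duration)` with lag 0 by default — no
reaction-time model is assumed, and the lag is configurable.

## What the simulator emulates — and what it does not

`simulate_recording()` builds, per channel:

* a **foreground unit**: inhomogeneous Poisson spikes (thinning, 1.5 ms
  absolute refractory period), baseline 10 Hz, rate multiplied up to 4×
  on tuned channels during cues, with a 1.2 ms biphasic negative-leading
  template (sharp 0.3 ms negative phase, slow area-balancing positive
  phase) at 80 µV negative peak;
* a **sub-threshold multi-unit background**: the same spike shape at
  25 µV — below a −4.5×RMS threshold at the 10 µV noise floor — at 60 Hz
  baseline, sharing the channel's tuning. Foreground units express only a
  quarter of the tuning (`unit_tuning_scale = 0.25`). This division is the
  mechanism behind the headline feature comparison: MUA and mf-MWP
  integrate all spike-band power, so they see the strongly tuned
  background, while TC counts only supra-threshold events and therefore
  carries weaker cue information — mirroring the argument that thresholding
  discards multi-unit signal;
* **spatially correlated oscillations**: each component (defaults 8 Hz /
  40 µV and 20 Hz / 20 µV) is a mixture of a few latent sinusoids anchored
  at random array sites, mixed into channels with `exp(−d/λ)` weights
  (λ = 2 mm) and slowly amplitude-modulated (0.3 Hz, depth 0.5) so that
  nearby channels share a fluctuating envelope — this is what makes
  low-frequency feature correlations decay with inter-electrode distance;
* **white Gaussian noise** at 10 µV RMS, and an optional per-day
  multiplicative `amplitude_decay` on all spike amplitudes as a
  phenomenological stand-in for chronic signal decline (no quantitative
  decline model is given by the source study).

Everything is driven by one seed; identical parameters reproduce
recordings bit-for-bit, and the injected spike times are attached to the
recording as a ground-truth ledger.

The simulator does **not** model electrode impedance or the
electrode–tissue interface, biophysical neuron dynamics, spike-waveform
diversity or drift, reaction-time variability, or non-stationary noise.
Consequently, passing tests demonstrate that the pipeline recovers the
structure the simulator injects (rates, band power, spatial correlation,
cue information) — they validate the *method implementation*, not the
clinical findings; the study's recorded-data values (e.g. absolute
accuracies or decline percentages) are not reproducible without the human
recordings and serve only as qualitative reference points.

## Problem sizes used by the shipped experiments

The test-suite experiments run on reduced arrays so that a full run stays
comfortably interactive on a single core: the decoder-comparison
experiment uses 20 simulated Task2 sessions of 12 channels (two 108.5 s
blocks each, all six feature kinds, ~10⁷ raw samples per block); spike
recovery uses 60 s × 8 channels; structural checks use a full 96-channel
array for 1 s. Accuracy differences between feature kinds are far larger
than the session-to-session spread at these sizes, and every number the
README quotes is produced by the corresponding code at these sizes.

## Known limitations

* Deep wavelet scales of a 100 ms bin are boundary-dominated; their
  absolute values depend on the extension mode (a documented consequence
  of binning before decomposing). In particular, under symmetric extension
  the pooled deepest scale can spuriously dominate for pure mid-band
  tones, so band-assignment checks compare the detail scales; train-block
  standardization absorbs these fixed per-scale gains in the feature
  pipeline.
* Causal filters bias measured spike amplitudes downward; absolute
  peak-to-peak values are only comparable within one filter configuration.
* The per-movement "individual accuracy" denominator follows the
  binary-decision reading; the precision reading is available behind a
  flag but not the default.
* The simulator's tuning is stationary within a session; no within-block
  adaptation or learning effects are modelled.
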