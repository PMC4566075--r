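---
title: "Methods: simulating and analysing glial activity during retinal waves"
author: "gliawave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing glial activity during retinal waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliawave)
```

## The scientific problem

In the developing retina, spontaneous depolarisations — retinal waves —
sweep across the ganglion-cell layer during the first two postnatal
weeks. Müller glial cells (MCs), the radial glia of the retina, extend
stalks and lateral processes through the inner plexiform layer (IPL)
during exactly this period, and they respond to the neurotransmitters
(acetylcholine early, glutamate later) that spill over from wave-driven
synaptic release. The experimental readout is simultaneous two-photon
imaging of an MC-expressed fluorescent sensor (a calcium indicator such
as GCaMP3, or the glutamate sensor iGluSnFR) and a whole-cell
voltage-clamp recording from a retinal ganglion cell (RGC), in which
each wave appears as a compound inward EPSC.

The headline statistic is *participation*: the percentage of segmented
ROIs (MC stalks and lateral processes) showing a detected fluorescence
transient coincident with a given wave. `gliawave` implements the full
analysis chain that produces this statistic — motion correction,
Laplacian ROI segmentation, ΔF/F normalisation, derivative-threshold
transient detection, wave-epoch detection from the current trace, and
coincidence scoring — plus a seeded synthetic-experiment generator that
provides ground truth for validating every stage.

## The synthetic experiment generator

Because no raw recordings ship with the package, the generator
(`generate_experiment()`) produces the three objects the analysis
consumes — a fluorescence movie, a current trace and an ROI layout —
together with the ground truth (wave onsets, recruited ROI sets, event
times) needed for recovery testing.

The generative model, per `simulation_config()`:

* **Layout.** `n_stalks` disks (radius 3–5 px) and `n_lateral` bars
  (length 12–20 px, width ~3 px, random orientation; aspect ratio ≥ 3)
  placed without overlap and with a 3 px guard margin on a 256 × 256
  field. Disks emulate stalk cross-sections, bars the lateral processes
  seen in the IPL.
* **Waves.** Onset intervals are drawn from a normal distribution
  truncated below (default mean 40 s, SD 20 s, minimum 15 s). The
  literature reports no wave frequency at these ages, so the default was
  chosen once to yield about five well-separated waves in a standard
  200 s recording; it is a configurable placeholder, not an empirical
  claim.
* **Recruitment.** Each ROI is recruited by each wave independently with
  probability `participation_p` — the central biological parameter. A
  recruited ROI receives exactly one transient, lagged uniformly within
  `[0, 3]` s of the wave onset (glial responses follow the neuronal wave
  by up to a few seconds; the exact lag is not quantified in the
  literature, so a uniform 0–3 s was chosen).
* **Fluorescence.** ROI pixels rest at `baseline_f0` (default 1000
  arbitrary units) and scale as `baseline_f0 * (1 + Σ kernels)` during
  events; background pixels sit at a dimmer `background_f0` (default
  200), since indicator-filled structures are visible at rest — this
  resting contrast is what makes the temporal-mean summary image
  segmentable, including ROIs that never respond. The transient kernel
  rises linearly over `transient_rise_s` and decays exponentially with
  `transient_decay_s`: calcium defaults (0.8 s, 1.4 s) give a full width
  at 10 % of peak of ≈ 3.9 s, inside the 3–5 s band characteristic of
  glial calcium transients; glutamate defaults (0.25 s, 0.9 s) are
  faster, as for a membrane-bound glutamate sensor.
* **Noise and drift.** Additive Gaussian noise per pixel per frame
  (default SD 80, i.e. a per-pixel SNR `peak_dff·baseline_f0/noise_sd`
  of ≈ 6; Gaussian rather than Poisson for simplicity). Slow scene drift
  is rendered as the *rounded cumulative* translation of the whole frame
  (default 0.02 px/frame in a random direction), so the injected motion
  is always integer-pixel and registration has an exact answer.
* **Electrophysiology.** Baseline current ≈ 0 pA with Gaussian noise
  (4 pA SD), sampled at 1 kHz (wave epochs are seconds long; the
  acquisition-grade 20 kHz would add nothing at this scale, and the rate
  is configurable). Each wave contributes one inward compound-EPSC
  envelope: linear rise (0.3 s) to −100 pA, exponential decay (1.2 s),
  truncated at 4 s. Amplitude and kinetics are configurable placeholders
  — the literature does not report compound-EPSC amplitudes at these
  ages.

What the generator deliberately does **not** model: optics and PSF,
Poisson photon statistics, mechanistic transmitter diffusion or
transporter kinetics, spike-level EPSC structure, non-rigid motion,
focal-plane (z) drift, bleaching, or overlapping/contacting ROIs.
Passing recovery tests therefore shows that the pipeline correctly
inverts this generative model at realistic SNR — not that it is robust
to every artefact of real recordings.

### The condition table

`inst/extdata/conditions.yaml` packages six experimental conditions
(ages P7/P9/P11; calcium vs glutamate sensor; glutamate-transporter
block with DL-TBOA). Each entry sets `participation_p` to the reported
mean fraction of responsive ROIs for that group and records the
published mean ± SD the recovery study is scored against. Calcium
conditions run at 0.74 Hz with 150 frames (≈ 203 s); glutamate-sensor
conditions run at 1.7 Hz with 340 frames so the recording *duration*
(and hence the expected number of waves) matches. Pharmacology is
represented purely as a change in `participation_p` — no receptor
kinetics are modelled.

## Analysis methods

### Registration

Integer-pixel translation per frame, estimated by maximum
cross-correlation (FFT-based, search radius 20 px) against a reference.
The reference defaults to the *first frame*: registering a drifting
movie against a multi-frame mean would blur the reference and recover
shifts only up to a constant offset, whereas the first-frame reference
makes "shift = cumulative drift" an exact, testable contract (a
`"mean10"` option is provided for noisy stills). A recording is flagged
as rejected when any estimated shift exceeds a configurable bound,
mirroring the practice of discarding recordings whose field of view
moved too far.

### Segmentation

The summary image (temporal mean by default; temporal SD available for
sparse sensors) is band-pass filtered with a Laplacian-of-Gaussian
(scale σ = 2 px, matched to the half-width of the thinnest structures).
Seed pixels exceed `mean + 2·SD` of the filtered image. Because the
band-pass response of a plateau concentrates at its centre and edges,
seeds alone under-segment shape interiors, so by default each seed is
grown to its full supporting structure: the summary image is thresholded
by Otsu's method and the connected components of that support mask which
contain at least one seed become the ROIs (`refine = FALSE` labels the
raw seed mask instead). Components below 6 px are discarded. A blank or
constant image yields zero ROIs, not an error.

ROI shape is classified by circularity `4πA/P²` (perimeter = count of
boundary pixels, i.e. pixels with a 4-neighbour outside the set; the
ratio is capped at 1) and the aspect ratio of the best-fit ellipse from
second moments. A ROI is a *stalk* iff circularity ≥ 0.7 **and** aspect
ratio ≤ 2; otherwise a *lateral process*. The cutoffs were chosen once
to separate the generator's disks from its bars with margin on both
criteria; on simulated layouts classification agrees with ground truth
for > 95 % of ROIs.

For neuronal glutamate-sensor recordings the field is instead
partitioned into 16 identical squares (`grid_roi_masks()`), each square
one ROI.

### ΔF/F and transient detection

Traces are ROI-mean pixel intensities; `ΔF/F = (F − F₀)/F₀` with F₀
defaulting to the 10th percentile of each ROI's raw trace (robust to
sparse transients; a first-n-frames mean and an externally supplied F₀
are alternatives). The baseline estimation method is unspecified in the
source literature; the percentile default slightly overestimates ΔF/F
(by ≈ 1.3 noise SD of the trace) but the offset cancels in the
derivative and in peak-minus-onset amplitudes.

Detection per ROI: binomial smoothing (width 3), first difference
scaled by the frame interval, threshold at `k` × SD of the derivative
trace (strictly greater; SD over the whole recording by default, with an
optional quiet-window estimator). `k` follows the two printed
acquisition regimes — 2 at rates ≤ 1 Hz, 4 above, 2.5 in
focal-stimulation mode. A crossing at derivative step *i* dates the
event from frame *i + 1* (the first sample of the rising transient);
the peak is the next local maximum of the smoothed trace, and the
offset is the half-peak return above the onset level. Events with onset
separation below 5 s are merged; ties at threshold resolve to
"no crossing" (strict inequality).

Two numerical choices deserve justification:

* **Amplitude floor** (`min_peak_dff = 0.05`). A purely SD-relative
  derivative threshold fires on ~2 % of the frames of *any* quiet trace
  regardless of SNR — an irreducible false-positive stream that would
  dominate low-participation conditions. A 5 % ΔF/F floor is far below
  real glial transients (≈ 0.25 ΔF/F after sampling attenuation at
  0.74 Hz) yet several noise SDs above a quiet ROI-mean trace at the
  default SNR, and restores detector precision ≈ 1.
* **Onset dating and coincidence margins.** At 0.74 Hz one frame is
  1.35 s, so detected onsets carry about a frame of timing uncertainty
  (smoothing spreads a rise one sample backwards). The coincidence
  window that decides whether an event belongs to a wave is therefore
  `[wave onset − 2 s, wave offset + 5 s]`: the 5 s tail covers the 0–3 s
  glial lag plus kinetics, the 2 s lead absorbs onset-timing error.
  Both margins are configuration keys.

Measured event amplitudes are attenuated roughly twofold relative to
the injected kernel peak (frame sampling rarely lands on the kernel
maximum, and smoothing spreads it); consequently the half-peak offset
lands ≈ 4 s after onset for the default calcium kernel, and detected
durations fall in the 3–5 s band expected of these transients.

### Wave epochs

The current trace is smoothed with a 0.2 s moving average; baseline =
median, spread = 1.4826 × MAD, and epochs are maximal runs below
`baseline − 4 × spread` lasting ≥ 1 s, with runs separated by < 2 s
merged. Median/MAD make the rule scale-covariant (rescaling the trace
in pA leaves epochs unchanged) and insensitive to the epochs
themselves. The source experiments identified waves by inspection; this
explicit criterion is the package's own, fully parameterised. Epoch
charge is the trapezoidal integral of baseline-subtracted sub-baseline
current, reported positive.

### Participation and statistics

Per wave, the percentage of ROIs with ≥ 1 event onset in the
coincidence window; each event is assigned to at most one wave (nearest
onset). Stalks and processes are pooled by default (their responses are
similar), with stratification available. Supporting summaries:
participation time-course histograms, at-least-one-wave participation,
pooled inter-transient-interval CDFs, and evoked-response averages over
focal-stimulation windows. Group comparisons delegate to standard
routines — Welch t-test for two groups, one-way ANOVA with Tukey or
Kruskal–Wallis with Dunn post-hoc for more — at the 0.05 convention;
Dunn's rank comparisons (with tie correction, Holm-adjusted) are
implemented in-package since no installed dependency provides them.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force circularity, exhaustive shift search, run-length threshold
scans, binomial closed forms) and the generator's ground truth. The
condition-recovery study — the package's core fidelity claim — runs the
*full* pipeline on six retinas per calcium condition (150 frames,
256 × 256, 40 ROIs, ≈ 5 waves each) and five per glutamate condition
(340 frames at 1.7 Hz), and requires the grand mean per-wave
participation to land within the published SD of the published mean for
all six conditions. At these sizes the binomial sampling error of the
grand mean is ≈ 1–2 percentage points, comfortably inside the published
SDs; the pipeline itself recovers the *realised* recruited fractions
essentially exactly at the default SNR. Unit and property tests use
smaller fields (96–128 px, 8–12 ROIs) where full scale adds nothing.

## Known limitations

* The generator's simplifications listed above bound what recovery
  tests can show about real recordings; in particular, non-rigid motion,
  z-drift and ROI overlap are the failure modes an experimenter should
  still check by eye.
* The detector is tuned for sparse, seconds-scale transients; dense
  activity (inter-event intervals approaching the transient width)
  inflates the derivative SD and reduces sensitivity.
* Wave detection assumes well-separated compound EPSCs on a stable
  baseline; slow baseline wander beyond the MAD spread would need
  detrending, which is not implemented.
* Percentile-based F₀ assumes each ROI is quiescent for ≥ 10 % of the
  recording.
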