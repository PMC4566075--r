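# gliawave

Analysis of Müller glial cell activity during retinal waves, from
simultaneous two-photon fluorescence imaging and ganglion-cell
voltage-clamp recordings.

## The problem

During the first two postnatal weeks, the mouse retina generates
*retinal waves* — spontaneous depolarisations that sweep across the
ganglion-cell layer while circuits are being wired. Müller glial cells
(MCs), the radial glia of the retina, grow their lateral processes into
the inner plexiform layer over the same period and respond to the
neurotransmitters spilling over from wave-driven synaptic release. The
standard experiment images an MC-expressed fluorescence sensor (a
calcium indicator such as GCaMP3, or the glutamate sensor iGluSnFR) at
0.74 or 1.7 Hz over a 256 × 256 px field while a whole-cell recording
from a retinal ganglion cell marks each wave as a compound inward EPSC.

The statistic of interest is **participation**: the percentage of
segmented glial ROIs (stalks and lateral processes) with a detected
fluorescence transient coincident with a given wave,

> % responsive per wave = 100 · #\{ROIs with an event onset in
> \[wave onset − pre, wave offset + post\]\} / #ROIs.

`gliawave` implements the whole chain that produces it:

* **Segmentation** — X-Y motion correction by integer-shift
  cross-correlation; ROI extraction from a summary image by
  Laplacian-of-Gaussian filtering and thresholding; shape classification
  (stalk vs lateral process) by circularity 4πA/P² and ellipse aspect
  ratio; or the fixed 16-square grid partition used for neuronal-sensor
  movies.
* **Traces** — per-ROI mean intensity, ΔF/F = (F − F₀)/F₀ with a
  percentile baseline, binomial smoothing, and transient detection by a
  first-derivative threshold at k × SD of the derivative trace (k = 2 at
  ≤ 1 Hz, 4 above, 2.5 for focal-stimulation recordings).
* **Ephys** — wave-epoch detection as sub-threshold excursions of the
  median/MAD-normalised current trace; focal-stimulation windows and
  evoked-response averaging.
* **Metrics** — per-wave and at-least-one-wave participation,
  participation time-courses, inter-transient-interval CDFs, and group
  comparisons (t-test / ANOVA + Tukey / Kruskal–Wallis + Dunn).
* **Synthetic experiments** — a seeded generator producing movies,
  current traces and ground truth with the statistical structure the
  analysis assumes, so every stage is validated by parameter recovery
  without any raw recordings.

See `vignettes/gliawave-methods.Rmd` for the generative model, the
numerical choices and their rationale.

## Worked example

```r
library(gliawave)

# a synthetic P9 retina: 150 frames at 0.74 Hz, 40 glial ROIs,
# each wave recruits an ROI with probability 0.48
cfg <- condition_config("P9_control", seed = 1)
exp <- generate_experiment(cfg)

res <- analyze_experiment(exp$movie, exp$ephys)
res$rois
#> roi_map: 40 ROIs on a 256 x 256 field (lateral_process 20, stalk 20)
res$waves
#>   onset_s offset_s peak_current_pA charge_pC
#> 1  33.488   37.555       -107.9438  129.3677
#> 2  56.147   60.255       -106.4031  129.6450
#> 3 109.998  114.098       -107.5484  129.0857
#> 4 174.955  179.051       -108.8096  129.7583
res$participation
#> participation: 48.8 +/- 10.3% responsive ROIs per wave (40 ROIs, 4 waves)

# ground truth agreement, wave by wave
round(100 * exp$truth$true_participation_per_wave, 1)
#> [1] 57.5 42.5 57.5 37.5
res$participation$per_wave_pct
#> [1] 57.5 42.5 57.5 37.5
```

The detector found four wave epochs at the injected onsets (each a
~−108 pA compound EPSC integrating ≈ 130 pC of inward charge), and the
full pipeline — segmentation from the movie alone, ΔF/F, transient
detection, coincidence — reproduces the simulated per-wave recruitment
exactly at the default SNR.

From a shell, the same workflow is available as subcommands
(`simulate`, `segment`, `detect`, `waves`, `analyze`, `all`):

```sh
Rscript inst/cli/gliawave.R all --condition P9_control --seed 1 --out out/
```

writing `events.csv`, `waves.csv`, `participation.csv`, `iti.csv`,
`rois.tif` and `run.log`.

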