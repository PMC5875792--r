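---
title: "Methods: Fourier-domain quantification of stimulus-locked calcium responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier-domain quantification of stimulus-locked calcium responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facile)
```

This vignette documents the analysis model behind `facile`: the harmonic
response measure, its statistical calibration, the registration and
segmentation machinery, the synthetic video generator used to validate all
of it, and the photometry arithmetic. It is the place where every numerical
convention and default is stated once, with its rationale.

## The measurement model

A retinal cell expressing a fluorescent calcium indicator (e.g. GCaMP6s) and
stimulated with a periodic light stimulus produces a fluorescence time
course that is, to first order, a baseline plus a periodic modulation at the
stimulus frequency, corrupted by broadband noise. The package quantifies
each cell (or pixel) by three numbers:

* **F0** — the mean of the time course over an integer number of stimulus
  cycles; the baseline fluorescence.
* **F1** — the amplitude of the discrete Fourier component at the stimulus
  fundamental, scaled as a cosine amplitude: for a DFT coefficient $X_k$
  over $N$ samples, $F_1 = 2\lvert X_k\rvert / N$, so a pure
  $a\cos(2\pi f t)$ yields $F_1 = a$ exactly.
* **phase** — $\operatorname{Arg}(X_k)$, wrapped to $(-\pi, \pi]$, with the
  time origin at the stimulus onset frame. A cosine peaking at onset has
  phase 0; a response delayed by indicator kinetics acquires a negative
  phase lag; a cell modulating in antiphase (an OFF cell) sits $\pi$ away.

The normalized response is $F_1/F_0$, a dimensionless modulation depth that
cancels expression level and illumination differences between cells.

### Windowing

The analysis window is truncated to a whole number of stimulus cycles
starting at the onset frame: with frame rate $r$ and stimulus frequency
$f$, the number of usable cycles is $\lfloor n_\text{avail} f / r \rfloor$
and the window length is `round(cycles * r / f)` samples. Whole-cycle
truncation makes the stimulus frequency land (near-)exactly on a DFT bin,
which is what makes the cosine-amplitude recovery exact rather than subject
to spectral leakage. The analysed bin is `round(f * n_used / r)`; an error
is raised if the stimulus frequency exceeds Nyquist or fewer than one full
cycle is available.

For a sampled square wave with an even period of $N$ samples per cycle, the
discrete fundamental obeys the closed form
$F_1/F_0 = 4 / (N \sin(\pi/N))$, which approaches the continuous-time
$4/\pi$ with an $O(1/N^2)$ correction. The test suite uses this identity as
an analytic oracle.

### Why a Fourier measure

Averaging over whole cycles makes the F1 estimator orthogonal to the DC
term (so it is invariant to baseline offsets) and to every other integer
harmonic bin of the noise. Under additive white noise of variance
$\sigma^2$, the complex bin amplitude is Gaussian with per-quadrature
variance $\sigma^2 N / 2$, so the F1 amplitude of a non-responsive trace is
Rayleigh-distributed with scale $\sigma\sqrt{2/N}$ — a fully known null,
exploited below.

## Significance: the mean + 3 SD noise criterion

Each trace's noise floor is estimated from the amplitude spectrum in a
high-frequency band (default 10–12 Hz, far above the 0.2 Hz stimulus and
its physiologically relevant harmonics) over the same truncated window. A
cell is **significant** when its F1 strictly exceeds the band's mean
amplitude plus three standard deviations.

Because the noise-band bins share the stimulus bin's Rayleigh null, the
criterion's false-positive rate has a closed form. With band mean
$\mu = s\sqrt{\pi/2}$ and SD $s\sqrt{(4-\pi)/2}$ for Rayleigh scale $s$,

$$ P(A > \mu + 3\,\mathrm{SD}) =
   \exp\!\left(-\tfrac{1}{2}\left(\sqrt{\pi/2} +
   3\sqrt{(4-\pi)/2}\right)^2\right) \approx 0.0056. $$

The acceptance tests verify the empirical false-positive rate against this
value on 10,000 simulated pure-noise cells within Monte-Carlo error. The
criterion is deliberately not a p-value machine — it reproduces the
field-standard "mean plus three SD of the noise" rule — but its calibration
is known and tested rather than assumed.

## Phase statistics, ON/OFF classification, Rayleigh test

Significant cells' phases are summarized on the circle:

* `estimate_on_center()` finds the dominant response axis from the doubled
  phases ($\operatorname{Arg} \sum e^{2i\phi}$ halves the antipodal
  ambiguity), picks the majority lobe, and refines a circular mean there.
  This avoids assuming the ON phase a priori.
* `classify_polarity()` calls a cell ON if its phase lies strictly within
  `polarity_half_width` (default $\pi/2$) of the ON center, OFF if within
  the same width of the antipode, and UNCLASSIFIED on the boundary.
* `rayleigh_test()` tests phase uniformity using $z = n r^2$ with Zar's
  approximation
  $p = \exp\!\left(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\right)$,
  clamped to $[0, 1]$. Its rejection rate at $\alpha = 0.01$ is verified at
  $0.01 \pm 0.01$ on uniform phases.

A population is summarized by the mean and SD (denominator $n-1$) of
$F_1/F_0$ over significant cells, the significant count, and the Rayleigh
statistics of their phases. Cells with non-positive F0 are excluded as
invalid, with an explicit message and count.

## Registration

Eye motion is modelled as frame-wise rigid translation. `estimate_shifts()`
cross-correlates each frame against a reference (default: the mean of the
first ten frames) via FFT, takes the integer-pixel correlation peak, and
optionally refines it with a matrix-multiply discrete Fourier transform
evaluated on a $1/\text{upsample}$-pixel grid around the peak (the
Guizar-Sicairos local-upsampling construction, implemented directly since
only a translation model is needed). `correct_motion()` applies the inverse
translations with bilinear interpolation and edge replication, so interior
photometry is preserved and no zero borders bias later averaging.

Choices worth stating:

* **Translation only.** The generator injects translational jitter, and
  the package claims nothing about rotation, shear, or intra-frame
  (line-level) distortion. Raster imagers distort within frames; a
  frame-level model is a documented simplification, not an oversight.
* **Reference choice fixes a gauge.** All shifts are relative to the
  reference; comparisons with a ground-truth trajectory must remove the
  arbitrary common offset first, and cross-session work must estimate the
  between-session offset separately (see `match_cells()`).
* Constant (featureless) stacks degenerate: the estimator warns and
  returns zero shifts rather than amplifying noise.

Subpixel accuracy is tested by injecting exact Fourier-domain shifts and
requiring recovery within 0.1 px, and end-to-end by requiring < 0.5 px RMS
trajectory recovery on rendered videos.

## Segmentation and time-course extraction

`auto_segment()` builds a cue image as the normalized SUM image (per-pixel
sum over frames — total fluorescence) plus a weighted normalized
F1-amplitude map, smooths it (Gaussian, $\sigma = 2$ px), thresholds with
Otsu's method, seeds one marker per regional maximum within a
soma-diameter window (9 px), and grows labels over the foreground. ROIs
whose pixel phases are incoherent (circular SD > 1 rad) are split along the
antipodal phase axis — this uses the phase map to separate touching cells
of opposite polarity, which a pure intensity cue fuses. Area bounds
(20–1200 px at 1 µm/px) drop debris and merged clumps.

Automated segmentation is a convenience for unattended runs; a manually
drawn or ground-truth label mask is first-class input everywhere
(`run_config(mask = ...)`).

`extract_timecourses()` averages the registered video over each ROI's
pixels, frame by frame. By DFT linearity the ROI-mean F1 equals the complex
mean of the pixel-wise F1s — an identity the tests verify at $10^{-9}$ —
so pixel maps and cell records are mutually consistent views of the same
analysis.

## Cross-session cell matching

`match_cells()` matches two sessions' cell centroids after a rigid
between-session translation, accepting pairs greedily in order of
increasing distance, each cell used at most once, and no pair beyond
`max_dist_um` (default 5 µm, about half a soma). On well-separated somata
this greedy rule equals the optimal assignment — the tests verify
agreement with an exact linear-assignment solution at 30 cells and with
exhaustive permutation enumeration at 6.

## The synthetic video generator

The generator is the package's ground-truth instrument; its defaults are
the study conditions, so tests and examples exercise realistic regimes.

* **Field**: 215 × 160 px at 1 µm/px (the 160 × 215 µm imaging field),
  default 30 somata of radius ~7.5 ± 2 µm placed by rejection sampling
  with a minimum spacing of 1.5 radii, fully inside the field. Each soma
  has a dimmer nucleus (40% intensity), a per-cell baseline, and a
  generative polarity drawn from an ON/OFF/non-responsive mix (default
  0.5/0.3/0.2).
* **Stimulus and kinetics**: 0.2 Hz square wave by default; the indicator
  impulse response is a difference of exponentials (rise 0.2 s, decay
  1.5 s, GCaMP6s-like), and the modulation envelope is the stimulus
  convolved with the unit-area kernel, so the rendered modulation depth
  equals the specified amplitude at DC gain 1.
* **Motion**: an integer (optionally subpixel) reflecting random walk with
  bounded excursion, applied to whole frames.
* **Noise**: additive Gaussian per pixel and frame.
* **Cohort traces**: `simulate_cell_traces()` draws target normalized
  responses from a *folded* normal $\lvert N(\mu, \sigma)\rvert$ (default
  $\mu = 0.16$, $\sigma = 0.08$, the wild-type cohort setting) — a
  modulation depth cannot be negative, and folding perturbs the realized
  mean/SD by < 0.002 at these parameters, unlike truncation-by-resampling
  which biases the mean by ~0.007. The per-trace amplitude is calibrated
  through the same F1 pipeline that will measure it, so recovery tests are
  closed-loop but not circular: the oracle is the generative draw, not the
  measurement.

Parameter-recovery acceptance: on a 296-cell cohort the pipeline recovers
the generative mean and SD within ±0.015, classifies polarity ≥ 98%
correctly at SNR ≥ 5, and registration recovers injected trajectories to
< 0.5 px RMS.

### What the generator does not model

Photon (Poisson) noise statistics, indicator nonlinearity and saturation,
bleaching, intra-frame raster distortion, vascular shadowing, focus drift,
and non-rigid tissue motion. Conclusions from synthetic data are therefore
about the *analysis* — its calibration, invariances and recovery — not
about biological effect sizes.

## Photometry

`retinal_irradiance()` divides pupil power by the retinal area of the
stimulated patch; `na_equivalent_power()` scales power between eyes by the
squared ratio of numerical apertures (mouse 0.49, human 0.24);
`expected_cell_count()` multiplies an areal density by the field area
(60 melanopsin cells/mm² × 160 × 215 µm ≈ 2 cells per field). The ANSI
maximum permissible exposure at 620 nm for 8 h (40 µW) is stored as a
constant for report annotation, not recomputed.

One deliberate wrinkle: the literature values this module reproduces use
**two mutually inconsistent retinal magnifications** for the mouse eye —
34.4 µm/deg back-solves the published irradiance numbers, while
32.0 µm/deg matches the published field conversion (5° = 160 µm). Both are
exported (`UM_PER_DEG_DOSIMETRY`, `UM_PER_DEG_FIELD`) and `um_per_deg` is
an explicit parameter everywhere; the package does not silently resolve
the inconsistency, and every dosimetry result carries its geometry in its
metadata.

## File formats and determinism

Videos and maps are written as multi-page TIFF. The `tiff` package offers
no float sample format on write, so stacks are affinely scaled to $[0, 1]$,
stored as 32-bit integers, and the min/span recorded in a JSON sidecar
(`<path>.json`, or the `map_scaling` block of the maps sidecar);
`read_stack()` inverts the scaling, giving round-trip error below $10^{-9}$
of the intensity span. Label masks use 16-bit TIFF and round-trip exactly.

`run_pipeline()` is deterministic under a fixed config and seed
(byte-identical CSV outputs, verified by test), writes a manifest with
input MD5 hashes and the full config, logs stage-by-stage cell counts, and
leaves a `FAILED` marker naming the stage if anything stops.

## Limitations

* Registration is frame-level rigid translation; raster-scan intra-frame
  distortion is out of scope.
* The significance criterion is calibrated under additive Gaussian noise;
  strongly non-Gaussian noise (e.g. photon-limited regimes) will shift the
  false-positive rate.
* `auto_segment()` is tuned for well-separated somata at ~1 µm/px; dense
  or low-SNR fields need manual masks.
* Phase-based ON/OFF classification assumes a single dominant response
  axis; populations with continuous phase gradients need the raw phases,
  which every record retains.
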