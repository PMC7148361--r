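---
title: "Quantifying choroidal neovascularisation in en-face OCTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal neovascularisation in en-face OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optical coherence tomography angiography (OCTA) renders retinal and
choroidal blood flow as en-face grayscale maps without dye injection. In
highly myopic eyes, choroidal neovascularisation (CNV) appears in the
outer-retina-to-choriocapillaris slab as a bright branching lesion, often
surrounded by a dark rim. Clinically one wants to quantify the lesion
(how much vessel, how long, how thick, how complex) and its detectability
(how well it stands out from its surround), and to ask how those
quantities change between a *single* acquisition, a *denoised* single
acquisition, and an *average of up to ten registered acquisitions* of the
same eye — a within-eye, three-arm repeated-measures design.

`octaquant` implements this measurement pipeline end to end, driven by a
synthetic phantom generator so that every stage is testable without
patient data: patient images from the motivating clinical setting are not
publicly deposited, and the vendor's on-device deep-learning denoiser is
undisclosed, so this package evaluates the *comparison framework* with
classical denoisers standing in.

## The metrics

All metrics are computed inside a lesion region of interest (ROI), after
binarisation and skeletonisation of the angiogram:

* **VD (vessel density)** — percent of ROI pixels marked vessel after
  Otsu binarisation: $\mathrm{VD} = 100\,|B|/|R|$.
* **VLD (vessel length density)** — percent of ROI pixels on the 1-px
  skeleton: $\mathrm{VLD} = 100\,|S|/|R|$. A calibre-independent length
  measure; the subset chain $S \subseteq B \subseteq R$ guarantees
  $\mathrm{VLD} \le \mathrm{VD}$.
* **VDI (vessel diameter index)** — the mean-calibre index
  $\mathrm{VDI} = (\mathrm{VD}/\mathrm{VLD}) \times t$, where $t$ is an
  ocular-magnification coefficient. With Bennett's reduced formula,
  $t = 3.382 \times 0.01306 \times (\mathrm{AL} - 1.82)$ for axial length
  AL in mm. Published clinical tables use a device/convention-specific
  scaling roughly an order of magnitude above Bennett's $t$ for plausible
  axial lengths (inverting printed example values gives $t \approx 10.5$);
  because that convention is not stated anywhere we can verify, the
  coefficient is exposed as configuration (`littmann_method = "bennett"`
  or `"fixed"`), and VDI is always reported alongside the coefficient
  actually used.
* **FD (fractal dimension)** — box-counting dimension of the skeleton:
  the slope of $\log N(s)$ against $\log(1/s)$, where $N(s)$ counts
  occupied boxes of side $s$ on a grid anchored at the ROI bounding-box
  origin. Box sizes default to powers of two from 2 px to a quarter of
  the bounding-box side. Anchoring at a fixed origin (rather than
  minimising over offsets) is cheap and deterministic; the test suite
  bounds the anchoring error against a brute-force oracle that examines
  every grid offset.
* **CNR (contrast-to-noise ratio)** —
  $(f - b)/\sqrt{\delta_f^2 + \delta_b^2}$ with $f, b$ the mean grey
  values of the foreground (the whole CNV area) and background (the
  darkest area around it — the dark rim, since the slab has no avascular
  zone to use), and $\delta_f, \delta_b$ their sample standard
  deviations. The same two sites are scored on every arm of an eye. The
  sign is preserved; a zero denominator yields a missing value, never
  infinity.

Undefined metrics (VDI at VLD = 0, FD of an empty skeleton) are reported
as missing values with a recorded reason, never as sentinel numbers.

## The synthetic scene

`scene_params()` + `generate_truth()` build a ground-truth phantom:

* a circular lesion (default radius 40 px ≈ 0.52 mm at the 3 mm / 232 px
  pitch) surrounded by a dark rim annulus (width 8 px, attenuation 0.25)
  on a mid-grey background (level 120);
* a vessel network grown from seed points on the lesion boundary by
  biased random-walk centerlines — heading wiggle SD 0.35 rad per step, a
  weak pull toward the lesion centre, Bernoulli branching, linearly
  tapering calibre — rasterised by stamping discs (vessel level 230,
  default 3 trunks, branch probability 0.03/step, calibre 2–3.5 px).
  These densities were calibrated once against the published clinical
  range of lesion vessel density (averaged-image VD ≈ 26 ± 12 %), giving
  phantoms with true VD ≈ 20–40 %;
* masks: foreground = lesion disc; background = the rim annulus eroded by
  1 px on both edges so inter-frame jitter cannot bleed foreign intensity
  into the background sample.

`render_frame()` produces one acquisition: the truth is translated by a
random global jitter (SD 0.5 px/axis), multiplied by i.i.d. per-pixel
gamma speckle with mean 1 and shape 4 (coefficient of variation
$1/\sqrt{4} = 0.5$, strong speckle as in coherent imaging), offset by
additive Gaussian read noise (SD 8 grey levels), then saturated to
[0, 255] and quantised to 8-bit. The gamma-times-signal model makes noise
variance intensity-dependent, as speckle is; no quantitative noise model
is published for the motivating device, so this is a modelling assumption
and is flagged as such.

All randomness flows from one integer seed through derived substreams
(`derive_seed()`): frame $k$ of eye $i$ always sees the same stream
regardless of what else ran, so studies are bit-reproducible and frames
are mutually independent.

What the phantom does *not* model: OCT volume physics, projection
artefacts, saccadic motion stripes, layer-segmentation errors, background
retinal vasculature texture, and lesion shapes other than a disc. Passing
tests therefore demonstrate correctness of the measurement pipeline and
the direction of noise-driven effects, not clinical performance on real
angiograms.

## The three arms

* **single** — frame 0 as acquired.
* **denoised** — frame 0 through a classical denoiser: non-local means
  (default; patch radius 2, search radius 5, filtering strength
  0.75 × a robust noise-SD estimate from horizontal pixel differences),
  median (3 × 3), or Gaussian (σ = 1 px). A classical filter stands in
  for the undisclosed vendor network deliberately: the object of study is
  the comparison framework, not the filter.
* **averaged** — all frames registered to frame 0 by Fourier phase
  correlation and averaged pixelwise in floating point (quantisation only
  at export). The cross-power spectrum is whitened and then weighted by a
  Gaussian low-pass (σ = 1.5 px⁻¹-scale): independent speckle dominates
  the phase at high frequencies, and without the weighting the
  correlation peak is frequently off by 1–2 px on realistic frames.
  Sub-pixel refinement is a parabolic fit to the correlation peak; shifts
  beyond 10 px are distrusted (warning, frame left unshifted); correction
  uses bilinear interpolation with edge replication.

The three arms feed the *identical* metric path; nothing downstream knows
which arm an image came from.

## Segmentation choices

* Binarisation is Otsu thresholding restricted to the ROI histogram —
  pixels outside the lesion never influence any threshold, mirroring a
  workflow in which cropping precedes binarisation. `mode = "global"`
  uses one threshold (the exact maximiser of between-class variance over
  all 256 grey levels); `mode = "local"` (default) computes a per-pixel
  Otsu threshold from the 15 × 15 px window centred at the pixel
  (≈ 200 µm at the 3 mm / 232 px pitch, spanning several vessel
  calibres; the window is a configurable because the exact radius used
  in clinical ImageJ workflows is unreported).
* Local thresholding carries a well-known pathology: in a window with no
  real structure, Otsu still splits the noise histogram roughly in half.
  We therefore apply a minimum-contrast guard: where the window SD is
  below `min_contrast_frac` (default 0.25) times the global
  between-class mean separation, the pixel is compared against the
  global threshold instead. On a noise-free phantom this makes local and
  global output agree and the pipeline recover true VD exactly.
* Skeletonisation is sequential simple-point thinning: border pixels
  whose Yokoi 8-connectivity number is 1 and that are not curve
  endpoints are deleted one at a time in fixed raster order until no
  removable simple pixel remains. Sequential deletion (as opposed to
  parallel sub-iterations) preserves the 8-connected component count
  exactly, and the fixed order makes results deterministic.

## Statistics

`octa_compare()` reports, per metric: group mean ± sample SD per arm, a
one-way within-subject (repeated-measures) ANOVA across arms — fitted
with `stats::aov` using an `Error(eye)` stratum, so
$F = \mathrm{MS}_{\text{arm}} / \mathrm{MS}_{\text{arm} \times \text{eye}}$
on $(a-1, (a-1)(n-1))$ df — and Bonferroni-adjusted pairwise comparisons:
two-sided paired t-tests per arm pair with raw p multiplied by 3 and
capped at 1. Degenerate structures are mapped explicitly: a zero
condition sum of squares reports F = 0, p = 1; zero-variance paired
differences report p = 1 with a warning. Sphericity corrections are not
applied by default, matching common clinical reporting of this design;
omnibus and pairwise results are reported independently (no gatekeeping),
and the pairwise base test is the paired t (the standard reading of "a
Bonferroni test" after RM-ANOVA in the clinical literature), not Tukey.
Only complete cases enter a given metric's analysis.

Under the null the RM-ANOVA is exact for Gaussian exchangeable arms; the
acceptance suite verifies a 5 % ± 1.5 % empirical type-I error over 2,000
simulated 20 × 3 tables and checks F against a from-scratch
sums-of-squares decomposition at 10⁻¹⁰.

## The study driver

`run_study(study_config())` simulates the full design: per eye it samples
a scene (lesion radius uniform on 32–48 px, 2–4 vessel trunks, axial
length ~ N(28.41, 1.27²) mm truncated to [26, 31.5] — the published
cohort's axial-length distribution for highly myopic eyes), renders 10
frames, builds the three arms, computes the five metrics per arm over the
true lesion and CNR sites, and fits the comparison. Failed eyes are
recorded and skipped. Outputs (metrics.csv, table1.csv, run_log.json,
optional PNG frames and masks) are byte-reproducible from
`(config, seed)`.

Problem sizes used by the test and acceptance suites: unit tests run on
96-px phantoms with 3–4 frames; the acceptance suite runs the full
232-px, 10-frame, 20-eye study once, 100 Monte-Carlo flat scenes for the
averaging physics, and 2,000 null tables for the calibration check.

## Known limitations

* The phantom's single-frame speckle (CV 0.5) makes single-frame
  skeletons noticeably noisier than clinical single frames (synthetic
  single-arm VLD means sit above the published clinical range even
  though every directional effect reproduces); treat absolute synthetic
  means as pipeline outputs, not clinical predictions.
* The magnification coefficient convention for VDI differs across
  devices and publications; comparisons across studies require fixing
  the coefficient explicitly.
* Registration handles global translation only — by design, matching the
  jitter model; rotational or non-rigid eye motion is out of scope.
* The CNR background is the synthetic dark rim; on real images the
  darkest-area selection is manual and should be supplied as a mask
  file.
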