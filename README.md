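# octaquant

Quantification of choroidal neovascularisation (CNV) in en-face optical
coherence tomography angiography (OCTA) images, with a synthetic phantom
generator and a three-arm repeated-measures study driver.

## The problem

OCTA renders blood flow as en-face grayscale angiograms. In highly myopic
eyes, CNV appears in the outer-retina-to-choriocapillaris slab as a bright
branching lesion with a dark rim. Clinicians quantify the lesion with five
indices computed inside a manually cropped region of interest (ROI), and
compare three preparations of the same eye — a single frame, a denoised
single frame, and an average of up to ten registered frames — to ask
whether denoising a single acquisition can replace time-consuming frame
averaging.

The indices, for binary vessel map *B*, skeleton *S* and ROI *R*:

- **VD** (vessel density) = 100·|B|/|R| %, after Otsu binarisation
  (global, or local with a homogeneous-window guard);
- **VLD** (vessel length density) = 100·|S|/|R| %, after
  topology-preserving thinning; always ≤ VD;
- **VDI** (vessel diameter index) = (VD/VLD) × *t*, a mean-calibre index,
  with *t* an ocular magnification coefficient — Bennett's reduced form
  *t* = 3.382 × 0.01306 × (AL − 1.82) from the axial length AL (mm), or a
  fixed device convention;
- **FD** (fractal dimension), the box-counting slope of log N(s) vs
  log(1/s) on the skeleton;
- **CNR** (contrast-to-noise ratio) = (f − b)/√(δ_f² + δ_b²) between the
  whole lesion (foreground) and the darkest surrounding area (background).

Arm comparison is a one-way within-subject (repeated-measures) ANOVA per
metric with Bonferroni-adjusted paired t-tests, reported as a clinical
comparison table (mean ± SD per arm, omnibus and pairwise p-values).

Because the motivating patient images are not publicly deposited, the
package ships a seeded phantom generator (branching vessel networks,
multiplicative gamma speckle, additive read noise, inter-frame jitter)
that reproduces the study design synthetically; all pipeline stages are
oracle-tested against it. See the methods vignette
(`vignettes/octa-cnv-quantification.Rmd`) for models, parameters and
design decisions.

## Worked example

```r
library(octaquant)

params <- scene_params(rng_seed = 42)          # 232 px, 3 x 3 mm, 10 frames
truth  <- generate_truth(params)               # phantom + true metric values
frames <- render_sequence(truth, params)       # 10 speckled, jittered frames
sites  <- cnr_regions(en_face_image(truth$intensity_truth),
                      truth$foreground_mask, truth$background_mask)

single   <- frames[[1]]
averaged <- average_frames(register_frames(frames))

print(truth$true_metrics)
print(compute_metrics(single,   truth$lesion_mask, sites, axial_length = 28.4))
print(compute_metrics(averaged, truth$lesion_mask, sites, axial_length = 28.4))
```

```
<vessel_metrics> VD 28.05%  VLD 5.49%  VDI 5.11  FD 1.27  CNR 2.45
<vessel_metrics> VD 42.00%  VLD 30.23%  VDI 1.63  FD 1.76  CNR 1.61
<vessel_metrics> VD 28.38%  VLD 8.16%  VDI 4.08  FD 1.23  CNR 3.05
```

Reading the numbers: the noisy single frame over-segments (VD 42 % vs the
phantom's true 28 %), its skeleton is littered with speckle specks (VLD
30 %), so its calibre index collapses (VDI 1.6) and its complexity
inflates (FD 1.76); the lesion stands out poorly (CNR 1.6). The 10-frame
registered average restores VD to the true value (28.4 %), thins the
skeleton back out, and doubles the lesion's detectability (CNR 3.05) —
the directional pattern reported for real eyes.

A complete synthetic study (20 eyes, three arms, comparison table):

```r
study <- run_study(study_config(n_eyes = 20, seed = 1), out_dir = "study_out")
print(study)        # clinical-style comparison table with RM-ANOVA + Bonferroni
plot(study, "cnr")  # per-arm boxplots
```

A thin command-line front end over the same functions lives at
`inst/cli/octaquant.R` (subcommands `simulate`, `process`, `metrics`,
`compare`, `run-study`, with YAML configs).

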