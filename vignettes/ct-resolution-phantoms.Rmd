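---
title: "Digital lung phantoms and CT resolution analysis: models and methods"
author: "ctresolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital lung phantoms and CT resolution analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package models

`ctresolve` evaluates how the spatial resolution of a CT system limits the
assessment of small lung nodules. It replaces a physical experiment — a
3D-printed anthropomorphic lung phantom scanned on several systems — with a
fully synthetic, seeded pipeline:

1. a **digital lung phantom** with spherical (benign-like) and spiked
   (malignant-like) nodules embedded in tubular vascular clutter;
2. an **image-domain acquisition emulator** for systems that differ in
   point-spread function, reconstruction voxel size and noise;
3. the **nodule analysis chain**: spherical-VOI extraction, two-cluster
   intensity segmentation, connectivity filtering, triplicate repetition,
   rigid registration to the reference masks, and concordance statistics
   (Dice overlap, linear regression, Bland–Altman limits of agreement,
   paired t-tests);
4. a **wire-phantom MTF estimator**: radial averaging, order-0 Hankel
   transform, finite-wire (Nickoloff) correction and 50%/10% cutoff
   extraction.

Everything is deterministic given one root seed; each stage draws from a
named substream (`seed_stream(root, "phantom.vessels")`, …) so stages can be
re-run in isolation.

# The phantom

## Tissue model

The phantom is a two-level HU field. The lung interior defaults to
−580 HU, emulating a printed part whose cavities are filled with residual
polyamide powder; an air-like interior of −875 HU is the common
alternative and both are configurable. All structures — vessels, feeding
vessels and nodules — render at a single `structure_hu`, constrained to
[−130, −90] HU (default −110 HU, the midpoint), matching soft-tissue
structures against a lung background. Before blurring, the volume
therefore has exactly two intensity modes; every contrast downstream comes
from the imaging model.

## Nodules

Nodules are parametric (`nodule_spec`): spheres of diameter $d$, and
spheres with conical spikes whose bases sit on the sphere surface and
whose apices reach radius $d/2 + L$. The spike population defaults to 6
axis-aligned plus 6 seeded random directions, $L = 2.5$ mm, base
half-angle 20°; these values are declared defaults, not measurements — the
insert geometry they imitate is only ever shown pictorially in the
literature. The spike length is capped at 3.25 mm so that the whole
nodule fits inside its segmentation VOI of diameter $d + 6.5$ mm.
Voxelisation is by voxel-centre membership; tests verify that the
voxelised sphere volume converges to $\tfrac{4}{3}\pi r^3$ as spacing
shrinks (error strictly decreasing at 0.2, 0.1, 0.05 mm).

## Vasculature and feeders

A seeded recursive branching tree (`generate_vessel_tree`) provides
connected tubular clutter: each branch spawns children tilted by a random
angle in a configurable range, with radius decaying geometrically per
generation. It stands in for patient-derived airway/vessel anatomy in a
statistical sense only — connected tubes of realistic calibre near the
nodules — and makes no anatomical claims.

Each nodule additionally receives a straight **feeding vessel**
(default radius 0.35 mm), because nodules in a real lung sit on
vasculature and the reference segmentation of such a nodule includes the
vessel parts connected to it inside the VOI. Feeders attach at the sphere
surface for spheres and **at a spike tip** for spiked nodules. The tip
attachment matters: the junction runs through the thinnest part of the
nodule, so once blur pushes the tip below the segmentation threshold the
whole vessel disconnects and the connectivity filter removes it — in every
modality — while the reference keeps it. This reproduces a failure mode
observed with real spiculated nodules resting on small vessels.

## Manufacturing undersizing

The physical experiment this pipeline emulates scans a *print* of the
digital template while using the *template* as the standard of reference;
additive manufacturing reproduces the template only to within its
dimensional tolerance, and the resulting template-vs-object mismatch is a
documented contributor to volume underestimation. `phantom_scene`
therefore has a `print_undersize_mm` parameter (default 0.05 mm,
conservative against typical selective-laser-sintering tolerances of
0.1–0.3 mm): the HU volume is rendered from structures whose radial
dimensions are reduced by this amount, while reference masks always use
the exact template shapes. Setting it to 0 gives an idealised phantom in
which an unblurred, noiseless acquisition segments back to the reference
exactly (Dice = 1) — the property the test suite uses to validate the
segmentation machinery itself.

# Acquisition emulation

Each system is an `acquisition_profile`: a Gaussian PSF, a reconstruction
voxel size, and an additive noise level. Simulation is image-domain only
— blur, then linear resampling to the reconstruction grid, then noise —
in that fixed order (noise is reconstruction-domain). Projection-domain
physics (helical sampling, reconstruction filters, photon statistics,
spectral binning) is deliberately out of scope.

Three presets encode the systems studied:

| preset  | recon voxel (mm)        | in-plane σ (mm) | matched 50% cutoff |
|---------|-------------------------|-----------------|--------------------|
| `ct`    | 0.13 × 0.13 × 0.625     | 0.2797          | 6.7 LP/cm          |
| `hrct`  | 0.13 × 0.13 × 0.625     | 0.3072          | 6.1 LP/cm          |
| `spcct` | 0.13 × 0.13 × 0.25      | 0.1704          | 11.0 LP/cm         |

The PSF width comes from inverting the Gaussian MTF
$\mathrm{MTF}(f) = e^{-2\pi^2\sigma^2 f^2}$ at the measured 50% cutoff:
$\sigma = \sqrt{-\ln(0.5)/(2\pi^2 f_{50}^2)}$. A single Gaussian cannot
match both published cutoffs of a real system simultaneously — measured
10%/50% cutoff ratios (e.g. 21.7/11.0 ≈ 1.97) exceed the Gaussian's fixed
ratio $\sqrt{\ln 0.1/\ln 0.5} \approx 1.82$, because reconstruction
filters shape the true MTF — so a profile is matched at one level at a
time, and analyses that need a specific 10% cutoff invert at that level
instead. Through-plane blur defaults to slice spacing / 2.355 (FWHM of
one slice). The preset noise level is 20 HU for all three systems: the
emulation intentionally equalises noise so that the downstream differences
are attributable to resolution alone, mirroring a study design that
matched dose but declined to compare noise.

## Wire acquisitions

A wire phantom is a sub-pixel object (100–200 µm wire on a 0.13 mm grid).
Blurring an image *after* it has been sampled at the detector pitch cannot
undo the aliasing introduced at sampling time, so
`simulate_wire_acquisition` renders the wire by exact pixel–disk area
overlap on a grid 8× finer, applies the PSF there, and then box-averages
each 8×8 block — the detector's area-integrating aperture — down to the
target grid. This is the same "blur happens before detection" ordering
that the lung-phantom simulator gets for free from its fine phantom grid.

# Segmentation

The segmentation chain follows the published procedure exactly:

* **VOI**: a sphere of diameter $d + 1.5$ mm (spheres) or $d + 6.5$ mm
  (spiked) around the seed centre; voxels outside the sphere never enter
  clustering and the final mask is clipped to it.
* **Two-cluster k-means** on the VOI intensities (`stats::kmeans`, Lloyd
  iteration). Initialisation is deterministic at the minimum and maximum
  value — in one dimension this gives a reproducible, order-independent
  fixed point, avoiding random restarts. The threshold is the midpoint of
  the final cluster means; foreground is the higher-mean cluster.
* **Connectivity**: only the 26-connected component containing the voxel
  nearest the seed centre survives (26-connectivity chosen for 3-D; the
  source procedure does not specify the connectivity). If the centre
  voxel is background, the nearest foreground voxel within one voxel
  radius seeds the component instead; otherwise the mask is empty with a
  warning.
* **Triplicate repetition**: the centre is perturbed by a seeded uniform
  offset within ±1 voxel per axis (repeat 1 unperturbed), standing in for
  the observer variability of manually re-selected centres of mass.
  Reported volumes and Dice values average the repeats.

# Registration and shape comparison

Masks from different reconstruction grids are compared on a common
0.14 mm isotropic grid: cubic interpolation of the 0/1 field,
re-binarised at 0.5 (the threshold that preserves volume on average for
symmetric interpolants). Registration is rigid:

1. resample the moving mask onto the reference's isotropic grid;
2. rotate about the mask centroid — either by configured angles (scripted
   replication) or by a coordinate-wise search over ±10° in 2° steps per
   axis maximising post-shift Dice. The search is coordinate-wise rather
   than a full 11³ factorial for runtime; the unrotated candidate is
   always scored, so a search never returns less than the unregistered
   Dice;
3. translate by the integer shift maximising the 2-D cross-correlation of
   the axial mid-slices, with ties broken toward the smallest magnitude;
   the through-plane shift comes from 1-D correlation of per-slice voxel
   counts (an extension — the source procedure specifies only the in-plane
   step).

In the default simulated experiment no rotation is needed (simulation
preserves orientation), so the pipeline registers with angles (0, 0, 0);
the search exists for data that were physically repositioned.

The Dice similarity coefficient is
$\mathrm{dice}(A, B) = 2\,|A \cap B| / (|A| + |B|)$ on voxel counts; two
empty masks are defined as Dice 1 with a warning.

# Statistics

* **Volume**: voxel count × voxel volume, on each modality's own grid.
* **Regression**: ordinary least squares of measured on reference volume;
  95% CIs from the t distribution with $n-2$ df;
  RMSE $= \sqrt{\mathrm{mean}(r_i^2)}$.
* **Bland–Altman**: differences measured − reference; limits
  $\Delta \pm 1.96\,\delta$ with the sample ($n-1$) SD — the convention
  chosen where the source is silent.
* **Paired t-test**: two-tailed, via `stats::t.test`.
* **Normality check**: one-sample Kolmogorov–Smirnov of the standardised
  differences against the standard normal — an interpretation (a
  Lilliefors-style correction is a known alternative); it is a coarse
  screen at the n ≤ 6 sample sizes involved.

# MTF estimation

The chain in `estimate_mtf`:

1. **Slice averaging** across z (the wire is axial, so slices are
   replicates).
2. **Wire centre**: intensity-weighted centroid of pixels above half the
   maximum excess, refined by three fixed-point iterations of the
   excess-weighted centroid over a 12-pixel circular window. The
   refinement removes the threshold-truncation bias; centring errors enter
   the profile quadratically, but at these widths (σ comparable to the
   pixel) even a 0.2-pixel error visibly biases the cutoff.
3. **Background subtraction**: mean over pixels beyond 10 wire diameters,
   subtracted everywhere.
4. **Pixel-aperture removal** (default): the image's DFT is divided by the
   separable $\mathrm{sinc}(\pi a f_x)\,\mathrm{sinc}(\pi a f_y)$ of the
   pixel box. The pixels integrate over their area, and this known
   aperture both attenuates and — being square — breaks the circular
   symmetry that radial averaging relies on; deconvolving it first makes
   the remaining field radially symmetric. A curve-level division by the
   direction-averaged aperture transform is available as an alternative
   (`mtf_options(pixel_aperture = "curve")`), as is disabling it.
5. **Radial profile**: quarter-pixel bins; each bin is reported at the
   *mean radius of its contributing pixels*. Near the centre an annulus
   contains only a handful of pixels at irregular radii, and pinning those
   values to bin centres biases the narrow peak by several percent of its
   height; the mean-radius abscissa removes this first-order error. The
   bin-centre convention with empty-bin interpolation remains available
   (`abscissa = "bin_center"`). The profile is truncated at the inscribed
   circle radius so every annulus is fully sampled.
6. **Hankel transform**:
   $\mathrm{MTF}(f) = \bigl|2\pi \int_0^\infty p(r)\,J_0(2\pi f r)\,r\,dr\bigr|$
   by trapezoidal quadrature, after spline-interpolating the profile onto
   a 4× finer grid using an even (mirror) extension about $r = 0$ — a
   radial function has zero slope at the origin, and the even extension
   extrapolates the unobserved peak correctly. The absolute value makes
   the curve non-negative by convention. A profile tail above 5% of the
   peak triggers a truncation-bias warning.
7. **Finite-wire correction**: division by the wire disk transform
   $2 J_1(\pi d f)/(\pi d f)$; frequencies at or beyond its first null are
   dropped with a warning.
8. **Normalisation** to unity at zero frequency, then **cutoffs** as the
   first downward crossings of 0.5 and 0.1, linearly interpolated.

The frequency grid spans 0–40 LP/cm in 0.1 LP/cm steps (covering a 10%
cutoff of ~22 LP/cm with headroom). The estimate is invariant to wire
contrast, and for noiseless Gaussian-blurred wires it tracks
$e^{-2\pi^2\sigma^2 f^2}$ to within 0.03 absolute up to the 10% cutoff
(σ ∈ {0.16, 0.25, 0.35} mm, both wire sizes) — the suite asserts both.
Residual cutoff error at the default wire position is ≲0.2%; adversarial
sub-pixel positions (exactly half-pixel on both axes) can reach ~2–3% for
the 100 µm wire because the radial samples then collapse onto few distinct
radii.

With noise, the $r\,dr$ weighting accumulates variance over the full
profile, so wire scans want dedicated low-noise acquisitions: the default
experiment uses 8 averaged slices and 5 HU wire-scan noise rather than
the 20 HU of the lung-phantom scans.

# The default experiment

`default_experiment_config()` describes the standard run: a
56 × 35 × 18 mm phantom section at 0.13 × 0.13 × 0.25 mm (431 × 270 × 72
voxels) with six nodules (3, 6, 9 mm × sphere, spiked) on a 2 × 3 layout,
three profiles, triplicate segmentation, registration at 0.14 mm, and
three wire scans (200 µm wire for `ct`/`hrct`, 100 µm for `spcct`). The
whole experiment runs in roughly half a minute on one CPU core; the wire
targets alone take a few seconds each.

```{r}
library(ctresolve)
report <- run_experiment(default_experiment_config(seed = 1),
                         out_dir = "runs/default")
report
```

The suite asserts the *directions* this experiment must reproduce — the
high-resolution profile has the highest mean Dice; within every profile
and nodule kind Dice rises with nodule size; every profile underestimates
volume on average; every regression slope is below 1 — and the
quantitative recovery of the published MTF cutoffs (within 2%) through
the full estimation chain. Absolute Dice/RMSE magnitudes of the physical
experiment are *not* asserted: they depend on scanner and printing
specifics that an image-domain emulation cannot, and does not try to,
reproduce.

# Known limitations

* The acquisition model is a separable Gaussian: no reconstruction-filter
  ringing, no helical/cone-beam artifacts, no beam hardening, no spatially
  correlated or textured noise. Passing tests show the analysis chain
  behaves correctly under this model, not that it is robust to all real
  scanner physics.
* The vessel tree is statistical clutter, not anatomy; feeder attachment
  is stylised (one straight vessel per nodule).
* Manufacturing error is modelled as a uniform radial undersizing; real
  prints have spatially varying, signed errors.
* A single Gaussian PSF cannot reproduce both published cutoffs of a
  filtered-backprojection system at once (see above).
* The KS normality check on ≤6 paired differences has little power; it is
  reported for procedural fidelity.
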