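# ctresolve

Digital lung phantoms and spatial-resolution analysis for computed
tomography.

## The problem

How much does the spatial resolution of a CT system limit what can be said
about small lung nodules — their volume, and the spiculated shape features
that separate malignant-looking from benign-looking lesions? Physically,
this is studied by scanning an anthropomorphic lung phantom with nodule
inserts on several systems and comparing each system's segmentations to the
digital ground truth, alongside a wire-phantom measurement of each system's
modulation transfer function (MTF). `ctresolve` implements that whole
evaluation as a seeded, fully synthetic pipeline for methodologists and
medical-physics researchers: a parametric digital phantom stands in for the
printed object, an image-domain acquisition model stands in for the
scanners, and the analysis chain (segmentation, registration, concordance
statistics, MTF estimation) is identical to what would be run on real
scans.

## The models at the core

**Phantom.** A two-level HU field: lung interior (default −580 HU,
powder-filled-print-like; −875 HU air-like alternative) and structures at a
single level in [−130, −90] HU — a seeded branching vessel tree, a feeding
vessel per nodule, and nodules that are either spheres of diameter
*d* ∈ {3, 6, 9} mm or spheres with conical spikes. Reference masks are the
exact digital shapes plus connected vessel parts inside each nodule's VOI;
the imaged volume can optionally be rendered from slightly undersized
structures to emulate manufacturing tolerance.

**Acquisition.** Gaussian point-spread blur with
MTF(f) = exp(−2π²σ²f²), σ matched to a measured 50% cutoff by
σ = sqrt(−ln 0.5 / (2π² f₅₀²)); linear resampling to the reconstruction
voxel size (0.13 × 0.13 × 0.625 mm for the `ct`/`hrct` presets,
0.13 × 0.13 × 0.25 mm for `spcct`); additive reconstruction-domain noise.

**Nodule analysis.** Spherical VOI of diameter *d* + 1.5 mm (spheres) or
*d* + 6.5 mm (spiked); two-cluster 1-D k-means with deterministic min/max
initialisation, threshold at the midpoint of the cluster means;
26-connectivity filtering to the seed point; triplicate segmentation with
seeded ±1-voxel centre perturbation; rigid registration to the reference on
a 0.14 mm isotropic grid; then

- Dice(A, B) = 2·|A ∩ B| / (|A| + |B|),
- ordinary least squares of measured on reference volume with 95% t-based
  CIs and RMSE,
- Bland–Altman limits of agreement Δ ± 1.96·δ,
- two-tailed paired t-tests between systems.

**MTF.** From a wire-phantom image: slice averaging, sub-pixel wire
centroid, background subtraction, pixel-aperture deconvolution, radial
profile in quarter-pixel bins, order-0 Hankel transform
MTF(f) = |2π ∫ p(r) J₀(2πfr) r dr|, finite-wire (Nickoloff) correction by
2J₁(πdf)/(πdf), normalisation to unity at f = 0, and 50%/10% cutoffs in
LP/cm.

## Worked example

Estimate the MTF of a simulated photon-counting-class system from a 100 µm
wire phantom:

```r
library(ctresolve)
psf <- gaussian_psf_from_cutoff(0.5, 11.0)   # sigma = 0.1704 mm
wire <- simulate_wire_acquisition(wire_phantom_spec(0.1), psf)
estimate_mtf(wire, wire_diameter_mm = 0.1)
#> <mtf_estimate> 50% cutoff 10.99 LP/cm, 10% cutoff 20.03 LP/cm
```

The 50% cutoff returns the 11.0 LP/cm the PSF was built from (to 0.1%);
the 10% cutoff sits at the Gaussian's fixed 1.82× ratio.

Run the full default experiment — six nodules, three system profiles,
triplicate segmentation, three wire scans — in about half a minute:

```r
report <- run_experiment(default_experiment_config(seed = 1))
report
#> == Bland-Altman (measured - reference, mm^3) ==
#>  profile mean_diff sd_diff loa_low loa_high
#>       ct     -8.83    8.67   -25.8     8.16
#>     hrct     -9.20    9.16   -27.2     8.76
#>    spcct     -7.09    5.55   -18.0     3.79
#> ...
#> == MTF cutoffs (LP/cm) ==
#>  profile wire_diameter_mm cutoff_50_lp_cm cutoff_10_lp_cm
#>       ct              0.2            6.69            12.1
#>     hrct              0.2            6.07            11.1
#>    spcct              0.1           10.69            20.1
```

Reading the (abridged) report: every profile underestimates nodule volume
on average, least so for the high-resolution `spcct` profile; the Dice
table (not shown) rises with nodule size within every profile and is
highest for `spcct` throughout, with the pairwise paired t-tests separating
`spcct` from both conventional profiles (p ≈ 0.01) but not the two
conventional profiles from each other. The wire-scan cutoffs recover each
profile's matched 50% value to within a few percent under 5 HU measurement
noise.

See `vignettes/ct-resolution-phantoms.Rmd` for the models, parameter
choices and numerical details.

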