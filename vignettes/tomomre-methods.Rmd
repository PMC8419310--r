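---
title: "Multifrequency MRE of the inflamed mouse brain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifrequency MRE of the inflamed mouse brain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomomre)
```

## The scientific problem

Neuroinflammation softens brain tissue.  In the mouse model of multiple
sclerosis (experimental autoimmune encephalomyelitis, EAE), multifrequency
magnetic resonance elastography (MRE) detects this softening *in vivo*:
externally driven shear waves (here 1,000--1,400 Hz in 100 Hz steps) are
imaged as complex displacement fields, and inversion algorithms convert them
into maps of

* **shear wave speed** `c` (m/s) --- the stiffness surrogate (softer tissue,
  lower `c`), and
* **loss angle** `phi` (rad) --- the phase of the complex shear modulus
  `G*`, a fluidity surrogate (`0` = elastic solid, `pi/2` = fluid).

Two contrast agents localize distinct facets of inflammation: a gadolinium
chelate (GBCA) marks blood--brain-barrier leakage as diffuse T1
hyperenhancement, and europium-doped very small iron oxide particles
(Eu-VSOP) mark cellular inflammation as small hypointense T2\* foci.  The
analysis overlays image-derived lesion masks on the MRE parameter maps and
asks, per animal and paired across the baseline and EAE timepoints, whether
tissue inside those masks softens more than the rest of the brain.

Because the original in vivo scans are not publicly deposited, the package
pairs every analysis stage with a synthetic-data generator whose defaults
encode the study conditions: 7 coronal slices of 0.8 mm, a 90 x 60 in-plane
matrix at 0.18 mm x 0.18 mm, five vibration frequencies, a brain-shaped
domain with paired ventricles, large diffuse Gd-type lesions near the
ventricles, small focal VSOP discs, and the reported group effect sizes
(whole brain 3.15 &plusmn; 0.11 m/s at baseline softening by about 8%; Gd
areas by -9.76 &plusmn; 13.32%; VSOP foci by -16.81 &plusmn; 16.49% against
a -5.85 &plusmn; 3.81% change in the rest of the brain; fluidity
0.69 &plusmn; 0.03 rad and unchanged).

## Wave model and conventions

A time-harmonic shear wave in a viscoelastic medium obeys, per slice, the
scalar Helmholtz equation `div(G* grad u) + rho omega^2 u = 0` with
`G* = rho c^2 cos^2(phi/2) exp(-i phi)` and density `rho` fixed at
1,000 kg/m^3 (soft-tissue convention; configurable).  The package's sign
convention makes a wave travelling along `+x`

`u(x) = exp(i k x)`, with `k = (omega / c) (1 + i tan(phi/2))`,

so `Re k = omega/c` defines the ground-truth phase speed --- precisely the
quantity the wavenumber inversion estimates --- and `Im k` sets the
attenuation.  At 1,000 Hz with `c = 3.15` m/s and `phi = 0.69` rad the
attenuation length `1/Im k` is about 1.4 mm (8 pixels): mouse-brain MRE at
kilohertz frequencies is strongly damped, which drives several design
choices below.

Two forward models generate fields:

* `simulate_wavefield(..., method = "helmholtz")` --- a per-slice
  finite-difference frequency-domain (FDFD) solve with full-edge Dirichlet
  excitation, a 10-pixel graded cubic damping layer on absorbing edges, and
  an optional `supersample` factor.  The complex sparse system is solved
  exactly (LU) via an equivalent real block system.  Second-order FDFD
  carries numerical dispersion `~ (kh)^2/24` in phase speed; at the
  acquisition grid (about 17 points per wavelength) the accumulated phase
  drift over the 16 mm field of view exceeds a few percent, so
  field-accuracy validations run at `supersample` 2--3, where the solution
  matches the analytic damped plane wave to 1.4--1.7% mean pointwise complex
  error.  Inversion accuracy is insensitive to this (dispersion shifts the
  local wavenumber by only ~0.15% at the acquisition grid).
* `method = "rays"` --- a phase-integration model that superposes four
  cardinal damped waves whose phase and attenuation accumulate from the
  local complex wavenumber.  Its ground truth is by construction the local
  phase speed `omega/c(x)`, making it the reference forward model for
  end-to-end recovery experiments and large replicate studies, at a tiny
  fraction of the FDFD cost.

In both models, each frequency has one *dominant* source direction (cycling
through the four cardinals across the five frequencies; secondary sources at
0.08 relative amplitude).  This emulates a cranial geometry that favors one
propagation direction per drive frequency while the multifrequency set
retains full directional coverage, and it keeps the inversion
well-conditioned in the strongly damped regime.  Paired scans of one animal
share the same drive phases (the animal holder and actuator are identical at
both visits); measurement noise --- complex Gaussian for wave images, Rician
for magnitude contrast images --- is drawn independently per scan.  The
physical field extends beyond the brain (the surrounding tissue vibrates
too) and is kept: zero-filling non-brain voxels before Fourier filtering
would corrupt a boundary band of the maps.

## The inversions

**Shear wave speed (`invert_stiffness`).**  Each field is first
amplitude-normalized to its phase-only form `u/|u|`: with an attenuation
length of a few pixels, the raw spectrum is a Lorentzian of width comparable
to the carrier and fan filtering the raw field leaves leakage that dominates
the damped interior.  The normalized field is decomposed into
half-overlapping raised-cosine angular sectors (a partition of unity)
restricted to a radial band (default
`[omega_max/(3 c_max), 3 omega_min / c_min]` for an expected 1--6 m/s speed
range).  Per sector, the local wavenumber is the smoothed magnitude of the
phase gradient, computed unwrap-free as `Arg(u[+1] Conj(u[-1]))/(2h)` ---
the discrete form of `Im(grad u / u)`, exact for locally linear phase.
Speeds `omega/k` are then averaged over all (frequency, sector) components
with weights `(sector amplitude)^2 x (raw local amplitude)^2`; the second
factor lets frequencies whose dominant wave is shadowed (behind ventricles
or strongly attenuating lesions) defer to frequencies with coverage.

The default sector count is 4.  A fan sector of angular width `Delta` passes
only `~ k sin(Delta/2)` of spatial frequency transverse to the carrier;
45-degree sectors (the conventional count of 8) clip the spatial bandwidth
of the focal lesions this study targets (radius ~0.5 mm at
`k ~ 2000` rad/m), attenuating their recovered contrast by almost half,
while 90-degree sectors pass it and match the four-point excitation
geometry.  Eight sectors remain available via `inversion_config()`.

**Loss angle (`invert_loss_angle`).**  The direct multifrequency estimator
`phi = arccos( -sum_j Re(Lap u_j Conj(u_j)) / sum_j |Lap u_j| |u_j| )`, with
the spacing-scaled 5-point in-plane Laplacian applied to Gaussian-smoothed
fields and the sum running over frequencies.  The discrete Laplacian of a
damped wave is `-(4/h^2) sin^2(k h/2) u` rather than `-k^2 u`, which shifts
the recovered angle by `-(kh)^2 tan(phi/2)/6` to leading order --- a bias
that grows as tissue softens (`k = omega/c`), so left uncorrected it leaks
stiffness changes into apparent fluidity changes.  The estimator therefore
applies the analytic leading-order debias `phi + k^2 h^2 sin(phi)/12`,
with `k^2` estimated locally as `sum |Lap u| |u| / sum |u|^2`.  The elastic
limit is exact to machine precision and the damped plane wave at
`phi = 0.70` is recovered to ~0.001 rad.  Slices are processed
independently (0.8 mm slice gap versus 0.18 mm in-plane).

**Validity.**  Maps carry an explicit validity mask: pixels within 2 px of
the brain boundary (stencils straddle the mask), below an amplitude or
weight floor, or with wavenumbers outside the physically admissible band are
invalid, and regional statistics ignore them.  Ventricles are never
analyzed --- shear waves do not propagate in fluid --- and the paired
regional analysis additionally excludes a 2-px partial-volume ring around
them and restricts both timepoints to their joint validity mask, so paired
means always compare identical pixel sets.

## Lesion masks

The mask pipeline replaces the study's manual lesion drawing with
reproducible thresholding (all thresholds configurable): Gd masks from the
percent signal change map `100 (post - pre)/pre` at a default +15%
threshold; VSOP masks where the post/pre ratio falls below 0.8; in-plane
connected components smaller than 5 px removed.  VSOP masks are dilated by
two pixels (4-connected cross applied twice --- a single pixel grows to the
13-pixel L1 ball) to absorb single-pixel effects at the MRE resolution,
in-plane only because the voxels are strongly anisotropic.  The frozen
order is threshold, dilate, mutual exclusion (voxels marked by both agents
are disregarded), ventricle removal; `lesion_masks` objects track this
state machine and refuse inconsistent states.  Whether dilation preceded
ventricle exclusion in the original workflow is not documented; the order
here is fixed and easy to vary for sensitivity analyses.

Incidence maps report, per voxel, the percentage of animals whose final
mask covers it, after nearest-neighbour resampling of the 7-slice slab onto
a 215-slice reference grid spanning 20.8 mm (the slab then populates about
58 reference slices).  The regional incidence table gives, per atlas label,
the percentage of animals whose mask intersects the region.  The bundled
atlas is a deliberately simple geometric partition (cortical shell, two
deep anterior zones, a fiber-tract band, a brain-stem zone); registration
to a real reference atlas is out of scope.

## Paired statistics

`paired_compare` reproduces the study's gated procedure: both groups are
tested with the D'Agostino--Pearson omnibus test (`K^2 = Z_skew^2 +
Z_kurt^2` against chi-squared with 2 df; implemented from the original
transforms since no installed package provides it, and verified against an
independent reference implementation).  If both groups pass at
`alpha = 0.05` (the GraphPad default; the test is read as applying to the
two compared groups, not their differences), a two-sided paired t-test is
used; otherwise the Wilcoxon matched-pairs signed-rank test (zero
differences dropped, exact null distribution for n &le; 25 without ties,
mid-rank normal approximation with continuity correction otherwise).  Below
8 pairs the omnibus test is undefined; the procedure warns and uses the
Wilcoxon branch.  No multiple-testing correction is applied: each comparison
is reported with its own unadjusted p, matching the reporting convention the
package emulates.  Monte-Carlo calibration (10^4 replicates, n = 19) puts
the type-I error of the full gated procedure in [0.04, 0.06] at the 5%
level for both Normal and strongly skewed data.

## The synthetic cohort: what it emulates, and what it does not

`make_cohort` draws, per animal: a baseline speed scale
(`Normal(3.15, 0.11)` m/s whole-brain); a shared *disease-severity factor*
that scales all of the animal's stiffness percent changes together, plus
independent per-class residuals, with the per-class factor capped so every
class keeps exactly its quoted marginal spread --- independent class draws
would imply `sd(lesion - rest) ~ 17` points and a far weaker paired
contrast than the study reports, so the reported statistics themselves
require strongly correlated lesion and rest-of-brain responses; a
fluidity scale (`Normal(0.69, 0.03)` rad) with a *null* fluidity change
(the reported 0.69 to 0.70 rad shift is within rounding and
non-significant; a zero-mean 8% between-animal jitter represents
measurement-scale variability), lesion-site presence (Bernoulli with
site-specific rates: the always-present deep site, the 80% periventricular
hotspot, the 78.9% brain-stem site, and VSOP sites at 90.9%/63.6%), and a
&plusmn;1 px positional jitter.  The quoted between-animal spreads are used
as the marginal spreads of the truth --- apart from the severity-factor
correlation, the generator makes no attempt to partition variance the
study does not report (per-animal values are not published).

Wave-image noise defaults to 2e-4 a.u. (source amplitude 1).  The 2D
forward models lack the reverberant three-dimensional energy
redistribution of real tissue and therefore overstate the decay dynamic
range: deep lesion interiors reach amplitudes of ~1e-3 of the source.  The
noise floor is anchored below that level so that viscoelasticity remains
measurable across the whole slab --- including inside VSOP foci, where the
study reports group statistics --- rather than to a nominal image-domain
SNR.  Noise robustness of the inversions themselves is verified separately
at 20 dB SNR on homogeneous phantoms.

Two geometric choices deserve emphasis:

* **Mechanical halos.**  The mechanically altered region extends beyond the
  visible contrast region by the inversion's point-spread reach (gradient
  stencil + two smoothing sigmas = 3 px), plus the 2-px mask dilation for
  VSOP foci (halos: Gd 3 px, VSOP 5 px).  Inflammatory tissue change around
  a contrast core is biologically plausible, and this construction is what
  makes image-derived masks sample lesion cores rather than partial-volume
  boundaries --- without it, no smoothing-based inversion can recover
  injected regional changes unbiasedly.
* **Lesion scale.**  VSOP contrast foci have radius 3 px (0.54 mm),
  matching "small and focal" at the acquisition resolution; Gd blobs are
  several-fold larger and sit near the ventricles.

The generator emulates the statistical structure the analysis assumes ---
paired design, class-wise effect sizes, presence rates, measurement noise
--- not scanner physics: there is no k-space simulation, no registration
error, no physiological motion, and the ray forward model has no
diffraction.  Passing tests therefore demonstrate that the *analysis chain*
(inversion, masking, statistics) recovers what was injected under the
study's conditions; they do not validate performance against unmodeled
acquisition artifacts.

## Numerical choices and reduced problem sizes

Deterministic sub-seeding (a counter scheme off one master seed) makes every
stage bit-reproducible and keeps earlier animals unchanged when a cohort
grows.  Degenerate inputs are explicit: empty frequency lists, all-NaN
fields, empty regions, all-zero paired differences and sub-gate sample
sizes all produce typed errors, warnings or flagged results rather than
NaNs.  The `arccos` argument is clipped to [-1, 1]; wavenumbers outside a
0.5--20 m/s speed window get zero weight.

Replicate studies (cohort power and direction-recovery rates) run on a
single-slice 60 x 90 phantom with the ray forward model --- about 0.3 s per
animal --- which keeps a 50-replicate, n = 8 study near two minutes while
preserving the full in-plane acquisition geometry.  The FDFD solver is
reserved for the physics validations, where its cost (seconds per slice at
`supersample` 2--3) is paid a handful of times.

## Known limitations

* The 2D scalar wave model ignores mode conversion and through-plane
  propagation; the study's own inversion is also slice-wise, but real
  displacement fields are 3D vectors.
* Focal lesions near one wavelength in size are partial-volume limited in
  any local-wavenumber method; recovered contrast depends on the
  sector aperture (see above) and on lesion size relative to `lambda`.
* The loss-angle stencil debias is leading-order and assumes near-axis
  propagation; residual bias at the acquisition settings is ~0.001 rad.
* The toy atlas supports region bookkeeping, not anatomical inference.

## A minimal session

```{r example, eval = FALSE}
library(tomomre)

# a small paired cohort at the study's effect sizes
cfg <- pipeline_config(
  cohort = cohort_spec(n_animals = 8, grid_shape = c(2, 60, 90), seed = 1,
                       lesion_presence = "always"),
  out_dir = "eae_run")
res <- run_pipeline(cfg)
print(res$summary)
render_report(res)

# lesion-vs-rest contrast of stiffness percent change
lesion_vs_rest(res$analysis, "vsop", "c")
```
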