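---
title: "Simulating and quantifying synaptic nano-organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying synaptic nano-organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsenano)
```

# The problem

Excitatory synapses on cortical dendritic spines are built from
sub-diffraction protein assemblies: postsynaptic PSD-95 nanoclusters
(NCs, roughly 100-200 nm across) aligned across the synaptic cleft with
presynaptic Bassoon NCs. A PSD-95 NC with at least one trans-synaptically
aligned Bassoon partner is a *nanomodule*; spines carry one to four of
them, and spine volume grows roughly linearly with the count. The
presynaptic input class of a spine is read out at confocal resolution
from vesicular glutamate transporter markers: VGluT1 marks
corticocortical (CC) input, VGluT2 marks thalamocortical (TC) input.

Quantifying this organization from multi-channel confocal/STED stacks
involves a chain of image-analysis stages — frame thresholding, 2D puncta
co-clustering, 3D nanocluster segmentation, object-based colocalization,
per-spine assignment and counting, input classification, line-profile
resolution measurements — each with conventions and thresholds whose
interaction is hard to validate on real microscopy, where no ground truth
exists. `synapsenano` therefore pairs the full analysis chain with a
scene generator that renders populations of spines with *known* identity,
nanomodule count, cleft offset and cluster size through a realistic
imaging model. Every stage is then validated by parameter recovery: the
analysis must return the numbers the generator put in.

# The imaging model

Emitters (nanoclusters, vesicle-cluster blobs, calibration beads) are
isotropic Gaussians of intrinsic full width at half maximum (FWHM)
`size_nm`; the microscope point-spread function (PSF) is a separable
anisotropic Gaussian. Because a Gaussian convolved with a Gaussian is
Gaussian, the rendered object has per-axis FWHM
`sqrt(size^2 + psf^2)` — the quadrature law — which gives the renderer a
closed-form oracle that the test suite checks across random sizes.

Rendering integrates the Gaussian over each voxel (differences of the
normal CDF per axis) rather than point-sampling it. This keeps total
photon flux exactly conserved on any grid, including the deliberately
sub-Nyquist 150 nm axial step of the STED stacks, at the cost of a small,
quantified widening (a boxcar of one voxel adds `spacing^2/12` to the
per-axis variance, about 0.7 nm of apparent FWHM on a 20 nm grid).
An isolated emitter is scaled so its brightest voxel has the expected
photon count `peak_photons`; a uniform `background_photons` is added; the
recorded stack is Poisson-distributed around that expectation, as for a
photon-counting detector. No read noise is modelled.

Channel defaults, recorded in `default_run_config()` and frozen in a test
fixture:

* STED channels (PSD-95, Bassoon): 20 nm XY / 150 nm Z voxels, 50 nm
  lateral PSF FWHM, 8 peak photons per voxel, background 0.02
  photons/voxel. The near-zero background reflects fluorescence-lifetime
  gated acquisition: the generator emits already background-removed
  stacks, which is what the downstream thresholds expect.
* The axial STED PSF FWHM is not stated by any imaging parameter we
  model from; it is set to 90 nm so that the simulated instrument
  reproduces the calibrated axial behaviour of the real one — two beads
  90 nm apart along z are separable. This is a package default, not a
  measured value.
* Confocal channels (morphology, VGluT1, VGluT2): 100 nm XY / 300 nm Z
  voxels, 250 nm lateral / 600 nm axial PSF FWHM, 30 peak photons,
  background 1 photon/voxel.

# The scene generator

`scene_config()` holds the population model; its defaults are the
layer-5 basal-dendrite study conditions used by the recovery
experiments:

* P(TC) = 68/507; nanomodule-count distributions over 1..4 of
  (308, 107, 20, 4)/439 for CC spines and (44, 21, 3, 0)/68 for TC
  spines;
* cleft offset 140 nm between paired PSD-95 and Bassoon centres, with a
  50/50 mix of laterally dominant (Type A) and axially dominant (Type B)
  orientations, azimuth uniform (`cleft_theta_deg` can pin the polar
  angle for orientation-recovery studies);
* intrinsic NC FWHM 150 +/- 25 nm (clamped to 80-220 nm);
* spine volume = 0.10 + 0.20 x count um^3 plus a positive lognormal
  perturbation (median 0.04 um^3), so the volume-per-nanomodule scaling
  law is recoverable by construction, with volumes in the realistic
  0.3-1 um^3 range for TC-scale spines.

Spine heads are spheres on a square lattice with at least 500 nm of
surface gap and sub-voxel placement jitter (without the jitter, every
mask would be voxelised at the same grid phase and mask volumes would be
systematically biased). A 600 nm neck along the spine axis (80% in-plane,
20% along z) breaks the sphere's symmetry so the principal-axis
orientation classifier has something to recover. A dendritic shaft
cylinder is rendered in the morphology channel only.

Nanomodules are placed on a ring in the head's equatorial plane at
radius `head_radius - nc_margin_nm` with at least 300 nm between
modules. The 330 nm default margin keeps a segmented NC's thresholded
footprint, plus the cross-grid nearest-neighbour quantisation slack,
strictly inside the spine mask. This idealisation stands in for an
effect the generator does not model: in real data the morphology mask
comes from thresholding a PSF-blurred fluorophore fill and is therefore
dilated well beyond the true membrane, which is what makes
membrane-apposed PSDs fall "entirely within" it. Each Bassoon emitter
sits exactly `cleft_offset_nm` from its PSD-95 partner; one VGluT blob
(intrinsic FWHM 300 nm) of the spine's class sits on the head surface.

What the generator deliberately does not emulate: dendrite tortuosity
and spine crowding, irregular (non-spheroidal) spine and cluster shapes,
labelling stochasticity and linkage error, depth-dependent aberrations,
fluorophore blinking/bleaching, and lifetime-gating artifacts. Passing
recovery therefore demonstrates that the analysis chain is correct and
internally consistent at realistic photon budgets and grids — not that it
is robust to every failure mode of real tissue microscopy.

# The analysis chain

**2D puncta co-clustering** (confocal): maximum-intensity projection;
binarisation at frame mean + 2 SD (strict inequality, so a constant
frame yields an empty mask); 8-connected components kept between 3 and
100 pixels; co-clusters defined as cross-channel pairs sharing strictly
more than one pixel; densities reported per 10 um of dendrite with a
50 um minimum-length convention.

**3D nanocluster segmentation** (STED): the analysis image is first
smoothed with a light 0.8-pixel per-slice lateral Gaussian blur (the
standard processing step; it also suppresses Poisson speckle that would
otherwise split seeds). Then (1) global threshold `T_g` = frame mean +
2 SD; (2) seeds are voxels above `T_g` that are strict maxima within an
ellipsoid of 5 pixels laterally and 2 voxels axially, ties broken toward
the lower linear index; (3) each seed grows a 26-connected region of
voxels strictly above `max(T_g, peak * exp(-1.5^2/2))` — the per-seed
"Gaussian fit" threshold at 1.5 SD of a Gaussian profile, about 32.5% of
the seed peak — within 20 pixels of the seed (the axial limit scaled by
`dx/dz` so the physical reach is near-isotropic); contested voxels are
resolved by seeded watershed on inverted intensity (Meyer's flooding in
decreasing-intensity order, deterministic tie rules); (4) components
outside 3..20000 voxels are discarded. The plugin convention this
emulates does not publish its local-threshold formula; the
`exp(-sd^2/2)` reading is an interpretation, and the multiplier is a
parameter. Cluster centroids are intensity-weighted with the region's
admission threshold subtracted from the weights; the pedestal
subtraction makes centroids robust to light contamination from an
overlapping partner cluster. Whether "centre" should be geometric or
intensity-weighted is not prescribed anywhere we model from; the
background-subtracted weighted centroid was chosen because it is the
least biased of the three on rendered scenes.

**Pairing and distances**: nearest-neighbour centre-to-centre distances
are asymmetric (each channel-1 object to its closest channel-2 object);
trans-synaptic pairs are cross-channel clusters sharing at least one
voxel, each with a Euclidean centre distance and an orientation class
(A if the lateral centroid offset dominates, B otherwise).

**Per-spine analysis**: spine ROIs come from the generator's truth in
synthetic mode (a provided label image or a mean + 2 SD morphology
threshold otherwise); the head ROI is the full mask — the head/neck split
is a manual operation in practice and is not reproduced. Discrete NCs
are re-identified per spine at ROI mean + 1.5 SD. PSD-95 NCs are
assigned only if *every* voxel centre lies inside the ROI; Bassoon NCs
are associated on any overlap or a centroid within 200 nm of the ROI
(the 0.15-0.2 um presynaptic band). The nanomodule count is the number
of assigned PSD-95 NCs with at least one trans-synaptic partner — keyed
on PSD-95, so one Bassoon shared by two PSD-95 NCs contributes two.
Spines with zero aligned modules are excluded from single/multiple
denominators and reported separately. A Bassoon NC may be associated
with two adjacent spines; the rule permits double counting and the
per-spine table makes it visible. Input classification: TC iff VGluT2
overlaps the projected spine mask by more than one pixel and VGluT1 does
not (CC conversely); dual overlaps are broken by the marker overlapping
the aligned nanomodule footprint, then by the larger overlap; no marker
leaves the spine unclassified.

**Profiling**: line profiles are bilinear/trilinear interpolations along
a direction through a centre (default 1 um long at one pixel per step).
FWHM comes from a least-squares Gaussian + offset fit
(`FWHM = 2 sqrt(2 ln 2) sigma`) rather than half-max crossings, which at
5-10 photons per pixel is far more stable; non-convergent or
boundary-peaked fits are flagged and excluded from summaries. Peak
separation fits one- and two-Gaussian models (shared width, optionally
fixed to a known PSF sigma during calibration) and is adjudicated by
AICc; the Rayleigh dip is measured between the *fitted curve's own
maxima* — near the resolution limit the apparent peaks sit well inside
the fitted centres, and evaluating at the centres would report spurious
negative dips. A pair is resolved iff the two-peak model is preferred
and the dip is positive.

# Numerical choices and degenerate inputs

All thresholds are strict; a constant image thresholds to an empty mask
rather than an error. The segmentation threshold is floored at one
photon (`min_threshold_photons`): on a sufficiently sparse frame the
mean + 2 SD statistic can fall below the single-photon level — made
worse by the smoothing, which shrinks the frame SD — at which point
every stray background photon would seed a small spurious cluster. The
floor only states that a cut below photon granularity is meaningless
for photon-counting data; on frames with realistic cluster density the
frame statistic is far above it and the floor is inactive. Maxima ties and watershed ties resolve toward the
lower linear index, making segmentation bit-deterministic. All
randomness flows through one seeded generator with documented sub-seed
derivation, so identical (config, seed) pairs give bit-identical scenes
and stacks; the caller's RNG state is restored afterwards. Coordinates
are physical nanometres everywhere outside voxel arrays; arrays are
`(nz, ny, nx)` with z fastest; externally reported voxel indices are
0-based. Zero-module spines have undefined (NA), not zero, volume
metrics. Segmentation of an empty or all-background stack returns an
empty table, not an error; nearest-neighbour distances against an empty
reference set are an error, because the quantity is undefined.

# Calibration phantoms and the axial grid

Nano-ruler phantoms place pairs of point emitters at a designed spacing
(lateral 50 nm or axial 90 nm by default, +/- a small manufacturing
jitter) at least 1 um apart. Lateral rulers are analysed on the standard
20 nm / 150 nm grid. Axial rulers are analysed on a 50 nm z-step: a
90 nm axial spacing is below the Nyquist limit of a 150 nm step, and
calibration of axial resolution requires (and, on the real instrument,
uses) finer z-sampling than tissue stacks; the tissue-scene grids keep
the 150 nm step throughout. The axial measurement integrates intensity
over a small lateral disc per plane and fits the two-Gaussian model with
the PSF-derived sigma held fixed (including the `spacing^2/12` sampling
term), which keeps the separation identifiable at Rayleigh-scale
spacings.

# Recovery experiments and problem sizes

The `recover_*` functions are the package's calibration suite and the
basis of `scripts/acceptance.R`:

* `recover_nanomodule_fraction()`: 500 VGluT1+ spines (rendered in
  fields of 25), full per-spine chain; the single-module fraction among
  spines with at least one aligned module recovers the generated 70%.
* `recover_input_fraction()`: 507 spines at the 68:439 TC:CC
  composition, drawn with exact class counts because the experiment
  emulates an observed population rather than a sampling model;
  classification recovers 13.4% TC with near-perfect accuracy.
* `recover_cleft_distance()`: whole-frame segmentation of both STED
  channels, >= 200 overlap pairs pooled; recovers the 140 nm offset.
  Across 80-200 nm offsets the recovered mean tracks the truth to
  within about 4%; the residual bias is the sub-Nyquist axial
  quantisation of centroids plus the selection imposed by the
  >= 1-voxel overlap rule at large offsets, both discussed above.
* `recover_axial_ruler()` / `recover_lateral_ruler()`: mean fitted
  separations of 100 axial and 43 lateral pairs (about 93 nm and 51 nm
  with a positive dip at the defaults).
* `recover_fwhm()`: 100 isolated clusters whose intrinsic size is set so
  the image-domain FWHM is 126 nm; profiles through the segmented
  centroid of the cluster matched to each designed position recover the
  target to a few nanometres.

These sizes keep the whole suite within a few minutes on one CPU while
leaving the Monte-Carlo standard errors several times smaller than the
tolerances they are compared against.

# Known limitations

The generator's geometric idealisations (spherical heads, ring-placed
modules, interior PSD placement) are chosen so that every assignment
rule has an unambiguous ground truth; they under-represent the boundary
cases real data is full of (PSDs at the mask edge, touching spines,
irregular clusters). The per-spine re-identification uses the padded
bounding box of each spine, so a cluster belonging to a neighbouring
spine can in principle appear in two spines' fields; the assignment
rules make this harmless at the generator's 500 nm spacing but it is not
prevented in general. ANCOVA-style slope comparison is implemented as
the interaction-term t-test in a pooled two-group linear model, the
homogeneity-of-slopes reading of that term. The CLI's `simulate`
subcommand writes plain TIFF with a YAML sidecar as its metadata channel
(the sidecar wins over any embedded OME description on conflict);
embedded OME-XML is parsed on read but not written.
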