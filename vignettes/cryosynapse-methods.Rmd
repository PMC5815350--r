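---
title: "Quantifying synaptic architecture in cryo-electron tomograms"
author: "cryosynapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic architecture in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryosynapse)
```

# Scope

Cryo-electron tomography resolves chemical synapses in a near-native
state, but telling an excitatory synapse from an inhibitory one in a grey
3-D volume requires quantitative operators, not adjectives. This package
implements a set of such operators — junction density profiling,
synapse-type clustering, vesicle template matching and shape fitting,
membrane-particle morphometry, receptor reference dimensions from atomic
models, and the landmark registration that ties fluorescence images to EM
stage coordinates — together with phantom generators that make every
operator testable against known ground truth. This vignette explains the
models behind each operator, the tunable parameters and their defaults,
the numerical choices, and what the synthetic validation does and does
not establish about real data.

# The junction density model and its metrics

The central quantity is the cross-sectional density profile `v(d)`: the
mean density at signed distance `d` from the postsynaptic membrane, with
`d = 0` at the membrane centre and `d > 0` into the postsynaptic
cytoplasm. The profile of a healthy junction shows, in order: the
presynaptic membrane peak near `d = -26` nm, an intercleft band
mid-cleft, the postsynaptic membrane at 0, a low-density gap, and the
postsynaptic density (PSD) rising to a crest at `d1` before decaying into
the flat cytoplasmic background.

Three numbers summarize the PSD. The crest position `d1`; the length
constant `lambda` of an exponential fit

  `v = A exp(-d / lambda) + B`

to the decay from the crest toward the background (`d` here measured from
the crest); and the thickness measure `d2 = d1 + lambda`. Thick-PSD
(excitatory-like) synapses have `d2` around 30 nm with large scatter;
thin-PSD (inhibitory-like) synapses sit near 12 nm with little scatter.
Cleft width is the distance between the two fitted membrane-peak centres.

## Profile construction

`project_slab()` averages a 10 nm slab along the beam (z) axis;
`extract_profile()` then averages the slab image over offset curves of a
hand-traced membrane polyline. The offset curves are implemented through
the signed Euclidean distance to the polyline (sign from the declared
postsynaptic side): a pixel contributes to the bin whose centre is
nearest its signed distance. For a straight trace this reduces exactly to
averaging along parallel virtual lines; for curved traces it is the
natural generalization and requires no explicit polyline offsetting. Bins
whose offset curve leaves the image are reported `NA` with per-bin pixel
counts, never silently truncated.

`normalize_profile()` maps the 100–200 nm "flat" window to mean 0 and SD
1. The operation is affine in value, hence idempotent, and removes the
arbitrary brightness/contrast of individual tomograms so profiles can be
averaged and compared across imaging sessions.

## Peak fitting choices

Detection uses local maxima of the profile after light Gaussian smoothing
(`smooth_sigma`, default 1.5 nm) above a threshold of 1.5 flat-window SDs
(configurable; these two values are exposed precisely because no
principled universal value exists). Smoothing matters for the membranes:
at sufficient resolution a bilayer resolves into two leaflet ridges
~3.5 nm apart, and the relevant landmark is the bilayer centre, which the
smoothed profile's single merged peak provides. Membrane and intercleft
positions are then refined by a Gaussian-plus-linear fit in a ±5 nm
window; the linear term absorbs the sloping background under each peak.

The PSD crest needs different treatment. Its shape is asymmetric by
construction — a fast rise out of the gap and a slow exponential fall —
and fitting a symmetric Gaussian to it drags the fitted centre toward the
tail, by up to ~3 nm when `lambda` is large. The crest is therefore
refined on the *unsmoothed* profile by the stationary point of a local
least-squares parabola over ±1.6 nm (about two profile samples at
tomographic sampling). The window size is a bias–variance compromise
established on phantoms during development: narrower windows are
noise-dominated, wider ones re-introduce the tail bias.

A synapse with no local maximum above threshold between the membrane edge
and 60 nm is reported as a structured "no visible PSD" result rather than
an error; such synapses exist in real data and are excluded from
clustering but counted separately.

## Exponential tail fit

`fit_psd_decay()` fits `A exp(-d/lambda) + B` by Levenberg–Marquardt
(minpack.lm) over samples from the crest to the start of the flat window
(100 nm). Initialization: `B` from the far end of the fit range, `A` from
the crest value, `lambda` from the distance at which the profile first
drops to `B + A/e`; bounds `lambda` in (0, 100] nm. Non-convergence is an
error carrying the initial state, not a silent `NA`.

# Synapse-type clustering

`cluster_psd_metrics()` partitions synapses in standardized `(d1, d2)`
space. The default model is a two-component Gaussian mixture (mclust)
rather than 2-means, for a structural reason: the thick class's scatter
in both coordinates is several times the thin class's, and an
equal-variance boundary (which 2-means implies) systematically absorbs
the thick class's low-`d2` tail into the thin cluster — on populations
simulated at the characteristic class means and SDs this costs ~8 % of labels,
while the variable-covariance mixture classifies ~99 % correctly. The
deterministic 2-means variant (farthest-pair initialization, Lloyd
iterations) is retained both as an option and as the carrier of exact
invariance guarantees (order, duplication, joint affine rescaling);
the two methods agree on well-separated data. The cluster with the larger
mean `d2` is labelled "thick". Fluorescence-marker labels, when present,
validate the clustering; they are never used during it.

`ks_two_sample()` compares distributions (e.g. per-synapse ellipsoidal
vesicle fractions between classes). `D` is the supremum ECDF distance;
the p-value is exact for `min(n, m) <= 10` — computed by lattice-path
counting over all label assignments, with ties handled through pooled
value blocks — and the asymptotic Kolmogorov series otherwise. The exact
path is cross-checked in the tests against a brute-force enumeration
oracle and against `stats::ks.test`.

# Vesicle detection and shape

## Template matching

`build_template_bank()` renders featureless spherical shells, 5 nm thick,
diameters 25–70 nm in 1 nm steps (46 templates), Gaussian low-passed to
10 nm resolution and normalized to zero mean, unit norm. The low-pass
convention throughout the package: amplitude falls to one half at spatial
frequency `1/resolution`.

`match_templates()` computes FFT cross-correlations of every template,
normalized by the local density energy under one shared spherical mask of
the bank's largest radius. Sharing the mask costs two convolutions in
total instead of two per template, and — because the denominator at a
given position is the same for all templates — leaves the per-position
diameter choice a pure matched-filter comparison, which is unbiased on
noiseless spheres to ±1 nm across the bank. The price is that the score
scale is not the classical NCC scale: true shell matches at unit SNR
score ~0.17–0.38 and pure-noise volumes peak near 0.03. The default
acceptance threshold, 0.1, sits three-fold above that measured noise
ceiling; it was calibrated against the noise floor, and remains
configurable because practice still expects visual curation of accepted
detections. Non-maximum suppression uses physical non-interpenetration:
a candidate is suppressed when its shell (outer radius = matched
radius + shell thickness/2) would overlap an already-accepted one, which
also removes the side-lobe responses of other template sizes riding on a
detected shell.

Templates are spherical only; strongly ellipsoidal vesicles match at
reduced score and, in real workflows, are supplied by manual picking —
the same route the 3-D fitting entry point accepts.

## 2-D and 3-D shape fits

`extract_equatorial_points()` implements the donut rule: on the central
x–y slice through a detection, pixels inside the annulus (matched radius
±5 nm by default, covering the 5 nm shell) whose density is strictly
above the annulus mean become the membrane point set. The strict
inequality makes a uniform slice an explicit error rather than a
degenerate fit. The rule presupposes phase-plate-grade contrast on the
single slice; at unit SNR the annulus fills with noise selections and
fitted ratios collapse toward 1 (the analysis driver demonstrates this by
running detection on the noisy field and shape extraction on a
high-contrast rendering).

`fit_ellipse_2d()` is the numerically stable block-decomposed direct
least-squares conic fit with the ellipse constraint `4ac - b^2 = 1`, after
centring and scaling for conditioning; it returns an ellipse for any
input in general position and is exact (1e-6) on noiseless points.
`fit_ellipsoid_3d()` fits the 9-coefficient quadric `x'Mx + g'x = 1` to
centred points by linear least squares and converts to centre and sorted
semi-axes via the eigendecomposition of `M`; a non-positive-definite `M`
is a documented failure ("not an ellipsoid"), not a silent answer. Both
fits are rigid-motion equivariant.

Classification rules: a vesicle is *ellipsoidal* when its 2-D
major/minor ratio strictly exceeds 1.14 — roughly twice the modal
departure (1.07) of near-spherical vesicles from a perfect circle; a
ratio exactly at the threshold counts as spherical. In 3-D, with sorted
semi-axes `a <= b <= c` and ratios `r1 = b/a`, `r2 = c/b` against the
same tolerance: sphere (`r1, r2` both small), discus/oblate (`r1` large
only), olive/prolate (`r2` large only), otherwise "other". The rule is
scale-invariant. Per-vesicle "diameter" is the mean of the 2-D major and
minor full axes.

The missing wedge blurs density along the beam axis but does not bias
fitted shapes, provided points are picked where the membrane is actually
visible — its normal within the tilt-sampled belt; the invisible z-caps
of a vesicle are never pickable. The test suite verifies this as a
property: belt-restricted picks on a wedge-filtered noiseless shell
refit its axes within 5 %.

# Particle morphometry

Manual caliper measurements of membrane-attached particles are replaced
by a reproducible operator. `measure_particle()` resamples the projection
into a frame attached to the membrane (u along the outward normal from
the base point, t tangential), estimates the background from a far
annulus (u in 22–30 nm by default), thresholds at
`background + level * (peak - background)` with `level = 0.5` (FWHM
convention for a Gaussian blob), and keeps the 4-connected component
containing the particle's peak. Rows within 2 nm of the membrane edge are
excluded from the component so the laterally continuous membrane density
cannot bridge neighbouring particles. The particle axis comes from
intensity-weighted second moments, seeded by the membrane normal: only a
clearly elongated component (moment ratio > 2) overrides the normal with
its own principal direction, so squat or near-square particles are
measured along the normal, as a human would. Length is the extent from
the membrane outer edge to the farthest component pixel along the axis;
width is the perpendicular extent at the same level. Note length is *not*
forced to exceed width — a squat receptor can be wider than it is long.

`classify_by_size()` gates measurements against reference receptor
centroids (elliptical gate, k = 2 SDs by default; reference SDs from
crystal-structure projections understate biological variability, so
absent values default to 1.5 nm). The receptor and non-receptor
populations overlap on real membranes; the labels are advisory and an
optional manual-label column rides alongside, preserving the separation
of measurement from classification. `align_and_average()` translates each
particle chip so the membrane attachment sits at the origin, rotates its
long axis vertical, and averages pixelwise with out-of-image samples
dropped and a per-pixel count map emitted.

# Reference dimensions from atomic models

`model_to_density()` splats atoms onto a grid (trilinear, unit mass per
atom) and low-passes to the target resolution, 2.7 nm by default, so each
atom becomes a Gaussian of resolution-set width and the integral equals
the atom count exactly. `project_density()` projects about the *longest*
intensity-weighted principal axis: all viewing directions are
perpendicular to that axis, so every projection sees the full molecular
length while the apparent width varies with angle — which is why length
SDs across projections are tiny and width SDs are not. The default 9
degree spacing over 180 degrees yields 20 projections; each voxel's mass
is pushed (bilinear scatter) into the projection plane, making every
projection's sum equal the volume total to machine precision.

`measure_projection()` thresholds at a fraction of the projection maximum
(default 0.1, capturing the low-density halo; 0.5 gives FWHM-style
dimensions) and measures extents along and across the principal axis of
the above-level region. Because the level behind any quoted dimension
is a reporting convention, `reference_dimensions()` results should be
read alongside a level sweep — the analysis driver and acceptance tests
do exactly that. Atom selections (chains, residue ranges) restrict the
model to the extracellular domain; membrane-buried residues are invisible
in projections of membrane-attached particles and should be excluded.

No receptor coordinate files ship with the package; `model_atoms()` reads
any local PDB via bio3d, and the validation uses synthetic ellipsoidal
pseudo-models (random pseudo-atoms filling an ellipsoid of known
extents — explicitly labelled synthetic, not molecules).

# Landmark registration

`estimate_transform()` fits the planar map between matched landmark lists
(carbon-film holes picked in both the fluorescence and low-magnification
EM images) by least squares: the full 6-parameter affine by default —
"linear regression" between camera frames should absorb anisotropic
magnification — with a 4-parameter similarity alternative, solved as a
linear problem in `(a, b, tx, ty)`. Degenerate configurations (collinear
or coincident sources) are rejected by rank checks with errors naming the
condition. No automatic outlier rejection is applied, matching the manual
picking workflow; instead per-landmark residuals are attached to the fit
for curation. `pixel_to_stage()` chains a second least-squares
calibration from image pixels to stage micrometres. Exactness on
noiseless landmark sets (1e-9) and residual invariance under joint rigid
motions are enforced as tests.

# The phantom generators

Every operator above is validated against `synthetic.R` phantoms whose
ground truth is known by construction:

* `make_synapse_phantom()` renders the junction as density varying only
  along the membrane normal: two bilayers (Gaussian leaflet pairs
  3.5 nm apart, since good tomograms resolve the leaflets) separated by
  the cleft width, an intercleft band, and the PSD term — a Gaussian
  rise (sigma 2 nm) to a crest at `d1` followed by the exponential tail,
  shifted so it reaches exactly zero at the 100 nm flat-window start.
  The default crest is the start of the exponential itself
  (`psd_peak_amp = 0`): the PSD peak in real profiles is the crest of
  the decaying density, and a separate additive Gaussian crest of
  comparable amplitude would make the decay non-exponential,
  contradicting the very model fitted to it. A non-zero crest amplitude
  remains available for sensitivity analysis. A 2 nm rise keeps the
  membrane–PSD gap visible even at the thin-PSD extreme (`d1` near
  8–9 nm), as real profiles show. Gaussian white noise is added voxelwise
  (SNR here means tail amplitude over noise SD), and a hard binary
  missing-wedge mask (±60 degrees about the tilt axis, DC preserved) is
  optional and off by default.
* `make_vesicle_field()` places non-overlapping hard shells, a
  configurable fraction of them oblate or prolate (axis ratio 1.2–1.6),
  by dart-throwing with bounded retries.
* `make_landmark_pairs()` and `make_ellipsoid_points()` generate exact
  geometric truth plus isotropic noise.
* `make_particle_field()` puts rectangular particles of known size on a
  flat membrane ridge.

All generators are seed-deterministic; the seed is part of the spec.

What the phantoms deliberately omit: contrast transfer function and
phase-plate image formation, per-tilt alignment errors, membrane
deformability and thickness variation, crowding by cytoplasmic
macromolecules, and any empirical SNR estimate for real tomograms (none
is published for this preparation, so noise levels are swept rather than
matched). Passing the recovery tests therefore establishes correctness of
the operators under the stated geometric and noise model — it does not
by itself certify accuracy on real micrographs, where contrast mechanisms
and clutter differ.

# Problem sizes and determinism

The shipped tests and the acceptance script run, per invocation: a
3×3 grid of (d1, lambda) junction phantoms at 20 seeds each
(360-voxel profiles), 50 clustering populations of 110 synapses, 100
registration and 100 ellipsoid noise draws, one 50-vesicle field of
200×200×100 voxels against the full 46-template bank, exact KS
enumeration at n = m <= 8, and 20 projections of ~2000-atom
pseudo-models. These sizes were chosen so a single-core run of the whole
battery completes in a few minutes while keeping every Monte-Carlo
estimate stable to well within its acceptance margin. All randomness
flows through explicit seeds; the acceptance script derives its seeds
from one `--seed` argument.

# Known limitations

* The profile operators assume the trace lies on the postsynaptic
  membrane to within a few nanometres; a badly placed trace shifts all
  metrics (the membrane re-centring absorbs small offsets only).
* When `d1` approaches the membrane half-width (thin PSDs below ~8 nm),
  the PSD rise overlaps the membrane envelope and both the membrane
  centre and the crest estimates degrade by ~1–2 nm; this is visible in
  the phantom sweeps as the bias at the `d1 = 8` grid edge.
* Template matching searches positions and diameters but not
  orientations; ellipsoidal vesicles are found at reduced score or
  supplied manually.
* The equatorial-slice shape rule requires high single-slice contrast;
  with noisy conventional-defocus data the fitted ratios collapse toward
  circularity rather than inflating, i.e. the failure mode is
  conservative for ellipticity claims.
* The particle-size operator's absolute numbers depend on the level
  convention (0.5 of peak) and on the background annulus; comparisons
  across datasets must hold these fixed. The same applies to the 0.1
  level behind reference dimensions — hence the level sweep.
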