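---
title: "Methods: simulating fiducial-based augmented-reality needle guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating fiducial-based augmented-reality needle guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(endoguide)
```

## The problem being modelled

Percutaneous ablation places a needle tip at the geometric centre of a
tumour under image guidance.  An augmented-reality guidance platform does
this without intraprocedural imaging: radiopaque fiducial squares on the
patient's skin are segmented from a planning CT, a tablet camera tracks the
same markers (and a marker cluster on the needle handle) during the
intervention, a rigid CT-to-tracker registration transfers the CT-derived
target into the live view, and the operator advances the needle until the
displayed tip-to-target distance reaches zero.  The clinically motivated
accuracy requirement is a final tip-to-centre distance below 5 mm: typical
ablated tumours are 1-3 cm across, and a 5 mm miss still permits complete
necrosis in one session.

`endoguide` rebuilds that whole chain in silico so each error source —
voxel discretization, camera noise, marker localisation noise, respiratory
motion — can be switched on separately and the end-to-end accuracy measured
against ground truth, which the physical experiments could only estimate
from follow-up CT.

## The simulated world

Three scenarios mirror the three physical accuracy studies:

* **Trunk phantom** (`build_anthropomorphic_scene()`): a rigid
  500 × 340 × 270 mm superellipsoid torso with five cylindrical bars inside
  and thirty 35 × 35 mm radiopaque squares on the upper surface.
* **Porcine model** (`build_porcine_scene()`): three implanted 2 × 1 mm
  point targets (kidney at 107.6 mm depth, liver at 123.7 and 92.5 mm,
  each depth being the exact entry-point-to-centre distance) and twelve
  skin fiducials, with respiratory motion.
* **Cadaver model** (`build_cadaver_scene()`): two spherical liver lesions
  (18 mm diameter at 50.6 mm depth, 30 mm at 91.2 mm) and twelve skin
  fiducials, gated breathing.

The body envelope is a superellipsoid, not an anatomical mesh: the
fiducial-on-skin and target-at-depth semantics only need a smooth closed
surface.  Fiducials sit on a jittered grid over the upper surface with
their normals following the surface; the jitter re-draws until stickers
keep ~50 mm clearance, because two 35 mm squares closer than that merge
into one 26-connected component after voxelization.

### Bar placement and the inconsistent reference distances

The phantom's ten reference centre-to-centre distances
(`reference_bar_distances()`) violate the triangle inequality
(156.0 > 48.4 + 104.5), so no Euclidean configuration reproduces them
exactly.  The builder embeds them by classical multidimensional scaling
followed by quasi-Newton refinement of the raw stress and records the
residuals (`scene$embedding`, RMS ≈ 1 mm).  A second inconsistency is
geometric: two centres 13.5 mm apart cannot belong to separate rigid bars
of 20-30 mm diameter — any two points on the bar axes being 13.5 mm apart
forces the shafts (radius sum ≥ 20 mm) to intersect.  Separate bars are a
harder requirement than full-size bars (segmentation must find five
components, and merged bars would corrupt every centroid), so crowded bars
are slimmed until they clear their nearest neighbour by 3 mm.  The centre
geometry — the quantity the accuracy study actually measures — is preserved.

### Lattice-aligned target centres

Bar centres and the porcine/cadaver target centres are snapped to the
integer-millimetre lattice, and the skin entry point is then solved on the
envelope surface so the stated depths remain exact.  The reason is
aliasing, not convenience: a 2 × 1 mm implanted marker spans 1-3 voxels at
the default 1 mm spacing, and the unweighted centroid of so few voxels
inherits an arbitrary sub-voxel placement error of up to ~0.5 mm that no
downstream stage can undo.  Snapping makes the voxelized solid symmetric
about its centre, so the segmented centroid is exact and the simulation
measures guidance error rather than rasterisation phase.  This is a stated
property of the synthetic world, fixed at design time.

## CT emulation and processing

`voxelize()` rasterises air (−1000), soft tissue (40), targets (300) and
fiducials (3000, HU-like) by a voxel-centre-inside-solid test at 1 mm
isotropic default spacing (the physical scans used ~0.5-0.9 mm in-plane
with 2 mm reconstruction; 1 mm isotropic is the desk-scale compromise).
Overlaps resolve with precedence fiducial > target > tissue > air.
Volumes read/write as uncompressed NIfTI-1 with an identity direction
matrix; the reader/writer is minimal and self-contained because no R NIfTI
package is available in the target environment.

`segment()` thresholds an intensity band and labels 26-connected components
(descending size, ties by smallest voxel index; components under 4 voxels
discarded by default — the target band uses `min_size = 1` so few-voxel
implanted markers survive).  26-connectivity is deliberate: tilted square
fiducials can voxelize corner-connected.  `extract_marker_frame()` runs
principal component analysis on each marker's voxel cloud; the
smallest-variance axis is the slab normal, its sign fixed outward, the
first axis sign fixed against world +x and the frame made right-handed so
frames are reproducible across runs.  Whole-cloud PCA (rather than
corner-based) is the literal reading of the physical system's marker
processing.

## Camera tracking

A pinhole camera (f = 1500 px, 4000 × 3000 image, principal point at the
centre — a stand-in for a 12-megapixel tablet camera on a tripod ~400 mm
above the entry point) observes marker positions with additive Gaussian
pixel noise.  Detection is simulated rather than rendered: the physical
system's corner detector lives in a commercial AR toolkit, and a pixel
noise parameter isolates the pose mathematics while keeping the accuracy
chain intact.

`estimate_pose()` minimises reprojection error over the rigid pose by
Levenberg-Marquardt (analytic Jacobian, C++; a pure-R numerical-Jacobian
twin serves as the test oracle).  Initialisation projects the layout onto
its best-fit plane and decomposes the plane-to-image homography; both
solutions of the planar two-fold ambiguity are refined and the winner is
the pose whose marker face points at the camera, ties broken by lower
reprojection RMS.  Inside the tracking loop the previous step's estimate
warm-starts the next one.  Stopping: relative cost change below 1e-10 or
100 iterations.

A note on accuracy: for the default handle cluster (40 mm square plus one
marker 20 mm proud) at 400 mm and 0.5 px noise, the median tip-position
error is ~1.7 mm.  That is the information limit of the geometry (the
lever arm from handle to tip multiplies the ~3 mrad rotational
uncertainty), confirmed by the independent pure-R maximum-likelihood
oracle, not an implementation artefact.

## Registration

`register_rigid()` aligns the CT fiducial centroids to the tracked marker
positions in closed form (SVD of the cross-covariance with determinant
correction), so no iteration or initialisation is involved and reflections
are impossible by construction.  FRE is reported as the RMS residual —
stated explicitly because mean-residual conventions exist.  Degeneracy is
declared when the second singular value of the centred point matrix falls
below 1e-6 of the largest; that is a true collinearity test — planar
marker sets remain registrable, which matters because skin markers are
nearly coplanar.  Correspondence is by label; `match_fiducials()` offers
exhaustive configuration matching for up to 8 unlabelled markers, selected
by minimal FRE with lexicographic tie-breaking.

## Respiratory motion

Displacement follows a raised cosine, `d(t) = A (1 − cos 2πt)/2`, zero at
phase 0 (maximum expiration, where the planning CT is acquired).  Internal
targets move along the cranio-caudal amplitude vector (default 12 mm, a
literature-typical abdominal value); skin fiducials move by
`skin_coupling × |A|` (default 0.3) along `skin_direction`.

The skin direction default is **anteroposterior**, not parallel to the
target motion, and this choice is load-bearing.  If all skin markers
translated parallel to the targets, the per-step rigid registration would
absorb that common translation exactly and compensate a fraction `c` of
the target displacement, capping the mean free-breathing error at
`(1 − c) · A/2 = 4.2 mm` — below the 5 mm threshold, contradicting the
observed free-breathing failure of the physical system.  Physiologically
the abdominal wall rises while liver and kidney slide cranio-caudally, so
the registration chases a shift orthogonal to the true target motion; the
mean free-breathing error is then `≈ A/2 · sqrt(1 + c²) ≈ 6.3 mm`, above
the threshold, while gating (phase fixed at 0) removes motion entirely.
Setting `skin_direction` parallel to the amplitude reproduces the
parallel-coupling variant for sensitivity analyses.

Gated sampling returns the reference phase exactly; free sampling draws a
uniform phase per tracking step.  Phases come from a dedicated RNG
substream so a zero-amplitude free run is bit-identical to its gated twin.

## The guidance loop

`simulate_insertion()` is the real-time loop: sample a phase; observe
patient and handle markers at their true (motion-displaced) world
positions; estimate both poses; perturb the tracked marker positions with
3-D localisation noise (default σ = 0.5 mm) and register the CT centroids
to them; display the tip in CT coordinates and the tip-to-target distance;
advance the true handle by `min(5 mm, displayed)` along the displayed
direction.  Registration refreshes every step (the continuous reading of
"real-time"); targets are never re-imaged intra-procedure.  The loop stops
when the displayed distance reaches 0.5 mm — the physical protocol stops at
a displayed zero, unattainable with finite steps, and 0.5 mm is below every
reported accuracy.  The operator model is idealised (straight steps, rigid
needle); needle bending is explicitly out of scope.  A non-converged pose
estimate skips the step; more than 20 consecutive skips aborts.

The default noise pair (0.5 mm fiducial localisation, 0.5 px pixel noise)
was fixed a priori as a plausible tracking-accuracy regime; both values are
configuration-exposed and swept in the monotonicity tests.

## What the synthetic world does and does not establish

The generator reproduces the *counts, sizes, depths and printed distances*
of the physical experiments and a physically structured motion model, but
not CT physics (no noise, beam hardening, or contrast), not anatomy, not
operator tremor, and not needle flexion.  A green simulation therefore
establishes that the mathematical chain — segmentation, PCA localisation,
monocular pose, rigid registration, distance-driven guidance — meets the
5 mm budget under stated noise, and that free breathing breaks it; it does
not certify the physical device.  The porcine free-breathing mean printed
by the physical study (8.0 mm) entangles the animal's true motion amplitude
with system error; only the above/below-threshold dichotomy is
reproducible, as the per-target amplitudes were never measured.

## Numerical choices and limitations

* Closed-form registration and closed-form homography initialisation make
  the noiseless chain deterministic; every stochastic stage takes an
  isolated seed, and scene builders restore the caller's RNG state.
* SD convention: population (divide by n), recorded in every report; the
  upstream study never states its convention.  For one trial the SD is 0.
* "Virtual distance" is computed as the 3-D distance between
  pipeline-mapped centres, not a 2-D on-screen distance; the millimetre
  framing of the accuracy study implies the 3-D reading.
* The camera-to-scene distance sweep uses 300/400/500 mm: the protocol text
  prints 30/40/50 mm, its own results table prints 300/400/500 mm, and only
  the latter is physically plausible for a tablet on a tripod.
* Noiseless end-to-end error does not reach zero: each near-flat skin
  fiducial carries a uniform ±spacing/2 centroid quantization error along
  its normal (independent of slab thickness), so with twelve fiducials at
  1 mm spacing the registration chain floors at roughly 0.1-0.3 mm.  This
  is the one acceptance bound (0.1 mm) the stated world cannot meet; the
  test asserts the stated bound and is expected to stay red rather than be
  loosened.
* The exhaustive correspondence matcher is factorial in the marker count
  and is capped at 8 markers by design.
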