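---
title: "Designing patient-specific brachytherapy applicators with curved needle channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing patient-specific brachytherapy applicators with curved needle channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(applicatr)
```

## The design problem

Gynaecological brachytherapy delivers radiation through source channels in
an applicator placed in the vaginal cavity, supplemented by interstitial
needles advanced into tumour-bearing tissue. Commercial applicators have
fixed shapes and fixed needle geometry; for large or laterally extended
tumours they align poorly with the anatomy. A patient-specific alternative
starts from MRI: the gel-distended vaginal vault is segmented, the
clinician marks desired needle trajectories during segmentation, and a
3D-printable applicator is designed whose outer surface matches the vault
topography and whose interior carries curved channels guiding 6F needles
to the marked targets.

`applicatr` implements that design chain as one tested pipeline:

1. **Contour import** (`read_rtstruct()`): DICOM RT-structure contours or
   an equivalent plain-text dialect, with channel waypoints stored as open
   polyline structures (`extract_waypoints()`).
2. **Surface reconstruction** (`voxelize()`, `extract_surface()`,
   `smooth_surface()`): stacked planar contours to a watertight triangle
   mesh of the vault.
3. **Channel planning** (`fit_spline()`, `curvature_profile()`,
   `validate_channels()`, `bundle_check()`): waypoints to smooth splines,
   checked against the radius-of-curvature constraints that keep needles
   from jamming or buckling.
4. **Solid construction** (`make_base()`, `build_applicator()`,
   `make_loop_channel()`, `write_stl()`): the vault solid is merged with a
   slim cylindrical base, swept channels (with tapered interstitial tips
   and an optional fillable reconstruction loop) are carved out, and the
   result is exported as STL.
5. **Insertion-force analysis** (`zero_phase_ma()`,
   `summarize_insertions()`, `two_way_anova()`, `tukey_kramer()`): the
   calibration experiment behind the curvature constraint, reproduced on
   synthetic data.

## Curvature constraints

A needle forced around a bend of radius $r$ presses against the channel
wall; friction grows steeply as $r$ shrinks, and below a critical radius
the axial load buckles the needle. The pipeline therefore treats the
minimum radius of curvature along a channel as a hard design quantity.

Curvature is estimated discretely: channels are resampled to uniform
arc-length steps (0.5 mm by default) and the radius at each interior
sample is the circumradius of the triangle through the sample and its two
neighbours, $r = abc/(4A)$. This estimator is independent of the spline
basis and exact on circles, which makes it directly testable: sampled
circles of any radius reproduce $r$ to better than $10^{-3}$ relative,
and a helix $(a\cos t, a\sin t, ct)$ reproduces the closed form
$(a^2+c^2)/a$.

`validate_channels()` applies two limits, both inclusive on the pass
side:

* **hard limit, 35 mm** — below this, insertion forces reach the
  buckling level of a 6F needle and the channel is rejected;
* **comfort limit, 50 mm** — between 35 and 50 mm the channel passes
  with an *advisory* flag, because friction in this band is high enough
  to degrade the force feedback a clinician relies on during placement.

The limits apply pointwise at the worst sample of a (possibly
multi-curved) channel — the conservative reading, since one tight bend
is enough to jam a needle.

### Spline end conditions

Channels are interpolated with chord-length parameterised C² cubic
splines. Natural end conditions (zero end curvature) are the common
default, but they are a poor choice here: a channel that is genuinely an
arc of a circle would be reconstructed with zero curvature at its ends,
deviating from a 60 mm arc through four waypoints by more than 0.8 mm.
`fit_spline()` instead clamps the end tangents to the tangent of the
circumcircle through the first (last) three waypoints. For waypoints on a
circle this end estimate is exact, and the reconstruction error on the
same four-point arc drops to 0.03 mm; for generic curves it is a
second-order-accurate tangent estimate, and for collinear ends it
degrades gracefully to the chord direction.

## Voxel solids rather than exact CSG

All boolean solid work — merging the vault with the base, carving swept
channels — happens on a binary voxel grid (0.2 mm pitch by default, 0.1 mm
for fine measurements), not by exact surface booleans. Boolean operations
on triangle meshes are notoriously fragile exactly where this pipeline
operates (tangential contacts, thin walls, meshes that came out of a
voxelisation themselves); voxel booleans are unconditionally robust,
deterministic for a given pitch, and their error is a single transparent
quantity, the pitch.

The closed surface of an occupancy grid is extracted as the boundary
between occupied and empty voxels — the 0.5-level isosurface of the
occupancy field under nearest-neighbour interpolation. This "blocky"
isosurface was chosen deliberately over triangle-table marching cubes:
on binary data the classic marching-cubes case tables can leave holes at
ambiguous face configurations, and watertightness is a hard invariant
here (every edge of every extracted mesh must be shared by exactly two
faces, which the test suite asserts throughout). Two voxel solids
touching only along an edge would violate that; such checkerboard
configurations are resolved by filling one voxel before extraction. The
enclosed volume of the blocky surface is exactly the voxel count times
the voxel volume, which makes the volume-accuracy tests sharp.

The staircase geometry is then smoothed with shrink-resistant Taubin
smoothing: alternating Laplacian steps $\lambda = 0.5$ towards the
neighbour average and $\mu = -0.53$ away from it. The single exposed
knob is a smoothing factor in $[0, 1]$ mapped to $\mathrm{round}(20
\cdot \text{factor})$ iterations; factor 0 is the identity. On a
voxelised sphere at the default factor 0.5 the surface area drops to
within ~1% of the true sphere while the volume changes by less than
0.5%; topology (components, Euler characteristic) is never touched.

Carving sweeps a sphere of the local channel diameter along the
resampled centreline: 2.6 mm bore everywhere, tapering linearly to
2.2 mm over the final 10 mm before the surface exit point of
interstitial channels (the taper improves the angular accuracy of the
protruding needle; its length is not a clinically fixed number and is
exposed as `taper_length`). The voxel pitch must be at most a quarter of
the tip diameter; at 0.1 mm pitch the removed volume of a straight
channel matches the analytic tube within 2% and carved aperture
diameters are reproduced within 0.05 mm. At coarser pitches the
quantisation error of a 1.3 mm-radius tube can reach several percent
depending on how the centreline happens to sit in the grid — accuracy
statements in the tests are therefore made at 0.1 mm, with a separate
convergence assertion from 0.2 to 0.1 mm.

Other numerical choices worth stating:

* **Between-slice occupancy** when rasterising contours uses the nearest
  slice's polygon (nearest-slice extrusion) with half-open axial
  coverage anchored at the first slice, so a prism of height $h$
  rasterises to exactly $h/\Delta$ layers. Occupancy is decided by
  even-odd point-in-polygon tests at voxel centres.
* **Mesh rasterisation** uses parity counting along grid columns with a
  top-left fill rule and a sub-voxel sample offset, so axis-aligned
  faces (ubiquitous after voxel meshing) never sit exactly on test
  points.
* **Degenerate inputs**: single-slice structures, empty meshes,
  non-watertight smoothing inputs, channels that miss the base, and
  carving pitches coarser than a quarter tip diameter all raise errors
  rather than producing silently wrong solids. Disconnected occupancy
  keeps the largest component with a warning (gel pockets can fragment
  a segmentation).

## The uniform base and the bundle constraint

The printable solid is the union of the vault topography and a slim
uniform cylinder (12 mm diameter, 60 mm long by default) at the
introitus, where a slim profile minimises tissue stress. Because every
channel must pass through this 12 mm disc, bundling interacts directly
with the curvature constraint: channels that fan out to lateral targets
must do all their bending distal to the base. `bundle_check()` verifies
both fits — each channel cross-section (bore + 0.4 mm clearance) inside
the base disc, and pairwise centreline separation of at least bore +
clearance — before any carving happens. The base's position and
orientation relative to the topography are clinician inputs, not
inferred.

One applicator variant interlinks two channels inside the solid into a
single loop (`make_loop_channel()`) that can be filled with water or
aqueous gel: the filled loop is MRI-visible and anchors applicator
reconstruction during dose planning. The joined plan is validated as a
whole, so a bridge tighter than 35 mm is reported as a violation rather
than silently accepted, and a correctly carved loop leaves exactly two
surface openings.

## The calibration template and force analysis

The 35/50 mm limits come from an insertion-force experiment:
a printed template with 2.6 mm channels at arc radii 20–75 mm in 5 mm
steps, each arc bridging a 5 mm wall, embedded in 10 wt% gelatin.
Needles with blunt and sharp tips are driven in at 5 mm/s while axial
force is recorded; radii are randomised per phantom, ten phantoms, five
repetitions. `make_calibration_template()` regenerates that template as
a solid plus the exact arc plans, and `randomize_design()` reproduces
the experiment layout as a pure function of its seed.

Force traces are processed exactly as in the original analysis chain:

* **zero-phase moving average**, kernel 20 samples, applied forward and
  backward with reflective edge padding. Reflective padding keeps
  constants exact; the forward-backward pass has provably zero lag
  (cross-correlation with the input peaks at lag 0) and its sinusoid
  gain is the squared Dirichlet gain of a single pass, which the tests
  check against the closed form.
* **per-insertion summaries**: force maximum, median, quartiles, peak
  depth. A needle is *buckled* when the filtered force strictly exceeds
  14 N — the axial load at which 6F needles collapse — and the insertion
  is treated as aborted at the first crossing. The threshold is applied
  to the filtered signal (the raw signal's sample noise would otherwise
  set the decision) and both the threshold and this choice are exposed
  as configuration.
* **two-way ANOVA** of peak force against radius and tip with
  interaction: classical sums of squares when the design is balanced,
  Type II when buckling exclusions unbalance it (the conventional choice
  when main effects are the interest; the interaction is still
  reported). Buckled insertions are excluded by default since their
  aborted traces carry no valid peak.
* **Tukey-Kramer** all-pairs comparisons on the factor level means,
  $q = |m_i - m_j| / \sqrt{(MS_E/2)(1/n_i + 1/n_j)}$, with critical
  values from the studentized range distribution computed numerically
  (`qtukey`), valid for unequal group sizes and identical to the
  classical HSD when sizes are equal — the test suite asserts that
  reduction to nine decimal places against an independent HSD
  implementation.

## What the synthetic generator does and does not emulate

Real patient contours and measured force traces are not distributable,
so `synth_topography()`, `synth_waypoints()`, `synth_force_trace()` and
`synth_force_dataset()` generate every input the pipeline needs. They
are first-class, tested code, and their defaults *are* the study
conditions of the calibration experiment.

The vault generator produces a half-ellipsoid stack (semi-axes 25 and
20 mm, 40 mm deep, 2 mm slices) perturbed by up to three angular
harmonics capped below 30% so every contour stays simple and
star-shaped. It emulates the scale and smooth asymmetry of a
gel-distended vault; it does not emulate segmentation jitter,
inter-slice misregistration, or topology changes (folds, pockets), so
passing tests say nothing about robustness to those.

The force generator encodes a friction-dominated model: the in-channel
force rises smoothly to a peak

$$F_\text{peak}(r) = a + b/r, \qquad a = 2\ \text{N},\ b = 420\ \text{N·mm}$$

at the 50 mm applicator exit depth, then drops by a fixed fraction and
grows linearly at 0.05 N/mm as the needle cuts phantom tissue; Gaussian
per-sample noise (sd 0.3 N), phantom-level intercepts (sd 0.2 N) and
optional insertion-level intercepts complete the stochastic structure.
The $1/r$ law is the simplest strictly decreasing relation consistent
with friction dominating the insertion force; no capstan exponential is
claimed. The calibration $a + b/35 = 14$ N places the 35 mm channel
exactly at the buckling level — faithful to the observation that this
radius sits at the testing limit, but it means the generator makes
r = 35 mm a knife-edge case: with noise, roughly half of its insertions
cross 14 N. End-to-end pattern tests therefore assert buckling for all
radii *below* 35 mm and none *above*, treating 35 mm as the boundary it
is. The tip type adds no mean effect by default, encoding the null
finding for blunt vs sharp tips; a nonzero `tip_effect` is available for
power studies.

One consequence of the $1/r$ mean structure deserves honesty: under it,
the pairwise peak-force differences among 55–75 mm channels (up to
2.0 N) are *larger* than the 45-vs-50 mm difference (0.9 N), so no noise
level can make every pair below 50 mm significant while all pairs above
50 mm are not — a threshold on mean differences is monotone. Real
friction grows faster than $1/r$ at tight radii. The post-hoc pattern
test therefore asserts the achievable analogue under realistic
insertion-level variability (sd 1 N): the 35 mm channel differs from
every channel in the comfortable range, while neighbouring comfortable
radii are indistinguishable.

## Problem sizes

The suite runs its geometry accuracy checks on 12–20 mm slabs at 0.1 mm
pitch, the full applicator build on a 32–40 mm-deep synthetic vault at
0.2–0.4 mm pitch, the null-calibration Monte Carlo at 1000 replicates,
and the end-to-end synthetic study at 3–5 phantoms x 2 tips x 2
repetitions across the full 20–75 mm radius ladder — sizes at which every
statistical margin asserted is stable across seeds while the whole suite
stays desk-scale.

## Known limitations

* Mesh smoothing and voxel booleans guarantee watertightness, not
  sub-voxel metric accuracy; printed-part tolerances (printer resolution,
  resin shrinkage) are out of scope.
* Automated channel path planning is out of scope: waypoints are
  clinician input, and the validator only accepts or rejects them.
* The buckling threshold is an empirical constant of 6F needles in this
  template geometry, not a mechanistic (Euler) prediction; needles of
  other stiffness shift both limits.
* `bundle_check()` measures centreline separation at the sample
  resolution (0.5 mm default), so clearances tighter than half a sample
  step need a finer `sample_step`.
* Contour rasterisation requires slice planes perpendicular to a
  coordinate axis (axial stacks); oblique reformats must be resampled
  upstream.
```{r}
sessionInfo()
```
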