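---
title: "Template-based fascicle tracking: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based fascicle tracking: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotract)
```

## The problem

Iodine staining makes skeletal muscle radio-dense in micro-CT: iodine binds
glycogen in the myofibers but not the collagenous sheaths (endomysium,
perimysium) around them, so fascicles appear as bright, roughly cylindrical
bundles separated by darker septa at voxel sizes below ~50 µm. `myotract`
reconstructs fascicle-scale architecture from such volumes in four stages:

1. **Cylinder correlation** — match an oriented cylindrical template against
   every voxel over a set of candidate axial orientations, yielding a
   correlation field (fit likelihood) and an orientation field (best-fit
   direction).
2. **Masking** — erode the muscle's segmentation label and zero the
   correlation outside it, so segmentation-boundary gradients cannot seed
   spurious tracts.
3. **Tracing** — grow streamlines ("tracts") through the correlation field
   along the orientation field, governed by seed/continuation thresholds, a
   direction-inertia coefficient, an inter-tract exclusion radius, and
   length/curvature limits.
4. **Editing and quantification** — prune implausible tracts, smooth the
   survivors, and summarise pennation angle θ, fascicle lengths, muscle
   volume/mass, and PCSA.

A tract is a proxy for a fascicle centerline; at DiceCT resolution a single
tract may follow several adjacent fascicles, which is why the quantitative
summaries (means over many tracts) are more robust than any individual
polyline.

## The correlation model

The template is a bright cylinder of radius $R$ (`outer_cylinder_radius`)
and length $L$ (`cylinder_length`) surrounded by a darker annulus out to
`mask_cylinder_radius`, voxelised along a candidate direction, shifted to
zero mean over its support and scaled to unit norm. For a volume patch $P$
around voxel $x$ the score is a normalized cross-correlation

$$ c(x, d) = \frac{\langle K_d, P \rangle}{\lVert P - \bar P \rVert}, $$

where the patch norm is taken over the template's bounding sphere — a
support common to all orientations, so the denominator is computed once.
Because the kernel is zero-mean and supported inside that sphere,
Cauchy–Schwarz bounds the score to $[-1, 1]$ and a constant image scores 0;
thresholds are therefore intensity-scale-free. Note that a perfectly
matching cylinder does *not* score 1 (the bounding sphere contains variance
outside the kernel support); on our phantoms, matched scores run ~0.3–0.5
against near-zero background, which is what the default thresholds are
calibrated to.

Orientations are axial ($v \equiv -v$), so candidates are spherical
Fibonacci points on the upper hemisphere; the count is grown until the
covering radius (verified against a fine reference set) is within
`angular_sampling` degrees, and the $+z$ pole is always a member. Each
orientation's correlation image is computed by FFT cross-correlation on a
reflect-padded grid; the per-voxel max/argmax over the orientation list is
the contract, with ties keeping the earliest list entry for reproducibility.

## Tracing rule

From each accepted seed (voxels above `min_seed_correlation`, visited in
descending correlation order), the tract is grown bidirectionally with the
update

$$ d_{new} = \mathrm{normalize}\big((1 - w)\, o(x) + w\, d_{prev}\big), $$

where $o(x)$ is the orientation field at the nearest voxel, sign-flipped
into the hemisphere of travel (axial data), and $w$ is the
`direction_coefficient`. The limits are interpretable: $w = 0$ follows the
orientation field exactly; $w = 1$ continues straight along the seed
orientation. Correlation is interpolated trilinearly at each step;
orientation is nearest-neighbour (linear interpolation of axial vectors is
ill-defined without tensor averaging). A direction terminates when the
interpolated correlation falls below `min_continuation_quality`, the step
turns by more than `max_step_angle`, the point leaves the grid or comes
within `min_distance` of another tract, or the step cap is reached. Greedy
seeding with a spatial hash at the exclusion radius makes the tract density
controllable through `min_distance` alone, and the whole procedure is
deterministic given the fields and parameters.

## Editing rules

Manual deletion of implausible tracts is replaced by three reproducible
rules: cumulative turning above `max_total_bend` (default 90°), mean
direction further than `max_off_axis` from a stated reference direction
(inactive unless a reference is supplied — real muscles rarely have a single
one), and curved length outside explicit bounds. One numerical subtlety
matters: with sub-voxel steps, the raw cumulative turning of a perfectly
good tract is dominated by per-step noise jitter (medians near 200° on our
noisy phantoms), so `run_pipeline()` evaluates the bend rule on the polyline
resampled at half the template length (`bend_scale`). Genuine hairpins
survive resampling; jitter does not. `prune_tracts()` itself defaults to the
raw points so that the rule matches a brute-force turning computation
exactly.

Smoothing is an iterated three-point (binomial-weight) centered average with
fixed endpoints, applied $(\mathrm{window}-1)/2$ times. We chose this over a
flat shrinking-window mean deliberately: each pass maps every new segment to
a convex combination of consecutive old segments, which *proves* the two
properties the editing stage relies on — curved length never increases, and
is monotone non-increasing in the window — whereas the flat variant violates
the monotonicity on unfavourable polylines.

## Architecture metrics

θ is the acute angle between a tract's mean direction and the tendon axis,
folded into [0°, 90°]; it is invariant under point-order reversal. Summary
statistics are unweighted per-tract mean ± sample SD (a length-weighted
option exists but is off by default, matching the way such tables are
reported). Muscle volume is the foreground voxel count times voxel volume;
mass uses a fixed-muscle density of 1.055 g/cm³; and

$$ \mathrm{PCSA} = \frac{V\,[\mathrm{cm^3}] \cdot \cos\bar\theta}{\bar L\,[\mathrm{cm}]} $$

uses the scalar means, exactly as the comparison tables it mirrors. No
sarcomere-length correction is applied. The orientation summary reports the
azimuth histogram about the tendon axis and the 2×2 second-moment matrix of
the transverse direction components (the "XY tensor" when the tendon is
z-aligned); its eigenstructure separates bipennate (two clusters) from
hemiradial (half-circle spread) arrangements.

## The phantom generator

Every stage is validated against synthetic phantoms with known ground
truth, generated at the DiceCT scale the package targets: 43.863 µm
isotropic voxels, bright cylindrical fascicle cores over darker sheaths
(default levels 200/90/50), additive Gaussian noise, and three layouts —
parallel, bipennate (two mirrored sets at ±pennation about a dark central
tendon plane), and hemiradial (azimuths over a half-circle). Degradation
modes emulate real failure cases: sheath dropout (insufficient
inter-fascicle contrast) and linear radius taper (variable-diameter
fascicles).

Numerical choices worth knowing:

* Voxelisation is by center-point inclusion with flat end caps (half-open at
  the far end), and fascicle anchors are snapped to the voxel lattice so the
  voxelisation phase is deterministic. A 10⁻⁹ relative epsilon keeps
  exact-boundary lattice points stably inside. With these choices the
  voxelised volume of a straight cylinder matches $\pi r^2 \ell$ to ~3% at
  radii of 2–3 voxels; note that center-point counting has a
  radius-dependent lattice error that can reach ~7% at unfavourable radii
  (e.g. 2.5 voxels), which is a property of the voxelisation, not a bug.
* The default fascicle radius (70 µm) mirrors the upper end of the typical
  fascicle-diameter range (65–140 µm). That is only ~3 voxels across at the
  default spacing — deliberately near the resolution limit. The validation
  phantom used by the test suite and the acceptance script uses a 90 µm
  radius (4.1-voxel diameter), inside the 3–6-voxel band where template
  matching is robust; the paper-scale radius is kept as a stress regime.
* Noise is plain additive Gaussian; no beam hardening, scanner PSF, or
  stain-diffusion gradients. Passing phantom tests therefore demonstrates
  correctness of the geometry/correlation/tracing chain, not robustness to
  every CT artefact. The phantom tendon is a plane (bipennate) or axis
  (hemiradial), never curved.

## Baseline parameters

The defaults were calibrated once on bipennate validation phantoms
(64³ voxels, 25° pennation, 40 fascicles of radius 90 µm, sheath 45 µm,
noise SD 20 — a contrast-to-noise ratio of 5.5 between core and sheath):

| parameter | default | units | role |
|---|---|---|---|
| `outer_cylinder_radius` | 90 | µm | template core radius (match the fascicle radius; note some tools quote this as a *diameter* — pass the diameter to mimic that usage) |
| `cylinder_length` | 450 | µm | template length; longer smooths the correlation ridge but costs tract ends |
| `angular_sampling` | 10 | deg | orientation grid step; also the orientation error bound on noiseless data |
| `mask_cylinder_radius` | 135 | µm | outer radius of the dark annulus (core + sheath) |
| erosion iterations | 1 | — | label shrink before masking |
| `min_seed_correlation` | 0.2 | — | seed threshold |
| `min_continuation_quality` | 0.12 | — | continuation threshold |
| `direction_coefficient` | 0.5 | — | step inertia; higher damps orientation-field jitter |
| `min_distance` | 150 | µm | inter-tract exclusion radius (controls density) |
| `min_length` | 1000 | µm | discard shorter tracts (fragments bias the mean length down) |
| `max_step_angle` | 45 | deg | per-step turn cap |
| `step_size` | spacing/2 | µm | sub-voxel stepping |

With these defaults the full pipeline on the validation phantom recovers
mean pennation to within ~2° of the true 25° and mean curved length to
within ~3–14% of ground truth across phantom seeds, with most of
the length error being truncation at fascicle ends (the correlation ridge
decays within about half a template length of an end). These are the
figures the acceptance script recomputes; the vignette states no number the
test suite does not itself compute.

## The sensitivity sweep

`sweep_plan()` builds the one-factor-at-a-time design over the 12 sweepable
parameters above (the four template parameters, the erosion depth, and the
seven tracing parameters): each is set to baseline × (1 ± 0.25) and
× (1 ± 0.75) — spanning reasonable to deliberately unrealistic values —
while everything else is held at baseline, giving 12 × 4 = 48 runs plus the
baseline, 49 in total. Erosion depth uses additive integer offsets (−2, −1,
+1, +2, clamped at 0 and bumped past collisions) because scaling an
iteration count is meaningless. `run_sweep()` caches correlation fields
across runs that share template parameters, records per-run failures
without aborting the sweep, and is order-independent; `flag_outliers()`
marks runs whose median length or θ leaves the baseline run's IQR, with
closed intervals (a median exactly on a quartile is inside).

## Known limitations

* NIfTI orientation matrices beyond the voxel scale are ignored: the grid
  frame is the analysis frame, and the tendon axis must be supplied (e.g.
  after aligning the tendon with z upstream). Automatic tendon detection is
  out of scope.
* The template has a single fixed radius per run; strongly
  variable-diameter fascicles are the known failure mode of template
  matching, emulated by the taper/dropout degradations but not solved.
* θ against a single axis is a proxy for pennation against a (possibly
  curved) tendon sheet; for muscles with non-planar internal tendons the
  distribution inherits that bias.
* Anisotropic voxels are rejected rather than resampled.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 64³
phantoms (tracking runs at a 10° angular step; the sweep summaries use a 20°
baseline step, on a 48³ phantom in the acceptance script)
and unit checks on 24³–48³ grids. These sizes were chosen because every
validation quantity — angular recovery, length recovery, sweep behaviour —
is already stable at them; larger volumes change runtimes, not conclusions.
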