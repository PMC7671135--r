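# myotract

Template-based muscle-fascicle tractography for contrast-enhanced micro-CT
(DiceCT) volumes, in R.

Iodine staining reveals muscle internal structure in micro-CT: the stain
binds glycogen in myofibers but not the connective-tissue sheaths around
fascicles, so fascicles appear as bright ~65–140 µm cylinders separated by
darker septa. `myotract` reconstructs fascicle architecture from such
volumes for comparative and functional morphologists who need quantitative
muscle architecture — fascicle lengths, pennation angles, volume, mass,
PCSA — without destructive dissection.

The pipeline is the classic template-matching workflow:

1. **Cylinder correlation**: a zero-mean, unit-norm cylindrical template
   (bright core of radius *R* and length *L*, dark annulus) is correlated
   against the volume over a near-uniform set of axial orientations
   (spherical Fibonacci hemisphere, step `AngularSampling`), giving a
   per-voxel correlation field and best-fit orientation field.
2. **Mask**: the muscle label is eroded (6-connected) and the correlation
   zeroed outside it.
3. **Trace**: streamlines grow bidirectionally from high-correlation seeds,
   with step update `d_new = normalize((1-w)·o(x) + w·d_prev)` (`w` =
   DirectionCoefficient), an inter-tract exclusion radius, and
   quality/curvature/length stopping rules.
4. **Edit + quantify**: tracts with >90° cumulative bend (at a macroscopic
   scale), off-axis travel, or out-of-range lengths are pruned; survivors
   are smoothed; architecture is summarised with

   PCSA = V (cm³) · cos θ̄ / L̄ (cm),

   θ being the acute angle between each tract and the tendon-aligned axis,
   folded into [0°, 90°].

A synthetic phantom generator (parallel / bipennate / hemiradial layouts
with known centerlines, sheath dropout and radius-taper degradations) makes
every stage testable without a scan, and a one-factor-at-a-time sensitivity
sweep (12 parameters × 4 values + baseline = 49 runs) maps parameter
influence.

## Worked example

Generate a bipennate phantom (25° pennation, 40 fascicles, noisy), run the
pipeline, and compare with ground truth:

```r
library(myotract)

spec <- phantom_spec(shape = c(64, 64, 64), layout = "bipennate",
                     pennation = 25, n_fascicles = 40,
                     fascicle_radius = 90, sheath_thickness = 45,
                     noise_sd = 20, seed = 7)
ph <- generate_phantom(spec)

res <- run_pipeline(ph$volume, ph$label,
                    template = template_params(90, 450, 10, 135),
                    trace = trace_params(),
                    erosion_iterations = 1)
res$summary
#> <mt_architecture>
#>   N tracts:        38
#>   Fiber length:    0.179 +/- 0.046 cm
#>   Pennation angle: 27.02 +/- 2.374 deg
#>   Volume:          0.0045 cm^3
#>   Mass:            0.0048 g (density 1.055 g/cm^3)
#>   PCSA:            0.023 cm^2
mean(ph$truth$fascicles$pennation)      # 25    (recovered: 27.02)
mean(ph$truth$fascicles$curved_length)  # 1869 um ~ 0.187 cm
```

The recovered pennation is within ~2° of the phantom's 25° (across phantom
seeds 1–8 the error stays below 2.1°), and the
mean curved length within ~4% of ground truth here (3–14% across seeds;
tract ends are truncated
where the correlation ridge decays — see the vignette). `autoplot(res$tracts)`
draws the tract model coloured by θ; `tidy(res$tracts)` returns the
per-tract table; `orientation_summary()` gives the azimuth histogram and
transverse second-moment ("XY tensor") matrix.

PCSA arithmetic from published-style summary inputs:

```r
pcsa(0.690, 23.53, 1.030)                           # 0.614 cm^2
pcsa(mass_volume_convert(0.5895), 18.71, 1.271)     # 0.416 cm^2
```

## Command line

A thin CLI over the same functions lives at `inst/cli/myotract.R`:

```sh
Rscript inst/cli/myotract.R phantom  --seed 7 --out out/
Rscript inst/cli/myotract.R pipeline --config inst/extdata/phantom_pipeline.yaml \
        --out out/ Volume=out/phantom.nii.gz Label=out/phantom_label.nii.gz
Rscript inst/cli/myotract.R quantify Volume=0.690 Theta=23.53 FascicleLength=1.030 --out out/
# prints: PCSA 0.614
```

Subcommands: `phantom`, `correlate`, `mask`, `trace`, `prune`, `quantify`,
`sweep`, `pipeline`. Config keys mirror the fiber-tracking nomenclature
(`OuterCylinderRadius`, `CylinderLength`, `AngularSampling`,
`MinimumSeedCorrelation`, `DirectionCoefficient`, `MinimumDistance`,
`MinimumLength`, ...); lengths are micrometres, angles degrees. Every run
writes a provenance JSON (parameters, seed, input hashes, version), and
identical config + seed gives byte-identical outputs.

## File formats

NIfTI-1/2 volumes and 8-bit label fields (RNifti), TIFF stacks
(16-bit integer slices), tract exports as points-CSV, per-tract JSON and
legacy-VTK polylines, ground truth as JSON/CSV, sweep tables as CSV.
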