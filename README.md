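# mycomorph

Morphometry and metabolite statistics for submerged cultivations of
filamentous microorganisms — in particular microparticle-enhanced
cultivation (MPEC), where inert microparticles such as ~10 µm talc are
added to *Streptomyces* or fungal cultures to steer their morphology
and boost secondary-metabolite production.

The package is for bioprocess and microbial-morphology researchers who
need to turn two raw data streams into quantitative, statistically
summarised results:

1. **Phase-contrast micrographs** → segmentation → per-object shape
   descriptors → morphological groups (spores, pellets, clumps/hyphae)
   with group statistics.
2. **Replicate culture time series** (metabolite amounts, glucose
   concentration) → enhancement factors with confidence bands and
   t-tests, and volumetric glucose uptake rates.

## The descriptors

For a segmented object of pixel count *n* at calibration *c* (µm/px):

- projected area *A* = *n·c²* (µm²),
- elongation *E* = (σ_L/σ_T)², the squared ratio of pixel deviations
  along and across the major principal (orthogonal regression) axis,
- solidity *S* = *A*/*A*_hull (≡ roughness *R*), the area relative to
  the convex hull of the object's pixel squares,
- maximum diameter *D*, the Feret maximum (µm),

combined into the **morphology number**

    Mo = 2·√A·S / (√π·D·E)  ∈ (0, 1]

which is 1 for a perfect circle and decreases for elongated or
irregular objects. Enhancement factors are

    EF = mean amount (microparticle run) / mean amount (control run)

and uptake rates are −dc/dt of a cubic-spline fit of the replicate-mean
glucose curve.

Because raw micrographs of such experiments are rarely published, the
package includes a seeded synthetic-data generator (scenes with
per-object ground truth; replicate time series with known effect
sizes) that makes the full pipeline testable end to end. See the
methods vignette (`vignettes/mycomorph-methods.Rmd`) for the models,
parameter choices and limitations.

## Worked example

```r
library(mycomorph)

# 1. a synthetic micrograph with known ground truth
scn <- make_scene(scene_spec(
  image_size = 512, n_pellet = 2, n_clump = 4,
  pellet_radius_um = c(45, 60), time_h = 24, talc_g_per_l = 5, seed = 7
))

# 2. segment and measure
masks   <- segment_objects(scn$image, segmentation_config())
records <- classify_objects(
  measure_objects(masks, time_h = 24, talc_g_per_l = 5))
print(records[, c("object_id", "A_um2", "E", "S", "D_um", "Mo", "class")],
      digits = 3)
#>   object_id A_um2      E     S  D_um      Mo        class
#> 1         1 11278   1.13 0.977 130.2 0.79698       pellet
#> 2         2 11163   1.60 0.986 137.6 0.53194       pellet
#> 3         3    52 142.96 0.550  27.5 0.00114 clump_hyphae
#> 4         4    42  16.97 0.627  15.7 0.01726 clump_hyphae
#> 5         5    39  26.46 0.655  17.0 0.01027 clump_hyphae
#> 6         6    23  24.18 0.708  11.4 0.01389 clump_hyphae
```

The two pellets (~1.1 × 10⁴ µm²) sit four orders of magnitude above
the clumps/hyphae in projected area but much closer in Mo — the
compact round pellet scores Mo ≈ 0.8, the strongly elongated filament
(E ≈ 143) scores Mo ≈ 0.001, and classification follows the area
decision rule (clumps ≤ 1000 µm² < pellets).

```r
# 3. metabolite enhancement from four replicate flasks per condition
ts <- make_timeseries(timeseries_spec(seed = 7))
ef <- enhancement_table(ts)
print(subset(ef, metabolite == "oxytetracycline" & time_h == 72), digits = 3)
#>         metabolite time_h talc_g_per_L   EF ci_lo ci_hi  p_value
#> 13 oxytetracycline     72          0.5 1.72  1.46  2.03 9.09e-05
#> 14 oxytetracycline     72          5.0 8.61  7.15 10.37 6.22e-05
#> 15 oxytetracycline     72         10.0 3.15  2.65  3.75 1.09e-06
#> 16 oxytetracycline     72         12.0 2.72  2.26  3.27 1.24e-05
```

The generator's true oxytetracycline enhancement at 72 h is 2, 9, 4
and 3 for talc 0.5, 5, 10 and 12 g/L; the estimates above recover
that pattern from 4 replicates with 10 % replicate noise, with bands
that cover the point estimates and p-values flagging every
enhancement as significant.

```r
# 4. glucose uptake rate of the control run (g GLU / L / h)
ut <- glucose_uptake_table(ts)
print(subset(ut, talc_g_per_L == 0), digits = 3)
#>   talc_g_per_L time_h rate_g_per_L_h
#> 1            0      0       -0.00646
#> 2            0     24        0.20665
#> 3            0     48        0.23289
#> 4            0     72        0.13998
#> 5            0     96       -0.00440
```

Uptake accelerates to a mid-run maximum (~0.23 g L⁻¹ h⁻¹ at 48 h) and
flattens as glucose approaches its final level; the small negative
values at the flat ends are replicate-noise wobble of the spline
derivative around zero.

A thin CLI over the same pipeline lives at
`inst/scripts/mycomorph.R` (subcommands `simulate`, `segment`,
`measure`, `metabolics`, `run`; configuration via a YAML file, see
`?pipeline_config`).

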