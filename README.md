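# hippocount

Cell counting, neuronal-debris detection and morphometry for three-channel
(NeuN / GFAP / IBA1) confocal z-stacks of hippocampal regions of interest,
with a synthetic-stack generator for validation, Bland–Altman
method-agreement statistics, and the small defined statistics of a
pentylenetetrazole-kindling study.

## Who this is for

Labs quantifying triple-immunostained hippocampal sections who want a
tested, scriptable replacement for interactive cell counting: per-ROI
densities of neurons, astrocytes, microglia and neuronal debris in
cells/mm², and the thickness of the stratum pyramidale — plus the
agreement analysis needed to show the automated counts are interchangeable
with manual ones.

## The algorithm

Each z layer of the counted channel is Gaussian-smoothed, binarized by
local-mean adaptive thresholding (foreground ⇔ intensity > block mean +
offset — robust to uneven background), refined by morphological
opening/closing, and decomposed into 8-connected blobs measured by area
and Feret (longest) diagonal in µm. Blobs in consecutive layers are linked
when their overlap is at least 60% of the smaller area:

> a track is a **cell** ⇔ it spans ≥ 2 consecutive layers **and**
> max Feret diagonal > 6.5 µm

Each cell is counted once per track. **Neuronal debris** are non-cell
fragments with Feret diagonal in [2.5, 6.5] µm whose surrounding 1 µm ring
is covered ≥ 50% by the astrocyte (GFAP) mask. Densities are counts over
the ROI area; pyramidal-layer thickness is measured column-wise on the
NeuN maximum-intensity projection. Method agreement follows Bland–Altman:
bias, precision (SD of differences), limits of agreement bias ± 1.96 SD,
with methods declared interchangeable when |percent bias| < 10% and the
differences show no trend against the pairwise means.

## Worked example

```r
library(hippocount)

# a calibrated synthetic ROI: 600 x 400 um at 1024 x 1024 px, 3 z layers,
# 25 neurons (8-15 um), 15 GFAP-encircled debris (2.5-6.5 um)
sc <- generate_scene(scene_spec(seed = 42))
sc$stack
#> <zstack> 1024 x 1024 px, 3 layer(s), channels: NeuN, GFAP, IBA1
#>   0.586 x 0.391 um/px, z step 5 um (600 x 400 um)

res <- run_detector(sc$stack)   # NeuN cells + debris via the GFAP mask
glance(res)
#> # A tibble: 1 × 5
#>   channel n_cells n_debris n_tracks n_blobs
#>   <chr>     <int>    <int>    <int>   <int>
#> 1 NeuN         25       15       40      65

ground_truth_density(sc$truth, scene_spec(seed = 42))
#> # A tibble: 4 × 3
#>   class         n density_mm2
#>   <chr>     <int>       <dbl>
#> 1 astrocyte    10        41.7
#> 2 debris       15        62.5
#> 3 microglia    12        50
#> 4 neuron       25       104.
```

All 25 seeded neurons and all 15 debris fragments are recovered here
(104.2 and 62.5 objects/mm² over the 0.24 mm² ROI); across ten seeds the
pooled recovery is 0.996 for cells and 0.92 for debris.

Agreement of algorithmic counts with a manual reference:

```r
d <- tibble::tibble(algo  = c(98, 110, 84, 120, 103),
                    manual = c(100, 112, 85, 118, 101))
bland_altman(d, algo, manual)
#> <bland_altman> n = 5
#>   bias -0.2 (-0.194% of grand mean), precision 2.049
#>   limits of agreement [-4.217, 3.817]
#>   trend p = 0.528; interchangeable
```

Pharmacokinetic bookkeeping from the published per-rat cannabidiol
concentrations:

```r
pk <- cbd_pk()
pk$ratio <- brain_plasma_ratio(pk$plasma_ng_ml, pk$brain_ng_g)
pk_summary(pk)
#> # A tibble: 6 × 5
#>   timepoint_h quantity         n    mean      sem
#>         <int> <chr>        <int>   <dbl>    <dbl>
#> 1           1 brain_ng_g       5 4504.   3110.
#> 2           1 plasma_ng_ml     5 1976.   1151.
#> 3           1 ratio            5    2.58    0.524
#> 4          24 brain_ng_g       4   91.4     9.99
#> 5          24 plasma_ng_ml     5   24.2     1.45
#> 6          24 ratio            4    3.73    0.375
```

(The 24 h mean brain concentration averages the four animals with an
adequately perfused brain sample; ratios are computed per animal and then
averaged.)

A thin CLI over the same functions lives in `inst/cli/hippocount.R`
(`simulate`, `count`, `thickness`, `agree`, `summarize` subcommands).

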