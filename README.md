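# neurofuzz

Fuzzy C-means segmentation of noisy brain MR images with PSO-chosen initial
centres, adaptive median denoising and Jaccard evaluation — plus a
resting-state ALFF/zALFF stage with motion QC, ROI group statistics and ROC
discrimination. A seeded phantom generator supplies ground-truthed tissue
images and 4D BOLD series, so the whole pipeline runs and is testable without
any acquired data.

## The problem and the methods

Tissue segmentation of MR slices (CSF / grey matter / white matter) is
sensitive to noise and to where the clustering starts. `neurofuzz` addresses
both: impulse noise is removed by a two-stage **adaptive median filter**
(window grows per pixel until its median is not a local extreme; only extreme
pixels are replaced), and **fuzzy C-means** then minimises

    J_m = Σ_i Σ_k u_ik^m (x_k − c_i)²,   Σ_i u_ik = 1

over memberships `u` and centres `c` (fuzzifier m = 2, cap T = 100,
tolerance ε = 1e-4), with the initial centres chosen by **particle swarm
optimisation** over candidate centre vectors scored by the same objective.
Hard labels are the per-pixel argmax; accuracy against ground truth is the
Jaccard coefficient `JS = |S1∩S2| / |S1∪S2|`.

For resting-state series, each voxel's **ALFF** is the mean amplitude of its
detrended spectrum over 0.01–0.08 Hz; **zALFF** standardises it against the
whole-brain mean and SD. Motion QC excludes subjects moving more than
3 mm / 3°, the first 15 volumes are dropped, and ROI mean zALFF feeds
Welch/pooled t tests, chi-square tables, and empirical ROC curves with
Youden-optimal cut-offs (trapezoidal AUC = Mann–Whitney pair proportion).

## Worked example

```r
library(neurofuzz)

ph  <- generateTissuePhantom(c(64, 64), c(20, 120, 220), tissueSd = 5, seed = 3)
img <- corruptImage(phantomImage(ph), "impulse", level = 0.1, seed = 3)
img <- adaptiveMedianFilter(img, sInit = 3, sMax = 7)
seg <- fcmSegment(img, C = 3, init = "pso", seed = 7)
seg
#> FuzzySegmentation: 3 clusters, 64 x 64 grid
#>   centers: 20.544, 120.039, 219.914
#>   3 iterations (converged), final J = 68383.7, init = pso
round(perClassJaccard(labelMap(seg), trueLabels(ph)), 3)
#>     1     2     3
#> 0.997 0.993 0.997
```

The centres land on the three tissue means (20/120/220); per-class Jaccard is
the overlap of each recovered tissue region with the ground truth (1 = exact) —
here above 0.99 for every tissue despite 10% impulse corruption.

```r
lab <- trueLabels(ph)
gb  <- generateBoldSeries(lab, list(oscillationSpec(2, frequency = 0.05,
                                                    amplitude = 3, noiseSd = 1)),
                          tr = 2, nVolumes = 240, seed = 1, noiseSd = 1)
qcMotion(gb$motion)$pass          #> TRUE
z <- computeZALFF(computeALFF(trimInitial(gb$series, 15)))
z
#> ZALFFMap: 64 x 64 grid, band 0.010-0.080 Hz
#>   source mean 0.1726, source SD 0.09191 (in-mask z: mean 0, SD 1)
set.seed(2); rocAnalysis(rnorm(50, 1.2), rnorm(50))
#> ROCCurve: AUC = 0.7920 (cases_high)
#>   Youden cut-off 0.0001: sensitivity 0.920, specificity 0.580
```

The ROI carrying the 0.05 Hz oscillation stands out in the zALFF map, and the
ROC summarises how well an ROI mean separates two groups.

A thin command-line wrapper over the same functions ships in
`inst/cli/neurofuzz.R` with subcommands `phantom | denoise | segment | alff |
roc | run`; `run --config config.json` executes the whole pipeline and writes
a JSON manifest plus per-artifact sidecars.

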