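---
title: "Fuzzy C-means MR segmentation and ALFF analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy C-means MR segmentation and ALFF analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuzz)
```

## What the package computes

`neurofuzz` implements two connected analysis stages for brain MR data, exercised
end to end on synthetic phantoms with known ground truth.

The **segmentation stage** removes impulse noise from an intensity image with an
adaptive median filter, clusters the pixel intensities into tissue classes
(CSF, grey matter, white matter) by fuzzy C-means (FCM) with the initial cluster
centres chosen by particle swarm optimisation (PSO), and evaluates the hard
segmentation against ground truth with the Jaccard similarity coefficient
$JS = |S_1 \cap S_2| / |S_1 \cup S_2|$.

The **resting-state stage** takes a 4D BOLD series, applies motion quality
control and initial-volume trimming, computes the per-voxel amplitude of
low-frequency fluctuation (ALFF) over 0.01–0.08 Hz, standardises it to zALFF
against the whole-brain mean and SD, and compares ROI mean zALFF between two
groups with t / chi-square tests and ROC discrimination.

## The FCM model

For intensities $x_k$ and centres $c_i$, FCM minimises the fuzzified
within-cluster sum of squares

$$J_m = \sum_{i=1}^{C}\sum_{k=1}^{N} u_{ik}^m\,(x_k - c_i)^2,
\qquad \sum_i u_{ik} = 1,$$

by alternating the stationary-point updates

$$u_{ik} = \Big[\sum_j (d_{ik}/d_{jk})^{2/(m-1)}\Big]^{-1},
\qquad
c_i = \frac{\sum_k u_{ik}^m x_k}{\sum_k u_{ik}^m},$$

with $d_{ik} = |x_k - c_i|$. Because each half-step minimises $J_m$ exactly in
its block, the objective trace is non-increasing — a property the test suite
asserts on every run. Clustering operates on intensity alone (a 1D feature):
that is the natural feature for grey/white/CSF contrast and keeps every update
closed-form; spatially regularised or kernelised variants are deliberately out
of scope.

Defaults are the conventional $m = 2$, iteration cap $T = 100$ and tolerance
$\varepsilon = 10^{-4}$. $\varepsilon$ is applied to the maximum absolute
centre displacement per sweep; monitoring $|\Delta J|$ instead is available via
`monitor = "objective"`. Two numerical edge cases are handled explicitly:
a point within `zeroDistanceEps` of a centre receives crisp membership there
(the update formula otherwise divides by zero, ties split equally), and a
cluster that loses all membership mass raises an error rather than silently
collapsing. Hard labels come from per-pixel argmax with ties broken toward the
lowest cluster index; clusters are finally sorted by ascending centre intensity
so label 1 is always the darkest (CSF-like) class (`relabel = FALSE` preserves
the initialisation order instead, which the label-permutation equivariance test
relies on).

## PSO initialisation

FCM converges to a local minimum of $J_m$, so the initial centres matter. Each
PSO particle is a candidate vector of $C$ centres whose fitness is $J_m$ at the
memberships those centres imply. Velocities follow
$v \leftarrow wv + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$ with
positions clamped to the data range. Hyperparameters default to the canonical
constriction-equivalent values $w = 0.72$, $c_1 = c_2 = 1.49$, 20 particles and
50 iterations; all are configurable through `psoControl`. The global-best
fitness is non-increasing by construction and the swarm is fully seeded, so the
initialisation is reproducible. The acceptance suite compares PSO against
random data-value initialisation over 20 seeds on a noisy 3-class phantom:
the benefit shows up mainly as far fewer FCM sweeps to tolerance (the final
objectives typically tie, since well-separated 1D intensity problems have an
easily found global optimum).

## Adaptive median filtering

The denoiser is the classical two-stage adaptive median scheme: per pixel the
window grows (3, 5, 7, …) until the window median is strictly between the
window minimum and maximum; the pixel is then replaced by that median only if
the pixel itself is a window extreme. If the window hits `sMax` while the
median is still an extreme, the median is output. Consequences the tests
exploit: impulse pixels (salt/pepper at 0 or 255) are always extremes and get
replaced; pixels interior to a constant region are never altered; output
values are always observed input values. Defaults `sInit = 3`, `sMax = 7` and
reflected borders; 3D volumes are filtered slice-wise by default (matching how
2D MR slices are displayed and processed), full cubic windows by flag.
Filtering precedes any cropping in the pipeline; a manual crop can be applied
afterwards.

## ALFF, mALFF and zALFF

Each voxel series is linearly detrended, Fourier transformed, and reduced to a
one-sided amplitude spectrum $2|X_k|/n$ — the square root of the periodogram
power up to a constant, scaled so a pure sinusoid of amplitude $A$ reads $A$ at
its bin. ALFF is the **mean** amplitude over the bins with
$f_{lo} \le k/(n \cdot TR) \le f_{hi}$, default band 0.01–0.08 Hz; a summed-power
variant is available (`method = "summed_power"`). Band limitation is realised
by spectral masking rather than a time-domain Butterworth filter, since the
amplitude is read directly from the FFT. The band must sit below the Nyquist
frequency $1/(2\,TR)$; the DC bin is always excluded, so a constant series has
ALFF 0.

Normalisations: mALFF divides by the whole-brain (in-mask) mean, giving mean 1;
zALFF is $(ALFF - \overline{ALFF})/SD$ with the **population** SD over the mask
(sample SD selectable), so the map has in-mask mean 0 and SD 1 exactly, and the
mean/SD used are stored in the object for provenance. The in-mask convention
(rather than the full grid) is used for both mean and SD. Because the DFT is
linear, zALFF is invariant to a global rescaling of the raw series. Nuisance
regression (mean signal, motion, CSF/WM signals) is available as OLS
residualisation via `residualizeSeries()` and is off by default — phantoms are
generated without such confounds.

Quality control follows two fixed rules: series whose motion trace exceeds
3 mm of translation or 3° of rotation on any axis at any volume are excluded
whole (the thresholds are strict inequalities, so exactly 3.0 passes), and the
first 15 volumes are dropped before analysis to remove pre-steady-state
magnetisation effects (200 volumes become 185).

## Group statistics and ROC

ROI means of zALFF are compared between groups with Welch (default) or pooled
t tests, and categorical tables with Pearson's chi-square; both wrap the
standard `stats` tests, with `twoSampleTSummary()` additionally computing t
from printed group summaries (mean ± SD, n) so published tables can be checked.
Inference is at ROI level with uncorrected p-values by default (Bonferroni/FDR
adjustment is a caller-side `p.adjust` away); voxel-wise mapping with cluster
correction is out of scope.

The ROC curve is empirical over all distinct observed scores; AUC is computed
by the trapezoidal rule, which equals the Mann–Whitney proportion of correctly
ordered case/control pairs with ties counted half — asserted against exhaustive
enumeration in the tests. The reported cut-off maximises the Youden index
(sensitivity + specificity − 1), ties resolved toward the lowest threshold.
With `direction = "auto"` the orientation is flipped when controls score
higher, so AUC ≥ 0.5 and the direction used is recorded.

## The phantom generator

The generator defines the study conditions for every test:

* **Tissue phantom** — concentric geometry (innermost disc/sphere = class 1,
  outermost shell = last class) on a 64×64 grid by default, matching a typical
  fMRI acquisition matrix; default class means 20/120/220 on a nominal 0–255
  scale with within-class SD 5. Concentric shapes keep class sizes known and
  every class non-empty for any grid of at least 8 pixels per axis.
* **Noise models** — salt-and-pepper impulse noise (an exact, sampled-without-
  replacement fraction of pixels forced to 0 or 255 with equal probability) and
  additive Gaussian noise. These are the canonical models the adaptive median
  filter targets; no Rician MR noise physics is modelled.
* **BOLD phantom** — TR 2 s and 240 volumes by default; voxels of a chosen ROI
  follow $baseline + A\sin(2\pi f t + \phi) + noise$, everything else
  $baseline + noise$, with a Nyquist guard on $f$. Test oscillations sit at
  0.05 Hz (inside the band) against 0.15 Hz controls (outside).
* **Motion scenarios** — a clean all-zero trace and a spike trace with one
  mid-series volume at 5 mm / 4°, enough to exercise both QC outcomes.

Everything is seeded and byte-reproducible. What the phantoms deliberately do
**not** emulate: anatomical templates, MNI space, partial-volume effects,
scanner drift beyond a linear trend, and physiological noise spectra. Passing
tests therefore demonstrate algorithmic correctness and the stated statistical
properties, not clinical performance on acquired cohorts — group-level effect
sizes on real data cannot be inferred from these phantoms.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 64×64 phantoms for
segmentation (4096 pixels, the default acquisition matrix), 16×16 grids with
240 volumes for the spectral stage, 20 seed replicates for the PSO-vs-random
comparison, and 200 replicates at $n = 50$ per group for the AUC recovery
study (whose binormal target is $\Phi(d/\sqrt{2}) \approx 0.802$ at
$d = 1.2$). These sizes give stable medians and sub-minute runtimes for each
block; all scale linearly if enlarged.

## A worked run

```{r pipeline, eval = FALSE}
config <- list(
  seed = 7, outDir = "run",
  phantom = list(shape = c(64, 64), tissueMeans = c(20, 120, 220),
                 tissueSd = 5),
  corrupt = list(model = "impulse", level = 0.1),
  denoise = list(sInit = 3, sMax = 7),
  segment = list(C = 3, init = "pso"))
manifest <- runPipeline(config)
manifest$stages$segment$perClassJaccard
```

Every written volume receives a JSON sidecar with the stage parameters, the
seed and the package version; rerunning the same configuration and seed
reproduces all numeric outputs exactly.

## Known limitations

* Intensity-only clustering cannot separate tissues with overlapping intensity
  distributions; heavy Gaussian noise (SD approaching half the class spacing)
  degrades Jaccard scores for the thin middle class first.
* The adaptive median filter may relocate a class boundary by a pixel where
  the local majority flips; boundary-adjacent Jaccard is accordingly slightly
  below 1 on filtered noisy images.
* ALFF from short series has coarse frequency resolution ($1/(n \cdot TR)$ Hz per
  bin); with 240 volumes at TR 2 s the 0.01–0.08 Hz band spans 34 bins.
* PSO is stochastic; all comparisons against random initialisation are made
  over seed ensembles, never single runs.
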