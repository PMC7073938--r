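---
title: "Colorimetric e-nose chemometrics: models, conventions and design choices"
author: "chromanose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric e-nose chemometrics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromanose)
```

## The measurement and the feature space

A colorimetric sensor array is a grid of chemoresponsive dye spots (metal
porphyrins, pH indicators, solvatochromic dyes) printed on a white
substrate. Exposed to the headspace of a meat sample, the dyes react with
the volatile organic compounds and shift colour. The array is scanned as an
8-bit RGB image before and after exposure, and the readout for spot $i$ is
the absolute change of the disc-averaged channel values,

$$\Delta R_i = |R_{a,i} - R_{b,i}|,\quad
  \Delta G_i = |G_{a,i} - G_{b,i}|,\quad
  \Delta B_i = |B_{a,i} - B_{b,i}|,$$

with $a$/$b$ the after/before scans. Concatenated channel-major over the
$N = 12$ spots this gives a $3N = 36$-dimensional colour-change profile per
sample — the array's "fingerprint" of the sample's odour.

Conventions this package fixes explicitly, because image-analysis papers
rarely do:

* **Coordinates** are 0-based `(row, col)` with the row increasing
  downward; spots are ordered row-major within the grid.
* **Disc membership**: a pixel belongs to a spot if its integer position
  lies within Euclidean distance `radiusPx` of the centre. At the default
  radius of 12 px this support has exactly `discPixelCount(12)` = 441
  pixels, a constant independent of spot and image. Protocols sometimes
  quote slightly different counts for a nominal radius because the lattice
  convention is left unstated; here the convention is pinned down and the
  radius is configurable, keeping fidelity to the averaging principle
  rather than to any particular count.
* **Feature order** is channel-major (all $\Delta R$, then $\Delta G$,
  then $\Delta B$), matching how difference-image colour tables are
  usually printed, with columns named `dye01_dR` … `dye12_dB`.

The central container is `SensorProfileSet`, a `SummarizedExperiment` with
the 36 features in rows and the samples in columns; `colData` carries the
pork mass fraction (`level` in $[0,1]$) and the derived `category`
(`pure_beef` at 0, `pure_pork` at 1, `mixture` in between — that order is
also the tie-break order used everywhere).

## The synthetic generator

No public dataset accompanies this kind of experiment, so the package
ships a generator that emulates the *statistical* structure of a dye-array
study rather than its photochemistry. The emulated design is the standard
one: six adulteration levels 0–100% in 20% steps, 14 replicates each, 84
samples.

Each of the 36 dye channels has a monotone mean response
$$\mu_j(\ell) = \sum_{r=1}^{3} \Lambda_{jr}\, g_r(\ell)
             + a_j\, g^{\mathrm{idio}}_j(\ell),$$
where the $g$'s are logistic ramps in the level $\ell$, normalized to run
from 0 at $\ell = 0$ to 1 at $\ell = 1$. The three *shared* ramps (midpoints
0.15, 0.5, 0.85; width 0.08) model the cross-sensitivity of real dyes —
every dye responds to many of the same volatiles — and make the channels
strongly collinear; the channel-specific ramp (35% of each channel's
amplitude, random midpoint) keeps the response matrix full-rank so the
eigenvalue spectrum has a realistic tail. Loadings are non-negative, so
every channel is strictly increasing in the level. Measurement noise is
additive Gaussian (`noiseSd`, default 4 intensity units), clamped to the
8-bit range; the clamp is the only deviation from exact Gaussianity and is
negligible for responses away from 0 and 255.

Defaults were chosen once so that a generated 84-sample dataset reproduces
the qualitative features reported for real arrays: roughly nine principal
components carry ~90% of the variance, adjacent levels overlap enough that
linear classification is imperfect, and the nonlinear learners outperform
the linear one. Channel amplitudes (up to `maxShift` = 35 units on a
baseline drawn from $U(60,160)$) are typical of scanned dye spots.

What the generator does **not** emulate: reaction kinetics, humidity and
temperature effects, scanner calibration drift, spot-shape irregularities,
or any real dye chemistry. Tests passing on synthetic data therefore
validate the *algorithms* and their contracts, not the chemistry; on real
scans the pipeline's accuracy will depend on properties the generator
idealizes away.

`renderArrayPair()` closes the loop for the imaging stage: it draws the
profile as uniform discs over the baseline colours so that
`differenceProfile()` must recover the programmed profile exactly up to
8-bit rounding (≤ 0.5 intensity units). The baseline is quantized to
integers before the shift is added, so a single rounding — the scanner's —
separates the programmed and recovered values.

## Preprocessing

**PCA** is fitted on the raw (un-normalized) difference profiles: the
features share units, and rescaling would distort the relative response
magnitudes of the dyes. The decomposition is the eigensystem of the sample
covariance with the $n-1$ denominator (the convention is stated because it
is rarely printed); component signs are fixed by making each loading
column's largest-magnitude entry positive. Correlation-matrix PCA is
available (`useCorrelation = TRUE`) for data with heterogeneous channel
scales, without any claim that it matches the usual practice.
`selectComponents()` returns the smallest $k$ whose cumulative eigenvalue
share reaches the threshold (default 0.90); on the default synthetic data
this lands at 7–9 components, the regime in which dye-array studies
typically operate (nine components at ≈ 91% is the textbook outcome).

**Min–max normalization** $y = (x - x_{\min})/(x_{\max} - x_{\min})$ is
fitted on training columns and stored, applied unchanged to later data —
prediction-set values may therefore fall outside $[0,1]$, deliberately
without clamping so the inverse stays exact. A degenerate column
($x_{\max} = x_{\min}$, e.g. a dead sensor channel) maps to 0 with a
warning rather than an error.

## Classification

**Fisher LDA.** The discriminant axes maximize between-class over
within-class scatter; with $k$ classes and $p$ inputs at most
$s \le \min(k-1, p)$ axes exist, so the three meat categories give two
discriminant functions whatever the PCA depth. The solve whitens by the
Cholesky factor of the within-class scatter and eigensolves the symmetrized
quotient; a singular scatter (possible with the 4-sample pure-meat strata)
gets a ridge of $10^{-6}\,\mathrm{tr}(S_w)/p$ with a warning. Prediction is
nearest class centroid in DF space by Euclidean distance, ties (to a
$10^{-9}$ relative tolerance) to the first class in the fixed order. Note a
geometric consequence of nearest-centroid reading: the mixture category
spans four levels and is elongated in feature space, so boundary-level
mixtures can legitimately fall nearer a pure-class centroid even on
noiseless data. Perfect identification is only guaranteed when every class
is compact (e.g. one profile per category), which is how the
linearly-separable test cases are constructed.

**ELM.** A single hidden layer whose input weights and biases are drawn
once from $U(-1,1)$ and never trained; with sigmoid activations
$S(x) = 1/(1+e^{-x})$ the output weights are the minimum-norm least-squares
solution $\beta = H^{+}T$ against one-hot targets ($U(-1,1)$ and the 0/1
coding are the ELM-literature defaults; the choices are not usually
printed). Inputs are min–max normalized inside the model — raw PCA scores
have magnitudes of tens, which would saturate the sigmoid and waste the
random layer. With $L$ equal to the number of distinct training samples the
hidden matrix is generically invertible and the training set is
interpolated exactly. The hidden size is tuned by the RMSE of the network
outputs against one-hot targets on a held-out set, ties to the smallest
$L$; the default grid is 5–45 by 5 for a 60-sample training set. A
hidden-layer size like the oft-reported 29 is a property of a specific
dataset and is not expected to reproduce on synthetic data.

## Regression of the adulteration level

The BP-ANN has topology $p\!-\!h\!-\!1$: tanh hidden units and a linear
output on min–max normalized inputs and targets. The output stays linear
because a tanh output could never reach the normalized 0 and 1 targets of
the pure meats. Training is plain gradient descent with momentum,
$\Delta w_t = -\eta \nabla E + \mu\, \Delta w_{t-1}$, with the standard
small-network recipe: $\eta = \mu = 0.1$, allowable training error (MSE on
the normalized scale) $2\times10^{-4}$, at most 10,000 epochs — a stated
cap of "10.000" training rounds is read as ten thousand, since ten epochs
cannot reach that error. Full-batch accumulation is the default (an online
flag exists); weights start at $U(-0.5, 0.5)$ from the seed. The hidden
size is tuned by validation RMSE on the level scale, ties to the smallest
$h$; for nine-PC inputs this search characteristically settles near a
$9\!-\!5\!-\!1$ architecture. Analytic gradients are verified against
central finite differences in the test suite.

Reported metrics are the identification rate $R = N_1/N_2 \times 100\%$,
the RMSE, and the statistic $r = 1 - \sum(\hat y_i - y_i)^2 / \sum(y_i -
\bar y)^2$. That last formula is reported in this field as "the
correlation coefficient", but algebraically it is the coefficient of
determination; it is implemented exactly as printed, under the name
`predictionR()`. All levels, RMSE values and $r$ are on the mass-fraction
scale (0–1), so an RMSE of 0.147 means ≈ 15 percentage points of
adulteration.

## Splitting and orchestration

`splitDataset()` draws, per stratum, a prediction share of
`round(predictFraction * n)` (at least 1). The default fraction is 2/7
*held out for prediction*: descriptions of this design sometimes say
two-sevenths formed the training set, but the canonical misclassification
counts (11 of 24 predicted, 14 of 60 trained) are only consistent with a
24-sample prediction and 60-sample training set, and that arithmetic wins.
Classifiers stratify by category, the regressor by level, each split
seeded from the master seed.

`runPipeline()` derives all stage seeds (generator, split, ELM, BP-ANN)
from one master seed via a fixed draw, so a rerun is byte-identical,
including `report.json`. Hidden-size tuning for both networks uses the
prediction set as the validation set — the historical practice for this
workflow, kept for fidelity; it optimistically biases the tuned models'
prediction metrics, which is worth remembering when quoting them.

## Problem sizes and numerical choices

The shipped defaults keep every stage interactive: 84 samples, 36
features, ELM grids of nine candidate sizes, BP-ANN grids of seven with a
2,000-epoch cap inside the pipeline (the full 10,000-epoch budget applies
when `bpannTrain()` is called directly; the pipeline cap was chosen because
on the synthetic data validation RMSE plateaus well before 2,000 epochs).
Seed-averaged evaluations in the tests use 20 replicate pipelines.
Degenerate inputs are handled as follows: constant feature matrices yield
uniform PCA contributions with a warning; constant normalization columns
map to 0 with a warning; a singular within-class scatter gets the ridge; a
diverging BP-ANN (non-finite loss) aborts with the failing epoch. Exact
ties in classifiers always resolve to the first class in
`pure_beef < mixture < pure_pork`.

## Known limitations

* The generator's class overlap is calibrated to qualitative statements
  only; real-data identification rates cannot be reproduced quantitatively
  without the original scans, and dataset-specific values (a 91.27%
  training rate, 29 hidden neurons) are documented as non-reproducible.
* Spot localization is layout-driven; there is no content-based spot
  detection, scanner colour calibration or white-balance correction.
* Nearest-centroid LDA is sensitive to elongated classes, as discussed
  above — an inherent property of the method, not a defect of the fit.
* The $r$ statistic of `predictionR()` can be negative for poor models; it
  is not Pearson's correlation and should not be compared against one.
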