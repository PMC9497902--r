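---
title: "Methods: hyperspectral chemometrics for pixel-wise pH prediction"
author: "hyperpH authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral chemometrics for pixel-wise pH prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperpH)
```

## The problem

Visible/near-infrared hyperspectral imaging records, for every pixel of a
sample surface, a full reflectance spectrum. For processed meats such as
sausages in modified casings, the surface spectrum carries chemical
information — heme-pigment absorption around 418–582 nm and O–H water
overtones near 780 and 980 nm — that correlates with pH, a key freshness
attribute. `hyperpH` implements the complete chemometrics workflow that
turns such hypercubes into pixel-wise pH maps, together with the response-
surface analysis used to study how five casing-modification factors (soy
lecithin, soy oil, orange extracts, lactic acid, treatment time) jointly
affect pH.

The pipeline is: reflectance calibration → segmentation → region-mean
spectra → pretreatment chains → PLSR calibration → feature-wavelength
selection → reduced model → pixel-wise prediction map. A synthetic phantom
generator stands in for instrument data, so every stage is validated by
recovery tests against known ground truth.

## Spectral core

Raw camera counts are converted to relative reflectance with the two-point
calibration
$$R = \frac{R_r - R_d}{R_w - R_d},$$
where $R_d$ is a dark reference (lens capped, 0 % reflectance) and $R_w$ a
white reference (100 %). References may be full images or per-band vectors;
vectors broadcast over pixels. Any band where $R_w - R_d \le 0$ is a hard
error — a calibration that cannot distinguish black from white is not
salvageable.

Absorbance is $A = -\log_{10} R$. The base of the logarithm is a
documented convention here: base 10 is the standard absorbance scale
(1 absorbance unit per decade of reflectance), and the round trip
$R = 10^{-A}$ is exact to machine precision. Reflectance values $\le 0$
are an error by default; an explicit `clip = TRUE` floors them at
$10^{-6}$ for workflows where sensor noise produces occasional nonpositive
calibrated values.

Band indexing is 1-based throughout: on the default 350–1100 nm grid with
5 nm steps (151 bands), band 70 sits at $350 + 69 \cdot 5 = 695$ nm.

## Segmentation and region spectra

Sausage pixels are those whose reflectance at band 70 (695 nm) strictly
exceeds 0.075; values exactly at the threshold are background. After
thresholding, only the largest 4-connected component is kept
(`EBImage::bwlabel`), since the bare threshold admits isolated background
speckle.

Each sausage is divided into five regions of equal area. No published
algorithm exists for this step, so the package makes the geometry explicit:
mask pixels are projected onto the mask's major principal axis (leading
eigenvector of the pixel-coordinate covariance) and cut into $k$ contiguous
quantile bins — the digital analogue of slicing a cylindrical sausage
crosswise. When the pixel count is not divisible by $k$, the earliest bins
take the remainder, so bin sizes differ by at most one pixel; projection
ties are broken by pixel index so the partition is deterministic. The mean
spectrum of each region, the sample code and the sausage-level reference pH
form one row of the spectra table (a `SummarizedExperiment` subclass, bands
× observations). All five regions of a sausage share that sausage's single
reference pH.

## Pretreatment chains

Five operators are provided, composable left-to-right via chain strings
such as `"Normalization + 1st Derivative"`:

* **SNV** — per-spectrum centring and scaling to unit standard deviation.
  The sample ($n-1$) standard deviation is used; SNV is idempotent and
  invariant to per-spectrum affine scatter.
* **MSC** — each spectrum is regressed on a reference spectrum by OLS,
  $x \approx a + b\,\mathrm{ref}$, and corrected to $(x-a)/b$. The
  reference is the mean spectrum of the *calibration* rows, computed after
  any preceding chain steps and frozen for prediction rows and for every
  cross-validation fold — prediction data never leak into the reference.
* **Normalization** — scaling to unit absolute area,
  $x / \sum_j |x_j|$. "Normalization" is ambiguous in the chemometrics
  literature; the equal-area-under-the-curve variant is adopted because it
  is the reading consistent with comparing spectral features on a common
  scale, and the variant is an explicit function (`normalizeArea`) so
  alternatives can be swapped in.
* **1st/2nd derivative** — Savitzky–Golay filters, window 7 bands,
  polynomial order 2 (order 3 for the second derivative), same-length
  output with the filter's polynomial edge handling. No smoothing
  algorithm is prescribed by the source workflow; SG is the field
  standard, and window/order are arguments. Derivatives are per band
  index (divide by the 5 nm step to express per nm).

The ten standard treatments (raw plus nine single/composed chains), each
applied in both the reflectance and absorbance domain, give the 20
configurations of the full-model comparison (`tableChains()`).

## PLSR and its metrics

Partial least squares regression is fitted by NIPALS on mean-centred
$X, y$: each component extracts a weight vector proportional to
$X^\top y$, scores $t = Xw$, $X$-loadings $p = X^\top t / t^\top t$ and a
response loading $q$, then deflates $X \leftarrow X - t p^\top$.
Convergence tolerance is $10^{-10}$ on the weight-vector change with at
most 500 iterations per component (for a univariate response the iteration
converges immediately; the loop guards the general case). The
latent-variable solution is collapsed to
$$b = W (P^\top W)^{-1} q, \qquad b_0 = \bar y - \bar x^\top b,$$
so prediction is the single affine map $\hat y = b_0 + X b$; tests assert
that the collapsed and latent-path predictions agree to $10^{-10}$, and
that at full rank PLSR reproduces the normal-equations OLS solution.

Model quality uses the standard formulas
$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad
\mathrm{RMSE} = \sqrt{\tfrac{1}{n} \sum_i (y_i - \hat y_i)^2},$$
with $\bar y$ always the mean of the evaluated set (so prediction-set
$R_p^2$ uses the prediction set's own mean). RMSE is reported in pH units.
A record is flagged `good_model` when calibration $R^2$ is high and
$|\mathrm{RMSEC} - \mathrm{RMSECV}|$ is small (thresholds are arguments).

Observations are split row-wise (region spectra, not sausages) into
calibration and prediction groups at the two-thirds fraction with
$\lceil 2n/3 \rceil$ calibration rows — 165 region spectra give 110 and
55. Row-wise splitting is the default because it is the only reading that
reproduces those group sizes exactly; a grouped (`by = "sample"`) split is
available when regions of one sausage must not straddle the groups.

Cross-validation defaults to leave-one-out: it is deterministic and cheap
at these sample sizes ($n \le 165$). Seeded k-fold is available. The whole
recipe — chain and fit — is re-run inside every fold. The latent-variable
count is not prescribed by the source workflow, so it is an explicit
argument everywhere, with `selectNLatent()` offering a parsimony rule: the
smallest count whose RMSECV is within 2 % of the global minimum.

## Feature wavelengths and the reduced model

Feature wavelengths are chosen from the collapsed coefficient vector $b$
("weighted regression coefficients"): its peaks and valleys carry the
model's largest local contributions. The package makes that idea
algorithmic — and each ingredient is an explicit knob because the original
procedure was visual:

1. candidates are interior bands where the first difference of $b$
   strictly changes sign (local extrema);
2. candidates are ranked by $|b|$;
3. a greedy pass keeps candidates at least `minSeparationBands` apart;
4. the list is truncated to $k$ (default 12) and sorted.

The published 12-wavelength set {365, 385, 405, 475, 525, 580, 640, 725,
875, 915, 1005, 1060} nm and its fitted reduced model
($\hat y_{pH} = 5.335 + 7.243\,\lambda_{365} - \dots - 9.730\,\lambda_{1060}$)
are shipped as presets (`presetFeatureWavelengths()`,
`presetReducedModel()`), since the coefficient profile they came from is
not numerically recoverable without the original spectra. Reducing 151
bands to 12 removes 92 % of wavelengths.

`buildReducedModel()` restricts the spectra to the selected wavelengths,
applies the chain to the reduced spectra (as a 12-band multispectral
instrument would record them), and refits. Only the raw (empty) chain
yields a collapsed `LinearSpectralModel` — per-spectrum transforms like
SNV are nonlinear in the 12 band values, so no intercept+coefficients form
exists for them; the function returns `NULL` there and keeps the PLSR
object. The preset reduced model is reflectance-domain and refuses
absorbance input.

## Prediction maps

`predictMap()` unfolds the masked pixels into a (pixels × feature
wavelengths) matrix, applies the linear model, and refolds into a 2-D
image with `NA` off the mask — tests compare this vectorised path against
a literal per-pixel double loop at $10^{-12}$. The display scale defaults
to the map's own range; a fixed scale (e.g. 4.4–6.5, spanning the pH range
the workflow targets) makes maps of different sausages comparable.
Rendering maps values linearly onto a palette and writes an RGBA PNG with
transparent background and a colour-bar strip; the encoder settings are
fixed so identical inputs give byte-identical files.

## Central composite design and response surface

The five-factor CCD is: a half-fraction $2^{5-1}$ factorial core, two
axial runs per factor at coded distance $\alpha = 2$, and six centre
replicates — 32 runs. The half-fraction's defining relation is
$X_5 = X_1 X_2 X_3 X_4$; this is not stated anywhere in the source
workflow's text but is *derived* from its printed treatment table, whose
16 factorial rows all satisfy it (a test asserts this on the shipped
verbatim table). Factor codings are affine,
uncoded $=$ centre $+$ coded $\times$ half-range, with centres taken from
the printed centre runs and half-ranges from the factorial levels. A few
printed uncoded values (the X1 and X2 axial points, and the X3 low axial
printed as 0.00 where exact coding gives $-0.02$) disagree with exact
coding at the second decimal; the generator uses exact coding and the
verbatim table is shipped separately (`publishedDesignTable()`) for
comparison.

The response surface is the full 21-term quadratic
$$Y = \beta_0 + \sum_a \beta_a X_a + \sum_a \beta_{aa} X_a^2 +
\sum_{a<b} \beta_{ab} X_a X_b,$$
fitted by OLS in uncoded units. The ANOVA uses adjusted (Type III) sums of
squares — each term's SS is the residual-SS increase when that term (or
term group) is dropped and the model refitted — matching the convention of
the commercial DOE software whose output the table layout mirrors.
Residual error is decomposed into pure error (within replicated design
points; degrees of freedom $n_c - 1$ for $n_c$ centre replicates) and lack
of fit, with $F_{LoF} = (SS_{LoF}/df_{LoF})/(SS_{PE}/df_{PE})$;
significance stars mark $p < 0.05$ only. For the 32-run design the df
column is Model 20, Error 11, Lack-of-Fit 6, Pure Error 5, Total 31.

The published fitted surface (intercept 59.0; e.g. orange extracts enter
with linear coefficient $-8.40$ and the soy-lecithin × orange-extracts
interaction with $-3.27$) ships as `presetSurface()`; noiseless responses
generated from it are recovered coefficient-for-coefficient by
`fitQuadraticSurface()` to $10^{-6}$ relative, which is the round-trip the
acceptance checks exercise.

## The phantom generator

`generatePhantomHypercube()` emulates the statistical structure the
analysis assumes, not the physics of meat:

* an elliptical sausage (about 0.84 × 0.64 of the frame) on a flat
  background at reflectance 0.03 — safely below the 0.075 threshold at
  695 nm, and validated against that invariant before generation;
* a smooth baseline (natural spline through seven knots rising from ~0.18
  at 350 nm to ~0.55 around 900 nm);
* Gaussian absorption features at 418, 544, 574, 582 nm (heme pigments)
  and 780, 980 nm (water), multiplied into the baseline as
  $(1 - d\,e^{-(\lambda-c)^2/2w^2})$;
* feature depths coupled linearly to a latent pH,
  $d = d_0 + s\,(\mathrm{pH} - 5.45)$ with negative slopes — a *fixture
  convention* proxying pigment loss at higher pH, explicitly not a
  chemical model;
* per-pixel multiplicative gain (sd 0.05) and additive offset (sd 0.005)
  to exercise MSC/SNV, plus i.i.d. spectral noise (sd 0.002);
* a constant or along-axis linear-gradient pH field, defaulting to the
  4.44–6.46 span the workflow targets.

Every generator is a pure function of its spec and seed (bit-reproducible;
all randomness flows through one seeded stream per call, and the caller's
RNG state is restored). `generateSpectraTable()` draws random smooth
spectra and assigns pH by a known linear rule — with the published reduced
model as the default truth, so a noiseless refit restricted to its 12
wavelengths recovers all 13 printed coefficients; and
`generateRSMResponses()` evaluates a known surface over a design.

Passing tests on these phantoms demonstrate that the *algorithms* are
correct — that segmentation recovers a known mask, that PLSR recovers a
known linear rule, that the ANOVA decomposes known variance. They do not
demonstrate predictive performance on real sausages: the phantoms have no
pixel-to-pixel chemistry covariance, no specular highlights, no casing
texture, and their pH–spectrum link is linear by construction. Published
performance tables from instrument data are therefore mirrored in layout
only, never in numeric values.

## Numerical choices and degenerate inputs

* NIPALS: tolerance $10^{-10}$, max 500 iterations; requesting more
  components than the centred predictor rank is an error, detected by a
  vanishing weight norm.
* Zero-variance responses, constant spectra under SNV, zero spectra under
  normalization, and MSC slopes $|b| < 10^{-12}$ are hard errors, not
  silent NaNs.
* Absorbance clipping floor: $10^{-6}$, opt-in.
* Region splitting ties on the projection axis break by pixel index;
  remainder pixels go to the earliest bins.
* Map CSV export uses $-9999$ as the no-data sentinel; PNGs use
  transparency.
* Problem sizes in the test and demo configurations — 40×60 to 48×72-pixel
  phantoms, 8–33 sausages × 5 regions, leave-one-out or 5–10-fold CV —
  were chosen as the smallest sizes at which every structural property
  (group sizes 110/55, ANOVA df partition, rank conditions) is exercised
  at full fidelity.

## Known limitations

* One sausage per scene; no multi-object parsing.
* The reduced model's collapsed linear form exists only for the raw
  chain (by mathematics, not implementation choice).
* The equal-area split assumes an elongated, roughly convex mask; a
  strongly curved sausage would make "crosswise" slices oblique.
* `selectNLatent()`'s 2 % parsimony band is a heuristic; for serious use
  inspect the full RMSECV profile it returns.
* The CCD generator fixes the half-fraction generator
  $X_5 = X_1 X_2 X_3 X_4$; other fractions would need a different
  defining relation.
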