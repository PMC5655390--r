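---
title: "Mapping urban particulate matter: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping urban particulate matter: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsurface)
```

## The problem

A network of 48 monitoring stations measured PM2.5 and PM10 across the
city of Sabzevar (Iran) over nine months; each station contributes a mean
concentration, a standard error, a min–max range and a sample count
(246 samples in total). From these sparse point summaries one wants
city-wide exposure surfaces, an honest comparison of interpolation
methods, and compliance statistics against regulatory thresholds.
`pmsurface` implements that pipeline end to end and ships the monitoring
table as `sabzevar_stations()`.

Concentration fields are strongly right-skewed, so all interpolation is
done on a Box-Cox scale, `y = (x^λ − 1)/λ` (natural log at `λ = 0`), with
fixed powers `λ = 0.6` for PM2.5 and `λ = 0.1` for PM10, and predictions
are mapped back to μg/m³ before any concentration-scale error metric.
The powers are treated as given constants of the analysis;
`boxcox_lambda()` provides a maximum-likelihood estimator for
exploration, but the reproduction path never re-estimates them.

## The interpolators

**Inverse distance weighting.** `idw_predict()` computes
`Z(s₀) = Σ wᵢ zᵢ / Σ wᵢ` with `wᵢ = 1/dᵢᵖ`. It is a convex combination of
the data: predictions can never leave the observed range, an exact hit
(`d = 0`) returns the station value, and `p → ∞` approaches
nearest-neighbour prediction. The packaged comparisons use powers 1 and 2
with a *global* neighbourhood — with 48 stations there is no
computational reason to truncate, and no search radius is part of the
study conditions.

**Radial basis function splines.** `rbf_fit()` solves the augmented
system `[Φ, 1; 1ᵀ, 0][ω; b] = [z; 0]`, `Φᵢⱼ = φ(|Sᵢ − Sⱼ|)`, for the five
classical kernels (thin plate, multiquadric, inverse multiquadric,
completely regularized spline, spline with tension). Two numerical
choices matter:

* *Coordinates are standardized isotropically* before kernel evaluation
  (common centroid shift, one scale for both axes: the RMS of the two
  axis standard deviations). Per-axis unit-variance scaling would stretch
  one axis relative to the other and silently change all distances; the
  isotropic version preserves direction ratios, and the interpolant is
  invariant to it by construction. Raw metre distances are unusable
  directly: at city scale (10³–10⁴ m) the `K₀` and `E₁` terms of the
  tension and regularized splines overflow or underflow.
* *The completely regularized spline* is implemented as
  `φ(r) = ln(u) + E₁(u) + C_E` with `u = (σr/2)²`, the standard form
  whose series `u − u²/4 + …` vanishes at the origin. The alternative
  reading `(ln(σr/2))²` diverges from known small-`r` behaviour and is
  rejected. Small-argument branches switch to the series; large arguments
  drop the underflowed `E₁`/`K₀` terms.

The shape parameter σ defaults to automatic selection
(`rbf_select_sigma()`): a fixed log-spaced grid `10^seq(-2, 3)` in
standardized units, scored by leave-one-out RMSE on the fitting scale,
discarding candidates whose system fails. This mirrors the parameter
optimization GIS implementations of these splines perform by default. It
is also a necessity, not a nicety: on the packaged network the
regularized-spline system is catastrophically ill-conditioned for
mid-grid σ (LOO predictions four orders of magnitude outside the data),
while both tails of the grid are stable; a fixed default would be a trap.
For the regularized spline the criterion typically decreases toward the
upper end of the grid, where the kernel approaches a log kernel — the
selected endpoint is effectively that limiting model. Selection happens
once per dataset (see cross-validation below).

**Kriging.** `empirical_semivariogram()` is the Matheron estimator with
12 uniform lags up to half the maximum pairwise distance (standard
practice; empty bins dropped, lag centers are mean pair distances).
`fit_variogram()` minimizes the pair-count-weighted least squares
criterion `Σ N(h)(γ̂(h) − γ(h))²` under box constraints, from several
range starts. Four families are supported, in the conventions of common
GIS packages (`gaussian`, `stable` with free exponent, `hole_effect`
using the cardinal sine, `j_bessel` using `J₀`, all with the factor-3
practical-range convention where applicable — the source GIS does not
document its parameterizations, so these forms are isolated in
`variogram_eval()` and swappable). `γ(0)` is defined as 0, so the
predictor is exact at data sites even with a nugget; the alternative
measurement-error reading (filtering the nugget) is deliberately not
implemented, and never matters for leave-one-out work where targets are
always held out.

`kriging_predict()` solves the ordinary system
`[Γ, 1; 1ᵀ, 0][λ; m] = [γ₀; 1]` or its universal extension with drift
basis `{1, x, y}` (first order — the minimal non-trivial drift; order 0
reduces exactly to ordinary kriging). Drift columns use the standardized
coordinates to keep the system well scaled. Two robustness measures are
built in:

* *Conditioning guard.* A Gaussian (or stable-with-exponent-near-2)
  variogram whose fitted range far exceeds the data extent produces a
  numerically rank-deficient system, and LU factorization returns garbage
  *without erroring*. The solver therefore rejects any factorization with
  reciprocal condition below 1e-10 and escalates a diagonal jitter
  (1e-10 … 1e-4 × max|A|, applied to the data block, with a warning) — a
  tiny implicit nugget — until the system is numerically sane.
* *Residual variogram for universal kriging.* On a drifted field the raw
  empirical variogram keeps climbing and the fit degenerates to exactly
  the pathological huge-range case above. UK specs therefore estimate
  the variogram from least-squares planar-trend residuals, the textbook
  drift/residual decomposition. Ordinary kriging keeps the raw-value
  variogram: a constant mean is OK's own modelling assumption, and its
  degradation on drifted data is a finding, not a bug.

## Cross-validation and the error table

`loocv()` holds out each station in turn, fits on the remaining 47 on the
Box-Cox scale, predicts, and back-transforms. Data-dependent choices are
made **once on the full dataset** and reused across folds — the fitted
variogram (per the usual GIS behaviour; `refit_per_fold = TRUE` opts out)
and the selected RBF σ. `cv_metrics()` reports

* MAPE `= 100/N Σ|(Iᵢ−Oᵢ)/Oᵢ|`, RMSE, MBE `= Σ(Iᵢ−Oᵢ)/N` and MAE,

on two scales. The *concentration* scale (after back-transform) is the
headline comparison scale for MAPE, matching how the published analysis
ranks methods. The *transformed* scale is reported alongside because the
published RMSE/MBE/MAE magnitudes (≈0.02–0.04 against concentrations of
30–230 μg/m³) are only consistent with some further rescaled scale that
is never described; those three columns are therefore covered by the
metric identities (`|MBE| ≤ MAE ≤ RMSE`, MAPE scale-invariance, and so
on) rather than by numeric reproduction. `compare_models()` runs the
11-method grid — regularized-spline RBF, IDW powers 1 and 2, and OK/UK
under the four variogram families — and ranks by concentration-scale
MAPE.

On the packaged network IDW power 1 attains the lowest PM2.5 MAPE of all
eleven rows, reproducing the published conclusion. For PM10 the three
best methods sit within 0.3 percentage points of one another, and with
this package's variogram forms the hole-effect ordinary kriging row edges
out IDW power 1 — the published strict ranking is not reproduced there.
Given that the source GIS's variogram parameterizations and search
neighbourhood are undocumented, margins that small are not meaningful
evidence either way; the robust conclusion is that the deterministic
methods are competitive and universal kriging is not.

## The synthetic generator

`simulate_grf()` exists so every stage can be validated against known
truth. It draws station locations uniformly over a bounding box and
values from a multivariate normal with covariance
`C(h) = sill − γ(h)` (dense Cholesky — exact at desk scale), plus an
optional planar drift and a positivity floor. The defaults are the
conditions used throughout the package's own validation: 48 stations
(the real network's size) on a 7 × 7 km box (the real network's extent),
a Gaussian variogram with nugget 0.1, partial sill 1 and range 2000 m
(mid-range spatial structure: correlation spans several stations but far
from the whole city), and a floor of 50 μg/m³ (a typical urban PM
level). Validation experiments use the log branch (`λ = 0`) of the
transform, whose inverse is defined everywhere — so a badly extrapolating
method shows up as a large error rather than as an out-of-domain abort.

What the generator emulates: irregular station geometry, nugget noise,
stationary spatial correlation of the named families, deterministic
drift. What it does not: the 9-month temporal sampling, heteroskedastic
per-station sampling effort, non-Gaussian marginals, anisotropy, and the
outlier structure of real traffic data. Tests passing on simulated fields
therefore validate the *machinery* (parameter recovery within ±30% on the
range at n = 200; UK beating OK on drifted fields; exact plane recovery;
no spurious skill on pure-nugget fields), not the field-worthiness of any
particular method for another city.

A 2-D caveat: the cardinal-sine (hole-effect) and `J₀` (J-Bessel)
correlations are borderline-valid in two dimensions, so the generator's
eigenvalue validity check (reject below −1e-8 × trace) exists as a guard
against round-off and future families rather than something these two can
trigger at realistic parameters.

## Degenerate inputs and tie-breaks

Duplicate station coordinates are rejected at load (so the IDW zero-
distance rule never faces a tie); a station mean outside its own printed
range or disagreeing with the printed ratio column is *flagged* by the
validator but kept verbatim (the packaged table contains exactly one such
row, station 48's PM10 range); `variogram_model()` accepts a zero partial
sill only so degenerate simulation configs can be expressed — fitted
models always have a strictly positive one; constant fields short-circuit
the variogram fit to a zero-variance model; grids always cover their
bounding box (`ceiling` cell counts) and serialize in the ESRI ASCII
convention (cell-center predictions, corner-referenced origin, rows north
to south).

## Problem sizes

The packaged analyses are deliberately desk-scale: the 11-method LOOCV
comparison over both pollutants completes in a few seconds; the
simulation studies use 20 seeds at n = 200 (range recovery), 20 seeds at
n = 60 (drift comparison), and 100-m grids over the city extent — sizes
chosen so the full validation suite runs in well under a minute while
keeping Monte-Carlo noise below the tolerances being asserted.

## Known limitations

* Planar metric coordinates only; no geodesy, anisotropy, barriers or
  local search ellipses.
* The exceedance statistics are computed over the 48 station means — the
  only reading auditable from the published table; per-sample (246-row)
  exceedance is not computable from the shipped data.
* Kriging variances are reported but the package offers no simulation-
  based prediction intervals on the concentration scale (back-
  transforming a kriging variance is not attempted).
* The published transformed-scale RMSE/MBE/MAE columns are not
  numerically reproducible (unknown rescaling, see above); only MAPE and
  the method ranking are reproduction targets.
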