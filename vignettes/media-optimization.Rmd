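---
title: "Two-stage media optimization: screening and response surface methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage media optimization: screening and response surface methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsm)
```

## The problem

Microbial production of an enzyme depends jointly on many medium components
and culture conditions. Testing each factor one at a time is both
inefficient and blind to interactions, so the standard workflow is
two-staged: a saturated two-level *screening* design to find the few factors
that matter, then a *response surface* design over those few to locate the
optimum. This package implements both stages, with the cellulase study
bundled as a worked case: eight candidate factors (CMC, sucrose, yeast
extract, peptone, K₂HPO₄, MgSO₄, temperature, pH), response in U/mL.

## Stage 1: Plackett–Burman screening

A 12-run Plackett–Burman design accommodates 11 two-level columns. Eight
carry real factors; the remaining three are left unassigned. The design is
built by cyclic rotation of a stored generator row (`pb_design()`); each
column is balanced (six runs high, six low) and all columns are mutually
orthogonal, so each main effect

$$E(X_i) = \frac{2(\sum M_+ - \sum M_-)}{N}$$

is estimated independently of the others. The model is purely additive:
a screening design of this resolution cannot estimate interactions, and the
package deliberately does not try.

**Error from dummy columns.** An unassigned column should have zero effect;
whatever effect it *appears* to have is experimental noise. With $n$ dummy
effects $E_d$,

$$V_{\mathrm{eff}} = \frac{\sum E_d^2}{n}, \qquad E_s = \sqrt{V_{\mathrm{eff}}},$$

and each factor is tested with $t = E(X_i)/E_s$ on $n$ degrees of freedom
(two-tailed; the screen cares about magnitude, not direction). The degrees
of freedom are the dummy count — with three dummies this reproduces the
case study's printed $p = 0.0216$ (confidence 97.84%) for CMC. A pooled
$E_s$ applies to every factor, which is what the error model implies; the
case-study source prints a different per-row standard error (5.04375) for
all rows except CMC, a value that is not derivable from its own formulas,
and we do not imitate it. Either way the screen's outcome is the same:
CMC, MgSO₄ and pH clear 95%.

Effects are stored signed, with a `magnitude` column mirroring the
convention of reporting $|E|$: a *negative* significant effect means the
factor matters but its low level favors production.

If all dummy effects are exactly zero (noise-free simulated data), $E_s = 0$
and $t$ is undefined; the screen then flags every nonzero effect significant
($p = 0$) and marks the result degenerate rather than failing.

## Stage 2: the central composite design

The three retained factors enter a rotatable CCD: $2^3$ factorial points at
±1, six axial points at $\pm\alpha$, and six center replicates — 20 runs,
following $2^k + 2k + \eta_0$.

**Axial distance.** The case-study narrative says "5 axial points (α ± 2)"
and "3 replications at the central point", but its own design table has six
axial and six center runs, and its printed actual levels (CMC 1.840896 g% at
$+\alpha$ around a center of 1.0 with step 0.5) imply
$\alpha = (2^3)^{1/4} = 1.681793$ — the rotatable value, which makes
prediction variance depend only on distance from the center. We follow the
tables: `ccd_design()` defaults to rotatable $\alpha$ (overridable), six
center points, and the fixed run order factorial → axial → center with no
randomization, so constructed designs are reproducible.

**Infeasible levels.** The MgSO₄ axial low maps to −0.1034 g%, a physically
impossible concentration. The constructor returns it as computed with a
feasibility warning available, because silently clipping would destroy
rotatability and misrepresent the design actually analyzed (the case study
itself tabulates the negative level).

**Coding.** All fitting is in coded units, $x = (\text{actual} -
\text{center})/\text{step}$; coefficients on the coded scale are directly
comparable across factors, and this is the scale on which such models are
conventionally reported. Actual-unit coordinates are derived views.

## Fitting, ANOVA and diagnostics

`quad_fit()` fits the full second-order polynomial (intercept, $k$ linear,
$k(k-1)/2$ interaction, $k$ quadratic terms — 10 parameters for $k=3$) by
QR least squares, refusing rank-deficient model matrices by name and
designs without residual degrees of freedom.

`rsm_anova()` partitions:

- corrected total SS = model SS + residual SS;
- residual SS = lack-of-fit SS + pure-error SS, pure error pooled within
  *replicate groups* (runs identical in every coded column to 1e−9 — the
  center replicates in a standard CCD, giving 5 pure-error df here);
- per-term SS by single-term deletion from the full model. On an orthogonal
  CCD this equals the closed form $\beta^2 \sum x^2$ for linear and
  interaction columns (asserted in the tests to 1e−8); for non-orthogonal
  user designs the deletion values are partial (type-III-style) SS.

Model and per-term F ratios are against the residual mean square;
lack-of-fit is against pure error. Diagnostics follow the field's standard
definitions: $R^2$, $CV = 100\sqrt{MS_{res}}/\bar{y}$ (undefined and flagged
when $\bar y = 0$), and adequate precision
$[\max\hat y - \min\hat y]/\sqrt{p\,MS_{res}/n}$ with $p$ the parameter
count and $n$ the run count — with $p = 10$, $n = 20$ this reproduces the
case study's printed 6.553, which its source never defines.

On the bundled data the fit reproduces the published analysis essentially
exactly: coefficients (27.32, 1.28, 0.87, −2.27, −0.86, 0.98, −0.01, −0.41,
−1.94, −1.33 at 2 dp; the BC interaction is −0.00625 before rounding, printed
as −0.006), model F = 3.79 (p = 0.0247), lack-of-fit F = 1.08 (p = 0.467),
CV = 9.51, adequate precision = 6.553. One garbled numeral in the published
ANOVA (the lack-of-fit F) is resolved by its narrative value, which equals
the ratio of the printed mean squares.

## Optimization

The fitted surface is $ \hat y = b_0 + b^\top x + x^\top B x$ with $B$
holding the quadratic coefficients on its diagonal and half the interaction
coefficients off it. `stationary_point()` solves $2Bx = -b$ and classifies
the point by the eigenvalues of $B$; a singular $B$ (a ridge) is an error
pointing the user to constrained search.

`optimize_region()` returns the *exact* global maximum over the coded design
region, deterministically:

- **box** $[-\alpha, \alpha]^k$ (default): enumeration of the $3^k$
  KKT bound patterns — each coordinate at its lower bound, upper bound, or
  interior-stationary — solving the free block analytically and keeping
  feasible candidates;
- **sphere** of radius $\alpha$: the trust-region eigenvalue equation,
  including the hard case.

Both are cross-checked in the tests against dense grid oracles and random
surfaces. The design choice of exact enumeration over multi-start numerical
search removes any dependence on starting points or RNG.

**Why the package reports a different optimum than the case study.** The
study states its optimum as CMC 1.84 g% ($+\alpha$), MgSO₄ 0.275 g%
(center), pH 8.5 (center) with "predicted" 29.95 U/mL. But 29.95 is the
*observed* response of the CMC-axial run; the fitted model predicts
28.31881 there, and since the fitted pH linear coefficient is negative
(−2.27) the model's actual maximizer has pH below center: coded
(0.937, 0.018, −0.510), i.e. CMC 1.47 g%, MgSO₄ 0.279 g%, pH 7.74,
predicted 28.51 U/mL. The package reports model-consistent numbers and
keeps the study's stated values (including the wet-lab validation
30.62 U/mL and the 6.81-fold claim, whose baseline is unreported) as
metadata in `cellulase_reported()`. Neither is ever produced as a model
output.

`surface_grid()` exports rectangular prediction grids for any factor pair
(others held fixed, default at center) for contour/surface plotting.

## Simulated data and what the tests show

`simulate_pb()` draws $y = \text{baseline} + \sum (E_j/2)\,x_j +
\varepsilon$ — the coded slope is half the effect, so the screening
estimator recovers the stated truth exactly at zero noise — and
`simulate_ccd()` draws from a known second-order polynomial; both use
i.i.d. Gaussian noise with a mandatory seed. Noise defaults in the analysis
scripts use sd 5 U/mL for screening runs and sd 2.36 U/mL for CCD runs,
the residual scale of the case study ($\sqrt{MS_{res}} = \sqrt{5.563}$),
which is what a replicate-level assay scatter of this system looks like.

The simulation checks establish: exact parameter recovery at zero noise,
seed-reproducibility, a null false-positive rate of the 95% screen
consistent with its nominal 5% (2000 replicates), detection power far above
the null for a 3-standard-error effect, and linear-coefficient RMSE
matching the theoretical $\sigma/\sqrt{\sum x^2}$ on this design. The
generator emulates the error structure the analysis assumes —
homoscedastic, independent, Gaussian noise around an additive or quadratic
truth. Real fermentation data can violate all three (variance growing with
the mean, batch effects, curvature beyond second order), so passing these
tests validates the *statistics*, not the biology: lack-of-fit and
residual diagnostics on real data remain essential.

## Problem sizes and numerical choices

All case-study computations are closed-form or small least squares (12–20
runs) and run in milliseconds; the Monte-Carlo checks use 2000 screening
replicates and 500 CCD refits, enough to pin the false-positive rate to
±1% and coefficient RMSEs to a few percent. Replicate-group detection uses
a 1e−9 coded tolerance; round-trip coding identities hold to 1e−12; grid
oracles in the tests resolve the optimum to 0.005 coded units. Ties in the
box enumeration resolve to the first pattern in lexicographic order, which
is immaterial since candidates are compared on predicted value.
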