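# pbrsm

Two-stage statistical optimization of fermentation media in R:
Plackett–Burman screening followed by response surface methodology on a
rotatable central composite design (CCD). The package is written for
bioprocess and fermentation scientists who run the classic
design-of-experiments workflow for maximizing a measured output — here,
cellulase activity (U/mL) of a *Bacillus amyloliquefaciens* culture, the
bundled case study — but every function is generic over factors and
responses.

## The statistics

**Stage 1 — screening.** An *N*-run Plackett–Burman design studies up to
*N* − 1 two-level factors; columns left unassigned ("dummies") estimate
experimental error. For factor *X<sub>i</sub>* with coded column
*x* ∈ {−1, +1}<sup>N</sup>:

- main effect: *E(X<sub>i</sub>)* = 2(ΣM₊ − ΣM₋)/N, the mean response at the
  high level minus the mean at the low level;
- effect variance from the *n* dummy-column effects *E<sub>d</sub>*:
  *V<sub>eff</sub>* = Σ*E<sub>d</sub>*²/*n*, standard error
  *E<sub>s</sub>* = √*V<sub>eff</sub>*;
- significance: *t(X<sub>i</sub>)* = *E(X<sub>i</sub>)*/*E<sub>s</sub>* on
  *n* degrees of freedom, two-tailed; a factor is retained when
  100(1 − *p*) meets the confidence threshold (default 95%).

**Stage 2 — response surface.** The retained factors enter a rotatable CCD
(2<sup>k</sup> factorial + 2k axial points at ±α, α = (2<sup>k</sup>)<sup>1/4</sup>,
plus replicated center points) and the response is fitted by ordinary least
squares, in coded variables, to

Y = β₀ + Σβ<sub>i</sub>x<sub>i</sub> + Σβ<sub>ii</sub>x<sub>i</sub>² + Σβ<sub>ij</sub>x<sub>i</sub>x<sub>j</sub>

The ANOVA partitions the residual into lack of fit and pure error (from the
replicated center runs), reports per-term F tests, R², the coefficient of
variation, and adequate precision. The fitted surface is then optimized:
analytically at its stationary point (classified maximum/minimum/saddle by
the eigenvalues of the quadratic-form matrix) and exactly over the coded
design region (box or sphere).

## Worked example

```r
library(pbrsm)

# Stage 1: screen the eight-factor cellulase medium
study <- cellulase_pb()
pb_screen(study$design, study$response)
#> Plackett-Burman screening (8 factors, Es = 3.96386 on 3 df, threshold 95%)
#>        factor  effect magnitude std_error       t      p confidence_pct significant
#>           CMC 17.4900   17.4900    3.9639  4.4124 0.0216        97.8400        TRUE
#>         MgSO4 18.4733   18.4733    3.9639  4.6604 0.0186        98.1357        TRUE
#>            pH 16.3333   16.3333    3.9639  4.1206 0.0259        97.4093        TRUE
#>       ... (five further factors, none significant)

# Stage 2: fit and diagnose the 20-run CCD over CMC, MgSO4, pH
ccd <- cellulase_ccd()
fit <- quad_fit(ccd$design, ccd$response)
round(fit$coefficients, 2)
#> (Intercept)   CMC MgSO4    pH CMC:MgSO4 CMC:pH MgSO4:pH CMC^2 MgSO4^2  pH^2
#>       27.32  1.28  0.87 -2.27     -0.86   0.98    -0.01 -0.41   -1.94 -1.33
rsm_anova(fit)          # model F 3.79 (p 0.0247); lack-of-fit F 1.08 (p 0.467)
fit_stats(fit)          # R2 0.774, CV 9.51%, adequate precision 6.553

# Optimize the fitted surface over the coded design box
optimize_region(fit)
#> Constrained maximum over the coded box (radius 1.682)
#>   coded:   CMC = 0.93723, MgSO4 = 0.017811, pH = -0.50967
#>   actual:  CMC = 1.4686, MgSO4 = 0.27901, pH = 7.7355
#>   predicted response: 28.507
```

The screen keeps CMC, MgSO₄ and pH (confidence > 95%); the quadratic model
is significant (model F = 3.79) with non-significant lack of fit
(F = 1.08), and its maximum over the explored region is ≈28.5 U/mL at
CMC 1.47 g%, MgSO₄ 0.28 g%, pH 7.7. Note the case study's own stated
optimum (CMC 1.84 g%, MgSO₄ 0.275 g%, pH 8.5; 29.95 U/mL) is its best
*observed* run rather than the fitted model's maximizer — see the vignette.

The same analysis, as a narrated workflow, lives under `analysis/`:

```sh
Rscript analysis/01_screen_factors.R     # screening table
Rscript analysis/02_fit_surface.R        # coefficients, ANOVA, diagnostics
Rscript analysis/03_optimize_surface.R   # stationary point, region optimum, surface grids
Rscript analysis/04_simulation_checks.R  # recovery, type-I error and power under known truth
```

Each script prints its findings and writes tables under `results/`.

## Simulated data

`simulate_pb()` and `simulate_ccd()` generate seeded design–response
datasets from known ground truth (additive main effects, or a full
second-order polynomial, plus i.i.d. Gaussian noise), so every stage of the
pipeline can be validated end to end; `cellulase_truth()` provides the
case-study surface as a realistic truth.
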