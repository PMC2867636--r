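---
title: "Estimating age-specific hazard functions in the log-linear age-period-cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating age-specific hazard functions in the log-linear age-period-cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llapc)
```

## The model

Observed age-specific cancer incidence rates mix three confounded time
scales: the age of the person, the calendar period of diagnosis, and the
birth cohort. `llapc` works with the multiplicative (log-linear)
age-period-cohort factorization

$$ I_{i,j,c}(t_i) \;=\; v_{j,c}\, u_{l,c}\, h_c(t_i), $$

where $I_{i,j,c}(t_i)$ is the observed rate (cases per 100,000
person-years) in five-year age group $i$ (midpoint $t_i$) and five-year
calendar period $j$ for a population exposed to category $c$ of some
categorical risk factor (geographical area, sex, lifestyle, ...);
$v_{j,c}$ is the period effect, $u_{l,c}$ the birth-cohort effect, and
$h_c(t_i)$ the age-specific hazard function, the quantity of interest:
the risk of onset at age $t_i$ freed of period and cohort influences.
The cohort index is not free: a cell $(i, j)$ lies on one Lexis diagonal,
$l = j - i + \mathrm{offset}$, so adjacent diagonals are adjacent
five-year birth cohorts. Under the standard layout (18 age groups 0–4
through 85+, six periods, usable ages from group 8, offset 18) the
usable cells span exactly 16 cohorts.

Because age, period and cohort are linearly dependent
($\text{cohort} = \text{period} - \text{age}$), the factors are
identified only up to anchoring: one period coefficient and one cohort
coefficient are fixed to 1 (by default the last period and cohort 8,
i.e. 2000–04 and 1925–29 in the standard layout). Every downstream
quantity carries its anchors, and hazard curves are compared only when
their anchors agree — the package refuses otherwise. Ratios of two
categories' hazards are invariant under a common change of anchors (this
is a tested property).

## Estimating the effect coefficients

The coefficient estimator implemented here is a **ratio-chaining
reconstruction** built from one assumption: *adjacent five-year birth
cohorts have nearly equal effect coefficients*. It is not a port of any
particular published fitting program, and `EffectEstimates()` /
`readEffects()` accept externally computed coefficients for users who
prefer another APC fitter.

1. **Adjacent-period ratios.** For each period pair $(j, j+1)$ and every
   age $i$ present in both, $I_{i,j+1}/I_{i,j} =
   (v_{j+1}/v_j)(u_{l+1}/u_l) \approx v_{j+1}/v_j$ under the
   neighbour-cohort assumption. Per-age ratios get first-order
   (delta-method) SEs and are pooled by inverse variance
   (*pool-then-chain*; pooling first stabilises each link before errors
   are accumulated along the chain).
2. **Chaining.** Pooled ratios are chained on the log scale and the
   series is rescaled so the anchor period equals exactly 1 (SE 0). The
   SE of each coefficient accumulates, in quadrature, the relative
   errors of the ratios between it and the anchor, treating links as
   independent.
3. **Cohort effects.** After dividing each cell by $v_j$ (SEs
   propagated), period-adjacent cells at the same age estimate
   $u_{l+1}/u_l$ exactly; these are pooled per cohort pair and chained
   outward from the anchor cohort. A cohort not connected to the anchor
   through observed cells is reported `NA`, never guessed.

**Bias of the reconstruction.** The adjacent-period ratio estimates
$v_{j+1}/v_j$ only up to the neighbour-cohort drift $u_{l+1}/u_l$. When
the cohort effects drift geometrically with per-cohort ratio $\rho$, the
period-ratio estimator is biased by exactly $\rho$; the synthetic
generator exposes this scenario and a test pins the effect. With exact
period coefficients supplied, the cohort estimator is exact on
noise-free data regardless of drift.

On noise-free grids the whole inversion is exact to machine precision
(with constant $u$ for the period step, or with exact $v$ supplied
otherwise) — the strongest available correctness check for a chained
estimator.

## Correcting rates and estimating the hazard

Corrected rates are $I^*_{i,j,c} = I_{i,j,c}/(v^*_{j,c} u^*_{l,c})$ with
first-order error propagation

$$ \mathrm{SE}^2[I^*] = \Big(\tfrac{1}{v u}\Big)^2 \mathrm{SE}^2[I]
 + \Big(\tfrac{I}{v^2 u}\Big)^2 \mathrm{SE}^2[v]
 + \Big(\tfrac{I}{v u^2}\Big)^2 \mathrm{SE}^2[u]. $$

Each corrected cell estimates $h_c(t_i)$, so the hazard per age group is
the inverse-variance weighted mean across periods, with
$\mathrm{SE}[h^*] = (\sum_j w_{i,j})^{-1/2}$ and $w = 1/\mathrm{SE}^2$ —
the minimum-variance combination for independent normal estimates. Rates
are treated as normal, which the case-count filter (only cells with more
than 15 cases are used, strictly) is there to justify; there is no
Poisson mode in this version.

Two approximations are made deliberately and consistently: (i) the
coefficients are usually estimated from the same grid being corrected,
and the correlation this induces between corrected cells is **ignored**;
(ii) ratio SEs treat numerator and denominator as independent. See
"What the validation shows" below for where this bites.

**Degenerate inputs.** A cell with SE 0 would take infinite weight, so a
mix of zero and positive SEs is refused, with an explicit `seFloor`
escape hatch. When *every* SE in a pool is zero the data are exact: the
values must agree and the common value is returned with SE 0. This is
what makes noise-free synthetic grids flow through the entire pipeline
and come out exact.

## Comparing categories

For categories $c$ and reference $0$ sharing anchors, the age-specific
relative hazard is $r_{c|0}(t_i) = h^*_c(t_i)/h^*_0(t_i)$ with
first-order SE and 95% limits $r \pm 1.96\,\mathrm{SE}$. The averaged
relative hazard $R_{c|0}$ is the inverse-variance weighted mean of the
unflagged $r$'s, SE $(\sum_i w_i)^{-1/2}$.

**Outlier rule.** The criterion adopted is the standardized residual
against the weighted fit: flag ages with $|r_i - \hat r_i| /
\mathrm{SE}[r_i] > 2$, in a single pass by default (`iterate = TRUE`
refits to a fixpoint), where $\hat r$ is the weighted mean
(`mode = "mean"`) or a weighted line in age (`mode = "trend"`). Both the
mode and the threshold are configurable; the default (mean, 2) is the
configuration under which the packaged SEER lung-cancer series reproduce
their published averaged hazards.

**Slope diagnostic.** Constancy of $r(t)$ in age is checked by weighted
least squares of $r$ on $t$ with weights $1/\mathrm{SE}^2$. The slope SE
is the residual-scaled standard regression SE (as `stats::lm` reports),
not the fixed-variance $(X'WX)^{-1}$ form; the two differ when the
residual scatter disagrees with the declared SEs, and the residual-scaled
convention is the one that matches the published fits this package
reproduces. Slopes are reported both with and without flagged points;
the headline value is the all-points fit.

**Adjusted curves.** `adjustCurve()` divides a curve (values and SEs) by
$R$ to overlay it on the reference scale. The uncertainty of $R$ itself
is intentionally not propagated — it is a display adjustment.

## The synthetic generator

`TruthSpec()` / `generateGrid()` draw grids from the multiplicative
truth with relative normal noise: $\mathrm{rate} = v_j u_l (R_c h(t_i))
(1+\varepsilon)$, $\varepsilon \sim N(0, cv^2)$ redrawn while
$\varepsilon \le -0.9$ (at the $cv \le 5\%$ levels used this never
triggers). The stored SE is the *oracle* value $cv \times$ (noise-free
product), not an SE re-estimated from the realized rate, so propagation
formulas have a clean target; counts are set to 1000 so the case-count
filter keeps every cell. Defaults used across the validation suite:
the standard 18 × 6 layout (11 usable ages, 16 cohorts), a hazard shaped
like the published male lung-cancer reference curve (rising from ~5 to
~283 per 100,000 with a turnover near age 77.5), a modest geometric
period trend, and $cv = 3\%$, a realistic error scale for SEER-sized
five-year cells passing the >15-case filter.

What the generator does **not** emulate: Poisson count noise (a labelled
extension point; rates are normal by construction), age-standardization
artefacts within five-year groups, registry-specific reporting changes,
or correlated errors between neighbouring cells. Passing tests therefore
validate the estimator's arithmetic and its error propagation under the
model's own assumptions — not robustness to violations of those
assumptions in real registry data.

## What the validation shows (and what it cannot)

Validation problem sizes, chosen to make Monte-Carlo error comfortably
smaller than the bands being checked: 500 replicates of 11 × 6 grids at
$cv = 3\%$ for coverage, 100 replicates for mean recovery of
$R_{\mathrm{true}} = 1.5$, exactness at $cv = 0$ to $10^{-10}$, and
brute-force oracle agreement to $10^{-12}$.

* Coverage of the true $h$ by $h^* \pm 1.96\,\mathrm{SE}$, with
  coefficients re-estimated per replicate, is ≈93% — slightly below
  nominal because of the ignored within-grid correlation, but inside
  the accepted 92–98% band.
* Coverage of $R_{\mathrm{true}}$ by $R \pm 1.96\,\mathrm{SE}$ is
  93–95% when the coefficients are exact (the propagation formulas are
  correct). With coefficients estimated from the same grids, the
  anchor-chain error is shared by all ages of a category, the per-age
  ratios become strongly correlated, and the sum-of-weights SE of $R$ is
  a substantial understatement: coverage drops to roughly one half.
  This is a real property of the method's error model, not of this
  implementation; treat the reported $\mathrm{SE}[R]$ as a lower bound
  whenever the coefficients come from the same data.
* Slopes of synthetic constant-ratio series center on zero.

## Design choices that were genuinely open

* **Case-count filter per cell**, not per age group: the filter's
  purpose (normality of the rate error) is a per-cell property. The
  threshold and the usable-age cut are configurable in
  `applyFilters()`.
* **Pool-then-chain** for ratio pooling, log-scale accumulation, ties
  broken by ascending index — deterministic throughout.
* **Anchors default** to the last period and cohort 8 (when there are at
  least eight cohorts), matching the configuration of the packaged SEER
  estimates.
* **Missing cells are first-class**: absent, never zero-filled; every
  pool records how many cells contributed (`n_cells`).
* The published relative-hazard tables that ship with the package print
  SE columns about 1.96× larger than first-order propagation of the
  hazard-table SEs gives, suggesting those columns are 95% half-widths;
  the package uses propagated SEs everywhere and does not calibrate to
  those columns.

## Known limitations

* No Poisson-likelihood APC fitting, no parametric hazard forms, no
  smoothing across coefficients, no drift decomposition, no
  heterogeneity test across ages, no multiple-testing control.
* The cohort-coefficient chain treats pooled adjacent ratios as
  independent although neighbouring links share cells; the 3-SE
  coverage checks in the test suite bound the practical effect at the
  noise levels considered.
* `ageStandardize()` requires user-supplied standard-population
  weights; none are bundled.
* Sub-five-year layouts are parameterized but only exercised at
  five-year spacing.
```{r session}
sessionInfo()
```
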