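---
title: "The hybrid heritability model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid heritability model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transherit)
```

## The problem

Family and registry studies of common neuropsychiatric disorders report
liability-scale heritabilities (H²) far above what measured genetic variants
explain: SNP-based estimates plus copy-number-variant contributions typically
cover only a third to a half of H². At the same time, those studies estimate
a large couple-shared environmental variance component (E_P) — the part of
liability variance that spouses share because they share a household,
diet, substance exposure and stress environment. If some fraction of that
parental environment is transmitted to offspring by non-genetic means
(epigenetic marks, in-utero exposure, vertical transmission of behaviour),
it inflates parent–offspring resemblance and is silently absorbed into H²
by estimators that treat all cross-generational resemblance as genetic.

`transherit` implements that hybrid model and the machinery to test it:

1. closed-form arithmetic decomposing H² into additive genetics plus
   transmitted environment,
2. a nuclear-family liability-threshold simulator whose generative model
   realises the transmission mechanism,
3. estimators (tetrachoric correlations, component inversion) that recover
   the generative parameters from binary family data and quantify the bias
   of the naive estimator.

## The model

Phenotypes are binary diagnoses arising from a standardized latent Gaussian
liability thresholded at the population prevalence K. On that scale,
broad-sense heritability under first-order direct genetic and environmental
variances is

$$H^2 \cong \frac{G_A + x E_P}{G_A + E}, \qquad
  E = E_P + E_F + E_S + E_U, \quad 0 < x < 1,$$

where \(G_A\) is additive genetic variance, \(E_P\) couple-shared parental
environment, \(E_F\) shared familial, \(E_S\) sibling-shared and \(E_U\)
unique environment, and \(x\) is the fraction of \(E_P\) transmitted to
offspring. The total "inherited" variance is \(G = G_A + x E_P\); the
residual heritability \(H^2 - G\) is what neither measured genetics nor
transmitted environment covers.

Solving the identity for \(G_A\) gives the unique algebraic inversion

$$G_A = \frac{H^2 E - x E_P}{1 - H^2},$$

which `solve_hybrid()` implements, verified in the test suite by
back-substitution to 1e-10 and against brute-force bisection. Inputs with
\(H^2 E < x E_P\) would force a negative variance; they raise an error
rather than clamping, because a negative variance component signals
inconsistent inputs, not a quantity to truncate.

Two modes cover the two data situations:

* **solved** — the user supplies \(E\) (or its components) and `solve_hybrid()`
  derives \(G_A\);
* **reproduced** — published per-disorder decompositions often print \(G_A\)
  but not \(E\); `reproduce_hybrid()` assembles \(G = G_A + xE_P\) directly so
  table reproduction does not depend on unprinted inputs.

Back-solving the bundled five-disorder table under the canonical inversion
implies per-disorder totals with \(H^2 + E \approx 1.03\): the source's
variance components need not sum to one, so the package never assumes
\(E = 1 - H^2\), and `total_environment()` only accepts an explicit total or
a component set that includes at least `E_P` and `E_U` (a "total" without
the unique-environment term would systematically understate \(E\)).

The transmission fraction is evaluated on the grid
`transmission_grid()` = {0.25, 0.5, 0.6, 0.667}, with \(x = 0.5\) as the
headline model used by the bundled table and the default throughout.

### Rounding conventions

Report output rounds variances to 3 decimals and percentages to 1 decimal,
range endpoints additionally to integer percent; ties round half away from
zero. Raw unrounded values are always retained in the returned tibbles. One
cell of the bundled table is internally inconsistent in the source: the
depression hybrid residual prints as 0.207 where the printed components give
0.579 − (0.192 + 0.181) = 0.206 (its percentage cells likewise derive from
an unrounded intermediate). `build_residual_table()` reports its own arithmetic and
attaches a provenance note to any row whose computed residual disagrees with
a supplied `residual_hybrid_printed` value, rather than forcing the printed
number.

### Aggregate ranges

`aggregate_claims()` recomputes the cross-disorder summaries: the share of
H² explained by measured genetics (G_SNP + CNV), and the hybrid model's
explained share and residual range. Autism spectrum disorder is excluded
from the hybrid ranges: its couple-shared environmental component is zero,
so the hybrid model degenerates to \(G = H^2\) (100% explained) and carries
no information about transmission.

## The generative model

`simulate_families()` realises the transmission mechanism for nuclear
families (2 parents, `n_offspring` children, default 2):

* couple deviate \(C \sim N(0, E_P)\), carried by both parents with loading
  1, so the spouse latent correlation is exactly \(E_P\);
* parental liability \(L_p = G_p + C + U_p\) with \(G_p \sim N(0, G_A)\) and
  unique environment filling to variance 1;
* offspring genetic value = mid-parent average plus a Mendelian segregation
  deviate \(N(0, G_A/2)\) (infinitesimal additive model);
* transmitted environment \(T_o = x C + \delta_o\), with independent per-child
  top-up \(\delta_o \sim N(0,\, x(1-x)E_P)\), so \(\mathrm{Var}(T_o) = xE_P\)
  **and** \(\mathrm{Cov}(T_o, C) = xE_P\);
* one sibling-shared deviate \(N(0, E_S)\) per family; offspring unique
  environment fills to 1;
* affected ⇔ liability > \(\Phi^{-1}(1-K)\).

The covariance-x loading is a deliberate convention. The transmission
mechanism fixes the variance contribution \(xE_P\) but not the
cross-generation covariance; a loading of \(\sqrt{x}\) would give variance
\(xE_P\) with covariance \(\sqrt{x}E_P\) instead. We use loading \(x\) plus
top-up so that the transmitted component contributes to parent–offspring
resemblance exactly as the model's numerator \(x E_P\) intends, and the
estimators in `recover_components()` are derived under the same convention,
so the simulator/estimator pair is internally consistent. Covariance algebra
then gives the closed forms checked by `expected_latent_correlations()`:

$$r_{spouse} = E_P,\qquad
  r_{po} = \tfrac{1}{2}G_A + xE_P,\qquad
  r_{sib} = \tfrac{1}{2}G_A + x^2E_P + E_S.$$

Since \(2 r_{po} = G_A + 2xE_P\), the classic "double the parent–offspring
correlation" heritability estimator overstates \(G_A\) by \(2xE_P\) whenever
transmission is active — the confounding thesis reduced to a statement that
is exactly true in the generative model.

What the generator deliberately does **not** emulate: assortative mating
(spouses correlate only through the shared deviate, not genetically),
dominance and epistasis, gene–environment covariance and interaction,
diagnostic misclassification, multi-generation (grandparent) transmission,
and variable family sizes within a run. Passing tests therefore validate the
internal consistency of model, simulator and estimators — not that real
family data are free of those second-order effects, which the model itself
relegates to its residual.

## Estimation

Binary statuses are cross-tabulated per relation — one spouse pair per
family, every parent × offspring pair, every unordered sibling pair — and
each 2×2 table yields a maximum-likelihood **tetrachoric correlation**:
thresholds fixed at the inverse normal of the margin prevalences (standard
two-step practice; prevalence is a design constant in simulations, so
nothing is gained by joint estimation), then a one-dimensional likelihood
search for \(\rho\) on \((-1+10^{-6},\, 1-10^{-6})\) to tolerance 1e-6, with
the standard error from the observed information (central second
difference, step 1e-4). Tables with a zero cell but interior margins get a
+0.5 continuity correction on all cells, flagged in the output; a margin
with no affected (or no unaffected) observations is degenerate and raises.

The bivariate-normal rectangle probabilities use an in-package vectorised
64-point Gauss–Legendre quadrature of the single-integral form

$$\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \frac{1}{2\pi}
  \int_0^{\arcsin\rho} \exp\!\Big(\frac{2hk\sin\theta - h^2-k^2}
  {2\cos^2\theta}\Big)\,d\theta,$$

vectorised over \(\rho\) so that dense likelihood grids are cheap; the
suite cross-checks it against adaptive quadrature of the conditional-normal
integral and against `mvtnorm::pmvnorm()`, and checks the optimiser against
a brute-force likelihood grid (step 1e-4).

`recover_components()` inverts the three closed-form correlations for
\((G_A, E_P, E_S)\) given an **assumed** \(x\). With three observed moments
and four unknowns the system is underdetermined, so \(x\) is treated as
known rather than jointly estimated. Estimates outside \([0,1]\) are flagged
but never truncated: truncation would bias the recovery experiment's bias
summaries. `recovery_experiment()` wraps the full pipeline over seeded
replicates and reports mean, bias and RMSE per component.

## Validation design and problem sizes

The package validates itself at these design points, chosen to put
Monte-Carlo error well below the effects being measured while keeping a
full run in tens of seconds:

* moment matching of simulated latent correlations against the closed
  forms on a 24-point grid (G_A ∈ {0, 0.2, 0.5} × E_P ∈ {0, 0.3} ×
  x ∈ {0, 0.5} × E_S ∈ {0, 0.1}) at 2×10⁵ families per point, within 4
  Monte-Carlo standard errors. The SEs are cluster-robust by family:
  parent–offspring pairs share parents and a couple deviate, so
  treating the 4 pairs per family as independent would understate the
  Monte-Carlo error;
* tetrachoric recovery of a generating latent correlation of 0.35 at 10⁶
  pairs within ±0.01, and consistency across prevalences K ∈ {0.01, 0.1,
  0.3};
* component recovery at the headline point (G_A = 0.4, E_P = 0.3,
  E_S = 0.1, x = 0.5, K = 0.1) over 20 replicates of 5×10⁴ families:
  |bias| < 0.02 for G_A and E_P when `x_assumed` equals the generating
  x, and inflation of G_A by ≈ 2xE_P = 0.3 when `x_assumed = 0`.

## Worked example

```{r example, eval = FALSE}
library(transherit)
library(dplyr)

# reproduce the published five-disorder decomposition at x = 0.5
tbl <- build_residual_table(example_disorders(), x = 0.5)
format_residual_table(tbl)
aggregate_claims(tbl, exclude_hybrid = "ASD")

# simulate the transmission model and recover its parameters
p <- sim_params(G_A = 0.4, E_P = 0.3, E_S = 0.1, x = 0.5,
                K = 0.1, n_families = 5e4, seed = 1)
fam <- simulate_families(p)
familial_correlations(fam)
recover_components(familial_correlations(fam), x_assumed = 0.5)
recover_components(familial_correlations(fam), x_assumed = 0) # naive

# the stacked-bar view of G = G_A + 0.5 E_P by decreasing H2
autoplot(build_variance_series(example_disorders(), x = 0.5))
```

## Known limitations

* The hybrid identity is a first-order approximation: no dominance,
  epistasis, gene–environment interaction or covariance, all of which land
  in the residual.
* `x` is not identifiable from the three pairwise correlations alone;
  analyses condition on an assumed transmission fraction (the grid above).
* The tetrachoric standard errors condition on margin-fixed thresholds and
  independent pairs; they are slight underestimates for clustered family
  designs (the latent-scale path uses cluster-robust SEs for exactly this
  reason).
* Real registry data bring ascertainment, diagnostic drift and assortative
  mating; none are modelled here, so parameter recovery on synthetic data
  is a necessary, not sufficient, check of the model on real cohorts.
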