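---
title: "Extremal health and behaviour profiles from survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extremal health and behaviour profiles from survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(surveyprofiles)
```

## The problem and the model

Large health and wellbeing surveys of older adults mix dozens of
categorical and ordinal items with descriptive variables (country,
gender, age group) and a calibrated sampling weight per respondent.
`surveyprofiles` implements a three-stage protocol for turning such a
table into a small number of interpretable population profiles anchored
at *extreme observed individuals*:

1. **Composite indicators.** Items are grouped into thematic blocks
   (general health, physical health, mental health, staying at home,
   safety measures, social contact, electronic social contact, direct
   COVID experience, healthcare access in the shipped configuration).
   Each block's polarity-aligned codes are summed and affinely rescaled
   onto a common 0–10 scale, so that higher always means a worse
   situation. This yields the $n \times m$ indicator matrix
   $\mathbf{X}$.

2. **Archetypoid analysis.** Archetypal analysis represents every row
   $\mathbf{x}_i$ as a convex combination of $k$ extreme points
   $\mathbf{z}_j$, minimising
   $RSS = \sum_i \lVert \mathbf{x}_i - \sum_j \alpha_{ij}\,\mathbf{z}_j \rVert^2$
   subject to $\alpha_{ij} \ge 0$, $\sum_j \alpha_{ij} = 1$, with
   $\mathbf{z}_j = \sum_l \beta_{jl}\mathbf{x}_l$ and the
   $\beta_j$ rows on the simplex. *Archetypoids* additionally constrain
   every $\beta_j$ row to be one-hot, so each extreme point is an
   actual respondent. Profiles built around extreme individuals ("the
   person with the worst health and most isolation") are easier to read
   than centroid-based clusters ("a person with intermediate values").

3. **Allocation and profiling.** Every respondent is assigned to the
   archetypoid nearest in squared Mahalanobis distance
   $(\mathbf{x}_i - \mathbf{z}_l)' \mathbf{S}^{-1} (\mathbf{x}_i - \mathbf{z}_l)$,
   where $\mathbf{S}$ is the sample covariance of $\mathbf{X}$
   (an $\alpha$-max rule is available as an alternative). The resulting
   clusters are then described with survey-weighted frequencies,
   population extrapolations, cross-tabulations by the descriptive
   variables and per-cluster weighted indicator summaries.

## Fitting machinery and numerical choices

Every estimation step reduces to *simplex-constrained least squares*.
It is solved by Lawson–Hanson active-set non-negative least squares on
a system augmented with a sum-to-one row (scale $200\,\lVert t
\rVert_\infty$, floored at 200 so near-zero targets keep the
constraint), followed by exact renormalisation; on the hot path
(candidate-set scoring) the equivalent normal-equation form with a
precomputed Gram matrix is used. Weights are accepted when the optimal
active set satisfies the KKT conditions to a scaled dual tolerance.

`fit_archetypes()` alternates: optimal $\alpha$ rows given
$\mathbf{Z}$; unconstrained least-squares update of $\mathbf{Z}$ given
$\mathbf{A}$; projection of each archetype back into the convex hull of
the data via a simplex $\beta$ row. A candidate iteration is accepted
only if it lowers the RSS, making the recorded RSS path non-increasing
by construction; iteration stops at relative improvement below `tol`
(default `1e-6`, `max_iter = 200`), and the best of `n_restarts = 5`
random initialisations (distinct data rows) is kept. These defaults
give stable fits at survey scale; note the alternating scheme
approaches hull vertices asymptotically, so recovering an exactly
planted vertex to high precision needs a larger `max_iter` — the
archetypoid (discrete) stage does not suffer from this, which is one
reason the protocol anchors profiles at observed rows.

`fit_archetypoids()` follows the PAM-style two-step search: BUILD takes
the observed row nearest to each continuous archetype (ties to the
lowest index, duplicates resolved by the next-nearest unused row), and
SWAP applies best-improvement exchanges until no exchange improves the
RSS by more than $10^{-9}$ relative. Best-improvement (rather than
first-improvement) swaps make the local optimum independent of
candidate order. Because the exchange neighbourhood has genuine local
optima on small datasets, the SWAP search is additionally restarted
from a few random index sets (`swap_restarts = 4`) and the best local
optimum kept; with this, the search attains the exhaustive
$\binom{n}{k}$ optimum on every small fixture we test. The model also
stores the continuous fit, refined from the archetypoid solution when
that improves it, so the constrained RSS never undercuts the reported
continuous RSS — the archetypoid problem is the $\beta$-constrained
problem.

### Subsampled search for large surveys

A full SWAP sweep is quadratic in $n$, so for survey-scale data
`adalara_fit()` uses CLARA-style subsampling: a random permutation of
the rows is swept in `N` subsamples of size $m$ (default 10), the first
holding $m$ fresh rows and every later one the incumbent $k$
archetypoids plus the next $m - k$ fresh rows. The number of subsamples

$$N = \left\lfloor 1 + \frac{n - m}{m - k} \right\rfloor$$

is exactly the number needed to sweep the whole dataset once; at the
motivating survey's configuration ($n = 33{,}219$, $m = 10$, $k = 6$)
it evaluates to $N = 8303$. Each subsample is fitted by the full
BUILD/SWAP search and every candidate set is scored by its *full-data*
RSS — the candidates compete as global solutions, not on their
subsample — with the best becoming the incumbent.

Two refinements address the scheme's inherent myopia (a 10-row
subsample can prefer a near-vertex copy over the true extreme row, and
no subsample-level objective can tell them apart): after the sweep the
incumbent is (a) refined by a warm-started continuous archetype fit
whose archetypes drift toward the underlying extremes, with the nearest
observed rows forming a new candidate, and (b) polished by a restricted
full-data SWAP whose entering candidates are limited to the
`polish_pool` worst-reconstructed rows, where a missing extreme profile
necessarily shows up. Both refinements only ever accept a candidate
with lower full-data RSS. Under the validation conditions below this
recovers all planted archetypoids in 20 of 20 generator seeds.

### Choosing k

`scree_rss()` reports RSS against $k$ with a warm-started sweep: the
solution at $k$ plus the worst-reconstructed row initialises $k + 1$,
which makes the curve non-increasing by construction — the property the
elbow heuristic assumes. The default curve sweeps the continuous
archetype fit, which is the curve one can afford at survey scale and
the one used when screening the motivating survey; `method =
"archetypoids"` sweeps the constrained fit for moderate $n$. The choice
of $k$ itself is left to the user; on nine indicators a small $k$
(the motivating analysis chose 6) is typical.

## The synthetic generator and what it validates

Access-controlled microdata cannot ship with the package, so
`simulate_survey()` generates surveys with known ground truth, and the
whole test suite runs against it. The generative model matches the
estimator's own assumptions: `k_true` well-separated vertices in
$[0,10]^m$ (pairwise distance at least 2), respondents as
Dirichlet-weighted convex mixtures of the vertices, Gaussian
indicator-scale noise clipped to the scale, and at least one row per
vertex planted exactly (noise-free). Item codes are then produced by
inverting the indicator construction: the raw block-sum target is
allocated greedily across the block's items in instrument order, so
rebuilding indicators from the emitted codes reproduces the target
within half a raw-sum step (the quantisation bound asserted in tests).

Default conditions — 2,000 respondents, 6 vertices over 9 indicators,
Dirichlet concentration 0.3, noise sd 0.1, one exact planted row per
vertex — are the validation conditions used throughout; descriptives
are drawn from 27 country labels, two genders and three age groups, and
weights are lognormal renormalised to mean 1 with coefficient of
variation 0.5, a positive right-skewed shape typical of calibration
weights (their construction is not modelled further). An optional
association knob tilts descriptive categories per dominant profile so
cross-tabulation logic can be validated against a known tilt; an
optional missing-at-random rate exercises the complete-case filter.

The generator deliberately does *not* emulate interview skip logic,
informative missingness, item-level measurement error correlated within
respondents, or calibration-margin weighting. Passing recovery tests
therefore show that the estimator finds planted convex-mixture
structure — not that any real survey satisfies that structure.

## Worked pipeline

```{r pipeline, eval = FALSE}
sim <- simulate_survey(synthetic_config(seed = 8))

X <- sim$survey |>
  filter_complete_cases() |>
  build_indicator_matrix()

fit <- adalara_fit(X, k = 6, subsample_scheme(10, seed = 8))
archetypoid_table(fit)

assignment <- mahalanobis_allocate(X, fit)
report <- profile_summary(X, assignment, total_population = 448e6)
report$frequencies
plot_profile_frequencies(report$frequencies)
plot_profile_crosstab(report$crosstabs$age_group)
```

A published per-country stringency index (a 0–100 composite of
restriction measures) can be joined onto country-level outputs with
`join_stringency()`; it is ingested as data, never computed.

## Degenerate inputs and conventions

* All-identical rows: the continuous fit returns that row repeated with
  zero RSS rather than failing.
* Singular covariance (e.g. a constant indicator): the Mahalanobis rule
  switches to the Moore–Penrose pseudo-inverse at condition number
  $> 10^{12}$.
* Ties break toward the lowest index everywhere (archetypoid order,
  allocation, $\alpha$-max), for reproducibility.
* Empty profiles keep a zero share in every table rather than being
  dropped or refitted.
* Calibration weights enter **descriptive summaries only** — the RSS
  objective and the covariance $\mathbf{S}$ are unweighted. $\mathbf{S}$
  is the plain sample covariance of the analysed indicator matrix, not
  per-cluster and not weight-adjusted.
* Weighted quantiles use the left-continuous inverse weighted ECDF,
  which coincides with `quantile(type = 1)` at equal weights.
* Complete-case (listwise) filtering over the analysis items is the
  only missing-data treatment; imputation is out of scope and the
  filter reports kept/dropped counts.

## Problem sizes used in the shipped validation

The test suite exercises: exhaustive-enumeration oracles at $n \le 12$,
$k \le 3$; simplex-grid and NNLS oracles on random small instances;
planted-vertex recovery and the scree elbow at the default generator
conditions ($n = 2000$, $k = 6$, $m = 9$, 20 seeds for recovery); a
1,000-row allocation oracle; and one full pipeline run at $n = 2000$.
These sizes were chosen so each property is checked at the smallest
scale where it is informative.

## Known limitations

* The alternating continuous fit converges slowly into exact hull
  vertices (documented above); use the archetypoid stage when extreme
  *observed* rows are the target, which is the protocol's premise.
* The subsampled search is a seeded stochastic heuristic: determinism
  is per seed, and global optimality is not guaranteed on adversarial
  data.
* The shipped indicator configuration assumes the Table-style item
  codings it documents; instruments with different codings need their
  own YAML configuration.
* Weighted RSS variants, robust archetypoids and kernel/functional
  extensions are out of scope.
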