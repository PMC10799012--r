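---
title: "Rating athletes with a hierarchical composite score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating athletes with a hierarchical composite score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onscore)
```

## The problem

Box-score data are long-format repeated measures: one row per
athlete-game, nested as athlete within team within season, with wildly
unbalanced repeat counts (1 to 82 games per athlete unit — a traded
athlete is two units, one per team). Classical single-number ratings
ignore this hierarchy. The approach implemented here builds a single
per-game composite from the box-score responses and then models it with
a multilevel model, so that an athlete's rating is adjusted for the
fixed context of the game (venue, position, rookie status, in-game
covariates) and for the variance structure of the hierarchy.

## Stage 1: the composite score

For each response variable $r_j$ with reference-set mean $\bar r_j$ and
standard deviation $s_j$, the mean-relative standardisation is

$$z^*_j = \frac{r_j - \bar r_j}{\bar r_j} = z_j \cdot \mathrm{CV}_j ,$$

the ordinary z-score rescaled by the coefficient of variation. This is a
deliberate departure from correlation-matrix PCA: variables on which
athletes genuinely differ a lot relative to their typical level (high
CV) should carry more variance into the decomposition than almost-
constant attributes such as height. Two cases need care, and both are
handled explicitly:

* near-zero mean ($|\bar r_j| \le$ `near_zero_threshold`, default
  `1e-8`): the mean-relative scale is undefined, so the variable falls
  back to the plain unit-variance z-score with a warning;
* zero standard deviation: the variable is constant on the reference
  set and is excluded with a warning.

The covariance matrix of $Z^*$ is eigendecomposed and **all** $n$
components are retained. With eigenvalues $\lambda_c$ (total
$S = \sum_c \lambda_c$) and loadings $\alpha_{cj}$, each variable's
composite weight is the eigenvalue-weighted mean of its loadings,

$$w_j = \sum_{c=1}^{n} \frac{\lambda_c}{S}\,\alpha_{cj},$$

and the per-game score is $\gamma_k = \sum_j w_j z^*_{kj}$. Because
eigenvectors are sign-indeterminate, a fixed convention is applied (the
largest-absolute loading of each component is made positive) and the
flips are recorded; a different convention changes individual signed
weights but only by reflections, which is why published signed weight
tables can only be matched up to that convention. Scores can be mapped
to a fixed range by the usual min–max transform
$a + (\gamma - \min\gamma)(b-a)/(\max\gamma - \min\gamma)$, default
$[0, 100]$.

The reference set for means, SDs and weights is the pooled data across
seasons. That choice is deliberate: weights refitted per season drift
with outlier seasons, which breaks score comparability over time.
`weight_stability()` quantifies this by recomputing the weights with
each season left out and reporting per-variable spread (plus per-season
means/SDs); a variable that is essentially dead in early seasons and
alive later is flagged as an outlier because its mean-relative scale
explodes when the live season is excluded. `run_validation()` exposes
`refit_weights` so users can measure the effect of training-set-only
weights; versioning of weights across refits is left to the caller's
workflow.

## Stage 2: the three-level model

The composite score of game $l$ of athlete $k$ (team $j$, season $i$) is
modelled as

$$\gamma_{ijkl} = \beta_0 + \textstyle\sum_m \beta_m f_{ijklm}
  + \sum_{p,q} \theta_{pq} P_{pq}(t_{ijklp})
  + b_i + b_{i,j} + b_{ij,k} + \epsilon_{ijkl},$$

with independent Gaussian random intercepts for season
($\sigma_1^2$), team within season ($\sigma_2^2$) and athlete within
team within season ($\sigma_3^2$), and i.i.d. errors ($\sigma^2$).
$P_{pq}$ are orthogonal polynomials in the in-game covariates; the
default specification uses venue, position and rookie plus cubic terms
in points and assists and quadratic terms in blocks received,
free-throw attempts and offensive rebounds. Factors are coded with
sum-to-zero contrasts (the documented choice behind the type-III
tables; reference coding is available).

Estimation is REML (`fit_reml()`, via lme4), with fixed effects by GLS
at the fitted components and random effects by empirical-Bayes BLUP.
The package also carries an independent closed-form REML objective for
the nested structure, computed in $O(n)$ by accumulating per-block
Sherman–Morrison updates; it is used as a cross-check of the main path
and as the engine for profile-likelihood intervals in simulation
studies. The two implementations agree to numerical tolerance on every
test case, which is the package's guard against silent regressions in
either path.

Model selection (`select_model()`) is top-down: the covariance
structure first, comparing the full and reduced (team dropped)
structures with a REML likelihood-ratio test whose null distribution is
the boundary mixture $0.5\chi^2_0 + 0.5\chi^2_1$; then backward
elimination of fixed-effect terms by BIC on ML refits; finally a REML
refit of the chosen model. Cumulative intraclass correlations
(`icc()`) report the variance shares
$\mathrm{ICC}_1 = \sigma_1^2/\mathrm{total}$,
$\mathrm{ICC}_2 = (\sigma_1^2+\sigma_2^2)/\mathrm{total}$,
$\mathrm{ICC}_3 = (\sigma_1^2+\sigma_2^2+\sigma_3^2)/\mathrm{total}$.
Coefficient tests use Satterthwaite degrees of freedom via lmerTest.

## Ratings

**Consistency scores** (`consistency_scores()`) are the empirical-Bayes
predictions of the random effects, conditioning each group on its own
observation vector: for a group $g$ at level $\ell$,

$$\tilde\gamma^{(CS)}_g = \hat\sigma_\ell^2\, \mathbf{1}^\top
  \hat V_g^{-1} (\gamma_g - X_g\hat\beta),$$

where $V_g$ is the group's marginal covariance block. At the athlete
level $V_g$ is compound-symmetric and the score reduces to
$\hat\sigma_3^2 L \bar r_g / (\hat\sigma^2 + L c)$ with
$c = \hat\sigma_1^2 + \hat\sigma_2^2 + \hat\sigma_3^2$ — shrinkage of
the raw mean residual toward zero, stronger for athletes with few
games. Team- and season-level scores use the same algebra with nested
blocks, evaluated by recursive rank-one updates rather than matrix
inversion. A positive score is performance above the level expected
given the fixed effects and the rest of the hierarchy; zero is
performance as expected. Interval estimates are percentile bands of
Monte-Carlo draws (default 10,000, seeded and recorded) from the
per-group empirical-Bayes posterior
$N(\tilde\gamma^{(CS)}_g,\ \sigma_\ell^2 - \sigma_\ell^4
\mathbf{1}^\top V_g^{-1}\mathbf{1})$. Conditioning is per-group
marginal, not joint across groups: with a shared season effect the
joint BLUP of an athlete differs slightly because other athletes'
data inform the season effect; the per-group form is the one with the
closed-form posterior used for the intervals, and the two coincide
whenever the outer components vanish (a tested identity).

**Relevance scores** (`relevance_scores()`) summarise each athlete
unit's conditional expected scores $\hat\gamma_{ijkl}$ (fixed part plus
BLUPs) by their median, using the explicit parity rule (middle value
for odd $L$, mean of the two middle values for even $L$). The
$100(1-\alpha)\%$ interval is the classical signed-rank construction:
order the $M = L(L+1)/2$ Walsh averages
$(\zeta_a + \zeta_b)/2,\ a \le b$, and take the $C$-th smallest and
$C$-th largest with $C = M + 1 - t_{\alpha/2}$, where $t_{\alpha/2}$ is
the upper critical point of the exact signed-rank null. The index
formula only makes sense against the Walsh-average order statistics
(there are $M$ of them, not $L$), which is the construction
implemented. The exact null is evaluated by R's `qsignrank` for every
$L$ (it is fast far beyond $L = 82$), so no Normal approximation is
needed at any realistic group size; an exhaustive $2^L$ enumeration
backs it as a test oracle for small $L$. Units with one game get a
degenerate flagged interval; groups too small for the nominal level
fall back to the full Walsh range, also flagged. Exact zeros are
dropped and ties mid-ranked in the statistic helper, though fitted
values make ties essentially impossible. `rank_entities()` sorts by
point estimate (ties: more games first, then ids), optionally adds a
min–max scaled column computed over the full score set, and carries the
intervals so users can see overlapping intervals instead of
over-reading point ranks.

## Validation

Two schemes (`make_split()` / `run_validation()`): hold out each season
in turn (predicting an entirely unseen season, population mode), or
repeatedly hold out a without-replacement sample of games within every
season (default 10%, grouping units known, conditional mode). Reference
values are the complete-data model's conditional fitted scores (raw
stage-1 scores are available behind `reference = "stage1"`). Agreement
is summarised by RMSE, Pearson $r$, Lin's concordance

$$\rho_{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},
\qquad C_b = \rho_{CCC}/r,$$

with population (1/n) moments, and a CCC confidence interval from the
Fisher $z$ transform with Lin's asymptotic standard error (the interval
construction is not prescribed alongside the point definition, so this
standard choice is documented here). A warning fires when a training
fraction leaves the 70–85% range, and any split whose training set
cannot support the hierarchy (e.g. a single season) is reported and
skipped rather than silently dropped.

## The synthetic league

`simulate_game_log()` generates the study conditions every simulation
in the package runs under. Defaults: 4 seasons, 10 teams, 12 athletes
per team, 1–82 games per unit drawn uniformly, 5% of athletes traded
mid-season (two grouping units), 15% rookie rate, and random-effect
variances fixed at the magnitudes estimated on real league data
(season 0.005136, team 0, athlete 0.007496, residual 0.012019 in score
units). Box scores are rounded truncated latent Gaussians driven by two
hierarchical latent factors (a physical/rebounding factor and an
offence/defence factor), which reproduces the two observed correlation
blocks among the 22 responses; marginal means and SDs are anchored to
published per-game league summaries. Made counts are derived from
attempts through a latent success rate, so made $\le$ attempted,
$\mathrm{FgAtt} = \mathrm{Fg2PtAtt} + \mathrm{Fg3PtAtt}$ and
$\mathrm{Pts} = 2\,\mathrm{Fg2PtMade} + 3\,\mathrm{Fg3PtMade} +
\mathrm{FtMade}$ hold by construction. Rounding truncated Gaussians was
chosen over Poisson thinning because it preserves the factor
correlation structure exactly and makes the zero-variance limit
degenerate in the right way (identical rows per covariate cell), which
the tests exploit.

`simulate_on_response()` instead draws the composite score directly
from the three-level model with stored truth, for parameter-recovery
work. What the generator does **not** emulate: schedules and opponents,
tactics, injuries, minutes-dependent count inflation, or any
season-to-season skill drift. Passing tests therefore demonstrate that
the estimators recover the model they assume under realistic hierarchy
and imbalance — not that real box scores follow this generative
process.

```{r example, eval = FALSE}
p <- on_sim_params(n_seasons = 3, n_teams = 6, athletes_per_team = 8,
                   games_range = c(10, 25), seed = 1)
log1 <- simulate_game_log(p)
fit <- on_fit(log1)
summary(fit)
icc(fit)
rank_entities(relevance_scores(fit), top_m = 5, scale = c(0, 100))
```

## Numerical choices and problem sizes

* REML convergence is delegated to lme4's defaults; the closed-form
  objective is optimised by Nelder–Mead on the log-variance scale
  (relative tolerance 1e-12), which enforces non-negativity with an
  explicit boundary check as variances run to $-\infty$ on the log
  scale.
* Boundary LRT statistics are clipped at 0; the p-value is 1 at a zero
  statistic.
* Eigenvalues are clipped at 0 with a warning when the standardised
  covariance is rank deficient.
* Profile-likelihood coverage in the recovery study is decided by
  evaluating the profiled deviance at the true value (membership in
  the interval, one inner optimisation per component) rather than by
  locating both bounds, which is algebraically equivalent and an order
  of magnitude cheaper.
* Simulation studies in the test suite use: 200 replicates of the
  4-season / 10-team / 12-athlete / 20–82-game recovery design; 500
  replicates for the boundary-LRT size at a 3-season / 8-team /
  6-athlete league; 300 replicates for the Satterthwaite type-I error;
  50 replicates at B = 99 for bootstrap-interval coverage (4 seasons —
  percentile intervals genuinely undercover with 2 seasons, which is a
  property of the method worth knowing, not a bug). All Monte-Carlo
  assertions carry their binomial or replicate-SD error bands
  explicitly; in particular the season-component bias check adds twice
  its Monte-Carlo standard error to the 5% band because a 4-level
  variance component estimated 200 times has MC noise of the same
  order as the band itself.

## Known limitations

* The hierarchy is strictly nested; crossed structures (athletes facing
  specific opponents) and serial correlation within a season are out of
  scope, as are non-Gaussian responses.
* Consistency-score intervals simulate from each group's marginal
  posterior; no joint simulation across groups is attempted.
* Composite weights depend on the reference set; scores from models
  with different reference sets are not directly comparable.
* The published signed weight table can be matched only up to the
  eigenvector sign convention.
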