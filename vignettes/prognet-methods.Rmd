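---
title: "Comparing symptom-network and sum-score models for depression prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing symptom-network and sum-score models for depression prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

About half of adults treated for depression in primary care do not recover
with their first treatment, and validated prognostic models are scarce. A
recurring methodological question is whether *individual symptom* data —
in particular, coefficient weights derived from symptom *network* models
or from factor-analytic loadings — improve predictions of post-treatment
outcome over plain questionnaire sum scores.

`prognet` implements a complete, reproducible pipeline for that
comparison. Nine modelling approaches predict two outcomes (the follow-up
depressive-severity total on the 0–63 scale, and remission defined as a
follow-up total ≤ 10), giving 18 fitted models per run:

| model | predictors | estimator |
|---|---|---|
| 1 | sum scores weighted by one-step expected influence (EI1) | OLS / logistic |
| 2 | sum scores weighted by two-step expected influence (EI2) | OLS / logistic |
| 3 | sum scores weighted by the geometric mean of the participation coefficient and participation ratio (PC/PR) | OLS / logistic |
| 4 | sum scores weighted by one-factor CFA loadings | OLS / logistic |
| 5 | unweighted sum scores | elastic net |
| 6 | unweighted sum scores | OLS / logistic |
| 7 | all 32 individual baseline variables | elastic net |
| 8 | all 32 individual baseline variables | OLS / logistic |
| 9 | null model: training-set outcome mean / remission proportion | constant |

The 32 baseline variables are 21 depressive-symptom items (0–3 each), 8
anxiety subscale totals (0–4 each) and three auxiliary totals (social
support, life events, alcohol use). Every model is fitted on training
studies only and evaluated (i) in the combined held-out test studies,
(ii) per test study, and (iii) by 10-fold internal cross-validation of the
training set.

## The fused network and its centrality weights

Models 1–3 need a single partial-correlation network over the 32 baseline
variables that is robust to between-study heterogeneity. We estimate it
with the fused graphical LASSO (FGL): one Gaussian graphical model per
training study, penalised jointly,

$$\min_{\{\Theta_k \succ 0\}}
\sum_k n_k\left[-\log\det\Theta_k + \mathrm{tr}(S_k\Theta_k)\right]
+ \lambda_1 \sum_k \sum_{i \ne j} |\theta^{(k)}_{ij}|
+ \lambda_2 \sum_{k<k'} \sum_{i,j} |\theta^{(k)}_{ij} - \theta^{(k')}_{ij}|,$$

where $S_k$ is study $k$'s within-study-standardized correlation matrix.
The fused edge matrix $W$ is the across-study mean of the per-study
partial correlations $-\theta^{(k)}_{ij}/\sqrt{\theta^{(k)}_{ii}
\theta^{(k)}_{jj}}$. Both penalties are selected by 10-fold
cross-validation (folds stratified by study) maximising the held-out
Gaussian log-likelihood $\sum_k[\log\det\Theta_k -
\mathrm{tr}(S^{\text{holdout}}_k\Theta_k)]$. We deliberately use
cross-validated likelihood rather than an information criterion so the
tuning target matches the prediction objective of the package.

**The solver.** The optimisation is ADMM. The smooth per-study subproblem
has the usual eigendecomposition solution. The proximal step of the
penalty factorises: the pairwise fusion prox is solved *exactly* for any
number of studies $K$ by reduction to isotonic regression — given one
entry's values $a_{(1)} \le \dots \le a_{(K)}$ across studies, the
minimiser of $\tfrac12\sum_k (z_k - a_k)^2 + \tau\sum_{k<k'}|z_k -
z_{k'}|$ is the pool-adjacent-violators fit of $b_i = a_{(i)} + \tau(K +
1 - 2i)$ — followed by elementwise soft-thresholding of the
off-diagonals (the classic fused-LASSO composition result). $K \le 3$ is
fully vectorised. Tests verify the ADMM objective against a brute-force
numerical minimiser on all instances with $p \in \{2,3\}$, $K \in
\{1,2\}$, and the closed-form inverse-correlation solution in the
unpenalised single-study limit.

**Numerical choices.** Convergence is declared when the max-norm primal
and dual residuals fall below `tol` (default `1e-5`; iteration cap 5000,
exceeding it is an error that reports the residuals). The ADMM step
parameter defaults to `max(1, mean(n)/5)`: because the likelihood term is
weighted by the per-study sample sizes, a step on the same scale cuts the
iteration count by more than an order of magnitude relative to a unit
step, with identical solutions (the tests pin this). The sparse `Z`
iterate is returned as the precision estimate; if it is not positive
definite (possible only at extreme penalties) the PD smooth iterate is
substituted.

**Centralities.** One-step expected influence is the signed edge sum
$EI1_i = \sum_j w_{ij}$; two-step adds each neighbour's one-step
influence, $EI2_i = EI1_i + \sum_j w_{ij}\,EI1_j$, *including* the edge
back to the focal node — the standard implementation; the verbal
definition does not exclude back-edges. For model 3, communities come
from Walktrap (random-walk length 4) on the *absolute* edge weights;
negative partial correlations contribute magnitude only, since walk
affinities must be non-negative. The participation coefficient is $PC_i =
1 - \sum_c (\kappa_{ic}/\kappa_i)^2$ on absolute weights; the
participation ratio — for which the literature gives no canonical formula
— is operationalised as the inverse Herfindahl index of a node's
normalised absolute edge weights, i.e. its effective number of
connections; this choice is isolated behind `participation_metrics()`.
Zero-strength nodes get $PC = PR = 0$. If Walktrap returns a single
community, $PC \equiv 0$ carries no information and the statistic
degenerates; the package then uses $PR$ alone for model 3's weights.

**Weight rescaling** is min–max to $[0,1]$, performed *within* each
instrument block (21 items; 8 subscales; 3 auxiliary totals). Global
rescaling would let one instrument's centrality range dominate another's
merely through scale. A consequence worth knowing: the weakest variable
in each block gets weight exactly 0, so the corresponding weighted
predictor can be a constant zero column; `fit_regression()` then excludes
that variable from the model (observed also in published weighted-sum
models, where not every auxiliary score survives into every final model).

## The factor model (model 4)

A unidimensional confirmatory factor model is fitted by maximum
likelihood to the pooled within-study-standardized training data: minimise
$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\log|S| - p$ with $\Sigma(\theta) = \lambda\lambda' + \Psi$ and the
factor variance fixed at 1. Optimisation is L-BFGS-B on $(\lambda, \Psi)$
with analytic gradients from a leading-eigenvector start, so the solution
is deterministic. Residual variances are bounded below at $10^{-4}$;
hitting the bound raises a Heywood flag. The sign convention makes the
majority of loadings positive. Fitting pooled (rather than per-study)
data is a design choice: within-study standardization already absorbs
between-study mean/scale heterogeneity, and a single loading vector is
what the weighting scheme needs. Loadings are converted to weights by the
same block-wise min–max rescaling. Whether the three auxiliary totals
belong in the factor model at all is genuinely open; they are included
for symmetry with models 1–3, so all four weighting schemes weight the
same 32 variables.

## Regressions and the elastic net

Models 1–4 and 6, 8 use OLS (continuous outcome) or logistic regression
(remission; IRLS capped at 100 iterations, non-convergence is an error).
Predictors enter on their natural scale — no extra standardization — so
published coefficients remain directly reusable. The elastic net (models
5, 7) uses coordinate descent via `glmnet` with internal standardization;
the mixing parameter grid is $\alpha \in \{0.05, 0.10, \dots, 1.00\}$
with a 100-value $\lambda$ path auto-scaled from the data, selected by
minimum mean 10-fold cross-validated MSE (gaussian) or deviance
(binomial), with folds stratified by study; the winning pair is refit on
the full training data. Both $\alpha$ and $\lambda$ are searched because
selected values reported for this design in the literature (e.g.
$\alpha = 0.82, \lambda = 0.20$) imply a two-dimensional search.

The null model (9) stores the training outcome mean or remission
proportion and predicts it for everyone.

## Missing data

The policy mirrors standard practice for multi-study prognosis work:

* Baseline variables with **under 30% missing** are imputed; at or above
  that bound a variable is flagged and left untouched.
* Imputation is iterative random-forest regression (the missForest
  algorithm, implemented here over the `ranger` engine): initialise
  missing cells at the observed mean, then cycle over incomplete
  variables in increasing order of missingness, regressing each on all
  other variables plus study membership (100 trees, deterministic seed),
  until the relative sum of squared changes in the imputed values
  increases or 10 iterations are reached. Imputed ordinals are rounded
  onto their valid ranges.
* **Test-set outcomes are never imputed** — nor even shown to the
  test-set imputation model; test patients without an outcome are
  excluded and counted.
* Training outcomes can be imputed (`impute_training_outcome = TRUE`) for
  cohorts where a training study lacks the follow-up measure.

Mask-and-recover tests verify that a duplicated column is recovered to
±0.5 and that recovery RMSE beats the marginal-SD baseline.

## Evaluation

$R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y_{\text{eval}})^2$ is
computed against the *evaluation set's own* mean, so a constant
prediction centred on a different population scores below zero — by
design: the null model's external $R^2$ measures exactly the train/test
distribution shift. RMSE and MAE as usual; AUC by the rank (Mann–Whitney)
formulation with midrank tie correction; Brier score as mean squared
probability error. Internal cross-validation re-runs the pipeline inside
each fold: the fused network is re-estimated and the factor model and
elastic net re-tuned on the fold-complement, and metrics are computed
once on the pooled held-out predictions (pooled-prediction metrics are
stable for $R^2$ where per-fold averaging is not). One concession keeps
the protocol tractable: the FGL *penalty pair* is selected once on the
full training set and reused inside folds — re-selecting it per fold
would nest 10-fold cross-validation inside 10-fold cross-validation
(~5000 ADMM fits) for no qualitative gain; the elastic net, whose tuning
is cheap, is re-tuned per fold (on a slightly coarser default
$\alpha$ grid, `cv_enr_alpha_grid`).

Clinical-relevance summaries: calibration bins of 50 patients sorted by
predicted score (a trailing partial bin is kept and flagged rather than
merged, preserving the bins-of-50 contract for all full bins); observed
remission by predicted severity band — minimal 0–13, mild 14–19, moderate
20–28, severe 29–63, after half-up rounding of predictions (and clamping
to 0–63 with a warning); and the inter-model Pearson correlation matrix
of predictions (the null model's constant vector is flagged `NA`).

## The synthetic cohort generator

Patient-level data from the six primary-care trials this design targets
are not publicly deposited, so the package ships a generator that
emulates their statistical structure, and the whole pipeline is exercised
on it:

* a latent severity factor $\eta \sim N(0,1)$ with per-variable loadings
  (defaults: 0.48–0.70 for depressive items, 0.35–0.55 for anxiety
  subscales, −0.35 for social support, 0.30 for life events, 0.15 for
  alcohol);
* residual item–item dependence from a sparse partial-correlation matrix
  (default: seven within-instrument pairs at 0.15), combined with the
  factor into the latent Gaussian covariance;
* ordinal items by thresholding the latent Gaussians at fixed quantile
  cut-points (matching the graphical-model treatment of items as
  continuous-ized ordinals); auxiliary totals by affine mapping and
  rounding onto their integer ranges;
* between-study heterogeneity as one latent mean shift per study drawn
  from $N(0, 0.15^2)$;
* a follow-up total that is linear in true latent severity and the three
  auxiliary totals plus Gaussian noise (SD 9), rounded and clipped to
  0–63; remission = total ≤ 10;
* a train/test distribution shift: test studies get a latent shift of
  +0.20 and an outcome shift of +2.1 points, derived analytically from
  the target deltas (+≈2.5 baseline points, +≈3.5 outcome points between
  training and test populations); together with the outcome model they
  produce training/test remission rates near 45%/33%;
* missingness: 0.8% MCAR on baseline cells (matching the sub-1% rates
  typical of trial baselines) and 19% missing test outcomes (loss to
  follow-up), exercising the exclusion rule.

The default ("paper-like") fixture has 3 training studies of 575 and 3
test studies of 300. What the generator does *not* emulate: treatment
assignment and treatment effects, item-level response styles,
non-monotone or MNAR missingness, floor effects beyond clipping, and any
nonlinearity in the outcome model. Passing tests therefore demonstrate
correctness of the machinery and the qualitative ordering of models under
a linear single-factor world — not performance on real trial data, where
the paper-level magnitudes (e.g. external $R^2 \approx 0.16$) depend on
unmodelled biology and measurement.

Default problem sizes used in the test suite are scaled to the check
budget: the structural end-to-end check runs the full 575/300 fixture
once; repeated-seed properties (20 seeds) use 200-patient training
studies with the same generating structure, no injected baseline
missingness and a fixed weak penalty pair, which leaves the
signal-vs-null ordering untouched while keeping each run a few seconds.

## Reproducibility

Every stochastic stage (generation, masking, imputation, fold
assignment, elastic-net tuning) derives its seed deterministically from
one master seed; two runs with the same configuration and seed are
byte-identical, and tests assert it. All weight estimation and tuning see
training data only; removing the test set changes no weight and no
coefficient (also asserted).

## Known limitations

* Pearson correlations on 0–3 ordinal items attenuate the latent
  associations relative to polychoric input; the FGL operates on the
  Pearson matrices by design (Gaussian likelihood), so network edges are
  conservative.
* The participation-ratio formula is one defensible reading of a metric
  without a canonical definition; swapping in another definition touches
  a single function.
* The elastic-net `lambda` path is data-adaptive (glmnet's default), so
  selected `lambda` values are comparable within a run but not across
  datasets of different scale.
* With heavy sparsity penalties an entire instrument block can lose all
  its edges, making centrality weights undefined (constant); the package
  raises an informative error rather than inventing weights.
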