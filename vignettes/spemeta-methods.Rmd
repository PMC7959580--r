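---
title: "Models and methods: from local confidence to global self-performance estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from local confidence to global self-performance estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When people decide which of two tasks they are better at, they must
aggregate trial-by-trial feelings of confidence ("local confidence") into a
belief about their overall ability ("global self-performance estimate",
SPE). `spemeta` implements the behavioral side of this question for a
two-alternative square-density discrimination task: a calibration session
establishes each subject's psychometric function; a blocked main task pits
an easy against a difficult version of the discrimination and asks, at the
end of every block, which task the subject would rather repeat; a separate
confidence-rating session measures metacognition directly and anchors a
regression model that is then transferred to the main task, where no
confidence was reported.

Because the package must be testable without human data, its first
component is a generative signal-detection observer whose sessions have
exactly the structure of the experiment. Every analysis in the package is
exercised against data from this observer, for which ground truth is known.

## The generative observer

On a trial with square difference $\delta$ (comparison box holds
$200 + \delta$ of 400 cells, reference 200) and correct side $s \in \{-1,
+1\}$, the observer draws decision evidence

$$e \sim \mathcal{N}\!\left(s\,\delta/\sigma_p,\; 1\right),$$

responds with the sign of $e$ (a random guess with probability
`lapse`, no response with probability `miss_rate`), and forms metacognitive
evidence $m = |e| + \mathcal{N}(0, \sigma_m)$, which five fixed criteria
map to a 1-6 confidence rating. Accuracy at level $\delta$ is therefore
$\Phi(\delta/\sigma_p)$ up to lapses — a cumulative normal through 0.5 at
$\delta = 0$, which is what the calibration fit assumes. Confidence built
on $|e|$ with additive Gaussian noise is the simplest generative mechanism
consistent with the type-2 SDT analyses applied downstream: with
$\sigma_m = 0$ the observer is metacognitively ideal (meta-d$'$ = d$'$,
M-ratio 1), and the M-ratio falls monotonically as $\sigma_m$ grows, which
the test suite verifies by simulation.

Log response time is linear in the evidence strength,
$\log \mathrm{RT} = a - b\,|e| + \mathcal{N}(0, \sigma_{rt})$, clipped to
(200 ms, 1500 ms] so log RT stays finite under the response deadline.

End-of-block task choices are generated by a softmax on the within-block
mean rating difference,
$P(\text{choose } A) = \mathrm{logit}^{-1}\!\big[(\bar{c}_A - \bar{c}_B)/\tau\big]$.
The experiment only measures these choices; how subjects produce them is
not observable, so this rule is a modelling choice. It encodes the view
that each local confidence signal is a sample of evidence about one's
ability at a task, with the temperature $\tau$ controlling how reliably
the accumulated difference drives the choice — and hence the observer's SPE
sensitivity, which the suite confirms is monotonically decreasing in
$\tau$.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `sigma_p` | 12 | square-difference units; places the 70%/85% levels near 6 and 12 squares, inside the printed calibration ladder |
| `lapse` | 0 | the calibration fit also fixes it at 0 by default (see below) |
| `sigma_m` | 0.4 | yields M-ratio ≈ 0.9, inside the range reported for healthy adults |
| `criteria` | 0.5 … 2.5 | spread over the realized range of $|e|$ at the two difficulty levels so all six ratings are used |
| `rt_intercept` | 6.85 | mean RTs ≈ 800 ms (easy) and 865 ms (difficult) |
| `rt_slope` | 0.12 | anchored to the observed easy/difficult RT difference of about 50-65 ms: $\Delta\log \mathrm{RT} \approx 0.064$ over $\Delta|e| \approx 0.55$ |
| `rt_sd` | 0.15 | within-condition RT coefficient of variation ≈ 15% |
| `miss_rate` | 0.02 | human sessions lose a few percent of trials to the deadline |
| `tau` | 1 | easy-task choice frequencies around 60%, comparable to observed behavior |

The RT parameters matter beyond realism: the transfer model predicts
confidence partly from log RT, so `rt_slope`/`rt_sd` set how much
single-trial confidence information RT carries. The defaults make RT a
moderately informative cue, which is required for the documented transfer
contract (median correlation above 0.5 between predicted and latent
confidence) to be attainable at all.

Cohort simulations draw `sigma_p` uniformly in [9, 16], `sigma_m` in
[0.2, 0.8] and `tau` in [0.6, 1.4] to create between-subject variability of
plausible width.

### What the generator does not emulate

Stimulus rendering (only numeric square counts are produced), feedback
effects and learning across the calibration session, serial dependence of
confidence, fatigue, and any systematic response bias (the observer's
type-1 criterion is 0). Passing tests therefore demonstrate that the
estimators recover the truth for a well-behaved stationary observer; they
cannot certify behavior on data with drift, bias or history effects.

## Calibration psychometrics

`fit_psychometric()` maximizes the Bernoulli likelihood of
$P(\text{correct}\mid\delta) = \lambda/2 + (1-\lambda)\,\Phi(\delta/\sigma_f)$
over $\sigma_f$ (log-parameterized, multistart over a fixed grid of eight
scales) with the lapse $\lambda$ fixed at 0 by default; the guess rate is
pinned at 0.5 by the 2AFC structure. A free-lapse variant (bounded at 0.1)
exists for robustness checks. The inversion
$\delta^* = \sigma_f\,\Phi^{-1}\!\big[(p - \lambda/2)/(1-\lambda)\big]$ is
closed-form; extracted levels are rounded to integer square counts because
stimuli are discrete, with a collision between the two targets resolved by
incrementing the easy level. All-correct or all-error calibration data
leave $\sigma_f$ unidentified; the fit is returned flagged rather than
raising an error.

At the study's session size (200 trials) the median relative error of
$\sigma_f$ is below 15%, which the suite measures over 100 replicates; the
residual miss of the accuracy targets after rounding is what the
acceptance checks quantify.

## Type-2 SDT metrics

Ratings are tabulated into the standard 2K-cell response-conditional
layout per stimulus class, with 1/(2K) added to every cell so all z-scores
and likelihoods are finite (raw counts are kept alongside). Type-1 indices
are $d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ and
$c = -\tfrac12\,[z(\mathrm{HR}) + z(\mathrm{FAR})]$.

`fit_metad()` estimates meta-d$'$ by maximizing the multinomial likelihood
of the response-conditional rating counts under a Gaussian observer of
sensitivity meta-d$'$ whose type-1 criterion is held at the scaled position
$c' = c \cdot \text{meta-}d'/d'$ — the dominant convention for this
estimator. Free parameters are meta-d$'$ and $2(K-1)$ type-2 criteria,
kept ordered by optimizing log-increments; the optimizer is a
deterministic three-start BFGS. The M-ratio is meta-d$'/d'$. Because SDT
assumes constant stimulus strength, metrics are estimated per difficulty
condition and averaged. AUROC2 sweeps the $K-1$ confidence thresholds over
the cumulative rating distributions of correct vs incorrect trials and
integrates by trapezoid, with ties handled by the cumulative distributions
themselves.

The 2×2 ANOVA of confidence on Accuracy × Difficulty is formulated as
nested linear-model comparisons (Type-II F tests against the full-model
residual), which keeps it defined for the unbalanced cell counts that
accuracy-based factors necessarily produce.

## The ordinal confidence model and its transfer

Confidence ratings are modelled with a cumulative-link (proportional-odds)
regression: $P(Y \le j \mid x) = F(\zeta_j - x^\top\beta)$, logit link by
default (probit behind a flag; the analyses are link-robust). Features are
the square difference, accuracy and log RT, each z-scored within subject
and session, plus the product of the z-scored difficulty and accuracy
columns. Cutpoints are kept increasing by an increment reparameterization;
initialization is deterministic from the empirical cumulative logits;
unobserved rating categories are collapsed and flagged; complete
separation triggers a small ridge penalty (10⁻⁴) with the fit flagged
non-converged. The implementation is exercised against an independent
proportional-odds fit in the test suite and agrees to the reported digits.

Model comparison fits a grid of candidate regressor subsets per subject
and ranks them by deviance summed over subjects. The default grid is the
seven nonempty subsets of {accuracy, RT, difficulty} plus the full model
with the interaction; an intercept-only model can be added explicitly.

Transfer applies the metacognition-session coefficients to main-session
features, producing a predicted confidence
$\hat{c} = \sum_k k\,P(Y = k \mid x) \in [1, 6]$ (the expected rating; the
modal category is available as an alternative through the probability
matrix). Main-session features are re-z-scored within the session being
scored, so coefficients meet inputs on the scale they were estimated on; a
switch to reuse the metacognition-session scaling exists for sensitivity
analyses. On synthetic subjects this transfer correlates with the latent
ratings the observer would have given (median r > 0.5), is higher on
correct than error trials and on easy than difficult trials, and its
between-task difference predicts the simulated end-of-block choices.

## SPE analyses

Missed trials and trials with log RT beyond 3 SD of the subject's mean
(computed once, no re-iteration) are excluded. Each main-task trial is
labelled higher- or lower-SPE according to whether its task was chosen at
the end of its block. Blocks are summarized per task (accuracy, mean log
RT, mean predicted confidence), and the analyses report: the easy-task
choice frequency (SPE sensitivity), the best-performed-task frequency
(blocks with exactly tied accuracies excluded from the denominator and
counted), the easy-choice frequency split by the sign of the between-task
performance difference (exact ties form the "null" class), a one-sample t
against 0.5 in the null class with its JZS Bayes factor, and paired t
tests between classes with subjects lacking a class excluded and reported.

The task-choice logistic predicts choice of the first-cued task from the
first-minus-second differences in difficulty and realized accuracy
(z-scored within subject) and their product; this coding makes
coefficients sign-interpretable and symmetric under task relabeling, which
the experiment's own description of its predictors leaves open. The
choice-model deviance comparison fits, per subject, a logistic regression
of the same outcome on a single between-task difference — predicted
confidence, accuracy, or log RT — and sums $-2\log L$ across subjects.
Separation in any logistic fit falls back to a ridge penalty (10⁻⁴) and is
flagged.

The JZS Bayes factor uses the default Cauchy prior (scale $\sqrt{2}/2$) on
the standardized effect, computed by adaptive quadrature over the
variance-ratio parameter with the null likelihood factored out for
stability; the suite checks it against a fine fixed-grid quadrature to 1%.

## Numerical choices and degenerate inputs

* Cell padding 1/(2K) is applied uniformly before all SDT computations.
* Probabilities inside likelihoods are floored at 10⁻¹² before logs.
* Block task sequences are rejection-sampled with a cap of 10⁴ draws;
  an unsatisfiable run constraint is a design error, not a hang.
* Missing inputs fail fast with the offending rows named; degenerate but
  interpretable inputs (all-correct calibration, one-class AUROC2,
  constant features) return flagged results instead of errors.
* All simulation entry points take explicit seeds; cohort subjects get
  seeds derived from the master seed by a fixed stride, so any subject can
  be regenerated in isolation.

## Problem sizes

The bundled analysis scripts simulate 40 subjects at the study's session
sizes (200 calibration trials, 32 × 12 main trials, 200 rating trials).
Test-suite simulations use between 200 and 10⁵ trials per check: parameter
recovery and oracle agreement run at sizes where Monte-Carlo error is well
below the asserted tolerance, and replicate counts (50-100) match the
documented property statements.

## Known limitations

* Group-level metacognition is summarized by means of per-subject point
  estimates; hierarchical (partial-pooling) estimation of meta-d$'$ is out
  of scope.
* The proportional-odds model assumes a common coefficient vector across
  cutpoints; the generator satisfies this only approximately, which is the
  realistic situation for human data too.
* The transfer's re-z-scoring assumes the main session provides enough
  trials for stable within-session moments; with very few usable trials
  the metacognition-session scaling switch is the safer choice.
* Exact accuracy ties define the null performance class; with six trials
  per task ties are common, so the null-class tests have appreciable n in
  synthetic cohorts.
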