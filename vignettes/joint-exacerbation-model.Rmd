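---
title: "Joint modelling of exacerbation rate, duration and severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of exacerbation rate, duration and severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsjoint)
```

## The model

Many chronic diseases — asthma, COPD, multiple sclerosis, cystic fibrosis —
progress through recurrent flare-ups (exacerbations).  Their burden has three
dimensions: how *often* episodes occur, how *long* they last, and how
*severe* they are.  `rdsjoint` treats a patient's follow-up as an alternating
two-state process (exacerbation-free vs. in-exacerbation) and models the
three dimensions jointly.

For patient $i$ with $M_i$ observed episodes over follow-up $T_i$, write
$B_{i,j}$ for the $j$-th between-exacerbation gap time (from the previous
termination, with the initial gap measured from randomization), $W_{i,j}$
for the episode duration, and $S_{i,j} \in \{0,1\}$ for binary severity.
The four submodels are:

* **Rate** (between-gaps): an accelerated failure time (AFT) model with an
  additive subject random effect,
  $\log B_{i,j} = x_{i,j}^\top\beta_B + Z_{B,i} + \epsilon_{i,j,B}$.
  Equivalently the hazard is
  $h(t) = \theta\, h^0_B(\theta (t - V_{i,j-1}))$ with
  $\theta = e^{-\eta}$, so $e^{\beta}$ multiplies the expected gap time
  (the *AFT factor*): an AFT factor above 1 means fewer events.
* **Duration** (within-gaps): a second AFT model with its own random
  effect, $\log W_{i,j} = x_{i,j}^\top\beta_W + Z_{W,i} + \epsilon_{i,j,W}$.
* **Severity**: logistic regression with a random effect,
  $\operatorname{logit} P(S_{i,j}=1) = x_{i,j}^\top\beta_S + Z_{S,i}$.
* **Zero inflation**: a latent non-susceptible class with probability
  $\operatorname{logit} \pi_i = x_{i,0}^\top\beta_{ZI}$ on baseline
  covariates only, analogous to a cure fraction; it explains the excess of
  patients with no events and carries no random effect.

$Z_i = (Z_{B,i}, Z_{W,i}, Z_{S,i})$ is mean-zero trivariate normal with an
unstructured covariance $\Sigma_Z$ (3 SDs, 3 correlations).  The random
effects produce within-subject autocorrelation in each outcome and, through
their correlations, the interdependencies among rate, duration and severity
(e.g. whether frequent exacerbators have longer or shorter episodes).
Conditional on $Z_i$, the $B$'s are independent of the $(W, S)$ pairs and
$W$ is independent of $S$.

### Baseline families and their parametrization

Each gap submodel chooses a residual law for $\epsilon = \sigma\xi$
(`shape` $= \sigma$, the residual scale of log-time):

| family | $\xi$ | implied gap law |
|---|---|---|
| `lognormal` | standard normal | log-normal |
| `loglogistic` | standard logistic | log-logistic |
| `weibull` | minimum extreme value | Weibull with shape $1/\sigma$ |
| `exponential` | minimum extreme value, $\sigma \equiv 1$ | exponential |

The linear predictor carries an explicit intercept (the log-scale location),
so `shape` is purely a scale parameter and one number per submodel.  The
within-gap laws are continuous, so tied or zero gaps are rejected on input
(minimum gap $10^{-8}$ days).  Times are handled in days internally; AFT
factors are unit-free, so the choice is inert in the reports.

### Censoring conventions

Dropout is assumed independent of the gap and severity processes.  By the
case-study convention, only the final between-gap is censored: a patient in
an exacerbation at the end of nominal follow-up is followed to that
episode's termination (the simulator reproduces this, leaving a final gap of
0).  A `within_censored` flag per episode nevertheless supports data where
within-gaps are censored.  The first between-gap is measured from
randomization with no left-truncation correction — a deliberate
simplification; it is benign when the baseline hazard of the rate submodel
is roughly constant, which the fitted shape lets you inspect, but it is a
modelling caveat for strongly time-varying baselines.

## Likelihood and integration

Given $Z_i = z$, a subject contributes AFT log-densities for observed gaps,
an AFT log-survival term for the censored final gap, and Bernoulli terms for
severities.  The marginal likelihood integrates $e^{\ell_i(z)}$ over the
trivariate normal; the zero-inflation mixture sits *outside* that integral:
subjects with events contribute $(1-\pi_i) E_Z[e^{\ell_i(Z)}]$, subjects
without events $\pi_i + (1-\pi_i)E_Z[e^{\ell_i(Z)}]$.

The integral uses tensor Gauss–Hermite quadrature, by default **adaptive**
with 5 points per dimension (125 nodes): the grid is recentred at the
subject's posterior mode of $Z$ and rescaled by the inverse square root of
the negative log-posterior Hessian.  Numerical choices worth knowing:

* For subjects with no events the conditional likelihood depends only on
  $Z_B$, so the integral collapses *exactly* to one dimension (5 nodes
  instead of 125 — roughly half the subjects in a zero-inflated cohort).
* The integral is computed in whitened coordinates $z = Lv$,
  $L = \operatorname{chol}(\Sigma_Z)$, $v \sim N(0, I)$.  No precision
  matrix is formed, so the likelihood stays accurate when the optimizer
  visits near-singular covariances (correlations near $\pm 1$).  The
  conditional log-likelihood is concave in $z$ for all four families, so
  the whitened Newton mode search (negative Hessian $I - L^\top D L$ with
  $D \le 0$) is globally convergent.
* Log-sum-exp is used in the quadrature sum and the mixture, so subjects
  with many episodes do not underflow.
* A fixed (prior-centred) rule is available (`quad_mode = "fixed"`), and is
  the automatic fallback in the rare case the adaptive Hessian is not
  numerically positive definite.

At the default 5 points per dimension, moving to 9 points changes the
dataset log-likelihood by about one part in $10^6$ under the default study
conditions (the absolute change on a 1000-subject sum is of order
$10^{-3}$); 9 versus 15 points differ by less than $10^{-4}$ absolute.  The
unit tests verify the quadrature against brute-force Monte-Carlo
integration with 20,000–200,000 draws.

## Estimation

`rds_fit()` maximizes the marginal likelihood over an unconstrained
parameter vector: coefficients, $\log$ shapes, $\log$ RE standard
deviations, and the RE correlation matrix through tanh-transformed canonical
partial correlations of its Cholesky factor (every real vector maps to a
valid correlation matrix).  Stage-wise starting values come from standard
fixed-effects fits (`survival::survreg` for the two gap submodels,
`stats::glm` for severity and for the any-event indicator of the
zero-inflation component), with RE SDs starting at 0.5 and correlations at
0; the stage-wise AFT scale hands its starting RE variance back to the
residual scale.

BFGS with a forward-difference gradient (posterior modes recycled between
neighbouring evaluations) is followed by Newton polishing steps using the
central finite-difference observed information; the same matrix supplies
the variance-covariance of the estimates.  Convergence requires a gradient
max-norm below $10^{-5}$ and a relative log-likelihood change below
$10^{-9}$ (at most 500 BFGS iterations); fits that miss the tolerances are
returned flagged, never silently.  Wald 95% intervals are computed on the
unconstrained scale and back-transformed: exponentiated for coefficients
(AFT factors and odds ratios) and shapes/SDs, and through $\tanh$ for
correlations, so correlation limits always lie in $(-1, 1)$.  AIC is
$-2\ell + 2k$ with $k$ counting all free parameters of the configured
model; `select_family()` ranks candidate baseline families by AIC with ties
broken toward the more parsimonious family.  Significance flags in the
report are at the 0.05 level with no multiplicity adjustment —
presentation only.

Quick exploratory fits can pass `hessian = FALSE` to skip the observed
information; they then report convergence from the optimizer status alone,
since the gradient criterion needs the polishing step.

Covariates are used on their raw scales; nothing in the pipeline assumes
centring or scaling.  `standardize_covariates()` is available for users who
prefer per-SD coefficients (it records the centres and scales used, and the
maximized likelihood is invariant to the reparametrization).

## Prediction

* `empirical_bayes()` returns the posterior mode of $Z_i$ given the
  subject's data (the usual empirical-Bayes predictor for nonlinear mixed
  models; the mode, not the mean).  For subjects with no events only $Z_B$
  is identified, and its posterior includes the zero-inflation mixture
  $[\pi_i + (1-\pi_i)S(T_i \mid z)]\phi(z)$ — omitting the mixture would
  bias every zero-event subject's $\hat z_B$ upward.
* `marginal_mean_gap()` uses the closed-form moments
  $E[T] = e^{x^\top\beta} E[e^\epsilon] E[e^{Z}]$ with
  $E[e^\epsilon] = e^{\sigma^2/2}$, $\Gamma(1+\sigma)$ or
  $\pi\sigma/\sin(\pi\sigma)$ (log-normal / Weibull / log-logistic; the
  last diverges for $\sigma \ge 1$ and is reported as `Inf`).  Passing an
  empirical-Bayes $\hat z$ gives the subject-conditional mean instead;
  both flavours are exposed because "marginal predicted mean" is ambiguous
  between them, and neither is labelled canonical.
* `marginal_cdf_curve()` averages the RE-integrated conditional CDF over
  the covariate rows realized in the data ("averaged over the predictors");
  `empirical_cdf_curve()` is one minus the Kaplan–Meier estimate on the
  pooled gap times, with censored final gaps entering as censored.  For
  the between-gap curve the zero-inflation class is conditioned away by
  default (`zi_conditional_cdf`), since the observed pooled gaps are
  dominated by event gaps; the unconditional variant (each row weighted by
  $1-\pi_i$) is a switch away.

A caution for the curve comparison: pooled gap times over-represent
subjects with many episodes.  Because episode count is driven by $Z_B$,
and $Z_B$ is correlated with $Z_W$ and $Z_S$, the pooled empirical curve is
a *selected* mixture while the fitted curve integrates the prior RE law.
Under the default study conditions (correlations 0.40–0.45) this produces a
systematic sup-distance of roughly 0.07–0.10 between the two curves even
when the model is exactly true (about 0.03 with uncorrelated REs).  The
goodness-of-fit test therefore uses a sup-distance band of 0.15 at ~2000
pooled gaps: the systematic component plus clustered sampling noise.  The
curves are a visual adequacy check, not a formal test.

## The synthetic-data generator

`simulate_subject()` draws baseline covariates, the non-susceptibility
indicator, $Z_i \sim N(0, \Sigma_Z)$ and an independent exponential dropout
time, then alternates between-gap and within-gap draws (inverse-CDF
sampling on the log scale, exact for all four families) until the end of
follow-up, reproducing the censoring conventions above.  Episode-specific
covariates $N$ (previous episodes) and $N_S$ (previous severe episodes) are
derived during generation with exactly the rule the fitter uses
($N = j-1$, $N_S$ = severe count among episodes $1..j-1$; final censored
gap: $N = M_i$, $N_S$ = total), closing the loop between generator and
fitter.

`default_case_study_config()` is the standard fixture: a two-trial pooled
cohort structure with ~1100 subjects, 52- and 32-week nominal follow-up
strata, dropout hazard $4\times10^{-4}$/day (~10% withdrawal over a
0.78-year mean follow-up), covariates `trt` (Bernoulli 0.5), `age_dec`
(N(4.9, 1.3²) — age in decades) and `female` (Bernoulli 0.6), log-normal
families with shapes 1.22 (rate) and 0.62 (duration), RE SDs
(0.8, 0.5, 1.5) with correlations (0.40, 0.45, 0.45), a treatment AFT
factor of 2.0 on the rate submodel, and a zero-inflation component
(intercept −1.1, i.e. $\pi \approx 0.25$ at reference covariates).  The
rate intercept (4.3 on log-days, a median untreated gap of ~180 days
before frailty) was calibrated once so that about half the cohort has no
events — echoing cohorts where a small majority of patients are event-free
— and the remaining coefficients are plausible small effects on the scales
of such trials.  These values are fixed study conditions for the tests,
not tuning knobs.

What the generator deliberately does *not* emulate: real covariate
correlation structures, time-varying covariates within follow-up,
measurement error in onset/termination dates, informative dropout, and
competing risks.  Passing tests on these data therefore show that the
estimator inverts its own generative model (consistency, calibrated Wald
coverage, family identification) — not that the model is adequate for any
particular real cohort.

## Verification strategy and problem sizes

The test suite checks, among other things: closed-form values of every
density/survival/hazard; unit integrals by numerical quadrature; the exact
AFT factor property $S(t \mid \eta + \beta) = S(te^{-\beta} \mid \eta)$;
agreement of the compiled likelihood with a plain-R reference and with
Monte-Carlo integration; collapse of the joint likelihood onto
`survreg`/`glm` fits when REs and zero-inflation are disabled (to $10^{-4}$);
Wald coverage of all generating parameters over 5 replicate fits at
$n = 1000$ (pooled coverage ≥ 0.85 with every parameter covered in at
least 3 of 5 — the binomially sensible gate at this replicate budget);
AIC selection of the generating log-normal family in at least 4 of 5
replicates at $n = 250$; and the Kaplan–Meier closure described above at
$n = 2500$ subjects.  These sizes keep the full suite within a
workstation-scale run while leaving the statistical gates meaningful.

## Known limitations

* Parametric baseline hazards only — no splines or piecewise-constant
  baselines; if no family fits, the model mis-specifies the gap laws.
* Binary severity; ordinal severity would need a different severity
  submodel.
* No competing risks (e.g. death) and no left-truncation correction for
  the first gap.
* Normal random effects; heavy-tailed or multimodal heterogeneity is
  absorbed, not represented.
* Out-of-sample predictive performance is not evaluated — predictions are
  in-sample empirical-Bayes summaries.

## A worked example

```{r example, eval = FALSE}
cfg <- default_case_study_config(600)
dat <- simulate_dataset(cfg, seed = 7)
fit <- rds_fit(dat, cfg$model_config)
print(fit)
pred <- predict_subjects(dat, fit)
head(pred)
```
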