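---
title: "Group testing regression with Bayesian additive regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group testing regression with Bayesian additive regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtbart)
```

## The problem

In disease surveillance by group testing, specimens are pooled and the pool
is assayed; individuals in negative pools are cleared at the cost of a single
test, while positive pools may be resolved by further testing.  Regression
analysis of such data is awkward for two reasons: the individual true disease
statuses $\tilde Y_i$ are never observed directly, and the assays themselves
misclassify.  `gtbart` estimates the individual-level probability-of-disease
surface

$$\Phi^{-1}\{P(\tilde Y_i = 1 \mid x_i)\} = f(x_i)$$

without assuming a functional form for $f$, by approximating it with a sum of
$K$ regularized regression trees,
$f(x) \approx \eta(x) = \sum_{k=1}^K g(x; T_k, M_k)$, and it simultaneously
estimates the assay sensitivities and specificities per test stratum.  A
parametric probit GLM fitted with the identical latent-variable machinery
(`gt_glm()`) is included as the natural first-order comparator: it is exactly
the model a practitioner would reach for, and it is correctly specified only
when $f$ is linear.

## Data model

A data set (`group_testing_data()`) consists of $J$ binary test responses
$Z_j$, the pool index sets $\mathcal P_j \subseteq \{1..N\}$ (pools may
overlap; an individual may be retested), a stratum label per test, and the
covariate matrix $X$.  The true status of a pool is
$\tilde Z_j = I(\sum_{i \in \mathcal P_j} \tilde Y_i > 0)$, and responses are
conditionally independent given the true statuses with
$P(Z_j = 1 \mid \tilde Z_j) = Se_{(l)} \tilde Z_j + (1 - Sp_{(l)})(1 -
\tilde Z_j)$ for test $j$ in stratum $l$.  Strata group tests that share one
$(Se, Sp)$ pair — e.g., pooled swabs versus individual retests; the mapping
from laboratory factors to strata is deliberately left to the caller.

Each stratum's accuracies are either known constants or carry independent
$beta(a_e, b_e)$, $beta(a_p, b_p)$ priors (uniform by default) and are
estimated.  Identifiability comes from protocols that retest: with Dorfman
data, a positive master pool whose members all retest negative is evidence
about error rates in both stages.  Under one-shot protocols (IT, MPT) with
flat priors there is essentially no information about the accuracies, so
they should be treated as known there.

## Posterior computation

The sampler augments twice, which restores conjugacy everywhere:

1. the latent statuses $\tilde Y_i$, each drawn from its closed-form full
   conditional — a Bernoulli whose odds multiply the probit prior
   $\Phi(\eta_i)$ by the likelihood of every test containing $i$, where a
   test's factor depends on whether any *other* member is currently positive
   ($s_{ij} > 0$); the per-pool positive counts are maintained incrementally
   during the sequential sweep;
2. probit latents $\omega_i \sim N(\eta_i, 1)$ truncated to $(0,\infty)$ or
   $(-\infty, 0]$ according to $\tilde Y_i$.

Given $\omega$, the trees see a unit-variance Gaussian regression problem and
are updated by Bayesian backfitting: for each tree, partial residuals
$r_i = \omega_i - \eta_i + g_k(x_i)$ are formed, one structural
Metropolis–Hastings move is attempted (GROW 0.25, PRUNE 0.25, CHANGE 0.40,
SWAP 0.10, renormalized over the moves available in the current state), the
acceptance ratio combines the integrated leaf likelihood, the tree prior and
the proposal ratio, and all leaf values are then redrawn from their normal
full conditionals.  Finally the accuracies of every unknown stratum get
conjugate beta draws from the counts of (observed, imputed-true) test
outcomes.  All four updates run in compiled code; every random number comes
from R's RNG, so `set.seed()` (or the `seed` arguments) makes entire fits
bit-reproducible.

Numerical choices worth knowing:

* status full conditionals are computed in log space with max subtraction —
  an individual can appear in arbitrarily many tests;
* one-sided truncated normal draws use plain rejection near the bulk and an
  exponential-envelope rejection in the tail, stable beyond $|\eta| = 10$
  (inverse-CDF sampling fails far earlier);
* the cached $\eta$ vector is refreshed from the trees every 256 sweeps to
  rule out incremental drift (tests assert draw-by-draw agreement with the
  stored ensembles at `1e-10`);
* cutpoint candidates are the unique observed values per covariate; a
  structural proposal that would leave a training-empty leaf is rejected
  outright, keeping the integrated likelihood well defined.

## Priors and tunable parameters

* `K` — number of trees; 20 and 200 are the customary configurations.  With
  small `K` covariates compete for splits, which is what makes the variable
  inclusion proportions interpretable.
* tree shape — a node at depth $d$ splits with probability
  $\alpha(1+d)^{-\beta}$, defaults $\alpha = 0.95$, $\beta = 2$ (favours 2–3
  leaves); split variable uniform, cutoff uniform over the observed values.
* leaf scale — $\mu_{kt} \sim N(0, \sigma_\mu^2)$ with
  $\sigma_\mu = 3/(H\sqrt K)$, $H = 2$.  One source prints the
  non-canonical $3/(HK)$; at $K = 200$ that shrinks the achievable signal to
  $\pm 0.015$ per tree and the ensemble cannot reach probit scores of
  $\pm 3$, so the $\sqrt K$ form is the default and the printed form remains
  available (`tree_prior(..., sigma_mu_form = "printed")`).
* accuracy priors — per-stratum beta hyperparameters, uniform by default;
  strata flagged `known` are never updated (verified bit-exactly in tests).
* chain length — defaults 2500 burn-in + 2500 retained, thinning 1.
  Convergence is reported (acceptance rates per move; draws for trace
  plots), not auto-enforced.

## Initialization (a deliberate deviation)

Two initialization rules differ from the obvious ones, and they matter.  The
posterior under diffuse accuracy priors is multimodal: besides the truth
there is a label-switched mode in which prevalence is high and the assay is
nearly useless ($Se \to 0$ explains every negative retest).  Initializing
every member of a positive master pool at $\tilde Y = 1$ starts Dorfman
chains at the master-pool positivity rate (~3 times the true prevalence),
and initializing $Se, Sp$ at uniform-prior means (0.5) makes the first
status sweep ignore the data entirely; together they reproducibly trap the
chain in the wrong mode.  `gtbart` therefore (a) starts an individual
positive only if it was tested and *all* tests containing it were positive —
a negative retest overrides its positive master pool — and (b) gives the
unknown accuracies one conjugate refresh from those initial statuses before
the first sweep (equivalent to running the accuracy update first in the
initial scan).  Neither changes the stationary distribution; both determine
which basin the chain starts in.

## The synthetic world

The simulators (`gt_simulate()`, `run_simulation_study()`) reproduce a
standard simulation design: $Q = 3$ covariates with $x_1, x_2 \sim
\mathrm{uniform}(0, 10)$ and $x_3 \sim \mathrm{Bernoulli}(0.5)$; three true
surfaces — M1 $\sin(\pi x_1) - 1.25$ (sharply non-linear, one active
covariate), M2 $-0.85 + 0.55x_1 - 1.25x_2 - 0.35x_3$ (linear; the GLM's home
turf), M3 $-\sin(x_1/3) - x_1x_3 + x_3$ (smooth non-linearity plus an
interaction; $x_2$ inactive) — all giving population prevalences around
0.15–0.18; master pools of size 4 assigned by random permutation (a
remainder pool stays in the same stratum); and three protocols: individual
testing, master pool testing, and two-stage Dorfman testing in which every
member of an *observed*-positive master pool is retested individually in a
second stratum.  Default generating accuracies are $Se = (0.95, 0.98)$,
$Sp = (0.98, 0.99)$ for the two Dorfman strata.  One master seed drives
derived streams for statuses, pooling and test noise, so different
protocols can be compared on identical populations.

The typography of M3 is ambiguous in its source ("sin x_i1 3"); this package
reads the argument as $x_1/3$, which is smooth over $(0, 10)$; the
`model = "custom"` hook lets a user test the $3x_1$ reading.

What the generator does *not* emulate: covariate-dependent misclassification,
dilution effects in large pools, correlated statuses (household structure),
or missing covariates.  A green simulation test therefore establishes
correctness of the sampler under the stated model, not robustness to those
violations.

## Verification strategy and known limitations

The primary correctness oracle is exhaustive enumeration: on instances with
$N \le 8$ the joint posterior of the latent statuses is computed exactly by
summing the misclassification likelihood over all $2^N$ configurations, and
long status-only Gibbs runs are required to match it within Monte-Carlo
error (batch-means standard errors).  Conjugate pieces — leaf full
conditionals, the integrated tree likelihood, the GLM coefficient update —
are checked against numerical quadrature and dense linear algebra to
$10^{-6}$ or better.  The tree proposal kernel is checked by running it with
a constant likelihood and comparing visit frequencies against closed-form
prior probabilities of enumerated small trees, and the GROW acceptance ratio
is verified against a hand-computed value on a one-cutpoint problem.

One scaled-down acceptance check fails honestly and deserves explanation: in
the Dorfman accuracy-recovery experiment at $N = 1000$ (a fifth of the
reference scale) the averaged posterior mean of the *stage-1 sensitivity* is
about 0.89–0.90 against a generating value of 0.95, while the other three
accuracy parameters land within ±0.015.  This is not a sampler defect: a
probit GLM handed the true surface $f(x)$ as its only covariate — correctly
specified by construction — produces the same value at $N = 1000$, and both
it and the BART fit recover 0.95 at the reference $N = 5000$.  With only
~250 master pools, the uniform prior and the feedback between imputed
statuses in untested (observed-negative) pools and the sensitivity draw
shift the posterior mean low; the information that pins $Se(1)$ grows with
the number of master pools.  The corresponding test asserts the stated
±0.02 band unchanged and is expected red for that one parameter.

## Reported summaries

`variable_inclusion()` computes $v_q = S^{-1}\sum_s z_{qs}/z_{\cdot s}$, the
mean share of decision rules splitting on covariate $q$; a draw whose
ensemble is all stumps ($z_{\cdot s} = 0$) contributes the uninformative
$1/Q$ to every covariate so $v$ stays a proper distribution (the source is
silent on this 0/0 case).  `predict_prob()` returns posterior means and
equal-tail quantiles of $\Phi(\eta(x))$; `auc_rank()` is the Mann–Whitney
AUC with ties counted ½, computed against simulated true statuses (with
real data, statuses are latent and an ROC analysis is not available —
out of scope here, as is any real-data likelihood comparison).
`coverage_rate()` and `run_simulation_study()` assemble the replicate-level
recovery and classification tables; replicate $r$ derives its seeds from
`seed + r`, so the full table is reproducible bit-exactly.
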