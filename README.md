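# gtbart — Bayesian regression trees for group testing data

`gtbart` estimates an individual-level probability-of-disease surface from
**group (pooled) testing data** — the screening design used for chlamydia,
HIV, SARS-CoV-2 and other low-prevalence infections, where specimens are
tested in pools and individual true statuses are never observed directly.
It is written for biostatisticians analysing surveillance data from pooling
protocols (individual testing, master pool testing, two-stage Dorfman
testing, or arbitrary overlapping pools from file) with possibly
misclassified assays.

## The model

True statuses follow a probit regression with an unknown surface,

    Phi^{-1}{ P(Y~_i = 1 | x_i) } = f(x_i)  ≈  eta(x_i) = sum_{k=1}^K g(x_i; T_k, M_k),

a sum of K regularized regression trees (BART).  Observed pool responses
Z_j are linked to the latent pool statuses Z~_j = I(sum_{i in P_j} Y~_i > 0)
through per-stratum sensitivities and specificities,
P(Z_j = 1 | Z~_j) = Se(l) Z~_j + (1 − Sp(l))(1 − Z~_j), which can be fixed
or estimated with conjugate beta priors.  Posterior sampling is a full
Gibbs scheme with two-stage data augmentation (latent statuses, then
truncated-normal probit latents), Bayesian backfitting for the trees
(GROW/PRUNE/CHANGE/SWAP Metropolis–Hastings with integrated leaf
likelihoods), and stratified beta updates for the accuracies.  A
first-order Bayesian probit GLM comparator (`gt_glm()`) shares the identical
latent machinery.  The compute core is C++ (Rcpp/RcppArmadillo).

## Worked example

Simulate Dorfman testing (master pools of 4, individual retests of observed
positive pools) from the interaction surface `M3`, then estimate the surface
and all four accuracy parameters from uniform priors:

```r
library(gtbart)
sim <- gt_simulate("M3", N = 1000, pool_size = 4, protocol = "DT", seed = 2024)
sim$data
#> Group testing data: 1000 individuals, 842 tests, 2 strata, 3 covariates
#>   pool sizes 1-4; 326 positive tests

acc <- assay_accuracy(c(0.95, 0.98), c(0.98, 0.99), known = FALSE)  # uniform priors
fit <- gt_bart(sim$data, acc, K = 20, n_burn = 1000, n_keep = 1000, seed = 7)
accuracy_summary(fit)
#>   stratum parameter  mean lower upper known
#> 1       1        Se 0.954 0.870 0.998 FALSE
#> 3       1        Sp 0.967 0.911 0.999 FALSE
#> 2       2        Se 0.960 0.908 0.997 FALSE
#> 4       2        Sp 0.996 0.984 1.000 FALSE

round(variable_inclusion(fit), 3)
#>    x1    x2    x3
#> 0.384 0.193 0.423
auc_rank(fit$prob_train_mean, sim$truth$y_true)
#> [1] 0.873
```

The generating accuracies were Se = (0.95, 0.98), Sp = (0.98, 0.99): all
four posterior means land close with 95% intervals covering the truth.  The
inclusion proportions identify `x1` and `x3` (the two covariates `M3`
actually uses) as the dominant splitters; the in-sample AUC of 0.87 is
computed against the simulated true statuses.  `predict_prob(fit)` returns
per-individual posterior means and equal-tail bands of `Phi(eta(x))`, and
`run_simulation_study()` drives the full replicate × protocol × method
recovery table.

## Command line

```sh
inst/cli/gtbart simulate --model M3 --n 1000 --protocol DT --seed 1 --out data/run1
inst/cli/gtbart fit --data data/run1 --trees 20 --burn 1000 --keep 1000 --seed 2 --out post/
inst/cli/gtbart summarize --posterior post/ --out report/
inst/cli/gtbart study --config study.json --out study_out/
```

Every subcommand writes a `manifest.json` (config echo + package version +
seed) alongside its outputs.

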