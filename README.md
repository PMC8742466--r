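# pleiosgl

Sparse group multi-task logistic regression for detecting **pleiotropic
genetic signals** across independent case-control studies.

## What it does

Given K independent case-control studies that share one panel of p variables
(SNP dosages grouped into genes or pathways), `pleiosgl` fits the K logistic
regressions *jointly* by minimising

```
  l(B)  +  lambda*(1-alpha) * ||B||_{G2,1}  +  lambda*alpha * ||B||_{l2,1}
```

where `l(B)` is the summed negative log-likelihood of the studies, `B` is
the p × K coefficient matrix, `||B||_{G2,1} = sum_g sqrt(n_g) * ||B_g||_F`
penalises whole gene/pathway blocks and `||B||_{l2,1} = sum_i ||B_i.||_2`
penalises variable rows across studies. Because both norms couple the
studies, selection is shared across them — exactly the pleiotropy question.
Setting `alpha = 0` gives group-only selection (GMT), `alpha = 1`
variable-level selection (SMT), and intermediate values the sparse-group
compromise (SGMT); the single-study special case (SGST) is the baseline.

The solver is ADMM with a damped-Newton inner step and an exact sparse-group
proximal operator; tuning is repeated stratified cross-validation with the
one-standard-error rule; stability comes from bootstrap selection
frequencies; and a four-scenario simulation benchmark with planted effects
of magnitude 0.8 (concordant and discordant across studies) scores TPR, TNR,
Matthews correlation and l1/l2 reconstruction error at variable and group
level.

Intended users: statistical geneticists and biostatisticians analysing
multiple GWAS-style case-control datasets with gene or pathway annotation.

## Worked example

```r
library(pleiosgl)

# a small synthetic two-study dataset: 2 of 80 variables active (effect 0.8),
# 4 groups of 20, 50 samples per study
scn <- simulation_scenario(1)
sim <- simulate_dataset(scn, seed = 2)

# tune the sparse multi-task model (alpha = 1) by 5-fold CV
grid <- cv_grid(alphas = 1, n_folds = 5, seed = 2)
cv <- cross_validate(sim$data, sim$groups, grid)
print(cv)
#> Cross-validation over 1 alpha value(s) x 30 lambda value(s)
#>   min rule: alpha = 1, lambda = 2.473 (mean deviance 0.8822)
#>   1se rule: alpha = 1, lambda = 3.397

fit <- admm_fit(sim$data, sim$groups,
                penalty_config(cv$best_1se$lambda, alpha = 1))
print(fit)
#> Sparse group multi-task fit (lambda = 3.397, alpha = 1)
#>   selected: 17 variables in 4 groups
#>   objective 47.3955; converged in 42 iterations
```

At n = 100 and p = 80 the single fit is noisy: the two planted variables
are selected, along with 15 spurious ones whose coefficient rows are small.
Bootstrap stability separates them — refitting on 200 stratified resamples
at the same tuning parameters, only the planted pair survives in every
resample:

```r
bs <- bootstrap_frequencies(sim$data, sim$groups,
                            penalty_config(cv$best_1se$lambda, 1),
                            M = 200, seed = 2)
sim$data$variable_ids[select_strict(bs)$variables]
#> [1] "snp0001" "snp0002"
round(bs$variable_freq[1:4], 3)
#> snp0001 snp0002 snp0003 snp0004
#>   1.000   1.000   0.505   0.135
```

A command-line wrapper for file-based workflows (TSV dosage matrices +
group map) lives at `inst/cli/pleiosgl.R` with subcommands `fit`, `cv`,
`bootstrap` and `simulate`.

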