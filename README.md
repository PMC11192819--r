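# recalleval

Do people evaluate an experience from the episodes they can actually recall
of it, or from the experience itself? `recalleval` implements a complete
simulation-and-analysis pipeline for a paradigm that asks this question
directly: participants watch sequences of seven numerical values in a
fictitious currency (Galactic Credits, GC), freely recall the values, and
bid for another draw from the sequence in an incentive-compatible
Becker-DeGroot-Marschak (BDM) auction. Because memoranda and evaluations
are both numeric, the recalled sample and the bid can be linked trial by
trial.

The package is aimed at researchers in memory-based decision making who
want to simulate the paradigm, fit its candidate evaluation models, and
validate the model comparison machinery.

## The models

Willingness to pay (WTP) on trial *i* of participant *j* is modelled as a
Bayesian hierarchical regression

    bid_ij ~ Normal(b0 + u_j + sum_k beta_k * x_ijk, sigma),   u_j ~ Normal(0, tau)

where the candidate predictors x are:

- **Recalled items** — the mean of all values reported on that trial,
  intrusions included;
- **Presented items** — the mean of the seven presented values (the true
  sequence value);
- **Temporal difference** — a recency-weighted running value
  `V <- V + alpha * (x_t - V)` with learning rate `alpha ~ Uniform(0,1)`;
- **Mixture** — each trial latently generated by the recalled-only,
  presented-only, or both regression, with per-participant weights
  `theta_j` on the simplex (flat Dirichlet prior), used to classify
  individual strategies.

Single-predictor models are compared by bridge-sampling marginal
likelihoods (Bayes factors); a model-recovery experiment (simulate from
each model, refit all, tally winners) validates that the comparison can
identify the true generator. Priors and sampler settings follow the
reference analysis (slope N(1, 0.5), intercept N(0, 10), group spread
half-t(3, 0, 10), R-hat gate at 1.05). Sampling runs in JAGS via `rjags`;
the bridge sampler and the JZS (Cauchy-prior) Bayes-factor t test are
implemented in the package and tested against analytic and Monte-Carlo
oracles.

## Worked example

```r
library(recalleval)

# a synthetic experiment: 12 participants, bids generated from the
# presented-items model at the strong-signal defaults
dataset <- generate_dataset(12, gen_params("presented"), spc_params(), seed = 42)

ex <- apply_exclusions(dataset)          # pre-registered filters
design <- build_design(complete_trials_subset(ex$clean))

mc <- mcmc_config(warmup = 1000, samples = 2000, chains = 2, seed = 1)
fits <- list(
  fit_hierarchical(design, "recalled",  mcmc = mc),
  fit_hierarchical(design, "presented", mcmc = mc),
  fit_td(design, mcmc = mc)
)
select_best(fits)
```

    # A tibble: 3 × 6
      model_id   logml   mc_se max_rhat bf_best_vs_this label
      <chr>      <dbl>   <dbl>    <dbl>           <dbl> <chr>
    1 presented  -977. 0.00792     1.00        1   e  0 no evidence
    2 td        -1083. 0.00786     1.00        1.43e 46 extreme evidence for the first model
    3 recalled  -1282. 0.00921     1.00        3.29e132 extreme evidence for the first model

The generating model (presented items) wins with overwhelming evidence:
its log marginal likelihood exceeds the temporal-difference model's by
~106 nats and the recalled-items model's by ~305. Its posterior summary
recovers the generating parameters (slope 0.936, tau = sigma = 3):

```r
fit_summary(fits[[2]])
```

    # A tibble: 4 × 5
      parameter       mean     sd  q2.5 q97.5
    1 b0             6.69  1.20   4.37  9.11
    2 beta_presented 0.916 0.0135 0.889 0.942
    3 sigma          2.92  0.110  2.71  3.15
    4 tau            3.16  0.796  2.02  5.06

Behavioural contrasts use the default JZS Bayes-factor t test. The
generator attenuates recency when recall is delayed (evaluation-first
trials), and the contrast detects it, while WTP accuracy shows no order
effect:

```r
task_order_contrasts(dataset)
```

    # A tibble: 2 × 6
      measure         mean_RE mean_ER     n    bf10 label
    1 recall_accuracy   0.496   0.410    12 133.    extreme evidence for the first model
    2 wtp_rmse          4.33    4.29    12   0.291 moderate evidence against the first model

Other entry points: `spc()` / `plot_spc()` (serial position curves with
Cousineau-Morey within-subject error bars), `wtp_rmse()` (bid accuracy),
`fit_mixture()` / `classify_participants()` (strategy classification),
`run_recovery()` (the confusion matrix), and `jzs_ttest_bf()`. A thin
command-line wrapper with `simulate` / `describe` / `fit` / `compare` /
`recover` subcommands is installed at `inst/cli/recalleval`.

## Package layout

- `R/task-synth.R` — sequence generator, recall simulator, bid generators,
  BDM payoffs, dataset assembly, trial-table I/O
- `R/predictors.R` — trial-level model predictors and design tables
- `R/fit.R`, `R/bridge.R`, `R/jzs.R` — JAGS fits, bridge-sampling marginal
  likelihoods, Bayes factors
- `R/mixture.R` — latent strategy mixture and classification
- `R/recovery.R` — model-recovery confusion matrix
- `R/descriptives.R`, `R/plots.R` — exclusions, serial position curves,
  WTP accuracy, figures
- `vignettes/memory-sampling-evaluation.Rmd` — the methods vignette: model
  definitions, priors, design decisions, limitations
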