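---
title: "Does episodic memory sampling predict evaluation? Models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does episodic memory sampling predict evaluation? Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Many models of judgment and choice assume that people evaluate an option by
retrieving discrete episodes from memory and aggregating those samples. The
paradigm this package implements tests that assumption directly. On each of
32 trials a participant watches a sequence of seven two-digit values in a
fictitious currency (Galactic Credits, GC), freely recalls as many values as
possible, and states a willingness to pay (WTP) for another draw from the
sequence in a Becker-DeGroot-Marschak (BDM) auction. Because both the
memoranda and the evaluation are numeric, the recalled sample and the
evaluation can be linked trial by trial: if evaluations are built from
memory samples, the mean of what was *recalled* should predict the bid; if
evaluations integrate the experience itself, the mean of what was
*presented* should predict it.

Four candidate models of the trial-level bid are compared:

| Model | Predictor of the bid |
|---|---|
| Recalled items | mean of all reported values on that trial (intrusions included) |
| Presented items | mean of the seven presented values (the true sequence value) |
| Temporal difference | recency-weighted running value estimate (learning rate $\alpha$) |
| Mixture | per-trial latent choice among recalled-only, presented-only, or both |

Each is a Bayesian hierarchical regression

$$\mathrm{bid}_{ij} \sim \mathrm{Normal}(b_0 + u_j + \textstyle\sum_k \beta_k x_{ijk},\ \sigma), \qquad
u_j \sim \mathrm{Normal}(0, \tau),$$

with participant intercepts $u_j$. The single-predictor models are compared
by marginal likelihood; ratios of marginal likelihoods are Bayes factors.

# Task structure and the synthetic-data generator

Real data from this paradigm are not distributed with the package; a
generator reproduces the statistical structure the analysis assumes, and is
itself first-class, tested code.

**Sequences.** A sequence mean is drawn uniformly from the integers 40-70;
the seven values are drawn independently and uniformly (with replacement)
from the integers within ±29 of that mean. Every per-sequence generating
range is exactly 58 wide and all values lie in [11, 99]. Within-sequence
variability is deliberately large relative to between-sequence variability.
Stimuli are integers; duplicates are permitted (the generating law is
sampling with replacement, and nothing in the task forbids repeats).

**Recall.** Each serial position is recalled independently with probability
`p_recall[i]`; the default profile `c(.50, .42, .38, .38, .40, .55, .70)`
gives the one-item primacy and two-position graded recency expected for
immediate free recall of seven-item lists. When evaluation precedes recall
(ER order) recall is effectively delayed, so the last two positions are
attenuated (default multiplier 0.6), reproducing the reduced-recency
signature of delay. Intrusions arrive at a Poisson rate (default 0.3 per
trial) and are drawn from the sequence's generating range *excluding*
presented values, so correctness scoring of synthetic data is unambiguous.
Output order is randomised and capped at 8 reports, standing in for the
task's 15-second response window. These defaults emulate the qualitative
shape of empirical serial position curves, not any fitted parameters; what
passing tests show is that the pipeline recovers whatever structure
generated the data, not that real recall follows this exact profile. The
generator also omits output-order dynamics (lag-contiguity, ascending-order
reporting of digits) that real recall exhibits.

**Bids.** The generating model's linear predictor plus Gaussian noise,
clipped to the response range [0, 100]. Clipping introduces a small bias
toward the interior at extreme predictor values; with the default
parameters (bids centred near 55 GC, $\sigma$ = 3) clipping is essentially
absent, and the fitted models likewise ignore it. Default slopes are the
fitted values reported for this paradigm (recalled 0.541, presented 0.936,
both 0.41/0.54), with intercepts chosen so bids centre near 55 GC;
$\tau$ = 3 GC and $\sigma$ = 3 GC give a strong-signal regime in which the
generating model is clearly identifiable. The TD generator uses
$\alpha$ = 0.7.

**Auction.** The selling price is continuous Uniform(40, 70) — the range of
sequence means. Continuity makes a bid-price tie an event of measure zero;
ties resolve as a purchase. If the bid is below the price the participant
keeps the 100 GC endowment; otherwise they pay the *price* and receive the
sequence's true value on top of the remainder. Because the bid never sets
the amount paid, expected earnings are maximised by bidding the believed
true value; the test suite verifies this incentive compatibility by
exhaustive grid search. (The maximiser is unique for values strictly
inside the price range; at the range's floor every bid at or below the
floor is equally optimal, since no purchase can profit there.) Task order is a random balanced permutation of 16
RE and 16 ER trials per participant (counterbalancing schedule unspecified
in the source design; randomised balance is the neutral choice). Bids are
not restricted to integers.

# Priors, sampling, and convergence

Priors follow the reference analysis: each slope Normal(1, 0.5) (centred on
the incentive-compatible slope of 1), population intercept Normal(0, 10),
participant-intercept spread half-Student-t(3, 0, 10), learning rate
Uniform(0, 1). The residual spread's prior is not stated in the source
analysis (the regression front-end it used derives a data-dependent
default); this package fixes it to the same half-Student-t(3, 0, 10) as the
group spread, for reproducibility. Both slopes of the two-predictor model
get the Normal(1, 0.5) prior (stated only for single-predictor models;
configurable via `prior_config()`).

Default sampler settings also follow the reference analysis: 1000 warmup +
4000 retained iterations on four chains, and 5000 + 10000 for the TD model,
whose learning rate mixes more slowly. Convergence is summarised by the
maximum potential-scale-reduction factor; fits above 1.05 are flagged and
`select_best()` refuses them unless forced.

Sampling runs in JAGS. Two pure reparameterisations are applied for the
Gibbs sampler's benefit and undone before draws are returned: participant
intercepts are sampled on the hierarchically centred scale
($a_j \sim N(b_0, \tau)$), and predictors are mean-centred with the
conditional prior of the shifted intercept adjusted so the joint prior is
exactly the one stated above. Without these, the intercept-slope coupling
inflates R-hat to 1.1-2 at practical chain lengths; with them, R-hat is
typically below 1.02.

# Marginal likelihoods and Bayes factors

Marginal likelihoods are estimated by bridge sampling: the iterative
optimal-bridge estimator with a moment-matched multivariate-normal proposal
on an unconstrained parameterisation (log for $\tau$ and $\sigma$, logit
for $\alpha$), a split-half scheme (half the posterior draws fit the
proposal, the other half enter the bridge identity), iteration to a
$10^{-10}$ tolerance, and a Monte-Carlo error estimate that uses a spectral
variance for the autocorrelated posterior-side term. The estimator is
validated against the analytic marginal likelihood of a conjugate
normal-normal model (agreement within 0.1 nats) and a simple
importance-sampling estimator is provided as an independent cross-check.
Model comparison selects the highest marginal likelihood and reports the
Bayes factor of the winner over each rival with conventional verbal labels.

For behavioural contrasts (e.g., task order effects on recall accuracy or
WTP error) the package provides the default JZS Bayes-factor t test: Cauchy
prior with scale $\sqrt{2}/2$ on the standardised effect and Jeffreys prior
on the variance, evaluated by adaptive quadrature of the one-dimensional
integral that the inverse-gamma mixture representation of the Cauchy
yields. The quadrature is tested against brute-force Monte-Carlo
integration.

# The strategy mixture

The mixture model asks whether different people use different strategies:
each trial is generated by the recalled-only, presented-only, or both
regression, with per-participant weights $\theta_j$ on the 3-simplex under
a flat Dirichlet(1, 1, 1) prior. Component indicators are marginalised
analytically inside the likelihood — identical posterior, far better
mixing. Design choices where the source analysis is silent:

- **Slopes are per component** (recalled, presented, and a separate pair
  for "both"), shared across participants within a component. The
  separately reported estimates for the individual models versus the both
  model (0.541/0.936 vs 0.41/0.54) indicate per-component slopes, and in
  simulation the shared-slope variant is bimodal and fails to recover
  both-generated data.
- **One residual spread and one intercept structure across components**, so
  components cannot explain variance through differing noise levels.
- **Ties in classification go to "both"** (the conservative choice; "both"
  nests the rivals' predictors). Classification is the argmax of the
  posterior-mean $\theta_j$.
- **All chains start from one plausible point** (slopes at prior means,
  equal weights, intercepts from participant means). Mixture posteriors
  have minor secondary modes; chains started from dispersed prior draws can
  land in different modes, in which case R-hat measures the mode split
  rather than within-basin mixing. With a common informed start, R-hat
  again plays its usual role.

A structural caveat governs how recovery is assessed: the components are
nested regressions on highly correlated predictors (the recalled mean is a
noisy subset-mean of the presented mean). In a population where *nobody*
uses a component, that component's slopes are informed only by their prior
and can drift to mimic a neighbour (the both component with
$\beta_{recall} \approx 0$ duplicates the presented component), which caps
the recoverable weight for the true component near 0.5. Weight recovery is
therefore assessed on *mixed* populations, where every component's slopes
are pinned by the participants who genuinely use it; there the package
recovers strategy labels essentially perfectly under the strong-signal
defaults.

# The model-recovery experiment

To validate that the marginal-likelihood comparison can identify the true
generator, the recovery experiment simulates datasets from each of the
recalled, presented, and TD models, refits all three candidates to each
dataset, and tallies the winner into a 3×3 confusion matrix. The generating
parameters are the strong-signal defaults above. Two presets set the
problem size: `full` (50 replicates per generator, 33 participants × 32
trials, reference sampler settings) and `desk` (10 replicates, the same 33
× 32 datasets, 500 warmup + 600 retained iterations on 2 chains), which is
the preset the automated tests run. Under the strong-signal defaults the
three models are separated by hundreds of nats, so the shorter chains leave
the ordering untouched; the desk preset reproduces a perfect diagonal. Any
fit with R-hat above 1.05 is re-run once with a fresh seed and otherwise
recorded as a no-win failure rather than silently compared. The whole
experiment, like every simulation in the package, is a pure function of its
seed.

# Descriptives and exclusions

Pre-registered exclusion rules: fewer than 80% of trials completed (a trial
counts as completed if at least one of its two responses is present — the
task-specific rules below handle one-sided gaps); fewer than one correctly
recalled item per attempted trial; fewer than 80% of evaluation trials
completed; any bid outside [0, 100] flags the participant for exclusion
from evaluation analyses. The joint model comparison keeps only
participants with every trial fully observed, because the TD model needs
complete sequences. Recall is scored by exact integer match with greedy
earliest-position assignment for duplicated values; unmatched reports are
intrusions. Greedy value matching shifts credit for duplicated values
toward earlier positions, a small bias documented in the tests. Serial
position curves carry within-subject standard errors by the
Cousineau-Morey method (participant-mean centring, $\sqrt{K/(K-1)}$
correction with $K = 7$ positions). WTP accuracy is the per-participant
root-mean-square error of bids against true sequence values.

# Numerical choices and problem sizes

- TD value initialised at the first presented value ($V_1 = x_1$): avoids
  an arbitrary anchor and yields exact $\alpha = 0$ / $\alpha = 1$ limits
  (first / last value). An anchor at the scale midpoint is available via
  the closed-form weights if wanted, but is not the default.
- Trials with an empty recall set are dropped from *every* model's design,
  so all marginal likelihoods address identical data; Bayes factors on
  differing data are refused.
- Duplicate reported values all enter the recalled mean (the predictor is
  the mean of reports, not of unique values).
- Bridge proposal covariances get a $10^{-10}$ relative diagonal jitter;
  bridge non-convergence after 1000 iterations is an error, never ignored.
- Simulation-based tests run at reduced sizes chosen to keep the full suite
  in the tens of minutes on one core: parameter recovery uses 20 replicates
  of 10-participant datasets (learning-rate recovery 10 replicates of 8),
  mixture recovery a 12-participant mixed population, and the confusion
  matrix the desk preset above. The vignette-level conclusions do not
  change at larger sizes; the full preset reproduces the same diagonal with
  50 replicates.

# Known limitations

- The fitted likelihood is an unclipped normal although generated bids are
  clipped to [0, 100]; with realistic parameters clipping is negligible,
  but at very large residual spreads the model is misspecified for its own
  generator (used only in noise-stress tests).
- Under weak signal the TD learning rate mixes slowly at desk-scale chain
  lengths and fits can fail the R-hat gate; the recovery machinery treats
  that as a reported failure, not an answer.
- The recalled and presented predictors are intrinsically correlated, so
  single-population mixture fits cannot distinguish a nested component from
  its mimic (see above); conclusions about strategy prevalence should rest
  on mixed-population behaviour.
- A TD value computed from a small learning rate approximates the
  unweighted mean, so TD-versus-presented discrimination weakens as
  $\alpha \to 0$; the recovery defaults use $\alpha = 0.7$, where the
  predictors differ clearly.
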