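# drtlearn

Reinforcement-learning and matching-law analysis of the **dynamic reward
task** (DRT) — a two-deck probabilistic choice task used to probe reward
prediction-error processing, for example in studies comparing people with
psychotic disorders to healthy controls.  On every trial the subject picks
one of two decks and receives a 0/1 point reward; the decks' reward
probabilities (always summing to 0.6) swap across six unsignaled blocks of
70–90 trials, 480 trials in all, so doing well requires continually
re-learning which deck is currently advantageous.

The package is aimed at computational-psychiatry and decision-science
researchers who want a complete, tested pipeline for this task family:
simulating the task, generating realistic synthetic cohorts, and running
the full analysis stack on trial-by-trial choice data.

## The models

**Q-learning with softmax choice.**  Each deck carries an expected value
that is updated after feedback by the delta rule

    Q(t+1) = Q(t) + α (R(t) − Q(t)),

where `R(t) − Q(t)` is the reward prediction error and the learning rate
α ∈ [0, 1] sets how fast beliefs change.  Choices follow the softmax rule

    P_A = exp(β Q_A) / (exp(β Q_A) + exp(β Q_B)),

where the choice perseveration (inverse temperature) β ≥ 0 sets how
strongly the currently higher-valued deck is exploited; β = 0 is random
choice.  Both values start at zero.

**Generalized matching law.**  Steady-state choice allocation is
summarised per block (trials 21–70) by

    log2(C_A / C_B) = s · log2(R_A / R_B) + log2 k,

with reward sensitivity `s` (s < 1 is undermatching) and bias `k`,
estimated by least squares over block-level points pooled within a group;
blocks with zero rewards from either deck are excluded.

**Hierarchical Bayesian estimation.**  Subject-level parameters are
probit-normal (α) and log-normal (β) within groups; group means and
scales get weakly informative hyperpriors.  An adaptive
Metropolis-within-Gibbs sampler (likelihood in C++) returns retained
draws under the classic 3-chain / burn-in / thinning protocol, split-chain
R-hat diagnostics, posterior group-difference probabilities, and
Savage–Dickey Bayes factors for standardized group-mean differences.

**Performance grid.**  `run_grid()` crosses α (0.05–1, step 0.05) with β
(0.5–10, step 0.5) and simulates 100 sessions per pair to map how the two
parameters shape the total score.

## Worked example

```r
library(drtlearn)

# a synthetic three-group cohort emulating the 24/19/26 study design
coh <- sample_cohort(default_cohort_specs(), seed = 1)
summarize_behavior(coh)
#>           group  n mean_score sd_score
#>         control 24      172.6    11.27
#>   low-psychosis 19      166.9    12.26
#>  high-psychosis 26      165.1    14.48
#> ANOVA on total score: F = 2.26, p = 0.112

# matching-law analysis: all groups undermatch, control most sensitive
ml <- matching_by_group(coh$subjects)
ml$fits$control
#> <matching_fit> s = 0.339 (SE 0.013), bias log2(k) = 0.007, R^2 = 0.859, n = 107
ml$fits$`high-psychosis`
#> <matching_fit> s = 0.277 (SE 0.012), bias log2(k) = 0.011, R^2 = 0.795, n = 132

# hierarchical Bayesian fit (reduced MCMC budget for interactive use)
fit <- fit_hierarchical(coh, settings = mcmc_settings(3, 4000, 1000, 3,
                                                      seed = 7))
fit
#> <posterior_result> 69 subjects, 3 groups, 3000 retained draws
#> converged: TRUE (max R-hat 1.100)
#>                  parameter  mean lower95 upper95
#>         mean_alpha.control 0.741   0.701   0.781
#>          mean_beta.control 3.190   2.557   3.912
#>   mean_alpha.low-psychosis 0.871   0.832   0.909
#>    mean_beta.low-psychosis 3.540   2.502   4.969
#>  mean_alpha.high-psychosis 0.884   0.836   0.928
#>   mean_beta.high-psychosis 2.323   1.789   2.948

gd <- group_difference(fit, "beta", "control", "high-psychosis")
gd$p_greater   # 0.974: controls almost surely perseverate more
gd$bf$bf10     # 3.7: positive evidence for the directional hypothesis

# the alpha x beta performance surface
g <- run_grid(seed = 42)
g
#> <drt_grid> 400 cells x 100 reps on sequence-1
#>   best cell: alpha = 0.30, beta = 10.0, mean score = 202.1
#>   cell SD range: 9.02 - 16.00
```

The cohort generator recovers the qualitative study pattern: learning
rates lowest in controls, perseveration lowest in the high-psychosis
group, reward sensitivity highest in controls, and total scores that
barely differ — the point of the modelling being exactly that the model
parameters separate the groups where raw scores do not.

A thin command-line wrapper over the same functions lives at
`inst/scripts/drt-cli.R` (verbs `schedule`, `simulate`, `synth`,
`simgrid`, `run`).

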