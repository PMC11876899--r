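# rstddm

Simulation, fitting and comparison of **relative-start-time drift diffusion
models (RST DDM)** for altruistic choice under a social-status
manipulation.

## The problem

In a binary dictator game each option carries a payoff for the chooser
(Ms) and one for an anonymous co-player (Mo).  How does a person's
*relative social status* — induced trial-by-trial by manipulated
performance feedback in a dot-estimation contest (better / equal / worse
than the co-player) — change how they weigh their own against the other's
payoff?  Two mechanisms are distinguishable from choices and response
times within a sequential-sampling framework:

* **attribute weight** (ωs, ωo): how strongly each payoff difference
  drives evidence accumulation, and
* **attribute latency** (RST, relative start time): *when* each attribute
  starts influencing the process.

Evidence accumulates in discrete 10-ms steps,

    E_t = E_{t-1} + ν_t·dt + ε_t,     ε_t ~ N(0, 0.1),
    ν_t = τs_t·ωs·ΔMs + τo_t·ωo·ΔMo,

with the gate of the late attribute opening at step ⌈|RST|/dt⌉ (RST > 0:
the self-payoff attribute leads).  A choice is made when |E_t| reaches the
threshold; RT = t·dt + nDT.  Four variants let status modulate the
weights (variant 1, RST = 0), the RSTs (variant 2, shared weights), or
both (variants 3–4); they are fitted per subject by a simulation-based
likelihood (histogram over choice × RT bins of thousands of simulated
outcomes per trial) maximised with differential evolution, and compared by
random-effects Bayesian model selection (exceedance probabilities from a
variational Dirichlet scheme).

The package also ships the full synthetic task generator (feedback
schedule 60/60/90/90 → status 90/120/90; option payoffs 1–20 with |r| ≤
0.1 constraints), model-free read-outs (choice proportions, logistic
decision betas, sliding-window betas over RT), split-half
cross-validation, social-value-orientation (SVO) scoring with the 22.45°
prosocial/individualistic split, and bootstrap mediation.

## Worked example

```r
library(rstddm)

# a prosocial synthetic subject: shared weights, status-monotone RSTs
truth <- group_preset("prosocial")
sched <- generate_feedback_schedule(seed = 1)
opts  <- generate_option_set(300, seed = 2)
subj  <- generate_synthetic_subject(truth, variant = 2, sched, opts,
                                    seed = 3, subject_id = "s01")

betas <- decision_betas(subj)
betas[, c("status", "beta_dms", "beta_dmo")]
#>   status  beta_dms   beta_dmo
#> 1 better 0.1598947 0.09378425
#> 2  equal 0.2356345 0.09585523
#> 3  worse 0.1306840 0.12082549

tapply(subj$rt, subj$status, mean)
#>   better    equal    worse
#> 1.313444 1.083083 1.334000
```

From better to worse status this subject's self-payoff beta falls
(0.160 → 0.131), the other-payoff beta rises (0.094 → 0.121), and
decisions slow — although the generating weights are *identical* across
status: the behavioural shift is carried entirely by the RST moving from
+0.5 s (self leads) to −0.35 s (other leads).  Single-subject,
90-trial-per-status estimates are noisy (the equal condition here sits
above both extremes on beta_dms); cohort-level means at 4 × 150 trials
order all three conditions correctly.  Fitting variant 2 recovers the
declining latency profile:

```r
prof <- fit_profile("desk", seed = 7)   # 300 sims/trial, 40 DE iters, 4 restarts
fit  <- fit_subject(subj, variant = 2, prof$like, prof$de)
round(fit$best_vector[c("rst_b", "rst_e", "rst_w")], 2)
#> rst_b rst_e rst_w
#>  0.92  0.40 -0.27
```

Cohort-level pipelines (`generate_cohort()`, `fit_cohort()`,
`random_effects_bms()`, `run_pipeline()`) and recovery harnesses
(`parameter_recovery()`, `model_recovery()`) scale the same machinery; a
CLI wrapper lives at `system.file("cli", "rstddm", package = "rstddm")`
with subcommands `simulate-cohort`, `simulate-trial`, `fit`, `compare`,
`recover-params`, `recover-models`, `analyze`, `svo`, `run`.

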