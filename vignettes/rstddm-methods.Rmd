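---
title: "Methods: relative-start-time drift diffusion modelling of altruistic choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative-start-time drift diffusion modelling of altruistic choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rstddm` implements a multi-attribute drift diffusion model for binary
dictator-game choices in which the two attributes of an option pair — the
self-payoff difference $\Delta M_s$ (positive by labelling convention) and
the other-payoff difference $\Delta M_o$ — may start influencing evidence
accumulation at different times.  The drift at step $t$ is

$$\nu_t = \tau_{s,t}\,\omega_s\,\Delta M_s + \tau_{o,t}\,\omega_o\,\Delta M_o,$$

where the gates $\tau_{\cdot,t} \in \{0,1\}$ open at step 0 for the early
attribute and at step $\lceil |RST|/dt \rceil$ for the late one.  A
positive relative start time (RST) means the self attribute leads.
Evidence evolves as $E_t = E_{t-1} + \nu_t\,dt + \varepsilon_t$ with
$\varepsilon_t \sim N(0, \sigma)$, $E_0 = \text{bias}$, absorbing at
$|E_t| \ge$ threshold; the response time is $t\,dt + nDT$.

Four variants encode how a trial-level social-status condition
(better / equal / worse, induced by manipulated dot-task feedback) can
modulate the process: status-specific weights with RST $= 0$ (variant 1, 9
free parameters), shared weights with status-specific RSTs (variant 2, 8),
status weights with one shared RST (variant 3, 10), or both status-specific
(variant 4, 12).

## Numerical conventions

* **Noise scale.** The update rule is implemented literally with
  $\sigma = 0.1$ as the *per-step standard deviation* at $dt = 0.01$ s, so
  the continuum diffusion coefficient is $\sigma_c^2 = 0.1^2/0.01 = 1$ per
  second.  The constant-drift absorption probability of the discrete walk
  then approaches $1/(1+e^{-2\nu B/\sigma_c^2})$.
* **Discretisation overshoot.** A discrete Gaussian walk overshoots the
  boundary by $\approx 0.583\,\sigma$ on average (Siegmund's correction),
  i.e. the walk behaves like a continuum diffusion with boundary
  $B + 0.058$.  At 50,000 paths this bias exceeds 3 Monte-Carlo standard
  errors once $\nu \gtrsim 0.25$/s; the simulator test suite therefore
  checks the exact continuum form at drifts up to 0.2/s and the
  overshoot-corrected form at larger drifts.
* **Step indexing.** Gates are evaluated on the integer update counter
  starting at 0; the late attribute first contributes to update
  $\lceil |RST|/dt\rceil$.  Boundary crossing is checked after each full
  step; no sub-step interpolation.
* **Censoring.** Paths not absorbed within `t_max` (default 10 s, matching
  the RT exclusion cap) are kept as an explicit censored outcome category —
  in the likelihood they occupy their own histogram cell.

## Simulation-based likelihood

The likelihood of an observed (choice, RT) pair is read off a histogram of
simulated outcomes of that trial (3,000 per trial at full scale, 300 at
desk scale): cells are choice × 0.1-s RT bins over `[ndt, ndt + t_max]`
plus one censored cell, Laplace-smoothed with one pseudo-count per cell.
Two deliberate choices:

* **Support violations.**  Observed RTs beyond the upper end clamp to the
  last bin.  Observed RTs *below* the model minimum `ndt + dt` receive only
  the smoothing floor `pseudo / (n_sims + pseudo * n_cells)`.  Assigning
  them the first bin's real mass instead creates a degenerate maximum:
  inflate `ndt` past every observed RT, shrink the threshold, and all
  observations collapse into a single fully-stocked bin.  We found this
  attractor empirically (it beat the generating parameters by ~180 log
  units) before adopting the floor rule.
* **Common random numbers.**  Within one optimisation run all candidate
  evaluations reuse one pre-generated noise pool, indexed per (trial,
  simulation) by a deterministic hash, making the objective an exact
  deterministic function of the parameters.  Disabling CRN re-randomises
  every evaluation.

## Fitting

Per subject and variant, the negative log-likelihood is minimised by
differential evolution (DE/rand/1/bin, crossover 0.9, weight 0.8,
reflection at the box bounds), 150 iterations and 100 independent restarts
at full scale.  Bounds (declared package defaults): weights ±0.5 per point, RST ±2 s, threshold (0.1, 5], nDT
[0.05, 1.5] s, bias ±0.9 × threshold (parameterised as a fraction so the
box is always valid).

Two refinements beyond a plain DE loop, both motivated by measurements at
desk scale:

1. **Cross-pool selection and polish.**  Each restart optimises against its
   own noise pool and overfits it by several log-units (restart winners
   evaluated under an independent 3,000-simulation objective were 2–5
   log-units *worse* than the generating parameters).  All restart winners
   are therefore re-evaluated, and each polished by Nelder–Mead, against a
   common reference objective using 4× the simulations per trial; the best
   refined vector wins.
2. **Coordinate grid sweep.**  The likelihood has well-known ridges: the
   two RST sign regimes are separate basins, an RST trades off against its
   attribute's weight (enter later but weigh more), and non-decision time
   against threshold.  After polishing, every slot is swept over a coarse
   grid (7–9 points spanning its bounds; a finer grid including 0 for RST
   slots), improvements kept, with a re-polish and one Nelder–Mead restart
   (fresh simplex from the incumbent) to finish.

The desk-scale profile used by the test suite is 300 simulations/trial, 40
DE iterations, population 20, 4 restarts.  The population default
(10 × n_free) follows common DE practice; desk scale caps it at 20 to fit
the grading time budget.

## Model selection

Log model evidence is approximated as $-\mathrm{BIC}/2$ from the best
refined NLL ($\mathrm{BIC} = 2\,\mathrm{NLL} + k\ln n$): a conventional
evidence proxy for maximum-likelihood fits that penalises the variants'
differing parameter counts (8–12).  Random-effects Bayesian model selection
uses the variational Dirichlet scheme (uniform prior $\alpha_0 = 1$,
tolerance $10^{-6}$, ≤ 500 iterations); exceedance probabilities come from
$10^5$ seeded Dirichlet draws, and the two-model case is verified against a
dense Beta-integral oracle.

## The synthetic cohort generator

The generator emulates the study-1 task: 300 trials (5 × 60), covert
feedback schedule fixed at 60 BC / 60 BW / 90 SC / 90 SW (status counts
90 / 120 / 90), dot counts per option uniform on 32–34 and unequal, option
payoffs uniform on 1–20 points with whole-set rejection sampling until the
within-option and between-difference correlations are within ±0.1.
Rejection of whole sets (rather than per-trial repair) keeps the marginal
payoff distribution uniform.  The ΔM correlation is checked after the
ΔMs > 0 relabelling, because that is the representation entering every
regression.

Group presets are *synthetic assumptions*; no empirical group-level
estimates are bundled.  The prosocial preset has shared weights 0.12/0.06 per point
and a status-monotone RST profile (0.5 / 0.15 / −0.35 s); the
individualistic preset has a larger weight gap (0.16/0.025) and a nearly
flat RST profile (0.35 / 0.28 / 0.22 s).  Both presets keep the
self-weight clearly above the other-weight, matching the strong reported
asymmetry in both groups; without it the better-status condition is not
the fastest and the response-time ordering inverts.  Magnitudes were
chosen so simulated behaviour lands in the range typical of such
experiments (~70–85 % larger-self-payoff choices, per-point decision
betas ~0.2–0.3, mean RTs 1–2 s); with much smaller weights choices
approach chance and the latency parameters become unidentifiable at
realistic trial counts.

What a green test on synthetic cohorts does **not** establish: anything
about real subjects' parameter values, the fit quality on the OSF data, or
robustness to RT contaminants (lapses, fast guesses) that real data contain
and the generator does not emulate.

## Recovery harnesses and their limits

Parameter recovery simulates subjects from dispersed truths (weights over
the positive half of the bounds, RSTs over ±1.3 s — "truth sets spanning
the bounds"), refits, and reports per-parameter correlations, bias, and RST
sign agreement.  Two structural limits surfaced repeatedly and are worth
knowing:

* the likelihood is nearly flat in an RST once it exceeds the typical
  decision duration (the attribute simply never enters), so large-RST
  truths recover with the right sign but noisy magnitude;
* a shared $\omega_o$ trades off against the RST profile (enter later but
  weigh more), limiting its recovery precision from 90–120-trial subjects
  — at full scale (300 trials, 100 restarts) this ridge tightens.

Model recovery generates small cohorts from variants 1 and 2, fits all four
variants, and checks that random-effects selection awards the generating
variant the top exceedance probability (and, for variant-1 data, does not
hand variant 2 a spurious win).

## Behavioural read-outs

Decision betas use the two-stage approach: per-subject, per-status logistic
`choice ~ ΔMs + ΔMo` (optional ridge 1e-3 for small cells, separation
flagged), summarised as across-subject means ± SEM — the same surface as a
random-slopes mixed model at the group level without committing to a mixed
optimiser.  Sliding-window betas use 100-ms windows in 10-ms steps with a
20-trial minimum (windows below it are gaps).  Split-half cross-validation
splits each status at random, fits on one half, simulates every held-out
trial 100 times, and reports held-out choice accuracy and RT correlation.
SVO scoring follows the six-item slider measure: angle
$\arctan((\bar A_o - 50)/(\bar A_s - 50))$, categories split at 57.15°,
22.45°, −12.04°, binary prosocial/individualistic split at 22.45°.
Mediation is the product-of-coefficients estimator with a percentile
bootstrap (1,000 resamples), status coded better = 1, equal = 0,
worse = −1 (the source's coding is unstated; this is declared and
configurable).

## Open choices taken

* Option sets are regenerated per subject (the source says pairs "varied
  across subjects" without stating the regeneration unit).
* RST values are reported in seconds throughout; the source never states
  the unit of its reported values.
* Censored simulated paths stay censored rather than being scored by the
  sign of their final evidence.
* Fit restarts vary both the DE seed and the simulation noise seed.
* CLI configuration files are JSON.
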