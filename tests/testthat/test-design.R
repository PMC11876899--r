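test_that("option sets satisfy payoff range, labelling and correlation limits", {
  for (case in list(list(n = 300, seed = 1), list(n = 50, seed = 7))) {
    opts <- generate_option_set(case$n, seed = case$seed)
    expect_equal(nrow(opts), case$n)
    payoffs <- unlist(opts[, c("ms1", "mo1", "ms2", "mo2")])
    expect_true(all(payoffs >= 1 & payoffs <= 20))
    expect_true(all(payoffs == round(payoffs)))
    expect_true(all(opts$delta_ms >= 1))
    # independent recomputation of the three constrained correlations
    expect_lte(abs(cor(opts$ms1, opts$mo1)), 0.1)
    expect_lte(abs(cor(opts$ms2, opts$mo2)), 0.1)
    expect_lte(abs(cor(opts$delta_ms, opts$delta_mo)), 0.1)
    expect_equal(opts$delta_ms, opts$ms1 - opts$ms2)
    expect_equal(opts$delta_mo, opts$mo1 - opts$mo2)
  }
})

test_that("option set generation is deterministic and validates inputs", {
  expect_identical(generate_option_set(40, seed = 5),
                   generate_option_set(40, seed = 5))
  expect_error(generate_option_set(5, seed = 1), "n_trials")
  expect_error(generate_option_set(40, seed = 1, max_tries = 1,
                                   max_abs_cor = 1e-6), "not satisfied")
})

test_that("feedback schedule has the fixed design counts under any seed", {
  for (seed in c(1, 2, 99)) {
    sched <- generate_feedback_schedule(seed)
    expect_equal(nrow(sched), 300)
    expect_equal(as.vector(table(sched$feedback)[c("BC", "BW", "SC", "SW")]),
                 c(60, 60, 90, 90))
    expect_equal(as.vector(table(sched$status)[c("better", "equal", "worse")]),
                 c(90, 120, 90))
    expect_true(all(sched$dots1 %in% 32:34 & sched$dots2 %in% 32:34))
    expect_true(all(sched$dots1 != sched$dots2))
  }
  # same counts, different orderings across seeds
  s1 <- generate_feedback_schedule(1)
  s2 <- generate_feedback_schedule(2)
  expect_false(identical(s1$feedback, s2$feedback))
})

test_that("schedule subsetting preserves the status ratio", {
  sched <- generate_feedback_schedule(3)
  sub <- rstddm:::subset_schedule(sched, 120)
  expect_equal(nrow(sub), 120)
  expect_equal(as.vector(table(sub$status)), c(36, 48, 36))
  expect_error(rstddm:::subset_schedule(sched, 400), "not supported")
})

test_that("synthetic subjects reflect their generating parameters", {
  d <- small_design()
  # zero drift, zero bias: symmetric choice
  p0 <- ddm_params(omega_s = 0, omega_o = 0, threshold = 1, ndt = 0.3)
  s0 <- generate_synthetic_subject(p0, 2, d$schedule, d$options, seed = 11)
  pc <- mean(s0$choice, na.rm = TRUE)
  expect_gt(pc, 0.5 - 3 * sqrt(0.25 / 120))
  expect_lt(pc, 0.5 + 3 * sqrt(0.25 / 120))
  # dominant self-payoff drift: near-certain larger-Ms choice
  p1 <- ddm_params(omega_s = 2, omega_o = 0, threshold = 1, ndt = 0.3)
  s1 <- generate_synthetic_subject(p1, 2, d$schedule, d$options, seed = 12)
  expect_gte(mean(s1$choice, na.rm = TRUE), 0.99)
  expect_true(all(s1$rt > 0, na.rm = TRUE))
})

test_that("cohorts are bookkept correctly and bit-identical under a seed", {
  spec <- cohort_spec(n_subjects = 2, n_trials = 60, seed = 21)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(cohort_spec(n_subjects = 2, n_trials = 60, seed = 21))
  expect_equal(nrow(coh1), 2 * 2 * 60)  # two groups x two subjects x trials
  expect_setequal(unique(coh1$group), c("prosocial", "individualistic"))
  expect_identical(coh1, coh2)
  coh3 <- generate_cohort(cohort_spec(n_subjects = 2, n_trials = 60, seed = 22))
  expect_false(identical(coh1$choice, coh3$choice))
})

test_that("study-2 layout blocks choices after dot trials and caps RTs", {
  spec <- cohort_spec(n_subjects = 1,
                      group_params = list(prosocial = group_preset("prosocial")),
                      n_trials = 60, study = "study2", seed = 41)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh), 60)
  expect_true(all(coh$rt <= 6 + 0.35 + 1e-9, na.rm = TRUE))
  # reproducible like every other design artefact
  expect_identical(coh, generate_cohort(spec))
})

test_that("status-monotone prosocial preset yields larger other-payoff betas in worse status", {
  # direction probe of the generator: with RST(worse) < RST(better) the
  # other-payoff difference influences choice more in the worse condition
  sched <- generate_feedback_schedule(31)
  opts <- generate_option_set(300, seed = 32)
  sub <- generate_synthetic_subject(group_preset("prosocial"), 2, sched,
                                    opts, seed = 33)
  b <- decision_betas(sub)
  expect_gt(b$beta_dmo[b$status == "worse"], b$beta_dmo[b$status == "better"])
})
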