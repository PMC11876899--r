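test_that("variant table demands the right parameter structure", {
  expect_equal(vapply(1:4, function(v) ddm_variant(v)$n_free_params, 0L),
               c(9L, 8L, 10L, 12L))
  expect_equal(vapply(1:4, function(v) length(rstddm:::param_slots(v)), 0L),
               c(9L, 8L, 10L, 12L))
  expect_error(ddm_variant(5), "variant_id")
})

test_that("effective_params resolves status slots per variant", {
  p <- ddm_params(omega_s = c(better = 0.1, equal = 0.2, worse = 0.3),
                  omega_o = c(better = 0.01, equal = 0.02, worse = 0.03),
                  rst = c(better = 0.5, equal = 0, worse = -0.5),
                  threshold = 1, ndt = 0.3)
  # variant 1: status weights, rst forced to zero
  e1 <- effective_params(p, 1, "worse")
  expect_equal(e1$omega_s, 0.3)
  expect_identical(e1$rst, 0)
  # variant 4: all three slots status-specific
  e4b <- effective_params(p, 4, "better")
  e4w <- effective_params(p, 4, "worse")
  expect_false(any(unlist(e4b) == unlist(e4w)))
  # variant 2 requires shared weights: status-varying weights are an error
  expect_error(effective_params(p, 2, "better"), "varies by status")
  p2 <- ddm_params(omega_s = 0.1, omega_o = 0.05,
                   rst = c(better = 0.4, equal = 0.1, worse = -0.2))
  expect_equal(effective_params(p2, 2, "better")$rst, 0.4)
  expect_equal(effective_params(p2, 2, "equal")$rst, 0.1)
})

test_that("latency gates and drift rate follow the RST convention", {
  # RST > 0: self attribute first, other enters at ceil(RST/dt)
  sch <- latency_schedule(0.5, dt = 0.01)
  expect_equal(sch$entry_step_s, 0L)
  expect_equal(sch$entry_step_o, 50L)
  expect_equal(drift_rate(0.01, 0.005, sch, dms = 10, dmo = -4, step = 10),
               0.1)  # other gate still closed
  expect_equal(drift_rate(0.01, 0.005, sch, dms = 10, dmo = -4, step = 50),
               0.1 - 0.02)  # both gates open: direct substitution
  # RST < 0 mirrors
  schn <- latency_schedule(-0.3, dt = 0.01)
  expect_equal(schn$entry_step_o, 0L)
  expect_equal(schn$entry_step_s, 30L)
  # RST = 0: both gates open from step 0
  sch0 <- latency_schedule(0)
  expect_equal(drift_rate(0.02, 0.01, sch0, 5, 5, 0), 0.15)
})

test_that("ddm_params validates its invariants", {
  expect_error(ddm_params(0.1, 0.1, threshold = -1), "threshold")
  expect_error(ddm_params(0.1, 0.1, bias = 1.5, threshold = 1), "bias")
  expect_error(ddm_params(0.1, 0.1, ndt = -0.1), "ndt")
  expect_error(ddm_params(Inf, 0.1), "non-finite")
})

test_that("single-trial simulation honours bias, determinism and censoring", {
  # bias at the boundary: immediate upper hit, rt -> ndt + dt
  p <- ddm_params(omega_s = 0, omega_o = 0, threshold = 1, ndt = 0.3,
                  bias = 0.999)
  hits <- vapply(1:50, function(s)
    simulate_trial(p, 2, "equal", 5, 0, seed = s)$choice, 0L)
  rts <- vapply(1:50, function(s)
    simulate_trial(p, 2, "equal", 5, 0, seed = s)$rt, 0)
  # limit behaviour: P(upper) -> 1 and rt -> ndt (an occasional path dips
  # back into the interior, so the assertions are statistical)
  expect_gte(mean(hits == 1), 0.95)
  expect_lte(median(rts), 0.3 + 0.02)
  # determinism under the seed
  a <- simulate_trial(group_preset("prosocial"), 2, "worse", 7, -3, seed = 9)
  b <- simulate_trial(group_preset("prosocial"), 2, "worse", 7, -3, seed = 9)
  expect_identical(a, b)
  # a tiny horizon forces censoring
  slow <- ddm_params(omega_s = 0, omega_o = 0, threshold = 5, ndt = 0.3)
  out <- simulate_trial(slow, 2, "equal", 5, 0, seed = 1, t_max = 0.05)
  expect_true(out$censored)
  expect_true(is.na(out$choice))
  # evidence trace stays inside the boundary until the final step
  tr <- simulate_trial(group_preset("prosocial"), 2, "equal", 8, 2,
                       seed = 17, return_path = TRUE)
  ev <- tr$evidence
  expect_true(all(abs(ev[-length(ev)]) < 1))
  if (!tr$censored) expect_gte(abs(ev[length(ev)]), 1)
})

test_that("trial distributions are reproducible and account for censoring", {
  p <- group_preset("prosocial")
  s1 <- simulate_trial_distribution(p, 2, "equal", 6, -2, 500, seed = 5)
  s2 <- simulate_trial_distribution(p, 2, "equal", 6, -2, 500, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 500)
  expect_equal(mean(s1$censored), attr(s1, "censored_fraction"))
  expect_true(all(s1$rt[!s1$censored] >= p$ndt))
})

test_that("absorption probability matches the constant-drift closed form at small drift", {
  # continuum limit: P(upper) = 1 / (1 + exp(-2 v B / sigma_c^2)) with
  # sigma_c^2 = sigma^2 / dt = 1; the discrete walk adds a boundary
  # overshoot of about 0.583 * sigma (Siegmund), checked separately below
  p <- ddm_params(omega_s = 0.01, omega_o = 0, threshold = 1, ndt = 0.3)
  v <- 0.1
  sim <- simulate_trial_distribution(p, 2, "equal", v / 0.01, 0, 20000,
                                     seed = 61)
  pu <- mean(sim$choice == 1, na.rm = TRUE)
  pth <- 1 / (1 + exp(-2 * v * 1))
  expect_lt(abs(pu - pth), 3 * sqrt(pth * (1 - pth) / 20000) + 0.004)
})

test_that("overshoot-corrected closed form holds at larger drift", {
  # at v = 0.5 the exact continuum form is off by ~0.011 (> 3 MC SEs at
  # 50k paths); the Siegmund-corrected boundary B + 0.5826 * sigma restores
  # agreement -- evidence the deviation is discretisation, not a bug
  p <- ddm_params(omega_s = 0.01, omega_o = 0, threshold = 1, ndt = 0.3)
  for (v in c(0.3, 0.5)) {
    sim <- simulate_trial_distribution(p, 2, "equal", v / 0.01, 0, 50000,
                                       seed = 62)
    pu <- mean(sim$choice == 1, na.rm = TRUE)
    b_eff <- 1 + 0.5826 * 0.1
    pth <- 1 / (1 + exp(-2 * v * b_eff))
    expect_lt(abs(pu - pth), 3 * sqrt(pth * (1 - pth) / 50000) + 0.002)
  }
})

test_that("choice probability is monotone in the other-payoff difference", {
  p <- ddm_params(omega_s = 0.1, omega_o = 0.08, threshold = 1, ndt = 0.3)
  pu <- vapply(c(-8, 0, 8), function(dmo) {
    sim <- simulate_trial_distribution(p, 2, "equal", 5, dmo, 20000,
                                       seed = 63)
    mean(sim$choice == 1, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(pu) > 0))
})

test_that("a growing positive RST delays the other attribute's influence", {
  # holding weights fixed, increasing RST shifts P(choice = 1) toward the
  # early (self) attribute's preference and lengthens RTs on conflict
  # trials (dmo favouring the other option)
  pu <- numeric(0); mrt <- numeric(0)
  for (rst in c(0, 0.6, 1.2)) {
    p <- ddm_params(omega_s = 0.08, omega_o = 0.12, rst = rst,
                    threshold = 1.5, ndt = 0.3)
    sim <- simulate_trial_distribution(p, 2, "equal", 4, -10, 30000,
                                       seed = 64)
    pu <- c(pu, mean(sim$choice == 1, na.rm = TRUE))
    mrt <- c(mrt, mean(sim$rt, na.rm = TRUE))
  }
  expect_true(all(diff(pu) > 0))   # later dmo entry => more self-driven
  expect_true(all(diff(mrt) > 0))  # and slower decisions
})

test_that("pre-RST choices are independent of the late attribute", {
  # among simulated decisions completed before the other attribute enters,
  # the logistic beta for dmo is indistinguishable from zero
  p <- ddm_params(omega_s = 0.1, omega_o = 0.1, rst = 0.8, threshold = 1,
                  ndt = 0.3)
  opts <- generate_option_set(200, seed = 65)
  rows <- list()
  for (i in seq_len(nrow(opts))) {
    sim <- simulate_trial_distribution(p, 2, "equal", opts$delta_ms[i],
                                       opts$delta_mo[i], 50,
                                       seed = 650 + i)
    sim$delta_ms <- opts$delta_ms[i]; sim$delta_mo <- opts$delta_mo[i]
    rows[[i]] <- sim
  }
  sim <- do.call(rbind, rows)
  early <- sim[!is.na(sim$choice) & (sim$rt - 0.3) < 0.8, ]
  fit <- rstddm:::logistic_fit(early$choice,
                               cbind(dms = early$delta_ms,
                                     dmo = early$delta_mo))
  Xd <- cbind(1, early$delta_ms, early$delta_mo)
  mu <- plogis(drop(Xd %*% fit$coef))
  se <- sqrt(diag(solve(crossprod(Xd, Xd * mu * (1 - mu)))))
  expect_lt(abs(fit$coef[["dmo"]] / se[3]), 3)
})
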