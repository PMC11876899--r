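test_that("choice proportions tally both attributes independently", {
  df <- data.frame(subject_id = "a",
                   status = rep(c("better", "equal", "worse"), each = 4),
                   delta_ms = 5, delta_mo = c(3, -3, 3, -3),
                   choice = 1)
  cp <- choice_proportions(df)
  expect_equal(cp$p_larger_ms, rep(1, 3))   # constant larger-Ms chooser
  expect_equal(cp$p_larger_mo, rep(0.5, 3)) # half those trials had dmo > 0
  # bookkeeping identity against an independent group-by count
  sub <- small_subject()
  cp2 <- choice_proportions(sub)
  for (st in levels(sub$status)) {
    i <- !is.na(sub$choice) & sub$status == st
    expect_equal(cp2$p_larger_ms[cp2$status == st], mean(sub$choice[i] == 1))
  }
})

test_that("decision betas recover known logistic generators", {
  set.seed(120)
  n <- 4000
  dms <- sample(1:19, n, TRUE)
  dmo <- sample(-19:19, n, TRUE)
  eta <- 0.3 * dms + 0.1 * dmo - 1.5
  df <- data.frame(subject_id = "a",
                   status = sample(c("better", "equal", "worse"), n, TRUE),
                   delta_ms = dms, delta_mo = dmo,
                   choice = rbinom(n, 1, plogis(eta)))
  b <- decision_betas(df, ridge = 0)
  expect_lt(abs(mean(b$beta_dms) - 0.3), 0.05)
  expect_lt(abs(mean(b$beta_dmo) - 0.1), 0.05)
  expect_equal(b$relative_beta, b$beta_dms - b$beta_dmo)
  # null covariate: beta_dmo near zero when choices ignore dmo
  df$choice <- rbinom(n, 1, plogis(0.3 * dms - 1.5))
  b0 <- decision_betas(df, ridge = 0)
  expect_lt(max(abs(b0$beta_dmo)), 0.05)
})

test_that("betas on simulated diffusion data are positive for positive weights", {
  sub <- small_subject()  # prosocial preset, both weights > 0
  b <- decision_betas(sub)
  expect_true(all(b$beta_dms > 0))
  expect_true(all(b$beta_dmo > -0.02))
  smry <- summarize_decision_betas(b)
  expect_equal(nrow(smry), 3)
  expect_true(all(smry$mean_beta_dms > 0))
})

test_that("perfect separation is flagged rather than silently dropped", {
  df <- data.frame(subject_id = "a", status = "equal",
                   delta_ms = c(1:20), delta_mo = 0,
                   choice = as.integer(1:20 > 10))
  b <- decision_betas(df, ridge = 0)
  expect_true(b$separated[1])
})

test_that("sliding windows skip sparse cells and track attribute onsets", {
  set.seed(121)
  n <- 6000
  df <- data.frame(delta_ms = sample(1:19, n, TRUE),
                   delta_mo = sample(-9:9, n, TRUE),
                   rt = runif(n, 0.5, 1.5))
  df$choice <- rbinom(n, 1, plogis(0.25 * df$delta_ms - 2))
  sw <- sliding_window_betas(df, min_trials = 20)
  expect_true(all(sw$n_trials >= 20))
  expect_true(all(sw$t_center > 0.5 & sw$t_center < 1.5))
  # a one-trial window is a gap, not an error
  tiny <- df[1:30, ]
  tiny$rt <- c(rep(1, 29), 5)
  sw2 <- sliding_window_betas(tiny, min_trials = 20)
  expect_false(any(sw2$t_center > 4))
})

test_that("SVO worked examples and boundary behaviour", {
  # arctan(1) = 45 degrees -> prosocial
  r1 <- svo_score(rep(85, 6), rep(85, 6))
  expect_equal(r1$angle_deg, 45)
  expect_equal(r1$category, "prosocial")
  expect_equal(r1$binary_group, "prosocial")
  # zero numerator -> 0 degrees -> individualist
  r2 <- svo_score(rep(100, 6), rep(50, 6))
  expect_equal(r2$angle_deg, 0)
  expect_equal(r2$category, "individualist")
  expect_equal(r2$binary_group, "individualistic")
  # category thresholds
  expect_equal(svo_category(60), "altruist")
  expect_equal(svo_category(-20), "competitive")
  expect_equal(svo_binary_group(22.45), "prosocial")
  expect_equal(svo_binary_group(22.4499), "individualistic")
  # vertical case: mean self = 50
  r3 <- svo_score(rep(50, 6), rep(80, 6))
  expect_equal(r3$angle_deg, 90)
  # undefined case flagged
  r4 <- svo_score(rep(50, 6), rep(50, 6))
  expect_true(r4$flagged)
  expect_true(is.na(r4$angle_deg))
  expect_error(svo_score(1:5, 1:5), "six")
})

test_that("mediation recovers a simulated indirect effect", {
  set.seed(122)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n, sd = 0.1)
  y <- 0.4 * m + 0.2 * x + rnorm(n, sd = 0.1)
  res <- mediate(x, m, y, n_boot = 500, seed = 9)
  expect_equal(res$indirect_ab, res$path_a * res$path_b)  # estimator identity
  expect_lt(abs(res$indirect_ab - 0.2), 0.1)
  expect_true(res$ci_low <= 0.2 && res$ci_high >= 0.2)  # CI covers truth
  expect_true(res$significant)
  # deterministic bootstrap under the seed
  res2 <- mediate(x, m, y, n_boot = 500, seed = 9)
  expect_identical(c(res$ci_low, res$ci_high), c(res2$ci_low, res2$ci_high))
})

test_that("null mediation covers zero and collinearity is named", {
  set.seed(123)
  n <- 150
  x <- rnorm(n)
  m <- rnorm(n)              # independent of x
  y <- 0.3 * x + rnorm(n)
  res <- mediate(x, m, y, n_boot = 400, seed = 11)
  expect_lt(res$ci_low, 0)
  expect_gt(res$ci_high, 0)
  expect_false(res$significant)
  expect_error(mediate(x, m, y, covariates = data.frame(dup = x)),
               "rank deficient|collinear")
})
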