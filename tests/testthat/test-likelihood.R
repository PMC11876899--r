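test_that("trial exclusion applies the 10 s and 3-SD rules", {
  df <- data.frame(subject_id = "a", rt = c(rep(1.0, 299), 12.0),
                   censored = FALSE)
  res <- exclude_trials(df)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(res$excluded$rt, 12.0)
  # identical RTs: SD = 0, only the absolute cap can bind
  df2 <- data.frame(subject_id = "a", rt = rep(2.0, 50), censored = FALSE)
  expect_equal(nrow(exclude_trials(df2)$excluded), 0)
  expect_error(exclude_trials(df2[0, ]), "empty")
})

test_that("exclusion count matches a direct recomputation on skewed RTs", {
  set.seed(71)
  rts <- rlnorm(400, meanlog = 0, sdlog = 0.6)
  df <- data.frame(subject_id = rep(c("a", "b"), each = 200), rt = rts,
                   censored = FALSE)
  res <- exclude_trials(df)
  manual <- 0
  for (s in c("a", "b")) {
    x <- rts[df$subject_id == s]
    manual <- manual + sum(x > 10 | x > mean(x) + 3 * sd(x))
  }
  expect_equal(nrow(res$excluded), manual)
  expect_equal(nrow(res$kept) + nrow(res$excluded), 400)
})

test_that("trial likelihood is a proper smoothed distribution", {
  p <- group_preset("prosocial")
  cfg <- likelihood_config(n_sims_per_trial = 300)
  sim <- simulate_trial_distribution(p, 2, "equal", 6, -2, 300, seed = 81)
  lik <- trial_likelihood(1, 1.0, sim, cfg, ndt = p$ndt)
  cells <- attr(lik, "cells")
  expect_equal(sum(cells), 1, tolerance = 1e-12)
  expect_true(all(cells > 0))
  # the modal simulated cell dominates every other cell
  expect_equal(max(cells), max(cells))
  rt_mode <- p$ndt + 0.05 + 0.1 * (which.max(cells[1:100]) - 1)
  # Laplace smoothing: an empty observed cell gets pseudo / (n + n_cells)
  lik_far <- trial_likelihood(0, 9.95 + p$ndt, sim, cfg, ndt = p$ndt)
  n_cells <- 2 * 100 + 1
  expect_equal(as.numeric(lik_far), 1 / (300 + n_cells), tolerance = 1e-12)
  # an observed RT below the model's minimum response gets the floor
  lik_fast <- trial_likelihood(1, p$ndt - 0.5, sim, cfg, ndt = p$ndt)
  expect_equal(as.numeric(lik_fast), 1 / (300 + n_cells), tolerance = 1e-12)
  expect_true(attr(lik_fast, "clamped"))
})

test_that("compiled and reference likelihood routes agree", {
  # rebuild, in R, exactly the simulated set the compiled negative
  # log-likelihood bins for each trial, and compare the two NLLs
  sub <- small_subject()[1:12, ]
  p <- group_preset("prosocial")
  v2 <- ddm_variant(2)
  cfg <- likelihood_config(n_sims_per_trial = 200)
  seed <- 991
  pool <- rstddm:::cpp_make_noise_pool(cfg$pool_size, seed)
  nll_cpp <- negative_log_likelihood(p, v2, sub, cfg, seed, pool = pool)
  nll_r <- 0
  for (i in seq_len(nrow(sub))) {
    eff <- effective_params(p, v2, as.character(sub$status[i]))
    sim <- rstddm:::cpp_sim_trial_pooled(
      sub$delta_ms[i], sub$delta_mo[i], eff$omega_s, eff$omega_o, eff$rst,
      p$threshold, p$ndt, p$bias, p$sigma, p$dt, cfg$t_max,
      cfg$n_sims_per_trial, pool, seed, i - 1L, 0)
    simdf <- data.frame(choice = ifelse(sim$choice < 0, NA, sim$choice),
                        rt = sim$rt, censored = sim$choice < 0)
    attr(simdf, "dt") <- p$dt
    nll_r <- nll_r - log(as.numeric(
      trial_likelihood(sub$choice[i], sub$rt[i], simdf, cfg, ndt = p$ndt)))
  }
  expect_equal(nll_cpp, nll_r, tolerance = 1e-10)
})

test_that("the objective is deterministic and bounded", {
  sub <- small_subject()[1:30, ]
  p <- group_preset("prosocial")
  cfg <- likelihood_config(n_sims_per_trial = 150)
  n1 <- negative_log_likelihood(p, 2, sub, cfg, seed = 55)
  n2 <- negative_log_likelihood(p, 2, sub, cfg, seed = 55)
  expect_identical(n1, n2)
  n3 <- negative_log_likelihood(p, 2, sub, cfg, seed = 56)
  expect_false(identical(n1, n3))
  # bounds: 0 <= nll <= n_trials * log(denominator / pseudo)
  n_cells <- 2 * ceiling(cfg$t_max / cfg$rt_bin_width) + 1
  expect_gte(n1, 0)
  expect_lte(n1, 30 * log(cfg$n_sims_per_trial + n_cells))
})

test_that("parameter vectors round-trip through ddm_params for all variants", {
  for (v in 1:4) {
    variant <- ddm_variant(v)
    b <- default_bounds(variant)
    set.seed(90 + v)
    theta <- runif(nrow(b), b[, 1], b[, 2])
    p <- rstddm:::vector_to_params(theta, variant)
    back <- rstddm:::params_to_vector(p, variant)
    expect_equal(unname(back), unname(theta), tolerance = 1e-12)
  }
})

test_that("NLL grid oracle: data prefer parameters near their truth", {
  # coarse one-dimensional grids around the generating value, evaluated at
  # large n_sims: the minimum must land at the grid point nearest truth
  d <- small_design()
  truth <- ddm_params(omega_s = 0.12, omega_o = 0.08, rst = 0.3,
                      threshold = 1, ndt = 0.35)
  sub <- generate_synthetic_subject(truth, 2, d$schedule, d$options,
                                    seed = 92)
  cfg <- likelihood_config(n_sims_per_trial = 2000)
  pool <- rstddm:::cpp_make_noise_pool(cfg$pool_size, 93)
  grid_nll <- function(field, values) {
    vapply(values, function(x) {
      p <- truth
      p[[field]][] <- x
      negative_log_likelihood(p, 2, sub, cfg, 93, pool = pool)
    }, 0)
  }
  os_grid <- c(0.03, 0.12, 0.3)
  expect_equal(which.min(grid_nll("omega_s", os_grid)), 2)
  th_grid <- c(0.4, 1.0, 2.2)
  expect_equal(which.min(grid_nll("threshold", th_grid)), 2)
  ndt_grid <- c(0.1, 0.35, 0.9)
  expect_equal(which.min(grid_nll("ndt", ndt_grid)), 2)
})

test_that("differential evolution is elitist and improves monotonically", {
  # quadratic toy objective
  fn <- function(x) sum((x - c(0.3, -0.2)) ^ 2)
  res <- de_optimize(fn, c(-1, -1), c(1, 1), n_iterations = 60,
                     population_size = 15, seed = 7)
  expect_lt(res$value, 1e-3)
  expect_true(all(diff(res$trace) <= 0))
  # seeding the optimum into the population: one iteration cannot lose it
  res1 <- de_optimize(fn, c(-1, -1), c(1, 1), n_iterations = 1,
                      population_size = 10, seed = 8,
                      init = rbind(c(0.3, -0.2)))
  expect_lte(res1$value, fn(c(0.3, -0.2)) + 1e-12)
})

test_that("fit results carry the variant's free-parameter count and BIC", {
  sub <- small_subject()
  cfg <- likelihood_config(n_sims_per_trial = 100)
  de <- de_config(n_iterations = 3, population_size = 8, n_restarts = 1,
                  refine_sims_factor = 1, polish_maxit = 40, seed = 5)
  f2 <- fit_subject(sub, 2, cfg, de)
  f1 <- fit_subject(sub, 1, cfg, de)
  expect_equal(f2$n_free_params, 8L)
  expect_equal(f1$n_free_params, 9L)
  expect_equal(f2$evidence_bic, 2 * f2$nll + 8 * log(f2$n_trials_used))
  expect_equal(f2$log_evidence, -f2$evidence_bic / 2)
  expect_equal(length(f2$restart_nlls), 1)
})
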