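#' Assemble a subjects x models log-evidence matrix from fit results
#'
#' Uses the −BIC/2 log-evidence approximation stored on each fit.
#'
#' @param fits list of `fit_result` objects (e.g. from [fit_cohort()]).
#' @return numeric matrix, rows = subjects, columns = `v1..v4` (or whichever
#'   variants are present).
#' @export
evidence_matrix <- function(fits) {
  sids <- unique(vapply(fits, `[[`, "", "subject_id"))
  vids <- sort(unique(vapply(fits, `[[`, 0L, "variant_id")))
  m <- matrix(NA_real_, length(sids), length(vids),
              dimnames = list(sids, paste0("v", vids)))
  for (f in fits) m[f$subject_id, paste0("v", f$variant_id)] <- f$log_evidence
  if (any(!is.finite(m)))
    stopf("evidence_matrix: missing subject x variant fits")
  m
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over population model frequencies: iterate
#' per-subject posterior model assignments
#' \eqn{u_{nm} \propto \exp(\log ev_{nm} + \psi(\alpha_m) - \psi(\sum\alpha))}
#' and the concentration update \eqn{\alpha_m = \alpha_0 + \sum_n u_{nm}}
#' until the concentration vector converges.  Exceedance probabilities (the
#' posterior probability that each model is the most frequent in the
#' population) are estimated by Monte-Carlo draws from the posterior
#' Dirichlet.
#'
#' @param log_evidence subjects x models matrix of log model evidence.
#' @param prior_alpha uniform prior concentration (default 1).
#' @param n_mc Dirichlet draws for the exceedance probabilities.
#' @param tol convergence tolerance on the concentration vector.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final concentrations.
#' @param seed seed for the Monte-Carlo step.
#' @return list of class `bms_result`: `alpha`, `expected_freq`,
#'   `exceedance_prob`, `assignments` (subjects x models), `n_iter`,
#'   `n_mc_samples`.
#' @export
random_effects_bms <- function(log_evidence, prior_alpha = 1, n_mc = 1e5,
                               tol = 1e-6, max_iter = 500, seed = 1) {
  m <- as.matrix(log_evidence)
  if (nrow(m) < 2 || ncol(m) < 2)
    stopf("random_effects_bms needs >= 2 subjects and >= 2 models")
  if (any(!is.finite(m))) stopf("log evidence must be finite")
  K <- ncol(m)
  alpha <- rep(prior_alpha, K)
  u <- NULL
  for (it in seq_len(max_iter)) {
    lw <- sweep(m, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- prior_alpha + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (it == max_iter)
      stopf("BMS did not converge in %d iterations (alpha = %s)", max_iter,
            paste(signif(alpha, 5), collapse = ", "))
  }
  exp_freq <- alpha / sum(alpha)
  xp <- with_seed(seed, {
    draws <- matrix(rgamma(n_mc * K, shape = rep(alpha, each = n_mc)),
                    nrow = n_mc)
    winners <- max.col(draws, ties.method = "first")
    tabulate(winners, K) / n_mc
  })
  structure(list(alpha = setNames(alpha, colnames(m)),
                 expected_freq = setNames(exp_freq, colnames(m)),
                 exceedance_prob = setNames(xp, colnames(m)),
                 assignments = u, n_iter = it,
                 n_mc_samples = as.integer(n_mc)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    exceedance_prob = x$exceedance_prob), 4))
  invisible(x)
}

#' Exact two-model exceedance probability by numerical integration
#'
#' For `K = 2` the exceedance probability of model 1 is
#' \eqn{P(p_1 > 1/2)} under `Beta(alpha1, alpha2)`, computed here by dense
#' quadrature — an independent oracle for the Monte-Carlo estimate.
#'
#' @param alpha1,alpha2 Dirichlet concentrations.
#' @param n_grid quadrature points.
#' @return exceedance probability of model 1.
#' @export
exceedance_two_model_exact <- function(alpha1, alpha2, n_grid = 200000) {
  # trapezoid rule on the Beta(alpha1, alpha2) density over (1/2, 1)
  x <- seq(0.5, 1, length.out = n_grid)
  fx <- stats::dbeta(x, alpha1, alpha2)
  sum((fx[-1] + fx[-n_grid]) / 2) * (x[2] - x[1])
}

#' Parameter-recovery harness
#'
#' Simulates one synthetic subject per truth set, refits with the same
#' variant, and tabulates per-parameter true-vs-recovered correlation and
#' bias, plus RST sign agreement for RST slots with `|RST| >= rst_sign_min`.
#'
#' @param truth_sets list of [ddm_params()] truths (>= 5 recommended,
#'   dispersed over the bounds).
#' @param variant generating and fitting variant.
#' @param n_trials trials per synthetic subject.
#' @param like_cfg,de_cfg fitting configuration (desk scale by default).
#' @param seed master seed.
#' @param rst_sign_min |RST| threshold for the sign-agreement tally.
#' @param verbose progress.
#' @return list of class `recovery_result`: `true` and `recovered`
#'   parameter matrices, `correlations`, `bias`, `rst_sign_agreement`,
#'   `fits`.
#' @export
parameter_recovery <- function(truth_sets, variant = 2, n_trials = 120,
                               like_cfg = fit_profile("desk")$like,
                               de_cfg = fit_profile("desk")$de,
                               seed = 1, rst_sign_min = 0.3,
                               verbose = FALSE) {
  if (length(truth_sets) < 2) stopf("need at least two truth sets")
  variant <- if (inherits(variant, "ddm_variant")) variant
             else ddm_variant(variant)
  slots <- param_slots(variant)
  n <- length(truth_sets)
  true_m <- matrix(NA_real_, n, length(slots),
                   dimnames = list(NULL, slots))
  rec_m <- true_m
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- derive_seed(seed, "recovery", i)
    sched <- subset_schedule(
      generate_feedback_schedule(derive_seed(sseed, "schedule")), n_trials)
    opts <- generate_option_set(n_trials, derive_seed(sseed, "options"))
    sub <- generate_synthetic_subject(truth_sets[[i]], variant, sched, opts,
                                      derive_seed(sseed, "play"),
                                      subject_id = sprintf("rec_%02d", i))
    sub <- exclude_trials(sub)$kept
    sub <- sub[!is.na(sub$choice), , drop = FALSE]
    de_i <- de_cfg; de_i$seed <- derive_seed(sseed, "fit")
    f <- tryCatch(fit_subject(sub, variant, like_cfg, de_i,
                              verbose = verbose),
                  error = function(e) e)
    if (inherits(f, "error")) {
      fits[[i]] <- f
      next
    }
    fits[[i]] <- f
    true_m[i, ] <- params_to_vector(truth_sets[[i]], variant)
    rec_m[i, ] <- f$best_vector
  }
  ok <- stats::complete.cases(true_m) & stats::complete.cases(rec_m)
  cors <- vapply(slots, function(s) {
    tv <- true_m[ok, s]; rv <- rec_m[ok, s]
    if (sd(tv) < 1e-12 || sd(rv) < 1e-12) NA_real_ else cor(tv, rv)
  }, 0)
  bias <- colMeans(rec_m[ok, , drop = FALSE] - true_m[ok, , drop = FALSE])
  rst_slots <- grep("^rst", slots, value = TRUE)
  sign_agree <- NA_real_
  if (length(rst_slots) > 0) {
    tv <- as.vector(true_m[ok, rst_slots])
    rv <- as.vector(rec_m[ok, rst_slots])
    big <- abs(tv) >= rst_sign_min
    if (any(big)) sign_agree <- mean(sign(tv[big]) == sign(rv[big]))
  }
  structure(list(true = true_m, recovered = rec_m, correlations = cors,
                 bias = bias, rst_sign_agreement = sign_agree,
                 n_completed = sum(ok), fits = fits),
            class = "recovery_result")
}

#' Model-recovery harness
#'
#' For each generating variant, simulates a small cohort, fits all candidate
#' variants to every subject, and runs random-effects model selection; the
#' confusion matrix tallies which variant wins (highest exceedance
#' probability) per generating variant.
#'
#' @param generating_variants variants to generate from.
#' @param fit_variants variants fitted to each cohort (default all four).
#' @param n_subjects,n_trials cohort size per generating variant.
#' @param truth_fn function(variant_id, subject_index, seed) returning the
#'   generating [ddm_params()]; defaults to dispersed draws around the
#'   prosocial preset, with RST structure appropriate to the variant.
#' @param like_cfg,de_cfg fitting configuration.
#' @param seed master seed.
#' @param verbose progress.
#' @return list of class `model_recovery_result`: `confusion` (generating x
#'   winning counts), `exceedance` (generating x fitted EXP), `bms` per
#'   generating variant.
#' @export
model_recovery <- function(generating_variants = c(1, 2), fit_variants = 1:4,
                           n_subjects = 5, n_trials = 90,
                           truth_fn = NULL,
                           like_cfg = fit_profile("desk")$like,
                           de_cfg = de_config(n_iterations = 40,
                                              population_size = 20,
                                              n_restarts = 2,
                                              refine_sims_factor = 2,
                                              polish_maxit = 200),
                           seed = 1, verbose = FALSE) {
  truth_fn <- truth_fn %||% default_truth_fn
  vlab <- paste0("v", fit_variants)
  confusion <- matrix(0L, length(generating_variants), length(fit_variants),
                      dimnames = list(paste0("gen_v", generating_variants),
                                      vlab))
  exceed <- matrix(NA_real_, length(generating_variants),
                   length(fit_variants),
                   dimnames = dimnames(confusion))
  bms_list <- list()
  for (gi in seq_along(generating_variants)) {
    gv <- generating_variants[gi]
    cohort <- list()
    for (k in seq_len(n_subjects)) {
      sseed <- derive_seed(seed, "modelrec", gv, k)
      truth <- truth_fn(gv, k, sseed)
      sched <- subset_schedule(
        generate_feedback_schedule(derive_seed(sseed, "schedule")), n_trials)
      opts <- generate_option_set(n_trials, derive_seed(sseed, "options"))
      cohort[[k]] <- generate_synthetic_subject(
        truth, gv, sched, opts, derive_seed(sseed, "play"),
        subject_id = sprintf("g%d_s%02d", gv, k))
    }
    cohort <- do.call(rbind, cohort)
    de_g <- de_cfg; de_g$seed <- derive_seed(seed, "modelrec-fit", gv)
    fits <- fit_cohort(cohort, variants = fit_variants, like_cfg, de_g,
                       verbose = verbose)
    ev <- evidence_matrix(fits)
    bms <- random_effects_bms(ev, seed = derive_seed(seed, "bms", gv))
    bms_list[[paste0("gen_v", gv)]] <- bms
    exceed[gi, ] <- bms$exceedance_prob[vlab]
    win <- which.max(bms$exceedance_prob[vlab])
    confusion[gi, win] <- confusion[gi, win] + 1L
  }
  structure(list(confusion = confusion, exceedance = exceed,
                 bms = bms_list),
            class = "model_recovery_result")
}

# Dispersed generating truths for recovery harnesses.  RST slots honour
# each variant's structure (zero for variant 1, shared for variant 3).
# Weight-by-status variants get a structured status gradient (other-weight
# rising, self-weight falling from better to worse) -- the behavioural
# pattern that variant expresses through weights; near-shared weights would
# make such truths indistinguishable from the shared-weight variants and
# parsimony would rightly vote against the generator.
default_truth_fn <- function(variant_id, subject_index, seed) {
  v <- ddm_variant(variant_id)
  with_seed(derive_seed(seed, "truth"), {
    os <- runif(1, 0.06, 0.32)
    oo <- runif(1, 0.03, 0.28)
    if (v$weights_by_status) {
      grad_s <- runif(1, 0.02, 0.06)
      grad_o <- runif(1, 0.03, 0.08)
      os <- pmax(0.02, os + grad_s * c(1, 0, -1) + runif(3, -0.01, 0.01))
      oo <- pmax(0.01, oo + grad_o * c(-1, 0, 1) + runif(3, -0.01, 0.01))
    }
    rst <- if (v$rst_fixed_zero) 0
           else if (v$rst_by_status) runif(3, -1.3, 1.3)
           else runif(1, -1.3, 1.3)
    threshold <- runif(1, 0.8, 1.5)
    ddm_params(omega_s = os, omega_o = oo, rst = rst,
               threshold = threshold,
               ndt = runif(1, 0.2, 0.55),
               bias = runif(1, -0.25, 0.25) * threshold)
  })
}
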