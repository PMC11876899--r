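#' Choice proportions per subject and status
#'
#' Fraction of trials in which the chosen option carried the larger
#' self-payoff, and the fraction in which it carried the larger
#' other-payoff.  The two proportions are computed independently, so trials
#' where one option dominates on both attributes count toward both tallies;
#' trials with `delta_mo == 0` are excluded from the larger-Mo denominator.
#'
#' @param data trial records with `choice` (1 = larger-Ms option chosen).
#' @return data.frame with `subject_id`, `status`, `n_trials`,
#'   `p_larger_ms`, `p_larger_mo`; empty cells yield NA with `flagged` TRUE.
#' @export
choice_proportions <- function(data) {
  stopifnot(all(c("choice", "status", "delta_mo") %in% names(data)))
  data <- data[!is.na(data$choice), , drop = FALSE]
  sid <- as.character(data$subject_id %||% "all")
  status <- as_status(data$status)
  out <- list()
  for (s in unique(sid)) {
    for (st in STATUS_LEVELS) {
      i <- which(sid == s & status == st)
      mo_def <- i[data$delta_mo[i] != 0]
      # chose larger Mo: option 1 when delta_mo > 0, option 2 when < 0
      chose_mo <- (data$choice[mo_def] == 1) == (data$delta_mo[mo_def] > 0)
      out[[paste(s, st)]] <- data.frame(
        subject_id = s, status = st, n_trials = length(i),
        p_larger_ms = if (length(i)) mean(data$choice[i] == 1) else NA_real_,
        p_larger_mo = if (length(mo_def)) mean(chose_mo) else NA_real_,
        flagged = length(i) == 0)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$status <- factor(res$status, levels = STATUS_LEVELS)
  res
}

#' Per-subject, per-status logistic decision betas
#'
#' Two-stage analogue of the random-slopes choice model: for every subject
#' and status cell, `choice ~ delta_ms + delta_mo` is fitted by logistic
#' regression (choice = 1 for the larger self-payoff option); group-level
#' summaries are means and SEMs across subjects.  Perfect separation is
#' flagged, and an optional ridge penalty stabilises small cells.
#'
#' @param data trial records.
#' @param ridge ridge penalty added to the logistic score equations (0
#'   disables; small cells at desk scale benefit from the default 1e-3).
#' @return data.frame of class `decision_betas` with `subject_id`, `status`,
#'   `intercept`, `beta_dms`, `beta_dmo`, `relative_beta`
#'   (= beta_dms − beta_dmo), `n_trials`, `separated`.
#' @export
decision_betas <- function(data, ridge = 1e-3) {
  data <- data[!is.na(data$choice), , drop = FALSE]
  sid <- as.character(data$subject_id %||% "all")
  status <- as_status(data$status)
  out <- list()
  for (s in unique(sid)) {
    for (st in STATUS_LEVELS) {
      i <- which(sid == s & status == st)
      if (length(i) == 0) next
      fit <- logistic_fit(data$choice[i],
                          cbind(dms = data$delta_ms[i],
                                dmo = data$delta_mo[i]), ridge)
      out[[paste(s, st)]] <- data.frame(
        subject_id = s, status = st, intercept = fit$coef[1],
        beta_dms = fit$coef[2], beta_dmo = fit$coef[3],
        relative_beta = fit$coef[2] - fit$coef[3],
        n_trials = length(i), separated = fit$separated)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$status <- factor(res$status, levels = STATUS_LEVELS)
  class(res) <- c("decision_betas", class(res))
  res
}

# Logistic regression with an optional ridge penalty via iterated
# reweighted least squares; flags (quasi-)separation.
logistic_fit <- function(y, X, ridge = 0) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  separated <- FALSE
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (all(w < 1e-10)) { separated <- TRUE; break }
    H <- crossprod(Xd, Xd * w) + diag(ridge, p)
    g <- crossprod(Xd, y - mu) - ridge * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  if (max(abs(beta[-1])) > 10) separated <- TRUE
  list(coef = setNames(drop(beta), c("intercept", colnames(X))),
       separated = separated)
}

#' Group-level summary of decision betas
#'
#' @param betas output of [decision_betas()].
#' @return data.frame with per-status mean and SEM of `beta_dms`,
#'   `beta_dmo` and `relative_beta` across subjects.
#' @export
summarize_decision_betas <- function(betas) {
  out <- list()
  for (st in STATUS_LEVELS) {
    b <- betas[betas$status == st, , drop = FALSE]
    sem <- function(x) sd(x) / sqrt(length(x))
    out[[st]] <- data.frame(
      status = st, n_subjects = nrow(b),
      mean_beta_dms = mean(b$beta_dms), sem_beta_dms = sem(b$beta_dms),
      mean_beta_dmo = mean(b$beta_dmo), sem_beta_dmo = sem(b$beta_dmo),
      mean_relative_beta = mean(b$relative_beta),
      sem_relative_beta = sem(b$relative_beta))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sliding-window decision betas over response time
#'
#' Logistic `choice ~ delta_ms + delta_mo` regressions over trials whose RT
#' falls in 100 ms windows moved in 10 ms steps — the read-out that makes an
#' attribute's onset latency visible: before the late attribute's entry its
#' beta is indistinguishable from zero.
#'
#' @param sim_data simulated (or observed) trial records with `rt`.
#' @param window window width in seconds.
#' @param step window step in seconds.
#' @param min_trials windows with fewer trials are skipped (gap, not error).
#' @param rt_range optional c(lo, hi) limits for window centres; defaults to
#'   the data range.
#' @param ridge ridge penalty for window fits.
#' @return data.frame with `t_center`, `n_trials`, `beta_dms`, `beta_dmo`,
#'   `se_dms`, `se_dmo`; skipped windows are absent.
#' @export
sliding_window_betas <- function(sim_data, window = 0.1, step = 0.01,
                                 min_trials = 20, rt_range = NULL,
                                 ridge = 1e-3) {
  data <- sim_data[!is.na(sim_data$choice) & !is.na(sim_data$rt), ,
                   drop = FALSE]
  if (nrow(data) == 0) stopf("sliding_window_betas: no usable trials")
  rt_range <- rt_range %||% range(data$rt)
  centers <- seq(rt_range[1] + window / 2, rt_range[2] - window / 2,
                 by = step)
  out <- list()
  for (tc in centers) {
    i <- which(data$rt >= tc - window / 2 & data$rt < tc + window / 2)
    if (length(i) < min_trials) next
    fit <- logistic_fit(data$choice[i],
                        cbind(dms = data$delta_ms[i],
                              dmo = data$delta_mo[i]), ridge)
    # large-sample SEs from the penalised information matrix
    se <- tryCatch({
      Xd <- cbind(1, data$delta_ms[i], data$delta_mo[i])
      mu <- plogis(drop(Xd %*% fit$coef))
      sqrt(diag(solve(crossprod(Xd, Xd * mu * (1 - mu)) + diag(ridge, 3))))
    }, error = function(e) rep(NA_real_, 3))
    out[[sprintf("%.3f", tc)]] <- data.frame(
      t_center = tc, n_trials = length(i),
      beta_dms = fit$coef[2], beta_dmo = fit$coef[3],
      se_dms = se[2], se_dmo = se[3], separated = fit$separated)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Split-half cross-validation of a fitted variant
#'
#' Splits each status condition's trials at random into two halves, fits the
#' variant on half A, then simulates every held-out trial `n_rep` times
#' under the fitted parameters.  Reports per-status held-out choice accuracy
#' (modal predicted choice vs actual) and the correlation between mean
#' simulated RT and actual RT.
#'
#' @param data one subject's trial records.
#' @param variant fitted [ddm_variant()] or id.
#' @param like_cfg,de_cfg fitting configuration.
#' @param n_rep simulations per held-out trial.
#' @param seed seed controlling both the split and the simulations.
#' @return list with `fit`, and `by_status` data.frame of `accuracy` and
#'   `rt_correlation`.
#' @export
split_half_crossval <- function(data, variant,
                                like_cfg = fit_profile("desk")$like,
                                de_cfg = fit_profile("desk")$de,
                                n_rep = 100, seed = 1) {
  data <- data[!is.na(data$choice), , drop = FALSE]
  status <- as_status(data$status)
  if (min(table(status)) < 20)
    stopf("split_half_crossval needs >= 20 trials per status")
  half_a <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(STATUS_LEVELS, function(st) {
      i <- which(status == st)
      sample(i, floor(length(i) / 2))
    }))
  })
  train <- data[half_a, , drop = FALSE]
  test <- data[-half_a, , drop = FALSE]
  de_cfg$seed <- derive_seed(seed, "cv-fit")
  fit <- fit_subject(train, variant, like_cfg, de_cfg)
  p <- fit$best_params
  out <- list()
  for (st in STATUS_LEVELS) {
    i <- which(as_status(test$status) == st)
    if (length(i) == 0) next
    pred_choice <- numeric(length(i)); pred_rt <- numeric(length(i))
    for (k in seq_along(i)) {
      row <- test[i[k], ]
      sim <- simulate_trial_distribution(
        p, variant, st, row$delta_ms, row$delta_mo, n_rep,
        derive_seed(seed, "cv-sim", st, k), t_max = like_cfg$t_max)
      pred_choice[k] <- mean(sim$choice, na.rm = TRUE)
      pred_rt[k] <- mean(sim$rt, na.rm = TRUE)
    }
    acc <- mean((pred_choice > 0.5) == (test$choice[i] == 1))
    rtc <- if (sd(pred_rt) > 0 && sd(test$rt[i]) > 0)
      cor(pred_rt, test$rt[i]) else NA_real_
    out[[st]] <- data.frame(status = st, n_test = length(i),
                            accuracy = acc, rt_correlation = rtc,
                            mean_pred_rt = mean(pred_rt),
                            mean_actual_rt = mean(test$rt[i]))
  }
  list(fit = fit,
       by_status = do.call(rbind, c(out, list(make.row.names = FALSE))))
}
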