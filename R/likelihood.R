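#' Likelihood configuration for the simulation-based likelihood
#'
#' The likelihood of an observed (choice, RT) pair is read off a smoothed
#' histogram of `n_sims_per_trial` simulated outcomes of that trial, binned
#' over choice x RT-bin cells with one extra cell for censored paths.
#'
#' @param n_sims_per_trial simulated outcomes per trial (full scale 3,000;
#'   desk scale 300).
#' @param rt_bin_width RT bin width in seconds.
#' @param pseudo_count Laplace smoothing mass added to every cell.
#' @param t_max accumulation horizon in seconds; RT support is
#'   `[ndt, ndt + t_max]`.
#' @param common_random_numbers reuse one noise pool across objective
#'   evaluations so the likelihood is a deterministic function of the
#'   parameters (recommended for optimisation); if `FALSE` each evaluation
#'   re-randomises.
#' @param pool_size size of the shared noise pool (power of two).
#' @return list of class `likelihood_config`.
#' @export
likelihood_config <- function(n_sims_per_trial = 300, rt_bin_width = 0.1,
                              pseudo_count = 1, t_max = 10,
                              common_random_numbers = TRUE,
                              pool_size = 2^18) {
  stopifnot(n_sims_per_trial >= 100, rt_bin_width > 0, pseudo_count > 0,
            t_max > 0)
  structure(list(n_sims_per_trial = as.integer(n_sims_per_trial),
                 rt_bin_width = rt_bin_width,
                 pseudo_count = pseudo_count,
                 t_max = t_max,
                 common_random_numbers = isTRUE(common_random_numbers),
                 pool_size = as.integer(pool_size)),
            class = "likelihood_config")
}

#' Exclude implausibly slow trials
#'
#' Removes trials with RT above 10 s, or above the subject's mean + 3 SD
#' (both statistics computed on the pre-exclusion set).  Applied per subject
#' when a `subject_id` column is present.
#'
#' @param data trial records with an `rt` column.
#' @param rt_cap absolute cap in seconds.
#' @param n_sd standard-deviation multiplier.
#' @return list with `kept`, `excluded` data.frames and a per-subject
#'   `report`.
#' @export
exclude_trials <- function(data, rt_cap = 10, n_sd = 3) {
  if (nrow(data) == 0) stopf("exclude_trials: empty input")
  if (any(!is.finite(data$rt) & !data$censored %||% FALSE))
    stopf("exclude_trials: missing RTs on non-censored trials")
  sid <- if ("subject_id" %in% names(data)) data$subject_id else "all"
  drop <- logical(nrow(data))
  report <- list()
  for (s in unique(sid)) {
    i <- which(sid == s)
    rts <- data$rt[i]
    mu <- mean(rts, na.rm = TRUE)
    sdev <- sd(rts, na.rm = TRUE)
    if (!is.finite(sdev)) sdev <- 0
    bad <- !is.na(rts) & (rts > rt_cap | rts > mu + n_sd * sdev)
    drop[i] <- bad
    report[[as.character(s)]] <- data.frame(
      subject_id = s, n_total = length(i), n_excluded = sum(bad),
      mean_rt = mu, sd_rt = sdev)
  }
  list(kept = data[!drop, , drop = FALSE],
       excluded = data[drop, , drop = FALSE],
       report = do.call(rbind, c(report, list(make.row.names = FALSE))))
}

#' Likelihood of one observed outcome under a simulated outcome set
#'
#' Reference (pure-R) implementation of the histogram likelihood: the
#' simulated outcomes are binned into choice x RT-bin cells (censored
#' outcomes in their own cell), each cell receives `pseudo_count` extra
#' mass, and the observed outcome's cell probability is returned.  Observed
#' RTs beyond the upper end of the support clamp to the last bin; RTs below
#' the model's minimum possible response (`ndt + dt`) receive the smoothing
#' floor only (flagged `clamped`), which keeps every probability strictly
#' positive without letting inflated non-decision times absorb observations.
#' The fitting path evaluates the identical construction in compiled code;
#' the two routes are cross-checked in the test suite.
#'
#' @param choice observed choice (0/1; NA for a censored observation).
#' @param rt observed RT in seconds.
#' @param sim data.frame from [simulate_trial_distribution()].
#' @param cfg a [likelihood_config()].
#' @param ndt non-decision time anchoring the RT support.
#' @return scalar probability; attributes `cells` (the full probability
#'   table) and `clamped`.
#' @export
trial_likelihood <- function(choice, rt, sim, cfg, ndt) {
  stopifnot(nrow(sim) > 0)
  n_bins <- as.integer(ceiling(cfg$t_max / cfg$rt_bin_width - 1e-12))
  n_cells <- 2L * n_bins + 1L
  counts <- numeric(n_cells)
  bin_of <- function(rt_rel) {
    # floor(x / w), not x %/% w: the integer-division operator uses fmod
    # semantics that disagree with plain division at exact bin boundaries
    b <- if (rt_rel <= 0) 0L else as.integer(floor(rt_rel / cfg$rt_bin_width))
    min(b, n_bins - 1L)
  }
  for (j in seq_len(nrow(sim))) {
    if (sim$censored[j]) counts[n_cells] <- counts[n_cells] + 1
    else {
      b <- bin_of(sim$rt[j] - ndt)
      counts[sim$choice[j] * n_bins + b + 1L] <-
        counts[sim$choice[j] * n_bins + b + 1L] + 1
    }
  }
  denom <- nrow(sim) + cfg$pseudo_count * n_cells
  probs <- (counts + cfg$pseudo_count) / denom
  clamped <- FALSE
  if (is.na(choice)) {
    p <- probs[n_cells]
  } else {
    rel <- rt - ndt
    dt <- attr(sim, "dt") %||% 0.01
    if (rel < dt) {
      # impossible under the model's minimum response ndt + dt: smoothing
      # floor only, so inflated ndt values cannot soak up observations
      p <- cfg$pseudo_count / denom
      clamped <- TRUE
    } else {
      clamped <- rel >= cfg$t_max
      p <- probs[choice * n_bins + bin_of(rel) + 1L]
    }
  }
  structure(p, cells = probs, clamped = clamped)
}

# Map a variant's free-parameter vector to/from a ddm_params object.  The
# bias is parameterised as a fraction of threshold so the box constraint
# |bias| < threshold holds for any vector inside the bounds.
param_slots <- function(variant) {
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  slots <- character(0)
  slots <- c(slots,
             if (variant$weights_by_status)
               c("omega_s_b", "omega_s_e", "omega_s_w",
                 "omega_o_b", "omega_o_e", "omega_o_w")
             else c("omega_s", "omega_o"))
  if (!variant$rst_fixed_zero)
    slots <- c(slots,
               if (variant$rst_by_status) c("rst_b", "rst_e", "rst_w")
               else "rst")
  c(slots, "threshold", "ndt", "bias_frac")
}

#' Default per-slot fitting bounds
#'
#' Attribute weights in `[-0.5, 0.5]` per point, RST in `[-2, 2]` s,
#' threshold in `[0.1, 5]`, non-decision time in `[0.05, 1.5]` s, and bias
#' as a fraction of threshold in `[-0.9, 0.9]`.  Declared package
#' defaults.
#'
#' @param variant a [ddm_variant()] or id.
#' @return matrix with rownames = slots and columns `lower`, `upper`.
#' @export
default_bounds <- function(variant) {
  slots <- param_slots(variant)
  base <- list(omega = c(-0.5, 0.5), rst = c(-2, 2), threshold = c(0.1, 5),
               ndt = c(0.05, 1.5), bias_frac = c(-0.9, 0.9))
  pick <- function(slot) {
    if (grepl("^omega", slot)) base$omega
    else if (grepl("^rst", slot)) base$rst
    else base[[slot]]
  }
  m <- t(vapply(slots, pick, numeric(2)))
  colnames(m) <- c("lower", "upper")
  m
}

vector_to_params <- function(theta, variant, sigma = 0.1, dt = 0.01) {
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  slots <- param_slots(variant)
  stopifnot(length(theta) == length(slots))
  th <- setNames(as.numeric(theta), slots)
  grab3 <- function(stem) {
    if (variant$weights_by_status && stem %in% c("omega_s", "omega_o"))
      c(better = th[[paste0(stem, "_b")]], equal = th[[paste0(stem, "_e")]],
        worse = th[[paste0(stem, "_w")]])
    else th[[stem]]
  }
  rst <- if (variant$rst_fixed_zero) 0
         else if (variant$rst_by_status)
           c(better = th[["rst_b"]], equal = th[["rst_e"]],
             worse = th[["rst_w"]])
         else th[["rst"]]
  ddm_params(omega_s = grab3("omega_s"), omega_o = grab3("omega_o"),
             rst = rst, threshold = th[["threshold"]], ndt = th[["ndt"]],
             bias = th[["bias_frac"]] * th[["threshold"]],
             sigma = sigma, dt = dt)
}

params_to_vector <- function(params, variant) {
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  slots <- param_slots(variant)
  eff <- lapply(setNames(STATUS_LEVELS, STATUS_LEVELS),
                function(s) effective_params(params, variant, s))
  val <- function(slot) {
    switch(slot,
      omega_s = eff$better$omega_s, omega_o = eff$better$omega_o,
      omega_s_b = eff$better$omega_s, omega_s_e = eff$equal$omega_s,
      omega_s_w = eff$worse$omega_s,
      omega_o_b = eff$better$omega_o, omega_o_e = eff$equal$omega_o,
      omega_o_w = eff$worse$omega_o,
      rst = eff$better$rst,
      rst_b = eff$better$rst, rst_e = eff$equal$rst, rst_w = eff$worse$rst,
      threshold = params$threshold, ndt = params$ndt,
      bias_frac = params$bias / params$threshold)
  }
  setNames(vapply(slots, val, 0), slots)
}

# Status-resolved parameter triples for the compiled likelihood.
resolve_triples <- function(params, variant) {
  eff <- lapply(STATUS_LEVELS, function(s) effective_params(params, variant, s))
  list(os = vapply(eff, `[[`, 0, "omega_s"),
       oo = vapply(eff, `[[`, 0, "omega_o"),
       rst = vapply(eff, `[[`, 0, "rst"))
}

#' Negative log-likelihood of a subject's data under one variant
#'
#' Sums `-log` trial likelihoods over all trials, simulating
#' `cfg$n_sims_per_trial` outcomes per trial from a noise pool derived
#' deterministically from `seed` (and, when common random numbers are off,
#' from a parameter hash), so identical inputs always give identical values.
#'
#' @param params a [ddm_params()] object.
#' @param variant a [ddm_variant()] or id.
#' @param data exclusion-filtered trial records with `delta_ms`, `delta_mo`,
#'   `status`, `choice`, `rt`.
#' @param cfg a [likelihood_config()].
#' @param seed integer seed for the simulation noise.
#' @param pool optional pre-built noise pool (internal reuse).
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, variant, data, cfg, seed,
                                    pool = NULL) {
  if (nrow(data) == 0) stopf("negative_log_likelihood: no trials")
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  tri <- resolve_triples(params, variant)
  if (is.null(pool)) pool <- cpp_make_noise_pool(cfg$pool_size, seed)
  salt <- if (cfg$common_random_numbers) 0
          else param_hash(params_to_vector(params, variant))
  st <- as.integer(as_status(data$status)) - 1L
  cpp_negloglik(as.numeric(data$delta_ms), as.numeric(data$delta_mo), st,
                as.integer(ifelse(is.na(data$choice), -1L, data$choice)),
                as.numeric(data$rt),
                tri$os, tri$oo, tri$rst,
                params$threshold, params$ndt, params$bias,
                params$sigma, params$dt, cfg$t_max,
                cfg$n_sims_per_trial, cfg$rt_bin_width, cfg$pseudo_count,
                pool, seed, salt)
}

# Deterministic 31-bit hash of a numeric parameter vector.
param_hash <- function(theta) {
  derive_seed(0, paste(sprintf("%.12g", theta), collapse = ","))
}
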