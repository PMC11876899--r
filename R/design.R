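#' Generate a dictator-game option set under the task's correlation limits
#'
#' Each option's self- and other-payoffs are drawn uniformly from 1..20
#' points.  A whole candidate set is accepted only if, after relabelling so
#' the larger self-payoff option is option 1 (so `delta_ms > 0`), (a) the
#' correlation between self- and other-payoffs within each option and (b)
#' the correlation between `delta_ms` and `delta_mo` all lie in
#' `[-0.1, 0.1]`.  Rejection sampling of whole sets keeps the marginal
#' payoff distribution uniform; per-trial repair would not.
#'
#' @param n_trials number of option pairs (>= 10; the correlation
#'   constraints are meaningless below that).
#' @param seed RNG seed.
#' @param max_tries resampling cap before giving up.
#' @param max_abs_cor correlation band half-width (task constant 0.1).
#' @return data.frame with columns `ms1, mo1, ms2, mo2, delta_ms, delta_mo`
#'   and attribute `tries`.
#' @export
generate_option_set <- function(n_trials, seed, max_tries = 10000,
                                max_abs_cor = 0.1) {
  if (n_trials < 10) stopf("n_trials must be >= 10")
  out <- with_seed(seed, {
    res <- NULL
    for (try in seq_len(max_tries)) {
      ms1 <- sample.int(20L, n_trials, replace = TRUE)
      mo1 <- sample.int(20L, n_trials, replace = TRUE)
      ms2 <- sample.int(20L, n_trials, replace = TRUE)
      mo2 <- sample.int(20L, n_trials, replace = TRUE)
      # delta_ms must be strictly positive, so equal self-payoff draws are
      # redrawn per trial (pairs stay uniform off the diagonal; rejecting
      # whole sets over ties would make large sets unreachable)
      for (guard in 1:100) {
        tie <- ms1 == ms2
        if (!any(tie)) break
        ms1[tie] <- sample.int(20L, sum(tie), replace = TRUE)
        ms2[tie] <- sample.int(20L, sum(tie), replace = TRUE)
      }
      if (any(ms1 == ms2)) next
      swap <- ms1 < ms2
      tmp <- ms1[swap]; ms1[swap] <- ms2[swap]; ms2[swap] <- tmp
      tmp <- mo1[swap]; mo1[swap] <- mo2[swap]; mo2[swap] <- tmp
      dms <- ms1 - ms2
      dmo <- mo1 - mo2
      cors <- c(opt1 = cor(ms1, mo1), opt2 = cor(ms2, mo2),
                delta = cor(dms, dmo))
      if (any(!is.finite(cors))) next
      if (all(abs(cors) <= max_abs_cor)) {
        res <- data.frame(ms1 = ms1, mo1 = mo1, ms2 = ms2, mo2 = mo2,
                          delta_ms = dms, delta_mo = dmo)
        attr(res, "tries") <- try
        attr(res, "correlations") <- cors
        break
      }
    }
    res
  })
  if (is.null(out))
    stopf(paste0("option-set constraints (|r| <= %.2g for within-option and ",
                 "delta correlations) not satisfied within %d tries"),
          max_abs_cor, max_tries)
  out
}

#' Generate the covert dot-task feedback schedule
#'
#' The manipulated feedback multiset is fixed: 60 trials where both players
#' are correct (BC), 60 both wrong (BW), 90 subject-correct/co-player-wrong
#' (SC) and 90 the reverse (SW).  BC and BW collapse to `equal` relative
#' status; SC maps to `better`, SW to `worse` — so status counts are always
#' 90 / 120 / 90.  Dot counts per option are drawn uniformly from 32..34
#' with unequal counts between options (metadata only; subjects' actual dot
#' accuracy is at chance and feedback is overwritten by this schedule).
#'
#' @param seed RNG seed.
#' @return data.frame with columns `trial_index`, `feedback` (BC/BW/SC/SW),
#'   `status` (better/equal/worse), `dots1`, `dots2`.
#' @export
generate_feedback_schedule <- function(seed) {
  with_seed(seed, {
    feedback <- sample(rep(c("BC", "BW", "SC", "SW"), c(60L, 60L, 90L, 90L)))
    status <- c(BC = "equal", BW = "equal", SC = "better",
                SW = "worse")[feedback]
    n <- length(feedback)
    dots1 <- sample(32:34, n, replace = TRUE)
    dots2 <- integer(n)
    for (i in seq_len(n)) {
      dots2[i] <- sample(setdiff(32:34, dots1[i]), 1L)
    }
    data.frame(trial_index = seq_len(n), feedback = feedback,
               status = factor(status, levels = STATUS_LEVELS),
               dots1 = dots1, dots2 = dots2, row.names = NULL)
  })
}

#' Simulate one subject's choices and RTs over a full design
#'
#' Plays every trial of the design through the RST DDM under the
#' status-appropriate effective parameters.  Trials whose diffusion path
#' fails to absorb within `t_max` are kept and flagged `censored`, never
#' silently dropped.
#'
#' @param params a [ddm_params()] object (the subject's truth).
#' @param variant generating [ddm_variant()] or id.
#' @param schedule a [generate_feedback_schedule()] table.
#' @param options a [generate_option_set()] table of the same length.
#' @param seed RNG seed for this subject.
#' @param subject_id identifier stored on each record.
#' @param t_max accumulation horizon (seconds).
#' @return data.frame of trial records: `subject_id`, `trial_index`,
#'   `status`, `ms1, mo1, ms2, mo2`, `delta_ms`, `delta_mo`, `choice`, `rt`,
#'   `censored`; attribute `seed`.
#' @export
generate_synthetic_subject <- function(params, variant, schedule, options,
                                       seed, subject_id = "s1", t_max = 10) {
  if (nrow(schedule) != nrow(options))
    stopf("schedule (%d) and options (%d) lengths differ",
          nrow(schedule), nrow(options))
  validate_ddm_params(params)
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  n <- nrow(schedule)
  choice <- integer(n); rt <- numeric(n); censored <- logical(n)
  for (st in STATUS_LEVELS) {
    idx <- which(schedule$status == st)
    if (length(idx) == 0) next
    eff <- effective_params(params, variant, st)
    for (i in idx) {
      res <- cpp_simulate_paths(1L, options$delta_ms[i], options$delta_mo[i],
                                eff$omega_s, eff$omega_o, eff$rst,
                                params$threshold, params$ndt, params$bias,
                                params$sigma, params$dt, t_max,
                                derive_seed(seed, "trial", i))
      censored[i] <- res$choice[1] < 0
      choice[i] <- if (censored[i]) NA_integer_ else res$choice[1]
      rt[i] <- res$rt[1]
    }
  }
  out <- data.frame(subject_id = subject_id,
                    trial_index = schedule$trial_index,
                    status = schedule$status,
                    options[, c("ms1", "mo1", "ms2", "mo2",
                                "delta_ms", "delta_mo")],
                    choice = choice, rt = rt, censored = censored,
                    row.names = NULL)
  attr(out, "seed") <- seed
  out
}

#' Group parameter presets for synthetic cohorts
#'
#' Declared, synthetic assumptions (no empirical group-level parameter
#' estimates are bundled): the prosocial preset has a smaller
#' self-over-other weight gap and a status-monotone RST profile (better >
#' equal > worse, crossing zero); the individualistic preset has a larger
#' `omega_s - omega_o` and a nearly flat RST profile.  Both are variant-2
#' parameter sets (shared weights, status-specific RSTs).
#'
#' @param group `"prosocial"` or `"individualistic"`.
#' @return a [ddm_params()] object.
#' @export
group_preset <- function(group = c("prosocial", "individualistic")) {
  group <- match.arg(group)
  if (group == "prosocial") {
    ddm_params(omega_s = 0.12, omega_o = 0.06,
               rst = c(better = 0.5, equal = 0.15, worse = -0.35),
               threshold = 1, ndt = 0.35, bias = 0)
  } else {
    ddm_params(omega_s = 0.16, omega_o = 0.025,
               rst = c(better = 0.35, equal = 0.28, worse = 0.22),
               threshold = 1, ndt = 0.35, bias = 0)
  }
}

#' Specify a synthetic cohort
#'
#' @param n_subjects subjects per group.
#' @param group_params named list mapping group label to a [ddm_params()]
#'   preset; defaults to [group_preset()] for both groups.
#' @param variant generating variant id (default 2, the RST-by-status model).
#' @param n_trials trials per subject (study-1 design: 5 sessions x 60).
#' @param study `"study1"` (one choice per dot trial, no RT cap) or
#'   `"study2"` (blocks of 2-4 choices per dot trial, 6 s response cap —
#'   slower diffusion paths are censored).
#' @param seed master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 4, group_params = NULL, variant = 2,
                        n_trials = 300, study = c("study1", "study2"),
                        seed = 1) {
  study <- match.arg(study)
  if (is.null(group_params))
    group_params <- list(prosocial = group_preset("prosocial"),
                         individualistic = group_preset("individualistic"))
  lapply(group_params, validate_ddm_params)
  structure(list(n_subjects = as.integer(n_subjects),
                 group_params = group_params,
                 variant = ddm_variant(variant),
                 n_trials = as.integer(n_trials),
                 study = study,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Study-2/3 layout: dictator trials come in blocks of 2-4 after each dot
# trial, inheriting the block's status feedback.  Returns a schedule-shaped
# table with an extra dot_block column; status ratios approximate 90/120/90.
block_schedule <- function(sched, n_trials, seed) {
  with_seed(seed, {
    rows <- list(); block <- 0L
    i <- 1L; total <- 0L
    while (total < n_trials) {
      block <- block + 1L
      k <- sample(2:4, 1L)
      k <- min(k, n_trials - total)
      src <- sched[((block - 1L) %% nrow(sched)) + 1L, ]
      for (j in seq_len(k)) {
        total <- total + 1L
        rows[[total]] <- data.frame(
          trial_index = total, feedback = src$feedback,
          status = src$status, dots1 = src$dots1, dots2 = src$dots2,
          dot_block = block)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a full synthetic cohort
#'
#' Each subject gets an independent option set, feedback schedule and RNG
#' stream (derived from the cohort seed, the group label and the subject
#' index), so the output is bit-identical under identical specs.  When
#' `n_trials` differs from 300 the feedback schedule is truncated or
#' recycled proportionally while preserving the 90/120/90 status ratio as
#' closely as integer counts allow.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of trial records over all subjects, with a `group`
#'   column; attribute `truth` holds each subject's generating parameters.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list(); truth <- list()
  for (group in names(spec$group_params)) {
    params <- spec$group_params[[group]]
    for (k in seq_len(spec$n_subjects)) {
      sid <- sprintf("%s_%02d", substr(group, 1, 4), k)
      sseed <- derive_seed(spec$seed, "cohort", group, k)
      sched <- generate_feedback_schedule(derive_seed(sseed, "schedule"))
      study2 <- identical(spec$study, "study2")
      sched <- if (study2)
        block_schedule(sched, spec$n_trials, derive_seed(sseed, "blocks"))
      else subset_schedule(sched, spec$n_trials)
      opts <- generate_option_set(spec$n_trials,
                                  derive_seed(sseed, "options"))
      rec <- generate_synthetic_subject(params, spec$variant, sched, opts,
                                        derive_seed(sseed, "play"),
                                        subject_id = sid,
                                        t_max = if (study2) 6 else 10)
      rec$group <- group
      out[[sid]] <- rec
      truth[[sid]] <- params
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "truth") <- truth
  attr(res, "variant") <- spec$variant$variant_id
  res
}

# Trim a 300-trial schedule to n trials keeping the 90/120/90 status ratio.
subset_schedule <- function(sched, n_trials) {
  if (n_trials == nrow(sched)) return(sched)
  if (n_trials > nrow(sched))
    stopf("n_trials beyond the 300-trial design is not supported")
  want <- round(n_trials * c(better = 90, equal = 120, worse = 90) / 300)
  while (sum(want) > n_trials) want[which.max(want)] <- want[which.max(want)] - 1L
  while (sum(want) < n_trials) want[which.min(want)] <- want[which.min(want)] + 1L
  keep <- unlist(lapply(STATUS_LEVELS, function(st) {
    which(sched$status == st)[seq_len(want[[st]])]
  }))
  keep <- sort(keep)
  out <- sched[keep, , drop = FALSE]
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Evaluate code under a local R RNG seed, restoring global state afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
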