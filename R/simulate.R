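#' Simulate a single RST-DDM trial
#'
#' Evidence starts at `bias` and is updated in discrete steps of `dt`
#' seconds, `E_t = E_{t-1} + nu_t dt + eps_t` with `eps_t ~ N(0, sigma)`
#' per step, until `|E_t|` reaches the threshold.  The response time is
#' `t * dt + ndt`.  Paths that fail to absorb within `t_max` seconds of
#' accumulation are returned as censored.
#'
#' @param params a [ddm_params()] object.
#' @param variant a [ddm_variant()] or integer id.
#' @param status `"better"`, `"equal"` or `"worse"`.
#' @param dms,dmo self- / other-payoff differences of the trial (points);
#'   `dms` must be positive by the labelling convention.
#' @param seed integer seed for the simulator's own RNG stream.
#' @param t_max accumulation horizon in seconds.
#' @param return_path if `TRUE`, also return the evidence trajectory.
#' @return list with `choice` (1 = upper boundary = larger self-payoff
#'   option, 0 = lower, NA = censored), `rt` (seconds, NA if censored),
#'   `censored`, and optionally `evidence` / `drift` vectors.
#' @export
simulate_trial <- function(params, variant, status, dms, dmo, seed,
                           t_max = 10, return_path = FALSE) {
  validate_ddm_params(params)
  if (t_max < params$dt) stopf("t_max must be at least dt")
  eff <- effective_params(params, variant, status)
  if (return_path) {
    res <- cpp_simulate_path_trace(dms, dmo, eff$omega_s, eff$omega_o,
                                   eff$rst, params$threshold, params$ndt,
                                   params$bias, params$sigma, params$dt,
                                   t_max, seed)
    return(list(choice = if (res$choice < 0) NA_integer_ else res$choice,
                rt = res$rt, censored = res$choice < 0,
                evidence = res$evidence, drift = res$drift))
  }
  res <- cpp_simulate_paths(1L, dms, dmo, eff$omega_s, eff$omega_o, eff$rst,
                            params$threshold, params$ndt, params$bias,
                            params$sigma, params$dt, t_max, seed)
  list(choice = if (res$choice[1] < 0) NA_integer_ else res$choice[1],
       rt = res$rt[1], censored = res$choice[1] < 0)
}

#' Simulate the empirical (choice, RT) distribution of a trial
#'
#' Draws `n_sims` independent outcomes for one option pair under one status
#' condition — the Monte-Carlo ensemble behind the simulation-based
#' likelihood (3,000 draws per trial at full scale).
#'
#' @inheritParams simulate_trial
#' @param n_sims number of simulated outcomes (>= 1).
#' @return data.frame with columns `choice` (0/1, NA when censored), `rt`
#'   (NA when censored) and `censored`; attribute `censored_fraction`.
#' @export
simulate_trial_distribution <- function(params, variant, status, dms, dmo,
                                        n_sims, seed, t_max = 10) {
  stopifnot(n_sims >= 1)
  validate_ddm_params(params)
  eff <- effective_params(params, variant, status)
  res <- cpp_simulate_paths(as.integer(n_sims), dms, dmo, eff$omega_s,
                            eff$omega_o, eff$rst, params$threshold,
                            params$ndt, params$bias, params$sigma, params$dt,
                            t_max, seed)
  censored <- res$choice < 0
  out <- data.frame(choice = ifelse(censored, NA_integer_, res$choice),
                    rt = res$rt, censored = censored)
  attr(out, "censored_fraction") <- mean(censored)
  out
}
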