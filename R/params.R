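#' Model variants of the relative-start-time DDM
#'
#' Four nested accounts of how relative social status (better / equal /
#' worse) can modulate the decision process:
#'
#' * **variant 1** — status-specific attribute weights, both attributes enter
#'   simultaneously (RST fixed at 0): 6 weights + threshold + nDT + bias =
#'   9 free parameters.
#' * **variant 2** — shared weights, status-specific relative start times:
#'   2 + 3 + 3 = 8.
#' * **variant 3** — status-specific weights, one shared RST: 6 + 1 + 3 = 10.
#' * **variant 4** — both weights and RSTs status-specific: 6 + 3 + 3 = 12.
#'
#' @param variant_id integer in 1..4.
#' @return an object of class `ddm_variant` with fields `variant_id`,
#'   `weights_by_status`, `rst_by_status`, `rst_fixed_zero`, `n_free_params`.
#' @export
ddm_variant <- function(variant_id) {
  variant_id <- as.integer(variant_id)
  if (!variant_id %in% 1:4) stopf("variant_id must be 1, 2, 3 or 4")
  v <- switch(variant_id,
    list(weights_by_status = TRUE,  rst_by_status = FALSE, rst_fixed_zero = TRUE,  n_free_params = 9L),
    list(weights_by_status = FALSE, rst_by_status = TRUE,  rst_fixed_zero = FALSE, n_free_params = 8L),
    list(weights_by_status = TRUE,  rst_by_status = FALSE, rst_fixed_zero = FALSE, n_free_params = 10L),
    list(weights_by_status = TRUE,  rst_by_status = TRUE,  rst_fixed_zero = FALSE, n_free_params = 12L))
  structure(c(list(variant_id = variant_id), v), class = "ddm_variant")
}

#' Construct a full RST-DDM parameter set
#'
#' Weights and RSTs may be scalars (shared across status) or length-3 vectors
#' named or ordered `better, equal, worse`.  The diffusion noise is the
#' per-step standard deviation of the Gaussian increment added at each
#' `dt = 0.01` s update (default 0.1, i.e. a continuum diffusion coefficient
#' of \eqn{0.1^2 / 0.01 = 1} per second).
#'
#' @param omega_s drift weight per point of the self-payoff difference.
#' @param omega_o drift weight per point of the other-payoff difference.
#' @param rst relative start time in seconds; positive means the self-payoff
#'   attribute enters accumulation first.
#' @param threshold symmetric evidence bound (> 0).
#' @param ndt non-decision time in seconds (>= 0).
#' @param bias starting evidence, `|bias| < threshold`.
#' @param sigma per-step noise standard deviation.
#' @param dt accumulation step in seconds.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(omega_s, omega_o, rst = 0, threshold = 1,
                       ndt = 0.3, bias = 0, sigma = 0.1, dt = 0.01) {
  expand <- function(x, what) {
    if (length(x) == 1) return(setNames(rep(as.numeric(x), 3), STATUS_LEVELS))
    if (length(x) != 3) stopf("%s must have length 1 or 3", what)
    if (!is.null(names(x))) {
      if (!setequal(names(x), STATUS_LEVELS))
        stopf("%s names must be better/equal/worse", what)
      return(setNames(as.numeric(x[STATUS_LEVELS]), STATUS_LEVELS))
    }
    setNames(as.numeric(x), STATUS_LEVELS)
  }
  p <- structure(list(
    omega_s = expand(omega_s, "omega_s"),
    omega_o = expand(omega_o, "omega_o"),
    rst = expand(rst, "rst"),
    threshold = as.numeric(threshold),
    ndt = as.numeric(ndt),
    bias = as.numeric(bias),
    sigma = as.numeric(sigma),
    dt = as.numeric(dt)), class = "ddm_params")
  validate_ddm_params(p)
  p
}

validate_ddm_params <- function(p) {
  num <- unlist(p[c("omega_s", "omega_o", "rst", "threshold", "ndt",
                    "bias", "sigma", "dt")])
  if (any(!is.finite(num))) stopf("ddm_params contains non-finite values")
  if (p$threshold <= 0) stopf("threshold must be > 0")
  if (p$ndt < 0) stopf("ndt must be >= 0")
  if (abs(p$bias) >= p$threshold) stopf("|bias| must be < threshold")
  if (p$sigma <= 0 || p$dt <= 0) stopf("sigma and dt must be > 0")
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("RST-DDM parameters\n")
  cat(sprintf("  omega_s: %s\n", paste(signif(x$omega_s, 4), collapse = " / ")))
  cat(sprintf("  omega_o: %s\n", paste(signif(x$omega_o, 4), collapse = " / ")))
  cat(sprintf("  rst    : %s s (better/equal/worse)\n",
              paste(signif(x$rst, 4), collapse = " / ")))
  cat(sprintf("  threshold %.3g, ndt %.3g s, bias %.3g, sigma %.3g, dt %.3g s\n",
              x$threshold, x$ndt, x$bias, x$sigma, x$dt))
  invisible(x)
}

#' Resolve the status-effective (omega_s, omega_o, rst) triple for a variant
#'
#' Variant 1 forces `rst = 0`; variant 2 collapses the weights to their
#' shared value; variant 3 collapses RST.  Collapsing requires the slot to
#' actually be shared: a status-varying value in a shared slot is an error,
#' because the parameter set does not belong to the variant.
#'
#' @param params a [ddm_params()] object.
#' @param variant a [ddm_variant()] object or integer id.
#' @param status one of `"better"`, `"equal"`, `"worse"`.
#' @return named list with `omega_s`, `omega_o`, `rst` scalars.
#' @export
effective_params <- function(params, variant, status) {
  if (!inherits(variant, "ddm_variant")) variant <- ddm_variant(variant)
  status <- match.arg(status, STATUS_LEVELS)
  shared <- function(x, what) {
    if (diff(range(x)) > 1e-12)
      stopf("%s varies by status but variant %d shares it", what,
            variant$variant_id)
    x[[1]]
  }
  os <- if (variant$weights_by_status) params$omega_s[[status]]
        else shared(params$omega_s, "omega_s")
  oo <- if (variant$weights_by_status) params$omega_o[[status]]
        else shared(params$omega_o, "omega_o")
  rst <- if (variant$rst_fixed_zero) 0
         else if (variant$rst_by_status) params$rst[[status]]
         else shared(params$rst, "rst")
  list(omega_s = os, omega_o = oo, rst = rst)
}

#' Attribute latency schedule implied by an RST
#'
#' With `rst >= 0` the self-payoff difference contributes from step 0 and the
#' other-payoff difference from step `ceil(|rst| / dt)`; with `rst < 0` the
#' roles swap.  Step indices count accumulation updates from 0.
#'
#' @param rst relative start time in seconds.
#' @param dt step size in seconds.
#' @return list with `entry_step_s`, `entry_step_o`, and gate functions
#'   `gate_s(step)`, `gate_o(step)` returning 0/1.
#' @export
latency_schedule <- function(rst, dt = 0.01) {
  lag <- as.integer(ceiling(abs(rst) / dt - 1e-12))
  entry_s <- if (rst >= 0) 0L else lag
  entry_o <- if (rst > 0) lag else 0L
  list(entry_step_s = entry_s, entry_step_o = entry_o,
       gate_s = function(step) as.numeric(step >= entry_s),
       gate_o = function(step) as.numeric(step >= entry_o))
}

#' Instantaneous drift rate with latency gates
#'
#' \eqn{\nu_t = \tau_{s,t}\,\omega_s\,\Delta M_s + \tau_{o,t}\,\omega_o\,\Delta M_o},
#' where the gates open at the entry steps of the latency schedule.
#'
#' @param omega_s,omega_o attribute drift weights.
#' @param schedule a [latency_schedule()].
#' @param dms,dmo attribute differences (points).
#' @param step integer step index (>= 0).
#' @return drift in evidence units per second.
#' @export
drift_rate <- function(omega_s, omega_o, schedule, dms, dmo, step) {
  stopifnot(all(step >= 0))
  schedule$gate_s(step) * omega_s * dms + schedule$gate_o(step) * omega_o * dmo
}
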