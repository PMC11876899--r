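#' Simple mediation with percentile-bootstrap confidence intervals
#'
#' Product-of-coefficients estimator for the single-mediator model
#' `x -> m -> y`: path a from `m ~ x (+ covariates)`, paths b and c' from
#' `y ~ m + x (+ covariates)`, indirect effect `a * b`.  Confidence
#' intervals come from a percentile bootstrap over observations (default
#' 1,000 resamples).  Typical use here: x = status score (better = 1,
#' equal = 0, worse = -1), m = fitted RST, y = a behavioural read-out, with
#' the attribute weights as covariates.
#'
#' @param x independent variable vector.
#' @param m mediator vector.
#' @param y outcome vector.
#' @param covariates optional data.frame / matrix of controls entering both
#'   regressions.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return list of class `mediation_result`: `path_a`, `path_b`,
#'   `direct_c_prime`, `total_c`, `indirect_ab`, `ci_low`, `ci_high`,
#'   `n_boot`, `significant`, `covariates_used`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 1000,
                    conf = 0.95, seed = 1) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(cov_m) && nrow(cov_m) != n)
    stopf("covariates must have one row per observation")
  design_rank_check(x, m, cov_m)
  est <- mediation_paths(x, m, y, cov_m)
  boot <- with_seed(derive_seed(seed, "mediate-boot"), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      cb <- if (is.null(cov_m)) NULL else cov_m[i, , drop = FALSE]
      e <- tryCatch(mediation_paths(x[i], m[i], y[i], cb),
                    error = function(err) NULL)
      if (is.null(e)) NA_real_ else e$indirect
    }, 0)
  })
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 6)
  structure(list(path_a = est$a, path_b = est$b,
                 direct_c_prime = est$c_prime, total_c = est$c_total,
                 indirect_ab = est$indirect,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = length(boot),
                 significant = ci[1] > 0 || ci[2] < 0,
                 covariates_used = colnames(cov_m) %||% character(0)),
            class = "mediation_result")
}

mediation_paths <- function(x, m, y, cov_m) {
  Xa <- cbind(1, x, cov_m)
  Xb <- cbind(1, m, x, cov_m)
  Xc <- cbind(1, x, cov_m)
  a <- unname(drop(solve(crossprod(Xa), crossprod(Xa, m)))[2])
  bc <- unname(drop(solve(crossprod(Xb), crossprod(Xb, y))))
  c_tot <- unname(drop(solve(crossprod(Xc), crossprod(Xc, y)))[2])
  list(a = a, b = bc[2], c_prime = bc[3], c_total = c_tot,
       indirect = a * bc[2])
}

design_rank_check <- function(x, m, cov_m) {
  X <- cbind(x = x, m = m, cov_m)
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(cbind(intercept = 1, X))[-keep]
    stopf("mediation design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("Mediation: a = %.4f, b = %.4f, indirect ab = %.4f ",
                     "[%.4f, %.4f]%s; direct c' = %.4f\n"),
              x$path_a, x$path_b, x$indirect_ab, x$ci_low, x$ci_high,
              if (x$significant) " *" else "", x$direct_c_prime))
  invisible(x)
}
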