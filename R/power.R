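# Statistical power for Mendelian randomization with a binary outcome,
# after the normal-approximation (noncentrality) calculator used by mRnd.

#' Power of a two-sample MR study with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio `or_alt`
#' per unit of exposure, given the variance in the exposure explained by
#' the instruments:
#' `power = Phi( sqrt(n_total * r2 * K * (1 - K)) * |ln(or_alt)| -
#' z_{1 - alpha/2} )`
#' with `K` the case fraction. Strictly increasing in `n_total`, `r2` and
#' `|ln or_alt|`. At `or_alt = 1` (or `r2 = 0`) there is no signal and the
#' value degenerates to the one-tail rejection rate `alpha/2`.
#'
#' @param n_total Total outcome sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2 Variance of the exposure explained by the instruments, in
#'   (0, 1) (0 allowed with a warning).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param or_alt Alternative-hypothesis odds ratio (> 0).
#' @return Power, a fraction in (0, 1).
#' @examples
#' mr_power(80610, 20806 / 80610, 0.0155, 0.05, 1.2)
#' @export
mr_power <- function(n_total, case_fraction, r2, alpha = 0.05, or_alt) {
  stopifnot(n_total > 0, case_fraction > 0, case_fraction < 1,
            r2 >= 0, r2 < 1, alpha > 0, alpha < 1, or_alt > 0)
  if (r2 == 0) {
    warning("r2 = 0: no instrument signal, power degenerates to alpha/2")
  }
  ncp <- sqrt(n_total * r2 * case_fraction * (1 - case_fraction)) *
    abs(log(or_alt))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power()] by monotone root-finding on the log-OR scale: the
#' smallest odds ratio above 1 whose power reaches `target_power`.
#'
#' @inheritParams mr_power
#' @param target_power Desired power, in (`alpha`, 1).
#' @param tol Relative tolerance for the root (default 1e-8).
#' @return The detectable odds ratio (> 1).
#' @examples
#' # the conventional 80%-power detectable effect for a 26%-case study
#' detectable_or(80610, 20806 / 80610, 0.0155, 0.05, 0.80)
#' @export
detectable_or <- function(n_total, case_fraction, r2, alpha = 0.05,
                          target_power, tol = 1e-8) {
  stopifnot(target_power > alpha, target_power < 1)
  if (r2 <= 0) stop("r2 must be > 0 to detect any effect", call. = FALSE)
  f <- function(log_or) {
    mr_power(n_total, case_fraction, r2, alpha, exp(log_or)) - target_power
  }
  upper <- 1
  while (f(upper) < 0 && upper < 700) upper <- upper * 2
  if (f(upper) < 0) {
    stop("target power unattainable at any odds ratio", call. = FALSE)
  }
  root <- stats::uniroot(f, c(1e-12, upper), tol = tol)$root
  exp(root)
}
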