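# Causal-effect estimators on harmonized instruments: Wald ratio, IVW,
# MR-Egger, weighted median, simple and weighted mode.

.z95 <- function(ci_level) stats::qnorm(1 - (1 - ci_level) / 2)

.new_estimate <- function(method, n_snps, beta, se, pvalue, ci_level = 0.95,
                          crit = .z95(ci_level), extras = list()) {
  structure(list(method = method, n_snps = n_snps, beta = beta, se = se,
                 or_ = exp(beta),
                 ci_low = exp(beta - crit * se),
                 ci_high = exp(beta + crit * se),
                 pvalue = pvalue, ci_level = ci_level, extras = extras),
            class = "mr_estimate")
}

.check_instruments <- function(dat, min_snps, method) {
  if (nrow(dat) < min_snps) {
    stop(sprintf("%s requires at least %d instruments (got %d)%s", method,
                 min_snps, nrow(dat),
                 if (min_snps == 2L) "; use mr_wald_ratio for a single instrument" else ""),
         call. = FALSE)
  }
  if (any(dat$se_out <= 0) || any(dat$se_exp <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  invisible(dat)
}

# Wald ratios and their first-order (default) or second-order delta-method SEs
.wald <- function(dat, second_order = FALSE) {
  ratio <- dat$beta_out / dat$beta_exp
  se <- if (second_order) {
    sqrt(dat$se_out^2 / dat$beta_exp^2 +
           dat$beta_out^2 * dat$se_exp^2 / dat$beta_exp^4)
  } else {
    dat$se_out / abs(dat$beta_exp)
  }
  list(ratio = ratio, se = se)
}

# orient instruments so every exposure beta is positive (joint sign flip
# per SNP leaves ratio-based quantities unchanged; required for Egger)
.orient <- function(dat) {
  s <- ifelse(dat$beta_exp < 0, -1, 1)
  dat$beta_exp <- dat$beta_exp * s
  dat$beta_out <- dat$beta_out * s
  dat
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The per-variant causal estimate `beta_out / beta_exp`, with the
#' first-order delta-method standard error `se_out / |beta_exp|` (which
#' ignores the exposure-side uncertainty) or, optionally, the second-order
#' version that propagates it.
#'
#' @param instrument One row of a harmonized instrument data frame.
#' @param second_order Use the second-order delta-method SE? Default
#'   `FALSE`.
#' @param ci_level Confidence level (default 0.95).
#' @return An `"mr_estimate"` object.
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)$instruments
#' mr_wald_ratio(h[h$variant_id == "rs1130864", ])
#' @export
mr_wald_ratio <- function(instrument, second_order = FALSE, ci_level = 0.95) {
  if (nrow(instrument) != 1L) stop("exactly one instrument expected", call. = FALSE)
  if (instrument$beta_exp == 0) {
    stop("Wald ratio undefined: exposure beta is 0", call. = FALSE)
  }
  w <- .wald(instrument, second_order)
  p <- 2 * stats::pnorm(-abs(w$ratio / w$se))
  .new_estimate("Wald ratio", 1L, w$ratio, w$se, p, ci_level,
                extras = list(variant_id = instrument$variant_id,
                              second_order = second_order))
}

# closed-form zero-intercept WLS pieces shared by IVW, PRESSO and Q
.ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

.ivw_q <- function(bx, by, w, slope) sum(w * (by - slope * bx)^2)

#' Inverse-variance weighted causal estimate
#'
#' Zero-intercept weighted regression of outcome betas on exposure betas
#' with weights `1/se_out^2` -- equivalently, the inverse-variance weighted
#' meta-analysis of the per-variant Wald ratios. Under the multiplicative
#' random-effects model (the default) the fixed-effect standard error is
#' inflated by `sqrt(Q/(L-1))`, floored at 1, where Q is Cochran's
#' heterogeneity statistic of the Wald ratios about the pooled estimate.
#' Inference uses the standard normal.
#'
#' @param instruments Harmonized instrument data frame with >= 2 rows.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param ci_level Confidence level (default 0.95).
#' @return An `"mr_estimate"`; `extras` carries `Q`, `Q_df`, `Q_pvalue` and
#'   the model name.
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)$instruments
#' mr_ivw(h)   # OR 0.964, 95% CI 0.830-1.119
#' @export
mr_ivw <- function(instruments, model = c("multiplicative_random", "fixed"),
                   ci_level = 0.95) {
  model <- match.arg(model)
  .check_instruments(instruments, 2L, "IVW")
  w <- 1 / instruments$se_out^2
  bx <- instruments$beta_exp; by <- instruments$beta_out
  slope <- .ivw_slope(bx, by, w)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- .ivw_q(bx, by, w, slope)
  df <- nrow(instruments) - 1L
  se <- if (model == "multiplicative_random") {
    se_fixed * max(1, sqrt(q / df))
  } else {
    se_fixed
  }
  p <- 2 * stats::pnorm(-abs(slope / se))
  .new_estimate(if (model == "fixed") "IVW (fixed effects)" else "IVW",
                nrow(instruments), slope, se, p, ci_level,
                extras = list(model = model, Q = q, Q_df = df,
                              Q_pvalue = stats::pchisq(q, df, lower.tail = FALSE),
                              se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted linear regression (weights `1/se_out^2`) of outcome betas on
#' exposure betas *with* an intercept, after orienting every instrument so
#' its exposure beta is positive. The slope estimates the causal effect
#' allowing for directional pleiotropy under the InSIDE assumption; the
#' intercept estimates the average direct (pleiotropic) effect -- zero in
#' its absence. Standard errors scale the weighted-regression covariance by
#' `max(1, Q'/(L-2))` (Ruecker's Q' is the residual heterogeneity of this
#' fit); slope and intercept p-values use the t distribution with `L-2`
#' degrees of freedom.
#'
#' @param instruments Harmonized instrument data frame with >= 3 rows.
#' @param ci_level Confidence level (default 0.95).
#' @return An `"mr_estimate"`; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_p`, `Q`, `Q_df`, `Q_pvalue`.
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)$instruments
#' mr_egger(h)$extras$intercept   # -0.092
#' @export
mr_egger <- function(instruments, ci_level = 0.95) {
  .check_instruments(instruments, 3L, "MR-Egger")
  dat <- .orient(instruments)
  w <- 1 / dat$se_out^2
  bx <- dat$beta_exp; by <- dat$beta_out
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  d <- sw * swxx - swx^2
  if (d <= 0) stop("degenerate design: exposure betas are constant", call. = FALSE)
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swxx * swy - swx * swxy) / d
  df <- nrow(dat) - 2L
  q <- sum(w * (by - intercept - slope * bx)^2)
  sigma2 <- max(1, q / df)
  se_slope <- sqrt(sigma2 * sw / d)
  se_int <- sqrt(sigma2 * swxx / d)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df)
  .new_estimate("MR-Egger", nrow(dat), slope, se_slope, p_slope, ci_level,
                crit = tcrit,
                extras = list(intercept = intercept, intercept_se = se_int,
                              intercept_p = p_int, Q = q, Q_df = df,
                              Q_pvalue = stats::pchisq(q, df, lower.tail = FALSE)))
}

# interpolated weighted median of `x` with weights `w`: cumulative weight
# midpoints, linear interpolation at 0.5
.weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  stats::approx(p, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

# parametric bootstrap SE: resample per-SNP betas from their sampling
# distributions, recompute `statistic(bx, by)`, take the SD
.bootstrap_se <- function(dat, statistic, n_boot, seed) {
  if (is.null(seed)) stop("a seed is required for bootstrap standard errors",
                          call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap SEs")
  L <- nrow(dat)
  est <- withr_seed(seed, {
    bx <- matrix(stats::rnorm(n_boot * L, dat$beta_exp, dat$se_exp),
                 n_boot, L, byrow = TRUE)
    by <- matrix(stats::rnorm(n_boot * L, dat$beta_out, dat$se_out),
                 n_boot, L, byrow = TRUE)
    vapply(seq_len(n_boot), function(b) statistic(bx[b, ], by[b, ]), 0.0)
  })
  stats::sd(est)
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant Wald ratios and interpolates the ratio at
#' cumulative inverse-variance weight 0.5. Consistent when instruments
#' contributing at least half the weight are valid, so robust to up to 50%
#' invalid instruments. The standard error is a seeded parametric
#' bootstrap: per-variant betas are resampled from their normal sampling
#' distributions, the estimator recomputed, and the SD taken.
#'
#' @param instruments Harmonized instrument data frame with >= 3 rows.
#' @param n_boot Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Integer seed (required -- reproducibility contract).
#' @param ci_level Confidence level (default 0.95).
#' @return An `"mr_estimate"`; `extras` carries `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               ci_level = 0.95) {
  .check_instruments(instruments, 3L, "weighted median")
  wd <- .wald(instruments)
  w <- 1 / wd$se^2
  est <- .weighted_median_value(wd$ratio, w)
  stat <- function(bx, by) {
    r <- by / bx
    .weighted_median_value(r, bx^2 / instruments$se_out^2)
  }
  se <- .bootstrap_se(instruments, stat, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_estimate("Weighted median", nrow(instruments), est, se, p, ci_level,
                extras = list(n_boot = n_boot, seed = seed))
}

# kernel-density mode of ratios x with weights w; bandwidth phi times the
# modified-Silverman rule on min(sd, mad)
.mode_value <- function(x, w, phi) {
  spread <- min(stats::sd(x), stats::mad(x))
  if (!is.finite(spread) || spread <= 0) return(stats::median(x))
  h <- phi * 0.9 * spread * length(x)^(-1 / 5)
  d <- stats::density(x, weights = w / sum(w), bw = h,
                      from = min(x) - 3 * h, to = max(x) + 3 * h, n = 1024)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimate (simple or weighted)
#'
#' Forms a kernel-smoothed empirical density of the per-variant Wald ratios
#' (normal kernel; bandwidth `phi` times 0.9 min(sd, mad) L^(-1/5)) and
#' takes its argmax. The simple mode weights every ratio equally; the
#' weighted mode uses inverse-variance weights. Consistent when the largest
#' group of instruments sharing the same ratio is valid (ZEMPA). Standard
#' error by seeded parametric bootstrap, as in [mr_weighted_median()].
#'
#' @param instruments Harmonized instrument data frame with >= 3 rows.
#' @param weighted Inverse-variance weights? Default `TRUE`.
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (required).
#' @param ci_level Confidence level (default 0.95).
#' @return An `"mr_estimate"`; `extras` carries `phi`, `n_boot`, `seed`.
#' @export
mr_mode <- function(instruments, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = NULL, ci_level = 0.95) {
  .check_instruments(instruments, 3L, "mode-based estimator")
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  wd <- .wald(instruments)
  weight_of <- function(se_ratio) {
    if (weighted) 1 / se_ratio^2 else rep(1, length(se_ratio))
  }
  est <- .mode_value(wd$ratio, weight_of(wd$se), phi)
  stat <- function(bx, by) {
    .mode_value(by / bx, weight_of(instruments$se_out / abs(bx)), phi)
  }
  se <- .bootstrap_se(instruments, stat, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_estimate(if (weighted) "Weighted mode" else "Simple mode",
                nrow(instruments), est, se, p, ci_level,
                extras = list(phi = phi, n_boot = n_boot, seed = seed))
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s (%d SNP%s): OR %.*f, %g%% CI %.*f-%.*f, p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              digits, x$or_, 100 * x$ci_level,
              digits, x$ci_low, digits, x$ci_high, x$pvalue))
  if (!is.null(x$extras$intercept)) {
    cat(sprintf("  intercept %.3f (SE %.3f, p = %.3g)\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Fit a panel of Mendelian randomization estimators
#'
#' Front-end over the individual estimators. With a single instrument only
#' the Wald ratio is available; with two, IVW; from three up the median and
#' mode estimators join; MR-Egger requires three.
#'
#' @param instruments Harmonized instrument data frame, or an
#'   `"mr_harmonized"` object (its `instruments` element is used).
#' @param methods Character vector among `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`,
#'   `"wald_ratio"`. Default: all that the instrument count admits.
#' @param n_boot,seed Bootstrap settings passed to the median/mode
#'   estimators (`seed` required when any of those run).
#' @param phi Mode bandwidth multiplier.
#' @param ivw_model IVW flavor, see [mr_ivw()].
#' @param ci_level Confidence level.
#' @return An object of class `"mr_fit"`: list with `estimates` (named list
#'   of `"mr_estimate"`), `instruments`, and the call. Methods: `print`,
#'   `summary`, `coef`, `confint`, `plot`, `residuals`,
#'   `as.data.frame`.
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)
#' fit <- mr_fit(h, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(instruments, methods = NULL, n_boot = 1000, seed = NULL,
                   phi = 1, ivw_model = "multiplicative_random",
                   ci_level = 0.95) {
  if (inherits(instruments, "mr_harmonized")) instruments <- instruments$instruments
  L <- nrow(instruments)
  if (L == 0L) stop("no instruments", call. = FALSE)
  if (is.null(methods)) {
    methods <- if (L == 1L) "wald_ratio"
    else if (L == 2L) "ivw"
    else c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  }
  methods <- match.arg(methods,
                       c("ivw", "egger", "weighted_median", "simple_mode",
                         "weighted_mode", "wald_ratio"), several.ok = TRUE)
  ests <- list()
  for (m in methods) {
    ests[[m]] <- switch(
      m,
      wald_ratio = mr_wald_ratio(instruments[1L, , drop = FALSE],
                                 ci_level = ci_level),
      ivw = mr_ivw(instruments, model = ivw_model, ci_level = ci_level),
      egger = mr_egger(instruments, ci_level = ci_level),
      weighted_median = mr_weighted_median(instruments, n_boot = n_boot,
                                           seed = seed, ci_level = ci_level),
      simple_mode = mr_mode(instruments, weighted = FALSE, phi = phi,
                            n_boot = n_boot, seed = seed, ci_level = ci_level),
      weighted_mode = mr_mode(instruments, weighted = TRUE, phi = phi,
                              n_boot = n_boot, seed = seed, ci_level = ci_level)
    )
  }
  structure(list(estimates = ests, instruments = instruments,
                 call = match.call()),
            class = "mr_fit")
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  do.call(rbind, lapply(unname(x$estimates), as.data.frame))
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mendelian randomization fit on %d instrument%s\n\n",
              nrow(x$instruments), if (nrow(x$instruments) == 1) "" else "s"))
  tab <- as.data.frame(x)
  tab$or <- sprintf("%.*f", digits, tab$or)
  tab$`95% CI` <- sprintf("%.*f-%.*f", digits, tab$ci_low, digits, tab$ci_high)
  tab$p <- sprintf("%.3g", tab$pvalue)
  print(tab[, c("method", "n_snps", "or", "95% CI", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, 0.0)
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  m <- t(vapply(object$estimates,
                function(e) c(log(e$ci_low), log(e$ci_high)), c(0.0, 0.0)))
  colnames(m) <- c("low", "high")
  m
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  e <- object$estimates[[method]]
  if (is.null(e)) stop("method not in fit: ", method, call. = FALSE)
  dat <- if (method == "egger") .orient(object$instruments) else object$instruments
  int <- if (method == "egger") e$extras$intercept else 0
  stats::setNames(dat$beta_out - int - e$beta * dat$beta_exp, dat$variant_id)
}

#' @export
summary.mr_fit <- function(object, ...) {
  out <- list(table = as.data.frame(object),
              n_snps = nrow(object$instruments),
              heterogeneity = tryCatch(
                cochran_q(object$instruments, object$estimates$ivw),
                error = function(e) NULL),
              egger_intercept = object$estimates$egger$extras[
                c("intercept", "intercept_se", "intercept_p")])
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat(sprintf("MR estimates over %d instruments\n\n", x$n_snps))
  print(x$table, row.names = FALSE)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("\nCochran's Q (IVW): %.3f on %d df, p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$pvalue))
  }
  if (!is.null(x$egger_intercept$intercept)) {
    cat(sprintf("Egger intercept: %.3f (SE %.3f, p = %.3g)\n",
                x$egger_intercept$intercept, x$egger_intercept$intercept_se,
                x$egger_intercept$intercept_p))
  }
  invisible(x)
}

#' @export
plot.mr_fit <- function(x, ...) {
  sd <- scatter_data(x$instruments, x$estimates)
  pts <- sd$points
  graphics::plot(pts$beta_exp, pts$beta_out,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::segments(pts$beta_exp, pts$beta_out - pts$se_out,
                     pts$beta_exp, pts$beta_out + pts$se_out)
  graphics::segments(pts$beta_exp - pts$se_exp, pts$beta_out,
                     pts$beta_exp + pts$se_exp, pts$beta_out)
  for (i in seq_len(nrow(sd$lines))) {
    graphics::abline(sd$lines$intercept[i], sd$lines$slope[i], col = i + 1)
  }
  graphics::legend("topleft", legend = sd$lines$method,
                   col = seq_len(nrow(sd$lines)) + 1, lty = 1, bty = "n")
  invisible(x)
}
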