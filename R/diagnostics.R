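# Heterogeneity statistics, leave-one-out sensitivity, and funnel/scatter
# plot data export.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (beta_out_j - fitted_j)^2` with weights `1/se_out_j^2`,
#' where the fitted values come from the zero-intercept IVW line or the
#' with-intercept MR-Egger line (Ruecker's Q'). Referred to a chi-square
#' with `L-1` (IVW) or `L-2` (Egger) degrees of freedom. For an IVW fit
#' this is identical to the Q used internally for the multiplicative
#' random-effects scaling.
#'
#' @param instruments Harmonized instrument data frame the fit was made on.
#' @param fit An `"mr_estimate"` from [mr_ivw()] or [mr_egger()].
#' @return List of class `"mr_heterogeneity"`: `method`, `q`, `df`,
#'   `pvalue`.
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)$instruments
#' cochran_q(h, mr_ivw(h))   # p = 0.102
#' @export
cochran_q <- function(instruments, fit) {
  stopifnot(inherits(fit, "mr_estimate"))
  is_egger <- fit$method == "MR-Egger"
  df <- nrow(instruments) - if (is_egger) 2L else 1L
  if (df < 1L) stop("too few instruments for a heterogeneity test", call. = FALSE)
  dat <- if (is_egger) .orient(instruments) else instruments
  int <- if (is_egger) fit$extras$intercept else 0
  w <- 1 / dat$se_out^2
  q <- sum(w * (dat$beta_out - int - fit$beta * dat$beta_exp)^2)
  structure(list(method = if (is_egger) "egger" else "ivw", q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): %.3f on %d df, p = %.4g\n",
              x$method, x$q, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the chosen estimator once per instrument with that instrument
#' removed, exposing instruments whose omission moves the causal estimate.
#' Rows where removal drops the set below the estimator's minimum are
#' flagged, never silently skipped.
#'
#' @param instruments Harmonized instrument data frame.
#' @param method `"ivw"` (default), `"egger"`, `"weighted_median"`,
#'   `"simple_mode"` or `"weighted_mode"`.
#' @param ... Passed to the estimator (e.g. `seed`, `n_boot`).
#' @return Data frame with one row per instrument: `left_out`, `n_snps`,
#'   `beta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`, `ok` (FALSE when
#'   the reduced set was too small; estimate columns are then `NA`).
#' @export
leave_one_out <- function(instruments, method = "ivw", ...) {
  est_fun <- switch(method,
                    ivw = mr_ivw,
                    egger = mr_egger,
                    weighted_median = mr_weighted_median,
                    simple_mode = function(d, ...) mr_mode(d, weighted = FALSE, ...),
                    weighted_mode = function(d, ...) mr_mode(d, weighted = TRUE, ...),
                    stop("unknown method: ", method, call. = FALSE))
  rows <- lapply(seq_len(nrow(instruments)), function(j) {
    sub <- instruments[-j, , drop = FALSE]
    est <- tryCatch(est_fun(sub, ...), error = function(e) NULL)
    if (is.null(est)) {
      data.frame(left_out = instruments$variant_id[j], n_snps = nrow(sub),
                 beta = NA_real_, se = NA_real_, or = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                 ok = FALSE, stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(left_out = instruments$variant_id[j],
                       stringsAsFactors = FALSE),
            as.data.frame(est)[, -1], ok = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Funnel plot data
#'
#' One row per instrument: the Wald ratio and its precision
#' `1/se_ratio = |beta_exp|/se_out`. Asymmetry of the ratios about the
#' pooled estimate at low precision indicates heterogeneity or directional
#' pleiotropy. The IVW and (when >= 3 instruments) Egger pooled slopes are
#' attached as reference abscissae.
#'
#' @param instruments Harmonized instrument data frame (>= 1 row).
#' @return Data frame `variant_id`, `ratio`, `precision`, with attribute
#'   `reference_lines` (named numeric: `ivw`, and `egger` when defined).
#' @export
funnel_data <- function(instruments) {
  if (nrow(instruments) < 1L) stop("at least one instrument required", call. = FALSE)
  wd <- .wald(instruments)
  out <- data.frame(variant_id = instruments$variant_id, ratio = wd$ratio,
                    precision = 1 / wd$se, stringsAsFactors = FALSE)
  refs <- c()
  if (nrow(instruments) >= 2L) refs["ivw"] <- mr_ivw(instruments)$beta
  if (nrow(instruments) >= 3L) refs["egger"] <- mr_egger(instruments)$beta
  attr(out, "reference_lines") <- refs
  out
}

#' Scatter plot data
#'
#' Per-instrument exposure/outcome effects (oriented so exposure betas are
#' positive) with standard-error bars, plus one (slope, intercept) row per
#' fitted method: the IVW line passes through the origin; the Egger line
#' carries its pleiotropy intercept.
#'
#' @param instruments Harmonized instrument data frame.
#' @param fits A list of `"mr_estimate"` objects (e.g. `fit$estimates`
#'   from [mr_fit()]).
#' @return List with `points` (data frame: `variant_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`) and `lines` (data frame: `method`,
#'   `slope`, `intercept`).
#' @export
scatter_data <- function(instruments, fits) {
  if (inherits(fits, "mr_estimate")) fits <- list(fits)
  dat <- .orient(instruments)
  pts <- data.frame(variant_id = dat$variant_id, beta_exp = dat$beta_exp,
                    se_exp = dat$se_exp, beta_out = dat$beta_out,
                    se_out = dat$se_out, stringsAsFactors = FALSE)
  lines <- do.call(rbind, lapply(fits, function(e) {
    data.frame(method = e$method, slope = e$beta,
               intercept = if (is.null(e$extras$intercept)) 0
                           else e$extras$intercept,
               stringsAsFactors = FALSE)
  }))
  list(points = pts, lines = lines)
}
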