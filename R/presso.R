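# MR-PRESSO: resampling-based global pleiotropy test, per-SNP outlier
# test, and distortion test.

# leave-one-out IVW slopes for every SNP at once, from running sums
.loo_slopes <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

# per-SNP weighted squared residuals from leave-one-out predictions;
# rows = simulations when bx/by are matrices
.loo_residuals2 <- function(bx, by, w) {
  if (is.matrix(bx)) {
    s1 <- as.vector((bx * by) %*% w)
    s2 <- as.vector((bx^2) %*% w)
    wm <- matrix(w, nrow(bx), ncol(bx), byrow = TRUE)
    slopes <- (s1 - wm * bx * by) / (s2 - wm * bx^2)
    wm * (by - slopes * bx)^2
  } else {
    slopes <- .loo_slopes(bx, by, w)
    w * (by - slopes * bx)^2
  }
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy globally and per instrument by comparing
#' observed residuals against a parametric resampling null:
#'
#' 1. For each instrument j, the inverse-variance weighted slope is refit
#'    leaving j out, and j's weighted squared residual from its
#'    leave-one-out prediction is recorded; their sum is the observed
#'    residual sum of squares (RSS).
#' 2. `n_sim` replicate datasets are drawn with each instrument's betas
#'    sampled from normal distributions centred on the leave-one-out
#'    predictions (outcome side) and observed values (exposure side), and
#'    the RSS is recomputed each time. The global p-value is the fraction
#'    of simulated RSS at or above the observed one, with the (k+1)/(n+1)
#'    correction.
#' 3. Each instrument's observed squared residual is referred to its own
#'    simulated residual distribution; per-SNP p-values are
#'    Bonferroni-adjusted across instruments and those below
#'    `outlier_alpha` are flagged as outliers.
#' 4. If outliers exist, the distortion test compares the raw IVW estimate
#'    with the outlier-removed one against a resampling null built by
#'    removing random subsets of the same size.
#'
#' @param instruments Harmonized instrument data frame with >= 4 rows.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param seed Integer seed (required).
#' @param outlier_alpha Significance level for the adjusted per-SNP
#'   outlier test (default 0.05).
#' @param ivw_model IVW flavor for the raw/corrected estimates.
#' @return An object of class `"mr_presso"`: list with `rss_obs`,
#'   `global_p`, `per_snp` (data frame: `variant_id`, `residual2`,
#'   `pvalue`, `pvalue_adjusted`, `outlier`), `outliers`,
#'   `distortion_coefficient`, `distortion_p` (both `NA` without
#'   outliers), `estimate_raw`, `estimate_outlier_corrected` (`NULL`
#'   without outliers), `n_sim`, `seed`, and `variant_resampling`
#'   ("leave-one-out" bookkeeping identifier).
#' @export
mr_presso <- function(instruments, n_sim = 1000, seed = NULL,
                      outlier_alpha = 0.05,
                      ivw_model = "multiplicative_random") {
  .check_instruments(instruments, 4L, "MR-PRESSO")
  if (is.null(seed)) stop("a seed is required for MR-PRESSO", call. = FALSE)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  L <- nrow(instruments)
  bx <- instruments$beta_exp; by <- instruments$beta_out
  sx <- instruments$se_exp; sy <- instruments$se_out
  w <- 1 / sy^2

  res2_obs <- .loo_residuals2(bx, by, w)
  rss_obs <- sum(res2_obs)
  pred <- .loo_slopes(bx, by, w) * bx

  sim <- withr_seed(seed, {
    bx_sim <- matrix(stats::rnorm(n_sim * L, rep(bx, each = n_sim),
                                  rep(sx, each = n_sim)), n_sim, L)
    by_sim <- matrix(stats::rnorm(n_sim * L, rep(pred, each = n_sim),
                                  rep(sy, each = n_sim)), n_sim, L)
    .loo_residuals2(bx_sim, by_sim, w)
  })
  rss_sim <- rowSums(sim)
  global_p <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)

  per_snp_p <- vapply(seq_len(L), function(j) {
    (sum(sim[, j] >= res2_obs[j]) + 1) / (n_sim + 1)
  }, 0.0)
  p_adj <- pmin(1, per_snp_p * L)
  outlier <- p_adj < outlier_alpha
  if (all(outlier)) {
    stop("all instruments flagged as outliers; instrument set is degenerate",
         call. = FALSE)
  }
  per_snp <- data.frame(variant_id = instruments$variant_id,
                        residual2 = res2_obs, pvalue = per_snp_p,
                        pvalue_adjusted = p_adj, outlier = outlier,
                        stringsAsFactors = FALSE)

  est_raw <- mr_ivw(instruments, model = ivw_model)
  est_corr <- NULL
  distortion_coef <- NA_real_
  distortion_p <- NA_real_
  if (any(outlier)) {
    keep <- instruments[!outlier, , drop = FALSE]
    est_corr <- mr_ivw(keep, model = ivw_model)
    distortion_coef <- 100 * (est_raw$beta - est_corr$beta) /
      abs(est_corr$beta)
    n_out <- sum(outlier)
    null_d <- withr_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop <- sample(which(!outlier), n_out)
        b_sub <- .ivw_slope(bx[-drop], by[-drop], w[-drop])
        100 * (est_raw$beta - b_sub) / abs(b_sub)
      }, 0.0)
    })
    distortion_p <- (sum(abs(null_d) >= abs(distortion_coef)) + 1) /
      (n_sim + 1)
  }

  structure(list(rss_obs = rss_obs, global_p = global_p, per_snp = per_snp,
                 outliers = instruments$variant_id[outlier],
                 distortion_coefficient = distortion_coef,
                 distortion_p = distortion_p,
                 estimate_raw = est_raw,
                 estimate_outlier_corrected = est_corr,
                 n_sim = n_sim, seed = seed,
                 variant_resampling = "leave-one-out"),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d, seed = %d, %s residual bookkeeping)\n",
              x$n_sim, x$seed, x$variant_resampling))
  cat(sprintf("  global test: RSS = %.4g, p = %.4g\n", x$rss_obs, x$global_p))
  if (length(x$outliers)) {
    cat(sprintf("  outliers: %s\n", paste(x$outliers, collapse = ", ")))
    cat(sprintf("  distortion: %.1f%% (p = %.3g)\n",
                x$distortion_coefficient, x$distortion_p))
    cat("  outlier-corrected ")
    print(x$estimate_outlier_corrected)
  } else {
    cat("  no outliers detected\n")
  }
  cat("  raw ")
  print(x$estimate_raw)
  invisible(x)
}

#' Serialize an MR-PRESSO result as a structured text report
#'
#' @param x An `"mr_presso"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_presso_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("rss_obs\t%.10g", x$rss_obs),
    sprintf("global_p\t%.10g", x$global_p),
    sprintf("n_sim\t%d", x$n_sim),
    sprintf("seed\t%d", x$seed),
    sprintf("variant_resampling\t%s", x$variant_resampling),
    sprintf("outliers\t%s", paste(x$outliers, collapse = ",")),
    sprintf("distortion_coefficient\t%.10g", x$distortion_coefficient),
    sprintf("distortion_p\t%.10g", x$distortion_p),
    ""
  ), con)
  utils::write.table(x$per_snp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
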