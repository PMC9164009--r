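test_that("Wald ratio arithmetic and delta-method SE", {
  dat <- make_instruments(0.5, 0.1, 0.05)
  est <- mr_wald_ratio(dat)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_, exp(est$beta))

  zero <- mr_wald_ratio(make_instruments(0.5, 0, 0.05))
  expect_equal(zero$or_, 1)

  expect_error(mr_wald_ratio(make_instruments(0, 0.1, 0.05)), "undefined")
})

test_that("IVW equals the closed-form WLS oracle and handles degeneracy", {
  for (seed in c(1, 2, 3)) {
    dat <- random_instruments(sample(3:10, 1), seed)
    est <- mr_ivw(dat)
    expect_equal(est$beta, oracle_ivw_slope(dat), tolerance = 1e-12)
  }
  # identical Wald ratios: zero heterogeneity, fixed = random
  dat <- make_instruments(c(0.1, 0.2), 0.3 * c(0.1, 0.2), c(0.02, 0.03))
  est_r <- mr_ivw(dat)
  est_f <- mr_ivw(dat, model = "fixed")
  expect_equal(est_r$beta, 0.3)
  expect_equal(est_r$extras$Q, 0, tolerance = 1e-20)
  expect_equal(est_r$se, est_f$se)

  expect_error(mr_ivw(make_instruments(0.1, 0.02, 0.01)), "at least 2")
})

test_that("IVW on n copies of one instrument equals its Wald ratio", {
  one <- make_instruments(0.17, 0.04, 0.02)
  copies <- do.call(rbind, replicate(5, one, simplify = FALSE))
  copies$variant_id <- sprintf("snp%d", 1:5)
  expect_equal(mr_ivw(copies)$beta, mr_wald_ratio(one)$beta, tolerance = 1e-12)
})

test_that("Egger matches the WLS oracle and uses t(L-2) inference", {
  for (seed in 4:6) {
    dat <- random_instruments(sample(3:10, 1), seed)
    est <- mr_egger(dat)
    orc <- oracle_egger(dat)
    expect_equal(est$beta, orc$slope, tolerance = 1e-10)
    expect_equal(est$extras$intercept, orc$intercept, tolerance = 1e-10)
  }
  # instruments exactly on a line through the origin
  dat <- make_instruments(c(0.1, 0.2, 0.3), 0.4 * c(0.1, 0.2, 0.3),
                          c(0.02, 0.03, 0.01))
  est <- mr_egger(dat)
  expect_equal(est$extras$intercept, 0, tolerance = 1e-12)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)

  # printed-anchor check: the conservative 4-SNP intercept p is consistent
  # with t(2), not the normal
  t1 <- mr_egger(table1_instruments())
  tstat <- t1$extras$intercept / t1$extras$intercept_se
  expect_equal(t1$extras$intercept_p, 2 * pt(-abs(tstat), 2))
  expect_equal(round(t1$extras$intercept_p, 3), 0.158)

  expect_error(mr_egger(make_instruments(c(0.1, 0.2), c(0, 0), c(0.01, 0.01))),
               "at least 3")
})

test_that("weighted median interpolates cumulative weights at 0.5", {
  # constant ratios: estimate is that constant regardless of weights
  dat <- make_instruments(c(0.1, 0.2, 0.4), 0.25 * c(0.1, 0.2, 0.4),
                          c(0.01, 0.03, 0.02))
  est <- mr_weighted_median(dat, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.25, tolerance = 1e-12)

  # equal weights on ratios 0.1/0.2/0.6: hand-computed interpolation
  # cumulative midpoints are 1/6, 3/6, 5/6, so 0.5 falls on the middle ratio
  dat2 <- make_instruments(c(1, 1, 1), c(0.1, 0.2, 0.6), c(0.05, 0.05, 0.05))
  est2 <- mr_weighted_median(dat2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 0.2, tolerance = 1e-12)
  # brute-force oracle: approx() over the same cumulative grid
  oracle <- approx(c(1, 3, 5) / 6, c(0.1, 0.2, 0.6), xout = 0.5)$y
  expect_equal(est2$beta, oracle)

  expect_error(mr_weighted_median(dat, n_boot = 200), "seed")
  expect_warning(mr_weighted_median(dat, n_boot = 50, seed = 1), "n_boot")
})

test_that("bootstrap SE is seed-reproducible and internally consistent", {
  dat <- random_instruments(8, 10)
  a <- mr_weighted_median(dat, n_boot = 500, seed = 7)
  b <- mr_weighted_median(dat, n_boot = 500, seed = 7)
  expect_identical(a$se, b$se)
  c1 <- mr_weighted_median(dat, n_boot = 1000, seed = 8)
  c2 <- mr_weighted_median(dat, n_boot = 5000, seed = 9)
  expect_equal(c1$se, c2$se, tolerance = 0.2)
})

test_that("mode estimators find the dominant ratio cluster", {
  # constant case
  dat <- make_instruments(c(0.1, 0.2, 0.3), 0.5 * c(0.1, 0.2, 0.3),
                          rep(0.02, 3))
  expect_equal(mr_mode(dat, n_boot = 200, seed = 1)$beta, 0.5,
               tolerance = 1e-9)

  # tight cluster of 8 near 0.5 with 2 outliers at 3.0
  set.seed(42)
  bx <- rep(0.2, 10)
  ratios <- c(rnorm(8, 0.5, 0.02), 3, 3)
  dat2 <- make_instruments(bx, ratios * bx, rep(0.02, 10))
  est <- mr_mode(dat2, weighted = FALSE, n_boot = 200, seed = 2)
  expect_lt(abs(est$beta - 0.5), 0.1)

  # equal ratio SEs make simple and weighted modes coincide
  dat3 <- make_instruments(rep(0.2, 5), c(0.02, 0.03, 0.05, 0.04, 0.06),
                           rep(0.02, 5))
  s <- mr_mode(dat3, weighted = FALSE, n_boot = 100, seed = 3)
  w <- mr_mode(dat3, weighted = TRUE, n_boot = 100, seed = 3)
  expect_equal(s$beta, w$beta, tolerance = 1e-12)
})

test_that("every estimator is equivariant under a joint sign flip", {
  dat <- random_instruments(6, 20)
  flip <- dat
  flip$beta_exp <- -flip$beta_exp
  flip$beta_out <- -flip$beta_out
  expect_equal(mr_ivw(flip)$beta, mr_ivw(dat)$beta, tolerance = 1e-12)
  eg <- mr_egger(dat); eg_f <- mr_egger(flip)
  expect_equal(eg_f$beta, eg$beta, tolerance = 1e-12)
  expect_equal(eg_f$extras$intercept, eg$extras$intercept, tolerance = 1e-12)
  wm <- mr_weighted_median(dat, n_boot = 100, seed = 5)
  wm_f <- mr_weighted_median(flip, n_boot = 100, seed = 5)
  expect_equal(wm_f$beta, wm$beta, tolerance = 1e-12)
  md <- mr_mode(dat, n_boot = 100, seed = 5)
  md_f <- mr_mode(flip, n_boot = 100, seed = 5)
  expect_equal(md_f$beta, md$beta, tolerance = 1e-9)
})

test_that("estimate objects keep OR and CI consistent with beta and se", {
  dat <- random_instruments(5, 30)
  for (est in list(mr_ivw(dat), mr_egger(dat),
                   mr_weighted_median(dat, n_boot = 100, seed = 1))) {
    expect_equal(est$or_, exp(est$beta))
    expect_lte(est$ci_low, est$or_)
    expect_gte(est$ci_high, est$or_)
  }
  ivw <- mr_ivw(dat)
  expect_equal(ivw$ci_high, exp(ivw$beta + qnorm(0.975) * ivw$se))
})

test_that("mr_fit assembles the method panel and its S3 surface works", {
  fit <- mr_fit(table1_instruments(), seed = 42, n_boot = 200)
  expect_s3_class(fit, "mr_fit")
  expect_named(fit$estimates, c("ivw", "egger", "weighted_median",
                                "simple_mode", "weighted_mode"))
  expect_equal(round(exp(unname(coef(fit)["ivw"])), 3), 0.964)
  ci <- confint(fit)
  expect_equal(dim(ci), c(5, 2))
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 5)
  res <- residuals(fit)
  expect_named(res, table1_instruments()$variant_id)
  expect_output(print(fit), "IVW")
  expect_output(print(summary(fit)), "Egger intercept")

  one <- table1_instruments()[3, , drop = FALSE]
  wfit <- mr_fit(one)
  expect_named(wfit$estimates, "wald_ratio")
})
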