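ld_of <- function(ids, r = 0) {
  m <- diag(1, length(ids))
  m[m == 0] <- r
  rownames(m) <- colnames(m) <- ids
  m
}

clump_frame <- function(p, pos, ids = sprintf("rs%d", seq_along(p))) {
  data.frame(variant_id = ids, pvalue = p, chrom = "1", pos = pos,
             stringsAsFactors = FALSE)
}

test_that("greedy clumping keeps the strongest variant in each LD cluster", {
  one <- clump_frame(1e-10, 1e6)
  expect_equal(clump(one, ld_of(one$variant_id))$variant_id, "rs1")

  two <- clump_frame(c(1e-12, 1e-9), c(1e6, 1e6 + 5e3))
  expect_equal(clump(two, ld_of(two$variant_id, sqrt(0.5)))$variant_id, "rs1")

  # brute force over discard decisions: pairwise r2 below threshold keeps all
  three <- clump_frame(c(1e-8, 1e-10, 1e-9), c(1e6, 1.1e6, 1.2e6))
  kept <- clump(three, ld_of(three$variant_id, sqrt(0.0005)))
  expect_setequal(kept$variant_id, three$variant_id)
  # output in selection (p-value) order
  expect_equal(kept$variant_id, c("rs2", "rs3", "rs1"))
})

test_that("clumping is idempotent and never leaves a correlated pair", {
  set.seed(3)
  L <- 12
  vars <- clump_frame(runif(L, 1e-12, 1e-6), sort(runif(L, 1e6, 5e7)))
  r <- matrix(runif(L^2, 0, 0.6), L)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  rownames(r) <- colnames(r) <- vars$variant_id
  kept <- clump(vars, r, window_kb = 10000, r2_threshold = 0.1)
  again <- clump(kept, r, window_kb = 10000, r2_threshold = 0.1)
  expect_equal(again$variant_id, kept$variant_id)
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i == j) next
      within <- abs(kept$pos[i] - kept$pos[j]) <= 1e7 * 1000
      if (within) {
        expect_lte(r[kept$variant_id[i], kept$variant_id[j]]^2, 0.1)
      }
    }
  }
})

test_that("variants outside the window are independent; missing LD is fatal", {
  far <- clump_frame(c(1e-12, 1e-9), c(1e6, 1e6 + 2e10))
  # r2 above threshold but outside the window: both kept
  expect_equal(nrow(clump(far, ld_of(far$variant_id, 0.9))), 2)

  near <- clump_frame(c(1e-12, 1e-9), c(1e6, 1.1e6))
  ld <- ld_of("rs1")
  expect_error(clump(near, ld, window_kb = 10000), "LD missing")
})

test_that("the F statistic follows beta^2/se^2 and scales quadratically", {
  expect_equal(f_statistic(0.18, 0.01), 324)
  expect_equal(f_statistic(0.21, 0.018), 0.21^2 / 0.018^2, tolerance = 1e-12)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_equal(f_statistic(0.2, 0.05), 4 * f_statistic(0.1, 0.05))
  expect_error(f_statistic(0.1, 0), "se must be > 0")
})

test_that("variance explained is 2 b^2 maf (1-maf) with quadratic scaling", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(0.4, 0.2),
               4 * variance_explained(0.2, 0.2))
  expect_error(variance_explained(0.1, 0.7), "maf must lie")
})

test_that("Steiger filtering keeps exposure-first variants and reports a Z test", {
  dat <- make_instruments(beta_exp = c(0.2, 0.01), beta_out = c(0.01, 0.2),
                          se_out = c(0.01, 0.01), eaf = c(0.3, 0.3))
  res <- steiger_filter(dat, n_exp = 2e5, n_out = 8e4)
  expect_equal(res$instruments$variant_id, "snp1")
  expect_true(res$instruments$steiger_direction)
  expect_lt(res$instruments$steiger_pvalue, 0.05)
  expect_equal(res$exclusions$reason, "Steiger direction FALSE")

  # tie in explained variance counts as failure (strict inequality)
  tie <- make_instruments(beta_exp = 0.1, beta_out = 0.1, se_out = 0.01,
                          eaf = 0.3)
  expect_equal(nrow(steiger_filter(tie)$instruments), 0)

  # missing EAF: excluded conservatively, not silently
  na_eaf <- make_instruments(beta_exp = 0.2, beta_out = 0.01, se_out = 0.01)
  na_eaf$eaf_out <- NA_real_
  res2 <- steiger_filter(na_eaf)
  expect_match(res2$exclusions$reason, "unevaluable")
})

test_that("confounder filtering excludes on sub-threshold annotations only", {
  dat <- make_instruments(beta_exp = c(0.1, 0.1, 0.1),
                          beta_out = c(0, 0, 0), se_out = rep(0.01, 3))
  ann <- data.frame(
    variant_id = c("snp1", "snp2", "snp3"),
    trait = c("LDL", "LDL", "height"),
    pvalue = c(1e-10, 5e-8, 1e-30), stringsAsFactors = FALSE)
  res <- confounder_filter(dat, ann)
  # snp2 sits exactly at the threshold (strict <), snp3's trait is benign
  expect_setequal(res$instruments$variant_id, c("snp2", "snp3"))
  expect_equal(res$exclusions$variant_id, "snp1")

  none <- confounder_filter(dat, ann, confounder_traits = character(0))
  expect_equal(nrow(none$instruments), 3)
})

test_that("the full cascade reproduces the 55 - 2 - 20 = 33 arithmetic", {
  cfg <- synth_config(n_snps = 55, n_palindromic_intermediate = 2,
                      n_confounder_annotated = 20, seed = 99)
  ds <- synth_generate(cfg)
  h <- harmonize(ds$exposure, ds$outcome)
  expect_equal(nrow(h$instruments), 53)
  cfr <- confounder_filter(h$instruments, ds$annotations)
  expect_equal(nrow(cfr$instruments), 33)
  st <- steiger_filter(cfr$instruments)
  ff <- f_filter(st$instruments)
  expect_equal(nrow(ff$instruments), 33)
})
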