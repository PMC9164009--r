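# Shared fixtures and independent oracles.

# minimal harmonized instrument table
make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(0.01, length(beta_exp)),
                             eaf = seq(0.1, 0.45, length.out = length(beta_exp)),
                             ids = sprintf("snp%d", seq_along(beta_exp))) {
  data.frame(
    variant_id = ids, effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp,
    pvalue_exp = 2 * pnorm(-abs(beta_exp / se_exp)), eaf_exp = eaf,
    n_exp = 204402, chrom = "1", pos = seq_along(beta_exp) * 2e7,
    beta_out = beta_out, se_out = se_out,
    pvalue_out = 2 * pnorm(-abs(beta_out / se_out)), eaf_out = eaf,
    n_out = 80610, palindromic = FALSE, flipped = FALSE,
    stringsAsFactors = FALSE
  )
}

# random instrument set for oracle comparisons
random_instruments <- function(L, seed) {
  set.seed(seed)
  make_instruments(beta_exp = runif(L, 0.05, 0.3),
                   beta_out = rnorm(L, 0, 0.03),
                   se_out = runif(L, 0.01, 0.05),
                   se_exp = runif(L, 0.005, 0.02))
}

# independent weighted-least-squares oracle via lm (QR path)
oracle_ivw_slope <- function(dat) {
  unname(coef(lm(beta_out ~ 0 + beta_exp, data = dat,
                 weights = 1 / se_out^2)))
}

oracle_egger <- function(dat) {
  s <- ifelse(dat$beta_exp < 0, -1, 1)
  dat$beta_exp <- dat$beta_exp * s
  dat$beta_out <- dat$beta_out * s
  fit <- lm(beta_out ~ beta_exp, data = dat, weights = 1 / se_out^2)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

table1_instruments <- function() {
  fx <- table1_fixture()
  harmonize(fx$exposure, fx$outcome)$instruments
}
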