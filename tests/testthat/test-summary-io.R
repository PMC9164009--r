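test_that("the conservative instrument files read back exactly as packaged", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$exposure), 4)
  rs <- fx$exposure[fx$exposure$variant_id == "rs3093077", ]
  expect_equal(rs$beta, 0.21)
  expect_equal(rs$se, 0.018)
  expect_equal(rs$eaf, 0.0716)
  expect_equal(fx$exposure$beta[fx$exposure$variant_id == "rs1800947"], 0.26)
  # serialization round-trip
  tmp <- tempfile(fileext = ".tsv")
  write_gwas_summary(fx$exposure, tmp)
  again <- read_gwas_summary(tmp)
  expect_equal(again, fx$exposure)
})

test_that("header-only files give an empty collection, malformed rows are named", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tN", tmp)
  expect_equal(nrow(read_gwas_summary(tmp)), 0)

  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tN",
               "rs1\tA\tG\t0.2\t0.1\tNA\t0.01\t100",
               "rs2\tA\tG\t0.2\t0.1\t0.05\t0.01\t100"), tmp)
  expect_error(read_gwas_summary(tmp), "row 1.*missing se")

  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tN",
               "rs1\tA\tG\t0.2\tx\t0.05\t0.01\t100"), tmp)
  expect_error(read_gwas_summary(tmp), "row 1: non-numeric beta")
})

test_that("missing required columns raise a configuration error", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tpval\tN",
               "rs1\tA\tG\t0.2\t0.01\t100"), tmp)
  expect_error(read_gwas_summary(tmp), "missing required column")
})

test_that("comma-delimited files and custom column maps are supported", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("rsid,ea,oa,freq,b,stderr,p",
               "rs1,a,g,0.2,0.1,0.05,0.01"), tmp)
  df <- read_gwas_summary(tmp, column_map = c(
    variant_id = "rsid", effect_allele = "ea", other_allele = "oa",
    eaf = "freq", beta = "b", se = "stderr", pvalue = "p"))
  expect_equal(df$effect_allele, "A")  # upper-cased
  expect_equal(df$beta, 0.1)
  expect_true(is.na(df$n))
})

test_that("palindromic allele pairs are recognised", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("A", "G", "T"), c("T", "C", "C")),
               c(TRUE, TRUE, FALSE))
  expect_error(is_palindromic("A", "N"), "invalid allele")
})

test_that("harmonization aligns swapped and strand-flipped outcome records", {
  exposure <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                         effect_allele = c("A", "C", "C"),
                         other_allele = c("G", "T", "T"),
                         eaf = c(0.3, 0.4, 0.25), beta = c(0.1, 0.2, 0.15),
                         se = 0.01, pvalue = 1e-20, n = 1000,
                         chrom = "1", pos = c(1e6, 2e6, 3e6),
                         stringsAsFactors = FALSE)
  outcome <- exposure
  # rs1 recorded swapped; rs2 aligned; rs3 on the other strand (G/A)
  outcome$effect_allele <- c("G", "C", "G")
  outcome$other_allele <- c("A", "T", "A")
  outcome$beta <- c(0.05, 0.07, 0.04)
  outcome$eaf <- c(0.7, 0.4, 0.25)
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h$instruments), 3)
  expect_equal(h$instruments$beta_out, c(-0.05, 0.07, 0.04))
  expect_equal(h$instruments$flipped, c(TRUE, FALSE, FALSE))
  expect_equal(h$instruments$eaf_out, c(0.3, 0.4, 0.25))
})

test_that("palindromic variants near 0.5 are excluded; others align by EAF", {
  exposure <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                         effect_allele = c("A", "C", "A"),
                         other_allele = c("T", "G", "T"),
                         eaf = c(0.5, 0.9, 0.1), beta = 0.1, se = 0.01,
                         pvalue = 1e-20, n = 1000, chrom = "1",
                         pos = c(1e6, 2e6, 3e6), stringsAsFactors = FALSE)
  outcome <- exposure
  outcome$beta <- c(0.05, 0.04, 0.03)
  outcome$eaf <- c(0.5, 0.9, 0.85)  # rs3 reported for the other allele
  h <- harmonize(exposure, outcome)
  expect_equal(h$exclusions$variant_id, "rs1")
  expect_match(h$exclusions$reason, "intermediate")
  expect_equal(h$instruments$flipped, c(FALSE, TRUE))
  expect_equal(h$instruments$beta_out, c(0.04, -0.03))
})

test_that("unresolvable or absent outcome records are excluded with reasons", {
  exposure <- data.frame(variant_id = c("rs1", "rs2"),
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 1e-20,
                         n = 1000, chrom = "1", pos = c(1e6, 2e6),
                         stringsAsFactors = FALSE)
  outcome <- exposure[1, ]
  outcome$effect_allele <- "A"
  outcome$other_allele <- "C"  # mismatched pair
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h$instruments), 0)
  expect_setequal(h$exclusions$reason,
                  c("allele mismatch", "missing in outcome"))
  # retained + excluded account for every exposure variant
  expect_equal(nrow(h$instruments) + nrow(h$exclusions), nrow(exposure))
})

test_that("harmonizing a dataset against itself is the identity", {
  cfg <- synth_config(n_snps = 30, n_palindromic_intermediate = 3, seed = 7)
  ds <- synth_generate(cfg)
  h <- harmonize(ds$exposure, ds$exposure)
  expect_false(any(h$instruments$flipped))
  expect_equal(h$instruments$beta_out, h$instruments$beta_exp)
  # only the intermediate palindromes drop out
  expect_setequal(h$exclusions$variant_id, ds$truth$palindromic_intermediate)
})

test_that("double allele swap recovers the original outcome betas", {
  cfg <- synth_config(n_snps = 25, seed = 11)
  ds <- synth_generate(cfg)
  h1 <- harmonize(ds$exposure, ds$outcome)
  # re-swap every harmonized record and harmonize again
  sw <- h1$instruments
  outcome2 <- data.frame(variant_id = sw$variant_id,
                         effect_allele = sw$other_allele,
                         other_allele = sw$effect_allele,
                         eaf = 1 - sw$eaf_out, beta = -sw$beta_out,
                         se = sw$se_out, pvalue = sw$pvalue_out, n = sw$n_out,
                         chrom = sw$chrom, pos = sw$pos,
                         stringsAsFactors = FALSE)
  h2 <- harmonize(ds$exposure, outcome2)
  expect_equal(h2$instruments$beta_out, h1$instruments$beta_out)
  expect_equal(h2$instruments$eaf_out, h1$instruments$eaf_out)
})
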