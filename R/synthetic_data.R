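# Seeded synthetic GWAS summary-statistic generator with known ground
# truth, plus the packaged 4-SNP conservative instrument fixture.

#' Configuration for the synthetic summary-statistic generator
#'
#' Encodes the generative model: per-variant true exposure effects
#' `gamma_j`, a linear causal effect `theta` of exposure on outcome, and
#' per-variant direct (pleiotropic) outcome effects `alpha_j`. Observed
#' betas are the truths plus normal sampling noise at the summary-statistic
#' standard errors implied by allele frequency and sample size
#' (`se = 1/sqrt(2 MAF (1-MAF) n)` for the standardized continuous
#' exposure, with the extra `K(1-K)` case-fraction factor for the binary
#' outcome's log-odds scale).
#'
#' @param n_snps Number of variants.
#' @param maf_range Minor-allele-frequency range (default 0.05-0.5).
#' @param true_theta Causal effect of exposure on outcome (log-odds per
#'   unit exposure; default 0).
#' @param exposure_beta_scale Scale of the true exposure effects; drawn
#'   uniformly in `[0.5, 1.5] * scale` (default 0.1, the magnitude of
#'   published per-allele effects on standardized inflammatory biomarkers,
#'   giving strong instruments -- F far above 10 and an unambiguous
#'   exposure-first Steiger direction -- at the default sample sizes).
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes (defaults
#'   204402 and 80610).
#' @param case_fraction Outcome case fraction (default 20806/80610).
#' @param pleiotropy_mode `"none"`, `"balanced"` (alpha ~ N(0, sd)) or
#'   `"directional"` (alpha ~ N(mean, sd)).
#' @param pleiotropy_sd,pleiotropy_mean Direct-effect distribution
#'   parameters.
#' @param pleiotropy_frac Fraction of variants carrying a direct effect
#'   (default 1 when pleiotropy is on).
#' @param inside_violation If `TRUE`, direct effects are made to covary
#'   with instrument strength (violating InSIDE) by adding a term
#'   proportional to `gamma_j - mean(gamma)`.
#' @param n_palindromic_intermediate Number of variants given A/T or C/G
#'   alleles with EAF inside (0.43, 0.57) so harmonization must drop them.
#' @param n_confounder_annotated Number of (non-palindromic-intermediate)
#'   variants annotated to a confounder trait at genome-wide significance.
#' @param ld_blocks Optional list of `list(size=, r=)` blocks of
#'   consecutive variants placed within one clumping window at pairwise
#'   correlation `r`; all other variants are placed far apart and
#'   uncorrelated.
#' @param seed Integer seed (mandatory).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_snps, maf_range = c(0.05, 0.5), true_theta = 0,
                         exposure_beta_scale = 0.1, n_exp = 204402,
                         n_out = 80610, case_fraction = 20806 / 80610,
                         pleiotropy_mode = c("none", "balanced", "directional"),
                         pleiotropy_sd = 0, pleiotropy_mean = 0,
                         pleiotropy_frac = 1,
                         inside_violation = FALSE,
                         n_palindromic_intermediate = 0,
                         n_confounder_annotated = 0,
                         ld_blocks = NULL, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_palindromic_intermediate + n_confounder_annotated > n_snps) {
    stop("palindromic + confounder-annotated counts exceed n_snps", call. = FALSE)
  }
  if (!is.null(ld_blocks) && sum(vapply(ld_blocks, `[[`, 0, "size")) > n_snps) {
    stop("ld_blocks sizes exceed n_snps", call. = FALSE)
  }
  structure(list(n_snps = n_snps, maf_range = maf_range,
                 true_theta = true_theta,
                 exposure_beta_scale = exposure_beta_scale,
                 n_exp = n_exp, n_out = n_out, case_fraction = case_fraction,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_frac = pleiotropy_frac,
                 inside_violation = inside_violation,
                 n_palindromic_intermediate = n_palindromic_intermediate,
                 n_confounder_annotated = n_confounder_annotated,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "synth_config")
}

.nonpal_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Generate paired synthetic exposure/outcome summary statistics
#'
#' Draws a dataset from the generative model described in
#' [synth_config()]: true exposure effects, outcome effects
#' `theta * gamma_j + alpha_j`, sampling noise on both sides, allele
#' assignments (including planted intermediate-frequency palindromes), an
#' LD matrix, confounder annotations, and a truth record. A configurable
#' fraction of outcome rows is stored with the allele order swapped (beta
#' negated, EAF complemented) to exercise harmonization.
#'
#' Deterministic: the same config yields identical output.
#'
#' @param config A `"synth_config"`.
#' @param swap_frac Fraction of outcome rows recorded on the swapped
#'   allele order (default 0.3).
#' @return List with `exposure` and `outcome` (data frames in the
#'   [read_gwas_summary()] layout), `ld` (correlation matrix),
#'   `annotations` (data frame `variant_id`, `trait`, `pvalue`), and
#'   `truth` (list: `theta`, `gamma`, `alpha`, `palindromic_intermediate`,
#'   `confounder_annotated`, `seed`).
#' @export
synth_generate <- function(config, swap_frac = 0.3) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  L <- cf$n_snps
  withr_seed(cf$seed, {
    ids <- sprintf("rs%07d", sample.int(9999999, L))
    maf <- stats::runif(L, cf$maf_range[1], cf$maf_range[2])

    idx_pal <- seq_len(cf$n_palindromic_intermediate)
    idx_conf <- if (cf$n_confounder_annotated > 0) {
      cf$n_palindromic_intermediate + seq_len(cf$n_confounder_annotated)
    } else {
      integer(0)
    }
    eaf <- maf
    eaf[idx_pal] <- stats::runif(length(idx_pal), 0.43, 0.57)

    alleles <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), L, replace = TRUE), ,
                             drop = FALSE]
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    if (length(idx_pal)) {
      alleles[idx_pal, ] <- pal_pairs[sample.int(4, length(idx_pal),
                                                 replace = TRUE), , drop = FALSE]
    }

    gamma <- cf$exposure_beta_scale * stats::runif(L, 0.5, 1.5)
    alpha <- numeric(L)
    if (cf$pleiotropy_mode != "none") {
      carrier <- stats::runif(L) < cf$pleiotropy_frac
      mu <- if (cf$pleiotropy_mode == "directional") cf$pleiotropy_mean else 0
      alpha[carrier] <- stats::rnorm(sum(carrier), mu, cf$pleiotropy_sd)
      if (cf$inside_violation) {
        alpha[carrier] <- alpha[carrier] +
          cf$pleiotropy_sd * (gamma[carrier] - mean(gamma)) / stats::sd(gamma)
      }
    }

    mafv <- .fold_maf(eaf)
    se_exp <- 1 / sqrt(2 * mafv * (1 - mafv) * cf$n_exp)
    kk <- cf$case_fraction * (1 - cf$case_fraction)
    se_out <- 1 / sqrt(2 * mafv * (1 - mafv) * cf$n_out * kk)

    beta_exp <- stats::rnorm(L, gamma, se_exp)
    beta_out <- stats::rnorm(L, cf$true_theta * gamma + alpha, se_out)
    # floor at a representable positive value: p = 0 is outside (0, 1]
    p_exp <- pmax(2 * stats::pnorm(-abs(beta_exp / se_exp)), 1e-300)
    p_out <- pmax(2 * stats::pnorm(-abs(beta_out / se_out)), 1e-300)

    # positions: LD-block members share a chromosome within one window,
    # everything else is spaced beyond any realistic window
    chrom <- rep("1", L)
    pos <- seq_len(L) * 2e7
    ld <- diag(1, L)
    rownames(ld) <- colnames(ld) <- ids
    if (!is.null(cf$ld_blocks)) {
      at <- 1L
      for (b in cf$ld_blocks) {
        take <- at:(at + b$size - 1L)
        pos[take] <- pos[take[1]] + (seq_len(b$size) - 1L) * 1e4
        ld[take, take] <- b$r
        at <- at + b$size
      }
      diag(ld) <- 1
    }

    exposure <- data.frame(
      variant_id = ids, effect_allele = alleles[, 1],
      other_allele = alleles[, 2], eaf = eaf, beta = beta_exp, se = se_exp,
      pvalue = p_exp, n = cf$n_exp, chrom = chrom, pos = pos,
      stringsAsFactors = FALSE)

    swap <- stats::runif(L) < swap_frac
    outcome <- data.frame(
      variant_id = ids,
      effect_allele = ifelse(swap, alleles[, 2], alleles[, 1]),
      other_allele = ifelse(swap, alleles[, 1], alleles[, 2]),
      eaf = ifelse(swap, 1 - eaf, eaf),
      beta = ifelse(swap, -beta_out, beta_out), se = se_out,
      pvalue = p_out, n = cf$n_out, chrom = chrom, pos = pos,
      stringsAsFactors = FALSE)

    annotations <- if (length(idx_conf)) {
      traits <- default_confounder_traits()
      data.frame(variant_id = ids[idx_conf],
                 trait = traits[(seq_along(idx_conf) - 1L) %% length(traits) + 1L],
                 pvalue = stats::runif(length(idx_conf), 1e-30, 5e-9),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variant_id = character(0), trait = character(0),
                 pvalue = numeric(0), stringsAsFactors = FALSE)
    }

    list(exposure = exposure, outcome = outcome, ld = ld,
         annotations = annotations,
         truth = list(theta = cf$true_theta, gamma = gamma, alpha = alpha,
                      palindromic_intermediate = ids[idx_pal],
                      confounder_annotated = ids[idx_conf],
                      seed = cf$seed))
  })
}

#' Write a synthetic dataset to a directory
#'
#' Serializes the output of [synth_generate()] in the delimited dialects
#' the readers consume: `exposure.tsv`, `outcome.tsv`, `ld.tsv`,
#' `annotations.tsv`, `truth.yaml`.
#'
#' @param x Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gwas_summary(x$exposure, file.path(dir, "exposure.tsv"))
  write_gwas_summary(x$outcome, file.path(dir, "outcome.tsv"))
  utils::write.table(cbind(variant_id = rownames(x$ld), as.data.frame(x$ld)),
                     file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(x$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' The packaged 4-SNP conservative instrument fixture
#'
#' The four variants at the CRP locus used as conservative instruments for
#' C-reactive protein (rs3093077, rs1205, rs1130864, rs1800947), with
#' their per-allele associations with ln(CRP) and with amyotrophic lateral
#' sclerosis log-odds, read from the delimited files shipped under
#' `inst/extdata/`. The two files are already harmonized; outcome-side
#' allele frequencies are not separately available, so the fixture reuses
#' the exposure-side alleles and EAF. Exposure p-values are the normal
#' approximation from the tabulated beta and SE.
#'
#' @return List with `exposure` and `outcome` data frames in the
#'   [read_gwas_summary()] layout (4 rows each).
#' @examples
#' fx <- table1_fixture()
#' fx$exposure$beta   # 0.21 0.18 0.13 0.26
#' @export
table1_fixture <- function() {
  list(
    exposure = read_gwas_summary(
      system.file("extdata", "crp_conservative_exposure.tsv",
                  package = "mrforge", mustWork = TRUE)),
    outcome = read_gwas_summary(
      system.file("extdata", "als_conservative_outcome.tsv",
                  package = "mrforge", mustWork = TRUE))
  )
}
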