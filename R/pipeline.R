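# Config-driven end-to-end runner: harmonize -> select instruments ->
# estimate -> diagnostics -> report bundle.

.default_run_config <- function() {
  list(
    exposure = NULL, outcome = NULL, ld = NULL, annotations = NULL,
    output_dir = NULL,
    clump_window_kb = 10000, clump_r2 = 0.001,
    intermediate_eaf_band = c(0.42, 0.58),
    gwas_p = 5e-8,
    confounder_traits = default_confounder_traits(),
    confounder_p = 5e-8,
    steiger = TRUE, n_exp = 204402, n_out = 80610,
    f_min = 10,
    n_boot = 1000, phi = 1, n_sim = 1000, seed = NULL,
    ivw_model = "multiplicative_random", ci_level = 0.95,
    bidirectional = FALSE
  )
}

#' Run the full Mendelian randomization pipeline
#'
#' Drives the whole workflow from a configuration list or YAML file:
#' read exposure and outcome summary statistics, optionally LD-clump the
#' exposure variants, harmonize the two datasets, apply the
#' confounder-association, Steiger-directionality and F-statistic filters,
#' fit every estimator the surviving instrument count admits, run
#' MR-PRESSO (>= 4 instruments), heterogeneity tests, leave-one-out, and
#' export funnel/scatter data plus a run-metadata block. Every exclusion
#' at every stage is recorded with a reason. All stochastic stages derive
#' from the single config seed, so a rerun with the same config is
#' byte-identical.
#'
#' Config keys (defaults in parentheses): `exposure`, `outcome` (file
#' paths, required), `ld`, `annotations` (paths, optional),
#' `output_dir` (optional; when set, the report bundle is written there),
#' `clump_window_kb` (10000), `clump_r2` (0.001), `intermediate_eaf_band`
#' (0.42-0.58), `gwas_p` (5e-8; exposure-significance screen when
#' clumping), `confounder_traits` ([default_confounder_traits()]),
#' `confounder_p` (5e-8), `steiger` (TRUE), `n_exp` (204402), `n_out`
#' (80610), `f_min` (10), `n_boot` (1000), `phi` (1), `n_sim` (1000),
#' `seed` (required for the stochastic stages), `ivw_model`, `ci_level`
#' (0.95), `bidirectional` (FALSE; reverse-direction analysis is refused
#' with an explanatory message when fewer than 2 reverse instruments are
#' supplied).
#'
#' @param config A named list, or path to a YAML file holding one.
#' @return List of class `"mr_pipeline"`: `instruments` (final QC'd
#'   table), `exclusions` (stage-tagged exclusion log), `fit`
#'   (`"mr_fit"`), `heterogeneity` (list: `ivw`, `egger`), `presso`,
#'   `leave_one_out`, `funnel`, `scatter`, `metadata`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .default_run_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config
  if (is.null(cfg$exposure) || is.null(cfg$outcome)) {
    stop("config must name exposure and outcome summary-statistic files",
         call. = FALSE)
  }
  if (isTRUE(cfg$bidirectional)) {
    stop(paste("reverse-direction analysis is disabled: too few variants",
               "instrument the outcome for a meaningful reverse estimate"),
         call. = FALSE)
  }

  exposure <- read_gwas_summary(cfg$exposure)
  outcome <- read_gwas_summary(cfg$outcome)
  log <- list()
  note <- function(stage, df) {
    if (nrow(df)) {
      df$stage <- stage
      log[[length(log) + 1L]] <<- df[, c("variant_id", "stage",
                                         setdiff(names(df), c("variant_id", "stage")))]
    }
  }
  bail_if_empty <- function(dat, stage) {
    if (nrow(dat) == 0L) {
      stop("no instruments survive stage '", stage, "'", call. = FALSE)
    }
    dat
  }

  if (!is.null(cfg$ld)) {
    ld <- if (is.matrix(cfg$ld)) cfg$ld else read_ld_matrix(cfg$ld)
    sig <- exposure[exposure$pvalue < cfg$gwas_p, , drop = FALSE]
    note("genome-wide significance",
         {
           drop_ids <- setdiff(exposure$variant_id, sig$variant_id)
           data.frame(variant_id = drop_ids,
                      reason = rep(sprintf("exposure p >= %g", cfg$gwas_p),
                                   length(drop_ids)),
                      stringsAsFactors = FALSE)
         })
    kept <- clump(sig, ld, cfg$clump_window_kb, cfg$clump_r2)
    note("clumping",
         {
           drop_ids <- setdiff(sig$variant_id, kept$variant_id)
           data.frame(variant_id = drop_ids,
                      reason = rep(sprintf("in LD (r2 > %g) with a stronger variant",
                                           cfg$clump_r2), length(drop_ids)),
                      stringsAsFactors = FALSE)
         })
    exposure <- bail_if_empty(kept, "clumping")
  }

  h <- harmonize(exposure, outcome, cfg$intermediate_eaf_band)
  note("harmonization", h$exclusions)
  dat <- bail_if_empty(h$instruments, "harmonization")

  if (!is.null(cfg$annotations)) {
    ann <- if (is.data.frame(cfg$annotations)) cfg$annotations
           else read_trait_annotations(cfg$annotations)
    cfr <- confounder_filter(dat, ann, cfg$confounder_traits, cfg$confounder_p)
    if (nrow(cfr$exclusions)) {
      note("confounder filter",
           data.frame(variant_id = cfr$exclusions$variant_id,
                      reason = sprintf("associated with %s (p = %.3g)",
                                       cfr$exclusions$trait,
                                       cfr$exclusions$pvalue),
                      stringsAsFactors = FALSE))
    }
    dat <- bail_if_empty(cfr$instruments, "confounder filter")
  }

  if (isTRUE(cfg$steiger)) {
    st <- steiger_filter(dat, cfg$n_exp, cfg$n_out)
    note("Steiger filter", st$exclusions)
    dat <- bail_if_empty(st$instruments, "Steiger filter")
  }

  ff <- f_filter(dat, cfg$f_min)
  note("F filter", ff$exclusions[, c("variant_id", "reason")])
  dat <- bail_if_empty(ff$instruments, "F filter")

  fit <- mr_fit(dat, n_boot = cfg$n_boot, seed = cfg$seed, phi = cfg$phi,
                ivw_model = cfg$ivw_model, ci_level = cfg$ci_level)

  heterogeneity <- list()
  if (!is.null(fit$estimates$ivw)) {
    heterogeneity$ivw <- cochran_q(dat, fit$estimates$ivw)
  }
  if (!is.null(fit$estimates$egger)) {
    heterogeneity$egger <- cochran_q(dat, fit$estimates$egger)
  }
  presso <- if (nrow(dat) >= 4L) {
    mr_presso(dat, n_sim = cfg$n_sim, seed = cfg$seed,
              ivw_model = cfg$ivw_model)
  }
  loo <- if (nrow(dat) >= 3L) leave_one_out(dat, "ivw")
  funnel <- funnel_data(dat)
  scatter <- if (length(fit$estimates)) scatter_data(dat, fit$estimates)

  exclusions <- if (length(log)) {
    do.call(rbind, lapply(log, function(d) d[, c("variant_id", "stage", "reason")]))
  } else {
    data.frame(variant_id = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  metadata <- list(
    package_version = as.character(utils::packageVersion("mrforge")),
    rng_kind = paste(RNGkind(), collapse = "/"),
    seed = cfg$seed,
    thresholds = cfg[c("clump_window_kb", "clump_r2", "intermediate_eaf_band",
                       "gwas_p", "confounder_p", "f_min", "n_boot", "phi",
                       "n_sim", "ivw_model", "ci_level")],
    n_instruments = nrow(dat)
  )

  out <- structure(list(instruments = dat, exclusions = exclusions, fit = fit,
                        heterogeneity = heterogeneity, presso = presso,
                        leave_one_out = loo, funnel = funnel,
                        scatter = scatter, metadata = metadata),
                   class = "mr_pipeline")
  if (!is.null(cfg$output_dir)) write_pipeline_report(out, cfg$output_dir)
  out
}

#' Write a pipeline report bundle as delimited text
#'
#' Emits the instrument table with QC flags, the stage-tagged exclusion
#' log, a results table (method, N SNPs, OR, 95% CI, p), heterogeneity and
#' Egger-intercept report, the MR-PRESSO report, leave-one-out, funnel and
#' scatter data, and a YAML run-metadata block.
#'
#' @param x An `"mr_pipeline"` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(x$instruments, "instruments.tsv")
  tsv(x$exclusions, "exclusions.tsv")
  res <- as.data.frame(x$fit)
  res$ci_95 <- sprintf("%.3f-%.3f", res$ci_low, res$ci_high)
  tsv(res[, c("method", "n_snps", "or", "ci_95", "pvalue")], "results.tsv")
  het <- do.call(rbind, lapply(x$heterogeneity, function(hh) {
    data.frame(method = hh$method, Q = hh$q, df = hh$df, pvalue = hh$pvalue)
  }))
  if (!is.null(het)) tsv(het, "heterogeneity.tsv")
  egger <- x$fit$estimates$egger
  if (!is.null(egger)) {
    tsv(data.frame(intercept = egger$extras$intercept,
                   se = egger$extras$intercept_se,
                   pvalue = egger$extras$intercept_p),
        "egger_intercept.tsv")
  }
  if (!is.null(x$presso)) write_presso_report(x$presso, file.path(dir, "presso.txt"))
  if (!is.null(x$leave_one_out)) tsv(x$leave_one_out, "leave_one_out.tsv")
  fun <- x$funnel
  tsv(fun, "funnel.tsv")
  refs <- attr(fun, "reference_lines")
  if (length(refs)) {
    tsv(data.frame(method = names(refs), slope = unname(refs)),
        "funnel_reference_lines.tsv")
  }
  if (!is.null(x$scatter)) {
    tsv(x$scatter$points, "scatter_points.tsv")
    tsv(x$scatter$lines, "scatter_lines.tsv")
  }
  yaml::write_yaml(x$metadata, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat(sprintf("MR pipeline: %d instruments retained, %d exclusions\n\n",
              nrow(x$instruments), nrow(x$exclusions)))
  print(x$fit)
  if (!is.null(x$heterogeneity$ivw)) {
    cat("\n")
    print(x$heterogeneity$ivw)
  }
  if (!is.null(x$presso)) {
    cat(sprintf("MR-PRESSO global p = %.3g, %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  invisible(x)
}
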