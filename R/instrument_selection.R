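# Instrument QC cascade: LD clumping, F statistic, variance explained,
# Steiger directionality filtering, confounder-association filtering.

#' Default list of confounder traits screened during instrument selection
#'
#' Traits with established causal links to the outcome that would violate
#' the independence assumption if an instrument were associated with them.
#'
#' @return Character vector of trait names.
#' @export
default_confounder_traits <- function() {
  c("LDL", "total cholesterol", "type 2 diabetes", "childhood BMI",
    "neutrophil count", "white blood cell count",
    "systolic blood pressure", "diastolic blood pressure")
}

#' Read a square LD correlation matrix from delimited text
#'
#' Expects a header row of variant IDs and a leading ID column; entries are
#' pairwise correlations r in [-1, 1] with unit diagonal.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return Numeric matrix with variant IDs as dimnames.
#' @export
read_ld_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

#' Validate an LD correlation matrix
#'
#' @param r Square numeric matrix with variant IDs as dimnames.
#' @return `r`, invisibly, after checking symmetry, unit diagonal, entries
#'   in [-1, 1] and matching dimnames.
#' @export
validate_ld_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop("LD matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r))) {
    stop("LD matrix needs identical row and column variant IDs", call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r) - 1) > 1e-8)) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  invisible(r)
}

#' Greedy LD clumping
#'
#' Prunes correlated variants so the retained instruments are approximately
#' independent: repeatedly keep the remaining variant with the smallest
#' p-value and discard all others within `window_kb` of it whose squared
#' correlation with it exceeds `r2_threshold`. Deterministic; ties in
#' p-value are broken by input order.
#'
#' @param variants Data frame with at least `variant_id` and `pvalue`;
#'   `chrom` and `pos` are required when `window_kb` is finite (variants on
#'   different chromosomes, or further apart than the window, are never
#'   pruned against each other).
#' @param ld Square correlation matrix (see [read_ld_matrix()]). A pair of
#'   candidates within the window that is missing from `ld` is a hard
#'   error; independence is never silently assumed.
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_threshold Squared-correlation cutoff (default 0.001).
#' @return The retained subset of `variants`, in selection order (increasing
#'   p-value).
#' @export
clump <- function(variants, ld, window_kb = 10000, r2_threshold = 0.001) {
  if (nrow(variants) == 0L) return(variants)
  if (any(is.na(variants$pvalue))) stop("clumping requires p-values", call. = FALSE)
  finite_window <- is.finite(window_kb)
  if (finite_window &&
      (is.null(variants$pos) || any(is.na(variants$pos)) ||
       is.null(variants$chrom) || any(is.na(variants$chrom)))) {
    stop("chrom/pos required for a finite clumping window", call. = FALSE)
  }
  validate_ld_matrix(ld)
  ord <- order(variants$pvalue)
  active <- rep(TRUE, nrow(variants))
  sel <- integer(0)
  for (i in ord) {
    if (!active[i]) next
    sel <- c(sel, i)
    active[i] <- FALSE
    cand <- which(active)
    if (finite_window) {
      cand <- cand[variants$chrom[cand] == variants$chrom[i] &
                     abs(variants$pos[cand] - variants$pos[i]) <= window_kb * 1000]
    }
    if (!length(cand)) next
    ids <- variants$variant_id[cand]
    id_i <- variants$variant_id[i]
    known <- id_i %in% rownames(ld) & ids %in% rownames(ld)
    if (!all(known)) {
      stop("LD missing for pair(s) within window: ",
           paste(id_i, ids[!known], sep = "/", collapse = ", "), call. = FALSE)
    }
    r2 <- ld[id_i, ids]^2
    active[cand[r2 > r2_threshold]] <- FALSE
  }
  variants[sel, , drop = FALSE]
}

#' Per-instrument F statistic
#'
#' `F = beta^2 / se^2`; values below 10 conventionally flag weak
#' instruments.
#'
#' @param beta Effect size(s).
#' @param se Standard error(s), > 0.
#' @return Numeric vector of F values.
#' @examples
#' f_statistic(0.18, 0.01)   # 324
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be > 0", call. = FALSE)
  beta^2 / se^2
}

#' Variance in a trait explained by a variant
#'
#' For a standardized trait, `R^2 = 2 beta^2 MAF (1 - MAF)` under
#' Hardy-Weinberg equilibrium.
#'
#' @param beta Per-allele effect on the standardized trait.
#' @param maf Minor-allele frequency in [0, 0.5]; fold effect-allele
#'   frequencies above 0.5 before calling.
#' @return R^2 fraction(s).
#' @export
variance_explained <- function(beta, maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("maf must lie in [0, 0.5] (fold EAF to MAF first)", call. = FALSE)
  }
  2 * beta^2 * maf * (1 - maf)
}

.fold_maf <- function(eaf) ifelse(eaf > 0.5, 1 - eaf, eaf)

#' Steiger directionality filtering
#'
#' Tests, per instrument, that it explains more variance in the exposure
#' than in the outcome (i.e. that the assumed causal direction exposure ->
#' outcome is supported). Variance explained on each side uses
#' [variance_explained()] with that dataset's own effect-allele frequency;
#' on the outcome side the formula is applied to log-odds coefficients,
#' which is an approximation (a liability-scale conversion can be slotted
#' in via `r2_fun_out`). A two-sided Z test on the Fisher-transformed
#' correlations, `z = (atanh(r_exp) - atanh(r_out)) /
#' sqrt(1/(n_exp - 3) + 1/(n_out - 3))`, is reported alongside.
#'
#' Instruments with `r2_exp <= r2_out` (ties count as failures) or with a
#' missing allele frequency are excluded and reported.
#'
#' @param instruments Harmonized instrument data frame
#'   (see [harmonize()]).
#' @param n_exp,n_out Exposure / outcome study sample sizes, used when the
#'   per-variant `n_exp` / `n_out` columns are missing.
#' @param r2_fun_out Function `(beta, maf) -> R^2` for the outcome side;
#'   defaults to [variance_explained()].
#' @return List with `instruments` (retained rows, plus columns `r2_exp`,
#'   `r2_out`, `steiger_direction`, `steiger_z`, `steiger_pvalue`) and
#'   `exclusions` (data frame `variant_id`, `reason`).
#' @export
steiger_filter <- function(instruments, n_exp = 204402, n_out = 80610,
                           r2_fun_out = variance_explained) {
  dat <- instruments
  ne <- ifelse(is.na(dat$n_exp), n_exp, dat$n_exp)
  no <- ifelse(is.na(dat$n_out), n_out, dat$n_out)
  evaluable <- !is.na(dat$eaf_exp) & !is.na(dat$eaf_out)
  r2e <- r2o <- z <- p <- rep(NA_real_, nrow(dat))
  r2e[evaluable] <- variance_explained(dat$beta_exp[evaluable],
                                       .fold_maf(dat$eaf_exp[evaluable]))
  r2o[evaluable] <- r2_fun_out(dat$beta_out[evaluable],
                               .fold_maf(dat$eaf_out[evaluable]))
  direction <- evaluable & r2e > r2o
  ze <- atanh(sqrt(pmin(r2e, 1 - 1e-12)))
  zo <- atanh(sqrt(pmin(r2o, 1 - 1e-12)))
  z[evaluable] <- (ze[evaluable] - zo[evaluable]) /
    sqrt(1 / (ne[evaluable] - 3) + 1 / (no[evaluable] - 3))
  p[evaluable] <- 2 * stats::pnorm(-abs(z[evaluable]))
  dat$r2_exp <- r2e; dat$r2_out <- r2o
  dat$steiger_direction <- direction
  dat$steiger_z <- z; dat$steiger_pvalue <- p
  reason <- ifelse(!evaluable, "Steiger unevaluable: missing allele frequency",
                   "Steiger direction FALSE")
  list(instruments = dat[direction, , drop = FALSE],
       exclusions = data.frame(variant_id = dat$variant_id[!direction],
                               reason = reason[!direction],
                               stringsAsFactors = FALSE))
}

#' Read a variant-trait annotation table
#'
#' A local stand-in for web-based trait lookups: delimited text with columns
#' `variant_id` (or `SNP`), `trait`, `pvalue` (or `pval`).
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @return Data frame with columns `variant_id`, `trait`, `pvalue`.
#' @export
read_trait_annotations <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  nm[nm == "SNP"] <- "variant_id"
  nm[nm == "pval"] <- "pvalue"
  names(df) <- nm
  need <- c("variant_id", "trait", "pvalue")
  if (!all(need %in% nm)) {
    stop("annotation table needs columns variant_id/SNP, trait, pvalue", call. = FALSE)
  }
  if (any(df$pvalue <= 0)) stop("annotation pvalue must be > 0", call. = FALSE)
  df[need]
}

#' Exclude instruments associated with confounder traits
#'
#' An instrument is excluded iff it carries at least one annotation to a
#' trait in `confounder_traits` with association p-value strictly below
#' `p_threshold` (genome-wide significance by default).
#'
#' @param instruments Data frame with a `variant_id` column.
#' @param annotations Annotation data frame (see
#'   [read_trait_annotations()]).
#' @param confounder_traits Character vector of trait names to screen
#'   against; defaults to [default_confounder_traits()].
#' @param p_threshold Significance threshold (default `5e-8`; strict
#'   inequality, so an annotation at exactly the threshold is kept).
#' @return List with `instruments` (retained rows) and `exclusions` (data
#'   frame `variant_id`, `trait`, `pvalue`, one row per triggering
#'   annotation).
#' @export
confounder_filter <- function(instruments, annotations,
                              confounder_traits = default_confounder_traits(),
                              p_threshold = 5e-8) {
  if (is.null(annotations) || nrow(annotations) == 0L ||
      length(confounder_traits) == 0L) {
    return(list(instruments = instruments,
                exclusions = data.frame(variant_id = character(0),
                                        trait = character(0),
                                        pvalue = numeric(0),
                                        stringsAsFactors = FALSE)))
  }
  hits <- annotations[annotations$trait %in% confounder_traits &
                        annotations$pvalue < p_threshold &
                        annotations$variant_id %in% instruments$variant_id, ,
                      drop = FALSE]
  keep <- !instruments$variant_id %in% hits$variant_id
  list(instruments = instruments[keep, , drop = FALSE],
       exclusions = data.frame(variant_id = hits$variant_id,
                               trait = hits$trait, pvalue = hits$pvalue,
                               stringsAsFactors = FALSE))
}

#' Weak-instrument filtering by F statistic
#'
#' @param instruments Harmonized instrument data frame.
#' @param f_min Minimum F (default 10); instruments with
#'   `F = beta_exp^2 / se_exp^2 < f_min` are excluded and reported.
#' @return List with `instruments` (retained, plus column `f_stat`) and
#'   `exclusions` (`variant_id`, `f_stat`, `reason`).
#' @export
f_filter <- function(instruments, f_min = 10) {
  f <- f_statistic(instruments$beta_exp, instruments$se_exp)
  instruments$f_stat <- f
  keep <- f >= f_min
  list(instruments = instruments[keep, , drop = FALSE],
       exclusions = data.frame(variant_id = instruments$variant_id[!keep],
                               f_stat = f[!keep],
                               reason = rep(sprintf("weak instrument (F < %g)", f_min),
                                            sum(!keep)),
                               stringsAsFactors = FALSE))
}
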