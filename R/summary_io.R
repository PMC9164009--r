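# Reading, validating and harmonizing GWAS summary statistics.

.required_cols <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
.optional_cols <- c("eaf", "n", "chrom", "pos")

.default_column_map <- c(
  variant_id = "SNP", effect_allele = "effect_allele",
  other_allele = "other_allele", eaf = "eaf", beta = "beta", se = "se",
  pvalue = "pval", n = "N", chrom = "chrom", pos = "pos"
)

#' Default column mapping for GWAS summary-statistic files
#'
#' Maps the internal field names onto GWAS-catalog-style column headers
#' (`SNP`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#' `N`, `chrom`, `pos`). Override entries to read files with other headers.
#'
#' @return Named character vector: internal field name -> file column name.
#' @export
gwas_column_map <- function() .default_column_map

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.check_allele <- function(a, what = "allele") {
  a <- toupper(as.character(a))
  bad <- !a %in% c("A", "C", "G", "T")
  if (any(bad)) {
    stop(sprintf("invalid %s: %s (must be one of A/C/G/T)", what,
                 paste(unique(a[bad]), collapse = ", ")), call. = FALSE)
  }
  a
}

#' Test whether an allele pair is palindromic
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone; such variants are ambiguous when the
#' allele frequency is near 0.5.
#'
#' @param a1,a2 Single bases (A/C/G/T), vectorised.
#' @return Logical vector, `TRUE` where `{a1, a2}` is `{A,T}` or `{C,G}`.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- .check_allele(a1)
  a2 <- .check_allele(a2)
  unname(.complement[a1] == a2)
}

#' Read a GWAS summary-statistic file
#'
#' Reads a delimited text file of per-variant association results into a
#' validated data frame (one row per variant). The delimiter (tab or comma)
#' is sniffed from the header line. Column names are resolved through
#' `column_map`; `variant_id`, `effect_allele`, `other_allele`, `beta`,
#' `se` and `pvalue` are required, `eaf`, `n`, `chrom` and `pos` optional.
#'
#' Malformed rows (non-numeric beta/se/pvalue, non-positive se, invalid
#' alleles, out-of-range eaf or pvalue) are collected and reported in a
#' single error naming the offending data rows; they are never silently
#' dropped.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param column_map Named character vector mapping internal field names to
#'   file column names; see [gwas_column_map()].
#' @return A data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, `chrom`, `pos`
#'   (optional columns are `NA` when absent from the file). Alleles are
#'   upper-cased.
#' @export
read_gwas_summary <- function(path, column_map = gwas_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  map <- .default_column_map
  map[names(column_map)] <- column_map
  missing_req <- .required_cols[!map[.required_cols] %in% names(raw)]
  if (length(missing_req)) {
    stop("missing required column(s) in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing_req, map[missing_req]),
               collapse = ", "), call. = FALSE)
  }
  n_row <- nrow(raw)
  get <- function(field) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n_row)
  }
  out <- data.frame(
    variant_id = get("variant_id"),
    effect_allele = toupper(get("effect_allele")),
    other_allele = toupper(get("other_allele")),
    eaf = rep(NA_real_, n_row), beta = rep(NA_real_, n_row),
    se = rep(NA_real_, n_row), pvalue = rep(NA_real_, n_row),
    n = rep(NA_real_, n_row), chrom = get("chrom"),
    pos = rep(NA_real_, n_row),
    stringsAsFactors = FALSE
  )
  if (n_row == 0L) return(out)

  problems <- character(0)
  num <- function(field, required) {
    x <- get(field)
    miss <- is.na(x) | x == "" | toupper(x) == "NA"
    v <- suppressWarnings(as.numeric(x))
    bad <- !miss & is.na(v)
    if (any(bad)) {
      problems <<- c(problems, sprintf("row %d: non-numeric %s '%s'",
                                       which(bad), field, x[bad]))
    }
    if (required && any(miss)) {
      problems <<- c(problems, sprintf("row %d: missing %s", which(miss), field))
    }
    v
  }
  out$beta <- num("beta", required = TRUE)
  out$se <- num("se", required = TRUE)
  out$pvalue <- num("pvalue", required = TRUE)
  out$eaf <- num("eaf", required = FALSE)
  out$n <- num("n", required = FALSE)
  out$pos <- num("pos", required = FALSE)

  bad_se <- !is.na(out$se) & out$se <= 0
  if (any(bad_se)) problems <- c(problems, sprintf("row %d: se must be > 0", which(bad_se)))
  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  if (any(bad_eaf)) problems <- c(problems, sprintf("row %d: eaf outside [0,1]", which(bad_eaf)))
  bad_p <- !is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1)
  if (any(bad_p)) problems <- c(problems, sprintf("row %d: pvalue outside (0,1]", which(bad_p)))
  bad_al <- !(out$effect_allele %in% names(.complement)) |
    !(out$other_allele %in% names(.complement))
  if (any(bad_al)) problems <- c(problems, sprintf("row %d: invalid allele", which(bad_al)))
  same <- !bad_al & out$effect_allele == out$other_allele
  if (any(same)) problems <- c(problems, sprintf("row %d: effect and other allele identical", which(same)))
  if (length(problems)) {
    stop("malformed rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Write a summary-statistic or result table as delimited text
#'
#' @param x Data frame.
#' @param path Output path; tab-delimited, no quoting, `NA` written as `NA`.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(x, path) {
  df <- x
  # column headers on the dialect read_gwas_summary expects
  rename <- c(variant_id = "SNP", pvalue = "pval", n = "N")
  nm <- names(df)
  hit <- nm %in% names(rename)
  nm[hit] <- rename[nm[hit]]
  names(df) <- nm
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared variant onto the exposure's
#' effect allele, so downstream estimators see (beta_exp, beta_out) pairs
#' expressed for the same allele. Resolution proceeds per variant:
#'
#' * alleles already aligned: kept as-is;
#' * alleles swapped (effect/other exchanged): outcome beta negated, outcome
#'   EAF replaced by 1 - EAF, `flipped = TRUE`;
#' * alleles matching after strand complement (non-palindromic only):
#'   aligned, with a swap-flip when needed;
#' * palindromic variants (A/T, C/G): excluded when the exposure EAF lies in
#'   `intermediate_eaf_band` (strand is unresolvable near 0.5); outside the
#'   band, aligned by EAF concordance -- outcome EAF on the same side of 0.5
#'   as the exposure EAF means same allele; palindromic variants lacking an
#'   outcome EAF are excluded conservatively;
#' * anything else: excluded as an allele mismatch.
#'
#' Variants absent from the outcome set are dropped and reported (no proxy
#' search is attempted).
#'
#' @param exposure,outcome Data frames as returned by [read_gwas_summary()].
#' @param intermediate_eaf_band Length-2 numeric, the open EAF interval in
#'   which a palindromic variant is considered ambiguous. Default
#'   `c(0.42, 0.58)`.
#' @return An object of class `"mr_harmonized"`: a list with
#'   `instruments` (data frame: `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `pvalue_exp`, `eaf_exp`, `n_exp`,
#'   `chrom`, `pos`, `beta_out`, `se_out`, `pvalue_out`, `eaf_out`, `n_out`,
#'   `palindromic`, `flipped`) and `exclusions` (data frame: `variant_id`,
#'   `reason`).
#' @examples
#' fx <- table1_fixture()
#' h <- harmonize(fx$exposure, fx$outcome)
#' h$instruments$variant_id
#' @export
harmonize <- function(exposure, outcome, intermediate_eaf_band = c(0.42, 0.58)) {
  stopifnot(length(intermediate_eaf_band) == 2L,
            intermediate_eaf_band[1] < intermediate_eaf_band[2])
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id)) {
    stop("variant_id must be unique within each dataset", call. = FALSE)
  }
  om <- outcome[match(exposure$variant_id, outcome$variant_id), , drop = FALSE]

  keep <- logical(nrow(exposure))
  flipped <- logical(nrow(exposure))
  reason <- character(nrow(exposure))
  beta_out <- om$beta
  eaf_out <- om$eaf

  for (i in seq_len(nrow(exposure))) {
    if (is.na(om$variant_id[i])) {
      reason[i] <- "missing in outcome"
      next
    }
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    ea2 <- om$effect_allele[i]; oa2 <- om$other_allele[i]
    pal <- unname(.complement[ea] == oa)
    if (pal) {
      # allele codes cannot distinguish swap from strand flip
      if (!setequal(c(ea, oa), c(ea2, oa2)) &&
          !setequal(c(ea, oa), c(.complement[ea2], .complement[oa2]))) {
        reason[i] <- "allele mismatch"
        next
      }
      eafx <- exposure$eaf[i]
      if (!is.na(eafx) && eafx > intermediate_eaf_band[1] &&
          eafx < intermediate_eaf_band[2]) {
        reason[i] <- "palindromic with intermediate allele frequency"
        next
      }
      if (is.na(eafx) || is.na(om$eaf[i])) {
        reason[i] <- "palindromic with missing allele frequency"
        next
      }
      # EAF concordance: same side of 0.5 means the same underlying allele
      if ((eafx < 0.5) == (om$eaf[i] < 0.5)) {
        keep[i] <- TRUE
      } else {
        keep[i] <- TRUE; flipped[i] <- TRUE
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    aligned <- (ea == ea2 && oa == oa2) ||
      (ea == .complement[ea2] && oa == .complement[oa2])
    swapped <- (ea == oa2 && oa == ea2) ||
      (ea == .complement[oa2] && oa == .complement[ea2])
    if (aligned) {
      keep[i] <- TRUE
    } else if (swapped) {
      keep[i] <- TRUE; flipped[i] <- TRUE
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      reason[i] <- "allele mismatch"
    }
  }

  instruments <- data.frame(
    variant_id = exposure$variant_id[keep],
    effect_allele = exposure$effect_allele[keep],
    other_allele = exposure$other_allele[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    pvalue_exp = exposure$pvalue[keep], eaf_exp = exposure$eaf[keep],
    n_exp = exposure$n[keep],
    chrom = if (is.null(exposure$chrom)) NA_character_ else exposure$chrom[keep],
    pos = if (is.null(exposure$pos)) NA_real_ else exposure$pos[keep],
    beta_out = beta_out[keep], se_out = om$se[keep],
    pvalue_out = om$pvalue[keep], eaf_out = eaf_out[keep], n_out = om$n[keep],
    palindromic = unname(.complement[exposure$effect_allele[keep]] ==
                           exposure$other_allele[keep]),
    flipped = flipped[keep],
    stringsAsFactors = FALSE
  )
  exclusions <- data.frame(variant_id = exposure$variant_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(instruments = instruments, exclusions = exclusions),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d retained, %d excluded\n",
              nrow(x$instruments), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  }
  invisible(x)
}
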