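#' Instrument construction settings
#'
#' Defaults follow standard two-sample MR practice: genome-wide significance
#' (p < 5e-8) and near-independence (r^2 < 0.001). A relaxed `clump_r2` of
#' 0.10 is conventional when weakly-linked SNPs are retained to maximize
#' instrument strength (their correlation must then be carried into
#' estimation via [mr_ivw_correlated()]). `cis_region` restricts candidates
#' to a window around a gene, e.g. +/- 100 kb.
#'
#' @param p_threshold Significance cutoff (keep p < threshold).
#' @param clump_r2 Squared-correlation pruning threshold.
#' @param cis_region Optional list/vector with `chrom`, `start`, `end`.
#' @param stricter_thresholds Optional numeric vector of more conservative
#'   p-value cutoffs for winner's-curse sensitivity reruns (e.g. 5e-9, 5e-10).
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                            cis_region = NULL, stricter_thresholds = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 cis_region = cis_region,
                 stricter_thresholds = stricter_thresholds),
            class = "instrument_spec")
}

#' Greedy LD clumping of SNPs by p-value
#'
#' Iteratively retains the unprocessed SNP with the smallest p-value and
#' discards every other unprocessed SNP whose squared correlation with it
#' reaches `r2_threshold`. Ties on p-value are broken by rsid (lexicographic)
#' for determinism.
#'
#' @param pvalues Numeric vector of per-SNP p-values.
#' @param ld Square correlation matrix matching `pvalues`.
#' @param r2_threshold Squared-correlation cutoff; pairs with r^2 >=
#'   threshold conflict.
#' @param rsids Optional identifiers used for tie-breaking (defaults to
#'   index order).
#' @return Sorted integer vector of retained indices.
#' @export
greedy_ld_clump <- function(pvalues, ld, r2_threshold, rsids = NULL) {
  k <- length(pvalues)
  if (nrow(ld) != k || ncol(ld) != k) {
    stop("LD matrix dimensions do not match the p-value vector", call. = FALSE)
  }
  if (max(abs(ld - t(ld))) > 1e-8) {
    stop("LD matrix is not symmetric", call. = FALSE)
  }
  if (is.null(rsids)) rsids <- sprintf("snp%09d", seq_len(k))
  ord <- order(pvalues, rsids)
  r2 <- ld^2
  alive <- rep(TRUE, k)
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    conflict <- alive & r2[i, ] >= r2_threshold
    conflict[i] <- FALSE
    alive[conflict] <- FALSE
    alive[i] <- FALSE
  }
  sort(kept)
}

#' Select genetic instruments from a summary dataset
#'
#' Applies, in order: the significance threshold, the optional cis-region
#' window, and greedy LD clumping (when an LD matrix is supplied). If no LD
#' matrix is given the surviving SNPs are assumed independent and clumping is
#' skipped.
#'
#' @param dataset A [summary_dataset()].
#' @param spec An [instrument_spec()].
#' @param ld Optional LD correlation matrix with rsid dimnames covering all
#'   candidates that reach the clumping stage.
#' @return A `summary_dataset` containing only the instrument SNPs.
#' @export
select_instruments <- function(dataset, spec = instrument_spec(), ld = NULL) {
  stopifnot(inherits(dataset, "summary_dataset"))
  snps <- dataset$snps
  snps <- snps[snps$pvalue < spec$p_threshold, , drop = FALSE]
  if (nrow(snps) == 0) {
    stop("no SNPs survive the p-value threshold (", spec$p_threshold,
         ") for '", dataset$trait_name, "'", call. = FALSE)
  }
  if (!is.null(spec$cis_region)) {
    reg <- spec$cis_region
    if (!all(c("chrom", "pos") %in% names(snps))) {
      stop("cis_region filtering requires chrom/pos columns", call. = FALSE)
    }
    inside <- snps$chrom == reg$chrom & snps$pos >= reg$start &
      snps$pos <= reg$end
    snps <- snps[inside %in% TRUE, , drop = FALSE]
    if (nrow(snps) == 0) {
      stop("no SNPs survive the cis-region filter for '",
           dataset$trait_name, "'", call. = FALSE)
    }
  }
  if (!is.null(ld) && nrow(snps) > 1) {
    missing_ld <- setdiff(snps$rsid, rownames(ld))
    if (length(missing_ld) > 0) {
      stop("LD matrix does not cover candidate rsids: ",
           paste(head(missing_ld, 5L), collapse = ", "), call. = FALSE)
    }
    sub <- ld[snps$rsid, snps$rsid, drop = FALSE]
    kept <- greedy_ld_clump(snps$pvalue, sub, spec$clump_r2,
                            rsids = snps$rsid)
    snps <- snps[kept, , drop = FALSE]
    if (nrow(snps) == 0) {
      stop("no SNPs survive LD clumping for '", dataset$trait_name, "'",
           call. = FALSE)
    }
  }
  out <- dataset
  out$snps <- snps
  rownames(out$snps) <- NULL
  out
}

#' Effective sample size for a case-control association
#'
#' `4 / (1/n_cases + 1/n_controls)`, the standard calibration used when
#' comparing variance explained between continuous and binary traits.
#'
#' @param n Total sample size.
#' @param n_cases Case count.
#' @return Effective sample size.
#' @export
effective_n <- function(n, n_cases) {
  4 / (1 / n_cases + 1 / (n - n_cases))
}

#' Per-SNP variance explained from summary statistics
#'
#' Uses the t-statistic approximation `r^2 = t^2 / (t^2 + n - 2)` with
#' `t = beta/se`. For binary traits `n` is replaced by the effective sample
#' size `4/(1/n_cases + 1/n_controls)`.
#'
#' @param beta,se Per-SNP effect and standard error.
#' @param n Sample size (>= 3).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_cases Case count (binary traits); alternatively supply
#'   `case_fraction`.
#' @param case_fraction Case fraction used when `n_cases` is missing.
#' @return Variance explained in \[0, 1\] (vectorized).
#' @export
snp_r2 <- function(beta, se, n, trait_type = "continuous", n_cases = NULL,
                   case_fraction = NULL) {
  if (any(!is.finite(n))) stop("sample size n is required", call. = FALSE)
  if (trait_type == "binary") {
    if (is.null(n_cases) || all(is.na(n_cases))) {
      if (is.null(case_fraction)) {
        stop("binary trait r^2 needs n_cases or case_fraction", call. = FALSE)
      }
      n_cases <- case_fraction * n
    }
    n <- effective_n(n, n_cases)
  }
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument strength summary (variance explained and F-statistics)
#'
#' Per-SNP `F_i = (n_i - 2) r2_i / (1 - r2_i)`; the instrument F is their
#' mean, and total variance explained sums per-SNP r^2 under independence.
#'
#' @param instrument A [summary_dataset()] of instrument SNPs.
#' @return An object of class `instrument_strength` with `r2_total`,
#'   `f_mean`, `n_snps` and `per_snp_r2`.
#' @export
instrument_strength <- function(instrument) {
  snps <- instrument$snps
  if (nrow(snps) == 0) stop("empty instrument", call. = FALSE)
  r2 <- snp_r2(snps$beta, snps$se, snps$n, instrument$trait_type,
               n_cases = snps$n_cases,
               case_fraction = instrument$case_fraction)
  if (any(r2 >= 1)) stop("degenerate per-SNP r^2 = 1", call. = FALSE)
  n_eff <- snps$n
  if (instrument$trait_type == "binary") {
    ncase <- snps$n_cases
    if (all(is.na(ncase))) ncase <- instrument$case_fraction * snps$n
    n_eff <- effective_n(snps$n, ncase)
  }
  f <- (n_eff - 2) * r2 / (1 - r2)
  structure(list(r2_total = sum(r2), f_mean = mean(f), n_snps = nrow(snps),
                 per_snp_r2 = r2, per_snp_f = f),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat("<instrument_strength> ", x$n_snps, " SNPs, R2 = ",
      signif(x$r2_total, 3), ", mean F = ", signif(x$f_mean, 4), "\n",
      sep = "")
  invisible(x)
}

#' Steiger directionality filtering
#'
#' Removes SNPs that explain more variance in the outcome than in the
#' exposure, the signature of a misspecified causal direction. Variance
#' explained on each side uses [snp_r2()] with the binary-trait effective
#' sample size where applicable.
#'
#' @param h A `harmonized_set`.
#' @param exposure_index Which exposure column to test against (default 1).
#' @return List with `harmonized` (the filtered set) and `removed`
#'   (data.frame of rsid and the two r^2 values).
#' @export
steiger_filter <- function(h, exposure_index = 1L) {
  k <- exposure_index
  r2_exp <- snp_r2(h$bx[, k], h$sx[, k], h$nx[, k], h$exposure_types[k])
  case_fraction <- h$case_fraction_y
  r2_out <- snp_r2(h$by, h$sy, h$ny, h$outcome_type,
                   n_cases = h$ncase_y, case_fraction = case_fraction)
  remove <- r2_out > r2_exp
  removed <- data.frame(rsid = h$rsids[remove], r2_exposure = r2_exp[remove],
                        r2_outcome = r2_out[remove], stringsAsFactors = FALSE)
  list(harmonized = subset_harmonized(h, !remove), removed = removed)
}
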