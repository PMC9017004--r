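#' Build a validated GWAS summary dataset
#'
#' A summary dataset holds one row per SNP (identifier, effect/other allele,
#' effect-allele frequency, beta, standard error, p-value, sample size and,
#' for case-control traits, case counts) together with trait metadata. Effects
#' for binary traits are held on the log-odds scale throughout; odds ratios
#' are a presentation transform `exp(beta)`.
#'
#' Rows violating per-SNP invariants (non-positive SE, frequency outside
#' \[0,1\], empty or identical alleles, p-value outside (0,1\], n < 1,
#' n_cases > n) are rejected with a reason and returned in the `rejected`
#' element rather than aborting the read. Duplicated SNP identifiers are an
#' error: they indicate a malformed file, not a bad row.
#'
#' @param snps data.frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` and optionally
#'   `n_cases`, `chrom`, `pos`.
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit_label Free-text unit description (e.g. `"SD (4.7 kg/m^2)"`).
#' @param case_fraction Dataset-level case fraction; required for binary
#'   traits when per-SNP `n_cases` is absent.
#' @return An object of class `summary_dataset`: a list with elements
#'   `trait_name`, `trait_type`, `unit_label`, `case_fraction`, `snps`
#'   (the validated rows) and `rejected` (data.frame of rsid/reason).
#' @export
summary_dataset <- function(snps, trait_name, trait_type = c("continuous", "binary"),
                            unit_label = "", case_fraction = NULL) {
  trait_type <- match.arg(trait_type)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("summary dataset is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"eaf" %in% names(snps)) snps$eaf <- NA_real_
  if (!"n_cases" %in% names(snps)) snps$n_cases <- NA_real_
  snps$rsid <- as.character(snps$rsid)
  snps$effect_allele <- toupper(as.character(snps$effect_allele))
  snps$other_allele <- toupper(as.character(snps$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n", "n_cases")) {
    snps[[col]] <- as.numeric(snps[[col]])
  }

  dup <- unique(snps$rsid[duplicated(snps$rsid)])
  if (length(dup) > 0) {
    stop("duplicated rsid(s) in '", trait_name, "': ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(snps))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag(!is.finite(snps$beta), "missing beta")
  flag(!is.finite(snps$se) | snps$se <= 0, "nonpositive se")
  flag(!is.na(snps$eaf) & (snps$eaf < 0 | snps$eaf > 1), "eaf outside [0,1]")
  flag(nchar(snps$effect_allele) == 0 | nchar(snps$other_allele) == 0,
       "empty allele")
  flag(snps$effect_allele == snps$other_allele, "identical alleles")
  flag(!is.finite(snps$pvalue) | snps$pvalue <= 0 | snps$pvalue > 1,
       "pvalue outside (0,1]")
  flag(!is.finite(snps$n) | snps$n < 1, "invalid n")
  flag(!is.na(snps$n_cases) & snps$n_cases > snps$n, "n_cases exceeds n")

  rejected <- data.frame(rsid = snps$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  snps <- snps[is.na(reason), , drop = FALSE]
  rownames(snps) <- NULL

  if (trait_type == "binary" && is.null(case_fraction) &&
      anyNA(snps$n_cases)) {
    stop("binary trait '", trait_name,
         "' requires n_cases on all records or a dataset-level case_fraction",
         call. = FALSE)
  }

  structure(list(trait_name = trait_name, trait_type = trait_type,
                 unit_label = unit_label, case_fraction = case_fraction,
                 snps = snps, rejected = rejected),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("<summary_dataset> ", x$trait_name, " (", x$trait_type, ")\n", sep = "")
  cat("  SNPs: ", nrow(x$snps), "  rejected rows: ", nrow(x$rejected), "\n",
      sep = "")
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path TSV file path.
#' @param column_map Named list mapping internal names (`rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `n_cases`, `chrom`, `pos`) to column names in the file. Only entries
#'   differing from the defaults need to be supplied.
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary_dataset <- function(path, trait_name, trait_type = "continuous",
                                 unit_label = "", case_fraction = NULL,
                                 column_map = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- list(rsid = "rsid", effect_allele = "effect_allele",
                   other_allele = "other_allele", eaf = "eaf", beta = "beta",
                   se = "se", pvalue = "pval", n = "n", n_cases = "ncase",
                   chrom = "chrom", pos = "pos")
  map <- utils::modifyList(defaults, column_map)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se",
                "pvalue", "n")
  for (field in required) {
    if (!map[[field]] %in% names(raw)) {
      stop("configured column '", map[[field]], "' (", field,
           ") not present in ", path, call. = FALSE)
    }
  }
  snps <- data.frame(rsid = raw[[map$rsid]],
                     effect_allele = raw[[map$effect_allele]],
                     other_allele = raw[[map$other_allele]],
                     beta = raw[[map$beta]], se = raw[[map$se]],
                     pvalue = raw[[map$pvalue]], n = raw[[map$n]],
                     stringsAsFactors = FALSE)
  for (opt in c("eaf", "n_cases", "chrom", "pos")) {
    if (map[[opt]] %in% names(raw)) snps[[opt]] <- raw[[map[[opt]]]]
  }
  ds <- summary_dataset(snps, trait_name = trait_name, trait_type = trait_type,
                        unit_label = unit_label, case_fraction = case_fraction)
  if (nrow(ds$snps) == 0) {
    stop("no valid rows in ", path, " after validation", call. = FALSE)
  }
  ds
}

#' Read a square LD correlation matrix keyed by rsid
#'
#' Expects a tab-separated file whose header row and first column both carry
#' SNP identifiers.
#'
#' @param path TSV file path.
#' @return Numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- read.delim(path, row.names = 1, check.names = FALSE)
  ld <- as.matrix(raw)
  validate_ld(ld)
  ld
}

validate_ld <- function(ld) {
  if (nrow(ld) != ncol(ld)) stop("LD matrix is not square", call. = FALSE)
  if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(ld) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(abs(ld) > 1 + 1e-8)) stop("LD entries must lie in [-1, 1]", call. = FALSE)
  invisible(ld)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  single <- a %in% names(DNA_COMPLEMENT)
  out <- a
  out[single] <- DNA_COMPLEMENT[a[single]]
  out
}

is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 &
    ea %in% names(DNA_COMPLEMENT) & complement_allele(ea) == oa
}

#' Harmonize exposure and outcome summary statistics to shared alleles
#'
#' Restricts all datasets to their shared SNPs and aligns every effect to the
#' first exposure's effect allele. Swapped alleles flip the sign of beta and
#' replace eaf by 1 - eaf; strand (complement) flips are resolved through the
#' complementary alleles for non-palindromic SNPs. Palindromic SNPs (A/T,
#' C/G) cannot be strand-resolved from allele labels: with either
#' effect-allele frequency inside `0.5 +/- eaf_window` (or missing on either
#' side) they are dropped as `"palindromic-ambiguous"`; outside the window
#' `"drop_ambiguous"` keeps the label orientation but treats a frequency
#' disagreement as a strand flip, while `"infer_by_eaf"` orients purely by
#' frequency.
#'
#' @param exposures A `summary_dataset` or list of them (K exposures).
#' @param outcome A `summary_dataset`.
#' @param palindrome_policy `"drop_ambiguous"` (default) or `"infer_by_eaf"`.
#' @param eaf_window Half-width of the frequency ambiguity window around 0.5.
#' @param ld Optional LD correlation matrix with rsid dimnames; subset to the
#'   harmonized SNPs.
#' @return An object of class `harmonized_set`: list with `rsids`,
#'   `exposure_names`, `bx`/`sx` (k x K matrices), `by`/`sy` vectors,
#'   per-side sample sizes and frequencies, optional `ld`, and `dropped`
#'   (data.frame of rsid/reason).
#' @export
harmonize <- function(exposures, outcome,
                      palindrome_policy = c("drop_ambiguous", "infer_by_eaf"),
                      eaf_window = 0.08, ld = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "summary_dataset"))

  all_sets <- c(exposures, list(outcome))
  shared <- Reduce(intersect, lapply(all_sets, function(d) d$snps$rsid))
  if (length(shared) == 0) {
    stop("no shared rsids across exposure and outcome datasets", call. = FALSE)
  }
  shared <- sort(shared)

  ref <- exposures[[1]]$snps
  ref <- ref[match(shared, ref$rsid), , drop = FALSE]
  dropped <- character(length(shared))

  # Align one dataset's rows (already subset to `shared`) to the reference
  # orientation; returns the aligned rows plus per-SNP failure reasons.
  align <- function(rows) {
    reason <- rep(NA_character_, nrow(rows))
    ea <- rows$effect_allele; oa <- rows$other_allele
    pal <- is_palindromic(ref$effect_allele, ref$other_allele)

    same <- ea == ref$effect_allele & oa == ref$other_allele
    swap <- ea == ref$other_allele & oa == ref$effect_allele
    cea <- complement_allele(ea); coa <- complement_allele(oa)
    strand_same <- !same & !swap & cea == ref$effect_allele & coa == ref$other_allele
    strand_swap <- !same & !swap & cea == ref$other_allele & coa == ref$effect_allele
    mismatch <- !(same | swap | strand_same | strand_swap)
    reason[mismatch] <- "allele mismatch"

    flip <- swap | strand_swap

    # Palindromes: labels carry no strand information.
    if (any(pal)) {
      eaf_na <- is.na(rows$eaf) | is.na(ref$eaf)
      ambiguous <- pal & (eaf_na |
        abs(rows$eaf - 0.5) <= eaf_window | abs(ref$eaf - 0.5) <= eaf_window)
      reason[ambiguous & is.na(reason)] <- "palindromic-ambiguous"
      informative <- pal & !ambiguous & is.na(reason)
      if (palindrome_policy == "infer_by_eaf") {
        flip[informative] <- (rows$eaf[informative] - 0.5) *
          (ref$eaf[informative] - 0.5) < 0
      } else {
        # keep label orientation, but a frequency disagreement after label
        # alignment signals an unlabelled strand flip
        eaf_aligned <- ifelse(flip[informative], 1 - rows$eaf[informative],
                              rows$eaf[informative])
        disagree <- (eaf_aligned - 0.5) * (ref$eaf[informative] - 0.5) < 0
        flip[informative] <- xor(flip[informative], disagree)
      }
    }

    rows$beta <- ifelse(flip, -rows$beta, rows$beta)
    rows$eaf <- ifelse(flip, 1 - rows$eaf, rows$eaf)
    rows$effect_allele <- ref$effect_allele
    rows$other_allele <- ref$other_allele
    list(rows = rows, reason = reason)
  }

  aligned <- vector("list", length(all_sets))
  reasons <- rep(NA_character_, length(shared))
  for (i in seq_along(all_sets)) {
    rows <- all_sets[[i]]$snps
    rows <- rows[match(shared, rows$rsid), , drop = FALSE]
    if (i == 1) {
      aligned[[i]] <- rows
    } else {
      res <- align(rows)
      aligned[[i]] <- res$rows
      reasons[is.na(reasons) & !is.na(res$reason)] <-
        res$reason[is.na(reasons) & !is.na(res$reason)]
    }
  }

  keep <- is.na(reasons)
  dropped <- data.frame(rsid = shared[!keep], reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  rsids <- shared[keep]
  K <- length(exposures)
  exposure_names <- vapply(exposures, function(d) d$trait_name, character(1))

  bx <- sapply(seq_len(K), function(k) aligned[[k]]$beta[keep])
  sx <- sapply(seq_len(K), function(k) aligned[[k]]$se[keep])
  nx <- sapply(seq_len(K), function(k) aligned[[k]]$n[keep])
  eaf_x <- sapply(seq_len(K), function(k) aligned[[k]]$eaf[keep])
  bx <- matrix(bx, ncol = K); sx <- matrix(sx, ncol = K)
  nx <- matrix(nx, ncol = K); eaf_x <- matrix(eaf_x, ncol = K)
  colnames(bx) <- colnames(sx) <- colnames(nx) <- colnames(eaf_x) <- exposure_names

  out_rows <- aligned[[K + 1L]]
  ld_sub <- NULL
  if (!is.null(ld)) {
    validate_ld(ld)
    missing_ld <- setdiff(rsids, rownames(ld))
    if (length(missing_ld) > 0) {
      stop("LD matrix does not cover rsids: ",
           paste(head(missing_ld, 5L), collapse = ", "), call. = FALSE)
    }
    ld_sub <- ld[rsids, rsids, drop = FALSE]
  }

  structure(list(
    rsids = rsids,
    exposure_names = exposure_names,
    exposure_types = vapply(exposures, function(d) d$trait_type, character(1)),
    outcome_name = outcome$trait_name,
    outcome_type = outcome$trait_type,
    effect_allele = ref$effect_allele[keep],
    other_allele = ref$other_allele[keep],
    bx = bx, sx = sx, nx = nx, eaf_x = eaf_x,
    by = out_rows$beta[keep], sy = out_rows$se[keep],
    ny = out_rows$n[keep], eaf_y = out_rows$eaf[keep],
    ncase_y = out_rows$n_cases[keep],
    case_fraction_y = outcome$case_fraction,
    ld = ld_sub,
    dropped = dropped
  ), class = "harmonized_set")
}

#' Construct a harmonized set directly from effect vectors
#'
#' Convenience constructor for simulated or already-aligned data, bypassing
#' allele harmonization. `bx`/`sx` may be vectors (one exposure) or k x K
#' matrices.
#'
#' @param bx,sx SNP-exposure effects and SEs.
#' @param by,sy SNP-outcome effects and SEs.
#' @param rsids SNP identifiers (generated if omitted).
#' @param exposure_names Exposure labels.
#' @param nx,ny Sample sizes (scalar or per-SNP).
#' @param ncase_y Outcome case counts (binary outcomes).
#' @param eaf Effect-allele frequencies (used on both sides).
#' @param exposure_types,outcome_type Trait types.
#' @param ld Optional correlation matrix.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(bx, sx, by, sy, rsids = NULL,
                           exposure_names = NULL, nx = NA_real_,
                           ny = NA_real_, ncase_y = NULL, eaf = NA_real_,
                           exposure_types = NULL, outcome_type = "binary",
                           ld = NULL) {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  k <- nrow(bx); K <- ncol(bx)
  stopifnot(length(by) == k, length(sy) == k, all(dim(sx) == dim(bx)))
  if (is.null(rsids)) rsids <- sprintf("rs%06d", seq_len(k))
  if (is.null(exposure_names)) exposure_names <- paste0("X", seq_len(K))
  if (is.null(exposure_types)) exposure_types <- rep("continuous", K)
  colnames(bx) <- colnames(sx) <- exposure_names
  nx <- matrix(rep(nx, length.out = k * K), k, K,
               dimnames = list(NULL, exposure_names))
  eaf_x <- matrix(rep(eaf, length.out = k * K), k, K,
                  dimnames = list(NULL, exposure_names))
  if (!is.null(ld)) {
    validate_ld(ld)
    if (is.null(rownames(ld))) dimnames(ld) <- list(rsids, rsids)
  }
  structure(list(
    rsids = rsids, exposure_names = exposure_names,
    exposure_types = exposure_types, outcome_name = "outcome",
    outcome_type = outcome_type,
    effect_allele = rep("A", k), other_allele = rep("G", k),
    bx = bx, sx = sx, nx = nx, eaf_x = eaf_x,
    by = by, sy = sy, ny = rep(ny, length.out = k),
    eaf_y = rep(eaf, length.out = k),
    ncase_y = if (is.null(ncase_y)) rep(NA_real_, k)
              else rep(ncase_y, length.out = k),
    case_fraction_y = NULL, ld = ld,
    dropped = data.frame(rsid = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", paste(x$exposure_names, collapse = " + "),
      " -> ", x$outcome_name, "\n", sep = "")
  cat("  SNPs: ", length(x$rsids), "  dropped: ", nrow(x$dropped),
      if (!is.null(x$ld)) "  (LD matrix attached)" else "", "\n", sep = "")
  invisible(x)
}

#' Number of SNPs in a harmonized set
#' @param h A `harmonized_set`.
#' @export
n_snps <- function(h) length(h$rsids)

#' Subset a harmonized set to selected SNPs
#'
#' @param h A `harmonized_set`.
#' @param keep Logical or integer index over the current SNPs.
#' @return A `harmonized_set` restricted to the kept SNPs (the drop log is
#'   carried over unchanged).
#' @export
subset_harmonized <- function(h, keep) {
  idx <- seq_along(h$rsids)[keep]
  h$rsids <- h$rsids[idx]
  h$effect_allele <- h$effect_allele[idx]
  h$other_allele <- h$other_allele[idx]
  h$bx <- h$bx[idx, , drop = FALSE]
  h$sx <- h$sx[idx, , drop = FALSE]
  h$nx <- h$nx[idx, , drop = FALSE]
  h$eaf_x <- h$eaf_x[idx, , drop = FALSE]
  h$by <- h$by[idx]; h$sy <- h$sy[idx]; h$ny <- h$ny[idx]
  h$eaf_y <- h$eaf_y[idx]; h$ncase_y <- h$ncase_y[idx]
  if (!is.null(h$ld)) h$ld <- h$ld[idx, idx, drop = FALSE]
  h
}

#' Write a harmonized set (and its drop log) to tab-separated files
#'
#' @param h A `harmonized_set`.
#' @param path Output TSV path; the drop log goes to `<path>.dropped.tsv`.
#' @return Invisibly, the main data.frame written.
#' @export
write_harmonized <- function(h, path) {
  df <- data.frame(rsid = h$rsids, effect_allele = h$effect_allele,
                   other_allele = h$other_allele, stringsAsFactors = FALSE)
  for (k in seq_along(h$exposure_names)) {
    nm <- gsub("[^A-Za-z0-9]+", "_", h$exposure_names[k])
    df[[paste0("beta_", nm)]] <- h$bx[, k]
    df[[paste0("se_", nm)]] <- h$sx[, k]
  }
  df$beta_outcome <- h$by
  df$se_outcome <- h$sy
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(h$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(df)
}
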