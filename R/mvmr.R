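#' Multivariable MR by weighted zero-intercept regression
#'
#' Regresses SNP-outcome effects on the K SNP-exposure effect columns with
#' weights `1/sy^2` and no intercept, yielding direct effects of each
#' exposure conditional on the others. Standard errors carry a
#' multiplicative inflation `phi = max(1, sqrt(Q/(k - K)))`, reducing to
#' classical weighted least squares under homogeneity.
#'
#' @param h A `harmonized_set` with K >= 2 exposures (typically the union of
#'   the per-exposure instruments) and at least K + 2 SNPs.
#' @return An object of class `mvmr_result`: `exposure_names`,
#'   `direct_betas`, `ses`, `pvalues`, `conditional_f`, `n_snps`, `q`,
#'   `phi`. Exposures whose SNP-effect column is identically zero are
#'   excluded from the regression and reported as `NA`.
#' @export
mvmr_ivw <- function(h) {
  K <- ncol(h$bx)
  k <- n_snps(h)
  if (K < 2) stop("mvmr_ivw needs >= 2 exposures; use mr_ivw()", call. = FALSE)
  if (k < K + 2) stop("mvmr_ivw needs at least K + 2 SNPs", call. = FALSE)
  x <- h$bx
  w <- 1 / h$sy^2
  # exposures with identically zero SNP effects carry no information and
  # would make the design singular: excluded with NA coefficients
  active <- colSums(abs(x)) > 0
  xa <- x[, active, drop = FALSE]
  check_collinearity(xa, h$exposure_names[active])
  xtwx <- crossprod(xa, xa * w)
  xtwy <- crossprod(xa, h$by * w)
  beta_a <- drop(solve(xtwx, xtwy))
  resid <- h$by - drop(xa %*% beta_a)
  q <- sum(w * resid^2)
  phi <- max(1, sqrt(q / (k - sum(active))))
  se_a <- sqrt(diag(solve(xtwx))) * phi
  betas <- ses <- rep(NA_real_, K)
  betas[active] <- beta_a
  ses[active] <- se_a
  pvals <- 2 * pnorm(-abs(betas / ses))
  structure(list(exposure_names = h$exposure_names,
                 direct_betas = setNames(betas, h$exposure_names),
                 ses = setNames(ses, h$exposure_names),
                 pvalues = setNames(pvals, h$exposure_names),
                 conditional_f = conditional_f_statistics(h),
                 n_snps = k, q = q, phi = phi),
            class = "mvmr_result")
}

check_collinearity <- function(x, names, tol = 1e-10) {
  xs <- scale(x, center = FALSE)
  qrx <- qr(xs)
  if (qrx$rank < ncol(x)) {
    cc <- stats::cor(x)
    pairs <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    desc <- if (nrow(pairs) > 0) {
      paste(apply(pairs, 1, function(ij) {
        paste0(names[ij[1]], " ~ ", names[ij[2]])
      }), collapse = ", ")
    } else "rank-deficient design"
    stop("exposure SNP-effect matrix is (near) collinear: ", desc,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("<mvmr_result> ", x$n_snps, " SNPs, ", length(x$direct_betas),
      " exposures\n", sep = "")
  df <- data.frame(beta = x$direct_betas, se = x$ses, p = x$pvalues,
                   cond_F = x$conditional_f)
  print(signif(df, 4))
  invisible(x)
}

#' Conditional instrument-strength F-statistics
#'
#' For each exposure j, the SNP-effect column is regressed (weights
#' `1/sx_j^2`, no intercept) on the remaining exposures' columns; the
#' weighted residual sum of squares Q_j scaled by `1/(k - K)` is the
#' conditional F. Values below 10 conventionally signal weak conditional
#' instruments. With K = 1 this reduces to the mean per-SNP F within the
#' accuracy of the t-statistic approximation.
#'
#' @param h A `harmonized_set` with K >= 1 exposures and more SNPs than
#'   exposures.
#' @return Named numeric vector of conditional F-statistics.
#' @export
conditional_f_statistics <- function(h) {
  K <- ncol(h$bx)
  k <- n_snps(h)
  if (k <= K) stop("need more SNPs than exposures", call. = FALSE)
  f <- numeric(K)
  for (j in seq_len(K)) {
    w <- 1 / h$sx[, j]^2
    yj <- h$bx[, j]
    xo <- h$bx[, -j, drop = FALSE]
    xo <- xo[, colSums(abs(xo)) > 0, drop = FALSE]
    if (ncol(xo) == 0) {
      resid <- yj
    } else {
      fit <- solve(crossprod(xo, xo * w), crossprod(xo, yj * w))
      resid <- yj - drop(xo %*% fit)
    }
    f[j] <- sum(w * resid^2) / (k - K)
  }
  setNames(f, h$exposure_names)
}
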