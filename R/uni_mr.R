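new_mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL,
                            heterogeneity_q = NULL, heterogeneity_df = NULL,
                            heterogeneity_p = NULL, egger_intercept = NULL,
                            egger_intercept_se = NULL,
                            egger_intercept_p = NULL, phi = NULL) {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 pvalue = pvalue, n_snps = n_snps,
                 heterogeneity_q = heterogeneity_q,
                 heterogeneity_df = heterogeneity_df,
                 heterogeneity_p = heterogeneity_p,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_p = egger_intercept_p,
                 phi = phi),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate> ", x$method, " (", x$n_snps, " SNPs)\n", sep = "")
  cat(sprintf("  beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
              x$pvalue))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             or = exp(x$beta), or_ci_low = exp(x$ci_low),
             or_ci_high = exp(x$ci_high), pvalue = x$pvalue,
             q = if (is.null(x$heterogeneity_q)) NA_real_ else x$heterogeneity_q,
             q_pvalue = if (is.null(x$heterogeneity_p)) NA_real_ else x$heterogeneity_p,
             egger_intercept = if (is.null(x$egger_intercept)) NA_real_ else x$egger_intercept,
             egger_intercept_p = if (is.null(x$egger_intercept_p)) NA_real_ else x$egger_intercept_p,
             stringsAsFactors = FALSE)
}

ratio_estimates <- function(h) {
  stopifnot(ncol(h$bx) == 1)
  list(ratio = h$by / h$bx[, 1], se1 = h$sy / abs(h$bx[, 1]))
}

#' Wald ratio causal estimate for a single SNP
#'
#' `beta = by/bx` with a first-order delta-method standard error `sy/|bx|`
#' or the second-order form `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)` that also
#' propagates uncertainty in the SNP-exposure association.
#'
#' @param bx,sx SNP-exposure effect and SE.
#' @param by,sy SNP-outcome effect and SE.
#' @param se_order `"first"` or `"second"`.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(bx, sx, by, sy, se_order = c("second", "first")) {
  se_order <- match.arg(se_order)
  if (bx == 0) stop("Wald ratio undefined: SNP-exposure effect is zero",
                    call. = FALSE)
  beta <- by / bx
  se <- if (se_order == "first") {
    sy / abs(bx)
  } else {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  new_mr_estimate("wald", beta, se, n_snps = 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted zero-intercept regression of SNP-outcome on SNP-exposure effects
#' with weights `1/sy^2`. Under the multiplicative random-effects model
#' (default, the conventional choice for trait screens) the standard error
#' is inflated by `phi = max(1, sqrt(Q/(k-1)))` so that it reduces to the
#' fixed-effects SE under homogeneity.
#'
#' @param h A `harmonized_set` with a single exposure and >= 2 SNPs.
#' @param effects_model `"multiplicative_random"` or `"fixed"`.
#' @return An `mr_estimate` carrying Cochran's Q and the inflation factor.
#' @examples
#' h <- harmonized_set(bx = c(0.1, 0.2, 0.3), sx = rep(0.01, 3),
#'                     by = c(0.05, 0.12, 0.14), sy = rep(0.01, 3))
#' mr_ivw(h)
#' @export
mr_ivw <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  stopifnot(ncol(h$bx) == 1)
  k <- n_snps(h)
  if (k < 2) {
    stop("IVW requires >= 2 SNPs; use wald_ratio() for single-SNP instruments",
         call. = FALSE)
  }
  bx <- h$bx[, 1]; by <- h$by; w <- 1 / h$sy^2
  swx2 <- sum(w * bx^2)
  beta <- sum(w * bx * by) / swx2
  se_fixed <- sqrt(1 / swx2)
  q <- sum(w * (by - beta * bx)^2)
  phi <- 1
  se <- se_fixed
  if (effects_model == "multiplicative_random") {
    phi <- max(1, sqrt(q / (k - 1)))
    se <- se_fixed * phi
  }
  new_mr_estimate(paste0("ivw_", sub("multiplicative_", "", effects_model)),
                  beta, se, n_snps = k, heterogeneity_q = q,
                  heterogeneity_df = k - 1L,
                  heterogeneity_p = pchisq(q, k - 1, lower.tail = FALSE),
                  phi = phi)
}

#' Correlation-adjusted IVW (generalized least squares)
#'
#' For instruments containing SNPs in linkage disequilibrium, estimation
#' uses GLS with outcome-error covariance `Omega_ij = sy_i sy_j rho_ij`.
#' With `with_intercept = TRUE` an intercept column is added, giving the
#' correlated MR-Egger variant. With an identity LD matrix this reproduces
#' fixed-effects IVW exactly.
#'
#' @param h A `harmonized_set` with its `ld` matrix present.
#' @param with_intercept Add an intercept (correlated Egger)?
#' @param ridge Diagonal ridge (times mean diagonal) applied before
#'   inversion to tolerate near-singular LD.
#' @return An `mr_estimate`.
#' @export
mr_ivw_correlated <- function(h, with_intercept = FALSE, ridge = 1e-6) {
  stopifnot(ncol(h$bx) == 1)
  if (is.null(h$ld)) stop("harmonized set has no LD matrix", call. = FALSE)
  k <- n_snps(h)
  bx <- h$bx[, 1]; by <- h$by; sy <- h$sy
  omega <- outer(sy, sy) * h$ld
  diag(omega) <- diag(omega) + ridge * mean(diag(omega))
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    stop("SNP-correlation covariance is singular after ridge; condition number ",
         format(kappa(omega), digits = 3), call. = FALSE)
  }
  x <- if (with_intercept) cbind(intercept = 1, bx = bx) else cbind(bx = bx)
  oi_x <- backsolve(ch, forwardsolve(t(ch), x))
  oi_y <- backsolve(ch, forwardsolve(t(ch), by))
  xtox <- crossprod(x, oi_x)
  cov_beta <- unname(solve(xtox))
  est <- unname(drop(cov_beta %*% crossprod(x, oi_y)))
  if (with_intercept) {
    new_mr_estimate("egger_correlated", est[2], sqrt(cov_beta[2, 2]),
                    n_snps = k, egger_intercept = est[1],
                    egger_intercept_se = sqrt(cov_beta[1, 1]),
                    egger_intercept_p = 2 * pnorm(-abs(est[1] / sqrt(cov_beta[1, 1]))))
  } else {
    new_mr_estimate("ivw_correlated", est[1], sqrt(cov_beta[1, 1]),
                    n_snps = k)
  }
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with an
#' unconstrained intercept, after orienting every SNP so its exposure effect
#' is positive. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Standard errors carry a multiplicative inflation `max(1, sqrt(Q/(k-2)))`.
#'
#' @param h A `harmonized_set` with >= 3 SNPs.
#' @return An `mr_estimate` with intercept fields populated.
#' @export
mr_egger <- function(h) {
  stopifnot(ncol(h$bx) == 1)
  k <- n_snps(h)
  if (k < 3) stop("MR-Egger requires >= 3 SNPs", call. = FALSE)
  s <- ifelse(h$bx[, 1] < 0, -1, 1)
  bx <- h$bx[, 1] * s; by <- h$by * s
  w <- 1 / h$sy^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  q <- sum(w * (by - intercept - slope * bx)^2)
  phi <- max(1, sqrt(q / (k - 2)))
  se_slope <- sqrt(sw / det) * phi
  se_int <- sqrt(swxx / det) * phi
  new_mr_estimate("egger", slope, se_slope, n_snps = k,
                  heterogeneity_q = q, heterogeneity_df = k - 2L,
                  heterogeneity_p = pchisq(q, k - 2, lower.tail = FALSE),
                  egger_intercept = intercept, egger_intercept_se = se_int,
                  egger_intercept_p = 2 * pnorm(-abs(intercept / se_int)),
                  phi = phi)
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord] / sum(weight)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(h, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- n_snps(h)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, h$bx[, 1], h$sx[, 1])
    by <- rnorm(k, h$by, h$sy)
    point_fun(bx, by)
  }, numeric(1))
  sd(est)
}

#' Weighted median causal estimate
#'
#' The causal estimate is the weighted median of the per-SNP ratio
#' estimates (weights proportional to inverse ratio variance), consistent
#' when at least half the weight comes from valid instruments. The standard
#' error is a parametric bootstrap: SNP-exposure and SNP-outcome effects are
#' redrawn from their sampling distributions and the point estimate
#' recomputed.
#'
#' @param h A `harmonized_set` with >= 3 SNPs.
#' @param n_boot Bootstrap draws for the SE (0 skips the bootstrap).
#' @param seed Optional seed making the bootstrap reproducible.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  stopifnot(ncol(h$bx) == 1)
  if (n_snps(h) < 3) stop("weighted median requires >= 3 SNPs", call. = FALSE)
  re <- ratio_estimates(h)
  weight <- 1 / re$se1^2
  beta <- weighted_median_point(re$ratio, weight)
  se <- boot_se(h, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / h$sy^2)
  }, n_boot, seed)
  new_mr_estimate("weighted_median", beta, se, n_snps = n_snps(h))
}

weighted_mode_point <- function(ratio, weight, bandwidth_factor = 1,
                                n_grid = 512L) {
  spread <- min(sd(ratio), mad(ratio))
  bw <- bandwidth_factor * 0.9 * spread * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  w <- weight / sum(weight)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode causal estimate
#'
#' Consistent when the largest group of SNPs sharing the same ratio
#' estimate is valid (plurality validity). The estimate is the argmax of a
#' weighted Gaussian kernel density over ratio estimates, with the modified
#' Silverman bandwidth `0.9 min(SD, MAD/0.6745) k^(-1/5)` scaled by
#' `bandwidth_factor`, evaluated on a regular grid spanning the ratios plus
#' three bandwidths. SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param n_grid Number of grid points for the density argmax.
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL, n_grid = 512L) {
  stopifnot(ncol(h$bx) == 1)
  if (n_snps(h) < 3) stop("weighted mode requires >= 3 SNPs", call. = FALSE)
  re <- ratio_estimates(h)
  weight <- 1 / re$se1^2
  beta <- weighted_mode_point(re$ratio, weight, bandwidth_factor, n_grid)
  se <- boot_se(h, function(bx, by) {
    weighted_mode_point(by / bx, bx^2 / h$sy^2, bandwidth_factor, n_grid)
  }, n_boot, seed)
  new_mr_estimate("weighted_mode", beta, se, n_snps = n_snps(h))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum (by_i - beta bx_i)^2 / sy_i^2` against a fixed causal slope,
#' with k - 1 degrees of freedom.
#'
#' @param h A `harmonized_set` (single exposure, >= 2 SNPs).
#' @param beta Causal slope to test against (defaults to the IVW estimate).
#' @return List with `q`, `df` and `p`.
#' @export
cochran_q <- function(h, beta = NULL) {
  stopifnot(ncol(h$bx) == 1, n_snps(h) >= 2)
  if (is.null(beta)) beta <- mr_ivw(h, "fixed")$beta
  q <- sum((h$by - beta * h$bx[, 1])^2 / h$sy^2)
  df <- n_snps(h) - 1L
  list(q = q, df = df, p = pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect with each SNP removed in turn and flags drops
#' whose estimate changes sign relative to the full-instrument estimate.
#'
#' @param h A `harmonized_set` with >= 3 SNPs.
#' @param effects_model Passed to [mr_ivw()].
#' @return data.frame with one row per dropped SNP: `rsid`, `beta`, `se`,
#'   `pvalue`, `sign_flip`.
#' @export
leave_one_out <- function(h, effects_model = "multiplicative_random") {
  k <- n_snps(h)
  if (k < 3) stop("leave-one-out requires >= 3 SNPs", call. = FALSE)
  full <- mr_ivw(h, effects_model)
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(subset_harmonized(h, -i), effects_model)
    data.frame(rsid = h$rsids[i], beta = est$beta, se = est$se,
               pvalue = est$pvalue,
               sign_flip = sign(est$beta) != sign(full$beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_beta") <- full$beta
  out
}

#' Classify MR evidence under a Bonferroni heuristic
#'
#' "Strong" evidence below `0.05/n_traits`, "suggestive" between that
#' threshold and 0.05, "little" otherwise.
#'
#' @param p Two-sided p-value.
#' @param n_traits Number of traits tested.
#' @return List with `label`, `threshold_strong`, `threshold_suggestive`.
#' @export
classify_evidence <- function(p, n_traits) {
  stopifnot(n_traits >= 1)
  threshold_strong <- 0.05 / n_traits
  label <- if (p < threshold_strong) "strong"
    else if (p < 0.05) "suggestive" else "little"
  list(label = label, threshold_strong = threshold_strong,
       threshold_suggestive = 0.05)
}

#' Post-hoc power for MR with a binary outcome
#'
#' Asymptotic approximation
#' `power = Phi(|ln OR| sqrt(n r2 cf (1 - cf)) - z_{1-alpha/2})`, where `n`
#' is the outcome GWAS sample size, `r2` the variance in the exposure
#' explained by the instrument and `cf` the case fraction.
#'
#' @param n_outcome Outcome sample size.
#' @param case_fraction Case fraction in (0, 1).
#' @param r2 Instrument variance explained in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio per exposure unit.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, case_fraction, r2, or_alt, alpha = 0.05) {
  stopifnot(case_fraction > 0, case_fraction < 1, r2 > 0, r2 < 1)
  ncp <- abs(log(or_alt)) *
    sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  pnorm(ncp - qnorm(1 - alpha / 2))
}
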