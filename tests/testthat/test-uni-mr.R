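test_that("Wald ratio and its delta-method standard errors", {
  w <- wald_ratio(1, 0.1, 0.5, 0.1, se_order = "first")
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$ci_low, 0.5 - 1.96 * 0.1)
  # second order closed form
  w2 <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(w2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  # null outcome effect
  w0 <- wald_ratio(0.5, 0.01, 0, 0.1)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)
  expect_error(wald_ratio(0, 0.1, 0.5, 0.1), "zero")
})

test_that("second-order Wald SE matches a Monte-Carlo oracle in its regime", {
  # 5% denominator CV: first-order delta theory applies
  set.seed(101)
  n <- 1e6
  emp <- sd(rnorm(n, 0.05, 0.01) / rnorm(n, 0.1, 0.005))
  expect_equal(wald_ratio(0.1, 0.005, 0.05, 0.01)$se, emp, tolerance = 0.02)
})

test_that("IVW equals closed-form weighted least squares", {
  # homogeneous 2-SNP case: exact ratio, Q = 0, phi = 1
  h0 <- toy_h(bx = c(0.1, 0.2), by = c(0.05, 0.1))
  est0 <- mr_ivw(h0)
  expect_equal(est0$beta, 0.5)
  expect_equal(est0$heterogeneity_q, 0, tolerance = 1e-20)
  expect_equal(est0$phi, 1)

  # 3-SNP toy against an independent lm() oracle
  h <- toy_h(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.12, 0.14), sy = 0.01)
  fit <- lm(h$by ~ 0 + h$bx[, 1], weights = 1 / h$sy^2)
  est <- mr_ivw(h, "fixed")
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  # fixed-effects SE: lm's SE divided by its residual scale
  se_fixed <- unname(summary(fit)$coefficients[1, 2] / summary(fit)$sigma)
  expect_equal(est$se, se_fixed, tolerance = 1e-12)

  # 2-SNP IVW with equal outcome SEs = inverse-variance mean of Wald ratios
  hr <- toy_h(bx = c(0.1, 0.25), by = c(0.07, 0.1))
  r <- hr$by / hr$bx[, 1]
  wts <- hr$bx[, 1]^2 / hr$sy^2
  expect_equal(mr_ivw(hr, "fixed")$beta, sum(wts * r) / sum(wts))

  expect_error(mr_ivw(subset_harmonized(h, 1)), "wald_ratio")
})

test_that("random-effects inflation never shrinks the fixed-effects SE", {
  set.seed(3)
  for (i in 1:10) {
    h <- toy_h(bx = runif(8, 0.05, 0.3), by = rnorm(8, 0.05, 0.05))
    expect_gte(mr_ivw(h)$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("correlation-adjusted IVW reduces and generalizes correctly", {
  h <- toy_h(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.12, 0.14),
             ld = diag(3))
  a <- mr_ivw_correlated(h)
  b <- mr_ivw(h, "fixed")
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
  expect_equal(a$se, b$se, tolerance = 1e-4)

  # duplicated SNP at rho = 1 collapses to the single-SNP Wald ratio
  ld_dup <- matrix(c(1, 1, 1, 1), 2)
  hd <- toy_h(bx = c(0.2, 0.2), by = c(0.1, 0.1), ld = ld_dup)
  est_dup <- mr_ivw_correlated(hd)
  expect_equal(est_dup$beta, 0.5, tolerance = 1e-6)

  # 2-SNP GLS against the explicit 2x2 solution
  rho <- 0.5
  ld2 <- matrix(c(1, rho, rho, 1), 2)
  h2 <- toy_h(bx = c(0.1, 0.3), by = c(0.04, 0.18), sy = c(0.01, 0.02),
              ld = ld2)
  omega <- outer(h2$sy, h2$sy) * ld2
  oi <- solve(omega)
  x <- h2$bx[, 1]
  beta_hand <- drop((t(x) %*% oi %*% h2$by) / (t(x) %*% oi %*% x))
  se_hand <- drop(sqrt(1 / (t(x) %*% oi %*% x)))
  est2 <- mr_ivw_correlated(h2, ridge = 0)
  expect_equal(est2$beta, beta_hand, tolerance = 1e-10)
  expect_equal(est2$se, se_hand, tolerance = 1e-10)

  expect_error(mr_ivw_correlated(toy_h(bx = 1:2 / 10, by = 1:2 / 20)),
               "no LD matrix")
})

test_that("MR-Egger separates slope from directional pleiotropy", {
  # collinear through the origin: intercept 0, slope = ratio
  h <- toy_h(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-12)

  # adding a constant to all (oriented) outcome betas moves only the intercept
  set.seed(8)
  bx <- runif(20, 0.05, 0.3)
  by <- 0.4 * bx + rnorm(20, 0, 0.01)
  h1 <- toy_h(bx = bx, by = by)
  h2 <- toy_h(bx = bx, by = by + 0.03)
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$egger_intercept - e1$egger_intercept, 0.03,
               tolerance = 1e-10)
  expect_error(mr_egger(subset_harmonized(h, 1:2)), ">= 3")
})

test_that("weighted median follows the cumulative-weight interpolation", {
  # hand-worked: ratios (1,2,3), weights (1,1,2)/4 -> interpolate to 2.333...
  bx <- c(1, 1, 1)
  by <- c(1, 2, 3)
  sy <- 1 / sqrt(c(1, 1, 2))   # weight = bx^2/sy^2 = (1,1,2)
  h <- harmonized_set(bx = bx, sx = rep(0.01, 3), by = by, sy = sy)
  est <- mr_weighted_median(h, n_boot = 0)
  expect_equal(est$beta, 2 + (0.5 - 0.375) / 0.375, tolerance = 1e-10)

  # identical ratios: the common value regardless of weights
  h2 <- toy_h(bx = c(0.1, 0.2, 0.4), by = 0.4 * c(0.1, 0.2, 0.4),
              sy = c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta, 0.4)

  # breakdown: 10 valid SNPs at ratio 0.5 vs 4 outliers at 5
  h3 <- toy_h(bx = rep(0.2, 14), by = c(rep(0.1, 10), rep(1, 4)))
  est3 <- mr_weighted_median(h3, n_boot = 0)
  expect_gte(est3$beta, 0.45); expect_lte(est3$beta, 0.55)

  # bootstrap SE deterministic under a fixed seed
  se_a <- mr_weighted_median(h3, n_boot = 200, seed = 7)$se
  se_b <- mr_weighted_median(h3, n_boot = 200, seed = 7)$se
  expect_identical(se_a, se_b)
  expect_gt(se_a, 0)
})

test_that("weighted mode finds the majority mode", {
  h <- toy_h(bx = rep(0.2, 5), by = rep(0.08, 5))
  expect_equal(mr_weighted_mode(h, n_boot = 0)$beta, 0.4)

  # bimodal: 12 SNPs at 0.5, 5 at 2.0, equal weights
  h2 <- toy_h(bx = rep(0.2, 17), by = c(rep(0.1, 12), rep(0.4, 5)) +
                rep(c(-0.002, 0.002), length.out = 17))
  est <- mr_weighted_mode(h2, n_boot = 0)
  expect_lt(abs(est$beta - 0.5), 0.15)

  # grid refinement changes the estimate by less than bandwidth/10
  set.seed(19)
  bx <- runif(25, 0.1, 0.3)
  h3 <- toy_h(bx = bx, by = 0.4 * bx + rnorm(25, 0, 0.01))
  est512 <- mr_weighted_mode(h3, n_boot = 0, n_grid = 512L)$beta
  est4096 <- mr_weighted_mode(h3, n_boot = 0, n_grid = 4096L)$beta
  ratios <- h3$by / h3$bx[, 1]
  bw <- 0.9 * min(sd(ratios), mad(ratios)) * length(ratios)^(-1 / 5)
  expect_lt(abs(est512 - est4096), bw / 10)
})

test_that("Cochran's Q calibrates and reacts to outliers", {
  h <- toy_h(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  q <- cochran_q(h)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)

  # homogeneous simulation: E[Q] = k - 1
  set.seed(12)
  k <- 20
  qs <- replicate(500, {
    bx <- runif(k, 0.05, 0.3)
    by <- rnorm(k, 0.3 * bx, 0.01)
    cochran_q(toy_h(bx = bx, by = by))$q
  })
  expect_equal(mean(qs), k - 1, tolerance = 0.08)

  # a gross outlier strictly increases Q
  h_out <- toy_h(bx = c(0.1, 0.2, 0.3, 0.2), by = c(0.05, 0.1, 0.15, 0.5))
  expect_gt(cochran_q(h_out)$q, cochran_q(h)$q)
})

test_that("leave-one-out matches brute-force subset recomputation", {
  set.seed(4)
  bx <- runif(5, 0.1, 0.3)
  by <- 0.5 * bx + rnorm(5, 0, 0.005)
  by[3] <- by[3] + 0.3   # influential outlier
  h <- toy_h(bx = bx, by = by)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 5)
  # brute force with an independent lm oracle per subset
  brute <- sapply(1:5, function(i) {
    unname(coef(lm(by[-i] ~ 0 + bx[-i], weights = rep(1e4, 4))))
  })
  expect_equal(loo$beta, brute, tolerance = 1e-10)
  full <- mr_ivw(h)$beta
  expect_equal(which.max(abs(loo$beta - full)), 3L)

  # homogeneous data: every drop reproduces the full estimate
  h0 <- toy_h(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  expect_equal(leave_one_out(h0)$beta, rep(0.5, 3), tolerance = 1e-12)
})

test_that("evidence classification reproduces the Bonferroni thresholds", {
  cls <- classify_evidence(1e-4, 15)
  expect_equal(cls$threshold_strong, 0.05 / 15)
  expect_equal(signif(cls$threshold_strong, 3), 3.33e-3)
  expect_equal(classify_evidence(1.71e-12, 15)$label, "strong")
  expect_equal(classify_evidence(4.01e-2, 15)$label, "suggestive")
  expect_equal(classify_evidence(0.2, 15)$label, "little")
})

test_that("power approximation behaves at its limits", {
  expect_equal(mr_power(1e5, 0.1, 0.01, or_alt = 1), 0.025)
  expect_gt(mr_power(1e9, 0.1, 0.01, or_alt = 1.5), 0.999)
  expect_error(mr_power(1e5, 0, 0.01, 1.3))
})

test_that("estimators are invariant to joint sign flips of SNP subsets", {
  set.seed(6)
  k <- 15
  bx <- runif(k, 0.05, 0.3)
  by <- 0.4 * bx + rnorm(k, 0, 0.01)
  flip <- c(rep(-1, 7), rep(1, 8))
  h1 <- toy_h(bx = bx, by = by)
  h2 <- toy_h(bx = flip * bx, by = flip * by)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta,
               mr_weighted_median(h1, n_boot = 0)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_mode(h2, n_boot = 0)$beta,
               mr_weighted_mode(h1, n_boot = 0)$beta, tolerance = 1e-12)
})
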