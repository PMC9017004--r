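small_cfg <- function(...) {
  sim_config(n_snps = 20, n_snps_mediator = 10, n_exposure = 3000,
             n_mediator = 3000, n_outcome = 3000, ...)
}

test_that("the simulator is deterministic under a fixed seed", {
  t1 <- simulate_mr_study(small_cfg(seed = 99))
  t2 <- simulate_mr_study(small_cfg(seed = 99))
  expect_identical(t1$datasets$exposure$snps, t2$datasets$exposure$snps)
  expect_identical(t1$datasets$outcome$snps, t2$datasets$outcome$snps)
  t3 <- simulate_mr_study(small_cfg(seed = 100))
  expect_false(identical(t1$datasets$exposure$snps,
                         t3$datasets$exposure$snps))
})

test_that("noiseless single-SNP exposure recovers the coefficient exactly", {
  truth <- simulate_mr_study(sim_config(
    n_snps = 1, n_exposure = 500, n_mediator = 500, n_outcome = 500,
    h2_exposure = 1, conf_exposure = 0, seed = 7))
  expect_equal(truth$datasets$exposure$snps$beta, truth$snps$a,
               tolerance = 1e-10)
  expect_lt(truth$datasets$exposure$snps$se, 1e-8)
})

test_that("emitted standard errors match the analytic GWAS expectation", {
  truth <- simulate_mr_study(sim_config(n_snps = 50, n_exposure = 20000,
                                        n_outcome = 5000, seed = 13))
  snps <- truth$datasets$exposure$snps
  expected <- 1 / sqrt(2 * snps$eaf * (1 - snps$eaf) * snps$n)
  expect_lt(mean(abs(snps$se / expected - 1)), 0.05)
})

test_that("LD blocks reproduce the requested genotype correlation", {
  set.seed(3)
  mafs <- rep(c(0.3, 0.2, 0.4), times = c(4, 4, 4))
  G <- sim_genotypes(8000, mafs,
                     ld_blocks = list(list(size = 4, rho = 0.8),
                                      list(size = 4, rho = 0.3)))
  cc <- cor(G)
  within1 <- cc[1:4, 1:4][upper.tri(diag(4))]
  within2 <- cc[5:8, 5:8][upper.tri(diag(4))]
  between <- cc[1:4, 5:8]
  expect_lt(max(abs(within1 - 0.8)), 0.05)
  expect_lt(max(abs(within2 - 0.3)), 0.05)
  expect_lt(max(abs(between)), 0.05)
  # independent tail keeps requested frequencies
  expect_equal(colMeans(G)[9:12] / 2, mafs[9:12], tolerance = 0.03)
})

test_that("the simulated truth satisfies its construction identities", {
  truth <- simulate_mediation_study(small_cfg(
    true_mediation_proportions = c(M1 = 0.15, M2 = 0.1), seed = 21))
  expect_equal(unname(truth$a_path * truth$b_path / truth$true_total),
               c(0.15, 0.1))
  expect_equal(truth$true_direct + sum(truth$true_indirect),
               truth$true_total)
  # requested proportion 0 disables the exposure -> mediator path
  t0 <- simulate_mediation_study(small_cfg(
    true_mediation_proportions = c(M1 = 0), seed = 22))
  expect_equal(unname(t0$a_path), 0)
  expect_equal(unname(t0$true_indirect), 0)
  expect_error(simulate_mediation_study(small_cfg(seed = 1)),
               "true_mediation_proportions")
  expect_error(sim_config(true_mediation_proportions = c(A = 0.7, B = 0.6)),
               "sum")
})

test_that("case fraction is honoured by the liability intercept solver", {
  truth <- simulate_mr_study(sim_config(n_snps = 20, n_exposure = 3000,
                                        n_outcome = 20000,
                                        case_fraction = 0.1, seed = 31))
  cf <- truth$datasets$outcome$snps$n_cases[1] /
    truth$datasets$outcome$snps$n[1]
  expect_equal(cf, 0.1, tolerance = 0.05)
  expect_equal(truth$datasets$outcome$trait_type, "binary")
})

test_that("winner's-curse selection behaves at its threshold limits", {
  truth <- simulate_mr_study(sim_config(n_snps = 25, n_exposure = 20000,
                                        n_outcome = 3000,
                                        keep_exposure_cohort = TRUE,
                                        seed = 41))
  # selection_pvalue = 1: every SNP selected
  wc_all <- add_winners_curse(truth, discovery_n = 10000,
                              selection_pvalue = 1)
  expect_equal(length(wc_all$instrument$selected), 25)
  expect_equal(wc_all$instrument$arm, "discovery")
  # impossible threshold: empty-instrument error
  expect_error(add_winners_curse(truth, discovery_n = 10000,
                                 selection_pvalue = 1e-300),
               "no SNP passes")
  # without the stored cohort the operation refuses
  t2 <- simulate_mr_study(small_cfg(seed = 42))
  expect_error(add_winners_curse(t2, 1000), "keep_exposure_cohort")
})

test_that("sample overlap pulls weak-instrument estimates toward confounding", {
  est <- function(ov, r) {
    tr <- simulate_mr_study(sim_config(
      n_snps = 30, n_exposure = 6000, n_outcome = 6000, h2_exposure = 0.01,
      true_total_logor = 0, conf_exposure = 0.5, conf_outcome = 0.5,
      overlap_fraction = ov, seed = 9000 + r))
    h <- harmonize(tr$datasets$exposure, tr$datasets$outcome)
    mr_ivw(h, "fixed")$beta
  }
  b0 <- vapply(1:25, function(r) est(0, r), numeric(1))
  b1 <- vapply(1:25, function(r) est(1, r + 500), numeric(1))
  # positive confounding: full overlap shifts the mean estimate upward
  expect_gt(mean(b1), mean(b0))
  expect_gt(mean(b1), 0)
})

test_that("null studies produce uniform IVW p-values through the pipeline", {
  pv <- vapply(1:400, function(r) {
    tr <- simulate_mr_study(sim_config(
      n_snps = 30, n_exposure = 4000, n_outcome = 4000, h2_exposure = 0.05,
      true_total_logor = 0, conf_exposure = 0, conf_outcome = 0,
      seed = 20000 + r))
    h <- harmonize(tr$datasets$exposure, tr$datasets$outcome)
    mr_ivw(h, "fixed")$pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("simulated studies round-trip through the TSV dialect", {
  truth <- simulate_mediation_study(small_cfg(
    true_mediation_proportions = c(M1 = 0.2),
    ld_blocks = list(list(size = 4, rho = 0.5)), seed = 55))
  dir <- tempfile()
  files <- write_sim_study(truth, dir)
  expect_true(all(file.exists(files)))
  back <- read_summary_dataset(file.path(dir, "exposure.tsv"),
                               trait_name = "exposure")
  expect_equal(back$snps$beta, truth$datasets$exposure$snps$beta)
  out <- read_summary_dataset(file.path(dir, "outcome.tsv"),
                              trait_name = "outcome", trait_type = "binary")
  expect_equal(out$snps$n_cases, truth$datasets$outcome$snps$n_cases)
  ld <- read_ld_matrix(file.path(dir, "ld.tsv"))
  expect_equal(ld, truth$ld)
  tr <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(tr$true_proportion_mediated$M1, 0.2)
})
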