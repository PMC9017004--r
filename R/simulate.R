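#' Configuration for the individual-level MR study simulator
#'
#' Defaults emulate the statistical structure of a large adiposity-to-cancer
#' MR study: a polygenic exposure instrumented by ~100 genome-wide
#' significant SNPs explaining ~8% of variance in a 200,000-person GWAS,
#' mediators with their own instruments (~5% variance explained), and a
#' binary outcome GWAS of ~120,000 individuals with a 10% case fraction
#' (matching 12,906 cases / 121,885 total). The causal chain is
#' exposure -> mediators -> outcome on a logistic liability scale, with an
#' optional shared confounder, directional or balanced pleiotropy, LD
#' blocks, reverse-causal SNPs, partial sample overlap between the exposure
#' and outcome GWAS, and winner's-curse discovery selection.
#'
#' The per-mediator path coefficients are solved so that each requested
#' mediation proportion holds exactly on the liability log-odds scale:
#' `a_m = mediator_path`, `b_m = pm_m * total / a_m`, and the direct effect
#' is `total * (1 - sum(pm))`.
#'
#' @param n_snps Exposure-associated SNPs.
#' @param n_snps_mediator Mediator-specific SNPs per mediator.
#' @param maf_range Minor-allele-frequency range (uniform draw).
#' @param n_exposure,n_mediator,n_outcome Per-GWAS cohort sizes.
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param true_total_logor Total causal effect of the exposure on the
#'   outcome, log-odds per exposure SD.
#' @param true_mediation_proportions Named numeric vector of per-mediator
#'   proportions mediated (sum <= 1); names label the mediator traits.
#' @param mediator_path Exposure-to-mediator path coefficient `a_m` used
#'   when the mediation proportion is nonzero.
#' @param h2_exposure,h2_mediator Variance explained by the trait's own
#'   SNPs.
#' @param conf_exposure,conf_outcome Loadings of a shared standard-normal
#'   confounder on the exposure and the outcome liability.
#' @param pleiotropy List with `type` (`"none"`, `"balanced"`,
#'   `"directional"`), `mean` and `sd` of direct SNP-outcome liability
#'   effects added to the exposure SNPs.
#' @param ld_blocks Optional list of `list(size =, rho =)` blocks placed at
#'   the start of the exposure SNP panel (genotype-scale correlation).
#' @param overlap_fraction Fraction of the outcome cohort drawn from the
#'   exposure cohort (sample overlap).
#' @param n_reverse_snps,reverse_effect,reverse_transmission Reverse-causal
#'   SNPs: each affects an outcome-proximal latent factor (per-allele effect
#'   `+/- reverse_effect`) which enters the outcome liability directly and
#'   leaks into the exposure scaled by `reverse_transmission`.
#' @param selection_pvalue Discovery significance threshold recorded for
#'   winner's-curse experiments (used by [add_winners_curse()]).
#' @param keep_exposure_cohort Keep the exposure cohort's genotypes and
#'   phenotype in the returned truth (required by [add_winners_curse()]).
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100, n_snps_mediator = 50,
                       maf_range = c(0.05, 0.5),
                       n_exposure = 200000, n_mediator = 200000,
                       n_outcome = 120000, case_fraction = 0.10,
                       true_total_logor = log(1.88),
                       true_mediation_proportions = numeric(0),
                       mediator_path = 0.3,
                       h2_exposure = 0.08, h2_mediator = 0.05,
                       conf_exposure = 0.3, conf_outcome = 0.3,
                       pleiotropy = list(type = "none", mean = 0, sd = 0),
                       ld_blocks = NULL, overlap_fraction = 0,
                       n_reverse_snps = 0, reverse_effect = 0.15,
                       reverse_transmission = 0.3,
                       selection_pvalue = NULL,
                       keep_exposure_cohort = FALSE, seed = 1) {
  stopifnot(case_fraction > 0, case_fraction < 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            h2_exposure >= 0, h2_exposure <= 1)
  if (length(true_mediation_proportions) > 0) {
    if (is.null(names(true_mediation_proportions))) {
      names(true_mediation_proportions) <-
        paste0("M", seq_along(true_mediation_proportions))
    }
    if (sum(true_mediation_proportions) > 1) {
      stop("mediation proportions must sum to <= 1", call. = FALSE)
    }
  }
  pleiotropy <- utils::modifyList(list(type = "none", mean = 0, sd = 0),
                                  pleiotropy)
  stopifnot(pleiotropy$type %in% c("none", "balanced", "directional"))
  structure(as.list(environment()), class = "sim_config")
}

# Latent-normal correlation producing a target genotype-scale correlation
# for two alleles thresholded at qnorm(maf) (tetrachoric inversion via
# one-dimensional quadrature of the bivariate normal orthant probability).
latent_rho <- function(target_rho, maf) {
  t <- qnorm(maf)
  binary_corr <- function(rho) {
    p11 <- integrate(function(z) {
      pnorm((t - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
    }, -Inf, t)$value
    (p11 - maf^2) / (maf * (1 - maf))
  }
  uniroot(function(rho) binary_corr(rho) - target_rho,
          interval = c(1e-6, 0.9999), tol = 1e-6)$root
}

#' Simulate a genotype dosage matrix
#'
#' Independent SNPs are binomial(2, maf) draws; LD blocks use a Gaussian
#' copula (equicorrelated latent normals thresholded at `qnorm(maf)` per
#' haplotype) with the latent correlation calibrated so the genotype-scale
#' correlation matches the requested `rho`. SNPs inside one block share a
#' single MAF.
#'
#' @param n Individuals.
#' @param mafs Per-SNP minor-allele frequencies.
#' @param ld_blocks Optional list of `list(size =, rho =)` blocks covering
#'   the leading SNPs.
#' @return Integer matrix of 0/1/2 dosages.
#' @export
sim_genotypes <- function(n, mafs, ld_blocks = NULL) {
  p <- length(mafs)
  if (is.null(ld_blocks)) return(sim_genotypes_cpp(n, mafs))
  G <- matrix(0L, n, p)
  at <- 1L
  for (blk in ld_blocks) {
    s <- blk$size
    idx <- at:(at + s - 1L)
    maf <- mafs[at]
    rho_lat <- latent_rho(blk$rho, maf)
    sigma <- matrix(rho_lat, s, s); diag(sigma) <- 1
    ch <- chol(sigma)
    thr <- qnorm(maf)
    hap <- function() {
      z <- matrix(rnorm(n * s), n, s) %*% ch
      (z < thr) * 1L
    }
    G[, idx] <- hap() + hap()
    at <- at + s
  }
  if (at <= p) {
    G[, at:p] <- sim_genotypes_cpp(n, mafs[at:p])
  }
  G
}

# Scale raw effect draws so the panel explains h2 of a unit-variance trait.
scale_to_h2 <- function(raw, mafs, h2) {
  if (h2 == 0 || all(raw == 0)) return(raw * 0)
  v <- sum(2 * mafs * (1 - mafs) * raw^2)
  raw * sqrt(h2 / v)
}

make_dataset <- function(scan, rsids, ea, oa, n, trait_name, trait_type,
                         n_cases = NULL, unit_label = "") {
  # clamp: exact fits give se = 0 and extreme tests give p = 0, both of
  # which would violate the per-SNP (se > 0, p in (0,1]) contract
  scan$se <- pmax(scan$se, 1e-300)
  pv <- pmax(2 * pnorm(-abs(scan$beta / scan$se)), .Machine$double.xmin)
  snps <- data.frame(rsid = rsids, effect_allele = ea, other_allele = oa,
                     eaf = scan$eaf, beta = scan$beta, se = scan$se,
                     pvalue = pv, n = n, stringsAsFactors = FALSE)
  cf <- NULL
  if (trait_type == "binary") {
    snps$n_cases <- n_cases
    cf <- n_cases / n
  }
  summary_dataset(snps, trait_name = trait_name, trait_type = trait_type,
                  unit_label = unit_label, case_fraction = cf)
}

#' Simulate a two-sample MR study with known truth
#'
#' Draws three non- (or partially-) overlapping cohorts — exposure GWAS,
#' mediator GWAS and outcome GWAS — from the structural model described in
#' [sim_config()], and computes per-SNP summary statistics in each by
#' single-SNP regression (linear for continuous traits, one-step logistic
#' score for the binary outcome). Everything is deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: the config, the realized per-SNP
#'   effect vectors, true total/direct/indirect effects and mediation
#'   proportions (liability log-odds scale), the theoretical LD matrix when
#'   LD blocks were requested, and one [summary_dataset()] per trait in
#'   `$datasets` (`exposure`, `mediators` list, `outcome`).
#' @examples
#' truth <- simulate_mr_study(sim_config(n_snps = 20, n_exposure = 2000,
#'                                       n_outcome = 2000, seed = 1))
#' h <- harmonize(truth$datasets$exposure, truth$datasets$outcome)
#' mr_ivw(h)
#' @export
simulate_mr_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  mediators <- names(cfg$true_mediation_proportions)
  n_med <- length(mediators)
  p_exp <- cfg$n_snps
  p_med <- if (n_med > 0) cfg$n_snps_mediator else 0
  p_rev <- cfg$n_reverse_snps
  p_all <- p_exp + n_med * p_med + p_rev
  roles <- c(rep("exposure", p_exp),
             rep(mediators, each = p_med),
             rep("reverse", p_rev))
  rsids <- sprintf("rs%06d", seq_len(p_all))

  mafs <- runif(p_all, cfg$maf_range[1], cfg$maf_range[2])
  if (!is.null(cfg$ld_blocks)) {
    at <- 1L
    for (blk in cfg$ld_blocks) {
      mafs[at:(at + blk$size - 1L)] <- mafs[at]
      at <- at + blk$size
    }
  }
  ea <- rep("A", p_all); oa <- rep("G", p_all)

  # --- realized effect vectors -------------------------------------------
  a <- numeric(p_all)           # SNP -> exposure
  is_exp <- roles == "exposure"
  a[is_exp] <- scale_to_h2(rnorm(p_exp), mafs[is_exp], cfg$h2_exposure)

  gamma <- matrix(0, p_all, max(n_med, 1))   # SNP -> mediator (own path)
  if (n_med > 0) {
    colnames(gamma) <- mediators
    for (m in seq_len(n_med)) {
      sel <- roles == mediators[m]
      gamma[sel, m] <- scale_to_h2(rnorm(p_med), mafs[sel], cfg$h2_mediator)
    }
  }

  # Direct SNP -> outcome liability effects (horizontal pleiotropy).
  # Directional pleiotropy acts on the exposure-increasing allele, so the
  # draws are oriented by the sign of each SNP's exposure effect.
  delta <- numeric(p_all)
  if (cfg$pleiotropy$type != "none") {
    mu <- if (cfg$pleiotropy$type == "balanced") 0 else cfg$pleiotropy$mean
    delta[is_exp] <- rnorm(p_exp, mu, cfg$pleiotropy$sd) *
      ifelse(a[is_exp] < 0, -1, 1)
  }

  delta_rev <- numeric(p_all)   # reverse-causal SNP -> outcome-proximal factor
  if (p_rev > 0) {
    sel <- roles == "reverse"
    delta_rev[sel] <- cfg$reverse_effect * sample(c(-1, 1), p_rev, TRUE)
  }

  # Mediation path coefficients solved on the liability log-odds scale.
  total <- cfg$true_total_logor
  pm <- cfg$true_mediation_proportions
  a_path <- setNames(rep(cfg$mediator_path, n_med), mediators)
  a_path[pm == 0] <- 0
  b_path <- setNames(numeric(n_med), mediators)
  nz <- a_path != 0
  b_path[nz] <- pm[nz] * total / a_path[nz]
  direct <- total - sum(a_path * b_path)

  # residual SDs targeting unit trait variances
  var_rev <- sum(2 * mafs * (1 - mafs) * delta_rev^2)
  e_x <- sqrt(max(0, 1 - cfg$h2_exposure - cfg$conf_exposure^2 -
                    cfg$reverse_transmission^2 * var_rev))
  e_m <- if (n_med > 0) {
    sqrt(pmax(0, 1 - a_path^2 - cfg$h2_mediator))
  } else numeric(0)

  # --- one cohort's full phenotype set -----------------------------------
  gen_cohort <- function(n) {
    G <- sim_genotypes(n, mafs, cfg$ld_blocks)
    U <- rnorm(n)
    R <- if (p_rev > 0) geno_score_cpp(G, delta_rev) else numeric(n)
    X <- geno_score_cpp(G, a) + cfg$conf_exposure * U +
      cfg$reverse_transmission * R + rnorm(n, 0, e_x)
    M <- if (n_med > 0) {
      sapply(seq_len(n_med), function(m) {
        a_path[m] * X + geno_score_cpp(G, gamma[, m]) + rnorm(n, 0, e_m[m])
      })
    } else NULL
    eta <- direct * X + cfg$conf_outcome * U +
      geno_score_cpp(G, delta) + R
    if (n_med > 0) eta <- eta + drop(M %*% b_path)
    list(G = G, U = U, X = X, M = M, eta = eta)
  }

  # exposure cohort
  co_e <- gen_cohort(cfg$n_exposure)
  scan_x <- gwas_linear_cpp(co_e$G, co_e$X)
  ds_exposure <- make_dataset(scan_x, rsids, ea, oa, cfg$n_exposure,
                              "exposure", "continuous", unit_label = "SD")

  # mediator cohort
  ds_mediators <- list()
  if (n_med > 0) {
    co_m <- gen_cohort(cfg$n_mediator)
    for (m in seq_len(n_med)) {
      scan_m <- gwas_linear_cpp(co_m$G, co_m$M[, m])
      ds_mediators[[mediators[m]]] <-
        make_dataset(scan_m, rsids, ea, oa, cfg$n_mediator, mediators[m],
                     "continuous", unit_label = "SD")
    }
    rm(co_m)
  }

  # outcome cohort, optionally sharing individuals with the exposure cohort
  n_ov <- round(cfg$overlap_fraction * min(cfg$n_outcome, cfg$n_exposure))
  if (n_ov > 0) {
    n_new <- cfg$n_outcome - n_ov
    co_new <- if (n_new > 0) gen_cohort(n_new) else NULL
    G_o <- if (n_new > 0) rbind(co_e$G[seq_len(n_ov), , drop = FALSE], co_new$G)
           else co_e$G[seq_len(n_ov), , drop = FALSE]
    eta_o <- c(co_e$eta[seq_len(n_ov)], if (n_new > 0) co_new$eta)
    rm(co_new)
  } else {
    co_o <- gen_cohort(cfg$n_outcome)
    G_o <- co_o$G; eta_o <- co_o$eta
    rm(co_o)
  }
  alpha <- uniroot(function(al) mean(plogis(al + eta_o)) - cfg$case_fraction,
                   interval = c(-50, 50), tol = 1e-10)$root
  y <- rbinom(cfg$n_outcome, 1, plogis(alpha + eta_o))
  scan_y <- gwas_logistic_cpp(G_o, y)
  ds_outcome <- make_dataset(scan_y, rsids, ea, oa, cfg$n_outcome, "outcome",
                             "binary", n_cases = sum(y),
                             unit_label = "log-odds")
  rm(G_o)

  ld <- NULL
  if (!is.null(cfg$ld_blocks)) {
    ld <- diag(p_all)
    at <- 1L
    for (blk in cfg$ld_blocks) {
      idx <- at:(at + blk$size - 1L)
      ld[idx, idx] <- blk$rho
      at <- at + blk$size
    }
    diag(ld) <- 1
    dimnames(ld) <- list(rsids, rsids)
  }

  truth <- structure(list(
    config = cfg,
    snps = data.frame(rsid = rsids, role = roles, maf = mafs, a = a,
                      delta = delta, delta_rev = delta_rev,
                      stringsAsFactors = FALSE),
    gamma = if (n_med > 0) gamma else NULL,
    a_path = a_path, b_path = b_path,
    true_total = total, true_direct = direct,
    true_indirect = a_path * b_path,
    true_pm = if (n_med > 0) (a_path * b_path) / total else numeric(0),
    intercept = alpha, ld = ld,
    datasets = list(exposure = ds_exposure, mediators = ds_mediators,
                    outcome = ds_outcome)
  ), class = "sim_truth")
  if (cfg$keep_exposure_cohort) {
    truth$cohort_exposure <- list(G = co_e$G, X = co_e$X)
  }
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$snps), " SNPs; total logOR ",
      signif(x$true_total, 3), sep = "")
  if (length(x$true_pm) > 0) {
    cat("; PM:", paste(sprintf("%s=%.2f", names(x$true_pm), x$true_pm),
                       collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Simulate a mediation study with exact target mediation proportions
#'
#' A thin validating wrapper around [simulate_mr_study()]: requires at least
#' one requested mediation proportion and returns a truth object whose
#' analytic `a_path * b_path / total` equals each requested proportion to
#' machine precision (a construction identity of the generator).
#'
#' @param config A [sim_config()] with non-empty
#'   `true_mediation_proportions`.
#' @return A `sim_truth`.
#' @export
simulate_mediation_study <- function(config) {
  if (length(config$true_mediation_proportions) == 0) {
    stop("simulate_mediation_study needs true_mediation_proportions",
         call. = FALSE)
  }
  simulate_mr_study(config)
}

#' Impose winner's-curse discovery selection on a simulated study
#'
#' Splits the stored exposure cohort into a discovery subsample (first
#' `discovery_n` individuals) and a replication subsample, selects SNPs
#' significant in the discovery scan, and returns an instrument dataset for
#' the selected SNPs whose betas come either from the discovery scan
#' (winner's curse present) or from the independent replication scan (curse
#' absent).
#'
#' @param truth A `sim_truth` generated with `keep_exposure_cohort = TRUE`.
#' @param discovery_n Discovery subsample size (< exposure cohort size).
#' @param selection_pvalue Discovery significance threshold.
#' @param reuse_discovery_betas Use discovery betas for the instrument?
#' @return The `sim_truth` with an added `instrument` element: the selected
#'   [summary_dataset()], the selected rsids, and the arm used.
#' @export
add_winners_curse <- function(truth, discovery_n,
                              selection_pvalue = 5e-8,
                              reuse_discovery_betas = TRUE) {
  if (is.null(truth$cohort_exposure)) {
    stop("truth has no stored exposure cohort; simulate with ",
         "keep_exposure_cohort = TRUE", call. = FALSE)
  }
  G <- truth$cohort_exposure$G
  X <- truth$cohort_exposure$X
  n <- nrow(G)
  if (discovery_n >= n) stop("discovery_n must be below the cohort size",
                             call. = FALSE)
  disc <- seq_len(discovery_n)
  scan_d <- gwas_linear_cpp(G[disc, , drop = FALSE], X[disc])
  scan_r <- gwas_linear_cpp(G[-disc, , drop = FALSE], X[-disc])
  p_d <- 2 * pnorm(-abs(scan_d$beta / scan_d$se))
  sel <- which(p_d < selection_pvalue)
  if (length(sel) == 0) {
    stop("no SNP passes the discovery selection threshold", call. = FALSE)
  }
  scan <- if (reuse_discovery_betas) scan_d else scan_r
  n_used <- if (reuse_discovery_betas) discovery_n else n - discovery_n
  snps <- data.frame(
    rsid = truth$snps$rsid[sel], effect_allele = "A", other_allele = "G",
    eaf = scan$eaf[sel], beta = scan$beta[sel], se = scan$se[sel],
    pvalue = pmax(2 * pnorm(-abs(scan$beta[sel] / scan$se[sel])),
                  .Machine$double.xmin),
    n = n_used, stringsAsFactors = FALSE)
  truth$instrument <- list(
    dataset = summary_dataset(snps, trait_name = "exposure",
                              trait_type = "continuous", unit_label = "SD"),
    selected = truth$snps$rsid[sel],
    arm = if (reuse_discovery_betas) "discovery" else "replication")
  truth
}

#' Fast summary-level MR data generator
#'
#' Draws SNP-exposure and SNP-outcome summary statistics directly from their
#' large-sample Gaussian sampling distributions, parameterized by the GWAS
#' sample sizes: `sx = 1/sqrt(2 maf (1-maf) n_x)` for a unit-variance
#' exposure and `sy = 1/sqrt(2 maf (1-maf) n_y cf (1-cf))` for per-allele
#' log-odds on a binary outcome (or the continuous analogue when
#' `case_fraction` is `NULL`). This is the appropriate tool for estimator
#' calibration experiments (type-I error, power, pleiotropy behaviour) where
#' thousands of replicates are needed; individual-level structure (sample
#' overlap, winner's curse, reverse causation) requires
#' [simulate_mr_study()].
#'
#' @param n_snps Number of instrument SNPs.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param true_beta Causal effect (log-odds per exposure SD when the outcome
#'   is binary).
#' @param case_fraction Outcome case fraction, or `NULL` for a continuous
#'   outcome.
#' @param h2_exposure Variance explained by the panel.
#' @param maf_range MAF range.
#' @param pleiotropy_mean,pleiotropy_sd Direct SNP-outcome effects added to
#'   every SNP (directional when the mean is nonzero).
#' @param exposure_noise Draw sampling noise on the SNP-exposure betas? Set
#'   `FALSE` to treat them as known (the classical power-calculation
#'   regime).
#' @return List with `h` (a ready `harmonized_set`) and `truth` (the
#'   generating per-SNP effects).
#' @export
simulate_summary_mr <- function(n_snps = 50, n_exposure = 2e5,
                                n_outcome = 1e5, true_beta = 0,
                                case_fraction = 0.1, h2_exposure = 0.08,
                                maf_range = c(0.05, 0.5),
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                exposure_noise = TRUE) {
  mafs <- runif(n_snps, maf_range[1], maf_range[2])
  a <- scale_to_h2(rnorm(n_snps), mafs, h2_exposure)
  vg <- 2 * mafs * (1 - mafs)
  sx <- 1 / sqrt(vg * n_exposure)
  sy <- if (is.null(case_fraction)) {
    1 / sqrt(vg * n_outcome)
  } else {
    1 / sqrt(vg * n_outcome * case_fraction * (1 - case_fraction))
  }
  # directional pleiotropy is defined on the exposure-increasing allele
  delta <- if (pleiotropy_mean != 0 || pleiotropy_sd != 0) {
    rnorm(n_snps, pleiotropy_mean, pleiotropy_sd) * ifelse(a < 0, -1, 1)
  } else numeric(n_snps)
  bx <- if (exposure_noise) rnorm(n_snps, a, sx) else a
  by <- rnorm(n_snps, true_beta * a + delta, sy)
  rsids <- sprintf("rs%06d", seq_len(n_snps))
  h <- harmonized_set(bx = bx, sx = sx, by = by, sy = sy, rsids = rsids,
                      nx = n_exposure, ny = n_outcome,
                      ncase_y = if (is.null(case_fraction)) NULL
                                else round(case_fraction * n_outcome),
                      eaf = mafs,
                      outcome_type = if (is.null(case_fraction)) "continuous"
                                     else "binary")
  list(h = h, truth = list(mafs = mafs, a = a, delta = delta,
                           true_beta = true_beta))
}

#' Write a simulated study to the summary-statistics TSV dialect
#'
#' Emits one TSV per trait (readable back via [read_summary_dataset()]), an
#' LD matrix TSV when present, and a plain-text truth file echoing the
#' generating parameters.
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_study <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dump <- function(ds, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    snps <- ds$snps
    names(snps)[names(snps) == "pvalue"] <- "pval"
    names(snps)[names(snps) == "n_cases"] <- "ncase"
    write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  dump(truth$datasets$exposure, "exposure")
  for (nm in names(truth$datasets$mediators)) {
    dump(truth$datasets$mediators[[nm]], nm)
  }
  dump(truth$datasets$outcome, "outcome")
  if (!is.null(truth$ld)) {
    path <- file.path(dir, "ld.tsv")
    write.table(data.frame(rsid = rownames(truth$ld), truth$ld,
                           check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  tr <- file.path(dir, "truth.yaml")
  cfg <- unclass(truth$config)
  cfg$keep_exposure_cohort <- NULL
  yaml::write_yaml(list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    true_total_logor = truth$true_total,
    true_direct_logor = truth$true_direct,
    true_indirect = as.list(truth$true_indirect),
    true_proportion_mediated = as.list(truth$true_pm)
  ), tr)
  files <- c(files, tr)
  invisible(files)
}
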