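estimate_row <- function(exposure_name, outcome_name, est, evidence = NA_character_) {
  df <- as.data.frame(est)
  cbind(data.frame(exposure = exposure_name, outcome = outcome_name,
                   stringsAsFactors = FALSE),
        df, data.frame(evidence = evidence, stringsAsFactors = FALSE))
}

#' Univariable MR screen of exposures against an outcome
#'
#' For each exposure: construct the instrument, harmonize against the
#' outcome, apply Steiger filtering, estimate the causal effect (Wald ratio
#' for single-SNP instruments, random-effects IVW otherwise; a
#' correlation-adjusted IVW when the instrument spec retains linked SNPs and
#' an LD matrix is available), add the MR-Egger / weighted median / weighted
#' mode battery for instruments of at least `sensitivity_min_snps` SNPs,
#' classify the evidence under the Bonferroni heuristic, and run
#' leave-one-out when the primary p-value is below 0.05 and either the
#' instrument has fewer than `sensitivity_min_snps` SNPs or all sensitivity
#' point estimates agree in sign with IVW. Exposures failing any stage are
#' skipped with a log entry, never fatal.
#'
#' @param exposures Named list of [summary_dataset()] exposures.
#' @param outcome A [summary_dataset()].
#' @param specs A single [instrument_spec()] or named list per exposure.
#' @param ld Optional LD matrix (or named list per exposure) for clumping
#'   and correlation-adjusted estimation.
#' @param n_traits Number of traits for the Bonferroni threshold.
#' @param steiger Apply Steiger directionality filtering?
#' @param sensitivity_min_snps Minimum SNPs for the pleiotropy-robust
#'   battery (default 10).
#' @param n_boot,seed Bootstrap settings for median/mode standard errors.
#' @return An object of class `mr_screen`: list with `results` (one row per
#'   exposure-method), `loo` (leave-one-out tables), `log` (gate
#'   decisions) and `harmonized` (the post-filter sets).
#' @export
univariable_screen <- function(exposures, outcome, specs = instrument_spec(),
                               ld = NULL, n_traits = length(exposures),
                               steiger = TRUE, sensitivity_min_snps = 10L,
                               n_boot = 1000, seed = 1) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(d) d$trait_name,
                               character(1))
  }
  get_for <- function(obj, nm) {
    if (is.null(obj)) return(NULL)
    if (is.list(obj) && !inherits(obj, "instrument_spec") &&
        !is.matrix(obj)) {
      return(obj[[nm]])
    }
    obj
  }
  rows <- list(); loo_tables <- list(); log <- character(0)
  harmonized <- list()
  note <- function(...) log <<- c(log, paste0(...))

  for (nm in names(exposures)) {
    spec <- get_for(specs, nm)
    if (is.null(spec)) spec <- instrument_spec()
    ld_nm <- get_for(ld, nm)
    res <- tryCatch({
      inst <- select_instruments(exposures[[nm]], spec, ld = ld_nm)
      note(nm, ": ", nrow(inst$snps), " instrument SNPs (p < ",
           spec$p_threshold, ", clump r2 ", spec$clump_r2, ")")
      h <- harmonize(inst, outcome, ld = ld_nm)
      if (steiger) {
        st <- steiger_filter(h)
        if (nrow(st$removed) > 0) {
          note(nm, ": Steiger removed ", nrow(st$removed), " SNP(s): ",
               paste(st$removed$rsid, collapse = ", "))
        }
        h <- st$harmonized
      }
      if (n_snps(h) == 0) stop("no SNPs left after filtering")
      harmonized[[nm]] <- h
      k <- n_snps(h)
      use_correlated <- !is.null(h$ld) && spec$clump_r2 > 0.001 && k >= 2

      if (k == 1) {
        primary <- wald_ratio(h$bx[1, 1], h$sx[1, 1], h$by[1], h$sy[1])
        note(nm, ": single SNP, Wald ratio")
      } else if (use_correlated) {
        primary <- mr_ivw_correlated(h)
        note(nm, ": correlated-IVW over ", k, " linked SNPs")
      } else {
        primary <- mr_ivw(h)
      }
      ev <- classify_evidence(primary$pvalue, n_traits)
      out_rows <- list(estimate_row(nm, outcome$trait_name, primary,
                                    ev$label))
      sens <- list()
      if (k >= sensitivity_min_snps) {
        sens$egger <- mr_egger(h)
        sens$median <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
        sens$mode <- mr_weighted_mode(h, n_boot = n_boot, seed = seed)
        for (s in sens) {
          out_rows <- c(out_rows,
                        list(estimate_row(nm, outcome$trait_name, s)))
        }
      } else if (k >= 2) {
        note(nm, ": < ", sensitivity_min_snps,
             " SNPs, pleiotropy battery skipped")
      }
      concordant <- length(sens) == 0 ||
        all(vapply(sens, function(s) sign(s$beta) == sign(primary$beta),
                   logical(1)))
      if (primary$pvalue < 0.05 && k >= 3 &&
          (k < sensitivity_min_snps || concordant)) {
        loo_tables[[nm]] <- leave_one_out(h)
        note(nm, ": leave-one-out over ", k, " SNPs",
             if (any(loo_tables[[nm]]$sign_flip)) " (sign flips present)"
             else "")
      } else {
        note(nm, ": leave-one-out not triggered (p = ",
             signif(primary$pvalue, 3), ", concordant = ", concordant, ")")
      }
      do.call(rbind, out_rows)
    }, error = function(e) {
      note(nm, ": skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) rows[[nm]] <- res
  }
  results <- if (length(rows) > 0) do.call(rbind, rows) else
    estimate_row(character(0), character(0),
                 new_mr_estimate("ivw", numeric(0), numeric(0), integer(0)))[0, ]
  rownames(results) <- NULL
  structure(list(results = results, loo = loo_tables, log = log,
                 harmonized = harmonized),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat("<mr_screen> ", length(unique(x$results$exposure)), " exposures, ",
      nrow(x$results), " estimate rows\n", sep = "")
  print(x$results[, c("exposure", "method", "n_snps", "or", "pvalue",
                      "evidence")])
  invisible(x)
}

harmonize_on <- function(datasets, outcome, rsids, ld = NULL) {
  subset_ds <- function(ds) {
    ds$snps <- ds$snps[ds$snps$rsid %in% rsids, , drop = FALSE]
    ds
  }
  harmonize(lapply(datasets, subset_ds), subset_ds(outcome), ld = ld)
}

#' MVMR mediation analysis of an exposure through candidate mediators
#'
#' For each mediator: the total effect (univariable exposure -> outcome
#' IVW), the exposure -> mediator effect `a` (univariable IVW on the
#' exposure instrument), the multivariable model (exposure + mediator ->
#' outcome on the union of both instruments) giving the direct effect, the
#' mediator's conditional effect `b` and conditional F-statistics, and the
#' product-of-coefficients indirect effect with the delta-method proportion
#' mediated. Mediators whose instrument construction fails are skipped with
#' a log entry. Optionally, pairwise mediator-only models quantify the
#' log-odds attenuation of each mediator upon adjustment for another
#' (presumed downstream) mediator.
#'
#' @param exposure A [summary_dataset()] (the upstream exposure).
#' @param mediators Named list of [summary_dataset()] mediators.
#' @param outcome A [summary_dataset()].
#' @param specs A single [instrument_spec()] or named list (keyed by
#'   exposure/mediator name).
#' @param ld Optional LD matrix or named list.
#' @param steiger Apply Steiger filtering to the total-effect model?
#' @param pairwise Also fit all mediator-pair models without the exposure?
#' @return An object of class `mr_mediation`: list with `table` (one row
#'   per mediator), `details` (the `mediation_result` objects), `pairwise`
#'   (attenuation table or NULL) and `log`.
#' @export
mediation_analysis <- function(exposure, mediators, outcome,
                               specs = instrument_spec(), ld = NULL,
                               steiger = TRUE, pairwise = TRUE) {
  if (inherits(mediators, "summary_dataset")) mediators <- list(mediators)
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, function(d) d$trait_name,
                               character(1))
  }
  get_for <- function(obj, nm) {
    if (is.null(obj)) return(NULL)
    if (is.list(obj) && !inherits(obj, "instrument_spec") &&
        !is.matrix(obj)) return(obj[[nm]])
    obj
  }
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  exp_name <- exposure$trait_name

  exp_spec <- get_for(specs, exp_name)
  if (is.null(exp_spec)) exp_spec <- instrument_spec()
  exp_inst <- select_instruments(exposure, exp_spec,
                                 ld = get_for(ld, exp_name))

  # total effect
  h_tot <- harmonize(exp_inst, outcome)
  if (steiger) h_tot <- steiger_filter(h_tot)$harmonized
  total <- if (n_snps(h_tot) == 1) {
    wald_ratio(h_tot$bx[1, 1], h_tot$sx[1, 1], h_tot$by[1], h_tot$sy[1])
  } else mr_ivw(h_tot)
  note(exp_name, " -> outcome total logOR ", signif(total$beta, 4),
       " over ", n_snps(h_tot), " SNPs")

  details <- list(); rows <- list()
  insts <- list()
  for (nm in names(mediators)) {
    res <- tryCatch({
      spec <- get_for(specs, nm)
      if (is.null(spec)) spec <- instrument_spec()
      med_inst <- select_instruments(mediators[[nm]], spec,
                                     ld = get_for(ld, nm))
      insts[[nm]] <- med_inst
      # a: exposure -> mediator on the exposure instrument
      h_a <- harmonize(exp_inst, mediators[[nm]])
      a_est <- if (n_snps(h_a) == 1) {
        wald_ratio(h_a$bx[1, 1], h_a$sx[1, 1], h_a$by[1], h_a$sy[1])
      } else mr_ivw(h_a)
      # MVMR on the union of instruments
      union_rsids <- union(exp_inst$snps$rsid, med_inst$snps$rsid)
      h_mv <- harmonize_on(list(exposure, mediators[[nm]]), outcome,
                           union_rsids)
      mv <- mvmr_ivw(h_mv)
      med <- mediation_result(total, a_est, mv, mediator_name = nm,
                              exposure_name = exp_name)
      if (min(mv$conditional_f) < 10) {
        note(nm, ": conditional F < 10 (",
             paste(sprintf("%s=%.1f", names(mv$conditional_f),
                           mv$conditional_f), collapse = ", "),
             "), possible weak-instrument bias")
      }
      med
    }, error = function(e) {
      note(nm, ": skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(res)) {
      details[[nm]] <- res
      rows[[nm]] <- as.data.frame(res)
    }
  }
  table <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (!is.null(table)) rownames(table) <- NULL

  pw <- NULL
  if (pairwise && length(insts) >= 2) {
    pw_rows <- list()
    nms <- names(insts)
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i == j) next
      m1 <- nms[i]; m2 <- nms[j]
      row <- tryCatch({
        h_uni <- harmonize(insts[[m1]], outcome)
        uni <- if (n_snps(h_uni) == 1) {
          wald_ratio(h_uni$bx[1, 1], h_uni$sx[1, 1], h_uni$by[1],
                     h_uni$sy[1])
        } else mr_ivw(h_uni)
        union_rsids <- union(insts[[m1]]$snps$rsid, insts[[m2]]$snps$rsid)
        h_mv <- harmonize_on(list(mediators[[m1]], mediators[[m2]]),
                             outcome, union_rsids)
        mv <- mvmr_ivw(h_mv)
        cond <- mv$direct_betas[[m1]]
        data.frame(trait = m1, adjusted_for = m2,
                   uni_logor = uni$beta, cond_logor = cond,
                   cond_se = mv$ses[[m1]],
                   cond_or = exp(cond),
                   cond_pvalue = mv$pvalues[[m1]],
                   attenuation_pct = logor_attenuation(uni$beta, cond),
                   conditional_f_trait = mv$conditional_f[[m1]],
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        note(m1, " | ", m2, ": pairwise model skipped (",
             conditionMessage(e), ")")
        NULL
      })
      if (!is.null(row)) pw_rows <- c(pw_rows, list(row))
    }
    if (length(pw_rows) > 0) {
      pw <- do.call(rbind, pw_rows)
      rownames(pw) <- NULL
    }
  }
  structure(list(total = total, table = table, details = details,
                 pairwise = pw, log = log),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("<mr_mediation> total OR ", sprintf("%.3f", exp(x$total$beta)), "\n",
      sep = "")
  if (!is.null(x$table)) {
    print(x$table[, c("mediator", "direct_or", "indirect_or",
                      "pct_mediated", "pm_pvalue")])
  }
  invisible(x)
}

#' Read a pipeline run configuration (YAML)
#'
#' @param path YAML file. See the package vignette for the schema: an
#'   `outcome` entry (path, trait_type, case_fraction), named `exposures`
#'   entries (path, optional p_threshold/clump_r2/ld), optional `mediation`
#'   section (exposure, mediators, pairwise), `n_traits_for_bonferroni`,
#'   `steiger`, `n_boot`, `seed`.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$outcome$path)) stop("config lacks outcome path", call. = FALSE)
  if (is.null(cfg$exposures)) stop("config lacks exposures", call. = FALSE)
  cfg
}

load_config_dataset <- function(entry, name, default_type = "continuous") {
  read_summary_dataset(entry$path, trait_name = name,
                       trait_type = entry$trait_type %||% default_type,
                       unit_label = entry$unit %||% "",
                       case_fraction = entry$case_fraction,
                       column_map = entry$column_map %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_specs <- function(cfg) {
  specs <- lapply(cfg$exposures, function(e) {
    instrument_spec(p_threshold = e$p_threshold %||% 5e-8,
                    clump_r2 = e$clump_r2 %||% 0.001)
  })
  names(specs) <- names(cfg$exposures)
  specs
}

#' Run the univariable screen from a configuration
#'
#' @param cfg Configuration list (from [read_run_config()]) or a YAML path.
#' @param outdir Output directory for report files (defaults to
#'   `cfg$output_dir`).
#' @return The `mr_screen`, invisibly after writing reports.
#' @export
run_screen <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  outdir <- outdir %||% cfg$output_dir %||% "."
  outcome <- load_config_dataset(cfg$outcome, cfg$outcome$name %||% "outcome",
                                 default_type = "binary")
  exposures <- lapply(names(cfg$exposures), function(nm) {
    load_config_dataset(cfg$exposures[[nm]], nm)
  })
  names(exposures) <- names(cfg$exposures)
  lds <- lapply(cfg$exposures, function(e) {
    if (!is.null(e$ld)) read_ld_matrix(e$ld) else NULL
  })
  screen <- univariable_screen(
    exposures, outcome, specs = config_specs(cfg), ld = lds,
    n_traits = cfg$n_traits_for_bonferroni %||% length(exposures),
    steiger = cfg$steiger %||% TRUE,
    n_boot = cfg$n_boot %||% 1000, seed = cfg$seed %||% 1)
  write_report(screen = screen, outdir = outdir, config = cfg,
               seed = cfg$seed %||% 1)
  invisible(screen)
}

#' Run the mediation analysis from a configuration
#'
#' @inheritParams run_screen
#' @return The `mr_mediation`, invisibly after writing reports.
#' @export
run_mediate <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$mediation)) stop("config lacks a mediation section",
                                   call. = FALSE)
  outdir <- outdir %||% cfg$output_dir %||% "."
  outcome <- load_config_dataset(cfg$outcome, cfg$outcome$name %||% "outcome",
                                 default_type = "binary")
  exp_nm <- cfg$mediation$exposure
  exposure <- load_config_dataset(cfg$exposures[[exp_nm]], exp_nm)
  med_nms <- unlist(cfg$mediation$mediators)
  meds <- lapply(med_nms, function(nm) {
    load_config_dataset(cfg$exposures[[nm]], nm)
  })
  names(meds) <- med_nms
  med <- mediation_analysis(
    exposure, meds, outcome, specs = config_specs(cfg),
    steiger = cfg$steiger %||% TRUE,
    pairwise = cfg$mediation$pairwise %||% TRUE)
  write_report(mediation = med, outdir = outdir, config = cfg,
               seed = cfg$seed %||% 1)
  invisible(med)
}

#' Write screen and mediation reports as tab-separated tables
#'
#' Emits `screen.tsv` (one row per exposure-method), `leave_one_out.tsv`,
#' `mediation.tsv`, `pairwise_mediators.tsv`, a run log and a config/seed
#' echo. Every number is taken from the estimate objects; nothing is
#' recomputed here.
#'
#' @param screen Optional `mr_screen`.
#' @param mediation Optional `mr_mediation`.
#' @param outdir Output directory (created if needed).
#' @param config,seed Echoed for provenance.
#' @return Invisibly, the files written.
#' @export
write_report <- function(screen = NULL, mediation = NULL, outdir,
                         config = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  log <- character(0)
  if (!is.null(screen)) {
    emit(screen$results, "screen.tsv")
    loo <- if (length(screen$loo) > 0) {
      do.call(rbind, lapply(names(screen$loo), function(nm) {
        cbind(data.frame(exposure = nm, stringsAsFactors = FALSE),
              screen$loo[[nm]])
      }))
    } else {
      data.frame(exposure = character(0), rsid = character(0),
                 beta = numeric(0), se = numeric(0), pvalue = numeric(0),
                 sign_flip = logical(0))
    }
    emit(loo, "leave_one_out.tsv")
    log <- c(log, screen$log)
  }
  if (!is.null(mediation)) {
    tab <- mediation$table
    if (is.null(tab)) {
      tab <- as.data.frame(list())[0, ]
      tab <- data.frame(mediator = character(0), exposure = character(0),
                        total_or = numeric(0), direct_or = numeric(0),
                        indirect_or = numeric(0), pct_mediated = numeric(0),
                        pct_ci_low = numeric(0), pct_ci_high = numeric(0),
                        pm_pvalue = numeric(0),
                        conditional_f_exposure = numeric(0),
                        conditional_f_mediator = numeric(0),
                        weak_instrument_flag = logical(0))
    }
    emit(tab, "mediation.tsv")
    pw <- mediation$pairwise
    if (is.null(pw)) {
      pw <- data.frame(trait = character(0), adjusted_for = character(0),
                       uni_logor = numeric(0), cond_logor = numeric(0),
                       cond_se = numeric(0), cond_or = numeric(0),
                       cond_pvalue = numeric(0), attenuation_pct = numeric(0),
                       conditional_f_trait = numeric(0))
    }
    emit(pw, "pairwise_mediators.tsv")
    log <- c(log, mediation$log)
  }
  writeLines(log, file.path(outdir, "run_log.txt"))
  files <- c(files, file.path(outdir, "run_log.txt"))
  if (!is.null(config)) {
    yaml::write_yaml(c(config, list(seed_echo = seed)),
                     file.path(outdir, "config_echo.yaml"))
    files <- c(files, file.path(outdir, "config_echo.yaml"))
  }
  invisible(files)
}
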