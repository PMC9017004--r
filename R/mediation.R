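#' Indirect effect by the product of coefficients
#'
#' `beta = a * b` with the first-order delta-method standard error
#' `sqrt(b^2 se_a^2 + a^2 se_b^2)`, assuming the two coefficients are
#' estimated in independent samples.
#'
#' @param a,se_a Exposure-to-mediator effect and SE (mediator units).
#' @param b,se_b Mediator-to-outcome direct effect and SE (log-odds).
#' @return List with `beta` and `se`.
#' @export
indirect_effect <- function(a, se_a, b, se_b) {
  list(beta = a * b, se = sqrt(b^2 * se_a^2 + a^2 * se_b^2))
}

#' Proportion of the total effect mediated
#'
#' `pm = indirect/total` on the log-odds scale, with the delta-method
#' standard error `|pm| sqrt(se_ind^2/ind^2 + se_tot^2/tot^2)` under
#' independence, a normal 95% interval and a two-sided p-value. Estimates
#' outside \[0, 1\] are reported as computed, never truncated.
#'
#' @param indirect,total Lists with elements `beta` and `se`.
#' @return List with `pm`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @examples
#' # indirect OR 1.07 against a total OR of 1.88: ~11% mediated
#' proportion_mediated(list(beta = log(1.07), se = 0.03),
#'                     list(beta = log(1.88), se = 0.05))$pm
#' @export
proportion_mediated <- function(indirect, total) {
  if (total$beta == 0) {
    stop("proportion mediated undefined: total effect is zero", call. = FALSE)
  }
  pm <- indirect$beta / total$beta
  se <- abs(pm) * sqrt(indirect$se^2 / indirect$beta^2 +
                         total$se^2 / total$beta^2)
  list(pm = pm, se = se, ci_low = pm - 1.96 * se, ci_high = pm + 1.96 * se,
       pvalue = 2 * pnorm(-abs(pm / se)))
}

#' Percent attenuation of a log-odds effect upon co-adjustment
#'
#' `100 (1 - beta_conditional / beta_univariable)`: the percent reduction of
#' a trait's log-odds effect when a putative downstream mediator enters the
#' model.
#'
#' @param beta_univariable Univariable log-odds effect (nonzero).
#' @param beta_conditional Conditional (multivariable) log-odds effect.
#' @return Percent reduction (negative when the effect grows).
#' @export
logor_attenuation <- function(beta_univariable, beta_conditional) {
  if (beta_univariable == 0) {
    stop("attenuation undefined: univariable effect is zero", call. = FALSE)
  }
  100 * (1 - beta_conditional / beta_univariable)
}

#' Assemble a full mediation result from its component estimates
#'
#' Combines the univariable total effect, the exposure-to-mediator effect
#' `a`, and the multivariable direct effects (of which the mediator's is
#' `b`) into the product-of-coefficients indirect effect and proportion
#' mediated. The difference-method indirect effect `total - direct` is
#' reported alongside as a cross-check.
#'
#' @param total An `mr_estimate` for exposure -> outcome.
#' @param a An `mr_estimate` for exposure -> mediator.
#' @param mvmr An `mvmr_result` for (exposure, mediator) -> outcome.
#' @param mediator_name Name of the mediator column in `mvmr`.
#' @param exposure_name Name of the exposure column in `mvmr`.
#' @return An object of class `mediation_result`.
#' @export
mediation_result <- function(total, a, mvmr, mediator_name,
                             exposure_name = mvmr$exposure_names[1]) {
  b <- mvmr$direct_betas[[mediator_name]]
  se_b <- mvmr$ses[[mediator_name]]
  direct <- mvmr$direct_betas[[exposure_name]]
  se_direct <- mvmr$ses[[exposure_name]]
  ind <- indirect_effect(a$beta, a$se, b, se_b)
  pm <- proportion_mediated(ind, list(beta = total$beta, se = total$se))
  structure(list(
    mediator = mediator_name, exposure = exposure_name,
    total_beta = total$beta, total_se = total$se,
    direct_beta = direct, direct_se = se_direct,
    a = a$beta, a_se = a$se, b = b, b_se = se_b,
    indirect_beta = ind$beta, indirect_se = ind$se,
    indirect_diff = total$beta - direct,
    proportion_mediated = pm$pm, pm_se = pm$se,
    pm_ci = c(pm$ci_low, pm$ci_high), pm_pvalue = pm$pvalue,
    conditional_f = mvmr$conditional_f
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> ", x$exposure, " -> ", x$mediator, " -> outcome\n",
      sep = "")
  cat(sprintf("  total OR %.3f, direct OR %.3f, indirect OR %.3f\n",
              exp(x$total_beta), exp(x$direct_beta), exp(x$indirect_beta)))
  cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f to %.1f%%), p = %.3g\n",
              100 * x$proportion_mediated, 100 * x$pm_ci[1],
              100 * x$pm_ci[2], x$pm_pvalue))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(mediator = x$mediator, exposure = x$exposure,
             total_or = exp(x$total_beta), direct_or = exp(x$direct_beta),
             indirect_or = exp(x$indirect_beta),
             pct_mediated = 100 * x$proportion_mediated,
             pct_ci_low = 100 * x$pm_ci[1], pct_ci_high = 100 * x$pm_ci[2],
             pm_pvalue = x$pm_pvalue,
             conditional_f_exposure = x$conditional_f[[x$exposure]],
             conditional_f_mediator = x$conditional_f[[x$mediator]],
             weak_instrument_flag = min(x$conditional_f) < 10,
             stringsAsFactors = FALSE)
}
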