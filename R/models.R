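#' Specification of the clinician-day mixed model
#'
#' The analysis model regresses a daily outcome (EHR time in minutes, or the
#' number of patient switches) on the exposure category (reference: no
#' concurrent conversations) adjusted for the percentage of messaging time
#' spent concurrent, daily messaging volume, patient load, clinician role,
#' age and sex, with crossed random intercepts for clinician and for
#' clinical service. Stratified specifications drop role from the fixed
#' effects; the interaction specification adds exposure x role.
#'
#' @param outcome `"ehr_time"` or `"n_switches"`.
#' @param interaction Add the exposure-by-role interaction block?
#' @param strata Optional role name; restricts the fit to that stratum and
#'   drops `role` from the fixed effects.
#' @return Object of class `convoload_spec`.
#' @export
model_spec <- function(outcome = c("ehr_time", "n_switches"),
                       interaction = FALSE, strata = NULL) {
  outcome <- match.arg(outcome)
  if (!is.null(strata) && interaction) {
    stop("a stratified model cannot include the exposure x role interaction",
         call. = FALSE)
  }
  structure(list(outcome = outcome, interaction = interaction, strata = strata),
            class = "convoload_spec")
}

spec_formula <- function(spec, include_role = is.null(spec$strata),
                         drop = character(0), service_term = TRUE) {
  fixed <- c("exposure", "pct_concurrent_time", "msg_volume", "patient_load",
             if (include_role) "role", "age", "sex",
             if (spec$interaction) "exposure:role")
  fixed <- setdiff(fixed, drop)
  as.formula(paste(spec$outcome, "~", paste(fixed, collapse = " + "),
                   "+ (1 | clinician_id)",
                   if (service_term) "+ (1 | service)"))
}

prepare_model_data <- function(cohort, spec) {
  need <- c(spec$outcome, "exposure", "pct_concurrent_time", "msg_volume",
            "patient_load", "role", "age", "sex", "clinician_id", "service")
  assert_cols(cohort, union(need, "included"), "cohort")
  d <- cohort[cohort$included, , drop = FALSE]
  if (!is.null(spec$strata)) d <- d[d$role == spec$strata, , drop = FALSE]
  d$exposure <- factor(as.character(d$exposure), levels = EXPOSURE_LEVELS)
  d$exposure <- droplevels(d$exposure)
  d$role <- factor(d$role, levels = c("attending", "APP", "trainee"))
  d$role <- droplevels(d$role)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$clinician_id <- factor(d$clinician_id)
  d$service <- factor(d$service)
  d
}

#' Fit the clinician-day linear mixed-effects model
#'
#' REML fit with crossed random intercepts for clinician and clinical
#' service. Fixed-effect 95% CIs are Wald intervals (estimate +/- 1.96 SE);
#' p-values use Satterthwaite denominator degrees of freedom by default, or
#' a normal approximation with `p_method = "wald"` (cheaper in simulation
#' loops). A random-intercept variance estimated at (or near) zero is
#' reported as such, not treated as an error; non-convergence is flagged in
#' the result, never silently dropped.
#'
#' @param cohort Clinician-day table from [build_cohort()] or
#'   [simulate_study()] (`included` rows are used).
#' @param spec A [model_spec()].
#' @param p_method `"satterthwaite"` or `"wald"`.
#' @param reml Use REML (default) or ML.
#' @param allow_single_service With a single observed service (as can happen
#'   in role strata), drop the service intercept, report its variance as 0
#'   and warn, instead of erroring.
#' @return An `effect_table`: tibble with `term`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, plus attributes `varcomp` (clinician, service,
#'   residual variances), `n_obs`, `n_clinicians`, `n_services`, `method`,
#'   `converged`, `singular`, and the fitted `merMod` as `model`.
#' @export
fit_lmm <- function(cohort, spec, p_method = c("satterthwaite", "wald"),
                    reml = TRUE, allow_single_service = FALSE) {
  stopifnot(inherits(spec, "convoload_spec"))
  p_method <- match.arg(p_method)
  d <- prepare_model_data(cohort, spec)
  single_service <- nlevels(d$service) == 1
  if (nlevels(d$clinician_id) < 2 || (single_service && !allow_single_service)) {
    stop("cohort must contain at least 2 clinicians and 2 services", call. = FALSE)
  }
  if (single_service) {
    warning("single clinical service observed; service variance fixed at 0",
            call. = FALSE)
  }
  if (nlevels(d$exposure) < 2) {
    stop("singular design: term 'exposure' has a single observed level; cannot estimate exposure effects",
         call. = FALSE)
  }
  if (spec$interaction && nlevels(d$role) < 2) {
    stop("exposure x role interaction requires at least 2 roles", call. = FALSE)
  }
  if (sd(d[[spec$outcome]]) == 0) {
    return(constant_outcome_table(d, spec, reml, p_method))
  }
  drop <- character(0)
  if (nlevels(droplevels(d$sex)) < 2) drop <- c(drop, "sex")
  if (is.null(spec$strata) && !spec$interaction && nlevels(d$role) < 2) {
    drop <- c(drop, "role")
  }
  if (length(drop)) {
    warning(sprintf("covariate(s) constant in this cohort and dropped: %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
  }
  form <- spec_formula(spec, drop = drop, service_term = !single_service)
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = reml,
                                         control = lme4::lmerControl(calc.derivs = FALSE)))
  converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (!converged) {
    warning("mixed-model fit did not converge cleanly; estimates flagged, inspect attr(, 'model')",
            call. = FALSE)
  }
  if (p_method == "satterthwaite") {
    co <- as.data.frame(summary(fit)$coefficients)
    pv <- co[["Pr(>|t|)"]]
  } else {
    co <- as.data.frame(summary(fit, ddf = "lme4")$coefficients)
    pv <- 2 * pnorm(-abs(co[["t value"]]))
  }
  est <- co[["Estimate"]]
  se <- co[["Std. Error"]]
  tab <- tibble::tibble(
    term = rownames(co),
    estimate = est,
    ci_low = est - qnorm(0.975) * se,
    ci_high = est + qnorm(0.975) * se,
    p_value = pv
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                      sub("clinician_id", "clinician",
                                          sub("service", "service", vc$grp))))
  if (single_service) varcomp <- c(varcomp, service = 0)
  varcomp <- varcomp[order(match(names(varcomp), c("clinician", "service", "residual")))]
  attr(tab, "varcomp") <- varcomp
  attr(tab, "n_obs") <- nrow(d)
  attr(tab, "n_clinicians") <- nlevels(d$clinician_id)
  attr(tab, "n_services") <- nlevels(d$service)
  attr(tab, "method") <- if (reml) "REML" else "ML"
  attr(tab, "p_method") <- p_method
  attr(tab, "converged") <- converged
  attr(tab, "singular") <- singular
  attr(tab, "outcome") <- spec$outcome
  attr(tab, "model") <- fit
  class(tab) <- c("effect_table", class(tab))
  tab
}

# Degenerate fit: a constant outcome has zero residual variance and no
# estimable slopes; report slopes 0, intercept = the constant, all variance
# components 0, flagged singular, rather than erroring.
constant_outcome_table <- function(d, spec, reml, p_method) {
  warning("outcome is constant; zero residual variance, slope estimates fixed at 0",
          call. = FALSE)
  form <- spec_formula(spec)
  terms <- colnames(stats::model.matrix(lme4::nobars(form), data = d))
  tab <- tibble::tibble(
    term = terms,
    estimate = c(d[[spec$outcome]][1], rep(0, length(terms) - 1)),
    ci_low = c(d[[spec$outcome]][1], rep(0, length(terms) - 1)),
    ci_high = c(d[[spec$outcome]][1], rep(0, length(terms) - 1)),
    p_value = NA_real_
  )
  attr(tab, "varcomp") <- c(clinician = 0, service = 0, residual = 0)
  attr(tab, "n_obs") <- nrow(d)
  attr(tab, "n_clinicians") <- nlevels(d$clinician_id)
  attr(tab, "n_services") <- nlevels(d$service)
  attr(tab, "method") <- if (reml) "REML" else "ML"
  attr(tab, "p_method") <- p_method
  attr(tab, "converged") <- TRUE
  attr(tab, "singular") <- TRUE
  attr(tab, "outcome") <- spec$outcome
  class(tab) <- c("effect_table", class(tab))
  tab
}

#' Likelihood-ratio test of the exposure-by-role interaction
#'
#' Refits the model with and without the exposure x role block by maximum
#' likelihood and compares them with a likelihood-ratio test; the
#' interaction model's REML effect table accompanies the p-value.
#'
#' @inheritParams fit_lmm
#' @return List: `p_value`, `statistic` (chi-squared), `df`, `lrt` (the
#'   anova table), `effects` (REML `effect_table` of the interaction model).
#' @export
interaction_test <- function(cohort, spec, p_method = "wald") {
  stopifnot(inherits(spec, "convoload_spec"))
  d <- prepare_model_data(cohort, model_spec(spec$outcome))
  if (nlevels(d$role) < 2) {
    stop("interaction test requires at least 2 roles in the cohort", call. = FALSE)
  }
  spec0 <- model_spec(spec$outcome, interaction = FALSE)
  spec1 <- model_spec(spec$outcome, interaction = TRUE)
  m0 <- suppressMessages(lme4::lmer(spec_formula(spec0), data = d, REML = FALSE,
                                    control = lme4::lmerControl(calc.derivs = FALSE)))
  m1 <- suppressMessages(lme4::lmer(spec_formula(spec1), data = d, REML = FALSE,
                                    control = lme4::lmerControl(calc.derivs = FALSE)))
  lrt <- anova(m0, m1)
  effects <- fit_lmm(cohort, spec1, p_method = p_method)
  list(p_value = lrt$`Pr(>Chisq)`[2],
       statistic = lrt$Chisq[2],
       df = lrt$Df[2],
       lrt = lrt,
       effects = effects)
}

#' Role-stratified mixed-model fits
#'
#' One model per clinician role, each retaining both random intercepts and
#' dropping role from the fixed effects. Strata that cannot support the fit
#' (no days, a single exposure level, fewer than 2 clinicians or services)
#' are skipped with a warning.
#'
#' @inheritParams fit_lmm
#' @return Named list of `effect_table`s, one per role actually fitted.
#' @export
stratified_fits <- function(cohort, spec, p_method = "satterthwaite") {
  stopifnot(inherits(spec, "convoload_spec"))
  roles <- intersect(c("attending", "APP", "trainee"),
                     unique(cohort$role[cohort$included]))
  out <- list()
  for (r in roles) {
    res <- tryCatch(
      fit_lmm(cohort, model_spec(spec$outcome, strata = r), p_method = p_method,
              allow_single_service = TRUE),
      error = function(e) {
        warning(sprintf("stratum '%s' skipped: %s", r, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(res)) out[[r]] <- res
  }
  out
}

#' Sensitivity of the exposure effects to the concurrency bin width
#'
#' Re-runs the full pipeline — exposure recomputation from raw messaging
#' metadata at each bin width, cohort assembly, and both outcome models —
#' and tabulates the exposure-category estimates across widths. The primary
#' analysis is bin width 1; widths 2 and 5 probe robustness of the
#' categorization to coarser time resolution.
#'
#' @param messages,audit_log,roster The three raw tables.
#' @param bin_widths Bin widths in minutes (subset of 1, 2, 5).
#' @param inactivity_threshold EHR inactivity threshold in minutes.
#' @param outcomes Outcomes to fit.
#' @param p_method Passed to [fit_lmm()].
#' @return List with `fits` (nested: `fits[[as.character(width)]][[outcome]]`),
#'   `cohorts` (one per width), and `comparison`, a tibble of
#'   exposure-category estimates and CIs by width and outcome.
#' @export
sensitivity_run <- function(messages, audit_log, roster, bin_widths = c(1, 2, 5),
                            inactivity_threshold = 5,
                            outcomes = c("ehr_time", "n_switches"),
                            p_method = "wald") {
  stopifnot(all(bin_widths %in% c(1, 2, 5)))
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  fits <- list(); cohorts <- list(); rows <- list()
  for (w in bin_widths) {
    cohort <- build_cohort(messages, audit_log, roster, bin_width = w,
                           inactivity_threshold = inactivity_threshold)
    cohorts[[as.character(w)]] <- cohort
    fits[[as.character(w)]] <- list()
    for (oc in outcomes) {
      tab <- fit_lmm(cohort, model_spec(oc), p_method = p_method)
      fits[[as.character(w)]][[oc]] <- tab
      keep <- grepl("^exposure", tab$term)
      rows[[paste(w, oc)]] <- tibble::tibble(
        bin_width = w, outcome = oc,
        term = tab$term[keep], estimate = tab$estimate[keep],
        ci_low = tab$ci_low[keep], ci_high = tab$ci_high[keep]
      )
    }
  }
  list(fits = fits, cohorts = cohorts, comparison = dplyr::bind_rows(rows))
}
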