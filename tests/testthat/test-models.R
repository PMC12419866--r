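metrics_cohort <- function(n_clin = 150, n_days = 10, seed = 1, ...) {
  simulate_study(sim_config(n_clinicians = n_clin, n_days = n_days, seed = seed, ...),
                 level = "metrics")$cohort
}

test_that("the mixed model recovers planted effects on a noiseless event-level cohort", {
  cfg <- sim_config(n_clinicians = 40, n_days = 8, sigma_resid = 0,
                    sigma_clinician = 0, sigma_service = 0,
                    night_shift_fraction = 0, seed = 19)
  sim <- simulate_study(cfg)
  cohort <- build_cohort(sim$messages, sim$audit_log, sim$roster)
  suppressWarnings({
    tab_e <- fit_lmm(cohort, model_spec("ehr_time"), p_method = "wald")
    tab_s <- fit_lmm(cohort, model_spec("n_switches"), p_method = "wald")
  })
  pick <- function(tab, term) tab$estimate[match(term, tab$term)]
  expect_equal(pick(tab_e, "exposureTWO"), 20.3, tolerance = 0.01)
  expect_equal(pick(tab_e, "exposureTHREE"), 38.0, tolerance = 0.01)
  expect_equal(pick(tab_e, "exposureFOUR_PLUS"), 54.8, tolerance = 0.01)
  # switch outcomes are integer-rounded, so allow one switch of slack
  expect_equal(pick(tab_s, "exposureTWO"), 14.5, tolerance = 1)
  expect_equal(pick(tab_s, "exposureTHREE"), 26.7, tolerance = 1)
  expect_equal(pick(tab_s, "exposureFOUR_PLUS"), 41.6, tolerance = 1)
  # zero planted variance components are reported near zero and flagged
  expect_true(attr(tab_e, "singular"))
  expect_lt(attr(tab_e, "varcomp")[["clinician"]], 1)
  expect_true(all(tab_e$ci_low <= tab_e$estimate & tab_e$estimate <= tab_e$ci_high))
})

test_that("with zero random-intercept SDs the mixed fit matches ordinary least squares", {
  cohort <- metrics_cohort(n_clin = 120, n_days = 8, seed = 23,
                           sigma_clinician = 0, sigma_service = 0)
  suppressWarnings(tab <- fit_lmm(cohort, model_spec("ehr_time"), p_method = "wald"))
  od <- cohort[cohort$included, ]
  od$role <- factor(od$role, levels = c("attending", "APP", "trainee"))
  od$sex <- factor(od$sex, levels = c("female", "male"))
  ols <- lm(ehr_time ~ exposure + pct_concurrent_time + msg_volume + patient_load +
              role + age + sex, data = od)
  expect_equal(tab$estimate, unname(coef(ols)[tab$term]), tolerance = 0.05)
})

test_that("adding a constant to the outcome shifts only the intercept", {
  cohort <- metrics_cohort(n_clin = 60, n_days = 6, seed = 29)
  tab1 <- fit_lmm(cohort, model_spec("ehr_time"), p_method = "wald")
  cohort2 <- dplyr::mutate(cohort, ehr_time = ehr_time + 100)
  tab2 <- fit_lmm(cohort2, model_spec("ehr_time"), p_method = "wald")
  i <- match("(Intercept)", tab1$term)
  expect_equal(tab2$estimate[i] - tab1$estimate[i], 100, tolerance = 1e-4)
  expect_equal(tab2$estimate[-i], tab1$estimate[-i], tolerance = 1e-4)
})

test_that("a constant outcome yields zero slopes and a flagged zero residual variance", {
  cohort <- metrics_cohort(n_clin = 20, n_days = 4, seed = 31)
  cohort$ehr_time <- 250
  expect_warning(tab <- fit_lmm(cohort, model_spec("ehr_time")), "constant")
  expect_equal(tab$estimate[tab$term != "(Intercept)"],
               rep(0, sum(tab$term != "(Intercept)")))
  expect_equal(unname(attr(tab, "varcomp")["residual"]), 0)
  expect_true(attr(tab, "singular"))
})

test_that("degenerate designs raise explicit errors naming the problem", {
  cohort <- metrics_cohort(n_clin = 30, n_days = 5, seed = 37)
  one_level <- dplyr::filter(cohort, exposure == "NONE")
  expect_error(fit_lmm(one_level, model_spec("ehr_time")), "exposure")
  one_clin <- dplyr::filter(cohort, clinician_id == cohort$clinician_id[1])
  expect_error(fit_lmm(one_clin, model_spec("ehr_time")), "2 clinicians")
  one_role <- dplyr::filter(cohort, role == "attending")
  expect_error(interaction_test(one_role, model_spec("ehr_time")), "2 roles")
})

test_that("role-stratified fits recover role-specific planted effects", {
  cohort <- metrics_cohort(n_clin = 400, n_days = 10, seed = 43,
                           role_beta_scale = c(attending = 1, APP = 0.7, trainee = 1.5))
  fits <- stratified_fits(cohort, model_spec("ehr_time"), p_method = "wald")
  expect_setequal(names(fits), c("attending", "APP", "trainee"))
  for (r in names(fits)) {
    scale <- c(attending = 1, APP = 0.7, trainee = 1.5)[[r]]
    tab <- fits[[r]]
    expect_false("roleAPP" %in% tab$term)  # role dropped within stratum
    for (term in c(TWO = "exposureTWO", THREE = "exposureTHREE",
                   FOUR_PLUS = "exposureFOUR_PLUS")) {
      i <- match(term, tab$term)
      truth <- 20.3 * scale * c(exposureTWO = 1, exposureTHREE = 38 / 20.3,
                                exposureFOUR_PLUS = 54.8 / 20.3)[[term]]
      expect_gt(tab$ci_high[i], truth - 2 * (tab$ci_high[i] - tab$estimate[i]))
      expect_lt(tab$ci_low[i], truth + 2 * (tab$estimate[i] - tab$ci_low[i]))
    }
  }
  # trainee effects clearly exceed APP effects at these scales
  expect_gt(fits$trainee$estimate[match("exposureFOUR_PLUS", fits$trainee$term)],
            fits$APP$estimate[match("exposureFOUR_PLUS", fits$APP$term)])
})

test_that("stratified fitting tolerates a single-service stratum with a warning", {
  cohort <- metrics_cohort(n_clin = 40, n_days = 6, seed = 47, n_services = 3)
  cohort$service[cohort$role == "trainee"] <- "S01"
  ws <- capture_warnings(
    fits <- stratified_fits(cohort, model_spec("ehr_time"), p_method = "wald"))
  expect_true(any(grepl("service variance fixed at 0", ws)))
  expect_true("trainee" %in% names(fits))
  expect_equal(unname(attr(fits$trainee, "varcomp")["service"]), 0)
})

test_that("the interaction test keeps size under the null and detects role-varying effects", {
  # null: identical betas across roles
  pvals <- vapply(1:25, function(r) {
    cohort <- metrics_cohort(n_clin = 60, n_days = 6, seed = 500 + r)
    suppressWarnings(interaction_test(cohort, model_spec("ehr_time"))$p_value)
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.2)   # 25 replicates: binomial slack around 5%
  expect_gt(mean(pvals), 0.25)          # p-values not collapsed near 0

  # power: trainee betas 1.5x attending at a larger n
  cohort <- metrics_cohort(n_clin = 400, n_days = 10, seed = 61,
                           role_beta_scale = c(attending = 1, APP = 1, trainee = 1.5))
  it <- interaction_test(cohort, model_spec("ehr_time"))
  expect_lt(it$p_value, 0.01)
  expect_true(any(grepl("exposure.*:role", it$effects$term)))
})
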