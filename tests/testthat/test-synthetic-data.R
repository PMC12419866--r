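test_that("roster composition follows the role mix within binomial bounds", {
  cfg <- sim_config(n_clinicians = 1000, seed = 7)
  withr::with_seed(7, r <- generate_roster(cfg))
  counts <- table(r$role)
  for (role in names(cfg$role_mix)) {
    bounds <- qbinom(c(0.0005, 0.9995), 1000, cfg$role_mix[[role]])
    expect_gte(counts[[role]], bounds[1])
    expect_lte(counts[[role]], bounds[2])
  }
  # default missingness fraction: flagged as NA, both fields together
  expect_equal(is.na(r$age), is.na(r$sex))
})

test_that("p_missing_demographics = 0 yields fully observed demographics", {
  cfg <- sim_config(n_clinicians = 300, p_missing_demographics = 0, seed = 3)
  withr::with_seed(3, r <- generate_roster(cfg))
  expect_false(anyNA(r$age))
  expect_false(anyNA(r$sex))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(role_mix = c(attending = 0.6, APP = 0.6, trainee = 0.1)),
               "configuration error")
  expect_error(sim_config(sigma_resid = -1), "configuration error")
  expect_error(sim_config(p_missing_demographics = 1.5), "configuration error")
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_clinicians = 4, n_days = 2, seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$messages, s2$messages)
  expect_identical(s1$audit_log, s2$audit_log)
  expect_identical(s1$roster, s2$roster)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(sim_config(n_clinicians = 4, n_days = 2, seed = 124))
  expect_false(identical(s1$messages, s3$messages))
})

test_that("zero overlap intensity forces every day into the no-concurrency group at all widths", {
  cfg <- sim_config(n_clinicians = 6, n_days = 3, overlap_intensity = 0, seed = 31)
  sim <- simulate_study(cfg)
  for (w in c(1, 2, 5)) {
    summ <- dplyr::bind_rows(lapply(split(sim$messages, sim$messages$clinician_id),
      function(ev) {
        dates <- unique(as.Date(ev$timestamp, tz = TZ))
        dplyr::bind_rows(lapply(dates, function(d) messaging_summary(ev, d, w)))
      }))
    expect_true(all(summ$category == "NONE"))
  }
})

test_that("a zero conversation rate gives an empty messaging day", {
  cfg <- sim_config(conversation_rate = 0, seed = 5)
  withr::with_seed(5, ev <- generate_messaging_day("C1", D0, cfg))
  expect_equal(nrow(ev), 0)
})

test_that("seeded overlapping day agrees with the brute-force concurrency oracle", {
  cfg <- sim_config(overlap_intensity = 0.8, seed = 17)
  withr::with_seed(17, ev <- generate_messaging_day("C1", D0, cfg, n_conversations = 6))
  iv <- conversation_intervals(ev, D0)
  tr <- concurrency_trace(iv, 1)
  expect_equal(tr$n_active, oracle_n_active(iv, tr$bin_start, 1))
  expect_equal(max_concurrent(tr), max(oracle_n_active(iv, tr$bin_start, 1)))
})

test_that("audit day construction hits planted targets exactly at zero noise", {
  cfg <- sim_config(sigma_resid = 0, sigma_clinician = 0, sigma_service = 0,
                    intercepts = c(ehr_time = 300, n_switches = 40),
                    covariate_betas = list(ehr_time = c(msg_volume = 0, patient_load = 0),
                                           n_switches = c(msg_volume = 0, patient_load = 0)),
                    seed = 2)
  withr::with_seed(2, {
    aud <- generate_audit_day("C1", D0,
                              list(category = "NONE", msg_volume = 10, patient_load = 5),
                              cfg)
  })
  expect_equal(ehr_time(aud, D0), 300, tolerance = 1 / 60)
  expect_equal(patient_load(aud, D0), 5L)
  # planted switch target 40 with load 5: exactly 40 within-threshold transitions
  expect_equal(patient_switches(aud, D0), 40L)

  # switch target 0: no qualifying transitions at all
  cfg0 <- sim_config(sigma_resid = 0, sigma_clinician = 0, sigma_service = 0,
                     intercepts = c(ehr_time = 120, n_switches = 0),
                     covariate_betas = list(ehr_time = c(msg_volume = 0, patient_load = 0),
                                            n_switches = c(msg_volume = 0, patient_load = 0)),
                     seed = 2)
  withr::with_seed(2, {
    aud0 <- generate_audit_day("C1", D0,
                               list(category = "NONE", msg_volume = 5, patient_load = 4),
                               cfg0)
  })
  expect_equal(patient_switches(aud0, D0), 0L)
  expect_equal(patient_load(aud0, D0), 4L)
})

test_that("a noiseless batch recovers the planted coefficients by least squares", {
  cfg <- sim_config(n_clinicians = 25, n_days = 8, sigma_resid = 0,
                    sigma_clinician = 0, sigma_service = 0,
                    night_shift_fraction = 0, seed = 41)
  sim <- simulate_study(cfg)
  cohort <- build_cohort(sim$messages, sim$audit_log, sim$roster)
  d_all <- cohort[cohort$included, ]
  # all four planted levels are realized under this seed
  expect_setequal(as.character(unique(d_all$exposure)), EXPOSURE_LEVELS)
  fit <- lm(ehr_time ~ exposure + msg_volume + patient_load, data = d_all)
  est <- coef(fit)
  expect_equal(unname(est["exposureTWO"]), 20.3, tolerance = 0.02)
  expect_equal(unname(est["exposureTHREE"]), 38.0, tolerance = 0.02)
  expect_equal(unname(est["exposureFOUR_PLUS"]), 54.8, tolerance = 0.02)
  expect_equal(unname(est["msg_volume"]), 0.37, tolerance = 0.02)
  expect_equal(unname(est["patient_load"]), 7.0, tolerance = 0.02)
})

test_that("an over-long EHR-time request is clipped with a warning", {
  cfg <- sim_config(sigma_resid = 0, sigma_clinician = 0, sigma_service = 0,
                    intercepts = c(ehr_time = 2000, n_switches = 10), seed = 9)
  withr::with_seed(9, {
    expect_warning(
      aud <- generate_audit_day("C1", D0,
                                list(category = "NONE", msg_volume = 5, patient_load = 3),
                                cfg),
      "clipped")
  })
  expect_lte(ehr_time(aud, D0), 1440)
})

test_that("failure modes produce days failing exactly one inclusion rule", {
  cfg <- sim_config(seed = 12)
  withr::with_seed(12, {
    exp_sum <- list(category = "TWO", msg_volume = 10, patient_load = 4)
    a_note <- generate_audit_day("C1", D0, exp_sum, cfg, failure_mode = "no_note")
    a_ordr <- generate_audit_day("C1", D0, exp_sum, cfg, failure_mode = "no_order")
    a_nght <- generate_audit_day("C1", D0, exp_sum, cfg, failure_mode = "night_shift")
  })
  expect_equal(sum(a_note$action_type == "note_sign"), 0)
  expect_gt(sum(a_note$action_type == "order"), 0)
  expect_equal(sum(a_ordr$action_type == "order"), 0)
  expect_gt(sum(a_ordr$action_type == "note_sign"), 0)
  first_login <- min(a_nght$timestamp[a_nght$action_type == "login"])
  expect_true(is_night_shift(first_login))
})

test_that("written tables round-trip through the readers", {
  cfg <- sim_config(n_clinicians = 3, n_days = 2, seed = 77)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_data(sim, dir)
  msg <- read_messages(paths["messages"])
  aud <- read_audit_log(paths["audit_log"])
  ros <- read_roster(paths["roster"])
  expect_equal(nrow(msg), nrow(sim$messages))
  expect_equal(msg$timestamp, sim$messages$timestamp)
  expect_equal(aud$patient_id, sim$audit_log$patient_id)
  expect_equal(ros$age, sim$roster$age)
  # byte-identical rewrite
  dir2 <- withr::local_tempdir()
  write_sim_data(simulate_study(cfg), dir2)
  expect_identical(readLines(file.path(dir, "messages.csv")),
                   readLines(file.path(dir2, "messages.csv")))
  expect_identical(readLines(file.path(dir, "audit_log.csv")),
                   readLines(file.path(dir2, "audit_log.csv")))
})
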