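two_outcomes <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- c(ehr_time = unname(x), n_switches = unname(x))
  }
  if (!all(c("ehr_time", "n_switches") %in% names(x))) {
    stop(sprintf("configuration error: %s must be named for both outcomes (ehr_time, n_switches)", what),
         call. = FALSE)
  }
  x[c("ehr_time", "n_switches")]
}

#' Configuration for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: roster composition,
#' messaging behaviour, and a planted linear model on the derived metrics
#' (exposure-category effects, covariate effects, crossed random intercepts
#' for clinician and service, residual noise). Defaults are calibrated to
#' the descriptive scale of a large inpatient secure-messaging cohort:
#' roughly half of clinician-days with some concurrency, median messaging
#' volume near 35 messages/day, patient load near 7, EHR time near 300
#' minutes/day and around 100 patient switches/day, with exposure effects of
#' 20.3/38.0/54.8 minutes (EHR time) and 14.5/26.7/41.6 switches for
#' maximum concurrency 2/3/>=4 versus none.
#'
#' @param n_clinicians,n_days Number of clinicians and of calendar days each
#'   clinician works, starting at `start_date`.
#' @param role_mix Named proportions over `attending`, `APP`, `trainee`;
#'   must sum to 1.
#' @param conversation_rate Mean conversation threads per clinician-day
#'   (Poisson).
#' @param msgs_per_conversation Mean message activities per thread
#'   (1 + Poisson).
#' @param overlap_intensity Probability in `[0, 1]` that a clinician-day is
#'   "bursty": on bursty days each new thread starts inside a randomly
#'   chosen earlier thread's interval with probability 0.35 (stacking
#'   concurrency), on focused days — and always when `overlap_intensity`
#'   is 0 — threads are spaced at least 10 minutes apart, so no two thread
#'   intervals of a day can share even a 5-minute bin.
#' @param conv_duration_meanlog,conv_duration_sdlog Log-normal parameters of
#'   thread duration in minutes.
#' @param true_betas Planted additive exposure effects: list with elements
#'   `ehr_time` and `n_switches`, each named `TWO`, `THREE`, `FOUR_PLUS`
#'   (units: minutes; switches), relative to the `NONE` reference.
#' @param intercepts Planted model intercepts, named per outcome.
#' @param covariate_betas Planted effects of `msg_volume` and `patient_load`
#'   per outcome (list of named vectors).
#' @param sigma_resid,sigma_clinician,sigma_service Residual and
#'   random-intercept SDs per outcome (scalars are recycled to both).
#' @param n_services Number of clinical services (login contexts).
#' @param p_missing_demographics Fraction of clinicians with absent age and
#'   sex.
#' @param night_shift_fraction Fraction of clinician-days that are night
#'   shifts (first login placed before 5 AM).
#' @param role_beta_scale Named multipliers (per role) applied to the
#'   exposure betas; all 1 by default. Used for interaction/stratification
#'   experiments.
#' @param category_probs Exposure-category probabilities used by the
#'   metrics-level simulator (`NONE`, `TWO`, `THREE`, `FOUR_PLUS`).
#' @param allow_midnight_span If `TRUE`, conversation threads may run past
#'   midnight (exercises the day-clipping rule); default `FALSE`.
#' @param start_date First study day.
#' @param seed Integer RNG seed; identical configurations give
#'   byte-identical simulations.
#' @return Validated configuration object of class `sim_config`.
#' @export
sim_config <- function(n_clinicians = 60,
                       n_days = 10,
                       role_mix = c(attending = 0.54, APP = 0.27, trainee = 0.19),
                       conversation_rate = 10,
                       msgs_per_conversation = 3.5,
                       overlap_intensity = 0.55,
                       conv_duration_meanlog = log(20),
                       conv_duration_sdlog = 0.9,
                       true_betas = list(
                         ehr_time = c(TWO = 20.3, THREE = 38.0, FOUR_PLUS = 54.8),
                         n_switches = c(TWO = 14.5, THREE = 26.7, FOUR_PLUS = 41.6)),
                       intercepts = c(ehr_time = 200, n_switches = 55),
                       covariate_betas = list(
                         ehr_time = c(msg_volume = 0.37, patient_load = 7.0),
                         n_switches = c(msg_volume = 0.30, patient_load = 3.4)),
                       sigma_resid = c(ehr_time = 60, n_switches = 30),
                       sigma_clinician = c(ehr_time = 40, n_switches = 25),
                       sigma_service = c(ehr_time = 15, n_switches = 10),
                       n_services = 8,
                       p_missing_demographics = 0.01,
                       night_shift_fraction = 0.05,
                       role_beta_scale = c(attending = 1, APP = 1, trainee = 1),
                       category_probs = c(NONE = 0.44, TWO = 0.24,
                                          THREE = 0.14, FOUR_PLUS = 0.18),
                       allow_midnight_span = FALSE,
                       start_date = as.Date("2023-02-01"),
                       seed = 1L) {
  cfg_err <- function(msg) stop(paste("configuration error:", msg), call. = FALSE)
  if (!all(c("attending", "APP", "trainee") %in% names(role_mix)) ||
      any(role_mix < 0) || abs(sum(role_mix) - 1) > 1e-8) {
    cfg_err("role_mix must be non-negative, named over attending/APP/trainee, and sum to 1")
  }
  for (fr in c(overlap_intensity, p_missing_demographics, night_shift_fraction)) {
    if (fr < 0 || fr > 1) cfg_err("fractions must lie in [0, 1]")
  }
  if (n_clinicians < 1 || n_days < 1 || n_services < 1) {
    cfg_err("n_clinicians, n_days and n_services must be >= 1")
  }
  if (conversation_rate < 0) cfg_err("conversation_rate must be >= 0")
  sigma_resid <- two_outcomes(sigma_resid, "sigma_resid")
  sigma_clinician <- two_outcomes(sigma_clinician, "sigma_clinician")
  sigma_service <- two_outcomes(sigma_service, "sigma_service")
  intercepts <- two_outcomes(intercepts, "intercepts")
  if (any(c(sigma_resid, sigma_clinician, sigma_service) < 0)) {
    cfg_err("all SDs must be >= 0")
  }
  for (oc in c("ehr_time", "n_switches")) {
    if (!all(c("TWO", "THREE", "FOUR_PLUS") %in% names(true_betas[[oc]]))) {
      cfg_err(sprintf("true_betas$%s must be named TWO/THREE/FOUR_PLUS", oc))
    }
    if (!all(c("msg_volume", "patient_load") %in% names(covariate_betas[[oc]]))) {
      cfg_err(sprintf("covariate_betas$%s must be named msg_volume/patient_load", oc))
    }
  }
  if (!all(names(role_mix) %in% names(role_beta_scale))) {
    cfg_err("role_beta_scale must cover every role")
  }
  if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0) ||
      !all(EXPOSURE_LEVELS %in% names(category_probs))) {
    cfg_err("category_probs must be a probability vector over the four exposure levels")
  }
  structure(list(
    n_clinicians = as.integer(n_clinicians), n_days = as.integer(n_days),
    role_mix = role_mix, conversation_rate = conversation_rate,
    msgs_per_conversation = msgs_per_conversation,
    overlap_intensity = overlap_intensity,
    conv_duration_meanlog = conv_duration_meanlog,
    conv_duration_sdlog = conv_duration_sdlog,
    true_betas = true_betas, intercepts = intercepts,
    covariate_betas = covariate_betas,
    sigma_resid = sigma_resid, sigma_clinician = sigma_clinician,
    sigma_service = sigma_service, n_services = as.integer(n_services),
    p_missing_demographics = p_missing_demographics,
    night_shift_fraction = night_shift_fraction,
    role_beta_scale = role_beta_scale, category_probs = category_probs,
    allow_midnight_span = allow_midnight_span,
    start_date = as.Date(start_date), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic clinician roster
#'
#' Roles are drawn from `role_mix`; ages and the female fraction are
#' role-typical (trainees younger); a `p_missing_demographics` fraction of
#' clinicians has both age and sex absent (`NA`, flagged, never imputed).
#' Uses the ambient RNG state; [simulate_study()] seeds it from the config.
#'
#' @param config A [sim_config()].
#' @return Tibble `clinician_id`, `role`, `age`, `sex`.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_clinicians
  roles <- sample(names(config$role_mix), n, replace = TRUE, prob = config$role_mix)
  age <- round(ifelse(roles == "trainee", rnorm(n, 30, 2.5),
               ifelse(roles == "APP", rnorm(n, 40, 7), rnorm(n, 43, 8))))
  age <- pmin(pmax(age, 25), 75)
  p_female <- c(attending = 0.42, APP = 0.86, trainee = 0.51)[roles]
  sex <- unname(ifelse(runif(n) < p_female, "female", "male"))
  miss <- runif(n) < config$p_missing_demographics
  age[miss] <- NA
  sex[miss] <- NA
  tibble::tibble(clinician_id = sprintf("C%04d", seq_len(n)),
                 role = roles, age = age, sex = sex)
}

#' Generate one clinician-day of secure-messaging metadata
#'
#' Draws a Poisson number of conversation threads; thread intervals are
#' placed in the working day with overlap structure governed by
#' `overlap_intensity` (a new thread starts inside the previous thread's
#' interval with that probability, otherwise at least 10 minutes after all
#' previous threads end). Each thread carries `1 + Poisson` message
#' activities (sent/read) timestamped to the second; a single-activity
#' thread yields a zero-length active interval. By default threads never
#' span midnight; `allow_midnight_span` in the config lifts the cap.
#'
#' @param clinician_id Clinician identifier.
#' @param date Calendar day.
#' @param config A [sim_config()].
#' @param n_conversations Optional fixed number of threads (overrides the
#'   Poisson draw).
#' @return Message-event tibble (possibly empty).
#' @export
generate_messaging_day <- function(clinician_id, date, config, n_conversations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  date <- as.Date(date)
  empty <- tibble::tibble(conversation_id = character(), clinician_id = character(),
                          direction = character(),
                          timestamp = as.POSIXct(character(), tz = .TZ))
  n_conv <- n_conversations %||% rpois(1, config$conversation_rate)
  if (n_conv == 0) return(empty)
  day_cap <- if (config$allow_midnight_span) Inf else 86340
  dur <- pmin(rlnorm(n_conv, config$conv_duration_meanlog, config$conv_duration_sdlog) * 60,
              8 * 3600)
  start <- end <- numeric(n_conv)
  keep <- rep(TRUE, n_conv)
  start[1] <- runif(1, 7 * 3600, 10 * 3600)
  end[1] <- min(start[1] + dur[1], day_cap)
  # A day is "bursty" with probability overlap_intensity; on bursty days new
  # threads usually start inside a randomly chosen earlier thread's interval,
  # stacking concurrency, while on focused days (and always when
  # overlap_intensity = 0) threads are spaced >= 10 minutes apart, which is
  # disjoint at every supported bin width. Threads that would start past the
  # end of the day are dropped rather than piled onto the cap.
  bursty <- runif(1) < config$overlap_intensity
  if (n_conv > 1) {
    for (j in 2:n_conv) {
      prev <- which(keep[seq_len(j - 1)])
      if (bursty && runif(1) < 0.35) {
        pick <- prev[sample.int(length(prev), 1)]
        start[j] <- runif(1, start[pick], end[pick])
      } else {
        start[j] <- max(end[prev]) + 600 + rexp(1, 1 / 600)
      }
      if (start[j] > day_cap - 60) {
        keep[j] <- FALSE
        start[j] <- start[1]; end[j] <- end[1]  # placeholder, never emitted
        next
      }
      end[j] <- min(start[j] + dur[j], day_cap)
    }
  }
  kept <- which(keep)
  ks <- 1 + rpois(length(kept), max(config$msgs_per_conversation - 1, 0))
  secs <- unlist(lapply(seq_along(kept), function(m) {
    j <- kept[m]; k <- ks[m]
    if (k == 1) start[j] else sort(c(start[j], end[j],
                                     if (k > 2) runif(k - 2, start[j], end[j])))
  }))
  conv <- rep(sprintf("%s-%s-c%02d", clinician_id, format(date), kept), times = ks)
  out <- tibble::tibble(
    conversation_id = conv,
    clinician_id = clinician_id,
    direction = sample(c("sent", "read"), length(secs), replace = TRUE,
                       prob = c(0.45, 0.55)),
    timestamp = instant_at(date, round(secs))
  )
  out[order(out$timestamp, out$conversation_id), ]
}

#' Generate one clinician-day of audit-log events with planted outcomes
#'
#' Targets for the day's EHR time and patient switches are drawn from the
#' planted linear model (intercept + exposure-category effect + covariate
#' effects + supplied clinician and service intercepts + residual), and an
#' event stream is then constructed whose derived metrics hit those targets
#' exactly up to second rounding: inter-event gaps of at most 4 minutes sum
#' to the EHR-time target, patient ids change across exactly the target
#' number of within-threshold transitions, and above-threshold breaks
#' introduce additional patients without switches when the patient load
#' exceeds the switch target. The day includes a first login (placed before
#' 5 AM on night shifts), at least one signed note and one order unless a
#' `failure_mode` suppresses them, and login contexts whose daily mode is
#' the clinician's home service.
#'
#' @param clinician_id Clinician identifier.
#' @param date Calendar day.
#' @param exposure_summary List or one-row tibble with the day's realized
#'   `category`, `msg_volume`, and optionally `patient_load` (drawn as
#'   `2 + Poisson(5)` when absent).
#' @param config A [sim_config()].
#' @param effects Optional list: `b_clinician`, `b_service` (named per
#'   outcome; default 0), `role_scale` (multiplier on the exposure betas),
#'   `home_service` identifier.
#' @param failure_mode One of `"none"`, `"no_note"`, `"no_order"`,
#'   `"night_shift"`; used to construct days that fail a single inclusion
#'   rule.
#' @return Audit-log tibble; attribute `"realized"` holds the constructed
#'   ground truth (`ehr_time`, `n_switches`, `patient_load`, targets and
#'   linear predictors).
#' @export
generate_audit_day <- function(clinician_id, date, exposure_summary, config,
                               effects = list(), failure_mode = "none") {
  stopifnot(inherits(config, "sim_config"))
  failure_mode <- match.arg(failure_mode, c("none", "no_note", "no_order", "night_shift"))
  date <- as.Date(date)
  cat <- as.character(exposure_summary$category)
  V <- exposure_summary$msg_volume
  L <- exposure_summary$patient_load %||% (2 + rpois(1, 5))
  scale <- effects$role_scale %||% 1
  b_cl <- two_outcomes(effects$b_clinician %||% c(ehr_time = 0, n_switches = 0), "b_clinician")
  b_sv <- two_outcomes(effects$b_service %||% c(ehr_time = 0, n_switches = 0), "b_service")
  home <- effects$home_service %||% "S01"

  lin_pred <- function(oc) {
    beta_cat <- if (cat == "NONE") 0 else unname(config$true_betas[[oc]][cat]) * scale
    unname(config$intercepts[oc]) + beta_cat +
      unname(config$covariate_betas[[oc]]["msg_volume"]) * V +
      unname(config$covariate_betas[[oc]]["patient_load"]) * L +
      unname(b_cl[oc]) + unname(b_sv[oc])
  }
  mu_ehr <- lin_pred("ehr_time")
  mu_sw <- lin_pred("n_switches")
  t_ehr <- mu_ehr + rnorm(1, 0, config$sigma_resid["ehr_time"])
  t_sw <- mu_sw + rnorm(1, 0, config$sigma_resid["n_switches"])
  S <- max(0L, as.integer(round(t_sw)))
  if (L < 2) S <- 0L

  night <- failure_mode == "night_shift"
  t0 <- if (night) 1800 + runif(1, 0, 2.5 * 3600) else 6 * 3600 + runif(1, 0, 3 * 3600)
  t0 <- round(t0)
  long_breaks <- max(0L, (L - 1L) - S)
  if (t_ehr > 1440) {
    warning(sprintf("%s %s: requested EHR time %.1f min exceeds 24 h; clipped",
                    clinician_id, format(date), t_ehr), call. = FALSE)
  }
  max_wall <- 86340 - t0 - 360 * long_breaks
  T_sec <- round(min(max(t_ehr, 2), 1440, max_wall / 60) * 60)

  gap <- 240
  n_gap <- T_sec %/% gap
  rem <- T_sec - n_gap * gap
  budget <- c(rep(gap, n_gap), if (rem > 0) rem)

  n_trans <- if (L >= 1) max(S, L - 1L) else 0L
  N <- max(length(budget) + long_breaks, n_trans + 1L, 3L)

  # patient id per segment: first L-1 transitions introduce new patients,
  # later ones bounce between the last two charts
  if (L >= 1) {
    pids <- sprintf("%s-P%03d", clinician_id, seq_len(L))
    seg_pid <- character(n_trans + 1L)
    seg_pid[1] <- pids[1]
    if (n_trans > 0) {
      for (t in seq_len(n_trans)) {
        seg_pid[t + 1L] <- if (t <= L - 1L) pids[t + 1L] else seg_pid[t - 1L]
      }
    }
    long_flag <- rep(FALSE, n_trans)
    if (long_breaks > 0) long_flag[seq_len(long_breaks)] <- TRUE
    nseg <- n_trans + 1L
    sizes <- rep(N %/% nseg, nseg)
    if (N %% nseg > 0) sizes[seq_len(N %% nseg)] <- sizes[seq_len(N %% nseg)] + 1L
    ev_pid <- rep(seg_pid, sizes)
    seg_first <- cumsum(c(1L, sizes[-nseg]))  # attached index starting each segment
  } else {
    ev_pid <- rep(NA_character_, N)
    long_flag <- logical(0)
    seg_first <- integer(0)
  }

  # adjacency slots: slot i is the gap before attached event i (slot 1 is
  # login -> first attached event); long-break transitions get 6 minutes,
  # the EHR-time budget fills the rest, padded with zero gaps
  slot_gap <- numeric(N)
  long_slots <- if (n_trans > 0) seg_first[-1][long_flag] else integer(0)
  slot_gap[long_slots] <- 360
  counted <- setdiff(seq_len(N), long_slots)
  fill <- c(budget, rep(0, length(counted) - length(budget)))
  slot_gap[counted] <- fill
  at <- t0 + cumsum(slot_gap)

  type <- rep("chart_access", N)
  other_idx <- which(seq_len(N) %% 11 == 0)
  type[other_idx] <- "other"
  if (N >= 2) type[2] <- if (failure_mode == "no_note") "chart_access" else "note_sign"
  if (N >= 3) type[3] <- if (failure_mode == "no_order") "chart_access" else "order"

  events <- tibble::tibble(
    clinician_id = clinician_id,
    timestamp = instant_at(date, c(t0, at)),
    action_type = c("login", type),
    patient_id = c(NA_character_, ev_pid),
    login_context = c(home, rep(NA_character_, N))
  )
  # occasional extra login at an existing event time (zero-gap: leaves the
  # derived metrics untouched); exercises modal-context assignment + ties
  if (runif(1) < 0.4 && N >= 2) {
    minority <- runif(1) < 0.4 && config$n_services > 1
    ctx <- if (minority) {
      others <- setdiff(seq_len(config$n_services), as.integer(sub("S", "", home)))
      sprintf("S%02d", others[sample.int(length(others), 1)])
    } else home
    k <- sample(N, 1)
    events <- dplyr::bind_rows(events, tibble::tibble(
      clinician_id = clinician_id, timestamp = instant_at(date, at[k]),
      action_type = "login", patient_id = NA_character_, login_context = ctx))
  }
  events <- dplyr::arrange(events, .data$timestamp)
  attr(events, "realized") <- list(
    ehr_time = T_sec / 60, n_switches = S, patient_load = max(L, 0L),
    target_ehr_time = t_ehr, target_switches = t_sw,
    mu_ehr_time = mu_ehr, mu_switches = mu_sw, night_shift = night
  )
  events
}

#' Simulate a complete synthetic study
#'
#' Two levels of fidelity share one planted model:
#'
#' * `level = "events"` generates the three raw tables (roster, messaging
#'   metadata, audit log) event by event; the clinician-day exposure is
#'   *realized* from the generated messaging via the package's own
#'   concurrency measurement, and audit streams are constructed so the
#'   derived outcomes equal draws from the planted linear model. Running
#'   [build_cohort()] on these tables closes the loop.
#' * `level = "metrics"` draws the derived clinician-day records directly
#'   from the same planted model (exposure category from `category_probs`),
#'   skipping event construction. This is the fast path for Monte-Carlo
#'   parameter-recovery and coverage experiments.
#'
#' @param config A [sim_config()]; `config$seed` fixes all randomness.
#' @param level `"events"` or `"metrics"`.
#' @return Object of class `convoload_sim`: for events level, a list with
#'   `messages`, `audit_log`, `roster`, `truth`, `config`; for metrics
#'   level, `cohort`, `roster`, `truth`, `config`.
#' @export
simulate_study <- function(config, level = c("events", "metrics")) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  set.seed(config$seed)
  roster <- generate_roster(config)
  n <- config$n_clinicians
  services <- sprintf("S%02d", seq_len(config$n_services))
  home_service <- sample(services, n, replace = TRUE)
  b_clin <- cbind(ehr_time = rnorm(n, 0, config$sigma_clinician["ehr_time"]),
                  n_switches = rnorm(n, 0, config$sigma_clinician["n_switches"]))
  b_serv <- cbind(ehr_time = rnorm(config$n_services, 0, config$sigma_service["ehr_time"]),
                  n_switches = rnorm(config$n_services, 0, config$sigma_service["n_switches"]))
  rownames(b_serv) <- services
  dates <- config$start_date + seq_len(config$n_days) - 1

  if (level == "metrics") {
    return(simulate_metrics_level(config, roster, home_service, b_clin, b_serv, dates))
  }

  msg_list <- vector("list", n * config$n_days)
  aud_list <- vector("list", n * config$n_days)
  truth_list <- vector("list", n * config$n_days)
  idx <- 0
  for (i in seq_len(n)) {
    cl <- roster$clinician_id[i]
    scale <- unname(config$role_beta_scale[roster$role[i]])
    eff <- list(b_clinician = b_clin[i, ], b_service = b_serv[home_service[i], ],
                role_scale = scale, home_service = home_service[i])
    for (d in seq_len(config$n_days)) {
      idx <- idx + 1
      night <- runif(1) < config$night_shift_fraction
      msgs <- generate_messaging_day(cl, dates[d], config)
      msum <- messaging_summary(
        if (nrow(msgs)) msgs else tibble::tibble(conversation_id = character(),
                                                 clinician_id = cl,
                                                 direction = character(),
                                                 timestamp = as.POSIXct(character(), tz = .TZ)),
        dates[d])
      pl <- 2 + rpois(1, 5)
      aud <- generate_audit_day(cl, dates[d],
                                list(category = msum$category, msg_volume = msum$msg_volume,
                                     patient_load = pl),
                                config, effects = eff,
                                failure_mode = if (night) "night_shift" else "none")
      rz <- attr(aud, "realized")
      msg_list[[idx]] <- msgs
      aud_list[[idx]] <- aud
      truth_list[[idx]] <- tibble::tibble(
        clinician_id = cl, date = dates[d], role = roster$role[i],
        service = home_service[i], night_shift = rz$night_shift,
        category = as.character(msum$category), msg_volume = msum$msg_volume,
        pct_concurrent_time = msum$pct_concurrent_time,
        patient_load = rz$patient_load,
        mu_ehr_time = rz$mu_ehr_time, mu_switches = rz$mu_switches,
        target_ehr_time = rz$target_ehr_time, target_switches = rz$target_switches,
        planted_ehr_time = rz$ehr_time, planted_switches = rz$n_switches,
        b_clin_ehr = unname(b_clin[i, "ehr_time"]),
        b_clin_sw = unname(b_clin[i, "n_switches"]),
        b_serv_ehr = unname(b_serv[home_service[i], "ehr_time"]),
        b_serv_sw = unname(b_serv[home_service[i], "n_switches"])
      )
    }
  }
  structure(list(messages = dplyr::bind_rows(msg_list),
                 audit_log = dplyr::bind_rows(aud_list),
                 roster = roster,
                 truth = dplyr::bind_rows(truth_list),
                 config = config),
            class = "convoload_sim")
}

simulate_metrics_level <- function(config, roster, home_service, b_clin, b_serv, dates) {
  n <- config$n_clinicians
  nd <- n * config$n_days
  ci <- rep(seq_len(n), each = config$n_days)
  cohort <- tibble::tibble(
    clinician_id = roster$clinician_id[ci],
    date = rep(dates, times = n),
    role = roster$role[ci],
    age = roster$age[ci],
    sex = roster$sex[ci],
    service = home_service[ci]
  )
  category <- sample(EXPOSURE_LEVELS, nd, replace = TRUE,
                     prob = config$category_probs[EXPOSURE_LEVELS])
  msg_volume <- pmax(1, round(rlnorm(nd, log(30), 0.9)))
  pct <- ifelse(category == "NONE", 0, 100 * rbeta(nd, 1.2, 1.8))
  pl <- 2 + rpois(nd, 5)
  scale <- unname(config$role_beta_scale[cohort$role])
  beta_of <- function(oc) {
    b <- config$true_betas[[oc]]
    ifelse(category == "NONE", 0, b[category]) * scale
  }
  mu_ehr <- unname(config$intercepts["ehr_time"]) + beta_of("ehr_time") +
    config$covariate_betas$ehr_time["msg_volume"] * msg_volume +
    config$covariate_betas$ehr_time["patient_load"] * pl +
    b_clin[ci, "ehr_time"] + b_serv[cohort$service, "ehr_time"]
  mu_sw <- unname(config$intercepts["n_switches"]) + beta_of("n_switches") +
    config$covariate_betas$n_switches["msg_volume"] * msg_volume +
    config$covariate_betas$n_switches["patient_load"] * pl +
    b_clin[ci, "n_switches"] + b_serv[cohort$service, "n_switches"]
  y_ehr <- pmin(pmax(mu_ehr + rnorm(nd, 0, config$sigma_resid["ehr_time"]), 2), 1440)
  y_sw <- pmax(0, round(mu_sw + rnorm(nd, 0, config$sigma_resid["n_switches"])))
  has_demo <- !is.na(cohort$age) & !is.na(cohort$sex)
  cohort <- dplyr::mutate(
    cohort,
    included = has_demo,
    exclusion_reason = factor(ifelse(has_demo, "none", "missing_demographics"),
                              levels = EXCLUSION_REASONS),
    exposure = factor(category, levels = EXPOSURE_LEVELS),
    max_concurrent = c(NONE = 1L, TWO = 2L, THREE = 3L, FOUR_PLUS = 5L)[category],
    msg_volume = as.integer(msg_volume),
    total_msg_time = pmin(1440, msg_volume * runif(nd, 2, 8)),
    pct_concurrent_time = pct,
    ehr_time = unname(y_ehr),
    n_switches = as.integer(y_sw),
    patient_load = as.integer(pl)
  )
  truth <- tibble::tibble(
    clinician_id = cohort$clinician_id, date = cohort$date, role = cohort$role,
    service = cohort$service, category = category,
    msg_volume = cohort$msg_volume, pct_concurrent_time = pct,
    patient_load = cohort$patient_load,
    mu_ehr_time = unname(mu_ehr), mu_switches = unname(mu_sw),
    planted_ehr_time = cohort$ehr_time, planted_switches = cohort$n_switches
  )
  structure(list(cohort = cohort, roster = roster, truth = truth, config = config),
            class = "convoload_sim")
}
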