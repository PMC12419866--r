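med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3])
}

#' Descriptive statistics of an analyzable cohort
#'
#' Medians with IQRs of the daily workload metrics and counts with
#' percentages of days per exposure category, per clinician role and
#' overall, plus clinician-level demographic summaries — the standard
#' first table of a clinician-day cohort analysis.
#'
#' @param cohort Clinician-day table; only `included` rows are described.
#' @return List of class `cohort_description` with tibbles `continuous`
#'   (role x variable median/IQR), `exposure` (role x category n and
#'   percent; percentages sum to 100 within role), and `demographics`
#'   (clinician counts, median age, sex distribution per role).
#' @export
describe_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0 || !any(cohort$included)) {
    stop("cannot describe an empty cohort", call. = FALSE)
  }
  d <- cohort[cohort$included, , drop = FALSE]
  d$role <- as.character(d$role)
  groups <- c(split(d, d$role), list(overall = d))
  vars <- c("ehr_time", "n_switches", "patient_load", "msg_volume",
            "total_msg_time", "pct_concurrent_time")
  cont <- dplyr::bind_rows(lapply(names(groups), function(g) {
    gd <- groups[[g]]
    dplyr::bind_rows(lapply(vars, function(v) {
      dplyr::mutate(med_iqr(gd[[v]]), role = g, variable = v, .before = 1)
    }))
  }))
  expo <- dplyr::bind_rows(lapply(names(groups), function(g) {
    gd <- groups[[g]]
    tab <- table(factor(as.character(gd$exposure), levels = EXPOSURE_LEVELS))
    tibble::tibble(role = g, category = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / nrow(gd))
  }))
  demo <- dplyr::bind_rows(lapply(names(groups), function(g) {
    gd <- groups[[g]]
    cl <- gd[!duplicated(gd$clinician_id), , drop = FALSE]
    tibble::tibble(role = g,
                   n_clinicians = nrow(cl),
                   n_days = nrow(gd),
                   age_median = median(cl$age, na.rm = TRUE),
                   n_female = sum(cl$sex == "female", na.rm = TRUE),
                   pct_female = 100 * mean(cl$sex == "female", na.rm = TRUE))
  }))
  structure(list(continuous = cont, exposure = expo, demographics = demo),
            class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat("Cohort description\n\nClinicians:\n")
  print(as.data.frame(x$demographics), row.names = FALSE, digits = 3)
  cat("\nDaily metrics, median (IQR):\n")
  print(as.data.frame(x$continuous), row.names = FALSE, digits = 4)
  cat("\nExposure categories, n (%):\n")
  print(as.data.frame(x$exposure), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Configuration of a full pipeline run
#'
#' Either the three input paths (`messages`, `audit_log`, `roster`) or a
#' [sim_config()] under `sim` must be supplied; with both, the simulation is
#' written to `out_dir` first and then analyzed from those files, which
#' makes a run fully reproducible from its output directory alone.
#'
#' @param out_dir Output directory for all artifacts.
#' @param messages,audit_log,roster Optional input CSV paths.
#' @param sim Optional [sim_config()] to generate inputs.
#' @param bin_width,inactivity_threshold Measurement parameters.
#' @param outcomes Outcomes to model.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, messages = NULL, audit_log = NULL, roster = NULL,
                       sim = NULL, bin_width = 1, inactivity_threshold = 5,
                       outcomes = c("ehr_time", "n_switches")) {
  if (is.null(sim)) {
    for (p in c(messages, audit_log, roster)) {
      if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
    }
    if (is.null(messages) || is.null(audit_log) || is.null(roster)) {
      stop("either supply all three input paths or a sim config", call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, messages = messages, audit_log = audit_log,
                 roster = roster, sim = sim, bin_width = bin_width,
                 inactivity_threshold = inactivity_threshold, outcomes = outcomes),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate and write the raw tables; read and validate
#' inputs; build the cohort; write the cohort, exclusion accounting,
#' descriptive tables and per-outcome effect tables into the output
#' directory, together with the run configuration for provenance. Reruns
#' with an identical configuration (and seed) are byte-identical. Per-stage
#' row counts are logged via `message()`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `cohort`, `description`, `fits` and
#'   the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(config$sim)) {
    sim <- simulate_study(config$sim, level = "events")
    p <- write_sim_data(sim, config$out_dir)
    config$messages <- unname(p["messages"])
    config$audit_log <- unname(p["audit_log"])
    config$roster <- unname(p["roster"])
    paths <- c(paths, p)
    message(sprintf("simulate: %d message events, %d audit events, %d clinicians",
                    nrow(sim$messages), nrow(sim$audit_log), nrow(sim$roster)))
  }
  messages <- read_messages(config$messages)
  audit_log <- read_audit_log(config$audit_log)
  roster <- read_roster(config$roster)
  message(sprintf("read: %d message rows, %d audit rows, %d roster rows",
                  nrow(messages), nrow(audit_log), nrow(roster)))
  cohort <- build_cohort(messages, audit_log, roster,
                         bin_width = config$bin_width,
                         inactivity_threshold = config$inactivity_threshold)
  excl <- exclusion_report(cohort)
  message(sprintf("cohort: %d candidate clinician-days, %d included",
                  excl$total, excl$included))
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  readr::write_csv(dplyr::mutate(cohort, date = format(.data$date)), cohort_path,
                   na = "", progress = FALSE)
  excl_path <- file.path(config$out_dir, "exclusion_report.json")
  jsonlite::write_json(excl, excl_path, auto_unbox = TRUE, pretty = TRUE)
  desc <- describe_cohort(cohort)
  desc_path <- file.path(config$out_dir, "descriptives.csv")
  readr::write_csv(desc$continuous, desc_path, progress = FALSE)
  readr::write_csv(desc$exposure, file.path(config$out_dir, "exposure_distribution.csv"),
                   progress = FALSE)
  fits <- list()
  for (oc in config$outcomes) {
    tab <- fit_lmm(cohort, model_spec(oc))
    fits[[oc]] <- tab
    fit_path <- file.path(config$out_dir, sprintf("effects_%s.csv", oc))
    readr::write_csv(tibble::tibble(term = tab$term, estimate = tab$estimate,
                                    ci_low = tab$ci_low, ci_high = tab$ci_high,
                                    p_value = tab$p_value),
                     fit_path, progress = FALSE)
    meta <- list(outcome = oc, method = attr(tab, "method"),
                 p_method = attr(tab, "p_method"),
                 converged = attr(tab, "converged"),
                 singular = attr(tab, "singular"),
                 n_obs = attr(tab, "n_obs"),
                 n_clinicians = attr(tab, "n_clinicians"),
                 n_services = attr(tab, "n_services"),
                 varcomp = as.list(attr(tab, "varcomp")))
    jsonlite::write_json(meta, file.path(config$out_dir, sprintf("effects_%s_meta.json", oc)),
                         auto_unbox = TRUE, pretty = TRUE)
    message(sprintf("fit %s: %d included days, converged = %s", oc,
                    attr(tab, "n_obs"), attr(tab, "converged")))
    paths <- c(paths, fit_path)
  }
  cfg_out <- config[setdiff(names(config), "sim")]
  cfg_out$sim <- if (!is.null(config$sim)) {
    lapply(unclass(config$sim), function(x) if (inherits(x, "Date")) format(x) else x)
  }
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(cohort = cohort, description = desc, fits = fits,
                 paths = c(paths, cohort = cohort_path, exclusions = excl_path,
                           descriptives = desc_path)))
}
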