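---
title: "Measuring conversational multitasking and its association with EHR workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conversational multitasking and its association with EHR workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Secure messaging lets inpatient clinicians hold several conversations at
once while they work in the electronic health record (EHR). `convoload`
quantifies that *conversational multitasking* from two routinely collected
metadata streams — secure-messaging metadata (conversation id, direction
sent/read, timestamp) and the EHR audit log (one row per click-based
action) — and estimates its association with two daily workload outcomes:
total EHR time and the number of switches between patient charts.

The unit of analysis throughout is the **clinician-day**: one clinician's
activity within one calendar day, timezone-naive local time.

## Exposure: concurrency of active conversations

A conversation is *active* from the first to the last of the clinician's
message activities (sent or read) in that thread on that day. Formally, for
clinician $c$, thread $k$ and day $d$ with activity times
$t_{1} \le \dots \le t_{m}$, the active interval is
$[\min_j t_{j},\ \max_j t_{j}]$. Threads are clipped at midnight: each
calendar day gets its own interval. A single-activity thread yields a
zero-length interval.

The day is tiled with half-open bins $[t, t+w)$ aligned to midnight, with
width $w = 1$ minute in the primary analysis (2 and 5 in sensitivity
analyses). An interval $[s, e)$ is counted in a bin when $s <$ bin end and
$e >$ bin start; a zero-length interval counts in the single bin containing
its instant. The per-bin count of active conversations `n_active` gives:

* **concurrency**: `n_active` when at least 2 threads are active, else 0 —
  a lone open conversation is not multitasking;
* **max_concurrent**: the day's maximum of `n_active`;
* the **exposure category**: `NONE` (maximum 0 or 1), `TWO`, `THREE`, or
  `FOUR_PLUS` ($\ge 4$), with `NONE` the reference group.

Treating the interval end as exclusive for bin intersection is what makes
the canonical three-conversation example (threads active 8:30–11:00,
8:40–10:30, 9:30–11:30) produce the piecewise-constant trace 0 / 2 / 3 /
2 / 0 exactly at the minute boundaries 8:40, 9:30, 10:30 and 11:00; an
end-inclusive rule would double-count the boundary minutes. Zero-length
intervals are still given one bin of attention, on the view that reading a
message occupies the clinician even if no reply follows.

Messaging covariates derive from the same intervals: `msg_volume` counts
the day's sent + read activities; `total_msg_time` is the Lebesgue measure
(minutes) of the *union* of active intervals; `pct_concurrent_time` is the
measure of the set where $\ge 2$ threads are active, divided by the union
time, times 100. Union semantics mean duplicated identical threads do not
double the time. Both measures are computed exactly by a sweep over
interval endpoints, not from the binned trace, so they are unaffected by
bin width.

### A pitfall worth knowing: bin grids do not all nest

Refining the bin grid can only lower the daily maximum, so
`max_concurrent` at width 2 or 5 is $\ge$ its value at width 1. It is
tempting to extend this to "5-minute $\ge$ 2-minute", but that is false:
the 2- and 5-minute grids are not nested in each other (2 does not divide
5), and a zero-length interval sitting near a 5-minute boundary can make
the 2-minute maximum exceed the 5-minute one. The package's property tests
and the sensitivity runner therefore compare coarser widths against the
primary width 1 only.

## Outcomes from the audit log

**EHR time** for a day is the sum of gaps between successive audit-log
actions, excluding gaps above the inactivity threshold (default 5 minutes,
boundary inclusive: a gap of exactly 5 minutes counts). The trailing action
contributes no imputed duration; zero or one action gives 0 minutes.

**Patient switches** count transitions between successive
*patient-attached* actions whose patient ids differ, unless the time
between those two actions exceeds the threshold. Actions without a patient
id are skipped when forming pairs and do not reset the clock — a deliberate
reading of an ambiguous rule, documented here because the alternative
(gap to the immediately preceding action of any kind) gives systematically
fewer switches.

**Patient load** is operationalized as the number of distinct non-missing
patient ids touched that day; the source studies do not pin this down, and
distinct-patients-touched is the simplest definition consistent with the
audit log.

## Cohort rules

A clinician-day is analyzable when the clinician signed at least one note,
placed at least one order, and sent or read at least one message that day;
the day is not a night shift (first EHR login strictly before 5 AM or
strictly after 5 PM; a 17:00:00 login is a day shift); and age and sex are
known. Exclusion reasons are assigned in the fixed order note → order →
message → login-present → night shift → demographics, so each day carries
exactly one reason and the accounting identity
`included + sum(by_reason) = total` holds exactly. A day with activity but
no login at all cannot be classified for shift or service; it is excluded
under its own reason (`no_login`) rather than folded into `night_shift`.

The day's clinical service is the modal login context, with ties broken by
the context whose first login came earliest. Service assignment feeds the
second random intercept of the models.

## The models

For each outcome $y_{cd}$ (EHR minutes, or switches) on clinician $c$'s
day $d$ in service $s(c,d)$:

$$y_{cd} = \beta_0 + \beta_{\text{exp}(cd)} + \gamma^\top x_{cd}
  + u_c + v_{s(c,d)} + \varepsilon_{cd},$$

with exposure category effects $\beta_{\text{TWO}}, \beta_{\text{THREE}},
\beta_{\text{FOUR\_PLUS}}$ relative to `NONE`; covariates $x_{cd}$ =
(percent concurrent time, message volume, patient load, role, age, sex);
and crossed random intercepts $u_c \sim N(0, \sigma^2_{\text{clin}})$,
$v_s \sim N(0, \sigma^2_{\text{serv}})$,
$\varepsilon \sim N(0, \sigma^2)$. The random effects are *crossed*, not
nested, because clinicians work across services. Estimation is REML via
`lme4`/`lmerTest`; 95% CIs are Wald ($\pm 1.96\,\text{SE}$); p-values use
Satterthwaite degrees of freedom by default (`p_method = "wald"` is the
cheap normal approximation used inside simulation loops). The
exposure-by-role interaction is tested by a likelihood-ratio test on ML
refits; when it matters, `stratified_fits()` runs one model per role with
role dropped from the fixed effects. No multiplicity adjustment is applied.
Sex is coded with female as reference; age enters in years, untransformed.

Degenerate inputs are contracts, not crashes: a single observed exposure
level is an explicit error naming the term; a constant outcome returns a
flagged table with zero slopes and zero residual variance; a stratum with
one service drops the service intercept, reports its variance as 0 and
warns; random-intercept variances estimated at the zero boundary are
reported as such with the `singular` flag set.

## The synthetic study generator

Real messaging metadata and audit logs cannot be shared, so the package
carries a generator whose defaults *are* the study conditions used by the
test suite, chosen once from the descriptive scale of a large inpatient
cohort (medians: ~37 messages/day, ~203 min messaging time, ~307 min EHR
time, ~107 switches, patient load ~7, roughly 44/24/14/18% of days in the
four exposure categories, 54/27/19% attending/APP/trainee mix, ~1%
missing demographics):

* **Roster**: roles from `role_mix`; role-typical ages and female
  fractions; a `p_missing_demographics` fraction with age and sex absent.
* **Messaging**: threads per day are Poisson (mean 10) with 1 + Poisson
  activities each; durations are log-normal (median 20 min, sdlog 0.9) — a
  modeling choice, since the marginal duration distribution is not
  published. A day is *bursty* with probability `overlap_intensity`
  (default 0.55): bursty days start new threads inside a randomly chosen
  earlier thread's interval with probability 0.35; focused days space
  threads at least 10 minutes apart, which keeps them disjoint at every
  supported bin width — so `overlap_intensity = 0` forces every day into
  the `NONE` group by construction. Threads that would start past the end
  of the day are dropped rather than piled at midnight (piling would
  manufacture spurious concurrency). Realized defaults land near
  47/24/20/9% across categories with messaging-time median ~237 min.
* **Audit log with planted effects**: effects are planted on the
  *derived-metric scale*. The day's realized exposure category (measured
  from the generated messaging by the package's own trace code) enters a
  linear predictor — intercept + category effect + covariate effects +
  clinician and service intercepts + Gaussian residual — whose draw becomes
  the target EHR time and switch count. The event stream is then
  constructed to hit those targets exactly up to second rounding:
  inter-action gaps of at most 4 minutes sum to the EHR-time target;
  patient ids change across exactly the target number of within-threshold
  transitions; when the drawn patient load exceeds the switch target + 1,
  extra patients are introduced across 6-minute breaks, which add patients
  without adding switches or EHR time. Default planted exposure effects
  are 20.3/38.0/54.8 minutes and 14.5/26.7/41.6 switches — the scale of
  published estimates — with residual SDs of 60 min and 30 switches and
  clinician/service intercept SDs of 40/15 min and 25/10 switches.
* Night-shift days (5% by default) place the first login between 00:30 and
  04:00 — the before-5-AM branch of the rule — so the whole stream stays
  inside the calendar day. `failure_mode` arguments produce days failing
  exactly one inclusion rule, used as filter fixtures.

Because effects are planted on derived metrics, a noiseless configuration
(all SDs 0) must round-trip: pipeline-derived outcomes equal the planted
linear predictor within 1 minute and 1 switch. That is an acceptance test,
not an aspiration. What the generator does *not* emulate: message content,
recipient behavior, realistic census dynamics, within-day autocorrelation
of EHR activity, or real audit-log action-code vocabularies. Passing tests
therefore validate the measurement and inference machinery, not the
epidemiology of any real cohort.

The generator has two fidelity levels sharing one planted model.
`level = "events"` emits the three raw tables and exercises every pipeline
stage. `level = "metrics"` draws clinician-day records directly from the
planted model (categories from `category_probs`), skipping event
construction; it is the Monte-Carlo engine for the recovery experiments,
where 200 replicates of 5000 clinician-days (500 clinicians × 10 days, 8
services) are fitted in a few minutes. The suite verifies < 5% relative
bias and nominal 95% CI coverage (within binomial error at 200 replicates)
for all six planted exposure effects, and the event-level path is held to
the round-trip and bin-width-sensitivity checks at 100–960 clinician-days.

## Numerical and design choices

* Timestamps are handled at 1-second resolution as timezone-naive local
  time (stored as UTC `POSIXct` so arithmetic never crosses DST).
* Gap comparisons are inclusive at the threshold ("exceeding 5 minutes" is
  excluded, 5:00 exactly is kept). Duplicate timestamps contribute
  zero-length gaps; row order never changes any metric.
* `total_msg_time` uses union semantics; the sum-over-threads alternative
  can be obtained from `conversation_intervals()` directly, but union is
  the default and the denominator of `pct_concurrent_time`, whose value is
  0 on days with no messaging time.
* Exposure categorization uses the raw active count (`max_concurrent`), so
  `TWO` genuinely means two simultaneously active threads, while the
  *reported* concurrency of a lone thread is 0.
* In real Clarity-style extracts, "signed a note" and "placed an order"
  map to site-specific action codes; the `action_type` vocabulary
  (`note_sign`, `order`, `login`, `chart_access`, `other`) is the pluggable
  abstraction for that mapping.

## Limitations

Concurrency assumes an open thread occupies attention for its entire
active interval, which likely overstates burden for long-lived threads.
The pipeline measures association, not causation: busy days plausibly
cause both more messaging and more EHR time. The synthetic
parameter-recovery results certify the estimator, not robustness to
violations the generator never produces (non-Gaussian residuals,
informative missingness, exposure measurement error). And `patient_load`
as distinct-patients-touched undercounts panel size on days with little
chart activity.
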