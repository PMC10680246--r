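READING_PERIOD <- c(fbg = "morning", breakfast = "morning",
                    lunch = "afternoon", dinner = "evening",
                    bg_0300 = "night")

#' First-passage day below a glycemic threshold
#'
#' @param readings Numeric vector of one reading per day, day 1 first.
#' @param threshold Target threshold in mmol/L; a reading exactly at the
#'   threshold is not at target (targets are "< threshold").
#' @param start_day First day eligible to count (e.g. 2 for FBG, which
#'   cannot respond before the second day when the basal is first injected
#'   at bedtime of day 1).
#' @return The smallest eligible day with `reading < threshold`, or `NA`
#'   (censored) if none.
#' @examples
#' days_to_target(c(12.1, 9.0, 7.7, 7.0), 7.8)  # 3
#' @export
days_to_target <- function(readings, threshold, start_day = 1L) {
  if (!length(readings)) stop("`readings` must be non-empty")
  hit <- which(readings < threshold & seq_along(readings) >= start_day)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Simulate one patient's inpatient stay under the protocol
#'
#' Couples the virtual-patient glucose model to the dosing engine day by
#' day: each morning the five-point panel's fasting and post-breakfast
#' readings are realized, the 09:00 round classifies any hypoglycemia of
#' the preceding 24 h, reads the governing values (same-day FBG and
#' post-breakfast 2hBG, previous-day post-lunch and post-dinner 2hBG) and
#' issues a titration decision. Lunch and dinner bolus changes take effect
#' the same day, the basal change at that night's injection, and the
#' breakfast change the following morning. The loop stops at `max_days` or
#' one day after all four targets have been reached with an all-hold
#' decision.
#'
#' @param profile A [sample_patient()] virtual patient.
#' @param params The arm's [protocol_params()].
#' @param max_days Maximum days simulated.
#' @param seed Optional integer seed for this patient's noise stream.
#' @param trace If `TRUE`, attach the per-day dose ledger and glucose
#'   panels to the record.
#' @return A `wit2_record` list: `id`, `arm`, `weight`, `days_to_target`
#'   (named over fbg/breakfast/lunch/dinner; `NA` = censored),
#'   `final_units` (administered units/day: basal and the three boluses),
#'   `days_observed`, `hypo` (data frame day/period/bg/level) and, with
#'   `trace`, `ledger` and `panels` data frames.
#' @export
run_patient <- function(profile, params, max_days = 10L, seed = NULL,
                        trace = FALSE) {
  stopifnot(inherits(params, "wit2_protocol"), max_days >= 2L)
  if (!is.null(seed)) set.seed(seed)
  state <- initiate_doses(profile$weight, params)
  latent <- glucose_latent0(profile)
  nd <- as.integer(max_days)

  fbg <- ppg_b <- ppg_l <- ppg_d <- bg03 <- rep(NA_real_, nd)
  adm_basal <- adm_b <- adm_l <- adm_d <- rep(NA_real_, nd)
  pk_basal <- pk_b <- pk_l <- pk_d <- rep(NA_real_, nd)
  reasons <- matrix(NA_character_, nd, 4L,
                    dimnames = list(NULL, INJECTIONS))
  hypo_day <- integer(0); hypo_period <- character(0); hypo_bg <- numeric(0)
  tgt <- c(fbg = NA_integer_, breakfast = NA_integer_,
           lunch = NA_integer_, dinner = NA_integer_)
  basal_prev <- 0       # no basal precedes the first morning
  days_observed <- nd

  for (d in seq_len(nd)) {
    eps <- stats::rnorm(5, 0, profile$noise_sd)
    # morning phase: FBG, pre-breakfast bolus (fixed by yesterday's round),
    # post-breakfast reading; lunch/dinner values provisional
    sim <- sim_day_core(profile, basal_prev, state$bolus, latent, eps)

    # hypoglycemia seen since yesterday's round: last night's 03:00 and this
    # morning's readings, plus yesterday's post-lunch/post-dinner values
    win_bg <- c(sim$bg_0300, sim$fbg, sim$ppg[["breakfast"]])
    win_period <- c("night", "morning", "morning")
    if (d > 1L) {
      win_bg <- c(win_bg, ppg_l[d - 1L], ppg_d[d - 1L])
      win_period <- c(win_period, "afternoon", "evening")
    }
    lv <- classify_hypoglycemia(win_bg)
    hypo24 <- if (any(lv > 0L)) {
      data.frame(period = win_period[lv > 0L], bg = win_bg[lv > 0L],
                 level = lv[lv > 0L])
    } else NULL

    readings <- c(basal = sim$fbg, breakfast = sim$ppg[["breakfast"]],
                  lunch = if (d > 1L) ppg_l[d - 1L] else NA_real_,
                  dinner = if (d > 1L) ppg_d[d - 1L] else NA_real_)
    decision <- decide_titration(state, readings, hypo24, params)
    nxt <- apply_decision(state, decision, params)

    # definitive simulation of the day with the post-round lunch/dinner
    # boluses, reusing the same noise draws
    bolus_today <- c(breakfast = unname(state$bolus["breakfast"]),
                     lunch = unname(nxt$bolus["lunch"]),
                     dinner = unname(nxt$bolus["dinner"]))
    sim <- sim_day_core(profile, basal_prev, bolus_today, latent, eps)
    latent <- sim$latent

    fbg[d] <- sim$fbg; ppg_b[d] <- sim$ppg[["breakfast"]]
    ppg_l[d] <- sim$ppg[["lunch"]]; ppg_d[d] <- sim$ppg[["dinner"]]
    bg03[d] <- sim$bg_0300
    adm_basal[d] <- administered_units(nxt$basal, profile$weight)
    adm_b[d] <- administered_units(bolus_today[["breakfast"]], profile$weight)
    adm_l[d] <- administered_units(bolus_today[["lunch"]], profile$weight)
    adm_d[d] <- administered_units(bolus_today[["dinner"]], profile$weight)
    pk_basal[d] <- nxt$basal; pk_b[d] <- bolus_today[["breakfast"]]
    pk_l[d] <- bolus_today[["lunch"]]; pk_d[d] <- bolus_today[["dinner"]]
    reasons[d, ] <- decision$reason[INJECTIONS]

    # hypoglycemia bookkeeping over the full day's five points
    day_bg <- c(sim$fbg, sim$ppg, sim$bg_0300)
    day_period <- unname(READING_PERIOD[c("fbg", MEALS, "bg_0300")])
    day_lv <- classify_hypoglycemia(day_bg)
    ev <- day_lv > 0L
    if (any(ev)) {
      hypo_day <- c(hypo_day, rep(d, sum(ev)))
      hypo_period <- c(hypo_period, day_period[ev])
      hypo_bg <- c(hypo_bg, day_bg[ev])
    }

    # first-passage endpoints (FBG eligible from day 2)
    if (is.na(tgt["fbg"]) && d >= 2L && sim$fbg < params$fbg_target) {
      tgt["fbg"] <- d
    }
    for (m in MEALS) {
      if (is.na(tgt[m]) && sim$ppg[[m]] < params$ppg_target) tgt[m] <- d
    }

    basal_prev <- nxt$basal   # tonight's bedtime injection
    state <- nxt
    if (!anyNA(tgt) && all(decision$delta == 0)) {
      days_observed <- d
      break
    }
  }

  keep <- seq_len(days_observed)
  rec <- list(
    id = profile$id, arm = params$arm, weight = profile$weight,
    days_to_target = tgt,
    final_units = c(basal = adm_basal[days_observed],
                    breakfast = adm_b[days_observed],
                    lunch = adm_l[days_observed],
                    dinner = adm_d[days_observed]),
    days_observed = days_observed,
    hypo = data.frame(day = hypo_day, period = hypo_period, bg = hypo_bg,
                      level = classify_hypoglycemia(hypo_bg)[seq_along(hypo_bg)])
  )
  if (trace) {
    rec$panels <- data.frame(day = keep, fbg = fbg[keep],
                             ppg_breakfast = ppg_b[keep],
                             ppg_lunch = ppg_l[keep],
                             ppg_dinner = ppg_d[keep],
                             bg_0300 = bg03[keep])
    rec$ledger <- data.frame(day = keep,
                             basal_perkg = pk_basal[keep],
                             bolus_breakfast_perkg = pk_b[keep],
                             bolus_lunch_perkg = pk_l[keep],
                             bolus_dinner_perkg = pk_d[keep],
                             basal_units = adm_basal[keep],
                             bolus_breakfast_units = adm_b[keep],
                             bolus_lunch_units = adm_l[keep],
                             bolus_dinner_units = adm_d[keep],
                             reason_basal = reasons[keep, "basal"],
                             reason_breakfast = reasons[keep, "breakfast"],
                             reason_lunch = reasons[keep, "lunch"],
                             reason_dinner = reasons[keep, "dinner"])
  }
  structure(rec, class = "wit2_record")
}

#' Run the full two-arm in-silico trial
#'
#' Samples one virtual cohort, assigns patients 1:1 to the 1:1.5 and 1:1
#' protocol arms by a seeded random permutation of the exact arm-label
#' multiset, runs every patient through [run_patient()], and collects
#' per-patient endpoints. Fully reproducible: the assignment, each
#' patient's profile and each patient's noise stream are all derived from
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Trial seed; defaults to `config$seed`.
#' @param n_arms Optional length-2 integer vector overriding the per-arm
#'   sizes (e.g. `c(89, 93)`); defaults to `n_per_arm` each.
#' @param hypo_action,bolus_stop Passed to [protocol_params()] for both
#'   arms.
#' @return A `wit2_trial` list: `records` (one row per patient: arm,
#'   weight, days-to-target per reading with `NA` for censored, final
#'   administered units/day, days observed), `hypo` (one row per
#'   hypoglycemic reading: id, arm, day, period, bg, level) and `meta`
#'   (seed, arm sizes, config hash, package version).
#' @export
run_trial <- function(config, seed = NULL, n_arms = NULL,
                      hypo_action = "reduce", bolus_stop = "suspend") {
  stopifnot(inherits(config, "wit2_cohort_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  if (is.null(n_arms)) n_arms <- rep(config$n_per_arm, 2L)
  stopifnot(length(n_arms) == 2L, all(n_arms >= 1L))
  arms <- c("1:1.5", "1:1")
  params <- lapply(arms, protocol_params,
                   hypo_action = hypo_action, bolus_stop = bolus_stop)
  names(params) <- arms

  cfg <- config; cfg$seed <- seed
  n <- sum(n_arms)
  set.seed(seed)
  assignment <- sample(rep(arms, n_arms))
  ids <- sprintf("P%04d", seq_len(n))

  rows <- vector("list", n)
  hypo <- vector("list", n)
  for (i in seq_len(n)) {
    profile <- sample_patient(cfg, ids[i])
    rec <- run_patient(profile, params[[assignment[i]]],
                       max_days = cfg$max_days,
                       seed = patient_seed(seed, paste0(ids[i], "/sim")))
    rows[[i]] <- data.frame(
      id = rec$id, arm = rec$arm, weight = rec$weight,
      days_fbg = rec$days_to_target[["fbg"]],
      days_breakfast = rec$days_to_target[["breakfast"]],
      days_lunch = rec$days_to_target[["lunch"]],
      days_dinner = rec$days_to_target[["dinner"]],
      final_basal_units = rec$final_units[["basal"]],
      final_breakfast_units = rec$final_units[["breakfast"]],
      final_lunch_units = rec$final_units[["lunch"]],
      final_dinner_units = rec$final_units[["dinner"]],
      days_observed = rec$days_observed
    )
    if (nrow(rec$hypo)) {
      hypo[[i]] <- cbind(id = rec$id, arm = rec$arm, rec$hypo)
    }
  }
  records <- do.call(rbind, rows)
  hypo <- do.call(rbind, hypo[!vapply(hypo, is.null, logical(1))])
  if (is.null(hypo)) {
    hypo <- data.frame(id = character(0), arm = character(0),
                       day = integer(0), period = character(0),
                       bg = numeric(0), level = integer(0))
  }
  structure(
    list(records = records, hypo = hypo,
         meta = list(seed = seed, n_arms = stats::setNames(n_arms, arms),
                     n_randomized = n, n_analyzed = n,
                     config_hash = config_hash(cfg),
                     version = as.character(utils::packageVersion("wit2sim")))),
    class = "wit2_trial"
  )
}

# order-stable hash of the configuration list (hex string)
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.wit2_trial <- function(x, ...) {
  cat(sprintf("In-silico WIT2 trial: %d patients (%s), seed %d\n",
              x$meta$n_randomized,
              paste(sprintf("%s n=%d", names(x$meta$n_arms), x$meta$n_arms),
                    collapse = ", "),
              x$meta$seed))
  cat(sprintf("  %d hypoglycemic readings in %d patients\n",
              nrow(x$hypo), length(unique(x$hypo$id))))
  invisible(x)
}

#' Patients with hypoglycemia by period and level
#'
#' Aggregates hypoglycemic readings into the trial's reporting unit: per
#' arm, time-of-day period (morning 06:30-12:00, afternoon 12:00-17:30,
#' evening 17:30-23:00, night 23:00-06:30) and level, the number of
#' patients with at least one event — a patient counts once per
#' (period, level) and once in the combined `"any"` row, matching the
#' "n/N (%)" patient-denominator style of inpatient trial reports.
#'
#' @param trial A `wit2_trial`, or a data frame of events with columns
#'   `id`, `arm`, `period`, `level`.
#' @param n_by_arm Named vector of per-arm denominators; taken from the
#'   trial metadata when a `wit2_trial` is given.
#' @return Data frame: `arm`, `period`, `level` (`"1"`, `"2"`, `"3"`,
#'   `"any"`), `n_patients`, `n_arm`, `pct` (percent of arm, one decimal).
#' @export
hypo_by_period <- function(trial, n_by_arm = NULL) {
  if (inherits(trial, "wit2_trial")) {
    events <- trial$hypo
    if (is.null(n_by_arm)) n_by_arm <- trial$meta$n_arms
  } else {
    events <- trial
    if (is.null(n_by_arm)) stop("`n_by_arm` is required with raw event data")
  }
  arms <- names(n_by_arm)
  out <- expand.grid(arm = arms, period = PERIODS,
                     level = c("1", "2", "3", "any"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  count <- function(arm, period, level) {
    sel <- events$arm == arm & events$period == period
    if (level != "any") sel <- sel & events$level == as.integer(level)
    length(unique(events$id[sel]))
  }
  out$n_patients <- mapply(count, out$arm, out$period, out$level)
  out$n_arm <- as.integer(n_by_arm[out$arm])
  out$pct <- round(100 * out$n_patients / out$n_arm, 1)
  out[order(out$arm, match(out$period, PERIODS), out$level), ]
}
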