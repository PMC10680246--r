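MEALS <- c("breakfast", "lunch", "dinner")
INJECTIONS <- c("basal", MEALS)
PERIODS <- c("morning", "afternoon", "evening", "night")

#' Protocol parameter set for one trial arm
#'
#' Returns the complete weight-based rule set of the WIT2 algorithm for one
#' of the two basal:bolus ratio arms. The 1:1.5 arm starts at a total daily
#' dose (TDD) of 0.5 units/kg (0.2 basal + 0.3 bolus) and titrates the basal
#' by 0.1 units/kg/day and each meal bolus by 0.05 units/kg/day; the 1:1 arm
#' starts at 0.4 units/kg (0.2 + 0.2) and titrates the basal by 0.1 and each
#' meal bolus by 0.1/3 units/kg/day. Hypoglycemia decrements mirror the
#' increments. Glycemic targets are fasting blood glucose (FBG) < 7.8 mmol/L
#' and 2-h postprandial glucose (2hBG) < 10.0 mmol/L in both arms.
#'
#' @param arm Arm label, `"1:1.5"` or `"1:1"` (basal:bolus ratio).
#' @param hypo_action What a hypoglycemic event in the preceding 24 h does to
#'   the attributed injection: `"reduce"` (apply the printed decrement, the
#'   default) or `"hold"` (suspend titration without reducing).
#' @param bolus_stop Once a meal's 2hBG is on target: `"suspend"` (titration
#'   may resume if the reading later rises above target, the default) or
#'   `"permanent"` (that meal's bolus is never escalated again).
#' @param tdd_ceiling Safety ceiling on total per-kg daily dose
#'   (units/kg/day). Escalation beyond it is clamped with a warning; the
#'   default 3.0 is far above doses reachable in a normal inpatient stay.
#'
#' @return An object of class `wit2_protocol`: a list with the arm label,
#'   per-kg initiation doses (`tdd_init`, `basal_init`, `bolus_init_total`),
#'   per-kg daily increments and decrements (`basal_increment`,
#'   `bolus_increment_meal`, `basal_decrement`, `bolus_decrement_meal`),
#'   targets (`fbg_target`, `ppg_target`, mmol/L) and the behaviour switches.
#' @examples
#' protocol_params("1:1.5")$tdd_init        # 0.5 units/kg
#' protocol_params("1:1")$bolus_init_total  # 0.2 units/kg, 1/3 per meal
#' @export
protocol_params <- function(arm = c("1:1.5", "1:1"),
                            hypo_action = c("reduce", "hold"),
                            bolus_stop = c("suspend", "permanent"),
                            tdd_ceiling = 3.0) {
  arm <- match.arg(arm)
  hypo_action <- match.arg(hypo_action)
  bolus_stop <- match.arg(bolus_stop)
  p <- if (arm == "1:1.5") {
    list(
      arm = arm,
      tdd_init = 0.5,
      basal_init = 0.2,
      bolus_init_total = 0.3,
      basal_increment = 0.1,
      bolus_increment_meal = 0.05,
      basal_decrement = 0.1,
      bolus_decrement_meal = 0.05
    )
  } else {
    list(
      arm = arm,
      tdd_init = 0.4,
      basal_init = 0.2,
      bolus_init_total = 0.2,
      basal_increment = 0.1,
      bolus_increment_meal = 0.1 / 3,
      basal_decrement = 0.1,
      bolus_decrement_meal = 0.1 / 3
    )
  }
  p$fbg_target <- 7.8
  p$ppg_target <- 10.0
  p$hypo_action <- hypo_action
  p$bolus_stop <- bolus_stop
  p$tdd_ceiling <- tdd_ceiling
  structure(p, class = "wit2_protocol")
}

#' @export
print.wit2_protocol <- function(x, ...) {
  cat("WIT2 protocol, basal:bolus arm ", x$arm, "\n", sep = "")
  cat(sprintf("  initiation : TDD %.2f U/kg = basal %.2f + bolus %.4g U/kg\n",
              x$tdd_init, x$basal_init, x$bolus_init_total))
  cat(sprintf("  titration  : basal +%.2f, each meal +%.4g U/kg/day\n",
              x$basal_increment, x$bolus_increment_meal))
  cat(sprintf("  hypoglycemia: basal -%.2f, meal -%.4g U/kg (%s)\n",
              x$basal_decrement, x$bolus_decrement_meal, x$hypo_action))
  cat(sprintf("  targets    : FBG < %.1f, 2hBG < %.1f mmol/L\n",
              x$fbg_target, x$ppg_target))
  invisible(x)
}

#' Initiate the per-kg dose ledger for a patient
#'
#' Day-1 doses: the basal analogue (glargine) as a single bedtime dose of
#' `basal_init` units/kg and the rapid analogue (aspart) as the bolus total
#' divided into three equal pre-meal parts.
#'
#' @param weight Body weight in kg (> 0).
#' @param params A [protocol_params()] object.
#' @return A `wit2_dose_state`: list with `day` (1), `weight`, `basal`
#'   (units/kg) and `bolus` (named units/kg vector over breakfast, lunch,
#'   dinner), plus the per-meal escalation lockout flags used when
#'   `bolus_stop = "permanent"`.
#' @examples
#' st <- initiate_doses(70, protocol_params("1:1.5"))
#' administered_units(st$basal, st$weight)              # 14 U glargine
#' administered_units(st$bolus[["breakfast"]], st$weight) # 7 U aspart
#' @export
initiate_doses <- function(weight, params) {
  stopifnot(inherits(params, "wit2_protocol"))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("`weight` must be a single positive number (kg)")
  }
  structure(
    list(
      day = 1L,
      weight = weight,
      basal = params$basal_init,
      bolus = stats::setNames(rep(params$bolus_init_total / 3, 3L), MEALS),
      locked = stats::setNames(rep(FALSE, 3L), MEALS)
    ),
    class = "wit2_dose_state"
  )
}

#' @export
print.wit2_dose_state <- function(x, ...) {
  cat(sprintf("Dose state day %d (%.1f kg)\n", x$day, x$weight))
  cat(sprintf("  basal %.4g U/kg (%d U)\n", x$basal,
              administered_units(x$basal, x$weight)))
  for (m in MEALS) {
    cat(sprintf("  %-9s %.4g U/kg (%d U)\n", m, x$bolus[[m]],
                administered_units(x$bolus[[m]], x$weight)))
  }
  invisible(x)
}

#' Whole-unit dose actually injected
#'
#' The titration ledger is kept in exact units/kg; discretization to whole
#' pen units happens only at administration, so rounding never compounds
#' across titration days. Rounding is to the nearest unit with halves away
#' from zero.
#'
#' @param per_kg Dose in units/kg (>= 0); vectorized.
#' @param weight Body weight in kg.
#' @param mode `"nearest"` (whole units, default) or `"exact"` (unrounded
#'   product, for analysis).
#' @return Administered dose in units.
#' @examples
#' administered_units(0.1, 66.8)  # 7
#' @export
administered_units <- function(per_kg, weight, mode = c("nearest", "exact")) {
  mode <- match.arg(mode)
  stopifnot(all(per_kg >= 0), weight > 0)
  u <- per_kg * weight
  if (mode == "exact") u else floor(u + 0.5)
}

#' Governing readings for a titration day
#'
#' The 09:00 round titrates each injection on a specific reading: the basal
#' on the same day's FBG, the breakfast bolus on the same day's 2hBG after
#' breakfast, and the lunch and dinner boluses on the previous day's 2hBG
#' after lunch and dinner (those readings post-date the round on their own
#' day). Readings that do not exist (e.g. lunch/dinner on day 1) are `NA`.
#'
#' @param panels A glucose-panel data frame with columns `day`, `fbg`,
#'   `ppg_breakfast`, `ppg_lunch`, `ppg_dinner` (and optionally `bg_0300`),
#'   one row per day, in mmol/L.
#' @param day Titration day (>= 1).
#' @return Named numeric vector over `basal`, `breakfast`, `lunch`,
#'   `dinner`; `NA` marks an absent reading.
#' @export
governing_readings <- function(panels, day) {
  if (!is.numeric(day) || length(day) != 1L || day < 1) {
    stop("`day` must be a single integer >= 1")
  }
  need <- c("day", "fbg", "ppg_breakfast", "ppg_lunch", "ppg_dinner")
  missing_cols <- setdiff(need, names(panels))
  if (length(missing_cols)) {
    stop("panel data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  pick <- function(d, col) {
    i <- which(panels$day == d)
    if (length(i)) panels[[col]][i[1L]] else NA_real_
  }
  c(
    basal = pick(day, "fbg"),
    breakfast = pick(day, "ppg_breakfast"),
    lunch = pick(day - 1L, "ppg_lunch"),
    dinner = pick(day - 1L, "ppg_dinner")
  )
}

#' Classify a blood glucose reading as a hypoglycemia level
#'
#' Level 1: 3.0 <= BG < 3.9 mmol/L; level 2: BG < 3.0 mmol/L; level 3: any
#' event requiring third-party assistance, regardless of the measured value.
#' Readings at or above 3.9 mmol/L are not events (level 0).
#'
#' @param bg Blood glucose in mmol/L (> 0); vectorized.
#' @param assisted Whether the event required assistance from another person
#'   (recycled along `bg`).
#' @return Integer level(s) 0, 1, 2 or 3.
#' @examples
#' classify_hypoglycemia(c(3.5, 2.9, 3.9))  # 1 2 0
#' @export
classify_hypoglycemia <- function(bg, assisted = FALSE) {
  stopifnot(is.numeric(bg), all(bg > 0))
  assisted <- rep_len(as.logical(assisted), length(bg))
  lvl <- ifelse(bg < 3.0, 2L, ifelse(bg < 3.9, 1L, 0L))
  lvl[assisted] <- 3L
  as.integer(lvl)
}

#' Map a hypoglycemia period to the injection whose titration it holds
#'
#' Period boundaries follow the trial's clock: morning 06:30-12:00,
#' afternoon 12:00-17:30, evening 17:30-23:00, night 23:00-06:30. The
#' temporally proximate insulin is held/reduced: night events map to the
#' bedtime basal, daytime events to the preceding meal's bolus.
#'
#' @param period `"morning"`, `"afternoon"`, `"evening"` or `"night"`
#'   (vectorized).
#' @return Injection key(s): `"basal"`, `"breakfast"`, `"lunch"` or
#'   `"dinner"`.
#' @export
attribute_hypo <- function(period) {
  map <- c(night = "basal", morning = "breakfast",
           afternoon = "lunch", evening = "dinner")
  bad <- setdiff(unique(period), names(map))
  if (length(bad)) stop("unknown period(s): ", paste(bad, collapse = ", "))
  unname(map[period])
}

#' Daily titration decision
#'
#' For each of the four injections, in priority order: (1) a hypoglycemic
#' event attributed to the injection in the preceding 24 h triggers the
#' printed per-kg decrement (or a hold, under `hypo_action = "hold"`);
#' (2) an absent governing reading holds the dose; (3) a governing reading
#' at or above its target (7.8 mmol/L FBG for the basal, 10.0 mmol/L 2hBG
#' for a meal bolus) triggers the printed per-kg increment; (4) otherwise
#' the dose is held. A reading exactly at the threshold counts as above
#' target, matching the "< 7.8 mmol/L" target definition. Under the default
#' `bolus_stop = "suspend"` a held meal bolus resumes escalating if its
#' reading later rises above target.
#'
#' @param state A `wit2_dose_state` for the decision day.
#' @param readings Governing readings from [governing_readings()].
#' @param hypo_events Hypoglycemic events of the preceding 24 h: a data
#'   frame with at least a `period` column (see [attribute_hypo()]), or
#'   `NULL`/zero rows for none.
#' @param params The arm's [protocol_params()].
#' @return A `wit2_decision`: list with `day`, signed per-kg `delta` and
#'   `reason` (both named over basal/breakfast/lunch/dinner). Reasons are
#'   `HYPO_DOWN`, `NO_READING_HOLD`, `ABOVE_TARGET_UP`, `AT_TARGET_HOLD`.
#' @export
decide_titration <- function(state, readings, hypo_events, params) {
  stopifnot(inherits(state, "wit2_dose_state"),
            inherits(params, "wit2_protocol"))
  if (!all(INJECTIONS %in% names(readings))) {
    stop("`readings` must be named over basal, breakfast, lunch, dinner")
  }
  hypo_inj <- character(0)
  if (!is.null(hypo_events) && NROW(hypo_events) > 0L) {
    hypo_inj <- unique(attribute_hypo(hypo_events$period))
  }
  delta <- stats::setNames(numeric(4L), INJECTIONS)
  reason <- stats::setNames(character(4L), INJECTIONS)
  for (inj in INJECTIONS) {
    r <- readings[[inj]]
    if (inj %in% hypo_inj) {
      dec <- if (inj == "basal") params$basal_decrement else params$bolus_decrement_meal
      delta[inj] <- if (params$hypo_action == "reduce") -dec else 0
      reason[inj] <- "HYPO_DOWN"
    } else if (is.na(r)) {
      reason[inj] <- "NO_READING_HOLD"
    } else if (inj == "basal" && r >= params$fbg_target) {
      delta[inj] <- params$basal_increment
      reason[inj] <- "ABOVE_TARGET_UP"
    } else if (inj != "basal" && r >= params$ppg_target) {
      if (params$bolus_stop == "permanent" && isTRUE(state$locked[[inj]])) {
        reason[inj] <- "AT_TARGET_HOLD"
      } else {
        delta[inj] <- params$bolus_increment_meal
        reason[inj] <- "ABOVE_TARGET_UP"
      }
    } else {
      reason[inj] <- "AT_TARGET_HOLD"
    }
  }
  structure(list(day = state$day, delta = delta, reason = reason),
            class = "wit2_decision")
}

#' Replay the protocol over a patient's recorded glucose panels
#'
#' Reconstructs the dose ledger of a real (or recorded) patient from their
#' glucose-panel history alone: starting from the initiation doses, each
#' day's 09:00 round is replayed — hypoglycemia of the preceding 24 h is
#' classified from the recorded readings (03:00 and fasting/post-breakfast
#' of the same morning, post-lunch/post-dinner of the previous day, plus
#' any symptomatic extra readings), the governing readings are looked up
#' and the titration applied — yielding the doses for the following day.
#'
#' @param weight Body weight, kg.
#' @param params The arm's [protocol_params()].
#' @param panels Glucose-panel data frame (see [read_glucose_panels()]);
#'   may have zero rows, in which case the initiation doses are returned.
#' @param through_day Last day whose round is replayed; defaults to the
#'   last recorded day.
#' @param extra_events Optional data frame of symptomatic readings with
#'   columns `day`, `period`, `bg` and optionally `assisted`; night/morning
#'   extras enter the same day's round, afternoon/evening extras the next
#'   day's.
#' @return List: `state` (the `wit2_dose_state` for day `through_day + 1`),
#'   `next_doses` (administered whole units for that day) and `ledger`
#'   (one row per replayed day: per-kg doses, administered units, reasons).
#' @export
replay_protocol <- function(weight, params, panels,
                            through_day = NULL, extra_events = NULL) {
  state <- initiate_doses(weight, params)
  if (is.null(through_day)) {
    through_day <- if (NROW(panels)) max(panels$day) else 0L
  }
  rows <- vector("list", through_day)
  if (!is.null(extra_events) && is.null(extra_events$assisted)) {
    extra_events$assisted <- FALSE
  }
  for (d in seq_len(through_day)) {
    pick <- function(day, col) {
      i <- which(panels$day == day)
      if (length(i)) panels[[col]][i[1L]] else NA_real_
    }
    win_bg <- c(pick(d, "bg_0300"), pick(d, "fbg"), pick(d, "ppg_breakfast"),
                pick(d - 1L, "ppg_lunch"), pick(d - 1L, "ppg_dinner"))
    win_period <- c("night", "morning", "morning", "afternoon", "evening")
    win_assist <- rep(FALSE, 5L)
    if (!is.null(extra_events) && NROW(extra_events)) {
      same <- extra_events$day == d &
        extra_events$period %in% c("night", "morning")
      prev <- extra_events$day == d - 1L &
        extra_events$period %in% c("afternoon", "evening")
      sel <- same | prev
      win_bg <- c(win_bg, extra_events$bg[sel])
      win_period <- c(win_period, extra_events$period[sel])
      win_assist <- c(win_assist, as.logical(extra_events$assisted[sel]))
    }
    keep <- !is.na(win_bg)
    lv <- classify_hypoglycemia(win_bg[keep], win_assist[keep])
    hypo24 <- if (any(lv > 0L)) {
      data.frame(period = win_period[keep][lv > 0L],
                 bg = win_bg[keep][lv > 0L], level = lv[lv > 0L])
    } else NULL
    decision <- decide_titration(state, governing_readings(panels, d),
                                 hypo24, params)
    nxt <- apply_decision(state, decision, params)
    rows[[d]] <- data.frame(
      day = d,
      basal_perkg = nxt$basal,             # effective at this night's dose
      bolus_breakfast_perkg = state$bolus[["breakfast"]],
      bolus_lunch_perkg = nxt$bolus[["lunch"]],
      bolus_dinner_perkg = nxt$bolus[["dinner"]],
      basal_units = administered_units(nxt$basal, weight),
      bolus_breakfast_units = administered_units(state$bolus[["breakfast"]], weight),
      bolus_lunch_units = administered_units(nxt$bolus[["lunch"]], weight),
      bolus_dinner_units = administered_units(nxt$bolus[["dinner"]], weight),
      reason_basal = decision$reason[["basal"]],
      reason_breakfast = decision$reason[["breakfast"]],
      reason_lunch = decision$reason[["lunch"]],
      reason_dinner = decision$reason[["dinner"]],
      row.names = NULL
    )
    state <- nxt
  }
  list(
    state = state,
    next_doses = c(
      basal = administered_units(state$basal, weight),
      breakfast = administered_units(state$bolus[["breakfast"]], weight),
      lunch = administered_units(state$bolus[["lunch"]], weight),
      dinner = administered_units(state$bolus[["dinner"]], weight)
    ),
    ledger = if (through_day) do.call(rbind, rows) else NULL
  )
}

#' Apply a titration decision to the dose ledger
#'
#' Returns the next day's per-kg ledger: each injection's dose moves by its
#' decision delta, clamped at zero. Timing of effect (handled by the trial
#' day loop, not the ledger): the basal delta takes effect at that night's
#' bedtime injection, lunch/dinner deltas the same day, and the breakfast
#' delta the following morning — the 09:00 round post-dates that morning's
#' pre-breakfast injection. If the summed per-kg TDD would exceed the
#' protocol's safety ceiling, positive deltas are scaled back to the
#' ceiling with a warning.
#'
#' @param state The `wit2_dose_state` the decision refers to.
#' @param decision The matching [decide_titration()] result.
#' @param params The arm's [protocol_params()] (for the ceiling and the
#'   permanent-lockout bookkeeping).
#' @return The next-day `wit2_dose_state`.
#' @export
apply_decision <- function(state, decision, params = NULL) {
  stopifnot(inherits(state, "wit2_dose_state"),
            inherits(decision, "wit2_decision"))
  if (decision$day != state$day) {
    stop(sprintf("decision is for day %d but state is day %d",
                 decision$day, state$day))
  }
  delta <- decision$delta
  ceiling_tdd <- if (is.null(params)) 3.0 else params$tdd_ceiling
  old <- c(basal = state$basal, state$bolus)
  new <- pmax(old + delta[names(old)], 0)
  if (sum(new) > ceiling_tdd) {
    pos <- pmax(delta[names(old)], 0)
    headroom <- max(ceiling_tdd - sum(pmax(old + pmin(delta[names(old)], 0), 0)), 0)
    scale <- if (sum(pos) > 0) min(headroom / sum(pos), 1) else 0
    new <- pmax(old + pmin(delta[names(old)], 0) + scale * pos, 0)
    warning(sprintf("per-kg TDD ceiling %.2f U/kg reached on day %d; escalation clamped",
                    ceiling_tdd, state$day))
  }
  locked <- state$locked
  if (!is.null(params) && params$bolus_stop == "permanent") {
    locked <- locked | (decision$reason[MEALS] == "AT_TARGET_HOLD")
  }
  structure(
    list(
      day = state$day + 1L,
      weight = state$weight,
      basal = unname(new["basal"]),
      bolus = new[MEALS],
      locked = locked
    ),
    class = "wit2_dose_state"
  )
}
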