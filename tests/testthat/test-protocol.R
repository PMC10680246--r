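test_that("each arm's parameter set carries the printed per-kg rules", {
  a <- protocol_params("1:1.5")
  expect_equal(a$tdd_init, 0.5)
  expect_equal(a$basal_init, 0.2)
  expect_equal(a$bolus_init_total, 0.3)
  expect_equal(a$basal_increment, 0.1)
  expect_equal(a$bolus_increment_meal, 0.05)
  expect_equal(a$basal_decrement, 0.1)
  expect_equal(a$bolus_decrement_meal, 0.05)
  expect_equal(a$bolus_init_total / a$basal_init, 1.5)

  b <- protocol_params("1:1")
  expect_equal(b$tdd_init, 0.4)
  expect_equal(b$basal_init, 0.2)
  expect_equal(b$bolus_init_total, 0.2)
  expect_equal(b$bolus_increment_meal, 0.1 / 3)
  expect_equal(b$bolus_init_total / b$basal_init, 1.0)

  for (p in list(a, b)) {
    expect_equal(p$basal_init + p$bolus_init_total, p$tdd_init)
    expect_equal(p$fbg_target, 7.8)
    expect_equal(p$ppg_target, 10.0)
    expect_lt(p$fbg_target, p$ppg_target)
  }
  expect_error(protocol_params("2:1"))
})

test_that("initiation divides the bolus into three equal parts and conserves the TDD", {
  st <- initiate_doses(70, protocol_params("1:1.5"))
  expect_equal(st$day, 1L)
  expect_equal(administered_units(st$basal, 70), 14)
  expect_equal(unname(administered_units(st$bolus, 70)), c(7, 7, 7))

  st2 <- initiate_doses(60, protocol_params("1:1"))
  expect_equal(administered_units(st2$basal, 60), 12)
  expect_equal(unname(administered_units(st2$bolus, 60)), c(4, 4, 4))

  for (arm in c("1:1.5", "1:1")) {
    p <- protocol_params(arm)
    s <- initiate_doses(83.4, p)
    expect_equal(length(unique(s$bolus)), 1L)   # three equal parts
    expect_equal(s$basal + sum(s$bolus), p$tdd_init)
  }
  expect_error(initiate_doses(0, protocol_params("1:1")), "positive")
  expect_error(initiate_doses(-5, protocol_params("1:1")))
})

test_that("administration rounds to whole units, half away from zero, ledger untouched", {
  expect_equal(administered_units(0.1, 66.8), 7)
  expect_equal(administered_units(0.2, 70), 14)
  expect_equal(administered_units(0, 55), 0)
  expect_equal(administered_units(0.05, 70), 4)       # 3.5 -> 4, not banker's 3
  expect_equal(administered_units(0.05, 70, mode = "exact"), 3.5)
  expect_error(administered_units(-0.1, 70))
})

test_that("governing readings use same-day FBG/post-breakfast and previous-day lunch/dinner", {
  panels <- make_panels(1:3, fbg = c(12, 10, 9), ppg_b = c(15, 13, 11),
                        ppg_l = c(16, 14, 12), ppg_d = c(17, 15, 13))
  g2 <- governing_readings(panels, 2)
  expect_equal(g2[["basal"]], 10)
  expect_equal(g2[["breakfast"]], 13)
  expect_equal(g2[["lunch"]], 16)     # day 1 value
  expect_equal(g2[["dinner"]], 17)

  g1 <- governing_readings(panels, 1)
  expect_true(is.na(g1[["lunch"]]) && is.na(g1[["dinner"]]))
  expect_equal(g1[["basal"]], 12)

  g3 <- governing_readings(panels, 3)
  expect_equal(g3[["dinner"]], 15)    # day 2 value

  expect_error(governing_readings(panels, 0))
  expect_error(governing_readings(panels[, -2], 2), "fbg")
})

test_that("hypoglycemia levels follow the 3.0/3.9 bounds with assisted override", {
  expect_identical(classify_hypoglycemia(3.5), 1L)
  expect_identical(classify_hypoglycemia(2.9), 2L)
  expect_identical(classify_hypoglycemia(3.9), 0L)   # exclusive upper bound
  expect_identical(classify_hypoglycemia(3.0), 1L)   # inclusive lower bound
  expect_identical(classify_hypoglycemia(5.6, assisted = TRUE), 3L)
  expect_identical(classify_hypoglycemia(c(3.5, 2.9, 3.9, 10)),
                   c(1L, 2L, 0L, 0L))
  expect_error(classify_hypoglycemia(0))
})

test_that("hypoglycemia periods map to the temporally proximate injection", {
  expect_equal(attribute_hypo("night"), "basal")
  expect_equal(attribute_hypo("morning"), "breakfast")
  expect_equal(attribute_hypo("afternoon"), "lunch")
  expect_equal(attribute_hypo("evening"), "dinner")
  expect_error(attribute_hypo("midnight"), "unknown period")
})

test_that("titration decisions follow hypo > no-reading > above-target > hold priority", {
  p <- protocol_params("1:1.5")
  st <- initiate_doses(70, p)
  above <- c(basal = 12, breakfast = 13, lunch = 14, dinner = 15)

  d <- decide_titration(st, above, NULL, p)
  expect_equal(unname(d$delta), c(0.1, 0.05, 0.05, 0.05))
  expect_true(all(d$reason == "ABOVE_TARGET_UP"))

  # one meal on target: that bolus is not titrated further
  mid <- above; mid[["lunch"]] <- 9.2
  d <- decide_titration(st, mid, NULL, p)
  expect_equal(d$delta[["lunch"]], 0)
  expect_equal(d$reason[["lunch"]], "AT_TARGET_HOLD")
  expect_true(all(d$delta[c("basal", "breakfast", "dinner")] > 0))

  # a reading exactly at its threshold still titrates up (< target rule)
  at <- c(basal = 7.8, breakfast = 10.0, lunch = 10.0, dinner = 10.0)
  d <- decide_titration(st, at, NULL, p)
  expect_true(all(d$reason == "ABOVE_TARGET_UP"))

  # night hypoglycemia reduces the basal regardless of the FBG
  hypo <- data.frame(period = "night", bg = 3.4, level = 1L)
  d <- decide_titration(st, above, hypo, p)
  expect_equal(d$delta[["basal"]], -0.1)
  expect_equal(d$reason[["basal"]], "HYPO_DOWN")
  expect_equal(d$delta[["breakfast"]], 0.05)

  # hold variant suspends without reducing
  ph <- protocol_params("1:1.5", hypo_action = "hold")
  d <- decide_titration(st, above, hypo, ph)
  expect_equal(d$delta[["basal"]], 0)
  expect_equal(d$reason[["basal"]], "HYPO_DOWN")

  # absent readings hold
  d1 <- decide_titration(st, c(basal = 12, breakfast = 13, lunch = NA,
                               dinner = NA), NULL, p)
  expect_equal(d1$reason[["lunch"]], "NO_READING_HOLD")
  expect_equal(d1$delta[["dinner"]], 0)

  # totality: every injection always gets a reason
  expect_true(all(nzchar(d1$reason)) && length(d1$reason) == 4)
})

test_that("applying decisions advances the per-kg ledger by the printed steps", {
  p <- protocol_params("1:1.5")
  st <- initiate_doses(70, p)
  above <- c(basal = 12, breakfast = 13, lunch = 14, dinner = 15)
  for (i in 1:2) {
    st <- apply_decision(st, decide_titration(st, above, NULL, p), p)
  }
  expect_equal(st$day, 3L)
  expect_equal(st$basal, 0.4)
  expect_equal(administered_units(st$basal, 70), 28)
  expect_equal(unname(st$bolus), rep(0.2, 3))
  expect_equal(unname(administered_units(st$bolus, 70)), rep(14, 3))

  # 1:1 arm: one escalation takes each meal to 0.2/3 + 0.1/3 = 0.1 per kg
  pb <- protocol_params("1:1")
  stb <- initiate_doses(60, pb)
  stb <- apply_decision(stb, decide_titration(stb, above, NULL, pb), pb)
  expect_equal(unname(stb$bolus), rep(0.1, 3))

  # all-hold decision only advances the day
  hold <- decide_titration(st, c(basal = 7.0, breakfast = 9, lunch = 9,
                                 dinner = 9), NULL, p)
  st2 <- apply_decision(st, hold, p)
  expect_equal(st2$day, st$day + 1L)
  expect_equal(st2$basal, st$basal)
  expect_equal(st2$bolus, st$bolus)

  # day mismatch is rejected
  expect_error(apply_decision(initiate_doses(70, p), hold, p), "day")
})

test_that("doses are clamped at zero under repeated hypoglycemia reductions", {
  p <- protocol_params("1:1.5")
  st <- initiate_doses(70, p)
  st$basal <- 0.05
  hypo <- data.frame(period = c("night", "morning", "afternoon", "evening"),
                     bg = rep(3.2, 4), level = rep(1L, 4))
  any_reading <- c(basal = 12, breakfast = 12, lunch = 12, dinner = 12)
  for (i in 1:4) {
    dec <- decide_titration(st, any_reading, hypo, p)
    expect_true(all(dec$delta <= 0))
    st <- apply_decision(st, dec, p)
  }
  expect_equal(st$basal, 0)
  expect_true(all(st$bolus >= 0))
})

test_that("the TDD safety ceiling clamps runaway escalation with a warning", {
  p <- protocol_params("1:1.5", tdd_ceiling = 0.6)
  st <- initiate_doses(70, p)
  above <- c(basal = 12, breakfast = 13, lunch = 14, dinner = 15)
  dec <- decide_titration(st, above, NULL, p)
  expect_warning(st2 <- apply_decision(st, dec, p), "ceiling")
  expect_equal(st2$basal + sum(st2$bolus), 0.6, tolerance = 1e-12)
})

test_that("permanent bolus lockout stops re-escalation after a target hit", {
  p <- protocol_params("1:1.5", bolus_stop = "permanent")
  st <- initiate_doses(70, p)
  on_target <- c(basal = 12, breakfast = 9.0, lunch = 12, dinner = 12)
  st <- apply_decision(st, decide_titration(st, on_target, NULL, p), p)
  # breakfast rises above target again: suspended permanently
  above <- c(basal = 12, breakfast = 13, lunch = 12, dinner = 12)
  dec <- decide_titration(st, above, NULL, p)
  expect_equal(dec$delta[["breakfast"]], 0)
  expect_equal(dec$reason[["breakfast"]], "AT_TARGET_HOLD")
  # default suspend behaviour resumes
  ps <- protocol_params("1:1.5")
  sts <- initiate_doses(70, ps)
  sts <- apply_decision(sts, decide_titration(sts, on_target, NULL, ps), ps)
  expect_equal(decide_titration(sts, above, NULL, ps)$delta[["breakfast"]], 0.05)
})

test_that("per-kg doses stay non-negative under random decision streams", {
  set.seed(424)
  for (rep in 1:60) {
    arm <- sample(c("1:1.5", "1:1"), 1)
    p <- protocol_params(arm)
    st <- initiate_doses(stats::runif(1, 40, 120), p)
    for (day in 1:12) {
      readings <- c(basal = stats::runif(1, 2, 25),
                    breakfast = stats::runif(1, 2, 25),
                    lunch = stats::runif(1, 2, 25),
                    dinner = stats::runif(1, 2, 25))
      hypo <- if (stats::runif(1) < 0.4) {
        data.frame(period = sample(c("night", "morning", "afternoon",
                                     "evening"),
                                   sample(1:3, 1), replace = TRUE),
                   bg = 3.2, level = 1L)
      } else NULL
      dec <- decide_titration(st, readings, hypo, p)
      expect_true(all(dec$delta %in%
        c(0, p$basal_increment, -p$basal_decrement,
          p$bolus_increment_meal, -p$bolus_decrement_meal)))
      st <- apply_decision(st, dec, p)
      expect_true(st$basal >= 0 && all(st$bolus >= 0))
    }
  }
})

test_that("replaying recorded panels reconstructs the dose ledger", {
  p <- protocol_params("1:1.5")
  # two all-above-target days; lunch/dinner have no day-1 governing reading,
  # so by day 3: basal 0.4, breakfast 0.2, lunch/dinner 0.15 per kg
  panels <- make_panels(1:2, fbg = c(14, 12), ppg_b = c(16, 14),
                        ppg_l = c(17, 15), ppg_d = c(18, 16),
                        bg_0300 = c(13, 11))
  rp <- replay_protocol(70, p, panels)
  expect_equal(rp$state$day, 3L)
  expect_equal(rp$state$basal, 0.4)
  expect_equal(unname(rp$next_doses), c(28, 14, 11, 11))
  expect_equal(nrow(rp$ledger), 2L)
  # day-1 round cannot see lunch/dinner readings
  expect_equal(rp$ledger$reason_lunch[1], "NO_READING_HOLD")
  # breakfast lag: the day-2 administered breakfast reflects day-1's round
  expect_equal(rp$ledger$bolus_breakfast_perkg, c(0.1, 0.15))

  # empty history returns the initiation doses
  rp0 <- replay_protocol(70, p, panels[0, ])
  expect_equal(unname(rp0$next_doses), c(14, 7, 7, 7))
  expect_null(rp0$ledger)

  # a symptomatic assisted reading forces a reduction on the attributed dose
  extra <- data.frame(day = 2, period = "morning", bg = 3.0, assisted = TRUE)
  rpe <- replay_protocol(70, p, panels, extra_events = extra)
  expect_equal(rpe$ledger$reason_breakfast[2], "HYPO_DOWN")
})
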