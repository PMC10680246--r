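# Independent scalar day-loop oracle for a noise-free inpatient stay.
#
# Written directly from the dosing rules and the first-order response model,
# deliberately sharing no code with the package: plain scalars, explicit
# if/else per injection, one while loop. Used to cross-check run_patient()
# and the dose-ledger arithmetic.

oracle_run <- function(weight, fbg0, ppg0, s_basal, s_bolus, c_spill,
                       lag, dip, arm, max_days = 10) {
  if (arm == "1:1.5") {
    basal <- 0.2; bol <- c(0.1, 0.1, 0.1)
    inc_basal <- 0.1; inc_meal <- 0.05
  } else {
    basal <- 0.2; bol <- c(0.2 / 3, 0.2 / 3, 0.2 / 3)
    inc_basal <- 0.1; inc_meal <- 0.1 / 3
  }
  dec_basal <- inc_basal; dec_meal <- inc_meal
  units <- function(x) floor(x * weight + 0.5)

  F <- fbg0; M <- ppg0              # latent levels
  basal_prev <- 0                   # basal injected the previous night
  fbg_s <- pb_s <- pl_s <- pd_s <- numeric(0)
  led <- NULL
  tgt <- c(fbg = NA_integer_, b = NA_integer_, l = NA_integer_,
           d = NA_integer_)
  d <- 1
  repeat {
    # morning: FBG and post-breakfast reading (breakfast dose from ledger)
    F <- F + lag * ((fbg0 - s_basal * basal_prev) - F)
    fbg <- F
    bg03 <- F - dip
    M[1] <- M[1] + lag * ((ppg0[1] - s_bolus * bol[1] - c_spill * basal_prev) - M[1])
    pb <- M[1]

    # hypoglycemia of the last 24 h, attributed by period
    hypo_basal <- bg03 < 3.9
    hypo_b <- fbg < 3.9 || pb < 3.9
    hypo_l <- d > 1 && pl_s[d - 1] < 3.9
    hypo_d <- d > 1 && pd_s[d - 1] < 3.9

    # decisions (hypo beats hyper; threshold counts as above target)
    db <- if (hypo_basal) -dec_basal else if (fbg >= 7.8) inc_basal else 0
    dbb <- if (hypo_b) -dec_meal else if (pb >= 10.0) inc_meal else 0
    dl <- if (hypo_l) -dec_meal else if (d > 1 && pl_s[d - 1] >= 10.0) inc_meal else 0
    dd <- if (hypo_d) -dec_meal else if (d > 1 && pd_s[d - 1] >= 10.0) inc_meal else 0

    basal_new <- max(basal + db, 0)
    bol_b_today <- bol[1]                       # changes apply next morning
    bol_l_new <- max(bol[2] + dl, 0)            # same-day effect
    bol_d_new <- max(bol[3] + dd, 0)

    # afternoon/evening readings with the post-round boluses
    M[2] <- M[2] + lag * ((ppg0[2] - s_bolus * bol_l_new - c_spill * basal_prev) - M[2])
    M[3] <- M[3] + lag * ((ppg0[3] - s_bolus * bol_d_new - c_spill * basal_prev) - M[3])
    pl <- M[2]; pd <- M[3]

    fbg_s[d] <- fbg; pb_s[d] <- pb; pl_s[d] <- pl; pd_s[d] <- pd
    led <- rbind(led, c(day = d, basal = basal_new, b = bol_b_today,
                        l = bol_l_new, dn = bol_d_new,
                        u_basal = units(basal_new), u_b = units(bol_b_today),
                        u_l = units(bol_l_new), u_d = units(bol_d_new)))

    if (is.na(tgt["fbg"]) && d >= 2 && fbg < 7.8) tgt["fbg"] <- as.integer(d)
    if (is.na(tgt["b"]) && pb < 10.0) tgt["b"] <- as.integer(d)
    if (is.na(tgt["l"]) && pl < 10.0) tgt["l"] <- as.integer(d)
    if (is.na(tgt["d"]) && pd < 10.0) tgt["d"] <- as.integer(d)

    basal_prev <- basal_new
    basal <- basal_new
    bol <- c(max(bol[1] + dbb, 0), bol_l_new, bol_d_new)
    all_hold <- db == 0 && dbb == 0 && dl == 0 && dd == 0
    if ((!anyNA(tgt) && all_hold) || d == max_days) break
    d <- d + 1
  }
  list(days_to_target = tgt, days_observed = d, ledger = led,
       final_units = c(basal = units(basal), b = units(bol_b_today),
                       l = units(bol_l_new), d = units(bol_d_new)),
       panels = cbind(fbg = fbg_s, pb = pb_s, pl = pl_s, pd = pd_s))
}
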