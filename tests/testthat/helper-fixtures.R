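# Hand-built deterministic virtual patients (noise off unless stated).

make_profile <- function(id = "T1", weight = 66, fbg0 = 14.1,
                         ppg0 = c(19.1, 19.6, 20.1),
                         s_basal = 18, s_bolus = 45, c_spill = 8,
                         lag = 0.75, noise_sd = 0, dip = 0.8) {
  structure(
    list(id = id, weight = weight, height = 164, admission_bg = fbg0 + 4.5,
         fbg_base = fbg0,
         ppg_base = c(breakfast = ppg0[1], lunch = ppg0[2], dinner = ppg0[3]),
         s_basal = s_basal, s_bolus = s_bolus, c_spill = c_spill,
         lag = lag, noise_sd = noise_sd, nocturnal_dip = dip),
    class = "wit2_patient"
  )
}

# glucose-panel data frame builder
make_panels <- function(days, fbg, ppg_b, ppg_l, ppg_d, bg_0300 = NULL) {
  data.frame(day = days, fbg = fbg, ppg_breakfast = ppg_b,
             ppg_lunch = ppg_l, ppg_dinner = ppg_d,
             bg_0300 = if (is.null(bg_0300)) fbg - 0.5 else bg_0300)
}

# minimal hand-assembled trial object for report/aggregation tests
make_trial <- function(records, hypo = NULL, n_arms = NULL) {
  arms <- unique(records$arm)
  if (is.null(n_arms)) {
    n_arms <- stats::setNames(as.integer(table(records$arm)[arms]), arms)
  }
  if (is.null(hypo)) {
    hypo <- data.frame(id = character(0), arm = character(0),
                       day = integer(0), period = character(0),
                       bg = numeric(0), level = integer(0))
  }
  structure(list(records = records, hypo = hypo,
                 meta = list(seed = 0L, n_arms = n_arms,
                             n_randomized = nrow(records),
                             n_analyzed = nrow(records),
                             config_hash = "test", version = "0")),
            class = "wit2_trial")
}
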