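#' Cohort configuration for the virtual-patient generator
#'
#' Defaults emulate the baseline table of a Chinese inpatient T2D cohort:
#' weight about 66 +/- 11 kg, admission blood glucose about 18.6 +/- 5.4
#' mmol/L, all admission values above 10 mmol/L (the trial's inclusion
#' threshold). Glucose-response parameters are log-normal across patients;
#' their medians are calibrated so the median patient reaches both glycemic
#' targets in 3-4 days under either protocol arm (see the package vignette).
#'
#' @param n_per_arm Patients per arm (>= 1).
#' @param seed Base seed; every random draw in cohort generation and
#'   simulation descends from it.
#' @param weight_mean,weight_sd,weight_range Body-weight distribution, kg
#'   (normal, truncated to `weight_range`).
#' @param height_mean,height_sd,height_range Height distribution, cm.
#' @param admission_bg_mean,admission_bg_sd,admission_bg_range Admission
#'   blood glucose distribution, mmol/L, truncated to `admission_bg_range`.
#' @param s_basal_med,s_bolus_med,c_spill_med Median glucose-lowering
#'   sensitivities, mmol/L per (unit/kg): fasting response to the bedtime
#'   basal dose, post-meal response to that meal's bolus, and the basal
#'   dose's carry-over ("spill") effect on post-meal readings.
#' @param sens_sdlog Log-scale SD shared by the three sensitivities.
#' @param lag_mean,lag_sd Daily fractional approach of glucose to its
#'   dose-determined setpoint (first-order rate, truncated to (0.2, 0.9]).
#' @param noise_sd Within-day measurement/biological noise SD, mmol/L.
#' @param nocturnal_dip Expected offset of the 03:00 reading below the
#'   morning fasting level, mmol/L.
#' @param max_days Maximum simulated length of stay, days.
#' @return A `wit2_cohort_config` list.
#' @export
cohort_config <- function(n_per_arm = 91,
                          seed = 20211,
                          weight_mean = 66, weight_sd = 11,
                          weight_range = c(40, 120),
                          height_mean = 164, height_sd = 8,
                          height_range = c(145, 190),
                          admission_bg_mean = 18.6, admission_bg_sd = 5.4,
                          admission_bg_range = c(10, 35),
                          s_basal_med = 18, s_bolus_med = 45, c_spill_med = 8,
                          sens_sdlog = 0.25,
                          lag_mean = 0.75, lag_sd = 0.08,
                          noise_sd = 0.8, nocturnal_dip = 0.8,
                          max_days = 10) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_range = weight_range,
    height_mean = height_mean, height_sd = height_sd,
    height_range = height_range,
    admission_bg_mean = admission_bg_mean, admission_bg_sd = admission_bg_sd,
    admission_bg_range = admission_bg_range,
    s_basal_med = s_basal_med, s_bolus_med = s_bolus_med,
    c_spill_med = c_spill_med, sens_sdlog = sens_sdlog,
    lag_mean = lag_mean, lag_sd = lag_sd,
    noise_sd = noise_sd, nocturnal_dip = nocturnal_dip,
    max_days = as.integer(max_days)
  )
  sds <- c(cfg$weight_sd, cfg$height_sd, cfg$admission_bg_sd, cfg$sens_sdlog,
           cfg$lag_sd, cfg$noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all spread parameters must be finite and >= 0")
  }
  if (cfg$n_per_arm < 1L) stop("`n_per_arm` must be >= 1")
  structure(cfg, class = "wit2_cohort_config")
}

# one draw from a truncated normal (rejection; falls back to clamping for
# degenerate sd = 0)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# deterministic 31-bit hash of a patient id, mixed with the base seed, so
# every patient owns an order-independent RNG substream
patient_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Sample one virtual patient
#'
#' Draws anthropometrics and glucose-response parameters from the cohort
#' configuration. The untreated fasting level is tied to the admission
#' glucose draw (`fbg_base = max(admission_bg - 4.5, 8.2)` mmol/L, always
#' above the 7.8 target) and the untreated 2-h post-meal levels sit at or
#' above the admission draw with small breakfast/lunch/dinner offsets, so
#' every sampled patient is admission-eligible (> 10 mmol/L). Each patient
#' id owns a deterministic RNG substream of `config$seed`, so a profile is
#' reproducible regardless of sampling order.
#'
#' @param config A [cohort_config()].
#' @param id Patient identifier (string).
#' @return A `wit2_patient` list: `id`, `weight` (kg), `height` (cm),
#'   `admission_bg`, `fbg_base`, `ppg_base` (mmol/L), sensitivities
#'   `s_basal`, `s_bolus`, `c_spill` (mmol/L per unit/kg), `lag` (/day),
#'   `noise_sd`, `nocturnal_dip` (mmol/L).
#' @export
sample_patient <- function(config, id = "P001") {
  stopifnot(inherits(config, "wit2_cohort_config"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(patient_seed(config$seed, id))
  weight <- rtrunc_norm(1, config$weight_mean, config$weight_sd,
                        config$weight_range[1], config$weight_range[2])
  height <- rtrunc_norm(1, config$height_mean, config$height_sd,
                        config$height_range[1], config$height_range[2])
  abg <- rtrunc_norm(1, config$admission_bg_mean, config$admission_bg_sd,
                     config$admission_bg_range[1] + 1e-9,
                     config$admission_bg_range[2])
  fbg_base <- max(abg - 4.5, 8.2)
  ppg_base <- stats::setNames(
    pmax(abg, 10.3) + c(0.5, 1.0, 1.5), MEALS)
  sens <- stats::rlnorm(3,
                        meanlog = log(c(config$s_basal_med, config$s_bolus_med,
                                        config$c_spill_med)),
                        sdlog = config$sens_sdlog)
  lag <- rtrunc_norm(1, config$lag_mean, config$lag_sd, 0.3, 0.95)
  structure(
    list(
      id = as.character(id), weight = weight, height = height,
      admission_bg = abg, fbg_base = fbg_base, ppg_base = ppg_base,
      s_basal = sens[1], s_bolus = sens[2], c_spill = sens[3],
      lag = lag, noise_sd = config$noise_sd,
      nocturnal_dip = config$nocturnal_dip
    ),
    class = "wit2_patient"
  )
}

#' Sample a whole cohort
#'
#' @param config A [cohort_config()].
#' @param n Number of patients (default `2 * n_per_arm`).
#' @param id_prefix Prefix for generated patient ids.
#' @return A list of `wit2_patient` profiles.
#' @export
sample_cohort <- function(config, n = 2L * config$n_per_arm,
                          id_prefix = "P") {
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  lapply(ids, function(id) sample_patient(config, id))
}

#' Initial latent glucose state of a virtual patient
#'
#' The latent fasting and post-meal glucose levels start at the patient's
#' untreated baselines; each simulated day moves them a fraction `lag`
#' toward their dose-determined setpoints.
#'
#' @param profile A [sample_patient()] profile.
#' @return List with `F` (latent fasting level, mmol/L) and `M` (named
#'   latent post-meal levels).
#' @export
glucose_latent0 <- function(profile) {
  list(F = profile$fbg_base, M = profile$ppg_base)
}

# deterministic day step: latent update + readings from pre-drawn noise
# eps = c(fbg, breakfast, lunch, dinner, bg_0300)
sim_day_core <- function(profile, basal_prev, bolus_today, latent, eps) {
  sp_f <- profile$fbg_base - profile$s_basal * basal_prev
  f_d <- latent$F + profile$lag * (sp_f - latent$F)
  sp_m <- profile$ppg_base - profile$s_bolus * bolus_today[MEALS] -
    profile$c_spill * basal_prev
  m_d <- latent$M + profile$lag * (sp_m - latent$M)
  list(
    fbg = max(f_d + eps[1], 1.0),
    ppg = pmax(m_d + eps[2:4], 1.0),
    bg_0300 = max(f_d - profile$nocturnal_dip + eps[5], 1.0),
    latent = list(F = f_d, M = m_d)
  )
}

#' Simulate one day's five-point glucose panel
#'
#' First-order response model: the latent fasting level approaches the
#' setpoint `fbg_base - s_basal * basal` (basal dose given the previous
#' night, units/kg) at fractional rate `lag` per day; each latent post-meal
#' level approaches `ppg_base - s_bolus * bolus - c_spill * basal`.
#' Readings are the latents plus independent Gaussian noise, floored at
#' 1.0 mmol/L; the 03:00 reading sits `nocturnal_dip` below the fasting
#' latent. Noise is drawn from R's current RNG stream.
#'
#' @param profile A [sample_patient()] profile.
#' @param basal_prev Basal dose injected the previous night, units/kg.
#' @param bolus_today Named units/kg vector (breakfast, lunch, dinner) of
#'   boluses injected this day.
#' @param latent Latent state from the previous day, or `NULL` for
#'   [glucose_latent0()].
#' @return List: `fbg`, `ppg` (named), `bg_0300` (mmol/L) and the updated
#'   `latent` state.
#' @export
simulate_day_glucose <- function(profile, basal_prev, bolus_today,
                                 latent = NULL) {
  stopifnot(basal_prev >= 0, all(bolus_today >= 0))
  if (is.null(latent)) latent <- glucose_latent0(profile)
  eps <- stats::rnorm(5, 0, profile$noise_sd)
  sim_day_core(profile, basal_prev, bolus_today, latent, eps)
}

#' Write / read a cohort as CSV
#'
#' One row per patient, all profile fields in plain columns; round-trips
#' through [read_cohort()].
#'
#' @param cohort List of `wit2_patient` profiles.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a list of `wit2_patient` profiles.
#' @export
write_cohort <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      id = p$id, weight = p$weight, height = p$height,
      admission_bg = p$admission_bg, fbg_base = p$fbg_base,
      ppg_base_breakfast = p$ppg_base[["breakfast"]],
      ppg_base_lunch = p$ppg_base[["lunch"]],
      ppg_base_dinner = p$ppg_base[["dinner"]],
      s_basal = p$s_basal, s_bolus = p$s_bolus, c_spill = p$c_spill,
      lag = p$lag, noise_sd = p$noise_sd, nocturnal_dip = p$nocturnal_dip
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(
      list(
        id = as.character(r$id), weight = r$weight, height = r$height,
        admission_bg = r$admission_bg, fbg_base = r$fbg_base,
        ppg_base = c(breakfast = r$ppg_base_breakfast,
                     lunch = r$ppg_base_lunch, dinner = r$ppg_base_dinner),
        s_basal = r$s_basal, s_bolus = r$s_bolus, c_spill = r$c_spill,
        lag = r$lag, noise_sd = r$noise_sd, nocturnal_dip = r$nocturnal_dip
      ),
      class = "wit2_patient"
    )
  })
}
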