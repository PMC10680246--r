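#' Ideal body weight by the height-minus-105 rule
#'
#' @param height Height in cm; must lie in (100, 250) and yield a positive
#'   ideal weight.
#' @return Ideal body weight in kg, `height - 105`.
#' @examples
#' ideal_body_weight(170)  # 65
#' @export
ideal_body_weight <- function(height) {
  stopifnot(is.numeric(height), length(height) == 1L, is.finite(height))
  if (height <= 100 || height >= 250) {
    stop("`height` must be between 100 and 250 cm")
  }
  ibw <- height - 105
  if (ibw <= 0) stop("height yields a non-positive ideal weight")
  ibw
}

#' Energy coefficient by weight status
#'
#' Total daily energy is prescribed per kg of ideal body weight: 25
#' kcal/kg/day for overweight or obese patients and 30 kcal/kg/day for
#' normal-weight or lean patients. The BMI cut-off defaults to 24 kg/m2
#' (Chinese adult overweight criterion); a BMI exactly at the cut-off
#' counts as overweight.
#'
#' @param bmi Body mass index in kg/m2 (> 0).
#' @param overweight_bmi Overweight threshold, kg/m2.
#' @return 25 or 30 (kcal/kg/day).
#' @export
energy_coefficient <- function(bmi, overweight_bmi = 24) {
  stopifnot(is.numeric(bmi), length(bmi) == 1L, bmi > 0)
  if (bmi >= overweight_bmi) 25 else 30
}

#' Standardized inpatient dietary prescription
#'
#' Ideal weight is height (cm) minus 105; total energy is 25 (overweight,
#' BMI >= cut-off) or 30 (lean/normal) kcal per kg ideal weight per day;
#' protein is 1.0 g/kg and fat 0.8 g/kg ideal weight; the remaining energy
#' is given as carbohydrate (Atwater factors 4/9/4 kcal/g). Total calories
#' are split 1:2:2 across breakfast, lunch and dinner; the breakfast share
#' is floored to a whole kcal and the remainder split equally between lunch
#' and dinner so the meal energies sum exactly to the total.
#'
#' @param height Height in cm.
#' @param weight Actual body weight in kg (used only for BMI).
#' @param overweight_bmi BMI cut-off passed to [energy_coefficient()].
#' @return A `wit2_diet` list: `ideal_weight` (kg), `bmi`, `kcal_per_kg`,
#'   `total_energy` (kcal/day), `protein`, `fat`, `carbohydrate` (g/day),
#'   `carb_fraction` (share of energy from carbohydrate) and `meal_energy`
#'   (named kcal vector, breakfast/lunch/dinner).
#' @examples
#' diet_prescription(170, 80)$total_energy  # 1625 kcal/day
#' @export
diet_prescription <- function(height, weight, overweight_bmi = 24) {
  stopifnot(is.numeric(weight), length(weight) == 1L, weight > 0)
  ibw <- ideal_body_weight(height)
  bmi <- weight / (height / 100)^2
  coef <- energy_coefficient(bmi, overweight_bmi)
  energy <- coef * ibw
  protein <- 1.0 * ibw
  fat <- 0.8 * ibw
  carb <- (energy - 4 * protein - 9 * fat) / 4
  if (carb < 0) {
    stop(sprintf(
      "negative carbohydrate allocation (%.1f g): protein and fat energy exceed %.0f kcal",
      carb, energy))
  }
  breakfast <- floor(energy / 5)
  rest <- (energy - breakfast) / 2
  structure(
    list(
      ideal_weight = ibw,
      bmi = bmi,
      kcal_per_kg = coef,
      total_energy = energy,
      protein = protein,
      fat = fat,
      carbohydrate = carb,
      carb_fraction = 4 * carb / energy,
      meal_energy = c(breakfast = breakfast, lunch = rest, dinner = rest)
    ),
    class = "wit2_diet"
  )
}

#' @export
print.wit2_diet <- function(x, ...) {
  cat(sprintf("Dietary prescription (ideal weight %.0f kg, BMI %.1f, %d kcal/kg/day)\n",
              x$ideal_weight, x$bmi, x$kcal_per_kg))
  cat(sprintf("  energy       %.0f kcal/day (breakfast %.0f, lunch %.0f, dinner %.0f)\n",
              x$total_energy, x$meal_energy[["breakfast"]],
              x$meal_energy[["lunch"]], x$meal_energy[["dinner"]]))
  cat(sprintf("  protein %.0f g, fat %.0f g, carbohydrate %.0f g (%.0f%% of energy)\n",
              x$protein, x$fat, x$carbohydrate, 100 * x$carb_fraction))
  invisible(x)
}
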