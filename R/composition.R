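## Food composition table and resting-energy-expenditure coefficients.

#' Nutrient column names
#'
#' Energy plus the 14 nutrients tracked by the pipeline, with units encoded in
#' the names (per day for intakes, per 100 g in composition tables).
#' @return Character vector of length 15 (energy first).
#' @export
nutrient_names <- function() {
  c("energy_kcal", "protein_g", "fat_g", "carbohydrate_g", "sucrose_g",
    "fibre_g", "alcohol_g", "vitamin_c_mg", "vitamin_d_ug", "folate_ug",
    "calcium_mg", "iron_mg", "sodium_mg", "potassium_mg", "magnesium_mg")
}

# per-group macro templates per 100 g: protein, fat, carb, sucrose, fibre, alcohol
.macro_templates <- function() {
  m <- rbind(
    milk                     = c(3.5, 2.5, 5, 0, 0, 0),
    soured_milk              = c(4, 3, 6, 3, 0, 0),
    cheese                   = c(25, 28, 1, 0, 0, 0),
    plant_dairy_alternatives = c(1.5, 1.5, 6, 2, 0.5, 0),
    wholegrain_products      = c(10, 3, 55, 2, 10, 0),
    refined_grain_products   = c(8, 4, 55, 5, 3, 0),
    porridge_cereals         = c(4, 2, 15, 1, 2, 0),
    potatoes                 = c(2, 0.2, 17, 0, 2, 0),
    rice_pasta               = c(4, 1, 28, 0, 1.5, 0),
    vegetables               = c(2, 0.3, 4, 1, 2.5, 0),
    root_vegetables          = c(1, 0.2, 8, 3, 2.5, 0),
    legumes                  = c(8, 1, 14, 1, 6, 0),
    fruits_berries           = c(0.7, 0.3, 12, 7, 2, 0),
    juice                    = c(0.6, 0.1, 10, 8, 0.2, 0),
    nuts_seeds               = c(20, 50, 8, 2, 7, 0),
    red_meat                 = c(22, 12, 0, 0, 0, 0),
    poultry                  = c(23, 6, 0, 0, 0, 0),
    sausages                 = c(12, 25, 3, 0, 0, 0),
    seafood                  = c(20, 8, 0, 0, 0, 0),
    eggs                     = c(12.5, 10, 0.7, 0, 0, 0),
    meat_substitutes         = c(18, 8, 6, 0, 4, 0),
    fats_oils                = c(0.5, 80, 0.5, 0, 0, 0),
    desserts_sweets          = c(4, 18, 55, 35, 1, 0),
    snacks                   = c(6, 30, 50, 3, 3, 0),
    sugar_sweetened_beverages = c(0, 0, 10, 10, 0, 0),
    diet_beverages           = c(0, 0, 0.5, 0, 0, 0),
    coffee                   = c(0.2, 0, 0.3, 0, 0, 0),
    tea                      = c(0, 0, 0.3, 0, 0, 0),
    alcoholic_beverages      = c(0.4, 0, 3, 1, 0, 5),
    sauces_condiments        = c(2, 10, 8, 3, 0.5, 0)
  )
  colnames(m) <- c("protein_g", "fat_g", "carbohydrate_g", "sucrose_g",
                   "fibre_g", "alcohol_g")
  m
}

#' Default food-composition table
#'
#' Energy and nutrient contents per 100 g for every questionnaire category.
#' Values are synthetic but plausible: each item draws a jittered copy of a
#' per-group macro template, and energy is computed from the macronutrients
#' (4 kcal/g protein and carbohydrate, 9 kcal/g fat, 7 kcal/g alcohol) so the
#' energy/macronutrient consistency invariant holds exactly. Micronutrients
#' are jittered group-level constants. The table is deterministic: it is
#' built under a fixed internal seed, independent of the caller's RNG state.
#'
#' @param schema an [ffq_schema()].
#' @return data.frame keyed by `item_id` with [nutrient_names()] columns,
#'   all per 100 g.
#' @export
default_composition <- function(schema = ffq_schema()) {
  items <- schema$items
  macros <- .macro_templates()[items$group_id, , drop = FALSE]
  micro_base <- c(vitamin_c_mg = 6, vitamin_d_ug = 0.8, folate_ug = 25,
                  calcium_mg = 40, iron_mg = 1.2, sodium_mg = 150,
                  potassium_mg = 200, magnesium_mg = 20)
  withr::with_seed(104729, {
    jit <- matrix(runif(nrow(items) * ncol(macros), 0.8, 1.2),
                  nrow = nrow(items))
    macros <- macros * jit
    micro <- sapply(micro_base, function(b) {
      b * runif(nrow(items), 0.3, 2.5)
    })
  })
  # vegetables & fruit rich in vitamin C/folate, fish in vitamin D, dairy in Ca
  veg <- items$group_id %in% c("vegetables", "root_vegetables",
                               "fruits_berries", "juice")
  micro[veg, "vitamin_c_mg"] <- micro[veg, "vitamin_c_mg"] * 6
  micro[veg, "folate_ug"] <- micro[veg, "folate_ug"] * 2.5
  fish <- items$group_id == "seafood"
  micro[fish, "vitamin_d_ug"] <- micro[fish, "vitamin_d_ug"] * 8
  dairy <- items$group_id %in% c("milk", "soured_milk", "cheese")
  micro[dairy, "calcium_mg"] <- micro[dairy, "calcium_mg"] * 4
  energy <- 4 * macros[, "protein_g"] + 9 * macros[, "fat_g"] +
    4 * macros[, "carbohydrate_g"] + 7 * macros[, "alcohol_g"]
  out <- data.frame(item_id = items$item_id, energy_kcal = energy,
                    macros, micro, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[, c("item_id", nutrient_names())]
}

#' Resting energy expenditure coefficient table
#'
#' Weight-based REE prediction equations by sex and age band (Henry/Oxford
#' family): REE in MJ/day = a * weight_kg + b, converted to kcal/day. Age
#' bands use a lower-inclusive boundary rule, so age 30 falls in the 30-60
#' band and age 60 in the 60+ band. The table is plain data so any other
#' equation set can be swapped in.
#'
#' @return data.frame with columns `sex`, `age_min`, `age_max`,
#'   `coef_weight_mj`, `intercept_mj`.
#' @export
default_ree_coefficients <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 3),
    age_min = rep(c(18, 30, 60), 2),
    age_max = rep(c(30, 60, Inf), 2),
    coef_weight_mj = c(0.0669, 0.0592, 0.0563, 0.0546, 0.0407, 0.0424),
    intercept_mj = c(2.28, 2.48, 2.15, 2.33, 2.90, 2.38),
    stringsAsFactors = FALSE
  )
}
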