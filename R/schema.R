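## Questionnaire schema, frequency mapping and portion tables.
##
## The shipped schema is a synthetic 108-item instrument organised in 30 food
## groups, mirroring the structure of modern Nordic semi-quantitative FFQs:
## nine ordered frequency levels per item plus three portion-photo indications
## (starch plate, protein plate, vegetable plate, each on a 1-4 scale).

# group id -> (number of items, portion class, label)
.default_groups <- function() {
  g <- rbind(
    data.frame(group_id = "milk",                    n = 3L, portion_class = "none"),
    data.frame(group_id = "soured_milk",             n = 3L, portion_class = "none"),
    data.frame(group_id = "cheese",                  n = 3L, portion_class = "none"),
    data.frame(group_id = "plant_dairy_alternatives", n = 3L, portion_class = "none"),
    data.frame(group_id = "wholegrain_products",     n = 4L, portion_class = "none"),
    data.frame(group_id = "refined_grain_products",  n = 4L, portion_class = "none"),
    data.frame(group_id = "porridge_cereals",        n = 4L, portion_class = "starch"),
    data.frame(group_id = "potatoes",                n = 4L, portion_class = "starch"),
    data.frame(group_id = "rice_pasta",              n = 4L, portion_class = "starch"),
    data.frame(group_id = "vegetables",              n = 4L, portion_class = "vegetable"),
    data.frame(group_id = "root_vegetables",         n = 4L, portion_class = "vegetable"),
    data.frame(group_id = "legumes",                 n = 4L, portion_class = "vegetable"),
    data.frame(group_id = "fruits_berries",          n = 4L, portion_class = "fixed_natural"),
    data.frame(group_id = "juice",                   n = 4L, portion_class = "none"),
    data.frame(group_id = "nuts_seeds",              n = 4L, portion_class = "none"),
    data.frame(group_id = "red_meat",                n = 4L, portion_class = "protein"),
    data.frame(group_id = "poultry",                 n = 3L, portion_class = "protein"),
    data.frame(group_id = "sausages",                n = 3L, portion_class = "protein"),
    data.frame(group_id = "seafood",                 n = 4L, portion_class = "protein"),
    data.frame(group_id = "eggs",                    n = 3L, portion_class = "fixed_natural"),
    data.frame(group_id = "meat_substitutes",        n = 3L, portion_class = "protein"),
    data.frame(group_id = "fats_oils",               n = 4L, portion_class = "none"),
    data.frame(group_id = "desserts_sweets",         n = 4L, portion_class = "none"),
    data.frame(group_id = "snacks",                  n = 4L, portion_class = "none"),
    data.frame(group_id = "sugar_sweetened_beverages", n = 3L, portion_class = "none"),
    data.frame(group_id = "diet_beverages",          n = 3L, portion_class = "none"),
    data.frame(group_id = "coffee",                  n = 3L, portion_class = "none"),
    data.frame(group_id = "tea",                     n = 3L, portion_class = "none"),
    data.frame(group_id = "alcoholic_beverages",     n = 4L, portion_class = "none"),
    data.frame(group_id = "sauces_condiments",       n = 4L, portion_class = "none")
  )
  g$label <- gsub("_", " ", g$group_id)
  g
}

# natural-unit grams for items in fixed_natural groups (an apple, an egg, ...)
.natural_grams <- c(fruits_berries = 125, eggs = 60)

# typical portion (g) used for the demographic median table, by group
.base_portion_g <- c(
  milk = 200, soured_milk = 200, cheese = 20, plant_dairy_alternatives = 200,
  wholegrain_products = 35, refined_grain_products = 35, juice = 200,
  nuts_seeds = 25, fats_oils = 12, desserts_sweets = 50, snacks = 30,
  sugar_sweetened_beverages = 250, diet_beverages = 250, coffee = 150,
  tea = 200, alcoholic_beverages = 250, sauces_condiments = 30
)

#' Nine-level frequency scale labels
#'
#' Ordered labels of the frequency scale used by the questionnaire, from
#' "never" to "four or more times per day".
#' @return Character vector of length nine.
#' @export
frequency_levels <- function() {
  c("never", "couple_per_year", "1-3_per_month", "1_per_week",
    "2-3_per_week", "4-6_per_week", "1_per_day", "2-3_per_day",
    "4plus_per_day")
}

#' Default frequency-to-daily mapping
#'
#' Maps each of the nine ordinal frequency levels to a representative intake
#' frequency in intakes/day. The endpoints are fixed by the instrument
#' definition ("never" = 0, top level = 4 intakes/day); intermediate levels use
#' the arithmetic midpoint of the stated range, e.g. "2-3 times a week" =
#' 2.5/7 per day. Any monotone mapping with the same endpoints may be
#' substituted.
#'
#' @return Named numeric vector of length nine, in intakes/day.
#' @export
default_frequency_mapping <- function() {
  setNames(
    c(0, 2 / 365.25, 2 / 30.44, 1 / 7, 2.5 / 7, 5 / 7, 1, 2.5, 4),
    frequency_levels()
  )
}

#' Validate a frequency mapping
#'
#' A valid mapping has one value per scale level, is monotone non-decreasing,
#' maps "never" to 0 and the top level to 4 intakes/day.
#' @param mapping numeric vector of length nine.
#' @return The mapping, invisibly; errors otherwise.
#' @export
validate_frequency_mapping <- function(mapping) {
  if (length(mapping) != 9L) {
    stop("frequency mapping must have exactly nine levels, got ",
         length(mapping), call. = FALSE)
  }
  if (any(diff(mapping) < 0)) {
    stop("frequency mapping must be monotone non-decreasing", call. = FALSE)
  }
  if (mapping[[1]] != 0) stop("level 'never' must map to 0", call. = FALSE)
  if (mapping[[9]] != 4) stop("top level must map to 4 intakes/day", call. = FALSE)
  invisible(mapping)
}

#' Build the questionnaire schema
#'
#' Constructs the item table of the instrument: item ids, labels, the food
#' group each item belongs to, its portion class (which of the three portion
#' photos applies, a fixed natural unit, or neither) and, where applicable,
#' the natural-unit grams. The shipped default has 108 items in 30 groups;
#' the group table is replaceable so the engine generalises to other
#' instruments. The item list is synthetic (constructed for this package),
#' not a published questionnaire.
#'
#' @param groups data.frame with columns `group_id`, `n` (items per group),
#'   `portion_class` and `label`; default [.default_groups()]-style 30-group
#'   table.
#' @return Object of class `ffq_schema`: list with `items` (data.frame),
#'   `groups` (data.frame), `levels` (character).
#' @export
ffq_schema <- function(groups = NULL) {
  if (is.null(groups)) groups <- .default_groups()
  stopifnot(all(c("group_id", "n", "portion_class") %in% names(groups)))
  bad <- setdiff(unique(groups$portion_class),
                 c("starch", "protein", "vegetable", "fixed_natural", "none"))
  if (length(bad)) stop("unknown portion class: ", paste(bad, collapse = ", "))
  n_items <- sum(groups$n)
  items <- data.frame(
    item_id = sprintf("item_%03d", seq_len(n_items)),
    group_id = rep(groups$group_id, groups$n),
    portion_class = rep(groups$portion_class, groups$n),
    stringsAsFactors = FALSE
  )
  items$label <- paste(gsub("_", " ", items$group_id),
                       unlist(lapply(groups$n, seq_len)))
  items$natural_g <- ifelse(items$portion_class == "fixed_natural",
                            unname(.natural_grams[items$group_id]), NA_real_)
  structure(
    list(items = items, groups = groups, levels = frequency_levels()),
    class = "ffq_schema"
  )
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat("<ffq_schema> ", nrow(x$items), " items, ", nrow(x$groups),
      " food groups, ", length(x$levels), " frequency levels\n", sep = "")
  invisible(x)
}

#' Default portion tables
#'
#' Portion sizes come from three sources, chosen per item by its portion
#' class: (1) the portion-photo plates (four increasing levels for starch,
#' protein and vegetable plates), (2) fixed natural units (an egg, a piece of
#' fruit), and (3) sex- and 10-year-age-band median portions for everything
#' else. All gram values here are synthetic defaults constructed for this
#' package.
#'
#' @param schema an [ffq_schema()].
#' @return Object of class `portion_table`: list with `photo` (3 x 4 matrix of
#'   grams), `demographic` (data.frame sex x age band x item with grams) and
#'   `age_bands` (break points).
#' @export
default_portion_table <- function(schema = ffq_schema()) {
  photo <- rbind(
    starch    = c(100, 150, 200, 250),
    protein   = c(75, 110, 145, 180),
    vegetable = c(40, 80, 120, 160)
  )
  colnames(photo) <- paste0("level", 1:4)
  bands <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70+")
  band_mult <- c(1.05, 1.02, 1.00, 0.97, 0.94, 0.90)
  sex_mult <- c(male = 1.15, female = 0.95)
  none_items <- schema$items[schema$items$portion_class == "none", ]
  demo <- expand.grid(sex = names(sex_mult), age_band = bands,
                      item_id = none_items$item_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- .base_portion_g[none_items$group_id[match(demo$item_id, none_items$item_id)]]
  demo$grams <- round(unname(base) * sex_mult[demo$sex] *
                        band_mult[match(demo$age_band, bands)], 1)
  structure(list(photo = photo, demographic = demo, age_bands = bands),
            class = "portion_table")
}

# 10-year age band label for an age; lower bound inclusive, so age 50 -> 50-59
.age_band <- function(age) {
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, Inf), right = FALSE,
      labels = c("18-29", "30-39", "40-49", "50-59", "60-69", "70+"))
}
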