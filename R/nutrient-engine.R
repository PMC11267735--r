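## Nutrient engine: FFQ-based energy/nutrient estimation, resting energy
## expenditure, misreporting screening, and energy adjustment.

#' Estimate daily energy and nutrient intakes from frequencies
#'
#' For each nutrient: the sum over categories of daily intake frequency times
#' portion grams times nutrient content per gram. Linear in both frequencies
#' and portions.
#'
#' @param freqs data.frame from [frequencies_to_daily()] (`participant_id` +
#'   item columns, intakes/day).
#' @param portions_g matrix participants x items from
#'   [assign_portion_sizes()] (grams per intake), or a single named vector
#'   applied to every participant.
#' @param composition per-100 g table from [default_composition()].
#' @param schema an [ffq_schema()].
#' @return data.frame `participant_id` + [nutrient_names()] columns, per day.
#' @export
estimate_nutrients <- function(freqs, portions_g, composition,
                               schema = ffq_schema()) {
  items <- schema$items$item_id
  f <- as.matrix(freqs[, items, drop = FALSE])
  if (is.null(dim(portions_g))) {
    portions_g <- matrix(portions_g[items], nrow = nrow(f), ncol = length(items),
                         byrow = TRUE, dimnames = list(NULL, items))
  }
  active <- colSums(f != 0) > 0
  gap <- items[active & !(items %in% composition$item_id)]
  if (length(gap)) stop("no composition entry for category ", gap[1], call. = FALSE)
  if (anyNA(portions_g[, active])) {
    stop("no portion size for a category with nonzero frequency", call. = FALSE)
  }
  comp <- as.matrix(composition[match(items, composition$item_id),
                                nutrient_names(), drop = FALSE]) / 100
  comp[is.na(comp)] <- 0
  grams <- f * portions_g[, items, drop = FALSE]
  grams[is.na(grams)] <- 0  # zero-frequency categories may lack portions
  out <- grams %*% comp
  data.frame(participant_id = freqs$participant_id, out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Resting energy expenditure
#'
#' Predicts REE (kcal/day) from sex, age and body weight using a coefficient
#' table of weight-based equations per sex and age band (see
#' [default_ree_coefficients()]). Band boundaries are lower-inclusive.
#'
#' @param participants data.frame with `sex`, `age`, `weight_kg`.
#' @param coefficients coefficient table; default
#'   [default_ree_coefficients()].
#' @return numeric vector, kcal/day.
#' @export
resting_energy_expenditure <- function(participants,
                                       coefficients = default_ree_coefficients()) {
  mj_to_kcal <- 239.005736
  out <- numeric(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    row <- coefficients[coefficients$sex == participants$sex[i] &
                          participants$age[i] >= coefficients$age_min &
                          participants$age[i] < coefficients$age_max, ]
    if (nrow(row) != 1) {
      stop("no REE coefficient row for (", participants$sex[i], ", age ",
           participants$age[i], ")", call. = FALSE)
    }
    out[i] <- (row$coef_weight_mj * participants$weight_kg[i] +
                 row$intercept_mj) * mj_to_kcal
  }
  out
}

#' Flag implausible energy reporting
#'
#' Computes the ratio of reported energy intake to resting energy expenditure
#' (the screening "PAL" value) and flags severe under-reporting when the
#' ratio is strictly below `under` (default 0.7) and implausible
#' over-reporting when it is at or above `over` (default 3.0).
#'
#' @param energy_kcal reported energy intake, kcal/day.
#' @param ree_kcal resting energy expenditure, kcal/day (> 0).
#' @param under,over thresholds; under-reporting uses a strict inequality,
#'   over-reporting a weak one.
#' @return data.frame `pal`, `flag` (factor severe_under/plausible/
#'   implausible_over).
#' @export
pal_flag <- function(energy_kcal, ree_kcal, under = 0.7, over = 3.0) {
  if (any(ree_kcal <= 0)) stop("resting energy expenditure must be > 0",
                               call. = FALSE)
  stopifnot(under > 0, over > under)
  pal <- energy_kcal / ree_kcal
  flag <- ifelse(pal < under, "severe_under",
                 ifelse(pal >= over, "implausible_over", "plausible"))
  data.frame(pal = pal,
             flag = factor(flag, levels = c("severe_under", "plausible",
                                            "implausible_over")))
}

#' Energy-adjust nutrient intakes
#'
#' Residual method: each nutrient is regressed on total energy by ordinary
#' least squares and the residual, plus the predicted value at the cohort
#' mean energy, is the energy-independent estimate (keeping natural units).
#' Density method: nutrient per 1,000 kcal.
#'
#' @param nutrients data.frame from [estimate_nutrients()] or
#'   [recall_nutrients()].
#' @param method "residual" or "density".
#' @return data.frame `participant_id` + adjusted nutrient columns (energy
#'   itself is carried through unadjusted). With the density method,
#'   zero-energy participants get NA and a warning.
#' @export
energy_adjust <- function(nutrients, method = c("residual", "density")) {
  method <- match.arg(method)
  energy <- nutrients$energy_kcal
  nut_cols <- setdiff(nutrient_names(), "energy_kcal")
  out <- nutrients[, c("participant_id", "energy_kcal")]
  if (method == "residual") {
    if (nrow(nutrients) < 3) stop("residual method needs >= 3 participants")
    for (nm in nut_cols) {
      fit <- lm(nutrients[[nm]] ~ energy)
      pred_at_mean <- sum(stats::coef(fit) * c(1, mean(energy)))
      out[[nm]] <- stats::resid(fit) + pred_at_mean
    }
  } else {
    bad <- energy == 0
    if (any(bad)) warning(sum(bad), " participant(s) with zero energy; ",
                          "density-adjusted values set to NA")
    for (nm in nut_cols) {
      out[[nm]] <- ifelse(bad, NA_real_, nutrients[[nm]] / energy * 1000)
    }
  }
  out
}
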