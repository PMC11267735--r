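## Synthetic validation-study generator with known ground truth.
##
## The latent model: each participant has a habitual intake frequency per
## questionnaire category, drawn log-normally (right-skewed, like real intake
## data) with a Bernoulli never-consumer mask for episodically consumed
## foods. The FFQ observes that truth through a multiplicative bias and
## log-normal noise, then discretises to the nine-level scale (nearest
## representative value, ties to the lower level). Recall days observe it
## through Poisson day-level occasion counts (the within-person day-to-day
## variation the reference method averages over), with log-normal amount
## noise around the true portion. The repeat FFQ redraws its error
## independently given the truth, so reproducibility has a closed-form
## target.

#' Construct an error model for the generator
#'
#' @param ffq_bias multiplicative per-category reporting bias of the FFQ
#'   (scalar or one value per item); 1 = unbiased.
#' @param ffq_noise_sd sd of the FFQ's log-scale random error.
#' @param recall_within_person_sd sd of the log-scale amount error around the
#'   true portion in recall records.
#' @param episodic_zero_prob per-category probability that a participant
#'   never consumes the food (exact zeros in truth and in both instruments).
#' @param repeat_drift log-scale shift of habitual intake at the repeat FFQ
#'   administration; 0 (the default) keeps the two administrations
#'   exchangeable.
#' @return list of class `ffq_error_model`.
#' @export
error_model <- function(ffq_bias = 1, ffq_noise_sd = 0.45,
                        recall_within_person_sd = 0.25,
                        episodic_zero_prob = 0.10, repeat_drift = 0) {
  if (any(ffq_noise_sd < 0)) stop("invalid error model: ffq_noise_sd must be >= 0",
                                  call. = FALSE)
  if (any(recall_within_person_sd < 0)) {
    stop("invalid error model: recall_within_person_sd must be >= 0",
         call. = FALSE)
  }
  if (any(episodic_zero_prob < 0 | episodic_zero_prob > 1)) {
    stop("invalid error model: episodic_zero_prob must be in [0, 1]",
         call. = FALSE)
  }
  if (any(ffq_bias <= 0)) stop("invalid error model: ffq_bias must be > 0",
                               call. = FALSE)
  structure(list(ffq_bias = ffq_bias, ffq_noise_sd = ffq_noise_sd,
                 recall_within_person_sd = recall_within_person_sd,
                 episodic_zero_prob = episodic_zero_prob,
                 repeat_drift = repeat_drift),
            class = "ffq_error_model")
}

.is_zero_error <- function(em) {
  all(em$ffq_bias == 1) && all(em$ffq_noise_sd == 0) &&
    all(em$recall_within_person_sd == 0) && all(em$repeat_drift == 0)
}

# median habitual intake frequency (intakes/day) per food group, split
# evenly across the group's items; synthetic but shaped like Nordic cohorts
# (coffee and fats frequent, legumes/seafood/meat substitutes episodic)
.group_freq_medians <- c(
  milk = 0.8, soured_milk = 0.5, cheese = 1.0, plant_dairy_alternatives = 0.1,
  wholegrain_products = 1.0, refined_grain_products = 0.5,
  porridge_cereals = 0.4, potatoes = 0.5, rice_pasta = 0.4, vegetables = 1.5,
  root_vegetables = 0.4, legumes = 0.15, fruits_berries = 1.2, juice = 0.2,
  nuts_seeds = 0.4, red_meat = 0.5, poultry = 0.25, sausages = 0.2,
  seafood = 0.25, eggs = 0.5, meat_substitutes = 0.08, fats_oils = 1.5,
  desserts_sweets = 0.6, snacks = 0.3, sugar_sweetened_beverages = 0.15,
  diet_beverages = 0.2, coffee = 2.5, tea = 0.5, alcoholic_beverages = 0.3,
  sauces_condiments = 0.8
)

.item_freq_medians <- function(schema) {
  g <- schema$items$group_id
  per_group <- table(g)[g]
  setNames(.group_freq_medians[g] / as.numeric(per_group),
           schema$items$item_id)
}

# latent dietary-pattern axes: items in these groups load (+/-) on a shared
# person-level factor, inducing the cross-category correlation that real
# eating patterns show (a prudent axis and a sweet/convenience axis)
.pattern_axes <- list(
  prudent = c(vegetables = 1, root_vegetables = 1, fruits_berries = 1,
              legumes = 1, wholegrain_products = 1, porridge_cereals = 1,
              nuts_seeds = 1, seafood = 1, tea = 1,
              red_meat = -1, sausages = -1, refined_grain_products = -1,
              sugar_sweetened_beverages = -1, desserts_sweets = -1,
              snacks = -1),
  sweet_convenience = c(desserts_sweets = 1, snacks = 1,
                        sugar_sweetened_beverages = 1, juice = 1,
                        sauces_condiments = 1, potatoes = 1, rice_pasta = 1,
                        diet_beverages = 1, meat_substitutes = -1,
                        coffee = 1))

# items x axes loading matrix with unit row norm where any loading exists
.pattern_loadings <- function(schema) {
  g <- schema$items$group_id
  L <- vapply(.pattern_axes, function(ax) {
    v <- ax[g]
    v[is.na(v)] <- 0
    v
  }, numeric(length(g)))
  nrm <- sqrt(rowSums(L^2))
  L[nrm > 0, ] <- L[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  L
}

#' Generator settings
#'
#' Bundles the study-design parameters the generator emulates: six scheduled
#' recall days with a completion distribution mirroring the attrition of a
#' real validation study (a majority completing all six, a tail completing
#' none or few), an age window of 35-64 years, roughly 60% women, and
#' habitual-intake medians per item with a common geometric standard
#' deviation of 2.5.
#'
#' @param schema an [ffq_schema()].
#' @param n_recall_days scheduled recall days; default 6.
#' @param completion_probs probabilities of completing 0..`n_recall_days`
#'   days.
#' @param freq_median named per-item median intake frequency (intakes/day);
#'   default a per-group table split across items.
#' @param freq_gsd geometric standard deviation of habitual intake across
#'   participants.
#' @param female_prop,age_range cohort demographics.
#' @param item_missing_prob per-item probability of a skipped FFQ answer.
#' @param portion_missing_prob per-indication probability of a skipped
#'   portion photo answer.
#' @param pattern_strength share of a loaded item's between-person log-scale
#'   variance carried by the latent dietary-pattern factors (0 = independent
#'   categories); default 0.35, which reproduces the explanatory power
#'   (R2 roughly 25-35% for two components) that pattern models show on
#'   real food-group intake data.
#' @param photo_level_probs distribution of true portion-photo levels 1-4.
#' @param mapping frequency mapping, see [default_frequency_mapping()].
#' @param composition composition table, see [default_composition()].
#' @param portions portion tables, see [default_portion_table()].
#' @return list of class `ffq_cohort_config`.
#' @export
cohort_config <- function(schema = ffq_schema(), n_recall_days = 6,
                          completion_probs = c(0.081, 0.052, 0.052, 0.052,
                                               0.027, 0.027, 0.709),
                          freq_median = NULL, freq_gsd = 2.5,
                          female_prop = 0.611, age_range = c(35, 64),
                          item_missing_prob = 0.01,
                          portion_missing_prob = 0,
                          pattern_strength = 0.35,
                          photo_level_probs = c(0.2, 0.35, 0.3, 0.15),
                          mapping = default_frequency_mapping(),
                          composition = default_composition(schema),
                          portions = default_portion_table(schema)) {
  if (length(completion_probs) != n_recall_days + 1) {
    stop("completion_probs must have n_recall_days + 1 entries", call. = FALSE)
  }
  if (abs(sum(completion_probs) - 1) > 1e-8) {
    stop("completion_probs must sum to 1", call. = FALSE)
  }
  if (freq_gsd <= 1) stop("freq_gsd must be > 1", call. = FALSE)
  if (pattern_strength < 0 || pattern_strength > 1) {
    stop("pattern_strength must be in [0, 1]", call. = FALSE)
  }
  if (is.null(freq_median)) freq_median <- .item_freq_medians(schema)
  validate_frequency_mapping(mapping)
  structure(list(schema = schema, n_recall_days = n_recall_days,
                 completion_probs = completion_probs,
                 freq_median = freq_median, freq_gsd = freq_gsd,
                 female_prop = female_prop, age_range = age_range,
                 item_missing_prob = item_missing_prob,
                 portion_missing_prob = portion_missing_prob,
                 pattern_strength = pattern_strength,
                 photo_level_probs = photo_level_probs, mapping = mapping,
                 composition = composition, portions = portions),
            class = "ffq_cohort_config")
}

#' Discretise a continuous frequency to the nine-level scale
#'
#' Assigns the level whose representative daily value is nearest; a value
#' exactly midway between two levels goes to the lower one, and values above
#' the top representative truncate to the top level.
#'
#' @param f numeric frequencies (intakes/day).
#' @param mapping frequency mapping.
#' @return integer level codes 1..9.
#' @export
discretise_frequency <- function(f, mapping = default_frequency_mapping()) {
  validate_frequency_mapping(mapping)
  bounds <- (mapping[-1] + mapping[-9]) / 2
  1L + vapply(f, function(v) sum(v > bounds), integer(1))
}

#' Simulate one set of FFQ responses from a true diet profile
#'
#' Applies the FFQ error model (multiplicative bias, log-normal noise) to the
#' true frequencies and discretises to the nine-level scale. Zero truth maps
#' to "never" regardless of noise.
#'
#' @param truth_freq named numeric vector of true intake frequencies.
#' @param em an [error_model()].
#' @param mapping frequency mapping.
#' @param seed optional seed for a self-contained draw; if NULL the current
#'   RNG stream is used.
#' @return integer vector of level codes 1..9, named as `truth_freq`.
#' @export
simulate_ffq_responses <- function(truth_freq, em = error_model(),
                                   mapping = default_frequency_mapping(),
                                   seed = NULL) {
  draw <- function() {
    noisy <- truth_freq * em$ffq_bias *
      exp(rnorm(length(truth_freq), 0, em$ffq_noise_sd))
    noisy[truth_freq == 0] <- 0
    setNames(discretise_frequency(noisy, mapping), names(truth_freq))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic validation study
#'
#' Draws a complete study dataset: participant anthropometrics, a baseline
#' and a repeat FFQ per participant, up to `n_recall_days` recall day
#' records, and the latent truth, all reproducible from the seed. When every
#' error term of the model is switched off (all sds 0, biases 1), the
#' generator runs in an exact diagnostic mode: true frequencies are drawn on
#' the nine-level representative grid and recall occasions are emitted so
#' that both instruments reproduce the truth exactly -- the configuration
#' used for end-to-end identity checks.
#'
#' @param n number of participants (>= 1).
#' @param em an [error_model()].
#' @param config a [cohort_config()].
#' @param seed integer seed; required for reproducibility.
#' @return list of class `ffq_study`: `participants`, `ffq_baseline`,
#'   `ffq_repeat`, `recalls`, `truth` (list: `frequency`, `portion_g`,
#'   `energy_kcal`, `photo_levels`), `config`, `error_model`, `seed`.
#' @export
generate_cohort <- function(n, em = error_model(), config = cohort_config(),
                            seed) {
  stopifnot(n >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!inherits(em, "ffq_error_model")) em <- do.call(error_model, em)
  schema <- config$schema
  items <- schema$items
  n_items <- nrow(items)
  bias <- rep(em$ffq_bias, length.out = n_items)
  p0 <- rep(em$episodic_zero_prob, length.out = n_items)
  zero_error <- .is_zero_error(em)
  mapping <- config$mapping

  withr::with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(runif(n) < config$female_prop, "female", "male")
    age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    height <- ifelse(sex == "male", rnorm(n, 180, 7), rnorm(n, 167, 6))
    bmi <- pmax(rnorm(n, 26.1, 4.3), 16)
    weight <- round(bmi * (height / 100)^2, 1)
    days <- sample(0:config$n_recall_days, n, replace = TRUE,
                   prob = config$completion_probs)
    participants <- data.frame(
      participant_id = ids, sex = sex, age = age,
      height_cm = round(height, 1), weight_kg = weight,
      completed_recall_days = days, stringsAsFactors = FALSE)

    # latent truth: habitual frequency per participant x item
    if (zero_error) {
      grid_probs <- c(0.15, 0.15, 0.15, 0.15, 0.12, 0.10, 0.08, 0.06, 0.04)
      lambda <- matrix(sample(unname(mapping), n * n_items, replace = TRUE,
                              prob = grid_probs), n, n_items)
    } else {
      z <- matrix(rnorm(n * n_items), n, n_items)
      s <- config$pattern_strength
      if (s > 0) {
        L <- .pattern_loadings(schema)
        u <- matrix(rnorm(n * ncol(L)), n, ncol(L))
        si <- s * rowSums(L^2)  # per-item pattern share (0 if unloaded)
        z <- sweep(z, 2, sqrt(1 - si), "*") + sqrt(s) * tcrossprod(u, L)
      }
      lambda <- exp(rep(log(config$freq_median), each = n) +
                      log(config$freq_gsd) * z)
      dim(lambda) <- c(n, n_items)
      lambda <- pmin(lambda, 4)  # mirror the instrument's upper bound
    }
    mask <- matrix(rbinom(n * n_items, 1, rep(1 - p0, each = n)), n, n_items)
    lambda <- lambda * mask
    dimnames(lambda) <- list(ids, items$item_id)

    # true portions: participant photo levels + natural/demographic grams
    photo_levels <- cbind(
      portion_starch = sample(1:4, n, TRUE, config$photo_level_probs),
      portion_protein = sample(1:4, n, TRUE, config$photo_level_probs),
      portion_vegetable = sample(1:4, n, TRUE, config$photo_level_probs))
    rownames(photo_levels) <- ids
    rec_stub <- data.frame(participant_id = ids, photo_levels,
                           stringsAsFactors = FALSE)
    portion_g <- assign_portion_sizes(rec_stub, participants, schema,
                                      config$portions)

    make_ffq <- function(lambda_adm, missing_ok = TRUE) {
      noisy <- lambda_adm * rep(bias, each = n) *
        exp(matrix(rnorm(n * n_items, 0, em$ffq_noise_sd), n, n_items))
      noisy[lambda_adm == 0] <- 0
      resp <- matrix(discretise_frequency(noisy, mapping), n, n_items,
                     dimnames = list(NULL, items$item_id))
      if (missing_ok && !zero_error && config$item_missing_prob > 0) {
        resp[matrix(runif(n * n_items) < config$item_missing_prob,
                    n, n_items)] <- NA
      }
      ind <- photo_levels
      if (missing_ok && !zero_error && config$portion_missing_prob > 0) {
        ind[matrix(runif(n * 3) < config$portion_missing_prob, n, 3)] <- NA
      }
      data.frame(participant_id = ids, resp, ind, check.names = FALSE,
                 stringsAsFactors = FALSE)
    }
    ffq_baseline <- make_ffq(lambda)
    lambda_repeat <- lambda * exp(rep(rep(em$repeat_drift,
                                          length.out = n_items), each = n))
    ffq_repeat <- make_ffq(lambda_repeat)

    # recall days
    if (zero_error) {
      has_days <- days >= 1
      nz <- which(lambda[has_days, , drop = FALSE] > 0, arr.ind = TRUE)
      pidx <- which(has_days)[nz[, 1]]
      occ <- lambda[cbind(pidx, nz[, 2])] * days[pidx]
      recalls <- data.frame(
        participant_id = ids[pidx], day = 1L, date_class = "weekday",
        food_id = items$item_id[nz[, 2]], occasions = occ,
        amount_g = occ * portion_g[cbind(pidx, nz[, 2])],
        stringsAsFactors = FALSE)
    } else {
      pday <- rep(seq_len(n), days)
      day_no <- sequence(days)
      rate <- lambda[pday, , drop = FALSE]
      counts <- matrix(rpois(length(rate), rate), nrow = nrow(rate))
      nz <- which(counts > 0, arr.ind = TRUE)
      occ <- counts[nz]
      amount <- occ * portion_g[cbind(pday[nz[, 1]], nz[, 2])] *
        exp(rnorm(length(occ), 0, em$recall_within_person_sd))
      recalls <- data.frame(
        participant_id = ids[pday[nz[, 1]]], day = day_no[nz[, 1]],
        date_class = ifelse(runif(length(occ)) < 2 / 7, "weekend", "weekday"),
        food_id = items$item_id[nz[, 2]], occasions = occ,
        amount_g = amount, stringsAsFactors = FALSE)
    }
    recalls <- recalls[order(recalls$participant_id, recalls$day,
                             recalls$food_id), , drop = FALSE]
    rownames(recalls) <- NULL

    truth_freq_df <- data.frame(participant_id = ids, lambda,
                                check.names = FALSE, stringsAsFactors = FALSE)
    energy <- estimate_nutrients(truth_freq_df, portion_g,
                                 config$composition, schema)$energy_kcal
    structure(list(
      participants = participants, ffq_baseline = ffq_baseline,
      ffq_repeat = ffq_repeat, recalls = recalls,
      truth = list(frequency = lambda, portion_g = portion_g,
                   energy_kcal = setNames(energy, ids),
                   photo_levels = photo_levels),
      config = config, error_model = em, seed = seed),
      class = "ffq_study")
  })
}

#' @export
print.ffq_study <- function(x, ...) {
  cat("<ffq_study> ", nrow(x$participants), " participants, ",
      nrow(x$config$schema$items), " items, seed ", x$seed, "\n", sep = "")
  cat("  recall days completed: ",
      paste(table(x$participants$completed_recall_days), collapse = "/"),
      " (0..", x$config$n_recall_days, ")\n", sep = "")
  invisible(x)
}
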