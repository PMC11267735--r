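## Plain-text study IO: the four study tables plus the truth, a data
## dictionary, and a YAML echo of the scalar generator settings.

#' Write a study dataset as CSV files
#'
#' Writes `participants.csv`, `ffq_baseline.csv`, `ffq_repeat.csv`,
#' `recalls.csv`, `truth_frequencies.csv`, a `data_dictionary.csv`
#' documenting every column, and `config.yaml` with the scalar generator
#' settings.
#'
#' @param study an `ffq_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write.csv(study$ffq_baseline, file.path(dir, "ffq_baseline.csv"),
            row.names = FALSE)
  write.csv(study$ffq_repeat, file.path(dir, "ffq_repeat.csv"),
            row.names = FALSE)
  write.csv(study$recalls, file.path(dir, "recalls.csv"), row.names = FALSE)
  truth <- data.frame(participant_id = rownames(study$truth$frequency),
                      study$truth$frequency, check.names = FALSE)
  write.csv(truth, file.path(dir, "truth_frequencies.csv"), row.names = FALSE)
  dict <- rbind(
    data.frame(file = "participants.csv",
               column = c("participant_id", "sex", "age", "height_cm",
                          "weight_kg", "completed_recall_days"),
               description = c("opaque identifier", "male/female", "years",
                               "measured height, cm", "measured weight, kg",
                               "completed recall days, 0..scheduled")),
    data.frame(file = "ffq_*.csv",
               column = c("item_*", "portion_starch", "portion_protein",
                          "portion_vegetable"),
               description = c("frequency level code 1-9 (NA = unanswered)",
                               rep("portion photo level 1-4 (NA = unanswered)",
                                   3))),
    data.frame(file = "recalls.csv",
               column = c("participant_id", "day", "date_class", "food_id",
                          "occasions", "amount_g"),
               description = c("participant", "recall day index",
                               "weekday/weekend", "questionnaire category id",
                               "eating occasions on that day", "grams eaten")),
    data.frame(file = "truth_frequencies.csv", column = "item_*",
               description = "latent habitual intake frequency, intakes/day"))
  write.csv(dict, file.path(dir, "data_dictionary.csv"), row.names = FALSE)
  cfg <- study$config
  yaml::write_yaml(
    list(seed = study$seed,
         n_recall_days = cfg$n_recall_days,
         completion_probs = cfg$completion_probs,
         freq_gsd = cfg$freq_gsd, female_prop = cfg$female_prop,
         age_range = cfg$age_range,
         item_missing_prob = cfg$item_missing_prob,
         portion_missing_prob = cfg$portion_missing_prob,
         error_model = unclass(study$error_model),
         frequency_mapping = as.list(cfg$mapping)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study dataset written by [write_cohort()]
#'
#' @param dir directory holding the CSV files.
#' @param config a [cohort_config()] describing the schema and tables to
#'   analyse the data with; defaults to the packaged defaults.
#' @return list of class `ffq_study` (without an error model; the truth is
#'   restored from `truth_frequencies.csv` when present).
#' @export
read_cohort <- function(dir, config = cohort_config()) {
  rd <- function(f) read.csv(file.path(dir, f), check.names = FALSE,
                             stringsAsFactors = FALSE)
  study <- list(participants = rd("participants.csv"),
                ffq_baseline = rd("ffq_baseline.csv"),
                ffq_repeat = rd("ffq_repeat.csv"),
                recalls = rd("recalls.csv"),
                config = config)
  tf <- file.path(dir, "truth_frequencies.csv")
  if (file.exists(tf)) {
    truth <- rd("truth_frequencies.csv")
    m <- as.matrix(truth[, -1])
    rownames(m) <- truth$participant_id
    study$truth <- list(frequency = m)
  }
  cf <- file.path(dir, "config.yaml")
  if (file.exists(cf)) study$seed <- yaml::read_yaml(cf)$seed
  structure(study, class = "ffq_study")
}
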