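# Builders for small hand-checkable fixtures.

# wide FFQ record table: responses is a matrix/vector of level codes (1..9 or
# NA), one row per participant
make_records <- function(responses, portions = c(2, 2, 2),
                         ids = NULL, schema = ffq_schema()) {
  responses <- rbind(responses)
  n <- nrow(responses)
  stopifnot(ncol(responses) == nrow(schema$items))
  colnames(responses) <- schema$items$item_id
  portions <- matrix(rep(portions, length.out = 3 * n), nrow = n, byrow = TRUE,
                     dimnames = list(NULL, c("portion_starch",
                                             "portion_protein",
                                             "portion_vegetable")))
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  data.frame(participant_id = ids, responses, portions,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# long recall table from per-(participant, day, item) occasion counts
make_recalls <- function(participant_id, day, food_id, occasions,
                         amount_g = occasions * 100) {
  data.frame(participant_id = participant_id, day = day,
             date_class = rep("weekday", length(participant_id)),
             food_id = food_id,
             occasions = occasions, amount_g = amount_g,
             stringsAsFactors = FALSE)
}

# a full nutrient-intake row set with named overrides, zeros elsewhere
make_nutrients <- function(ids, ...) {
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (nm in nutrient_names()) out[[nm]] <- 0
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# zero-error model: both instruments reproduce the truth exactly
zero_error_model <- function() {
  error_model(ffq_bias = 1, ffq_noise_sd = 0, recall_within_person_sd = 0,
              episodic_zero_prob = 0)
}
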