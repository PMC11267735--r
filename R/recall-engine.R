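## Recall engine: harmonise 24-hour recall day records to the questionnaire
## category space and apply inclusion rules.
##
## Recalls are a long data.frame: one row per (participant, day, food), with
## columns `participant_id`, `day`, `date_class`, `food_id`, `occasions`,
## `amount_g`. A food-to-item map translates recall food ids into
## questionnaire categories; by default food ids are already category ids.

.map_foods <- function(recalls, schema, food_map = NULL) {
  if (is.null(food_map)) {
    item_id <- recalls$food_id
  } else {
    stopifnot(all(c("food_id", "item_id") %in% names(food_map)))
    item_id <- food_map$item_id[match(recalls$food_id, food_map$food_id)]
  }
  unknown <- !(item_id %in% schema$items$item_id)
  if (any(unknown)) {
    stop("recall food id not mapped to any questionnaire category: ",
         recalls$food_id[which(unknown)[1]], call. = FALSE)
  }
  item_id
}

.completed_days <- function(recalls, participants = NULL) {
  if (!is.null(participants)) {
    setNames(participants$completed_recall_days, participants$participant_id)
  } else {
    tab <- tapply(recalls$day, recalls$participant_id,
                  function(d) length(unique(d)))
    setNames(as.integer(tab), names(tab))
  }
}

#' Daily intake frequencies from recall days
#'
#' For each participant and questionnaire category, sums eating occasions over
#' all recall days and divides by the number of completed recall days,
#' yielding intakes/day on the same scale as the FFQ-derived frequencies.
#' Days with no reported items count as completed days when the completed-day
#' count is supplied through `participants` (a fasting day is information).
#'
#' @param recalls long recall data.frame (see above); must cover >= 1 day per
#'   participant included.
#' @param schema an [ffq_schema()].
#' @param food_map optional data.frame `food_id` -> `item_id`; NULL means
#'   food ids already are category ids.
#' @param participants optional participant table carrying
#'   `completed_recall_days`; if NULL, days observed in `recalls` are counted.
#' @return data.frame `participant_id` plus one intakes/day column per item;
#'   attribute `source` = "recall".
#' @export
recall_daily_frequencies <- function(recalls, schema = ffq_schema(),
                                     food_map = NULL, participants = NULL) {
  if (nrow(recalls) == 0) stop("no completed recall days", call. = FALSE)
  item_id <- .map_foods(recalls, schema, food_map)
  days <- .completed_days(recalls, participants)
  if (any(days[unique(as.character(recalls$participant_id))] < 1)) {
    stop("no completed recall days", call. = FALSE)
  }
  days <- days[days >= 1]
  ids <- names(days)
  m <- matrix(0, nrow = length(ids), ncol = nrow(schema$items),
              dimnames = list(ids, schema$items$item_id))
  pi <- match(as.character(recalls$participant_id), ids)
  ci <- match(item_id, schema$items$item_id)
  sums <- rowsum(recalls$occasions, group = (ci - 1L) * length(ids) + pi)
  m[as.integer(rownames(sums))] <- sums
  m <- m / as.numeric(days)
  out <- data.frame(participant_id = ids, m, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "source") <- "recall"
  out
}

#' Energy and nutrient intakes from recall days
#'
#' Per participant and nutrient: the sum over all recorded items of amount in
#' grams times the per-gram nutrient content, divided by the number of
#' completed recall days.
#'
#' @inheritParams recall_daily_frequencies
#' @param composition per-100 g composition table keyed by `item_id`, see
#'   [default_composition()].
#' @return data.frame `participant_id` plus [nutrient_names()] columns
#'   (per day); attribute `source` = "recall".
#' @export
recall_nutrients <- function(recalls, composition, schema = ffq_schema(),
                             food_map = NULL, participants = NULL) {
  if (nrow(recalls) == 0) stop("no completed recall days", call. = FALSE)
  item_id <- .map_foods(recalls, schema, food_map)
  comp_row <- match(item_id, composition$item_id)
  if (anyNA(comp_row)) {
    stop("no composition entry for food: ", item_id[which(is.na(comp_row))[1]],
         call. = FALSE)
  }
  days <- .completed_days(recalls, participants)
  days <- days[days >= 1]
  ids <- names(days)
  nut <- as.matrix(composition[, nutrient_names()]) / 100  # per gram
  contrib <- recalls$amount_g * nut[comp_row, , drop = FALSE]
  totals <- rowsum(contrib, group = as.character(recalls$participant_id))
  out <- matrix(0, nrow = length(ids), ncol = length(nutrient_names()),
                dimnames = list(ids, nutrient_names()))
  out[rownames(totals), ] <- totals
  out <- out / as.numeric(days)
  res <- data.frame(participant_id = ids, out, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "source") <- "recall"
  res
}

#' Inclusion filter on completed recall days
#'
#' Restricts a study dataset to participants with at least `min_days`
#' completed recall days and reports the attrition steps (consented, at least
#' one day, at least `min_days` days).
#'
#' @param study a study dataset from [generate_cohort()] (or any list with a
#'   `participants` table and matching `ffq_baseline`, `ffq_repeat`,
#'   `recalls` tables).
#' @param min_days minimum completed recall days; default 4.
#' @return The filtered study (same shape), with an `attrition` data.frame
#'   attached listing counts at each step.
#' @export
inclusion_filter <- function(study, min_days = 4) {
  stopifnot(min_days >= 1)
  p <- study$participants
  keep <- p$completed_recall_days >= min_days
  attrition <- data.frame(
    step = c("consented", "completed_ge_1_day",
             paste0("completed_ge_", min_days, "_days")),
    n = c(nrow(p), sum(p$completed_recall_days >= 1), sum(keep))
  )
  ids <- p$participant_id[keep]
  out <- study
  out$participants <- p[keep, , drop = FALSE]
  for (tab in c("ffq_baseline", "ffq_repeat")) {
    if (!is.null(study[[tab]])) {
      out[[tab]] <- study[[tab]][study[[tab]]$participant_id %in% ids, ,
                                 drop = FALSE]
    }
  }
  if (!is.null(study$recalls)) {
    out$recalls <- study$recalls[study$recalls$participant_id %in% ids, ,
                                 drop = FALSE]
  }
  if (!is.null(study$truth)) {
    tkeep <- rownames(study$truth$frequency) %in% ids
    out$truth <- study$truth
    out$truth$frequency <- study$truth$frequency[tkeep, , drop = FALSE]
    out$truth$portion_g <- study$truth$portion_g[tkeep, , drop = FALSE]
  }
  out$attrition <- attrition
  out
}
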