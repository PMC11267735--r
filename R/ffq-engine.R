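## FFQ engine: raw questionnaire records -> daily intake frequencies,
## data-quality classification, and portion assignment.
##
## Records are held as a wide data.frame: one row per participant, columns
## `participant_id`, `item_001`..`item_NNN` (integer frequency-level codes
## 1..9 or NA for unanswered) and `portion_starch`, `portion_protein`,
## `portion_vegetable` (1..4 or NA).

.item_cols <- function(records, schema) {
  miss <- setdiff(schema$items$item_id, names(records))
  if (length(miss)) {
    stop("FFQ records are missing item columns: ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) " ...", call. = FALSE)
  }
  as.matrix(records[, schema$items$item_id, drop = FALSE])
}

#' Transform frequency responses to daily intake frequencies
#'
#' Maps each answered item through the nine-level frequency mapping to obtain
#' intakes/day in the closed range 0 to 4. Unanswered items are imputed as 0
#' intakes/day ("never"); the imputation is recorded in the `imputed`
#' attribute so downstream provenance is preserved.
#'
#' @param records wide FFQ record data.frame (see package overview); may hold
#'   one or many participants.
#' @param mapping named numeric vector, see [default_frequency_mapping()].
#' @param schema an [ffq_schema()].
#' @return data.frame `participant_id` plus one intakes/day column per item;
#'   attribute `imputed` is the logical matrix of imputed cells.
#' @export
frequencies_to_daily <- function(records, mapping = default_frequency_mapping(),
                                 schema = ffq_schema()) {
  validate_frequency_mapping(mapping)
  resp <- .item_cols(records, schema)
  bad <- which(!is.na(resp) & (resp < 1 | resp > 9 | resp != floor(resp)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("response level outside the nine-level scale for item ",
         colnames(resp)[bad[1, 2]], " (participant ",
         records$participant_id[bad[1, 1]], ")", call. = FALSE)
  }
  imputed <- is.na(resp)
  vals <- matrix(unname(mapping)[resp], nrow = nrow(resp),
                 dimnames = dimnames(resp))
  vals[imputed] <- 0
  out <- data.frame(participant_id = records$participant_id, vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "imputed") <- imputed
  attr(out, "source") <- "ffq"
  out
}

#' Classify record quality into exclude levels
#'
#' Three-tier quality score used for cohort curation: level 2 if any of the
#' three portion indications is unanswered; otherwise level 1 if 10% or more
#' of the frequency items are unanswered; otherwise level 0 (usable).
#'
#' @param records wide FFQ record data.frame.
#' @param schema an [ffq_schema()].
#' @param missing_threshold fraction of unanswered items at or above which a
#'   record with complete portions is exclude level 1; default 0.10.
#' @return data.frame with `participant_id`, `missing_fraction`,
#'   `portion_complete`, `exclude_level`.
#' @export
assign_exclude_level <- function(records, schema = ffq_schema(),
                                 missing_threshold = 0.10) {
  resp <- .item_cols(records, schema)
  pcols <- c("portion_starch", "portion_protein", "portion_vegetable")
  miss <- setdiff(pcols, names(records))
  if (length(miss)) stop("records lack portion columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  portions <- as.matrix(records[, pcols, drop = FALSE])
  missing_fraction <- rowMeans(is.na(resp))
  portion_complete <- rowSums(is.na(portions)) == 0
  exclude_level <- ifelse(!portion_complete, 2L,
                          ifelse(missing_fraction >= missing_threshold, 1L, 0L))
  data.frame(participant_id = records$participant_id,
             missing_fraction = missing_fraction,
             portion_complete = portion_complete,
             exclude_level = exclude_level,
             stringsAsFactors = FALSE)
}

#' Assign per-category portion sizes
#'
#' Resolves a gram portion for every questionnaire category of every
#' participant: photo-class items (starch/protein/vegetable plates) use the
#' participant's indicated photo level, fixed-natural items use their natural
#' unit grams, and the remaining items use the sex x 10-year-age-band median
#' table.
#'
#' @param records wide FFQ record data.frame (for the portion indications).
#' @param participants data.frame with `participant_id`, `sex`, `age`.
#' @param schema an [ffq_schema()].
#' @param portions a [default_portion_table()]-style object.
#' @param impute_missing_photo if TRUE, a missing portion indication falls
#'   back to photo level 2; default FALSE, in which case it is an error
#'   (such records are exclude level 2 and normally filtered out first).
#' @return numeric matrix participants x items, grams per intake.
#' @export
assign_portion_sizes <- function(records, participants,
                                 schema = ffq_schema(),
                                 portions = default_portion_table(schema),
                                 impute_missing_photo = FALSE) {
  items <- schema$items
  idx <- match(records$participant_id, participants$participant_id)
  if (anyNA(idx)) stop("record references unknown participant: ",
                       records$participant_id[which(is.na(idx))[1]],
                       call. = FALSE)
  sex <- participants$sex[idx]
  band <- as.character(.age_band(participants$age[idx]))
  out <- matrix(NA_real_, nrow = nrow(records), ncol = nrow(items),
                dimnames = list(NULL, items$item_id))
  photo_col <- c(starch = "portion_starch", protein = "portion_protein",
                 vegetable = "portion_vegetable")
  for (j in seq_len(nrow(items))) {
    cls <- items$portion_class[j]
    if (cls %in% names(photo_col)) {
      lev <- records[[photo_col[[cls]]]]
      if (anyNA(lev)) {
        if (impute_missing_photo) lev[is.na(lev)] <- 2L
        else stop("missing portion indication (", cls, ") for participant ",
                  records$participant_id[which(is.na(lev))[1]],
                  "; record is exclude level 2", call. = FALSE)
      }
      if (any(lev < 1 | lev > 4)) stop("portion indication outside 1-4")
      out[, j] <- portions$photo[cls, lev]
    } else if (cls == "fixed_natural") {
      out[, j] <- items$natural_g[j]
    } else {
      key <- paste(sex, band, items$item_id[j])
      demo_key <- paste(portions$demographic$sex, portions$demographic$age_band,
                        portions$demographic$item_id)
      m <- match(key, demo_key)
      if (anyNA(m)) {
        k <- which(is.na(m))[1]
        stop("no demographic portion entry for (", sex[k], ", ", band[k],
             ", ", items$item_id[j], ")", call. = FALSE)
      }
      out[, j] <- portions$demographic$grams[m]
    }
  }
  rownames(out) <- records$participant_id
  out
}
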