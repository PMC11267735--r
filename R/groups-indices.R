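## Food-group aggregation and a priori diet-index scoring.

#' Default 30-group mapping
#'
#' The shipped mapping assigns each questionnaire item to exactly one of the
#' 30 food groups defined by the schema.
#' @param schema an [ffq_schema()].
#' @return Named list: group id -> character vector of item ids.
#' @export
default_group_mapping <- function(schema = ffq_schema()) {
  split(schema$items$item_id, schema$items$group_id)[schema$groups$group_id]
}

#' Aggregate category intakes into food groups
#'
#' Each group value is the exact sum of its member category intakes/day.
#'
#' @param intakes data.frame from [frequencies_to_daily()] or
#'   [recall_daily_frequencies()] (`participant_id` + item columns).
#' @param mapping named list group id -> item ids; default the 30-group map.
#' @param schema an [ffq_schema()].
#' @return data.frame `participant_id` plus one intakes/day column per group;
#'   the `source` attribute of `intakes` is carried over.
#' @export
aggregate_food_groups <- function(intakes, mapping = NULL,
                                  schema = ffq_schema()) {
  if (is.null(mapping)) mapping <- default_group_mapping(schema)
  if (any(lengths(mapping) == 0)) stop("empty food group in mapping")
  unknown <- setdiff(unlist(mapping), names(intakes))
  if (length(unknown)) {
    stop("group mapping references unknown category: ", unknown[1],
         call. = FALSE)
  }
  m <- vapply(mapping, function(ids) {
    rowSums(as.matrix(intakes[, ids, drop = FALSE]))
  }, numeric(nrow(intakes)))
  if (nrow(intakes) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(mapping)))
  out <- data.frame(participant_id = intakes$participant_id, m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "source") <- attr(intakes, "source")
  out
}

#' Construct a diet-index specification
#'
#' An index is a sum of component scores. Each component is the combined
#' intake of one or more food groups, ranked within the scoring cohort and
#' converted to points by its cut rule: `median` (0/1), `tertile` (0/1/2),
#' `quintile` (1..5), or `range` (full points inside a closed interval, zero
#' outside). Direction `-` reverses the point order (higher intake, fewer
#' points). Values equal to a cut point fall in the higher rank class
#' (the at-or-above-median convention).
#'
#' @param id index identifier.
#' @param components list of lists with fields `groups` (character), `direction`
#'   (`"+"` or `"-"`), `cut` (one of median/tertile/quintile/range), and for
#'   `range` a numeric `range = c(lo, hi)` plus `points` (points when inside).
#' @param stratify_by_sex compute rank cut points within sex strata.
#' @return Object of class `diet_index_spec`.
#' @export
diet_index_spec <- function(id, components, stratify_by_sex = FALSE) {
  for (cmp in components) {
    stopifnot(is.character(cmp$groups), cmp$direction %in% c("+", "-"),
              cmp$cut %in% c("median", "tertile", "quintile", "range"))
    if (cmp$cut == "range") stopifnot(length(cmp$range) == 2)
  }
  structure(list(id = id, components = components,
                 stratify_by_sex = stratify_by_sex),
            class = "diet_index_spec")
}

.cut_points <- function(cmp) {
  switch(cmp$cut,
         median = c(0, 1), tertile = c(0, 1, 2), quintile = 1:5,
         range = c(0, if (is.null(cmp$points)) 2 else cmp$points))
}

.score_component <- function(values, cmp, warn_id = "") {
  pts <- .cut_points(cmp)
  if (cmp$cut == "range") {
    inside <- values >= cmp$range[1] & values <= cmp$range[2]
    return(ifelse(inside, pts[2], pts[1]))
  }
  if (cmp$direction == "-") pts <- rev(pts)
  k <- length(pts)
  if (isTRUE(all.equal(var(values), 0)) || length(unique(values)) == 1L) {
    warning("constant component (", paste(cmp$groups, collapse = "+"),
            ") in index ", warn_id, "; all participants get lowest-rank points")
    return(rep(pts[1], length(values)))
  }
  cuts <- quantile(values, probs = seq_len(k - 1) / k, type = 7, names = FALSE)
  cls <- 1L + vapply(values, function(v) sum(v >= cuts), integer(1))
  pts[cls]
}

#' Score a diet index across a cohort
#'
#' Rank-class cut points (median/tertile/quintile) are computed within the
#' scoring cohort itself -- and within sex strata when the spec requests it --
#' so scores are relative to the analysed sample, as is standard for these
#' indices. Scores from different recording methods are each ranked within
#' their own method unless a shared cohort is passed explicitly.
#'
#' @param group_intakes data.frame from [aggregate_food_groups()].
#' @param spec a [diet_index_spec()].
#' @param sex optional character vector (one per row) when the spec
#'   stratifies by sex.
#' @return data.frame `participant_id`, `score` (integer-valued).
#' @export
score_index <- function(group_intakes, spec, sex = NULL) {
  stopifnot(inherits(spec, "diet_index_spec"))
  n <- nrow(group_intakes)
  strata <- if (spec$stratify_by_sex) {
    if (is.null(sex)) stop("spec stratifies by sex but no sex vector given")
    as.character(sex)
  } else rep("all", n)
  score <- numeric(n)
  for (cmp in spec$components) {
    miss <- setdiff(cmp$groups, names(group_intakes))
    if (length(miss)) stop("index component references unknown group: ",
                           miss[1], call. = FALSE)
    values <- rowSums(as.matrix(group_intakes[, cmp$groups, drop = FALSE]))
    for (s in unique(strata)) {
      i <- strata == s
      score[i] <- score[i] + .score_component(values[i], cmp, spec$id)
    }
  }
  data.frame(participant_id = group_intakes$participant_id, score = score,
             stringsAsFactors = FALSE)
}

#' Score range implied by an index spec
#' @param spec a [diet_index_spec()].
#' @return numeric c(min, max).
#' @export
index_score_range <- function(spec) {
  lo <- hi <- 0
  for (cmp in spec$components) {
    pts <- .cut_points(cmp)
    lo <- lo + min(pts)
    hi <- hi + max(pts)
  }
  c(min = lo, max = hi)
}

#' Default diet-index specifications
#'
#' Ships three indices in the families used in Nordic FFQ validation work,
#' operationalised on the package's 30 food groups (the component lists are
#' package defaults, marked as such, and are plain data that can be replaced):
#' \describe{
#'   \item{rMED}{nine components scored 0-2 by cohort tertiles: positive for
#'     fruits and berries, vegetables (incl. roots), legumes, cereals
#'     (wholegrain + porridge), seafood and vegetable fats; negative for red
#'     and processed meat and for dairy; alcohol scores 2 points inside a
#'     moderate-intake window (between one drink a week and two a day) and 0
#'     outside. Range 0-18.}
#'   \item{HNFI}{six healthy Nordic components scored 0/1 at the cohort
#'     median: seafood, root vegetables, vegetables, fruits and berries,
#'     wholegrain products, porridge/oatmeal. Range 0-6.}
#'   \item{PDI}{eighteen components scored 1-5 by cohort quintiles: twelve
#'     plant groups ascending, six animal groups reversed. Range 18-90.}
#' }
#' @return Named list of [diet_index_spec()] objects.
#' @export
default_index_specs <- function() {
  plus <- function(groups, cut) list(groups = groups, direction = "+", cut = cut)
  minus <- function(groups, cut) list(groups = groups, direction = "-", cut = cut)
  rmed <- diet_index_spec("rMED", list(
    plus("fruits_berries", "tertile"),
    plus(c("vegetables", "root_vegetables"), "tertile"),
    plus("legumes", "tertile"),
    plus(c("wholegrain_products", "porridge_cereals"), "tertile"),
    plus("seafood", "tertile"),
    plus("fats_oils", "tertile"),
    minus(c("red_meat", "sausages"), "tertile"),
    minus(c("milk", "soured_milk", "cheese"), "tertile"),
    list(groups = "alcoholic_beverages", direction = "+", cut = "range",
         range = c(1 / 7, 2), points = 2)
  ))
  hnfi <- diet_index_spec("HNFI", list(
    plus("seafood", "median"),
    plus("root_vegetables", "median"),
    plus("vegetables", "median"),
    plus("fruits_berries", "median"),
    plus("wholegrain_products", "median"),
    plus("porridge_cereals", "median")
  ))
  pdi_plant <- c("wholegrain_products", "refined_grain_products", "potatoes",
                 "rice_pasta", "vegetables", "root_vegetables", "legumes",
                 "fruits_berries", "juice", "nuts_seeds",
                 "plant_dairy_alternatives", "sugar_sweetened_beverages")
  pdi_animal <- list("eggs", "seafood", "red_meat",
                     c("poultry", "sausages"),
                     c("milk", "soured_milk", "cheese"), "fats_oils")
  pdi <- diet_index_spec("PDI", c(
    lapply(pdi_plant, plus, cut = "quintile"),
    lapply(pdi_animal, minus, cut = "quintile")
  ))
  list(rMED = rmed, HNFI = hnfi, PDI = pdi)
}
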