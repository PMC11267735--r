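## Pipeline: orchestrates the full validation analysis from a study dataset
## to a validation report (correlations, cross-classification, agreement,
## reproducibility, intake patterns, descriptives, attrition accounting).

#' Analysis run configuration
#'
#' @param min_recall_days minimum completed recall days for inclusion in the
#'   validation group; default 4.
#' @param pal_under,pal_over energy-misreporting screening thresholds on the
#'   ratio of reported energy intake to resting energy expenditure (strictly
#'   below / at-or-above); defaults 0.7 and 3.0.
#' @param exclusion_policy `report_all` computes nutrient statistics both on
#'   the full group and on the subgroup inside the screening limits (the
#'   default, mirroring reporting both with and without exclusions);
#'   `exclude_pal_outliers` drops flagged participants from nutrient
#'   statistics; `flag_only` never excludes, only marks.
#' @param strata `none` or `sex` (sex-stratified sensitivity correlations).
#' @param pca_components components for the intake-pattern models.
#' @param index_specs diet-index specifications; default
#'   [default_index_specs()].
#' @return list of class `ffq_run_config`.
#' @export
run_config <- function(min_recall_days = 4, pal_under = 0.7, pal_over = 3.0,
                       exclusion_policy = c("report_all",
                                            "exclude_pal_outliers",
                                            "flag_only"),
                       strata = c("sex", "none"), pca_components = 2,
                       index_specs = default_index_specs()) {
  stopifnot(min_recall_days >= 1, pal_under > 0, pal_over > pal_under)
  structure(list(min_recall_days = min_recall_days, pal_under = pal_under,
                 pal_over = pal_over,
                 exclusion_policy = match.arg(exclusion_policy),
                 strata = match.arg(strata),
                 pca_components = pca_components,
                 index_specs = index_specs),
            class = "ffq_run_config")
}

.align <- function(df, ids) df[match(ids, df$participant_id), , drop = FALSE]

.validity_stats <- function(ref, test, ids, cor_method) {
  ct <- correlate(ref, test, cor_method)
  cc <- tertile_cross_classify(ref, test, ids)
  ba <- bland_altman(ref, test)
  c(list(coefficient = ct$coefficient, p_value = ct$p_value, n = ct$n),
    cc[c("pct_same", "pct_same_lowest", "pct_same_highest", "pct_adjacent",
         "pct_gross")],
    list(ba_mean_diff = ba$mean_diff, ba_sd_diff = ba$sd_diff,
         ba_loa_lower = ba$loa[1], ba_loa_upper = ba$loa[2],
         ba_outside = ba$n_above + ba$n_below))
}

#' Run the full validation analysis
#'
#' Executes the complete pipeline on a study dataset: inclusion filtering on
#' completed recall days, record-quality exclusion, frequency transformation
#' of both instruments, food-group aggregation, diet-index scoring, nutrient
#' estimation with energy-misreporting screening and energy adjustment, and
#' the statistics battery, plus repeat-FFQ reproducibility, intake-pattern
#' models per method, descriptives, attrition accounting and (optionally)
#' sex-stratified correlations. Deterministic given the inputs; the report
#' does not depend on input row order.
#'
#' @param study an `ffq_study` (from [generate_cohort()] or [read_cohort()]).
#' @param config a [run_config()].
#' @return list of class `validation_report`.
#' @export
run_validation <- function(study, config = run_config()) {
  schema <- study$config$schema
  mapping <- study$config$mapping
  composition <- study$config$composition

  # inclusion and quality filtering
  study <- inclusion_filter(study, config$min_recall_days)
  attrition <- study$attrition
  quality <- assign_exclude_level(study$ffq_baseline, schema)
  keep_ids <- sort(quality$participant_id[quality$exclude_level == 0])
  attrition <- rbind(attrition,
                     data.frame(step = "exclude_level_0",
                                n = length(keep_ids)))
  participants <- .align(study$participants, keep_ids)
  ffq_base <- .align(study$ffq_baseline, keep_ids)
  ffq_rep <- .align(study$ffq_repeat, keep_ids)
  recalls <- study$recalls[study$recalls$participant_id %in% keep_ids, ]

  # daily frequencies, groups, indices
  freq_ffq <- frequencies_to_daily(ffq_base, mapping, schema)
  freq_rep <- frequencies_to_daily(ffq_rep, mapping, schema)
  freq_rec <- .align(
    recall_daily_frequencies(recalls, schema, participants = participants),
    keep_ids)
  grp_ffq <- aggregate_food_groups(freq_ffq, schema = schema)
  grp_rep <- aggregate_food_groups(freq_rep, schema = schema)
  grp_rec <- aggregate_food_groups(freq_rec, schema = schema)
  scores <- lapply(config$index_specs, function(spec) {
    data.frame(
      participant_id = keep_ids,
      ffq = score_index(grp_ffq, spec, participants$sex)$score,
      ffq_repeat = score_index(grp_rep, spec, participants$sex)$score,
      recall = score_index(grp_rec, spec, participants$sex)$score)
  })

  # nutrients, screening, adjustment
  portions <- assign_portion_sizes(ffq_base, participants, schema,
                                   study$config$portions)
  nut_ffq <- estimate_nutrients(freq_ffq, portions, composition, schema)
  nut_rep <- estimate_nutrients(freq_rep, portions, composition, schema)
  nut_rec <- .align(
    recall_nutrients(recalls, composition, schema, participants = participants),
    keep_ids)
  ree <- resting_energy_expenditure(participants)
  pal_f <- pal_flag(nut_ffq$energy_kcal, ree, config$pal_under, config$pal_over)
  pal_r <- pal_flag(nut_rec$energy_kcal, ree, config$pal_under, config$pal_over)
  pal_outlier <- pal_f$flag != "plausible" | pal_r$flag != "plausible"
  attrition <- rbind(attrition,
                     data.frame(step = "within_pal_limits",
                                n = sum(!pal_outlier)))
  adj <- list(
    ffq_residual = energy_adjust(nut_ffq, "residual"),
    recall_residual = energy_adjust(nut_rec, "residual"),
    ffq_density = energy_adjust(nut_ffq, "density"),
    recall_density = energy_adjust(nut_rec, "density"))

  # statistics: food groups (rank-based)
  group_ids <- schema$groups$group_id
  food_groups <- do.call(rbind, lapply(group_ids, function(g) {
    s <- .validity_stats(grp_rec[[g]], grp_ffq[[g]], keep_ids, "spearman")
    data.frame(group = g, as.data.frame(s))
  }))

  # indices (product-moment, rank also reported)
  indices <- do.call(rbind, lapply(names(scores), function(ix) {
    sc <- scores[[ix]]
    s <- .validity_stats(sc$recall, sc$ffq, keep_ids, "pearson")
    data.frame(index = ix,
               mean_ffq = mean(sc$ffq), sd_ffq = sd(sc$ffq),
               mean_recall = mean(sc$recall), sd_recall = sd(sc$recall),
               as.data.frame(s),
               spearman = correlate(sc$recall, sc$ffq, "spearman")$coefficient)
  }))

  # energy and nutrients: raw and energy-adjusted, full group and screened
  use_sub <- config$exclusion_policy != "flag_only"
  nutrients <- do.call(rbind, lapply(nutrient_names(), function(nm) {
    full <- .validity_stats(nut_rec[[nm]], nut_ffq[[nm]], keep_ids, "pearson")
    row <- data.frame(
      nutrient = nm,
      mean_ffq = mean(nut_ffq[[nm]]), sd_ffq = sd(nut_ffq[[nm]]),
      mean_recall = mean(nut_rec[[nm]]), sd_recall = sd(nut_rec[[nm]]),
      as.data.frame(full),
      spearman = correlate(nut_rec[[nm]], nut_ffq[[nm]],
                           "spearman")$coefficient)
    row$pearson_residual_adj <- if (nm == "energy_kcal") NA_real_ else
      correlate(adj$recall_residual[[nm]], adj$ffq_residual[[nm]],
                "pearson")$coefficient
    row$pearson_density_adj <- if (nm == "energy_kcal") NA_real_ else
      correlate(adj$recall_density[[nm]], adj$ffq_density[[nm]],
                "pearson")$coefficient
    row$pearson_pal_screened <- if (use_sub && sum(!pal_outlier) >= 3) {
      correlate(nut_rec[[nm]][!pal_outlier], nut_ffq[[nm]][!pal_outlier],
                "pearson")$coefficient
    } else NA_real_
    row
  }))

  # reproducibility of the repeat FFQ
  repro_block <- function(base, rep_, vars, label) {
    do.call(rbind, lapply(vars, function(v) {
      r <- icc_agreement_average(cbind(base[[v]], rep_[[v]]))
      data.frame(kind = label, variable = v, icc = r$icc,
                 ci_lower = r$ci[1], ci_upper = r$ci[2], band = r$band,
                 pearson = correlate(base[[v]], rep_[[v]],
                                     "pearson")$coefficient)
    }))
  }
  idx_base <- data.frame(lapply(scores, function(s) s$ffq))
  idx_rep <- data.frame(lapply(scores, function(s) s$ffq_repeat))
  reproducibility <- rbind(
    repro_block(grp_ffq, grp_rep, group_ids, "food_group"),
    repro_block(idx_base, idx_rep, names(scores), "index"),
    repro_block(nut_ffq, nut_rep, nutrient_names(), "nutrient"))

  # intake-pattern models per method
  pca <- lapply(list(ffq = grp_ffq, recall = grp_rec), function(g) {
    pca_patterns(g, k = config$pca_components)
  })

  # sex-stratified sensitivity correlations
  strata <- NULL
  if (config$strata == "sex") {
    strata <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      i <- participants$sex == sx
      if (sum(i) < 3) return(NULL)
      rows <- lapply(group_ids, function(g) {
        data.frame(sex = sx, variable = g,
                   spearman = correlate(grp_rec[[g]][i], grp_ffq[[g]][i],
                                        "spearman")$coefficient)
      })
      rows <- c(rows, lapply(names(scores), function(ix) {
        data.frame(sex = sx, variable = ix,
                   spearman = correlate(scores[[ix]]$recall[i],
                                        scores[[ix]]$ffq[i],
                                        "spearman")$coefficient)
      }))
      do.call(rbind, rows)
    }))
  }

  structure(list(
    attrition = attrition,
    n = length(keep_ids),
    food_groups = food_groups,
    indices = indices,
    nutrients = nutrients,
    reproducibility = reproducibility,
    pca = pca,
    pal = data.frame(participant_id = keep_ids, ree_kcal = ree,
                     pal_ffq = pal_f$pal, flag_ffq = pal_f$flag,
                     pal_recall = pal_r$pal, flag_recall = pal_r$flag,
                     outlier = pal_outlier),
    descriptives = list(
      food_groups_ffq = descriptives(grp_ffq[group_ids], "median_iqr"),
      food_groups_recall = descriptives(grp_rec[group_ids], "median_iqr"),
      nutrients_ffq = descriptives(nut_ffq[nutrient_names()], "mean_sd"),
      nutrients_recall = descriptives(nut_rec[nutrient_names()], "mean_sd")),
    strata = strata,
    config = config),
    class = "validation_report")
}

#' Summary statistics table
#'
#' Medians with 25th/75th percentiles (linear interpolation of order
#' statistics, R quantile type 7) for skewed intake variables, or means with
#' standard deviations for approximately symmetric ones.
#'
#' @param x data.frame of numeric columns (one variable each).
#' @param type "median_iqr" or "mean_sd".
#' @return data.frame, one row per variable.
#' @export
descriptives <- function(x, type = c("median_iqr", "mean_sd")) {
  type <- match.arg(type)
  x <- x[, setdiff(names(x), "participant_id"), drop = FALSE]
  if (nrow(x) == 0) stop("empty subset", call. = FALSE)
  if (type == "median_iqr") {
    do.call(rbind, lapply(names(x), function(v) {
      q <- quantile(x[[v]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(variable = v, median = q[2], p25 = q[1], p75 = q[3])
    }))
  } else {
    do.call(rbind, lapply(names(x), function(v) {
      data.frame(variable = v, mean = mean(x[[v]]), sd = sd(x[[v]]))
    }))
  }
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$n, "\n")
  cat("  food-group Spearman: ",
      sprintf("%.3f-%.3f", min(x$food_groups$coefficient, na.rm = TRUE),
              max(x$food_groups$coefficient, na.rm = TRUE)), "\n", sep = "")
  cat("  index correlations:  ",
      paste(sprintf("%s %.3f", x$indices$index, x$indices$coefficient),
            collapse = ", "), "\n", sep = "")
  cat("  PCA R2 (ffq/recall): ",
      sprintf("%.1f%% / %.1f%%", 100 * max(x$pca$ffq$r2),
              100 * max(x$pca$recall$r2)), "\n", sep = "")
  invisible(x)
}

#' Write a validation report to disk
#'
#' Tidy CSV tables (one per statistic family) plus a JSON summary.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$attrition, file.path(dir, "attrition.csv"), row.names = FALSE)
  write.csv(report$food_groups, file.path(dir, "food_groups.csv"),
            row.names = FALSE)
  write.csv(report$indices, file.path(dir, "indices.csv"), row.names = FALSE)
  write.csv(report$nutrients, file.path(dir, "nutrients.csv"), row.names = FALSE)
  write.csv(report$reproducibility, file.path(dir, "reproducibility.csv"),
            row.names = FALSE)
  write.csv(report$pal, file.path(dir, "pal_screening.csv"), row.names = FALSE)
  if (!is.null(report$strata)) {
    write.csv(report$strata, file.path(dir, "strata.csv"), row.names = FALSE)
  }
  summary <- list(
    n = report$n,
    attrition = report$attrition,
    pca = lapply(report$pca, function(p) list(r2 = p$r2, q2 = p$q2)),
    quantile_rule = "type 7 (linear interpolation of order statistics)")
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
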