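# Food-group aggregation and diet-index scoring.

schema <- ffq_schema()
n_items <- nrow(schema$items)

test_that("group values are exact sums of member categories", {
  st <- generate_cohort(15, seed = 9)
  freq <- frequencies_to_daily(st$ffq_baseline, schema = schema)
  grp <- aggregate_food_groups(freq, schema = schema)
  expect_equal(ncol(grp) - 1, 30)
  mapping <- default_group_mapping(schema)
  for (g in c("milk", "vegetables", "alcoholic_beverages")) {
    brute <- rowSums(as.matrix(freq[, mapping[[g]], drop = FALSE]))
    expect_equal(grp[[g]], unname(brute), tolerance = 1e-15)
  }
  # singleton group passes the value through unchanged
  one <- list(solo = "item_001")
  expect_equal(aggregate_food_groups(freq, one, schema)$solo, freq$item_001)
  expect_error(aggregate_food_groups(freq, list(g = "item_999"), schema),
               "item_999")
})

test_that("tertile-scored components match a brute-force rank-and-cut oracle", {
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  gi <- data.frame(participant_id = letters[1:9], fruits_berries = vals)
  spec <- diet_index_spec("toy", list(
    list(groups = "fruits_berries", direction = "+", cut = "tertile")))
  got <- score_index(gi, spec)$score
  # oracle: sort, cut into thirds, assign 0/1/2 by third
  thirds <- cut(rank(vals), breaks = c(0, 3, 6, 9), labels = FALSE) - 1
  expect_identical(got, as.numeric(thirds))
})

test_that("extreme intake profiles reach the score-range endpoints", {
  specs <- default_index_specs()
  st <- generate_cohort(30, seed = 13)
  freq <- frequencies_to_daily(st$ffq_baseline, schema = schema)
  grp <- aggregate_food_groups(freq, schema = schema)
  # a participant at/above the median on every HNFI component scores 6
  best <- grp[1, ]
  for (cmp in specs$HNFI$components) {
    best[[cmp$groups]] <- max(grp[[cmp$groups]]) + 1
  }
  grp2 <- rbind(best, grp[-1, ])
  expect_equal(score_index(grp2, specs$HNFI)$score[1],
               unname(index_score_range(specs$HNFI)["max"]))
  ranges <- vapply(specs, index_score_range, numeric(2))
  expect_equal(unname(ranges[, "rMED"]), c(0, 18))
  expect_equal(unname(ranges[, "HNFI"]), c(0, 6))
  expect_equal(unname(ranges[, "PDI"]), c(18, 90))
  for (ix in names(specs)) {
    sc <- score_index(grp, specs[[ix]])$score
    expect_true(all(sc >= ranges[1, ix] & sc <= ranges[2, ix]))
  }
})

test_that("scores are rank-based: invariant to monotone transforms, equivariant to permutation", {
  st <- generate_cohort(40, seed = 21)
  freq <- frequencies_to_daily(st$ffq_baseline, schema = schema)
  grp <- aggregate_food_groups(freq, schema = schema)
  spec <- diet_index_spec("mono", list(
    list(groups = "coffee", direction = "+", cut = "tertile"),
    list(groups = "vegetables", direction = "-", cut = "quintile")))
  base <- score_index(grp, spec)$score
  grp_t <- grp
  grp_t$coffee <- exp(grp$coffee)          # strictly increasing
  grp_t$vegetables <- grp$vegetables^3
  expect_identical(score_index(grp_t, spec)$score, base)
  perm <- sample(nrow(grp))
  expect_identical(score_index(grp[perm, ], spec)$score, base[perm])
})

test_that("reversing every component direction reflects the score range", {
  st <- generate_cohort(35, seed = 22)
  freq <- frequencies_to_daily(st$ffq_baseline, schema = schema)
  grp <- aggregate_food_groups(freq, schema = schema)
  spec <- default_index_specs()$PDI
  flipped <- spec
  flipped$components <- lapply(spec$components, function(cmp) {
    cmp$direction <- if (cmp$direction == "+") "-" else "+"
    cmp
  })
  s <- score_index(grp, spec)$score
  s_rev <- score_index(grp, flipped)$score
  rng <- index_score_range(spec)
  expect_equal(s_rev, rng["max"] + rng["min"] - s, ignore_attr = TRUE)
})

test_that("a constant component warns and scores everyone at the lowest rank", {
  gi <- data.frame(participant_id = letters[1:6], legumes = rep(0, 6),
                   coffee = 1:6)
  spec <- diet_index_spec("deg", list(
    list(groups = "legumes", direction = "+", cut = "tertile")))
  expect_warning(sc <- score_index(gi, spec), "constant component")
  expect_true(all(sc$score == 0))
})
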