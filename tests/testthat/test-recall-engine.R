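# Recall engine: day harmonisation, nutrient totals, inclusion rules.

schema <- ffq_schema()

test_that("occasion totals divide by completed days", {
  # 3 occasions over 6 days -> 0.5/day
  r <- make_recalls("A", c(1, 3, 5), "item_001", c(1, 1, 1))
  p <- data.frame(participant_id = "A", completed_recall_days = 6)
  f <- recall_daily_frequencies(r, schema, participants = p)
  expect_equal(f$item_001, 0.5)
  # once every day of 4 days -> 1.0/day
  r <- make_recalls("A", 1:4, "item_002", rep(1, 4))
  p$completed_recall_days <- 4
  expect_equal(recall_daily_frequencies(r, schema,
                                        participants = p)$item_002, 1)
  # occasion counts {0,0,1,2,0} over 5 days -> 3/5
  r <- make_recalls("A", c(3, 4), "item_003", c(1, 2))
  p$completed_recall_days <- 5
  expect_equal(recall_daily_frequencies(r, schema,
                                        participants = p)$item_003, 3 / 5)
})

test_that("frequencies depend only on totals, not the partition across days", {
  p <- data.frame(participant_id = "A", completed_recall_days = 6)
  a <- make_recalls("A", c(1, 2, 3), "item_005", c(2, 2, 2))
  b <- make_recalls("A", c(1, 6), "item_005", c(5, 1))
  fa <- recall_daily_frequencies(a, schema, participants = p)
  fb <- recall_daily_frequencies(b, schema, participants = p)
  expect_equal(fa$item_005, fb$item_005)
})

test_that("empty inputs and unmapped foods raise informative errors", {
  expect_error(recall_daily_frequencies(make_recalls(character(0), integer(0),
                                                     character(0), numeric(0)),
                                        schema),
               "no completed recall days")
  r <- make_recalls("A", 1, "pizza_margherita", 1)
  expect_error(recall_daily_frequencies(r, schema), "pizza_margherita")
  # an explicit food map resolves vocabulary differences
  fmap <- data.frame(food_id = "pizza_margherita", item_id = "item_040")
  p <- data.frame(participant_id = "A", completed_recall_days = 2)
  f <- recall_daily_frequencies(r, schema, food_map = fmap, participants = p)
  expect_equal(f$item_040, 0.5)
})

test_that("nutrient totals match a hand-computed oracle and are linear", {
  comp <- default_composition(schema)
  r <- make_recalls("A", c(1, 1, 2), c("item_001", "item_016", "item_050"),
                    c(1, 1, 1), amount_g = c(150, 40, 80))
  p <- data.frame(participant_id = "A", completed_recall_days = 2)
  n1 <- recall_nutrients(r, comp, schema, participants = p)
  for (nm in nutrient_names()) {
    per_g <- comp[match(c("item_001", "item_016", "item_050"), comp$item_id), nm] / 100
    expect_equal(n1[[nm]], sum(c(150, 40, 80) * per_g) / 2, tolerance = 1e-12)
  }
  r2 <- r; r2$amount_g <- r$amount_g * 2
  n2 <- recall_nutrients(r2, comp, schema, participants = p)
  expect_equal(as.matrix(n2[, -1]), 2 * as.matrix(n1[, -1]), tolerance = 1e-12)
})

test_that("with 100 g portions and a unit marker nutrient, nutrients equal frequencies", {
  comp <- default_composition(schema)
  comp$fibre_g <- 100  # 1 per gram x 100 g per occasion = 1 per occasion
  r <- make_recalls("A", c(1, 2, 2), "item_007", c(1, 2, 1),
                    amount_g = c(100, 200, 100))
  p <- data.frame(participant_id = "A", completed_recall_days = 4)
  nut <- recall_nutrients(r, comp, schema, participants = p)
  frq <- recall_daily_frequencies(r, schema, participants = p)
  expect_equal(nut$fibre_g / 100, frq$item_007, tolerance = 1e-12)
})

test_that("inclusion filter retains exactly the participants with enough days", {
  st <- generate_cohort(80, seed = 5)
  sub <- inclusion_filter(st, min_days = 4)
  expect_true(all(sub$participants$completed_recall_days >= 4))
  expect_equal(nrow(sub$participants),
               sum(st$participants$completed_recall_days >= 4))
  expect_identical(sub$attrition$step[1], "consented")
  expect_equal(sub$attrition$n[1], 80)
  expect_equal(sub$attrition$n[2],
               sum(st$participants$completed_recall_days >= 1))
  # every companion table is restricted to the retained ids
  ids <- sub$participants$participant_id
  expect_true(all(sub$ffq_baseline$participant_id %in% ids))
  expect_true(all(sub$recalls$participant_id %in% ids))
  expect_identical(rownames(sub$truth$frequency), ids)
  # min_days = 1 keeps anyone with at least one day
  expect_equal(nrow(inclusion_filter(st, 1)$participants),
               sum(st$participants$completed_recall_days >= 1))
})
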