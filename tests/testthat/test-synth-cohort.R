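# Synthetic-cohort generator: determinism, zero-noise identity, error-model
# validation, and agreement of recall aggregates with the latent truth.

test_that("zero-noise generation is an exact round trip for both instruments", {
  st <- generate_cohort(10, zero_error_model(), seed = 1)
  freq <- frequencies_to_daily(st$ffq_baseline, st$config$mapping,
                               st$config$schema)
  expect_equal(as.matrix(freq[, -1]), st$truth$frequency,
               ignore_attr = TRUE, tolerance = 1e-12)
  rec <- recall_daily_frequencies(st$recalls, st$config$schema,
                                  participants = st$participants)
  truth_sub <- st$truth$frequency[rec$participant_id, , drop = FALSE]
  expect_equal(as.matrix(rec[, -1]), truth_sub, ignore_attr = TRUE,
               tolerance = 1e-9)
  # repeat administration is identical under zero error
  freq2 <- frequencies_to_daily(st$ffq_repeat, st$config$mapping,
                                st$config$schema)
  expect_identical(freq[, -1], freq2[, -1])
})

test_that("generation is bit-identical under the same seed and differs across seeds", {
  a <- generate_cohort(10, seed = 1)
  b <- generate_cohort(10, seed = 1)
  expect_identical(a, b)
  c <- generate_cohort(10, seed = 2)
  expect_false(identical(a$ffq_baseline, c$ffq_baseline))
})

test_that("recall-derived frequency means track the truth within Monte-Carlo error", {
  st <- generate_cohort(500, error_model(episodic_zero_prob = 0), seed = 7)
  rec <- recall_daily_frequencies(st$recalls, st$config$schema,
                                  participants = st$participants)
  lam <- st$truth$frequency[rec$participant_id, , drop = FALSE]
  days <- st$participants$completed_recall_days[
    match(rec$participant_id, st$participants$participant_id)]
  for (item in c("item_001", "item_050", "item_094")) {
    obs <- mean(rec[[item]])
    # per-participant variance of a k-day Poisson mean is lambda/k; the
    # cohort mean has variance (var(lambda) + mean(lambda/k)) / n
    mc_se <- sqrt((var(lam[, item]) + mean(lam[, item] / days))
                  / nrow(rec))
    expect_lt(abs(obs - mean(lam[, item])), 3 * mc_se)
  }
})

test_that("invalid error models are rejected with the offending field named", {
  expect_error(error_model(ffq_noise_sd = -1), "ffq_noise_sd")
  expect_error(error_model(recall_within_person_sd = -0.1),
               "recall_within_person_sd")
  expect_error(error_model(episodic_zero_prob = 1.5), "episodic_zero_prob")
  expect_error(error_model(ffq_bias = 0), "ffq_bias")
  expect_error(cohort_config(completion_probs = c(0.5, 0.5)),
               "completion_probs")
})

test_that("episodic categories are exactly zero for never-consumers", {
  em <- error_model(episodic_zero_prob = 0.5)
  st <- generate_cohort(400, em, seed = 11)
  zero_frac <- mean(st$truth$frequency[, "item_001"] == 0)
  expect_gt(zero_frac, 0.40)
  expect_lt(zero_frac, 0.60)
  # never-consumers answer "never" and report nothing in recalls
  zero_ids <- rownames(st$truth$frequency)[st$truth$frequency[, "item_001"] == 0]
  resp <- st$ffq_baseline$item_001[st$ffq_baseline$participant_id %in% zero_ids]
  expect_true(all(resp == 1L | is.na(resp)))
  expect_false(any(st$recalls$food_id == "item_001" &
                     st$recalls$participant_id %in% zero_ids))
})

test_that("simulated responses discretise to the nearest representative level", {
  em0 <- zero_error_model()
  expect_identical(
    unname(simulate_ffq_responses(c(a = 0), em0, seed = 1)), 1L)
  expect_identical(
    unname(simulate_ffq_responses(c(a = 4.5), em0, seed = 1)), 9L)
  # nearest-value search over the nine mapped values, computed independently
  mapping <- default_frequency_mapping()
  for (f in c(0.5, 0.05, 1.7, 1.75, 3.25)) {
    got <- unname(simulate_ffq_responses(setNames(f, "a"), em0, seed = 1))
    dist <- abs(mapping - f)
    nearest <- which(dist == min(dist))  # ties resolve to the lower level
    expect_identical(got, as.integer(nearest[1]), label = paste("f =", f))
  }
})

test_that("latent pattern factors induce the expected cross-category correlation", {
  em <- error_model(episodic_zero_prob = 0)
  st1 <- generate_cohort(400, em, cohort_config(pattern_strength = 0),
                         seed = 17)
  st2 <- generate_cohort(400, em, cohort_config(pattern_strength = 0.6),
                         seed = 17)
  # two items on the same side of the prudent axis (vegetables, fruits)
  veg <- "item_034"; fruit <- "item_046"
  l1 <- log(st1$truth$frequency[, c(veg, fruit)])
  l2 <- log(st2$truth$frequency[, c(veg, fruit)])
  expect_lt(abs(cor(l1)[1, 2]), 0.15)
  expect_gt(cor(l2)[1, 2], 0.3)
  # marginal spread per item is unchanged by the factor structure
  expect_equal(sd(l1[, 1]), sd(l2[, 1]), tolerance = 0.15)
})

test_that("completed-day counts follow the configured completion distribution", {
  st <- generate_cohort(2000, seed = 3)
  days <- st$participants$completed_recall_days
  expect_true(all(days >= 0 & days <= 6))
  expect_equal(mean(days >= 4), sum(st$config$completion_probs[5:7]),
               tolerance = 0.05)
  # day indices in the recall table never exceed the completed count
  got <- tapply(st$recalls$day, st$recalls$participant_id, max)
  lim <- st$participants$completed_recall_days[
    match(names(got), st$participants$participant_id)]
  expect_true(all(got <= lim))
})
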