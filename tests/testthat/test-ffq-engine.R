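# FFQ engine: frequency transformation, quality classification, portions.

schema <- ffq_schema()
n_items <- nrow(schema$items)

test_that("frequency levels map to their representative daily intakes", {
  rec <- make_records(rbind(rep(1L, n_items), rep(9L, n_items),
                            rep(5L, n_items)))
  freq <- frequencies_to_daily(rec, schema = schema)
  expect_true(all(freq[1, -1] == 0))          # "never"
  expect_true(all(freq[2, -1] == 4))          # "4 times a day or more"
  expect_true(all(freq[3, -1] == 2.5 / 7))    # "2-3 times a week"
  expect_true(all(as.matrix(freq[, -1]) >= 0 & as.matrix(freq[, -1]) <= 4))
})

test_that("missing responses are imputed as never and flagged in provenance", {
  resp <- rep(7L, n_items)
  resp[c(3, 10)] <- NA
  freq <- frequencies_to_daily(make_records(resp), schema = schema)
  expect_equal(freq[[schema$items$item_id[3]]], 0)
  expect_equal(freq[[schema$items$item_id[4]]], 1)
  imp <- attr(freq, "imputed")
  expect_identical(which(imp[1, ]), setNames(c(3L, 10L),
                                             schema$items$item_id[c(3, 10)]))
})

test_that("out-of-scale responses are rejected with the item named", {
  resp <- rep(5L, n_items)
  resp[17] <- 10L
  expect_error(frequencies_to_daily(make_records(resp), schema = schema),
               schema$items$item_id[17])
})

test_that("frequency transformation is monotone in the responses", {
  withr::with_seed(42, {
    for (rep_i in 1:20) {
      a <- sample(1:9, n_items, replace = TRUE)
      b <- pmin(a + sample(0:2, n_items, replace = TRUE), 9L)
      fa <- frequencies_to_daily(make_records(a), schema = schema)
      fb <- frequencies_to_daily(make_records(b), schema = schema)
      expect_true(all(as.matrix(fb[, -1]) >= as.matrix(fa[, -1])))
    }
  })
})

test_that("exclude levels follow the portion-first, then 10%-missing rule", {
  full <- rep(4L, n_items)
  m11 <- full; m11[1:11] <- NA    # 11/108 = 10.2% >= 10%
  m10 <- full; m10[1:10] <- NA    # 9.26% < 10%
  rec <- make_records(rbind(full, m11, m10, full, m11),
                      ids = sprintf("P%02d", 1:5))
  rec[4, "portion_protein"] <- NA
  rec[5, "portion_starch"] <- NA  # portion missing dominates item missing
  q <- assign_exclude_level(rec, schema)
  expect_identical(q$exclude_level, c(0L, 1L, 0L, 2L, 2L))
  expect_equal(q$missing_fraction[2], 11 / 108)
  # every record gets exactly one level, independent of row order
  qr <- assign_exclude_level(rec[5:1, ], schema)
  expect_identical(qr$exclude_level, rev(q$exclude_level))
})

test_that("photo-plate portions increase strictly with the indicated level", {
  pt <- default_portion_table(schema)
  for (cls in c("starch", "protein", "vegetable")) {
    expect_true(all(diff(pt$photo[cls, ]) > 0))
  }
  participants <- data.frame(participant_id = c("A", "B"),
                             sex = "female", age = 47)
  rec <- make_records(rbind(rep(5L, n_items), rep(5L, n_items)),
                      ids = c("A", "B"))
  rec[1, c("portion_starch", "portion_protein", "portion_vegetable")] <- 1L
  rec[2, c("portion_starch", "portion_protein", "portion_vegetable")] <- 4L
  g <- assign_portion_sizes(rec, participants, schema, pt)
  photo_items <- schema$items$item_id[
    schema$items$portion_class %in% c("starch", "protein", "vegetable")]
  expect_true(all(g["B", photo_items] > g["A", photo_items]))
  # fixed-natural categories ignore the photo indications entirely
  egg <- schema$items$item_id[schema$items$group_id == "eggs"][1]
  expect_equal(unname(g["A", egg]), unname(g["B", egg]))
  expect_equal(unname(g["A", egg]),
               schema$items$natural_g[schema$items$item_id == egg])
})

test_that("demographic portions come from the (sex, 10-year band) median table", {
  pt <- default_portion_table(schema)
  participants <- data.frame(participant_id = "A", sex = "female", age = 47)
  rec <- make_records(rep(5L, n_items), ids = "A")
  g <- assign_portion_sizes(rec, participants, schema, pt)
  milk1 <- schema$items$item_id[schema$items$group_id == "milk"][1]
  expected <- pt$demographic$grams[pt$demographic$sex == "female" &
                                     pt$demographic$age_band == "40-49" &
                                     pt$demographic$item_id == milk1]
  expect_equal(unname(g["A", milk1]), expected)
})

test_that("a missing portion indication blocks photo-class portions by default", {
  participants <- data.frame(participant_id = "A", sex = "male", age = 50)
  rec <- make_records(rep(5L, n_items), ids = "A")
  rec$portion_protein <- NA
  expect_error(assign_portion_sizes(rec, participants, schema),
               "exclude level 2")
  g <- assign_portion_sizes(rec, participants, schema,
                            impute_missing_photo = TRUE)
  expect_false(anyNA(g))
})
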