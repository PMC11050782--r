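test_that("the scoresheet schema enforces the published structure", {
  expect_equal(names(schema$regions),
               c("UPPER_EXTREMITIES", "LOWER_EXTREMITIES", "NECK_AND_TRUNK",
                 "SEQUENCE"))
  expect_equal(vapply(schema$regions, `[[`, 0, "max"),
               c(UPPER_EXTREMITIES = 16, LOWER_EXTREMITIES = 16,
                 NECK_AND_TRUNK = 4, SEQUENCE = 2))
  expect_equal(sum(vapply(schema$regions, `[[`, 0, "max")), 38)
  expect_length(schema$regions$UPPER_EXTREMITIES$items, 8)
  expect_length(schema$regions$LOWER_EXTREMITIES$items, 8)
  expect_length(schema$regions$NECK_AND_TRUNK$items, 2)
  expect_length(schema$regions$SEQUENCE$items, 1)
  expect_setequal(schema$allowed_detail, c(0, 0.5, 1, 1.5, 2))
  expect_setequal(schema$allowed_sequence, c(0, 1, 2))
})

test_that("sequence subscore follows the GM category", {
  expect_identical(sequence_from_category("normal"), 2)
  expect_identical(sequence_from_category("poor_repertoire"), 1)
  expect_identical(sequence_from_category("cramped_synchronized"), 0)
  expect_identical(sequence_from_category("chaotic"), 0)
  expect_error(sequence_from_category("hypokinetic"), "unknown GM category")
})

test_that("validation reports illegal values, missing items and mismatches", {
  rec <- flat_record(1, "normal")
  expect_equal(nrow(validate_assessment(rec, schema)), 0)

  bad <- rec
  bad[[detail_cols[3]]] <- 1.7
  v <- validate_assessment(bad, schema)
  expect_equal(nrow(v), 1)
  expect_match(v$message, "not in \\{0, 0.5, 1, 1.5, 2\\}")

  mis <- rec
  mis[[detail_cols[1]]] <- NA
  v <- validate_assessment(mis, schema)
  expect_match(v$message, "missing item")

  clash <- flat_record(0, "cramped_synchronized")
  clash[[schema$sequence_column]] <- 2
  v <- validate_assessment(clash, schema)
  expect_match(v$message, "sequence/category mismatch")
  # non-strict mode accepts a contradicting provided value
  expect_equal(
    nrow(validate_assessment(clash, schema, strict_sequence = FALSE)), 0)
})

test_that("scoring reproduces the boundary cases of the instrument", {
  expect_equal(compute_score(flat_record(2, "normal"), schema)$total, 38)
  expect_equal(compute_score(flat_record(0, "cramped_synchronized"),
                             schema)$total, 0)
  # raw sum 23.5 must round up to 24, subscores stay unrounded
  rec <- flat_record(0, "poor_repertoire")  # sequence contributes 1
  rec[detail_cols[1:15]] <- 1.5             # raw = 22.5 + 1 = 23.5
  s <- compute_score(rec, schema)
  expect_equal(s$raw_sum, 23.5)
  expect_equal(s$total, 24)
  expect_equal(unname(s$subscores["SEQUENCE"]), 1)
  expect_error(compute_score(flat_record(3, "normal"), schema),
               "does not validate")
})

test_that("ceiling applies to the final total only and preserves invariants", {
  set.seed(11)
  for (i in 1:300) {
    rec <- random_record()
    s <- compute_score(rec, schema)
    expect_true(s$total - s$raw_sum >= 0 && s$total - s$raw_sum < 1)
    expect_identical(s$total, as.integer(s$total))
    expect_true(all(s$subscores >=
                      0 & s$subscores <=
                      vapply(schema$regions, `[[`, 0, "max")))
  }
})

test_that("raising any single item never decreases the total", {
  set.seed(12)
  for (i in 1:50) {
    rec <- random_record()
    base <- compute_score(rec, schema)$total
    col <- sample(detail_cols, 1)
    v <- rec[[col]]
    if (v < 2) {
      up <- rec
      up[[col]] <- v + 0.5
      expect_gte(compute_score(up, schema)$total, base)
    }
  }
})

test_that("vectorised cohort scoring agrees with single-record scoring", {
  set.seed(13)
  recs <- lapply(1:40, function(i) random_record())
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  scored <- score_assessments(df, schema)
  singles <- vapply(recs, function(r) compute_score(r, schema)$total, 0L)
  expect_equal(scored$total, singles)
  expect_equal(scored$total, vapply(recs, oracle_total, 0))
  # a contradicting sequence value is rejected in strict mode
  df2 <- df
  df2[[schema$sequence_column]] <- 2
  df2$category <- "cramped_synchronized"
  expect_error(score_assessments(df2, schema), "mismatch")
})
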