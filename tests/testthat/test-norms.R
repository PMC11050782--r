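test_that("empirical percentiles match the scan oracle and handle ties", {
  expect_equal(unname(unclass(empirical_anchors(1:100))["p10"]), 10)
  # degenerate distribution: every anchor equals the constant
  a <- unclass(empirical_anchors(rep(7, 30)))
  expect_true(all(a == 7))
  # heavy ties collapse low percentiles onto the minimum
  heavy <- c(rep(5, 50), rep(20, 50))
  a <- unclass(empirical_anchors(heavy))
  expect_equal(unname(a["p10"]), 5)
  expect_equal(unname(a["p10"]), oracle_percentile(heavy, 10))

  set.seed(21)
  for (i in 1:200) {
    scores <- sample(0:38, sample(15:500, 1), replace = TRUE)
    a <- unclass(empirical_anchors(scores))
    for (k in c(10, 25, 50, 75, 90)) {
      expect_equal(unname(a[paste0("p", k)]),
                   as.numeric(oracle_percentile(scores, k)))
    }
    expect_equal(unname(a["min"]), min(scores))
    expect_equal(unname(a["max"]), max(scores))
    expect_false(is.unsorted(a))
  }
})

test_that("anchor sets validate ordering and flag small samples", {
  expect_error(percentile_anchors(min = 10, p50 = 5, max = 20),
               "non-decreasing")
  expect_error(percentile_anchors(min = 0, max = 40), "0-38")
  a <- empirical_anchors(sample(5:20, 10, replace = TRUE))
  expect_true(attr(a, "below_threshold"))
  expect_error(empirical_anchors(numeric(0)), "non-empty")
})

test_that("shipped norm tables pass their structural invariants", {
  for (which in c("full_period", "age_specific")) {
    tab <- gmosr_norms(which)
    expect_s3_class(tab, "gmosr_norm_table")
    expect_silent(validate_norm_table(tab))
  }
  full <- gmosr_norms("full_period")
  expect_equal(sum(full$n), 1983)
  age <- gmosr_norms("age_specific")
  # interior anchors only for cells meeting the publication threshold
  has_interior <- !is.na(age$p50)
  expect_true(all(age$n[has_interior] >= 15))
})

test_that("band lookup reproduces the worked normative examples", {
  b <- band_lookup(35, "normal", "UMIC")
  expect_equal(b$relation, "on_anchor")
  expect_equal(b$anchors, "p75")
  expect_equal(band_percentile(b), 75)

  b <- band_lookup(35, "normal", "LMIC")
  expect_equal(b$relation, "between")
  expect_equal(b$lower, "p75")
  expect_equal(b$upper, "max")

  b <- band_lookup(21, "poor_repertoire", "HIC")
  expect_equal(b$anchors, "p50")

  b <- band_lookup(14, "poor_repertoire", "LMIC", period = "very_preterm")
  expect_equal(b$cell$income_band, "LMIC_UMIC")
  expect_equal(b$anchors, "p50")

  b <- band_lookup(14, "poor_repertoire", "HIC", period = "lt_32")
  expect_equal(b$relation, "between")
  expect_equal(b$upper, "p10")
})

test_that("band lookup covers ties, extremes and error cases", {
  # score equal to several anchors reports the full tied set
  b <- band_lookup(33, "normal", "HIC")
  expect_setequal(b$anchors, c("p25", "p50"))
  expect_match(format(b), "on P25 \\(= P50\\)")
  b <- band_lookup(8, "poor_repertoire", "LMIC_UMIC", period = "lt_32")
  expect_setequal(b$anchors, c("min", "p10"))

  expect_equal(band_lookup(0, "poor_repertoire", "HIC")$relation, "below_min")
  expect_equal(band_lookup(38, "poor_repertoire", "HIC")$relation,
               "above_max")
  expect_error(band_lookup(39, "normal", "HIC"), "outside the instrument")
  expect_error(band_lookup(20.5, "normal", "HIC"), "integer")
  expect_error(band_lookup(10, "chaotic", "LMIC_UMIC", period = "term"),
               "no norm-table cell")
  # an encoded cell below the publication threshold names itself
  expect_error(band_lookup(30, "normal", "LMIC_UMIC", period = "lt_32"),
               "no published anchors")
  # min/max-only cells still band
  expect_equal(band_lookup(12, "chaotic", "LMIC")$relation, "between")
})

test_that("every integer score maps to exactly one band per anchor set", {
  cells <- list(
    list(cat = "normal", band = "HIC", period = "ALL"),
    list(cat = "poor_repertoire", band = "LMIC_UMIC", period = "term"),
    list(cat = "cramped_synchronized", band = "HIC", period = "post_term")
  )
  for (cell in cells) {
    for (s in 0:38) {
      b <- band_lookup(s, cell$cat, cell$band, cell$period)
      expect_true(b$relation %in%
                    c("below_min", "on_anchor", "between", "above_max"))
    }
  }
})

test_that("rebuilding a norm table honours the n >= 15 suppression rule", {
  set.seed(31)
  scored <- data.frame(
    total = c(sample(10:30, 40, replace = TRUE),
              sample(5:20, 7, replace = TRUE)),
    category = rep("poor_repertoire", 47),
    income_band = c(rep("HIC", 40), rep("LMIC", 7)),
    period = "term",
    stringsAsFactors = FALSE
  )
  tab <- build_norm_table(scored, "full_period")
  hic <- tab[tab$income_band == "HIC", ]
  expect_false(anyNA(hic[, c("p10", "p25", "p50", "p75", "p90")]))
  lmic <- tab[tab$income_band == "LMIC", ]
  expect_equal(lmic$n, 7)
  expect_true(all(is.na(lmic[, c("p10", "p25", "p50", "p75", "p90")])))
  expect_false(anyNA(lmic[, c("min", "max")]))
  # empty strata are simply absent
  expect_false("UMIC" %in% tab$income_band)
  # age-specific grouping combines LMIC and UMIC
  tab2 <- build_norm_table(scored, "age_specific")
  expect_setequal(tab2$income_band, c("HIC", "LMIC_UMIC"))
})

test_that("simulator draws rebuild the generating anchors", {
  anchors <- percentile_anchors(min = 26, p10 = 28, p25 = 31, p50 = 35,
                                p75 = 37, p90 = 38, max = 38, n = 71)
  set.seed(32)
  draws <- sample_total(anchors, 20000)
  re <- unclass(empirical_anchors(draws))
  for (nm in c("p10", "p25", "p50", "p75", "p90")) {
    expect_lte(abs(re[[nm]] - unclass(anchors)[[nm]]), 1)
  }
})
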