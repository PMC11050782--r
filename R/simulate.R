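# Seeded synthetic cohort generation. Totals are simulated at the
# total-score level through the piecewise-linear inverse CDF of the published
# percentile anchors, then item scores are back-filled to match; the
# normative sample publishes only total-score distributions, so item-level
# correlation structure is deliberately not modelled.

#' Category counts of the normative cohort by age period and income group
#'
#' The encoded cohort-composition table (n = 1983): counts of normal, poor
#' repertoire, cramped-synchronized and chaotic GMs per recording-age period
#' and income group.
#'
#' @param path Optional path to a counts JSON file; shipped default otherwise.
#' @return Data frame with columns `period`, `income_band`, `category`,
#'   `count`.
#' @export
cohort_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_counts.json", package = "gmosr")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  periods <- raw$periods
  rows <- list()
  for (i in seq_len(nrow(periods))) {
    for (band in c("LMIC", "UMIC", "HIC")) {
      cell <- periods[[band]][i, ]
      for (cat in gm_categories()) {
        rows[[length(rows) + 1L]] <- data.frame(
          period = periods$period[i], income_band = band, category = cat,
          count = as.integer(cell[[cat]]), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Default simulation configuration
#'
#' Bundles the generating model of [simulate_cohort()]: the joint
#' (period, income group, GM category) distribution taken from the encoded
#' cohort counts; per-stratum score anchors from the age-specific normative
#' table with fall-back to the full-period table; metadata missingness rates
#' (sex not disclosed 473/1983, gestational age not disclosed 234/1983,
#' female share among disclosed 636/1510); and a gestational-age model
#' calibrated to the cohort description (preterm share 1544/1749 of disclosed,
#' preterm GA distribution over 22-36 weeks with median 28 and quartiles
#' 26-31, term GA uniform over 37-41 weeks, recording 1-23 weeks after
#' birth).
#'
#' @return A list of class `gmosr_sim_config`.
#' @export
default_sim_config <- function() {
  joint <- cohort_counts()
  joint <- joint[joint$count > 0L, , drop = FALSE]
  rownames(joint) <- NULL
  registry <- income_registry()
  countries <- split(names(registry$groups), unname(registry$groups))
  # preterm GA weights over completed weeks 22..36, calibrated so the
  # discrete quartiles are 26 / 28 / 31
  ga_weights <- c(2, 3, 6, 8, 10, 10, 9, 8, 7, 7, 6, 5, 4, 3, 2)
  structure(
    list(
      joint = joint,
      age_norms = gmosr_norms("age_specific"),
      full_norms = gmosr_norms("full_period"),
      sex_not_disclosed = 473 / 1983,
      p_female_disclosed = 636 / 1510,
      ga_not_disclosed = 234 / 1983,
      p_term_disclosed = 205 / 1749,
      ga_preterm_weeks = 22:36,
      ga_preterm_weights = ga_weights,
      ga_term_weeks = 37:41,
      postnatal_min_days = 7L,    # recordings taken 1 to 23 weeks after birth
      postnatal_max_days = 161L,
      half_point_prob = 0.25,     # chance the raw item sum ends in .5
      countries = countries
    ),
    class = "gmosr_sim_config"
  )
}

#' Draw GMOS-R totals from a percentile anchor set
#'
#' Inverse-CDF sampling through the piecewise-linear curve joining the
#' available anchors at their cumulative probabilities ((0, min), (0.10, P10),
#' (0.25, P25), (0.50, P50), (0.75, P75), (0.90, P90), (1, max)); absent
#' anchors are skipped, so a min/max-only cell yields a uniform draw over its
#' range. Draws are rounded to the nearest integer and clamped to [min, max].
#'
#' @param anchors A [percentile_anchors()] object (at least min and max
#'   present).
#' @param n Number of draws (ignored when `u` is given).
#' @param u Optional uniform variates in 0-1, for deterministic evaluation of
#'   the inverse CDF.
#' @return Integer vector of totals.
#' @export
sample_total <- function(anchors, n = 1L, u = NULL) {
  stopifnot(inherits(anchors, "gmosr_anchors"))
  probs <- c(min = 0, p10 = 0.10, p25 = 0.25, p50 = 0.50,
             p75 = 0.75, p90 = 0.90, max = 1)
  v <- unclass(anchors)
  keep <- !is.na(v)
  if (!keep[["min"]] || !keep[["max"]]) {
    stop("anchor set must include min and max to sample from")
  }
  if (is.null(u)) u <- stats::runif(n)
  stopifnot(all(u >= 0 & u <= 1))
  if (v[["min"]] == v[["max"]]) {
    return(rep(as.integer(v[["min"]]), length(u)))
  }
  q <- stats::approx(x = probs[keep], y = v[keep], xout = u,
                     ties = "ordered")$y
  out <- floor(q + 0.5)  # round half up, independent of banker's rounding
  as.integer(pmin(pmax(out, v[["min"]]), v[["max"]]))
}

#' Back-fill item scores consistent with a total and GM category
#'
#' Constructs a random item vector whose ceiling-rounded sum equals `total`
#' and whose sequence item carries the category-implied value. The detail sum
#' is distributed sequentially over the 18 detail items in random order, each
#' step drawing uniformly from the feasible values given the remaining sum
#' and remaining capacity (a simple feasible construction, not uniform over
#' all compositions). With probability `half_prob` the raw sum is placed at
#' `total - 0.5`, exercising the half-point/ceiling rule.
#'
#' @param total Target integer GMOS-R total.
#' @param category GM category label.
#' @param schema A [gmosr_schema()].
#' @param half_prob Probability that the raw sum ends in .5.
#' @return Named numeric vector over all schema item columns.
#' @export
sample_items <- function(total, category, schema = gmosr_schema(),
                         half_prob = 0.25) {
  stopifnot(length(total) == 1L, total == floor(total))
  s <- sequence_from_category(category)
  detail_target <- total - s
  if (detail_target < 0 || detail_target > 36) {
    stop("total ", total, " is not achievable for category '", category,
         "' (sequence score ", s, " forces the detail sum into 0-36)")
  }
  # optionally land the raw sum half a point below the total (ceiling rule)
  if (detail_target >= 0.5 && stats::runif(1) < half_prob) {
    detail_target <- detail_target - 0.5
  }
  detail_cols <- setdiff(schema$columns, schema$sequence_column)
  halves <- as.integer(round(2 * detail_target))  # per-item units of 0.5
  order_cols <- sample(detail_cols)
  out <- setNames(numeric(length(detail_cols)), detail_cols)
  remaining <- halves
  for (j in seq_along(order_cols)) {
    capacity_after <- 4L * (length(order_cols) - j)
    lo <- max(0L, remaining - capacity_after)
    hi <- min(4L, remaining)
    val <- if (lo >= hi) lo else sample(lo:hi, 1L)
    out[order_cols[j]] <- val / 2
    remaining <- remaining - val
  }
  c(out, setNames(s, schema$sequence_column))[schema$columns]
}

.sim_anchor_lookup <- function(config, income_band, period, category) {
  band4 <- if (income_band %in% c("LMIC", "UMIC")) "LMIC_UMIC" else income_band
  grp <- norm_age_group(period)
  a <- .cell_anchors(config$age_norms, band4, grp, category)
  if (!is.null(a) && !is.na(unclass(a)[["min"]])) {
    return(list(anchors = a, source = "age_specific"))
  }
  a <- .cell_anchors(config$full_norms, income_band, "ALL", category)
  if (is.null(a) || is.na(unclass(a)[["min"]])) {
    stop("no usable anchors for ", income_band, " / ", period, " / ",
         category)
  }
  src <- if (all(!is.na(unclass(a)[c("p25", "p50", "p75")]))) {
    "full_period"
  } else {
    "full_period_range"  # min/max only: uniform draw
  }
  list(anchors = a, source = src)
}

#' Simulate a synthetic GMOS-R assessment cohort
#'
#' Generates `n` assessments with the statistical structure of the normative
#' sample: the joint (recording-age period, income group, GM category)
#' distribution follows the encoded cohort counts; totals are drawn from the
#' stratum's published anchors via [sample_total()]; item scores are
#' back-filled with [sample_items()]; country, sex/GA missingness and the
#' gestational-age model follow the configuration. Reproducible under a fixed
#' seed: each infant uses an independent substream derived from the root seed
#' by counter, so any subset of infants regenerates identically.
#'
#' @param n Number of infants.
#' @param seed Root integer seed.
#' @param config A [default_sim_config()] object.
#' @param schema A [gmosr_schema()].
#' @return Data frame of assessments (one row per recording, schema item
#'   columns included) with ground-truth columns `true_period`,
#'   `true_income_band`, `true_total` and `anchors_source`.
#' @export
simulate_cohort <- function(n, seed, config = default_sim_config(),
                            schema = gmosr_schema()) {
  stopifnot(n >= 1L, is.finite(seed))
  joint <- config$joint
  periods <- age_periods()
  per_lo <- setNames(periods$lower_weeks * 7L + periods$lower_days,
                     periods$label)
  per_hi <- setNames(periods$upper_weeks * 7L + periods$upper_days,
                     periods$label)

  out <- data.frame(
    infant_id = sprintf("SIM%05d", seq_len(n)),
    country = character(n), sex = character(n),
    ga_weeks = rep(NA_integer_, n), ga_days = rep(NA_integer_, n),
    pma_weeks = integer(n), pma_days = integer(n),
    category = character(n), stringsAsFactors = FALSE
  )
  items <- matrix(NA_real_, nrow = n, ncol = length(schema$columns),
                  dimnames = list(NULL, schema$columns))
  true_period <- character(n)
  true_band <- character(n)
  true_total <- integer(n)
  anchors_source <- character(n)

  for (i in seq_len(n)) {
    # per-infant substream: subsets of the cohort regenerate identically
    set.seed((as.integer(seed) + 1000003 * i) %% 2147483629L)

    cell <- joint[sample.int(nrow(joint), 1L, prob = joint$count), ]
    period <- cell$period; band <- cell$income_band; category <- cell$category

    pma_total <- sample(per_lo[[period]]:per_hi[[period]], 1L)
    out$pma_weeks[i] <- pma_total %/% 7L
    out$pma_days[i] <- pma_total %% 7L

    # gestational age at birth, honouring recording 1-23 weeks after birth
    if (stats::runif(1) >= config$ga_not_disclosed) {
      ga_max <- pma_total - config$postnatal_min_days
      ga_min <- pma_total - config$postnatal_max_days
      term <- stats::runif(1) < config$p_term_disclosed
      weeks <- if (term) config$ga_term_weeks else config$ga_preterm_weeks
      weights <- if (term) rep(1, length(weeks)) else config$ga_preterm_weights
      feasible <- weeks * 7L <= ga_max & weeks * 7L + 6L >= ga_min
      if (!any(feasible)) {  # e.g. term GA infeasible before term-age recording
        weeks <- config$ga_preterm_weeks
        weights <- config$ga_preterm_weights
        feasible <- weeks * 7L <= ga_max & weeks * 7L + 6L >= ga_min
      }
      if (any(feasible)) {
        w <- weeks[feasible]
        wt <- weights[feasible]
        gw <- if (length(w) == 1L) w else sample(w, 1L, prob = wt)
        d_lo <- max(0L, ga_min - gw * 7L)
        d_hi <- min(6L, ga_max - gw * 7L)
        gd <- if (d_lo >= d_hi) d_lo else sample(d_lo:d_hi, 1L)
        out$ga_weeks[i] <- gw
        out$ga_days[i] <- as.integer(gd)
      }  # no feasible GA (earliest recordings): left not disclosed
    }

    out$sex[i] <- if (stats::runif(1) < config$sex_not_disclosed) {
      "not_disclosed"
    } else if (stats::runif(1) < config$p_female_disclosed) {
      "female"
    } else {
      "male"
    }
    out$country[i] <- sample(config$countries[[band]], 1L)
    out$category[i] <- category

    src <- .sim_anchor_lookup(config, band, period, category)
    total <- sample_total(src$anchors, 1L)
    items[i, ] <- sample_items(total, category, schema,
                               half_prob = config$half_point_prob)

    true_period[i] <- period
    true_band[i] <- band
    true_total[i] <- total
    anchors_source[i] <- src$source
  }

  out <- cbind(out, as.data.frame(items))
  out$true_period <- true_period
  out$true_income_band <- true_band
  out$true_total <- true_total
  out$anchors_source <- anchors_source
  out
}
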