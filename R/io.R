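# Assessment file I/O and cohort reporting.
#
# Assessment files are plain CSV, one row per recording:
#   infant_id, country, sex {F,M,ND}, ga_weeks, ga_days, pma_weeks, pma_days,
#   category {N,PR,CS,CH}, then one column per schema item.
# "ND" marks not-disclosed metadata; item scores may be half points.

.meta_cols <- c("infant_id", "country", "sex", "ga_weeks", "ga_days",
                "pma_weeks", "pma_days", "category")

.sex_codes <- c(F = "female", M = "male", ND = "not_disclosed")

#' Round half away from zero
#'
#' Deterministic commercial rounding (0.5 always rounds away from zero),
#' used for all printed percentages so that reported shares are stable and
#' reproduce the normative cohort's printed figures.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Write an assessment table to CSV
#'
#' Serialises assessments in the standard column layout, encoding categories
#' as N/PR/CS/CH, sex as F/M/ND and not-disclosed gestational age as ND.
#' Ground-truth columns from [simulate_cohort()] and score columns are
#' dropped; the file holds the assessment record only.
#'
#' @param df Assessment data frame.
#' @param path Output file path.
#' @param schema A [gmosr_schema()].
#' @return `path`, invisibly.
#' @export
write_assessments <- function(df, path, schema = gmosr_schema()) {
  cols <- c(.meta_cols, schema$columns)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("assessment table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- df[, cols, drop = FALSE]
  code_of <- setNames(names(.category_codes), unname(.category_codes))
  out$category <- code_of[out$category]
  sex_of <- setNames(names(.sex_codes), unname(.sex_codes))
  out$sex <- sex_of[out$sex]
  out$ga_weeks <- ifelse(is.na(out$ga_weeks), "ND", out$ga_weeks)
  out$ga_days <- ifelse(is.na(out$ga_days), "ND", out$ga_days)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an assessment table from CSV
#'
#' Parses and types an assessment file, decoding category and sex codes and
#' the ND (not disclosed) markers. Structural problems (missing mandatory
#' columns) are hard errors; malformed rows (unknown category code, illegal
#' sex code, non-numeric ages) are collected into a row-level error report
#' with line numbers while the remaining rows load.
#'
#' @param path CSV file path.
#' @param schema A [gmosr_schema()].
#' @return A list of class `gmosr_read_result`: `assessments` (typed data
#'   frame of well-formed rows) and `errors` (data frame with `line` and
#'   `message`). Line numbers count the header as line 1.
#' @export
read_assessments <- function(path, schema = gmosr_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cols <- c(.meta_cols, schema$columns)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("assessment file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  errors <- list()
  bad_row <- function(i, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      line = i + 1L, message = message, stringsAsFactors = FALSE)
  }

  n <- nrow(raw)
  keep <- rep(TRUE, n)
  num_or_na <- function(x) suppressWarnings(as.numeric(x))

  for (i in seq_len(n)) {
    if (!(raw$category[i] %in% names(.category_codes))) {
      bad_row(i, paste0("unknown category code '", raw$category[i], "'"))
      keep[i] <- FALSE
      next
    }
    if (!(raw$sex[i] %in% names(.sex_codes))) {
      bad_row(i, paste0("unknown sex code '", raw$sex[i], "'"))
      keep[i] <- FALSE
      next
    }
    ga_nd <- raw$ga_weeks[i] == "ND" | raw$ga_days[i] == "ND"
    if (!ga_nd && (is.na(num_or_na(raw$ga_weeks[i])) ||
                   is.na(num_or_na(raw$ga_days[i])))) {
      bad_row(i, "gestational age is neither numeric nor 'ND'")
      keep[i] <- FALSE
      next
    }
    if (is.na(num_or_na(raw$pma_weeks[i])) ||
        is.na(num_or_na(raw$pma_days[i]))) {
      bad_row(i, "postmenstrual age at recording must be numeric")
      keep[i] <- FALSE
      next
    }
    bad_item <- NULL
    for (col in schema$columns) {
      if (is.na(num_or_na(raw[[col]][i]))) { bad_item <- col; break }
    }
    if (!is.null(bad_item)) {
      bad_row(i, paste0("item ", bad_item, " is not numeric"))
      keep[i] <- FALSE
    }
  }

  good <- raw[keep, , drop = FALSE]
  df <- data.frame(
    infant_id = good$infant_id,
    country = good$country,
    sex = unname(.sex_codes[good$sex]),
    ga_weeks = ifelse(good$ga_weeks == "ND", NA, good$ga_weeks),
    ga_days = ifelse(good$ga_days == "ND", NA, good$ga_days),
    pma_weeks = as.integer(good$pma_weeks),
    pma_days = as.integer(good$pma_days),
    category = unname(.category_codes[good$category]),
    stringsAsFactors = FALSE
  )
  df$ga_weeks <- as.integer(df$ga_weeks)
  df$ga_days <- as.integer(df$ga_days)
  for (col in schema$columns) df[[col]] <- as.numeric(good[[col]])
  rownames(df) <- NULL

  errors <- if (length(errors) == 0L) {
    data.frame(line = integer(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, errors)
  }
  structure(list(assessments = df, errors = errors),
            class = "gmosr_read_result")
}

#' @export
print.gmosr_read_result <- function(x, ...) {
  cat("read ", nrow(x$assessments), " assessment(s), ",
      nrow(x$errors), " malformed row(s)\n", sep = "")
  if (nrow(x$errors) > 0L) {
    for (i in seq_len(nrow(x$errors))) {
      cat("  line ", x$errors$line[i], ": ", x$errors$message[i], "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Summarise a period-by-income-by-category count table
#'
#' Computes the cohort-composition report from a count table in the shape of
#' [cohort_counts()]: per-period category distributions (integer percentages,
#' rounded half away from zero), overall category shares, one-decimal income
#' group and period shares, and the per-category distribution across periods.
#'
#' @param counts Data frame with columns `period`, `income_band`, `category`,
#'   `count`.
#' @return A list of class `gmosr_count_summary` with elements `n`,
#'   `by_period_category` (counts + row percentages within period),
#'   `category_totals`, `income_shares`, `period_shares` and
#'   `category_by_period` (each category's split across periods, in percent).
#' @export
summarize_counts <- function(counts) {
  stopifnot(all(c("period", "income_band", "category", "count") %in%
                  names(counts)))
  n <- sum(counts$count)
  period_levels <- intersect(age_periods()$label, unique(counts$period))

  agg <- function(by) {
    out <- stats::aggregate(counts$count, by = by, FUN = sum)
    names(out)[ncol(out)] <- "count"
    out
  }

  pc <- agg(list(period = counts$period, category = counts$category))
  period_tot <- setNames(
    vapply(split(pc$count, pc$period), sum, 0), NULL)
  ptot <- agg(list(period = counts$period))
  pc$period_total <- ptot$count[match(pc$period, ptot$period)]
  pc$pct_within_period <- round_half_away(100 * pc$count / pc$period_total)
  pc <- pc[order(match(pc$period, period_levels),
                 match(pc$category, gm_categories())), ]
  rownames(pc) <- NULL

  ct <- agg(list(category = counts$category))
  ct$pct <- round_half_away(100 * ct$count / n)
  ct <- ct[order(match(ct$category, gm_categories())), ]
  rownames(ct) <- NULL

  ish <- agg(list(income_band = counts$income_band))
  ish$pct <- round_half_away(100 * ish$count / n, 1)

  psh <- ptot
  psh$pct <- round_half_away(100 * psh$count / n, 1)
  psh <- psh[order(match(psh$period, period_levels)), ]
  rownames(psh) <- NULL

  cbp <- pc[, c("period", "category", "count")]
  cat_tot <- setNames(ct$count, ct$category)
  cbp$pct_within_category <-
    round_half_away(100 * cbp$count / cat_tot[cbp$category])

  structure(
    list(n = n, by_period_category = pc, category_totals = ct,
         income_shares = ish, period_shares = psh,
         category_by_period = cbp),
    class = "gmosr_count_summary"
  )
}

#' Summarise an assessment cohort
#'
#' Scores and stratifies a cohort, then reports its composition (counts and
#' percentages by recording-age period, income group and GM category) and the
#' per-category total-score summaries (median, quartiles, range), in the
#' shape of the published cohort tables.
#'
#' @param df Assessment data frame (see [read_assessments()]).
#' @param schema A [gmosr_schema()].
#' @param registry A [income_registry()].
#' @return A list of class `gmosr_report` with elements `n`, `counts` (the
#'   period x income x category count table), `composition` (a
#'   [summarize_counts()] result) and `score_summary` (per category: n,
#'   median, P25, P75, min, max of the totals).
#' @export
summarize_cohort <- function(df, schema = gmosr_schema(),
                             registry = income_registry()) {
  scored <- score_assessments(df, schema)
  scored$period <- classify_age_period(scored$pma_weeks, scored$pma_days)
  scored$income_band <- classify_income_group(scored$country, registry)

  key <- interaction(scored$period, scored$income_band, scored$category,
                     drop = TRUE)
  counts <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- scored[key == k, , drop = FALSE]
    data.frame(period = sub$period[1], income_band = sub$income_band[1],
               category = sub$category[1], count = nrow(sub),
               stringsAsFactors = FALSE)
  }))

  score_summary <- do.call(rbind, lapply(
    split(scored, scored$category), function(sub) {
      data.frame(
        category = sub$category[1], n = nrow(sub),
        median = stats::median(sub$total),
        p25 = unname(unclass(empirical_anchors(sub$total))[["p25"]]),
        p75 = unname(unclass(empirical_anchors(sub$total))[["p75"]]),
        min = min(sub$total), max = max(sub$total),
        stringsAsFactors = FALSE
      )
    }))
  score_summary <- score_summary[
    order(match(score_summary$category, gm_categories())), ]
  rownames(score_summary) <- NULL

  structure(
    list(n = nrow(scored), counts = counts,
         composition = summarize_counts(counts),
         score_summary = score_summary, scored = scored),
    class = "gmosr_report"
  )
}

#' @export
print.gmosr_report <- function(x, ...) {
  cat("GMOS-R cohort report (n = ", x$n, " recordings)\n\n", sep = "")
  comp <- x$composition
  cat("Income groups:\n")
  for (i in seq_len(nrow(comp$income_shares))) {
    cat(sprintf("  %-5s n = %4d (%.1f%%)\n",
                comp$income_shares$income_band[i],
                comp$income_shares$count[i], comp$income_shares$pct[i]))
  }
  cat("\nGM categories:\n")
  for (i in seq_len(nrow(comp$category_totals))) {
    cat(sprintf("  %-22s n = %4d (%d%%)\n",
                comp$category_totals$category[i],
                comp$category_totals$count[i], comp$category_totals$pct[i]))
  }
  cat("\nCategory distribution within each recording-age period (%):\n")
  pc <- comp$by_period_category
  for (p in unique(pc$period)) {
    sub <- pc[pc$period == p, ]
    cat(sprintf("  %-18s %s\n", p,
                paste(sprintf("%s %d%%", sub$category,
                              sub$pct_within_period), collapse = ", ")))
  }
  cat("\nGMOS-R totals by category (median [P25-P75], min-max):\n")
  ss <- x$score_summary
  for (i in seq_len(nrow(ss))) {
    cat(sprintf("  %-22s %g [%g-%g], %g-%g (n = %d)\n",
                ss$category[i], ss$median[i], ss$p25[i], ss$p75[i],
                ss$min[i], ss$max[i], ss$n[i]))
  }
  invisible(x)
}

#' Box-whisker summary plot of GMOS-R totals
#'
#' Box plots of the total score per GM category, optionally split by income
#' group, mirroring the usual presentation of the normative distributions.
#' Plotting is additive: it draws on the active graphics device and is never
#' required by any other function.
#'
#' @param scored A scored cohort (with `total`, `category` and optionally
#'   `income_band` columns).
#' @param by_income Split each category by income group.
#' @return Invisibly, the statistics returned by [graphics::boxplot()].
#' @export
plot_score_distribution <- function(scored, by_income = TRUE) {
  stopifnot(all(c("total", "category") %in% names(scored)))
  if (by_income && "income_band" %in% names(scored)) {
    f <- interaction(scored$income_band, scored$category, drop = TRUE)
  } else {
    f <- factor(scored$category, levels = gm_categories())
  }
  invisible(graphics::boxplot(scored$total ~ f, las = 2,
                              ylab = "GMOS-R total",
                              main = "GMOS-R distribution"))
}
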