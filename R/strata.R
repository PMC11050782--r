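# Recording-age periods and World Bank income groups.
#
# Ages are handled in the obstetric weeks+days notation (e.g. 31+6 = 31
# completed weeks and 6 days), kept day-exact throughout.

.period_table <- data.frame(
  label = c("extremely_preterm", "very_preterm", "moderate_preterm",
            "late_preterm", "term", "post_term"),
  lower_weeks = c(22, 28, 32, 34, 37, 42),
  lower_days  = c(0, 0, 0, 0, 0, 0),
  upper_weeks = c(27, 31, 33, 36, 41, 45),
  upper_days  = c(6, 6, 6, 6, 6, 6),
  stringsAsFactors = FALSE
)

#' Recording-age periods of the GMOS-R norms
#'
#' The six postmenstrual-age periods used to stratify recordings:
#' extremely preterm (below 28+0 weeks, from 22+0), very preterm (28+0 to
#' 31+6), moderate preterm (32+0 to 33+6), late preterm (34+0 to 36+6), term
#' (37+0 to 41+6) and post-term (42+0 to 45+6). The intervals are disjoint,
#' contiguous, and closed on both printed bounds.
#'
#' @return Data frame with columns `label`, `lower_weeks`, `lower_days`,
#'   `upper_weeks`, `upper_days`.
#' @export
age_periods <- function() .period_table

.wd_to_days <- function(weeks, days) {
  if (any(!is.finite(weeks) | !is.finite(days))) {
    stop("weeks and days must be finite numbers")
  }
  if (any(days < 0 | days > 6 | days != floor(days))) {
    stop("days must be whole numbers in 0-6")
  }
  if (any(weeks < 0 | weeks != floor(weeks))) {
    stop("weeks must be non-negative whole numbers")
  }
  as.integer(weeks) * 7L + as.integer(days)
}

#' Classify a recording into its postmenstrual-age period
#'
#' @param weeks Completed postmenstrual weeks at recording.
#' @param days Additional days (0-6).
#' @return Character vector of period labels (see [age_periods()]);
#'   `"out_of_range"` for ages below 22+0 or above 45+6 weeks.
#' @examples
#' classify_age_period(31, 6)  # "very_preterm"
#' classify_age_period(32, 0)  # "moderate_preterm"
#' @export
classify_age_period <- function(weeks, days = 0) {
  n <- max(length(weeks), length(days))
  weeks <- rep_len(weeks, n)
  days <- rep_len(days, n)
  d <- .wd_to_days(weeks, days)
  lo <- .wd_to_days(.period_table$lower_weeks, .period_table$lower_days)
  hi <- .wd_to_days(.period_table$upper_weeks, .period_table$upper_days)
  out <- rep("out_of_range", n)
  for (i in seq_len(nrow(.period_table))) {
    out[d >= lo[i] & d <= hi[i]] <- .period_table$label[i]
  }
  out
}

#' Map a six-way age period onto the age-specific norm grouping
#'
#' The age-specific normative table folds the few extremely preterm
#' recordings into the very preterm block, yielding five groups: `lt_32`
#' (below 32+0 weeks), `moderate_preterm`, `late_preterm`, `term` and
#' `post_term`.
#'
#' @param period Character vector of [age_periods()] labels.
#' @return Character vector of norm-group labels.
#' @export
norm_age_group <- function(period) {
  known <- c(.period_table$label, "out_of_range")
  bad <- !(period %in% known)
  if (any(bad)) {
    stop("unknown age period label(s): ",
         paste(unique(period[bad]), collapse = ", "))
  }
  ifelse(period %in% c("extremely_preterm", "very_preterm"), "lt_32", period)
}

#' Postmenstrual age from gestational age at birth and postnatal age
#'
#' Day-exact addition in weeks+days notation, renormalised so the day
#' component is 0-6.
#'
#' @param ga_weeks,ga_days Gestational age at birth.
#' @param pn_weeks,pn_days Postnatal (chronological) age at recording.
#' @return A list with integer vectors `weeks` and `days`.
#' @examples
#' pma_from_birth(30, 5, 1, 4)  # 32 weeks + 2 days
#' @export
pma_from_birth <- function(ga_weeks, ga_days, pn_weeks, pn_days) {
  total <- .wd_to_days(ga_weeks, ga_days) + .wd_to_days(pn_weeks, pn_days)
  list(weeks = total %/% 7L, days = total %% 7L)
}

#' Country-to-income-group registry
#'
#' Loads the frozen registry assigning each country of the normative cohort to
#' its World Bank income group (LMIC, UMIC or HIC) at the time the reference
#' sample was assembled, together with an alias map for common alternative
#' country names. The registry is a snapshot, deliberately not a live feed, so
#' percentile lookups stay reproducible against the published norms.
#'
#' @param path Path to a registry JSON file; the shipped default is used when
#'   `NULL`.
#' @return An object of class `gmosr_registry`: a list with `groups` (named
#'   character vector, canonical country name -> income group) and `aliases`
#'   (named character vector, alias -> canonical name).
#' @export
income_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "income_registry.json", package = "gmosr")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- unlist(lapply(names(raw$groups), function(g) {
    setNames(rep(g, length(raw$groups[[g]])), raw$groups[[g]])
  }))
  if (anyDuplicated(names(groups))) {
    stop("registry assigns some country to more than one income group: ",
         paste(names(groups)[duplicated(names(groups))], collapse = ", "))
  }
  aliases <- unlist(raw$aliases)
  unknown_target <- setdiff(aliases, names(groups))
  if (length(unknown_target) > 0L) {
    stop("alias targets not in the registry: ",
         paste(unknown_target, collapse = ", "))
  }
  structure(list(groups = groups, aliases = aliases),
            class = "gmosr_registry")
}

#' Classify a country into its income group
#'
#' Case-insensitive, alias-normalising lookup in the frozen registry. Unknown
#' countries return the explicit marker `"unknown"`, never a silent default.
#'
#' @param country Character vector of country names.
#' @param registry A [income_registry()] object.
#' @return Character vector with values `"LMIC"`, `"UMIC"`, `"HIC"` or
#'   `"unknown"`.
#' @examples
#' classify_income_group("India")   # "LMIC"
#' classify_income_group("Brazil")  # "UMIC"
#' @export
classify_income_group <- function(country, registry = income_registry()) {
  if (length(country) == 0L) return(character(0))
  country <- as.character(country)
  if (any(is.na(country) | !nzchar(trimws(country)))) {
    stop("country names must be non-empty strings")
  }
  key <- tolower(trimws(country))
  canon <- setNames(names(registry$groups), tolower(names(registry$groups)))
  alias <- setNames(unname(registry$aliases), tolower(names(registry$aliases)))
  resolved <- canon[key]
  use_alias <- is.na(resolved) & key %in% names(alias)
  resolved[use_alias] <- alias[key[use_alias]]
  out <- rep("unknown", length(country))
  hit <- !is.na(resolved)
  out[hit] <- unname(registry$groups[resolved[hit]])
  out
}
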