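# Normative percentile tables: encoded published anchors, band lookup, and
# rebuilding anchors from cohorts with the unsmoothed tied-percentile method.

.anchor_names <- c("min", "p10", "p25", "p50", "p75", "p90", "max")

#' Construct a percentile anchor set
#'
#' The seven-point summary {min, P10, P25, P50, P75, P90, max} of the GMOS-R
#' distribution for one stratum and GM category. Anchors may be partially
#' absent (`NA`), e.g. published tables that report median and quartiles only,
#' or small cells where only the observed extremes are retained.
#'
#' @param min,p10,p25,p50,p75,p90,max Integer scores in 0-38 or `NA`.
#' @param n Sample size behind the anchors.
#' @param below_threshold Flag marking cells below the publication threshold
#'   of n = 15.
#' @return Object of class `gmosr_anchors`: a named numeric vector with
#'   attributes `n` and `below_threshold`.
#' @export
percentile_anchors <- function(min = NA, p10 = NA, p25 = NA, p50 = NA,
                               p75 = NA, p90 = NA, max = NA, n = NA,
                               below_threshold = FALSE,
                               instrument_range = TRUE) {
  v <- list(min = min, p10 = p10, p25 = p25, p50 = p50,
            p75 = p75, p90 = p90, max = max)
  v <- setNames(vapply(v, function(x) as.numeric(x)[1], 0), .anchor_names)
  present <- v[!is.na(v)]
  if (length(present) > 0L) {
    if (instrument_range && any(present < 0 | present > 38)) {
      stop("anchors must lie in the instrument range 0-38")
    }
    if (is.unsorted(present)) {
      stop("anchors must be non-decreasing: min <= p10 <= ... <= max")
    }
  }
  structure(v, n = as.integer(n), below_threshold = isTRUE(below_threshold),
            class = "gmosr_anchors")
}

#' @export
print.gmosr_anchors <- function(x, ...) {
  cat("GMOS-R percentile anchors (n = ", attr(x, "n"), ")\n", sep = "")
  shown <- vapply(unclass(x), function(v) {
    if (is.na(v)) "n.a." else format(v)
  }, "")
  cat(" ", paste(sprintf("%s=%s", names(shown), shown), collapse = "  "), "\n")
  if (isTRUE(attr(x, "below_threshold"))) {
    cat("  (below the n = 15 publication threshold)\n")
  }
  invisible(x)
}

#' Load a normative percentile table
#'
#' Two encoded tables ship with the package: `"full_period"` (whole recording
#' age range, separate LMIC / UMIC / HIC strata; median, quartiles and range
#' only) and `"age_specific"` (five recording-age groups, combined LMIC+UMIC
#' versus HIC strata, full seven-anchor sets for cells with at least 15
#' recordings). The loader validates anchor ordering for every cell and, for
#' the age-specific table, the n >= 15 publication rule.
#'
#' @param which `"full_period"` or `"age_specific"`, ignored when `path` is
#'   given.
#' @param path Optional path to a norm-table JSON file.
#' @return Object of class `gmosr_norm_table`: a data frame with columns
#'   `income_band`, `period`, `category`, `n` and the seven anchor columns,
#'   plus attributes `provenance` and `note`.
#' @export
gmosr_norms <- function(which = c("full_period", "age_specific"),
                        path = NULL) {
  if (is.null(path)) {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("norms_", which, ".json"),
                        package = "gmosr")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- raw$entries
  for (col in .anchor_names) {
    entries[[col]] <- as.numeric(entries[[col]])
  }
  entries$n <- as.integer(entries$n)
  tab <- structure(entries, provenance = raw$provenance, note = raw$note,
                   class = c("gmosr_norm_table", "data.frame"))
  validate_norm_table(tab)
  tab
}

#' Validate a normative table's structural invariants
#'
#' Checks per-cell anchor ordering, the 0-38 range, and (for age-specific
#' provenance) that interior anchors are only published for cells with
#' n >= 15.
#'
#' @param table A `gmosr_norm_table`.
#' @return The table, invisibly; stops on violation.
#' @export
validate_norm_table <- function(table) {
  stopifnot(inherits(table, "gmosr_norm_table"))
  for (i in seq_len(nrow(table))) {
    v <- as.numeric(table[i, .anchor_names])
    present <- v[!is.na(v)]
    cell <- paste(table$income_band[i], table$period[i], table$category[i],
                  sep = " / ")
    if (length(present) > 0L &&
        (any(present < 0 | present > 38) || is.unsorted(present))) {
      stop("norm table cell ", cell, " violates anchor ordering")
    }
    interior <- as.numeric(table[i, c("p10", "p25", "p50", "p75", "p90")])
    if (identical(attr(table, "provenance"), "age_specific") &&
        any(!is.na(interior)) && table$n[i] < 15L) {
      stop("norm table cell ", cell,
           " publishes interior anchors with n < 15")
    }
  }
  invisible(table)
}

.cell_anchors <- function(table, income_band, period, category) {
  hit <- table$income_band == income_band & table$period == period &
    table$category == category
  if (!any(hit)) return(NULL)
  i <- which(hit)[1]
  percentile_anchors(
    min = table$min[i], p10 = table$p10[i], p25 = table$p25[i],
    p50 = table$p50[i], p75 = table$p75[i], p90 = table$p90[i],
    max = table$max[i], n = table$n[i],
    below_threshold = !is.na(table$n[i]) && table$n[i] < 15L
  )
}

#' Locate a GMOS-R total within a normative anchor set
#'
#' Places an integer GMOS-R total relative to the published percentile anchors
#' for the requested stratum and GM category. Scores equal to one or more
#' anchors land `on_anchor` (all tied anchor names are reported, e.g. a score
#' equal to both P10 and the minimum); scores strictly between adjacent
#' anchors land `between` them; scores outside the observed range are
#' `below_min` / `above_max`. Band queries accept finalized integer totals
#' only, since rounding precedes interpretation.
#'
#' @param score Integer GMOS-R total in 0-38.
#' @param category GM category label (see [gm_categories()]).
#' @param income_band `"LMIC"`, `"UMIC"`, `"HIC"`, or `"LMIC_UMIC"`. For the
#'   age-specific table, LMIC and UMIC map onto the combined `LMIC_UMIC`
#'   stratum automatically.
#' @param period `"ALL"` for the full-period table, or a recording-age label
#'   (six-way [age_periods()] labels are folded onto the table's five groups).
#' @param table A `gmosr_norm_table`; defaults to the shipped table implied by
#'   `period`.
#' @return Object of class `gmosr_band`: a list with `relation` (`"on_anchor"`,
#'   `"between"`, `"below_min"`, `"above_max"`), `anchors` (tied anchor names
#'   for `on_anchor`), `lower`/`upper` (for `between`), the queried `score`,
#'   the matched `cell`, and the cell's `anchor_values`.
#' @examples
#' band_lookup(35, "normal", "UMIC")                       # on P75
#' band_lookup(21, "poor_repertoire", "HIC")               # on P50
#' band_lookup(14, "poor_repertoire", "LMIC_UMIC", "lt_32") # on P50
#' @export
band_lookup <- function(score, category, income_band, period = "ALL",
                        table = NULL) {
  if (length(score) != 1L || !is.finite(score) || score != floor(score)) {
    stop("band queries accept a single integer score (a finalized total)")
  }
  if (score < 0 || score > 38) {
    stop("score ", score, " is outside the instrument range 0-38")
  }
  if (!(category %in% gm_categories())) {
    stop("unknown GM category: ", category)
  }
  if (is.null(table)) {
    table <- gmosr_norms(if (identical(period, "ALL")) "full_period"
                         else "age_specific")
  }
  if (income_band %in% c("LMIC", "UMIC") &&
      !(income_band %in% table$income_band) &&
      "LMIC_UMIC" %in% table$income_band) {
    income_band <- "LMIC_UMIC"
  }
  if (!identical(period, "ALL") && !(period %in% table$period) &&
      period %in% age_periods()$label) {
    period <- norm_age_group(period)
  }
  anchors <- .cell_anchors(table, income_band, period, category)
  cell_id <- paste(income_band, period, category, sep = " / ")
  if (is.null(anchors)) {
    stop("no norm-table cell for ", cell_id)
  }
  av <- unclass(anchors)
  present <- av[!is.na(av)]
  if (length(present) == 0L) {
    stop("norm-table cell ", cell_id,
         " has no published anchors (n = ", attr(anchors, "n"),
         ", below the publication threshold)")
  }
  res <- list(score = as.integer(score),
              cell = list(income_band = income_band, period = period,
                          category = category, n = attr(anchors, "n")),
              anchor_values = anchors)
  if (score < min(present)) {
    res$relation <- "below_min"
  } else if (score > max(present)) {
    res$relation <- "above_max"
  } else if (any(present == score)) {
    res$relation <- "on_anchor"
    res$anchors <- names(present)[present == score]
  } else {
    below <- present[present < score]
    above <- present[present > score]
    res$relation <- "between"
    # among tied values take the highest percentile name below and the
    # lowest above, so the band reads e.g. "between P50 and P75"
    res$lower <- names(below)[length(below)]
    res$upper <- names(above)[1]
  }
  structure(res, class = "gmosr_band")
}

.anchor_label <- function(nm) {
  ifelse(nm %in% c("min", "max"), nm, toupper(nm))
}

#' @export
format.gmosr_band <- function(x, ...) {
  lab <- switch(
    x$relation,
    below_min = "below the observed minimum",
    above_max = "above the observed maximum",
    on_anchor = {
      nm <- .anchor_label(x$anchors)
      if (length(nm) > 1L) {
        paste0("on ", nm[1], " (= ", paste(nm[-1], collapse = " = "), ")")
      } else {
        paste0("on ", nm)
      }
    },
    between = paste0("between ", .anchor_label(x$lower), " and ",
                     .anchor_label(x$upper))
  )
  sprintf("GMOS-R %d (%s, %s, %s): %s", x$score, x$cell$category,
          x$cell$income_band, x$cell$period, lab)
}

#' @export
print.gmosr_band <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Percentile rank of the anchor a band query landed on
#'
#' Convenience accessor: for an `on_anchor` band result, returns the numeric
#' percentile level of the matched anchor (e.g. 75 for P75). When the score
#' ties several anchors, percentile-named anchors take precedence over
#' min/max; min and max themselves have no percentile level and give `NA`.
#'
#' @param band A `gmosr_band` result.
#' @return A single number, or `NA` when the band is not on a percentile
#'   anchor.
#' @export
band_percentile <- function(band) {
  stopifnot(inherits(band, "gmosr_band"))
  if (!identical(band$relation, "on_anchor")) return(NA_real_)
  p <- band$anchors[grepl("^p[0-9]+$", band$anchors)]
  if (length(p) == 0L) return(NA_real_)
  as.numeric(sub("^p", "", p[1]))
}

#' Unsmoothed empirical percentile anchors of an ordinal score sample
#'
#' Computes percentile ranks directly on the observed scores, without
#' smoothing or interpolation: the k-th percentile is the smallest observed
#' value v such that at least k% of the scores are less than or equal to v
#' (the left-continuous inverse of the empirical distribution). With heavy
#' ties, low percentiles can collapse onto the minimum. Min and max are the
#' observed extremes.
#'
#' @param scores Non-empty numeric vector of totals. The engine itself is
#'   generic; GMOS-R totals lie in 0-38.
#' @param levels Percentile levels to compute, in percent.
#' @return A [percentile_anchors()] object; cells with fewer than 15 scores
#'   carry the `below_threshold` flag.
#' @examples
#' empirical_anchors(1:100)["p10"]  # 10
#' @export
empirical_anchors <- function(scores, levels = c(10, 25, 50, 75, 90)) {
  if (length(scores) == 0L) stop("scores must be non-empty")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(!(levels > 0 & levels < 100))) {
    stop("percentile levels must lie strictly between 0 and 100")
  }
  n <- length(scores)
  vals <- sort(unique(scores))
  cum <- cumsum(tabulate(match(sort(scores), vals), nbins = length(vals))) / n
  at <- function(k) vals[which(cum >= k / 100)[1]]
  out <- setNames(rep(NA_real_, 7L), .anchor_names)
  out["min"] <- vals[1]
  out["max"] <- vals[length(vals)]
  for (k in levels) {
    nm <- paste0("p", k)
    if (nm %in% .anchor_names) out[nm] <- at(k)
  }
  percentile_anchors(
    min = out["min"], p10 = out["p10"], p25 = out["p25"], p50 = out["p50"],
    p75 = out["p75"], p90 = out["p90"], max = out["max"], n = n,
    below_threshold = n < 15L, instrument_range = FALSE
  )
}

#' Rebuild a normative percentile table from a scored cohort
#'
#' Applies the unsmoothed percentile method per (stratum, GM category) cell.
#' Cells with at least `min_n` recordings receive the full seven-anchor set;
#' smaller non-empty cells retain the observed min and max only (matching the
#' published convention of suppressing interior anchors below n = 15); empty
#' cells are absent.
#'
#' @param scored Data frame with columns `total`, `category`, `income_band`
#'   and `period` (six-way [age_periods()] labels or `"ALL"`).
#' @param grouping `"full_period"` keeps LMIC / UMIC / HIC strata and pools
#'   all recording ages; `"age_specific"` combines LMIC+UMIC versus HIC and
#'   groups ages onto the five norm blocks (see [norm_age_group()]).
#' @param min_n Publication threshold for interior anchors.
#' @return A `gmosr_norm_table` data frame.
#' @export
build_norm_table <- function(scored,
                             grouping = c("full_period", "age_specific"),
                             min_n = 15L) {
  grouping <- match.arg(grouping)
  need <- c("total", "category", "income_band")
  if (identical(grouping, "age_specific")) need <- c(need, "period")
  missing_cols <- setdiff(need, names(scored))
  if (length(missing_cols) > 0L) {
    stop("scored cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- scored
  if (identical(grouping, "full_period")) {
    df$stratum_band <- df$income_band
    df$stratum_period <- "ALL"
  } else {
    df$stratum_band <- ifelse(df$income_band %in% c("LMIC", "UMIC"),
                              "LMIC_UMIC", df$income_band)
    df$stratum_period <- norm_age_group(df$period)
  }
  df <- df[df$stratum_band %in% c("LMIC", "UMIC", "HIC", "LMIC_UMIC") &
             df$stratum_period != "out_of_range", , drop = FALSE]

  key <- interaction(df$stratum_band, df$stratum_period, df$category,
                     drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- key == k
    sub <- df[idx, , drop = FALSE]
    a <- empirical_anchors(sub$total)
    v <- unclass(a)
    if (nrow(sub) < min_n) v[c("p10", "p25", "p50", "p75", "p90")] <- NA_real_
    data.frame(
      income_band = sub$stratum_band[1], period = sub$stratum_period[1],
      category = sub$category[1], n = nrow(sub),
      min = v[["min"]], p10 = v[["p10"]], p25 = v[["p25"]], p50 = v[["p50"]],
      p75 = v[["p75"]], p90 = v[["p90"]], max = v[["max"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$income_band, out$period, out$category), ]
  rownames(out) <- NULL
  structure(out, provenance = "rebuilt",
            note = paste0("Rebuilt from a scored cohort with the unsmoothed ",
                          "tied-percentile method (interior anchors require ",
                          "n >= ", min_n, ")."),
            class = c("gmosr_norm_table", "data.frame"))
}
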