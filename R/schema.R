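#' @importFrom jsonlite read_json write_json
#' @importFrom stats aggregate approx median pchisq pnorm runif
#' @importFrom utils read.csv write.csv
#' @importFrom graphics boxplot
NULL

#' GM category labels
#'
#' The four Gestalt categories of general movements recognised by the GMOS-R:
#' normal, poor repertoire (PR), cramped-synchronized (CS) and chaotic.
#' The instrument has no "hypokinetic" category; it cannot be applied when no
#' general movements occur during the observation.
#'
#' @return Character vector of the four category labels.
#' @export
gm_categories <- function() {
  c("normal", "poor_repertoire", "cramped_synchronized", "chaotic")
}

# short codes used in assessment files
.category_codes <- c(
  N  = "normal",
  PR = "poor_repertoire",
  CS = "cramped_synchronized",
  CH = "chaotic"
)

.sequence_map <- c(
  normal = 2,
  poor_repertoire = 1,
  cramped_synchronized = 0,
  chaotic = 0
)

#' Sequence subscore implied by the GM category
#'
#' The SEQUENCE item is not scored independently: it is assigned from the
#' categorical GM classification. Normal GMs (variable sequence) score 2,
#' poor-repertoire GMs (monotonous and/or incomplete sequence) score 1, and
#' cramped-synchronized or chaotic GMs (synchronized or disorganized) score 0.
#'
#' @param category Character vector of GM category labels
#'   (see [gm_categories()]).
#' @return Integer vector of sequence scores (0, 1 or 2).
#' @examples
#' sequence_from_category("normal")           # 2
#' sequence_from_category("poor_repertoire")  # 1
#' @export
sequence_from_category <- function(category) {
  bad <- !(category %in% names(.sequence_map))
  if (any(bad)) {
    stop("unknown GM category label(s): ",
         paste(unique(category[bad]), collapse = ", "),
         "; expected one of ", paste(gm_categories(), collapse = ", "))
  }
  unname(.sequence_map[category])
}

#' Load and validate a GMOS-R scoresheet schema
#'
#' The schema describes the structure of the revised scoresheet: four regions
#' (UPPER_EXTREMITIES, LOWER_EXTREMITIES, NECK_AND_TRUNK, SEQUENCE), the items
#' within each region, the permitted score values, and the per-region subscore
#' maxima. The shipped default enforces the published structure: 8 items per
#' extremity region (max 16 each), 2 neck/trunk items (max 4), 1 sequence item
#' (max 2), for a total score range of 0-38. Detail items permit half points
#' (0, 0.5, 1, 1.5, 2); the sequence item permits 0, 1 or 2 only.
#'
#' @param path Path to a schema JSON file; the shipped default is used when
#'   `NULL`.
#' @return An object of class `gmosr_schema`: a list with elements `regions`
#'   (each with `name`, `prefix`, `items`, `max`, `columns`), `columns` (all
#'   item column names in scoresheet order), `sequence_column`,
#'   `allowed_detail` and `allowed_sequence`.
#' @export
gmosr_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gmosr_schema.json", package = "gmosr")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(seq_len(nrow(raw$regions)), function(i) {
    r <- list(
      name  = raw$regions$name[i],
      prefix = raw$regions$prefix[i],
      items = raw$regions$items[[i]],
      max   = raw$regions$max[i]
    )
    r$columns <- paste(r$prefix, r$items, sep = "_")
    r
  })
  names(regions) <- vapply(regions, `[[`, "", "name")

  expected <- c(UPPER_EXTREMITIES = 16, LOWER_EXTREMITIES = 16,
                NECK_AND_TRUNK = 4, SEQUENCE = 2)
  if (!identical(names(regions), names(expected))) {
    stop("schema must define regions ",
         paste(names(expected), collapse = ", "), " in that order")
  }
  for (nm in names(expected)) {
    r <- regions[[nm]]
    if (r$max != expected[[nm]]) {
      stop("region ", nm, " must have subscore max ", expected[[nm]])
    }
    n_items <- length(r$items)
    # each item scores at most 2, so max = 2 * item count
    if (n_items * 2 != r$max) {
      stop("region ", nm, " has ", n_items,
           " items, inconsistent with subscore max ", r$max)
    }
  }
  if (sum(vapply(regions, `[[`, 0, "max")) != 38) {
    stop("region subscore maxima must sum to 38")
  }
  allowed_detail <- as.numeric(raw$allowed_values$detail)
  allowed_sequence <- as.numeric(raw$allowed_values$sequence)
  if (!setequal(allowed_detail, c(0, 0.5, 1, 1.5, 2))) {
    stop("detail items must permit exactly {0, 0.5, 1, 1.5, 2}")
  }
  if (!setequal(allowed_sequence, c(0, 1, 2))) {
    stop("the sequence item must permit exactly {0, 1, 2}")
  }

  structure(
    list(
      name = raw$name,
      regions = regions,
      columns = unlist(lapply(regions, `[[`, "columns"), use.names = FALSE),
      sequence_column = regions$SEQUENCE$columns[1],
      allowed_detail = sort(allowed_detail),
      allowed_sequence = sort(allowed_sequence)
    ),
    class = "gmosr_schema"
  )
}

#' @export
print.gmosr_schema <- function(x, ...) {
  cat("GMOS-R scoresheet schema (", x$name, ")\n", sep = "")
  for (r in x$regions) {
    cat(sprintf("  %-18s %d item(s), subscore max %d\n",
                r$name, length(r$items), r$max))
  }
  cat("  total score range 0-",
      sum(vapply(x$regions, `[[`, 0, "max")), "\n", sep = "")
  invisible(x)
}

# coerce a single assessment (named list / one-row data frame) to a plain list
.as_record <- function(a) {
  if (is.data.frame(a)) {
    if (nrow(a) != 1L) stop("expected a single assessment (one row)")
    a <- as.list(a)
  }
  if (!is.list(a)) stop("an assessment must be a named list or one-row data frame")
  a
}

#' Validate a single assessment against the scoresheet schema
#'
#' Checks that the GM category is one of the four recognised labels, that every
#' schema item carries a permitted value (half points on detail items, 0/1/2 on
#' the sequence item), and that a provided sequence value does not contradict
#' the category-implied value. A missing (`NA`) sequence value is acceptable:
#' it is derived from the category at scoring time. Missing detail items make
#' the record unscorable; the instrument has no partial-score provision.
#'
#' @param a A named list or one-row data frame with a `category` field and one
#'   field per schema item column.
#' @param schema A [gmosr_schema()] object.
#' @param strict_sequence When `TRUE` (default), a provided sequence value that
#'   contradicts the category is reported as a violation.
#' @return A data frame of violations with columns `field` and `message`;
#'   zero rows if and only if the assessment conforms.
#' @export
validate_assessment <- function(a, schema = gmosr_schema(),
                                strict_sequence = TRUE) {
  a <- .as_record(a)
  bad <- list()
  note <- function(field, message) {
    bad[[length(bad) + 1L]] <<- data.frame(field = field, message = message,
                                           stringsAsFactors = FALSE)
  }

  category <- a$category
  if (is.null(category) || is.na(category) ||
      !(category %in% gm_categories())) {
    note("category", paste0("invalid or missing GM category: ",
                            if (is.null(category)) "<absent>" else category))
    category <- NA_character_
  }

  detail_cols <- setdiff(schema$columns, schema$sequence_column)
  for (col in detail_cols) {
    v <- a[[col]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      note(col, "missing item value (record unscorable)")
    } else if (!is.numeric(v) || !(v %in% schema$allowed_detail)) {
      note(col, paste0("value ", v, " not in {0, 0.5, 1, 1.5, 2}"))
    }
  }

  seq_col <- schema$sequence_column
  seq_val <- a[[seq_col]]
  if (!is.null(seq_val) && length(seq_val) == 1L && !is.na(seq_val)) {
    if (!(seq_val %in% schema$allowed_sequence)) {
      note(seq_col, paste0("value ", seq_val, " not in {0, 1, 2}"))
    } else if (strict_sequence && !is.na(category) &&
               seq_val != sequence_from_category(category)) {
      note(seq_col, paste0(
        "sequence/category mismatch: category '", category,
        "' implies sequence score ", sequence_from_category(category),
        " but ", seq_val, " was provided"))
    }
  }

  if (length(bad) == 0L) {
    data.frame(field = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Compute the GMOS-R subscores and total for one assessment
#'
#' Sums item values within each region to form the four subscores, sums the
#' subscores into the raw total, and rounds the raw total up to the next whole
#' number when half points leave it fractional. Rounding applies to the final
#' total only; subscores are reported unrounded. The sequence item is taken
#' from the record when provided and otherwise derived from the GM category.
#'
#' @inheritParams validate_assessment
#' @return An object of class `gmosr_score`: a list with `subscores` (named,
#'   possibly half-integer), `raw_sum` and `total` (integer in 0-38).
#' @examples
#' schema <- gmosr_schema()
#' rec <- c(list(category = "normal"),
#'          setNames(as.list(rep(2, 18)),
#'                   setdiff(schema$columns, schema$sequence_column)))
#' compute_score(rec)$total  # 38
#' @export
compute_score <- function(a, schema = gmosr_schema(),
                          strict_sequence = TRUE) {
  a <- .as_record(a)
  v <- validate_assessment(a, schema, strict_sequence = strict_sequence)
  if (nrow(v) > 0L) {
    stop("assessment does not validate: [", v$field[1], "] ", v$message[1])
  }
  seq_col <- schema$sequence_column
  if (is.null(a[[seq_col]]) || is.na(a[[seq_col]])) {
    a[[seq_col]] <- sequence_from_category(a$category)
  }
  subscores <- vapply(schema$regions, function(r) {
    sum(vapply(r$columns, function(col) as.numeric(a[[col]]), 0))
  }, 0)
  raw_sum <- sum(subscores)
  structure(
    list(subscores = subscores, raw_sum = raw_sum,
         total = as.integer(ceiling(raw_sum))),
    class = "gmosr_score"
  )
}

#' @export
print.gmosr_score <- function(x, ...) {
  cat("GMOS-R score\n")
  for (nm in names(x$subscores)) {
    cat(sprintf("  %-18s %g\n", nm, x$subscores[[nm]]))
  }
  cat(sprintf("  raw sum %g -> total %d\n", x$raw_sum, x$total))
  invisible(x)
}

#' Score a cohort of assessments
#'
#' Vectorised scoring of an assessment table: validates every row, fills
#' missing sequence values from the GM category, and appends the four region
#' subscores, the raw sum and the (ceiling-rounded) integer total.
#'
#' @param df Data frame of assessments, one row per recording, with a
#'   `category` column and one column per schema item.
#' @param schema A [gmosr_schema()] object.
#' @param strict_sequence Passed to [validate_assessment()].
#' @return `df` with added columns `sub_upper_extremities`,
#'   `sub_lower_extremities`, `sub_neck_and_trunk`, `sub_sequence`, `raw_sum`
#'   and `total`.
#' @export
score_assessments <- function(df, schema = gmosr_schema(),
                              strict_sequence = TRUE) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) {
    for (col in c("sub_upper_extremities", "sub_lower_extremities",
                  "sub_neck_and_trunk", "sub_sequence", "raw_sum")) {
      df[[col]] <- numeric(0)
    }
    df$total <- integer(0)
    return(df)
  }
  missing_cols <- setdiff(c("category", schema$columns), names(df))
  # the sequence column may be absent entirely (derived from category)
  missing_cols <- setdiff(missing_cols, schema$sequence_column)
  if (length(missing_cols) > 0L) {
    stop("assessment table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  bad_cat <- which(!(df$category %in% gm_categories()))
  if (length(bad_cat) > 0L) {
    stop("row ", bad_cat[1], ": invalid GM category '",
         df$category[bad_cat[1]], "'")
  }

  detail_cols <- setdiff(schema$columns, schema$sequence_column)
  m <- as.matrix(df[, detail_cols, drop = FALSE])
  storage.mode(m) <- "numeric"
  ok <- is.finite(m) & matrix(m %in% schema$allowed_detail, nrow = nrow(m))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("row ", idx[1], ", item ", detail_cols[idx[2]], ": value ",
         m[idx[1], idx[2]], " not in {0, 0.5, 1, 1.5, 2}")
  }

  seq_expected <- sequence_from_category(df$category)
  seq_col <- schema$sequence_column
  if (seq_col %in% names(df)) {
    seq_given <- as.numeric(df[[seq_col]])
    if (strict_sequence) {
      clash <- which(!is.na(seq_given) & seq_given != seq_expected)
      if (length(clash) > 0L) {
        stop("row ", clash[1], ": sequence/category mismatch (category '",
             df$category[clash[1]], "' implies ", seq_expected[clash[1]],
             ", got ", seq_given[clash[1]], ")")
      }
    }
    seq_val <- ifelse(is.na(seq_given), seq_expected, seq_given)
    if (any(!(seq_val %in% schema$allowed_sequence))) {
      bad <- which(!(seq_val %in% schema$allowed_sequence))[1]
      stop("row ", bad, ": sequence value ", seq_val[bad], " not in {0, 1, 2}")
    }
  } else {
    seq_val <- seq_expected
  }
  df[[seq_col]] <- seq_val

  sub <- function(region) {
    cols <- schema$regions[[region]]$columns
    if (identical(region, "SEQUENCE")) return(seq_val)
    rowSums(m[, cols, drop = FALSE])
  }
  df$sub_upper_extremities <- sub("UPPER_EXTREMITIES")
  df$sub_lower_extremities <- sub("LOWER_EXTREMITIES")
  df$sub_neck_and_trunk <- sub("NECK_AND_TRUNK")
  df$sub_sequence <- seq_val
  df$raw_sum <- df$sub_upper_extremities + df$sub_lower_extremities +
    df$sub_neck_and_trunk + df$sub_sequence
  df$total <- as.integer(ceiling(df$raw_sum))
  df
}
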