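# Nonparametric comparison and interrater agreement statistics, in the forms
# used for ordinal GMOS-R totals: midrank U and H statistics with automatic
# tie correction and large-sample normal / chi-square p-values, two-way
# random-effects single-measure ICC with absolute agreement, Cohen's kappa,
# and within-delta interrater agreement.

.rank_test_result <- function(statistic_name, statistic, p, n_per_group,
                              ties_corrected = TRUE, undefined = FALSE,
                              extra = list()) {
  structure(
    c(list(statistic_name = statistic_name, statistic = statistic,
           p_value = p, n_per_group = n_per_group,
           ties_corrected = ties_corrected, undefined = undefined), extra),
    class = "gmosr_rank_test"
  )
}

#' @export
print.gmosr_rank_test <- function(x, ...) {
  if (x$undefined) {
    cat(x$statistic_name,
        "undefined: all observations identical (zero tie-corrected variance)\n")
  } else {
    cat(sprintf("%s = %.4g, two-tailed p = %.4g (n = %s%s)\n",
                x$statistic_name, x$statistic, x$p_value,
                paste(x$n_per_group, collapse = ", "),
                if (x$ties_corrected) ", ties corrected" else ""))
  }
  invisible(x)
}

# sum of (t^3 - t) over tie groups
.tie_term <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

#' Mann-Whitney rank test with tie-corrected normal approximation
#'
#' U is computed from midranks; the standardized Z uses the normal
#' approximation with the tie-corrected variance, and the two-tailed p-value
#' comes from the normal law. The sign of Z follows the direction of the
#' first group's rank sum: Z is negative when `x` tends to rank below `y`.
#'
#' @param x,y Numeric vectors of scores for the two groups, non-empty.
#' @param correct Apply the continuity correction (0.5 shrinkage of the
#'   deviation) to the normal approximation. The default is the plain
#'   large-sample statistic; the corrected variant tracks exact enumeration
#'   closely even in very small groups.
#' @return A `gmosr_rank_test` with `statistic_name = "Z"`, plus elements `U`
#'   (the first group's U statistic) and `rank_sums`. When all N observations
#'   are identical the tie-corrected variance is zero and the result carries
#'   the `undefined` flag instead of a value.
#' @export
mann_whitney <- function(x, y, correct = FALSE) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - .tie_term(c(x, y)) / (n * (n - 1)))
  extra <- list(U = u1, rank_sums = c(w1, sum(r) - w1))
  if (sigma2 <= 0) {
    return(.rank_test_result("Z", NA_real_, NA_real_, c(n1, n2),
                             undefined = TRUE, extra = extra))
  }
  dev <- u1 - mu
  if (correct) dev <- sign(dev) * max(0, abs(dev) - 0.5)
  z <- dev / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  .rank_test_result("Z", z, p, c(n1, n2), extra = extra)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H is computed from midranks and divided by the tie-correction factor
#' 1 - sum(t^3 - t) / (N^3 - N); the p-value comes from the chi-square law
#' with k - 1 degrees of freedom.
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return A `gmosr_rank_test` with `statistic_name = "H"` and element `df`.
#'   All observations identical yields the `undefined` flag.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 0L) > 0L))
  v <- unlist(groups, use.names = FALSE)
  n <- length(v)
  sizes <- vapply(groups, length, 0L)
  r <- rank(v)
  idx <- rep(seq_along(groups), sizes)
  rank_sums <- vapply(split(r, idx), sum, 0)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  correction <- 1 - .tie_term(v) / (n^3 - n)
  if (correction <= 0) {
    return(.rank_test_result("H", NA_real_, NA_real_, sizes,
                             undefined = TRUE,
                             extra = list(df = length(groups) - 1L)))
  }
  h <- h / correction
  df <- length(groups) - 1L
  p <- stats::pchisq(h, df = df, lower.tail = FALSE)
  .rank_test_result("H", h, p, sizes, extra = list(df = df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Computes the Pearson statistic N (ad - bc)^2 / (r1 r2 c1 c2) on one degree
#' of freedom, without continuity correction by default; Yates' continuity
#' correction is available as an option.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply Yates' continuity correction.
#' @return A `gmosr_rank_test` with `statistic_name = "chi2"` and element
#'   `df = 1`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  n <- sum(table)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("2x2 table has a zero margin; the chi-square statistic is undefined")
  }
  delta <- abs(table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])
  if (correct) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / prod(c(rs, cs))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  .rank_test_result("chi2", chi2, p, n_per_group = rs,
                    ties_corrected = FALSE, extra = list(df = 1L))
}

#' Pairwise intraclass correlation of two raters' total scores
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation coefficient (ICC(A,1) in the McGraw-Wong taxonomy), computed
#' from the ANOVA mean squares of the videos-by-raters score matrix. This is
#' the form appropriate when both raters score every video and rater-level
#' shifts should count against agreement.
#'
#' @param ratings A matrix or data frame with one row per video and two
#'   columns (one per rater), or a list of two aligned numeric vectors.
#' @return A list of class `gmosr_agreement` with elements `icc`, `ms`
#'   (the ANOVA mean squares) and `n`. Zero between-video variance yields
#'   `icc = NA` with the `undefined` flag.
#' @export
icc_pairwise <- function(ratings) {
  m <- .rating_matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k == 2L)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (ss_rows <= 0 || denom <= 0) {
    return(structure(list(icc = NA_real_, undefined = TRUE,
                          ms = c(rows = msr, raters = msc, error = mse),
                          n = n),
                     class = "gmosr_agreement"))
  }
  icc <- (msr - mse) / denom
  structure(list(icc = icc, undefined = FALSE,
                 ms = c(rows = msr, raters = msc, error = mse), n = n),
            class = "gmosr_agreement")
}

#' @export
print.gmosr_agreement <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("ICC undefined: no between-video variance\n")
  } else {
    cat(sprintf("pairwise ICC (two-way random, absolute agreement, single measure) = %.4f (n = %d videos)\n",
                x$icc, x$n))
  }
  invisible(x)
}

.rating_matrix <- function(ratings) {
  if (is.list(ratings) && !is.data.frame(ratings)) {
    stopifnot(length(ratings) == 2L,
              length(ratings[[1]]) == length(ratings[[2]]))
    ratings <- cbind(ratings[[1]], ratings[[2]])
  }
  m <- as.matrix(ratings)
  storage.mode(m) <- "numeric"
  stopifnot(!anyNA(m))
  m
}

#' Fraction of rater pairs agreeing within a score difference
#'
#' Interrater agreement on the numerical total, defined as the fraction of
#' videos for which the two raters' totals differ by at most `delta` points
#' (default 2, the difference conventionally regarded as not clinically
#' relevant).
#'
#' @param ratings As in [icc_pairwise()].
#' @param delta Maximum absolute score difference counted as agreement.
#' @return A single fraction in 0-1.
#' @export
within_delta_agreement <- function(ratings, delta = 2) {
  m <- .rating_matrix(ratings)
  stopifnot(ncol(m) == 2L, delta >= 0)
  mean(abs(m[, 1] - m[, 2]) <= delta)
}

#' Cohen's kappa for two raters' categorical labels
#'
#' Chance-corrected agreement (po - pe) / (1 - pe), with the expected
#' agreement pe taken from the product of the two raters' marginal label
#' distributions.
#'
#' @param labels_a,labels_b Aligned vectors of categorical labels.
#' @return A single value in -1..1, or `NA` when pe = 1 (both raters constant
#'   and equal, leaving chance correction undefined).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0L)
  lev <- union(labels_a, labels_b)
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Kappa-style chance correction of within-delta agreement
#'
#' A non-standard construction: dichotomises each rater pair into
#' within-`delta` versus not, and chance-corrects the observed within-delta
#' rate against a permutation-based chance model (the expected within-delta
#' rate when the second rater's scores are paired with the first rater's at
#' random). Provided because score-difference agreement is sometimes
#' summarised on the kappa scale; it is not Cohen's kappa on categorical
#' labels (see [cohen_kappa()]).
#'
#' @inheritParams within_delta_agreement
#' @return A single value, or `NA` when the chance rate is 1.
#' @export
kappa_within_delta <- function(ratings, delta = 2) {
  m <- .rating_matrix(ratings)
  stopifnot(ncol(m) == 2L)
  po <- mean(abs(m[, 1] - m[, 2]) <= delta)
  pe <- mean(outer(m[, 1], m[, 2], function(a, b) abs(a - b) <= delta))
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Significance flag under the study's multiplicity policy
#'
#' Univariate comparisons are judged at two-tailed p < 0.05; families of three
#' pairwise comparisons among three groups are judged at p < 0.017. Other
#' family sizes fall back to a 0.05 / m Bonferroni threshold with a warning.
#' Thresholds are strict inequalities.
#'
#' @param p P-value(s) in 0-1.
#' @param family_size Number of comparisons in the family (1 or 3 under the
#'   stated policy).
#' @return Logical vector: significant or not.
#' @export
flag_significance <- function(p, family_size = 1L) {
  stopifnot(all(p >= 0 & p <= 1))
  alpha <- if (family_size == 1L) {
    0.05
  } else if (family_size == 3L) {
    0.017
  } else {
    warning("no stated threshold for a family of ", family_size,
            " comparisons; using Bonferroni 0.05/", family_size)
    0.05 / family_size
  }
  p < alpha
}
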