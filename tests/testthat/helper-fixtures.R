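# Shared fixtures and independent oracles, built in code at test time.

schema <- gmosr_schema()
detail_cols <- setdiff(schema$columns, schema$sequence_column)

# a conforming record with every detail item at the same value
flat_record <- function(value, category) {
  c(list(category = category),
    setNames(as.list(rep(value, length(detail_cols))), detail_cols))
}

# a random conforming record (detail items drawn from the permitted set)
random_record <- function(category = sample(gm_categories(), 1)) {
  c(list(category = category),
    setNames(as.list(sample(c(0, 0.5, 1, 1.5, 2), length(detail_cols),
                            replace = TRUE)),
             detail_cols))
}

# independent scoring oracle: plain sum over items plus the category-implied
# sequence value, then ceiling
oracle_total <- function(rec) {
  vals <- unlist(rec[detail_cols])
  ceiling(sum(vals) + sequence_from_category(rec$category))
}

# independent percentile oracle: scan candidate values in ascending order and
# take the first whose cumulative share reaches the level
oracle_percentile <- function(scores, k) {
  for (v in sort(unique(scores))) {
    if (mean(scores <= v) >= k / 100) return(v)
  }
  stop("unreachable")
}

# exact Mann-Whitney permutation oracle: enumerate all group assignments and
# compute the two-tailed tail probability of |U - E[U]|
oracle_mw_exact_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_of <- function(idx) {
    r <- rank(v)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(u_of(seq_len(n1)) - mu)
  combos <- utils::combn(length(v), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= obs - 1e-12)
}

# closed-form tie-corrected variance of U
oracle_mw_variance <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  t <- table(c(x, y))
  n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
}

# ICC(A,1) oracle via stats::aov mean squares
oracle_icc_a1 <- function(m) {
  d <- data.frame(score = c(m[, 1], m[, 2]),
                  video = factor(rep(seq_len(nrow(m)), 2)),
                  rater = factor(rep(1:2, each = nrow(m))))
  ms <- summary(stats::aov(score ~ video + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# simulated two-rater fixture: second rater perturbs a fraction of scores
simulated_ratings <- function(n, noise_sd, seed = 99) {
  set.seed(seed)
  truth <- sample(5:35, n, replace = TRUE)
  cbind(truth, pmin(38, pmax(0, round(truth + rnorm(n, 0, noise_sd)))))
}
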