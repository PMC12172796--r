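# Small in-code fixtures shared across the suite.

tiny_config <- function(n = 120, seed = 1L, ...) {
  generator_config(n, n_regions = 4, seed = seed, ...)
}

tiny_dataset <- function(n = 120, seed = 1L, ...) {
  generate_cohort(tiny_config(n, seed = seed, ...))$dataset
}

# Hand-built two-version dataset from raw matrices (ids P1..Pn).
toy_mvd <- function(X5, X7 = X5, age = NULL, sex = NULL, site = NULL) {
  n <- nrow(X5)
  ids <- sprintf("P%03d", seq_len(n))
  rownames(X5) <- rownames(X7) <- ids
  if (is.null(colnames(X5)))
    colnames(X5) <- colnames(X7) <- paste0("lh_region", seq_len(ncol(X5)),
                                           "_thickness")
  demo <- data.frame(
    participant_id = ids,
    age = if (is.null(age)) seq(50, 80, length.out = n) else age,
    sex = factor(if (is.null(sex)) rep(c("F", "M"), length.out = n) else sex,
                 levels = c("F", "M")),
    site = factor(if (is.null(site)) rep(1:3, length.out = n) else site,
                  levels = 1:3),
    stringsAsFactors = FALSE
  )
  as_multiversion_dataset(demo, list(v5 = X5, v7 = X7))
}

# R-squared of predictions against observations.
r2_score <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

# Random correlation triple (r_jk, r_jh, r_kh) guaranteed PSD: sample data.
random_corr_triple <- function() {
  Z <- matrix(stats::rnorm(30), 10, 3)
  R <- stats::cor(Z)
  c(r_jk = R[1, 2], r_jh = R[1, 3], r_kh = R[2, 3])
}

# Trivariate-normal sampler with given correlations, via Cholesky.
rtrivariate <- function(n, r_jk, r_jh, r_kh) {
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
}
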