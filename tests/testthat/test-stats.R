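test_that("metrics match hand-computed values on toy vectors", {
  m <- compute_metrics(c(60, 70), c(62, 66), k = 2)
  expect_equal(m$MAE, 3)
  expect_equal(m$RMSE, sqrt(10))
  perfect <- suppressWarnings(compute_metrics(c(60, 65, 70), c(60, 65, 70),
                                              k = 1))
  expect_equal(perfect$MAE, 0)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$R, 1)
  expect_error(compute_metrics(c(60, 65, 70), c(64, 64, 64), k = 1),
               "constant")
})

test_that("BIC minus AIC equals k(log n - 2) for any k and n", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(10:3000, 1)
    k <- sample(1:300, 1)
    y <- rnorm(n, 65, 7)
    yhat <- y + rnorm(n)
    m <- compute_metrics(y, yhat, k = k)
    expect_equal(m$BIC - m$AIC, k * (log(n) - 2), tolerance = 1e-9)
  }
})

test_that("R is invariant to affine transforms of the predictions; MAE and RMSE are not", {
  set.seed(21)
  y <- rnorm(100, 65, 7)
  yhat <- y + rnorm(100, 0, 3)
  a <- compute_metrics(y, yhat, k = 5)
  b <- compute_metrics(y, 2 * yhat - 30, k = 5)
  expect_equal(a$R, b$R, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$MAE, b$MAE)))
  expect_false(isTRUE(all.equal(a$RMSE, b$RMSE)))
})

test_that("covariate-corrected adjusted R2 uses sex and site", {
  set.seed(22)
  n <- 200
  cov <- data.frame(sex = factor(rep(c("F", "M"), n / 2)),
                    site = factor(rep(1:2, each = n / 2)))
  y <- rnorm(n, 65, 7) + 3 * (cov$sex == "F")
  yhat <- y + rnorm(n, 0, 3)
  m <- compute_metrics(y, yhat, covariates = cov, k = 5)
  expect_false(is.na(m$R2_adj_corrected))
  expect_gte(m$R2_adj_corrected, m$R2_adj - 0.05)
})

test_that("Zou interval is symmetric for equal correlations and brackets the estimate", {
  ci <- zou_interval(0.5, 0.5, 0.7, 200)
  expect_equal(ci[["CI_lower"]], -ci[["CI_upper"]], tolerance = 1e-9)
  set.seed(23)
  for (rep in 1:50) {
    tr <- random_corr_triple()
    ci <- zou_interval(tr[["r_jk"]], tr[["r_jh"]], tr[["r_kh"]], 150)
    d <- tr[["r_jk"]] - tr[["r_jh"]]
    expect_lte(ci[["CI_lower"]], d)
    expect_gte(ci[["CI_upper"]], d)
  }
  expect_error(zou_interval(0.9, -0.9, 0.9, 100), "positive semi-definite")
  expect_error(zou_interval(1, 0.5, 0.5, 100), "strictly")
  expect_error(zou_interval(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("Hittner Z is zero under equality and antisymmetric in its arguments", {
  h <- hittner_test(0.5, 0.5, 0.7, 200)
  expect_equal(h[["Z"]], 0)
  expect_equal(h[["p"]], 1)
  a <- hittner_test(0.6, 0.4, 0.5, 150)
  b <- hittner_test(0.4, 0.6, 0.5, 150)
  expect_equal(a[["Z"]], -b[["Z"]], tolerance = 1e-12)
  expect_equal(a[["p"]], b[["p"]], tolerance = 1e-12)
})

test_that("Hittner and Zou agree in their alpha = 0.05 decision on random inputs", {
  set.seed(24)
  agree <- vapply(1:1000, function(i) {
    tr <- random_corr_triple()
    ci <- zou_interval(tr[["r_jk"]], tr[["r_jh"]], tr[["r_kh"]], 500)
    h <- hittner_test(tr[["r_jk"]], tr[["r_jh"]], tr[["r_kh"]], 500)
    zou_sig <- ci[["CI_lower"]] > 0 || ci[["CI_upper"]] < 0
    identical(zou_sig, h[["p"]] < 0.05)
  }, logical(1))
  expect_gt(mean(agree), 0.95)
})

test_that("FDR adjustment is the BH step-up: hand example, monotone, order-invariant", {
  expect_equal(fdr_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(25)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(20)
  expect_equal(fdr_adjust(p[perm]), adj[perm])
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("marginal contrasts recover exact shifts and match the least-squares oracle", {
  set.seed(26)
  n <- 40
  age <- rnorm(n, 65, 7)
  cov <- data.frame(sex = factor(rep(c("F", "M"), n / 2)),
                    site = factor(rep(1:2, each = n / 2)))
  base <- age + rnorm(n, 0, 2)
  # identical cells: zero estimate and t
  same <- marginal_contrasts(list(a = base, b = base), age, cov)
  expect_equal(same$estimate, 0, tolerance = 1e-12)
  expect_equal(same$t, 0, tolerance = 1e-12)
  # constant 0.5-year shift is recovered exactly, covariates notwithstanding
  shift <- marginal_contrasts(list(a = base, b = base + 0.5), age, cov)
  expect_equal(shift$estimate, -0.5, tolerance = 1e-9)
  # three-cell instance against a direct normal-equations solve
  preds <- list(a = base, b = base + rnorm(n), c = base + rnorm(n))
  got <- marginal_contrasts(preds, age, cov)
  stacked_y <- unlist(preds)
  cell <- factor(rep(c("a", "b", "c"), each = n), levels = c("a", "b", "c"))
  Xd <- model.matrix(~ cell + rep(age, 3) + rep(cov$sex, 3) +
                       rep(cov$site, 3))
  beta <- solve(crossprod(Xd), crossprod(Xd, stacked_y))
  resid <- stacked_y - Xd %*% beta
  df <- nrow(Xd) - ncol(Xd)
  s2 <- sum(resid^2) / df
  V <- s2 * solve(crossprod(Xd))
  ct <- c(0, -1, 0, 0, 0, 0)  # a - b: -(cellb)
  expect_equal(got$estimate[got$contrast == "a & b"],
               drop(ct %*% beta), tolerance = 1e-8)
  expect_equal(got$SE[got$contrast == "a & b"],
               sqrt(drop(t(ct) %*% V %*% ct)), tolerance = 1e-8)
  expect_equal(got$df, rep(df, 3))
  ct2 <- c(0, 1, -1, 0, 0, 0)  # b - c
  expect_equal(got$estimate[got$contrast == "b & c"],
               drop(ct2 %*% beta), tolerance = 1e-8)
})

test_that("sex differences are recovered with the female-positive convention", {
  set.seed(27)
  n <- 400
  age <- rnorm(n, 65, 7)
  cov <- data.frame(sex = factor(rep(c("F", "M"), n / 2)),
                    site = factor(rep(1:2, each = n / 2)))
  pred_null <- age + rnorm(n, 0, 2)
  pred_f1 <- pred_null + 1 * (cov$sex == "F")
  res <- sex_difference(list(null = pred_null, planted = pred_f1), age, cov)
  null_row <- res[res$cell == "null", ]
  plant_row <- res[res$cell == "planted", ]
  expect_lt(abs(null_row$estimate), 3 * null_row$SE)
  expect_equal(plant_row$estimate, 1, tolerance = 4 * plant_row$SE)
  # flipping the labels flips the sign
  cov_fl <- cov
  cov_fl$sex <- factor(ifelse(cov$sex == "F", "M", "F"), levels = c("F", "M"))
  res_fl <- sex_difference(list(planted = pred_f1), age, cov_fl)
  expect_equal(res_fl$estimate, -plant_row$estimate, tolerance = 1e-9)
  expect_error(sex_difference(list(a = pred_null), age,
                              data.frame(sex = factor(rep("F", n)),
                                         site = cov$site)),
               "both sexes")
})

test_that("the site mixed model detects a planted site shift and degenerates gracefully", {
  set.seed(28)
  n <- 1000
  rec <- data.frame(
    participant_id = rep(sprintf("P%04d", 1:(n / 2)), 2),
    train_source = rep(c("v5", "v7"), each = n / 2),
    age = rep(rnorm(n / 2, 65, 7), 2),
    sex = factor(rep(sample(c("F", "M"), n / 2, TRUE), 2)),
    site = factor(rep(sample(1:3, n / 2, TRUE), 2)))
  rec$predicted_age <- rec$age + 2 * (rec$site == "2") + rnorm(n, 0, 2)
  fit <- site_mixed_model(rec)
  expect_lt(fit$site_effects$p[fit$site_effects$term == "site2"], 1e-3)
  # one training-version group: falls back to fixed-effects OLS
  one <- rec[rec$train_source == "v5", ]
  fit1 <- site_mixed_model(one)
  expect_true(fit1$boundary)
  ols <- summary(lm(predicted_age ~ site + age + sex, one))$coefficients
  expect_equal(fit1$site_effects$estimate[1], ols["site2", 1],
               tolerance = 1e-9)
})

test_that("null site effects yield roughly uniform p-values across replicates", {
  set.seed(29)
  pvals <- vapply(1:150, function(i) {
    n <- 300
    rec <- data.frame(
      train_source = rep(c("v5", "v7"), each = n / 2),
      age = rnorm(n, 65, 7),
      sex = factor(sample(c("F", "M"), n, TRUE)),
      site = factor(sample(1:3, n, TRUE)))
    rec$predicted_age <- rec$age + rnorm(n, 0, 2)
    min(site_mixed_model(rec)$site_effects$p)
  }, 0)
  # two site terms, Bonferroni-ish bound on the minimum
  frac <- mean(pvals < 0.025)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})

test_that("paired correlation tests match the d = t/sqrt(n) identity and symmetry", {
  set.seed(30)
  r5 <- runif(204, -0.4, 0)
  r7 <- r5 + 0.02 + rnorm(204, 0, 0.01)
  res <- paired_correlation_test(r5, r7)
  expect_equal(res$t, res$d * sqrt(204), tolerance = 1e-9)
  expect_lt(res$d, -1.5)
  expect_gt(res$d, -2.7)
  swapped <- paired_correlation_test(r7, r5)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$d, -res$d)
  # identical vectors: zero statistic by convention
  same <- paired_correlation_test(r5, r5)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_error(paired_correlation_test(r5, r5 - 0.1), "zero-variance")
})
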