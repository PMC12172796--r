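#' Performance summary for one set of age predictions
#'
#' Computes the evaluation battery for a prediction vector: Pearson R between
#' chronological and predicted age; adjusted R-squared of the linear model
#' `age ~ predicted` (and, covariate-corrected, `age ~ predicted + sex +
#' site`); MAE and RMSE of the raw residuals `age - predicted` (years); and
#' Gaussian information criteria on the raw residual sum of squares,
#' \deqn{AIC = n \log(RSS/n) + 2k, \quad BIC = n \log(RSS/n) + k \log n,}
#' with `k` the number of model features, so that `BIC - AIC = k(log n - 2)`
#' identically.
#'
#' @param y Observed ages (years).
#' @param yhat Predicted ages; must be non-constant (the correlation is
#'   undefined otherwise).
#' @param covariates Optional data.frame with `sex` and `site` columns aligned
#'   to `y` for the corrected adjusted R-squared.
#' @param k Parameter count used by AIC/BIC (number of features; 204 for the
#'   full Desikan-Killiany table).
#' @return A one-row data.frame: R, R2_adj, R2_adj_corrected, MAE, RMSE, AIC,
#'   BIC, n, k.
#' @export
compute_metrics <- function(y, yhat, covariates = NULL, k = 204) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")
  if (stats::sd(yhat) == 0)
    stop("constant predictions: correlation undefined")
  resid <- y - yhat
  rss <- sum(resid^2)
  r2a <- function(fit) summary(fit)$adj.r.squared
  corrected <- if (!is.null(covariates)) {
    df <- data.frame(y = y, yhat = yhat, sex = covariates$sex,
                     site = covariates$site)
    r2a(stats::lm(y ~ yhat + sex + site, data = df))
  } else NA_real_
  data.frame(
    R = stats::cor(y, yhat),
    R2_adj = r2a(stats::lm(y ~ yhat)),
    R2_adj_corrected = corrected,
    MAE = mean(abs(resid)),
    RMSE = sqrt(mean(resid^2)),
    AIC = n * log(rss / n) + 2 * k,
    BIC = n * log(rss / n) + k * log(n),
    n = n, k = k
  )
}

.check_corr_triple <- function(r_jk, r_jh, r_kh, n) {
  rs <- as.numeric(c(r_jk, r_jh, r_kh))
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly in (-1, 1)")
  if (n < 4) stop("need n >= 4")
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("the implied 3x3 correlation matrix is not positive semi-definite")
  invisible(TRUE)
}

# Correlation between the two sample correlations r_jk and r_jh, which share
# variable j (Zou 2007, following Olkin/Pearson).
.corr_of_corrs <- function(r_jk, r_jh, r_kh) {
  ((r_kh - 0.5 * r_jk * r_jh) * (1 - r_jk^2 - r_jh^2 - r_kh^2) + r_kh^3) /
    ((1 - r_jk^2) * (1 - r_jh^2))
}

#' Zou's confidence interval for the difference of two overlapping correlations
#'
#' Modified-asymptotic interval for `r_jk - r_jh` where both correlations are
#' computed on the same sample and share variable j (here: chronological age
#' correlated with two prediction vectors). Individual Fisher-z limits for
#' each correlation are recombined using the correlation between the two
#' sample correlations, which depends on `r_kh` (the correlation between the
#' two prediction vectors).
#'
#' @param r_jk,r_jh The two overlapping correlations (sharing variable j).
#' @param r_kh Correlation between variables k and h.
#' @param n Sample size.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return Numeric length-2 vector `c(CI_lower, CI_upper)`.
#' @export
zou_interval <- function(r_jk, r_jh, r_kh, n, alpha = 0.05) {
  r_jk <- as.numeric(r_jk); r_jh <- as.numeric(r_jh); r_kh <- as.numeric(r_kh)
  .check_corr_triple(r_jk, r_jh, r_kh, n)
  zcrit <- stats::qnorm(1 - alpha / 2)
  se <- 1 / sqrt(n - 3)
  lim <- function(r) tanh(atanh(r) + c(-1, 1) * zcrit * se)
  l1u1 <- lim(r_jk); l2u2 <- lim(r_jh)
  c12 <- .corr_of_corrs(r_jk, r_jh, r_kh)
  d <- r_jk - r_jh
  lower <- d - sqrt((r_jk - l1u1[1])^2 + (l2u2[2] - r_jh)^2 -
                      2 * c12 * (r_jk - l1u1[1]) * (l2u2[2] - r_jh))
  upper <- d + sqrt((l1u1[2] - r_jk)^2 + (r_jh - l2u2[1])^2 -
                      2 * c12 * (l1u1[2] - r_jk) * (r_jh - l2u2[1]))
  c(CI_lower = lower, CI_upper = upper)
}

#' Hittner-May-Silver Z test for two overlapping dependent correlations
#'
#' Dunn-and-Clark-type Z statistic with the backtransformed average Fisher z
#' substituted for both correlations in the correlation-of-correlations term.
#' Two-sided p from the standard normal.
#'
#' @inheritParams zou_interval
#' @return Named numeric vector `c(Z, p)`.
#' @export
hittner_test <- function(r_jk, r_jh, r_kh, n) {
  r_jk <- as.numeric(r_jk); r_jh <- as.numeric(r_jh); r_kh <- as.numeric(r_kh)
  .check_corr_triple(r_jk, r_jh, r_kh, n)
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rbar <- tanh((z1 + z2) / 2)
  cov_term <- (r_kh * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) / (1 - rbar^2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  c(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Compare age--prediction correlations between two cells
#'
#' Convenience wrapper: given chronological age and two prediction vectors on
#' the same participants, computes the three pairwise correlations and runs
#' both [zou_interval()] and [hittner_test()].
#'
#' @param age Chronological ages.
#' @param pred_a,pred_b Two prediction vectors on the same participants.
#' @param alpha CI level for the Zou interval.
#' @return One-row data.frame: r_jk, r_jh, r_kh, r_diff, CI_lower, CI_upper,
#'   Z, p, n.
#' @export
compare_prediction_correlations <- function(age, pred_a, pred_b,
                                            alpha = 0.05) {
  stopifnot(length(age) == length(pred_a), length(age) == length(pred_b))
  r_jk <- stats::cor(age, pred_a)
  r_jh <- stats::cor(age, pred_b)
  r_kh <- stats::cor(pred_a, pred_b)
  ci <- zou_interval(r_jk, r_jh, r_kh, length(age), alpha)
  ht <- hittner_test(r_jk, r_jh, r_kh, length(age))
  data.frame(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, r_diff = r_jk - r_jh,
             CI_lower = ci[["CI_lower"]], CI_upper = ci[["CI_upper"]],
             Z = ht[["Z"]], p = ht[["p"]], n = length(age))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone in the raw values, capped at 1,
#' invariant to input order).
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.covariate_formula_terms <- function(covariates) {
  terms <- character()
  if (length(unique(covariates$sex)) > 1) terms <- c(terms, "sex")
  if (length(unique(covariates$site)) > 1) terms <- c(terms, "site")
  terms
}

#' Marginal-mean contrasts between prediction cells
#'
#' Stacks predictions from several (source, target) cells covering the same
#' participants, fits one OLS model `predicted ~ cell + age + sex + site`, and
#' returns every pairwise difference of cell-adjusted means with its standard
#' error, residual-df t test, and raw plus FDR-adjusted p-values (the family
#' is all pairwise contrasts in the call).
#'
#' @param predictions Named list of prediction vectors, one per cell, all on
#'   the same participants in the same order.
#' @param age,covariates Chronological ages and a data.frame with `sex` and
#'   `site`, aligned to the prediction vectors.
#' @return data.frame: contrast, estimate (years), SE, df, t, p, p_FDR.
#' @export
marginal_contrasts <- function(predictions, age, covariates) {
  cells <- names(predictions)
  if (length(cells) < 2) stop("need at least 2 cells")
  n <- length(age)
  if (any(vapply(predictions, length, 0L) != n))
    stop("all cells must cover the same participants")
  stacked <- data.frame(
    pred = unlist(predictions, use.names = FALSE),
    cell = factor(rep(cells, each = n), levels = cells),
    age = rep(age, length(cells)),
    sex = rep(covariates$sex, length(cells)),
    site = rep(covariates$site, length(cells))
  )
  rhs <- paste(c("cell", "age", .covariate_formula_terms(covariates)),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("pred ~", rhs)), data = stacked)
  if (anyNA(stats::coef(fit))) stop("collinear covariates in stacked model")
  V <- stats::vcov(fit)
  cf <- stats::coef(fit)
  # Adjusted cell means differ only through the cell dummies (identical
  # covariate distributions per cell by construction).
  cell_coef <- c(0, cf[paste0("cell", cells[-1])])
  names(cell_coef) <- cells
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    ct <- stats::setNames(numeric(length(cf)), names(cf))
    if (pr[1] != cells[1]) ct[paste0("cell", pr[1])] <- 1
    if (pr[2] != cells[1]) ct[paste0("cell", pr[2])] <- -1
    est <- cell_coef[pr[1]] - cell_coef[pr[2]]
    se <- sqrt(drop(t(ct) %*% V %*% ct))
    tval <- est / se
    df <- fit$df.residual
    data.frame(contrast = paste(pr[1], "&", pr[2]),
               estimate = unname(est), SE = se, df = df, t = unname(tval),
               p = 2 * stats::pt(-abs(tval), df))
  })
  out <- do.call(rbind, res)
  out$p_FDR <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Marginal sex difference in predicted age, per cell
#'
#' For each cell, fits `predicted ~ age + sex + site` and reports the sex
#' coefficient with the convention b > 0 when females have the higher
#' predicted age. FDR adjustment spans the cells in the call.
#'
#' @param predictions Named list of prediction vectors (one per cell).
#' @param age,covariates As in [marginal_contrasts()]; `sex` must contain both
#'   levels.
#' @return data.frame: cell, estimate (years, female minus male), SE, df, t,
#'   p, p_FDR.
#' @export
sex_difference <- function(predictions, age, covariates) {
  if (length(unique(covariates$sex)) < 2)
    stop("both sexes must be present")
  res <- lapply(names(predictions), function(cell) {
    df <- data.frame(pred = predictions[[cell]], age = age,
                     # reference level M so the reported coefficient is F - M
                     sex = stats::relevel(factor(covariates$sex), "M"),
                     site = covariates$site)
    rhs <- c("age", "sex")
    if (length(unique(df$site)) > 1) rhs <- c(rhs, "site")
    fit <- stats::lm(stats::as.formula(
      paste("pred ~", paste(rhs, collapse = " + "))), data = df)
    sm <- summary(fit)$coefficients["sexF", ]
    data.frame(cell = cell, estimate = sm["Estimate"],
               SE = sm["Std. Error"], df = fit$df.residual,
               t = sm["t value"], p = sm["Pr(>|t|)"])
  })
  out <- do.call(rbind, res)
  out$p_FDR <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Mixed-effects check of scanner-site effects on predicted age
#'
#' Random-intercept model of predicted age grouped by the version of the
#' training data, with site, age and sex as fixed effects:
#' `predicted ~ site + age + sex + (1 | train_source)`. Site coefficients are
#' reported with Wald z p-values. With fewer than two training-version groups
#' the model degenerates to the fixed-effects OLS site coefficients.
#'
#' @param records data.frame with columns predicted_age, train_source, age,
#'   sex, site (one row per prediction).
#' @return List: `site_effects` (data.frame term/estimate/SE/z/p),
#'   `random_intercept_sd`, `boundary` (TRUE when the group variance is
#'   estimated at/near zero), `model` (the fitted object).
#' @export
site_mixed_model <- function(records) {
  need <- c("predicted_age", "train_source", "age", "sex", "site")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (length(unique(records$site)) < 2) stop("need >= 2 sites")
  records$site <- factor(records$site)
  wald <- function(cf) {
    sel <- grepl("^site", rownames(cf))
    data.frame(term = rownames(cf)[sel], estimate = cf[sel, 1],
               SE = cf[sel, 2], z = cf[sel, 1] / cf[sel, 2],
               p = 2 * stats::pnorm(-abs(cf[sel, 1] / cf[sel, 2])),
               row.names = NULL)
  }
  if (length(unique(records$train_source)) < 2) {
    fit <- stats::lm(predicted_age ~ site + age + sex, data = records)
    return(list(site_effects = wald(summary(fit)$coefficients),
                random_intercept_sd = 0, boundary = TRUE, model = fit))
  }
  fit <- lme4::lmer(predicted_age ~ site + age + sex + (1 | train_source),
                    data = records,
                    control = lme4::lmerControl(
                      check.conv.singular = lme4::.makeCC(action = "ignore",
                                                          tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "train_source"][1]
  list(site_effects = wald(summary(fit)$coefficients),
       random_intercept_sd = ri_sd,
       boundary = ri_sd < 1e-6,
       model = fit)
}

#' Paired t-test on per-feature correlation vectors
#'
#' Compares per-feature correlations (e.g. feature-age correlations under the
#' two pipeline versions) with a paired-samples t-test and paired Cohen's d
#' (mean difference over SD of differences).
#'
#' @param r_a,r_b Equal-length correlation vectors (one entry per feature).
#' @return One-row data.frame: mean_a, mean_b, t, df, p, d.
#' @export
paired_correlation_test <- function(r_a, r_b) {
  if (length(r_a) != length(r_b)) stop("vectors must have equal length")
  if (length(r_a) < 3) stop("need at least 3 paired values")
  d <- r_a - r_b
  if (all(d == 0))
    return(data.frame(mean_a = mean(r_a), mean_b = mean(r_b), t = 0,
                      df = length(d) - 1, p = 1, d = 0))
  if (stats::sd(d) <= 1e-12 * max(abs(d))) stop("zero-variance differences")
  tt <- stats::t.test(r_a, r_b, paired = TRUE)
  data.frame(mean_a = mean(r_a), mean_b = mean(r_b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = mean(d) / stats::sd(d))
}
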