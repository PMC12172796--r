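#' Per-feature cross-version correlations
#'
#' Pearson correlation between the v5 and v7 columns of every feature,
#' optionally stratified by age decade. Bins are closed-open, with the last
#' bin absorbing the upper bound; bins with fewer than 3 participants are
#' flagged and their r omitted (NA).
#'
#' @param dataset A `multiversion_dataset` with versions v5 and v7.
#' @param age_bins Optional numeric vector of bin edges (e.g.
#'   `c(49, 60, 70, 83)` for the default decades); NULL = overall only.
#' @param ids Optional participant subset.
#' @return data.frame: feature, r (overall) and, with bins, one `r_<lo>_<hi>`
#'   column per bin plus a `small_bins` attribute naming under-filled bins.
#' @export
cross_version_correlations <- function(dataset, age_bins = NULL, ids = NULL) {
  stopifnot(inherits(dataset, "multiversion_dataset"))
  v5 <- dataset$features_by_version$v5
  v7 <- dataset$features_by_version$v7
  if (is.null(v5) || is.null(v7)) stop("dataset must carry versions v5 and v7")
  if (!is.null(ids)) {
    v5 <- v5[ids, , drop = FALSE]; v7 <- v7[ids, , drop = FALSE]
  }
  col_cor <- function(a, b) {
    if (nrow(a) < 3) return(rep(NA_real_, ncol(a)))
    vapply(seq_len(ncol(a)), function(j) stats::cor(a[, j], b[, j]), 0)
  }
  out <- data.frame(feature = colnames(v5), r = col_cor(v5, v7),
                    stringsAsFactors = FALSE)
  small <- character()
  if (!is.null(age_bins)) {
    age <- dataset$demographics$age[
      match(rownames(v5), dataset$demographics$participant_id)]
    nb <- length(age_bins) - 1
    for (b in seq_len(nb)) {
      lo <- age_bins[b]; hi <- age_bins[b + 1]
      inbin <- age >= lo & (if (b == nb) age <= hi else age < hi)
      lab <- paste0("r_", lo, "_", hi)
      if (sum(inbin) < 3) {
        small <- c(small, lab)
        out[[lab]] <- NA_real_
      } else {
        out[[lab]] <- col_cor(v5[inbin, , drop = FALSE],
                              v7[inbin, , drop = FALSE])
      }
    }
  }
  attr(out, "small_bins") <- small
  out
}

#' Per-feature correlations with age
#'
#' @param dataset A `multiversion_dataset`.
#' @param version Version tag ("v5" or "v7").
#' @param ids Optional participant subset (e.g. one side of a split).
#' @return data.frame: feature, r (NA with a `zero_variance` flag column for
#'   constant features).
#' @export
age_correlations <- function(dataset, version, ids = NULL) {
  stopifnot(inherits(dataset, "multiversion_dataset"))
  m <- dataset$features_by_version[[version]]
  if (is.null(m)) stop("unknown version: ", version)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 participants")
  age <- dataset$demographics$age[
    match(rownames(m), dataset$demographics$participant_id)]
  sds <- apply(m, 2, stats::sd)
  r <- rep(NA_real_, ncol(m))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(m[, ok, drop = FALSE], age))
  data.frame(feature = colnames(m), r = r, zero_variance = !ok,
             stringsAsFactors = FALSE)
}

#' Permutation feature importance
#'
#' For every feature, importance is the mean (over `n_repeats` seeded
#' permutations) drop in R-squared — `1 - RSS/TSS` of the predictions against
#' `y` — when that feature's column is randomly permuted, breaking its
#' association with the outcome. Ranks break ties by feature name
#' (lexicographic) for determinism.
#'
#' @param model A `fitted_model`.
#' @param X,y Evaluation features (training column order) and ages.
#' @param n_repeats Permutations per feature (>= 1).
#' @param seed Integer seed.
#' @return An `importance_ranking` data.frame: feature, importance, rank;
#'   attributes `n_repeats`, `metric` ("R2_drop"), `baseline`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  X <- as.matrix(X)
  r2 <- function(pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  baseline <- r2(predict_ages(model, X))
  set.seed(seed)
  p <- ncol(X)
  drops <- matrix(NA_real_, n_repeats, p)
  n <- nrow(X)
  for (rep_i in seq_len(n_repeats)) {
    for (j in seq_len(p)) {
      Xp <- X
      Xp[, j] <- X[sample.int(n), j]
      drops[rep_i, j] <- baseline - r2(predict_ages(model, Xp))
    }
  }
  imp <- colMeans(drops)
  ord <- order(-imp, colnames(X))
  out <- data.frame(feature = colnames(X), importance = imp,
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(p), ord)
  out <- out[ord, ]
  out$rank <- seq_len(p)
  rownames(out) <- NULL
  attr(out, "n_repeats") <- n_repeats
  attr(out, "metric") <- "R2_drop"
  attr(out, "baseline") <- baseline
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Principal-component structure by feature type
#'
#' PCA per version on (by default z-scored) features. Reports the
#' variance-explained proportions of the first `n_components` components and,
#' per component, the loading-mass composition over the measure types
#' (share of squared loadings attributable to thickness, area, volume; sums
#' to 1 per component).
#'
#' @param dataset A `multiversion_dataset`.
#' @param n_components Number of leading components to keep (default 10).
#' @param scale. Z-score the features first (default TRUE; raw mixed units
#'   would otherwise be dominated by the widest-variance features).
#' @return Named list (one entry per version) of lists with
#'   `variance_explained` (length `n_components`, non-increasing) and
#'   `composition` (components x measure-type matrix, rows summing to 1).
#' @export
pca_by_feature_type <- function(dataset, n_components = 10, scale. = TRUE) {
  stopifnot(inherits(dataset, "multiversion_dataset"))
  measures <- unique(dataset$feature_info$measure)
  lapply(dataset$features_by_version, function(m) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) stop("degenerate (zero-variance) feature column")
    pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
    nc <- min(n_components, length(pc$sdev))
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    comp <- do.call(rbind, lapply(seq_len(nc), function(ci) {
      l2 <- pc$rotation[, ci]^2
      vapply(measures, function(ms)
        sum(l2[dataset$feature_info$measure == ms]) / sum(l2), 0)
    }))
    rownames(comp) <- paste0("PC", seq_len(nc))
    list(variance_explained = ve[seq_len(nc)], composition = comp)
  })
}

#' Exploratory: region-level association of importance with age correlations
#'
#' For each measure type, correlates region-level mean permutation importance
#' with region-level mean feature-age correlation (averaging the two
#' hemispheres). This is an exploratory definition — one defensible way to ask
#' whether strongly age-associated regions also carry the prediction signal —
#' and is documented as such, not claimed to be uniquely canonical.
#'
#' @param importance An `importance_ranking` for one fitted model.
#' @param age_corr Output of [age_correlations()] on the matching data.
#' @param feature_info The dataset's feature_info table.
#' @return data.frame: measure, r (Spearman correlation across regions),
#'   n_regions.
#' @export
region_importance_age_correlation <- function(importance, age_corr,
                                              feature_info) {
  df <- merge(merge(importance, age_corr, by = "feature",
                    suffixes = c("_imp", "_age")),
              feature_info, by.x = "feature", by.y = "name")
  out <- lapply(split(df, df$measure), function(g) {
    agg <- stats::aggregate(cbind(importance, r) ~ region, data = g, FUN = mean)
    data.frame(measure = g$measure[1],
               r = stats::cor(agg$importance, agg$r, method = "spearman"),
               n_regions = nrow(agg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
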