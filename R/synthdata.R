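# Desikan-Killiany cortical parcellation: 34 regions per hemisphere.
.DK_REGIONS <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.MEASURES <- c("thickness", "area", "volume")

#' Desikan-Killiany region labels
#'
#' @return Character vector of the 34 Desikan-Killiany cortical region labels
#'   (one hemisphere).
#' @export
dk_regions <- function() .DK_REGIONS

#' Configuration for the two-version cortical feature generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults emulate
#' the statistical structure of a large multi-site ageing cohort (ages ~49-83)
#' whose cortical features were estimated twice, by two releases ("v5", "v7")
#' of a surface-reconstruction pipeline: per-feature cross-version agreement
#' averaging r = 0.88, with entorhinal cortex and the temporal/frontal poles
#' showing markedly lower agreement (r < 0.69) for area and volume, and mean
#' feature-age correlations of -0.17 (v5) and -0.15 (v7).
#'
#' @param n_participants Number of participants to simulate.
#' @param age_range Numeric length-2, truncation bounds for age in years.
#' @param age_mean,age_sd Mean and SD of the (truncated) normal age
#'   distribution, in years.
#' @param sex_fraction_female Proportion of females.
#' @param site_weights Length-3 proportions over the three scanner sites;
#'   must sum to 1.
#' @param n_regions Number of Desikan-Killiany regions per hemisphere
#'   (the first `n_regions` of [dk_regions()]).
#' @param measures Character subset of `c("thickness","area","volume")`.
#' @param target_cross_version_r Target mean per-feature Pearson correlation
#'   between the two versions' estimates of the same feature.
#' @param low_agreement_regions Regions whose area/volume features get the
#'   reduced agreement target.
#' @param low_agreement_r Cross-version correlation target for those features.
#' @param mean_age_corr_v5,mean_age_corr_v7 Target mean feature-age Pearson
#'   correlation per version (same sign; ratio fixes the per-version split of
#'   shared signal).
#' @param strong_age_regions Regions planted with extra age signal
#'   (their thickness features carry the strongest loadings), defining the
#'   ground-truth importance ordering.
#' @param sex_effect_size Additive sex shift, in feature SD units, applied to
#'   area and volume features (females lower; cortical area/volume scale with
#'   head size).
#' @param site_effect_size Additive per-site shift in SD units (0 = no site
#'   effect).
#' @param version_offset Mean per-feature offset, in SD units, of the affine
#'   map applied to v7 features (systematic between-release shift; feature
#'   offsets vary around this mean). Affects means, not correlations.
#' @param version_scale_jitter SD of the per-feature multiplicative scale of
#'   the v7 affine map around 1 (between-release rescaling; Pearson
#'   correlations are invariant to it).
#' @param version_offset_jitter Relative SD of the independent per-feature
#'   spread of the v7 offsets around `version_offset`. Feature-specific
#'   offsets make the release identifiable from the feature vector along
#'   many low-variance directions, which is what lets a mixture-trained model
#'   absorb the between-release shift almost freely.
#' @param version_offset_age_coupling Weight of the offset component
#'   proportional to each feature's age loading: version disagreement
#'   concentrates in age-sensitive (atrophy-prone) regions, so the systematic
#'   v7 shift projects onto the age-prediction direction and cross-version
#'   predictions inherit a genuine bias (in years), as single-version models
#'   carry it into data they were not trained on.
#' @param reliability_tilt_sd SD of the per-feature log-ratio tilt of the two
#'   versions' shares of the shared latent signal (heteroscedastic version
#'   noise: per feature, one version is the more reliable measurement). The
#'   geometric mean of the shares is pinned to the cross-version target, so
#'   agreement calibration is unaffected; the tilt is what makes the optimal
#'   prediction weights version-specific.
#' @param version_age_jitter SD of the per-feature jitter of each version's
#'   noise age-alignment around its version mean (each release has its own
#'   idiosyncratic feature-age dependencies, independent between versions;
#'   zero-mean, so per-version mean age-correlation targets are unaffected).
#' @param outlier_fraction Fraction of cells displaced by [inject_outliers()]
#'   at generation time (0 = clean data).
#' @param outlier_magnitude Displacement size in SD units for planted outliers.
#' @param measure_factor_loading Loading of the per-measure-type common factor
#'   (shapes the principal-component structure; shared by the version noise so
#'   both versions decompose similarly).
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_participants,
                             age_range = c(49.33, 82.84),
                             age_mean = 64.84,
                             age_sd = 7.27,
                             sex_fraction_female = 0.5253,
                             site_weights = c(0.5538, 0.3499, 0.0962),
                             n_regions = 34,
                             measures = c("thickness", "area", "volume"),
                             target_cross_version_r = 0.88,
                             low_agreement_regions = c("entorhinal",
                                                       "temporalpole",
                                                       "frontalpole"),
                             low_agreement_r = 0.60,
                             mean_age_corr_v5 = -0.17,
                             mean_age_corr_v7 = -0.15,
                             strong_age_regions = c("inferiorparietal",
                                                    "superiorfrontal",
                                                    "precentral"),
                             sex_effect_size = 0.2,
                             site_effect_size = 0,
                             version_offset = 0.25,
                             version_scale_jitter = 0.03,
                             version_offset_jitter = 1,
                             version_offset_age_coupling = 1,
                             reliability_tilt_sd = 0.05,
                             version_age_jitter = 0.03,
                             outlier_fraction = 0,
                             outlier_magnitude = 6,
                             measure_factor_loading = 0.4,
                             seed = 1L) {
  stopifnot(length(n_participants) == 1, is.finite(n_participants))
  if (n_participants < 1) stop("n_participants must be positive")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range lower bound must be below the upper bound")
  measures <- match.arg(measures, .MEASURES, several.ok = TRUE)
  if (n_regions < 1 || n_regions > length(.DK_REGIONS))
    stop("n_regions must be in 1..", length(.DK_REGIONS))
  if (n_regions * 2 * length(measures) < 1) stop("feature count of zero")
  props <- c(sex_fraction_female, site_weights, outlier_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  # The published site percentages (55.38 / 34.99 / 9.62) sum to 99.99 after
  # rounding; renormalize anything within 1% of 1, reject the rest.
  if (abs(sum(site_weights) - 1) > 1e-2) stop("site_weights must sum to 1")
  site_weights <- site_weights / sum(site_weights)
  if (any(c(target_cross_version_r, low_agreement_r) <= 0) ||
      any(c(target_cross_version_r, low_agreement_r) > 1))
    stop("cross-version correlation targets must lie in (0, 1]")
  if (any(abs(c(mean_age_corr_v5, mean_age_corr_v7)) >= 1))
    stop("age-correlation targets must lie in (-1, 1)")
  if (sign(mean_age_corr_v5) != sign(mean_age_corr_v7) ||
      mean_age_corr_v5 == 0 || mean_age_corr_v7 == 0)
    stop("mean age correlations must be nonzero and share a sign")
  regions <- .DK_REGIONS[seq_len(n_regions)]
  cfg <- list(
    n_participants = as.integer(n_participants),
    age_range = as.numeric(age_range),
    age_mean = age_mean, age_sd = age_sd,
    sex_fraction_female = sex_fraction_female,
    site_weights = site_weights,
    regions = regions,
    measures = measures,
    target_cross_version_r = target_cross_version_r,
    low_agreement_regions = intersect(low_agreement_regions, regions),
    low_agreement_r = low_agreement_r,
    mean_age_corr_v5 = mean_age_corr_v5,
    mean_age_corr_v7 = mean_age_corr_v7,
    strong_age_regions = intersect(strong_age_regions, regions),
    sex_effect_size = sex_effect_size,
    site_effect_size = site_effect_size,
    version_offset = version_offset,
    version_scale_jitter = version_scale_jitter,
    version_offset_jitter = version_offset_jitter,
    version_offset_age_coupling = version_offset_age_coupling,
    reliability_tilt_sd = reliability_tilt_sd,
    version_age_jitter = version_age_jitter,
    outlier_fraction = outlier_fraction,
    outlier_magnitude = outlier_magnitude,
    measure_factor_loading = measure_factor_loading,
    seed = as.integer(seed)
  )
  structure(cfg, class = "generator_config")
}

#' Feature name table for a configuration
#'
#' @param config A `generator_config`.
#' @return data.frame with columns `name` ("<hemi>_<region>_<measure>"),
#'   `hemi`, `region`, `measure`, in canonical column order.
#' @export
feature_table <- function(config) {
  grid <- expand.grid(measure = config$measures, region = config$regions,
                      hemi = c("lh", "rh"), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("hemi", "region", "measure")]
  grid$name <- paste(grid$hemi, grid$region, grid$measure, sep = "_")
  grid[, c("name", "hemi", "region", "measure")]
}

# Truncated-normal ages by rejection; bounds are a few SD wide so this is cheap.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 16, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a paired two-version cortical feature dataset
#'
#' Linear-Gaussian latent-factor simulator. Each participant has one latent
#' anatomy signal per feature, driven by a global ageing factor (standardised
#' age) plus a per-measure-type common factor. Each pipeline version observes
#' that signal with a version-specific share of variance equal to the
#' feature's cross-version agreement target, plus version noise that retains
#' the measure-type factor structure (so both versions have near-identical
#' principal-component profiles) and carries a small version-specific
#' age-aligned component, sized in closed form so the mean feature-age
#' correlation per version equals `mean_age_corr_v5` / `mean_age_corr_v7` in
#' expectation. The cross-version correlation of feature f then equals its
#' target (`target_cross_version_r`, or `low_agreement_r` for area/volume of
#' the low-agreement regions) up to a negligible second-order term.
#'
#' The v7 view additionally passes through a per-feature affine map
#' (multiplicative scale jittered around 1, additive offset around
#' `version_offset`), emulating systematic between-release estimation
#' differences. Pearson correlations — all calibration targets — are invariant
#' to this map, but models trained on one version and applied to the other
#' inherit a genuine cross-version prediction penalty. Sex (area/volume only)
#' and site shifts are additive and shared by both versions. Features are
#' emitted on the standardised (z) scale; no physical units are simulated.
#'
#' @param config A [generator_config()].
#' @return A list with components `dataset` (a `multiversion_dataset`: see
#'   [as_multiversion_dataset()]) and `truth` (ground-truth record: per-feature
#'   age slopes per version, cross-version targets, planted effects, the
#'   importance ordering, and any displaced outlier cells).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_participants
  feats <- feature_table(config)
  p <- nrow(feats)
  if (p == 0) stop("feature count of zero")

  age <- .rtruncnorm(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$sex_fraction_female, "F", "M")
  site <- sample(1:3, n, replace = TRUE, prob = config$site_weights)
  demographics <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = factor(sex, levels = c("F", "M")),
    site = factor(site, levels = 1:3),
    stringsAsFactors = FALSE
  )

  # Per-feature cross-version agreement targets.
  low <- feats$region %in% config$low_agreement_regions &
    feats$measure %in% c("area", "volume")
  r_target <- ifelse(low, config$low_agreement_r, config$target_cross_version_r)

  # Heteroscedastic split of the shared latent variance: per feature, one
  # version measures slightly more reliably than the other (log-ratio tilt),
  # with the geometric mean pinned to the agreement target so that
  # sqrt(rho5 * rho7) = r_target exactly. The tilt is what makes the two
  # versions' optimal prediction weights genuinely differ.
  tilt <- stats::rnorm(p, 0, config$reliability_tilt_sd)
  tcap <- log(1 / r_target)  # keeps both shares <= 1; zero when r = 1
  tilt <- pmin(pmax(tilt, -tcap), tcap)
  rho5 <- r_target * exp(tilt)
  rho7 <- r_target * exp(-tilt)
  a5 <- abs(config$mean_age_corr_v5)
  a7 <- abs(config$mean_age_corr_v7)
  a_mid <- (a5 + a7) / 2
  sgn <- sign(config$mean_age_corr_v5)

  # Age loadings: positive weights, boosted for the planted strong regions
  # (thickness), then scaled once so the across-version mean feature-age
  # correlation hits the midpoint of the two per-version targets; the
  # version-noise age component covers the remaining split between versions.
  w <- abs(stats::rnorm(p, 1, 0.3)) + 0.05
  strong <- feats$region %in% config$strong_age_regions &
    feats$measure == "thickness"
  w[strong] <- w[strong] * 3
  b <- w * a_mid / mean((sqrt(rho5) + sqrt(rho7)) / 2 * w)
  b <- pmin(b, 0.9)

  # Per-version age alignment of the noise: cor(X_v, age) =
  # sqrt(rho_v)*b + sqrt(1-rho_v)*d_vf, with d_vf = d_v + per-feature jitter
  # (independent between versions: each release has its own idiosyncratic
  # feature-age dependencies). The version mean d_v is solved in closed form
  # so the mean feature-age correlation hits its per-version target in
  # expectation. With no version noise at all (r target 1) the versions
  # coincide up to the affine map and the targets collapse to their midpoint.
  m5 <- mean(sqrt(1 - rho5)); m7 <- mean(sqrt(1 - rho7))
  d5 <- if (m5 > 0) sgn * (a5 - mean(sqrt(rho5) * b)) / m5 else 0
  d7 <- if (m7 > 0) sgn * (a7 - mean(sqrt(rho7) * b)) / m7 else 0
  jsd <- if (m5 > 0) config$version_age_jitter else 0
  d5_f <- pmin(pmax(d5 + stats::rnorm(p, 0, jsd), -0.9), 0.9)
  d7_f <- pmin(pmax(d7 + stats::rnorm(p, 0, jsd), -0.9), 0.9)

  z_age <- as.numeric(scale(age))
  c_m <- config$measure_factor_loading
  measure_idx <- match(feats$measure, .MEASURES)

  # Latent anatomy: unit-variance, correlated with z_age via b.
  g_shared <- matrix(stats::rnorm(n * 3), n, 3)           # measure-type factors
  eps <- matrix(stats::rnorm(n * p), n, p)
  resid <- g_shared[, measure_idx, drop = FALSE] * c_m +
    eps * sqrt(1 - c_m^2)
  latent <- sweep(resid, 2, sqrt(1 - b^2), `*`) +
    outer(z_age, sgn * b)

  # Version noise keeps the measure-factor structure, carries the small
  # version-specific age component d_v, and is independent between versions.
  version_view <- function(rho_v, d_vf) {
    g_v <- matrix(stats::rnorm(n * 3), n, 3)
    eta <- matrix(stats::rnorm(n * p), n, p)
    base <- g_v[, measure_idx, drop = FALSE] * c_m + eta * sqrt(1 - c_m^2)
    noise <- sweep(base, 2, sqrt(1 - d_vf^2), `*`) + outer(z_age, d_vf)
    sweep(latent, 2, sqrt(rho_v), `*`) +
      sweep(noise, 2, sqrt(1 - rho_v), `*`)
  }
  X5 <- version_view(rho5, d5_f)
  X7 <- version_view(rho7, d7_f)

  # Additive demographic shifts, shared by both versions (applied before the
  # affine map: the release transforms the full measured value).
  av <- feats$measure %in% c("area", "volume")
  sex_shift <- outer(ifelse(sex == "F", -0.5, 0.5) * config$sex_effect_size,
                     as.numeric(av))
  site_centers <- (as.integer(site) - 2) * config$site_effect_size
  shift <- sex_shift + site_centers
  X5 <- X5 + shift
  X7 <- X7 + shift

  # Between-release affine map on the v7 view: per-feature scale jittered
  # around 1 and offset around version_offset, with an extra offset component
  # proportional to each feature's age loading (the strongest version
  # disagreements sit in age-sensitive, atrophy-prone regions, so the
  # systematic shift projects onto the age-prediction direction). Pearson
  # correlations (all calibration targets) are invariant; cross-version model
  # transfer is not.
  scale7 <- pmax(1 + stats::rnorm(p, 0, config$version_scale_jitter), 0.5)
  offset7 <- config$version_offset *
    (1 + config$version_offset_jitter * stats::rnorm(p)) +
    config$version_offset_age_coupling * sgn * b
  X7 <- sweep(sweep(X7, 2, scale7, `*`), 2, offset7, `+`)

  dimnames(X5) <- dimnames(X7) <- list(demographics$participant_id, feats$name)

  dataset <- as_multiversion_dataset(demographics,
                                     list(v5 = X5, v7 = X7), feats)
  truth <- list(
    feature_names = feats$name,
    age_loading = sgn * b,
    age_slope_v5 = sgn * b * sqrt(rho5) + sqrt(1 - rho5) * d5_f,
    age_slope_v7 = sgn * b * sqrt(rho7) + sqrt(1 - rho7) * d7_f,
    reliability_v5 = rho5,
    reliability_v7 = rho7,
    v7_scale = scale7,
    v7_offset = offset7,
    cross_version_target = r_target,
    low_agreement = low,
    strong_features = feats$name[strong],
    importance_order = feats$name[order(-b)],
    sex_effect = config$sex_effect_size,
    site_effect = config$site_effect_size,
    version_offset = config$version_offset,
    displaced = NULL
  )

  if (config$outlier_fraction > 0) {
    out <- inject_outliers(dataset, config$outlier_fraction,
                           config$outlier_magnitude,
                           seed = config$seed + 1L)
    dataset <- out$dataset
    truth$displaced <- out$displaced
  }

  list(dataset = dataset, truth = truth)
}

#' Construct a multi-version dataset container
#'
#' @param demographics data.frame with columns participant_id, age, sex, site.
#' @param features_by_version Named list of numeric matrices (participants x
#'   features), identical dimnames across versions.
#' @param feature_info Optional data.frame as returned by [feature_table()];
#'   parsed from column names when missing.
#' @return An object of class `multiversion_dataset`.
#' @export
as_multiversion_dataset <- function(demographics, features_by_version,
                                    feature_info = NULL) {
  stopifnot(is.data.frame(demographics),
            all(c("participant_id", "age", "sex", "site") %in%
                  names(demographics)),
            is.list(features_by_version), length(features_by_version) >= 1)
  ids <- demographics$participant_id
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  cols <- colnames(features_by_version[[1]])
  if (anyDuplicated(cols)) stop("feature names must be unique")
  for (v in names(features_by_version)) {
    m <- features_by_version[[v]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("features for version ", v, " must be a numeric matrix")
    if (nrow(m) != nrow(demographics))
      stop("version ", v, ": row count does not match demographics")
    if (!identical(colnames(m), cols))
      stop("version ", v, ": feature column order differs")
    if (is.null(rownames(m))) rownames(features_by_version[[v]]) <- ids
    else if (!identical(rownames(m), ids))
      stop("version ", v, ": row order differs from demographics")
    if (anyNA(m)) stop("version ", v, ": missing values are not allowed")
  }
  if (is.null(feature_info)) {
    parts <- strsplit(cols, "_", fixed = TRUE)
    feature_info <- data.frame(
      name = cols,
      hemi = vapply(parts, `[`, "", 1),
      region = vapply(parts, function(x)
        paste(x[-c(1, length(x))], collapse = "_"), ""),
      measure = vapply(parts, function(x) x[length(x)], ""),
      stringsAsFactors = FALSE
    )
  }
  structure(list(demographics = demographics,
                 features_by_version = features_by_version,
                 feature_info = feature_info),
            class = "multiversion_dataset")
}

#' @export
print.multiversion_dataset <- function(x, ...) {
  cat("multiversion_dataset:", nrow(x$demographics), "participants,",
      nrow(x$feature_info), "features, versions:",
      paste(names(x$features_by_version), collapse = ", "), "\n")
  invisible(x)
}

#' Number of participants / features
#' @param dataset A `multiversion_dataset`.
#' @return Integer count.
#' @export
n_participants <- function(dataset) nrow(dataset$demographics)

#' @rdname n_participants
#' @export
n_features <- function(dataset) nrow(dataset$feature_info)

#' Displace random cells to plant feature-level outliers
#'
#' Randomly selects `fraction` of all participant x feature x version cells
#' and displaces each by `magnitude` column standard deviations *away from*
#' the column mean (the sign follows the cell's side of the mean, so every
#' displaced cell is guaranteed to sit at least `magnitude` SDs out). Cells
#' are allocated as evenly as possible across columns (random rows within a
#' column), so no single column's mean/SD is dominated by the planted
#' outliers; the fixture's purpose is to exercise the downstream 5-SD
#' exclusion rule, which estimates column moments from the contaminated data.
#'
#' @param dataset A `multiversion_dataset`.
#' @param fraction Fraction of cells to displace, in [0, 1].
#' @param magnitude Displacement in SD units; must be > 0 (>= 5 to guarantee
#'   detection at the default threshold).
#' @param seed Integer seed.
#' @return List with `dataset` (modified copy) and `displaced` (data.frame of
#'   version, participant_id, feature cells that were displaced; NULL if none).
#' @export
inject_outliers <- function(dataset, fraction, magnitude, seed = 1L) {
  stopifnot(inherits(dataset, "multiversion_dataset"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (magnitude <= 0) stop("magnitude must be positive")
  if (fraction == 0) return(list(dataset = dataset, displaced = NULL))
  set.seed(seed)
  versions <- names(dataset$features_by_version)
  n <- n_participants(dataset)
  p <- n_features(dataset)
  total <- n * p * length(versions)
  n_cells <- round(fraction * total)
  if (n_cells == 0) return(list(dataset = dataset, displaced = NULL))
  # even allocation over (version, column); random distinct rows per column
  ncols <- p * length(versions)
  per_col <- rep(n_cells %/% ncols, ncols)
  extra <- n_cells %% ncols
  if (extra > 0) {
    bump <- sample.int(ncols, extra)
    per_col[bump] <- per_col[bump] + 1
  }
  ver_i <- integer(0); col_i <- integer(0); row_i <- integer(0)
  for (vc in which(per_col > 0)) {
    ver_i <- c(ver_i, rep(((vc - 1) %/% p) + 1, per_col[vc]))
    col_i <- c(col_i, rep(((vc - 1) %% p) + 1, per_col[vc]))
    row_i <- c(row_i, sample.int(n, min(per_col[vc], n)))
  }
  displaced <- data.frame(
    version = versions[ver_i],
    participant_id = dataset$demographics$participant_id[row_i],
    feature = dataset$feature_info$name[col_i],
    stringsAsFactors = FALSE
  )
  for (v in unique(ver_i)) {
    m <- dataset$features_by_version[[versions[v]]]
    sel <- ver_i == v
    mu <- colMeans(m)
    sdev <- apply(m, 2, stats::sd)
    ri <- row_i[sel]; ci <- col_i[sel]
    cell <- m[cbind(ri, ci)]
    dir <- ifelse(cell >= mu[ci], 1, -1)
    m[cbind(ri, ci)] <- mu[ci] + dir * (abs(cell - mu[ci]) +
                                          magnitude * sdev[ci])
    dataset$features_by_version[[versions[v]]] <- m
  }
  list(dataset = dataset, displaced = displaced)
}

#' Write / read a dataset as delimited text
#'
#' Writes `demographics.csv`, one `features_<version>.csv` per version (wide,
#' one row per participant, feature columns named `<hemi>_<region>_<measure>`)
#' and, when ground truth is supplied, `ground_truth.yaml`.
#'
#' @param dataset A `multiversion_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$demographics,
                   file.path(dir, "demographics.csv"), row.names = FALSE)
  for (v in names(dataset$features_by_version)) {
    m <- dataset$features_by_version[[v]]
    df <- data.frame(participant_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(dir, paste0("features_", v, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    if (!is.null(tr$displaced)) tr$displaced <- as.list(tr$displaced)
    yaml::write_yaml(tr, file.path(dir, "ground_truth.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param versions Version tags to read (default: all `features_*.csv` found).
#' @return For `read_cohort`, a `multiversion_dataset`.
#' @export
read_cohort <- function(dir, versions = NULL) {
  demo <- utils::read.csv(file.path(dir, "demographics.csv"),
                          stringsAsFactors = FALSE)
  demo$sex <- factor(demo$sex, levels = c("F", "M"))
  demo$site <- factor(demo$site)
  if (is.null(versions)) {
    files <- list.files(dir, pattern = "^features_.*\\.csv$")
    versions <- sub("^features_(.*)\\.csv$", "\\1", files)
  }
  fb <- lapply(versions, function(v) {
    df <- utils::read.csv(file.path(dir, paste0("features_", v, ".csv")),
                          check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$participant_id
    m[demo$participant_id, , drop = FALSE]
  })
  names(fb) <- versions
  as_multiversion_dataset(demo, fb)
}
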