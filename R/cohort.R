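#' Remove feature-level outlier participants
#'
#' A participant is excluded when any feature, in any version, lies more than
#' `threshold` standard deviations from that feature column's mean. Column
#' means and SDs are computed once on the full sample (a single pass; the rule
#' is not re-estimated after exclusions). Both version matrices drop the same
#' rows so the dataset stays row-aligned.
#'
#' @param dataset A `multiversion_dataset`.
#' @param threshold Exclusion threshold in SD units (default 5).
#' @return List with `dataset` (filtered), `excluded_ids` (character vector)
#'   and `flagged` (data.frame of version/participant_id/feature cells that
#'   triggered exclusion).
#' @export
remove_outliers <- function(dataset, threshold = 5) {
  stopifnot(inherits(dataset, "multiversion_dataset"))
  if (n_participants(dataset) == 0) stop("dataset is empty")
  if (threshold <= 0) stop("threshold must be positive")
  flagged <- list()
  bad <- logical(n_participants(dataset))
  for (v in names(dataset$features_by_version)) {
    m <- dataset$features_by_version[[v]]
    mu <- colMeans(m)
    sdev <- apply(m, 2, stats::sd)
    zero <- sdev == 0 | is.na(sdev)
    if (any(zero)) {
      warning("version ", v, ": skipping zero-SD column(s): ",
              paste(colnames(m)[zero], collapse = ", "))
      sdev[zero] <- Inf  # z-score undefined; cells can never be flagged
    }
    z <- abs(sweep(sweep(m, 2, mu), 2, sdev, `/`))
    hits <- which(z > threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      flagged[[v]] <- data.frame(
        version = v,
        participant_id = rownames(m)[hits[, 1]],
        feature = colnames(m)[hits[, 2]],
        z = z[hits],
        stringsAsFactors = FALSE
      )
      bad[hits[, 1]] <- TRUE
    }
  }
  excluded <- dataset$demographics$participant_id[bad]
  keep <- !bad
  demo <- dataset$demographics[keep, , drop = FALSE]
  rownames(demo) <- NULL
  fb <- lapply(dataset$features_by_version, function(m) m[keep, , drop = FALSE])
  list(
    dataset = as_multiversion_dataset(demo, fb, dataset$feature_info),
    excluded_ids = excluded,
    flagged = if (length(flagged)) do.call(rbind, c(flagged,
                                                    make.row.names = FALSE))
              else NULL
  )
}

#' Draw a random train/test split
#'
#' Uniform random partition of the participant ids without replacement. With
#' an odd count the training side receives the extra participant.
#'
#' @param ids Character vector of participant ids.
#' @param fraction Training fraction in (0, 1); default 0.5 (the 50-50 design).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param iteration_id Integer label stored on the plan.
#' @return A `split_plan` list: `iteration_id`, `train_ids`, `test_ids`,
#'   `version_assignment` (empty until [assign_versions()]).
#' @export
make_split <- function(ids, fraction = 0.5, seed = 1L, iteration_id = 1L) {
  if (length(ids) < 4) stop("need at least 4 participants to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  n_train <- ceiling(length(ids) * fraction)
  train <- sample(ids, n_train)
  structure(list(iteration_id = as.integer(iteration_id),
                 train_ids = sort(train),
                 test_ids = sort(setdiff(ids, train)),
                 version_assignment = NULL),
            class = "split_plan")
}

#' Assign a pipeline version to every participant of a split
#'
#' The shuffling unit is the participant row: each participant contributes all
#' of their features from a single version. In `shuffled_50_50` mode a uniform
#' random half of the training participants (and, independently, of the test
#' participants) is assigned "v5" and the other half "v7" (odd counts: the v5
#' side gets the extra row). Single-version modes assign one constant version.
#'
#' @param plan A `split_plan` from [make_split()].
#' @param mode One of "single_v5", "single_v7", "shuffled_50_50".
#' @param seed Integer seed (used by the shuffled mode).
#' @return The plan with `version_assignment` filled (named character vector
#'   over all train and test ids).
#' @export
assign_versions <- function(plan, mode = c("single_v5", "single_v7",
                                           "shuffled_50_50"), seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  mode <- match.arg(mode)
  all_ids <- c(plan$train_ids, plan$test_ids)
  if (mode == "single_v5") {
    asg <- stats::setNames(rep("v5", length(all_ids)), all_ids)
  } else if (mode == "single_v7") {
    asg <- stats::setNames(rep("v7", length(all_ids)), all_ids)
  } else {
    set.seed(seed)
    half <- function(ids) {
      v5 <- sample(ids, ceiling(length(ids) / 2))
      stats::setNames(ifelse(ids %in% v5, "v5", "v7"), ids)
    }
    asg <- c(half(plan$train_ids), half(plan$test_ids))
  }
  plan$version_assignment <- asg
  plan$mode <- mode
  plan
}

#' Assemble the design matrix for one side of a split
#'
#' Row i takes participant i's feature row from the version matrix named by
#' the plan's assignment; ages and covariates are aligned by participant id.
#' Column order is the dataset's canonical feature order for every assembly.
#'
#' @param dataset A `multiversion_dataset`.
#' @param plan A `split_plan` with version assignments.
#' @param side "train" or "test".
#' @return List with `X` (feature matrix), `age` (numeric vector),
#'   `covariates` (data.frame with participant_id, sex, site) and `ids`.
#' @export
assemble_design_matrix <- function(dataset, plan, side = c("train", "test")) {
  stopifnot(inherits(dataset, "multiversion_dataset"),
            inherits(plan, "split_plan"))
  side <- match.arg(side)
  ids <- if (side == "train") plan$train_ids else plan$test_ids
  if (is.null(plan$version_assignment) ||
      !all(ids %in% names(plan$version_assignment)))
    stop("plan has no version assignment covering the ", side, " side")
  asg <- plan$version_assignment[ids]
  missing_v <- setdiff(unique(asg), names(dataset$features_by_version))
  if (length(missing_v))
    stop("version(s) absent from dataset: ", paste(missing_v, collapse = ", "))
  X <- matrix(NA_real_, length(ids), n_features(dataset),
              dimnames = list(ids, dataset$feature_info$name))
  for (v in unique(asg)) {
    sel <- ids[asg == v]
    m <- dataset$features_by_version[[v]]
    if (!all(sel %in% rownames(m)))
      stop("participants missing from version ", v, " matrix")
    X[sel, ] <- m[sel, , drop = FALSE]
  }
  di <- dataset$demographics
  rows <- match(ids, di$participant_id)
  if (anyNA(rows)) stop("split ids missing from demographics")
  list(X = X,
       age = di$age[rows],
       covariates = data.frame(participant_id = ids,
                               sex = di$sex[rows], site = di$site[rows],
                               stringsAsFactors = FALSE),
       ids = ids,
       versions = asg)
}

#' Serialize / restore a split plan
#'
#' Plain-text sidecar (YAML) recording the iteration id, both sides and the
#' version assignment, sufficient to replay a run exactly.
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @return `path` (write) / a `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  yaml::write_yaml(list(iteration_id = plan$iteration_id,
                        mode = plan$mode %||% NA,
                        train_ids = plan$train_ids,
                        test_ids = plan$test_ids,
                        version_assignment =
                          as.list(plan$version_assignment %||% character())),
                   path)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- yaml::read_yaml(path)
  asg <- unlist(x$version_assignment)
  structure(list(iteration_id = as.integer(x$iteration_id),
                 train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 version_assignment = if (length(asg)) asg else NULL,
                 mode = if (is.character(x$mode)) x$mode else NULL),
            class = "split_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
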