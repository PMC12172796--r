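# Seed hierarchy: one master seed deterministically yields per-iteration
# (split, assignment, model) seeds, so sub-experiments replay independently.
.derive_seeds <- function(master, i) {
  set.seed(master)
  matrix(sample.int(.Machine$integer.max - 1L, 3L * i, replace = TRUE),
         nrow = i, dimnames = list(NULL, c("split", "assign", "model")))
}

.respec <- function(spec, seed) {
  spec$seed <- as.integer(seed %% .Machine$integer.max)
  spec
}

.record <- function(ids, iteration, source, target, side, age, pred) {
  data.frame(participant_id = ids, iteration_id = iteration,
             train_source = source, test_target = target, side = side,
             true_age = age, predicted_age = pred,
             stringsAsFactors = FALSE)
}

# Evaluate one model on one assembled side and return (records, metrics row).
.evaluate_cell <- function(model, asm, iteration, source, target, side, k) {
  pred <- predict_ages(model, asm$X)
  rec <- .record(asm$ids, iteration, source, target, side, asm$age, pred)
  met <- compute_metrics(asm$age, pred, asm$covariates, k = k)
  met <- cbind(data.frame(iteration_id = iteration, train_source = source,
                          test_target = target, side = side,
                          stringsAsFactors = FALSE), met)
  list(records = rec, metrics = met)
}

.single_plan <- function(plan, version) {
  assign_versions(plan, paste0("single_", version))
}

.bind_results <- function(parts) {
  list(records = do.call(rbind, lapply(parts, `[[`, "records")),
       metrics = do.call(rbind, lapply(parts, `[[`, "metrics")))
}

.design_result <- function(design, parts, seeds, master_seed, spec) {
  out <- .bind_results(parts)
  rownames(out$records) <- rownames(out$metrics) <- NULL
  structure(list(design = design, records = out$records,
                 metrics = out$metrics, seeds = seeds,
                 master_seed = master_seed, spec = spec),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("design_result", x$design, "-", nrow(x$metrics), "iteration-cell",
      "metric rows,", nrow(x$records), "prediction records\n")
  invisible(x)
}

#' Design A: repeated random train/test splitting of single-version models
#'
#' For each of `i` iterations a fresh 50-50 split is drawn; one model is fit
#' per version on its training matrix, then all four source-to-target cells
#' (v5\eqn{\to}v5, v5\eqn{\to}v7, v7\eqn{\to}v7, v7\eqn{\to}v5) are evaluated.
#' Test-side performance uses the test rows of the target version; "train"
#' performance follows the same split semantics, i.e. the source model
#' evaluated on the train-side rows of the target version.
#'
#' @param dataset A `multiversion_dataset` with versions v5 and v7.
#' @param spec A [model_spec()].
#' @param i Number of split iterations.
#' @param seed Master seed for the whole design.
#' @param fraction Training fraction (default 0.5).
#' @return A `design_result`: `records` (one row per participant, iteration,
#'   cell and side), `metrics` (one row per iteration-cell-side), `seeds`.
#' @export
run_split_permutations <- function(dataset, spec, i = 100, seed = 1L,
                                   fraction = 0.5) {
  stopifnot(inherits(dataset, "multiversion_dataset"), i >= 1)
  seeds <- .derive_seeds(seed, i)
  ids <- dataset$demographics$participant_id
  k <- n_features(dataset)
  parts <- vector("list", i)
  for (it in seq_len(i)) {
    plan <- make_split(ids, fraction, seed = seeds[it, "split"],
                       iteration_id = it)
    plans <- list(v5 = .single_plan(plan, "v5"), v7 = .single_plan(plan, "v7"))
    train_asm <- lapply(plans, assemble_design_matrix, dataset = dataset,
                        side = "train")
    test_asm <- lapply(plans, assemble_design_matrix, dataset = dataset,
                       side = "test")
    models <- lapply(c(v5 = "v5", v7 = "v7"), function(v)
      tryCatch(fit_model(.respec(spec, seeds[it, "model"]),
                         train_asm[[v]]$X, train_asm[[v]]$age),
               error = function(e)
                 stop("iteration ", it, ", training version ", v, ": ",
                      conditionMessage(e), call. = FALSE)))
    cells <- expand.grid(source = c("v5", "v7"), target = c("v5", "v7"),
                         stringsAsFactors = FALSE)
    parts[[it]] <- .bind_results(unlist(lapply(seq_len(nrow(cells)),
      function(ci) {
        src <- cells$source[ci]; tgt <- cells$target[ci]
        list(.evaluate_cell(models[[src]], train_asm[[tgt]], it, src, tgt,
                            "train", k),
             .evaluate_cell(models[[src]], test_asm[[tgt]], it, src, tgt,
                            "test", k))
      }), recursive = FALSE))
  }
  .design_result("A_splits", parts, seeds, seed, spec)
}

#' Design B: version shuffling on a fixed train/test split
#'
#' One fixed 50-50 split (the *initial iteration*) is held constant. The two
#' single-version models are fit once on it and the four single-to-single
#' cells are evaluated once. Then, for each of `i` iterations, fresh 50-50
#' version assignments are drawn independently within the training and test
#' sides; a mix-trained model is fit per iteration and every mix-involved cell
#' of the 3x3 source-by-target grid (mix/v5/v7 each way) is evaluated, so the
#' grid has exactly 9 cells.
#'
#' @inheritParams run_split_permutations
#' @param fixed_split_seed Seed of the single fixed split.
#' @return A `design_result` (mix-involved cells carry `i` iterations;
#'   single-version cells iteration 1 only).
#' @export
run_version_shuffle <- function(dataset, spec, i = 100, fixed_split_seed = 1L,
                                seed = 1L, fraction = 0.5) {
  stopifnot(inherits(dataset, "multiversion_dataset"), i >= 1)
  seeds <- .derive_seeds(seed, i)
  ids <- dataset$demographics$participant_id
  k <- n_features(dataset)
  plan <- make_split(ids, fraction, seed = fixed_split_seed, iteration_id = 1L)

  single_plans <- list(v5 = .single_plan(plan, "v5"),
                       v7 = .single_plan(plan, "v7"))
  single_train <- lapply(single_plans, assemble_design_matrix,
                         dataset = dataset, side = "train")
  single_test <- lapply(single_plans, assemble_design_matrix,
                        dataset = dataset, side = "test")
  single_models <- lapply(c(v5 = "v5", v7 = "v7"), function(v)
    fit_model(.respec(spec, seeds[1, "model"]),
              single_train[[v]]$X, single_train[[v]]$age))

  parts <- list()
  for (src in c("v5", "v7")) for (tgt in c("v5", "v7"))
    parts[[paste(src, tgt)]] <-
      .evaluate_cell(single_models[[src]], single_test[[tgt]], 1L, src, tgt,
                     "test", k)

  for (it in seq_len(i)) {
    mplan <- assign_versions(plan, "shuffled_50_50",
                             seed = seeds[it, "assign"])
    mplan$iteration_id <- it
    mix_train <- assemble_design_matrix(dataset, mplan, "train")
    mix_test <- assemble_design_matrix(dataset, mplan, "test")
    mix_model <- tryCatch(
      fit_model(.respec(spec, seeds[it, "model"]), mix_train$X,
                mix_train$age),
      error = function(e) stop("iteration ", it, ", mix training: ",
                               conditionMessage(e), call. = FALSE))
    parts[[paste("it", it)]] <- .bind_results(list(
      .evaluate_cell(mix_model, mix_train, it, "mix", "mix", "train", k),
      .evaluate_cell(mix_model, mix_test, it, "mix", "mix", "test", k),
      .evaluate_cell(mix_model, single_test$v5, it, "mix", "v5", "test", k),
      .evaluate_cell(mix_model, single_test$v7, it, "mix", "v7", "test", k),
      .evaluate_cell(single_models$v5, mix_test, it, "v5", "mix", "test", k),
      .evaluate_cell(single_models$v7, mix_test, it, "v7", "mix", "test", k)
    ))
  }
  res <- .design_result("B_shuffle", parts, seeds, seed, spec)
  res$fixed_split_seed <- fixed_split_seed
  res$fixed_plan <- plan
  res
}

#' Design C: joint variation of splits and version composition
#'
#' As Design B but the 50-50 split itself is re-drawn each iteration; the
#' single-version and mix models are all re-fit per iteration on the fresh
#' split, and all 9 grid cells are evaluated every iteration.
#'
#' @inheritParams run_split_permutations
#' @return A `design_result` with all 9 cells aggregated over `i` iterations.
#' @export
run_joint_permutations <- function(dataset, spec, i = 100, seed = 1L,
                                   fraction = 0.5) {
  stopifnot(inherits(dataset, "multiversion_dataset"), i >= 1)
  seeds <- .derive_seeds(seed, i)
  ids <- dataset$demographics$participant_id
  k <- n_features(dataset)
  parts <- vector("list", i)
  for (it in seq_len(i)) {
    plan <- make_split(ids, fraction, seed = seeds[it, "split"],
                       iteration_id = it)
    plans <- list(v5 = .single_plan(plan, "v5"),
                  v7 = .single_plan(plan, "v7"),
                  mix = assign_versions(plan, "shuffled_50_50",
                                        seed = seeds[it, "assign"]))
    train_asm <- lapply(plans, assemble_design_matrix, dataset = dataset,
                        side = "train")
    test_asm <- lapply(plans, assemble_design_matrix, dataset = dataset,
                       side = "test")
    models <- lapply(train_asm, function(a)
      fit_model(.respec(spec, seeds[it, "model"]), a$X, a$age))
    cells <- expand.grid(source = names(plans), target = names(plans),
                         stringsAsFactors = FALSE)
    parts[[it]] <- .bind_results(lapply(seq_len(nrow(cells)), function(ci) {
      src <- cells$source[ci]; tgt <- cells$target[ci]
      .evaluate_cell(models[[src]], test_asm[[tgt]], it, src, tgt, "test", k)
    }))
  }
  .design_result("C_joint", parts, seeds, seed, spec)
}

#' Aggregate per-iteration metrics to a mean-and-SD grid
#'
#' @param result A `design_result` (or its `metrics` data.frame).
#' @return data.frame with one row per (train_source, test_target, side) and,
#'   for each metric, `<metric>_mean` and `<metric>_sd` over iterations, plus
#'   the iteration count.
#' @export
summarize_design <- function(result) {
  metrics <- if (inherits(result, "design_result")) result$metrics else result
  cols <- c("R", "R2_adj", "R2_adj_corrected", "MAE", "RMSE", "AIC", "BIC")
  key <- interaction(metrics$train_source, metrics$test_target, metrics$side,
                     drop = TRUE)
  rows <- lapply(split(metrics, key), function(g) {
    out <- data.frame(train_source = g$train_source[1],
                      test_target = g$test_target[1], side = g$side[1],
                      iterations = nrow(g), stringsAsFactors = FALSE)
    for (cl in cols) {
      out[[paste0(cl, "_mean")]] <- mean(g[[cl]])
      out[[paste0(cl, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[cl]]) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$train_source, out$test_target, out$side), ]
  rownames(out) <- NULL
  out
}

#' Bag predictions across iterations
#'
#' For each (train_source, test_target) cell, the bagged prediction of a
#' participant is the arithmetic mean of their predicted ages over all
#' iterations in which they appeared on the test side of that cell.
#' Participants never tested in a cell are absent (not imputed).
#'
#' @param records A `design_result` or its `records` data.frame.
#' @param cells Optional character matrix/data.frame restricting to given
#'   (source, target) pairs; default: every cell present.
#' @return data.frame: train_source, test_target, participant_id, true_age,
#'   predicted_age (bagged), n_iterations.
#' @export
bag_predictions <- function(records, cells = NULL) {
  if (inherits(records, "design_result")) records <- records$records
  records <- records[records$side == "test", , drop = FALSE]
  if (nrow(records) == 0) stop("no test-side prediction records")
  if (!is.null(cells)) {
    keep <- paste(records$train_source, records$test_target) %in%
      paste(cells[[1]], cells[[2]])
    records <- records[keep, , drop = FALSE]
  }
  key <- interaction(records$train_source, records$test_target,
                     records$participant_id, drop = TRUE)
  agg <- lapply(split(records, key), function(g)
    data.frame(train_source = g$train_source[1],
               test_target = g$test_target[1],
               participant_id = g$participant_id[1],
               true_age = g$true_age[1],
               predicted_age = mean(g$predicted_age),
               n_iterations = nrow(g), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$train_source, out$test_target, out$participant_id), ]
  rownames(out) <- NULL
  out
}

#' Write a design result as tidy CSVs
#'
#' Emits `records_<design>.csv` (one row per prediction record),
#' `metrics_<design>.csv` (one row per iteration-cell-side) and
#' `summary_<design>.csv` (the mean-and-SD grid).
#'
#' @param result A `design_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_design_result <- function(result, dir) {
  stopifnot(inherits(result, "design_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- result$design
  utils::write.csv(result$records,
                   file.path(dir, paste0("records_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(result$metrics,
                   file.path(dir, paste0("metrics_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(summarize_design(result),
                   file.path(dir, paste0("summary_", tag, ".csv")),
                   row.names = FALSE)
  invisible(dir)
}
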