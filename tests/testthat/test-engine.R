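spec_lin <- model_spec("linear", seed = 1)

test_that("one split-permutation iteration equals the manual split-fit-evaluate run", {
  d <- tiny_dataset(n = 120, seed = 41)
  res <- run_split_permutations(d, spec_lin, i = 1, seed = 55)
  # replicate by hand with the same derived seeds
  seeds <- res$seeds
  plan <- make_split(d$demographics$participant_id, 0.5,
                     seed = seeds[1, "split"])
  p5 <- assign_versions(plan, "single_v5")
  tr <- assemble_design_matrix(d, p5, "train")
  te <- assemble_design_matrix(d, p5, "test")
  m5 <- fit_model(model_spec("linear", seed = seeds[1, "model"]), tr$X, tr$age)
  manual <- predict_ages(m5, te$X)
  rec <- res$records
  got <- rec[rec$train_source == "v5" & rec$test_target == "v5" &
               rec$side == "test", ]
  expect_equal(got$predicted_age[match(te$ids, got$participant_id)], manual,
               tolerance = 1e-12)
})

test_that("identical version matrices collapse the within-version cells", {
  base <- tiny_dataset(n = 100, seed = 42)
  d <- toy_mvd(base$features_by_version$v5, base$features_by_version$v5,
               age = base$demographics$age)
  res <- run_split_permutations(d, spec_lin, i = 3, seed = 5)
  m <- res$metrics[res$metrics$side == "test", ]
  for (it in 1:3) {
    a <- m[m$iteration_id == it & m$train_source == "v5" & m$test_target == "v5", ]
    b <- m[m$iteration_id == it & m$train_source == "v7" & m$test_target == "v7", ]
    expect_equal(a$MAE, b$MAE, tolerance = 1e-12)
    expect_equal(a$R, b$R, tolerance = 1e-12)
  }
})

test_that("reported mean and SD equal direct recomputation from stored metrics", {
  d <- tiny_dataset(n = 100, seed = 43)
  res <- run_split_permutations(d, spec_lin, i = 5, seed = 6)
  sm <- summarize_design(res)
  g <- res$metrics[res$metrics$train_source == "v5" &
                     res$metrics$test_target == "v7" &
                     res$metrics$side == "test", ]
  row <- sm[sm$train_source == "v5" & sm$test_target == "v7" &
              sm$side == "test", ]
  expect_equal(row$MAE_mean, mean(g$MAE))
  expect_equal(row$MAE_sd, sd(g$MAE))
  expect_equal(row$AIC_mean, mean(g$AIC))
})

test_that("design results replay bit-identically from the master seed", {
  d <- tiny_dataset(n = 100, seed = 44)
  a <- run_version_shuffle(d, spec_lin, i = 3, fixed_split_seed = 2, seed = 9)
  b <- run_version_shuffle(d, spec_lin, i = 3, fixed_split_seed = 2, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$metrics, b$metrics)
})

test_that("the shuffle design fills exactly the 3x3 source-by-target grid", {
  d <- tiny_dataset(n = 100, seed = 45)
  res <- run_version_shuffle(d, spec_lin, i = 4, fixed_split_seed = 3, seed = 7)
  cells <- unique(res$metrics[res$metrics$side == "test",
                              c("train_source", "test_target")])
  expect_equal(nrow(cells), 9)
  expect_setequal(paste(cells$train_source, cells$test_target),
                  as.vector(outer(c("v5", "v7", "mix"), c("v5", "v7", "mix"),
                                  paste)))
  # single-version cells are computed once, mix-involved cells i times
  counts <- table(paste(res$metrics$train_source, res$metrics$test_target,
                        res$metrics$side))
  expect_equal(unname(counts[["v5 v5 test"]]), 1)
  expect_equal(unname(counts[["mix v5 test"]]), 4)
  expect_equal(unname(counts[["mix mix test"]]), 4)
})

test_that("every test participant yields exactly one record per evaluated cell", {
  d <- tiny_dataset(n = 80, seed = 46)
  res <- run_joint_permutations(d, spec_lin, i = 3, seed = 8)
  rec <- res$records
  tab <- table(rec$participant_id, rec$iteration_id,
               paste(rec$train_source, rec$test_target))
  expect_true(all(tab %in% c(0, 1)))
  # per iteration-cell, the record count equals the test-side size
  per <- aggregate(participant_id ~ iteration_id + train_source + test_target,
                   rec, length)
  expect_true(all(per$participant_id == 40))
})

test_that("a mix assignment forced to one version reproduces the single-version model", {
  d <- tiny_dataset(n = 80, seed = 47)
  plan <- make_split(d$demographics$participant_id, seed = 12)
  forced <- assign_versions(plan, "single_v5")    # boundary: 100% v5 "mix"
  tr <- assemble_design_matrix(d, forced, "train")
  m_forced <- fit_model(spec_lin, tr$X, tr$age)
  m_single <- fit_model(spec_lin,
                        d$features_by_version$v5[plan$train_ids, ],
                        tr$age)
  te7 <- assemble_design_matrix(d, assign_versions(plan, "single_v7"), "test")
  expect_equal(predict_ages(m_forced, te7$X), predict_ages(m_single, te7$X),
               tolerance = 1e-10)
})

test_that("joint permutations vary more than assignment-only shuffling", {
  d <- tiny_dataset(n = 240, seed = 48)
  b <- run_version_shuffle(d, spec_lin, i = 30, fixed_split_seed = 5, seed = 21)
  c <- run_joint_permutations(d, spec_lin, i = 30, seed = 21)
  sdev <- function(res, src, tgt) {
    m <- res$metrics
    sd(m$MAE[m$train_source == src & m$test_target == tgt & m$side == "test"])
  }
  expect_gt(sdev(c, "mix", "mix"), sdev(b, "mix", "mix"))
})

test_that("bagging averages per participant and never exceeds the mean per-iteration MAE", {
  rec <- data.frame(
    participant_id = c("P1", "P1", "P2", "P2"),
    iteration_id = c(1, 2, 1, 2),
    train_source = "mix", test_target = "mix", side = "test",
    true_age = c(61, 61, 70, 70),
    predicted_age = c(60, 64, 68, 66))
  bag <- bag_predictions(rec)
  expect_equal(bag$predicted_age, c(62, 67))
  expect_equal(bag$n_iterations, c(2, 2))
  # all iterations identical -> bagged equals the single iteration
  rec2 <- rec
  rec2$predicted_age <- c(60, 60, 68, 68)
  expect_equal(bag_predictions(rec2)$predicted_age, c(60, 68))
  # Jensen: with a fixed test set the bagged MAE cannot exceed the mean MAE
  d <- tiny_dataset(n = 100, seed = 49)
  res <- run_version_shuffle(d, spec_lin, i = 10, fixed_split_seed = 3,
                             seed = 30)
  bagged <- bag_predictions(res, cells = data.frame(src = "mix", tgt = "mix"))
  bag_mae <- mean(abs(bagged$true_age - bagged$predicted_age))
  per_iter <- res$metrics[res$metrics$train_source == "mix" &
                            res$metrics$test_target == "mix" &
                            res$metrics$side == "test", "MAE"]
  expect_lte(bag_mae, mean(per_iter) + 1e-12)
  expect_error(bag_predictions(rec[0, ]), "no test-side")
})
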