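# Fold construction, weighted training, prediction contracts, random search.

test_that("grouped folds are exclusive, exhaustive and leak-free", {
  groups <- rep(sprintf("g%03d", 1:110), each = 3)
  plan <- make_folds(groups, "leave_k_groups_out", k = 10, seed = 1)
  test_groups <- lapply(plan$folds, `[[`, "test_groups")
  expect_equal(vapply(test_groups, length, integer(1)), rep(11L, 10))
  expect_equal(sort(unlist(test_groups)), sort(unique(groups)))
  expect_equal(anyDuplicated(unlist(test_groups)), 0L)
  assert_no_leakage(plan, groups)

  logo <- make_folds(groups[1:30], "leave_one_group_out", seed = 2)
  expect_equal(logo$k, 10) # one fold per group
  expect_true(all(vapply(logo$folds, function(f) length(f$test_groups), integer(1)) == 1))
  expect_equal(
    sort(unlist(lapply(logo$folds, `[[`, "test_groups"))),
    sort(unique(groups[1:30]))
  )

  kf <- make_folds(groups, "kfold", k = 10, seed = 3)
  expect_equal(sort(unlist(lapply(kf$folds, `[[`, "test"))), seq_along(groups))
  expect_error(make_folds(groups, "leave_k_groups_out", k = 111, seed = 1), "exceeds")
  expect_error(make_folds("g1", "leave_one_group_out"), ">= 2 groups")
})

test_that("training is deterministic and validates its inputs", {
  tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 4, sites_per_guide = 150), seed = 2))
  fm <- encode_dataset(tab, encoder_spec("OH", with_distance = TRUE))
  y <- as.integer(tab$label == "active")
  w <- sample_weights(tab)
  probe <- fm[1:50, , drop = FALSE]
  m1 <- train_gbt(fm, y, w, model_spec("classification", seed = 7))
  m2 <- train_gbt(fm, y, w, model_spec("classification", seed = 7))
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_true(all(predict(m1, probe) >= 0 & predict(m1, probe) <= 1))

  bad <- unclass(fm)
  bad[1, 1] <- NA
  expect_error(train_gbt(bad, y, w, model_spec("classification")), "NaN/NA")
  expect_error(
    train_gbt(fm, rep(0L, nrow(fm)), w, model_spec("classification")),
    "single-class"
  )
  expect_error(
    train_gbt(fm, y + 0.5, w, model_spec("classification")),
    "binary"
  )
})

test_that("prediction refuses permuted or renamed feature schemas", {
  tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 3, sites_per_guide = 80), seed = 4))
  fm <- encode_dataset(tab, "MM")
  m <- train_gbt(fm, as.integer(tab$label == "active"), NULL, model_spec("classification"))
  swapped <- fm[, c(2, 1, 3:ncol(fm))]
  expect_error(predict(m, swapped), "schema mismatch")
  renamed <- fm
  colnames(renamed)[1] <- "posX"
  expect_error(predict(m, renamed), "schema mismatch")
})

test_that("regression predictions back-transform above the count floor", {
  tab <- simulate_ko(ko_sim_params(n_guides = 3, sites_per_guide = 100), seed = 6)
  fm <- encode_dataset(tab, encoder_spec("MM", with_distance = TRUE))
  m <- train_gbt(fm, log_transform(tab$read_count), NULL, model_spec("regression"))
  p <- predict(m, fm)
  expect_true(all(inv_log_transform(p) > -1))
})

test_that("pure-noise targets yield held-out AUPR near prevalence", {
  set.seed(202)
  prev <- 0.1
  vals <- vapply(1:5, function(s) {
    x <- matrix(rnorm(600 * 10), 600, 10,
      dimnames = list(NULL, paste0("f", 1:10))
    )
    y <- rbinom(600, 1, prev)
    tr <- 1:400
    te <- 401:600
    if (sum(y[te]) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
    m <- train_gbt(x[tr, ], y[tr], NULL, model_spec("classification", seed = s))
    aupr(y[te], predict(m, x[te, ]))
  }, numeric(1))
  expect_lt(abs(mean(vals, na.rm = TRUE) - prev), 0.08)
})

test_that("class weighting changes predictions on imbalanced data", {
  tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 5, sites_per_guide = 200), seed = 8))
  fm <- encode_dataset(tab, encoder_spec("OH", with_distance = TRUE))
  y <- as.integer(tab$label == "active")
  mw <- train_gbt(fm, y, sample_weights(tab), model_spec("classification", seed = 1))
  mu <- train_gbt(fm, y, NULL, model_spec("classification", seed = 1))
  pw <- predict(mw, fm)
  pu <- predict(mu, fm)
  expect_gt(max(abs(pw - pu)), 0.05)
  # weighting pushes predicted probabilities of actives upward on average
  expect_gt(mean(pw[y == 1]), mean(pu[y == 1]))
})

test_that("random search is reproducible and returns the argmax candidate", {
  tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 4, sites_per_guide = 100), seed = 10))
  fm <- encode_dataset(tab, encoder_spec("MM", with_distance = TRUE))
  y <- as.integer(tab$label == "active")
  plan <- make_folds(tab$guide_id, "leave_one_group_out", seed = 1)
  space <- list(
    learning_rate = c(0.05, 0.3), max_depth = 3:4, n_trees = c(20L, 60L),
    reg_lambda = c(0.1, 2), reg_alpha = c(0.001, 0.1),
    subsample = c(0.8, 1), colsample = c(0.8, 1)
  )
  r1 <- random_search(fm, y, NULL, plan, "classification", space, n_iter = 4, seed = 5)
  r2 <- random_search(fm, y, NULL, plan, "classification", space, n_iter = 4, seed = 5)
  expect_identical(r1$results, r2$results)
  expect_equal(r1$best_score, max(r1$results$score, na.rm = TRUE))
  # n_iter = 1 returns the single candidate
  r3 <- random_search(fm, y, NULL, plan, "classification", space, n_iter = 1, seed = 6)
  expect_equal(nrow(r3$results), 1)
  expect_equal(r3$best_score, r3$results$score[1])
})

test_that("run_experiment predicts every record exactly once with leak-free folds", {
  tab <- label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 6, sites_per_guide = 120), seed = 12))
  res <- run_experiment(tab, encoder_spec("OH", with_distance = TRUE),
    task = "classification", scheme = "leave_one_group_out", seed = 12
  )
  expect_equal(nrow(res$predictions), nrow(tab))
  expect_false(anyNA(res$predictions$score))
  expect_equal(sort(unique(res$predictions$fold)), 1:6)
  # each guide's rows all fall in one fold (its held-out fold)
  per_guide_folds <- tapply(res$predictions$fold, res$predictions$guide_id, function(x) length(unique(x)))
  expect_true(all(per_guide_folds == 1))
  expect_true(all(c("aupr", "f1", "accuracy", "precision", "recall", "auroc")
  %in% names(res$aggregate)))
  expect_match(res$aggregate$aupr$formatted, "^[0-9.]+±[0-9.]+$")
})

test_that("aggregate SD is zero when all folds are identical", {
  expect_equal(format_mean_sd(rep(0.7, 4)), "0.700±0.000")
})
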