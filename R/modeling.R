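# Guide-grouped cross-validation and weighted gradient-boosted-tree models.
# Grouped schemes keep every record of a guide on one side of each split, so
# no guide's sites leak between train and test; this is the evaluation that
# matters for generalization to unseen guides.

#' Cross-validation fold plan
#'
#' Grouped schemes operate on guide identities: the unique groups are
#' permuted with the seed and chunked into contiguous folds, so test sets are
#' mutually exclusive and jointly exhaustive over groups. `kfold` operates on
#' sample indices directly (the base-editing screen convention, one row per
#' guide).
#'
#' @param groups character vector of group (guide) ids, one per record.
#' @param scheme `"leave_one_group_out"`, `"leave_k_groups_out"` or
#'   `"kfold"`.
#' @param k number of folds (`leave_k_groups_out`, `kfold`).
#' @param seed permutation seed.
#' @return a `fold_plan`: list of folds, each with `train` and `test` row
#'   indices, plus `train_groups`/`test_groups` for grouped schemes.
#' @export
make_folds <- function(groups,
                       scheme = c("leave_one_group_out", "leave_k_groups_out", "kfold"),
                       k = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  groups <- as.character(groups)
  n <- length(groups)
  ug <- unique(groups)
  set.seed(seed)
  if (scheme == "kfold") {
    if (is.null(k)) k <- 10L
    if (k > n) stop("k exceeds the number of samples", call. = FALSE)
    perm <- sample.int(n)
    fold_of <- rep(seq_len(k), length.out = n)[order(perm)]
    folds <- lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  } else {
    if (length(ug) < 2) stop("grouped schemes need >= 2 groups", call. = FALSE)
    if (scheme == "leave_one_group_out") k <- length(ug)
    if (is.null(k)) stop("k required for leave_k_groups_out", call. = FALSE)
    if (k > length(ug)) stop("k exceeds the number of groups", call. = FALSE)
    perm <- sample(ug)
    chunk <- rep(seq_len(k), length.out = length(ug))
    chunk <- sort(chunk) # contiguous chunking of the permuted groups
    folds <- lapply(seq_len(k), function(f) {
      test_g <- perm[chunk == f]
      list(
        train = which(!groups %in% test_g),
        test = which(groups %in% test_g),
        train_groups = setdiff(ug, test_g),
        test_groups = test_g
      )
    })
  }
  structure(list(scheme = scheme, k = length(folds), folds = folds),
    class = "fold_plan"
  )
}

#' Assert that a fold plan has no group leakage
#'
#' @param plan a `fold_plan`.
#' @param groups group ids, one per record.
#' @export
assert_no_leakage <- function(plan, groups) {
  for (f in plan$folds) {
    shared <- intersect(unique(groups[f$train]), unique(groups[f$test]))
    if (length(shared) > 0) {
      stop("group leakage: ", paste(shared, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Gradient-boosted-tree model specification
#'
#' @param task `"classification"` (logistic loss, probability output) or
#'   `"regression"` (squared error on the transformed target scale).
#' @param learning_rate shrinkage eta in (0, 1].
#' @param max_depth maximum tree depth.
#' @param n_trees boosting rounds.
#' @param reg_lambda,reg_alpha L2/L1 regularization.
#' @param subsample,colsample row/column subsampling fractions.
#' @param seed integer seed for the ensemble's internal randomness.
#' @return a `model_spec` list.
#' @export
model_spec <- function(task = c("classification", "regression"),
                       learning_rate = 0.1, max_depth = 6L, n_trees = 200L,
                       reg_lambda = 1, reg_alpha = 0,
                       subsample = 1, colsample = 1, seed = 1L) {
  task <- match.arg(task)
  stopifnot(
    learning_rate > 0, learning_rate <= 1, max_depth >= 1, n_trees >= 1,
    subsample > 0, subsample <= 1, colsample > 0, colsample <= 1
  )
  structure(
    list(
      task = task, learning_rate = learning_rate,
      max_depth = as.integer(max_depth), n_trees = as.integer(n_trees),
      reg_lambda = reg_lambda, reg_alpha = reg_alpha,
      subsample = subsample, colsample = colsample, seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

#' Train a gradient-boosted-tree model
#'
#' Single-threaded, seeded, and therefore deterministic: two runs with the
#' same spec produce identical predictions.
#'
#' @param features a `feature_matrix` (or numeric matrix with column names).
#' @param targets numeric vector: 0/1 for classification, transformed counts
#'   or z-scores for regression.
#' @param weights optional per-sample weights.
#' @param spec a [model_spec()].
#' @return a `trained_model`.
#' @export
train_gbt <- function(features, targets, weights = NULL, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  x <- unclass(features)
  if (anyNA(x)) stop("NaN/NA in feature matrix", call. = FALSE)
  stopifnot(nrow(x) == length(targets))
  if (spec$task == "classification") {
    if (!all(targets %in% c(0, 1))) {
      stop("classification targets must be binary 0/1", call. = FALSE)
    }
    if (length(unique(targets)) < 2) {
      stop("single-class classification target", call. = FALSE)
    }
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = targets, nthread = 1)
  if (!is.null(weights)) xgboost::setinfo(dtrain, "weight", weights)
  params <- list(
    objective = if (spec$task == "classification") {
      "binary:logistic"
    } else {
      "reg:squarederror"
    },
    eta = spec$learning_rate,
    max_depth = spec$max_depth,
    lambda = spec$reg_lambda,
    alpha = spec$reg_alpha,
    subsample = spec$subsample,
    colsample_bytree = spec$colsample,
    nthread = 1,
    seed = spec$seed
  )
  booster <- xgboost::xgb.train(
    params = params, data = dtrain,
    nrounds = spec$n_trees, verbose = 0
  )
  structure(
    list(
      booster = booster, spec = spec,
      feature_names = colnames(x),
      encoding_id = attr(features, "encoding_id")
    ),
    class = "trained_model"
  )
}

check_feature_schema <- function(model, x) {
  if (!identical(colnames(x), model$feature_names)) {
    stop(
      "feature schema mismatch: prediction input must carry exactly the ",
      "training feature names in training order",
      call. = FALSE
    )
  }
}

#' Predict from a trained model
#'
#' Classification returns probabilities in `[0, 1]`; regression returns
#' scores on the training target scale. The input must carry exactly the
#' training feature names in training order — mismatches are an error, never
#' silently reordered.
#'
#' @param object a `trained_model`.
#' @param features feature matrix with the training schema.
#' @param output `"response"` (default) or `"margin"` (raw additive score).
#' @param ... unused.
#' @export
predict.trained_model <- function(object, features, output = c("response", "margin"),
                                  ...) {
  output <- match.arg(output)
  x <- unclass(features)
  check_feature_schema(object, x)
  d <- xgboost::xgb.DMatrix(x, nthread = 1)
  stats::predict(object$booster, d, outputmargin = (output == "margin"))
}

#' Default randomized-search space for boosted trees
#'
#' Standard tabular-data ranges: learning rate log-uniform on
#' `[0.01, 0.3]`, depth 3-10, 100-1000 trees, L1/L2 log-uniform on
#' `[1e-3, 10]`, subsampling fractions on `[0.6, 1]`.
#'
#' @export
default_search_space <- function() {
  list(
    learning_rate = c(0.01, 0.3), # log-uniform
    max_depth = 3:10,
    n_trees = c(100L, 1000L),
    reg_lambda = c(1e-3, 10), # log-uniform
    reg_alpha = c(1e-3, 10), # log-uniform
    subsample = c(0.6, 1),
    colsample = c(0.6, 1)
  )
}

sample_spec <- function(space, task, seed) {
  runif_log <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  model_spec(
    task = task,
    learning_rate = runif_log(space$learning_rate),
    max_depth = sample(space$max_depth, 1),
    n_trees = sample(seq(space$n_trees[1], space$n_trees[2]), 1),
    reg_lambda = runif_log(space$reg_lambda),
    reg_alpha = runif_log(space$reg_alpha),
    subsample = stats::runif(1, space$subsample[1], space$subsample[2]),
    colsample = stats::runif(1, space$colsample[1], space$colsample[2]),
    seed = seed
  )
}

cv_score <- function(features, targets, weights, plan, task) {
  function(spec) {
    scores <- vapply(plan$folds, function(f) {
      m <- train_gbt(
        features[f$train, , drop = FALSE], targets[f$train],
        if (is.null(weights)) NULL else weights[f$train], spec
      )
      p <- predict(m, features[f$test, , drop = FALSE])
      if (task == "classification") {
        if (sum(targets[f$test]) == 0) return(NA_real_)
        aupr(targets[f$test], p)
      } else {
        suppressWarnings(stats::cor(targets[f$test], p))
      }
    }, numeric(1))
    mean(scores, na.rm = TRUE)
  }
}

#' Randomized hyperparameter search with cross-validation
#'
#' Samples `n_iter` parameter combinations from `space` and scores each by
#' the mean cross-validated metric over `plan` (AUPR for classification,
#' Pearson correlation for regression). Reproducible given `seed`.
#'
#' @param features,targets,weights training data (as in [train_gbt()]).
#' @param plan a [make_folds()] plan over the same rows.
#' @param task `"classification"` or `"regression"`.
#' @param space parameter ranges, see [default_search_space()].
#' @param n_iter number of sampled candidates.
#' @param seed RNG seed for the candidate stream.
#' @return list with `best_spec`, `best_score`, and `results` (one row per
#'   candidate, in sampling order).
#' @export
random_search <- function(features, targets, weights = NULL, plan,
                          task = c("classification", "regression"),
                          space = default_search_space(), n_iter = 50L,
                          seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_iter >= 1, length(space) > 0)
  set.seed(seed)
  candidates <- lapply(seq_len(n_iter), function(i) sample_spec(space, task, seed))
  scorer <- cv_score(features, targets, weights, plan, task)
  rows <- vector("list", n_iter)
  scores <- numeric(n_iter)
  errors <- character(0)
  for (i in seq_len(n_iter)) {
    sc <- tryCatch(scorer(candidates[[i]]), error = function(e) {
      errors <<- c(errors, sprintf("candidate %d: %s", i, conditionMessage(e)))
      NA_real_
    })
    scores[i] <- sc
    rows[[i]] <- data.frame(
      iter = i, score = sc,
      learning_rate = candidates[[i]]$learning_rate,
      max_depth = candidates[[i]]$max_depth,
      n_trees = candidates[[i]]$n_trees,
      reg_lambda = candidates[[i]]$reg_lambda,
      reg_alpha = candidates[[i]]$reg_alpha,
      subsample = candidates[[i]]$subsample,
      colsample = candidates[[i]]$colsample
    )
  }
  if (all(is.na(scores))) {
    stop(
      "all candidates failed:\n", paste(errors, collapse = "\n"),
      call. = FALSE
    )
  }
  best <- which.max(scores)
  list(
    best_spec = candidates[[best]], best_score = scores[best],
    results = do.call(rbind, rows)
  )
}

#' Run a full encode-weight-train-evaluate experiment
#'
#' Orchestrates one model variant end to end: label the table, build the
#' encoding (optionally with the explicit distance column), derive class
#' weights, split by guide groups (or plain k-fold for base editing), train
#' one model per fold and score its held-out predictions. Every record is
#' predicted exactly once, by the fold that holds it out.
#'
#' @param table a `dataset_table` (KO or BE).
#' @param encoding an [encoder_spec()] or encoding id string; set its
#'   `with_distance` for the "-seq-dist" variant.
#' @param task `"classification"` or `"regression"`.
#' @param scheme,k,seed fold construction, see [make_folds()].
#' @param spec a [model_spec()]; its task is overridden by `task`.
#' @param ko_threshold,be_cutoff labeling parameters.
#' @param weighted apply class weighting (default TRUE for classification
#'   and for the knockout task).
#' @return list with `predictions` (row, fold, score, target, label),
#'   `per_fold` metrics, and `aggregate` (mean, sd and formatted
#'   "mean±sd" per metric).
#' @export
run_experiment <- function(table, encoding,
                           task = c("classification", "regression"),
                           scheme = c("leave_one_group_out", "leave_k_groups_out", "kfold"),
                           k = NULL, seed = 1L, spec = NULL,
                           ko_threshold = 100, be_cutoff = -2.0,
                           weighted = NULL) {
  task <- match.arg(task)
  scheme <- match.arg(scheme)
  if (is.character(encoding)) encoding <- encoder_spec(encoding)
  data_task <- dataset_task(table)
  if (!"label" %in% names(table)) {
    table <- if (data_task == "KO") {
      label_ko_by_count(table, ko_threshold)
    } else {
      label_be_by_zscore(table, be_cutoff)
    }
  }
  y_class <- as_binary_labels(table$label)
  targets <- if (task == "classification") {
    y_class
  } else if (data_task == "KO") {
    log_transform(table$read_count)
  } else {
    table$zscore
  }
  if (is.null(weighted)) weighted <- task == "classification" || data_task == "KO"
  weights <- if (weighted) sample_weights(table) else NULL
  if (is.null(spec)) {
    spec <- model_spec(task = task, seed = seed)
  } else {
    spec$task <- task
  }
  features <- encode_dataset(table, encoding)
  plan <- make_folds(table$guide_id, scheme, k = k, seed = seed)
  if (plan$scheme != "kfold") assert_no_leakage(plan, table$guide_id)

  pred <- rep(NA_real_, nrow(table))
  fold_of <- rep(NA_integer_, nrow(table))
  per_fold <- vector("list", plan$k)
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    fit <- tryCatch(
      train_gbt(
        features[fold$train, , drop = FALSE], targets[fold$train],
        if (is.null(weights)) NULL else weights[fold$train], spec
      ),
      error = function(e) {
        stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    p <- predict(fit, features[fold$test, , drop = FALSE])
    pred[fold$test] <- p
    fold_of[fold$test] <- f
    yl <- y_class[fold$test]
    per_fold[[f]] <- if (task == "classification") {
      if (sum(yl) == 0 || sum(yl) == length(yl)) {
        NULL # fold metrics undefined without both classes
      } else {
        c(fold = f, unlist(classification_report(yl, p)[
          c("aupr", "f1", "accuracy", "precision", "recall", "auroc")
        ]))
      }
    } else {
      truth <- if (data_task == "KO") table$read_count[fold$test] else table$zscore[fold$test]
      r <- regression_report(truth, p, yl,
        back_transform = if (data_task == "KO") "exp" else "none"
      )
      c(fold = f, pearson = r$pearson, spearman = r$spearman, rmse = r$rmse)
    }
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold[!vapply(per_fold, is.null, logical(1))]))
  metric_cols <- setdiff(names(per_fold), "fold")
  aggregate <- lapply(metric_cols, function(mc) {
    v <- per_fold[[mc]]
    list(
      mean = mean(v, na.rm = TRUE),
      sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0,
      formatted = format_mean_sd(v)
    )
  })
  names(aggregate) <- metric_cols
  stopifnot(!anyNA(fold_of)) # every record predicted exactly once
  list(
    predictions = data.frame(
      row = seq_len(nrow(table)), guide_id = table$guide_id,
      fold = fold_of, score = pred, target = targets, label = table$label,
      stringsAsFactors = FALSE
    ),
    per_fold = per_fold,
    aggregate = aggregate,
    encoding_id = encoding$encoding_id,
    with_distance = isTRUE(encoding$with_distance),
    task = task
  )
}
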