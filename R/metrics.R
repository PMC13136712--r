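# Imbalance-aware evaluation. AUPR (average-precision estimator, no linear
# interpolation) is the primary classification metric: with ~97% inactive
# sites, AUROC is inflated by the overwhelming true negatives while
# precision-recall focuses on the rare active class. Regression is scored by
# correlation on active sites only, and RMSE on the raw count scale.

as_binary_labels <- function(labels) {
  if (is.character(labels)) {
    stopifnot(all(labels %in% c("active", "inactive")))
    return(as.integer(labels == "active"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  stopifnot(all(labels %in% c(0, 1)))
  as.integer(labels)
}

#' Precision-recall curve and AUPR
#'
#' Scores are swept from high to low; tied scores are grouped into a single
#' threshold step. AUPR is the average-precision sum
#' `sum((R_i - R_(i-1)) * P_i)` over threshold steps — no interpolation.
#'
#' @param labels binary labels (0/1, logical, or "active"/"inactive"); at
#'   least one positive required.
#' @param scores finite numeric scores, higher = more positive.
#' @return a `pr_curve` list with `thresholds`, `precision`, `recall`, `aupr`.
#' @export
pr_curve <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  P <- sum(y)
  if (P == 0) stop("AUPR undefined: no positive labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- y[o]
  s <- scores[o]
  # group tied scores: cumulative TP/FP at the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  n_pred <- seq_along(y)[last]
  prec <- tp / n_pred
  rec <- tp / P
  aupr <- sum((rec - c(0, rec[-length(rec)])) * prec)
  structure(
    list(thresholds = s[last], precision = prec, recall = rec, aupr = aupr),
    class = "pr_curve"
  )
}

#' Area under the precision-recall curve
#' @inheritParams pr_curve
#' @export
aupr <- function(labels, scores) pr_curve(labels, scores)$aupr

#' Rank-based AUROC (Mann-Whitney formulation)
#'
#' @inheritParams pr_curve
#' @export
auroc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  n1 <- sum(y)
  n0 <- sum(1 - y)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: single-class labels", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Thresholded classification metrics
#'
#' Confusion-matrix metrics at a fixed probability threshold (default 0.5;
#' scores at or above the threshold are called positive), plus rank-based
#' AUROC and AUPR. When no positive predictions are made, precision and F1
#' are reported as 0 with `no_positive_predictions = TRUE`.
#'
#' @inheritParams pr_curve
#' @param threshold decision threshold.
#' @return named list of metrics.
#' @export
classification_report <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  no_pos_pred <- (tp + fp) == 0
  precision <- if (no_pos_pred) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (no_pos_pred || is.na(recall) || (precision + recall) == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(
    aupr = aupr(y, scores),
    f1 = f1,
    accuracy = (tp + tn) / length(y),
    precision = precision,
    recall = recall,
    auroc = auroc(y, scores),
    no_positive_predictions = no_pos_pred
  )
}

#' Regression metrics for activity-count and z-score prediction
#'
#' Pearson and Spearman correlations are computed on active-labeled rows only
#' (fewer than 3 active rows yields `NA` correlations). For the knockout task
#' predictions live on the log scale, so they are back-transformed with
#' `exp(y') - 1` and RMSE is reported on the raw count scale; for base
#' editing both vectors are z-scores and are compared directly.
#'
#' @param truth observed targets: raw read counts (KO) or z-scores (BE).
#' @param predicted model predictions: log-scale (KO) or z-scores (BE).
#' @param labels optional binary activity labels; when omitted all rows count
#'   as active.
#' @param back_transform `"exp"` (KO count scale) or `"none"` (BE).
#' @return named list with `pearson`, `spearman`, `rmse`, `n_active`.
#' @export
regression_report <- function(truth, predicted, labels = NULL,
                              back_transform = c("exp", "none")) {
  back_transform <- match.arg(back_transform)
  stopifnot(length(truth) == length(predicted))
  pred_raw <- if (back_transform == "exp") inv_log_transform(predicted) else predicted
  act <- if (is.null(labels)) rep(TRUE, length(truth)) else as_binary_labels(labels) == 1
  if (sum(act) >= 3) {
    pearson <- stats::cor(truth[act], pred_raw[act], method = "pearson")
    spearman <- stats::cor(truth[act], pred_raw[act], method = "spearman")
  } else {
    pearson <- NA_real_
    spearman <- NA_real_
  }
  list(
    pearson = pearson,
    spearman = spearman,
    rmse = sqrt(mean((truth - pred_raw)^2)),
    n_active = sum(act)
  )
}

#' Tail-error analysis for z-score regression
#'
#' Flags the `worst_fraction` largest absolute errors and reports the mean
#' signed error (predicted minus true) within true-z strata
#' `(-Inf,-4), [-4,-2), [-2,2], (2,Inf)`, exposing regression-to-the-mean: a
#' mean-reverting predictor under-predicts the magnitude of the strongly
#' negative tail, giving a positive mean signed error below -2.
#'
#' @param true_z,predicted_z observed and predicted z-scores.
#' @param worst_fraction fraction of samples to flag (default 0.10).
#' @return list with `flagged` (indices of the worst errors, size
#'   `ceiling(worst_fraction * n)`) and `strata` (data.frame of stratum,
#'   n, mean signed error, mean absolute error).
#' @export
tail_error_analysis <- function(true_z, predicted_z, worst_fraction = 0.10) {
  stopifnot(length(true_z) == length(predicted_z))
  err <- predicted_z - true_z
  n_flag <- ceiling(worst_fraction * length(err))
  flagged <- order(abs(err), decreasing = TRUE)[seq_len(n_flag)]
  stratum <- cut(true_z,
    breaks = c(-Inf, -4, -2, 2, Inf),
    labels = c("z < -4", "-4 <= z < -2", "-2 <= z <= 2", "z > 2"),
    right = FALSE
  )
  # the [-2, 2] band is closed on both ends per the reporting convention
  stratum[true_z == 2] <- "-2 <= z <= 2"
  strata <- do.call(rbind, lapply(levels(stratum), function(lv) {
    idx <- which(stratum == lv)
    data.frame(
      stratum = lv, n = length(idx),
      mean_signed_error = if (length(idx)) mean(err[idx]) else NA_real_,
      mean_abs_error = if (length(idx)) mean(abs(err[idx])) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  list(flagged = flagged, strata = strata)
}

#' Format a mean +/- SD metric string
#'
#' @param x numeric vector of per-fold values.
#' @param digits digits after the decimal point (default 3).
#' @return string like `"0.612±0.165"`.
#' @export
format_mean_sd <- function(x, digits = 3) {
  x <- x[!is.na(x)]
  s <- if (length(x) > 1) stats::sd(x) else 0
  sprintf(paste0("%.", digits, "f±%.", digits, "f"), mean(x), s)
}
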