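# Model explainability: exact per-sample tree-path (TreeSHAP) attributions
# with summary roll-ups, and first-order accumulated local effects (ALE) for
# individual features. Attributions live on the model's raw additive margin
# (log-odds for classification) — the scale on which tree attributions are
# exact and sum to the prediction.

#' TreeSHAP attributions for a trained model
#'
#' Computes exact tree-path attributions for every sample, the global ranking
#' by mean absolute attribution, and a per-position roll-up (sum of mean
#' absolute attribution over features sharing a `pos{p}` component in their
#' name). The local-accuracy identity — attributions plus base value equal
#' the raw-margin prediction — is asserted on every call.
#'
#' @param model a `trained_model`.
#' @param features feature matrix with the training schema.
#' @param tol relative tolerance for the local-accuracy assertion. The
#'   default 1e-5 leaves headroom for single-precision accumulation in the
#'   tree backend: leaf weights are stored and summed in 32-bit floats, so
#'   deep ensembles reconstruct the margin to about 1e-6 to 1e-5 relative;
#'   small ensembles satisfy 1e-6.
#' @return an `attribution_report`: `phi` (n x p), `base_value`,
#'   `ranking` (feature, mean_abs_phi, descending), `positional`
#'   (position, mean_abs_phi), `feature_values`.
#' @export
shap_attributions <- function(model, features, tol = 1e-5) {
  x <- unclass(features)
  check_feature_schema(model, x)
  d <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- stats::predict(model$booster, d, predcontrib = TRUE)
  p <- ncol(x)
  phi <- contrib[, seq_len(p), drop = FALSE]
  colnames(phi) <- colnames(x)
  base_value <- contrib[1, p + 1L]
  margin <- stats::predict(model$booster, d, outputmargin = TRUE)
  recon <- rowSums(phi) + contrib[, p + 1L]
  rel <- abs(recon - margin) / pmax(abs(margin), 1)
  if (any(rel > tol)) {
    stop("SHAP local-accuracy identity violated (max relative error ",
      signif(max(rel), 3), ")",
      call. = FALSE
    )
  }
  mean_abs <- colMeans(abs(phi))
  ranking <- data.frame(
    feature = names(mean_abs)[order(mean_abs, decreasing = TRUE)],
    mean_abs_phi = sort(mean_abs, decreasing = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  has_pos <- grepl("^(guide_|target_)?pos[0-9]+", colnames(phi))
  positional <- NULL
  if (any(has_pos)) {
    pos_id <- as.integer(sub("^(guide_|target_)?pos([0-9]+).*$", "\\2",
      colnames(phi)[has_pos]
    ))
    agg <- tapply(mean_abs[has_pos], pos_id, sum)
    positional <- data.frame(
      position = as.integer(names(agg)),
      mean_abs_phi = as.numeric(agg)
    )
    positional <- positional[order(positional$position), ]
    row.names(positional) <- NULL
  }
  structure(
    list(
      phi = phi, base_value = base_value, ranking = ranking,
      positional = positional, feature_values = x
    ),
    class = "attribution_report"
  )
}

#' @export
print.attribution_report <- function(x, n = 10, ...) {
  cat("<attribution_report> n=", nrow(x$phi), " p=", ncol(x$phi),
    " base=", signif(x$base_value, 4), "\n", sep = ""
  )
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' First-order accumulated local effects (ALE) curve
#'
#' Estimates the marginal effect of one feature on the model prediction
#' while respecting feature correlations: within each bin, the mean
#' prediction difference between samples moved to the bin's upper and lower
#' edge is accumulated, and the curve is centered so its sample-weighted
#' mean is zero. Integer-valued features (such as the mismatch-count
#' "distance") get one bin per observed integer; continuous features get
#' quantile bins.
#'
#' @param model a `trained_model`, or a prediction function
#'   `function(matrix) -> numeric`.
#' @param features feature matrix.
#' @param feature_name the feature to analyze (must be non-constant).
#' @param n_bins number of quantile bins for continuous features
#'   (default 20).
#' @param output prediction scale for `trained_model` inputs (default
#'   `"margin"`, the additive raw score).
#' @return an `ale_curve` data.frame with columns `x` (bin edge), `effect`
#'   (centered ALE at that edge) and `n` (samples in the bin ending there;
#'   0 for the first edge).
#' @export
ale_curve <- function(model, features, feature_name, n_bins = 20L,
                      output = "margin") {
  x <- unclass(features)
  if (!feature_name %in% colnames(x)) {
    stop("unknown feature: ", feature_name, call. = FALSE)
  }
  f <- if (is.function(model)) {
    model
  } else {
    function(m) predict(model, new_feature_matrix(m,
      attr(features, "encoding_id") %||% "NA"
    ), output = output)
  }
  xj <- x[, feature_name]
  vals <- sort(unique(xj))
  if (length(vals) < 2) stop("constant feature: ", feature_name, call. = FALSE)
  if (all(xj == round(xj)) && length(vals) <= n_bins + 1L) {
    edges <- vals # unit bins for integer features
  } else {
    edges <- unique(stats::quantile(xj, probs = seq(0, 1, length.out = n_bins + 1L),
      names = FALSE, type = 7
    ))
  }
  K <- length(edges) - 1L
  # bin k covers (edges[k], edges[k+1]]; values at the minimum join bin 1
  bin <- findInterval(xj, edges, left.open = TRUE, all.inside = TRUE)
  d <- numeric(K)
  nk <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(bin == k)
    nk[k] <- length(idx)
    if (length(idx) == 0) {
      d[k] <- 0
      next
    }
    hi <- x[idx, , drop = FALSE]
    lo <- hi
    hi[, feature_name] <- edges[k + 1L]
    lo[, feature_name] <- edges[k]
    d[k] <- mean(f(hi) - f(lo))
  }
  acc <- c(0, cumsum(d)) # ALE at edges[1..K+1]
  center <- sum(nk * acc[-1]) / sum(nk)
  structure(
    data.frame(x = edges, effect = acc - center, n = c(0L, nk)),
    class = c("ale_curve", "data.frame"),
    feature = feature_name
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export SHAP summary-plot data
#'
#' Long-format beeswarm data for the top-k features by global importance:
#' one row per (sample, feature) with the feature value and its attribution.
#' Deterministic ordering: features by rank, samples by row.
#'
#' @param report an `attribution_report`.
#' @param top_k number of top-ranked features to keep (default 20; clipped
#'   with a warning when it exceeds the feature count).
#' @return data.frame with columns `sample`, `feature`, `feature_value`,
#'   `phi`.
#' @export
summary_export <- function(report, top_k = 20L) {
  stopifnot(inherits(report, "attribution_report"))
  p <- ncol(report$phi)
  if (top_k > p) {
    warning("top_k clipped from ", top_k, " to ", p)
    top_k <- p
  }
  feats <- report$ranking$feature[seq_len(top_k)]
  n <- nrow(report$phi)
  do.call(rbind, lapply(feats, function(fn) {
    data.frame(
      sample = seq_len(n), feature = fn,
      feature_value = report$feature_values[, fn],
      phi = report$phi[, fn],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}
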