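# Labeling, target transformation and class weighting. Off-target datasets
# are severely imbalanced (~97% inactive), so active/inactive classes are
# re-weighted to contribute equal total mass during training, and raw read
# counts are log-transformed to tame their heavy tail.

#' Label knockout records by read-count threshold
#'
#' A site is active iff its read count strictly exceeds `threshold`
#' (default 100); a count of exactly 100 is inactive.
#'
#' @param table a KO `dataset_table`.
#' @param threshold count threshold (strict).
#' @return the table with a `label` column.
#' @export
label_ko_by_count <- function(table, threshold = 100) {
  stopifnot(inherits(table, "dataset_table"), dataset_task(table) == "KO")
  if (any(table$read_count < 0)) stop("negative read counts", call. = FALSE)
  table$label <- ifelse(table$read_count > threshold, "active", "inactive")
  table
}

#' Label base-editing records by z-score cutoff
#'
#' A guide is active (strongly effective) iff its viability z-score is
#' strictly below `cutoff` (default -2.0); z = -2.0 exactly is inactive.
#'
#' @param table a BE `dataset_table`.
#' @param cutoff z-score cutoff (strict).
#' @return the table with a `label` column.
#' @export
label_be_by_zscore <- function(table, cutoff = -2.0) {
  stopifnot(inherits(table, "dataset_table"), dataset_task(table) == "BE")
  table$label <- ifelse(table$zscore < cutoff, "active", "inactive")
  table
}

#' Log transform of read counts
#'
#' `y' = log(y + 1)` (natural log by default; base configurable). Applied to
#' knockout read counts only — z-scores are already on a normalized scale.
#'
#' @param y non-negative counts.
#' @param base logarithm base (default `exp(1)`).
#' @export
log_transform <- function(y, base = exp(1)) {
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  log(y + 1, base = base)
}

#' Inverse of [log_transform()]
#'
#' @param yprime transformed values.
#' @param base logarithm base.
#' @export
inv_log_transform <- function(yprime, base = exp(1)) {
  base^yprime - 1
}

#' Class-weight scheme for an imbalanced labeled table
#'
#' The active class receives weight
#' `w_active = n_inactive / (n_active + n_inactive)` and the inactive class
#' `w_inactive = n_active / (n_active + n_inactive)`, so each class carries
#' the same total weight (`n_active * w_active == n_inactive * w_inactive`).
#'
#' @param table a labeled `dataset_table`.
#' @return list with `n_active`, `n_inactive`, `w_active`, `w_inactive`.
#' @export
compute_class_weights <- function(table) {
  if (!"label" %in% names(table)) stop("table is not labeled", call. = FALSE)
  n_active <- sum(table$label == "active")
  n_inactive <- sum(table$label == "inactive")
  if (n_active == 0) stop("no active records in table", call. = FALSE)
  if (n_inactive == 0) stop("no inactive records in table", call. = FALSE)
  n <- n_active + n_inactive
  structure(
    list(
      n_active = n_active, n_inactive = n_inactive,
      w_active = n_inactive / n, w_inactive = n_active / n
    ),
    class = "weight_scheme"
  )
}

#' Per-sample weight vector from a weight scheme
#'
#' @param table a labeled `dataset_table`.
#' @param scheme a `weight_scheme`; computed from `table` when omitted.
#' @return numeric vector, one weight per row.
#' @export
sample_weights <- function(table, scheme = NULL) {
  if (is.null(scheme)) scheme <- compute_class_weights(table)
  ifelse(table$label == "active", scheme$w_active, scheme$w_inactive)
}
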