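# Tabular dataset containers and readers/writers.
#
# A dataset table is a plain data.frame with class "dataset_table" and an
# attribute `task` ("KO" or "BE"):
#   KO columns: guide_id, guide_seq, target_seq, read_count [, label]
#   BE columns: guide_id, guide_seq, zscore [, label]
# `label`, when present, is "active"/"inactive".

KO_COLS <- c("guide_id", "guide_seq", "target_seq", "read_count")
BE_COLS <- c("guide_id", "guide_seq", "zscore")

#' Construct a validated dataset table
#'
#' @param df data.frame with the task's required columns.
#' @param task `"KO"` (paired guide/off-target rows with read counts) or
#'   `"BE"` (single-guide rows with z-scores).
#' @param provenance optional free-text metadata (source, seed, parameters).
#' @param length_ungapped canonical gap-free sequence length (default 23).
#' @return a `dataset_table`.
#' @export
dataset_table <- function(df, task = c("KO", "BE"), provenance = NULL,
                          length_ungapped = 23L) {
  task <- match.arg(task)
  required <- if (task == "KO") KO_COLS else BE_COLS
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$guide_id <- as.character(df$guide_id)
  df$guide_seq <- toupper(as.character(df$guide_seq))
  if (task == "KO") {
    df$target_seq <- toupper(as.character(df$target_seq))
    df$read_count <- as.numeric(df$read_count)
  } else {
    df$zscore <- as.numeric(df$zscore)
  }

  bad <- integer(0)
  msgs <- character(0)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(
      {
        if (task == "KO") {
          validate_pair(df$guide_seq[i], df$target_seq[i], length_ungapped)
          if (is.na(df$read_count[i]) || df$read_count[i] < 0) {
            stop("read_count must be a non-negative number", call. = FALSE)
          }
        } else {
          validate_seq(df$guide_seq[i], allow_gap = FALSE, what = "guide_seq")
          if (nchar(df$guide_seq[i]) != length_ungapped) {
            stop("guide_seq must have length ", length_ungapped, call. = FALSE)
          }
          if (!is.finite(df$zscore[i])) stop("zscore must be finite", call. = FALSE)
        }
        NULL
      },
      error = function(e) conditionMessage(e)
    )
    if (!is.null(res)) {
      bad <- c(bad, i)
      msgs <- c(msgs, res)
    }
  }
  if (length(bad) > 0) {
    stop(
      "validation error in ", length(bad), " row(s):\n",
      paste0("  row ", bad, ": ", msgs, collapse = "\n"),
      call. = FALSE
    )
  }
  if ("label" %in% names(df)) {
    df$label <- as.character(df$label)
    if (!all(df$label %in% c("active", "inactive", NA_character_))) {
      stop("label values must be 'active' or 'inactive'", call. = FALSE)
    }
  }
  structure(df,
    class = c("dataset_table", "data.frame"),
    task = task, provenance = provenance
  )
}

#' Task of a dataset table
#' @param table a `dataset_table`.
#' @export
dataset_task <- function(table) attr(table, "task")

#' @export
as.data.frame.dataset_table <- function(x, ...) {
  attr(x, "task") <- NULL
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

#' Read a tabular dataset (TSV or CSV)
#'
#' The delimiter is sniffed from the header line. Required columns:
#' KO `guide_id, guide_seq, target_seq, read_count`;
#' BE `guide_id, guide_seq, zscore`. Rows violating sequence invariants are
#' rejected with their row numbers reported.
#'
#' @inheritParams dataset_table
#' @param path file path.
#' @return a validated `dataset_table`.
#' @export
read_dataset <- function(path, task = c("KO", "BE"), length_ungapped = 23L) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    stop("empty input file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "",
    stringsAsFactors = FALSE, comment.char = "",
    colClasses = "character"
  )
  dataset_table(df, task, provenance = paste0("file:", path),
    length_ungapped = length_ungapped
  )
}

#' Write a dataset table as TSV
#'
#' The canonical on-disk dialect is tab-separated with a header;
#' `read_dataset(write_dataset(t))` reproduces `t` field for field.
#'
#' @param table a `dataset_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path) {
  stopifnot(inherits(table, "dataset_table"))
  df <- as.data.frame(table)
  ok <- tryCatch(
    {
      utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
      )
      TRUE
    },
    error = function(e) stop("I/O error writing ", path, ": ",
        conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a FASTA guide list
#'
#' @param path FASTA file.
#' @return data.frame with columns `guide_id`, `guide_seq` (uppercased,
#'   validated DNA), in file order.
#' @export
read_guides_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    validate_seq(seqs[i], allow_gap = FALSE, what = paste0("record '", ids[i], "'"))
  }
  data.frame(guide_id = ids, guide_seq = unname(seqs), stringsAsFactors = FALSE)
}
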