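# Engineered biophysical descriptors of the guide sequence: compositional
# (GC%), thermodynamic (Wallace-rule Tm, appropriate for short oligos), and
# RNA secondary-structure stability (minimum free energy from RNAfold when
# the executable is available).

#' GC content of a sequence
#'
#' @param seqs gap-free sequence(s).
#' @return percentage in `[0, 100]`.
#' @export
gc_content <- function(seqs) {
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  if (any(has_gap(seqs))) stop("gc_content requires gap-free sequences", call. = FALSE)
  vapply(seqs, function(s) {
    ch <- seq_chars(toupper(s))
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Melting temperature (Wallace rule)
#'
#' Tm = 2(#A + #T) + 4(#G + #C) degrees Celsius — the standard short-oligo
#' approximation.
#'
#' @param seqs gap-free sequence(s).
#' @return degrees Celsius.
#' @export
melting_temperature <- function(seqs) {
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  if (any(has_gap(seqs))) stop("melting_temperature requires gap-free sequences", call. = FALSE)
  vapply(seqs, function(s) {
    ch <- seq_chars(toupper(s))
    2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' RNA secondary-structure minimum free energy via RNAfold
#'
#' Runs the RNAfold executable when present on the PATH and parses the MFE
#' (kcal/mol) from its output. When the tool is absent the function degrades
#' gracefully, returning `NA` for every sequence with a message, so pipelines
#' can omit the column rather than fail. A present-but-unparseable output is
#' an error (distinct from the unavailable case).
#'
#' @param seqs gap-free sequence(s) (T is treated as U by RNAfold).
#' @return numeric vector of MFE values (kcal/mol), or all-`NA` when RNAfold
#'   is unavailable.
#' @export
folding_energy <- function(seqs) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    message("RNAfold not found on PATH; folding energy unavailable")
    return(rep(NA_real_, length(seqs)))
  }
  if (any(has_gap(seqs))) stop("folding_energy requires gap-free sequences", call. = FALSE)
  out <- suppressWarnings(system2(exe, c("--noPS"),
    input = toupper(seqs), stdout = TRUE, stderr = FALSE
  ))
  # RNAfold emits two lines per sequence; the second ends "( -12.70)" / "(  0.00)"
  mfe_lines <- out[seq(2, by = 2, length.out = length(seqs))]
  m <- regmatches(mfe_lines, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", mfe_lines))
  if (length(m) != length(seqs) || any(!nzchar(m))) {
    stop("failed to parse RNAfold output", call. = FALSE)
  }
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Biophysical feature block for a dataset
#'
#' @param table a `dataset_table`.
#' @param which subset of `c("gc", "tm", "dg")`.
#' @return numeric matrix with the requested columns (the `dg` column is
#'   omitted, with a message, when RNAfold is unavailable).
#' @export
biophys_features <- function(table, which = c("gc", "tm")) {
  which <- match.arg(which, c("gc", "tm", "dg"), several.ok = TRUE)
  cols <- list()
  if ("gc" %in% which) cols$gc_content <- gc_content(table$guide_seq)
  if ("tm" %in% which) cols$melting_temp <- melting_temperature(table$guide_seq)
  if ("dg" %in% which) {
    dg <- folding_energy(table$guide_seq)
    if (!all(is.na(dg))) cols$folding_energy <- dg
  }
  do.call(cbind, cols)
}
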