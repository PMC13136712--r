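#' @keywords internal
"_PACKAGE"

# Alphabets. Position 1 is PAM-distal; with the default L = 23 the PAM
# occupies positions 21-23 (20-nt protospacer + 3-nt PAM).
DNA_BASES <- c("A", "C", "G", "T")
GAP <- "-"
AMBIG <- "N"
SEQ_ALPHABET <- c(DNA_BASES, GAP, AMBIG)

#' Split a sequence string into single-character symbols
#'
#' @param seq character scalar.
#' @return character vector of symbols.
#' @keywords internal
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Validate a nucleotide sequence
#'
#' Sequences are uppercase strings over `{A,C,G,T}` plus the gap symbol `-`
#' and the ambiguity code `N`. Validation is strict: any other symbol is an
#' error.
#'
#' @param seq character scalar.
#' @param allow_gap logical; permit `-`.
#' @param allow_n logical; permit `N`.
#' @param what label used in error messages.
#' @return the uppercased sequence, invisibly usable.
#' @export
validate_seq <- function(seq, allow_gap = TRUE, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single non-NA character string", call. = FALSE)
  }
  seq <- toupper(seq)
  ok <- DNA_BASES
  if (allow_gap) ok <- c(ok, GAP)
  if (allow_n) ok <- c(ok, AMBIG)
  ch <- seq_chars(seq)
  bad <- setdiff(unique(ch), ok)
  if (length(bad) > 0) {
    stop(
      what, " contains invalid symbol(s): ",
      paste(shQuote(bad), collapse = ", "),
      call. = FALSE
    )
  }
  seq
}

#' Check whether sequences contain a gap or an N
#' @keywords internal
has_gap <- function(seq) grepl(GAP, seq, fixed = TRUE)

#' @keywords internal
has_n <- function(seq) grepl(AMBIG, seq, fixed = TRUE)

#' Validate a guide/off-target pair alignment
#'
#' Enforces the pair invariants: equal aligned length, ungapped pairs have the
#' canonical length, and no column is gap-aligned-to-gap.
#'
#' @param guide_seq,target_seq aligned sequences (strings).
#' @param length_ungapped expected length when both are gap-free (default 23).
#' @return invisible TRUE; errors otherwise.
#' @export
validate_pair <- function(guide_seq, target_seq, length_ungapped = 23L) {
  g <- validate_seq(guide_seq, what = "guide_seq")
  t <- validate_seq(target_seq, what = "target_seq")
  if (nchar(g) != nchar(t)) {
    stop("guide_seq and target_seq must have equal aligned length (",
      nchar(g), " vs ", nchar(t), ")",
      call. = FALSE
    )
  }
  if (!has_gap(g) && !has_gap(t) && !is.null(length_ungapped) &&
    nchar(g) != length_ungapped) {
    stop("gap-free pair must have length ", length_ungapped,
      ", got ", nchar(g),
      call. = FALSE
    )
  }
  gc <- seq_chars(g)
  tc <- seq_chars(t)
  if (any(gc == GAP & tc == GAP)) {
    stop("gap aligned to gap at position(s) ",
      paste(which(gc == GAP & tc == GAP), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Generate random gap-free DNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length (default 23).
#' @return character vector.
#' @export
random_dna <- function(n, length = 23L) {
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""),
    character(1)
  )
}
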