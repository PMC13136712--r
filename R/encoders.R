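# Encoding strategies for paired gRNA/off-target alignments and single guide
# sequences. All encoders derive their dimensionality from the aligned length
# L, with the canonical counts recovered at L = 23:
#   NPM 16L = 368, BULGES 25L = 575, LEP L = 23, MM L = 23, 8XL 8L = 184,
#   OH 4L = 92, OH5C 5L = 115, KMER 4^k = 64 (63 with the compat vocabulary).
#
# Feature-name conventions: positional features are "pos{p}_*" with p = 1 at
# the PAM-distal end; paired-substitution cells are "pos{p}_{guide}{target}".

ENCODING_IDS <- c("NPM", "BULGES", "LEP", "MM", "8XL", "OH", "OH5C", "KMER")

#' Encoder specification
#'
#' @param encoding_id one of `"NPM"`, `"BULGES"`, `"LEP"`, `"MM"`, `"8XL"`,
#'   `"OH"`, `"OH5C"`, `"KMER"`.
#' @param k k-mer order (KMER only; default 3).
#' @param with_distance append the explicit Hamming-distance column.
#' @param kmer_paper_compat drop the lexicographically last k-mer (`TTT` at
#'   k = 3) from the vocabulary, reducing 4^k counts to 4^k - 1. This is the
#'   standard fix for compositional collinearity (k-mer counts per sequence
#'   sum to L - k + 1).
#' @return an `encoder_spec` list.
#' @export
encoder_spec <- function(encoding_id, k = 3L, with_distance = FALSE,
                         kmer_paper_compat = FALSE) {
  encoding_id <- toupper(encoding_id)
  encoding_id <- match.arg(encoding_id, ENCODING_IDS)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(
    list(
      encoding_id = encoding_id, k = as.integer(k),
      with_distance = isTRUE(with_distance),
      kmer_paper_compat = isTRUE(kmer_paper_compat)
    ),
    class = "encoder_spec"
  )
}

# ---- internal helpers -------------------------------------------------------

# character matrix (n x L) from equal-length sequences
char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("all sequences must share one aligned length; got lengths ",
      paste(sort(unique(nchar(seqs))), collapse = ", "),
      call. = FALSE
    )
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), ncol = L, byrow = TRUE
  )
}

reject_symbols <- function(cm, allowed, context) {
  bad <- !(cm %in% allowed)
  if (any(bad)) {
    rows <- sort(unique(row(cm)[bad]))
    stop(context, ": unsupported symbol(s) ",
      paste(shQuote(sort(unique(cm[bad]))), collapse = ", "),
      " in row(s) ", paste(utils::head(rows, 10), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

new_feature_matrix <- function(values, encoding_id, has_distance = FALSE) {
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique", call. = FALSE)
  }
  structure(values,
    class = c("feature_matrix", class(values)),
    encoding_id = encoding_id, has_distance = has_distance
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(
    "<feature_matrix> encoding=", attr(x, "encoding_id"),
    " n=", nrow(x), " p=", ncol(x),
    if (isTRUE(attr(x, "has_distance"))) " (+distance)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

# ---- paired, alignment-based encoders --------------------------------------

# NPM over an arbitrary symbol set `alph` (ACGT for NPM, ACGT- for BULGES)
pair_grid_encode <- function(guide, target, alph, context) {
  gm <- char_matrix(guide)
  tm <- char_matrix(target)
  if (ncol(gm) != ncol(tm)) {
    stop(context, ": guide and target aligned lengths differ", call. = FALSE)
  }
  reject_symbols(gm, alph, context)
  reject_symbols(tm, alph, context)
  L <- ncol(gm)
  A <- length(alph)
  gi <- match(gm, alph)
  ti <- match(tm, alph)
  if (GAP %in% alph && any(gm == GAP & tm == GAP)) {
    stop(context, ": gap aligned to gap", call. = FALSE)
  }
  out <- matrix(0, nrow = nrow(gm), ncol = A * A * L)
  # column of cell (r, d) at position p: (p-1)*A^2 + (r-1)*A + d
  pos <- rep(seq_len(L), each = nrow(gm))
  cols <- (pos - 1L) * A * A + (gi - 1L) * A + ti
  out[cbind(rep(seq_len(nrow(gm)), L), cols)] <- 1
  # names run guide-base-major, matching the column index formula
  nm <- unlist(lapply(seq_len(L), function(p) {
    sprintf(
      "pos%d_%s%s", p,
      rep(alph, each = A), rep(alph, times = A)
    )
  }))
  colnames(out) <- nm
  out
}

#' Nucleotides-to-Position Mapping (NPM) encoding
#'
#' One indicator per (position, guide base, target base) cell: a 4x4 grid per
#' aligned position recording exactly which substitution (or match) occurred.
#' 16L features; 368 at L = 23.
#'
#' @param guide_seq,target_seq gap-free aligned sequences (vectors allowed).
#' @return a `feature_matrix` (one row per pair).
#' @export
encode_npm <- function(guide_seq, target_seq) {
  if (any(has_gap(guide_seq)) || any(has_gap(target_seq))) {
    stop("NPM does not support gapped alignments; use the BULGES encoding",
      call. = FALSE
    )
  }
  out <- pair_grid_encode(guide_seq, target_seq, DNA_BASES, "NPM")
  new_feature_matrix(out, "NPM")
}

#' Bulge-aware pairing grid encoding
#'
#' Extends the NPM grid to the 5-symbol alphabet `{A,C,G,T,-}` on both axes so
#' gapped alignments (RNA/DNA bulges) are representable: a gap in the target
#' sets cell `(r, -)`, a gap in the guide sets `(-, d)`; the `(-,-)` cell is
#' never set. 25L features; 575 at L = 23. On ungapped input the nonzero
#' cells coincide with NPM's, embedded in the extended grid.
#'
#' @inheritParams encode_npm
#' @export
encode_bulges <- function(guide_seq, target_seq) {
  out <- pair_grid_encode(
    guide_seq, target_seq, c(DNA_BASES, GAP), "BULGES"
  )
  new_feature_matrix(out, "BULGES")
}

#' Label Encoding Pairwise (LEP)
#'
#' Each aligned position is a single integer in 0..15, the lexicographic index
#' of the (guide, target) base pair: AA = 0, AC = 1, ..., TT = 15. L features.
#'
#' @inheritParams encode_npm
#' @export
encode_lep <- function(guide_seq, target_seq) {
  if (any(has_gap(guide_seq)) || any(has_gap(target_seq))) {
    stop("LEP does not support gapped alignments; use the BULGES encoding",
      call. = FALSE
    )
  }
  gm <- char_matrix(guide_seq)
  tm <- char_matrix(target_seq)
  reject_symbols(gm, DNA_BASES, "LEP")
  reject_symbols(tm, DNA_BASES, "LEP")
  vals <- (match(gm, DNA_BASES) - 1L) * 4L + (match(tm, DNA_BASES) - 1L)
  out <- matrix(as.numeric(vals), nrow = nrow(gm))
  colnames(out) <- sprintf("pos%d", seq_len(ncol(gm)))
  new_feature_matrix(out, "LEP")
}

#' Decode an LEP row back to its guide/target pair
#'
#' Inverse of [encode_lep()]; makes the lexicographic pair ordering auditable.
#'
#' @param codes numeric vector of integers in 0..15.
#' @return list with `guide_seq` and `target_seq`.
#' @export
decode_lep <- function(codes) {
  stopifnot(all(codes %in% 0:15))
  g <- DNA_BASES[codes %/% 4 + 1]
  t <- DNA_BASES[codes %% 4 + 1]
  list(
    guide_seq = paste(g, collapse = ""),
    target_seq = paste(t, collapse = "")
  )
}

#' Match/mismatch (MM) encoding
#'
#' Binary indicator of a mismatch at each aligned position, ignoring
#' nucleotide identity; a gap column counts as a mismatch. The row sum equals
#' [compute_distance()].
#'
#' @inheritParams encode_npm
#' @export
encode_mm <- function(guide_seq, target_seq) {
  gm <- char_matrix(guide_seq)
  tm <- char_matrix(target_seq)
  out <- matrix(as.numeric(gm != tm), nrow = nrow(gm))
  colnames(out) <- sprintf("pos%d", seq_len(ncol(gm)))
  new_feature_matrix(out, "MM")
}

# one-hot over a symbol set; n x (A*L); names "{prefix}pos{p}_{sym}"
onehot_core <- function(seqs, alph, context, prefix = "") {
  cm <- char_matrix(seqs)
  reject_symbols(cm, alph, context)
  L <- ncol(cm)
  A <- length(alph)
  out <- matrix(0, nrow = nrow(cm), ncol = A * L)
  pos <- rep(seq_len(L), each = nrow(cm))
  cols <- (pos - 1L) * A + match(cm, alph)
  out[cbind(rep(seq_len(nrow(cm)), L), cols)] <- 1
  colnames(out) <- unlist(lapply(
    seq_len(L),
    function(p) sprintf("%spos%d_%s", prefix, p, alph)
  ))
  out
}

#' 8XL encoding: concatenated one-hots of guide and off-target
#'
#' First 4L entries are the one-hot of the guide, last 4L the one-hot of the
#' target; 8L features, 184 at L = 23.
#'
#' @inheritParams encode_npm
#' @export
encode_8xl <- function(guide_seq, target_seq) {
  if (any(has_gap(guide_seq)) || any(has_gap(target_seq))) {
    stop("8XL does not support gapped alignments; use the BULGES encoding",
      call. = FALSE
    )
  }
  g <- onehot_core(guide_seq, DNA_BASES, "8XL", prefix = "guide_")
  t <- onehot_core(target_seq, DNA_BASES, "8XL", prefix = "target_")
  new_feature_matrix(cbind(g, t), "8XL")
}

#' One-hot (OH) encoding
#'
#' Single sequence: standard positional one-hot (4L features, 92 at L = 23).
#' Pair: the two one-hots are combined with a bitwise OR, so matched positions
#' have block sum 1 and mismatched positions block sum 2, at unchanged
#' dimensionality — mismatches are represented implicitly.
#'
#' @param guide_seq sequence(s).
#' @param target_seq optional off-target sequence(s); when supplied, the OR
#'   pairing is applied.
#' @export
encode_onehot <- function(guide_seq, target_seq = NULL) {
  if (any(has_gap(guide_seq)) ||
    (!is.null(target_seq) && any(has_gap(target_seq)))) {
    stop("OH does not support gapped alignments; use OH5C",
      call. = FALSE
    )
  }
  g <- onehot_core(guide_seq, DNA_BASES, "OH")
  if (!is.null(target_seq)) {
    t <- onehot_core(target_seq, DNA_BASES, "OH")
    g <- pmax(g, t) # bitwise OR on 0/1 indicators
  }
  new_feature_matrix(g, "OH")
}

#' Five-channel one-hot (OH5C) encoding
#'
#' One-hot over the channels `{A,C,G,T,X}` where the X channel fires for the
#' gap symbol `-` or the ambiguity code `N`; pairs are combined with the same
#' OR rule as [encode_onehot()]. 5L features, 115 at L = 23. This is the only
#' encoder that represents `N`.
#'
#' @inheritParams encode_onehot
#' @export
encode_oh5c <- function(guide_seq, target_seq = NULL) {
  alph5 <- c(DNA_BASES, "X")
  to_x <- function(s) chartr("-N", "XX", s)
  g <- onehot_core(to_x(guide_seq), alph5, "OH5C")
  if (!is.null(target_seq)) {
    t <- onehot_core(to_x(target_seq), alph5, "OH5C")
    g <- pmax(g, t)
  }
  new_feature_matrix(g, "OH5C")
}

#' K-mer composition encoding
#'
#' Counts of overlapping length-k subsequences (default k = 3); positional
#' context is discarded, motif composition retained. The full vocabulary has
#' 4^k entries; with `paper_compat = TRUE` the lexicographically last k-mer
#' (`TTT` at k = 3) is dropped, giving 63 features at k = 3 (counts per
#' sequence sum to L - k + 1, so one level is redundant).
#'
#' For the knockout task the off-target sequence is the one encoded (the
#' compositional context of the cleavage site); for base editing, the gRNA.
#'
#' @param seqs gap-free, N-free sequence(s).
#' @param k k-mer order.
#' @param paper_compat drop the last vocabulary k-mer.
#' @export
encode_kmer <- function(seqs, k = 3L, paper_compat = FALSE) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (any(nchar(seqs) < k)) {
    stop("sequence shorter than k = ", k, call. = FALSE)
  }
  cm <- char_matrix(seqs)
  reject_symbols(cm, DNA_BASES, "KMER")
  vocab <- apply(
    expand.grid(rev(replicate(k, DNA_BASES, simplify = FALSE)),
      stringsAsFactors = FALSE
    )[, k:1, drop = FALSE],
    1, paste, collapse = ""
  )
  vocab <- sort(vocab) # lexicographic AAA..TTT
  L <- ncol(cm)
  n <- nrow(cm)
  out <- matrix(0, nrow = n, ncol = length(vocab))
  colnames(out) <- paste0("kmer_", vocab)
  starts <- seq_len(L - k + 1L)
  for (s in starts) {
    kmers <- do.call(paste0, lapply(seq_len(k), function(j) cm[, s + j - 1L, drop = FALSE]))
    idx <- match(kmers, vocab)
    out[cbind(seq_len(n), idx)] <- out[cbind(seq_len(n), idx)] + 1
  }
  if (paper_compat) out <- out[, -ncol(out), drop = FALSE]
  new_feature_matrix(out, "KMER")
}

# ---- distance ---------------------------------------------------------------

#' Hamming distance between aligned guide and off-target
#'
#' Number of aligned positions where the symbols differ; a gap opposite a base
#' counts as one edit.
#'
#' @inheritParams encode_npm
#' @return non-negative integer vector.
#' @export
compute_distance <- function(guide_seq, target_seq) {
  gm <- char_matrix(guide_seq)
  tm <- char_matrix(target_seq)
  if (ncol(gm) != ncol(tm)) stop("aligned lengths differ", call. = FALSE)
  as.integer(rowSums(gm != tm))
}

#' Append the explicit distance column to a feature matrix
#'
#' @param matrix a `feature_matrix` without a distance column.
#' @param guide_seq,target_seq the aligned pairs (one per row of `matrix`).
#' @return the matrix with a final `"distance"` column.
#' @export
append_distance <- function(matrix, guide_seq, target_seq) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (isTRUE(attr(matrix, "has_distance"))) {
    stop("distance column already present", call. = FALSE)
  }
  d <- compute_distance(guide_seq, target_seq)
  if (length(d) != nrow(matrix)) {
    stop("row count mismatch between matrix and pairs", call. = FALSE)
  }
  out <- cbind(matrix, distance = as.numeric(d))
  new_feature_matrix(out, attr(matrix, "encoding_id"), has_distance = TRUE)
}

# ---- dataset-level dispatcher ----------------------------------------------

#' Encode a dataset table into a feature matrix
#'
#' Applies the encoder named by `spec` to every record of `table`. Paired
#' (alignment-based) encoders use (guide, target); OH/OH5C use OR pairing for
#' the knockout task and the bare guide for base editing; KMER encodes the
#' off-target sequence for KO and the guide for BE. With
#' `spec$with_distance = TRUE` (KO only) the explicit Hamming-distance column
#' is appended.
#'
#' @param table a `dataset_table`.
#' @param spec an [encoder_spec()] (or an encoding id string).
#' @return a `feature_matrix` with `nrow(table)` rows.
#' @export
encode_dataset <- function(table, spec) {
  stopifnot(inherits(table, "dataset_table"))
  if (is.character(spec)) spec <- encoder_spec(spec)
  task <- dataset_task(table)
  id <- spec$encoding_id
  paired <- task == "KO"
  if (!paired && id %in% c("NPM", "BULGES", "LEP", "MM", "8XL")) {
    stop(id, " is an alignment-based encoding and requires paired (KO) data",
      call. = FALSE
    )
  }
  fm <- switch(id,
    NPM = encode_npm(table$guide_seq, table$target_seq),
    BULGES = encode_bulges(table$guide_seq, table$target_seq),
    LEP = encode_lep(table$guide_seq, table$target_seq),
    MM = encode_mm(table$guide_seq, table$target_seq),
    `8XL` = encode_8xl(table$guide_seq, table$target_seq),
    OH = if (paired) {
      encode_onehot(table$guide_seq, table$target_seq)
    } else {
      encode_onehot(table$guide_seq)
    },
    OH5C = if (paired) {
      encode_oh5c(table$guide_seq, table$target_seq)
    } else {
      encode_oh5c(table$guide_seq)
    },
    KMER = encode_kmer(
      if (paired) table$target_seq else table$guide_seq,
      k = spec$k, paper_compat = spec$kmer_paper_compat
    )
  )
  if (isTRUE(spec$with_distance)) {
    if (!paired) {
      stop("distance feature requires paired (KO) data", call. = FALSE)
    }
    fm <- append_distance(fm, table$guide_seq, table$target_seq)
  }
  fm
}
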