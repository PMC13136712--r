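# Encoding strategies: dimensionality, one-hot structure, pairing semantics,
# and mutual consistency between the mismatch-aware encoders.

L23A <- paste(rep("A", 23), collapse = "")

test_that("dimensionality table holds at L = 23", {
  g <- random_dna(1)
  t <- subst(g, 7, setdiff(c("A", "C", "G", "T"), substr(g, 7, 7))[1])
  expect_equal(ncol(encode_npm(g, t)), 368)
  expect_equal(ncol(encode_bulges(g, t)), 575)
  expect_equal(ncol(encode_lep(g, t)), 23)
  expect_equal(ncol(encode_mm(g, t)), 23)
  expect_equal(ncol(encode_8xl(g, t)), 184)
  expect_equal(ncol(encode_onehot(g)), 92)
  expect_equal(ncol(encode_onehot(g, t)), 92)
  expect_equal(ncol(encode_oh5c(g)), 115)
  expect_equal(ncol(encode_kmer(g, 3)), 64)
  expect_equal(ncol(encode_kmer(g, 3, paper_compat = TRUE)), 63)
})

test_that("encoders derive dimensions from length: toy lengths are first-class", {
  g <- "ACG"
  t <- "ACT"
  expect_equal(ncol(encode_npm(g, t)), 48)
  expect_equal(ncol(encode_lep(g, t)), 3)
  expect_equal(ncol(encode_8xl(g, t)), 24)
  expect_equal(ncol(encode_onehot(g)), 12)
})

test_that("NPM marks exactly one (guide, target) cell per position", {
  v <- encode_npm(L23A, L23A)
  expect_equal(sum(v), 23)
  hit <- colnames(v)[v[1, ] == 1]
  expect_true(all(grepl("_AA$", hit))) # identity pairs on the diagonal
  # toy single-mismatch construction
  v2 <- encode_npm("ACG", "ACT")
  expect_equal(colnames(v2)[v2[1, ] == 1], c("pos1_AA", "pos2_CC", "pos3_GT"))
  # per-position block sums are exactly 1
  set.seed(1)
  g <- random_dna(20)
  t <- vapply(g, function(s) subst(s, sample(23, 1), sample(c("A", "C", "G", "T"), 1)),
    character(1)
  )
  v3 <- encode_npm(g, unname(t))
  for (p in c(1, 12, 23)) {
    block <- v3[, grepl(sprintf("^pos%d_", p), colnames(v3)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 20))
  }
  expect_error(encode_npm("A-G", "ACT"), "BULGES")
  expect_error(encode_npm("ANG", "ACT"), "unsupported symbol")
})

test_that("BULGES reduces to NPM on ungapped input and encodes gap cells", {
  set.seed(2)
  g <- random_dna(10)
  t <- random_dna(10)
  b <- encode_bulges(g, t)
  n <- encode_npm(g, t)
  # the nonzero cells agree after name matching into the extended grid
  expect_equal(unclass(b)[, colnames(n)], unclass(n), ignore_attr = TRUE)
  # every cell involving '-' is zero on ungapped data
  gap_cols <- grepl("-", colnames(b), fixed = TRUE)
  expect_equal(sum(b[, gap_cols]), 0)
  # toy construction: guide gap at pos 3 sets cell ('-', 'G')
  v <- encode_bulges("AC-", "ACG")
  expect_equal(colnames(v)[v[1, ] == 1], c("pos1_AA", "pos2_CC", "pos3_-G"))
  # target gap sets (r, '-'); the ('-','-') column stays all-zero
  v2 <- encode_bulges("ACG", "AC-")
  expect_true(unname(v2[1, "pos3_G-"]) == 1)
  tab <- inject_bulges(
    label_ko_by_count(simulate_ko(ko_sim_params(n_guides = 3, sites_per_guide = 50), seed = 5)),
    fraction = 0.5, seed = 5
  )
  bb <- encode_bulges(tab$guide_seq, tab$target_seq)
  expect_equal(sum(bb[, grepl("_--$", colnames(bb))]), 0)
  expect_error(encode_bulges("A-G", "A-T"), "gap aligned to gap")
})

test_that("LEP uses the lexicographic pair index and round-trips", {
  expect_equal(as.numeric(encode_lep(L23A, L23A)), rep(0, 23))
  # TT is the 16th ordered pair -> index 15
  g <- paste(rep("T", 23), collapse = "")
  expect_equal(as.numeric(encode_lep(g, g)), rep(15, 23))
  expect_equal(as.numeric(encode_lep("ACG", "ACT"))[3], 4 * 2 + 3) # GT
  # bijectivity on random pairs
  set.seed(3)
  for (i in 1:25) {
    gs <- random_dna(1)
    ts <- random_dna(1)
    dec <- decode_lep(as.numeric(encode_lep(gs, ts)))
    expect_identical(dec$guide_seq, gs)
    expect_identical(dec$target_seq, ts)
  }
})

test_that("MM flags mismatches and sums to the Hamming distance", {
  expect_equal(sum(encode_mm(L23A, L23A)), 0)
  expect_equal(as.numeric(encode_mm("ACG", "ACT")), c(0, 0, 1))
  set.seed(4)
  g <- random_dna(1000)
  t <- vapply(g, function(s) {
    for (p in sample(23, sample(0:6, 1))) s <- subst(s, p, sample(c("A", "C", "G", "T"), 1))
    s
  }, character(1))
  t <- unname(t)
  expect_equal(unname(rowSums(encode_mm(g, t))), as.numeric(compute_distance(g, t)))
})

test_that("8XL concatenates the two one-hots with 4-hot blocks", {
  v <- encode_8xl(L23A, L23A)
  expect_equal(unname(v[1, 1:92]), unname(v[1, 93:184]))
  set.seed(5)
  g <- random_dna(5)
  t <- random_dna(5)
  v2 <- encode_8xl(g, t)
  expect_equal(unclass(v2)[, 1:92], unclass(encode_onehot(g)),
    ignore_attr = TRUE
  )
  # every per-position 4-block sums to 1
  expect_true(all(abs(rowSums(unclass(v2)) - 46) < 1e-12))
  for (p in seq(1, 184, by = 4)) {
    expect_equal(unname(rowSums(v2[, p:(p + 3), drop = FALSE])), rep(1, 5))
  }
})

test_that("one-hot OR pairing represents mismatches implicitly", {
  g <- random_dna(1)
  expect_equal(unclass(encode_onehot(g, g)), unclass(encode_onehot(g)),
    ignore_attr = TRUE
  ) # OR idempotence
  # guide A / target G at position 5
  gs <- paste(rep("A", 23), collapse = "")
  ts <- subst(gs, 5, "G")
  v <- encode_onehot(gs, ts)
  expect_equal(unname(v[1, c("pos5_A", "pos5_C", "pos5_G", "pos5_T")]), c(1, 0, 1, 0))
  # positions with block-sum 2 count the Hamming distance
  set.seed(6)
  g <- random_dna(500)
  t <- vapply(g, function(s) {
    for (p in sample(23, sample(0:6, 1))) s <- subst(s, p, sample(c("A", "C", "G", "T"), 1))
    s
  }, character(1))
  t <- unname(t)
  v2 <- unclass(encode_onehot(g, t))
  bs <- sapply(1:23, function(p) rowSums(v2[, (4 * (p - 1) + 1):(4 * p), drop = FALSE]))
  expect_true(all(bs %in% c(1, 2)))
  expect_equal(unname(rowSums(bs == 2)), as.numeric(compute_distance(g, t)))
})

test_that("OH5C adds an X channel for gaps and N and reduces to OH otherwise", {
  g <- random_dna(1)
  v <- encode_oh5c(g)
  xcols <- grepl("_X$", colnames(v))
  expect_equal(sum(v[, xcols]), 0)
  oh <- encode_onehot(g)
  expect_equal(unname(v[1, !xcols]), unname(oh[1, ]))
  # N at position 2 fires the X channel; only OH5C accepts N
  gn <- subst(g, 2, "N")
  expect_equal(unname(encode_oh5c(gn)[1, "pos2_X"]), 1)
  expect_error(encode_onehot(gn), "unsupported symbol")
  # pair block sums stay in {1, 2}
  gg <- subst(g, 4, "-")
  v2 <- unclass(encode_oh5c(gg, g))
  bs <- sapply(1:23, function(p) sum(v2[1, (5 * (p - 1) + 1):(5 * p)]))
  expect_true(all(bs %in% c(1, 2)))
  expect_equal(unname(v2[1, "pos4_X"]), 1)
})

test_that("k-mer counts follow the sliding window and compat vocabulary", {
  v <- encode_kmer("AAAAA", k = 3)
  expect_equal(unname(v[1, "kmer_AAA"]), 3)
  expect_equal(sum(v), 3) # L - k + 1
  v2 <- encode_kmer("ACGT", k = 3)
  expect_equal(v2[1, c("kmer_ACG", "kmer_CGT")], c(kmer_ACG = 1, kmer_CGT = 1))
  expect_equal(sum(v2), 2)
  # paper-compat drops TTT, the lexicographically last 3-mer
  v3 <- encode_kmer(random_dna(1), k = 3, paper_compat = TRUE)
  expect_false("kmer_TTT" %in% colnames(v3))
  expect_equal(ncol(v3), 63)
  expect_error(encode_kmer("AC", k = 3), "shorter than k")
})

test_that("distance counts differing columns, gaps included", {
  expect_equal(compute_distance(L23A, L23A), 0L)
  expect_equal(compute_distance("ACG", "ACT"), 1L)
  expect_equal(compute_distance("A-G", "ACG"), 1L)
})

test_that("append_distance adds a final named column exactly once", {
  tab <- tiny_ko_table()
  fm <- encode_npm(tab$guide_seq, tab$target_seq)
  fm2 <- append_distance(fm, tab$guide_seq, tab$target_seq)
  expect_equal(ncol(fm2), 369)
  expect_identical(colnames(fm2)[369], "distance")
  expect_equal(
    unname(fm2[, "distance"]),
    as.numeric(compute_distance(tab$guide_seq, tab$target_seq))
  )
  expect_false(anyDuplicated(colnames(fm2)) > 0)
  expect_error(append_distance(fm2, tab$guide_seq, tab$target_seq), "already present")
})

test_that("MM, OH and NPM agree on which positions mismatch", {
  set.seed(7)
  n <- 2000
  g <- random_dna(n)
  t <- vapply(g, function(s) {
    for (p in sample(23, sample(0:6, 1))) s <- subst(s, p, sample(c("A", "C", "G", "T"), 1))
    s
  }, character(1))
  t <- unname(t)
  mm <- unclass(encode_mm(g, t))
  oh <- unclass(encode_onehot(g, t))
  npm <- unclass(encode_npm(g, t))
  offdiag <- !grepl("_(AA|CC|GG|TT)$", colnames(npm))
  for (p in c(1, 8, 17, 23)) {
    oh_bs <- rowSums(oh[, (4 * (p - 1) + 1):(4 * p), drop = FALSE])
    npm_off <- rowSums(npm[, offdiag & grepl(sprintf("^pos%d_", p), colnames(npm)), drop = FALSE])
    expect_equal(unname(mm[, p]), unname(oh_bs - 1))
    expect_equal(unname(mm[, p]), unname(npm_off))
  }
})

test_that("encoders are deterministic and row-order independent", {
  tab <- tiny_ko_table()
  f1 <- encode_dataset(tab, "NPM")
  f2 <- encode_dataset(tab, "NPM")
  expect_identical(f1, f2)
  perm <- c(4, 1, 6, 2, 5, 3)
  f3 <- encode_dataset(tab[perm, ], "NPM")
  expect_equal(unclass(f3), unclass(f1)[perm, ], ignore_attr = TRUE)
})

test_that("encode_dataset dispatches task-appropriate inputs", {
  be <- tiny_be_table()
  expect_error(encode_dataset(be, "NPM"), "alignment-based")
  expect_equal(ncol(encode_dataset(be, "OH")), 92)
  # KO k-mers come from the off-target sequence
  ko <- tiny_ko_table()
  km <- encode_dataset(ko, "KMER")
  expect_equal(unclass(km), unclass(encode_kmer(ko$target_seq)), ignore_attr = TRUE)
  # BE k-mers come from the guide
  km_be <- encode_dataset(be, "KMER")
  expect_equal(unclass(km_be), unclass(encode_kmer(be$guide_seq)), ignore_attr = TRUE)
  # distance refused for single-sequence data
  expect_error(
    encode_dataset(be, encoder_spec("OH", with_distance = TRUE)),
    "paired"
  )
  fm <- encode_dataset(ko, encoder_spec("OH", with_distance = TRUE))
  expect_true(attr(fm, "has_distance"))
  expect_equal(ncol(fm), 93)
})
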