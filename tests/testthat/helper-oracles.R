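# Independent oracles and small fixture builders shared across the suite.

# Brute-force average precision: recompute the confusion matrix from scratch
# at every distinct score threshold (predict positive iff score >= t),
# then sum (R_i - R_{i-1}) * P_i walking thresholds from high to low.
# Independent of pr_curve's cumulative-sum implementation.
oracle_ap <- function(labels, scores) {
  labels <- as.integer(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prev_r <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / P
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

# Pairwise-comparison AUROC: fraction of (positive, negative) pairs ranked
# correctly, ties counted half.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random binary instance with at least one positive
random_instance <- function(n, score_levels = NULL) {
  repeat {
    y <- rbinom(n, 1, 0.4)
    if (sum(y) > 0) break
  }
  s <- if (is.null(score_levels)) {
    runif(n)
  } else {
    sample(score_levels, n, replace = TRUE) # discrete scores force ties
  }
  list(labels = y, scores = s)
}

# tiny valid KO table (2 guides x 3 sites)
tiny_ko_table <- function() {
  g1 <- paste(rep(c("A", "C", "G", "T"), length.out = 23), collapse = "")
  g2 <- paste(rep(c("G", "T"), length.out = 23), collapse = "")
  mutate_at <- function(s, p, b) {
    ch <- strsplit(s, "")[[1]]
    ch[p] <- b
    paste(ch, collapse = "")
  }
  dataset_table(
    data.frame(
      guide_id = c("g1", "g1", "g1", "g2", "g2", "g2"),
      guide_seq = c(g1, g1, g1, g2, g2, g2),
      target_seq = c(
        g1, mutate_at(g1, 5, "T"), mutate_at(mutate_at(g1, 2, "G"), 20, "C"),
        g2, mutate_at(g2, 11, "A"), mutate_at(g2, 23, "C")
      ),
      read_count = c(500, 101, 100, 0, 250, 7),
      stringsAsFactors = FALSE
    ),
    task = "KO"
  )
}

tiny_be_table <- function() {
  set.seed(42)
  dataset_table(
    data.frame(
      guide_id = sprintf("b%02d", 1:8),
      guide_seq = random_dna(8),
      zscore = c(-3.1, -2.0, -1.9, 0.0, 0.4, 1.2, -2.5, 2.0),
      stringsAsFactors = FALSE
    ),
    task = "BE"
  )
}

# substitute one character of a sequence string
subst <- function(s, p, b) {
  ch <- strsplit(s, "")[[1]]
  ch[p] <- b
  paste(ch, collapse = "")
}
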