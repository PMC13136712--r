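# Synthetic datasets with the statistical structure of genome-wide off-target
# assays (paired 23-mers, <=6 mismatches, ~3% active prevalence, heavy-tailed
# negative-binomial read counts with a PAM-proximal seed-region penalty) and
# base-editor viability screens (z-scores driven by PAM-proximal positional
# effects plus motif effects, with a rare z < -2 tail).
#
# All randomness flows from a single integer seed through a per-guide stream:
# guide g's records depend only on (seed, g), not on n_guides.

#' Parameters for the knockout off-target simulator
#'
#' @param n_guides number of guides (default 20).
#' @param sites_per_guide candidate sites per guide (default 500).
#' @param max_mismatches maximum mismatch count (default 6).
#' @param prevalence_active target fraction of sites with read count above the
#'   activity threshold (default 0.03).
#' @param beta0 baseline log read count for a perfect match (default 6.0).
#' @param beta_mm per-mismatch log-count penalty (default 1.2).
#' @param seed_region positions whose mismatches are penalized more strongly
#'   (default 13:20, the PAM-proximal seed).
#' @param seed_penalty_multiplier burden multiplier for seed-region mismatches
#'   (default 2.0).
#' @param dispersion negative-binomial size parameter (default 2.0; smaller =
#'   heavier tail).
#' @param length sequence length (default 23).
#' @param active_threshold count threshold defining "active" for calibration
#'   (default 100).
#' @return a `ko_sim_params` list.
#' @export
ko_sim_params <- function(n_guides = 20L, sites_per_guide = 500L,
                          max_mismatches = 6L, prevalence_active = 0.03,
                          beta0 = 6.0, beta_mm = 1.2,
                          seed_region = 13:20, seed_penalty_multiplier = 2.0,
                          dispersion = 2.0, length = 23L,
                          active_threshold = 100) {
  stopifnot(
    prevalence_active > 0, prevalence_active < 1,
    max_mismatches <= length, n_guides >= 1, sites_per_guide >= 1
  )
  structure(as.list(environment()), class = "ko_sim_params")
}

# Exact P(read_count > threshold | m mismatches): the number of seed-region
# mismatches among m uniformly placed ones is hypergeometric, and the count
# is negative binomial given the resulting burden.
p_active_given_m <- function(m, p) {
  if (m == 0) {
    return(1 - stats::pnbinom(p$active_threshold,
      size = p$dispersion, mu = exp(p$beta0)
    ))
  }
  n_seed <- length(p$seed_region)
  s <- 0:min(m, n_seed)
  ps <- stats::dhyper(s, n_seed, p$length - n_seed, m)
  burden <- s * p$seed_penalty_multiplier + (m - s)
  mu <- exp(p$beta0 - p$beta_mm * burden)
  sum(ps * (1 - stats::pnbinom(p$active_threshold, size = p$dispersion, mu = mu)))
}

# Mismatch-count sampling weights targeting the requested active prevalence.
# Base weights grow with m (more candidate sites exist at higher mismatch
# count); low-m mass (m <= 1, the activity-prone sites) and high-m mass are
# rescaled jointly by solving sum(w) = 1, sum(w * p_active) = prevalence.
mismatch_weights <- function(p) {
  m <- 0:p$max_mismatches
  b <- (m + 1) / sum(m + 1)
  pa <- vapply(m, p_active_given_m, numeric(1), p = p)
  lo <- m <= 1
  A1 <- sum(b[lo])
  A2 <- sum(b[!lo])
  P1 <- sum(b[lo] * pa[lo])
  P2 <- sum(b[!lo] * pa[!lo])
  # solve [A1 A2; P1 P2] [s c]' = [1 prev]'
  det <- A1 * P2 - A2 * P1
  s <- (P2 - A2 * p$prevalence_active) / det
  cc <- (A1 * p$prevalence_active - P1) / det
  if (!is.finite(s) || !is.finite(cc) || s < 0 || cc < 0) {
    w <- b
    achieved <- sum(b * pa)
    warning(
      "requested prevalence ", p$prevalence_active,
      " infeasible at given betas; achieved ~", signif(achieved, 3)
    )
  } else {
    w <- b
    w[lo] <- s * b[lo]
    w[!lo] <- cc * b[!lo]
  }
  list(weights = w / sum(w), p_active = pa)
}

# first n_guides values of the guide-seed stream for a master seed
guide_seed_stream <- function(seed, n_guides) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_guides)
}

#' Simulate a knockout-style paired off-target dataset
#'
#' For each guide, a random 23-mer protospacer+PAM is drawn; each candidate
#' site draws a mismatch count (weighted so that the fraction of sites
#' exceeding the activity threshold matches `prevalence_active`), uniform
#' mismatch positions (seed-region positions carry an extra burden
#' multiplier), and uniform substituted bases. The latent mean log count is
#' `beta0 - beta_mm * burden` and read counts are negative binomial around
#' it. Deterministic given `seed`.
#'
#' @param params a [ko_sim_params()] object.
#' @param seed integer RNG seed.
#' @return a KO `dataset_table`.
#' @export
simulate_ko <- function(params = ko_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "ko_sim_params"))
  cal <- mismatch_weights(params)
  seeds <- guide_seed_stream(seed, params$n_guides)
  L <- params$length
  per_guide <- lapply(seq_len(params$n_guides), function(g) {
    set.seed(seeds[g])
    guide <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    gch <- seq_chars(guide)
    n <- params$sites_per_guide
    m <- sample(0:params$max_mismatches, n, replace = TRUE, prob = cal$weights)
    targets <- character(n)
    burden <- numeric(n)
    for (i in seq_len(n)) {
      tch <- gch
      if (m[i] > 0) {
        pos <- sample.int(L, m[i])
        for (p in pos) {
          tch[p] <- sample(setdiff(DNA_BASES, gch[p]), 1)
        }
        burden[i] <- sum(ifelse(pos %in% params$seed_region,
          params$seed_penalty_multiplier, 1
        ))
      }
      targets[i] <- paste(tch, collapse = "")
    }
    mu <- exp(params$beta0 - params$beta_mm * burden)
    counts <- stats::rnbinom(n, size = params$dispersion, mu = mu)
    data.frame(
      guide_id = sprintf("guide%03d", g),
      guide_seq = guide, target_seq = targets,
      read_count = counts, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, per_guide)
  dataset_table(df, "KO",
    provenance = sprintf(
      "simulate_ko(seed=%d, n_guides=%d, sites_per_guide=%d)",
      seed, params$n_guides, params$sites_per_guide
    ),
    length_ungapped = L
  )
}

#' Parameters for the base-editing screen simulator
#'
#' Default position effects are concentrated at PAM-proximal positions
#' (strongly negative effects for A at positions 20 and 17, consistent with
#' a deaminase editing window near the PAM), with weaker effects elsewhere;
#' default motif effects attach small coefficients to the GGC and AAA
#' triplets.
#'
#' @param n_guides number of guides (default 5000).
#' @param position_effects L x 4 numeric matrix (columns A,C,G,T) of additive
#'   per-position per-base effects on the z-score.
#' @param motif_effects named numeric vector of 3-mer effects.
#' @param noise_sd Gaussian noise standard deviation (default 0.6).
#' @param tail_fraction target fraction with z < -2 (default 0.08).
#' @param length sequence length (default 23).
#' @return a `be_sim_params` list.
#' @export
be_sim_params <- function(n_guides = 5000L, position_effects = NULL,
                          motif_effects = NULL, noise_sd = 0.6,
                          tail_fraction = 0.08, length = 23L) {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5, n_guides >= 1)
  if (is.null(position_effects)) {
    position_effects <- matrix(0, nrow = length, ncol = 4,
      dimnames = list(NULL, DNA_BASES)
    )
    position_effects[20, "A"] <- -1.0
    position_effects[17, "A"] <- -0.9
    position_effects[16, "T"] <- -0.6
    position_effects[15, "A"] <- -0.4
    position_effects[19, "G"] <- 0.5
    position_effects[18, "C"] <- 0.4
    position_effects[1, "G"] <- 0.2
  }
  if (is.null(motif_effects)) {
    motif_effects <- c(GGC = -0.35, AAA = 0.25)
  }
  stopifnot(
    nrow(position_effects) == length, ncol(position_effects) == 4,
    all(is.finite(position_effects)), all(is.finite(motif_effects))
  )
  structure(as.list(environment()), class = "be_sim_params")
}

#' Simulate a base-editing viability screen
#'
#' Each guide's raw score is the sum of per-position per-base effects, 3-mer
#' motif effects and Gaussian noise; an affine calibration maps the median to
#' 0 and the `tail_fraction` quantile to -2, so the strongly-effective tail
#' (z < -2) has approximately the requested mass. Deterministic given `seed`.
#'
#' @param params a [be_sim_params()] object.
#' @param seed integer RNG seed.
#' @return a BE `dataset_table`.
#' @export
simulate_be <- function(params = be_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "be_sim_params"))
  seeds <- guide_seed_stream(seed, params$n_guides)
  L <- params$length
  eff <- params$position_effects
  motifs <- names(params$motif_effects)
  rows <- lapply(seq_len(params$n_guides), function(g) {
    set.seed(seeds[g])
    ch <- sample(DNA_BASES, L, replace = TRUE)
    z <- sum(eff[cbind(seq_len(L), match(ch, DNA_BASES))])
    if (length(motifs) > 0) {
      s <- paste(ch, collapse = "")
      for (j in seq_along(motifs)) {
        hits <- gregexpr(paste0("(?=", motifs[j], ")"), s, perl = TRUE)[[1]]
        n_hits <- if (hits[1] == -1) 0L else length(hits)
        z <- z + n_hits * params$motif_effects[[j]]
      }
    } else {
      s <- paste(ch, collapse = "")
    }
    z <- z + stats::rnorm(1, 0, params$noise_sd)
    data.frame(
      guide_id = sprintf("guide%05d", g), guide_seq = s,
      zscore = z, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (stats::sd(df$zscore) < 1e-8) {
    stop("degenerate z-score variance: effects and noise produce a constant score",
      call. = FALSE
    )
  }
  zs <- (df$zscore - mean(df$zscore)) / stats::sd(df$zscore)
  med <- stats::median(zs)
  q <- stats::quantile(zs, params$tail_fraction, names = FALSE)
  df$zscore <- (zs - med) * (-2) / (q - med)
  dataset_table(df, "BE",
    provenance = sprintf("simulate_be(seed=%d, n_guides=%d)", seed, params$n_guides),
    length_ungapped = L
  )
}

#' Inject single-gap bulge columns into a knockout dataset
#'
#' For a chosen fraction of rows, one aligned column is converted into a gap
#' column: the base of one pair member (guide or target, equiprobable) is
#' replaced by `-` while the other member keeps its base, preserving the
#' aligned length and the no-gap-aligned-to-gap invariant.
#'
#' @param table a KO `dataset_table` with gap-free pairs.
#' @param fraction fraction of rows to modify, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the modified `dataset_table`.
#' @export
inject_bulges <- function(table, fraction, seed = 1L) {
  stopifnot(
    inherits(table, "dataset_table"), dataset_task(table) == "KO",
    fraction >= 0, fraction <= 1
  )
  n <- nrow(table)
  if (fraction == 0 || n == 0) return(table)
  set.seed(seed)
  n_mod <- round(fraction * n)
  rows <- sample.int(n, n_mod)
  for (i in rows) {
    gch <- seq_chars(table$guide_seq[i])
    tch <- seq_chars(table$target_seq[i])
    free <- which(gch != GAP & tch != GAP)
    p <- if (length(free) == 1L) free else sample(free, 1)
    if (stats::runif(1) < 0.5) gch[p] <- GAP else tch[p] <- GAP
    table$guide_seq[i] <- paste(gch, collapse = "")
    table$target_seq[i] <- paste(tch, collapse = "")
  }
  table
}
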