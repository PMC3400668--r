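# Sequence-set generator under the Kimura two-parameter substitution
# model: a star-of-stars genealogy (root -> group ancestors -> tips)
# with branch lengths chosen so the expected within- and between-group
# K2P distances hit the requested targets.

# K80 substitution probabilities at branch length d (expected
# substitutions per site) and transition/transversion rate ratio kappa:
# returns c(p_same, p_transition, p_each_transversion).
k80_site_probs <- function(d, kappa) {
  if (d <= 0) return(c(1, 0, 0))
  # rates normalised so total substitution rate is 1: transversion rate
  # b (two targets), transition rate a = kappa * b, a + 2b = 1
  b <- 1 / (kappa + 2)
  a <- kappa * b
  e1 <- exp(-4 * b * d)
  e2 <- exp(-2 * (a + b) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  c(1 - p_ts - 2 * p_tv, p_ts, p_tv)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

evolve_sequence <- function(chars, d, kappa) {
  if (d <= 0) return(chars)
  pr <- k80_site_probs(d, kappa)
  fate <- sample.int(3L, length(chars), replace = TRUE,
                     prob = c(pr[1], pr[2], 2 * pr[3]))
  out <- chars
  ts_idx <- which(fate == 2L)
  out[ts_idx] <- TS_PARTNER[chars[ts_idx]]
  tv_idx <- which(fate == 3L)
  if (length(tv_idx)) {
    pick <- sample.int(2L, length(tv_idx), replace = TRUE)
    out[tv_idx] <- vapply(seq_along(tv_idx), function(j) {
      TV_PARTNERS[[chars[tv_idx[j]]]][pick[j]]
    }, character(1))
  }
  out
}

#' Generate aligned sequence sets with known divergence structure
#'
#' Sequences evolve from a random root under the Kimura two-parameter
#' process: each group descends from its own ancestor at distance
#' `(between_d - within_d) / 2` from the root, and each individual sits
#' at distance `within_d / 2` from its group ancestor. Distances are
#' additive in expectation under this model, so realised mean within-
#' and between-group K2P distances converge to `within_d` and
#' `between_d` as `length` grows.
#'
#' @param groups Number of groups (populations).
#' @param n_per_group Individuals per group.
#' @param length Alignment length in sites.
#' @param within_d Target expected within-group K2P distance.
#' @param between_d Target expected between-group K2P distance
#'   (`> within_d` unless both are 0).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Optional integer seed.
#' @return An `aligned_sequences`: list with `sequences` (named
#'   character vector), `groups` (label per sequence), and the target
#'   parameters in `truth`.
#' @export
gen_sequences <- function(groups, n_per_group, length, within_d = 0.004,
                          between_d = 0.008, kappa = 2, seed = NULL) {
  groups <- check_count(groups, "groups")
  n_per_group <- check_count(n_per_group, "n_per_group")
  length <- check_count(length, "length")
  check_nonneg(within_d, "within_d")
  check_nonneg(between_d, "between_d")
  check_positive(kappa, "kappa")
  if (between_d < within_d) {
    stop("`between_d` must be >= `within_d`", call. = FALSE)
  }
  maybe_seed(seed)
  root <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  b_anc <- (between_d - within_d) / 2
  b_tip <- within_d / 2
  seqs <- character(0)
  labels <- character(0)
  group_ids <- sprintf("G%02d", seq_len(groups))
  for (g in seq_len(groups)) {
    anc <- evolve_sequence(root, b_anc, kappa)
    for (i in seq_len(n_per_group)) {
      tip <- evolve_sequence(anc, b_tip, kappa)
      seqs <- c(seqs, paste(tip, collapse = ""))
      labels <- c(labels, group_ids[g])
    }
  }
  names(seqs) <- sprintf("%s_i%02d", labels,
                         rep(seq_len(n_per_group), times = groups))
  structure(list(sequences = seqs, groups = labels,
                 truth = list(within_d = within_d, between_d = between_d,
                              kappa = kappa)),
            class = "aligned_sequences")
}
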