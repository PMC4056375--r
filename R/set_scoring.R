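# Pairwise association statistics: hypergeometric overlap tail and the
# AUC / average-precision recovery of a terminal set from a diffusion
# ranking.

#' Hypergeometric overlap tail probability
#'
#' Probability of observing an overlap of at least `k` genes between a
#' query set of size `n` and a pathway set of size `m` drawn from a
#' universe of `N` known genes:
#' `P(x >= k) = sum_{x=k}^{min(n,m)} C(m,x) C(N-m,n-x) / C(N,n)`.
#' Evaluated in log space for numerical stability.
#'
#' @param N Universe size (number of known genes, i.e. network genes).
#' @param m Pathway set size.
#' @param n Query set size.
#' @param k Observed overlap size.
#' @param log.p Return the natural log of the tail probability.
#' @return Tail probability in (0, 1] (or its log).
#' @export
hypergeometric_tail <- function(N, m, n, k, log.p = FALSE) {
  stopifnot(length(N) == 1L, length(m) == 1L, length(n) == 1L, length(k) == 1L)
  N <- as.integer(N); m <- as.integer(m); n <- as.integer(n); k <- as.integer(k)
  if (anyNA(c(N, m, n, k)) || k < 0 || m < 0 || n < 0 ||
      n > N || m > N || k > min(n, m)) {
    stop("require 0 <= k <= min(n, m) <= N")
  }
  if (k == 0L) return(if (log.p) 0 else 1)
  stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE, log.p = log.p)
}

# Internal: validate a ranking data.frame and locate terminal genes.
terminal_ranks <- function(ranking, terminal) {
  stopifnot(is.data.frame(ranking), all(c("gene", "rank") %in% names(ranking)))
  members <- set_members(terminal)
  ranking$rank[ranking$gene %in% members]
}

#' Recovery AUC of a terminal set over a ranking
#'
#' Area under the ROC curve of terminal-gene recovery, computed as the
#' Mann-Whitney statistic U / (n1 * n2) on midranks — identical to the
#' trapezoidal ROC area, with ties counted one half.
#'
#' @param ranking Data frame from [rank_genes()] (columns `gene`, `rank`
#'   with midranks, rank 1 = best).
#' @param terminal A [gene_set] or character vector of terminal genes.
#' @return AUC in \[0, 1\].
#' @export
auc_recovery <- function(ranking, terminal) {
  r_t <- terminal_ranks(ranking, terminal)
  n1 <- length(r_t)
  n2 <- nrow(ranking) - n1
  if (n1 == 0L || n2 == 0L) {
    stop("AUC undefined: terminal set covers none or all of the ranking")
  }
  (n1 * n2 + n1 * (n1 + 1) / 2 - sum(r_t)) / (n1 * n2)
}

#' Recovery average precision of a terminal set over a ranking
#'
#' With the k in-ranking terminal genes sorted by ascending rank,
#' `AP = (1/k) * sum_i i / rank_i`. AP is 1 exactly when the terminal
#' genes occupy the top k ranks.
#'
#' @inheritParams auc_recovery
#' @param normalize If `TRUE`, return AP divided by the terminal-set size k
#'   (a diagnostic that removes the size confound; not used as a model
#'   feature).
#' @return AP in \[0, 1\].
#' @export
ap_recovery <- function(ranking, terminal, normalize = FALSE) {
  r_t <- sort(terminal_ranks(ranking, terminal))
  k <- length(r_t)
  if (k == 0L) stop("AP undefined: no terminal gene in the ranking")
  ap <- mean(seq_len(k) / r_t)
  if (normalize) ap / k else ap
}

#' Reflective-diffusion recovery scores for a pair of gene sets
#'
#' Runs the diffusion twice so that each set has a turn as the seed:
#' forward diffuses from `a` and measures recovery of `b`; reverse diffuses
#' from `b` and measures recovery of `a`. Seed genes not shared with the
#' terminal set are excluded from the ranking (they are not candidates);
#' shared genes stay in and take the ranks they earn.
#'
#' @param net A [gene_network].
#' @param a,b [gene_set]s (or character vectors), each with at least one
#'   in-network member.
#' @param params A [diffusion_params] object.
#' @param profiles Optional list with elements `a` and/or `b`: precomputed
#'   [diffusion_profile]s seeded at the respective set (a cache hook used
#'   by the batch layers).
#' @return List with elements `forward` and `reverse`, each a list
#'   `auc`, `ap`, `k_terminal`.
#' @export
reflective_scores <- function(net, a, b, params = diffusion_params(),
                              profiles = NULL) {
  prof_a <- if (!is.null(profiles$a)) profiles$a else diffuse(net, a, params)
  prof_b <- if (!is.null(profiles$b)) profiles$b else diffuse(net, b, params)
  list(forward = recovery_score(prof_a, b),
       reverse = recovery_score(prof_b, a))
}

# Recovery of `terminal` from one diffusion profile, applying the
# seed-exclusion convention above.
recovery_score <- function(profile, terminal) {
  members <- set_members(terminal)
  ranking <- rank_genes(profile, exclude_seed = TRUE, retain = members)
  list(auc = auc_recovery(ranking, members),
       ap = ap_recovery(ranking, members),
       k_terminal = sum(ranking$gene %in% members))
}
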