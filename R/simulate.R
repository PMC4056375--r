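# Synthetic planted-module worlds and the simulated test regimes used for
# training and benchmarking: overlapping half-size draws, disjoint halves,
# a time-split-like asymmetric split, and centrality-binned random sets.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic world: planted-module network plus ground truth
#'
#' Planted-partition graph: gene pairs inside the same module are linked
#' with probability `p_in`, all other pairs (including background genes)
#' with probability `p_out`; edge weights are drawn log-normal. The module
#' memberships are returned as ground-truth gene sets. All randomness is a
#' pure function of the parameters and `seed`.
#'
#' @param n_modules Number of planted modules (default 30).
#' @param module_size Genes per module (default 25; must be >= 4).
#' @param p_in,p_out Within- and between-module edge probabilities
#'   (defaults 0.25 and 0.01; `p_in > p_out >= 0`).
#' @param n_background Genes outside every module (default 500).
#' @param weight_meanlog,weight_sdlog Log-normal weight parameters
#'   (defaults 0 and 0.5).
#' @param seed Integer seed.
#' @return An object of class `synthetic_world`: `network`
#'   (a [gene_network] over all genes, isolated ones included), `modules`
#'   (named list of [gene_set]s), `params`, `seed`.
#' @export
synthetic_world <- function(n_modules = 30L, module_size = 25L,
                            p_in = 0.25, p_out = 0.01,
                            n_background = 500L,
                            weight_meanlog = 0, weight_sdlog = 0.5,
                            seed = 1L) {
  stopifnot(n_modules >= 1, module_size >= 4,
            p_in > p_out, p_out >= 0, p_in <= 1,
            n_background >= 0, weight_sdlog >= 0)
  n_total <- n_modules * module_size + n_background
  width <- max(4L, nchar(as.character(n_total)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n_total))
  module_of <- c(rep(seq_len(n_modules), each = module_size),
                 rep(0L, n_background))

  edges <- with_seed(seed, {
    ii <- rep(seq_len(n_total - 1L), (n_total - 1L):1L)
    jj <- sequence((n_total - 1L):1L) + ii
    p_edge <- ifelse(module_of[ii] > 0L & module_of[ii] == module_of[jj],
                     p_in, p_out)
    sel <- stats::runif(length(ii)) < p_edge
    data.frame(g1 = genes[ii[sel]], g2 = genes[jj[sel]],
               w = stats::rlnorm(sum(sel), weight_meanlog, weight_sdlog),
               stringsAsFactors = FALSE)
  })
  if (nrow(edges) == 0L) stop("generated world has no edges; raise p_in/p_out")
  net <- gene_network(edges, genes = genes)

  modules <- lapply(seq_len(n_modules), function(i) {
    gene_set(sprintf("M%02d", i), genes[module_of == i],
             name = sprintf("planted module %d", i))
  })
  names(modules) <- vapply(modules, `[[`, "", "id")

  structure(list(network = net, modules = modules,
                 params = list(n_modules = n_modules,
                               module_size = module_size,
                               p_in = p_in, p_out = p_out,
                               n_background = n_background,
                               weight_meanlog = weight_meanlog,
                               weight_sdlog = weight_sdlog),
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d modules x %d genes + %d background; %d edges (seed %d)\n",
    x$params$n_modules, x$params$module_size, x$params$n_background,
    x$network$n_edges, x$seed))
  invisible(x)
}

new_subset_pair <- function(module_id, regime, query, known, matched = TRUE) {
  structure(list(module_id = module_id, regime = regime,
                 query = query, known = known, matched = matched),
            class = "subset_pair")
}

#' Overlapping subset pair from a module
#'
#' Two independent uniform draws of `ceiling(frac * n)` distinct genes
#' each from the module; overlap between the two draws is allowed (the
#' expected overlap of two independent half draws is about n/4).
#'
#' @param module A [gene_set] with at least 4 members.
#' @param frac Fraction of the module drawn into each subset (default 0.5).
#' @param seed Optional integer seed; `NULL` uses the session RNG.
#' @return A `subset_pair` with `regime = "overlap"`.
#' @export
overlapping_subsets <- function(module, frac = 0.5, seed = NULL) {
  members <- set_members(module)
  n <- length(members)
  stopifnot(n >= 4, frac > 0, frac <= 1)
  size <- ceiling(frac * n)
  with_seed(seed, {
    q <- sample(members, size)
    k <- sample(members, size)
    new_subset_pair(set_id(module), "overlap",
                    gene_set(paste0(set_id(module), "_q"), q),
                    gene_set(paste0(set_id(module), "_k"), k))
  })
}

#' Disjoint halves of a module
#'
#' Random partition into two non-overlapping sets whose sizes differ by at
#' most one and whose union is the module.
#'
#' @param module A [gene_set] with at least 2 members.
#' @param seed Optional integer seed.
#' @return A `subset_pair` with `regime = "disjoint"`.
#' @export
disjoint_halves <- function(module, seed = NULL) {
  members <- set_members(module)
  n <- length(members)
  stopifnot(n >= 2)
  with_seed(seed, {
    perm <- sample(members)
    h <- floor(n / 2)
    new_subset_pair(set_id(module), "disjoint",
                    gene_set(paste0(set_id(module), "_q"), perm[seq_len(h)]),
                    gene_set(paste0(set_id(module), "_k"), perm[(h + 1L):n]))
  })
}

#' Time-split-like asymmetric disjoint split of a module
#'
#' Emulates an annotation time split: the "known" subset holds an earlier,
#' larger fraction of the module and the query holds the remainder, with
#' no overlap. Harder than symmetric halves because the query is small.
#'
#' @param module A [gene_set] with at least 2 members.
#' @param known_frac Fraction assigned to the known subset (default 0.7).
#' @param seed Optional integer seed.
#' @return A `subset_pair` with `regime = "timesplit"`.
#' @export
timesplit_pair <- function(module, known_frac = 0.7, seed = NULL) {
  members <- set_members(module)
  n <- length(members)
  stopifnot(n >= 2, known_frac > 0, known_frac < 1)
  nk <- min(max(1L, round(known_frac * n)), n - 1L)
  with_seed(seed, {
    perm <- sample(members)
    new_subset_pair(set_id(module), "timesplit",
                    gene_set(paste0(set_id(module), "_q"), perm[(nk + 1L):n]),
                    gene_set(paste0(set_id(module), "_k"), perm[seq_len(nk)]))
  })
}

subset_pair_for <- function(module, regime, seed = NULL) {
  switch(regime,
         overlap = overlapping_subsets(module, seed = seed),
         disjoint = disjoint_halves(module, seed = seed),
         timesplit = timesplit_pair(module, seed = seed),
         stop(sprintf("unknown regime '%s'", regime)))
}

centrality_bins <- function(net, n_bins) {
  cent <- net$strength
  rng <- range(cent)
  if (rng[1] == rng[2]) return(rep(1L, length(cent)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  findInterval(cent, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Centrality-matched random gene set
#'
#' Network genes are binned into `n_bins` equally spaced (equal-width)
#' centrality bins; each in-network template member is replaced by a
#' uniform random gene from its bin, without repeats. If a bin cannot
#' supply enough distinct genes, the nearest non-empty bin is used (with a
#' message). The result preserves the template's size and approximate
#' centrality profile while destroying its module structure.
#'
#' @param net A [gene_network].
#' @param template A [gene_set] intersecting the network.
#' @param n_bins Number of centrality bins (default 10; must be >= 2).
#' @param seed Optional integer seed.
#' @return A [gene_set] of the same in-network size as the template.
#' @export
centrality_matched_random_set <- function(net, template, n_bins = 10L,
                                          seed = NULL) {
  stopifnot(n_bins >= 2)
  members <- intersect(set_members(template), net$genes)
  if (length(members) == 0L) {
    stop(sprintf("template set '%s' has no members in the network",
                 set_id(template)))
  }
  bin <- centrality_bins(net, n_bins)
  names(bin) <- net$genes
  with_seed(seed, {
    chosen <- character(0)
    need_by_bin <- table(bin[members])
    for (b in as.integer(names(need_by_bin))) {
      need <- need_by_bin[[as.character(b)]]
      pool <- setdiff(net$genes[bin == b], chosen)
      if (length(pool) < need) {
        # borrow from nearest non-empty bins
        for (dist in seq_len(max(bin))) {
          for (bb in c(b - dist, b + dist)) {
            if (bb < 1L || bb > max(bin)) next
            pool <- union(pool, setdiff(net$genes[bin == bb], chosen))
            if (length(pool) >= need) break
          }
          if (length(pool) >= need) break
        }
        message(sprintf("centrality bin %d exhausted; borrowing from nearby bins", b))
      }
      chosen <- c(chosen, sample(pool, need))
    }
    gene_set(paste0(set_id(template), "_rnd"), chosen,
             name = sprintf("centrality-matched random set for %s",
                            set_id(template)))
  })
}

#' Build a labeled training corpus of subset pairs
#'
#' Positives are matched query/known pairs from each module under the
#' requested regimes. Negatives are, per positive query, `mismatches`
#' known subsets drawn from other modules, plus (optionally) one
#' centrality-matched random set per module paired with a randomly chosen
#' real module — so the negative class also contains set pairs with
#' realistic sizes and centralities but no functional relationship.
#'
#' @param world A [synthetic_world].
#' @param mismatches Mismatched known subsets per query (default 10).
#' @param regimes Character vector of regimes to include.
#' @param random_negatives Include centrality-matched random-set negatives.
#' @param seed Integer seed.
#' @return List with elements `positives` and `negatives`, each a list of
#'   `subset_pair`s.
#' @export
make_training_corpus <- function(world, mismatches = 10L,
                                 regimes = c("overlap", "disjoint", "timesplit"),
                                 random_negatives = TRUE, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"),
            length(world$modules) >= 5L, mismatches >= 1L)
  with_seed(seed, {
    module_ids <- names(world$modules)
    positives <- list()
    for (regime in regimes) {
      for (m in module_ids) {
        pr <- subset_pair_for(world$modules[[m]], regime)
        pr$query$id <- sprintf("%s_%s_q", m, regime)
        pr$known$id <- sprintf("%s_%s_k", m, regime)
        positives[[length(positives) + 1L]] <- pr
      }
    }
    known_by_regime <- split(positives,
                             vapply(positives, `[[`, "", "regime"))

    negatives <- list()
    for (pr in positives) {
      pool <- known_by_regime[[pr$regime]]
      pool <- pool[vapply(pool, `[[`, "", "module_id") != pr$module_id]
      take <- sample(length(pool), min(mismatches, length(pool)))
      for (j in take) {
        negatives[[length(negatives) + 1L]] <-
          new_subset_pair(pr$module_id, pr$regime,
                          pr$query, pool[[j]]$known, matched = FALSE)
      }
    }
    if (random_negatives) {
      for (m in module_ids) {
        template <- world$modules[[m]]
        rnd <- centrality_matched_random_set(world$network, template)
        target <- world$modules[[sample(module_ids, 1L)]]
        negatives[[length(negatives) + 1L]] <-
          new_subset_pair(m, "random", rnd, target, matched = FALSE)
      }
    }
    list(positives = positives, negatives = negatives)
  })
}

#' Feature matrices for a training corpus
#'
#' Computes the 13 combiner features for every pair in the corpus, sharing
#' one diffusion-profile cache across pairs (each distinct gene set is
#' diffused once).
#'
#' @param world A [synthetic_world].
#' @param corpus Output of [make_training_corpus()].
#' @param cfg A [riddle_config].
#' @return List with matrices `positives` and `negatives` (one feature
#'   vector per row).
#' @export
corpus_features <- function(world, corpus, cfg = riddle_config()) {
  cache <- new_profile_cache()
  fmat <- function(pairs) {
    t(vapply(pairs, function(pr) {
      compute_features(world$network, pr$query, pr$known, cfg, cache)
    }, numeric(length(riddle_feature_names))))
  }
  list(positives = fmat(corpus$positives),
       negatives = fmat(corpus$negatives))
}

#' Train a combiner on a synthetic world
#'
#' Convenience wrapper: builds the training corpus, computes its features,
#' and trains the SVM combiner.
#'
#' @param world A [synthetic_world].
#' @param cfg A [riddle_config].
#' @param params A [combiner_params].
#' @param mismatches,regimes,random_negatives Passed to
#'   [make_training_corpus()].
#' @param seed Integer seed (corpus draws and split randomization).
#' @return A trained `riddle_combiner`.
#' @export
train_on_world <- function(world, cfg = riddle_config(),
                           params = combiner_params(),
                           mismatches = 10L,
                           regimes = c("overlap", "disjoint", "timesplit"),
                           random_negatives = TRUE, seed = 1L) {
  corpus <- make_training_corpus(world, mismatches = mismatches,
                                 regimes = regimes,
                                 random_negatives = random_negatives,
                                 seed = seed)
  feats <- corpus_features(world, corpus, cfg)
  train_combiner(feats$positives, feats$negatives, params, seed = seed)
}

# midrank of the correct candidate given candidate scores (higher = better)
midrank_of <- function(scores, correct) {
  rank(-scores, ties.method = "average")[correct]
}

#' Benchmark subset-matching recovery on a synthetic world
#'
#' For each module, draws a query/known pair under `regime`, then ranks
#' every module's known subset against the query by each method: the
#' trained combiner (RAS), the hypergeometric test (ascending p), local
#' extension (ascending reverse-direction p), and reflective diffusion
#' (descending reverse-direction AUC or AP). A module counts as matched
#' only when its own known subset has midrank exactly 1, so methods whose
#' scores are all tied (hypergeometric with zero overlaps) can never
#' register a perfect match.
#'
#' @param world A [synthetic_world].
#' @param model A trained `riddle_combiner`, or `NULL` to skip the
#'   combiner rows.
#' @param regime One of `"overlap"`, `"disjoint"`, `"timesplit"`.
#' @param cfg A [riddle_config].
#' @param seed Integer seed for the subset draws.
#' @return Data frame with one row per method: `regime`, `method`,
#'   `fraction_matched`, `mean_reciprocal_rank`, `n_modules`. Per-module
#'   midranks are attached as attribute `"detail"`.
#' @export
benchmark_recovery <- function(world, model = NULL,
                               regime = c("disjoint", "overlap", "timesplit"),
                               cfg = riddle_config(), seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(inherits(world, "synthetic_world"))
  pairs <- with_seed(seed, lapply(world$modules, subset_pair_for, regime = regime))
  module_ids <- names(world$modules)
  P <- length(pairs)
  cache <- new_profile_cache()

  # features for every query x known candidate
  feats <- vector("list", P)
  for (qi in seq_len(P)) {
    feats[[qi]] <- t(vapply(pairs, function(cand) {
      compute_features(world$network, pairs[[qi]]$query, cand$known,
                       cfg, cache)
    }, numeric(length(riddle_feature_names))))
  }

  method_scores <- function(fm) {
    out <- list(hypergeometric = -exp(fm[, "log_p_hg"]),
                le = -exp(fm[, "log_p_le_rev"]),
                rd_auc = fm[, "auc_rev"],
                rd_ap = fm[, "ap_rev"])
    if (!is.null(model)) out <- c(list(riddle = ras_score(model, fm)), out)
    out
  }

  methods <- names(method_scores(feats[[1L]]))
  detail <- matrix(NA_real_, nrow = P, ncol = length(methods),
                   dimnames = list(module_ids, methods))
  for (qi in seq_len(P)) {
    sc <- method_scores(feats[[qi]])
    for (m in methods) detail[qi, m] <- midrank_of(sc[[m]], qi)
  }

  summary <- data.frame(regime = regime,
                        method = methods,
                        fraction_matched = colMeans(detail == 1),
                        mean_reciprocal_rank = colMeans(1 / detail),
                        n_modules = P,
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  attr(summary, "detail") <- detail
  summary
}

#' Survey AUC/AP confounds with terminal size and centrality
#'
#' Draws random seed sets of fixed size and random terminal sets of
#' varying size and centrality (members sampled around a randomly chosen
#' centrality bin), then measures the recovery AUC and AP of each terminal
#' from a diffusion seeded at the random seed set. Because seeds and
#' terminals are unrelated, any trend in the scores reflects intrinsic
#' properties of the measures: AP grows with terminal size while AUC does
#' not, and AUC grows with terminal centrality.
#'
#' @param net A [gene_network].
#' @param n_tests Number of random seed/terminal pairs (default 150).
#' @param seed_size Size of each random seed set (default 15).
#' @param size_range Integer range of terminal-set sizes (default 10-60).
#' @param n_bins Number of equal-width centrality bins (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `terminal_size`, `terminal_centrality`,
#'   `auc`, `ap` (one row per test).
#' @export
recovery_confound_survey <- function(net, n_tests = 150L, seed_size = 15L,
                                     size_range = c(10L, 60L), n_bins = 10L,
                                     seed = 1L) {
  stopifnot(inherits(net, "gene_network"), n_tests >= 10L,
            size_range[1] >= 2L, size_range[2] >= size_range[1])
  bin <- centrality_bins(net, n_bins)
  names(bin) <- net$genes
  max_bin <- max(bin)
  with_seed(seed, {
    res <- vector("list", n_tests)
    for (t in seq_len(n_tests)) {
      size <- sample(size_range[1]:size_range[2], 1L)
      b <- sample.int(max_bin, 1L)
      # fill the terminal from bin b outward so its centrality tracks b
      terminal <- character(0)
      for (dist in 0:max_bin) {
        cand <- net$genes[abs(bin - b) == dist]
        cand <- setdiff(cand, terminal)
        if (length(cand) > 0L) {
          terminal <- c(terminal,
                        sample(cand, min(length(cand), size - length(terminal))))
        }
        if (length(terminal) >= size) break
      }
      seed_set <- sample(net$genes, seed_size)
      prof <- diffuse(net, seed_set)
      ranking <- rank_genes(prof, exclude_seed = TRUE, retain = terminal)
      res[[t]] <- data.frame(
        terminal_size = length(terminal),
        terminal_centrality = mean(net$strength[terminal]),
        auc = auc_recovery(ranking, terminal),
        ap = ap_recovery(ranking, terminal))
    }
    do.call(rbind, res)
  })
}
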