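# Fixtures are built in code: small deterministic networks for unit tests
# and one memoized default synthetic world + trained combiner shared by the
# heavier end-to-end tests.

# A1..A4 and B1..B4 form two within-module cliques (weight 2); C1..C4 are
# background genes linked to each other in a chain (weight 1). The bridge
# edges connect the B side to A1/A2 with a configurable weight.
two_module_network <- function(bridge_weight = 3, bridge_genes = c("B1", "B2"),
                               bridge_anchors = c("A1", "A2")) {
  clique <- function(genes, w) {
    p <- t(utils::combn(genes, 2L))
    data.frame(g1 = p[, 1L], g2 = p[, 2L], w = w, stringsAsFactors = FALSE)
  }
  chain <- data.frame(g1 = c("C1", "C2", "C3"), g2 = c("C2", "C3", "C4"),
                      w = 1, stringsAsFactors = FALSE)
  bridges <- expand.grid(g1 = bridge_anchors, g2 = bridge_genes,
                         stringsAsFactors = FALSE)
  bridges$w <- bridge_weight
  gene_network(rbind(clique(paste0("A", 1:4), 2),
                     clique(paste0("B", 1:4), 2),
                     chain, bridges))
}

path_network <- function(weights = c(1, 1)) {
  n <- length(weights) + 1L
  genes <- LETTERS[seq_len(n)]
  gene_network(data.frame(g1 = genes[-n], g2 = genes[-1L], w = weights))
}

random_network <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_nodes))
    pairs <- t(utils::combn(n_nodes, 2L))
    sel <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    gene_network(data.frame(g1 = genes[pairs[sel, 1L]],
                            g2 = genes[pairs[sel, 2L]],
                            w = stats::runif(length(sel), 0.5, 2)),
                 genes = genes)
  })
}

# Two well-separated Gaussian clusters in the 13-feature space.
separable_features <- function(n_per_class = 60L, seed = 1L, gap = 6) {
  withr::with_seed(seed, {
    base <- function(shift) {
      m <- matrix(stats::rnorm(n_per_class * 13L), ncol = 13L)
      m <- m + shift
      colnames(m) <- riddle_feature_names
      m
    }
    list(pos = base(0), neg = base(gap))
  })
}

# Memoized heavy fixtures (built on first use only).
.fixture_env <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.fixture_env$world)) {
    .fixture_env$world <- synthetic_world(seed = 101L)
  }
  .fixture_env$world
}

default_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- suppressMessages(
      train_on_world(default_world(), seed = 101L))
  }
  .fixture_env$model
}

# Brute-force hypergeometric tail: enumerate every size-n draw from a
# universe of N genes of which the first m are marked, and count the
# fraction achieving overlap >= k.
enum_tail <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k)
}
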