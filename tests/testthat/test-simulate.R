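test_that("the planted-partition generator is deterministic and respects p_out", {
  w1 <- synthetic_world(n_modules = 4, module_size = 10, n_background = 30,
                        seed = 17)
  w2 <- synthetic_world(n_modules = 4, module_size = 10, n_background = 30,
                        seed = 17)
  expect_identical(network_edges(w1$network), network_edges(w2$network))
  w3 <- synthetic_world(n_modules = 4, module_size = 10, n_background = 30,
                        seed = 18)
  expect_false(identical(network_edges(w1$network), network_edges(w3$network)))

  # p_out = 0 leaves between-module edges absent
  w0 <- synthetic_world(n_modules = 4, module_size = 10, p_in = 0.5,
                        p_out = 0, n_background = 10, seed = 1)
  mod_of <- rep(NA_character_, 50)
  for (m in w0$modules) mod_of[match(m$members, w0$network$genes)] <- m$id
  e <- network_edges(w0$network)
  expect_true(all(mod_of[match(e$gene1, w0$network$genes)] ==
                    mod_of[match(e$gene2, w0$network$genes)]))

  expect_error(synthetic_world(p_in = 0.1, p_out = 0.2))
})

test_that("realized within-module density is within 3 binomial SDs of p_in", {
  w <- default_world()
  p_in <- w$params$p_in
  n_pairs <- choose(w$params$module_size, 2) * w$params$n_modules
  n_within <- 0L
  for (m in w$modules) {
    sub <- w$network$adj[m$members, m$members]
    n_within <- n_within + Matrix::nnzero(sub) / 2
  }
  sd3 <- 3 * sqrt(n_pairs * p_in * (1 - p_in))
  expect_lt(abs(n_within - n_pairs * p_in), sd3)
})

test_that("overlapping draws have the required sizes and expected overlap n/4", {
  module <- gene_set("M", sprintf("g%02d", 1:20))
  pr <- overlapping_subsets(module, seed = 4)
  expect_equal(length(pr$query$members), 10L)
  expect_equal(length(pr$known$members), 10L)
  expect_identical(pr$regime, "overlap")

  # frac = 1 recovers the whole module on both sides
  pr_full <- overlapping_subsets(module, frac = 1, seed = 4)
  expect_setequal(pr_full$query$members, module$members)
  expect_setequal(pr_full$known$members, module$members)

  ov <- withr::with_seed(8, vapply(1:400, function(i) {
    p <- overlapping_subsets(module)
    length(intersect(p$query$members, p$known$members))
  }, numeric(1)))
  expect_lt(abs(mean(ov) - 5), 0.4)  # E = n * frac^2 = 5
})

test_that("disjoint and time-split splits partition the module", {
  module <- gene_set("M", sprintf("g%02d", 1:17))
  withr::with_seed(3, {
    for (i in 1:200) {
      pr <- disjoint_halves(module)
      expect_length(intersect(pr$query$members, pr$known$members), 0)
      expect_setequal(c(pr$query$members, pr$known$members), module$members)
      expect_lte(abs(length(pr$query$members) - length(pr$known$members)), 1)
    }
  })
  pr7 <- disjoint_halves(gene_set("S", letters[1:7]), seed = 2)
  expect_setequal(c(length(pr7$query$members), length(pr7$known$members)),
                  c(3L, 4L))

  ts <- timesplit_pair(module, seed = 5)
  expect_length(intersect(ts$query$members, ts$known$members), 0)
  expect_setequal(c(ts$query$members, ts$known$members), module$members)
  expect_equal(length(ts$known$members), 12L)  # round(0.7 * 17)
  expect_identical(ts$regime, "timesplit")
})

test_that("centrality-matched random sets preserve size and bin structure", {
  w <- default_world()
  net <- w$network
  template <- w$modules[[3]]
  rnd <- centrality_matched_random_set(net, template, seed = 6)
  expect_equal(length(rnd$members),
               length(intersect(template$members, net$genes)))

  bin <- riddler:::centrality_bins(net, 10L)
  names(bin) <- net$genes
  t_bins <- table(factor(bin[intersect(template$members, net$genes)],
                         levels = 1:10))
  r_bins <- table(factor(bin[rnd$members], levels = 1:10))
  expect_equal(as.vector(r_bins), as.vector(t_bins))

  # mean centrality within one bin width of the template's
  bin_width <- diff(range(net$strength)) / 10
  expect_lt(abs(set_centrality(net, rnd) - set_centrality(net, template)),
            bin_width)
})

test_that("the training corpus has the prescribed shape and is reproducible", {
  w <- default_world()
  corpus <- suppressMessages(make_training_corpus(w, seed = 9))
  n_mod <- length(w$modules)
  expect_length(corpus$positives, 3 * n_mod)  # three regimes
  # ten mismatched knowns per query plus one random-set negative per module
  expect_length(corpus$negatives, 10 * 3 * n_mod + n_mod)
  expect_true(all(vapply(corpus$positives, `[[`, TRUE, "matched")))
  expect_false(any(vapply(corpus$negatives, `[[`, TRUE, "matched")))

  # no mismatched pair re-uses the query's own module
  own <- vapply(corpus$negatives, function(pr) {
    pr$regime != "random" &&
      identical(pr$known$id, sprintf("%s_%s_k", pr$module_id, pr$regime))
  }, TRUE)
  expect_false(any(own))

  corpus2 <- suppressMessages(make_training_corpus(w, seed = 9))
  expect_identical(corpus, corpus2)
})

test_that("diffusing from half a module ranks the other half above background", {
  w <- default_world()
  pr <- disjoint_halves(w$modules[[5]], seed = 12)
  prof <- diffuse(w$network, pr$query)
  ranking <- rank_genes(prof, exclude_seed = TRUE,
                        retain = pr$known$members)
  expect_gt(auc_recovery(ranking, pr$known), 0.9)
})

test_that("benchmark summary reports every method with valid fractions", {
  w <- default_world()
  bm <- benchmark_recovery(w, model = NULL, regime = "overlap", seed = 44)
  expect_setequal(bm$method, c("hypergeometric", "le", "rd_auc", "rd_ap"))
  expect_true(all(bm$fraction_matched >= 0 & bm$fraction_matched <= 1))
  expect_true(all(bm$mean_reciprocal_rank > 0 & bm$mean_reciprocal_rank <= 1))
  detail <- attr(bm, "detail")
  expect_equal(dim(detail), c(length(w$modules), 4L))
})
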