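test_that("the 13 features agree with independent single-statistic calls", {
  net <- two_module_network(bridge_weight = 3)
  query <- gene_set("q", c("A1", "A2", "B1", "QQ_out"))  # one out-of-network
  pathway <- gene_set("p", c("B1", "B2", "B3"))
  cfg <- riddle_config()
  fv <- compute_features(net, query, pathway, cfg)

  expect_named(fv, riddle_feature_names)
  N <- length(net$genes)
  expect_equal(unname(fv["query_size"]), 3)
  expect_equal(unname(fv["pathway_size"]), 3)
  expect_equal(unname(fv["overlap_size"]), 1)
  expect_equal(unname(fv["query_coverage"]), 3 / 4)
  expect_equal(unname(fv["query_centrality"]),
               set_centrality(net, query))
  expect_equal(unname(fv["pathway_centrality"]),
               set_centrality(net, pathway))
  expect_equal(unname(fv["log_p_hg"]),
               log(hypergeometric_tail(N, 3, 3, 1)))
  expect_equal(unname(fv["log_p_le_fwd"]),
               log(le_pvalue(net, query, pathway)$p))
  expect_equal(unname(fv["log_p_le_rev"]),
               log(le_pvalue(net, pathway, query)$p))
  rd <- reflective_scores(net, query, pathway)
  expect_equal(unname(fv[c("auc_fwd", "auc_rev", "ap_fwd", "ap_rev")]),
               c(rd$forward$auc, rd$reverse$auc, rd$forward$ap, rd$reverse$ap))
})

test_that("feature computation is symmetric under the forward/reverse exchange", {
  net <- two_module_network(bridge_weight = 3)
  q <- gene_set("q", c("A1", "A2", "A3"))
  p <- gene_set("p", c("B1", "B2", "B3"))
  f_qp <- compute_features(net, q, p)
  f_pq <- compute_features(net, p, q)
  swap <- c(log_p_hg = "log_p_hg",
            log_p_le_fwd = "log_p_le_rev", log_p_le_rev = "log_p_le_fwd",
            auc_fwd = "auc_rev", auc_rev = "auc_fwd",
            ap_fwd = "ap_rev", ap_rev = "ap_fwd",
            query_size = "pathway_size", pathway_size = "query_size",
            overlap_size = "overlap_size",
            query_centrality = "pathway_centrality",
            pathway_centrality = "query_centrality")
  expect_equal(unname(f_qp[names(swap)]), unname(f_pq[unname(swap)]))

  # disjoint sets: zero overlap and p = 1
  expect_equal(unname(f_qp["overlap_size"]), 0)
  expect_equal(unname(f_qp["log_p_hg"]), 0)

  # errors name the offending set
  expect_error(compute_features(net, gene_set("ghost", "ZZ"), p), "ghost")
})

test_that("a separable synthetic corpus trains to perfect validation accuracy", {
  feats <- separable_features(60, seed = 3)
  model <- train_combiner(feats$pos, feats$neg, seed = 5)
  rep <- model$report
  expect_equal(rep$accuracy[rep$split == "validation"], 1.0)
  # positive prototypes score above negative prototypes
  expect_gt(min(ras_score(model, feats$pos)), max(ras_score(model, feats$neg)))
  # deterministic scoring
  expect_identical(ras_score(model, feats$pos[1, ]),
                   ras_score(model, feats$pos[1, ]))
  # scoring refuses a wrong feature dimension
  expect_error(ras_score(model, c(a = 1, b = 2)), "feature")
})

test_that("label-permuted training collapses to the class prior", {
  withr::with_seed(9, {
    pool <- matrix(stats::rnorm(240 * 13), ncol = 13,
                   dimnames = list(NULL, riddle_feature_names))
    idx <- sample(240, 120)
  })
  model <- train_combiner(pool[idx, ], pool[-idx, ],
                          params = combiner_params(cost = 1),
                          seed = 6)
  acc <- model$report$accuracy[model$report$split == "validation"]
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("training validates its inputs", {
  feats <- separable_features(60, seed = 3)
  expect_error(train_combiner(feats$pos[1:5, ], feats$neg), "at least 20")
  bad <- feats$pos
  bad[1, 1] <- NA
  expect_error(train_combiner(bad, feats$neg), "non-finite")
})

test_that("empirical FDR matches hand counts and is monotone after smoothing", {
  pos <- c(2, 3, 4)
  neg <- c(0, 1, 2)
  expect_equal(empirical_fdr(pos, neg, 2), 0.25)   # Nbar=1/3, Pbar=1
  expect_equal(empirical_fdr(pos, neg, -10), 0.5)  # both tails full
  expect_equal(empirical_fdr(pos, neg, 3.5), 0)    # above all negatives
  expect_equal(empirical_fdr(pos, neg, 99), 0)     # above everything

  withr::with_seed(14, {
    pos <- stats::rnorm(200, mean = 1)
    neg <- stats::rnorm(500, mean = -1)
    s <- sort(stats::rnorm(100))
    fdr <- empirical_fdr(pos, neg, s)
    expect_true(all(diff(fdr) <= 1e-12))
    expect_true(all(fdr >= 0 & fdr <= 1))
  })
  expect_error(empirical_fdr(numeric(), neg, 1), "non-empty")
})

test_that("pathway ranking is deterministic, order-invariant, and self-matching", {
  world <- default_world()
  model <- default_model()
  query <- world$modules[[1]]
  lib <- c(world$modules[1:5],
           list(rnd = centrality_matched_random_set(world$network,
                                                    world$modules[[6]],
                                                    seed = 31)))
  res <- rank_pathways(world$network, model, query, lib)
  expect_equal(res$pathway_id[1], "M01")  # identical pathway ranks first
  expect_equal(res$rank, 1:6)
  expect_equal(res$reciprocal_rank[3], 1 / 3)
  # FDR is monotone non-increasing in RAS
  expect_true(all(diff(res$fdr) >= -1e-12))

  res_shuffled <- rank_pathways(world$network, model, query, rev(lib))
  expect_equal(res_shuffled, res)

  # pathways absent from the network are skipped with a message
  lib$ghost <- gene_set("ghost", "NOT_A_GENE")
  expect_message(res2 <- rank_pathways(world$network, model, query, lib),
                 "ghost")
  expect_equal(nrow(res2), 6L)
})

test_that("combiner round-trips through disk with a version check", {
  model <- default_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_combiner(model, path)
  model2 <- load_combiner(path)
  fv <- compute_features(default_world()$network,
                         default_world()$modules[[2]],
                         default_world()$modules[[3]])
  expect_identical(ras_score(model, fv), ras_score(model2, fv))

  broken <- model
  broken$version <- "riddler-combiner/0"
  save_combiner(broken, path)
  expect_error(load_combiner(path), "version|compatible")
})
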