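# The combiner layer: assemble the 13 per-pair features, train the
# class-weighted RBF-SVM, score query-pathway pairs (RAS), attach an
# empirical FDR, and rank a pathway library against a query.

#' Names of the 13 combiner features, in canonical order
#' @export
riddle_feature_names <- c(
  "log_p_hg", "log_p_le_fwd", "log_p_le_rev",
  "auc_fwd", "auc_rev", "ap_fwd", "ap_rev",
  "query_size", "pathway_size", "overlap_size",
  "query_centrality", "pathway_centrality", "query_coverage"
)

#' Scoring configuration
#'
#' @param diffusion A [diffusion_params] object.
#' @param alpha,beta Local-extension cutoff parameters
#'   (see [extension_cutoff()]).
#' @param p_floor Smallest p-value used when taking logs (avoids -Inf
#'   features).
#' @return An object of class `riddle_config`.
#' @export
riddle_config <- function(diffusion = diffusion_params(),
                          alpha = 0.8, beta = 100, p_floor = 1e-300) {
  stopifnot(inherits(diffusion, "diffusion_params"),
            alpha > 0, beta >= 1, p_floor > 0, p_floor <= 1)
  structure(list(diffusion = diffusion, alpha = alpha, beta = beta,
                 p_floor = p_floor),
            class = "riddle_config")
}

#' Create a diffusion-profile cache
#'
#' Profiles are keyed by the sorted in-network seed members, so batch
#' layers that reuse the same sets (benchmarks, training corpora) diffuse
#' each set only once.
#'
#' @return An environment usable as the `cache` argument of
#'   [compute_features()].
#' @export
new_profile_cache <- function() new.env(parent = emptyenv())

cached_profile <- function(cache, net, s, params) {
  if (is.null(cache)) return(diffuse(net, s, params))
  key <- paste(sort(intersect(set_members(s), net$genes)), collapse = "\r")
  if (is.null(cache[[key]])) cache[[key]] <- diffuse(net, s, params)
  cache[[key]]
}

# log tail probability floored at log(p_floor)
log_tail <- function(logp, p_floor) max(logp, log(p_floor))

#' Compute the 13 combiner features for a query-pathway pair
#'
#' Runs the hypergeometric test, forward and reverse local extension
#' (query and pathway extended, respectively), forward and reverse
#' reflective diffusion (AUC and AP each direction), and the five
#' size/centrality/coverage features. Set sizes and overlaps are counted
#' on in-network members; coverage reports the fraction of the original
#' query inside the network.
#'
#' @param net A [gene_network].
#' @param query,pathway [gene_set]s (or character vectors); each must have
#'   at least one in-network member.
#' @param cfg A [riddle_config].
#' @param cache Optional [new_profile_cache()] environment.
#' @return Named numeric vector of length 13 in [riddle_feature_names]
#'   order.
#' @export
compute_features <- function(net, query, pathway, cfg = riddle_config(),
                             cache = NULL) {
  q_members <- set_members(query)
  p_members <- set_members(pathway)
  q_in <- intersect(q_members, net$genes)
  p_in <- intersect(p_members, net$genes)
  if (length(q_in) == 0L) {
    stop(sprintf("query set '%s' has no members in the network", set_id(query)))
  }
  if (length(p_in) == 0L) {
    stop(sprintf("pathway set '%s' has no members in the network", set_id(pathway)))
  }
  N <- length(net$genes)
  k <- length(intersect(q_in, p_in))

  log_p_hg <- log_tail(
    hypergeometric_tail(N, length(p_in), length(q_in), k, log.p = TRUE),
    cfg$p_floor)

  le_fwd <- le_pvalue(net, query, pathway, cfg$alpha, cfg$beta)
  le_rev <- le_pvalue(net, pathway, query, cfg$alpha, cfg$beta)

  prof_q <- cached_profile(cache, net, query, cfg$diffusion)
  prof_p <- cached_profile(cache, net, pathway, cfg$diffusion)
  rd <- reflective_scores(net, query, pathway, cfg$diffusion,
                          profiles = list(a = prof_q, b = prof_p))

  c(log_p_hg = log_p_hg,
    log_p_le_fwd = log_tail(log(le_fwd$p), cfg$p_floor),
    log_p_le_rev = log_tail(log(le_rev$p), cfg$p_floor),
    auc_fwd = rd$forward$auc,
    auc_rev = rd$reverse$auc,
    ap_fwd = rd$forward$ap,
    ap_rev = rd$reverse$ap,
    query_size = length(q_in),
    pathway_size = length(p_in),
    overlap_size = k,
    query_centrality = mean(net$strength[q_in]),
    pathway_centrality = mean(net$strength[p_in]),
    query_coverage = length(q_in) / length(q_members))
}

#' Combiner (SVM) hyperparameters
#'
#' Defaults follow the published model: positive-class weight `w1 = 1`,
#' negative-class weight `w0 = 0.3` (the negative class is much larger),
#' cost `C = 1e9`, termination tolerance `e = 0.01`, radial-basis kernel
#' parameter `gamma = 0.07`, and a modeling / cross-validation / final
#' validation split of 25/25/50.
#'
#' @param w1,w0 Class weights for the matched (positive) and mismatched
#'   (negative) classes.
#' @param cost Soft-margin cost C.
#' @param tolerance Optimizer termination criterion.
#' @param gamma RBF kernel width parameter.
#' @param fractions Named numeric of split fractions `modeling`, `cv`,
#'   `validation`; must sum to 1.
#' @return An object of class `combiner_params`.
#' @export
combiner_params <- function(w1 = 1, w0 = 0.3, cost = 1e9, tolerance = 0.01,
                            gamma = 0.07,
                            fractions = c(modeling = 0.25, cv = 0.25,
                                          validation = 0.5)) {
  stopifnot(w1 > 0, w0 > 0, cost > 0, tolerance > 0, gamma > 0,
            length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  names(fractions) <- c("modeling", "cv", "validation")
  structure(list(w1 = w1, w0 = w0, cost = cost, tolerance = tolerance,
                 gamma = gamma, fractions = fractions),
            class = "combiner_params")
}

# Coerce a list of named feature vectors (or a matrix) to a canonical
# 13-column matrix.
as_feature_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(riddle_feature_names, colnames(x))
    if (length(missing) > 0L) {
      stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
    }
    x <- x[, riddle_feature_names, drop = FALSE]
  } else if (ncol(x) != length(riddle_feature_names)) {
    stop("feature dimension mismatch: expected 13 features")
  } else {
    colnames(x) <- riddle_feature_names
  }
  if (any(!is.finite(x))) stop("non-finite feature value")
  x
}

split_indices <- function(n, fractions) {
  idx <- sample.int(n)
  n_mod <- max(1L, round(fractions[["modeling"]] * n))
  n_cv <- max(1L, round(fractions[["cv"]] * n))
  n_cv <- min(n_cv, n - n_mod - 1L)
  list(modeling = idx[seq_len(n_mod)],
       cv = idx[n_mod + seq_len(n_cv)],
       validation = idx[(n_mod + n_cv + 1L):n])
}

#' Train the RBF-SVM combiner
#'
#' Splits each class into modeling, cross-validation, and final-validation
#' subsets, standardizes features on the modeling split (z-score; the
#' scaling is stored in the model so scoring is reproducible), trains a
#' class-weighted radial-basis SVM on the modeling split, and records
#' per-split classification accuracy plus the final-validation score
#' distributions used for the empirical FDR.
#'
#' @param positives,negatives Feature matrices (or lists of named feature
#'   vectors) for matched and mismatched pairs; at least 20 rows each.
#' @param params A [combiner_params].
#' @param seed Integer seed controlling the split randomization.
#' @return An object of class `riddle_combiner` with elements `svm`,
#'   `center`, `scale`, `sign`, `params`, `report` (per-split metrics),
#'   `val_pos_scores`, `val_neg_scores`, `version`.
#' @importFrom e1071 svm
#' @export
train_combiner <- function(positives, negatives, params = combiner_params(),
                           seed = 1L) {
  pos <- as_feature_matrix(positives)
  neg <- as_feature_matrix(negatives)
  if (nrow(pos) < 20L || nrow(neg) < 20L) {
    stop("need at least 20 examples per class")
  }
  with_seed(seed, {
    sp_pos <- split_indices(nrow(pos), params$fractions)
    sp_neg <- split_indices(nrow(neg), params$fractions)
  })

  x_mod <- rbind(pos[sp_pos$modeling, , drop = FALSE],
                 neg[sp_neg$modeling, , drop = FALSE])
  y_mod <- factor(rep(c("match", "mismatch"),
                      c(length(sp_pos$modeling), length(sp_neg$modeling))),
                  levels = c("match", "mismatch"))
  center <- colMeans(x_mod)
  scale <- apply(x_mod, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1

  standardize <- function(x) scale(x, center = center, scale = scale)

  fit <- e1071::svm(x = standardize(x_mod), y = y_mod,
                    kernel = "radial", gamma = params$gamma,
                    cost = params$cost, tolerance = params$tolerance,
                    class.weights = c(match = params$w1,
                                      mismatch = params$w0),
                    scale = FALSE)

  # orient the decision value so higher = more match-like
  d_mod <- attr(stats::predict(fit, standardize(x_mod),
                               decision.values = TRUE),
                "decision.values")[, 1L]
  sgn <- if (mean(d_mod[y_mod == "match"]) >= mean(d_mod[y_mod == "mismatch"]))
    1 else -1

  model <- structure(list(svm = fit, center = center, scale = scale,
                          sign = sgn, params = params,
                          feature_names = riddle_feature_names,
                          version = "riddler-combiner/1"),
                     class = "riddle_combiner")

  split_metrics <- function(split) {
    x <- rbind(pos[sp_pos[[split]], , drop = FALSE],
               neg[sp_neg[[split]], , drop = FALSE])
    y <- rep(c("match", "mismatch"),
             c(length(sp_pos[[split]]), length(sp_neg[[split]])))
    pred <- as.character(stats::predict(fit, standardize(x)))
    data.frame(split = split,
               n_pos = length(sp_pos[[split]]),
               n_neg = length(sp_neg[[split]]),
               accuracy = mean(pred == y),
               stringsAsFactors = FALSE)
  }
  model$report <- do.call(rbind, lapply(c("modeling", "cv", "validation"),
                                        split_metrics))
  model$val_pos_scores <- ras_score(model, pos[sp_pos$validation, , drop = FALSE])
  model$val_neg_scores <- ras_score(model, neg[sp_neg$validation, , drop = FALSE])
  model
}

#' @export
print.riddle_combiner <- function(x, ...) {
  cat(sprintf("riddle_combiner (%s): gamma=%g cost=%g w1=%g w0=%g\n",
              x$version, x$params$gamma, x$params$cost,
              x$params$w1, x$params$w0))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' RIDDLE association score (RAS) of feature vectors
#'
#' The RAS is the signed decision value of the trained SVM, oriented so
#' higher means more match-like, after applying the model's stored
#' feature standardization.
#'
#' @param model A trained `riddle_combiner`.
#' @param fv A named feature vector, or a matrix with one feature vector
#'   per row.
#' @return Numeric vector of scores.
#' @export
ras_score <- function(model, fv) {
  stopifnot(inherits(model, "riddle_combiner"))
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1L,
                                     dimnames = list(NULL, names(fv)))
  x <- as_feature_matrix(fv)
  xs <- scale(x, center = model$center, scale = model$scale)
  d <- attr(stats::predict(model$svm, xs, decision.values = TRUE),
            "decision.values")[, 1L]
  unname(model$sign * d)
}

#' Empirical false discovery rate at a score threshold
#'
#' With `Pbar(s)` and `Nbar(s)` the fractions of positive and negative
#' validation scores at or above `s` (each distribution area-normalized
#' to 1), the raw FDR is `Nbar / (Nbar + Pbar)`. Finite samples make the
#' raw ratio non-monotone, so it is smoothed by isotonic regression over
#' the pooled score grid to be non-increasing in `s`; values are clamped
#' to \[0, 1\] and the FDR above all scores is 0.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors (e.g. the
#'   final-validation RAS distributions stored in the trained model).
#' @param s Score threshold(s) at which to evaluate the FDR.
#' @return Numeric vector of FDR values in \[0, 1\], same length as `s`.
#' @export
empirical_fdr <- function(pos_scores, neg_scores, s) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score distributions must be non-empty")
  }
  grid <- sort(unique(c(pos_scores, neg_scores)))
  raw <- vapply(grid, function(g) {
    nb <- mean(neg_scores >= g)
    pb <- mean(pos_scores >= g)
    if (nb + pb == 0) 0 else nb / (nb + pb)
  }, numeric(1L))
  # isotonic fit, non-increasing in s
  fitted <- if (length(grid) > 1L) -stats::isoreg(grid, -raw)$yf else raw
  fitted <- pmin(pmax(fitted, 0), 1)
  # fdr(s) is a step function: its value on (grid[i-1], grid[i]] is
  # fitted[i]; below the grid both tails are full; above it the FDR is 0.
  j <- findInterval(s, grid, left.open = TRUE) + 1L
  out <- numeric(length(s))
  inside <- j <= length(grid)
  out[inside] <- fitted[j[inside]]
  out[!inside] <- 0
  out
}

#' Rank a pathway library against a query set
#'
#' Computes the 13 features and the RAS for every pathway in the library,
#' sorts descending by RAS (ties broken by pathway id), and attaches
#' ranks, reciprocal ranks, and the empirical FDR derived from the
#' model's stored final-validation score distributions. Pathways with no
#' in-network member are skipped with a message.
#'
#' @param net A [gene_network].
#' @param model A trained `riddle_combiner`.
#' @param query A [gene_set] (or character vector).
#' @param library Named list of [gene_set]s.
#' @param cfg A [riddle_config].
#' @param cache Optional [new_profile_cache()].
#' @return Data frame with one row per scored pathway: `pathway_id`,
#'   `ras`, `fdr`, `rank`, `reciprocal_rank`, the component p-values and
#'   recovery scores, and the size/centrality/coverage features.
#' @export
rank_pathways <- function(net, model, query, library,
                          cfg = riddle_config(), cache = NULL) {
  stopifnot(length(library) > 0L)
  if (is.null(cache)) cache <- new_profile_cache()
  ids <- vapply(library, set_id, "")
  usable <- vapply(library, function(s) {
    length(intersect(set_members(s), net$genes)) > 0L
  }, logical(1L))
  if (any(!usable)) {
    message(sprintf("skipping %d pathway(s) with no network presence: %s",
                    sum(!usable), paste(ids[!usable], collapse = ", ")))
  }
  library <- library[usable]
  ids <- ids[usable]
  if (length(library) == 0L) stop("no pathway in the library intersects the network")

  feats <- t(vapply(library, function(p) {
    compute_features(net, query, p, cfg, cache)
  }, numeric(length(riddle_feature_names))))
  ras <- ras_score(model, feats)
  fdr <- empirical_fdr(model$val_pos_scores, model$val_neg_scores, ras)

  o <- order(-ras, ids)
  res <- data.frame(pathway_id = ids[o],
                    ras = ras[o],
                    fdr = fdr[o],
                    rank = seq_along(o),
                    reciprocal_rank = 1 / seq_along(o),
                    p_hg = exp(feats[o, "log_p_hg"]),
                    p_le_fwd = exp(feats[o, "log_p_le_fwd"]),
                    p_le_rev = exp(feats[o, "log_p_le_rev"]),
                    feats[o, c("auc_fwd", "auc_rev", "ap_fwd", "ap_rev",
                               "overlap_size", "query_size", "pathway_size",
                               "query_centrality", "pathway_centrality",
                               "query_coverage"), drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Save / load a trained combiner
#'
#' The model file carries a version tag; loading refuses a mismatched
#' version so stale models are never silently scored.
#'
#' @param model A `riddle_combiner`.
#' @param path File path.
#' @return `save_combiner` returns `path` invisibly; `load_combiner`
#'   returns the model.
#' @export
save_combiner <- function(model, path) {
  stopifnot(inherits(model, "riddle_combiner"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_combiner
#' @export
load_combiner <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "riddle_combiner") ||
      !identical(model$version, "riddler-combiner/1")) {
    stop("not a compatible combiner model file")
  }
  model
}
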