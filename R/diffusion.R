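# Network diffusion: random walk with restart over the weighted adjacency,
# the engine behind the reflective-diffusion association statistics.

#' Diffusion parameters
#'
#' @param restart Restart probability in (0, 1]. At each step a fraction
#'   `restart` of the probability mass is re-injected at the seed genes;
#'   larger values keep the profile closer to the seed.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   score vector between iterations.
#' @param max_iter Maximum number of propagation iterations.
#' @param normalization Either `"symmetric"` (D^-1/2 W D^-1/2, the default)
#'   or `"row"` (D^-1 W, a plain random walk).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(restart = 0.5, tol = 1e-9, max_iter = 1000L,
                             normalization = c("symmetric", "row")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(restart), length(restart) == 1L,
            restart > 0, restart <= 1,
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1)
  structure(list(restart = restart, tol = tol,
                 max_iter = as.integer(max_iter),
                 normalization = normalization),
            class = "diffusion_params")
}

# Normalized propagation operator. Zero-degree rows/columns stay zero, so
# isolated genes neither receive nor emit mass.
normalized_adjacency <- function(net, normalization) {
  d <- net$strength
  if (normalization == "symmetric") {
    inv <- ifelse(d > 0, 1 / sqrt(d), 0)
    Matrix::Diagonal(x = inv) %*% net$adj %*% Matrix::Diagonal(x = inv)
  } else {
    Matrix::Diagonal(x = ifelse(d > 0, 1 / d, 0)) %*% net$adj
  }
}

#' Diffuse a seed gene set over the network
#'
#' Iterates the propagation `F <- (1 - restart) * What %*% F + restart * Y`
#' to its fixed point, where `What` is the normalized weight matrix and `Y`
#' places uniform unit mass on the in-network seed genes (1/|seed| each, so
#' profiles are comparable across seed sizes). For `restart > 0` the
#' iteration is a contraction and converges to the unique solution of
#' `(I - (1 - restart) * What) F = restart * Y`.
#'
#' @param net A [gene_network].
#' @param seed A [gene_set] or character vector; at least one member must be
#'   in the network.
#' @param params A [diffusion_params] object.
#' @return An object of class `diffusion_profile`: `scores` (named numeric
#'   over all network genes), `seed_genes` (in-network seed members),
#'   `params`, `iterations`, `residual`, `converged`. Genes in components
#'   disjoint from the seed score exactly 0.
#' @export
diffuse <- function(net, seed, params = diffusion_params()) {
  stopifnot(inherits(net, "gene_network"), inherits(params, "diffusion_params"))
  seed_in <- intersect(set_members(seed), net$genes)
  if (length(seed_in) == 0L) {
    stop(sprintf("seed set '%s' has no members in the network", set_id(seed)))
  }
  n <- length(net$genes)
  W <- normalized_adjacency(net, params$normalization)
  if (params$normalization == "row") W <- Matrix::t(W)

  y <- numeric(n)
  y[match(seed_in, net$genes)] <- 1 / length(seed_in)
  f <- y
  r <- params$restart
  res <- Inf
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    f_new <- as.numeric((1 - r) * (W %*% f) + r * y)
    res <- max(abs(f_new - f))
    f <- f_new
    if (res <= params$tol) break
  }
  converged <- res <= params$tol
  if (!converged) {
    warning(sprintf("diffusion did not converge in %d iterations (residual %.3g)",
                    it, res))
  }
  structure(list(scores = stats::setNames(f, net$genes),
                 seed_genes = seed_in,
                 params = params,
                 iterations = it,
                 residual = res,
                 converged = converged),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("diffusion_profile: %d genes, %d seed genes, %d iterations (residual %.2g)\n",
              length(x$scores), length(x$seed_genes), x$iterations, x$residual))
  invisible(x)
}

#' Rank network genes by diffusion score
#'
#' Sorts genes by descending score; tied scores receive the mean of the
#' ranks they span (midrank), so the recovery AUC computed downstream
#' equals the Mann-Whitney statistic under ties. Isolated or unreachable
#' genes score 0 and tie at the bottom.
#'
#' @param profile A [diffusion_profile].
#' @param exclude_seed If `TRUE` (default), in-network seed genes are
#'   removed before ranking — they are not candidates for recovery.
#' @param retain Character vector of genes to keep in the ranking even when
#'   they are seed genes (used when seed and terminal sets overlap).
#' @return Data frame with columns `gene`, `score`, `rank`, ordered by
#'   descending score then gene id.
#' @export
rank_genes <- function(profile, exclude_seed = TRUE, retain = character()) {
  stopifnot(inherits(profile, "diffusion_profile"))
  sc <- profile$scores
  if (exclude_seed) {
    drop <- setdiff(profile$seed_genes, retain)
    if (length(drop) > 0L) sc <- sc[setdiff(names(sc), drop)]
  }
  if (length(sc) == 0L) stop("no genes left to rank")
  rk <- rank(-sc, ties.method = "average")
  o <- order(-sc, names(sc))
  data.frame(gene = names(sc)[o], score = unname(sc[o]), rank = unname(rk[o]),
             stringsAsFactors = FALSE)
}

#' Write a diffusion profile to TSV (gene, score, rank)
#'
#' @param profile A [diffusion_profile].
#' @param path Output path.
#' @param ... Passed to [rank_genes()].
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, ...) {
  utils::write.table(rank_genes(profile, ...), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
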