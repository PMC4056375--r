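# Network and gene-set containers plus the centrality/coverage primitives
# used by every downstream module. Genes are opaque case-sensitive strings;
# no identifier mapping is performed.

#' Construct a weighted undirected gene network
#'
#' Builds the network object used throughout the package from a three-column
#' edge table. Edge weights are evidence strengths and must be strictly
#' positive. Self-loops are dropped (diffusion and centrality semantics
#' assume none) and duplicate edges keep the maximum weight, so the result
#' is independent of edge listing order.
#'
#' @param edges A data frame whose first three columns are gene, gene,
#'   weight. Additional columns are ignored.
#' @param genes Optional character vector of gene identifiers to include in
#'   the network universe even when isolated (no incident edges). Edge
#'   endpoints are always included.
#' @return An object of class `gene_network` with elements `adj` (symmetric
#'   sparse adjacency matrix of weights), `genes`, `strength` (weighted
#'   degree per gene), `n_edges`, and `self_loops_dropped`.
#' @examples
#' net <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                                w = c(1.5, 2)))
#' centrality(net, "B")
#' @export
gene_network <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges))
  if (ncol(edges) < 3L) stop("edge table needs at least 3 columns: gene, gene, weight")
  g1 <- as.character(edges[[1L]])
  g2 <- as.character(edges[[2L]])
  w <- as.numeric(edges[[3L]])
  if (anyNA(g1) || anyNA(g2) || anyNA(w)) stop("edge table contains missing values")
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive and finite")

  self <- g1 == g2
  n_self <- sum(self)
  if (n_self > 0L) {
    message(sprintf("dropped %d self-loop(s)", n_self))
    g1 <- g1[!self]; g2 <- g2[!self]; w <- w[!self]
  }
  if (length(g1) == 0L) stop("no edges")

  # canonical endpoint order, then max-weight deduplication
  a <- pmin(g1, g2)
  b <- pmax(g1, g2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -w)
  keep <- !duplicated(key[o])
  a <- a[o][keep]; b <- b[o][keep]; w <- w[o][keep]

  gene_ids <- sort(unique(c(a, b, as.character(genes))))
  n <- length(gene_ids)
  ia <- match(a, gene_ids)
  ib <- match(b, gene_ids)
  adj <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = c(w, w),
                              dims = c(n, n),
                              dimnames = list(gene_ids, gene_ids))
  structure(list(adj = adj,
                 genes = gene_ids,
                 strength = stats::setNames(Matrix::colSums(adj), gene_ids),
                 n_edges = length(w),
                 self_loops_dropped = n_self),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges (total weight %.4g)\n",
              length(x$genes), x$n_edges, sum(x$strength) / 2))
  invisible(x)
}

#' Edge table of a gene network
#'
#' @param net A `gene_network`.
#' @return Data frame with columns `gene1`, `gene2`, `weight`, one row per
#'   undirected edge, endpoints in lexicographic order.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  tri <- Matrix::summary(Matrix::triu(net$adj))
  df <- data.frame(gene1 = net$genes[tri$i],
                   gene2 = net$genes[tri$j],
                   weight = tri$x,
                   stringsAsFactors = FALSE)
  df[order(df$gene1, df$gene2), , drop = FALSE]
}

#' Read a weighted edge list
#'
#' Reads a HumanNet-style tab-separated edge list (gene TAB gene TAB weight,
#' no header; lines starting with `#` are ignored). Lines with a
#' non-positive weight are rejected with a message; malformed lines are an
#' error naming the line number.
#'
#' @param path Path to the TSV file.
#' @return A [gene_network].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges")
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("malformed edge line %d: expected 3 tab-separated fields",
                 idx[which(nf < 3L)[1L]]))
  }
  g1 <- vapply(parts, `[[`, "", 1L)
  g2 <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) {
    stop(sprintf("malformed edge line %d: weight is not numeric",
                 idx[which(is.na(w))[1L]]))
  }
  bad <- w <= 0
  if (any(bad)) {
    message(sprintf("rejected %d line(s) with non-positive weight", sum(bad)))
    g1 <- g1[!bad]; g2 <- g2[!bad]; w <- w[!bad]
  }
  if (length(g1) == 0L) stop("no edges")
  gene_network(data.frame(g1 = g1, g2 = g2, w = w, stringsAsFactors = FALSE))
}

#' Write a network as a tab-separated edge list
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  df <- network_edges(net)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param id Unique identifier.
#' @param members Character vector of gene identifiers; duplicates are
#'   removed, order is not meaningful.
#' @param name Human-readable description (defaults to `id`).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(id, members, name = id) {
  id <- as.character(id)
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) stop(sprintf("gene set '%s' has no members", id))
  structure(list(id = id, name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$id, length(x$members)))
  invisible(x)
}

# Accept either a gene_set or a bare character vector of members.
set_members <- function(s) {
  if (inherits(s, "gene_set")) s$members else unique(as.character(s))
}

set_id <- function(s) {
  if (inherits(s, "gene_set")) s$id else "<anonymous>"
}

#' Read gene sets from a GMT file
#'
#' Standard Broad-dialect GMT: one set per line, fields set-id TAB
#' description TAB gene1 TAB gene2 ... Duplicate member genes are removed;
#' a duplicated set id or a line with fewer than three fields is an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_set] objects (names are the set ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no gene sets in GMT file")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields",
                 keep[which(nf < 3L)[1L]]))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene set id '%s'", ids[duplicated(ids)][1L]))
  }
  sets <- lapply(parts, function(p) gene_set(p[[1L]], p[-c(1L, 2L)], name = p[[2L]]))
  stats::setNames(sets, ids)
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$id, s$name, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Weighted-degree centrality of genes
#'
#' Centrality of a gene is the sum of its incident edge weights; isolated
#' genes have centrality 0.
#'
#' @param net A `gene_network`.
#' @param genes Character vector of gene identifiers, or `NULL` for all
#'   network genes.
#' @return Named numeric vector of centralities.
#' @export
centrality <- function(net, genes = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(genes)) return(net$strength)
  genes <- as.character(genes)
  missing <- setdiff(genes, net$genes)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in network: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  net$strength[genes]
}

#' Average centrality of a gene set
#'
#' Mean weighted degree over the set members present in the network;
#' members outside the network are excluded from the mean.
#'
#' @param net A `gene_network`.
#' @param s A [gene_set] or character vector of members.
#' @return Scalar average centrality.
#' @export
set_centrality <- function(net, s) {
  members <- intersect(set_members(s), net$genes)
  if (length(members) == 0L) {
    stop(sprintf("gene set '%s' has no members in the network", set_id(s)))
  }
  mean(net$strength[members])
}

#' Fraction of a gene set covered by the network
#'
#' @param net A `gene_network`.
#' @param s A [gene_set] or character vector of members.
#' @return Fraction in \[0, 1\] of set members present in the network.
#' @export
network_coverage <- function(net, s) {
  members <- set_members(s)
  if (length(members) == 0L) stop("empty gene set")
  mean(members %in% net$genes)
}
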