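#' Construct a probabilistic functional network
#'
#' A `fnet` is an undirected graph over gene-product identifiers whose edges
#' carry positive real weights — log-likelihood scores (LLS) in the
#' YeastNet/AraNet convention, where larger scores mean more confident
#' functional linkage. Edges are stored once per unordered pair, self-loops
#' are rejected, and weights must be strictly positive.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `lls` (or any
#'   three columns in that order). Duplicate rows for the same unordered pair
#'   with identical weight are collapsed with a warning; duplicates with
#'   conflicting weights are an error.
#' @param nodes Optional character vector of node identifiers; the node set is
#'   the union of these with all edge endpoints, so isolated nodes can be
#'   represented.
#' @return An object of class `fnet`: a list with elements `edges` (a tibble
#'   with columns `gene_a`, `gene_b`, `lls`, endpoints ordered so that
#'   `gene_a < gene_b`) and `nodes` (sorted character vector).
#' @examples
#' net <- fnet(data.frame(gene_a = c("g1", "g2"), gene_b = c("g2", "g3"),
#'                        lls = c(2.5, 1.0)))
#' net
#' @export
fnet <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 3) {
    abort("`edges` needs three columns: gene_a, gene_b, lls.")
  }
  edges <- stats::setNames(edges[, 1:3], c("gene_a", "gene_b", "lls"))
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$lls <- as.numeric(edges$lls)

  if (any(is.na(edges$lls))) {
    abort("Edge weights contain missing/non-numeric values.")
  }
  if (any(edges$lls <= 0)) {
    bad <- which(edges$lls <= 0)[1]
    abort(sprintf(
      "Edge weights must be strictly positive (scores > 0 denote functional linkage); row %d has lls = %g.",
      bad, edges$lls[bad]
    ))
  }
  if (any(edges$gene_a == edges$gene_b)) {
    bad <- which(edges$gene_a == edges$gene_b)[1]
    abort(sprintf("Self-loop on node '%s' (row %d) is not allowed.", edges$gene_a[bad], bad))
  }

  # canonical unordered representation
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b

  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    w_first <- edges$lls[match(key, key)]
    conflict <- dup & edges$lls != w_first
    if (any(conflict)) {
      i <- which(conflict)[1]
      abort(sprintf(
        "Conflicting duplicate edge %s--%s: weights %g and %g.",
        edges$gene_a[i], edges$gene_b[i], w_first[i], edges$lls[i]
      ))
    }
    warn(sprintf("Dropped %d duplicate edge row(s) with identical weights.", sum(dup)))
    edges <- edges[!dup, ]
  }

  nodes <- sort(unique(c(as.character(nodes), edges$gene_a, edges$gene_b)))
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  structure(list(edges = edges, nodes = nodes), class = "fnet")
}

#' @export
print.fnet <- function(x, ...) {
  cat(sprintf(
    "<fnet> %d nodes, %d edges (lls range %s)\n",
    length(x$nodes), nrow(x$edges),
    if (nrow(x$edges)) sprintf("%.3g-%.3g", min(x$edges$lls), max(x$edges$lls)) else "NA"
  ))
  invisible(x)
}

#' @export
format.fnet <- function(x, ...) {
  sprintf("<fnet: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

is_fnet <- function(x) inherits(x, "fnet")

assert_fnet <- function(x) {
  if (!is_fnet(x)) abort("Expected a `fnet` network object.")
  invisible(x)
}

#' Convert a functional network to an igraph graph
#'
#' The edge weight is carried in the `weight` edge attribute, so igraph's
#' weighted routines apply directly.
#'
#' @param net A [fnet] object.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  assert_fnet(net)
  igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

# Adjacency in index space: returns list(adj = list of integer neighbor
# indices, w = parallel list of weights), over `net$nodes` order.
adjacency_index <- function(net) {
  n <- length(net$nodes)
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  w <- net$edges$lls
  from <- c(ia, ib)
  to <- c(ib, ia)
  ww <- c(w, w)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; ww <- ww[ord]
  adj <- vector("list", n)
  wl <- vector("list", n)
  if (length(from)) {
    splits <- split(seq_along(from), factor(from, levels = seq_len(n)))
    for (i in seq_len(n)) {
      idx <- splits[[i]]
      adj[[i]] <- to[idx]
      wl[[i]] <- ww[idx]
    }
  } else {
    for (i in seq_len(n)) {
      adj[[i]] <- integer(0)
      wl[[i]] <- numeric(0)
    }
  }
  list(adj = adj, w = wl)
}
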