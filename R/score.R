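# Precompute the index-space representation the optimizers and scorers share:
# the uncharacterized node list, the field matrix h (uncharacterized x term),
# and the uncharacterized-uncharacterized edge arrays.
build_problem <- function(net, ann, alphabet = NULL) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  alphabet <- sort(unique(as.character(alphabet)))
  unchar <- uncharacterized(net, ann)
  char <- characterized(net, ann)
  n_u <- length(unchar)
  K <- length(alphabet)

  e <- net$edges
  dir <- tibble::tibble(
    node = c(e$gene_a, e$gene_b),
    nbr = c(e$gene_b, e$gene_a),
    w = c(e$lls, e$lls)
  )

  h <- matrix(0, nrow = n_u, ncol = K, dimnames = list(unchar, alphabet))
  if (n_u > 0 && K > 0 && nrow(dir) > 0) {
    fld <- dir[dir$node %in% unchar & dir$nbr %in% char, ]
    if (nrow(fld)) {
      fld <- dplyr::inner_join(fld, tibble::as_tibble(ann), by = c(nbr = "gene"),
                               relationship = "many-to-many")
      fld <- fld[fld$term %in% alphabet, ]
      if (nrow(fld)) {
        agg <- dplyr::summarise(
          dplyr::group_by(fld, .data$node, .data$term),
          w = sum(.data$w), .groups = "drop"
        )
        h[cbind(match(agg$node, unchar), match(agg$term, alphabet))] <- agg$w
      }
    }
  }

  both_u <- e$gene_a %in% unchar & e$gene_b %in% unchar
  uu <- e[both_u, ]

  list(
    nodes = net$nodes,
    unchar = unchar,
    char = char,
    alphabet = alphabet,
    h = h,
    uu_i = match(uu$gene_a, unchar),
    uu_j = match(uu$gene_b, unchar),
    uu_w = uu$lls
  )
}

#' Neighbor field of a node
#'
#' For a node \eqn{i}, the field \eqn{h_i(f)} is the summed weight of edges
#' linking \eqn{i} to characterized neighbors annotated with function
#' \eqn{f}. A multi-label neighbor contributes its full edge weight to each
#' of its terms; terms carried by no neighbor map to 0.
#'
#' @param net A [fnet] network.
#' @param ann An [annotation_map] (or a gene/term data frame).
#' @param node A node identifier present in the network.
#' @param alphabet Optional term alphabet; defaults to the terms in `ann`.
#' @return A tibble with columns `term` and `field`, one row per alphabet
#'   term, sorted by decreasing `field` then term.
#' @export
neighbor_field <- function(net, ann, node, alphabet = NULL) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (length(node) != 1 || !node %in% net$nodes) {
    abort(sprintf("Node '%s' is not in the network.", as.character(node)[1]))
  }
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  alphabet <- sort(unique(as.character(alphabet)))
  e <- net$edges
  hit_a <- e$gene_a == node
  hit_b <- e$gene_b == node
  nbr <- c(e$gene_b[hit_a], e$gene_a[hit_b])
  w <- c(e$lls[hit_a], e$lls[hit_b])
  df <- tibble::tibble(gene = nbr, w = w)
  df <- dplyr::inner_join(df, tibble::as_tibble(ann), by = "gene",
                          relationship = "many-to-many")
  df <- df[df$term %in% alphabet, ]
  field <- stats::setNames(numeric(length(alphabet)), alphabet)
  if (nrow(df)) {
    agg <- tapply(df$w, factor(df$term, levels = alphabet), sum, default = 0)
    field[names(agg)] <- agg
  }
  out <- tibble::tibble(term = alphabet, field = as.numeric(field))
  dplyr::arrange(out, dplyr::desc(.data$field), .data$term)
}

#' Evaluate the weighted Potts score of a function assignment
#'
#' The objective extends the edge-counting assignment score to weighted
#' networks: it sums, over all edges joining same-labelled gene products, the
#' edge log-likelihood scores. The pair term covers edges between two
#' uncharacterized nodes whose assigned labels agree; the field term sums
#' each node's neighbor field \eqn{h_i(\sigma_i)} at its assigned label
#' (edges to characterized nodes sharing the label).
#'
#' @param net A [fnet] network.
#' @param ann An [annotation_map]; its genes are the characterized nodes.
#' @param assignment A data frame with columns `gene`, `term`: exactly one
#'   label per uncharacterized node.
#' @return A one-row tibble with columns `pair_term`, `field_term`, `total`.
#' @examples
#' net <- fnet(data.frame(a = c("u1", "u1", "u2"), b = c("u2", "a1", "a2"),
#'                        w = c(2, 3, 1)))
#' ann <- annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f2")))
#' weighted_score(net, ann, data.frame(gene = c("u1", "u2"), term = c("f1", "f1")))
#' @export
weighted_score <- function(net, ann, assignment) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  assignment <- tibble::as_tibble(assignment)
  if (!all(c("gene", "term") %in% names(assignment))) {
    names(assignment)[1:2] <- c("gene", "term")
  }
  unchar <- uncharacterized(net, ann)
  if (anyDuplicated(assignment$gene)) {
    abort("`assignment` must give exactly one label per gene.")
  }
  if (!setequal(assignment$gene, unchar)) {
    abort("`assignment` must cover exactly the uncharacterized node set.")
  }
  alphabet <- sort(unique(c(function_alphabet(ann), assignment$term)))
  prob <- build_problem(net, ann, alphabet)
  lab <- match(assignment$term[match(prob$unchar, assignment$gene)], prob$alphabet)
  score_breakdown(prob, lab)
}

# prob: build_problem() output; lab: integer labels (into prob$alphabet)
# aligned with prob$unchar
score_breakdown <- function(prob, lab) {
  pair <- if (length(prob$uu_w)) {
    sum(prob$uu_w[lab[prob$uu_i] == lab[prob$uu_j]])
  } else 0
  field <- if (length(lab)) sum(prob$h[cbind(seq_along(lab), lab)]) else 0
  tibble::tibble(pair_term = pair, field_term = field, total = pair + field)
}
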