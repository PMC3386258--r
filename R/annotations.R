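#' Construct an annotation map
#'
#' An annotation map assigns each characterized gene product a non-empty set
#' of function terms from one Gene Ontology domain (GO slim terms in the
#' intended use). It is stored tidily as one row per (gene, term) pair.
#'
#' @param assignments A data frame with columns `gene` and `term` (or any two
#'   columns in that order). Duplicate rows collapse (set semantics).
#' @param ontology Optional ontology tag, conventionally one of `"CC"`,
#'   `"BP"`, `"MF"`. Stored as an attribute; `NA` when unknown.
#' @return A tibble of class `annotation_map` with columns `gene`, `term`.
#' @examples
#' ann <- annotation_map(data.frame(gene = c("g1", "g1", "g2"),
#'                                  term = c("f1", "f2", "f1")), "BP")
#' annotated_genes(ann)
#' @export
annotation_map <- function(assignments, ontology = NA_character_) {
  df <- tibble::as_tibble(assignments)
  if (ncol(df) < 2) abort("`assignments` needs two columns: gene, term.")
  df <- stats::setNames(df[, 1:2], c("gene", "term"))
  df$gene <- as.character(df$gene)
  df$term <- as.character(df$term)
  if (any(is.na(df$gene) | df$gene == "")) abort("Empty gene identifier in annotations.")
  if (any(is.na(df$term) | df$term == "")) abort("Empty term identifier in annotations.")
  df <- dplyr::distinct(df)
  df <- dplyr::arrange(df, .data$gene, .data$term)
  if (length(ontology) != 1) abort("`ontology` must be a single tag.")
  structure(df, class = c("annotation_map", class(tibble::tibble()))) -> out
  attr(out, "ontology") <- as.character(ontology)
  out
}

is_annotation_map <- function(x) inherits(x, "annotation_map")

as_annotation_map <- function(x, ontology = NA_character_) {
  if (is_annotation_map(x)) x else annotation_map(x, ontology)
}

#' @export
print.annotation_map <- function(x, ...) {
  ont <- attr(x, "ontology")
  cat(sprintf(
    "<annotation_map%s> %d genes, %d terms, %d (gene, term) pairs\n",
    if (is.na(ont)) "" else paste0(" ", ont),
    dplyr::n_distinct(x$gene), dplyr::n_distinct(x$term), nrow(x)
  ))
  NextMethod()
}

#' Genes carrying at least one annotation
#'
#' @param ann An [annotation_map].
#' @return Sorted character vector of annotated gene identifiers.
#' @export
annotated_genes <- function(ann) {
  sort(unique(ann$gene))
}

#' The function alphabet of an annotation map
#'
#' @param ann An [annotation_map].
#' @return Sorted character vector of distinct function terms.
#' @export
function_alphabet <- function(ann) {
  sort(unique(ann$term))
}

#' Characterized and uncharacterized nodes of a network
#'
#' The network's node set is partitioned into characterized nodes (present in
#' the annotation map) and uncharacterized nodes (absent from it). Annotated
#' genes that do not appear in the network are retained in the map but are
#' not part of either partition; they can never influence scoring.
#'
#' @param net A [fnet] network.
#' @param ann An [annotation_map].
#' @return Sorted character vector of node identifiers.
#' @export
characterized <- function(net, ann) {
  assert_fnet(net)
  intersect(net$nodes, unique(ann$gene))
}

#' @rdname characterized
#' @export
uncharacterized <- function(net, ann) {
  assert_fnet(net)
  setdiff(net$nodes, unique(ann$gene))
}

# gene -> character vector of terms, as a named list
term_sets <- function(ann) {
  split(ann$term, ann$gene)
}
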