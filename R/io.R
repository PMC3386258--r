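#' Read a probabilistic functional network edge list
#'
#' Reads the tab-separated edge-list dialect distributed with YeastNet and
#' AraNet: one edge per line, columns `gene_a`, `gene_b`, `lls`
#' (log-likelihood score, strictly positive). Lines starting with `#` and
#' blank lines are skipped. Extra columns beyond the third are ignored.
#'
#' @param path Path to the edge-list file.
#' @return A [fnet] network.
#' @seealso [write_pfn()], [read_annotations()]
#' @export
read_pfn <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(fnet(tibble::tibble(gene_a = character(), gene_b = character(), lls = numeric())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(sprintf("Parse error at line %d of %s: expected >= 3 tab-separated fields, got %d.",
                  lineno[bad], path, nf[bad]))
  }
  ga <- vapply(parts, `[[`, "", 1)
  gb <- vapply(parts, `[[`, "", 2)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (any(is.na(w))) {
    bad <- which(is.na(w))[1]
    abort(sprintf("Parse error at line %d of %s: third field is not a number.",
                  lineno[bad], path))
  }
  fnet(tibble::tibble(gene_a = ga, gene_b = gb, lls = w))
}

#' Write a network in the PFN edge-list dialect
#'
#' @param net A [fnet] network.
#' @param path Output file path.
#' @return `path`, invisibly. Isolated nodes are not representable in an edge
#'   list and are dropped with a warning.
#' @export
write_pfn <- function(net, path) {
  assert_fnet(net)
  iso <- setdiff(net$nodes, unique(c(net$edges$gene_a, net$edges$gene_b)))
  if (length(iso)) {
    warn(sprintf("%d isolated node(s) cannot be represented in an edge list and were dropped.",
                 length(iso)))
  }
  lines <- sprintf("%s\t%s\t%.15g", net$edges$gene_a, net$edges$gene_b, net$edges$lls)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Reads a tab-separated table with one (gene, GO-slim term) pair per row;
#' rows sharing a gene accumulate into that gene's term set. Lines starting
#' with `#` and blank lines are skipped.
#'
#' @param path Path to the annotation table.
#' @param ontology Ontology tag (`"CC"`, `"BP"`, `"MF"`, or anything else
#'   meaningful to the caller).
#' @return An [annotation_map].
#' @export
read_annotations <- function(path, ontology = NA_character_) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(annotation_map(tibble::tibble(gene = character(), term = character()), ontology))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- which(nf < 2)[1]
    abort(sprintf("Parse error at line %d of %s: expected >= 2 tab-separated fields, got %d.",
                  lineno[bad], path, nf[bad]))
  }
  gene <- vapply(parts, `[[`, "", 1)
  term <- vapply(parts, `[[`, "", 2)
  if (any(term == "")) {
    bad <- which(term == "")[1]
    abort(sprintf("Parse error at line %d of %s: empty term field.", lineno[bad], path))
  }
  annotation_map(tibble::tibble(gene = gene, term = term), ontology)
}

#' Write an annotation table
#'
#' @param ann An [annotation_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  writeLines(sprintf("%s\t%s", ann$gene, ann$term), path)
  invisible(path)
}

#' Summarize a network and its annotation state
#'
#' Counts nodes and edges, summarizes the weight distribution, partitions the
#' node set into characterized/uncharacterized under `ann`, and tabulates
#' per-term annotation frequencies. Term frequencies sum to the total number
#' of (gene, term) pairs among network nodes.
#'
#' @param net A [fnet] network.
#' @param ann Optional [annotation_map]; when omitted every node is
#'   uncharacterized.
#' @return A list of class `pfn_summary` with fields `n_nodes`, `n_edges`,
#'   `lls_min`, `lls_max`, `lls_mean`, `n_characterized`, `n_uncharacterized`,
#'   and `term_freq` (tibble with columns `term`, `n`).
#' @export
network_summary <- function(net, ann = NULL) {
  assert_fnet(net)
  w <- net$edges$lls
  if (is.null(ann)) {
    ann <- annotation_map(tibble::tibble(gene = character(), term = character()))
  }
  in_net <- ann[ann$gene %in% net$nodes, ]
  term_freq <- dplyr::count(tibble::as_tibble(in_net), .data$term, name = "n")
  out <- list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    lls_min = if (length(w)) min(w) else NA_real_,
    lls_max = if (length(w)) max(w) else NA_real_,
    lls_mean = if (length(w)) mean(w) else NA_real_,
    n_characterized = length(characterized(net, ann)),
    n_uncharacterized = length(uncharacterized(net, ann)),
    term_freq = term_freq
  )
  class(out) <- "pfn_summary"
  out
}

#' @export
print.pfn_summary <- function(x, ...) {
  cat(sprintf("Probabilistic functional network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  LLS weights: min %.4g / mean %.4g / max %.4g\n", x$lls_min, x$lls_mean, x$lls_max))
  cat(sprintf("  Characterized nodes: %d; uncharacterized: %d\n",
              x$n_characterized, x$n_uncharacterized))
  if (nrow(x$term_freq)) {
    cat(sprintf("  %d function terms; top terms:\n", nrow(x$term_freq)))
    top <- head(dplyr::arrange(x$term_freq, dplyr::desc(.data$n)), 5)
    for (i in seq_len(nrow(top))) cat(sprintf("    %s: %d\n", top$term[i], top$n[i]))
  }
  invisible(x)
}
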