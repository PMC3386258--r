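#' Specify a planted-module synthetic network
#'
#' Describes a planted-partition generator that emulates a probabilistic
#' functional network with ground-truth annotations: nodes are partitioned
#' into functional modules, within-module pairs are connected with
#' probability `p_in` and weights drawn from `weight_in`, between-module
#' pairs with probability `p_out` and weights from `weight_out`. Every node
#' is annotated with its module's function term, plus one uniformly random
#' extra term with probability `multi_label_rate` (emulating multi-label GO
#' slim annotation). Default weight samplers are log-normal with medians 2.0
#' (within) and 0.5 (between), mimicking the positive right-skewed LLS scale.
#'
#' @param n_nodes Number of nodes.
#' @param n_functions Number of modules / function terms.
#' @param module_sizes Optional integer vector of module sizes summing to
#'   `n_nodes`; equal split (remainder spread over the first modules) when
#'   omitted.
#' @param p_in,p_out Within- and between-module edge probabilities in
#'   \eqn{[0,1]}.
#' @param weight_in,weight_out Functions of `n` returning `n` strictly
#'   positive weights.
#' @param multi_label_rate Probability a node carries a second, uniformly
#'   chosen function term.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_planted_network()]
#' @export
synthetic_spec <- function(n_nodes = 500L,
                           n_functions = 5L,
                           module_sizes = NULL,
                           p_in = 0.2,
                           p_out = 0.02,
                           weight_in = function(n) rlnorm(n, meanlog = log(2.0), sdlog = 0.5),
                           weight_out = function(n) rlnorm(n, meanlog = log(0.5), sdlog = 0.5),
                           multi_label_rate = 0.2) {
  n_nodes <- as.integer(n_nodes)
  n_functions <- as.integer(n_functions)
  if (n_nodes < 1) abort("`n_nodes` must be positive.")
  if (n_functions < 1) abort("`n_functions` must be positive.")
  if (n_functions > n_nodes) abort("Infeasible spec: more functions than nodes.")
  if (is.null(module_sizes)) {
    base <- n_nodes %/% n_functions
    module_sizes <- rep(base, n_functions)
    extra <- n_nodes - sum(module_sizes)
    if (extra > 0) module_sizes[seq_len(extra)] <- module_sizes[seq_len(extra)] + 1L
  }
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) != n_functions) {
    abort("`module_sizes` must have one entry per function.")
  }
  if (any(module_sizes < 1) || sum(module_sizes) != n_nodes) {
    abort("`module_sizes` must be positive and sum to `n_nodes`.")
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    abort("`p_in` and `p_out` must lie in [0, 1].")
  }
  if (multi_label_rate < 0 || multi_label_rate > 1) {
    abort("`multi_label_rate` must lie in [0, 1].")
  }
  structure(
    list(
      n_nodes = n_nodes, n_functions = n_functions, module_sizes = module_sizes,
      p_in = p_in, p_out = p_out,
      weight_in = weight_in, weight_out = weight_out,
      multi_label_rate = multi_label_rate
    ),
    class = "synthetic_spec"
  )
}

#' Generate a planted-module network with ground-truth annotations
#'
#' Samples a network and full annotation map from a [synthetic_spec]. The
#' output is reproducible: the same `spec` and `seed` give identical results.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer seed for all sampling.
#' @return A list with elements `network` (a [fnet]), `annotations` (an
#'   [annotation_map] covering every node), and `modules` (tibble with
#'   columns `gene`, `module` giving the planted partition).
#' @examples
#' sim <- generate_planted_network(synthetic_spec(n_nodes = 30, n_functions = 3), seed = 1)
#' sim$network
#' @export
generate_planted_network <- function(spec, seed) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a `synthetic_spec`.")
  n <- spec$n_nodes
  genes <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  terms <- sprintf("f%02d", seq_len(spec$n_functions))
  module <- rep(seq_len(spec$n_functions), times = spec$module_sizes)

  with_seed(seed, {
    # enumerate unordered pairs once; partition by within/between module
    if (n >= 2L) {
      pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
      pair_j <- sequence((n - 1L):1L, from = 2L:n)
    } else {
      pair_i <- integer(0)
      pair_j <- integer(0)
    }
    within <- module[pair_i] == module[pair_j]

    keep_in <- which(within)[runif(sum(within)) < spec$p_in]
    keep_out <- which(!within)[runif(sum(!within)) < spec$p_out]
    w_in <- spec$weight_in(length(keep_in))
    w_out <- spec$weight_out(length(keep_out))
    if (any(c(w_in, w_out) <= 0)) abort("Weight samplers must return strictly positive values.")

    edges <- tibble::tibble(
      gene_a = genes[c(pair_i[keep_in], pair_i[keep_out])],
      gene_b = genes[c(pair_j[keep_in], pair_j[keep_out])],
      lls = c(w_in, w_out)
    )
    net <- fnet(edges, nodes = genes)

    primary <- tibble::tibble(gene = genes, term = terms[module])
    extra_mask <- runif(n) < spec$multi_label_rate
    extra <- tibble::tibble(
      gene = genes[extra_mask],
      term = terms[sample.int(spec$n_functions, sum(extra_mask), replace = TRUE)]
    )
    ann <- annotation_map(dplyr::bind_rows(primary, extra))

    list(
      network = net,
      annotations = ann,
      modules = tibble::tibble(gene = genes, module = module)
    )
  })
}

#' Mask the annotations of a random fraction of genes
#'
#' Implements the clearing step of leave-a-percent-out cross-validation:
#' exactly `round(fraction * n_annotated)` genes (round half-up, so replicate
#' counts are platform-stable) are chosen uniformly at random and lose all
#' their annotations at once. The removed truth is returned alongside the
#' masked map, and the two partition the original map exactly.
#'
#' @param ann An [annotation_map].
#' @param fraction Fraction of annotated genes to clear, in \eqn{(0, 1]}.
#' @param seed Integer seed controlling the mask.
#' @return A list with `masked` (an [annotation_map]) and `truth` (tibble
#'   with columns `gene`, `term` covering exactly the cleared genes).
#' @export
clear_annotations <- function(ann, fraction, seed) {
  ann <- as_annotation_map(ann)
  if (!nrow(ann)) abort("`ann` is empty; nothing to clear.")
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1].")
  }
  genes <- annotated_genes(ann)
  n_clear <- as.integer(floor(fraction * length(genes) + 0.5))  # half-up
  cleared <- with_seed(seed, sort(sample(genes, n_clear)))
  keep <- !(ann$gene %in% cleared)
  masked <- annotation_map(tibble::as_tibble(ann)[keep, ], attr(ann, "ontology"))
  truth <- tibble::as_tibble(ann)[!keep, ]
  class(truth) <- class(tibble::tibble())
  list(masked = masked, truth = truth, cleared = cleared)
}
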