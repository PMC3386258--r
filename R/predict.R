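#' Construct a prediction set
#'
#' The common output contract of all six algorithms: per target node, an
#' ordered list of (function term, score), descending by score. Stored tidily
#' as one row per (gene, term) pair with a `rank` column.
#'
#' @param df Data frame with columns `gene`, `term`, `score`.
#' @param algorithm Character tag naming the producing algorithm.
#' @param params List of provenance (config, seed); stored as an attribute.
#' @return A tibble of class `prediction_set`, sorted within gene by
#'   decreasing score (term as tie-break).
#' @export
prediction_set <- function(df, algorithm = "unknown", params = list()) {
  df <- tibble::as_tibble(df)
  if (!all(c("gene", "term", "score") %in% names(df))) {
    abort("A prediction set needs columns gene, term, score.")
  }
  df <- dplyr::arrange(df, .data$gene, dplyr::desc(.data$score), .data$term)
  df <- dplyr::mutate(dplyr::group_by(df, .data$gene), rank = dplyr::row_number())
  df <- dplyr::ungroup(df)
  out <- structure(df, class = c("prediction_set", class(tibble::tibble())))
  attr(out, "algorithm") <- algorithm
  attr(out, "params") <- params
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set: %s> %d genes, %d scored (gene, term) pairs\n",
              attr(x, "algorithm"), dplyr::n_distinct(x$gene), nrow(x)))
  NextMethod()
}

# drop the prediction_set class/attrs for plain tibble work
as_plain_tibble <- function(x) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  attr(out, "algorithm") <- NULL
  attr(out, "params") <- NULL
  out
}

# Ensemble consensus over annealing restarts: run n_restarts chains, then
# score each (node, term) by the fraction of restarts assigning it.
consensus_predict <- function(prob, cfg, algorithm) {
  n <- length(prob$unchar)
  if (n == 0) {
    return(prediction_set(
      tibble::tibble(gene = character(), term = character(), score = numeric()),
      algorithm, list(config = cfg)
    ))
  }
  if (length(prob$alphabet) == 0) abort("`alphabet` must be non-empty.")
  labels <- matrix(0L, nrow = n, ncol = cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    res <- run_chain(prob, cfg, derive_seed(cfg$seed, r))
    labels[, r] <- res$best_labels
  }
  counts <- tibble::tibble(
    gene = rep(prob$unchar, times = cfg$n_restarts),
    term = prob$alphabet[as.vector(labels)]
  )
  votes <- dplyr::count(counts, .data$gene, .data$term, name = "n_runs")
  votes$score <- votes$n_runs / cfg$n_restarts
  prediction_set(votes[, c("gene", "term", "score")], algorithm, list(config = cfg))
}

#' Predict functions with the Weighted Network Predictor
#'
#' Runs `config$n_restarts` independent generalized-simulated-annealing
#' maximizations of the weighted score and pools them by consensus: each
#' function's confidence at a node is the fraction of restarts whose best
#' assignment gave the node that function, so per-node confidences sum to 1.
#' Multi-label predictions arise when restarts disagree (near-optimal
#' alternative labellings).
#'
#' @inheritParams gsa_optimize
#' @return A [prediction_set] with algorithm tag `"wnp"`.
#' @examples
#' net <- fnet(data.frame(a = c("u1", "u1", "u2"), b = c("u2", "a1", "a2"),
#'                        w = c(2, 3, 1)))
#' ann <- annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f2")))
#' wnp_predict(net, ann, config = gsa_config(n_steps = 2000, n_restarts = 5))
#' @export
wnp_predict <- function(net, ann, alphabet = NULL, config = gsa_config()) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (!inherits(config, "anneal_config") || config$schedule != "gsa") {
    abort("`config` must come from gsa_config().")
  }
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  prob <- build_problem(net, ann, alphabet)
  consensus_predict(prob, config, "wnp")
}

#' Predict functions with the binary simulated annealing baseline
#'
#' The classical assignment scheme on the binarized network: every existing
#' edge gets weight 1, the objective counts same-labelled edges (the field
#' term counts characterized neighbors per function), and optimization uses
#' classical Metropolis annealing with geometric cooling. The same
#' restart-consensus layer as [wnp_predict()] is applied, so the comparison
#' between the two isolates the objective and schedule difference.
#'
#' @inheritParams gsa_optimize
#' @param config An [sa_config()] object.
#' @return A [prediction_set] with algorithm tag `"sa"`.
#' @export
sa_predict <- function(net, ann, alphabet = NULL, config = sa_config()) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (!inherits(config, "anneal_config") || config$schedule != "metropolis") {
    abort("`config` must come from sa_config().")
  }
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  bin <- binarize(net)
  prob <- build_problem(bin, ann, alphabet)
  consensus_predict(prob, config, "sa")
}

#' Binarize a weighted network
#'
#' Sets every edge weight to 1, keeping the topology.
#'
#' @param net A [fnet] network.
#' @return A [fnet] network with unit weights.
#' @export
binarize <- function(net) {
  assert_fnet(net)
  e <- net$edges
  e$lls <- rep(1, nrow(e))
  fnet(e, nodes = net$nodes)
}
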