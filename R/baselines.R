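#' Chi-square neighborhood predictor
#'
#' For each uncharacterized node \eqn{p}, looks at the characterized members
#' of its `n_hop`-neighborhood and scores each candidate function \eqn{f} by
#' \deqn{S(f) = (n_f - e_f)^2 / e_f,} where \eqn{n_f} is the observed number
#' of neighborhood members annotated with \eqn{f} and \eqn{e_f} is the
#' expected number under the network-wide frequency of \eqn{f} among
#' characterized nodes. Functions with \eqn{e_f = 0} are skipped; isolated
#' nodes get no predictions.
#'
#' @inheritParams gsa_optimize
#' @param n_hop Neighborhood radius (graph distance).
#' @return A [prediction_set] with algorithm tag `"chis"`.
#' @export
chi_square_predict <- function(net, ann, alphabet = NULL, n_hop = 1L) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (n_hop < 1) abort("`n_hop` must be >= 1.")
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  char <- characterized(net, ann)
  targets <- uncharacterized(net, ann)
  empty <- tibble::tibble(gene = character(), term = character(), score = numeric())
  if (!length(char)) {
    warn("No annotated genes in the network; chi-square emits no predictions.")
    return(prediction_set(empty, "chis", list(n_hop = n_hop)))
  }

  sets <- term_sets(ann[ann$gene %in% char & ann$term %in% alphabet, ])
  freq <- table(unlist(sets, use.names = FALSE)) / length(char)

  g <- as_igraph(net)
  hoods <- igraph::ego(g, order = n_hop, nodes = targets, mindist = 1)
  rows <- purrr::map2(targets, hoods, function(p, hood) {
    members <- intersect(names(hood), char)
    if (!length(members)) return(NULL)
    nf <- table(unlist(sets[members], use.names = FALSE))
    terms <- names(nf)
    ef <- length(members) * as.numeric(freq[terms])
    keep <- !is.na(ef) & ef > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      gene = p,
      term = terms[keep],
      score = (as.numeric(nf[keep]) - ef[keep])^2 / ef[keep]
    )
  })
  prediction_set(dplyr::bind_rows(empty, rows), "chis", list(n_hop = n_hop))
}

#' FunctionalFlow predictor
#'
#' Network-propagation scheme in which every annotated node acts as an
#' infinite source of "functional flow" for each of its functions. At each
#' iteration, flow moves downhill only (from fuller to emptier reservoirs),
#' splits across eligible edges proportionally to edge weight, and is capped
#' per edge by the edge weight. An uncharacterized node's score for a
#' function is its total inflow over all iterations.
#'
#' @inheritParams gsa_optimize
#' @param n_iterations Number of spreading iterations.
#' @return A [prediction_set] with algorithm tag `"ff"` (zero-inflow terms
#'   are omitted).
#' @export
functional_flow_predict <- function(net, ann, alphabet = NULL, n_iterations = 6L) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  nodes <- net$nodes
  n <- length(nodes)
  targets <- uncharacterized(net, ann)
  e <- net$edges
  # directed edge arrays (both orientations)
  from <- match(c(e$gene_a, e$gene_b), nodes)
  to <- match(c(e$gene_b, e$gene_a), nodes)
  w <- c(e$lls, e$lls)

  sets <- term_sets(ann[ann$gene %in% nodes & ann$term %in% alphabet, ])
  results <- vector("list", length(alphabet))
  audit <- vector("list", length(alphabet))
  for (k in seq_along(alphabet)) {
    f <- alphabet[k]
    src <- names(sets)[vapply(sets, function(s) f %in% s, logical(1))]
    if (!length(src)) next
    is_src <- nodes %in% src
    reservoir <- numeric(n)
    reservoir[is_src] <- Inf
    inflow <- numeric(n)
    dispensed <- 0
    for (it in seq_len(n_iterations)) {
      downhill <- reservoir[from] > reservoir[to]
      if (!any(downhill)) break
      # proportional split among eligible (downhill) edges, capped by weight
      w_elig <- w * downhill
      denom <- rowsum_vec(w_elig, from, n)
      share <- ifelse(downhill & denom[from] > 0,
                      pmin(w, reservoir[from] * w / denom[from]), 0)
      share[downhill & is.infinite(reservoir[from])] <-
        w[downhill & is.infinite(reservoir[from])]
      outflow <- rowsum_vec(share, from, n)
      gain <- rowsum_vec(share, to, n)
      reservoir <- reservoir + gain - outflow
      inflow <- inflow + gain
      dispensed <- dispensed + sum(outflow[is_src])
    }
    idx <- match(targets, nodes)
    got <- inflow[idx] > 0
    if (any(got)) {
      results[[k]] <- tibble::tibble(gene = targets[got], term = f, score = inflow[idx][got])
    }
    audit[[k]] <- tibble::tibble(term = f, dispensed = dispensed,
                                 received = sum(reservoir[!is_src]))
  }
  empty <- tibble::tibble(gene = character(), term = character(), score = numeric())
  prediction_set(dplyr::bind_rows(empty, results), "ff",
                 list(n_iterations = n_iterations,
                      flow_audit = dplyr::bind_rows(audit)))
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' FS-weighted averaging predictor
#'
#' Topological-similarity voting over the 1- and 2-neighborhood: each
#' characterized node \eqn{q} within distance 2 of target \eqn{p} contributes
#' its FS similarity to \eqn{p}, down-weighted by inverse distance
#' (\eqn{1/d}), to every function it carries. FS similarity between \eqn{p}
#' and \eqn{q} with closed neighbor sets \eqn{N_p, N_q} (each including the
#' node itself) is
#' \deqn{\frac{2|N_p \cap N_q|}{|N_p \setminus N_q| + 2|N_p \cap N_q| + \lambda}
#'   \times
#'   \frac{2|N_p \cap N_q|}{|N_q \setminus N_p| + 2|N_p \cap N_q| + \lambda}.}
#'
#' @inheritParams gsa_optimize
#' @param lambda Smoothing constant \eqn{\lambda \ge 0} in both FS ratios.
#' @return A [prediction_set] with algorithm tag `"wa"`.
#' @export
wa_predict <- function(net, ann, alphabet = NULL, lambda = 0) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  char <- characterized(net, ann)
  targets <- uncharacterized(net, ann)
  empty <- tibble::tibble(gene = character(), term = character(), score = numeric())
  if (!length(char) || !length(targets)) {
    return(prediction_set(empty, "wa", list(lambda = lambda)))
  }
  sets <- term_sets(ann[ann$gene %in% char & ann$term %in% alphabet, ])
  g <- as_igraph(net)
  nbrs <- igraph::adjacent_vertices(g, v = net$nodes)
  closed <- stats::setNames(
    lapply(seq_along(net$nodes), function(i) c(net$nodes[i], names(nbrs[[i]]))),
    net$nodes
  )
  hoods <- igraph::ego(g, order = 2, nodes = targets, mindist = 1)
  direct <- igraph::ego(g, order = 1, nodes = targets, mindist = 1)

  rows <- purrr::pmap(list(targets, hoods, direct), function(p, hood, d1) {
    members <- intersect(names(hood), names(sets))
    if (!length(members)) return(NULL)
    np <- closed[[p]]
    sim <- vapply(members, function(q) {
      nq <- closed[[q]]
      common <- length(intersect(np, nq))
      if (common == 0) return(0)
      only_p <- length(np) - common
      only_q <- length(nq) - common
      (2 * common / (only_p + 2 * common + lambda)) *
        (2 * common / (only_q + 2 * common + lambda))
    }, numeric(1))
    dist_w <- ifelse(members %in% names(d1), 1, 0.5)
    contrib <- sim * dist_w
    keep <- contrib > 0
    if (!any(keep)) return(NULL)
    df <- tibble::tibble(
      gene = p,
      term = unlist(sets[members[keep]], use.names = FALSE),
      contrib = rep(contrib[keep], lengths(sets[members[keep]]))
    )
    dplyr::summarise(dplyr::group_by(df, .data$gene, .data$term),
                     score = sum(.data$contrib), .groups = "drop")
  })
  prediction_set(dplyr::bind_rows(empty, rows), "wa", list(lambda = lambda))
}

#' Weighted-average neighbor voting predictor
#'
#' For each uncharacterized node, a function's score is the fraction of the
#' summed edge weight to characterized direct neighbors that supports it:
#' \deqn{score(f) = \sum_{q} w_{pq} [f \in ann(q)] / \sum_{q} w_{pq},} the sum
#' running over characterized neighbors \eqn{q}. Nodes with no characterized
#' neighbor get no predictions.
#'
#' @inheritParams gsa_optimize
#' @return A [prediction_set] with algorithm tag `"pc"`.
#' @export
pc_predict <- function(net, ann, alphabet = NULL) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  char <- characterized(net, ann)
  targets <- uncharacterized(net, ann)
  e <- net$edges
  dir <- tibble::tibble(
    gene = c(e$gene_a, e$gene_b),
    nbr = c(e$gene_b, e$gene_a),
    w = c(e$lls, e$lls)
  )
  dir <- dir[dir$gene %in% targets & dir$nbr %in% char, ]
  empty <- tibble::tibble(gene = character(), term = character(), score = numeric())
  if (!nrow(dir)) return(prediction_set(empty, "pc", list()))
  denom <- dplyr::summarise(dplyr::group_by(dir, .data$gene),
                            w_total = sum(.data$w), .groups = "drop")
  hits <- dplyr::inner_join(dir, tibble::as_tibble(ann), by = c(nbr = "gene"),
                            relationship = "many-to-many")
  hits <- hits[hits$term %in% alphabet, ]
  if (!nrow(hits)) return(prediction_set(empty, "pc", list()))
  num <- dplyr::summarise(dplyr::group_by(hits, .data$gene, .data$term),
                          w_f = sum(.data$w), .groups = "drop")
  out <- dplyr::inner_join(num, denom, by = "gene")
  out$score <- out$w_f / out$w_total
  prediction_set(out[, c("gene", "term", "score")], "pc", list())
}

#' Names of the registered prediction algorithms
#'
#' @return Character vector of the algorithm tags accepted by
#'   [run_benchmark()].
#' @export
wnp_algorithms <- function() c("wnp", "sa", "ff", "wa", "pc", "chis")
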