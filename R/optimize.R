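#' Configure the generalized simulated annealing optimizer
#'
#' Generalized simulated annealing (GSA) in the Tsallis–Stariolo formulation:
#' the visiting temperature follows
#' \deqn{T_{q_v}(t) = t_0 \frac{2^{q_v-1} - 1}{(1+t)^{q_v-1} - 1},}
#' the acceptance temperature is \eqn{T_{q_v}(t)/t}, and an uphill move in the
#' cost \eqn{\Delta C > 0} is accepted with probability
#' \eqn{[1 + (q_a-1)\Delta C/T_a]^{1/(1-q_a)}} (zero when the base is
#' non-positive; the \eqn{q_a \to 1} limit is the classical Metropolis rule).
#' In the discrete label space the heavy-tailed visiting distribution is
#' emulated by mixing two proposal kernels with temperature-dependent weight:
#' with probability \eqn{T_{q_v}(s)/t_0} the new label is uniform over the
#' full alphabet (hot, global move), otherwise uniform over the node's
#' candidate set (positive-field terms plus the current labels of its
#' uncharacterized neighbors, falling back to the full alphabet when empty).
#' Schedule time advances once per sweep (one proposal per uncharacterized
#' node) and wraps every `cycle_sweeps` sweeps, so a long chain performs
#' repeated hot-to-cold reannealing cycles from its current state — the
#' discrete counterpart of generalized-annealing restarts.
#'
#' @param q_v Visiting-distribution shape parameter, \eqn{> 1}.
#' @param q_a Acceptance shape parameter; negative values make the acceptance
#'   rule sharper than Metropolis.
#' @param t0 Initial temperature, \eqn{> 0}.
#' @param n_steps Iterations per run; `NULL` (default) resolves at run time to
#'   `min(1e4 * n_uncharacterized, step_cap)`.
#' @param step_cap Upper bound on the automatic `n_steps`.
#' @param n_restarts Independent runs pooled by the consensus layer of
#'   [wnp_predict()].
#' @param seed Integer master seed; restart seeds derive from it.
#' @param init Either `"field"` (start each node at the argmax of its neighbor
#'   field, ties broken at random) or `"random"`.
#' @param traj_every Record the best-so-far score every this many steps.
#' @param cycle_sweeps Length of one reannealing cycle, in sweeps; by that
#'   point the acceptance temperature has effectively reached zero, so longer
#'   cycles only extend the greedy tail.
#' @return A list of class `anneal_config`.
#' @export
gsa_config <- function(q_v = 2.7, q_a = -5, t0 = 40,
                       n_steps = NULL, step_cap = 2e5,
                       n_restarts = 20L, seed = 1L,
                       init = c("field", "random"), traj_every = 1000L,
                       cycle_sweeps = 100L) {
  init <- match.arg(init)
  cfg <- list(
    schedule = "gsa", q_v = q_v, q_a = q_a, t0 = t0, cool = NA_real_,
    n_steps = n_steps, step_cap = step_cap,
    n_restarts = as.integer(n_restarts), seed = as.integer(seed),
    init = init, traj_every = as.integer(traj_every),
    cycle_sweeps = as.integer(cycle_sweeps)
  )
  validate_config(cfg)
}

#' Configure the classical simulated annealing baseline
#'
#' Classical Metropolis acceptance with geometric cooling: the temperature is
#' multiplied by `cool` once per sweep (one sweep = one proposed move per
#' uncharacterized node). Used by [sa_predict()] on the binarized network, so
#' the WNP/SA comparison isolates the objective and schedule difference.
#'
#' @param t0 Initial temperature.
#' @param cool Geometric cooling ratio per sweep, in \eqn{(0, 1)}.
#' @inheritParams gsa_config
#' @return A list of class `anneal_config`.
#' @export
sa_config <- function(t0 = 1, cool = 0.995,
                      n_steps = NULL, step_cap = 2e5,
                      n_restarts = 20L, seed = 1L,
                      init = c("field", "random"), traj_every = 1000L) {
  init <- match.arg(init)
  cfg <- list(
    schedule = "metropolis", q_v = NA_real_, q_a = NA_real_, t0 = t0, cool = cool,
    n_steps = n_steps, step_cap = step_cap,
    n_restarts = as.integer(n_restarts), seed = as.integer(seed),
    init = init, traj_every = as.integer(traj_every), cycle_sweeps = 1L
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$t0) || cfg$t0 <= 0) abort("`t0` must be positive.")
  if (!is.null(cfg$n_steps) && (!is.numeric(cfg$n_steps) || cfg$n_steps < 1)) {
    abort("`n_steps` must be >= 1 (or NULL for automatic).")
  }
  if (cfg$n_restarts < 1) abort("`n_restarts` must be >= 1.")
  if (cfg$schedule == "gsa") {
    if (!is.numeric(cfg$q_v) || cfg$q_v <= 1) abort("`q_v` must be > 1.")
    if (!is.numeric(cfg$q_a) || is.na(cfg$q_a)) abort("`q_a` must be numeric.")
  } else {
    if (!is.numeric(cfg$cool) || cfg$cool <= 0 || cfg$cool >= 1) {
      abort("`cool` must lie in (0, 1).")
    }
  }
  structure(cfg, class = "anneal_config")
}

resolve_steps <- function(cfg, n_unchar) {
  if (!is.null(cfg$n_steps)) return(as.integer(cfg$n_steps))
  as.integer(min(1e4 * max(n_unchar, 1L), cfg$step_cap))
}

# Initial labels (1-based indices into prob$alphabet) for one chain.
init_labels <- function(prob, init, seed) {
  n <- length(prob$unchar)
  K <- length(prob$alphabet)
  with_seed(seed, {
    if (init == "field" && n > 0) {
      vapply(seq_len(n), function(i) {
        hi <- prob$h[i, ]
        top <- which(hi == max(hi))
        if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
      }, integer(1))
    } else {
      sample.int(K, n, replace = TRUE)
    }
  })
}

# terms with a positive field at each node (static part of candidate sets)
static_candidates <- function(prob) {
  n <- length(prob$unchar)
  lapply(seq_len(n), function(i) which(prob$h[i, ] > 0))
}

# One annealing chain on a prebuilt problem; returns labels + score + traj.
run_chain <- function(prob, cfg, seed) {
  n <- length(prob$unchar)
  n_steps <- resolve_steps(cfg, n)
  init <- init_labels(prob, cfg$init, seed)
  res <- anneal_chain(
    prob$h, prob$uu_i, prob$uu_j, prob$uu_w,
    init, static_candidates(prob),
    n_steps, cfg$t0,
    if (is.na(cfg$q_v)) 2 else cfg$q_v,
    if (is.na(cfg$q_a)) 1 else cfg$q_a,
    cfg$schedule,
    if (is.na(cfg$cool)) 1 else cfg$cool,
    seed, cfg$traj_every,
    if (is.null(cfg$cycle_sweeps)) 100L else cfg$cycle_sweeps
  )
  res$n_steps <- n_steps
  res
}

#' Maximize the weighted score by generalized simulated annealing
#'
#' Runs a single GSA chain and returns the best-scoring assignment ever
#' visited (not the final state). Identical network, annotations, alphabet,
#' and config (including seed) give identical output.
#'
#' @inheritParams weighted_score
#' @param alphabet Candidate function terms; defaults to the terms in `ann`.
#' @param config An [gsa_config()] (or [sa_config()]) object; its `seed`
#'   drives the chain.
#' @return A list of class `gsa_fit` with elements `assignment` (tibble
#'   `gene`, `term`), `score`, `breakdown` (one-row tibble), `trajectory`
#'   (tibble `step`, `best_score`, non-decreasing), `config`, `n_steps`.
#' @seealso [exhaustive_optimize()] for the brute-force oracle,
#'   [wnp_predict()] for the restart-consensus predictor.
#' @export
gsa_optimize <- function(net, ann, alphabet = NULL, config = gsa_config()) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (!inherits(config, "anneal_config")) abort("`config` must come from gsa_config()/sa_config().")
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  prob <- build_problem(net, ann, alphabet)
  if (length(prob$unchar) == 0) {
    return(structure(list(
      assignment = tibble::tibble(gene = character(), term = character()),
      score = 0, breakdown = tibble::tibble(pair_term = 0, field_term = 0, total = 0),
      trajectory = tibble::tibble(step = integer(), best_score = numeric()),
      config = config, n_steps = 0L
    ), class = "gsa_fit"))
  }
  if (length(prob$alphabet) == 0) abort("`alphabet` must be non-empty.")
  res <- run_chain(prob, config, config$seed)
  lab <- res$best_labels
  structure(list(
    assignment = tibble::tibble(gene = prob$unchar, term = prob$alphabet[lab]),
    score = res$best_score,
    breakdown = score_breakdown(prob, lab),
    trajectory = tibble::tibble(step = res$traj_step, best_score = res$traj_best),
    config = config, n_steps = res$n_steps
  ), class = "gsa_fit")
}

#' @export
print.gsa_fit <- function(x, ...) {
  cat(sprintf("<gsa_fit> %d nodes labelled, score %.6g (%d steps)\n",
              nrow(x$assignment), x$score, x$n_steps))
  invisible(x)
}

#' @export
glance.gsa_fit <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    pair_term = x$breakdown$pair_term,
    field_term = x$breakdown$field_term,
    n_assigned = nrow(x$assignment),
    n_steps = x$n_steps
  )
}

#' @export
tidy.gsa_fit <- function(x, ...) x$assignment

#' @export
autoplot.gsa_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$step, y = .data$best_score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "annealing step", y = "best score so far") +
    ggplot2::theme_minimal()
}

#' Exhaustively maximize the weighted score (test oracle)
#'
#' Enumerates every assignment of alphabet terms to uncharacterized nodes and
#' returns the global maximum. Ties break by lexicographic order of
#' (node, term), so the result is deterministic. Intended as an oracle on
#' small instances; refuses when \eqn{|alphabet|^{n}} exceeds `cap`.
#'
#' @inheritParams gsa_optimize
#' @param cap Maximum number of assignments to enumerate.
#' @return A list of class `wnp_assignment` with `assignment`, `score`,
#'   `breakdown`.
#' @export
exhaustive_optimize <- function(net, ann, alphabet = NULL, cap = 1e6) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (is.null(alphabet)) alphabet <- function_alphabet(ann)
  prob <- build_problem(net, ann, alphabet)
  n <- length(prob$unchar)
  K <- length(prob$alphabet)
  if (n == 0) {
    return(structure(list(
      assignment = tibble::tibble(gene = character(), term = character()),
      score = 0, breakdown = tibble::tibble(pair_term = 0, field_term = 0, total = 0)
    ), class = "wnp_assignment"))
  }
  if (K == 0) abort("`alphabet` must be non-empty.")
  total <- K^n
  if (total > cap) {
    abort(sprintf(
      "Exhaustive enumeration refused: %d^%d = %.3g assignments exceeds cap %g.",
      K, n, total, cap
    ))
  }
  total <- as.double(total)
  block <- 65536
  best_score <- -Inf
  best_idx <- NA_real_
  pow <- K^((n - 1):0)  # node 1 most significant => enumeration is lexicographic
  lo <- 0
  while (lo < total) {
    hi <- min(lo + block, total)
    idx <- seq(lo, hi - 1)
    B <- length(idx)
    score <- numeric(B)
    labs <- matrix(0L, nrow = B, ncol = n)
    for (i in seq_len(n)) {
      li <- as.integer((idx %/% pow[i]) %% K) + 1L
      labs[, i] <- li
      score <- score + prob$h[cbind(rep.int(i, B), li)]
    }
    for (e in seq_along(prob$uu_w)) {
      same <- labs[, prob$uu_i[e]] == labs[, prob$uu_j[e]]
      score[same] <- score[same] + prob$uu_w[e]
    }
    w <- which.max(score)
    if (score[w] > best_score) {
      best_score <- score[w]
      best_idx <- idx[w]
      best_lab <- labs[w, ]
    }
    lo <- hi
  }
  structure(list(
    assignment = tibble::tibble(gene = prob$unchar, term = prob$alphabet[best_lab]),
    score = best_score,
    breakdown = score_breakdown(prob, best_lab)
  ), class = "wnp_assignment")
}

#' @export
print.wnp_assignment <- function(x, ...) {
  cat(sprintf("<wnp_assignment> %d nodes labelled, score %.6g\n",
              nrow(x$assignment), x$score))
  invisible(x)
}

#' @export
tidy.wnp_assignment <- function(x, ...) x$assignment
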