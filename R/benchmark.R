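# dispatch one algorithm on a masked instance
run_algorithm <- function(algorithm, net, masked, alphabet, seed, opts) {
  switch(
    algorithm,
    wnp = {
      cfg <- opts$wnp %||% gsa_config()
      cfg$seed <- seed
      wnp_predict(net, masked, alphabet, cfg)
    },
    sa = {
      cfg <- opts$sa %||% sa_config()
      cfg$seed <- seed
      sa_predict(net, masked, alphabet, cfg)
    },
    ff = functional_flow_predict(net, masked, alphabet,
                                 n_iterations = opts$ff_iterations %||% 6L),
    wa = wa_predict(net, masked, alphabet, lambda = opts$wa_lambda %||% 0),
    pc = pc_predict(net, masked, alphabet),
    chis = chi_square_predict(net, masked, alphabet, n_hop = opts$chis_hop %||% 1L),
    abort(sprintf("Unknown algorithm '%s'. Registered: %s.",
                  algorithm, paste(wnp_algorithms(), collapse = ", ")))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-a-percent-out cross-validation benchmark
#'
#' For each clearing fraction and replicate, masks the annotations of a
#' random fraction of annotated genes (per-replicate seeds derive from the
#' master seed, so every replicate is independently re-runnable), runs each
#' requested algorithm on the masked instance, and evaluates the predictions
#' against the held-out truth: ROC/AUC and the success-rate-versus-
#' functional-degree profile at the per-simulation threshold that keeps at
#' least one prediction per covered gene. All algorithms within a replicate
#' see the identical mask. A failing stage aborts that (algorithm, replicate)
#' cell with a warning and leaves an `NA` row, so partial coverage is
#' explicit.
#'
#' @param net A [fnet] network.
#' @param ann The full [annotation_map] (ground truth).
#' @param algorithms Character vector of algorithm tags; see
#'   [wnp_algorithms()].
#' @param fractions Clearing fractions in \eqn{(0, 1]}.
#' @param n_replicates Replicates per fraction.
#' @param seed Master seed.
#' @param opts Named list of per-algorithm options: `wnp` ([gsa_config()]),
#'   `sa` ([sa_config()]), `ff_iterations`, `wa_lambda`, `chis_hop`.
#' @param success_unit Passed to [sr_vs_fd()].
#' @return An object of class `wnp_benchmark`: list with `replicates` (one
#'   row per algorithm x fraction x replicate: `auc`, `sr`, `coverage`,
#'   `threshold`, `n_targets`, and the `sr_fd` table as a list column) and
#'   `summary` (per algorithm x fraction means and standard deviations).
#' @export
run_benchmark <- function(net, ann,
                          algorithms = wnp_algorithms(),
                          fractions = c(0.05, 0.10, 0.15, 0.20),
                          n_replicates = 10L,
                          seed = 1L,
                          opts = list(),
                          success_unit = "prediction") {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  if (any(fractions <= 0 | fractions > 1)) abort("`fractions` must lie in (0, 1].")
  bad <- setdiff(algorithms, wnp_algorithms())
  if (length(bad)) abort(sprintf("Unknown algorithm(s): %s.", paste(bad, collapse = ", ")))
  alphabet <- function_alphabet(ann)

  grid <- tidyr::expand_grid(
    f_idx = seq_along(fractions),
    replicate = seq_len(as.integer(n_replicates))
  )
  rows <- purrr::pmap(grid, function(f_idx, replicate) {
    fraction <- fractions[f_idx]
    mask_seed <- derive_seed(seed, f_idx, replicate)
    cl <- clear_annotations(ann, fraction, mask_seed)
    purrr::imap(stats::setNames(algorithms, algorithms), function(algorithm, nm) {
      algo_seed <- derive_seed(seed, f_idx, replicate, match(algorithm, wnp_algorithms()))
      tryCatch({
        pred <- run_algorithm(algorithm, net, cl$masked, alphabet, algo_seed, opts)
        ev <- roc_and_auc(pred, cl$truth)
        srtab <- sr_vs_fd(pred, cl$truth, net, cl$masked, success_unit = success_unit)
        tibble::tibble(
          algorithm = algorithm, fraction = fraction, replicate = replicate,
          seed = algo_seed, n_targets = ev$n_targets, coverage = ev$coverage,
          auc = ev$auc, sr = attr(srtab, "sr_global"),
          threshold = attr(srtab, "threshold"),
          sr_fd = list(tibble::as_tibble(srtab))
        )
      }, error = function(e) {
        warn(sprintf("%s at fraction %.2f, replicate %d failed: %s",
                     algorithm, fraction, replicate, conditionMessage(e)))
        tibble::tibble(
          algorithm = algorithm, fraction = fraction, replicate = replicate,
          seed = algo_seed, n_targets = NA_integer_, coverage = NA_real_,
          auc = NA_real_, sr = NA_real_, threshold = NA_real_,
          sr_fd = list(tibble::tibble())
        )
      })
    }) |> dplyr::bind_rows()
  })
  replicates <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$algorithm, .data$fraction),
    n_ok = sum(!is.na(.data$auc)),
    auc_mean = mean(.data$auc, na.rm = TRUE),
    auc_sd = stats::sd(.data$auc, na.rm = TRUE),
    sr_mean = mean(.data$sr, na.rm = TRUE),
    sr_sd = stats::sd(.data$sr, na.rm = TRUE),
    .groups = "drop"
  )
  structure(
    list(replicates = replicates, summary = summary,
         seed = seed, algorithms = algorithms, fractions = fractions),
    class = "wnp_benchmark"
  )
}

#' @export
print.wnp_benchmark <- function(x, ...) {
  cat(sprintf("<wnp_benchmark> %d algorithms x %d fractions x %d replicates (seed %d)\n",
              length(x$algorithms), length(x$fractions),
              max(x$replicates$replicate), x$seed))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wnp_benchmark <- function(x, ...) {
  dplyr::select(x$replicates, -"sr_fd")
}

#' @export
glance.wnp_benchmark <- function(x, ...) x$summary

#' Pool the SR-versus-FD tables of a benchmark
#'
#' Aggregates the per-replicate success-rate-by-functional-degree tables of
#' one clearing fraction (or all of them) into pooled bins per algorithm.
#'
#' @param x A `wnp_benchmark`.
#' @param fraction Optional single fraction to restrict to.
#' @return Tibble with columns `algorithm`, `fd`, `n`, `n_success`, `sr`.
#' @export
pool_sr_fd <- function(x, fraction = NULL) {
  reps <- x$replicates
  if (!is.null(fraction)) reps <- reps[reps$fraction == fraction, ]
  tabs <- dplyr::bind_rows(
    purrr::map2(reps$sr_fd, reps$algorithm,
                function(t, a) if (nrow(t)) dplyr::mutate(t, algorithm = a) else NULL)
  )
  if (!nrow(tabs)) return(tibble::tibble(algorithm = character(), fd = integer(),
                                         n = integer(), n_success = integer(), sr = numeric()))
  dplyr::summarise(
    dplyr::group_by(tabs, .data$algorithm, .data$fd),
    n = sum(.data$n), n_success = sum(.data$n_success),
    sr = sum(.data$n_success) / sum(.data$n), .groups = "drop"
  )
}

#' @export
autoplot.wnp_benchmark <- function(object, metric = c("auc", "sr"), ...) {
  metric <- match.arg(metric)
  s <- object$summary
  s$mid <- s[[paste0(metric, "_mean")]]
  s$sd <- s[[paste0(metric, "_sd")]]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$algorithm, y = .data$mid,
                                  fill = .data$algorithm)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mid - .data$sd,
                                        ymax = .data$mid + .data$sd), width = 0.3) +
    ggplot2::facet_wrap(~fraction, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot pooled SR-versus-FD curves
#'
#' @param df Output of [pool_sr_fd()] (or a compatible tibble).
#' @param min_n Hide bins supported by fewer predictions than this.
#' @return A ggplot object.
#' @export
plot_sr_fd <- function(df, min_n = 5L) {
  df <- df[df$n >= min_n, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fd, y = .data$sr,
                                   colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "functional degree", y = "success rate") +
    ggplot2::theme_minimal()
}
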