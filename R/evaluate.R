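#' Classify one multi-label prediction as TP or FP
#'
#' A gene's prediction is a true positive when more than half of the
#' predicted functions are correct (strict majority: exactly half is a false
#' positive).
#'
#' @param predicted_terms Non-empty character vector of predicted terms.
#' @param true_terms Non-empty character vector of true terms.
#' @return `"TP"` or `"FP"`.
#' @examples
#' classify_prediction(c("f1", "f2", "f3"), c("f1", "f2"))  # "TP"
#' classify_prediction(c("f1", "f2"), "f1")                 # "FP": exactly half
#' @export
classify_prediction <- function(predicted_terms, true_terms) {
  predicted_terms <- unique(as.character(predicted_terms))
  true_terms <- unique(as.character(true_terms))
  if (!length(predicted_terms)) abort("`predicted_terms` must be non-empty; filter unpredicted genes upstream.")
  if (!length(true_terms)) abort("`true_terms` must be non-empty.")
  if (length(intersect(predicted_terms, true_terms)) / length(predicted_terms) > 0.5) "TP" else "FP"
}

#' ROC curve and AUC for a prediction set against held-out truth
#'
#' Sweeps the confidence threshold over the observed scores, from the most
#' confident down to the per-simulation threshold — the largest value that
#' still leaves at least one prediction for every covered gene (see
#' [select_threshold()]), which is where classified coverage first reaches
#' its maximum. At each threshold a gene's predicted set is its terms scoring
#' at or above it; genes with a non-empty set are classified TP/FP by the
#' strict-majority rule, and TPR/FPR both use the total number of genes to be
#' predicted as denominator (so TPR + FPR is the classified coverage, at most
#' 1). Genes with no surviving prediction at a threshold count toward neither
#' rate. Sweeping below the coverage point would only dilute every gene's set
#' with low-confidence terms and eventually turn all genes into
#' majority-rule false positives, so the sweep stops there.
#'
#' AUC is the trapezoidal area under the points sorted by (FPR, TPR), with
#' (0, 0) prepended. With `mode = "normalized"` (default), when the most
#' permissive threshold classifies every target the final point connects to
#' (1, 1); otherwise the curve extends horizontally to FPR = 1 at its last
#' TPR and the area is divided by the attained coverage. `mode = "connect"`
#' always connects the last point straight to (1, 1) with no normalization.
#'
#' @param predictions A [prediction_set] (or gene/term/score data frame).
#' @param truth Data frame with columns `gene`, `term`: the held-out true
#'   annotations. Its genes define the target set.
#' @param mode AUC endpoint handling; see Details.
#' @return A list of class `wnp_eval`: `roc` (sweep tibble with `threshold`,
#'   `tp`, `fp`, `tpr`, `fpr`), `points` (vertices used for integration),
#'   `auc`, `n_targets`, `coverage`, `mode`.
#' @export
roc_and_auc <- function(predictions, truth, mode = c("normalized", "connect")) {
  mode <- match.arg(mode)
  truth <- tibble::as_tibble(truth)
  if (!all(c("gene", "term") %in% names(truth))) names(truth)[1:2] <- c("gene", "term")
  if (!nrow(truth)) abort("`truth` is empty.")
  preds <- as_plain_tibble(predictions)
  targets <- sort(unique(truth$gene))
  n_targets <- length(targets)
  preds <- preds[preds$gene %in% targets, c("gene", "term", "score")]

  true_sets <- split(truth$term, truth$gene)

  if (!nrow(preds)) {
    roc <- tibble::tibble(threshold = numeric(), tp = integer(), fp = integer(),
                          tpr = numeric(), fpr = numeric())
    pts <- tibble::tibble(fpr = 0, tpr = 0)
    out <- list(roc = roc, points = pts, auc = NA_real_, n_targets = n_targets,
                coverage = 0, mode = mode)
    class(out) <- "wnp_eval"
    return(out)
  }

  genes <- sort(unique(preds$gene))
  # stop the sweep at the point of maximal coverage: the min over covered
  # genes of their top score (the per-simulation threshold)
  theta_star <- min(tapply(preds$score, preds$gene, max))
  thresholds <- sort(unique(preds$score[preds$score >= theta_star]), decreasing = TRUE)
  # per gene: ascending score vector and matching correctness flags
  by_gene <- split(preds[, c("term", "score")], preds$gene)
  U <- length(thresholds)
  tot <- matrix(0L, nrow = length(genes), ncol = U)
  cor <- matrix(0L, nrow = length(genes), ncol = U)
  for (gi in seq_along(genes)) {
    gdf <- by_gene[[genes[gi]]]
    ord <- order(gdf$score)
    s_asc <- gdf$score[ord]
    ok <- gdf$term[ord] %in% true_sets[[genes[gi]]]
    k <- length(s_asc)
    # number of scores >= threshold (thresholds are observed values: exact)
    n_lt <- findInterval(thresholds, s_asc, left.open = TRUE)
    tot[gi, ] <- k - n_lt
    cs <- cumsum(rev(ok))  # correct among the top-j scores (desc order)
    n_ge <- k - n_lt
    cor[gi, ] <- ifelse(n_ge > 0, cs[pmax(n_ge, 1L)], 0L)
  }
  made <- tot > 0L
  tp <- colSums(made & (2L * cor > tot))
  fp <- colSums(made) - tp
  roc <- tibble::tibble(
    threshold = thresholds,
    tp = as.integer(tp), fp = as.integer(fp),
    tpr = tp / n_targets, fpr = fp / n_targets
  )
  coverage <- max((tp + fp) / n_targets)

  pts <- dplyr::distinct(roc[, c("fpr", "tpr")])
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  pts <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0), pts)
  auc <- auc_from_points(pts, coverage, mode)

  out <- list(roc = roc, points = pts, auc = auc, n_targets = n_targets,
              coverage = coverage, mode = mode)
  class(out) <- "wnp_eval"
  out
}

# trapezoid over sorted points with the documented endpoint handling
auc_from_points <- function(pts, coverage, mode) {
  x <- pts$fpr
  y <- pts$tpr
  if (mode == "connect" || coverage >= 1 - 1e-12) {
    x <- c(x, 1)
    y <- c(y, 1)
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  } else {
    x <- c(x, 1)
    y <- c(y, y[length(y)])
    raw <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
    if (coverage > 0) raw / coverage else NA_real_
  }
}

#' @export
print.wnp_eval <- function(x, ...) {
  cat(sprintf("<wnp_eval> AUC %.4f over %d targets (coverage %.2f, mode %s)\n",
              x$auc, x$n_targets, x$coverage, x$mode))
  invisible(x)
}

#' @export
tidy.wnp_eval <- function(x, ...) x$roc

#' @export
glance.wnp_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_targets = x$n_targets, coverage = x$coverage,
                 n_thresholds = nrow(x$roc))
}

#' @export
autoplot.wnp_eval <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Per-simulation prediction threshold
#'
#' The largest threshold that still leaves at least one prediction for every
#' target gene: the minimum over genes of each gene's maximum score.
#'
#' @param predictions A [prediction_set].
#' @param targets Optional character vector of genes that must be covered;
#'   defaults to the genes present in `predictions`. A target with no
#'   predictions is an error naming the gene.
#' @return A single numeric threshold.
#' @export
select_threshold <- function(predictions, targets = NULL) {
  preds <- as_plain_tibble(predictions)
  if (is.null(targets)) targets <- unique(preds$gene)
  if (!length(targets)) abort("No target genes to threshold over.")
  missing <- setdiff(targets, preds$gene)
  if (length(missing)) {
    abort(sprintf("Gene '%s' has no scored prediction.", missing[1]))
  }
  maxima <- tapply(preds$score[preds$gene %in% targets],
                   preds$gene[preds$gene %in% targets], max)
  min(maxima)
}

#' Success rate as a function of functional degree
#'
#' Keeps the predictions scoring at or above `threshold`, groups them by the
#' target's functional degree — the number of characterized (post-masking)
#' direct neighbors — and reports each bin's success rate. With
#' `success_unit = "prediction"` (default) a prediction (gene, term) is
#' successful iff the term is among the gene's true terms and SR is the
#' fraction of successful predictions; with `"gene"` each gene's surviving
#' set is classified by the strict-majority rule and SR is the fraction of TP
#' genes.
#'
#' @param predictions A [prediction_set].
#' @param truth Data frame `gene`, `term` with the held-out annotations.
#' @param net The [fnet] network (for degrees).
#' @param ann The masked [annotation_map] the predictor saw.
#' @param threshold Score cutoff; defaults to [select_threshold()] over the
#'   genes present in `predictions`.
#' @param success_unit `"prediction"` or `"gene"`.
#' @return A tibble with columns `fd`, `n`, `n_success`, `sr`, plus
#'   attributes `threshold` and `sr_global` (pooled success rate).
#' @export
sr_vs_fd <- function(predictions, truth, net, ann,
                     threshold = NULL, success_unit = c("prediction", "gene")) {
  success_unit <- match.arg(success_unit)
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  truth <- tibble::as_tibble(truth)
  if (!all(c("gene", "term") %in% names(truth))) names(truth)[1:2] <- c("gene", "term")
  preds <- as_plain_tibble(predictions)
  if (is.null(threshold)) threshold <- select_threshold(predictions)
  targets <- sort(unique(truth$gene))
  keep <- preds$gene %in% targets & preds$score >= threshold
  preds <- preds[keep, ]
  true_sets <- split(truth$term, truth$gene)

  fd <- functional_degree(net, ann, targets)

  if (!nrow(preds)) {
    out <- tibble::tibble(fd = integer(), n = integer(),
                          n_success = integer(), sr = numeric())
    attr(out, "threshold") <- threshold
    attr(out, "sr_global") <- NA_real_
    return(out)
  }

  if (success_unit == "prediction") {
    success <- mapply(function(g, f) f %in% true_sets[[g]], preds$gene, preds$term)
    df <- tibble::tibble(fd = unname(fd[preds$gene]), success = as.logical(success))
  } else {
    by_gene <- split(preds$term, preds$gene)
    cls <- vapply(names(by_gene),
                  function(g) classify_prediction(by_gene[[g]], true_sets[[g]]),
                  character(1))
    df <- tibble::tibble(fd = unname(fd[names(by_gene)]), success = cls == "TP")
  }
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$fd),
    n = dplyr::n(), n_success = sum(.data$success), sr = mean(.data$success),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$fd)
  attr(out, "threshold") <- threshold
  attr(out, "sr_global") <- mean(df$success)
  out
}

#' Functional degree of target nodes
#'
#' The number of characterized direct neighbors each node has under `ann`.
#'
#' @inheritParams sr_vs_fd
#' @param nodes Character vector of nodes to measure.
#' @return Named integer vector aligned with `nodes`.
#' @export
functional_degree <- function(net, ann, nodes) {
  assert_fnet(net)
  ann <- as_annotation_map(ann)
  char <- characterized(net, ann)
  e <- net$edges
  dir_from <- c(e$gene_a, e$gene_b)
  dir_to <- c(e$gene_b, e$gene_a)
  hit <- dir_from %in% nodes & dir_to %in% char
  counts <- table(factor(dir_from[hit], levels = nodes))
  stats::setNames(as.integer(counts), nodes)
}
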