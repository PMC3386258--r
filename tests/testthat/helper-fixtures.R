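# Shared fixtures and independent oracles. Oracles are written as naive
# loops so they stay independent of the vectorized/compiled paths they check.

# the 4-node worked example: u1, u2 uncharacterized; a1 {f1}, a2 {f2};
# edges u1-u2 (2), u1-a1 (3), u2-a2 (1)
toy_net <- function() {
  fnet(data.frame(
    gene_a = c("u1", "u1", "u2"),
    gene_b = c("u2", "a1", "a2"),
    lls = c(2, 3, 1)
  ))
}

toy_ann <- function() {
  annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f2")))
}

# Random small instance: characterized core plus a few uncharacterized nodes,
# random topology, positive random weights, 1-2 terms per characterized gene.
random_instance <- function(seed, max_unchar = 7, max_terms = 4,
                            n_char = NULL, p_edge = 0.45, unit_weights = FALSE) {
  set.seed(seed)
  n_u <- sample.int(max_unchar, 1)
  n_c <- if (is.null(n_char)) sample(3:6, 1) else n_char
  K <- sample(2:max_terms, 1)
  nodes <- c(sprintf("u%d", seq_len(n_u)), sprintf("c%d", seq_len(n_c)))
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  take <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[take, , drop = FALSE]
  w <- if (unit_weights) rep(1, nrow(pairs)) else round(runif(nrow(pairs), 0.1, 5), 3)
  edges <- data.frame(gene_a = nodes[pairs[, 1]], gene_b = nodes[pairs[, 2]], lls = w)
  net <- fnet(edges, nodes = nodes)
  terms <- sprintf("f%d", seq_len(K))
  ann_rows <- do.call(rbind, lapply(seq_len(n_c), function(i) {
    k <- sample(1:2, 1)
    data.frame(gene = sprintf("c%d", i), term = sample(terms, k))
  }))
  list(net = net, ann = annotation_map(ann_rows), alphabet = terms)
}

# Independent count-based score (binary assignment objective): number of
# uncharacterized-uncharacterized edges with equal labels, plus per node the
# count of characterized direct neighbors annotated with its label.
count_score_oracle <- function(net, ann, assignment) {
  lab <- setNames(assignment$term, assignment$gene)
  char <- intersect(net$nodes, unique(ann$gene))
  sets <- split(ann$term, ann$gene)
  total <- 0
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[r]; b <- net$edges$gene_b[r]
    if (a %in% names(lab) && b %in% names(lab)) {
      if (lab[[a]] == lab[[b]]) total <- total + 1
    } else if (a %in% names(lab) && b %in% char) {
      if (lab[[a]] %in% sets[[b]]) total <- total + 1
    } else if (b %in% names(lab) && a %in% char) {
      if (lab[[b]] %in% sets[[a]]) total <- total + 1
    }
  }
  total
}

# Independent weighted-score oracle (naive loops over edges).
weighted_score_oracle <- function(net, ann, assignment) {
  lab <- setNames(assignment$term, assignment$gene)
  char <- intersect(net$nodes, unique(ann$gene))
  sets <- split(ann$term, ann$gene)
  total <- 0
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[r]; b <- net$edges$gene_b[r]; w <- net$edges$lls[r]
    if (a %in% names(lab) && b %in% names(lab)) {
      if (lab[[a]] == lab[[b]]) total <- total + w
    } else if (a %in% names(lab) && b %in% char) {
      if (lab[[a]] %in% sets[[b]]) total <- total + w
    } else if (b %in% names(lab) && a %in% char) {
      if (lab[[b]] %in% sets[[a]]) total <- total + w
    }
  }
  total
}

# Brute-force ROC/AUC oracle: explicit loops over thresholds and genes,
# applying the strict-majority rule, the maximal-coverage sweep stop, and the
# documented endpoint handling.
roc_oracle <- function(predictions, truth, mode = "normalized") {
  preds <- tibble::as_tibble(predictions)
  targets <- sort(unique(truth$gene))
  n_targets <- length(targets)
  preds <- preds[preds$gene %in% targets, ]
  true_sets <- split(truth$term, truth$gene)
  theta_star <- min(vapply(split(preds$score, preds$gene), max, numeric(1)))
  thresholds <- sort(unique(preds$score[preds$score >= theta_star]), decreasing = TRUE)
  pts <- data.frame(threshold = thresholds, tp = NA_integer_, fp = NA_integer_)
  for (ti in seq_along(thresholds)) {
    tp <- 0L; fp <- 0L
    for (g in unique(preds$gene)) {
      sel <- preds$term[preds$gene == g & preds$score >= thresholds[ti]]
      if (!length(sel)) next
      n_ok <- length(intersect(unique(sel), true_sets[[g]]))
      if (n_ok / length(unique(sel)) > 0.5) tp <- tp + 1L else fp <- fp + 1L
    }
    pts$tp[ti] <- tp; pts$fp[ti] <- fp
  }
  pts$tpr <- pts$tp / n_targets
  pts$fpr <- pts$fp / n_targets
  coverage <- max((pts$tp + pts$fp) / n_targets)
  xy <- unique(pts[, c("fpr", "tpr")])
  xy <- xy[order(xy$fpr, xy$tpr), ]
  x <- c(0, xy$fpr); y <- c(0, xy$tpr)
  if (mode == "connect" || coverage >= 1 - 1e-12) {
    x <- c(x, 1); y <- c(y, 1)
    auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  } else {
    x <- c(x, 1); y <- c(y, y[length(y)])
    auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2) / coverage
  }
  list(roc = pts, auc = auc, coverage = coverage)
}

# Brute-force SR-vs-FD oracle (per-prediction successes).
sr_fd_oracle <- function(predictions, truth, net, ann, threshold) {
  preds <- tibble::as_tibble(predictions)
  targets <- sort(unique(truth$gene))
  true_sets <- split(truth$term, truth$gene)
  char <- intersect(net$nodes, unique(ann$gene))
  fd <- sapply(targets, function(g) {
    nb <- c(net$edges$gene_b[net$edges$gene_a == g], net$edges$gene_a[net$edges$gene_b == g])
    sum(nb %in% char)
  })
  rows <- preds[preds$gene %in% targets & preds$score >= threshold, ]
  if (!nrow(rows)) return(data.frame(fd = integer(), n = integer(),
                                     n_success = integer(), sr = numeric()))
  rows$fd <- fd[rows$gene]
  rows$success <- mapply(function(g, f) f %in% true_sets[[g]], rows$gene, rows$term)
  out <- do.call(rbind, lapply(sort(unique(rows$fd)), function(d) {
    s <- rows$success[rows$fd == d]
    data.frame(fd = d, n = length(s), n_success = sum(s), sr = mean(s))
  }))
  out
}
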