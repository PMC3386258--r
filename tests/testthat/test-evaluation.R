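test_that("the strict-majority rule classifies predictions", {
  expect_equal(classify_prediction(c("f1", "f2", "f3"), c("f1", "f2")), "TP")
  expect_equal(classify_prediction(c("f1", "f2"), "f1"), "FP")  # exactly half
  expect_equal(classify_prediction("f1", "f1"), "TP")
  expect_error(classify_prediction(character(), "f1"), "non-empty")
  expect_error(classify_prediction("f1", character()), "non-empty")
})

test_that("the per-simulation threshold is the min of per-gene maxima", {
  p <- prediction_set(data.frame(
    gene = c("a", "a", "b", "c"),
    term = c("f1", "f2", "f1", "f2"),
    score = c(0.9, 0.3, 0.6, 0.8)
  ))
  expect_equal(select_threshold(p), 0.6)
  expect_equal(select_threshold(p, targets = "c"), 0.8)
  expect_error(select_threshold(p, targets = c("a", "zz")), "zz")

  same <- prediction_set(data.frame(gene = c("a", "b"), term = "f1", score = 1))
  expect_equal(select_threshold(same), 1)
  single <- prediction_set(data.frame(gene = "a", term = "f1", score = 0.37))
  expect_equal(select_threshold(single), 0.37)
})

test_that("a perfect predictor reaches AUC 1", {
  truth <- data.frame(gene = sprintf("g%d", 1:10),
                      term = rep(c("f1", "f2"), 5))
  p <- prediction_set(data.frame(gene = truth$gene, term = truth$term, score = 1))
  ev <- roc_and_auc(p, truth)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$coverage, 1.0)
})

test_that("a single threshold level gives the closed-form trapezoid", {
  # 4 targets, 3 predicted correctly, 1 wrongly, all at confidence 0.5
  truth <- data.frame(gene = c("a", "b", "c", "d"), term = "f1")
  p <- prediction_set(data.frame(gene = c("a", "b", "c", "d"),
                                 term = c("f1", "f1", "f1", "f2"),
                                 score = 0.5))
  ev <- roc_and_auc(p, truth)
  expect_equal(nrow(ev$roc), 1)
  # trapezoid through (0,0), (1/4, 3/4), (1,1)
  expect_equal(ev$auc, 0.25 * 0.75 / 2 + 0.75 * (0.75 + 1) / 2)
})

test_that("random guesses on two balanced functions give AUC near 1/2", {
  # null predictor: one uniformly chosen term per gene, uniform confidence
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    genes <- sprintf("g%03d", 1:n)
    truth <- data.frame(gene = genes, term = sample(c("f1", "f2"), n, replace = TRUE))
    p <- prediction_set(data.frame(
      gene = genes, term = sample(c("f1", "f2"), n, replace = TRUE),
      score = runif(n)
    ))
    roc_and_auc(p, truth)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  inst <- random_instance(12, max_unchar = 6)
  cl <- clear_annotations(inst$ann, 0.5, seed = 1)
  p <- pc_predict(inst$net, cl$masked, inst$alphabet)
  if (!nrow(p)) skip("degenerate random instance")
  ev1 <- roc_and_auc(p, cl$truth)
  p2 <- prediction_set(dplyr::mutate(tibble::as_tibble(p), score = exp(3 * score) - 0.5))
  ev2 <- roc_and_auc(p2, cl$truth)
  expect_equal(ev1$auc, ev2$auc)
  expect_equal(ev1$roc$tp, ev2$roc$tp)
})

test_that("classified coverage is non-decreasing along the sweep", {
  for (s in c(3, 9)) {
    inst <- random_instance(s)
    cl <- clear_annotations(inst$ann, 0.5, seed = s)
    p <- functional_flow_predict(inst$net, cl$masked, inst$alphabet)
    if (!nrow(p)) next
    ev <- roc_and_auc(p, cl$truth)
    made <- ev$roc$tp + ev$roc$fp
    expect_true(all(diff(made) >= 0))
    expect_true(all(ev$roc$tp + ev$roc$fp <= ev$n_targets))
  }
})

test_that("SR-vs-FD bins group thresholded predictions by functional degree", {
  # four targets, each with one characterized neighbor (FD 1), known outcomes
  net <- fnet(data.frame(a = c("u1", "u2", "u3", "u4"),
                         b = c("a1", "a2", "a3", "a4"), w = 1))
  ann <- annotation_map(data.frame(gene = sprintf("a%d", 1:4), term = "f9"))
  truth <- data.frame(gene = c("u1", "u2", "u3", "u4"),
                      term = c("f1", "f9", "f2", "f1"))
  p <- prediction_set(data.frame(gene = c("u1", "u2", "u3", "u4"),
                                 term = c("f1", "f1", "f2", "f1"),
                                 score = 0.8))
  tab <- sr_vs_fd(p, truth, net, ann)
  expect_equal(tab$fd, 1L)
  expect_equal(tab$n, 4L)
  expect_equal(tab$sr, 0.75)

  # isolated node lands in the FD 0 bin
  net2 <- fnet(data.frame(a = "a1", b = "a2", w = 1), nodes = c("a1", "a2", "u"))
  fd <- functional_degree(net2, ann, "u")
  expect_equal(unname(fd), 0L)
})

test_that("masking annotations never increases functional degree", {
  inst <- random_instance(14)
  cl <- clear_annotations(inst$ann, 0.5, seed = 2)
  nodes <- inst$net$nodes
  fd_full <- functional_degree(inst$net, inst$ann, nodes)
  fd_masked <- functional_degree(inst$net, cl$masked, nodes)
  expect_true(all(fd_masked <= fd_full))
})

test_that("per-gene success applies the majority rule within bins", {
  net <- fnet(data.frame(a = c("u1", "u2"), b = c("a1", "a2"), w = 1))
  ann <- annotation_map(data.frame(gene = c("a1", "a2"), term = "f9"))
  truth <- data.frame(gene = c("u1", "u1", "u2"), term = c("f1", "f2", "f3"))
  p <- prediction_set(data.frame(gene = c("u1", "u1", "u2"),
                                 term = c("f1", "f2", "f4"),
                                 score = c(0.5, 0.5, 0.5)))
  tab_pred <- sr_vs_fd(p, truth, net, ann, success_unit = "prediction")
  expect_equal(attr(tab_pred, "sr_global"), 2 / 3)
  tab_gene <- sr_vs_fd(p, truth, net, ann, success_unit = "gene")
  expect_equal(attr(tab_gene, "sr_global"), 1 / 2)  # u1 TP (2/2), u2 FP
})

test_that("a one-cell benchmark equals running the stages by hand", {
  sim <- generate_planted_network(synthetic_spec(n_nodes = 60, n_functions = 3), seed = 8)
  bm <- run_benchmark(sim$network, sim$annotations, algorithms = "ff",
                      fractions = 0.2, n_replicates = 1, seed = 99)
  row <- bm$replicates
  expect_equal(nrow(row), 1)
  mask_seed <- wnp:::derive_seed(99, 1, 1)
  cl <- clear_annotations(sim$annotations, 0.2, mask_seed)
  p <- functional_flow_predict(sim$network, cl$masked,
                               function_alphabet(sim$annotations))
  ev <- roc_and_auc(p, cl$truth)
  srt <- sr_vs_fd(p, cl$truth, sim$network, cl$masked)
  expect_equal(row$auc, ev$auc)
  expect_equal(row$sr, attr(srt, "sr_global"))
  expect_equal(row$threshold, attr(srt, "threshold"))
})

test_that("benchmark aggregation is reproducible and tidy-accessible", {
  sim <- generate_planted_network(synthetic_spec(n_nodes = 50, n_functions = 3), seed = 4)
  opts <- list(wnp = gsa_config(n_steps = 3000, n_restarts = 3))
  b1 <- run_benchmark(sim$network, sim$annotations, algorithms = c("wnp", "pc"),
                      fractions = c(0.1, 0.2), n_replicates = 2, seed = 7, opts = opts)
  b2 <- run_benchmark(sim$network, sim$annotations, algorithms = c("wnp", "pc"),
                      fractions = c(0.1, 0.2), n_replicates = 2, seed = 7, opts = opts)
  expect_equal(tidy(b1), tidy(b2))
  expect_equal(nrow(tidy(b1)), 2 * 2 * 2)
  expect_setequal(names(glance(b1)),
                  c("algorithm", "fraction", "n_ok", "auc_mean", "auc_sd",
                    "sr_mean", "sr_sd"))
  expect_error(run_benchmark(sim$network, sim$annotations, algorithms = "nope"),
               "Unknown algorithm")
})

test_that("evaluation matches the brute-force oracle on small instances", {
  n_checked <- 0
  for (s in 1:25) {
    inst <- random_instance(s, max_unchar = 4)
    cl <- clear_annotations(inst$ann, 0.5, seed = s + 1000)
    p <- pc_predict(inst$net, cl$masked, inst$alphabet)
    p_t <- tibble::as_tibble(p)[tibble::as_tibble(p)$gene %in% cl$truth$gene, ]
    if (!nrow(p_t)) next
    ev <- roc_and_auc(p, cl$truth)
    or <- roc_oracle(p, cl$truth)
    expect_equal(ev$auc, or$auc)
    expect_equal(ev$coverage, or$coverage)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
})
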