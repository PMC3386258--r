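test_that("binary SA finds the binarized toy optimum", {
  # binarized toy: optimum sigma = (f1, f1) with score 2 (pair 1 + field 1+0)
  ex <- exhaustive_optimize(binarize(toy_net()), toy_ann())
  expect_equal(ex$score, 2)
  expect_equal(ex$assignment$term, c("f1", "f1"))
  p <- sa_predict(toy_net(), toy_ann(),
                  config = sa_config(n_steps = 2000, n_restarts = 10, seed = 1))
  expect_gte(p$score[p$gene == "u1" & p$term == "f1"], 0.9)
})

test_that("weight-blind SA and WNP disagree where counts and weights conflict", {
  # u1 sees f1 through one heavy edge (w=10) and f2 through two light ones
  net <- fnet(data.frame(a = c("u1", "u1", "u1"), b = c("a1", "a2", "a3"),
                         w = c(10, 1, 1)))
  ann <- annotation_map(data.frame(gene = c("a1", "a2", "a3"),
                                   term = c("f1", "f2", "f2")))
  sa <- sa_predict(net, ann, config = sa_config(n_steps = 2000, n_restarts = 10, seed = 2))
  wnp <- wnp_predict(net, ann, config = gsa_config(n_steps = 2000, n_restarts = 10, seed = 2))
  expect_equal(sa$term[sa$gene == "u1" & sa$rank == 1], "f2")   # count 2 > 1
  expect_equal(wnp$term[wnp$gene == "u1" & wnp$rank == 1], "f1") # weight 10 > 2
})

test_that("on unit weights the two annealing objectives coincide", {
  for (s in 1:10) {
    inst <- random_instance(s, unit_weights = TRUE, max_unchar = 4, max_terms = 3)
    ex_w <- exhaustive_optimize(inst$net, inst$ann, inst$alphabet)
    ex_b <- exhaustive_optimize(binarize(inst$net), inst$ann, inst$alphabet)
    expect_identical(ex_w$score, ex_b$score)
  }
})

test_that("the chi-square statistic follows its formula", {
  # target p has 3 characterized neighbors, 2 carrying f1; 8 characterized
  # genes total, 2 with f1 -> network frequency 0.25, e = 0.75
  genes <- sprintf("c%d", 1:8)
  net <- fnet(data.frame(a = "p", b = genes[1:3], w = 1), nodes = c("p", genes))
  terms <- c("f1", "f1", "f2", "f2", "f2", "f2", "f2", "f2")
  ann <- annotation_map(data.frame(gene = genes, term = terms))
  p <- chi_square_predict(net, ann)
  s_f1 <- p$score[p$gene == "p" & p$term == "f1"]
  expect_equal(s_f1, (2 - 0.75)^2 / 0.75)

  # n_f equal to e_f exactly gives statistic 0: 4 neighbors, 1 with f1,
  # frequency 2/8 = 0.25 -> e = 1 = n
  net2 <- fnet(data.frame(a = "p", b = genes[1:4], w = 1), nodes = c("p", genes))
  ann2 <- annotation_map(data.frame(
    gene = genes, term = c("f1", rep("f2", 6), "f1")))
  p2 <- chi_square_predict(net2, ann2)
  expect_equal(p2$score[p2$gene == "p" & p2$term == "f1"], 0)

  # isolated target gets no predictions
  net3 <- fnet(data.frame(a = "c1", b = "c2", w = 1), nodes = c("p", "c1", "c2"))
  ann3 <- annotation_map(data.frame(gene = c("c1", "c2"), term = c("f1", "f1")))
  p3 <- chi_square_predict(net3, ann3)
  expect_false("p" %in% p3$gene)

  # no annotated genes at all -> empty predictions with a warning
  net4 <- fnet(data.frame(a = "p", b = "q", w = 1))
  ann4 <- annotation_map(data.frame(gene = "z", term = "f1"))
  expect_warning(p4 <- chi_square_predict(net4, ann4), "No annotated")
  expect_equal(nrow(p4), 0)
})

test_that("functional flow moves weight-capped flow downhill", {
  # one infinite source across a w=2 edge: the cap binds, u receives 2
  net <- fnet(data.frame(a = "a", b = "u", w = 2))
  ann <- annotation_map(data.frame(gene = "a", term = "f1"))
  p <- functional_flow_predict(net, ann, n_iterations = 1)
  expect_equal(p$score[p$gene == "u" & p$term == "f1"], 2)

  # no path to any source of f -> no score for f
  net2 <- fnet(data.frame(a = c("a", "u2"), b = c("u1", "u3"), w = c(1, 1)))
  ann2 <- annotation_map(data.frame(gene = "a", term = "f1"))
  p2 <- functional_flow_predict(net2, ann2, n_iterations = 4)
  expect_false(any(p2$gene %in% c("u2", "u3")))
  expect_true("u1" %in% p2$gene)

  # two equal sources on opposite sides contribute symmetrically
  net3 <- fnet(data.frame(a = c("a1", "u"), b = c("u", "a2"), w = c(3, 3)))
  ann3 <- annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f1")))
  p3 <- functional_flow_predict(net3, ann3, n_iterations = 1)
  one_sided <- functional_flow_predict(
    fnet(data.frame(a = "a1", b = "u", w = 3)),
    annotation_map(data.frame(gene = "a1", term = "f1")), n_iterations = 1)
  expect_equal(p3$score[p3$gene == "u"], 2 * one_sided$score[one_sided$gene == "u"])
})

test_that("flow is conserved: sinks never receive more than sources dispense", {
  for (s in c(2, 21)) {
    inst <- random_instance(s, max_unchar = 6)
    p <- functional_flow_predict(inst$net, inst$ann, n_iterations = 6)
    audit <- attr(p, "params")$flow_audit
    expect_true(all(audit$received <= audit$dispensed + 1e-9))
  }
})

test_that("FS similarity hits its limits and the star example", {
  # p and q adjacent, sharing all other neighbors -> similarity 1 at lambda 0
  net <- fnet(data.frame(a = c("p", "p", "q", "q", "p"),
                         b = c("x", "y", "x", "y", "q"), w = 1))
  ann <- annotation_map(data.frame(gene = "q", term = "f1"))
  p <- wa_predict(net, ann)
  expect_equal(p$score[p$gene == "p" & p$term == "f1"], 1)

  # no common neighbors and not adjacent -> no contribution at all
  net2 <- fnet(data.frame(a = c("p", "x", "y"), b = c("x", "y", "q"), w = 1))
  ann2 <- annotation_map(data.frame(gene = "q", term = "f1"))
  p2 <- wa_predict(net2, ann2)
  expect_false("p" %in% p2$gene)

  # star: center p, leaves q1(f1), q2(f1), q3(f2) -> f1 scores twice f2
  net3 <- fnet(data.frame(a = "p", b = c("q1", "q2", "q3"), w = 1))
  ann3 <- annotation_map(data.frame(gene = c("q1", "q2", "q3"),
                                    term = c("f1", "f1", "f2")))
  p3 <- wa_predict(net3, ann3)
  expect_equal(p3$score[p3$gene == "p" & p3$term == "f1"],
               2 * p3$score[p3$gene == "p" & p3$term == "f2"])
})

test_that("weighted-average voting returns weight fractions", {
  net <- fnet(data.frame(a = c("p", "p"), b = c("a1", "a2"), w = c(3, 1)))
  ann <- annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f2")))
  p <- pc_predict(net, ann)
  expect_equal(p$score[p$gene == "p" & p$term == "f1"], 0.75)
  expect_equal(p$score[p$gene == "p" & p$term == "f2"], 0.25)

  # all neighbors sharing f gives score 1; single-label neighbors sum to 1
  ann2 <- annotation_map(data.frame(gene = c("a1", "a2"), term = c("f1", "f1")))
  p2 <- pc_predict(net, ann2)
  expect_equal(p2$score[p2$gene == "p"], 1)

  for (s in 1:10) {
    inst <- random_instance(s)
    pr <- pc_predict(inst$net, inst$ann, inst$alphabet)
    sums <- tapply(pr$score, pr$gene, sum)
    sets <- split(inst$ann$term, inst$ann$gene)
    multiplicity <- max(lengths(sets))
    expect_true(all(sums <= multiplicity + 1e-9))
  }
})

test_that("on unit weights PC reduces to the neighbor fraction carrying f", {
  inst <- random_instance(5, unit_weights = TRUE)
  pr <- pc_predict(inst$net, inst$ann, inst$alphabet)
  char <- characterized(inst$net, inst$ann)
  sets <- split(inst$ann$term, inst$ann$gene)
  for (r in seq_len(nrow(pr))) {
    g <- pr$gene[r]
    nb <- c(inst$net$edges$gene_b[inst$net$edges$gene_a == g],
            inst$net$edges$gene_a[inst$net$edges$gene_b == g])
    nb <- nb[nb %in% char]
    frac <- mean(vapply(nb, function(q) pr$term[r] %in% sets[[q]], logical(1)))
    expect_equal(pr$score[r], frac)
  }
})

test_that("every algorithm emits a valid prediction set on a common instance", {
  sim <- generate_planted_network(synthetic_spec(n_nodes = 60, n_functions = 3), seed = 5)
  cl <- clear_annotations(sim$annotations, 0.15, seed = 6)
  al <- function_alphabet(sim$annotations)
  preds <- list(
    wnp = wnp_predict(sim$network, cl$masked, al,
                      gsa_config(n_steps = 5000, n_restarts = 4, seed = 7)),
    sa = sa_predict(sim$network, cl$masked, al,
                    sa_config(n_steps = 5000, n_restarts = 4, seed = 7)),
    ff = functional_flow_predict(sim$network, cl$masked, al),
    wa = wa_predict(sim$network, cl$masked, al),
    pc = pc_predict(sim$network, cl$masked, al),
    chis = chi_square_predict(sim$network, cl$masked, al)
  )
  for (nm in names(preds)) {
    p <- preds[[nm]]
    expect_s3_class(p, "prediction_set")
    expect_true(all(p$term %in% al), info = nm)
    by_gene <- split(p$score, p$gene)
    expect_true(all(vapply(by_gene, function(s) all(diff(s) <= 0), logical(1))), info = nm)
  }
})
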