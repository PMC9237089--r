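test_that("NMI handles identity, independence and a hand contingency table", {
  p <- c(a = "1", b = "1", c = "2", d = "2")
  expect_equal(nmi(p, p), 1)

  one <- c(a = "x", b = "x", c = "x", d = "x")
  expect_equal(nmi(p, one), 0)
  expect_equal(nmi(one, one), 1)  # both single-community: defined as 1

  # p = {a,b | c,d}, q = {a,b,c | d}: entropies and MI from the 2x2 table
  q <- c(a = "A", b = "A", c = "A", d = "B")
  h1 <- -2 * (0.5 * log(0.5))
  h2 <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  mi <- 0.5 * log(0.5 / (0.5 * 0.75)) + 0.25 * log(0.25 / (0.5 * 0.75)) +
    0.25 * log(0.25 / (0.5 * 0.25))
  expect_equal(nmi(p, q), 2 * mi / (h1 + h2))
  expect_equal(nmi(p, q, variant = "max"), mi / max(h1, h2))
  expect_equal(nmi(p, q, variant = "sqrt"), mi / sqrt(h1 * h2))

  expect_error(nmi(p, q[1:3]), "universe")
})

test_that("NMI is symmetric, relabeling-invariant and agrees with igraph", {
  withr::local_seed(11)
  for (i in 1:8) {
    nodes <- sprintf("n%02d", 1:30)
    p <- stats::setNames(as.character(sample(4, 30, TRUE)), nodes)
    q <- stats::setNames(as.character(sample(3, 30, TRUE)), nodes)
    expect_equal(nmi(p, q), nmi(q, p))
    relab <- stats::setNames(letters[as.integer(p)], nodes)
    expect_equal(nmi(p, q), nmi(relab, q))
    ig <- igraph::compare(as.integer(factor(p)), as.integer(factor(q[nodes])),
                          method = "nmi")
    expect_equal(nmi(p, q), ig, tolerance = 1e-12)
  }
})

test_that("pairwise IR metrics match enumerated pair counts", {
  truth <- c(a = "1", b = "1", c = "2", d = "2")
  expect_equal(as.numeric(pairwise_ir_metrics(truth, truth)), rep(1, 4))

  # detected all-singletons: no pair together, sensitivity 0
  singles <- c(a = "w", b = "x", c = "y", d = "z")
  m0 <- pairwise_ir_metrics(truth, singles)
  expect_equal(unname(m0["sensitivity"]), 0)
  expect_true("precision" %in% attr(m0, "undefined"))

  # detected one big community: TP=2, FP=4, FN=0, TN=0 over the 6 pairs
  merged <- c(a = "m", b = "m", c = "m", d = "m")
  m1 <- pairwise_ir_metrics(truth, merged)
  expect_equal(unname(m1["precision"]), 1 / 3)
  expect_equal(unname(m1["sensitivity"]), 1)
  expect_equal(unname(m1["accuracy"]), 2 / 6)
  expect_equal(unname(m1["f1"]), 2 * (1 / 3) / (4 / 3))

  expect_error(pairwise_ir_metrics(truth["a"], singles["a"]), "2 nodes")
})

test_that("pairwise metrics are relabeling-invariant; accuracy 1 iff equal partitions", {
  withr::local_seed(13)
  nodes <- sprintf("n%02d", 1:20)
  truth <- stats::setNames(as.character(sample(3, 20, TRUE)), nodes)
  det <- stats::setNames(as.character(sample(3, 20, TRUE)), nodes)
  relab <- stats::setNames(paste0("c", det), nodes)
  expect_equal(pairwise_ir_metrics(truth, det), pairwise_ir_metrics(truth, relab))
  expect_lt(unname(pairwise_ir_metrics(truth, det)["accuracy"]), 1)
  expect_equal(unname(pairwise_ir_metrics(truth, truth)["accuracy"]), 1)
})

test_that("node-majority scheme scores plurality-mapped labels", {
  truth <- c(a = "1", b = "1", c = "2", d = "2")
  merged <- c(a = "m", b = "m", c = "m", d = "m")
  m <- pairwise_ir_metrics(truth, merged, scheme = "node_majority")
  # the single community maps to label "1" (tie 2-2 -> lexicographic)
  expect_equal(unname(m["accuracy"]), 0.5)
})

test_that("pathway protein ratio uses plurality labels with lexicographic ties", {
  det <- c(p1 = "c1", p2 = "c1", p3 = "c1", q1 = "c2", q2 = "c2", z1 = "c3")
  ann <- list(p1 = "Auxin", p2 = "Auxin", q1 = "Auxin", q2 = "ABA")
  ppr <- pathway_protein_ratio(det, ann)
  expect_equal(nrow(ppr), 2)  # c3 has no annotated member
  c1 <- ppr[ppr$community == "c1", ]
  expect_equal(c1$label, "Auxin")
  expect_equal(c1$ratio, 2 / 3)
  # c2 ties Auxin vs ABA -> ABA (lexicographically smaller), ratio 1/2
  c2 <- ppr[ppr$community == "c2", ]
  expect_equal(c2$label, "ABA")
  expect_equal(c2$ratio, 1 / 2)
  expect_equal(attr(ppr, "mean_ratio"), mean(c(2 / 3, 1 / 2)))
})

test_that("size classes split at 3 and 5 inclusively", {
  det <- rep(c("a", "b", "c"), times = c(2, 4, 7))
  names(det) <- sprintf("n%02d", seq_along(det))
  expect_equal(size_classes(det), c(n_small = 1L, n_motif = 1L, n_module = 1L))

  det2 <- rep(c("a", "b"), times = c(3, 5))
  names(det2) <- sprintf("n%02d", seq_along(det2))
  expect_equal(size_classes(det2), c(n_small = 1L, n_motif = 1L, n_module = 0L))

  empty <- structure(character(), names = character())
  expect_equal(size_classes(empty), c(n_small = 0L, n_motif = 0L, n_module = 0L))
})

test_that("overlap and variation ratios follow the set arithmetic", {
  baseline <- stats::setNames(rep("W", 4), c("n1", "n2", "n3", "n4"))
  exact <- stats::setNames(rep("d1", 4), c("n1", "n2", "n3", "n4"))
  ov <- overlap_variation(exact, baseline)
  expect_equal(ov$overlap_ratio, 1)
  expect_equal(ov$variation_ratio, 0)

  shifted <- stats::setNames(rep("d1", 4), c("n3", "n4", "n5", "n6"))
  ov2 <- overlap_variation(shifted, baseline)
  expect_equal(ov2$overlap_ratio, 0.5)
  expect_equal(ov2$variation_ratio, 0.5)

  disjoint <- stats::setNames(rep("d1", 2), c("m1", "m2"))
  ov3 <- overlap_variation(disjoint, baseline)
  expect_equal(ov3$overlap_ratio, 0)

  # |D| = |D n B| + |D \ B| bookkeeping on random partitions
  withr::local_seed(17)
  nodes <- sprintf("n%02d", 1:40)
  det <- stats::setNames(as.character(sample(5, 40, TRUE)), nodes)
  base <- stats::setNames(as.character(sample(4, 40, TRUE)), nodes)
  ovr <- overlap_variation(det, base)
  for (k in seq_len(nrow(ovr))) {
    expect_equal(ovr$matched_size[k],
                 ovr$intersection[k] +
                   round(ovr$variation_ratio[k] * ovr$baseline_size[k]))
  }
})

test_that("oversized matches are flagged untestable and left out of the aggregate", {
  baseline <- stats::setNames(rep(c("small", "big"), c(2, 10)), sprintf("n%02d", 1:12))
  # one giant detected community swallowing everything
  det <- stats::setNames(rep("all", 12), sprintf("n%02d", 1:12))
  ov <- overlap_variation(det, baseline)
  expect_true(ov$untestable[ov$baseline == "small"])   # 12 > 5 * 2
  expect_false(ov$untestable[ov$baseline == "big"])
  agg <- attr(ov, "aggregate")
  expect_equal(unname(agg["mean_overlap"]), 1)  # only "big" counts
})

test_that("a trivially recoverable grid cell scores NMI 1 for both partitions", {
  cfg <- experiment_config(block_sizes = c(8, 8, 8), p_in = 1, p_out = 0,
                           obs_grid = 1, si_grid = 0, repeats = 1, seed = 1)
  res <- run_grid(cfg)
  expect_equal(res$rows$nmi, c(1, 1))
  expect_equal(nrow(res$summary), 2)
})

test_that("grid bookkeeping: row counts and reproducibility", {
  cfg <- experiment_config(block_sizes = c(10, 10), p_in = 0.6, p_out = 0.05,
                           obs_grid = c(0.6, 1), si_grid = c(0, 0.5),
                           repeats = 2, seed = 7)
  res <- run_grid(cfg)
  expect_equal(nrow(res$rows), 2 * 2 * 2 * 2)  # obs x si x repeats x kinds
  expect_equal(nrow(res$summary), 2 * 2 * 2)   # obs x si x kinds
  expect_true(all(res$rows$nmi >= 0 & res$rows$nmi <= 1))
  res2 <- run_grid(cfg)
  expect_identical(res$rows, res2$rows)
})

test_that("corrupted side information degrades pairwise accuracy", {
  accs <- sapply(c(0, 0.5, 1), function(fc) {
    vals <- sapply(1:4, function(s) {
      g <- generate_sbm(sbm_config(c(25, 25, 25), 0.3, 0.02, seed = 200 + s))
      inst <- observe(g$network, g$truth, 1, seed = 200 + s)
      si <- sample_side_info(inst, 0.5, seed = 200 + s)
      if (fc > 0) si <- corrupt_side_info(si, inst$truth, fc, seed = 200 + s)
      tr <- detect(inst$graph, side_info = si)
      unname(pairwise_ir_metrics(inst$truth, tr$final_partition)["accuracy"])
    })
    mean(vals)
  })
  expect_true(all(diff(accs) <= 1e-12))
})
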