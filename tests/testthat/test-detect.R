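test_that("edge protection requires a shared label on both endpoints", {
  si <- list(p1 = "Auxin", p2 = c("ABA", "Auxin"), p3 = "ET")
  expect_true(is_protected(c("p1", "p2"), si))
  expect_false(is_protected(c("p1", "p3"), si))
  expect_false(is_protected(c("p1", "p9"), si))
  expect_false(is_protected(c("p1", "p2"), NULL))
})

test_that("component partition labels communities by smallest member id", {
  two_tri <- network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("x", "y"), c("x", "z"), c("y", "z")))
  p <- components_partition(two_tri)
  expect_equal(unname(p[c("a", "b", "c")]), rep("a", 3))
  expect_equal(unname(p[c("x", "y", "z")]), rep("x", 3))

  conn <- path_net(5)
  expect_length(unique(components_partition(conn)), 1)

  iso <- network(nodes = c("u", "v", "w"))
  expect_equal(components_partition(iso), c(u = "u", v = "v", w = "w"))
})

test_that("modularity matches closed forms and the igraph implementation", {
  two_tri <- network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                           c("x", "y"), c("x", "z"), c("y", "z")))
  comp <- components_partition(two_tri)
  # 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(modularity_q(two_tri, comp), 0.5)

  one <- stats::setNames(rep("all", 6), two_tri$nodes)
  expect_equal(modularity_q(two_tri, one), 0)

  # all singletons: -sum((d_i / 2m)^2), always negative
  for (s in 1:5) {
    net <- random_net(12, 0.3, seed = s)
    if (nrow(net$edges) == 0) next
    singles <- stats::setNames(net$nodes, net$nodes)
    degs <- table(factor(c(net$edges[, 1], net$edges[, 2]), levels = net$nodes))
    closed <- -sum((as.numeric(degs) / (2 * nrow(net$edges)))^2)
    expect_equal(modularity_q(net, singles), closed)
    expect_lt(modularity_q(net, singles), 0)
  }

  expect_error(modularity_q(network(nodes = c("a", "b")), c(a = "1", b = "1")),
               "edgeless")
  expect_error(modularity_q(two_tri, comp[-1]), "total")
})

test_that("trace modularity and component counts agree with igraph at every step", {
  for (s in 1:5) {
    net <- random_net(16, 0.2, seed = 20 + s)
    if (nrow(net$edges) < 3) next
    tr <- detect(net)
    expect_equal(tr$initial$modularity, modularity_q(net, tr$initial$partition))
    for (k in seq_len(nrow(tr$steps))) {
      p <- tr$partitions[[k]]
      expect_equal(tr$steps$modularity[k], modularity_q(net, p), tolerance = 1e-12)
      expect_equal(tr$steps$n_communities[k], length(unique(p)))
    }
  }
})

test_that("barbell: the bridge is the only removal, and SI on its endpoints prevents it", {
  bb <- barbell_net()
  tr <- detect(bb)
  expect_equal(nrow(tr$steps), 1)
  expect_equal(c(tr$steps$u, tr$steps$v), c("c", "d"))
  expect_equal(tr$steps$kappa, -2 / 3, tolerance = 1e-9)
  expect_length(unique(tr$final_partition), 2)
  expect_equal(unname(tr$final_partition[c("a", "b", "c")]), rep("a", 3))

  tr_si <- detect(bb, side_info = list(c = "X", d = "X"))
  expect_equal(nrow(tr_si$steps), 0)
  expect_length(unique(tr_si$final_partition), 1)
})

test_that("graphs without negative edges are left untouched", {
  tr <- detect(triangle_net())
  expect_equal(nrow(tr$steps), 0)
  expect_identical(tr$final_partition, tr$initial$partition)
  expect_equal(tr$mm_step_index, 0)
})

test_that("edgeless input yields an all-singleton trace with no steps", {
  net <- network(nodes = c("a", "b", "c"))
  tr <- detect(net)
  expect_equal(nrow(tr$steps), 0)
  expect_equal(length(unique(tr$final_partition)), 3)
  expect_true(is.na(tr$initial$modularity))
})

test_that("partitions nest, community counts never decrease, protected edges survive", {
  for (s in 1:8) {
    net <- random_net(20, 0.15, seed = 40 + s)
    if (nrow(net$edges) < 4) next
    si <- list()
    si[[net$edges[1, 1]]] <- "L"
    si[[net$edges[1, 2]]] <- "L"
    tr <- detect(net, side_info = si)
    parts <- c(list(tr$initial$partition), tr$partitions)
    for (k in seq_along(parts)[-1]) {
      prev <- parts[[k - 1]]; cur <- parts[[k]]
      # refinement: equal labels now implies equal labels before
      expect_true(all(tapply(prev[names(cur)], cur, function(x) length(unique(x))) == 1))
    }
    expect_true(all(diff(c(tr$initial$n_communities, tr$steps$n_communities)) >= 0))
    expect_lte(nrow(tr$steps), nrow(net$edges))
    # the protected edge's endpoints stay in one community throughout
    expect_equal(unname(tr$final_partition[net$edges[1, 1]]),
                 unname(tr$final_partition[net$edges[1, 2]]))
  }
})

test_that("maximum-modularity state maximises Q with earliest-step tie-breaking", {
  for (s in 1:6) {
    net <- random_net(18, 0.18, seed = 60 + s)
    if (nrow(net$edges) < 3) next
    tr <- detect(net)
    qs <- c(tr$initial$modularity, tr$steps$modularity)
    expect_equal(tr$mm_step_index, which.max(qs) - 1L)
    mm <- if (tr$mm_step_index == 0) tr$initial$partition else tr$partitions[[tr$mm_step_index]]
    expect_identical(tr$mm_partition, mm)
  }
})

test_that("detection on a disjoint union equals the union of per-component detections", {
  a <- random_net(12, 0.25, seed = 71)
  b_el <- barbell_net()$edges
  b_el[] <- paste0("zz", b_el)
  both <- network(rbind(a$edges, b_el), nodes = c(a$nodes, paste0("zz", barbell_net()$nodes)))
  tr_both <- detect(both)
  tr_a <- detect(a)
  tr_b <- detect(network(b_el))
  removed_both <- paste(tr_both$steps$u, tr_both$steps$v)
  removed_sep <- c(paste(tr_a$steps$u, tr_a$steps$v), paste(tr_b$steps$u, tr_b$steps$v))
  expect_setequal(removed_both, removed_sep)
  # final communities agree on each part
  expect_equal(length(unique(tr_both$final_partition)),
               length(unique(tr_a$final_partition)) + length(unique(tr_b$final_partition)))
})

test_that("full ground-truth side information preserves every planted community", {
  for (s in 1:5) {
    g <- generate_sbm(sbm_config(c(12, 12, 12), 0.5, 0.05, seed = 80 + s))
    si <- as.list(g$truth)
    tr <- detect(g$network, side_info = si)
    if (nrow(tr$steps)) {
      removed_intra <- g$truth[tr$steps$u] == g$truth[tr$steps$v]
      expect_false(any(removed_intra))
    }
    # each planted community's induced subgraph keeps its connectivity
    for (blk in unique(g$truth)) {
      members <- names(g$truth)[g$truth == blk]
      em <- g$network$edges
      induced <- em[em[, 1] %in% members & em[, 2] %in% members, , drop = FALSE]
      sub <- network(induced, nodes = members)
      before <- length(unique(components_partition(sub)))
      after <- length(unique(tr$final_partition[members]))
      expect_equal(after, before)
    }
  }
})

test_that("incremental and full recomputation produce identical traces", {
  for (s in 1:10) {
    net <- random_net(10 + s, 0.15, seed = 90 + s)
    t1 <- detect(net)
    t2 <- detect(net, config = detection_config(full_recompute = TRUE))
    expect_identical(t1$steps, t2$steps)
    expect_identical(t1$partitions, t2$partitions)
    expect_identical(t1$mm_step_index, t2$mm_step_index)
  }
})

test_that("trace TSV writer emits the documented columns", {
  f <- withr::local_tempfile()
  write_trace(detect(barbell_net()), f)
  lines <- readLines(f)
  expect_equal(lines[1], "step\tremoved_u\tremoved_v\tkappa\tn_communities\tmodularity")
  expect_match(lines[2], "^1\tc\td\t-0\\.6666666667\t2\t")
})
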