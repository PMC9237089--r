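# Independent oracles used to freeze expected values.  These never call the
# package's transport solver: the Wasserstein oracle enumerates integer
# transport plans by depth-first search with branch-and-bound, after scaling
# the (rational) masses to integers.

# smallest integer scaling factor for a rational mass vector
mass_denominator <- function(mass, max_den = 5000L) {
  for (d in seq_len(max_den)) {
    if (all(abs(mass * d - round(mass * d)) < 1e-9)) return(d)
  }
  stop("masses are not rational with a small denominator")
}

# exact W1 by exhaustive enumeration of integer transport plans (flows are
# multiples of 1/denominator at some optimal vertex), with branch-and-bound
oracle_wasserstein <- function(mass_a, mass_b, cost) {
  d <- mass_denominator(c(mass_a, mass_b))
  r <- as.integer(round(mass_a * d))
  cc <- as.integer(round(mass_b * d))
  m <- length(r); n <- length(cc)
  cost <- matrix(as.numeric(cost), m, n)

  # greedy incumbent: fill cheapest cells first
  ord <- order(cost)
  rem_r <- r; rem_c <- cc
  ub <- 0
  for (k in ord) {
    i <- (k - 1) %% m + 1; j <- (k - 1) %/% m + 1
    f <- min(rem_r[i], rem_c[j])
    if (f > 0) { ub <- ub + f * cost[i, j]; rem_r[i] <- rem_r[i] - f; rem_c[j] <- rem_c[j] - f }
  }
  best <- ub

  row_min_available <- function(i, rem_c) {
    avail <- rem_c > 0
    if (!any(avail)) Inf else min(cost[i, avail])
  }

  rec <- function(i, j, rem_i, rem_c, acc) {
    # admissible lower bound: every remaining unit pays at least its row's
    # cheapest available cost
    lb <- acc + (if (rem_i > 0) rem_i * row_min_available(i, rem_c) else 0)
    if (i < m) {
      for (i2 in (i + 1):m) {
        if (r[i2] > 0) lb <- lb + r[i2] * row_min_available(i2, rem_c)
      }
    }
    if (lb >= best - 1e-12) return(invisible(NULL))
    if (j > n) {
      if (rem_i > 0) return(invisible(NULL))
      if (i == m) { best <<- min(best, acc); return(invisible(NULL)) }
      return(rec(i + 1, 1, r[i + 1], rem_c, acc))
    }
    slack_after <- if (j < n) sum(rem_c[(j + 1):n]) else 0
    f_min <- max(0L, rem_i - slack_after)
    f_max <- min(rem_i, rem_c[j])
    if (f_min > f_max) return(invisible(NULL))
    for (f in f_min:f_max) {
      rc2 <- rem_c; rc2[j] <- rc2[j] - f
      rec(i, j + 1, rem_i - f, rc2, acc + f * cost[i, j])
    }
    invisible(NULL)
  }
  rec(1, 1, r[1], cc, 0)
  best / d
}

# oracle edge curvature: uniform neighbour masses (laziness 0), true hop
# distances from igraph on the component, exhaustive transport enumeration
oracle_edge_orc <- function(net, edge) {
  g <- as_igraph(net)
  x <- edge[1]; y <- edge[2]
  sx <- sort(names(igraph::neighbors(g, x)), method = "radix")
  sy <- sort(names(igraph::neighbors(g, y)), method = "radix")
  dmat <- igraph::distances(g, v = sx, to = sy)
  1 - oracle_wasserstein(rep(1 / length(sx), length(sx)),
                         rep(1 / length(sy), length(sy)),
                         dmat)
}

# --- small named fixtures ---

triangle_net <- function() network(rbind(c("a", "b"), c("a", "c"), c("b", "c")))

path_net <- function(k = 3) {
  ids <- sprintf("p%02d", seq_len(k))
  network(cbind(ids[-k], ids[-1]))
}

cycle_net <- function(k = 4) {
  ids <- sprintf("c%02d", seq_len(k))
  network(cbind(ids, ids[c(2:k, 1)]))
}

complete_net <- function(k = 4) {
  ids <- letters[seq_len(k)]
  network(t(combn(ids, 2)))
}

# two triangles {a,b,c} and {d,e,f} joined by the bridge c--d
barbell_net <- function() {
  network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                c("d", "e"), c("d", "f"), c("e", "f"),
                c("c", "d")))
}

# seeded Erdos-Renyi graph over zero-padded string ids
random_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("r%03d", seq_len(n))
    el <- t(combn(ids, 2))
    el <- el[stats::runif(nrow(el)) < p, , drop = FALSE]
    network(el, nodes = ids)
  })
}
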