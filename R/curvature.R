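# Ollivier-Ricci curvature of edges.
#
# For an edge (x, y) of an unweighted graph, the mass distribution m_x puts a
# "laziness" fraction alpha at x itself and spreads the rest uniformly over
# the neighbours of x (alpha = 0 gives the plain uniform ball).  The edge
# curvature is kappa(x, y) = 1 - W1(m_x, m_y), with W1 the Wasserstein-1
# (earth mover's) distance under hop distance in the current graph.  Positive
# curvature marks intra-community edges, negative curvature marks bridges.

#' Curvature computation settings
#'
#' @param laziness Fraction of probability mass retained at the centre node
#'   when forming a neighbourhood mass distribution; in `[0, 1)`.  The default
#'   0 spreads all mass uniformly over the neighbours.
#' @param tolerance Numerical feasibility tolerance of the transport solver;
#'   also the margin used when comparing curvature against a removal
#'   threshold.
#' @return A list of class `curvature_config`.
#' @export
curvature_config <- function(laziness = 0, tolerance = 1e-9) {
  stopifnot(is.numeric(laziness), length(laziness) == 1,
            laziness >= 0, laziness < 1,
            is.numeric(tolerance), tolerance > 0)
  structure(list(laziness = laziness, tolerance = tolerance),
            class = "curvature_config")
}

#' Probability mass distribution over nodes
#'
#' @param support Character vector of distinct node ids.
#' @param mass Non-negative weights aligned with `support`, summing to 1
#'   (tolerance 1e-9).
#' @return A list of class `mass_distribution`.
#' @export
mass_distribution <- function(support, mass) {
  support <- as.character(support)
  if (anyDuplicated(support)) stop("support nodes must be distinct")
  if (length(support) != length(mass)) stop("support and mass lengths differ")
  if (any(mass < 0)) stop("masses must be non-negative")
  if (abs(sum(mass) - 1) > 1e-9) stop("masses must sum to 1")
  structure(list(support = support, mass = as.numeric(mass)),
            class = "mass_distribution")
}

#' Neighbourhood mass distribution of a node
#'
#' With laziness `alpha`, the node keeps `alpha` of the mass and each
#' neighbour receives `(1 - alpha) / degree`.  Isolated nodes have no defined
#' distribution and raise an error.
#'
#' @param net An `orcci_network`.
#' @param x A node id present in `net`.
#' @param config A [curvature_config()].
#' @return A [mass_distribution()].
#' @examples
#' p <- network(rbind(c("a", "b"), c("b", "c")))
#' neighbor_mass(p, "b")
#' @export
neighbor_mass <- function(net, x, config = curvature_config()) {
  stopifnot(inherits(net, "orcci_network"))
  if (!x %in% net$nodes) stop("node not in network: ", x)
  nb <- radix_sort(c(net$edges[net$edges[, 1] == x, 2],
                     net$edges[net$edges[, 2] == x, 1]))
  if (length(nb) == 0) {
    stop("node '", x, "' is isolated: its mass distribution is undefined")
  }
  a <- config$laziness
  if (a > 0) {
    mass_distribution(c(x, nb), c(a, rep((1 - a) / length(nb), length(nb))))
  } else {
    mass_distribution(nb, rep(1 / length(nb), length(nb)))
  }
}

#' Wasserstein-1 distance between two mass distributions
#'
#' Solves the standard transportation linear program: minimise
#' `sum(flow * dist)` subject to row sums = `mu`, column sums = `nu`,
#' `flow >= 0`, by an exact successive-shortest-path solver.
#'
#' @param mu,nu [mass_distribution()] objects.
#' @param dist Numeric matrix of pairwise ground distances, rows indexed by
#'   `mu$support`, columns by `nu$support`.  Entries must be finite and
#'   non-negative; an infinite entry means the supports live in different
#'   components and transport is undefined.
#' @return The minimum transport cost (a single number).
#' @examples
#' mu <- mass_distribution("b", 1)
#' nu <- mass_distribution(c("a", "c"), c(0.5, 0.5))
#' wasserstein1(mu, nu, matrix(1, 1, 2))
#' @export
wasserstein1 <- function(mu, nu, dist) {
  stopifnot(inherits(mu, "mass_distribution"), inherits(nu, "mass_distribution"))
  dist <- as.matrix(dist)
  if (nrow(dist) != length(mu$support) || ncol(dist) != length(nu$support)) {
    stop("dist must be |support(mu)| x |support(nu)|")
  }
  if (any(!is.finite(dist))) {
    stop("transport undefined: non-finite ground distance (supports in different components?)")
  }
  if (any(dist < 0)) stop("ground distances must be non-negative")
  cpp_transport(mu$mass, nu$mass, dist)
}

# node ids -> 0-based indices into net$nodes; edges assumed normalized
edge_index_matrix <- function(net) {
  matrix(match(net$edges, net$nodes) - 1L, ncol = 2)
}

#' Ollivier-Ricci curvature of one edge
#'
#' `kappa(x, y) = 1 - W1(m_x, m_y)` for an existing edge (hop distance 1).
#' Ground distances are hop distances in the current network, restricted to
#' the component containing the edge.  An edge whose component is exactly the
#' edge itself has `m_x = delta_y`, `m_y = delta_x` and curvature 0.
#'
#' @param net An `orcci_network`.
#' @param edge Character vector of the two endpoint ids.
#' @param config A [curvature_config()].
#' @return The curvature, a number in `[-2, 1]` for laziness 0.
#' @examples
#' tri <- network(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
#' edge_orc(tri, c("a", "b"))  # 1/2
#' @export
edge_orc <- function(net, edge, config = curvature_config()) {
  stopifnot(inherits(net, "orcci_network"), length(edge) == 2)
  em <- net$edges
  e <- radix_sort(as.character(edge))
  hit <- which(em[, 1] == e[1] & em[, 2] == e[2])
  if (length(hit) == 0) stop("edge not in network: ", e[1], " -- ", e[2])
  cpp_edge_curvatures(n_nodes(net), edge_index_matrix(net),
                      hit - 1L, config$laziness)
}

#' Curvature of every edge
#'
#' @param net An `orcci_network`.
#' @param config A [curvature_config()].
#' @return A data frame with columns `u`, `v`, `kappa`, one row per
#'   normalized edge in lexicographic order (the edge curvature map).
#' @export
all_edge_orc <- function(net, config = curvature_config()) {
  stopifnot(inherits(net, "orcci_network"))
  m <- n_edges(net)
  kap <- if (m == 0) numeric() else {
    cpp_edge_curvatures(n_nodes(net), edge_index_matrix(net),
                        seq_len(m) - 1L, config$laziness)
  }
  data.frame(u = net$edges[, 1], v = net$edges[, 2], kappa = kap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Edges whose curvature may change after a removal
#'
#' After deleting `removed`, only edges with an endpoint within 3 hops of an
#' endpoint of `removed` (hop distance measured in the pre-removal graph) can
#' change curvature: every ground distance entering an edge's transport
#' problem is at most 3 while that edge exists, so a removal outside this
#' radius cannot lie on any relevant shortest path.
#'
#' @param net The network BEFORE the removal.
#' @param removed Character vector of the two endpoints of the removed edge.
#' @return Two-column character matrix of the remaining edges to recompute.
#' @export
affected_edges <- function(net, removed) {
  stopifnot(inherits(net, "orcci_network"), length(removed) == 2)
  e <- radix_sort(as.character(removed))
  em <- net$edges
  is_removed <- em[, 1] == e[1] & em[, 2] == e[2]
  if (!any(is_removed)) stop("removed edge not in network")
  g <- as_igraph(net)
  ball <- unique(names(unlist(igraph::ego(g, order = 3, nodes = e))))
  keep <- !is_removed & (em[, 1] %in% ball | em[, 2] %in% ball)
  em[keep, , drop = FALSE]
}

#' Write an edge curvature map as TSV
#'
#' Columns `node_u`, `node_v`, `kappa`, with kappa printed at fixed 10-decimal
#' precision for reproducible diffs.
#'
#' @param curvatures Data frame as returned by [all_edge_orc()].
#' @param path Output path.
#' @export
write_curvature <- function(curvatures, path) {
  lines <- c("node_u\tnode_v\tkappa",
             sprintf("%s\t%s\t%.10f", curvatures$u, curvatures$v,
                     curvatures$kappa))
  writeLines(lines, path)
  invisible(NULL)
}
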