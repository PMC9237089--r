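# Community detection by iterative removal of the most negatively curved
# edge, with optional protection of edges whose endpoints share a-priori
# side-information labels.  Communities are the connected components of the
# residual graph; the trace records every intermediate partition together
# with its Newman modularity on the original graph, from which both the
# final ("all negative edges removed") and the maximum-modularity partitions
# are read off.

#' Detection settings
#'
#' @param curvature_threshold Only edges with curvature strictly below this
#'   value are removable; the default 0 removes exactly the negatively curved
#'   edges.
#' @param laziness Passed to [curvature_config()].
#' @param use_side_info If `FALSE`, side information is ignored even when
#'   supplied to [detect()].
#' @param tie_break Rule for equally most-negative edges; only
#'   `"lexicographic"` (smallest normalized edge first) is implemented, which
#'   makes removal traces deterministic.
#' @param full_recompute If `TRUE`, recompute every surviving edge's
#'   curvature after each removal instead of only the radius-3 affected set;
#'   the results are identical (see [affected_edges()]) and this flag exists
#'   for verification.
#' @param tolerance Numerical margin for the threshold comparison, so that
#'   transport round-off (e.g. a curvature of -1e-16 on an exactly flat edge)
#'   never triggers a removal.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(curvature_threshold = 0, laziness = 0,
                             use_side_info = TRUE,
                             tie_break = "lexicographic",
                             full_recompute = FALSE, tolerance = 1e-9) {
  stopifnot(is.finite(curvature_threshold),
            laziness >= 0, laziness < 1)
  tie_break <- match.arg(tie_break, "lexicographic")
  structure(list(curvature_threshold = curvature_threshold,
                 laziness = laziness, use_side_info = use_side_info,
                 tie_break = tie_break, full_recompute = full_recompute,
                 tolerance = tolerance),
            class = "detection_config")
}

#' Is an edge protected by side information?
#'
#' An edge is retained (never removed) when both endpoints carry side
#' information and their label sets intersect; an unlabeled endpoint never
#' protects.
#'
#' @param edge Character vector of the two endpoint ids.
#' @param side_info Named list mapping node id to a character vector of
#'   labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_protected <- function(edge, side_info) {
  if (is.null(side_info) || length(side_info) == 0) return(FALSE)
  a <- side_info[[edge[1]]]
  b <- side_info[[edge[2]]]
  !is.null(a) && !is.null(b) && length(intersect(a, b)) > 0
}

#' Connected-component partition of a network
#'
#' Each connected component becomes one community; isolated nodes become
#' singletons.  Community ids are deterministic: each community is labelled
#' by its lexicographically smallest member node id.
#'
#' @param net An `orcci_network`.
#' @return Named character vector mapping node id to community id.
#' @export
components_partition <- function(net) {
  stopifnot(inherits(net, "orcci_network"))
  if (n_nodes(net) == 0) return(structure(character(), names = character()))
  comp <- igraph::components(as_igraph(net))$membership
  # vertex order equals sorted node order, so the first node seen per
  # component is its smallest member
  first <- !duplicated(comp)
  labels <- stats::setNames(net$nodes[first], comp[first])
  stats::setNames(unname(labels[as.character(comp)]), net$nodes)
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c/m - (d_c/(2m))^2 ]`, with `m` the edge count of the
#' (original) network, `e_c` the intra-community edge count and `d_c` the
#' total degree of community `c`.  Always evaluate against the original
#' observed graph, not a residual one.
#'
#' @param net An `orcci_network` with at least one edge.
#' @param partition Named character vector covering all nodes of `net`.
#' @return The modularity Q.
#' @export
modularity_q <- function(net, partition) {
  stopifnot(inherits(net, "orcci_network"))
  if (n_edges(net) == 0) stop("modularity is undefined for an edgeless graph")
  if (!setequal(names(partition), net$nodes)) {
    stop("partition must be total on the network's nodes")
  }
  memb <- as.integer(factor(unname(partition[net$nodes])))
  igraph::modularity(as_igraph(net), membership = memb)
}

#' Detect communities by curvature-guided edge removal
#'
#' Repeatedly removes the unprotected edge with the most negative
#' Ollivier-Ricci curvature (strictly below the threshold), recomputing
#' curvature on the evolving residual graph, until no removable edge remains.
#' Two partitions are reported: the final partition (components once all
#' removable negative edges are gone) and the maximum-modularity partition
#' (the intermediate state, possibly the untouched graph, with the highest
#' modularity measured on the original graph; ties resolve to the earliest,
#' coarsest state).
#'
#' @param net An `orcci_network`.
#' @param side_info Optional named list (node id -> labels); edges whose
#'   endpoints share a label are never removed.
#' @param config A [detection_config()].
#' @return An object of class `orc_trace` with elements
#'   \describe{
#'     \item{steps}{data frame, one row per removal: `step`, `u`, `v`,
#'       `kappa`, `n_communities`, `modularity`.}
#'     \item{partitions}{list of the component partitions after each step.}
#'     \item{initial}{list(partition, modularity, n_communities) before any
#'       removal.}
#'     \item{final_partition, mm_partition}{the two reported partitions.}
#'     \item{mm_step_index}{0 for the initial state, otherwise the step
#'       number of the maximum-modularity state.}
#'   }
#' @examples
#' barbell <- network(rbind(
#'   c("a", "b"), c("a", "c"), c("b", "c"),
#'   c("d", "e"), c("d", "f"), c("e", "f"), c("c", "d")))
#' tr <- detect(barbell)
#' tr$steps$kappa  # the bridge, curvature -2/3
#' @export
detect <- function(net, side_info = NULL, config = detection_config()) {
  stopifnot(inherits(net, "orcci_network"))
  if (n_nodes(net) == 0) stop("cannot run detection on an empty network")

  m <- n_edges(net)
  if (m == 0) {
    p0 <- components_partition(net)
    return(new_orc_trace(net, steps = empty_steps(), partitions = list(),
                         initial = list(partition = p0, modularity = NA_real_,
                                        n_communities = length(unique(p0))),
                         q = NA_real_))
  }

  prot <- rep(FALSE, m)
  if (config$use_side_info && !is.null(side_info) && length(side_info) > 0) {
    has_si <- net$edges[, 1] %in% names(side_info) &
      net$edges[, 2] %in% names(side_info)
    idx <- which(has_si)
    prot[idx] <- vapply(idx, function(e) is_protected(net$edges[e, ], side_info),
                        logical(1))
  }

  res <- cpp_detect(n_nodes(net), edge_index_matrix(net), prot,
                    config$laziness, config$curvature_threshold,
                    config$tolerance, config$full_recompute)

  k <- length(res$removed)
  memb_to_partition <- function(row) {
    stats::setNames(net$nodes[row + 1L], net$nodes)
  }
  partitions <- lapply(seq_len(k), function(s) {
    memb_to_partition(res$membership[s + 1L, ])
  })
  steps <- data.frame(
    step = seq_len(k),
    u = net$edges[res$removed + 1L, 1],
    v = net$edges[res$removed + 1L, 2],
    kappa = res$kappa,
    n_communities = res$n_communities[-1L][seq_len(k)],
    modularity = res$modularity[-1L][seq_len(k)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  initial <- list(partition = memb_to_partition(res$membership[1L, ]),
                  modularity = res$modularity[1L],
                  n_communities = res$n_communities[1L])
  new_orc_trace(net, steps, partitions, initial, q = res$modularity)
}

empty_steps <- function() {
  data.frame(step = integer(), u = character(), v = character(),
             kappa = numeric(), n_communities = integer(),
             modularity = numeric(), stringsAsFactors = FALSE)
}

# q: modularity of initial + each step; ties -> earliest (coarsest) state
new_orc_trace <- function(net, steps, partitions, initial, q) {
  final_partition <- if (length(partitions)) partitions[[length(partitions)]]
                     else initial$partition
  mm_idx <- if (all(is.na(q))) 0L else which.max(q) - 1L
  mm_partition <- if (mm_idx == 0L) initial$partition else partitions[[mm_idx]]
  structure(list(steps = steps, partitions = partitions, initial = initial,
                 final_partition = final_partition,
                 mm_partition = mm_partition,
                 mm_step_index = mm_idx,
                 network = net),
            class = "orc_trace")
}

#' @export
print.orc_trace <- function(x, ...) {
  cat(sprintf(paste0(
    "<orc_trace> %d removal(s)\n",
    "  initial : %d communities, Q = %s\n",
    "  final   : %d communities\n",
    "  max mod : %d communities at step %d, Q = %s\n"),
    nrow(x$steps),
    x$initial$n_communities, format(x$initial$modularity, digits = 4),
    length(unique(x$final_partition)),
    length(unique(x$mm_partition)), x$mm_step_index,
    format(if (x$mm_step_index == 0) x$initial$modularity
           else x$steps$modularity[x$mm_step_index], digits = 4)))
  invisible(x)
}

#' Write a removal trace as TSV
#'
#' Columns: `step`, `removed_u`, `removed_v`, `kappa`, `n_communities`,
#' `modularity`.
#'
#' @param trace An `orc_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  s <- trace$steps
  lines <- c("step\tremoved_u\tremoved_v\tkappa\tn_communities\tmodularity",
             sprintf("%d\t%s\t%s\t%.10f\t%d\t%.10f",
                     s$step, s$u, s$v, s$kappa, s$n_communities, s$modularity))
  writeLines(lines, path)
  invisible(NULL)
}
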