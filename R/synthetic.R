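# Synthetic benchmark: stochastic block model networks with planted
# communities, partial observability (induced subgraph on a sampled node
# subset), sampled ground-truth side information, and optional side-
# information corruption.
#
# Random streams for graph generation, observation, side-information
# sampling, and corruption are independent sub-streams derived from the
# instance seed, so varying one grid axis never perturbs the others.

# deterministic sub-stream seeds, kept below 2^31
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 2654435) %% 2147483647) + 1L
}

# round-half-up sample sizes, matching percentage grids exactly
round_half_up <- function(x) floor(x + 0.5)

#' Stochastic block model configuration
#'
#' @param block_sizes Positive integer community sizes; the benchmark design
#'   used throughout is [sbm_benchmark_config()]'s 10 blocks totalling 1000
#'   nodes.
#' @param p_in Probability of an edge inside a block.
#' @param p_out Probability of an edge between blocks.  An assortative model
#'   (`p_out <= p_in`) is expected; the reverse draws a warning but runs.
#' @param seed Integer seed; the same configuration always generates the same
#'   network.
#' @return A list of class `sbm_config`.
#' @export
sbm_config <- function(block_sizes, p_in, p_out, seed = 1L) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 1))
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("edge probabilities must be in [0, 1]")
  }
  if (p_out > p_in) {
    warning("p_out > p_in: disassortative configuration; planted communities will not be assortative")
  }
  structure(list(block_sizes = as.integer(block_sizes),
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "sbm_config")
}

#' The benchmark SBM design
#'
#' Ten planted communities of sizes 150, 125, 125, 110, 100, 100, 90, 75, 75
#' and 50 (1000 nodes in total).  The intra/inter edge probabilities are this
#' package's defaults (`p_in = 0.10`, `p_out = 0.005`), chosen to give a
#' detectable but nontrivial assortative structure at this size; any result
#' that depends on them should state them explicitly.
#'
#' @param seed Integer seed.
#' @param p_in,p_out Override the default edge probabilities.
#' @return An `sbm_config`.
#' @export
sbm_benchmark_config <- function(seed = 1L, p_in = 0.10, p_out = 0.005) {
  sbm_config(c(150L, 125L, 125L, 110L, 100L, 100L, 90L, 75L, 75L, 50L),
             p_in = p_in, p_out = p_out, seed = seed)
}

#' Generate an SBM network with its ground-truth partition
#'
#' Every unordered node pair receives an edge independently with probability
#' `p_in` (same block) or `p_out` (different blocks).  Node ids are
#' deterministic zero-padded strings (`"v0001"`, ...) and block ids are
#' `"b01"`, ... in the order of `block_sizes`.
#'
#' @param config An [sbm_config()].
#' @return A list with elements `network` (an `orcci_network`) and `truth`
#'   (named character vector, node -> block id).
#' @examples
#' g <- generate_sbm(sbm_config(c(3, 4), p_in = 1, p_out = 0))
#' n_distinct <- length(unique(g$truth))  # 2 planted communities
#' @export
generate_sbm <- function(config) {
  stopifnot(inherits(config, "sbm_config"))
  sizes <- config$block_sizes
  n <- sum(sizes)
  nb <- length(sizes)
  pref <- matrix(config$p_out, nb, nb)
  diag(pref) <- config$p_in
  g <- withr::with_seed(substream_seed(config$seed, 1L),
                        igraph::sample_sbm(n, pref.matrix = pref,
                                           block.sizes = sizes))
  ids <- sprintf("v%0*d", max(4L, nchar(n)), seq_len(n))
  blocks <- sprintf("b%02d", seq_len(nb))
  truth <- stats::setNames(rep(blocks, sizes), ids)
  el <- igraph::as_edgelist(g, names = FALSE)
  net <- network(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
  list(network = net, truth = truth)
}

#' Partially observe a network
#'
#' Uniformly samples `round(fraction * |V|)` nodes without replacement
#' (round-half-up) and restricts to the induced subgraph: an edge survives
#' only if both endpoints are observed.  Ground-truth labels are restricted
#' to the observed nodes and kept as-is, so a community fragmented by the
#' sampling keeps one label across its islands.
#'
#' @param net An `orcci_network`.
#' @param truth Named character vector of ground-truth community ids.
#' @param fraction Observability in `(0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `observed_instance`: `graph`, `truth`,
#'   `observed_fraction`, `si` (initially empty), `si_fraction`,
#'   `corrupt_fraction`, `seed`.
#' @export
observe <- function(net, truth, fraction, seed = 1L) {
  stopifnot(inherits(net, "orcci_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("observability fraction must be in (0, 1]")
  }
  n_obs <- round_half_up(fraction * n_nodes(net))
  obs <- withr::with_seed(substream_seed(seed, 2L),
                          sample(net$nodes, n_obs))
  obs <- radix_sort(obs)
  keep <- net$edges[, 1] %in% obs & net$edges[, 2] %in% obs
  structure(list(graph = network(net$edges[keep, , drop = FALSE], nodes = obs),
                 truth = truth[obs],
                 observed_fraction = fraction,
                 si = structure(list(), names = character()),
                 si_fraction = 0,
                 corrupt_fraction = 0,
                 seed = as.integer(seed)),
            class = "observed_instance")
}

#' @export
print.observed_instance <- function(x, ...) {
  cat(sprintf("<observed_instance> %d/%s nodes observed (%.0f%%), %d edges, %d labelled\n",
              n_nodes(x$graph), "parent", 100 * x$observed_fraction,
              n_edges(x$graph), length(x$si)))
  invisible(x)
}

#' Sample ground-truth side information
#'
#' Uniformly selects `round(fraction * n_obs)` observed nodes; each selected
#' node's side information is its ground-truth community id (a single label).
#' This is the strong-correlation assumption of the benchmark; see
#' [corrupt_side_info()] for the stress test where it is violated.
#'
#' @param instance An `observed_instance`.
#' @param fraction Fraction of observed nodes to label, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named list mapping node id to a single ground-truth label.
#' @export
sample_side_info <- function(instance, fraction, seed = 1L) {
  stopifnot(inherits(instance, "observed_instance"))
  if (fraction < 0 || fraction > 1) stop("side information fraction must be in [0, 1]")
  nodes <- instance$graph$nodes
  n_s <- round_half_up(fraction * length(nodes))
  if (n_s == 0) return(structure(list(), names = character()))
  picked <- withr::with_seed(substream_seed(seed, 3L), sample(nodes, n_s))
  picked <- radix_sort(picked)
  stats::setNames(lapply(picked, function(v) unname(instance$truth[v])), picked)
}

#' Corrupt side information
#'
#' Uniformly selects `round(fraction * |si|)` labelled nodes and replaces each
#' one's label with a community id drawn uniformly from the OTHER ground-truth
#' communities, so every corrupted label is guaranteed wrong.
#'
#' @param si Named list of side information (single-label entries).
#' @param truth Named character vector of ground-truth community ids with at
#'   least two distinct communities when `fraction > 0`.
#' @param fraction Fraction of labelled nodes to corrupt, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted side information (same nodes, some labels replaced).
#' @export
corrupt_side_info <- function(si, truth, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("corrupt fraction must be in [0, 1]")
  if (fraction == 0 || length(si) == 0) return(si)
  comms <- radix_sort(unique(unname(truth)))
  if (length(comms) < 2) {
    stop("cannot corrupt side information: ground truth has a single community, no wrong label exists")
  }
  nodes <- radix_sort(names(si))
  n_c <- round_half_up(fraction * length(nodes))
  withr::with_seed(substream_seed(seed, 4L), {
    victims <- radix_sort(sample(nodes, n_c))
    for (v in victims) {
      wrong <- setdiff(comms, unname(truth[v]))
      si[[v]] <- sample(wrong, 1L)
    }
  })
  si
}
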