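# Graph, side-information and partition I/O.  Internal data model:
#   network   - list(nodes = sorted character, edges = m x 2 character matrix,
#                    rows normalized (u < v in C locale) and lexicographically
#                    sorted), class "orcci_network"
#   side info - named list: node id -> character vector of labels (a set)
#   partition - named character vector: node id -> community id

# C-locale ordering everywhere so gene ids such as "AT1G22920" order
# reproducibly across platforms and locales.
radix_sort <- function(x) sort(x, method = "radix")

radix_order <- function(...) order(..., method = "radix")

#' Construct an undirected, unweighted simple network
#'
#' Nodes are opaque strings (no numeric coercion, so locus tags like
#' `"AT1G22920"` survive untouched).  Edges are normalized so the
#' lexicographically smaller endpoint comes first; duplicate edges (in either
#' orientation) collapse, and self-loops are dropped with a warning.  Isolated
#' nodes are legal and become singleton communities downstream.
#'
#' @param edges A two-column character matrix or data frame of endpoints, or
#'   `NULL` for an edgeless graph.
#' @param nodes Optional character vector of node ids; endpoints of `edges`
#'   are always included.
#' @return An object of class `orcci_network` with elements `nodes` (sorted
#'   character vector) and `edges` (normalized two-column character matrix).
#' @examples
#' net <- network(rbind(c("a", "b"), c("b", "c")))
#' net$nodes
#' @export
network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  colnames(em) <- c("u", "v")
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)))
    em <- em[!loops, , drop = FALSE]
  }
  # normalize orientation in C locale (ranks over the shared id universe)
  if (nrow(em) > 0) {
    rk <- xtfrm_c(c(em[, 1], em[, 2]))
    swap <- rk[seq_len(nrow(em))] > rk[nrow(em) + seq_len(nrow(em))]
    tmp <- em[swap, 1]
    em[swap, 1] <- em[swap, 2]
    em[swap, 2] <- tmp
    em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\r")), , drop = FALSE]
    em <- em[radix_order(em[, 1], em[, 2]), , drop = FALSE]
  }
  all_nodes <- radix_sort(unique(c(as.character(nodes), em[, 1], em[, 2])))
  structure(list(nodes = all_nodes, edges = em), class = "orcci_network")
}

# C-locale sort keys for character comparison (rank within radix order)
xtfrm_c <- function(x) {
  u <- radix_sort(unique(x))
  match(x, u)
}

#' @export
print.orcci_network <- function(x, ...) {
  cat(sprintf("<orcci_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Convert between networks and igraph graphs
#'
#' @param net An `orcci_network`.
#' @return `as_igraph()` returns an undirected `igraph` graph whose vertex
#'   order is the sorted node order of `net`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "orcci_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' @rdname as_igraph
#' @param g An `igraph` graph (edge directions and weights are discarded).
#' @export
as_network <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  network(cbind(nm[el[, 1]], nm[el[, 2]]), nodes = nm)
}

strip_comments <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an edge list file
#'
#' Two-column delimited text; `#`-prefixed and blank lines are skipped.
#' Duplicate rows and reversed duplicates collapse to one edge; self-loop rows
#' are dropped with a warning.  A line with a single non-empty field declares
#' an isolated (degree-0) node.  A third column, if present, is ignored with a
#' warning: the model is strictly unweighted.
#'
#' @param path Path to the file.
#' @param delimiter Field separator; default splits on any run of whitespace.
#' @return An `orcci_network`.
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  raw <- strip_comments(readLines(path, warn = FALSE))
  if (is.null(delimiter)) {
    lines <- trimws(raw$lines)
    fields <- strsplit(lines, "[ \t]+")
    trailing <- rep(FALSE, length(lines))
  } else {
    lines <- sub("\r$", "", raw$lines)
    fields <- strsplit(lines, delimiter)
    # strsplit drops a trailing empty field, so catch it from the raw line
    trailing <- grepl(paste0("(", delimiter, ")$"), lines)
  }
  bad <- trailing |
    vapply(fields, function(f) any(!nzchar(f)) || length(f) == 0, logical(1))
  if (any(bad)) {
    stop(sprintf("malformed edge list line %d: empty field",
                 raw$lineno[which(bad)[1]]))
  }
  nf <- lengths(fields)
  if (any(nf > 2)) {
    warning(sprintf("%d line(s) carry extra columns; weights are ignored (graphs are unweighted)",
                    sum(nf > 2)))
  }
  iso <- unlist(lapply(fields[nf == 1], `[`, 1))
  em <- do.call(rbind, lapply(fields[nf >= 2], function(f) f[1:2]))
  network(edges = em, nodes = iso)
}

#' Read a GraphML graph (read-only convenience)
#'
#' The edge-list TSV is the canonical format; GraphML support exists for
#' interoperability and discards any weights or directions.
#'
#' @param path Path to a GraphML file.
#' @return An `orcci_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  as_network(igraph::read_graph(path, format = "graphml"))
}

#' Write a network as an edge list TSV
#'
#' @param net An `orcci_network`.
#' @param path Output path.  Isolated nodes are written as single-field lines.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "orcci_network"))
  iso <- setdiff(net$nodes, c(net$edges[, 1], net$edges[, 2]))
  lines <- c(paste(net$edges[, 1], net$edges[, 2], sep = "\t"), iso)
  writeLines(lines, path)
}

#' Read node side information
#'
#' Two-column TSV `(node, label)`; rows sharing a node accumulate into one
#' label set, so repeated rows express multi-label nodes.
#'
#' @param path Path to the TSV.
#' @return A named list mapping node id to a character vector of labels.
#' @export
read_side_info <- function(path) {
  if (!file.exists(path)) stop("side information file not found: ", path)
  raw <- strip_comments(readLines(path, warn = FALSE))
  if (length(raw$lines) == 0) return(structure(list(), names = character()))
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(f) length(f) >= 2 && all(nzchar(f[1:2])), logical(1))
  if (!all(ok)) {
    stop(sprintf("malformed side information line %d: need non-empty node and label",
                 raw$lineno[which(!ok)[1]]))
  }
  node <- vapply(parts, `[`, "", 1)
  label <- vapply(parts, `[`, "", 2)
  si <- lapply(split(label, node), function(l) radix_sort(unique(l)))
  si[radix_sort(names(si))]
}

#' Write node side information as TSV
#'
#' @param si Named list mapping node id to labels.
#' @param path Output path.
#' @export
write_side_info <- function(si, path) {
  nodes <- radix_sort(names(si))
  rows <- unlist(lapply(nodes, function(nd) paste(nd, si[[nd]], sep = "\t")))
  writeLines(as.character(rows), path)
}

#' Read and write partitions
#'
#' A partition is a named character vector mapping node id to community id.
#' The file format is a two-column TSV `(node, community)`, rows sorted by
#' node id; an empty partition writes an empty file.  `read_partition()`
#' inverts `write_partition()` exactly.
#'
#' @param partition Named character vector (node -> community id).
#' @param path File path.
#' @return `read_partition()` returns a named character vector.
#' @export
write_partition <- function(partition, path) {
  nodes <- radix_sort(names(partition))
  lines <- if (length(nodes)) paste(nodes, unname(partition[nodes]), sep = "\t") else character()
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  raw <- strip_comments(readLines(path, warn = FALSE))
  if (length(raw$lines) == 0) return(structure(character(), names = character()))
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(f) length(f) >= 2 && all(nzchar(f[1:2])), logical(1))
  if (!all(ok)) {
    stop(sprintf("malformed partition line %d", raw$lineno[which(!ok)[1]]))
  }
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}
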