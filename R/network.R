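#' @importFrom stats sd median cor hclust as.dist setNames quantile rnorm runif
#' @importFrom utils read.delim write.table head
NULL

# gene_network: a simple undirected graph over gene identifiers, backed by
# igraph. Node names are opaque case-sensitive strings; no aliasing.

#' Construct a gene network from an edge table
#'
#' Builds a simple undirected graph (no self-loops, no multi-edges) over
#' gene identifiers. `(a, b)` and `(b, a)` are the same edge.
#'
#' @param edges two-column character matrix or data frame of endpoints;
#'   may have zero rows.
#' @param nodes character vector of node identifiers; defaults to the
#'   identifiers appearing in `edges`. Extra entries become isolated nodes.
#' @return An object of class `gene_network` (an igraph graph with
#'   attributes `n_self_loops` and `n_duplicates` recording rows dropped
#'   during simplification).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) < 2L) stop("edge table must have two columns")
  edges <- edges[, 1:2, drop = FALSE]
  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  nodes <- unique(as.character(nodes))
  if (!all(as.vector(edges) %in% nodes)) {
    stop("every edge endpoint must be a declared node")
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  n_loops <- sum(igraph::which_loop(g))
  g2 <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dups <- igraph::ecount(g) - n_loops - igraph::ecount(g2)
  g2$n_self_loops <- n_loops
  g2$n_duplicates <- n_dups
  class(g2) <- c("gene_network", class(g2))
  g2
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}

#' Node identifiers of a network
#' @param g a `gene_network`.
#' @return character vector of node names.
#' @export
network_nodes <- function(g) igraph::V(g)$name

#' Edge list of a network
#' @param g a `gene_network`.
#' @return two-column character matrix, each row one undirected edge with
#'   endpoints sorted within the row, rows sorted lexicographically.
#' @export
network_edges <- function(g) {
  e <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(e) == 0L) return(matrix(character(), ncol = 2L))
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, c(2L, 1L), drop = FALSE]
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Read a network from an edge-list or SIF file
#'
#' Edge-list rows are tab- or whitespace-separated with at least two
#' fields; columns beyond the second (e.g. interaction scores) are
#' ignored. SIF rows are `nodeA relation nodeB [nodeC ...]` and rows with
#' several targets are expanded into one edge per target. Lines starting
#' with `#` and blank lines are skipped. Duplicate rows (in either
#' orientation) are collapsed and self-loop rows dropped; both tallies are
#' reported in a warning and stored on the result.
#'
#' @param source path to a file, or a connection.
#' @param format `"edgelist"` (default) or `"sif"`.
#' @return a `gene_network`.
#' @export
read_network <- function(source, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty network input: no data lines found")
  rows <- strsplit(trimws(lines[idx]), "[ \t]+")
  pairs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (format == "edgelist") {
      if (length(f) < 2L) {
        stop(sprintf("parse error at line %d: expected >= 2 fields, got %d",
                     idx[i], length(f)))
      }
      pairs[[i]] <- matrix(f[1:2], ncol = 2L)
    } else {
      if (length(f) < 3L) {
        stop(sprintf("parse error at line %d: SIF row needs >= 3 fields",
                     idx[i]))
      }
      pairs[[i]] <- cbind(f[1L], f[-(1:2)])
    }
  }
  em <- do.call(rbind, pairs)
  g <- gene_network(em)
  if (g$n_self_loops > 0L || g$n_duplicates > 0L) {
    warning(sprintf("dropped %d self-loop row(s) and %d duplicate edge row(s)",
                    g$n_self_loops, g$n_duplicates))
  }
  g
}

#' Write a network as a canonical sorted two-column edge list
#' @param g a `gene_network`.
#' @param path output file path.
#' @export
write_network <- function(g, path) {
  e <- network_edges(g)
  write.table(e, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; among equally large
#' components the one containing the lexicographically smallest node
#' label wins, so the result is deterministic.
#'
#' @param g a `gene_network` with at least one node.
#' @return a `gene_network`.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph has no connected component")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: component holding the smallest label
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)[1L]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  class(sub) <- c("gene_network", class(sub))
  sub
}

#' Breadth-first shortest-path lengths from one node
#'
#' @param g a `gene_network`.
#' @param v a node name present in `g`.
#' @return named integer vector of distances to all reachable nodes
#'   (`v` itself at 0); unreachable nodes are absent.
#' @export
shortest_path_lengths <- function(g, v) {
  if (!v %in% igraph::V(g)$name) stop(sprintf("unknown node '%s'", v))
  d <- igraph::distances(g, v = v, algorithm = "unweighted")[1L, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Global clustering coefficient (transitivity)
#'
#' 3 x triangles / connected triples, i.e. the transitivity of the graph;
#' defined as 0 when the graph has no connected triple. This is the
#' triple-based global coefficient, not the mean of local coefficients.
#'
#' @param g a `gene_network`.
#' @return real in \[0, 1\].
#' @export
global_clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc) || is.na(cc)) 0 else cc
}

#' Average shortest-path length over unordered node pairs
#'
#' @param g a connected `gene_network` with at least 2 nodes.
#' @return mean shortest-path length (>= 1).
#' @export
average_path_length <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("average path length needs >= 2 nodes")
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; take largest_connected_component() first")
  }
  igraph::mean_distance(g, directed = FALSE, unconnected = FALSE)
}

#' Network diameter
#'
#' Maximum shortest-path length over node pairs; 0 for a single node.
#'
#' @param g a connected `gene_network`.
#' @return nonnegative integer.
#' @export
network_diameter <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  if (n == 1L) return(0L)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; take largest_connected_component() first")
  }
  as.integer(igraph::diameter(g, directed = FALSE, unconnected = FALSE))
}

#' Sphere cardinalities of a node
#'
#' Entry `j` is the number of nodes at shortest-path distance exactly `j`
#' from `v` (the j-sphere S_j(v)). For a connected graph with
#' `rho >= ecc(v)` the entries sum to `n - 1`.
#'
#' @param g a connected `gene_network`.
#' @param v node name.
#' @param rho vector length; typically `network_diameter(g)`.
#' @return integer vector of length `rho`.
#' @export
sphere_cardinalities <- function(g, v, rho) {
  rho <- as.integer(rho)
  if (rho < 1L) stop("rho must be a positive integer")
  d <- shortest_path_lengths(g, v)
  if (length(d) < igraph::vcount(g)) {
    stop("graph is disconnected; take largest_connected_component() first")
  }
  ecc <- max(d)
  if (rho < ecc) {
    stop(sprintf("rho = %d is below eccentricity %d of '%s'", rho, ecc, v))
  }
  tabulate(d[d > 0L], nbins = rho)
}

# all-pairs unweighted distance matrix (rows/cols named); internal
all_pairs_distances <- function(g) {
  igraph::distances(g, algorithm = "unweighted")
}
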