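# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# adjacency matrix (0/1, named) of a gene_network
adjacency_of <- function(g) {
  nodes <- network_nodes(g)
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- network_edges(g)
  for (i in seq_len(nrow(e))) {
    A[e[i, 1L], e[i, 2L]] <- 1L
    A[e[i, 2L], e[i, 1L]] <- 1L
  }
  A
}

# Floyd-Warshall all-pairs shortest paths from an adjacency matrix
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  dimnames(D) <- dimnames(A)
  D
}

# transitivity by brute-force triangle / connected-triple enumeration
oracle_transitivity <- function(A) {
  n <- nrow(A)
  tri <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k && A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1L
  }
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  if (triples == 0) 0 else 3 * tri / triples
}

# sphere-based entropy by direct exponentiation (safe for small g-scores)
oracle_entropy <- function(A, scheme, alpha) {
  D <- oracle_floyd_warshall(A)
  rho <- max(D)
  j <- seq_len(rho)
  cj <- switch(scheme, const = rep(1, rho), lin = rho - j + 1,
               exp = rho * exp(-j))
  f <- apply(D, 1L, function(d) {
    alpha^sum(cj * tabulate(d[d > 0], nbins = rho))
  })
  p <- f / sum(f)
  -sum(p * log2(p))
}

# random simple graph as an edge matrix, built with base R only
oracle_random_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# upper-tail hypergeometric by exhaustive enumeration of all draws
oracle_hyper_enum <- function(k, n1, n2, N) {
  universe <- seq_len(N)
  A <- seq_len(n1)
  draws <- combn(N, n2)
  mean(colSums(matrix(draws %in% A, nrow = n2)) >= k)
}

# average-linkage agglomeration on a distance matrix, O(n^3); returns
# the merge heights and the member set created at each step
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  members <- c(as.list(seq_len(n)), vector("list", n - 1L))
  heights <- numeric(n - 1L)
  merged_sets <- vector("list", n - 1L)
  avg_d <- function(a, b) mean(D[members[[a]], members[[b]]])
  live <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(live)) for (j in seq_along(live)) {
      if (i < j) {
        d <- avg_d(live[i], live[j])
        if (d < best_d) { best_d <- d; best <- c(live[i], live[j]) }
      }
    }
    new <- n + step
    members[[new]] <- sort(c(members[[best[1L]]], members[[best[2L]]]))
    merged_sets[[step]] <- members[[new]]
    heights[step] <- best_d
    live <- c(setdiff(live, best), new)
  }
  list(height = heights, sets = merged_sets)
}

# member set created at each merge step of an hclust tree
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[step]] <- sort(c(grab(hc$merge[step, 1L]),
                           grab(hc$merge[step, 2L])))
  }
  sets
}
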