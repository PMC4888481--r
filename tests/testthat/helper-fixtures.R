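# Small graph fixtures built in code.

fix_cycle <- function(n) {
  v <- sprintf("c%02d", seq_len(n))
  gene_network(cbind(v, v[c(2:n, 1L)]))
}

fix_complete <- function(n) {
  v <- sprintf("k%02d", seq_len(n))
  gene_network(t(combn(v, 2L)))
}

fix_path <- function(labels) {
  gene_network(cbind(labels[-length(labels)], labels[-1L]))
}

fix_star <- function(n_leaves, center = "hub") {
  leaves <- sprintf("leaf%d", seq_len(n_leaves))
  gene_network(cbind(center, leaves))
}

# 3-dimensional hypercube (vertex-transitive, 8 nodes)
fix_cube <- function() {
  bits <- expand.grid(0:1, 0:1, 0:1)
  v <- apply(bits, 1L, paste, collapse = "")
  edges <- NULL
  for (i in 1:8) for (j in 1:8) {
    if (i < j && sum(bits[i, ] != bits[j, ]) == 1L) {
      edges <- rbind(edges, c(v[i], v[j]))
    }
  }
  gene_network(edges)
}

# vertex-transitive fixture set used by the closed-form entropy checks
vertex_transitive_fixtures <- function() {
  fixtures <- c(lapply(3:12, fix_cycle), lapply(2:8, fix_complete),
                list(fix_cube()))
  names(fixtures) <- c(sprintf("C%d", 3:12), sprintf("K%d", 2:8), "Q3")
  fixtures
}

# screen-table text block for reader tests
screen_tsv <- function(rows,
                       header = "orf\tname\tdon\tttc\tmdr") {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c(header, rows), tmp)
  tmp
}
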