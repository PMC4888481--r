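# Synthetic-data generators with ground-truth bookkeeping. They emulate
# the statistical structure the analysis assumes: a sparse genome-scale
# interaction network containing a more-clustered seed module; 1-4
# sensitivity scores concentrated on module genes with MDR
# contamination; and expression matrices where ribosomal-protein genes
# move coherently against a respiration set (pattern A down/up, B
# inverted) under additive Gaussian noise. Every generator is a pure
# function of its parameters and rng_seed.

gene_ids <- function(n) sprintf("G%06d", seq_len(n))

with_seed <- function(rng_seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(rng_seed)
  force(code)
}

#' Generate a random gene network
#'
#' Models: `erdos_renyi` (G(n, p)), `watts_strogatz` (ring lattice with
#' `k` neighbours, rewiring probability `beta`) and
#' `duplication_divergence` (each new gene copies a random template's
#' neighbours, keeping each with probability `retention`). Nodes are
#' labelled `G000001`, `G000002`, ...
#'
#' @param n number of genes, >= 2.
#' @param model model name.
#' @param params named list of model parameters: `p` for `erdos_renyi`;
#'   `k` (even, < n) and `beta` for `watts_strogatz`; `retention` in
#'   (0, 1) for `duplication_divergence`.
#' @param rng_seed integer seed.
#' @return a `gene_network`.
#' @export
generate_network <- function(n,
                             model = c("erdos_renyi", "watts_strogatz",
                                       "duplication_divergence"),
                             params = list(), rng_seed = 1L) {
  model <- match.arg(model)
  if (n < 2L) stop("n must be >= 2")
  ids <- gene_ids(n)
  g <- with_seed(rng_seed, {
    switch(model,
      erdos_renyi = {
        p <- params$p
        if (is.null(p) || p < 0 || p > 1) stop("erdos_renyi needs p in [0, 1]")
        igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
      },
      watts_strogatz = {
        k <- params$k; beta <- params$beta
        if (is.null(k) || k %% 2 != 0 || k >= n) {
          stop("watts_strogatz needs even k < n")
        }
        if (is.null(beta) || beta < 0 || beta > 1) {
          stop("watts_strogatz needs beta in [0, 1]")
        }
        igraph::sample_smallworld(1, n, k / 2, beta, loops = FALSE,
                                  multiple = FALSE)
      },
      duplication_divergence = {
        ret <- params$retention
        if (is.null(ret) || ret <= 0 || ret >= 1) {
          stop("duplication_divergence needs retention in (0, 1)")
        }
        el <- matrix(c(1L, 2L), ncol = 2L)
        for (v in 3:n) {
          tmpl <- sample.int(v - 1L, 1L)
          nb <- unique(c(el[el[, 1L] == tmpl, 2L], el[el[, 2L] == tmpl, 1L]))
          kept <- nb[runif(length(nb)) < ret]
          new_edges <- unique(c(kept, tmpl))  # always attach to template
          el <- rbind(el, cbind(v, new_edges))
        }
        igraph::graph_from_edgelist(el, directed = FALSE)
      })
  })
  g <- igraph::simplify(g)
  missing <- n - igraph::vcount(g)
  if (missing > 0L) g <- igraph::add_vertices(g, missing)
  igraph::V(g)$name <- ids
  class(g) <- c("gene_network", class(g))
  g
}

#' Plant a clustered module into a network
#'
#' Chooses `size` nodes uniformly and adds each absent within-module
#' edge independently with probability `p_in`, producing the locally
#' clustered seed structure a screen is expected to hit.
#'
#' @param g a `gene_network`.
#' @param size module size, `<= |nodes|`.
#' @param p_in within-module edge probability, in (0, 1].
#' @param rng_seed integer seed.
#' @return list `(network, truth)`; `truth$module_genes` records the
#'   planted module.
#' @export
plant_module <- function(g, size, p_in, rng_seed = 1L) {
  nodes <- igraph::V(g)$name
  if (size > length(nodes)) stop("module size exceeds node count")
  if (p_in <= 0 || p_in > 1) stop("p_in must be in (0, 1]")
  res <- with_seed(rng_seed, {
    module <- sort(sample(nodes, size))
    pairs <- t(combn(module, 2L))
    have <- igraph::get_edge_ids(g, t(pairs), error = FALSE) > 0
    add <- !have & (runif(nrow(pairs)) < p_in)
    list(module = module, new_edges = pairs[add, , drop = FALSE])
  })
  g2 <- igraph::add_edges(g, t(res$new_edges))
  class(g2) <- c("gene_network", class(g2))
  truth <- list(module_genes = res$module, rng_seed = rng_seed)
  list(network = g2, truth = truth)
}

#' Generate a synthetic screen score table
#'
#' Module genes become DON-sensitive and (independently) TTC-sensitive
#' with probability `sens_prob_module`, background genes with
#' `sens_prob_background`; sensitive genes get scores uniform on 1-4.
#' Independently, a fraction `mdr_fraction` of all genes receives an MDR
#' score uniform on 1-15, so the MDR filter's effect is measurable.
#'
#' @param g a `gene_network` providing the gene universe.
#' @param truth truth list from [plant_module()] (or any list with a
#'   `module_genes` field).
#' @param sens_prob_module,sens_prob_background sensitivity
#'   probabilities in \[0, 1\].
#' @param mdr_fraction fraction of genes carrying an MDR score.
#' @param rng_seed integer seed.
#' @return list `(records, truth)`: a `screen_table` over all genes and
#'   the input truth extended with `don_true` / `ttc_true` sets.
#' @export
generate_screen_table <- function(g, truth, sens_prob_module = 0.8,
                                  sens_prob_background = 0.01,
                                  mdr_fraction = 0.05, rng_seed = 1L) {
  stopifnot(sens_prob_module >= 0, sens_prob_module <= 1,
            sens_prob_background >= 0, sens_prob_background <= 1,
            mdr_fraction >= 0, mdr_fraction <= 1)
  genes <- igraph::V(g)$name
  in_module <- genes %in% truth$module_genes
  tab <- with_seed(rng_seed, {
    prob <- ifelse(in_module, sens_prob_module, sens_prob_background)
    don_hit <- runif(length(genes)) < prob
    ttc_hit <- runif(length(genes)) < prob
    don <- ifelse(don_hit, sample(1:4, length(genes), replace = TRUE), 0L)
    ttc <- ifelse(ttc_hit, sample(1:4, length(genes), replace = TRUE), 0L)
    has_mdr <- runif(length(genes)) < mdr_fraction
    mdr <- ifelse(has_mdr, sample(1:15, length(genes), replace = TRUE),
                  NA_integer_)
    screen_table(genes, genes, don, ttc, mdr)
  })
  truth$don_true <- genes[tab$don >= 1L]
  truth$ttc_true <- genes[tab$ttc >= 1L]
  truth$rng_seed_screen <- rng_seed
  list(records = tab, truth = truth)
}

#' Generate a synthetic expression matrix with planted patterns
#'
#' Builds disjoint ribosomal-protein (RP) and respiration gene sets.
#' Pattern-A conditions put `-effect` on RP genes and `+effect` on
#' respiration genes (the slow-growth signature); pattern-B conditions
#' invert the signs; every cell gets additive Gaussian noise.
#'
#' @param n_genes total genes.
#' @param conditions condition labels (length = number of columns).
#' @param rp_fraction,resp_fraction fractions of genes in each set
#'   (`rp_fraction + resp_fraction < 1`).
#' @param effect effect size in log2 units, >= 0.
#' @param noise_sd Gaussian noise sd, >= 0.
#' @param patterns character vector of "A"/"B", one per condition.
#' @param rng_seed integer seed.
#' @return list `(matrix, truth)`; truth holds `rp_genes`, `resp_genes`,
#'   `pattern_by_condition`, `de_genes` and the seed.
#' @export
generate_expression <- function(n_genes, conditions, rp_fraction = 0.1,
                                resp_fraction = 0.1, effect = 1,
                                noise_sd = 0.5,
                                patterns = rep("A", length(conditions)),
                                rng_seed = 1L) {
  stopifnot(rp_fraction + resp_fraction < 1, effect >= 0, noise_sd >= 0,
            length(patterns) == length(conditions),
            all(patterns %in% c("A", "B")))
  genes <- gene_ids(n_genes)
  n_rp <- round(rp_fraction * n_genes)
  n_resp <- round(resp_fraction * n_genes)
  m <- with_seed(rng_seed, {
    chosen <- sample(genes, n_rp + n_resp)
    rp <- sort(chosen[seq_len(n_rp)])
    resp <- sort(chosen[n_rp + seq_len(n_resp)])
    base <- matrix(0, n_genes, length(conditions),
                   dimnames = list(genes, conditions))
    sgn <- ifelse(patterns == "A", 1, -1)
    base[rp, ] <- matrix(-effect, n_rp, length(conditions)) %*% diag(sgn, length(sgn))
    base[resp, ] <- matrix(effect, n_resp, length(conditions)) %*% diag(sgn, length(sgn))
    noisy <- base + matrix(rnorm(length(base), sd = noise_sd),
                           nrow(base), ncol(base))
    list(mat = noisy, rp = rp, resp = resp)
  })
  truth <- list(rp_genes = m$rp, resp_genes = m$resp,
                pattern_by_condition = setNames(patterns, conditions),
                de_genes = union(m$rp, m$resp),
                rng_seed = rng_seed)
  list(matrix = m$mat, truth = truth)
}

#' Generate a log2 ratio matrix with planted differentially expressed genes
#'
#' Null genes get Gaussian noise of sd `noise_sd`; `n_de` planted genes
#' additionally get `+/-fc` (alternating sign) in one randomly chosen
#' condition each. The planted set is the ground truth for the
#' fold-change filter.
#'
#' @param n_genes total genes; `n_de` of them planted.
#' @param n_conditions number of columns.
#' @param fc planted absolute log2 fold change.
#' @param noise_sd background noise sd.
#' @param rng_seed integer seed.
#' @return list `(matrix, truth)` with `truth$de_genes`.
#' @export
generate_fc_matrix <- function(n_genes, n_conditions, n_de, fc = 1,
                               noise_sd = 0.1, rng_seed = 1L) {
  genes <- gene_ids(n_genes)
  conds <- sprintf("cond%02d", seq_len(n_conditions))
  m <- with_seed(rng_seed, {
    mat <- matrix(rnorm(n_genes * n_conditions, sd = noise_sd),
                  n_genes, n_conditions, dimnames = list(genes, conds))
    de <- sort(sample(genes, n_de))
    for (i in seq_along(de)) {
      j <- sample.int(n_conditions, 1L)
      mat[de[i], j] <- mat[de[i], j] + fc * if (i %% 2 == 0) -1 else 1
    }
    list(mat = mat, de = de)
  })
  list(matrix = m$mat, truth = list(de_genes = m$de, rng_seed = rng_seed))
}
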