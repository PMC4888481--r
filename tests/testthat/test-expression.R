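test_that("quantile_normalize equalizes column distributions and keeps ranks", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  rownames(m) <- paste0("p", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3, 4.5))

  ident <- matrix(c(5, 1, 3), 3, 4, dimnames = list(paste0("p", 1:3), NULL))
  expect_equal(quantile_normalize(ident), ident)

  set.seed(12)
  big <- matrix(rexp(500), 100, 5,
                dimnames = list(sprintf("p%03d", 1:100), LETTERS[1:5]))
  qb <- quantile_normalize(big)
  expect_equal(max(abs(colMeans(qb) - mean(colMeans(qb)))), 0,
               tolerance = 1e-9)
  for (j in 1:5) {
    expect_equal(rank(qb[, j]), rank(big[, j]))  # rank order preserved
    expect_equal(sort(qb[, j]), sort(qb[, 1]), ignore_attr = TRUE)
  }
  # agreement with the standard microarray implementation
  if (requireNamespace("limma", quietly = TRUE)) {
    expect_equal(unname(qb), unname(limma::normalizeQuantiles(big)),
                 tolerance = 1e-9)
  }
  expect_warning(one <- quantile_normalize(big[, 1, drop = FALSE]), "single")
  expect_equal(one, big[, 1, drop = FALSE])
})

test_that("average_duplicates means duplicate probes and drops unmapped ones", {
  m <- rbind(p1 = c(1, 3), p2 = c(3, 5), p3 = c(10, 10), px = c(0, 0))
  colnames(m) <- c("c1", "c2")
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- average_duplicates(m, map)
  expect_equal(out["gA", ], c(c1 = 2, c2 = 4))
  expect_equal(out["gB", ], c(c1 = 10, c2 = 10))
  expect_equal(attr(out, "n_unmapped"), 1)
  # all-unique mapping is the identity up to relabeling
  map2 <- setNames(paste0("G_", rownames(m)), rownames(m))
  out2 <- average_duplicates(m, map2)
  expect_equal(unname(out2), unname(m), ignore_attr = TRUE)
  expect_error(average_duplicates(m, character()), "empty")
})

test_that("fold_change_filter applies a strict threshold in at least one condition", {
  m <- rbind(up = c(0.6, 0), boundary = c(0.5, -0.5),
             down = c(0, -0.7), flat = c(0.1, -0.2))
  colnames(m) <- c("c1", "c2")
  expect_equal(fold_change_filter(m), c("up", "down"))
  expect_equal(fold_change_filter(m, 0.65), "down")
  expect_error(fold_change_filter(m, 0), "> 0")
  # monotone in the threshold
  set.seed(8)
  big <- matrix(rnorm(600), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  for (t in c(0.2, 0.5, 1, 2)) {
    expect_true(all(fold_change_filter(big, t * 2) %in%
                      fold_change_filter(big, t)))
  }
})

test_that("fold_change_filter recovers a planted DE set exactly", {
  sim <- generate_fc_matrix(440, 4, n_de = 40, fc = 1, noise_sd = 0.1,
                            rng_seed = 60)
  expect_setequal(fold_change_filter(sim$matrix, 0.5), sim$truth$de_genes)
})

test_that("signed_log_differences is odd, logarithmic and median-centered", {
  t0 <- matrix(c(8, 1, 1, 1), 1, 4, dimnames = list("g", paste0("c", 1:4)))
  c0 <- matrix(1, 1, 4, dimnames = dimnames(t0))
  # raw transform: delta 7 -> log2(8) = 3 before centering
  d <- signed_log_differences(t0, c0)
  expect_equal(unname(d[1, ]), c(3, 0, 0, 0))  # median of (3,0,0,0) is 0
  # odd symmetry before centering: swap treated/control flips signs
  t1 <- matrix(runif(12, 1, 50), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  c1 <- matrix(runif(12, 1, 50), 3, 4, dimnames = dimnames(t1))
  raw <- function(a, b) sign(a - b) * log2(1 + abs(a - b))
  expect_equal(raw(t1, c1), -raw(c1, t1))
  expect_equal(unname(apply(signed_log_differences(t1, c1), 1, median)),
               rep(0, 3))
  expect_error(signed_log_differences(t1, c1[1:2, ]), "shape")
})

test_that("hierarchical_cluster matches the agglomeration oracle", {
  r <- c(1, 2, 3, 4)
  m <- rbind(a = r, b = r + 0.001 * c(1, -1, 1, -1), c = -r,
             d = c(4, 3, 2, 1) + c(0.2, -0.1, 0.3, 0),
             e = c(1, 5, 2, 8))
  colnames(m) <- paste0("c", 1:4)
  hc <- hierarchical_cluster(m, "genes")
  D <- 1 - cor(t(m))
  oracle <- oracle_average_linkage(as.matrix(as.dist(D)))
  expect_equal(hc$height, oracle$height, tolerance = 1e-12)
  expect_equal(hclust_merge_sets(hc), oracle$sets)
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights

  # identical rows merge at 0; an anticorrelated row joins at distance 2
  m2 <- rbind(x = r, y = r, z = -r)
  colnames(m2) <- paste0("c", 1:4)
  hc2 <- hierarchical_cluster(m2, "genes")
  expect_equal(hc2$height, c(0, 2), tolerance = 1e-12)
  expect_equal(hclust_merge_sets(hc2)[[1]], c(1, 2))

  expect_error(hierarchical_cluster(rbind(flat = rep(1, 4), x = r), "genes"),
               "flat")
  nwk <- cluster_to_newick(hc2)
  expect_match(nwk, "^\\(.*\\);$")
  if (requireNamespace("ape", quietly = TRUE)) {
    tr <- ape::read.tree(text = nwk)
    expect_setequal(tr$tip.label, rownames(m2))
  }
})

test_that("clustering over conditions transposes the matrix", {
  set.seed(4)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("cond", 1:5)))
  hc <- hierarchical_cluster(m, "conditions")
  expect_setequal(hc$labels, colnames(m))
})

test_that("signature_score separates patterns A and B and tolerates shifts", {
  rp <- c("rp1", "rp2"); resp <- c("re1", "re2")
  profA <- c(rp1 = -1, rp2 = -1, re1 = 1, re2 = 1, other = 0)
  sA <- signature_score(profA, rp, resp)
  expect_equal(sA$score, 2)
  expect_equal(sA$pattern, "A")
  sB <- signature_score(-profA, rp, resp)
  expect_equal(sB$score, -2)
  expect_equal(sB$pattern, "B")
  # shift invariance
  expect_equal(signature_score(profA + 5, rp, resp)$score, 2)
  # empty intersection => none
  expect_equal(signature_score(profA, c("absent"), resp)$pattern, "none")
  expect_equal(signature_score(profA, rp, resp = character())$pattern, "none")
})

test_that("signature calls recover planted patterns at >= 95%", {
  conds <- sprintf("cond%03d", 1:100)
  pats <- rep(c("A", "B"), 50)
  sim <- generate_expression(n_genes = 1000, conditions = conds,
                             rp_fraction = 0.1, resp_fraction = 0.1,
                             effect = 1, noise_sd = 0.5, patterns = pats,
                             rng_seed = 17)
  calls <- signature_calls(sim$matrix, sim$truth$rp_genes,
                           sim$truth$resp_genes)
  expect_gte(mean(calls$pattern == pats), 0.95)
})

test_that("matrix TSV round-trips", {
  m <- matrix(round(rnorm(12), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("cond", 1:4)))
  f <- tempfile()
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m)
})
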