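# Expression-matrix processing: quantile normalization, duplicate-probe
# averaging, fold-change filtering, signed-log differences, hierarchical
# clustering on correlation distance, and slow-growth-signature scoring.
#
# Matrices are plain numeric matrices with probe/gene rownames and
# condition colnames; readers/writers use TSV with an id column.

#' Read a gene/probe x condition matrix from TSV
#' @param source path or connection; first column holds row identifiers,
#'   header row holds condition labels.
#' @return numeric matrix with rownames and colnames.
#' @export
read_matrix_tsv <- function(source) {
  df <- read.delim(source, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers in matrix input")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a matrix as TSV with an id column
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_name header of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile normalization across arrays
#'
#' Classic quantile normalization: sort each column, average the order
#' statistics across columns into a reference distribution, and give
#' every value the reference value of its rank. Ties within a column
#' receive the mean of their rank positions' reference values, so tied
#' entries stay tied. Afterwards all columns share one distribution and
#' within-column rank order is preserved.
#'
#' @param m numeric matrix (probes x arrays), no missing values.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("quantile normalization requires a complete matrix")
  if (ncol(m) < 2L) {
    warning("single array: quantile normalization is a no-op")
    return(m)
  }
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' Average duplicate probes into gene rows
#'
#' Rows whose probes map to the same gene are replaced by their
#' arithmetic mean row. Probes without a mapping are dropped; the count
#' is stored as attribute `n_unmapped`.
#'
#' @param m numeric matrix with probe rownames.
#' @param probe_to_gene named character vector, probe -> gene.
#' @return gene x condition matrix (rows ordered by first appearance of
#'   each gene among the mapped probes).
#' @export
average_duplicates <- function(m, probe_to_gene) {
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  genes <- unname(probe_to_gene[rownames(m)])
  mapped <- !is.na(genes)
  n_unmapped <- sum(!mapped)
  mm <- m[mapped, , drop = FALSE]
  genes <- genes[mapped]
  if (nrow(mm) == 0L) stop("no probe mapped to a gene")
  glev <- unique(genes)
  out <- rowsum(mm, group = factor(genes, levels = glev), reorder = FALSE)
  out <- out / as.vector(table(factor(genes, levels = glev)))
  rownames(out) <- glev
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Fold-change filter
#'
#' Genes whose log2 value is strictly above `threshold` or strictly
#' below `-threshold` in at least one condition, in input order. The
#' boundary is excluded (strict inequality), so a gene sitting exactly
#' at the cut does not pass.
#'
#' @param m genes x conditions log2 matrix.
#' @param threshold positive log2 cut (default 0.5).
#' @return character vector of retained gene identifiers.
#' @export
fold_change_filter <- function(m, threshold = 0.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  hit <- apply(m, 1L, function(x) any(x > threshold | x < -threshold,
                                      na.rm = TRUE))
  rownames(m)[hit]
}

#' Signed-log expression differences
#'
#' Per cell `delta = treated - control`, mapped through the odd
#' transform `sign(delta) * log2(1 + |delta|)` (monotone, odd, and
#' ~ `log2 delta` for large positive `delta`), then each gene row is
#' median-centered across conditions.
#'
#' @param treated,control numeric matrices of identical shape and
#'   dimnames (matched genes and condition pairing).
#' @return genes x conditions matrix of centered signed-log differences.
#' @export
signed_log_differences <- function(treated, control) {
  if (!identical(dim(treated), dim(control))) {
    stop("treated and control matrices differ in shape")
  }
  if (!is.null(rownames(treated)) && !is.null(rownames(control)) &&
      !identical(rownames(treated), rownames(control))) {
    stop("treated and control matrices differ in gene order")
  }
  d <- treated - control
  v <- sign(d) * log2(1 + abs(d))
  v - apply(v, 1L, median)
}

#' Hierarchical clustering on correlation distance
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` and
#' average linkage, over rows (`axis = "genes"`) or columns
#' (`axis = "conditions"`).
#'
#' @param m numeric matrix.
#' @param axis `"genes"` (rows) or `"conditions"` (columns).
#' @return an object of class `hclust` (merge tree with heights and
#'   labels); see [cluster_to_newick()] for serialization.
#' @export
hierarchical_cluster <- function(m, axis = c("genes", "conditions")) {
  axis <- match.arg(axis)
  x <- if (axis == "genes") m else t(m)
  if (nrow(x) < 2L) stop("need >= 2 items to cluster")
  v <- apply(x, 1L, sd)
  if (any(v == 0)) {
    stop("zero-variance item(s): ",
         paste(rownames(x)[v == 0], collapse = ", "))
  }
  d <- as.dist(1 - cor(t(x)))
  hclust(d, method = "average")
}

#' Serialize an hclust tree to Newick
#'
#' @param hc an `hclust` object.
#' @param digits branch-length precision.
#' @return a single Newick string (heights become branch lengths).
#' @export
cluster_to_newick <- function(hc, digits = 6) {
  node_h <- numeric(nrow(hc$merge))
  fmt <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.*f", hc$labels[-i], digits, parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.*f",
              fmt(hc$merge[i, 1L], h), fmt(hc$merge[i, 2L], h),
              digits, parent_h - h)
    }
  }
  k <- nrow(hc$merge)
  paste0("(", fmt(hc$merge[k, 1L], hc$height[k]), ",",
         fmt(hc$merge[k, 2L], hc$height[k]), ");")
}

#' Slow-growth signature score of one expression profile
#'
#' `score = mean over respiration genes - mean over ribosomal-protein
#' genes` of the profile's log2 values. Positive scores are the
#' slow-growth signature (pattern A: ribosomal proteins down,
#' respiration up); negative scores the inverted pattern B; a zero score
#' or an empty gene-set intersection yields pattern `none`. Adding a
#' constant to the whole profile leaves the score unchanged.
#'
#' @param profile named numeric vector, gene -> log2 value, for one
#'   condition.
#' @param rp_set ribosomal-protein gene set.
#' @param resp_set respiratory gene set.
#' @return list of class `signature_call` with fields `score` and
#'   `pattern` (`"A"`, `"B"` or `"none"`).
#' @export
signature_score <- function(profile, rp_set, resp_set) {
  rp <- intersect(names(profile), rp_set)
  resp <- intersect(names(profile), resp_set)
  if (length(rp) == 0L || length(resp) == 0L) {
    out <- list(score = 0, pattern = "none")
  } else {
    s <- mean(profile[resp]) - mean(profile[rp])
    out <- list(score = s,
                pattern = if (s > 0) "A" else if (s < 0) "B" else "none")
  }
  class(out) <- "signature_call"
  out
}

#' Signature calls for every condition of a matrix
#'
#' @param m genes x conditions log2 matrix.
#' @param rp_set,resp_set gene sets, see [signature_score()].
#' @return data frame (condition, score, pattern).
#' @export
signature_calls <- function(m, rp_set, resp_set) {
  rows <- lapply(colnames(m), function(cond) {
    sc <- signature_score(setNames(m[, cond], rownames(m)), rp_set, resp_set)
    data.frame(condition = cond, score = sc$score, pattern = sc$pattern,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
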