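# Screen-table ingestion, MDR filtering, seed sets, subnetwork extraction.
#
# A screen record carries per-gene DON and TTC sensitivity scores in
# 0-4 (0 = not in the hit list, 1-4 grade severity) plus an optional
# multidrug-resistance (MDR) hypersensitivity score from a prior
# compendium; genes with MDR > 3 are regarded as nonspecific and removed
# before network analysis.

#' Read a screen score table
#'
#' TSV with a header naming at least `orf`, `don` and `ttc` columns
#' (case-insensitive; a `name` display column and an `mdr` column are
#' optional). Empty `don`/`ttc` cells become 0; empty `mdr` cells mean
#' "no MDR score".
#'
#' @param source path or connection.
#' @return data frame of class `screen_table` with columns `orf`, `name`,
#'   `don`, `ttc` (integers 0-4) and `mdr` (integer or NA).
#' @export
read_screen_table <- function(source) {
  df <- read.delim(source, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("orf", "don", "ttc")) {
    if (!col %in% names(df)) stop(sprintf("missing required column '%s'", col))
  }
  if (!"name" %in% names(df)) df$name <- df$orf
  if (!"mdr" %in% names(df)) df$mdr <- NA_integer_
  screen_table(df$orf, df$name, df$don, df$ttc, df$mdr)
}

#' Construct a validated screen table
#'
#' @param orf unique nonempty gene identifiers.
#' @param name display names (defaults to `orf`).
#' @param don,ttc sensitivity scores in 0-4; NA/empty read as 0.
#' @param mdr optional nonnegative MDR scores; NA means absent.
#' @return data frame of class `screen_table`.
#' @export
screen_table <- function(orf, name = orf, don = 0L, ttc = 0L,
                         mdr = NA_integer_) {
  orf <- as.character(orf)
  if (any(!nzchar(orf))) stop("empty orf identifier")
  if (anyDuplicated(orf)) {
    dups <- unique(orf[duplicated(orf)])
    stop("duplicate orf identifier(s): ", paste(dups, collapse = ", "))
  }
  to_score <- function(x, label) {
    x <- suppressWarnings(as.integer(ifelse(x %in% c("", NA), 0L, x)))
    x[is.na(x)] <- 0L
    bad <- which(x < 0L | x > 4L)
    if (length(bad)) {
      stop(sprintf("%s score out of range 0-4 at row %d (value %d)",
                   label, bad[1L], x[bad[1L]]))
    }
    x
  }
  don <- to_score(rep_len(don, length(orf)), "don")
  ttc <- to_score(rep_len(ttc, length(orf)), "ttc")
  mdr <- suppressWarnings(as.integer(ifelse(mdr %in% "", NA, mdr)))
  mdr <- rep_len(mdr, length(orf))
  if (any(!is.na(mdr) & mdr < 0L)) stop("mdr score must be nonnegative")
  out <- data.frame(orf = orf, name = as.character(rep_len(name, length(orf))),
                    don = don, ttc = ttc, mdr = mdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Write a screen table as TSV
#' @param records a `screen_table`.
#' @param path output path.
#' @export
write_screen_table <- function(records, path) {
  out <- records
  out$mdr <- ifelse(is.na(out$mdr), "", as.character(out$mdr))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove multidrug-sensitive genes
#'
#' Retains records whose MDR score is absent or `<= threshold`
#' (strictly-greater removal, default threshold 3). Idempotent and
#' order-preserving.
#'
#' @param records a `screen_table`.
#' @param threshold integer cut; genes with `mdr > threshold` are removed.
#' @return filtered `screen_table`.
#' @export
mdr_filter <- function(records, threshold = 3L) {
  keep <- is.na(records$mdr) | records$mdr <= threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Build the four seed-gene sets
#'
#' DON = genes with `don >= min_score`, TTC likewise, plus their union
#' and intersection. Call after [mdr_filter()]; seed membership is flat
#' (scores only grade severity).
#'
#' @param records a `screen_table`, already MDR-filtered.
#' @param min_score minimum sensitivity score for seed membership
#'   (default 1, i.e. any listed sensitivity).
#' @return named list of character vectors `DON`, `TTC`, `UNION`,
#'   `INTERSECTION`.
#' @export
build_seed_sets <- function(records, min_score = 1L) {
  don <- records$orf[records$don >= min_score]
  ttc <- records$orf[records$ttc >= min_score]
  list(DON = don,
       TTC = ttc,
       UNION = union(don, ttc),
       INTERSECTION = intersect(don, ttc))
}

#' Extract the seed-induced subnetwork
#'
#' Nodes are the seed genes present in the universe (isolated seeds are
#' retained); edges are universe edges with both endpoints among the
#' seeds. The largest connected component is *not* taken here — that is
#' a separate profiling step. Seed genes absent from the universe are
#' dropped; the count is stored as attribute `n_missing_seeds`.
#'
#' @param universe a `gene_network`.
#' @param seeds character vector of seed genes.
#' @return a `gene_network` on `seeds` intersect `nodes(universe)`.
#' @export
extract_subnetwork <- function(universe, seeds) {
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, igraph::V(universe)$name)
  sub <- igraph::induced_subgraph(universe, present)
  class(sub) <- c("gene_network", class(sub))
  sub$n_missing_seeds <- length(seeds) - length(present)
  sub
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param source path or connection.
#' @return named list of character vectors (set members; descriptions
#'   attached as attribute `descriptions`).
#' @export
read_gmt <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # sentinel keeps trailing empty fields (strsplit drops them)
  parts <- lapply(strsplit(paste0(lines, "\t\r"), "\t", fixed = TRUE),
                  function(f) f[-length(f)])
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop(sprintf("malformed GMT line %d", bad[1L]))
  sets <- lapply(parts, function(f) {
    members <- f[-(1:2)]
    unique(members[nzchar(members)])
  })
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  sets
}
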