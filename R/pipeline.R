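# End-to-end orchestration: configuration, the topology analysis
# (screen table -> seed sets -> subnetworks -> profiles -> null), the
# expression analysis, report writing and a small CLI.

#' Assemble a run configuration
#'
#' @param network path to the interaction-network edge list.
#' @param screen path to the screen score table TSV.
#' @param expression path to a log2 ratio matrix TSV (expression
#'   analysis).
#' @param gene_sets path to a GMT file holding at least `RP` and `RESP`
#'   sets (expression analysis).
#' @param out_dir output directory (created if absent).
#' @param mdr_threshold MDR removal cut (default 3).
#' @param seed_score_min minimum sensitivity score for seeds (default 1).
#' @param B null-resample count (default 1000).
#' @param entropy_scheme,alpha,lambda entropy descriptor parameters.
#' @param fc_threshold fold-change cut (default 0.5).
#' @param rng_seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(network = NULL, screen = NULL, expression = NULL,
                       gene_sets = NULL, out_dir = "toxnet_out",
                       mdr_threshold = 3L, seed_score_min = 1L, B = 1000L,
                       entropy_scheme = "exp", alpha = 2, lambda = 1,
                       fc_threshold = 0.5, rng_seed = 1L) {
  cfg <- list(network = network, screen = screen, expression = expression,
              gene_sets = gene_sets, out_dir = out_dir,
              mdr_threshold = as.integer(mdr_threshold),
              seed_score_min = as.integer(seed_score_min),
              B = as.integer(B), entropy_scheme = entropy_scheme,
              alpha = alpha, lambda = lambda,
              fc_threshold = fc_threshold, rng_seed = as.integer(rng_seed))
  for (f in c("network", "screen", "expression", "gene_sets")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("config path '%s' does not exist (%s)", cfg[[f]], f))
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments.
#' Keys match the arguments of [run_config()].
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*?)\\s*$",
                                  lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line")
  args <- setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, character(1), 2L))
  num <- c("mdr_threshold", "seed_score_min", "B", "alpha", "lambda",
           "fc_threshold", "rng_seed")
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  do.call(run_config, args)
}

# derive per-stage seeds from the master seed (kept < 2^31)
stage_seed <- function(rng_seed, stage) {
  offs <- c(null_DON = 11L, null_TTC = 23L, null_UNION = 37L,
            null_INTERSECTION = 53L, simulate = 71L)
  (as.integer(rng_seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Run the network-topology analysis
#'
#' read network and screen table -> MDR filter -> seed sets (DON, TTC,
#' UNION, INTERSECTION) -> induced subnetworks -> LCC topology profiles
#' -> seed-resampling null (same number of seeds, resampled from the
#' network universe) -> empirical p and z per descriptor. Writes
#' `topology_report.tsv`, `topology_null.json` (full null samples for
#' audit) and `run_log.txt` into `out_dir`.
#'
#' @param config a `run_config` with `network` and `screen` set.
#' @return the report data frame, invisibly; also written to disk.
#' @export
run_topology_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$network) || is.null(config$screen)) {
    stop("topology analysis needs 'network' and 'screen' paths")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("toxnet %s", as.character(utils::packageVersion("toxnet"))),
                 sprintf("rng_seed %d  B %d  mdr_threshold %d  seed_score_min %d",
                         config$rng_seed, config$B, config$mdr_threshold,
                         config$seed_score_min))
  universe <- withCallingHandlers(
    read_network(config$network),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("network:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  records <- read_screen_table(config$screen)
  filtered <- mdr_filter(records, config$mdr_threshold)
  log_lines <- c(log_lines,
                 sprintf("screen: %d records, %d after MDR filter",
                         nrow(records), nrow(filtered)))
  seeds <- build_seed_sets(filtered, config$seed_score_min)

  reports <- list()
  nulls <- list()
  for (lab in names(seeds)) {
    sub <- extract_subnetwork(universe, seeds[[lab]])
    log_lines <- c(log_lines,
                   sprintf("%s: %d seeds, %d in network (%d missing), %d edges",
                           lab, length(seeds[[lab]]), igraph::vcount(sub),
                           sub$n_missing_seeds, igraph::ecount(sub)))
    if (igraph::vcount(sub) == 0L) {
      log_lines <- c(log_lines, sprintf("%s: empty subnetwork", lab))
      next
    }
    prof <- topology_profile(sub, config$entropy_scheme, config$alpha,
                             config$lambda)
    if (prof$degenerate) {
      log_lines <- c(log_lines,
                     sprintf("%s: degenerate observed profile (LCC %d)",
                             lab, prof$lcc_size))
      next
    }
    # same number of seed genes as observed in the universe
    ens <- sample_null(universe, n_seeds = igraph::vcount(sub),
                       B = config$B,
                       rng_seed = stage_seed(config$rng_seed,
                                             paste0("null_", lab)),
                       entropy_scheme = config$entropy_scheme,
                       alpha = config$alpha, lambda = config$lambda)
    rep <- profile_vs_null(prof, ens)
    rep <- cbind(seed_set = lab, rep, stringsAsFactors = FALSE)
    reports[[lab]] <- rep
    nulls[[lab]] <- lapply(profile_metrics, function(mt) null_values(ens, mt))
    names(nulls[[lab]]) <- profile_metrics
    nulls[[lab]]$n_degenerate <- ens$n_degenerate
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(seed_set = character(), metric = character(),
               observed = numeric())
  rownames(report) <- NULL
  write.table(report, file.path(config$out_dir, "topology_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(nulls, file.path(config$out_dir, "topology_null.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(report)
}

#' Run the expression analysis
#'
#' Loads a genes x conditions log2 matrix, applies the fold-change
#' filter, hierarchically clusters the retained genes (correlation
#' distance, average linkage) and scores the slow-growth signature per
#' condition against the `RP` and `RESP` sets of the configured GMT
#' file. Writes `filtered_genes.txt`, `gene_cluster.nwk` and
#' `signature_calls.tsv`.
#'
#' @param config a `run_config` with `expression` and `gene_sets` set.
#' @return the signature-call data frame, invisibly.
#' @export
run_expression_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$expression) || is.null(config$gene_sets)) {
    stop("expression analysis needs 'expression' and 'gene_sets' paths")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- read_matrix_tsv(config$expression)
  sets <- read_gmt(config$gene_sets)
  rp <- if ("RP" %in% names(sets)) sets$RP else character()
  resp <- if ("RESP" %in% names(sets)) sets$RESP else character()
  if (length(rp) == 0L || length(resp) == 0L) {
    warning("empty RP or RESP set: all signature calls will be 'none'")
  }
  genes <- fold_change_filter(m, config$fc_threshold)
  writeLines(genes, file.path(config$out_dir, "filtered_genes.txt"))
  if (length(genes) >= 2L) {
    sel <- m[genes, , drop = FALSE]
    v <- apply(sel, 1L, sd)
    hc <- hierarchical_cluster(sel[v > 0, , drop = FALSE], axis = "genes")
    writeLines(cluster_to_newick(hc),
               file.path(config$out_dir, "gene_cluster.nwk"))
  }
  calls <- signature_calls(m, rp, resp)
  write.table(calls, file.path(config$out_dir, "signature_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Command-line entry point
#'
#' Verbs: `topology`, `expression`, `simulate`; each takes
#' `--config FILE` plus overrides (`--B`, `--mdr-threshold`, `--seed`,
#' `--out`). `simulate` writes a synthetic universe, screen table and
#' expression matrix into the output directory.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
toxnet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: toxnet <topology|expression|simulate> --config FILE ",
            "[--B N] [--mdr-threshold N] [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  verb <- args[1L]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else
    run_config()
  if (!is.null(opts$B)) cfg$B <- as.integer(opts$B)
  if (!is.null(opts[["mdr-threshold"]])) {
    cfg$mdr_threshold <- as.integer(opts[["mdr-threshold"]])
  }
  if (!is.null(opts$seed)) cfg$rng_seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  switch(verb,
    topology = run_topology_analysis(cfg),
    expression = run_expression_analysis(cfg),
    simulate = {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      s <- stage_seed(cfg$rng_seed, "simulate")
      g <- generate_network(1000, "erdos_renyi", list(p = 0.01), s)
      pm <- plant_module(g, 50, 0.3, s + 1L)
      st <- generate_screen_table(pm$network, pm$truth, rng_seed = s + 2L)
      ex <- generate_expression(500, sprintf("cond%02d", 1:10),
                                patterns = rep(c("A", "B"), 5),
                                rng_seed = s + 3L)
      write_network(pm$network, file.path(cfg$out_dir, "network.tsv"))
      write_screen_table(st$records, file.path(cfg$out_dir, "screen.tsv"))
      write_matrix_tsv(ex$matrix, file.path(cfg$out_dir, "expression.tsv"))
      write_gmt(list(RP = ex$truth$rp_genes, RESP = ex$truth$resp_genes),
                file.path(cfg$out_dir, "gene_sets.gmt"),
                description = c("ribosomal proteins", "respiration"))
      jsonlite::write_json(
        list(module_genes = pm$truth$module_genes,
             don_true = st$truth$don_true, ttc_true = st$truth$ttc_true,
             pattern_by_condition = as.list(ex$truth$pattern_by_condition),
             rng_seed = cfg$rng_seed),
        file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE)
    },
    stop("unknown verb '", verb, "'"))
  invisible(0L)
}
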