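#' Pipeline configuration
#'
#' Assembles and validates the full parameter set of the end-to-end run.
#' The defaults are the study's published parameter block: signal-to-noise
#' ranking, 1,000 phenotype permutations, set sizes 15-500, the classic
#' enrichment statistic, significance at p < 0.05 and FDR q < 0.25,
#' expression filter at the 20th percentile, fold cutoff 2 with adjusted
#' p < 0.05.
#'
#' @param gct,cls,probe_map,gmt Input paths (`gmt` may be a named
#'   character vector of collections). NULL entries are allowed when the
#'   corresponding stage is skipped.
#' @param out_dir Output directory.
#' @param filter_percentile,filter_min_samples Expression filter.
#' @param fold_min,p_max_de Differential-expression thresholds.
#' @param n_perm,min_size,max_size,p_max,q_max GSEA parameters.
#' @param seed Integer seed for the permutation null.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(gct = NULL, cls = NULL, probe_map = NULL,
                            gmt = NULL, out_dir = ".",
                            filter_percentile = 20, filter_min_samples = 1,
                            fold_min = 2, p_max_de = 0.05, n_perm = 1000,
                            min_size = 15, max_size = 500, p_max = 0.05,
                            q_max = 0.25, seed = 1) {
  cfg <- list(gct = gct, cls = cls, probe_map = probe_map, gmt = gmt,
              out_dir = out_dir, filter_percentile = filter_percentile,
              filter_min_samples = filter_min_samples, fold_min = fold_min,
              p_max_de = p_max_de, n_perm = n_perm, min_size = min_size,
              max_size = max_size, p_max = p_max, q_max = q_max,
              seed = seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  num <- c("filter_percentile", "filter_min_samples", "fold_min",
           "p_max_de", "n_perm", "min_size", "max_size", "p_max", "q_max",
           "seed")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1)
      stop(sprintf("config key '%s' must be a single number", k),
           call. = FALSE)
  if (cfg$filter_percentile < 0 || cfg$filter_percentile >= 100)
    stop("filter_percentile must lie in [0, 100)", call. = FALSE)
  if (cfg$min_size > cfg$max_size)
    stop("min_size must be <= max_size", call. = FALSE)
  if (cfg$p_max <= 0 || cfg$p_max > 1 || cfg$q_max <= 0 || cfg$q_max > 1)
    stop("significance thresholds must lie in (0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text format, one pair per line, `#` comments
#' allowed; unknown keys are an error so typos cannot silently fall back
#' to defaults.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2)
  if (length(bad))
    parse_error(path, bad[1], "expected 'key = value'")
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  args <- as.list(vals)
  names(args) <- keys
  numkeys <- intersect(keys, c("filter_percentile", "filter_min_samples",
                               "fold_min", "p_max_de", "n_perm", "min_size",
                               "max_size", "p_max", "q_max", "seed"))
  args[numkeys] <- lapply(args[numkeys], as.numeric)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  keep <- !vapply(cfg, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(cfg)[keep],
                     vapply(cfg[keep], function(v) paste(v, collapse = ","),
                            "")), path)
  invisible(path)
}

#' Run the full expression-to-enrichment pipeline
#'
#' Executes filter, probe collapse (when a probe map is supplied),
#' differential expression, and one GSEA per supplied gene set
#' collection; writes per-stage TSVs, a combined significant-sets table,
#' and a run log recording every parameter and per-stage count, into
#' `cfg$out_dir`. Any stage failure aborts with the stage name. Reruns
#' with an identical config and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()]. Alternatively pass preloaded objects
#'   via `inputs` (list with `matrix`, `phenotype`, `probe_to_gene`,
#'   `collections`), bypassing file reads.
#' @param inputs Optional preloaded inputs (see above).
#' @return Invisible list with `de`, `gsea` (per collection), and
#'   `log_lines`.
#' @export
run_end_to_end <- function(cfg, inputs = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("regensea run log",
                 sprintf("  %s = %s", names(cfg),
                         vapply(cfg, function(v)
                           if (is.null(v)) "NULL"
                           else paste(v, collapse = ","), "")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(inputs)) {
    mat <- stage("read_gct", read_gct(cfg$gct, id_level =
                   if (is.null(cfg$probe_map)) "gene" else "probe"))
    phen <- stage("read_cls", read_cls(cfg$cls,
                    sample_ids = colnames(mat$values)))
    pmap <- if (!is.null(cfg$probe_map))
      stage("read_probe_map", read_probe_map(cfg$probe_map)) else NULL
    gmt_paths <- cfg$gmt
    if (is.null(names(gmt_paths)))
      names(gmt_paths) <- tools::file_path_sans_ext(basename(gmt_paths))
    colls <- lapply(gmt_paths, function(p) stage("read_gmt", read_gmt(p)))
  } else {
    mat <- inputs$matrix; phen <- inputs$phenotype
    pmap <- inputs$probe_to_gene; colls <- inputs$collections
  }
  n0 <- nrow(mat$values)
  mat <- stage("filter_by_expression",
               filter_by_expression(mat, cfg$filter_percentile,
                                    cfg$filter_min_samples))
  log_lines <- c(log_lines,
                 sprintf("filter: %d of %d rows retained", nrow(mat$values),
                         n0))
  if (!is.null(pmap) && mat$id_level == "probe") {
    mat <- stage("collapse_probes_to_genes",
                 suppressMessages(collapse_probes_to_genes(mat, pmap)))
    log_lines <- c(log_lines,
                   sprintf("collapse: %d genes", nrow(mat$values)))
  }
  de <- stage("differential_expression",
              differential_expression(mat, phen))
  sel <- select_de_genes(de, cfg$fold_min, cfg$p_max_de)
  log_lines <- c(log_lines,
                 sprintf("de: %d significant (adj p < %g), %d up / %d down at fold >= %g",
                         sel$counts["significant"], cfg$p_max_de,
                         sel$counts["up"], sel$counts["down"],
                         cfg$fold_min))
  write_de_table(de, file.path(cfg$out_dir, "de_table.tsv"),
                 cfg$fold_min, cfg$p_max_de)
  writeLines(sel$up, file.path(cfg$out_dir, "de_up.txt"))
  writeLines(sel$down, file.path(cfg$out_dir, "de_down.txt"))
  gsea <- list()
  sig_rows <- list()
  for (nm in names(colls)) {
    g <- stage(paste0("gsea:", nm),
               suppressMessages(run_gsea(mat, phen, colls[[nm]],
                        n_perm = cfg$n_perm, min_size = cfg$min_size,
                        max_size = cfg$max_size, p_max = cfg$p_max,
                        q_max = cfg$q_max, seed = cfg$seed)))
    gsea[[nm]] <- g
    write_gsea_table(g, file.path(cfg$out_dir,
                                  sprintf("gsea_%s.tsv", nm)))
    log_lines <- c(log_lines,
                   sprintf("gsea %s: %d sets tested, %d significant",
                           nm, nrow(g$results), nrow(g$significant)))
    if (nrow(g$significant)) {
      s <- g$significant
      sig_rows[[nm]] <- data.frame(collection = nm, set = s$set,
                                   enriched_class = s$enriched_class,
                                   p = s$p_nominal, fdr_q = s$fdr_q,
                                   stringsAsFactors = FALSE)
    }
  }
  sig_tab <- if (length(sig_rows)) do.call(rbind, sig_rows)
             else data.frame(collection = character(), set = character(),
                             enriched_class = character(), p = numeric(),
                             fdr_q = numeric())
  rownames(sig_tab) <- NULL
  write.table(sig_tab, file.path(cfg$out_dir, "significant_sets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(de = de, gsea = gsea, significant = sig_tab,
                 log_lines = log_lines))
}

#' Run the synthetic benchmark suite
#'
#' Exercises the pipeline's core guarantees on seeded synthetic data —
#' exhaustive-null agreement at a small design, running-sum termination,
#' planted-set recovery with correct enrichment side, negative-control
#' specificity, and noiseless 2^-ddCt recovery — and prints a measured
#' vs. required table. Scales are reduced relative to the full acceptance
#' suite so the whole run stays interactive.
#'
#' @param seeds Integer vector of seeds (default `1:3`).
#' @param n_perm Permutations per GSEA run (default 100).
#' @return Data.frame (`property`, `measured`, `required`, `pass`);
#'   attribute `ok` is TRUE when every row passes.
#' @export
benchmark_suite <- function(seeds = 1:3, n_perm = 100) {
  rows <- list()
  add <- function(property, measured, required, pass)
    rows[[length(rows) + 1]] <<- data.frame(property = property,
                                            measured = measured,
                                            required = required,
                                            pass = pass,
                                            stringsAsFactors = FALSE)
  # running-sum termination
  sim <- simulate_expression_experiment(n_genes = 200, n_null_sets = 20,
                                        n_up_sets = 2, n_down_sets = 2,
                                        pool_size = 30, seed = seeds[1])
  ranked <- signal_to_noise_ranking(sim$matrix, sim$phenotype)
  ends <- vapply(sim$collection$sets, function(m)
    abs(tail(enrichment_score(ranked, m)$running_sum, 1)), 0)
  add("running sum terminates at 0", max(ends), 1e-9, max(ends) < 1e-9)
  # planted recovery + negative control across seeds
  rec <- numeric(0); fp <- numeric(0)
  for (s in seeds) {
    sim <- simulate_expression_experiment(n_genes = 400, n_up_sets = 3,
                                          n_down_sets = 3, set_size = 20,
                                          pool_size = 25, n_null_sets = 40,
                                          seed = s)
    g <- suppressMessages(run_gsea(sim$matrix, sim$phenotype,
                                   sim$collection, n_perm = n_perm,
                                   min_size = 10, seed = s))
    res <- g$results
    planted <- sim$truth$planted
    side_ok <- vapply(seq_len(nrow(planted)), function(i) {
      r <- res[res$set == planted$set[i], ]
      r$significant && ((planted$direction[i] == "up") == (r$es > 0))
    }, logical(1))
    rec <- c(rec, mean(side_ok))
    null_res <- res[res$set %in% sim$truth$null_sets, ]
    fp <- c(fp, mean(null_res$p_nominal < 0.05))
    sim0 <- simulate_expression_experiment(n_genes = 400, n_up_sets = 0,
                                           n_down_sets = 0, n_null_sets = 40,
                                           set_size = 20, seed = s)
    g0 <- suppressMessages(run_gsea(sim0$matrix, sim0$phenotype,
                                    sim0$collection, n_perm = n_perm,
                                    min_size = 10, seed = s))
    fp <- c(fp, mean(g0$results$p_nominal < 0.05))
  }
  add("planted sets recovered with correct side", mean(rec), 0.9,
      mean(rec) >= 0.9)
  # nominal p calibration: the null-set rate at alpha = 0.05 should sit
  # near 0.05 (slack for permutation granularity and set overlap)
  add("null-set nominal p rate at alpha 0.05", mean(fp), 0.1,
      mean(fp) <= 0.1)
  # exhaustive 3v3 null is the full 20-labeling enumeration
  sim3 <- simulate_expression_experiment(n_genes = 50, n_per_class = 3,
                                         n_up_sets = 1, n_down_sets = 0,
                                         set_size = 10, pool_size = 12,
                                         n_null_sets = 3, seed = seeds[1])
  pn <- permutation_null(sim3$matrix, sim3$phenotype, sim3$collection,
                         exhaustive = TRUE)
  add("exhaustive 3v3 labelings", pn$n_perm, 20, pn$n_perm == 20)
  # noiseless ddCt recovery
  rec4 <- ddct_fold_change(simulate_qpcr_cts(true_fold = 4,
                                             replicate_sd = 0,
                                             seed = seeds[1]))$fold
  add("noiseless 2^-ddCt recovery of fold 4", rec4, 4,
      isTRUE(all.equal(rec4, 4)))
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  out
}
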