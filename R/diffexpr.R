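#' Filter rows by per-sample expression percentile
#'
#' Keeps a row when, in at least `min_samples` samples, its value reaches
#' that sample's `lower_percentile`-th percentile. The percentile is the
#' order-statistic (inverse-ECDF) quantile, so on one sample holding the
#' values 1..100 the 20th percentile is 20 and 81 rows survive. The
#' alternative published phrasing — keep rows reaching a fraction of the
#' sample maximum — is available as `method = "fraction_of_max"`.
#'
#' @param matrix An [expression_matrix()].
#' @param lower_percentile Percentile in `[0, 100)`; 0 keeps everything.
#' @param min_samples Minimum number of samples in which the row must pass.
#' @param method `"percentile"` (default) or `"fraction_of_max"` (keep
#'   rows with value >= `lower_percentile`/100 of the sample maximum).
#' @return A filtered [expression_matrix()] (row order preserved). Warns
#'   if nothing survives.
#' @export
filter_by_expression <- function(matrix, lower_percentile = 20,
                                 min_samples = 1,
                                 method = c("percentile", "fraction_of_max")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  method <- match.arg(method)
  if (lower_percentile < 0 || lower_percentile >= 100)
    stop("`lower_percentile` must lie in [0, 100)", call. = FALSE)
  v <- matrix$values
  thr <- if (method == "percentile") {
    apply(v, 2, quantile, probs = lower_percentile / 100, type = 1,
          names = FALSE)
  } else {
    apply(v, 2, max) * lower_percentile / 100
  }
  pass <- sweep(v, 2, thr, ">=")
  keep <- rowSums(pass) >= min_samples
  if (!any(keep)) warning("expression filter removed every row")
  out <- v[keep, , drop = FALSE]
  if (is.null(rownames(out))) rownames(out) <- rownames(v)[keep]
  expression_matrix(out, id_level = matrix$id_level,
                    description = matrix$description[keep])
}

#' Collapse probe-level rows to gene symbols by median
#'
#' Redundant probes mapping to one gene symbol are summarised per sample
#' by their median (even counts: mean of the central pair). Probes absent
#' from the mapping are dropped and their count reported via `message()`.
#' Output rows are sorted by gene symbol for determinism.
#'
#' @param matrix A probe-level [expression_matrix()].
#' @param probe_to_gene Data.frame with columns `probe`, `gene`.
#' @return A gene-level [expression_matrix()].
#' @export
collapse_probes_to_genes <- function(matrix, probe_to_gene) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$id_level != "probe")
    stop("`matrix` must be probe-level", call. = FALSE)
  if (nrow(probe_to_gene) == 0)
    stop("probe-to-gene mapping is empty", call. = FALSE)
  map <- setNames(toupper(probe_to_gene$gene), probe_to_gene$probe)
  probes <- rownames(matrix$values)
  gene <- map[probes]
  dropped <- sum(is.na(gene))
  if (dropped > 0)
    message(sprintf("collapse_probes_to_genes: dropped %d unmapped probe(s)",
                    dropped))
  keep <- !is.na(gene)
  if (!any(keep)) stop("no probes map to a gene symbol", call. = FALSE)
  v <- matrix$values[keep, , drop = FALSE]
  gene <- gene[keep]
  idx <- split(seq_len(nrow(v)), gene)          # sorted by gene symbol
  out <- vapply(idx, function(rows) {
    apply(v[rows, , drop = FALSE], 2, median)
  }, numeric(ncol(v)))
  out <- t(out)
  colnames(out) <- colnames(v)
  expression_matrix(out, id_level = "gene")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]): sorted ascending,
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in
#' input order. Inputs outside `[0,1]` are a parameter error.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised two-sample t-tests over matrix rows. Welch is the array-software
# convention; pooled Student is the convention for the validation module.
# Zero variance in both groups: equal means -> p = 1, unequal -> p = 0.
row_t_tests <- function(x_pos, x_neg, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  n1 <- ncol(x_pos); n2 <- ncol(x_neg)
  m1 <- rowMeans(x_pos); m2 <- rowMeans(x_neg)
  v1 <- rowSums((x_pos - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_neg - m2)^2) / (n2 - 1)
  if (flavor == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  tt[degen & m1 == m2] <- 0
  list(t = tt, df = df, p = p, mean_pos = m1, mean_neg = m2)
}

#' Differential expression between two phenotype classes
#'
#' Per row: unpaired two-sample t-test on the linear-scale values (Welch
#' by default; pooled Student available), Benjamini-Hochberg adjustment
#' across all tested rows, and the fold change as the ratio of class
#' means with a direction flag (`neg_over_pos` folds are the "1/x"
#' down-regulation notation in the report writer).
#'
#' @param matrix An [expression_matrix()] (gene- or probe-level).
#' @param phen A [phenotype_assignment()]; each class needs >= 2 samples.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @param log2_transform Test on `log2(x + 1)` instead of linear values.
#' @return Object of class `de_result`: a data.frame with columns `id`,
#'   `mean_pos`, `mean_neg`, `fold_change`, `direction`, `p_raw`, `p_adj`.
#' @export
differential_expression <- function(matrix, phen,
                                    flavor = c("welch", "pooled"),
                                    log2_transform = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(phen, "phenotype_assignment"))
  flavor <- match.arg(flavor)
  check_class_sizes(phen, 2L)
  v <- matrix$values
  if (!all(phen$samples %in% colnames(v)))
    stop("phenotype samples missing from the matrix", call. = FALSE)
  xp <- v[, positive_samples(phen), drop = FALSE]
  xn <- v[, negative_samples(phen), drop = FALSE]
  tp <- if (log2_transform) row_t_tests(log2(xp + 1), log2(xn + 1), flavor)
        else row_t_tests(xp, xn, flavor)
  mean_pos <- rowMeans(xp); mean_neg <- rowMeans(xn)
  fold <- mean_pos / mean_neg
  out <- data.frame(id = rownames(v), mean_pos = mean_pos,
                    mean_neg = mean_neg, fold_change = fold,
                    direction = ifelse(fold >= 1, "pos_over_neg",
                                       "neg_over_pos"),
                    p_raw = tp$p, p_adj = bh_adjust(tp$p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Up: `p_adj < p_max` and `fold_change >= fold_min`; down: `p_adj <
#' p_max` and `fold_change <= 1/fold_min`. Fold thresholds are inclusive,
#' the p threshold strict.
#'
#' @param de A `de_result` from [differential_expression()].
#' @param fold_min Fold-change cutoff (>= 1).
#' @param p_max Adjusted-p cutoff.
#' @return List with `up`, `down` (character vectors of ids) and `counts`.
#' @export
select_de_genes <- function(de, fold_min = 2, p_max = 0.05) {
  stopifnot(inherits(de, "de_result"))
  if (fold_min < 1) stop("`fold_min` must be >= 1", call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("`p_max` must lie in (0, 1]", call. = FALSE)
  sig <- de$p_adj < p_max
  up <- de$id[sig & de$fold_change >= fold_min]
  down <- de$id[sig & de$fold_change <= 1 / fold_min]
  list(up = up, down = down,
       counts = c(significant = sum(sig), up = length(up),
                  down = length(down)))
}

#' Write a differential expression report
#'
#' TSV with means, the fold change plus a display column using the "1/x"
#' notation for down-regulation, raw and adjusted p, and pass flags at the
#' supplied thresholds.
#'
#' @inheritParams select_de_genes
#' @param path Output path.
#' @export
write_de_table <- function(de, path, fold_min = 2, p_max = 0.05) {
  stopifnot(inherits(de, "de_result"))
  sel <- select_de_genes(de, fold_min, p_max)
  out <- as.data.frame(de)
  out$fold_display <- format_fold(de$fold_change)
  out$pass <- de$id %in% c(sel$up, sel$down)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
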