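#' Signal-to-noise gene ranking
#'
#' Ranks genes by `s(g) = (mu_pos - mu_neg) / (sd_pos + sd_neg)` between
#' the two phenotype classes, with each class's sample standard deviation
#' floored at `max(0.2 * |mu_class|, 0.2)` so zero-variance genes cannot
#' dominate the ranking. Ties are broken lexicographically by gene symbol
#' so rankings are deterministic across platforms.
#'
#' @param matrix A gene-level [expression_matrix()].
#' @param phen A [phenotype_assignment()] with >= 2 samples per class.
#' @return Object of class `ranked_list`: list with `genes` (descending
#'   score order) and `scores` (the matching signal-to-noise values).
#' @export
signal_to_noise_ranking <- function(matrix, phen) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$id_level != "gene")
    stop("ranking requires a gene-level matrix", call. = FALSE)
  check_class_sizes(phen, 2L)
  v <- matrix$values
  if (!all(phen$samples %in% colnames(v)))
    stop("phenotype samples missing from the matrix", call. = FALSE)
  s <- s2n_scores(v, positive_samples(phen), negative_samples(phen))
  ord <- order(-s, rownames(v))
  structure(list(genes = rownames(v)[ord], scores = unname(s[ord])),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list: %d genes, scores %.4g .. %.4g\n",
              length(x$genes), x$scores[1], x$scores[length(x$scores)]))
  invisible(x)
}

# Signal-to-noise scores with the variance floor; `pos`/`neg` are column
# names or indices into `v`.
s2n_scores <- function(v, pos, neg) {
  xp <- v[, pos, drop = FALSE]; xn <- v[, neg, drop = FALSE]
  mp <- rowMeans(xp); mn <- rowMeans(xn)
  sp <- sqrt(rowSums((xp - mp)^2) / (ncol(xp) - 1))
  sn <- sqrt(rowSums((xn - mn)^2) / (ncol(xn) - 1))
  sp <- pmax(sp, pmax(0.2 * abs(mp), 0.2))
  sn <- pmax(sn, pmax(0.2 * abs(mn), 0.2))
  (mp - mn) / (sp + sn)
}

#' Classic running-sum enrichment score
#'
#' Walks the ranked list adding `1/Nh` at each set member ("hit") and
#' subtracting `1/(N-Nh)` at each non-member, where `Nh` is the number of
#' members present in the list. The enrichment score is the signed value
#' of the running sum at its point of maximum absolute deviation from
#' zero (the unweighted, "classic" statistic); the full running sum is
#' returned for inspection and always terminates at zero.
#'
#' @param ranked A `ranked_list`.
#' @param members Character vector of gene symbols (any case).
#' @return List with `es` (in `[-1, 1]`) and `running_sum`.
#' @export
enrichment_score <- function(ranked, members) {
  stopifnot(inherits(ranked, "ranked_list"))
  hits <- ranked$genes %in% toupper(members)
  nh <- sum(hits); n <- length(hits)
  if (nh == 0 || nh == n)
    stop(sprintf("degenerate set: %d of %d ranked genes are members", nh, n),
         call. = FALSE)
  run <- cumsum(ifelse(hits, 1 / nh, -1 / (n - nh)))
  list(es = run[which.max(abs(run))], running_sum = run)
}

# Enrichment scores for many sets at once. `ord` is the ranking as integer
# indices into the gene universe; `memb` is a genes x sets logical matrix;
# `nh` the per-set hit counts. Returns the per-set signed max-deviation ES.
es_for_membership <- function(ord, memb, nh) {
  n <- nrow(memb)
  hits <- memb[ord, , drop = FALSE]
  inc <- sweep(hits, 2, 1 / nh, "*") - sweep(!hits, 2, 1 / (n - nh), "*")
  run <- apply(inc, 2, cumsum)
  if (is.null(dim(run))) run <- matrix(run, nrow = n)
  apply(run, 2, function(r) r[which.max(abs(r))])
}

# memb matrix + hit counts for a collection over a fixed gene universe.
membership_matrix <- function(collection, genes) {
  memb <- vapply(collection$sets, function(m) genes %in% m,
                 logical(length(genes)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(genes))
  colnames(memb) <- names(collection$sets)
  memb
}

#' Restrict a collection to a gene universe and size window
#'
#' Intersects every set with the ranked universe and drops sets whose
#' post-intersection size falls outside `[min_size, max_size]`; the
#' number dropped is reported via `message()`.
#'
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of gene symbols.
#' @param min_size,max_size Inclusive size window (defaults 15 and 500).
#' @return A restricted [gene_set_collection()].
#' @export
restrict_sets <- function(collection, universe, min_size = 15,
                          max_size = 500) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  universe <- toupper(universe)
  trimmed <- lapply(collection$sets, function(m) m[m %in% universe])
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  if (any(!keep))
    message(sprintf("restrict_sets: dropped %d of %d sets outside [%d, %d]",
                    sum(!keep), length(keep), min_size, max_size))
  gene_set_collection(trimmed[keep],
                      descriptions = collection$descriptions[keep])
}

#' Phenotype-permutation null enrichment scores
#'
#' Reassigns the class labels (preserving class sizes), recomputes the
#' signal-to-noise ranking, and recomputes every set's enrichment score,
#' either for `n_perm` random label draws (sampled with replacement over
#' labelings; the identity labeling is not excluded) or exhaustively over
#' all `choose(n, n_pos)` distinct labelings when `exhaustive = TRUE`.
#' With a fixed `seed` the output is bit-reproducible.
#'
#' @param matrix A gene-level [expression_matrix()].
#' @param phen A [phenotype_assignment()].
#' @param collection A (already restricted) [gene_set_collection()].
#' @param n_perm Number of random permutations (ignored when exhaustive).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all labelings (design must give
#'   `choose(n, n_pos) <= 10000`).
#' @return List with `es_null` (permutations x sets matrix), `es_obs`
#'   (named vector for the true labeling) and `n_perm`.
#' @export
permutation_null <- function(matrix, phen, collection, n_perm = 1000,
                             seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(collection, "gene_set_collection"))
  check_class_sizes(phen, 2L)
  if (length(collection$sets) == 0) stop("empty collection", call. = FALSE)
  v <- matrix$values[, phen$samples, drop = FALSE]
  genes <- rownames(v)
  memb <- membership_matrix(collection, genes)
  nh <- colSums(memb)
  if (any(nh == 0) || any(nh == length(genes)))
    stop("degenerate set in collection; run restrict_sets() first",
         call. = FALSE)
  n <- ncol(v)
  n_pos <- length(positive_samples(phen))
  obs_pos <- match(positive_samples(phen), colnames(v))
  score_labeling <- function(pos_idx) {
    s <- s2n_scores(v, pos_idx, setdiff(seq_len(n), pos_idx))
    es_for_membership(order(-s, genes), memb, nh)
  }
  es_obs <- score_labeling(obs_pos)
  names(es_obs) <- names(collection$sets)
  if (exhaustive) {
    if (choose(n, n_pos) > 10000)
      stop(sprintf("exhaustive enumeration of %d labelings exceeds the 10000 cap",
                   choose(n, n_pos)), call. = FALSE)
    labelings <- combn(n, n_pos)
    es_null <- t(apply(labelings, 2, function(ix) score_labeling(ix)))
    if (ncol(memb) == 1) es_null <- matrix(es_null, ncol = 1)
  } else {
    if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    es_null <- matrix(NA_real_, n_perm, ncol(memb))
    for (b in seq_len(n_perm))
      es_null[b, ] <- score_labeling(sample(n, n_pos))
  }
  colnames(es_null) <- names(collection$sets)
  list(es_null = es_null, es_obs = es_obs, n_perm = nrow(es_null))
}

#' Normalise enrichment scores and estimate significance
#'
#' For each set the normalised enrichment score is
#' `NES = ES / mean(|null ES|)` over the null samples whose sign matches
#' the observed ES; the nominal p is the fraction of those same-sign null
#' scores at least as extreme. The FDR q follows the standard pooled-NES
#' procedure: every null ES is normalised the same way, and
#' `q = (fraction of pooled same-sign null NES at least as extreme) /
#' (fraction of observed same-sign NES at least as extreme)`, clipped to
#' `[0,1]` with a monotone cleanup so q never decreases as |NES| shrinks.
#' Sets with no same-sign null sample get the boundary estimate
#' `p = 1/(n_null + 1)` and are flagged.
#'
#' @param es_obs Named numeric vector of observed enrichment scores.
#' @param es_null Permutations x sets matrix of null enrichment scores
#'   (columns matching `es_obs`).
#' @return Object of class `enrichment_result`: data.frame with columns
#'   `set`, `es`, `nes`, `p_nominal`, `fdr_q`, `boundary`.
#' @export
normalize_and_fdr <- function(es_obs, es_null) {
  if (is.null(names(es_obs)) ||
      !identical(names(es_obs), colnames(es_null)))
    stop("`es_obs` names must match `es_null` columns", call. = FALSE)
  n_sets <- length(es_obs)
  n_null <- nrow(es_null)
  nes <- p <- numeric(n_sets)
  boundary <- logical(n_sets)
  nes_null <- matrix(NA_real_, n_null, n_sets)
  for (j in seq_len(n_sets)) {
    nj <- es_null[, j]; e <- es_obs[[j]]
    pos <- nj[nj > 0]; neg <- nj[nj < 0]
    m_pos <- if (length(pos)) mean(pos) else NA_real_
    m_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    same <- if (e >= 0) pos else neg
    if (length(same) == 0) {
      boundary[j] <- TRUE
      p[j] <- 1 / (n_null + 1)
      # no same-sign null to normalise against: fall back to overall scale
      nes[j] <- e / mean(abs(nj))
    } else {
      p[j] <- mean(abs(same) >= abs(e))
      nes[j] <- if (e >= 0) e / m_pos else e / m_neg
    }
    scale_j <- ifelse(nj >= 0,
                      if (is.na(m_pos)) mean(abs(nj)) else m_pos,
                      if (is.na(m_neg)) mean(abs(nj)) else m_neg)
    nes_null[, j] <- nj / scale_j
  }
  pool <- as.vector(nes_null)
  pool_pos <- pool[pool >= 0]; pool_neg <- pool[pool < 0]
  obs_pos <- nes[nes >= 0]; obs_neg <- nes[nes < 0]
  q <- vapply(seq_len(n_sets), function(j) {
    x <- nes[j]
    if (x >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= x) else 0
      den <- mean(obs_pos >= x)
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= x) else 0
      den <- mean(obs_neg <= x)
    }
    min(1, num / den)
  }, 0)
  # monotone cleanup per sign side: q is made non-decreasing as |NES|
  # decreases (suffix minimum over sets ordered by decreasing |NES|)
  for (side in list(which(nes >= 0), which(nes < 0))) {
    if (length(side) < 2) next
    o <- side[order(-abs(nes[side]))]
    q[o] <- rev(cummin(rev(q[o])))
  }
  out <- data.frame(set = names(es_obs), es = unname(es_obs), nes = nes,
                    p_nominal = p, fdr_q = q, boundary = boundary,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Run a full gene set enrichment analysis
#'
#' Orchestrates ranking, size restriction, observed scores, the
#' phenotype-permutation null and normalisation. A set is called
#' significant when `p_nominal < p_max` and `fdr_q < q_max` (both
#' strict); `enriched_class` reports the positive class for `ES > 0` and
#' the negative class otherwise. Results are sorted by decreasing NES.
#'
#' @inheritParams permutation_null
#' @param min_size,max_size Set size window after intersection with the
#'   ranked universe.
#' @param p_max,q_max Significance thresholds (defaults 0.05 and 0.25).
#' @return Object of class `gsea_result`: list with `results` (an
#'   `enrichment_result` data.frame plus `size_used`, `enriched_class`,
#'   `significant`), `significant` (the subset), and `params`.
#' @export
run_gsea <- function(matrix, phen, collection, n_perm = 1000,
                     min_size = 15, max_size = 500, p_max = 0.05,
                     q_max = 0.25, seed = NULL, exhaustive = FALSE) {
  ranked <- signal_to_noise_ranking(matrix, phen)
  restricted <- restrict_sets(collection, ranked$genes, min_size, max_size)
  if (length(restricted$sets) == 0)
    stop("no sets survive the size restriction", call. = FALSE)
  null <- permutation_null(matrix, phen, restricted, n_perm = n_perm,
                           seed = seed, exhaustive = exhaustive)
  res <- normalize_and_fdr(null$es_obs, null$es_null)
  res$size_used <- unname(lengths(restricted$sets)[res$set])
  res$enriched_class <- ifelse(res$es > 0, phen$class_order[1],
                               phen$class_order[2])
  res$significant <- res$p_nominal < p_max & res$fdr_q < q_max
  res <- res[order(-res$nes), ]
  rownames(res) <- NULL
  structure(list(results = res, significant = res[res$significant, ],
                 params = list(n_perm = null$n_perm, min_size = min_size,
                               max_size = max_size, p_max = p_max,
                               q_max = q_max, seed = seed,
                               exhaustive = exhaustive,
                               metric = "signal_to_noise",
                               statistic = "classic",
                               permutation = "phenotype")),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: %d sets, %d significant (p < %g and q < %g), %d permutations\n",
              nrow(x$results), nrow(x$significant), x$params$p_max,
              x$params$q_max, x$params$n_perm))
  invisible(x)
}

#' Write a GSEA report TSV
#' @param x A `gsea_result`.
#' @param path Output path.
#' @export
write_gsea_table <- function(x, path) {
  stopifnot(inherits(x, "gsea_result"))
  cols <- c("set", "size_used", "es", "nes", "p_nominal", "fdr_q",
            "enriched_class", "significant")
  write.table(x$results[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
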