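# Independent brute-force oracles and small fixtures. Everything here is
# deliberately written from the definitions, without reusing package
# internals, so it can stand as a cross-check of the implementation.

# Benjamini-Hochberg by the min-over-tails definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) p[ord[j]] * m / j, 0)
    adj[ord[i]] <- min(1, min(tail_vals))
  }
  adj
}

# Signal-to-noise score by the definition, one gene at a time.
oracle_s2n <- function(x_pos, x_neg) {
  floorv <- function(s, mu) max(s, max(0.2 * abs(mu), 0.2))
  (mean(x_pos) - mean(x_neg)) /
    (floorv(sd(x_pos), mean(x_pos)) + floorv(sd(x_neg), mean(x_neg)))
}

# Classic enrichment score by walking the list, scalar loop.
oracle_es <- function(ranked_genes, members) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% members
  nh <- sum(hit)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) 1 / nh else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Full exhaustive 3v3 GSEA from definitions: observed ES and nominal p
# for one set, recomputing ranking and ES for every labeling.
oracle_exhaustive_gsea <- function(values, pos_cols, members) {
  n <- ncol(values)
  rank_of <- function(pos_idx) {
    neg_idx <- setdiff(seq_len(n), pos_idx)
    s <- apply(values, 1, function(x) oracle_s2n(x[pos_idx], x[neg_idx]))
    rownames(values)[order(-s, rownames(values))]
  }
  es_obs <- oracle_es(rank_of(pos_cols), members)
  labelings <- combn(n, length(pos_cols))
  es_null <- apply(labelings, 2, function(ix) oracle_es(rank_of(ix), members))
  same <- if (es_obs >= 0) es_null[es_null > 0] else es_null[es_null < 0]
  list(es = es_obs, es_null = es_null,
       p = sum(abs(same) >= abs(es_obs)) / length(same))
}

# A sharp 10-position frequency matrix whose consensus is unambiguous.
sharp_pwm <- function(id = "SYNTH_TF", peak = 0.88,
                      core_cutoff = 0.75, matrix_cutoff = 0.85) {
  f <- matrix((1 - peak) / 3, 4, 10,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c(1, 2, 4, 4, 3, 3, 1, 2, 4, 1)   # ACTTGGACTA
  for (i in seq_len(10)) f[cons[i], i] <- peak
  position_frequency_matrix(id, f, core_cutoff = core_cutoff,
                            matrix_cutoff = matrix_cutoff)
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm$freq)[apply(pwm$freq, 2, which.max)], collapse = "")
}

rc_string <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Tiny ranked list constructed directly (descending scores).
mk_ranked <- function(genes, scores = rev(seq_along(genes))) {
  structure(list(genes = toupper(genes), scores = as.numeric(scores)),
            class = "ranked_list")
}

# Small expression matrix fixture with named rows/columns.
mk_matrix <- function(values, genes, samples, id_level = "gene") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, id_level = id_level)
}
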