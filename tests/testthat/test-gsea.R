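# The enrichment engine: ranking, running-sum scores, permutation null,
# normalisation, FDR, and orchestration.

test_that("signal-to-noise scores match hand computations and the floor rule", {
  m <- mk_matrix(c(4, 6, 1, 3,
                   2, 2, 1, 1),
                 c("PLAIN", "FLOORED"), c("p1", "p2", "n1", "n2"))
  phen <- phenotype_assignment(colnames(m$values), c("T", "T", "C", "C"),
                               c("T", "C"))
  r <- signal_to_noise_ranking(m, phen)
  # sd floor: sd = 0 in both classes, floored at max(0.2*|mu|, 0.2)
  expect_equal(r$scores[match("FLOORED", r$genes)], 1 / (0.4 + 0.2),
               tolerance = 1e-6)
  expect_equal(r$scores[match("PLAIN", r$genes)],
               (5 - 2) / (sqrt(2) + sqrt(2)), tolerance = 1e-6)

  swapped <- phenotype_assignment(phen$samples, phen$classes, c("C", "T"))
  r2 <- signal_to_noise_ranking(m, swapped)
  expect_identical(r2$genes, rev(r$genes))
  expect_equal(r2$scores, -rev(r$scores))
})

test_that("signal-to-noise matches the scalar oracle on random data", {
  set.seed(3)
  v <- matrix(2^rnorm(40 * 8, 8, 1.5), 40, 8,
              dimnames = list(sprintf("G%02d", 1:40),
                              sprintf("s%d", 1:8)))
  m <- expression_matrix(v, id_level = "gene")
  phen <- phenotype_assignment(colnames(v), rep(c("T", "C"), each = 4),
                               c("T", "C"))
  r <- signal_to_noise_ranking(m, phen)
  want <- vapply(rownames(v), function(g)
    oracle_s2n(v[g, 1:4], v[g, 5:8]), 0)
  expect_equal(r$scores, unname(want[r$genes]), tolerance = 1e-12)
})

test_that("running-sum scores reproduce hand enumerations", {
  rl <- mk_ranked(c("G1", "G2", "G3", "G4"))
  top <- enrichment_score(rl, "G1")
  expect_equal(top$es, 1)
  expect_equal(top$running_sum, c(1, 2/3, 1/3, 0))

  alt <- enrichment_score(rl, c("G2", "G4"))
  expect_equal(alt$running_sum, c(-1/2, 0, -1/2, 0))
  expect_equal(alt$es, -1/2)

  expect_equal(enrichment_score(rl, "G4")$es, -1)
  expect_error(enrichment_score(rl, "ABSENT"), "degenerate set")
  expect_error(enrichment_score(rl, c("G1", "G2", "G3", "G4")),
               "degenerate set")
})

test_that("running sum terminates at zero; ES bounded and antisymmetric", {
  set.seed(21)
  genes <- sprintf("G%04d", 1:300)
  for (i in 1:50) {
    rl <- mk_ranked(sample(genes), scores = sort(rnorm(300), decreasing = TRUE))
    members <- sample(genes, sample(c(2:60), 1))
    e <- enrichment_score(rl, members)
    expect_lt(abs(e$running_sum[300]), 1e-9)
    expect_true(abs(e$es) <= 1 + 1e-12)
    rev_rl <- mk_ranked(rev(rl$genes), scores = rev(rl$scores))
    expect_equal(enrichment_score(rev_rl, members)$es, -e$es,
                 tolerance = 1e-12)
    expect_equal(e$es, oracle_es(rl$genes, toupper(members)),
                 tolerance = 1e-12)
  }
})

test_that("classic ES agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(9)
  genes <- sprintf("G%03d", 1:120)
  stats <- setNames(sort(rnorm(120), decreasing = TRUE), genes)
  rl <- mk_ranked(genes, scores = unname(stats))
  for (i in 1:10) {
    members <- sample(genes, sample(5:30, 1))
    ours <- enrichment_score(rl, members)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(genes %in% members),
                               gseaParam = 0)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("restrict_sets intersects with the universe and applies size bounds", {
  coll <- gene_set_collection(list(
    SMALL = sprintf("G%02d", 1:10),
    OK = sprintf("G%02d", 1:20),
    PARTIAL = c(sprintf("G%02d", 1:18), sprintf("X%02d", 1:10)),
    ALL = sprintf("G%02d", 1:30)))
  universe <- sprintf("G%02d", 1:30)
  expect_message(out <- restrict_sets(coll, universe),
                 "dropped 1 of 4")
  expect_identical(names(out$sets), c("OK", "PARTIAL", "ALL"))
  expect_length(out$sets$PARTIAL, 18)   # out-of-universe members removed
  expect_length(out$sets$ALL, 30)       # a set equal to the universe is kept
})

test_that("exhaustive 3v3 null enumerates all 20 labelings, reproducibly", {
  sim <- simulate_expression_experiment(n_genes = 30, n_per_class = 3,
                                        n_up_sets = 1, n_down_sets = 0,
                                        set_size = 8, pool_size = 10,
                                        n_null_sets = 2, seed = 2)
  pn <- permutation_null(sim$matrix, sim$phenotype, sim$collection,
                         exhaustive = TRUE)
  expect_identical(pn$n_perm, 20L)

  a <- permutation_null(sim$matrix, sim$phenotype, sim$collection,
                        n_perm = 25, seed = 99)
  b <- permutation_null(sim$matrix, sim$phenotype, sim$collection,
                        n_perm = 25, seed = 99)
  expect_identical(a$es_null, b$es_null)

  big <- simulate_expression_experiment(n_genes = 30, n_per_class = 10,
                                        n_up_sets = 1, n_down_sets = 0,
                                        set_size = 8, pool_size = 10,
                                        n_null_sets = 1, seed = 2)
  expect_error(permutation_null(big$matrix, big$phenotype, big$collection,
                                exhaustive = TRUE), "10000")
})

test_that("null ES of a random set on null data is centred at zero", {
  sim <- simulate_expression_experiment(n_genes = 200, n_up_sets = 0,
                                        n_down_sets = 0, n_null_sets = 1,
                                        set_size = 30, seed = 8)
  pn <- permutation_null(sim$matrix, sim$phenotype, sim$collection,
                         n_perm = 1000, seed = 8)
  es <- pn$es_null[, 1]
  expect_lt(abs(mean(es)), 3 * sd(es) / sqrt(length(es)))
})

test_that("NES normalisation identities and FDR boundary behave as defined", {
  # observed ES equal to the same-sign null mean magnitude -> |NES| = 1
  es_null <- matrix(c(0.2, 0.4, -0.1, -0.3,
                      0.5, 0.1, -0.2, -0.4), ncol = 2,
                    dimnames = list(NULL, c("A", "B")))
  es_obs <- c(A = 0.3, B = -0.3)   # null means: +0.3 / |-0.3|
  res <- normalize_and_fdr(es_obs, es_null)
  expect_equal(res$nes, c(1, -1), tolerance = 1e-12)
  expect_equal(res$p_nominal, c(0.5, 0.5))

  # a uniquely most extreme observed set beyond every pooled null gets q=0
  es_null2 <- matrix(rep(c(0.1, 0.15, -0.1, -0.15), 2), ncol = 2,
                     dimnames = list(NULL, c("TOP", "MID")))
  res2 <- normalize_and_fdr(c(TOP = 0.9, MID = 0.05), es_null2)
  expect_equal(res2$fdr_q[res2$set == "TOP"], 0)
  expect_identical(res2$boundary, c(FALSE, FALSE))
})

test_that("FDR q is monotone non-decreasing as |NES| decreases", {
  sim <- simulate_expression_experiment(n_genes = 300, n_up_sets = 2,
                                        n_down_sets = 2, set_size = 15,
                                        pool_size = 20, n_null_sets = 30,
                                        seed = 4)
  pn <- permutation_null(sim$matrix, sim$phenotype, sim$collection,
                         n_perm = 100, seed = 4)
  res <- normalize_and_fdr(pn$es_obs, pn$es_null)
  for (side in list(res[res$nes >= 0, ], res[res$nes < 0, ])) {
    o <- order(-abs(side$nes))
    expect_true(all(diff(side$fdr_q[o]) >= -1e-12))
  }
})

test_that("exhaustive nominal p equals the definition-level brute force", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:10)
  v <- matrix(2^rnorm(60, 7, 1), 10, 6,
              dimnames = list(genes, sprintf("s%d", 1:6)))
  m <- expression_matrix(v, id_level = "gene")
  phen <- phenotype_assignment(colnames(v), rep(c("T", "C"), each = 3),
                               c("T", "C"))
  members <- c("G02", "G05", "G07")
  coll <- gene_set_collection(list(S = members))
  pn <- permutation_null(m, phen, coll, exhaustive = TRUE)
  res <- normalize_and_fdr(pn$es_obs, pn$es_null)
  want <- oracle_exhaustive_gsea(v, 1:3, members)
  expect_identical(pn$n_perm, 20L)
  expect_equal(pn$es_obs[["S"]], want$es, tolerance = 1e-12)
  expect_equal(sort(pn$es_null[, 1]), sort(want$es_null), tolerance = 1e-12)
  expect_equal(res$p_nominal, want$p, tolerance = 1e-12)
})

test_that("class swap under the exhaustive null negates ES and preserves p and q", {
  # fixture must be in general position: when the running sum's maximum
  # deviation is attained with equal magnitude on both sides, the signed
  # ES is ambiguous (ties break toward the earlier extremum) and exact
  # antisymmetry degenerates, so such fixtures are rejected up front
  sim <- simulate_expression_experiment(n_genes = 47, n_per_class = 3,
                                        n_up_sets = 1, n_down_sets = 1,
                                        set_size = 7, pool_size = 9,
                                        n_null_sets = 4, seed = 1)
  for (ix in asplit(combn(6, 3), 2)) {
    ph <- phenotype_assignment(sim$phenotype$samples,
                               ifelse(seq_len(6) %in% ix, "T", "C"),
                               c("T", "C"))
    rl <- signal_to_noise_ranking(sim$matrix, ph)
    for (m in sim$collection$sets) {
      r <- enrichment_score(rl, m)$running_sum
      expect_gt(abs(max(r) + min(r)), 1e-9)
    }
  }
  g1 <- suppressMessages(run_gsea(sim$matrix, sim$phenotype, sim$collection,
                                  min_size = 5, exhaustive = TRUE))
  swapped <- phenotype_assignment(sim$phenotype$samples,
                                  sim$phenotype$classes,
                                  rev(sim$phenotype$class_order))
  g2 <- suppressMessages(run_gsea(sim$matrix, swapped, sim$collection,
                                  min_size = 5, exhaustive = TRUE))
  a <- g1$results[order(g1$results$set), ]
  b <- g2$results[order(g2$results$set), ]
  expect_equal(b$es, -a$es, tolerance = 1e-12)
  expect_equal(b$nes, -a$nes, tolerance = 1e-12)
  expect_equal(b$p_nominal, a$p_nominal, tolerance = 1e-12)
  expect_equal(b$fdr_q, a$fdr_q, tolerance = 1e-12)
  # the biological call is orientation-invariant: flipped ES sign under
  # flipped class order names the same enriched class
  expect_identical(b$enriched_class, a$enriched_class)
})

test_that("a planted down-shifted target set is called on the control side", {
  sim <- simulate_expression_experiment(n_genes = 500, n_up_sets = 0,
                                        n_down_sets = 5, set_size = 25,
                                        pool_size = 35, n_null_sets = 45,
                                        seed = 12)
  g <- suppressMessages(run_gsea(sim$matrix, sim$phenotype, sim$collection,
                                 n_perm = 200, seed = 12))
  planted <- g$results[g$results$set %in% sim$truth$planted$set, ]
  expect_true(all(planted$significant))
  expect_true(all(planted$enriched_class == "CTL"))
  expect_identical(g$results$significant,
                   g$results$p_nominal < 0.05 & g$results$fdr_q < 0.25)
  # results sorted by decreasing NES
  expect_true(all(diff(g$results$nes) <= 1e-12))
})
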