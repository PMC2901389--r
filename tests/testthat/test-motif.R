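# MATCH-style scoring, scanning, conservation filtering, promoter-window
# extraction, and the motif gene-set builders.

test_that("information vector hits its closed-form values and derives the core", {
  f <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  f[, 2] <- c(1, 0, 0, 0)
  f[, 3] <- c(0.5, 0.5, 0, 0)
  pwm <- position_frequency_matrix("IV", f)
  iv <- information_vector(pwm)
  expect_equal(iv[1], 0, tolerance = 1e-12)
  expect_equal(iv[2], log(4), tolerance = 1e-12)
  expect_equal(iv[3], log(2), tolerance = 1e-12)
  # windows 1 and 2 tie (both contain positions 2 and 3): leftmost wins
  expect_identical(attr(iv, "core_start"), 1L)

  short <- position_frequency_matrix("S", f[, 1:4])
  expect_error(information_vector(short), "core undefined")
})

test_that("match scores reproduce the analytic examples", {
  pwm <- sharp_pwm()
  cons <- pwm_consensus(pwm)
  sc <- match_scores(pwm, cons)
  expect_equal(sc$mss, 1, tolerance = 1e-12)
  expect_equal(sc$css, 1, tolerance = 1e-12)

  # 2-position matrix, f(1,A)=1, f(2,C)=1, window "AG":
  # Current = ln4, Min = 0, Max = 2 ln4 -> mss = 0.5
  f2 <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, 2,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2 <- position_frequency_matrix("TWO", f2)
  expect_equal(match_scores(pwm2, "AG")$mss, 0.5, tolerance = 1e-12)

  uni <- position_frequency_matrix("UNI",
           matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_error(match_scores(uni, "ACGTAC"), "degenerate matrix")
  expect_error(match_scores(pwm, "ACGTNACGTA"), "non-ACGT")
})

test_that("scanning finds planted sites on both strands and skips N windows", {
  pwm <- sharp_pwm()
  cons <- pwm_consensus(pwm)
  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
              collapse = "")
  seq_fwd <- paste0(substr(bg, 1, 7), cons, substr(bg, 18, 50))
  hits <- scan_sequence(pwm, seq_fwd)
  expect_true(any(hits$offset == 7 & hits$strand == "+" &
                  abs(hits$mss - 1) < 1e-12))

  seq_rev <- paste0(substr(bg, 1, 7), rc_string(cons), substr(bg, 18, 50))
  hits_r <- scan_sequence(pwm, seq_rev)
  expect_true(any(hits_r$offset == 7 & hits_r$strand == "-"))
  expect_identical(nrow(scan_sequence(pwm, seq_rev, both_strands = FALSE)), 0L)

  expect_identical(nrow(scan_sequence(pwm, strrep("N", 60))), 0L)
})

test_that("hit lists mirror exactly under reverse complementation", {
  pwm <- sharp_pwm(matrix_cutoff = 0.5, core_cutoff = 0.4)
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  h <- scan_sequence(pwm, s)
  hr <- scan_sequence(pwm, rc_string(s))
  L <- 10; n <- 400
  mirrored <- data.frame(offset = n - h$offset - L,
                         strand = ifelse(h$strand == "+", "-", "+"),
                         mss = h$mss, css = h$css)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  rownames(mirrored) <- NULL
  rownames(hr) <- NULL
  expect_equal(hr, mirrored, tolerance = 1e-12)
})

test_that("conservation requires gap-free columns and an above-cutoff partner", {
  pwm <- sharp_pwm()
  cons <- pwm_consensus(pwm)
  pad <- strrep("ACGT", 5)
  ref <- paste0(pad, cons, pad)
  # identical rows: conserved
  h <- conserved_hits(pwm, ref, ref)
  expect_true(any(h$conserved & h$offset == 20))
  # gap column inside the hit span in the other row: not conserved
  gap_oth <- paste0(substr(ref, 1, 24), "-", substr(ref, 26, nchar(ref)))
  h2 <- conserved_hits(pwm, ref, gap_oth)
  expect_true(any(h2$offset == 20) && !any(h2$conserved[h2$offset == 20]))
  # other-species site mutated at informative positions below cutoff
  broken <- cons
  iv <- information_vector(pwm)
  worst <- order(-iv)[1:2]
  for (p in worst)
    substr(broken, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    strsplit(cons, "")[[1]][p])[1]
  expect_lt(match_scores(pwm, broken)$css, pwm$core_cutoff)
  h3 <- conserved_hits(pwm, ref, paste0(pad, broken, pad))
  expect_true(any(h3$offset == 20) && !any(h3$conserved[h3$offset == 20]))
  # conserved hits are a subset of reference hits on random pairs
  set.seed(77)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 300, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 300, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    lo <- sharp_pwm(matrix_cutoff = 0.3, core_cutoff = 0.3)
    hh <- conserved_hits(lo, a, b)
    ss <- scan_sequence(lo, gsub("-", "", a), matrix_cutoff = 0.3,
                        core_cutoff = 0.3)
    expect_true(all(hh$offset %in% ss$offset))
    expect_true(all(hh$conserved %in% c(TRUE, FALSE)))
  }
})

test_that("TSS windows are extracted with containment, strand sense and coverage log", {
  blk <- pairwise_alignment_block("chr1", 3000,
                                  strrep("ACGTT", 1000),   # [3000, 8000)
                                  "frog", strrep("ACGTT", 1000))
  tss <- data.frame(gene = c("GPLUS", "GMINUS", "GOUT"), chrom = "chr1",
                    tss = c(5000L, 5000L, 20000L),
                    strand = c("+", "-", "+"))
  w <- extract_tss_windows(tss, list(blk), flank = 1000)
  expect_identical(names(w), c("GPLUS", "GMINUS"))
  expect_identical(nchar(w$GPLUS$ref), 2000L)
  expect_identical(w$GMINUS$ref, rc_string(w$GPLUS$ref))
  cov <- attr(w, "coverage")
  expect_identical(cov$covered, c(TRUE, TRUE, FALSE))

  # a window straddling two abutting blocks is stitched
  b1 <- pairwise_alignment_block("chr2", 0, strrep("AC", 500),
                                 "frog", strrep("AC", 500))
  b2 <- pairwise_alignment_block("chr2", 1000, strrep("GT", 500),
                                 "frog", strrep("GT", 500))
  tss2 <- data.frame(gene = "GSPAN", chrom = "chr2", tss = 1000L,
                     strand = "+")
  w2 <- extract_tss_windows(tss2, list(b1, b2), flank = 1000)
  expect_identical(w2$GSPAN$ref, paste0(strrep("AC", 500), strrep("GT", 500)))

  overlap <- pairwise_alignment_block("chr1", 2999, "AAAA", "frog", "AAAA")
  expect_error(extract_tss_windows(tss, list(blk, overlap)),
               "overlapping alignment blocks")
})

test_that("TF gene-set construction reproduces planted conservation truth", {
  pwm <- sharp_pwm()
  for (seed in 1:3) {
    sim <- simulate_conserved_promoters(pwm, n_genes = 40, seed = seed)
    built <- build_tf_genesets(list(pwm), sim$tss, sim$blocks)
    expect_setequal(built$collection$sets[["V$SYNTH_TF"]],
                    toupper(sim$truth$conserved))
    # decoys are seen by the scanner but rejected by the filter
    decoy_hits <- built$hits[built$hits$gene %in% sim$truth$decoys, ]
    expect_true(all(!decoy_hits$conserved))
  }
  # a matrix whose consensus never occurs yields no (empty) set
  f <- matrix(0.04, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  f["G", ] <- 0.88
  never <- position_frequency_matrix("NEVER", f)
  sim <- simulate_conserved_promoters(pwm, n_genes = 10, seed = 4)
  built2 <- build_tf_genesets(list(never), sim$tss, sim$blocks)
  expect_false("V$NEVER" %in% names(built2$collection$sets))
})

test_that("miRNA seed sets use exact forward-strand substring matching", {
  utrs <- c(HIT = "AAATGAATGTCC",           # contains TGAATGT
            RCONLY = rc_string("ACTGTGAACCGGTT"),  # reverse complement only
            NONE = "CCCCCCCCCCCC")
  motifs <- data.frame(motif = c("TGAATGT", "ACTGTGA", "GGGGGGG"),
                       name = c("MIR-181A", "MIR-27A", "MIR-NONE"))
  coll <- build_mirna_seed_genesets(utrs, motifs)
  expect_identical(coll$sets[["TGAATGT,MIR-181A"]], "HIT")
  expect_false("ACTGTGA,MIR-27A" %in% names(coll$sets))  # rc does not count
  expect_false("GGGGGGG,MIR-NONE" %in% names(coll$sets)) # empty set omitted
  expect_error(build_mirna_seed_genesets(character(), motifs), "no UTR")
  expect_error(build_mirna_seed_genesets(utrs,
                 data.frame(motif = "ACGT", name = "X")), "length >= 6")
})
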