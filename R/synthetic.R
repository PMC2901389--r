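#' Simulate a two-class expression experiment with planted gene sets
#'
#' Emulates the normalised linear-scale matrix a two-condition microarray
#' study starts from: per gene a baseline log2 level drawn from
#' `Normal(baseline_mean, baseline_sd)`, per sample Gaussian log2 noise,
#' and a coordinated class shift of `+delta` (up-sets) or `-delta`
#' (down-sets) log2 units in the positive (treated) class for planted-set
#' members. Planted regulator sets are sampled from a shared per-direction
#' target pool (real motif-set collections are highly redundant: sets of
#' the same factor or miRNA family are near-duplicates), and null sets are
#' drawn from the genes outside both pools. The matrix is emitted on the
#' linear scale (`2^x`); with `probes_per_gene > 1` each gene is expanded
#' into redundant probes with extra probe-level noise to exercise the
#' median collapse.
#'
#' @param n_genes Gene universe size (default 1000).
#' @param n_per_class Samples per class (default 6, the 6v6 design).
#' @param n_up_sets,n_down_sets Planted sets per direction (default 10
#'   each).
#' @param set_size Members per set (default 30).
#' @param pool_size Shared target pool per direction (default 40).
#' @param delta Coordinated class shift in log2 units (default 1).
#' @param n_null_sets Unplanted sets of the same size (default 180).
#' @param baseline_mean,baseline_sd Log2 baseline distribution (8, 2).
#' @param noise_sd Per-sample log2 noise (default 0.5).
#' @param probes_per_gene Redundant probes per gene (default 1 = emit a
#'   gene-level matrix).
#' @param probe_noise_sd Extra log2 noise per probe (default 0.25).
#' @param class_labels Length-2 labels, positive first (default
#'   `c("FSK", "CTL")`).
#' @param seed Integer seed; the output is a pure function of the
#'   parameters and the seed.
#' @return List with `matrix` ([expression_matrix()]), `phenotype`
#'   ([phenotype_assignment()]), `collection` ([gene_set_collection()]
#'   holding planted and null sets), `probe_to_gene` (data.frame or NULL)
#'   and `truth` (planted membership, directions, pools, parameters).
#' @export
simulate_expression_experiment <- function(n_genes = 1000, n_per_class = 6,
                                           n_up_sets = 10, n_down_sets = 10,
                                           set_size = 30, pool_size = 40,
                                           delta = 1, n_null_sets = 180,
                                           baseline_mean = 8,
                                           baseline_sd = 2, noise_sd = 0.5,
                                           probes_per_gene = 1,
                                           probe_noise_sd = 0.25,
                                           class_labels = c("FSK", "CTL"),
                                           seed = 1) {
  n_planted <- n_up_sets + n_down_sets
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (set_size > pool_size && n_planted > 0)
    stop("`set_size` cannot exceed `pool_size`", call. = FALSE)
  need_pool <- (n_up_sets > 0) + (n_down_sets > 0)
  if (need_pool * pool_size + set_size > n_genes)
    stop("planted pools larger than the gene universe", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  pool_genes <- sample(genes, need_pool * pool_size)
  up_pool <- if (n_up_sets > 0) pool_genes[seq_len(pool_size)] else character()
  down_pool <- if (n_down_sets > 0)
    pool_genes[(length(pool_genes) - pool_size + 1):length(pool_genes)]
  else character()
  sets <- list(); dirs <- character()
  for (i in seq_len(n_up_sets)) {
    sets[[sprintf("PLANTED_UP_%02d", i)]] <- sample(up_pool, set_size)
    dirs <- c(dirs, "up")
  }
  for (i in seq_len(n_down_sets)) {
    sets[[sprintf("PLANTED_DOWN_%02d", i)]] <- sample(down_pool, set_size)
    dirs <- c(dirs, "down")
  }
  null_universe <- setdiff(genes, c(up_pool, down_pool))
  for (i in seq_len(n_null_sets)) {
    sets[[sprintf("NULL_%03d", i)]] <- sample(null_universe, set_size)
    dirs <- c(dirs, "null")
  }
  shift <- setNames(numeric(n_genes), genes)
  shift[up_pool] <- delta
  shift[down_pool] <- -delta
  n <- 2 * n_per_class
  samples <- c(sprintf("%s_%d", class_labels[1], seq_len(n_per_class)),
               sprintf("%s_%d", class_labels[2], seq_len(n_per_class)))
  classes <- rep(class_labels, each = n_per_class)
  baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
  logx <- matrix(rnorm(n_genes * n, 0, noise_sd), n_genes, n) + baseline
  logx[, seq_len(n_per_class)] <- logx[, seq_len(n_per_class)] + shift
  dimnames(logx) <- list(genes, samples)
  probe_map <- NULL
  if (probes_per_gene > 1) {
    probe_rows <- rep(seq_len(n_genes), each = probes_per_gene)
    probes <- sprintf("%s_at%d", genes[probe_rows],
                      rep(seq_len(probes_per_gene), times = n_genes))
    logx <- logx[probe_rows, , drop = FALSE] +
      matrix(rnorm(length(probe_rows) * n, 0, probe_noise_sd),
             length(probe_rows), n)
    rownames(logx) <- probes
    probe_map <- data.frame(probe = probes, gene = genes[probe_rows],
                            stringsAsFactors = FALSE)
  }
  mat <- expression_matrix(2^logx,
                           id_level = if (is.null(probe_map)) "gene"
                                      else "probe")
  planted <- data.frame(set = names(sets)[dirs != "null"],
                        direction = dirs[dirs != "null"],
                        delta = rep(delta, sum(dirs != "null")),
                        stringsAsFactors = FALSE)
  truth <- list(planted = planted,
                members = sets[dirs != "null"],
                null_sets = names(sets)[dirs == "null"],
                up_pool = up_pool, down_pool = down_pool,
                positive_class = class_labels[1], seed = seed,
                params = list(n_genes = n_genes, n_per_class = n_per_class,
                              set_size = set_size, pool_size = pool_size,
                              delta = delta, noise_sd = noise_sd,
                              baseline_mean = baseline_mean,
                              baseline_sd = baseline_sd))
  list(matrix = mat,
       phenotype = phenotype_assignment(samples, classes, class_labels),
       collection = gene_set_collection(sets),
       probe_to_gene = probe_map, truth = truth)
}

#' Write / read a planted-truth manifest
#'
#' Every generator emits a `truth` object; recovery tests are meant to
#' read the planted truth only from this structured plain-text (YAML)
#' manifest, never from the generator's internals.
#'
#' @param truth A generator's `truth` element.
#' @param path Output path.
#' @export
write_truth_manifest <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @return [read_truth_manifest()] returns the truth list.
#' @export
read_truth_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' Simulate aligned promoter pairs with planted conserved motif sites
#'
#' For each gene a 2 x `flank`-base promoter window is rendered as one
#' pairwise alignment block: an i.i.d. uniform-ACGT reference row, an
#' "other species" row derived from it by per-base substitution, and
#' random gap columns (rate `gap_rate`) outside planted sites. Planted
#' genes carry the matrix consensus at an aligned, gap-free position in
#' both rows; decoy genes carry it in the reference row only — the
#' other-row site is mutated at its most informative positions until it
#' falls below the cutoffs, or a gap column is inserted inside the site —
#' so decoys must fail the conservation filter. A fraction of genes is
#' placed on the `-` strand (sites are planted promoter-sense).
#'
#' @param pwm A [position_frequency_matrix()].
#' @param n_genes Number of genes (default 60).
#' @param planted_fraction Fraction of genes receiving a conserved
#'   consensus site (default 0.25).
#' @param decoy_fraction Fraction receiving a non-conserved decoy site
#'   (default 0.15).
#' @param flank Promoter half-width (default 1000).
#' @param gap_rate Per-column gap probability outside sites (default
#'   0.05), split evenly between other-row deletions (reference base over
#'   a gap) and other-row insertions (gap in the reference row); neither
#'   kind alters the reference coordinate system.
#' @param substitution_rate Fraction of background other-row positions
#'   redrawn uniformly (default 1: the two background rows are
#'   independent, so chance cross-species conservation is negligible;
#'   lower values create correlated rows).
#' @param minus_fraction Fraction of genes on the `-` strand (default
#'   0.2).
#' @param seed Integer seed.
#' @return List with `blocks`, `tss` and `truth` (elements `conserved`,
#'   `decoys`, `background`, `matrix_id`, `seed`).
#' @export
simulate_conserved_promoters <- function(pwm, n_genes = 60,
                                         planted_fraction = 0.25,
                                         decoy_fraction = 0.15,
                                         flank = 1000, gap_rate = 0.05,
                                         substitution_rate = 1,
                                         minus_fraction = 0.2, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm$freq)
  consensus <- bases[apply(pwm$freq, 2, which.max)]
  I <- info_values(pwm$freq)
  mcut <- pwm$matrix_cutoff; ccut <- pwm$core_cutoff
  # a site sequence (promoter-sense) mutated until it misses the cutoffs
  broken_site <- function() {
    s <- consensus
    for (pos in order(-I)) {
      s[pos] <- bases[which.min(pwm$freq[, pos])]
      sc <- match_scores(pwm, paste(s, collapse = ""))
      if (sc$mss < mcut || sc$css < ccut) return(s)
    }
    stop(sprintf("matrix '%s' cannot be broken below its cutoffs", pwm$id),
         call. = FALSE)
  }
  width <- 2L * flank
  genes <- sprintf("PGENE%04d", seq_len(n_genes))
  n_cons <- round(planted_fraction * n_genes)
  n_decoy <- round(decoy_fraction * n_genes)
  role <- rep("background", n_genes)
  role[seq_len(n_cons)] <- "conserved"
  if (n_decoy > 0) role[n_cons + seq_len(n_decoy)] <- "decoy"
  role <- sample(role)
  strand <- ifelse(runif(n_genes) < minus_fraction, "-", "+")
  blocks <- vector("list", n_genes)
  tss <- data.frame(gene = genes, chrom = "chr1",
                    tss = flank + (seq_len(n_genes) - 1L) * (width + 100L),
                    strand = strand, stringsAsFactors = FALSE)
  sense <- function(chars, minus) {
    if (!minus) return(chars)
    strsplit(revcomp(paste(chars, collapse = "")), "")[[1]]
  }
  for (g in seq_len(n_genes)) {
    ref <- sample(bases, width, replace = TRUE)
    mut <- runif(width) < substitution_rate
    oth <- ref
    oth[mut] <- sample(bases, sum(mut), replace = TRUE)
    site_span <- integer()
    gap_in_site <- FALSE
    if (role[g] != "background") {
      site_start <- sample(width - L + 1L, 1)
      site_span <- site_start:(site_start + L - 1L)
      minus <- strand[g] == "-"
      ref[site_span] <- sense(consensus, minus)
      if (role[g] == "conserved") {
        oth[site_span] <- sense(consensus, minus)
      } else if (runif(1) < 0.5) {
        oth[site_span] <- sense(broken_site(), minus)
      } else {
        oth[site_span] <- sense(consensus, minus)
        gap_in_site <- TRUE
      }
    }
    # gap columns outside the planted site. Deletions overwrite an
    # existing column's other-row base with "-"; insertions add a column
    # with "-" in the reference row. Neither changes the ungapped
    # reference length, so block coordinates stay exact.
    del_at <- setdiff(which(runif(width) < gap_rate / 2), site_span)
    oth[del_at] <- "-"
    gaps <- setdiff(which(runif(width) < gap_rate / 2), site_span)
    n_cols <- width + length(gaps)
    tgt <- seq_len(width) + findInterval(seq_len(width) - 1L, gaps)
    new_ref <- character(n_cols); new_oth <- character(n_cols)
    new_ref[tgt] <- ref; new_oth[tgt] <- oth
    ins_at <- setdiff(seq_len(n_cols), tgt)
    if (length(ins_at)) {
      new_ref[ins_at] <- "-"
      new_oth[ins_at] <- sample(bases, length(ins_at), replace = TRUE)
    }
    if (gap_in_site) {
      # a reference-gap column splitting the site breaks conservation
      # without disturbing the ungapped reference sequence
      at <- tgt[site_span[L %/% 2]]
      new_ref <- append(new_ref, "-", after = at)
      new_oth <- append(new_oth, sample(bases, 1), after = at)
    }
    blocks[[g]] <- pairwise_alignment_block(
      "chr1", tss$tss[g] - flank, paste(new_ref, collapse = ""),
      "other", paste(new_oth, collapse = ""))
  }
  list(blocks = blocks, tss = tss,
       truth = list(conserved = genes[role == "conserved"],
                    decoys = genes[role == "decoy"],
                    background = genes[role == "background"],
                    matrix_id = pwm$id, seed = seed))
}

#' Simulate 3'-UTR sequences with planted seed motifs
#'
#' Planted member genes contain each of their motifs at least once;
#' non-members are rejection-sampled until they contain none of the
#' motifs (an error after `max_attempts` failures means the motifs are
#' too permissive for the UTR length).
#'
#' @param motifs Data.frame with columns `motif`, `name`.
#' @param n_genes Number of genes (default 50).
#' @param planted_members Named list: motif name -> member gene symbols.
#'   Defaults to the first 10 genes for every motif.
#' @param utr_length UTR length in bases (default 500).
#' @param max_attempts Rejection-sampling cap per gene (default 100).
#' @param seed Integer seed.
#' @return List with `utrs` (named character vector) and `truth`.
#' @export
simulate_utr_set <- function(motifs, n_genes = 50, planted_members = NULL,
                             utr_length = 500, max_attempts = 100,
                             seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mot <- toupper(motifs$motif)
  genes <- sprintf("UGENE%04d", seq_len(n_genes))
  if (is.null(planted_members))
    planted_members <- setNames(
      rep(list(genes[seq_len(min(10, n_genes))]), nrow(motifs)),
      motifs$name)
  all_members <- unique(unlist(planted_members))
  utrs <- setNames(character(n_genes), genes)
  for (g in genes) {
    my_motifs <- mot[vapply(names(planted_members),
                            function(nm) g %in% planted_members[[nm]],
                            logical(1))]
    for (attempt in seq_len(max_attempts)) {
      s <- paste(sample(bases, utr_length, replace = TRUE), collapse = "")
      for (m in my_motifs) {
        at <- sample(utr_length - nchar(m) + 1L, 1)
        substr(s, at, at + nchar(m) - 1L) <- m
      }
      hit <- vapply(mot, function(m) grepl(m, s, fixed = TRUE), logical(1))
      ok <- all(hit[mot %in% my_motifs]) && !any(hit[!mot %in% my_motifs])
      if (ok) break
      if (attempt == max_attempts)
        stop("rejection sampling failed: motifs too permissive for this UTR length",
             call. = FALSE)
    }
    utrs[[g]] <- s
  }
  list(utrs = utrs,
       truth = list(planted_members = planted_members,
                    non_members = setdiff(genes, all_members),
                    seed = seed))
}

#' Simulate qPCR cycle-threshold records
#'
#' Per sample, a reference level `~ Normal(10, 0.1)`; the target's dCt is
#' fixed at `control_dct` for controls and shifted by `-log2(true_fold)`
#' for treated samples; each well carries technical noise
#' `Normal(0, replicate_sd)` over `n_replicates` replicates. With
#' `replicate_sd = 0` the 2^-ddCt estimator recovers `true_fold` exactly.
#'
#' @param true_fold True treated/control expression ratio (> 0).
#' @param n_per_arm Biological samples per condition (default 3).
#' @param replicate_sd Technical Ct noise, cycles (default 0.2).
#' @param n_replicates Technical replicates per well (default 3).
#' @param control_dct Baseline target-minus-reference dCt (default 5).
#' @param target Target gene name (default `"TARGET"`).
#' @param reference_gene Normaliser name (default `"18S"`).
#' @param seed Integer seed.
#' @return Data.frame with columns `sample`, `condition`, `gene`, `ct`.
#' @export
simulate_qpcr_cts <- function(true_fold = 4, n_per_arm = 3,
                              replicate_sd = 0.2, n_replicates = 3,
                              control_dct = 5, target = "TARGET",
                              reference_gene = "18S", seed = 1) {
  if (true_fold <= 0) stop("`true_fold` must be > 0", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (cond in c("treated", "control")) {
    shift <- if (cond == "treated") -log2(true_fold) else 0
    for (s in seq_len(n_per_arm)) {
      id <- sprintf("%s_%d", toupper(substr(cond, 1, 1)), s)
      ref_level <- rnorm(1, 10, 0.1)
      tgt_level <- ref_level + control_dct + shift
      rows[[length(rows) + 1]] <- data.frame(
        sample = id, condition = cond,
        gene = rep(c(target, reference_gene), each = n_replicates),
        ct = c(tgt_level + rnorm(n_replicates, 0, replicate_sd),
               ref_level + rnorm(n_replicates, 0, replicate_sd)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate per-explant count groups
#'
#' Draws per-explant counts (the BrdU-positive-nucleus setting) from a
#' Poisson with the given group mean, or a negative binomial when a
#' `dispersion` is supplied (`size = 1/dispersion`).
#'
#' @param group_means Named numeric vector of group means (>= 0).
#' @param ns Integer vector of group sizes, parallel to `group_means`.
#' @param dispersion Optional overdispersion; NULL = Poisson.
#' @param seed Integer seed.
#' @return Data.frame with columns `group`, `count`.
#' @export
simulate_count_groups <- function(group_means, ns, dispersion = NULL,
                                  seed = 1) {
  if (any(group_means < 0)) stop("means must be >= 0", call. = FALSE)
  if (length(group_means) != length(ns))
    stop("`ns` must be parallel to `group_means`", call. = FALSE)
  set.seed(seed)
  nm <- names(group_means)
  if (is.null(nm)) nm <- sprintf("group%d", seq_along(group_means))
  out <- lapply(seq_along(group_means), function(i) {
    counts <- if (is.null(dispersion)) rpois(ns[i], group_means[i])
              else rnbinom(ns[i], mu = group_means[i], size = 1 / dispersion)
    data.frame(group = nm[i], count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
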