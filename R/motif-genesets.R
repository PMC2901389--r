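#' Extract aligned promoter windows around transcription start sites
#'
#' Maps the interval `[tss - flank, tss + flank)` of each gene (0-based,
#' half-open, on the ungapped reference) into the overlapping alignment
#' blocks and returns the gapped (reference, other) row pair restricted
#' to that interval. Genes on the `-` strand have both rows
#' reverse-complemented so downstream scanning is promoter-sense. Genes
#' whose window is not fully covered by blocks are absent from the output
#' and listed in the coverage log. Blocks covering the same reference
#' base twice are an input error.
#'
#' @param tss Data.frame from [read_tss_table()].
#' @param blocks List of [pairwise_alignment_block()].
#' @param flank Bases either side of the TSS (default 1000, i.e. the 2 kb
#'   promoter window).
#' @return Named list (by gene) of lists with `ref`, `other`, `strand`;
#'   attribute `coverage` holds a data.frame (`gene`, `covered`).
#' @export
extract_tss_windows <- function(tss, blocks, flank = 1000) {
  if (flank < 1) stop("`flank` must be positive", call. = FALSE)
  chroms <- vapply(blocks, `[[`, "", "ref_name")
  starts <- vapply(blocks, `[[`, 0L, "ref_start")
  ends <- vapply(blocks, `[[`, 0L, "ref_end")
  # reject overlapping blocks on the same reference chromosome
  for (ch in unique(chroms)) {
    ix <- which(chroms == ch)
    o <- ix[order(starts[ix])]
    if (length(o) > 1 && any(starts[o][-1] < ends[o][-length(o)]))
      stop(sprintf("overlapping alignment blocks on %s cover the same reference base",
                   ch), call. = FALSE)
  }
  out <- list()
  covered <- logical(nrow(tss))
  for (g in seq_len(nrow(tss))) {
    ws <- tss$tss[g] - flank; we <- tss$tss[g] + flank
    ix <- which(chroms == tss$chrom[g] & starts < we & ends > ws)
    ix <- ix[order(starts[ix])]
    if (length(ix) == 0) next
    # the window must be fully and contiguously covered
    if (starts[ix[1]] > max(ws, 0) || ends[ix[length(ix)]] < we) next
    if (length(ix) > 1 && any(starts[ix][-1] != ends[ix][-length(ix)]))
      next
    if (ws < 0) next
    ref_parts <- character(0); oth_parts <- character(0)
    for (b in ix) {
      blk <- blocks[[b]]
      rc <- strsplit(blk$ref_text, "")[[1]]
      oc <- strsplit(blk$other_text, "")[[1]]
      refpos <- rep(NA_integer_, length(rc))
      refpos[rc != "-"] <- blk$ref_start + seq_len(sum(rc != "-")) - 1L
      lo <- max(ws, blk$ref_start); hi <- min(we, blk$ref_end)
      keep_base <- which(!is.na(refpos) & refpos >= lo & refpos < hi)
      cols <- keep_base[1]:keep_base[length(keep_base)]
      ref_parts <- c(ref_parts, paste(rc[cols], collapse = ""))
      oth_parts <- c(oth_parts, paste(oc[cols], collapse = ""))
    }
    ref <- paste(ref_parts, collapse = "")
    oth <- paste(oth_parts, collapse = "")
    if (tss$strand[g] == "-") { ref <- revcomp(ref); oth <- revcomp(oth) }
    out[[tss$gene[g]]] <- list(ref = ref, other = oth,
                               strand = tss$strand[g])
    covered[g] <- TRUE
  }
  attr(out, "coverage") <- data.frame(gene = tss$gene, covered = covered,
                                      stringsAsFactors = FALSE)
  out
}

#' Build conserved transcription-factor motif gene sets
#'
#' For every frequency matrix, scans each gene's aligned promoter window
#' pair and assembles the set of genes with at least one conserved hit
#' (both species above cutoff at the aligned, gap-free positions). Sets
#' are named `V$<matrix_id>`; matrices with no conserved hit anywhere are
#' omitted.
#'
#' @param matrices List of [position_frequency_matrix()].
#' @param tss Data.frame from [read_tss_table()].
#' @param blocks List of [pairwise_alignment_block()].
#' @param flank Promoter half-width in bases (default 1000).
#' @param core_cutoff,matrix_cutoff Global cutoff defaults.
#' @param cutoff_profile Optional data.frame (`matrix_id`, `core_cutoff`,
#'   `matrix_cutoff`) of per-matrix overrides.
#' @return List with `collection` (a [gene_set_collection()]) and `hits`
#'   (data.frame: `gene`, `matrix_id`, `offset`, `strand`, `mss`, `css`,
#'   `conserved`).
#' @export
build_tf_genesets <- function(matrices, tss, blocks, flank = 1000,
                              core_cutoff = 0.75, matrix_cutoff = 0.85,
                              cutoff_profile = NULL) {
  windows <- extract_tss_windows(tss, blocks, flank = flank)
  sets <- list(); descs <- character()
  hit_rows <- list()
  for (pwm in matrices) {
    ccut <- core_cutoff; mcut <- matrix_cutoff
    if (!is.null(cutoff_profile)) {
      ovr <- cutoff_profile[cutoff_profile$matrix_id == pwm$id, , drop = FALSE]
      if (nrow(ovr) == 1) {
        ccut <- ovr$core_cutoff; mcut <- ovr$matrix_cutoff
      }
    }
    members <- character()
    for (g in names(windows)) {
      h <- conserved_hits(pwm, windows[[g]]$ref, windows[[g]]$other,
                          matrix_cutoff = mcut, core_cutoff = ccut)
      if (nrow(h)) {
        h$gene <- g; h$matrix_id <- pwm$id
        hit_rows[[length(hit_rows) + 1]] <- h
        if (any(h$conserved)) members <- c(members, g)
      }
    }
    if (length(members)) {
      nm <- paste0("V$", pwm$id)
      sets[[nm]] <- members
      descs <- c(descs, sprintf("%s conserved hits (core>=%.2f, matrix>=%.2f)",
                                pwm$id, ccut, mcut))
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else data.frame(offset = integer(), strand = character(),
                          mss = numeric(), css = numeric(),
                          conserved = logical(), gene = character(),
                          matrix_id = character())
  list(collection = gene_set_collection(sets, descriptions = descs),
       hits = hits[, c("gene", "matrix_id", "offset", "strand", "mss",
                       "css", "conserved")])
}

#' Build microRNA seed-motif target gene sets
#'
#' A gene joins a motif's set when its 3'-UTR contains the seed motif as
#' an exact forward-strand substring (the 7-mer seed-match convention of
#' the motif-derived target collections; no thermodynamic model). Sets
#' are named `<MOTIF>,<NAME>`; motifs matching no UTR are omitted.
#'
#' @param utrs Named character vector of 3'-UTR sequences (from
#'   [read_utr_fasta()]).
#' @param motifs Data.frame with columns `motif` (ACGT, length >= 6) and
#'   `name` (e.g. the miRNA family list).
#' @return A [gene_set_collection()].
#' @export
build_mirna_seed_genesets <- function(utrs, motifs) {
  if (length(utrs) == 0) stop("no UTR sequences supplied", call. = FALSE)
  if (!all(c("motif", "name") %in% names(motifs)))
    stop("`motifs` needs columns motif, name", call. = FALSE)
  mot <- toupper(motifs$motif)
  if (any(nchar(mot) < 6) || any(grepl("[^ACGT]", mot)))
    stop("motifs must be ACGT strings of length >= 6", call. = FALSE)
  seqs <- toupper(utrs)
  sets <- list(); descs <- character()
  for (i in seq_along(mot)) {
    members <- names(seqs)[grepl(mot[i], seqs, fixed = TRUE)]
    if (length(members)) {
      nm <- paste(mot[i], motifs$name[i], sep = ",")
      sets[[nm]] <- members
      descs <- c(descs, sprintf("3'-UTR seed match %s", mot[i]))
    }
  }
  gene_set_collection(sets, descriptions = descs)
}
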