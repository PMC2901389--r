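#' Pairwise alignment block
#'
#' One MAF alignment block restricted to a reference/other species pair
#' (the chicken/frog promoter-alignment setting). Coordinates are 0-based
#' on the ungapped reference; the reference strand must be `+` — blocks on
#' the reverse reference strand are rejected rather than flipped, because
#' silent coordinate reversal is a classic source of bugs.
#'
#' @param ref_name,other_name Sequence source names (`chrom` for the
#'   reference).
#' @param ref_start 0-based start of the block on the ungapped reference.
#' @param ref_text,other_text Equal-length alignment rows over
#'   `A,C,G,T,N,-`.
#' @return Object of class `pairwise_alignment_block`.
#' @export
pairwise_alignment_block <- function(ref_name, ref_start, ref_text,
                                     other_name, other_text) {
  ref_text <- toupper(ref_text); other_text <- toupper(other_text)
  if (nchar(ref_text) != nchar(other_text))
    stop("alignment rows must have equal length", call. = FALSE)
  if (grepl("[^ACGTN-]", ref_text) || grepl("[^ACGTN-]", other_text))
    stop("alignment rows may only contain A,C,G,T,N,-", call. = FALSE)
  if (ref_start < 0) stop("ref_start must be >= 0", call. = FALSE)
  ungapped <- nchar(gsub("-", "", ref_text, fixed = TRUE))
  structure(list(ref_name = ref_name, ref_start = as.integer(ref_start),
                 ref_text = ref_text, other_name = other_name,
                 other_text = other_text,
                 ref_end = as.integer(ref_start) + ungapped),
            class = "pairwise_alignment_block")
}

#' Read a pairwise-dialect MAF alignment file
#'
#' Accepts the MAF dialect with exactly two `s` lines per `a` block; the
#' first `s` line is the reference (chicken-role) row. The stated ungapped
#' size of each row must match its non-gap character count, rows must be
#' equal length, and reference rows on the `-` strand are rejected.
#'
#' @param path File path.
#' @return List of [pairwise_alignment_block()] in file order.
#' @export
read_pairwise_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, "a")) { i <- i + 1; next }
    s_lines <- integer()
    j <- i + 1
    while (j <= length(lines) && startsWith(trimws(lines[j]), "s")) {
      s_lines <- c(s_lines, j); j <- j + 1
    }
    if (length(s_lines) != 2)
      parse_error(path, i,
                  sprintf("pairwise dialect requires exactly 2 's' lines per block, got %d",
                          length(s_lines)))
    parse_s <- function(k) {
      f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      if (length(f) != 7)
        parse_error(path, k, "'s' line needs: s src start size strand srcSize text")
      size <- suppressWarnings(as.integer(f[4]))
      start <- suppressWarnings(as.integer(f[3]))
      if (is.na(size) || is.na(start))
        parse_error(path, k, "non-integer start/size field")
      text <- toupper(f[7])
      if (nchar(gsub("-", "", text, fixed = TRUE)) != size)
        parse_error(path, k,
                    sprintf("stated size %d does not match %d non-gap characters",
                            size, nchar(gsub("-", "", text, fixed = TRUE))))
      list(src = f[2], start = start, strand = f[5], text = text)
    }
    ref <- parse_s(s_lines[1]); oth <- parse_s(s_lines[2])
    if (ref$strand != "+")
      parse_error(path, s_lines[1],
                  "reverse-strand reference rows are not supported (re-orient upstream)")
    if (nchar(ref$text) != nchar(oth$text))
      parse_error(path, s_lines[2], "alignment rows have unequal lengths")
    blocks[[length(blocks) + 1]] <-
      pairwise_alignment_block(ref$src, ref$start, ref$text, oth$src, oth$text)
    i <- j
  }
  blocks
}

#' Write pairwise alignment blocks as MAF
#' @param blocks List of [pairwise_alignment_block()].
#' @param path Output path.
#' @export
write_pairwise_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    ug_ref <- nchar(gsub("-", "", b$ref_text, fixed = TRUE))
    ug_oth <- nchar(gsub("-", "", b$other_text, fixed = TRUE))
    writeLines(c("a score=0",
                 sprintf("s %s %d %d + %d %s", b$ref_name, b$ref_start,
                         ug_ref, b$ref_end, b$ref_text),
                 sprintf("s %s 0 %d + %d %s", b$other_name, ug_oth, ug_oth,
                         b$other_text),
                 ""), con)
  }
  invisible(path)
}

#' Read / write a transcription start site table
#'
#' Tab-separated columns `gene`, `chrom`, `tss` (0-based), `strand`
#' (`+`/`-`), one record per (gene, chrom, tss).
#'
#' @param path File path.
#' @return A data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    parse_error(path, 1, paste("TSS table needs columns:",
                               paste(need, collapse = ", ")))
  if (any(is.na(df$tss)) || any(df$tss < 0))
    parse_error(path, which(is.na(df$tss) | df$tss < 0)[1] + 1,
                "tss must be a non-negative 0-based coordinate")
  if (!all(df$strand %in% c("+", "-")))
    parse_error(path, which(!df$strand %in% c("+", "-"))[1] + 1,
                "strand must be '+' or '-'")
  if (anyDuplicated(df[c("gene", "chrom", "tss")]))
    parse_error(path, which(duplicated(df[c("gene", "chrom", "tss")]))[1] + 1,
                "duplicate (gene, chrom, tss) record")
  df$gene <- toupper(df$gene)
  df[need]
}

#' @rdname read_tss_table
#' @param tss Data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
write_tss_table <- function(tss, path) {
  write.table(tss[c("gene", "chrom", "tss", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write 3'-UTR sequences as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning a plain named
#' character vector (names upper-cased gene symbols, sequences upper-case
#' DNA), the representation the seed-matching code consumes.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0)
    parse_error(path, 1, "FASTA file contains no sequences")
  out <- toupper(as.character(ss))
  names(out) <- toupper(sub("\\s.*$", "", names(ss)))
  out
}

#' @rdname read_utr_fasta
#' @param utrs Named character vector of sequences.
#' @export
write_utr_fasta <- function(utrs, path) {
  ss <- Biostrings::DNAStringSet(unname(utrs))
  names(ss) <- names(utrs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a two-column probe-to-gene mapping table
#'
#' Tab-separated columns `probe`, `gene`; the explicit mapping the probe
#' collapse step consumes (the array's annotation source is supplied by
#' the user, not assumed).
#'
#' @param path File path.
#' @return Data.frame with columns `probe`, `gene` (gene upper-cased).
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(df)))
    parse_error(path, 1, "probe map needs columns: probe, gene")
  df$gene <- toupper(df$gene)
  df[c("probe", "gene")]
}
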