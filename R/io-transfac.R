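#' Position frequency matrix
#'
#' Per-position nucleotide frequencies of a transcription-factor binding
#' motif, the scoring model of MATCH-style promoter scanning. Columns are
#' motif positions, rows the bases A, C, G, T; every column sums to 1.
#' `core_cutoff` and `matrix_cutoff` are the similarity-score thresholds a
#' window must reach at the 5-position core and over the full matrix.
#'
#' @param id Matrix identifier (e.g. a TRANSFAC accession or factor name).
#' @param freq Numeric 4 x L matrix, rownames `A,C,G,T`, columns summing
#'   to 1 within 1e-6.
#' @param core_cutoff,matrix_cutoff Similarity cutoffs in `[0,1]`.
#' @return Object of class `position_frequency_matrix`.
#' @export
position_frequency_matrix <- function(id, freq, core_cutoff = 0.75,
                                      matrix_cutoff = 0.85) {
  if (!is.matrix(freq) || nrow(freq) != 4)
    stop("`freq` must be a 4 x L matrix", call. = FALSE)
  rn <- rownames(freq)
  if (is.null(rn) || !identical(sort(rn), c("A", "C", "G", "T")))
    stop("`freq` rows must be named A, C, G, T", call. = FALSE)
  freq <- freq[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(freq < 0) || any(abs(colSums(freq) - 1) > 1e-6))
    stop("each position's frequencies must be non-negative and sum to 1",
         call. = FALSE)
  if (any(c(core_cutoff, matrix_cutoff) < 0) ||
      any(c(core_cutoff, matrix_cutoff) > 1))
    stop("cutoffs must lie in [0,1]", call. = FALSE)
  structure(list(id = as.character(id), freq = freq,
                 core_cutoff = core_cutoff, matrix_cutoff = matrix_cutoff),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat(sprintf("position_frequency_matrix '%s': %d positions (cutoffs core %.2f, matrix %.2f)\n",
              x$id, ncol(x$freq), x$core_cutoff, x$matrix_cutoff))
  invisible(x)
}

#' Read TRANSFAC-format frequency matrices
#'
#' Parses the TRANSFAC flat-file matrix dialect: records separated by
#' `//`, an `ID` line per record, and numbered position lines
#' `NN  a c g t  consensus`. Counts are converted to per-position
#' frequencies by dividing by the position's count sum; a position with a
#' zero count sum is a format error.
#'
#' @param path File path.
#' @param core_cutoff,matrix_cutoff Default cutoffs attached to every
#'   matrix (overridable downstream).
#' @return List of [position_frequency_matrix()] in file order.
#' @export
read_transfac_matrices <- function(path, core_cutoff = 0.75,
                                   matrix_cutoff = 0.85) {
  lines <- readLines(path)
  out <- list()
  id <- NULL
  counts <- NULL
  rec_start <- 1
  flush <- function(at_line) {
    if (is.null(id) && is.null(counts)) return(invisible())
    if (is.null(id))
      parse_error(path, rec_start, "matrix record has no ID line")
    if (is.null(counts) || ncol(counts) < 1)
      parse_error(path, rec_start,
                  sprintf("matrix '%s' has no position lines", id))
    cs <- colSums(counts)
    if (any(cs == 0))
      parse_error(path, at_line,
                  sprintf("matrix '%s' position %d has zero count sum",
                          id, which(cs == 0)[1]))
    freq <- sweep(counts, 2, cs, "/")
    out[[length(out) + 1]] <<- position_frequency_matrix(
      id, freq, core_cutoff = core_cutoff, matrix_cutoff = matrix_cutoff)
    id <<- NULL; counts <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "//") { flush(i); rec_start <- i + 1; next }
    if (grepl("^ID\\s+", ln)) {
      id <- sub("^ID\\s+", "", ln)
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 5)
        parse_error(path, i, "position line needs 4 base counts")
      v <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(v) || any(v < 0))
        parse_error(path, i, "non-numeric or negative count")
      counts <- cbind(counts, v)
      if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
    }
    # other annotation lines (P0, NA, BF, ...) are ignored
  }
  flush(length(lines))
  out
}
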