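#' Read a GCT (#1.2) expression matrix
#'
#' The GCT format is the expression interchange format of the GSEA
#' ecosystem: a `#1.2` version line, a `rows<TAB>cols` dimension line, a
#' header line `NAME<TAB>Description<TAB><sample>...`, then one row per
#' probe/gene. Values are taken as linear-scale intensities.
#'
#' @param path File path.
#' @param id_level `"probe"` (duplicate NAMEs allowed) or `"gene"`.
#' @return An [expression_matrix()].
#' @export
read_gct <- function(path, id_level = c("probe", "gene")) {
  id_level <- match.arg(id_level)
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
    parse_error(path, 1, "not a GCT file: first line must be '#1.2'")
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    parse_error(path, 2, "expected '<rows>\\t<cols>' dimension line")
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  hdr <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != nc + 2 || toupper(hdr[1]) != "NAME")
    parse_error(path, 3,
                sprintf("header must be NAME, Description and %d sample columns", nc))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != nr)
    parse_error(path, 3 + min(length(body), nr) + 1,
                sprintf("header declares %d rows but body has %d", nr,
                        length(body)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != nc + 2)
  if (length(bad))
    parse_error(path, 3 + bad[1],
                sprintf("expected %d fields, got %d", nc + 2,
                        lengths(fields)[bad[1]]))
  m <- matrix(NA_real_, nr, nc)
  ids <- character(nr); desc <- character(nr)
  for (i in seq_len(nr)) {
    f <- fields[[i]]
    ids[i] <- f[1]; desc[i] <- f[2]
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      parse_error(path, 3 + i,
                  sprintf("non-numeric value '%s' in row %d ('%s'), sample column %d",
                          f[j + 2], i, ids[i], j))
    }
    m[i, ] <- v
  }
  rownames(m) <- ids
  colnames(m) <- hdr[-(1:2)]
  expression_matrix(m, id_level = id_level, description = desc)
}

#' Write a GCT (#1.2) expression matrix
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  desc <- x$description
  if (is.null(desc)) desc <- rep("na", nrow(x$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2",
               paste(nrow(x$values), ncol(x$values), sep = "\t"),
               paste(c("NAME", "Description", colnames(x$values)),
                     collapse = "\t")), con)
  body <- cbind(rownames(x$values), desc,
                format(x$values, trim = TRUE, scientific = FALSE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a two-class CLS phenotype file
#'
#' Line 1 is `N 2 1`, line 2 `# <classA> <classB>`, line 3 the per-sample
#' labels (either the names from line 2 or 0/1 indices mapped by order of
#' first occurrence). The first-named class is the positive class.
#'
#' @param path File path.
#' @param sample_ids Optional sample identifiers (defaults to `S1..SN`).
#' @return A [phenotype_assignment()].
#' @export
read_cls <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) parse_error(path, length(lines), "truncated CLS file")
  h <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(h) < 2 || anyNA(suppressWarnings(as.integer(h[1:2]))))
    parse_error(path, 1, "expected '<N> <classes> 1'")
  n <- as.integer(h[1]); k <- as.integer(h[2])
  if (k != 2)
    stop(sprintf("%s:1: unsupported design: %d classes declared (only 2 supported)",
                 path, k), call. = FALSE)
  cl <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (cl[1] != "#" || length(cl) != 3)
    parse_error(path, 2, "expected '# <classA> <classB>'")
  class_order <- cl[2:3]
  lab <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  if (length(lab) != n)
    parse_error(path, 3, sprintf("declared %d samples but found %d labels",
                                 n, length(lab)))
  if (all(lab %in% class_order)) {
    classes <- lab
  } else if (!anyNA(suppressWarnings(as.integer(lab)))) {
    # numeric dialect: indices map to class names by order of first occurrence
    idx <- as.integer(lab)
    first <- unique(idx)
    if (length(first) != 2)
      parse_error(path, 3, "numeric labels must take exactly 2 values")
    classes <- class_order[match(idx, first)]
  } else {
    parse_error(path, 3, "labels are neither the declared class names nor numeric")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  phenotype_assignment(sample_ids, classes, class_order)
}

#' Write a two-class CLS phenotype file
#' @param phen A [phenotype_assignment()].
#' @param path Output path.
#' @export
write_cls <- function(phen, path) {
  stopifnot(inherits(phen, "phenotype_assignment"))
  writeLines(c(sprintf("%d 2 1", length(phen$samples)),
               paste("#", phen$class_order[1], phen$class_order[2]),
               paste(phen$classes, collapse = " ")), path)
  invisible(path)
}
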