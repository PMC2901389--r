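#' regensea: enrichment analysis and conserved regulator gene sets
#'
#' Tools for a two-condition expression study of induced proliferation:
#' differential expression with fold-change and Benjamini-Hochberg filtering,
#' a classic running-sum gene set enrichment engine with
#' phenotype-permutation significance, MATCH-style promoter scanning with
#' cross-species conservation filtering to build transcription-factor motif
#' gene sets, microRNA seed-match target sets, qPCR and count-based
#' validation statistics, and seeded synthetic-data generators with planted
#' truth.
#'
#' @keywords internal
#' @importFrom stats median pt qt quantile rnorm rpois rnbinom sd var runif
#'   aggregate setNames
#' @importFrom utils combn read.delim write.table tail
#' @importFrom tools file_path_sans_ext
"_PACKAGE"

# Shared error helper: every parse error carries file and line.
parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

#' Expression matrix container
#'
#' A probe- or gene-level matrix of linear-scale expression intensities.
#' Rows are probes or gene symbols, columns are samples. Values must be
#' finite and non-negative (the linear scale produced by array
#' normalisation); gene-level matrices must have unique row identifiers,
#' probe-level matrices may carry duplicated identifiers.
#'
#' @param values Numeric matrix with row and column names.
#' @param id_level `"probe"` or `"gene"`.
#' @param description Optional character vector of per-row annotations
#'   (the GCT `Description` column); carried through but never interpreted.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `id_level` and `description`.
#' @export
expression_matrix <- function(values, id_level = c("probe", "gene"),
                              description = NULL) {
  id_level <- match.arg(id_level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have row and column names", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("sample identifiers must be unique", call. = FALSE)
  if (id_level == "gene" && anyDuplicated(rownames(values)))
    stop("gene-level row identifiers must be unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative (linear scale)",
         call. = FALSE)
  if (!is.null(description) && length(description) != nrow(values))
    stop("`description` must have one entry per row", call. = FALSE)
  structure(list(values = values, id_level = id_level,
                 description = description),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %s rows x %d samples (linear scale)\n",
              nrow(x$values), x$id_level, ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Two-class phenotype assignment
#'
#' @param samples Character vector of sample identifiers (ordered).
#' @param classes Character vector, parallel to `samples`, with exactly two
#'   distinct labels.
#' @param class_order Length-2 character vector giving the two labels in
#'   order; the first is the "positive" class (the treated condition by
#'   convention). Defaults to order of first appearance in `classes`.
#' @return An object of class `phenotype_assignment`.
#' @export
phenotype_assignment <- function(samples, classes, class_order = NULL) {
  if (length(samples) != length(classes))
    stop("`samples` and `classes` must have equal length", call. = FALSE)
  if (anyDuplicated(samples))
    stop("sample identifiers must be unique", call. = FALSE)
  lv <- unique(classes)
  if (length(lv) != 2L)
    stop(sprintf("unsupported design: need exactly 2 classes, got %d",
                 length(lv)), call. = FALSE)
  if (is.null(class_order)) class_order <- lv
  if (!setequal(class_order, lv) || length(class_order) != 2L)
    stop("`class_order` must name the two class labels", call. = FALSE)
  structure(list(samples = as.character(samples),
                 classes = as.character(classes),
                 class_order = as.character(class_order)),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  n <- table(factor(x$classes, levels = x$class_order))
  cat(sprintf("phenotype_assignment: %d samples (%s: %d positive, %s: %d negative)\n",
              length(x$samples), x$class_order[1], n[[1]],
              x$class_order[2], n[[2]]))
  invisible(x)
}

#' Samples in the positive / negative phenotype class
#' @param phen A `phenotype_assignment`.
#' @return Character vector of sample identifiers.
#' @export
positive_samples <- function(phen) phen$samples[phen$classes == phen$class_order[1]]

#' @rdname positive_samples
#' @export
negative_samples <- function(phen) phen$samples[phen$classes == phen$class_order[2]]

# Class sizes, with an optional minimum enforced for variance-based work.
check_class_sizes <- function(phen, min_per_class = 2L) {
  n <- c(length(positive_samples(phen)), length(negative_samples(phen)))
  if (any(n < min_per_class))
    stop(sprintf("each class needs >= %d samples (got %d and %d)",
                 min_per_class, n[1], n[2]), call. = FALSE)
  invisible(n)
}

#' Named gene set collection
#'
#' Gene symbols are upper-cased at construction: the upper-cased symbol is
#' the join key everywhere in this package. Set names must be unique and
#' member lists non-empty; duplicate members within a set are collapsed.
#'
#' @param sets Named list of character vectors (members).
#' @param descriptions Optional character vector parallel to `sets`
#'   (defaults to the set names).
#' @return An object of class `gene_set_collection` with elements `sets`
#'   (named list of upper-cased unique members) and `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0)
    return(structure(list(sets = setNames(list(), character()),
                          descriptions = character()),
                     class = "gene_set_collection"))
  nm <- names(sets)
  if (is.null(nm) || any(nm == ""))
    stop("all sets must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate set name: %s", nm[duplicated(nm)][1]),
         call. = FALSE)
  sets <- lapply(sets, function(m) unique(toupper(as.character(m))))
  if (any(lengths(sets) == 0))
    stop("gene sets must have at least one member", call. = FALSE)
  if (is.null(descriptions)) descriptions <- nm
  if (length(descriptions) != length(sets))
    stop("`descriptions` must be parallel to `sets`", call. = FALSE)
  structure(list(sets = sets,
                 descriptions = setNames(as.character(descriptions), nm)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
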