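#' Read / write GMT gene set collections
#'
#' GMT is the tab-separated gene set format used by the MSigDB-style set
#' packages: `name<TAB>description<TAB>member1<TAB>member2...` per line.
#' Members are upper-cased on ingestion (the package-wide join key);
#' duplicate set names, lines with fewer than three fields, and empty
#' member lists are format errors.
#'
#' @param path File path.
#' @return [read_gmt()] returns a [gene_set_collection()]; [write_gmt()]
#'   returns `path` invisibly. `read_gmt(write_gmt(x, p))` reproduces `x`
#'   exactly (names, order, members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    parse_error(path, lineno[short[1]],
                "GMT line needs name, description and >= 1 member")
  nm <- vapply(fields, `[[`, "", 1)
  dup <- which(duplicated(nm))
  if (length(dup))
    parse_error(path, lineno[dup[1]],
                sprintf("duplicate set name '%s'", nm[dup[1]]))
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    m[nzchar(m)]
  })
  empty <- which(lengths(members) == 0)
  if (length(empty))
    parse_error(path, lineno[empty[1]],
                sprintf("set '%s' has an empty member list", nm[empty[1]]))
  gene_set_collection(setNames(members, nm),
                      descriptions = vapply(fields, `[[`, "", 2))
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Case-insensitive set membership query
#' @param collection A [gene_set_collection()].
#' @param set_name Name of a set in the collection.
#' @param genes Character vector of gene symbols (any case).
#' @return Logical vector: is each gene a member?
#' @export
set_has_member <- function(collection, set_name, genes) {
  stopifnot(set_name %in% names(collection$sets))
  toupper(genes) %in% collection$sets[[set_name]]
}
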