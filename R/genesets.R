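#' Read a gene-set collection from a GMT file
#'
#' GMT (gene-matrix-transposed) format: one gene set per line,
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Set IDs must be unique
#' and every set must contain at least one gene.
#'
#' @param path Path to the GMT file.
#' @return An object of class `gene_set_collection`: a named list of
#'   character vectors (the gene sets) with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0) {
    abort(sprintf(
      "Malformed GMT line %d: need id, description and at least one gene.", short[1]
    ))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  gene_set_collection(setNames(sets, ids), descriptions = setNames(desc, ids))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene IDs.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("Gene sets must have unique names.")
  }
  if (any(lengths(sets) == 0L)) {
    abort(sprintf(
      "Empty gene set(s): %s",
      paste(head(names(sets)[lengths(sets) == 0L], 5), collapse = ", ")
    ))
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "Gene set collection: %d sets, sizes %d-%d\n",
    length(x), min(lengths(x)), max(lengths(x))
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.gene_set_collection <- function(x, ...) {
  tibble(
    set_id = names(x),
    description = unname(attr(x, "descriptions")[names(x)]),
    size = unname(lengths(x)),
    genes = unname(unclass(x))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param col A `gene_set_collection` (or named list of gene vectors).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(col, path) {
  desc <- attr(col, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(col)), names(col))
  lines <- vapply(names(col), function(id) {
    paste(c(id, desc[[id]], col[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
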