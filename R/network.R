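#' Read an interaction network from an edge-list or SIF file
#'
#' Accepts a two-column tab-separated edge list (`src<TAB>dst`) or a
#' three-column SIF file (`src<TAB>type<TAB>dst`; the middle interaction-type
#' column is ignored). Lines are simplified on load: duplicate edges (in
#' either orientation) and self-loops are dropped with a message reporting the
#' counts, so BioGRID-style multi-edges collapse to one.
#'
#' @param path Path to the file.
#' @param comment Lines starting with this prefix are skipped (default `"#"`).
#' @return A tibble with columns `from` and `to`, one row per unique
#'   undirected edge.
#' @export
read_edges <- function(path, comment = "#") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed line %d in %s: expected 2 (edge list) or 3 (SIF) tab-separated fields, found %d.",
      idx[bad[1]], path, nf[bad[1]]
    ))
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, function(p) p[[length(p)]], character(1))
  simplify_edges(tibble(from = from, to = to))
}

#' @rdname read_edges
#' @param edges A data frame with columns `from` and `to`.
#' @export
simplify_edges <- function(edges) {
  edges <- as_tibble(edges)[, c("from", "to")]
  n0 <- nrow(edges)
  loops <- edges$from == edges$to
  if (any(loops)) {
    inform(sprintf("Dropped %d self-loop(s).", sum(loops)))
    edges <- edges[!loops, ]
  }
  key <- ifelse(edges$from <= edges$to,
    paste(edges$from, edges$to, sep = "\r"),
    paste(edges$to, edges$from, sep = "\r")
  )
  dup <- duplicated(key)
  if (any(dup)) {
    inform(sprintf("Collapsed %d duplicate edge(s).", sum(dup)))
    edges <- edges[!dup, ]
  }
  attr(edges, "n_dropped") <- n0 - nrow(edges)
  edges
}

#' Read a gene-level p-value table
#'
#' Expects a tab-separated file with a header line `gene_id<TAB>pvalue`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id` (character) and `pvalue` (numeric).
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = c("character", "numeric"))
  names(df)[1:2] <- c("gene_id", "pvalue")
  if (anyDuplicated(df$gene_id)) abort("Duplicate gene IDs in p-value table.")
  as_tibble(df[, c("gene_id", "pvalue")])
}

#' Restrict an interactome to differentially expressed genes
#'
#' Implements the network-construction filter: keep exactly the interactions
#' with at least one endpoint in the differentially expressed set (genes whose
#' adjusted p-value is at most `p_cutoff`), then take the graph on the nodes
#' incident to the kept edges. This retains indirect interactions through one
#' non-differentially-expressed partner.
#'
#' @param edges Data frame of interactions with columns `from`, `to` (or a
#'   file path readable by [read_edges()]).
#' @param de_table Data frame with `gene_id` and `pvalue` columns holding
#'   adjusted p-values.
#' @param p_cutoff Adjusted p-value cutoff defining differential expression
#'   (default 0.05).
#' @return A tibble of the kept edges (columns `from`, `to`).
#' @export
build_network <- function(edges, de_table, p_cutoff = 0.05) {
  if (is.character(edges) && length(edges) == 1L) edges <- read_edges(edges)
  edges <- simplify_edges(edges)
  de_genes <- de_table$gene_id[de_table$pvalue <= p_cutoff]
  keep <- edges$from %in% de_genes | edges$to %in% de_genes
  if (!any(keep)) {
    abort(sprintf(
      "No interaction has a differentially expressed endpoint at p <= %g; consider relaxing the cutoff.",
      p_cutoff
    ))
  }
  edges[keep, ]
}

#' Construct a scored network
#'
#' Combines an edge table with per-gene p-values and an FDR scoring scheme
#' into the search-ready network object. The node ordering of the membership
#' vectors used throughout the search is fixed here: lexicographic by gene ID
#' (C locale), stable and recorded in the object.
#'
#' Genes present in the edge table but absent from `pvalues` receive p = 1
#' (score at its minimum for the scheme) with a message.
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param pvalues Data frame with columns `gene_id`, `pvalue`; optional if
#'   `scores` supplied.
#' @param scheme A `scoring_scheme` from [scoring_scheme()]; optional if
#'   `scores` supplied.
#' @param scores Optional data frame with columns `gene_id`, `score`,
#'   bypassing the scheme (p-values then optional).
#' @param p_min Clamp for zero p-values.
#' @return An object of class `scored_network`: list with `graph` (igraph,
#'   vertices in the fixed order), `nodes` (tibble `gene_id`, `pvalue`,
#'   `score`), and `node_order` (character vector).
#' @export
scored_network <- function(edges, pvalues = NULL, scheme = NULL, scores = NULL,
                           p_min = 1e-300) {
  edges <- simplify_edges(edges)
  ids <- sort(unique(c(edges$from, edges$to)), method = "radix")
  nodes <- tibble(gene_id = ids)
  if (!is.null(pvalues)) {
    nodes <- dplyr::left_join(nodes, as_tibble(pvalues)[, c("gene_id", "pvalue")],
      by = "gene_id"
    )
    if (anyNA(nodes$pvalue)) {
      inform(sprintf(
        "%d network gene(s) missing from the p-value table; assigned p = 1.",
        sum(is.na(nodes$pvalue))
      ))
      nodes$pvalue[is.na(nodes$pvalue)] <- 1
    }
  } else {
    nodes$pvalue <- NA_real_
  }
  if (!is.null(scores)) {
    nodes <- dplyr::left_join(nodes, as_tibble(scores)[, c("gene_id", "score")],
      by = "gene_id"
    )
    if (anyNA(nodes$score)) abort("`scores` must cover every network gene.")
  } else if (!is.null(scheme)) {
    nodes$score <- node_score(clamp_pvalues(nodes$pvalue, p_min), scheme)
  } else {
    abort("Provide either a `scheme` (with p-values) or explicit `scores`.")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes$gene_id)
  structure(
    list(graph = g, nodes = nodes, node_order = ids, scheme = scheme),
    class = "scored_network"
  )
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf(
    "Scored network: %d nodes, %d edges (%d with positive score)\n",
    length(x$node_order), igraph::ecount(x$graph), sum(x$nodes$score > 0)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.scored_network <- function(x, ...) x$nodes

#' Edge table of a scored network
#'
#' @param net A `scored_network`.
#' @return Tibble with columns `from`, `to`.
#' @export
network_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph, names = TRUE)
  tibble(from = e[, 1], to = e[, 2])
}

# Coerce a module given as gene IDs or a logical/0-1 vector over the fixed
# node order into a logical membership vector.
as_membership <- function(net, members) {
  n <- length(net$node_order)
  if (is.logical(members)) {
    stopifnot(length(members) == n)
    return(members)
  }
  if (is.numeric(members) && length(members) == n && all(members %in% c(0, 1))) {
    return(members == 1)
  }
  if (is.character(members)) {
    unknown <- setdiff(members, net$node_order)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown gene ID(s): %s", paste(head(unknown, 5), collapse = ", ")))
    }
    return(net$node_order %in% members)
  }
  abort("`members` must be gene IDs or a membership vector over the node order.")
}

#' Laplacian matrix of an induced module
#'
#' L = D - A of the subgraph induced by the selected nodes, where D is the
#' degree matrix and A the adjacency matrix. Symmetric with zero row sums.
#'
#' @param net A `scored_network`.
#' @param members Gene IDs or a logical membership vector over
#'   `net$node_order`.
#' @return A dense symmetric numeric matrix with dimnames.
#' @export
module_laplacian <- function(net, members) {
  sel <- as_membership(net, members)
  if (!any(sel)) abort("Empty module has no Laplacian.")
  sub <- igraph::induced_subgraph(net$graph, which(sel))
  A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
  diag(rowSums(A), nrow = nrow(A)) - A
}

#' Algebraic connectivity (Fiedler value) of an induced module
#'
#' The second-smallest eigenvalue of the module's Laplacian, computed with a
#' dense symmetric eigensolver. It is strictly positive if and only if the
#' induced subgraph is connected.
#'
#' @inheritParams module_laplacian
#' @return A single number (>= 0 up to numerical noise).
#' @export
algebraic_connectivity <- function(net, members) {
  sel <- as_membership(net, members)
  k <- sum(sel)
  if (k < 2) abort("Algebraic connectivity requires a module of size >= 2.")
  L <- module_laplacian(net, sel)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev) - 1L]
}

#' Is a module connected?
#'
#' Feasibility test used by the search: a module of size 0 is not connected
#' (infeasible), size 1 is connected by convention, and larger modules are
#' connected when their algebraic connectivity exceeds a small tolerance
#' absorbing floating-point noise.
#'
#' @inheritParams module_laplacian
#' @param eps Positivity tolerance on the Fiedler value (default `1e-8`).
#' @return `TRUE` or `FALSE`.
#' @export
is_connected_module <- function(net, members, eps = 1e-8) {
  sel <- as_membership(net, members)
  k <- sum(sel)
  if (k == 0L) return(FALSE)
  if (k == 1L) return(TRUE)
  algebraic_connectivity(net, sel) > eps
}

#' Write network files
#'
#' `write_edges()` writes a two-column tab-separated edge list;
#' `write_gene_list()` writes one gene ID per line (the plain format accepted
#' by gene-ontology web tools).
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges[, c("from", "to")]), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_edges
#' @param genes Character vector of gene IDs.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname read_pvalues
#' @param pvalues Data frame with `gene_id`, `pvalue`.
#' @export
write_pvalues <- function(pvalues, path) {
  utils::write.table(as.data.frame(pvalues[, c("gene_id", "pvalue")]), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
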