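#' Specification of a synthetic benchmark dataset
#'
#' Describes a network with a planted active module, matching the
#' distributional assumptions of the node-scoring model: background p-values
#' are Uniform(0, 1) (the null), planted-module p-values are Beta(a, 1) with
#' small shape `signal_a` (the signal). Gene sets are generated so that a few
#' "on-target" pathways draw most of their members from the planted module
#' and the rest are uniform decoys.
#'
#' The default specification is the package's benchmark: a 300-node
#' preferential-attachment graph (2 links per new node), a connected planted
#' module of 25 nodes with `signal_a = 0.1`, and 20 pathways of 10 to 30
#' genes of which 5 draw at least 80 percent of their members from the
#' planted module.
#'
#' @param n_nodes Number of network nodes.
#' @param edge_model `"preferential_attachment"` or `"uniform"`.
#' @param pa_m Links added per node (preferential attachment).
#' @param edge_prob Edge probability (uniform model).
#' @param planted_module_size Size of the planted connected module
#'   (< `n_nodes`).
#' @param signal_a Beta shape of signal p-values, in (0, 1).
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Integer pair: smallest and largest set size.
#' @param n_planted_pathways How many sets are on-target.
#' @param planted_pathway_overlap Minimum fraction of an on-target set drawn
#'   from the planted module, in \[0, 1\].
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(n_nodes = 300L,
                           edge_model = c("preferential_attachment", "uniform"),
                           pa_m = 2L,
                           edge_prob = 0.02,
                           planted_module_size = 25L,
                           signal_a = 0.1,
                           n_pathways = 20L,
                           pathway_size_range = c(10L, 30L),
                           n_planted_pathways = 5L,
                           planted_pathway_overlap = 0.8,
                           seed = 1L) {
  edge_model <- match.arg(edge_model)
  if (planted_module_size >= n_nodes) {
    abort("`planted_module_size` must be smaller than `n_nodes`.")
  }
  check_unit_open(signal_a, "signal_a")
  structure(
    list(
      n_nodes = as.integer(n_nodes), edge_model = edge_model,
      pa_m = as.integer(pa_m), edge_prob = edge_prob,
      planted_module_size = as.integer(planted_module_size),
      signal_a = signal_a, n_pathways = as.integer(n_pathways),
      pathway_size_range = as.integer(pathway_size_range),
      n_planted_pathways = as.integer(n_planted_pathways),
      planted_pathway_overlap = planted_pathway_overlap,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic benchmark dataset
#'
#' Builds the network, plants a connected module (grown by seeded
#' breadth-first expansion from a random start node), assigns p-values
#' (signal nodes by the inverse transform `u^(1/a)`, i.e. Beta(a, 1);
#' background Uniform(0, 1)), and generates the gene-set collection.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `edges` (tibble `from`, `to`), `pvalues` (tibble
#'   `gene_id`, `pvalue`), `genesets` (a `gene_set_collection`), `truth`
#'   (character vector: the planted module), and `spec`.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  n <- spec$n_nodes
  ids <- sprintf("g%04d", seq_len(n))
  g <- switch(spec$edge_model,
    preferential_attachment = igraph::sample_pa(n, m = spec$pa_m, directed = FALSE),
    uniform = igraph::sample_gnp(n, spec$edge_prob)
  )
  # make sure the uniform model yields one usable component
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  if (comp$csize[big] <= spec$planted_module_size) {
    abort("Largest component is smaller than the requested planted module.")
  }

  # planted module: breadth-first expansion from a random node of the
  # largest component until the requested size is reached
  start <- sample(which(comp$membership == big), 1L)
  bfs_order <- as.integer(igraph::bfs(g, root = start, unreachable = FALSE)$order)
  planted <- bfs_order[seq_len(spec$planted_module_size)]

  pv <- runif(n)
  pv[planted] <- runif(spec$planted_module_size)^(1 / spec$signal_a)

  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
    spec$n_pathways,
    replace = TRUE
  )
  planted_ids <- ids[planted]
  sets <- vector("list", spec$n_pathways)
  for (i in seq_len(spec$n_pathways)) {
    if (i <= spec$n_planted_pathways) {
      k_in <- min(
        ceiling(spec$planted_pathway_overlap * sizes[i]),
        length(planted_ids), sizes[i]
      )
      inside <- sample(planted_ids, k_in)
      outside <- sample(setdiff(ids, planted_ids), sizes[i] - k_in)
      sets[[i]] <- c(inside, outside)
    } else {
      sets[[i]] <- sample(ids, sizes[i])
    }
  }
  names(sets) <- sprintf("path%02d", seq_len(spec$n_pathways))
  desc <- setNames(
    c(
      rep("on-target", spec$n_planted_pathways),
      rep("decoy", spec$n_pathways - spec$n_planted_pathways)
    ),
    names(sets)
  )

  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- simplify_edges(tibble(from = ids[el[, 1]], to = ids[el[, 2]]))
  list(
    edges = edges,
    pvalues = tibble(gene_id = ids, pvalue = pv),
    genesets = gene_set_collection(sets, descriptions = desc),
    truth = ids[sort(planted)],
    spec = spec
  )
}

#' Write a generated benchmark to disk
#'
#' Writes `edges.tsv`, `pvalues.tsv`, `pathways.gmt` and `truth.txt` into
#' `dir`, in the same plain-text formats the search consumes.
#'
#' @param bench Result of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edges(bench$edges, file.path(dir, "edges.tsv"))
  write_pvalues(bench$pvalues, file.path(dir, "pvalues.tsv"))
  write_gmt(bench$genesets, file.path(dir, "pathways.gmt"))
  write_gene_list(bench$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Overlap of recovered modules with a known ground truth
#'
#' Per front member, the Jaccard index, precision and recall of the module's
#' gene set against the planted (true) module.
#'
#' @param result A `pareto_result` from [evolve()].
#' @param truth Character vector of true module gene IDs.
#' @return A tibble with columns `module`, `size`, `s_a`, `r_a`, `jaccard`,
#'   `precision`, `recall`; the attribute `"best"` holds the row with the
#'   highest Jaccard.
#' @export
score_recovery <- function(result, truth) {
  stopifnot(inherits(result, "pareto_result"), nrow(result$front) > 0)
  metrics <- purrr::map_dfr(result$front$genes, function(g) {
    inter <- length(intersect(g, truth))
    tibble(
      jaccard = inter / length(union(g, truth)),
      precision = if (length(g) > 0) inter / length(g) else 0,
      recall = inter / length(truth)
    )
  })
  out <- dplyr::bind_cols(
    dplyr::select(result$front, "module", "size", "s_a", "r_a"),
    metrics
  )
  attr(out, "best") <- out[which.max(out$jaccard), ]
  out
}
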