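#' Write a search result to a run directory
#'
#' Writes `front.tsv` (module, size, s_a, r_a, label), one `module_<id>.txt`
#' gene list per front member, and `run.json`: the configuration echo, input
#' checksums, package version, seed and the per-generation objective summary —
#' enough to re-run the search bit-identically. Refuses to overwrite an
#' existing run directory.
#'
#' @param result A `pareto_result`.
#' @param dir Output directory (must not already contain a run).
#' @param inputs Optional named character vector of input file paths; their
#'   MD5 checksums are recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, inputs = NULL) {
  stopifnot(inherits(result, "pareto_result"))
  if (file.exists(file.path(dir, "run.json"))) {
    abort(sprintf("Run directory %s already holds a result; refusing to overwrite.", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  front <- dplyr::select(result$front, -"genes")
  utils::write.table(as.data.frame(front), file.path(dir, "front.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (i in seq_len(nrow(result$front))) {
    write_gene_list(
      result$front$genes[[i]],
      file.path(dir, sprintf("module_%d.txt", result$front$module[i]))
    )
  }
  manifest <- list(
    package = "pamod",
    version = as.character(packageVersion("pamod")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(result$config),
    seed = result$config$seed,
    n_nodes = length(result$node_order),
    inputs = if (!is.null(inputs)) {
      as.list(setNames(unname(tools::md5sum(inputs)), names(inputs)))
    },
    history = result$history
  )
  jsonlite::write_json(manifest, file.path(dir, "run.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Report a stored run, re-scoring modules from their gene lists
#'
#' Reads the gene lists of a run directory, recomputes both objectives from
#' scratch against the supplied network and gene sets, and returns the front
#' table annotated with the extreme and knee labels. A mismatch between the
#' stored and recomputed objectives raises an error, so stale or edited runs
#' are caught.
#'
#' @param dir Run directory written by [write_result()].
#' @param net A `scored_network` (same scoring scheme as the run).
#' @param col A `gene_set_collection`.
#' @param r_ratio Cover-rate threshold used by the run.
#' @param restrict Pathway-denominator convention used by the run.
#' @param tol Absolute tolerance for the activity-score consistency check.
#' @return Tibble: `module`, `size`, `s_a`, `r_a`, `label`, `genes`.
#' @export
report_run <- function(dir, net, col, r_ratio, restrict = FALSE, tol = 1e-8) {
  front_path <- file.path(dir, "front.tsv")
  if (!file.exists(front_path)) abort(sprintf("No front.tsv in %s.", dir))
  stored <- as_tibble(utils::read.delim(front_path, sep = "\t"))
  genes <- lapply(stored$module, function(i) {
    readLines(file.path(dir, sprintf("module_%d.txt", i)))
  })
  recomputed <- purrr::map_dfr(genes, function(g) {
    ev <- evaluate_module(net, col, g, r_ratio, restrict = restrict)
    tibble(s_a = ev$s_a, r_a = ev$r_a)
  })
  if (any(abs(recomputed$s_a - stored$s_a) > tol) ||
    any(recomputed$r_a != stored$r_a)) {
    abort("Stored objectives do not match re-scored gene lists; wrong network, gene sets or parameters?")
  }
  out <- dplyr::mutate(
    dplyr::select(stored, "module", "size"),
    s_a = recomputed$s_a, r_a = recomputed$r_a
  )
  out$label <- label_front(out)
  out$genes <- genes
  out
}

#' Export a BUM fit report as JSON
#'
#' @param fit A `bum_fit`.
#' @param alpha FDR level for the derived threshold.
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_fit_report <- function(fit, alpha, path) {
  report <- list(
    a = fit$a,
    lambda = fit$lambda,
    pi_hat = bum_pi_hat(fit),
    tau = bum_tau(fit, alpha),
    loglik = fit$log_likelihood,
    n = fit$n,
    alpha = alpha
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
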