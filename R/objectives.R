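#' Activity score of a module
#'
#' The sum of the FDR node scores of the module's genes,
#' \eqn{S_A = \sum_{x \in A} S^{FDR}(x)}. Additive over disjoint selections;
#' an empty module scores 0.
#'
#' @param net A `scored_network`.
#' @param members Gene IDs or a logical membership vector over the node order.
#' @return A single number.
#' @export
module_score <- function(net, members) {
  sel <- as_membership(net, members)
  sum(net$nodes$score[sel])
}

#' Cover rate of one pathway by a module
#'
#' \eqn{R_i = |V_i \cap V_A| / |V_i|}: the fraction of the pathway's genes
#' inside the module. The denominator is the pathway as annotated, which may
#' include genes absent from the network (see [pathway_coverage_count()] for
#' the restricted alternative).
#'
#' @param pathway Character vector of the pathway's gene IDs (non-empty).
#' @param module_genes Character vector of the module's gene IDs.
#' @return A number in \[0, 1\].
#' @export
pathway_cover_rate <- function(pathway, module_genes) {
  stopifnot(length(pathway) > 0)
  length(intersect(pathway, module_genes)) / length(pathway)
}

#' Pathway coverage count of a module
#'
#' The number of pathways whose cover rate strictly exceeds `r_ratio`:
#' \eqn{R_A = |\{i : R_i > R_{ratio}\}|}. A pathway covered at exactly
#' `r_ratio` does not count.
#'
#' @param col A `gene_set_collection`.
#' @param net A `scored_network` (used to resolve `members` and, when
#'   `restrict = TRUE`, to restrict pathway denominators to network genes).
#' @param members Gene IDs or a logical membership vector.
#' @param r_ratio Cover-rate threshold in (0, 1).
#' @param restrict If `TRUE`, each pathway is first intersected with the
#'   network's genes, so the denominator counts only genes that the search
#'   can actually reach. Default `FALSE`: the full annotated pathway is the
#'   denominator.
#' @return A non-negative integer, at most `length(col)`.
#' @export
pathway_coverage_count <- function(col, net, members, r_ratio, restrict = FALSE) {
  if (r_ratio <= 0 || r_ratio >= 1) abort("`r_ratio` must be in (0, 1).")
  sel <- as_membership(net, members)
  module_genes <- net$node_order[sel]
  sets <- unclass(col)
  if (restrict) {
    sets <- lapply(sets, intersect, net$node_order)
    sets <- sets[lengths(sets) > 0L]
  }
  rates <- vapply(sets, pathway_cover_rate, numeric(1), module_genes = module_genes)
  sum(rates > r_ratio)
}

#' Evaluate both objectives for a module
#'
#' Computes the activity score and the pathway coverage count for one module.
#' Internally the search minimises, so the stored objective vector is the
#' negated pair \eqn{(-S_A, -R_A)}; user-facing values keep the maximisation
#' sign.
#'
#' @inheritParams pathway_coverage_count
#' @return A list with `s_a`, `r_a` (maximisation scale) and `minimized`
#'   (the internal negated vector).
#' @export
evaluate_module <- function(net, col, members, r_ratio, restrict = FALSE) {
  s_a <- module_score(net, members)
  r_a <- pathway_coverage_count(col, net, members, r_ratio, restrict = restrict)
  list(s_a = s_a, r_a = r_a, minimized = c(-s_a, -r_a))
}
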