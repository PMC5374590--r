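# Fixtures are built in code; no files ship with the tests.

# A scored network from an explicit edge list and per-node scores.
toy_net <- function(edges, scores) {
  suppressMessages(scored_network(
    tibble::tibble(from = edges[, 1], to = edges[, 2]),
    scores = tibble::tibble(gene_id = names(scores), score = unname(scores))
  ))
}

# Path a-b-c-d-e with unit scores.
path5_net <- function(scores = setNames(rep(1, 5), letters[1:5])) {
  toy_net(cbind(letters[1:4], letters[2:5]), scores)
}

# Erdos-Renyi style random scored network; isolated vertices are dropped at
# construction, so the realised node count is length(net$node_order).
random_net <- function(n, p = 0.2, scores = NULL) {
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) el <- cbind(1, 2) # keep at least one edge
  ids <- sprintf("n%02d", seq_len(n))
  if (is.null(scores)) scores <- stats::rnorm(n)
  suppressMessages(scored_network(
    tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]]),
    scores = tibble::tibble(gene_id = ids, score = scores[seq_len(n)])
  ))
}

# Independent O(N^2) Pareto-ranking oracle: repeatedly peel the set of
# points not dominated by any remaining point (minimisation).
pareto_rank_oracle <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 1L
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, logical(1)))
    }, logical(1))]
    rank[nd] <- r
    remaining <- setdiff(remaining, nd)
    r <- r + 1L
  }
  rank
}

# Brute-force BUM log-likelihood maximum over a parameter grid.
bum_grid_oracle <- function(pvals, k = 99) {
  lx <- log(pvals)
  as_ <- seq(0.01, 0.99, length.out = k)
  ls_ <- seq(0.01, 0.99, length.out = k)
  best <- -Inf
  for (a in as_) {
    xa <- a * exp((a - 1) * lx)
    for (l in ls_) {
      ll <- sum(log(l + (1 - l) * xa))
      if (ll > best) best <- ll
    }
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
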