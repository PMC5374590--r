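#' Search configuration
#'
#' Bundles all tunable parameters of the evolutionary search. Defaults:
#' population 50, 200 generations, cover-rate threshold `r_ratio = 0.6`,
#' FDR level 0.01 for the node-scoring threshold, single-node mutation,
#' crossover rate 0.9, and tournament selection skipped once more than half
#' the population are duplicates (reducing selection pressure when the
#' population has converged).
#'
#' @param population_size Number of individuals kept per generation (>= 2).
#' @param generations Number of generational cycles (the stopping criterion).
#' @param r_ratio Pathway cover-rate threshold in (0, 1).
#' @param fdr_alpha FDR level used to derive the scoring threshold tau.
#' @param seed Integer seed; the whole search is reproducible from it.
#' @param tournament_skip_dup_fraction Duplicate fraction above which binary
#'   tournament is skipped and the whole population reproduces.
#' @param crossover_rate Probability a parent pair is recombined.
#' @param mutation_additions Nodes added per mutation event.
#' @param restrict_pathways If `TRUE`, pathway denominators are restricted to
#'   network genes when computing coverage.
#' @return An object of class `search_config` (a named list).
#' @export
search_config <- function(population_size = 50L,
                          generations = 200L,
                          r_ratio = 0.6,
                          fdr_alpha = 0.01,
                          seed = 42L,
                          tournament_skip_dup_fraction = 0.5,
                          crossover_rate = 0.9,
                          mutation_additions = 1L,
                          restrict_pathways = FALSE) {
  if (population_size < 2) abort("`population_size` must be at least 2.")
  for (r in c(r_ratio, tournament_skip_dup_fraction, crossover_rate)) {
    if (r < 0 || r > 1) abort("Rates must lie in [0, 1].")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      r_ratio = r_ratio,
      fdr_alpha = fdr_alpha,
      seed = as.integer(seed),
      tournament_skip_dup_fraction = tournament_skip_dup_fraction,
      crossover_rate = crossover_rate,
      mutation_additions = as.integer(mutation_additions),
      restrict_pathways = restrict_pathways
    ),
    class = "search_config"
  )
}

#' Seeded initial population
#'
#' Seeds are the nodes with the top `population_size` node scores (ties broken
#' by gene ID); when the population size exceeds the network size every node
#' becomes a seed. Each initial individual is its seed together with the
#' seed's one-hop neighbours that have positive score, hence connected by
#' construction.
#'
#' @param net A `scored_network`.
#' @param population_size Number of seeds requested.
#' @return A list of logical membership vectors over `net$node_order`.
#' @export
initialize_population <- function(net, population_size) {
  s <- net$nodes$score
  if (!any(s > 0)) {
    abort("No node has a positive score; increase the FDR level alpha.")
  }
  n <- length(s)
  ord <- order(-s, net$node_order, method = "radix")
  seeds <- ord[seq_len(min(population_size, n))]
  adj <- adjacency_list(net)
  lapply(seeds, function(v) {
    sel <- logical(n)
    sel[v] <- TRUE
    nb <- adj[[v]]
    sel[nb[s[nb] > 0]] <- TRUE
    sel
  })
}

#' Constrained fast non-dominated sort
#'
#' Ranks a population under constrained dominance: every feasible solution
#' dominates every infeasible one; among solutions of equal feasibility,
#' standard Pareto dominance on the (minimised) objective vectors applies.
#' Front 1 is the non-dominated set, front 2 the non-dominated set of the
#' remainder, and so on.
#'
#' @param objectives Numeric matrix, one row per individual, minimisation
#'   orientation.
#' @param feasible Logical vector, one entry per individual (default: all).
#' @return Integer vector of ranks (1 = best front).
#' @export
fast_nondominated_sort <- function(objectives, feasible = rep(TRUE, nrow(objectives))) {
  n <- nrow(objectives)
  if (n == 0L) return(integer(0))
  dominates <- function(i, j) {
    if (feasible[i] != feasible[j]) return(feasible[i])
    all(objectives[i, ] <= objectives[j, ]) && any(objectives[i, ] < objectives[j, ])
  }
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(j, i)) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  rank <- integer(n)
  current <- which(dom_count == 0L)
  r <- 1L
  while (length(current) > 0L) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
    r <- r + 1L
  }
  rank
}

#' Crowding distance within one front
#'
#' The standard NSGA-II diversity measure: per objective, boundary individuals
#' receive infinity and interior individuals accumulate the normalised gap
#' between their neighbours; objectives with zero range contribute nothing.
#' Fronts of size <= 2 are all-infinite.
#'
#' @param objectives Numeric matrix, one row per member of a single front.
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n == 0L) return(numeric(0))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    v <- objectives[, m]
    ord <- order(v)
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    r <- v[ord[n]] - v[ord[1L]]
    if (n > 2L && r > 0) {
      inner <- ord[2:(n - 1L)]
      d[inner] <- d[inner] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / r
    }
  }
  d
}

#' Binary tournament selection under constrained-crowded comparison
#'
#' Each of `n` tournaments draws two individuals uniformly; the winner is
#' decided by feasibility first (feasible beats infeasible), then lower rank,
#' then larger crowding distance, with remaining ties broken by a coin flip.
#'
#' @param rank Integer ranks from [fast_nondominated_sort()].
#' @param crowding Crowding distances aligned with `rank`.
#' @param feasible Logical feasibility flags.
#' @param n Number of winners to draw (default `length(rank)`).
#' @return Integer vector of winning indices.
#' @export
binary_tournament <- function(rank, crowding, feasible, n = length(rank)) {
  pool_n <- length(rank)
  winners <- integer(n)
  for (k in seq_len(n)) {
    ij <- sample.int(pool_n, 2L, replace = TRUE)
    winners[k] <- crowded_better(ij[1L], ij[2L], rank, crowding, feasible)
  }
  winners
}

crowded_better <- function(i, j, rank, crowding, feasible) {
  if (feasible[i] != feasible[j]) return(if (feasible[i]) i else j)
  if (rank[i] != rank[j]) return(if (rank[i] < rank[j]) i else j)
  if (crowding[i] != crowding[j]) return(if (crowding[i] > crowding[j]) i else j)
  if (runif(1) < 0.5) i else j
}

#' Single-point crossover of two membership vectors
#'
#' A cut position is drawn uniformly from 1 .. |V|-1 and the prefixes are
#' swapped. Offspring may be disconnected; feasibility is decided later by
#' the connectivity constraint, not repaired here.
#'
#' @param p1,p2 Logical membership vectors of equal length.
#' @return A list of two offspring vectors.
#' @export
single_point_crossover <- function(p1, p2) {
  n <- length(p1)
  stopifnot(length(p2) == n, n >= 2L)
  cut <- sample.int(n - 1L, 1L)
  c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):n])
  c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):n])
  list(c1, c2)
}

#' Growth mutation
#'
#' Adds up to `additions` nodes drawn uniformly without replacement from the
#' module's eligible neighbours: nodes adjacent to the module that either
#' have a positive node score or belong to at least one pathway of the
#' collection. Adding only neighbours preserves connectedness; if no
#' neighbour is eligible the module is returned unchanged. There is no
#' deletion operator — modules shrink only through crossover.
#'
#' @param net A `scored_network`.
#' @param col A `gene_set_collection`.
#' @param members Gene IDs or a logical membership vector (non-empty).
#' @param additions Number of nodes to add (default 1).
#' @return A logical membership vector.
#' @export
mutate_module <- function(net, col, members, additions = 1L) {
  sel <- as_membership(net, members)
  if (!any(sel)) abort("Cannot mutate an empty module.")
  eligible <- mutation_eligible(net, col)
  mutate_sel(sel, adjacency_list(net), eligible, additions)
}

mutation_eligible <- function(net, col) {
  in_pathway <- net$node_order %in% unique(unlist(unclass(col), use.names = FALSE))
  net$nodes$score > 0 | in_pathway
}

mutate_sel <- function(sel, adj, eligible, additions) {
  for (k in seq_len(additions)) {
    nb <- unique(unlist(adj[sel], use.names = FALSE))
    nb <- nb[!sel[nb]]
    nb <- nb[eligible[nb]]
    if (length(nb) == 0L) break
    sel[nb[sample.int(length(nb), 1L)]] <- TRUE
  }
  sel
}

#' Clearing: demote duplicated solutions
#'
#' Detects groups of bit-identical selections in a (combined) population,
#' keeps the first member of each group and marks the remaining copies
#' infeasible so that sorting and replacement eliminate them. Distinct
#' individuals are untouched.
#'
#' @param selections List of logical membership vectors.
#' @param feasible Logical feasibility flags (defaults to all feasible).
#' @return Updated logical feasibility vector.
#' @export
clearing <- function(selections, feasible = rep(TRUE, length(selections))) {
  keys <- vapply(selections, selection_key, character(1))
  feasible & !duplicated(keys)
}

selection_key <- function(sel) paste(which(sel), collapse = ",")

# Integer adjacency list in node order (cached on the network object's env).
adjacency_list <- function(net) {
  lapply(igraph::as_adj_list(net$graph, mode = "all"), as.integer)
}

#' Run the multi-objective active-module search
#'
#' The generational loop of the modified NSGA-II: binary tournament (skipped
#' when the population is dominated by duplicates), single-point crossover,
#' growth mutation, merging parents and offspring, clearing of duplicates,
#' constrained non-dominated sorting with crowding distance, and truncation
#' back to the population size. Feasibility of every individual is decided by
#' the algebraic-connectivity constraint (plus non-emptiness and
#' non-duplication). After the final generation the feasible rank-1 front is
#' returned, deduplicated.
#'
#' @param net A `scored_network` (scores assigned to all nodes).
#' @param col A `gene_set_collection` (the prior knowledge).
#' @param config A `search_config`.
#' @return An object of class `pareto_result` with elements `front` (tibble:
#'   `module`, `size`, `s_a`, `r_a`, `genes` list-column, labels for the
#'   extreme and knee solutions), `selections` (list of membership vectors),
#'   `history` (per-generation tibble), `config`, and `node_order`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
evolve <- function(net, col, config = search_config()) {
  stopifnot(inherits(net, "scored_network"), inherits(config, "search_config"))
  withr::with_seed(config$seed, evolve_impl(net, col, config))
}

evolve_impl <- function(net, col, cfg) {
  n <- length(net$node_order)
  scores <- net$nodes$score
  adj <- adjacency_list(net)
  eligible <- mutation_eligible(net, col)
  A_full <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = TRUE))

  sets <- unclass(col)
  if (cfg$restrict_pathways) {
    sets <- lapply(sets, intersect, net$node_order)
    sets <- sets[lengths(sets) > 0L]
  }
  set_idx <- lapply(sets, function(g) which(net$node_order %in% g))
  set_size <- lengths(sets)

  eval_one <- function(sel) {
    k <- sum(sel)
    if (k == 0L) {
      return(list(obj = c(0, 0), connected = FALSE))
    }
    s_a <- sum(scores[sel])
    r_a <- sum(vapply(set_idx, function(ix) sum(sel[ix]), numeric(1)) / set_size > cfg$r_ratio)
    connected <- if (k == 1L) {
      TRUE
    } else {
      v <- which(sel)
      Asub <- A_full[v, v]
      L <- diag(rowSums(Asub), nrow = k) - Asub
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      ev[k - 1L] > 1e-8
    }
    list(obj = c(-s_a, -r_a), connected = connected)
  }

  make_pop <- function(sels) {
    lapply(sels, function(sel) c(list(sel = sel), eval_one(sel)))
  }

  pop <- make_pop(initialize_population(net, cfg$population_size))
  N <- length(pop)

  sort_assign <- function(pop) {
    objs <- do.call(rbind, lapply(pop, `[[`, "obj"))
    connected <- vapply(pop, `[[`, logical(1), "connected")
    feas <- clearing(lapply(pop, `[[`, "sel"), connected)
    rank <- fast_nondominated_sort(objs, feas)
    crowd <- numeric(length(pop))
    for (r in unique(rank)) {
      in_front <- which(rank == r)
      crowd[in_front] <- crowding_distance(objs[in_front, , drop = FALSE])
    }
    for (i in seq_along(pop)) {
      pop[[i]]$feasible <- feas[i]
      pop[[i]]$rank <- rank[i]
      pop[[i]]$crowding <- crowd[i]
    }
    pop
  }

  pop <- sort_assign(pop)
  history <- vector("list", cfg$generations)

  for (gen in seq_len(cfg$generations)) {
    sels <- lapply(pop, `[[`, "sel")
    dup_frac <- 1 - length(unique(vapply(sels, selection_key, character(1)))) / N

    if (dup_frac > cfg$tournament_skip_dup_fraction) {
      parents <- seq_len(N)
    } else {
      parents <- binary_tournament(
        vapply(pop, `[[`, integer(1), "rank"),
        vapply(pop, `[[`, numeric(1), "crowding"),
        vapply(pop, `[[`, logical(1), "feasible"),
        n = N
      )
    }

    offspring_sels <- vector("list", N)
    i <- 1L
    while (i <= N) {
      p1 <- pop[[parents[i]]]$sel
      p2 <- pop[[parents[if (i < N) i + 1L else 1L]]]$sel
      if (runif(1) < cfg$crossover_rate) {
        kids <- single_point_crossover(p1, p2)
      } else {
        kids <- list(p1, p2)
      }
      kids <- lapply(kids, function(sel) {
        if (any(sel)) mutate_sel(sel, adj, eligible, cfg$mutation_additions) else sel
      })
      offspring_sels[[i]] <- kids[[1L]]
      if (i < N) offspring_sels[[i + 1L]] <- kids[[2L]]
      i <- i + 2L
    }

    combined <- c(pop, make_pop(offspring_sels))
    combined <- sort_assign(combined)
    ord <- order(
      vapply(combined, `[[`, integer(1), "rank"),
      -vapply(combined, `[[`, numeric(1), "crowding")
    )
    pop <- combined[ord[seq_len(N)]]

    feas <- vapply(pop, `[[`, logical(1), "feasible")
    objs <- do.call(rbind, lapply(pop, `[[`, "obj"))
    history[[gen]] <- tibble(
      generation = gen,
      best_s_a = if (any(feas)) max(-objs[feas, 1]) else NA_real_,
      best_r_a = if (any(feas)) max(-objs[feas, 2]) else NA_real_,
      n_feasible = sum(feas),
      n_unique = N - round(dup_frac * N)
    )
  }

  # final feasible non-dominated front, deduplicated
  pop <- sort_assign(pop)
  front_idx <- which(
    vapply(pop, `[[`, integer(1), "rank") == 1L &
      vapply(pop, `[[`, logical(1), "feasible")
  )
  front_pop <- pop[front_idx]
  front_tbl <- tibble(
    size = vapply(front_pop, function(x) sum(x$sel), integer(1)),
    s_a = vapply(front_pop, function(x) -x$obj[1], numeric(1)),
    r_a = vapply(front_pop, function(x) -x$obj[2], numeric(1)),
    genes = lapply(front_pop, function(x) net$node_order[x$sel])
  )
  ord <- order(-front_tbl$s_a, front_tbl$r_a)
  front_tbl <- front_tbl[ord, ]
  front_pop <- front_pop[ord]
  front_tbl <- dplyr::mutate(front_tbl, module = dplyr::row_number(), .before = 1)
  front_tbl$label <- label_front(front_tbl)

  structure(
    list(
      front = front_tbl,
      selections = lapply(front_pop, `[[`, "sel"),
      history = dplyr::bind_rows(history),
      config = cfg,
      node_order = net$node_order
    ),
    class = "pareto_result"
  )
}

#' Label the extreme and knee solutions of a front
#'
#' The maximum-activity and maximum-coverage members are the front's extreme
#' points; the knee is the member at maximum perpendicular distance from the
#' line joining the two extremes after min-max normalisation of both
#' objectives (a front of one or two members has no distinct knee).
#'
#' @param front A tibble with columns `s_a` and `r_a`.
#' @return Character vector of labels (`"max_s_a"`, `"max_r_a"`, `"knee"`,
#'   possibly comma-combined, `NA` otherwise), one per row.
#' @export
label_front <- function(front) {
  k <- nrow(front)
  lab <- rep(NA_character_, k)
  if (k == 0L) return(lab)
  i_s <- which.max(front$s_a)
  i_r <- which.max(front$r_a)
  add <- function(lab, i, tag) {
    lab[i] <- if (is.na(lab[i])) tag else paste(lab[i], tag, sep = ",")
    lab
  }
  lab <- add(lab, i_s, "max_s_a")
  lab <- add(lab, i_r, "max_r_a")
  i_k <- knee_point(front)
  lab <- add(lab, i_k, "knee")
  lab
}

#' @rdname label_front
#' @return `knee_point()` returns the row index of the knee solution.
#' @export
knee_point <- function(front) {
  k <- nrow(front)
  if (k <= 2L) return(which.max(front$s_a))
  norm <- function(v) if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else rep(0.5, length(v))
  x <- norm(front$s_a)
  y <- norm(front$r_a)
  i_s <- which.max(front$s_a)
  i_r <- which.max(front$r_a)
  if (i_s == i_r) return(i_s)
  # distance from the line through the two extreme points
  dx <- x[i_r] - x[i_s]
  dy <- y[i_r] - y[i_s]
  d <- abs(dx * (y[i_s] - y) - dy * (x[i_s] - x)) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf(
    "Pareto front of %d connected module(s) (pop %d, %d generations, seed %d)\n",
    nrow(x$front), x$config$population_size, x$config$generations, x$config$seed
  ))
  print(dplyr::select(x$front, -"genes"))
  invisible(x)
}

#' @rdname evolve
#' @param x A `pareto_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pareto_result <- function(x, ...) {
  dplyr::select(x$front, -"genes")
}

#' @rdname evolve
#' @exportS3Method generics::glance
glance.pareto_result <- function(x, ...) {
  tibble(
    n_solutions = nrow(x$front),
    max_s_a = max(x$front$s_a),
    max_r_a = max(x$front$r_a),
    generations = x$config$generations,
    population_size = x$config$population_size,
    seed = x$config$seed
  )
}
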