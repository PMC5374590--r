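# small benchmark shared by the evolve() tests
small_bench <- generate_benchmark(synthetic_spec(
  n_nodes = 80, planted_module_size = 10, n_pathways = 8,
  pathway_size_range = c(4L, 8L), n_planted_pathways = 3, seed = 99
))
small_net <- local({
  fit <- fit_bum(small_bench$pvalues)
  suppressMessages(scored_network(
    small_bench$edges, small_bench$pvalues, scoring_scheme(fit, 0.05)
  ))
})

test_that("initialisation grows each top-scoring seed by its positive neighbours", {
  # star: centre best-scored, all leaves positive -> first individual is the whole star
  ids <- c("hub", paste0("leaf", 1:4))
  star <- toy_net(
    cbind(rep("hub", 4), paste0("leaf", 1:4)),
    setNames(c(5, 1, 1, 1, 1), ids)
  )
  pop <- initialize_population(star, 1)
  expect_length(pop, 1)
  expect_true(all(pop[[1]]))

  # negative-score neighbours are not added
  star2 <- toy_net(
    cbind(rep("hub", 4), paste0("leaf", 1:4)),
    setNames(c(5, 1, -1, 1, -1), ids)
  )
  sel <- initialize_population(star2, 1)[[1]]
  expect_equal(star2$node_order[sel], sort(c("hub", "leaf1", "leaf3")))

  # population larger than the network: every node becomes a seed
  expect_length(initialize_population(small_net, 500), 80)

  # seeds match a brute-force top-k sort of scores (ties by gene ID)
  k <- 10
  pop <- initialize_population(small_net, k)
  expected_seeds <- small_net$node_order[
    order(-small_net$nodes$score, small_net$node_order)[1:k]
  ]
  for (i in seq_len(k)) {
    expect_true(pop[[i]][match(expected_seeds[i], small_net$node_order)])
  }

  all_neg <- toy_net(cbind("a", "b"), c(a = -1, b = -2))
  expect_error(initialize_population(all_neg, 2), "positive")
})

test_that("constrained non-dominated sorting matches a pairwise oracle", {
  expect_equal(
    fast_nondominated_sort(rbind(c(1, 3), c(2, 2), c(3, 1))),
    c(1L, 1L, 1L)
  )
  expect_equal(fast_nondominated_sort(rbind(c(1, 1), c(2, 2))), c(1L, 2L))

  set.seed(81)
  for (trial in 1:10) {
    obj <- matrix(runif(200), ncol = 2)
    expect_equal(fast_nondominated_sort(obj), pareto_rank_oracle(obj))
  }

  # infeasible solutions never outrank feasible ones
  set.seed(82)
  obj <- matrix(runif(60), ncol = 2)
  feas <- runif(30) < 0.5
  feas[1] <- TRUE # ensure at least one of each
  feas[2] <- FALSE
  rank <- fast_nondominated_sort(obj, feas)
  expect_lt(max(rank[feas]), min(rank[!feas]) + 1e-9)
})

test_that("crowding distance follows the standard diversity formula", {
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  # three equally spaced points on a line: middle accumulates a full
  # normalised range per objective, hence 2
  d <- crowding_distance(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(d, c(Inf, 2, Inf))
  # identical objective vectors: zero-range objectives contribute nothing
  d0 <- crowding_distance(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(d0[2], 0)
})

test_that("binary tournaments respect constrained-crowded comparison", {
  rank <- c(1L, 1L, 2L)
  crowd <- c(Inf, 1, 5)
  feas <- c(TRUE, TRUE, FALSE)
  set.seed(91)
  winners <- binary_tournament(rank, crowd, feas, n = 2000)
  # the infeasible individual can only win against itself
  tab <- tabulate(winners, 3)
  expect_lt(tab[3] / 2000, 0.2) # P(draw {3,3}) = 1/9
  # individual 1 beats 2 on crowding and 3 on feasibility:
  # wins unless the draw is {2,2}, {3,3}, {2,3} or {3,2} -> P = 5/9
  p <- 5 / 9
  expect_lt(abs(tab[1] - 2000 * p), 3 * sqrt(2000 * p * (1 - p)))
})

test_that("single-point crossover conserves bits and respects the cut", {
  set.seed(103)
  p1 <- runif(40) < 0.3
  p2 <- runif(40) < 0.6
  kids <- single_point_crossover(p1, p2)
  expect_equal(kids[[1]] + kids[[2]], p1 + p2) # per-position multiset conserved
  same <- single_point_crossover(p1, p1)
  expect_identical(same[[1]], p1)
  expect_identical(same[[2]], p1)
  # the cut is interior: each child shares a prefix with one parent and a
  # suffix with the other
  k1 <- kids[[1]]
  cut <- max(which(cumsum(k1 != p1) == 0), 0)
  expect_true(cut >= 1 || all(k1[1] == p2[1]))
  expect_true(all(k1[(cut + 1):40] == p2[(cut + 1):40]) || all(k1 == p1))
})

test_that("mutation only adds eligible neighbours of the module", {
  # module with no eligible neighbour is returned unchanged
  line <- toy_net(cbind(c("a", "b"), c("b", "c")), c(a = 1, b = -1, c = -1))
  col0 <- gene_set_collection(list(p = "zzz_not_in_network"))
  expect_equal(
    mutate_module(line, col0, "a"),
    as.logical(c(1, 0, 0))
  )
  # pathway membership makes a negative-score neighbour eligible
  col1 <- gene_set_collection(list(p = "b"))
  expect_equal(mutate_module(line, col1, "a"), as.logical(c(1, 1, 0)))

  set.seed(104)
  col <- small_bench$genesets
  adj <- igraph::as_adj_list(small_net$graph, mode = "all")
  for (trial in 1:1000) {
    start <- sample(80, 1)
    sel <- logical(80)
    sel[start] <- TRUE
    out <- mutate_module(small_net, col, sel)
    expect_gte(sum(out), sum(sel)) # addition only
    added <- which(out & !sel)
    if (length(added) == 1) {
      expect_true(added %in% as.integer(adj[[start]])) # adjacent to prior module
    }
  }
})

test_that("clearing keeps one copy of each duplicated selection", {
  a <- c(TRUE, FALSE, TRUE)
  b <- c(FALSE, TRUE, TRUE)
  expect_equal(clearing(list(a, a, a)), c(TRUE, FALSE, FALSE))
  expect_equal(clearing(list(a, b)), c(TRUE, TRUE))
  # a representative that is already infeasible stays infeasible
  expect_equal(clearing(list(a, a), feasible = c(FALSE, TRUE)), c(FALSE, FALSE))

  # mixed population equals a pairwise brute-force dedup
  set.seed(105)
  sels <- lapply(1:30, function(i) runif(6) < 0.5)
  sels[sample(30, 10)] <- sels[sample(5, 10, replace = TRUE)]
  got <- clearing(sels)
  oracle <- vapply(seq_along(sels), function(i) {
    !any(vapply(seq_len(i - 1), function(j) identical(sels[[i]], sels[[j]]), logical(1)))
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("the evolutionary search returns a reproducible, feasible Pareto front", {
  cfg <- search_config(population_size = 20, generations = 30, seed = 7, r_ratio = 0.5)
  res <- evolve(small_net, small_bench$genesets, cfg)
  expect_s3_class(res, "pareto_result")
  expect_gt(nrow(res$front), 0)

  # determinism: the same seed gives a bit-identical result
  res2 <- evolve(small_net, small_bench$genesets, cfg)
  expect_identical(res$front, res2$front)
  expect_identical(res$history, res2$history)

  # every reported module is connected and re-evaluates to its stored objectives
  for (i in seq_len(nrow(res$front))) {
    genes <- res$front$genes[[i]]
    expect_true(is_connected_module(small_net, genes))
    ev <- evaluate_module(small_net, small_bench$genesets, genes, cfg$r_ratio)
    expect_equal(ev$s_a, res$front$s_a[i])
    expect_equal(ev$r_a, res$front$r_a[i])
  }

  # mutual non-domination and no duplicated selections on the front
  obj <- cbind(-res$front$s_a, -res$front$r_a)
  expect_true(all(pareto_rank_oracle(obj) == 1))
  keys <- vapply(res$front$genes, function(g) paste(sort(g), collapse = ","), character(1))
  expect_false(any(duplicated(keys)))

  # elitism: best feasible activity never decreases across generations
  expect_true(all(diff(res$history$best_s_a) >= -1e-9))

  # front extremes dominate their own objective
  expect_equal(max(res$front$s_a), res$front$s_a[grepl("max_s_a", res$front$label)])
  expect_equal(max(res$front$r_a), res$front$r_a[grepl("max_r_a", res$front$label)][1])
})

test_that("front labelling identifies extremes and the knee", {
  # single solution: simultaneously both extremes and the knee
  one <- tibble::tibble(s_a = 5, r_a = 2)
  expect_equal(label_front(one), "max_s_a,max_r_a,knee")
  # right-angled front: the corner is the knee
  front <- tibble::tibble(s_a = c(10, 9.5, 1), r_a = c(0, 5, 6))
  expect_equal(knee_point(front), 2)
  lab <- label_front(front)
  expect_equal(lab, c("max_s_a", "knee", "max_r_a"))
})
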