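make_small_run <- function(seed = 13) {
  b <- generate_benchmark(synthetic_spec(
    n_nodes = 60, planted_module_size = 8, n_pathways = 6,
    pathway_size_range = c(4L, 6L), n_planted_pathways = 2, seed = seed
  ))
  fit <- fit_bum(b$pvalues)
  net <- suppressMessages(scored_network(b$edges, b$pvalues, scoring_scheme(fit, 0.05)))
  cfg <- search_config(population_size = 12, generations = 15, seed = seed, r_ratio = 0.5)
  list(bench = b, net = net, cfg = cfg, res = evolve(net, b$genesets, cfg))
}

test_that("results round-trip through a run directory and re-score exactly", {
  run <- make_small_run()
  dir <- file.path(withr::local_tempdir(), "run1")
  write_result(run$res, dir, inputs = NULL)

  expect_true(file.exists(file.path(dir, "front.tsv")))
  expect_true(file.exists(file.path(dir, "run.json")))
  for (m in run$res$front$module) {
    expect_true(file.exists(file.path(dir, sprintf("module_%d.txt", m))))
  }

  # the manifest echoes the configuration needed for an identical re-run
  manifest <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(manifest$seed, run$cfg$seed)
  expect_equal(manifest$config$population_size, run$cfg$population_size)
  expect_equal(length(manifest$history), run$cfg$generations)

  # report recomputes both objectives from the stored gene lists and agrees
  tbl <- report_run(dir, run$net, run$bench$genesets, run$cfg$r_ratio)
  expect_equal(tbl$s_a, run$res$front$s_a)
  expect_equal(tbl$r_a, run$res$front$r_a)
  expect_equal(tbl$label, run$res$front$label)

  # wrong parameters are caught rather than silently reported
  expect_error(
    report_run(dir, run$net, run$bench$genesets, r_ratio = 0.99),
    "do not match"
  )

  # prior runs are never overwritten
  expect_error(write_result(run$res, dir), "refusing")
})

test_that("fit reports serialise the mixture parameters and threshold", {
  set.seed(3)
  fit <- fit_bum(rbum(500, 0.3, 0.6))
  f <- withr::local_tempfile(fileext = ".json")
  rep <- write_fit_report(fit, 1e-3, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$a, fit$a, tolerance = 1e-12)
  expect_equal(back$tau, bum_tau(fit, 1e-3), tolerance = 1e-12)
  expect_equal(back$n, 500)
})

test_that("plot methods return printable objects", {
  run <- make_small_run()
  expect_s3_class(autoplot(run$res), "ggplot")
  expect_s3_class(plot_history(run$res), "ggplot")
  set.seed(4)
  fit <- fit_bum(rbum(300, 0.3, 0.6))
  expect_no_error(p <- autoplot(fit, bins = 20))
  expect_s3_class(tidy(fit), "tbl_df")
})

# ---- command-line interface --------------------------------------------------

cli_path <- system.file("cli", "pamod.R", package = "pamod")

run_cli <- function(...) {
  args <- c(cli_path, ...)
  out <- suppressWarnings(system2("Rscript", shQuote(args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = paste(out, collapse = "\n"))
}

test_that("every CLI subcommand answers --help with exit status 0", {
  skip_if(cli_path == "", "CLI script not installed")
  for (cmd in c("fit-bum", "generate", "search", "report")) {
    r <- run_cli(cmd, "--help")
    expect_equal(r$status, 0L, info = cmd)
    expect_match(r$output, "Options", info = cmd)
  }
  expect_equal(run_cli("--help")$status, 0L)
  expect_equal(run_cli("no-such-command")$status, 2L)
})

test_that("the CLI runs generate, fit-bum, search and report end to end", {
  skip_if(cli_path == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  run_dir <- file.path(dir, "run")

  g <- run_cli(
    "generate", "--out", data_dir, "--n-nodes", "60", "--planted-size", "8",
    "--n-pathways", "6", "--seed", "2"
  )
  expect_equal(g$status, 0L, info = g$output)

  f <- run_cli(
    "fit-bum", "--pvalues", file.path(data_dir, "pvalues.tsv"),
    "--alpha", "0.05", "--out", file.path(dir, "fit.json")
  )
  expect_equal(f$status, 0L, info = f$output)
  fit <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_true(fit$tau > 0 && fit$tau <= 1)

  common <- c(
    "--network", file.path(data_dir, "edges.tsv"),
    "--pvalues", file.path(data_dir, "pvalues.tsv"),
    "--gmt", file.path(data_dir, "pathways.gmt"),
    "--alpha", "0.05", "--r-ratio", "0.5"
  )
  s <- run_cli(
    "search", common, "--pop", "10", "--gens", "10",
    "--seed", "2", "--out", run_dir
  )
  expect_equal(s$status, 0L, info = s$output)
  expect_true(file.exists(file.path(run_dir, "front.tsv")))
  expect_true(file.exists(file.path(run_dir, "run.json")))
  expect_true(file.exists(file.path(run_dir, "pamod.log")))

  # report re-scores the stored gene lists against the same inputs
  r <- run_cli("report", "--run", run_dir, common)
  expect_equal(r$status, 0L, info = r$output)
  expect_match(r$output, "max_s_a")

  # a second search into the same directory must refuse
  s2 <- run_cli("search", common, "--pop", "10", "--gens", "10", "--seed", "2", "--out", run_dir)
  expect_false(s2$status == 0L)
})

test_that("a config file supplies flag defaults that the command line overrides", {
  skip_if(cli_path == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "pamod.cfg")
  writeLines(c("n-nodes=40", "planted-size=6", "seed=9"), cfg)
  g <- run_cli("generate", "--out", file.path(dir, "d"), "--config", cfg, "--n-pathways", "5")
  expect_equal(g$status, 0L, info = g$output)
  pv <- read_pvalues(file.path(dir, "d", "pvalues.tsv"))
  expect_equal(nrow(pv), 40)
  expect_length(readLines(file.path(dir, "d", "truth.txt")), 6)
})
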