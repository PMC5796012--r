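test_that("pareto front matches hand and brute-force dominance filters", {
  expect_equal(pareto_front(matrix(c(5, 10), 1)), 1L)
  obj <- rbind(c(5, 10), c(6, 9), c(7, 11))
  expect_setequal(pareto_front(obj), c(1L, 2L))
  set.seed(71)
  for (i in 1:100) {
    obj <- cbind(sample(1:20, 30, TRUE), sample(1:20, 30, TRUE))
    expect_setequal(pareto_front(obj), oracle_pareto(obj))
  }
})

test_that("hypervolume matches the grid oracle and the box cases", {
  expect_equal(hypervolume(NULL, c(1, 1)), 0)
  expect_equal(hypervolume(matrix(numeric(0), 0, 2), c(1, 1)), 0)
  expect_equal(hypervolume(c(0, 0), c(1, 1)), 1)
  # points on the reference box boundary dominate zero area
  expect_equal(hypervolume(rbind(c(0, 1), c(1, 0)), c(1, 1)), 0)
  expect_error(hypervolume(c(2, 0), c(1, 1)), "no better")
  set.seed(83)
  for (i in 1:20) {
    front <- cbind(runif(6), runif(6))
    hv <- hypervolume(front, c(1, 1))
    expect_equal(hv, oracle_hypervolume(front, c(1, 1)), tolerance = 2e-3)
    # monotone under adding a non-dominated point
    extra <- rbind(front, c(0, 0))
    expect_gte(hypervolume(extra, c(1, 1)), hv)
  }
})

test_that("config validation enforces divisibility and probability ranges", {
  expect_error(run_config(population_size = 10, n_subpops = 4), "divisible")
  expect_error(run_config(crossover_prob = 1.2), "probabilities")
  expect_error(run_config(stop = "evaluations"), "max_evaluations")
  cfg <- run_config(population_size = 12, n_subpops = 4)
  expect_s3_class(cfg, "moearc_config")
})

test_that("a zero-generation run returns the evaluated initial population", {
  bm <- small_benchmark()
  cfg <- run_config(population_size = 8, n_subpops = 4, generations = 0,
                    seed = 3)
  res <- evolve(bm$alignment, cfg)
  expect_length(res$trees, 8L)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$evaluations, 8L)
  expect_true(all(res$objectives[, 1] >= 0))
})

test_that("population size is conserved and running bests are monotone", {
  bm <- small_benchmark()
  cfg <- run_config(population_size = 8, n_subpops = 4, generations = 8,
                    seed = 11)
  res <- evolve(bm$alignment, cfg)
  expect_length(res$trees, 8L)
  expect_true(all(diff(res$trace$best_parsimony) <= 0))
  expect_true(all(diff(res$trace$best_negloglik) <= 0))
  expect_true(all(diff(res$trace$z1) <= 0))
  expect_true(all(diff(res$trace$znad1) >= 0))
  # front members are mutually non-dominated
  fr <- res$objectives[res$front, , drop = FALSE]
  expect_setequal(seq_len(nrow(fr)), oracle_pareto(unname(fr)))
})

test_that("the ablation mode never protects branches and both modes are
           deterministic under a seed", {
  bm <- small_benchmark()
  for (consensus in c(TRUE, FALSE)) {
    cfg <- run_config(population_size = 8, n_subpops = 4, generations = 5,
                      consensus = consensus, seed = 19)
    r1 <- evolve(bm$alignment, cfg)
    r2 <- evolve(bm$alignment, cfg)
    expect_identical(r1$trace, r2$trace)
    expect_identical(vapply(r1$trees, write_newick, character(1)),
                     vapply(r2$trees, write_newick, character(1)))
    if (consensus) {
      expect_identical(r1$algorithm, "MOEA-RC")
      expect_gt(sum(r1$trace$consensus_branches), 0)
    } else {
      expect_identical(r1$algorithm, "MOEA-R")
      expect_true(all(r1$trace$consensus_branches == 0))
    }
  }
})

test_that("with frozen reference points the best weighted-sum fitness in each
           sub-population never worsens", {
  set.seed(27)
  bm <- small_benchmark()
  pat <- compress_patterns(bm$alignment)
  taxa <- rownames(bm$alignment)
  N <- 8L; n_sub <- 4L
  weights <- make_weights(n_sub)
  trees <- replicate(N, random_tree(taxa), simplify = FALSE)
  obj <- t(vapply(trees, evaluate_objectives, numeric(2),
                  patterns = pat, model = bm$model))
  # a wide frozen box guaranteed to contain everything that follows
  ref <- update_reference_points(NULL, rbind(c(0, 0), 3 * apply(obj, 2, max)))
  red <- redistribute(obj, weights, ref, target = N)
  cfg <- run_config(population_size = N, n_subpops = n_sub, seed = 5)
  empty_sets <- replicate(n_sub, character(0), simplify = FALSE)
  best_per_set <- function(red) vapply(red$subpops, function(idx)
    if (length(idx)) min(red$fitness[idx]) else Inf, numeric(1))
  prev <- best_per_set(red)
  for (gen in 1:5) {
    kids <- make_offspring(trees, obj, red$assignment, empty_sets, cfg, ref)
    kobj <- t(vapply(kids, function(k)
      if (is.null(k$objectives)) evaluate_objectives(k$tree, pat, bm$model)
      else k$objectives, numeric(2)))
    all_trees <- c(trees, lapply(kids, `[[`, "tree"))
    all_obj <- unname(rbind(obj, kobj))
    red <- redistribute(all_obj, weights, ref, target = N)
    trees <- all_trees[red$survivors]
    obj <- all_obj[red$survivors, , drop = FALSE]
    keep <- red
    keep$subpops <- lapply(red$subpops, function(i) match(i, red$survivors))
    keep$assignment <- red$assignment[red$survivors]
    keep$fitness <- red$fitness[red$survivors]
    cur <- best_per_set(keep)
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
    red <- keep
  }
})

test_that("evaluation-budget stopping works", {
  bm <- small_benchmark()
  cfg <- run_config(population_size = 8, n_subpops = 4,
                    stop = "evaluations", max_evaluations = 30, seed = 2)
  res <- evolve(bm$alignment, cfg)
  expect_gte(res$evaluations, 30)
  expect_lt(res$evaluations, 30 + 8)
})

test_that("file-mode initialization passes user trees through", {
  bm <- small_benchmark()
  taxa <- rownames(bm$alignment)
  set.seed(99)
  start <- replicate(8, random_tree(taxa), simplify = FALSE)
  cfg <- run_config(population_size = 8, n_subpops = 4, generations = 0,
                    seed = 1, start_trees = start)
  res <- evolve(bm$alignment, cfg)
  expect_identical(vapply(res$trees, write_newick, character(1)),
                   vapply(start, write_newick, character(1)))
  bad <- replicate(8, random_tree(paste0("z", 1:10)), simplify = FALSE)
  cfgb <- run_config(population_size = 8, n_subpops = 4, generations = 0,
                     seed = 1, start_trees = bad)
  expect_error(evolve(bm$alignment, cfgb), "do not match")
})

test_that("YAML config round-trips through read_run_config", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("population_size: 12",
               "n_subpops: 4",
               "generations: 7",
               "crossover_prob: 0.6",
               "consensus: false",
               "model:",
               "  frequencies: [0.3, 0.2, 0.3, 0.2]",
               "  alpha: 0.7"), f)
  cfg <- read_run_config(f, seed = 4)
  expect_equal(cfg$population_size, 12L)
  expect_equal(cfg$generations, 7L)
  expect_false(cfg$consensus)
  expect_equal(cfg$seed, 4L)
  expect_equal(unname(cfg$model$frequencies), c(0.3, 0.2, 0.3, 0.2))
  writeLines("not_a_field: 1", f)
  expect_error(read_run_config(f), "unknown config field")
})
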