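## The main evolutionary loop:
##   1. initialize N trees (random or user-supplied)
##   2. evaluate (MP, -lnL) and update reference/nadir points
##   3. redistribute into weight-vector sub-populations
##   4. compute consensus branches per sub-population (skipped in the
##      non-consensus ablation)
##   5. generate N offspring (binary tournament, PDG, NNI, protection)
##   6. merge with parents and go to 2 until the stop condition
## plus Pareto-front extraction and 2-D hypervolume reporting.

#' Run configuration
#'
#' Bundles and validates all tunables of the search. The defaults are the
#' standard settings: population 100, 100 generations, crossover 0.8,
#' mutation 0.2, binary-tournament parent selection, 10 sub-populations
#' with 5 elites each feeding the consensus.
#'
#' @param population_size Number of trees `N` kept per generation; must be
#'   divisible by `n_subpops`.
#' @param n_subpops Number of weight vectors / sub-populations (>= 2;
#'   consensus needs >= 3).
#' @param generations Number of generations (used when
#'   `stop = "generations"`).
#' @param max_evaluations Evaluation budget (used when
#'   `stop = "evaluations"`); one evaluation is one (MP, ML) scoring of one
#'   tree, and unchanged copies are never re-scored.
#' @param stop Stop condition: `"generations"` (default) or
#'   `"evaluations"`.
#' @param crossover_prob Probability that a parent pair is recombined by
#'   PDG rather than copied.
#' @param mutation_prob Per-child probability of one NNI move.
#' @param elites_per_set Trees per contributing sub-population entering the
#'   consensus.
#' @param consensus `TRUE` for the full algorithm (MOEA-RC), `FALSE` for
#'   the ablation without consensus protection (MOEA-R).
#' @param consensus_rule Passed to [consensus_branches()].
#' @param t_max Protection resampling bound for [pdg_crossover()].
#' @param bl_floor Branch-length floor for the likelihood.
#' @param init_branch_mean Mean of the exponential branch lengths of random
#'   starting trees (substitutions/site).
#' @param seed Integer seed; all randomness in [evolve()] flows from it.
#' @param model A [gtr_model()], or `NULL` to use [default_model()] of the
#'   alignment.
#' @param start_trees Optional list of `"phylo"` trees (or a path to a
#'   Newick file, one tree per line) used as generation 0; must contain at
#'   least `population_size` trees on the alignment's taxa.
#' @param freeze_reference If `TRUE`, reference/nadir points are fixed
#'   after the initial population (diagnostic mode; makes per-sub-population
#'   best fitness provably non-increasing).
#' @param consensus_log Optional path; per-generation consensus sets are
#'   appended as tab-separated lines (generation, sub-population, branch
#'   count, branches).
#' @return An object of class `"moearc_config"` (a validated list).
#' @export
run_config <- function(population_size = 100L, n_subpops = 10L,
                       generations = 100L, max_evaluations = NULL,
                       stop = c("generations", "evaluations"),
                       crossover_prob = 0.8, mutation_prob = 0.2,
                       elites_per_set = 5L, consensus = TRUE,
                       consensus_rule = "majority_plus",
                       t_max = 20L, bl_floor = 1e-6,
                       init_branch_mean = 0.1, seed = 1L,
                       model = NULL, start_trees = NULL,
                       freeze_reference = FALSE, consensus_log = NULL) {
  stop <- match.arg(stop)
  population_size <- as.integer(population_size)
  n_subpops <- as.integer(n_subpops)
  if (population_size < 4L) stop("population_size must be >= 4")
  if (n_subpops < 2L) stop("n_subpops must be >= 2")
  if (population_size %% n_subpops != 0L)
    stop("population_size must be divisible by n_subpops (per-set capacity ",
         "is used as an integer)")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop("probabilities must be in [0, 1]")
  if (stop == "evaluations" && (is.null(max_evaluations) || max_evaluations < 1))
    stop("stop = 'evaluations' needs a positive max_evaluations")
  if (!is.null(model) && !inherits(model, "gtr_model"))
    stop("'model' must be a gtr_model or NULL")
  if (is.character(start_trees)) start_trees <- read_trees(start_trees)
  cfg <- list(population_size = population_size, n_subpops = n_subpops,
              generations = as.integer(generations),
              max_evaluations = max_evaluations, stop = stop,
              crossover_prob = crossover_prob, mutation_prob = mutation_prob,
              elites_per_set = as.integer(elites_per_set),
              consensus = isTRUE(consensus), consensus_rule = consensus_rule,
              t_max = as.integer(t_max), bl_floor = bl_floor,
              init_branch_mean = init_branch_mean, seed = as.integer(seed),
              model = model, start_trees = start_trees,
              freeze_reference = isTRUE(freeze_reference),
              consensus_log = consensus_log)
  class(cfg) <- "moearc_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] can be set in a YAML file; a nested
#' `model:` block (fields of [gtr_model()]) defines the substitution
#' model. Unknown fields are rejected.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `"moearc_config"`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$model)) {
    m <- cfg$model
    cfg$model <- gtr_model(
      frequencies = if (!is.null(m$frequencies)) as.numeric(m$frequencies) else rep(0.25, 4),
      rates = if (!is.null(m$rates)) as.numeric(m$rates) else rep(1, 6),
      alpha = if (!is.null(m$alpha)) m$alpha else 1.0,
      ncat = if (!is.null(m$ncat)) m$ncat else 4L)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Initial population of trees
#'
#' Random mode builds uniformly random topologies with exponential branch
#' lengths (mean `init_branch_mean`); file mode passes through
#' user-supplied trees after checking their taxon set.
#'
#' @param config A [run_config()].
#' @param taxa Character vector of taxon labels (the alignment's rownames).
#' @return List of `population_size` `"phylo"` trees (unevaluated).
#' @export
initialize_population <- function(config, taxa) {
  N <- config$population_size
  if (!is.null(config$start_trees)) {
    trees <- config$start_trees
    if (length(trees) < N)
      stop("need at least ", N, " starting trees, got ", length(trees))
    trees <- trees[seq_len(N)]
    for (t in trees)
      if (!setequal(t$tip.label, taxa))
        stop("starting tree taxa do not match the alignment")
    return(trees)
  }
  rate <- 1 / config$init_branch_mean
  lapply(seq_len(N), function(i)
    random_tree(taxa, branch_fn = function(k) stats::rexp(k, rate = rate)))
}

#' Non-dominated solutions of a population
#'
#' Returns the indices of objective vectors not dominated by any other
#' (minimization in all columns); exact duplicates in objective space are
#' collapsed to their first representative.
#'
#' @param objectives Numeric matrix, rows = solutions, columns =
#'   objectives.
#' @return Integer vector of row indices, ordered by the first objective.
#' @export
pareto_front <- function(objectives) {
  if (is.null(dim(objectives))) objectives <- matrix(objectives, nrow = 1L)
  M <- nrow(objectives)
  if (M == 1L) return(1L)
  keep <- !duplicated(objectives)
  idx <- which(keep)
  nondom <- vapply(idx, function(i) {
    fi <- objectives[i, ]
    !any(vapply(idx, function(j) {
      if (i == j) return(FALSE)
      fj <- objectives[j, ]
      all(fj <= fi) && any(fj < fi)
    }, logical(1)))
  }, logical(1))
  out <- idx[nondom]
  out[order(objectives[out, 1L], objectives[out, 2L])]
}

#' 2-D hypervolume of a front
#'
#' Area of objective space dominated by the front up to a reference point
#' (both objectives minimized), by the usual sort-and-sum staircase
#' computation. Points outside the reference box (any component exceeding
#' the reference point) raise an error; points on its boundary contribute
#' zero area.
#'
#' @param front Numeric matrix of objective vectors (rows = points), or a
#'   single vector; an empty front gives 0.
#' @param ref Reference point (length 2), componentwise no better than any
#'   front member.
#' @return Non-negative area.
#' @export
hypervolume <- function(front, ref) {
  if (is.null(front) || length(front) == 0L) return(0)
  if (is.null(dim(front))) front <- matrix(front, ncol = 2L)
  stopifnot(length(ref) == 2L)
  if (any(front[, 1L] > ref[1L]) || any(front[, 2L] > ref[2L]))
    stop("reference point must be no better than every front member")
  front <- front[pareto_front(front), , drop = FALSE]
  ord <- order(front[, 1L])
  f1 <- front[ord, 1L]; f2 <- front[ord, 2L]
  prev <- ref[2L]
  area <- 0
  for (i in seq_along(f1)) {
    area <- area + (ref[1L] - f1[i]) * (prev - f2[i])
    prev <- f2[i]
  }
  area
}

#' Run the evolutionary search
#'
#' Executes the full loop (see the package vignette): initialization,
#' evaluation with running reference/nadir tracking, redistribution,
#' per-sub-population consensus branches (unless `consensus = FALSE`),
#' protected PDG/NNI offspring, merge, repeat. Bit-reproducible for a fixed
#' seed and configuration.
#'
#' @param alignment Character matrix alignment (see [read_alignment()]).
#' @param config A [run_config()].
#' @return An object of class `"moearc_result"`: list with `trees` (final
#'   population), `objectives` (matrix, columns parsimony and negloglik),
#'   `front` (indices of the non-dominated set), `trace` (one data-frame
#'   row per generation: running best objectives, normalized-front
#'   hypervolume, reference points, protected-branch count, evaluations),
#'   `ref`, `evaluations`, `config` and `algorithm` (`"MOEA-RC"` or
#'   `"MOEA-R"`).
#' @export
evolve <- function(alignment, config = run_config()) {
  stopifnot(inherits(config, "moearc_config"))
  validate_alignment(alignment)
  set.seed(config$seed)
  patterns <- compress_patterns(alignment)
  model <- if (is.null(config$model)) default_model(alignment) else config$model
  taxa <- rownames(alignment)
  N <- config$population_size
  n_sub <- config$n_subpops
  weights <- make_weights(n_sub)
  evals <- 0L
  score <- function(tree) {
    evals <<- evals + 1L
    evaluate_objectives(tree, patterns, model, config$bl_floor)
  }

  trees <- initialize_population(config, taxa)
  objectives <- t(vapply(trees, score, numeric(2)))
  ref <- update_reference_points(NULL, objectives)
  red <- redistribute(objectives, weights, ref, target = N)

  best <- c(min(objectives[, 1L]), min(objectives[, 2L]))
  trace <- list(trace_row(0L, best, objectives, ref, 0L, evals))
  cons_sets <- replicate(n_sub, character(0), simplify = FALSE)

  gen <- 0L
  repeat {
    if (config$stop == "generations") {
      if (gen >= config$generations) break
    } else if (evals >= config$max_evaluations) break
    gen <- gen + 1L

    ## Step 4: consensus branches per sub-population
    if (config$consensus && n_sub >= 3L) {
      cons_sets <- lapply(seq_len(n_sub), function(i) {
        elites <- collect_elites(red$subpops, trees, i, config$elites_per_set)
        if (length(elites) < 2L) return(character(0))
        consensus_branches(elites, rule = config$consensus_rule)$branches
      })
      if (!is.null(config$consensus_log))
        log_consensus(config$consensus_log, gen, cons_sets, sort(taxa))
    }

    ## Step 5: offspring
    kids <- make_offspring(trees, objectives, red$assignment, cons_sets,
                           config, ref)
    kid_obj <- matrix(NA_real_, N, 2L)
    for (i in seq_len(N)) {
      kid_obj[i, ] <- if (is.null(kids[[i]]$objectives))
        score(kids[[i]]$tree) else kids[[i]]$objectives
    }
    if (!config$freeze_reference)
      ref <- update_reference_points(ref, kid_obj)

    ## Step 6: merge and reselect
    all_trees <- c(trees, lapply(kids, `[[`, "tree"))
    all_obj <- rbind(objectives, kid_obj)
    red <- redistribute(all_obj, weights, ref, target = N)
    trees <- all_trees[red$survivors]
    objectives <- all_obj[red$survivors, , drop = FALSE]
    red$subpops <- lapply(red$subpops, function(idx) match(idx, red$survivors))
    red$assignment <- red$assignment[red$survivors]

    best <- pmin(best, c(min(all_obj[, 1L]), min(all_obj[, 2L])))
    n_branches <- sum(lengths(cons_sets))
    trace[[length(trace) + 1L]] <-
      trace_row(gen, best, objectives, ref, n_branches, evals)
  }

  dimnames(objectives) <- list(NULL, c("parsimony", "negloglik"))
  out <- list(trees = trees,
              objectives = objectives,
              front = pareto_front(objectives),
              trace = do.call(rbind, trace),
              ref = ref,
              evaluations = evals,
              config = config,
              algorithm = if (config$consensus) "MOEA-RC" else "MOEA-R")
  class(out) <- "moearc_result"
  out
}

trace_row <- function(gen, best, objectives, ref, n_branches, evals) {
  best <- unname(best)
  fbar <- normalize_objectives(objectives, ref)
  hv <- hypervolume(fbar[pareto_front(objectives), , drop = FALSE], c(1.1, 1.1))
  data.frame(generation = gen,
             best_parsimony = best[1L], best_negloglik = best[2L],
             front_size = length(pareto_front(objectives)),
             hypervolume = hv,
             z1 = unname(ref$z[1L]), z2 = unname(ref$z[2L]),
             znad1 = unname(ref$znad[1L]), znad2 = unname(ref$znad[2L]),
             consensus_branches = n_branches,
             evaluations = evals,
             row.names = NULL)
}

log_consensus <- function(path, gen, cons_sets, taxa) {
  lines <- vapply(seq_along(cons_sets), function(i) {
    branches <- vapply(cons_sets[[i]], function(key)
      paste0("{", paste(split_labels(key, taxa), collapse = ","), "}"),
      character(1))
    paste(gen, i, length(branches), paste(branches, collapse = " "),
          sep = "\t")
  }, character(1))
  cat(lines, file = path, sep = "\n", append = TRUE)
}

#' @export
print.moearc_result <- function(x, ...) {
  cat(x$algorithm, "run:", nrow(x$trace) - 1L, "generations,",
      x$evaluations, "evaluations\n")
  cat("final population:", length(x$trees), "trees;",
      length(x$front), "on the Pareto front\n")
  cat(sprintf("best parsimony: %d   best -lnL: %.4f\n",
              as.integer(min(x$objectives[, 1L])), min(x$objectives[, 2L])))
  invisible(x)
}

#' Extract the Pareto-front trees of a finished run
#'
#' @param result A `"moearc_result"`.
#' @return List of `"phylo"` trees with an `"objectives"` attribute each.
#' @export
front_trees <- function(result) {
  stopifnot(inherits(result, "moearc_result"))
  lapply(result$front, function(i) {
    t <- result$trees[[i]]
    attr(t, "objectives") <- result$objectives[i, ]
    t
  })
}
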