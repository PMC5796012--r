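## The two search objectives, both minimized:
##   f1 = Fitch parsimony score (state changes)
##   f2 = negated GTR+GAMMA log-likelihood
## plus the [0,1] normalization against dynamically tracked reference
## (componentwise best) and nadir (componentwise worst) points.

#' Fitch parsimony score of a tree
#'
#' Minimum number of state changes needed to explain each site pattern on
#' the tree, summed with pattern weights. Ambiguity codes and gaps enter as
#' their state sets, so missing data never forces a change. The score is
#' independent of the arbitrary internal rooting.
#'
#' @param tree A `"phylo"` tree whose tips match the pattern taxa.
#' @param patterns A `"site_patterns"` object from [compress_patterns()].
#' @return Non-negative integer parsimony score.
#' @export
fitch_parsimony <- function(tree, patterns) {
  stopifnot(inherits(patterns, "site_patterns"))
  masks <- patterns_for_tree(patterns, tree)
  tr <- stats::reorder(tree, "postorder")
  fitch_count(tr$edge, ape::Ntip(tree), ape::Ntip(tree) + tree$Nnode,
              masks, as.integer(patterns$weights))
}

#' GTR+GAMMA log-likelihood of a tree
#'
#' Felsenstein pruning over the tree's internal trichotomy; per-site
#' likelihoods are averaged over the model's equal-probability gamma
#' categories and summed as `weight * log(site likelihood)`. By model
#' reversibility the result does not depend on the internal root choice.
#'
#' @inheritParams fitch_parsimony
#' @param model A [gtr_model()].
#' @param bl_floor Minimum branch length used in the calculation; edges
#'   shorter than this are clamped up so that topologically degenerate
#'   edges produced by the search operators cannot drive the likelihood to
#'   `-Inf`. Set to 0 to disable.
#' @return The log-likelihood (a finite negative number for valid input).
#' @export
log_likelihood <- function(tree, patterns, model, bl_floor = 1e-6) {
  stopifnot(inherits(patterns, "site_patterns"), inherits(model, "gtr_model"))
  masks <- patterns_for_tree(patterns, tree)
  tr <- stats::reorder(tree, "postorder")
  el <- pmax(tr$edge.length, bl_floor)
  ll <- pruning_loglik(tr$edge, ape::Ntip(tree), ape::Ntip(tree) + tree$Nnode,
                       el, masks, as.integer(patterns$weights),
                       model$U, model$Uinv, model$eigenvalues,
                       unname(model$frequencies), model$category_rates)
  if (!is.finite(ll)) {
    bad <- which(!is.finite(site_log_likelihoods(tree, patterns, model, bl_floor)))
    stop("non-finite likelihood at pattern(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ll
}

## per-pattern log site likelihoods (diagnostics; one category at a time)
site_log_likelihoods <- function(tree, patterns, model, bl_floor = 1e-6) {
  masks <- patterns_for_tree(patterns, tree)
  vapply(seq_along(patterns$weights), function(k) {
    p1 <- patterns
    p1$masks <- patterns$masks[, k, drop = FALSE]
    p1$weights <- 1L
    tr <- stats::reorder(tree, "postorder")
    pruning_loglik(tr$edge, ape::Ntip(tree), ape::Ntip(tree) + tree$Nnode,
                   pmax(tr$edge.length, bl_floor),
                   patterns_for_tree(p1, tree), 1L,
                   model$U, model$Uinv, model$eigenvalues,
                   unname(model$frequencies), model$category_rates)
  }, numeric(1))
}

#' Evaluate both objectives for a tree
#'
#' @inheritParams log_likelihood
#' @return Named numeric vector `c(parsimony =, negloglik =)`; both are
#'   minimized by the search.
#' @export
evaluate_objectives <- function(tree, patterns, model, bl_floor = 1e-6) {
  stopifnot(inherits(patterns, "site_patterns"), inherits(model, "gtr_model"))
  masks <- patterns_for_tree(patterns, tree)
  tr <- stats::reorder(tree, "postorder")
  n_node <- ape::Ntip(tree) + tree$Nnode
  w <- as.integer(patterns$weights)
  mp <- fitch_count(tr$edge, ape::Ntip(tree), n_node, masks, w)
  ll <- pruning_loglik(tr$edge, ape::Ntip(tree), n_node,
                       pmax(tr$edge.length, bl_floor), masks, w,
                       model$U, model$Uinv, model$eigenvalues,
                       unname(model$frequencies), model$category_rates)
  if (!is.finite(ll)) stop("non-finite likelihood")
  c(parsimony = mp, negloglik = -ll)
}

#' Reference and nadir points
#'
#' Running componentwise extremes of all objective vectors observed so far:
#' the reference point `z` holds the best (smallest) value seen for each
#' objective, the nadir `znad` the worst. They only tighten monotonically
#' over a run, which keeps the normalization stable across generations.
#'
#' @param ref An existing reference-point object, or `NULL` to initialize
#'   from the first batch of observations.
#' @param observed Numeric matrix of objective vectors (rows = solutions,
#'   columns = objectives), or a single numeric vector.
#' @return An object of class `"reference_points"`: list with `z` (best)
#'   and `znad` (worst).
#' @export
update_reference_points <- function(ref, observed) {
  if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1L)
  if (nrow(observed) == 0L) stop("empty set of observed objective vectors")
  if (any(!is.finite(observed))) stop("non-finite objective value observed")
  lo <- apply(observed, 2L, min)
  hi <- apply(observed, 2L, max)
  if (is.null(ref)) {
    ref <- structure(list(z = lo, znad = hi), class = "reference_points")
  } else {
    stopifnot(inherits(ref, "reference_points"))
    ref$z <- pmin(ref$z, lo)
    ref$znad <- pmax(ref$znad, hi)
  }
  ref
}

#' @export
print.reference_points <- function(x, ...) {
  cat("reference z    =", paste(format(x$z), collapse = ", "), "\n")
  cat("nadir     znad =", paste(format(x$znad), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize objective vectors to the unit box
#'
#' Affine rescaling `(f - z) / (znad - z)` per objective; the reference
#' point maps to 0 and the nadir to 1. A degenerate objective with
#' `znad = z` maps to 0.
#'
#' @param f Numeric vector (one solution) or matrix (rows = solutions).
#' @param ref A `"reference_points"` object.
#' @return Normalized vector or matrix with values in `[0, 1]` whenever
#'   `f` lies inside the tracked box.
#' @export
normalize_objectives <- function(f, ref) {
  stopifnot(inherits(ref, "reference_points"))
  vec <- is.null(dim(f))
  if (vec) f <- matrix(f, nrow = 1L)
  span <- ref$znad - ref$z
  out <- sweep(f, 2L, ref$z, "-")
  for (j in seq_along(span))
    out[, j] <- if (span[j] > 0) out[, j] / span[j] else 0
  if (vec) out[1L, ] else out
}
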