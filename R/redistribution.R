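## Redistribution: the selection operator. The merged parent/offspring
## population is assigned to weight-vector sub-populations by relative
## degree (how closely a solution's normalized objective ratio matches a
## weight), sorted within each sub-population by weighted-sum fitness, and
## over-full sub-populations are trimmed worst-first until the target
## population size remains. Under-full sub-populations keep all members,
## which preserves coverage of every search direction.

#' Evenly spaced two-objective weight vectors
#'
#' @param n Number of weight vectors (= sub-populations), `n >= 2`.
#' @return An `n x 2` matrix with rows `(w1, 1 - w1)`, `w1 = (i-1)/(n-1)`
#'   ascending.
#' @export
make_weights <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 weight vectors, got ", n)
  w1 <- (seq_len(n) - 1L) / (n - 1L)
  cbind(w1 = w1, w2 = 1 - w1)
}

#' Relative degree of a solution to a weight vector
#'
#' The distance between a solution's normalized-objective ratio
#' `f1 / (f1 + f2)` and the first weight component; the ratio of the
#' all-zero vector (a solution sitting at the reference point) is defined
#' as 0.5, i.e. equally good in both directions.
#'
#' @param fbar Normalized objective vector `(f1, f2)`, componentwise >= 0,
#'   or a matrix of such rows.
#' @param w1 First component(s) of the weight vector(s).
#' @return `|f1/(f1+f2) - w1|`, vectorized over rows of `fbar` and over
#'   `w1` (an outer combination if both have length > 1 is not formed; use
#'   equal lengths or a scalar).
#' @export
relative_degree <- function(fbar, w1) {
  if (is.null(dim(fbar))) fbar <- matrix(fbar, ncol = 2L)
  s <- fbar[, 1L] + fbar[, 2L]
  ratio <- ifelse(s == 0, 0.5, fbar[, 1L] / s)
  abs(ratio - w1)
}

#' Weighted-sum fitness
#'
#' `G = w1 * f1 + w2 * f2` on normalized objectives; smaller is better.
#'
#' @inheritParams relative_degree
#' @param w Weight vector `(w1, w2)`.
#' @return Numeric fitness value(s).
#' @export
weighted_sum <- function(fbar, w) {
  if (is.null(dim(fbar))) fbar <- matrix(fbar, ncol = 2L)
  as.vector(fbar %*% w)
}

#' Redistribute a merged population into weight-vector sub-populations
#'
#' Each solution is assigned to the weight vector minimizing its relative
#' degree (ties go to the lowest weight index). Solutions are ranked within
#' each sub-population by weighted-sum fitness under that sub-population's
#' weight. While more than `target` solutions survive, the globally worst
#' member (largest fitness; ties broken towards the highest solution index)
#' among sub-populations whose current size exceeds `capacity` is removed.
#' Sub-populations at or under capacity never lose members.
#'
#' @param objectives Numeric matrix of raw objective vectors (rows =
#'   solutions).
#' @param weights Weight matrix from [make_weights()].
#' @param ref A `"reference_points"` object covering the observations.
#' @param target Total number of survivors (the population size `m`).
#' @param capacity Per-sub-population capacity; defaults to
#'   `target / nrow(weights)` and must be a whole number.
#' @return A list with `assignment` (sub-population index per input row),
#'   `fitness` (weighted-sum fitness per input row), `survivors` (row
#'   indices of the `min(target, nrow)` survivors) and `subpops` (list of
#'   surviving row indices per sub-population, sorted by ascending
#'   fitness with index order as tie-break).
#' @export
redistribute <- function(objectives, weights, ref, target,
                         capacity = target / nrow(weights)) {
  stopifnot(is.matrix(objectives), ncol(objectives) == 2L,
            inherits(ref, "reference_points"))
  n_sets <- nrow(weights)
  if (abs(capacity - round(capacity)) > 1e-9)
    stop("capacity (target / number of sub-populations) must be an integer")
  capacity <- as.integer(round(capacity))
  M <- nrow(objectives)
  fbar <- normalize_objectives(objectives, ref)
  s <- fbar[, 1L] + fbar[, 2L]
  ratio <- ifelse(s == 0, 0.5, fbar[, 1L] / s)
  ## assignment: minimal |ratio - w1|, ties to the lowest index
  d <- abs(outer(ratio, weights[, 1L], "-"))
  assignment <- apply(d, 1L, which.min)
  fitness <- weights[assignment, 1L] * fbar[, 1L] +
    weights[assignment, 2L] * fbar[, 2L]
  alive <- rep(TRUE, M)
  while (sum(alive) > target) {
    sizes <- tabulate(assignment[alive], nbins = n_sets)
    over <- which(sizes > capacity)
    cand <- which(alive & assignment %in% over)
    ## worst fitness; among exact ties, drop the highest index
    worst <- cand[fitness[cand] == max(fitness[cand])]
    alive[worst[length(worst)]] <- FALSE
  }
  survivors <- which(alive)
  subpops <- lapply(seq_len(n_sets), function(i) {
    idx <- survivors[assignment[survivors] == i]
    idx[order(fitness[idx], idx)]
  })
  list(assignment = assignment, fitness = fitness,
       survivors = survivors, subpops = subpops)
}
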