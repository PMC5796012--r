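## Consensus branches. For each sub-population, the best few trees of the
## sub-population and its two weight-vector neighbors vote on bipartitions.
## Splits in a strict majority form the core (classic majority rule);
## the "(+)" extension then admits remaining observed splits in decreasing
## frequency order when compatible with everything accepted so far. The
## result is kept as a set of protected branches, never materialized as a
## consensus tree.

#' Indices of a sub-population and its two nearest neighbors
#'
#' Interior sub-populations take `{i-1, i, i+1}`; the boundary ones take
#' their two nearest indices so that three sets always contribute.
#'
#' @param i Sub-population index (1-based).
#' @param n Number of sub-populations, `n >= 3`.
#' @return Integer vector of 3 indices.
#' @export
neighbor_sets <- function(i, n) {
  if (n < 3L) {
    warning("fewer than 3 sub-populations: consensus disabled")
    return(integer(0))
  }
  if (i < 1L || i > n) stop("sub-population index out of range")
  if (i == 1L) return(1:3)
  if (i == n) return((n - 2L):n)
  (i - 1L):(i + 1L)
}

#' Are two bipartitions compatible?
#'
#' Two splits can coexist on one tree iff at least one of the four pairwise
#' side intersections is empty.
#'
#' @param a,b Canonical split keys over the same taxon set (0/1 membership
#'   strings as produced by [bipartitions()]).
#' @return Logical.
#' @export
is_compatible <- function(a, b) {
  va <- key_to_logical(a); vb <- key_to_logical(b)
  if (length(va) != length(vb))
    stop("bipartitions are over different taxon sets")
  !any(va & vb) || !any(va & !vb) || !any(!va & vb) || !any(!va & !vb)
}

#' Majority-rule(+) consensus branches of a tree profile
#'
#' The strict-majority core contains every split found in more than half of
#' the trees. The `"majority_plus"` rule extends it by net support: a split
#' enters the consensus iff the number of trees containing it exceeds the
#' number of trees holding a conflicting split (trees doing neither
#' abstain). Two conflicting splits cannot both have support exceeding
#' rejection, so the returned set is automatically pairwise compatible and
#' therefore realizable on a single tree; it always contains the core.
#'
#' @param trees List of `k >= 2` `"phylo"` trees on an identical taxon set.
#' @param rule `"majority_plus"` (default) or `"majority"` (strict-majority
#'   core only).
#' @return An object of class `"consensus_branches"`: list with `branches`
#'   (canonical split keys), `core` (the strict-majority subset), `taxa`
#'   (sorted taxon set) and `k` (number of input trees).
#' @export
consensus_branches <- function(trees, rule = c("majority_plus", "majority")) {
  rule <- match.arg(rule)
  k <- length(trees)
  if (k < 2L) stop("need at least 2 trees to form a consensus, got ", k)
  taxa <- sort(trees[[1L]]$tip.label)
  splits <- lapply(trees, function(t) {
    if (!identical(sort(t$tip.label), taxa))
      stop("trees have mismatched taxon sets")
    bipartitions(t)
  })
  counts <- table(unlist(splits))
  if (length(counts) == 0L) {
    out <- list(branches = character(0), core = character(0), taxa = taxa, k = k)
    class(out) <- "consensus_branches"
    return(out)
  }
  keys <- names(counts)
  support <- as.integer(counts)
  core <- sort(keys[support > k / 2])
  accepted <- core
  if (rule == "majority_plus") {
    minority_idx <- which(!(keys %in% core))
    if (length(minority_idx)) {
      ## pairwise split compatibility from side-intersection cardinalities
      M <- vapply(keys, key_to_logical, logical(nchar(keys[1L])))
      cnt <- colSums(M)
      AB <- crossprod(M)                       # |A $\cap$ B|
      n_tax <- nrow(M)
      incompat <- (AB > 0) &
        (outer(cnt, rep(1, length(cnt))) - AB > 0) &
        (outer(rep(1, length(cnt)), cnt) - AB > 0) &
        (n_tax - outer(cnt, cnt, "+") + AB > 0)
      tree_keys <- lapply(splits, match, table = keys)
      reject <- vapply(minority_idx, function(i) {
        sum(vapply(tree_keys, function(idx) any(incompat[i, idx]), logical(1)))
      }, integer(1))
      extra <- keys[minority_idx][support[minority_idx] > reject]
      accepted <- sort(c(core, extra))
    }
  }
  out <- list(branches = accepted, core = core, taxa = taxa, k = k)
  class(out) <- "consensus_branches"
  out
}

#' @export
print.consensus_branches <- function(x, ...) {
  cat("Consensus branches from", x$k, "trees:", length(x$branches),
      "protected split(s) (", length(x$core), "in the majority core )\n")
  for (key in x$branches)
    cat("  {", paste(split_labels(key, x$taxa), collapse = ","), "}\n")
  invisible(x)
}

#' Collect the elite trees feeding one sub-population's consensus
#'
#' Takes the top `q` members (already sorted by weighted-sum fitness under
#' their own sub-population's weight) of the sub-population and of its two
#' neighbors; sub-populations with fewer members contribute what they have.
#'
#' @param subpops List of per-sub-population member index vectors, each
#'   sorted best-first (as returned by [redistribute()]).
#' @param trees List of trees indexed by the values in `subpops`.
#' @param i Sub-population index.
#' @param q Elites taken per contributing sub-population.
#' @return List of at most `3 q` `"phylo"` trees.
#' @export
collect_elites <- function(subpops, trees, i, q) {
  nb <- neighbor_sets(i, length(subpops))
  idx <- unlist(lapply(nb, function(j) utils::head(subpops[[j]], q)))
  trees[idx]
}
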