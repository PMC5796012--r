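## Genetic operators. Prune-Delete-Graft (PDG) crossover moves a random
## subtree of one parent into the other; nearest-neighbor-interchange (NNI)
## mutation swaps subtrees across a random internal edge. Both respect a
## set of protected consensus branches: an offspring must retain every
## protected bipartition its recipient parent contained, enforced by
## rejection sampling with a bounded number of attempts and a fall-back to
## an unmodified parent copy.

#' Prune-Delete-Graft crossover
#'
#' A random edge of `p1` is chosen whose far side holds between 1 and
#' `n - 3` leaves; that subtree is pruned, its leaves are deleted from a
#' copy of `p2` (degree-2 nodes suppressed, merged branch lengths summed),
#' and the subtree is grafted onto a random edge of the reduced `p2`,
#' splitting that edge's length in half. The pruned subtree keeps its stem
#' length. With a non-empty `protected` set, prune/graft choices are
#' resampled up to `t_max` times until the offspring retains every
#' protected bipartition present in `p2`; on exhaustion an unmodified copy
#' of `p2` is returned (flagged with attribute `"pdg_fallback"`).
#'
#' @param p1,p2 `"phylo"` trees on the same taxon set with `n >= 4` leaves.
#'   `p1` donates the subtree, `p2` receives it.
#' @param protected Character vector of canonical split keys (see
#'   [bipartitions()]); typically a `consensus_branches$branches` set.
#' @param t_max Maximum resampling attempts under protection.
#' @return A `"phylo"` tree on the full taxon set.
#' @export
pdg_crossover <- function(p1, p2, protected = character(0), t_max = 20L) {
  n <- ape::Ntip(p1)
  if (n < 4L) stop("PDG crossover needs at least 4 taxa")
  if (!setequal(p1$tip.label, p2$tip.label))
    stop("parents have different taxon sets")
  must_keep <- if (length(protected))
    intersect(as.character(protected), bipartitions(p2)) else character(0)
  clades1 <- clade_tips_per_edge(p1)
  sizes <- lengths(clades1)
  eligible <- which(sizes >= 1L & sizes <= n - 3L)
  attempts <- if (length(must_keep)) max(1L, t_max) else 1L
  for (a in seq_len(attempts)) {
    child <- try(pdg_once(p1, p2, clades1, eligible), silent = TRUE)
    if (inherits(child, "try-error")) next
    if (!length(must_keep) || all(must_keep %in% bipartitions(child)))
      return(child)
  }
  out <- p2
  attr(out, "pdg_fallback") <- TRUE
  out
}

## one unchecked prune/graft draw
pdg_once <- function(p1, p2, clades1, eligible) {
  k <- eligible[sample.int(length(eligible), 1L)]
  tips <- p1$tip.label[clades1[[k]]]
  reduced <- ape::drop.tip(p2, tips)
  j <- sample.int(nrow(reduced$edge), 1L)
  sub <- if (length(tips) == 1L) NULL else ape::extract.clade(p1, p1$edge[k, 2L])
  child <- as_unrooted(graft_subtree(reduced, j, sub, tips,
                                     stem = p1$edge.length[k]))
  validate_phylo_tree(child)
  child
}

## Graft a rooted subtree (or a single tip when sub is NULL) onto the middle
## of edge row `row` of `tree`, by explicit edge-matrix surgery: a new node
## splits the target edge in half and the subtree hangs from it by `stem`.
graft_subtree <- function(tree, row, sub, tips, stem) {
  ntipR <- ape::Ntip(tree)
  s <- length(tips)
  ns_internal <- if (s == 1L) 0L else sub$Nnode
  ntip <- ntipR + s
  w <- ntip + tree$Nnode + 1L              # the node splitting the edge
  ## old reduced ids -> combined ids (tips keep, internals shift by s)
  mapR <- function(v) ifelse(v > ntipR, v + s, v)
  E <- cbind(mapR(tree$edge[, 1L]), mapR(tree$edge[, 2L]))
  el <- tree$edge.length
  old_child <- E[row, 2L]; len <- el[row]
  E[row, 2L] <- w
  el[row] <- len / 2
  E <- rbind(E, c(w, old_child))
  el <- c(el, len / 2)
  if (s == 1L) {
    E <- rbind(E, c(w, ntipR + 1L))
    el <- c(el, stem)
  } else {
    ## sub ids -> combined: tips shift by ntipR, internals after w
    off <- ntip + tree$Nnode + 1L - s
    mapS <- function(v) ifelse(v > s, v + off, v + ntipR)
    E <- rbind(E, c(w, mapS(s + 1L)),       # stem to the subtree's root
               cbind(mapS(sub$edge[, 1L]), mapS(sub$edge[, 2L])))
    el <- c(el, stem, sub$edge.length)
  }
  new_labels <- if (s == 1L) tips else sub$tip.label
  out <- structure(list(edge = E, edge.length = el,
                        tip.label = c(tree$tip.label, new_labels),
                        Nnode = tree$Nnode + 1L + ns_internal),
                   class = "phylo")
  storage.mode(out$edge) <- "integer"
  stats::reorder(out, "cladewise")
}

#' Nearest-neighbor-interchange mutation
#'
#' Picks a random internal edge whose bipartition is not protected and
#' swaps one of the two subtree pairs across it (each of the two
#' alternative local topologies with probability 1/2); every subtree keeps
#' its own subtending branch length. If all internal edges are protected
#' the tree is returned unchanged (attribute `"nni_changed"` is `FALSE`).
#'
#' @param tree A `"phylo"` tree with `n >= 4` leaves.
#' @inheritParams pdg_crossover
#' @return A `"phylo"` tree differing from the input in exactly the chosen
#'   edge's bipartition (or identical, if fully protected).
#' @export
nni_mutation <- function(tree, protected = character(0)) {
  n <- ape::Ntip(tree)
  if (n < 4L) stop("NNI needs at least 4 taxa")
  E <- tree$edge
  internal <- which(E[, 2L] > n)
  if (length(protected)) {
    taxa <- sort(tree$tip.label)
    pos <- match(tree$tip.label, taxa)
    clades <- clade_tips_per_edge(tree)
    keys <- vapply(internal, function(r) {
      member <- logical(n)
      member[pos[clades[[r]]]] <- TRUE
      split_key(member)
    }, character(1))
    internal <- internal[!(keys %in% as.character(protected))]
  }
  if (length(internal) == 0L) {
    attr(tree, "nni_changed") <- FALSE
    return(tree)
  }
  r <- internal[sample.int(length(internal), 1L)]
  u <- E[r, 1L]; v <- E[r, 2L]
  rows_v <- which(E[, 1L] == v)                      # the two subtrees at v
  rows_u <- which(E[, 1L] == u & E[, 2L] != v)       # u's other subtree(s)
  c_row <- rows_u[sample.int(length(rows_u), 1L)]
  x_row <- rows_v[sample.int(2L, 1L)]
  ## swap the two subtrees; each keeps its subtending branch length
  tmp <- E[x_row, 2L]; E[x_row, 2L] <- E[c_row, 2L]; E[c_row, 2L] <- tmp
  tmpl <- tree$edge.length[x_row]
  tree$edge.length[x_row] <- tree$edge.length[c_row]
  tree$edge.length[c_row] <- tmpl
  tree$edge <- E
  attr(tree, "order") <- NULL   # the edit invalidates the stored edge order
  out <- stats::reorder(tree, "cladewise")
  attr(out, "nni_changed") <- TRUE
  out
}

## binary tournament: Pareto dominance on raw objectives, then smaller sum
## of normalized objectives, then a fair coin
tournament_pick <- function(objectives, ref) {
  N <- nrow(objectives)
  ij <- sample.int(N, 2L)
  a <- objectives[ij[1L], ]; b <- objectives[ij[2L], ]
  if (all(a <= b) && any(a < b)) return(ij[1L])
  if (all(b <= a) && any(b < a)) return(ij[2L])
  fa <- sum(normalize_objectives(a, ref))
  fb <- sum(normalize_objectives(b, ref))
  if (fa < fb) return(ij[1L])
  if (fb < fa) return(ij[2L])
  ij[sample.int(2L, 1L)]
}

#' Generate one generation of offspring
#'
#' Repeats until `N` offspring exist: two parents are drawn by binary
#' tournament (Pareto dominance, then smaller normalized-objective sum,
#' then random); with probability `crossover_prob` PDG is applied in both
#' directions to give two children, otherwise the parents are copied. Each
#' child is then NNI-mutated with probability `mutation_prob`. The
#' protection set for a child is the consensus-branch set of the
#' sub-population of the parent it was grafted into (for copies, the
#' parent's own set).
#'
#' @param trees List of `N` parent trees.
#' @param objectives `N x 2` matrix of raw parent objectives.
#' @param assignment Sub-population index per parent (from
#'   [redistribute()]).
#' @param protected_sets List (one per sub-population) of protected split
#'   keys; use empty sets for the non-consensus ablation.
#' @param config A [run_config()].
#' @param ref A `"reference_points"` object.
#' @return List of `N` offspring records, each a list with `tree`,
#'   `objectives` (numeric or `NULL` if the tree needs scoring) and
#'   `protection` (the split keys used).
#' @export
make_offspring <- function(trees, objectives, assignment, protected_sets,
                           config, ref) {
  N <- length(trees)
  offspring <- vector("list", N)
  count <- 0L
  while (count < N) {
    i <- tournament_pick(objectives, ref)
    j <- tournament_pick(objectives, ref)
    if (stats::runif(1) < config$crossover_prob) {
      prot_j <- protected_sets[[assignment[j]]]
      prot_i <- protected_sets[[assignment[i]]]
      c1 <- pdg_crossover(trees[[i]], trees[[j]], prot_j, config$t_max)
      c2 <- pdg_crossover(trees[[j]], trees[[i]], prot_i, config$t_max)
      kids <- list(
        list(tree = c1,
             objectives = if (isTRUE(attr(c1, "pdg_fallback"))) objectives[j, ] else NULL,
             protection = prot_j),
        list(tree = c2,
             objectives = if (isTRUE(attr(c2, "pdg_fallback"))) objectives[i, ] else NULL,
             protection = prot_i))
    } else {
      kids <- list(
        list(tree = trees[[i]], objectives = objectives[i, ],
             protection = protected_sets[[assignment[i]]]),
        list(tree = trees[[j]], objectives = objectives[j, ],
             protection = protected_sets[[assignment[j]]]))
    }
    for (kid in kids) {
      if (count >= N) break
      if (stats::runif(1) < config$mutation_prob) {
        mutated <- nni_mutation(kid$tree, kid$protection)
        if (isTRUE(attr(mutated, "nni_changed"))) kid$objectives <- NULL
        kid$tree <- mutated
      }
      attr(kid$tree, "pdg_fallback") <- NULL
      attr(kid$tree, "nni_changed") <- NULL
      count <- count + 1L
      offspring[[count]] <- kid
    }
  }
  offspring
}
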