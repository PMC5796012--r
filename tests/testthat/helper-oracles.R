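# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: parsimony and likelihood enumerate internal-node state
# assignments directly, splits are found by deleting an edge and
# flood-filling the adjacency graph, the hypervolume is a Riemann sum.

BASES <- c("A", "C", "G", "T")

# state set (indices into BASES) encoded by a 4-bit mask
mask_states <- function(mask) which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)

# minimum number of changes for one pattern by exhaustive enumeration over
# internal-node states; a tip contributes 0 if its state set contains the
# parent state, else 1 (tips are optimized independently given the parent)
oracle_fitch_pattern <- function(tree, masks_col) {
  ntip <- ape::Ntip(tree)
  E <- tree$edge
  internal <- sort(unique(E[E > ntip]))
  m <- length(internal)
  best <- Inf
  for (code in 0:(4L^m - 1L)) {
    st <- integer(max(E))
    rest <- code
    for (i in seq_len(m)) {
      st[internal[i]] <- rest %% 4L + 1L
      rest <- rest %/% 4L
    }
    cost <- 0L
    for (k in seq_len(nrow(E))) {
      p <- E[k, 1L]; ch <- E[k, 2L]
      if (ch <= ntip) {
        if (!(st[p] %in% mask_states(masks_col[ch]))) cost <- cost + 1L
      } else if (st[p] != st[ch]) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

# same enumeration, vectorized over the 4^m internal assignments (for the
# larger acceptance batches)
oracle_fitch_fast <- function(tree, patterns) {
  ntip <- ape::Ntip(tree)
  E <- tree$edge
  internal <- sort(unique(E[E > ntip]))
  m <- length(internal)
  A <- as.matrix(expand.grid(rep(list(1:4), m)))
  masks <- patterns$masks[match(tree$tip.label, patterns$taxa), , drop = FALSE]
  bits <- c(1L, 2L, 4L, 8L)
  total <- 0
  for (j in seq_along(patterns$weights)) {
    cost <- integer(nrow(A))
    for (k in seq_len(nrow(E))) {
      pcol <- A[, match(E[k, 1L], internal)]
      ch <- E[k, 2L]
      if (ch <= ntip) {
        allowed <- bitwAnd(masks[ch, j], bits) > 0L
        cost <- cost + !allowed[pcol]
      } else {
        cost <- cost + (pcol != A[, match(ch, internal)])
      }
    }
    total <- total + patterns$weights[j] * min(cost)
  }
  total
}

oracle_fitch <- function(tree, patterns) {
  masks <- patterns$masks[match(tree$tip.label, patterns$taxa), , drop = FALSE]
  sum(vapply(seq_along(patterns$weights), function(j)
    oracle_fitch_pattern(tree, masks[, j]) * patterns$weights[j], numeric(1)))
}

# likelihood by direct summation over all internal-node state combinations
# (single rate category); transition matrices from ape's matexpo
oracle_loglik <- function(tree, patterns, model, rate = 1) {
  ntip <- ape::Ntip(tree)
  tr <- reorder(tree, "postorder")
  E <- tr$edge
  root <- E[nrow(E), 1L]
  internal <- sort(unique(E[E > ntip]))
  m <- length(internal)
  masks <- patterns$masks[match(tree$tip.label, patterns$taxa), , drop = FALSE]
  P <- lapply(seq_len(nrow(E)), function(k)
    ape::matexpo(model$Q * rate * tr$edge.length[k]))
  pi <- unname(model$frequencies)
  ll <- 0
  for (j in seq_along(patterns$weights)) {
    lik <- 0
    for (code in 0:(4L^m - 1L)) {
      st <- integer(max(E))
      rest <- code
      for (i in seq_len(m)) {
        st[internal[i]] <- rest %% 4L + 1L
        rest <- rest %/% 4L
      }
      term <- pi[st[root]]
      for (k in seq_len(nrow(E))) {
        p <- E[k, 1L]; ch <- E[k, 2L]
        term <- term * if (ch <= ntip)
          sum(P[[k]][st[p], mask_states(masks[ch, j])])
        else P[[k]][st[p], st[ch]]
      }
      lik <- lik + term
    }
    ll <- ll + patterns$weights[j] * log(lik)
  }
  ll
}

# splits by edge deletion + flood fill over the adjacency graph; returns
# canonical "a,b|c,d" strings (each side sorted, sides ordered so the one
# with the lexicographically smallest taxon comes first)
oracle_splits <- function(tree) {
  ntip <- ape::Ntip(tree)
  E <- tree$edge
  out <- character(0)
  for (k in seq_len(nrow(E))) {
    keep <- E[-k, , drop = FALSE]
    comp <- seq_len(ntip + tree$Nnode)
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(keep))) {
        a <- comp[keep[r, 1L]]; b <- comp[keep[r, 2L]]
        if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
      }
      if (!changed) break
    }
    side1 <- tree$tip.label[which(comp[seq_len(ntip)] == comp[E[k, 1L]])]
    side2 <- tree$tip.label[which(comp[seq_len(ntip)] == comp[E[k, 2L]])]
    if (length(side1) < 2L || length(side2) < 2L) next
    sides <- list(sort(side1), sort(side2))
    first <- if (min(side1) <= min(side2)) 1L else 2L
    out <- c(out, paste(paste(sides[[first]], collapse = ","),
                        paste(sides[[3L - first]], collapse = ","),
                        sep = "|"))
  }
  sort(unique(out))
}

# convert the package's canonical split keys to the oracle's string form
keys_to_oracle <- function(keys, taxa) {
  sort(vapply(keys, function(key) {
    side2 <- moearc:::split_labels(key, taxa)
    side1 <- sort(setdiff(taxa, side2))
    paste(paste(side1, collapse = ","), paste(side2, collapse = ","), sep = "|")
  }, character(1), USE.NAMES = FALSE))
}

# Riemann-sum hypervolume on a fine grid in the first objective
oracle_hypervolume <- function(front, ref, res = 1e-3) {
  if (is.null(dim(front))) front <- matrix(front, ncol = 2L)
  xs <- seq(min(front[, 1L]), ref[1L], by = res)
  xs <- xs[-length(xs)] + res / 2
  heights <- vapply(xs, function(x) {
    ok <- front[, 1L] <= x
    if (!any(ok)) return(0)
    max(0, ref[2L] - min(front[ok, 2L]))
  }, numeric(1))
  sum(heights) * res
}

# O(N^2) dominance filter (minimization), duplicates collapsed
oracle_pareto <- function(obj) {
  keep <- !duplicated(obj)
  idx <- which(keep)
  idx[vapply(idx, function(i) {
    !any(vapply(idx, function(j) {
      i != j && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
    }, logical(1)))
  }, logical(1))]
}

# random test alignment over the plain four bases (optionally with missing)
random_alignment <- function(taxa, nsites, p_missing = 0) {
  pool <- c(BASES, if (p_missing > 0) c("-", "N"))
  prob <- c(rep((1 - p_missing) / 4, 4),
            if (p_missing > 0) rep(p_missing / 2, 2))
  m <- matrix(sample(pool, length(taxa) * nsites, TRUE, prob = prob),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  m
}

# signature identifying an unrooted topology
topo_signature <- function(tree) paste(sort(bipartitions(tree)), collapse = "|")

# sides of compatible splits (excluding a fixed taxon) must form a laminar
# family, which is exactly tree-realizability
is_laminar <- function(keys) {
  sets <- lapply(keys, function(k) which(moearc:::key_to_logical(k)))
  if (length(sets) < 2L) return(TRUE)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i >= j) next
    a <- sets[[i]]; b <- sets[[j]]
    inter <- length(intersect(a, b))
    if (inter > 0L && inter < min(length(a), length(b))) return(FALSE)
  }
  TRUE
}

# a tiny fixed benchmark shared by several test files
small_benchmark <- function() make_benchmark(n_taxa = 10L, length = 200L, seed = 7L)
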