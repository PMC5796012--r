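## Unrooted binary tree handling built on ape's "phylo" representation.
## All trees in a run share one taxon set; internally a tree is stored with
## an arbitrary basal trichotomy (ape's unrooted convention) but every
## user-visible quantity (bipartitions, scores) is invariant to that choice.

#' Parse a Newick string into an unrooted binary tree
#'
#' Reads a Newick description, collapses a degree-2 root if present (the
#' two root edges are merged and their lengths summed), and validates that
#' the result is a fully resolved unrooted tree: `n` leaves, `n - 2`
#' internal nodes and `2n - 3` edges for `n >= 3`.
#'
#' @param text A single Newick string (trailing semicolon optional).
#' @param default_branch_length Length assigned to edges whose length is
#'   missing in the input. Must be non-negative; the default 0.1 keeps
#'   likelihood finite on length-less input.
#' @return An object of class `"phylo"` (unrooted, binary, with
#'   `edge.length` set on every edge).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
#' bipartitions(tr, as_labels = TRUE)
#' @export
parse_newick <- function(text, default_branch_length = 0.1) {
  stopifnot(is.character(text), length(text) == 1L)
  if (default_branch_length < 0)
    stop("'default_branch_length' must be non-negative")
  if (!grepl(";", text)) text <- paste0(text, ";")
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick string: '", text, "'")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  if (ape::Ntip(tree) < 3L)
    stop("a tree needs at least 3 leaves, got ", ape::Ntip(tree))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  tree <- as_unrooted(tree)
  validate_phylo_tree(tree)
  tree
}

#' Write a tree as a canonical Newick string
#'
#' The output uses a deterministic orientation: the tree is traversed from
#' the internal node adjacent to the lexicographically smallest leaf and at
#' every internal node children are ordered by the smallest leaf label in
#' their subtree. Two trees with the same unrooted topology, labels and
#' branch lengths therefore print identically, which makes outputs diffable.
#'
#' @param tree A `"phylo"` tree as produced by [parse_newick()] or
#'   [random_tree()].
#' @param digits Number of significant digits for branch lengths.
#' @return A single Newick string (with trailing semicolon).
#' @export
write_newick <- function(tree, digits = 10) {
  tree <- as_unrooted(tree)
  validate_phylo_tree(tree)
  ntip <- ape::Ntip(tree)
  root_tip <- order(tree$tip.label)[1L]
  ## adjacency over the undirected tree
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  elen <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b); elen[[a]] <- c(elen[[a]], tree$edge.length[k])
    adj[[b]] <- c(adj[[b]], a); elen[[b]] <- c(elen[[b]], tree$edge.length[k])
  }
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  ## recursive writer returning c(newick, min tip label) for the subtree
  walk <- function(node, parent) {
    if (node <= ntip)
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    kids <- adj[[node]][adj[[node]] != parent]
    lens <- elen[[node]][adj[[node]] != parent]
    parts <- lapply(kids, walk, parent = node)
    ord <- order(vapply(parts, `[[`, character(1), "min"))
    pieces <- vapply(seq_along(ord), function(i) {
      j <- ord[i]
      paste0(parts[[j]]$str, ":", fmt(lens[j]))
    }, character(1))
    list(str = paste0("(", paste(pieces, collapse = ","), ")"),
         min = min(vapply(parts, `[[`, character(1), "min")))
  }
  ## start from the internal node next to the reference tip so the
  ## orientation does not depend on how the tree happens to be stored
  anchor <- adj[[root_tip]][1L]
  stem <- elen[[root_tip]][1L]
  inner <- walk(anchor, root_tip)
  paste0("(", tree$tip.label[root_tip], ":", fmt(stem), ",",
         substring(inner$str, 2L, nchar(inner$str) - 1L), ");")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Every internal edge of an unrooted tree splits the taxa into two sets of
#' at least two; these splits identify the tree's branches for consensus
#' purposes. Keys are canonical: a split is encoded as a 0/1 membership
#' string over the lexicographically sorted taxon set, flipped so that the
#' smallest taxon is always on the 0 side.
#'
#' @param tree A `"phylo"` tree.
#' @param as_labels If `TRUE`, return a list of character vectors (the
#'   taxa on the canonical side) instead of key strings.
#' @return A character vector of canonical split keys (empty for `n < 4`),
#'   with attribute `"taxa"` carrying the sorted taxon set, or a list of
#'   label vectors when `as_labels = TRUE`.
#' @export
bipartitions <- function(tree, as_labels = FALSE) {
  ntip <- ape::Ntip(tree)
  taxa <- sort(tree$tip.label)
  if (ntip < 4L) {
    out <- character(0)
    attr(out, "taxa") <- taxa
    return(if (as_labels) list() else out)
  }
  tr <- stats::reorder(tree, "postorder")
  pos <- match(tree$tip.label, taxa)   # tip i -> position in sorted taxa
  nnode <- ntip + tr$Nnode
  member <- matrix(FALSE, nnode, ntip)
  member[cbind(seq_len(ntip), pos)] <- TRUE
  keys <- character(0)
  E <- tr$edge
  for (k in seq_len(nrow(E))) {
    ch <- E[k, 2L]
    member[E[k, 1L], ] <- member[E[k, 1L], ] | member[ch, ]
    if (ch > ntip) {
      sz <- sum(member[ch, ])
      if (sz >= 2L && sz <= ntip - 2L)
        keys <- c(keys, split_key(member[ch, ]))
    }
  }
  keys <- unique(keys)
  if (as_labels) return(lapply(keys, split_labels, taxa = taxa))
  attr(keys, "taxa") <- taxa
  keys
}

## canonical key for a logical membership vector over the sorted taxon set:
## flip so the first (lexicographically smallest) taxon is excluded
split_key <- function(member) {
  if (member[1L]) member <- !member
  paste(as.integer(member), collapse = "")
}

## decode a key back to taxon labels (the canonical side)
split_labels <- function(key, taxa) {
  taxa[strsplit(key, "", fixed = TRUE)[[1L]] == "1"]
}

key_to_logical <- function(key) {
  strsplit(key, "", fixed = TRUE)[[1L]] == "1"
}

#' Generate a uniformly random unrooted binary tree topology
#'
#' Builds the topology by sequential random edge attachment: starting from
#' the unique 3-leaf tree, each further leaf is attached to an edge chosen
#' uniformly at random, which yields every unrooted binary topology on the
#' given taxa with equal probability. Branch lengths are drawn from
#' `branch_fn`. Randomness comes from R's global RNG; call [set.seed()]
#' for reproducibility.
#'
#' @param taxa Character vector of at least 3 unique leaf labels.
#' @param branch_fn Function taking a count and returning that many
#'   non-negative branch lengths; default exponential with mean 0.1
#'   substitutions/site.
#' @return A `"phylo"` tree.
#' @export
random_tree <- function(taxa, branch_fn = function(k) stats::rexp(k, rate = 10)) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("taxa must be unique")
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa, got ", n)
  root <- n + 1L
  parent <- c(root, root, root)
  child <- c(1L, 2L, 3L)
  next_internal <- n + 2L
  for (i in seq_len(n)[-(1:3)]) {
    r <- sample.int(length(parent), 1L)
    w <- next_internal; next_internal <- next_internal + 1L
    old_child <- child[r]
    child[r] <- w
    parent <- c(parent, w, w)
    child <- c(child, old_child, i)
  }
  tree <- structure(list(
    edge = cbind(parent, child, deparse.level = 0),
    tip.label = taxa,
    Nnode = n - 2L,
    edge.length = branch_fn(2L * n - 3L)
  ), class = "phylo")
  storage.mode(tree$edge) <- "integer"
  tree <- stats::reorder(tree, "cladewise")
  validate_phylo_tree(tree)
  tree
}

#' @rdname parse_newick
#' @param path Path to a file of Newick trees, one per line.
#' @return `read_trees()` returns a list of `"phylo"` trees.
#' @export
read_trees <- function(path, default_branch_length = 0.1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees found in '", path, "'")
  lapply(lines, parse_newick, default_branch_length = default_branch_length)
}

## --- internal helpers --------------------------------------------------

## normalize any phylo into the package's unrooted storage form
as_unrooted <- function(tree) {
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree) && ape::Ntip(tree) >= 3L) tree <- ape::unroot(tree)
  storage.mode(tree$edge) <- "integer"
  attr(tree, "order") <- NULL
  tree <- stats::reorder(tree, "cladewise")
  tree
}

## check the closed-form node/edge counts of an unrooted binary tree
validate_phylo_tree <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 3L) stop("tree has fewer than 3 leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree")
  if (tree$Nnode != n - 2L)
    stop("tree is not a fully resolved unrooted tree: expected ",
         n - 2L, " internal nodes, found ", tree$Nnode)
  if (nrow(tree$edge) != 2L * n - 3L)
    stop("tree is not a fully resolved unrooted tree: expected ",
         2L * n - 3L, " edges, found ", nrow(tree$edge))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  invisible(tree)
}

## tips (as tip indices) below the child end of each edge, in edge order
clade_tips_per_edge <- function(tree) {
  ntip <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tr$Nnode
  member <- matrix(FALSE, nnode, ntip)
  member[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(tr$edge)))
    member[tr$edge[k, 1L], ] <- member[tr$edge[k, 1L], ] | member[tr$edge[k, 2L], ]
  ## map back to the original edge order
  ord <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
               paste(tr$edge[, 1L], tr$edge[, 2L]))
  lapply(ord, function(k) which(member[tr$edge[k, 2L], ]))
}
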