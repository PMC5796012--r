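## Sequence simulation along a known tree under the same GTR+GAMMA model
## the likelihood assumes: a root sequence is drawn from the stationary
## frequencies, each site gets one gamma-category rate (constant across the
## tree), and states evolve edge by edge through the transition matrices.
## This gives self-contained benchmark inputs with known ground truth.

#' Simulate a DNA alignment on a tree
#'
#' @param tree A `"phylo"` tree with non-negative branch lengths.
#' @param model A [gtr_model()].
#' @param length Number of sites (>= 1).
#' @return Character matrix alignment (taxa x sites) over A/C/G/T, rows in
#'   the tree's tip order. Uses R's global RNG; seed for reproducibility.
#' @export
simulate_alignment <- function(tree, model, length) {
  stopifnot(inherits(model, "gtr_model"))
  validate_phylo_tree(tree)
  length <- as.integer(length)
  if (length < 1L) stop("'length' must be >= 1")
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  E <- tr$edge
  root <- E[nrow(E), 1L]
  site_cat <- sample.int(model$ncat, length, replace = TRUE)
  states <- matrix(NA_integer_, nnode, length)
  states[root, ] <- sample.int(4L, length, replace = TRUE,
                               prob = model$frequencies)
  ## preorder = reverse postorder: parents are filled before children
  for (k in rev(seq_len(nrow(E)))) {
    p <- E[k, 1L]; ch <- E[k, 2L]
    for (cat in unique(site_cat)) {
      P <- gtr_transition_matrix(model, tr$edge.length[k],
                                 model$category_rates[cat])
      cols <- which(site_cat == cat)
      for (s in 1:4) {
        cs <- cols[states[p, cols] == s]
        if (length(cs))
          states[ch, cs] <- sample.int(4L, length(cs), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  }
  aln <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(aln) <- tree$tip.label
  aln
}

#' Build a reproducible synthetic benchmark
#'
#' Draws a uniformly random tree with exponential(mean 0.1) branch lengths,
#' a mildly randomized GTR+GAMMA model (Dirichlet-like frequencies around
#' 1/4, exchangeabilities between 0.5 and 2, gamma shape 1, 4 categories), and an
#' alignment simulated on that tree -- the self-contained stand-in for an
#' empirical dataset, with known ground truth.
#'
#' @param n_taxa Number of taxa (>= 4); labels are `t01, t02, ...`.
#' @param length Alignment length in sites.
#' @param seed Integer seed controlling everything.
#' @param dir If non-`NULL`, the fixture is written there:
#'   `alignment.fasta`, `true_tree.nwk`, `model.json`.
#' @return List with `tree`, `alignment`, `model` and `seed`.
#' @export
make_benchmark <- function(n_taxa = 20L, length = 500L, seed = 42L,
                           dir = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 4L) stop("'n_taxa' must be >= 4")
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  tree <- random_tree(taxa, branch_fn = function(k) stats::rexp(k, rate = 10))
  freqs <- stats::runif(4, 0.15, 0.35)
  freqs <- freqs / sum(freqs)
  model <- gtr_model(frequencies = freqs,
                     rates = stats::runif(6, 0.5, 2),
                     alpha = 1.0, ncat = 4L)
  aln <- simulate_alignment(tree, model, length)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(aln, file.path(dir, "alignment.fasta"))
    writeLines(write_newick(tree), file.path(dir, "true_tree.nwk"))
    write_model_json(model, file.path(dir, "model.json"))
  }
  list(tree = tree, alignment = aln, model = model, seed = seed)
}
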