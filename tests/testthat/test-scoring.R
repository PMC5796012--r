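# helper: the smallest tree the pruning recursion accepts -- two tips
# joined through one internal node (used for the closed-form checks)
two_taxon_tree <- function(t1, t2, labels = c("a", "b")) {
  structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = c(t1, t2),
                 tip.label = labels, Nnode = 1L),
            class = "phylo")
}

patterns_from_chars <- function(...) {
  rows <- list(...)
  compress_patterns(do.call(rbind, rows))
}

test_that("fitch parsimony reproduces the quartet hand examples", {
  tr <- parse_newick("((A,B),(C,D));")
  p1 <- compress_patterns(matrix(c("A", "A", "G", "G"), 4, 1,
                                 dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(fitch_parsimony(tr, p1), 1L)
  p2 <- compress_patterns(matrix(c("A", "G", "A", "G"), 4, 1,
                                 dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(fitch_parsimony(tr, p2), 2L)
  p3 <- compress_patterns(matrix("C", 4, 5,
                                 dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(fitch_parsimony(tr, p3), 0L)
})

test_that("fitch parsimony equals exhaustive enumeration on random instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:7, 1)
    taxa <- paste0("t", seq_len(n))
    tr <- random_tree(taxa)
    pat <- compress_patterns(random_alignment(taxa, sample(3:10, 1),
                                              p_missing = 0.1))
    expect_equal(fitch_parsimony(tr, pat), oracle_fitch(tr, pat))
  }
})

test_that("transition matrix satisfies P(0)=I, stochasticity, detailed balance,
           Chapman-Kolmogorov and the stationary limit", {
  set.seed(9)
  model <- gtr_model(frequencies = c(0.35, 0.15, 0.25, 0.25),
                     rates = c(0.5, 2.1, 0.8, 1.3, 3.0, 1.0), alpha = 0.5)
  expect_equal(unname(gtr_transition_matrix(model, 0)), diag(4),
               tolerance = 1e-12)
  pi <- unname(model$frequencies)
  for (i in 1:20) {
    s <- runif(1, 0, 2); t <- runif(1, 0, 2); r <- runif(1, 0.2, 3)
    P <- gtr_transition_matrix(model, t, r)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    # detailed balance pi_i P_ij = pi_j P_ji
    F <- diag(pi) %*% P
    expect_equal(F, t(F), tolerance = 1e-10, ignore_attr = TRUE)
    # Chapman-Kolmogorov against the independent matrix exponential
    PsPt <- gtr_transition_matrix(model, s, r) %*% P
    expect_equal(unname(PsPt),
                 unname(gtr_transition_matrix(model, s + t, r)),
                 tolerance = 1e-10)
    expect_equal(unname(P), ape::matexpo(model$Q * r * t), tolerance = 1e-9)
  }
  Pinf <- gtr_transition_matrix(model, 100)
  for (i in 1:4) expect_equal(unname(Pinf[i, ]), pi, tolerance = 1e-6)
})

test_that("zero-distance two-taxon likelihood hits the L log(1/4) limit", {
  tr <- two_taxon_tree(0, 0)
  L <- 17L
  aln <- matrix("G", 2, L, dimnames = list(c("a", "b"), NULL))
  pat <- compress_patterns(aln)
  model <- gtr_model(ncat = 1)
  expect_equal(log_likelihood(tr, pat, model, bl_floor = 0), L * log(0.25),
               tolerance = 1e-12)
})

test_that("two-taxon pattern probabilities match the closed-form JC formula", {
  model <- gtr_model(ncat = 1)  # equal frequencies, equal exchangeabilities
  bases <- c("A", "C", "G", "T")
  for (t in c(0.05, 0.3, 1.2)) {
    tr <- two_taxon_tree(t / 3, 2 * t / 3)
    p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    p_diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    for (x in bases) for (y in bases) {
      aln <- matrix(c(x, y), 2, 1, dimnames = list(c("a", "b"), NULL))
      expected <- 0.25 * (if (x == y) p_same else p_diff)
      expect_equal(log_likelihood(tr, compress_patterns(aln), model,
                                  bl_floor = 0),
                   log(expected), tolerance = 1e-8)
    }
  }
})

test_that("pruning equals brute-force state enumeration on 4-5 taxon trees", {
  set.seed(15)
  for (i in 1:25) {
    n <- sample(4:5, 1)
    taxa <- paste0("t", seq_len(n))
    tr <- random_tree(taxa)
    pat <- compress_patterns(random_alignment(taxa, 6, p_missing = 0.1))
    model <- gtr_model(frequencies = runif(4, 0.5, 1.5),
                       rates = runif(6, 0.3, 3), ncat = 1)
    got <- log_likelihood(tr, pat, model, bl_floor = 0)
    want <- oracle_loglik(tr, pat, model)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant to rerooting and leaf order", {
  set.seed(23)
  bm <- small_benchmark()
  pat <- compress_patterns(bm$alignment)
  base <- log_likelihood(bm$tree, pat, bm$model)
  for (tip in c("t03", "t08")) {
    rerooted <- ape::unroot(ape::root(bm$tree, outgroup = tip,
                                      resolve.root = TRUE))
    expect_equal(log_likelihood(rerooted, pat, bm$model), base,
                 tolerance = 1e-9)
  }
  perm <- sample(nrow(bm$alignment))
  expect_equal(log_likelihood(bm$tree,
                              compress_patterns(bm$alignment[perm, ]),
                              bm$model),
               base, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  bm <- small_benchmark()
  dat <- phangorn::phyDat(bm$alignment)
  fit <- phangorn::pml(bm$tree, dat,
                       bf = unname(bm$model$frequencies),
                       Q = unname(bm$model$rates),
                       shape = bm$model$alpha, k = bm$model$ncat)
  expect_equal(log_likelihood(bm$tree, compress_patterns(bm$alignment),
                              bm$model, bl_floor = 0),
               as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("a constant column adds exactly its own site log-likelihood and no
           parsimony", {
  set.seed(12)
  taxa <- paste0("t", 1:6)
  tr <- random_tree(taxa)
  aln <- random_alignment(taxa, 40)
  model <- default_model(aln, ncat = 4)
  cc <- matrix("T", length(taxa), 1, dimnames = list(taxa, NULL))
  aln2 <- cbind(aln, cc)
  expect_identical(fitch_parsimony(tr, compress_patterns(aln2)),
                   fitch_parsimony(tr, compress_patterns(aln)))
  delta <- log_likelihood(tr, compress_patterns(aln2), model) -
    log_likelihood(tr, compress_patterns(aln), model)
  expect_equal(delta, log_likelihood(tr, compress_patterns(cc), model),
               tolerance = 1e-9)
})

test_that("normalization maps the reference box onto the unit square", {
  ref <- update_reference_points(NULL, rbind(c(10, 100), c(20, 300)))
  expect_equal(normalize_objectives(c(10, 100), ref), c(0, 0))
  expect_equal(normalize_objectives(c(20, 300), ref), c(1, 1))
  expect_equal(normalize_objectives(c(15, 200), ref), c(0.5, 0.5))
  # degenerate span maps to 0
  flat <- update_reference_points(NULL, rbind(c(5, 1), c(5, 2)))
  expect_equal(normalize_objectives(c(5, 1.5), flat), c(0, 0.5))
})

test_that("reference points are monotone running extremes, order-independent", {
  set.seed(2)
  obs <- matrix(rnorm(60), ncol = 2)
  ref <- update_reference_points(NULL, obs[1:10, ])
  # updates within the current box change nothing
  inside <- rbind(ref$z + 0.25 * (ref$znad - ref$z))
  expect_identical(update_reference_points(ref, inside), ref)
  # sequential updates equal one bulk update regardless of order
  seq1 <- update_reference_points(NULL, obs[1:10, ])
  for (i in 11:30) seq1 <- update_reference_points(seq1, obs[i, ])
  seq2 <- NULL
  for (i in sample(30)) seq2 <- update_reference_points(seq2, obs[i, ])
  bulk <- update_reference_points(NULL, obs)
  expect_equal(seq1, bulk)
  expect_equal(seq2, bulk)
  # and monotonicity
  expect_true(all(seq1$z <= ref$z) && all(seq1$znad >= ref$znad))
})
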