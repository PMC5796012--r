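## General time-reversible substitution model with discrete-gamma rate
## variation. The rate matrix is normalized to one expected substitution
## per unit branch length at stationarity, and transition probabilities are
## computed from the eigendecomposition of the symmetrized generator.

GTR_RATE_ORDER <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a GTR+GAMMA substitution model
#'
#' @param frequencies Stationary base frequencies in order A, C, G, T;
#'   strictly positive, normalized internally to sum to 1.
#' @param rates Six symmetric exchangeabilities in order
#'   AC, AG, AT, CG, CT, GT; strictly positive, scale-free.
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param ncat Number of discrete gamma categories (>= 1); with
#'   `ncat = 1` rate variation is disabled.
#' @return An object of class `"gtr_model"` with the normalized rate
#'   matrix `Q`, its eigendecomposition and the per-category rates.
#' @examples
#' jc <- gtr_model()                      # Jukes-Cantor as a special case
#' gtr_transition_matrix(jc, t = 0.1)
#' @export
gtr_model <- function(frequencies = rep(0.25, 4), rates = rep(1, 6),
                      alpha = 1.0, ncat = 4L) {
  if (length(frequencies) != 4L || any(!is.finite(frequencies)) ||
      any(frequencies <= 0))
    stop("'frequencies' must be 4 positive numbers (A, C, G, T)")
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be 6 positive exchangeabilities (",
         paste(GTR_RATE_ORDER, collapse = ", "), ")")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("'ncat' must be >= 1")
  pi <- frequencies / sum(frequencies)
  names(pi) <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    Q[i, j] <- rates[k] * pi[j]
    Q[j, i] <- rates[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))            # mean rate at stationarity
  Q <- Q / mu
  ## reversible Q is similar to a symmetric matrix: S = D^1/2 Q D^-1/2
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  model <- list(
    frequencies = pi,
    rates = stats::setNames(rates / rates[6L], GTR_RATE_ORDER),
    alpha = alpha,
    ncat = ncat,
    Q = Q,
    U = diag(1 / d) %*% eig$vectors,
    Uinv = t(eig$vectors) %*% diag(d),
    eigenvalues = eig$values,
    category_rates = discrete_gamma_rates(alpha, ncat)
  )
  class(model) <- "gtr_model"
  model
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+GAMMA model\n")
  cat("  frequencies:", paste(sprintf("%s=%.4f", names(x$frequencies),
                                      x$frequencies), collapse = " "), "\n")
  cat("  exchangeabilities:", paste(sprintf("%s=%.4f", GTR_RATE_ORDER,
                                            x$rates), collapse = " "), "\n")
  cat("  alpha:", x$alpha, " categories:", x$ncat,
      " rates:", paste(sprintf("%.4f", x$category_rates), collapse = " "), "\n")
  invisible(x)
}

#' Mean-of-bin discrete gamma category rates
#'
#' Divides the mean-1 gamma(shape = alpha, rate = alpha) distribution into
#' `ncat` equal-probability bins and returns each bin's conditional mean;
#' the rates therefore average exactly 1.
#'
#' @inheritParams gtr_model
#' @return Numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat) {
  ncat <- as.integer(ncat)
  if (ncat == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = ncat + 1L),
                          shape = alpha, rate = alpha)
  ## E[X | bin] via the incomplete-gamma identity for gamma(alpha, alpha)
  cdf1 <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  ncat * diff(cdf1)
}

#' GTR transition probability matrix
#'
#' Computes `P(r t) = exp(Q r t)` from the stored eigendecomposition of the
#' normalized generator. Rows sum to 1 and the matrix satisfies detailed
#' balance with respect to the stationary frequencies.
#'
#' @param model A [gtr_model()].
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param rate Site-rate multiplier (> 0), e.g. a gamma category rate.
#' @return A 4x4 stochastic matrix over states A, C, G, T.
#' @export
gtr_transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "gtr_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (!is.finite(rate) || rate <= 0) stop("'rate' must be > 0")
  P <- model$U %*% (exp(model$eigenvalues * rate * t) * model$Uinv)
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Default model from an alignment
#'
#' Empirical base frequencies (counting unambiguous residues only, with a
#' uniform fallback if a base is unseen), all exchangeabilities equal and
#' gamma shape 1 -- a neutral starting point when no externally estimated
#' parameters are supplied.
#'
#' @param aln Character matrix alignment.
#' @inheritParams gtr_model
#' @return A `"gtr_model"`.
#' @export
default_model <- function(aln, alpha = 1.0, ncat = 4L) {
  validate_alignment(aln)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(aln == b), numeric(1))
  if (any(counts == 0)) counts <- counts + 1
  gtr_model(frequencies = counts / sum(counts), alpha = alpha, ncat = ncat)
}

#' Read substitution-model parameters from a YAML or JSON config file
#'
#' Recognized fields: `frequencies` (4 numbers, A C G T), `rates`
#' (6 numbers, AC AG AT CG CT GT), `alpha`, `ncat`. Missing fields fall
#' back to the [gtr_model()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"gtr_model"`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path)
  gtr_model(
    frequencies = if (!is.null(cfg$frequencies)) as.numeric(cfg$frequencies) else rep(0.25, 4),
    rates = if (!is.null(cfg$rates)) as.numeric(cfg$rates) else rep(1, 6),
    alpha = if (!is.null(cfg$alpha)) as.numeric(cfg$alpha) else 1.0,
    ncat = if (!is.null(cfg$ncat)) as.integer(cfg$ncat) else 4L
  )
}

#' Write model parameters to JSON
#'
#' @param model A `"gtr_model"`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gtr_model"))
  jsonlite::write_json(
    list(frequencies = unname(model$frequencies),
         rates = unname(model$rates),
         alpha = model$alpha,
         ncat = model$ncat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
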