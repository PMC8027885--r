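#' Per-sample ancestry proportions
#'
#' Container for an n x K matrix of ancestry proportions (rows on the
#' simplex), with a scope flag distinguishing autosomal from X-chromosome
#' estimates.
#'
#' @param Q Numeric n x K matrix; each row must sum to 1 within 1e-6
#'   (rows of all-NA are allowed, e.g. samples without X data).
#' @param scope `"autosomal"` or `"X"`.
#' @return Object of class `admix_proportions`.
#' @export
admix_proportions <- function(Q, scope = c("autosomal", "X")) {
  scope <- match.arg(scope)
  Q <- as.matrix(Q)
  ok <- stats::complete.cases(Q)
  if (any(Q[ok, ] < -1e-9 | Q[ok, ] > 1 + 1e-9))
    stop("Q entries must lie in [0, 1]")
  if (any(abs(rowSums(Q[ok, , drop = FALSE]) - 1) > 1e-6))
    stop("Q rows must sum to 1 within 1e-6")
  structure(list(Q = Q, scope = scope), class = "admix_proportions")
}

#' @export
print.admix_proportions <- function(x, ...) {
  cat("admix_proportions (", x$scope, "): ", nrow(x$Q), " samples x ",
      ncol(x$Q), " ancestries\n", sep = "")
  print(utils::head(round(x$Q, 4), 4))
  if (nrow(x$Q) > 4) cat("...\n")
  invisible(x)
}

#' Supervised ancestry-proportion estimation by EM
#'
#' Maximum-likelihood estimation of each individual's ancestry proportions
#' q under the binomial admixture model with known ancestral allele
#' frequencies: genotype g_l ~ Binomial(ploidy, q . f_l) independently
#' across loci. The EM update is the standard ADMIXTURE-style step
#' restricted to the Q coordinates (F held at the supplied truth), which
#' makes the log-likelihood non-decreasing and keeps q on the simplex.
#'
#' @param G n x L genotype dosage matrix (NA = missing).
#' @param freqs An `ancestral_freqs` object or bare K x L matrix of
#'   ancestral allele frequencies, strictly inside (0, 1).
#' @param ploidy Scalar or length-n vector (2 autosomal; 1 for male X).
#' @param tol Convergence threshold on max |delta q| (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An `admix_proportions` with attributes `converged` (logical
#'   per sample) and `loglik` (final log-likelihood per sample).
#' @export
estimate_ancestry_supervised <- function(G, freqs, ploidy = 2, tol = 1e-6,
                                         max_iter = 500L) {
  f <- if (inherits(freqs, "ancestral_freqs")) freqs$freq else as.matrix(freqs)
  if (any(f <= 0 | f >= 1)) stop("ancestral frequencies must lie in (0, 1)")
  K <- nrow(f)
  n <- nrow(G)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, n)
  Q <- matrix(1 / K, n, K)
  converged <- logical(n)
  loglik <- numeric(n)
  for (i in seq_len(n)) {
    g <- G[i, ]
    obs <- which(!is.na(g))
    g <- as.numeric(g[obs])
    fo <- f[, obs, drop = FALSE]
    m <- ploidy[i]
    q <- rep(1 / K, K)
    if (K == 1L) {
      Q[i, ] <- 1
      converged[i] <- TRUE
      loglik[i] <- sum(g * log(fo[1, ]) + (m - g) * log1p(-fo[1, ]))
      next
    }
    for (it in seq_len(max_iter)) {
      mu <- as.numeric(q %*% fo)              # q . f_l
      # E-step responsibilities folded into the multiplicative update
      alt_term <- (q * fo) %*% (g / mu)        # K-vector
      ref_term <- (q * (1 - fo)) %*% ((m - g) / (1 - mu))
      q_new <- as.numeric(alt_term + ref_term) / (m * length(g))
      q_new <- q_new / sum(q_new)
      delta <- max(abs(q_new - q))
      q <- q_new
      if (delta < tol) break
    }
    converged[i] <- delta < tol
    if (!converged[i])
      warning("sample ", i, ": EM did not converge in ", max_iter,
              " iterations; last iterate returned")
    mu <- as.numeric(q %*% fo)
    loglik[i] <- sum(g * log(mu) + (m - g) * log1p(-mu))
    Q[i, ] <- q
  }
  rownames(Q) <- rownames(G)
  colnames(Q) <- rownames(f)
  out <- admix_proportions(Q, scope = "autosomal")
  attr(out, "converged") <- converged
  attr(out, "loglik") <- loglik
  out
}

# Per-iteration log-likelihood of one sample (used by tests to check EM
# monotonicity without touching the estimator's internals).
admixture_loglik <- function(g, f, q, ploidy = 2) {
  obs <- which(!is.na(g))
  mu <- as.numeric(q %*% f[, obs, drop = FALSE])
  sum(g[obs] * log(mu) + (ploidy - g[obs]) * log1p(-mu))
}
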