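#' Greedy windowed LD pruning
#'
#' PLINK-style pruning: within each window of `window` variants the later
#' variant of any pair with squared Pearson genotype correlation above
#' `r2_threshold` is dropped; the window then slides forward by `step`
#' variants. Windows never span chromosomes. Missing genotypes are handled
#' with pairwise-complete correlations.
#'
#' @param G n x L genotype matrix (NA allowed).
#' @param r2_threshold Squared-correlation cutoff (default 0.5).
#' @param window Window size in variants (default 50).
#' @param step Window slide in variants (default 5).
#' @param chrom Optional per-variant chromosome labels.
#' @return Integer vector of retained variant indices.
#' @export
ld_prune <- function(G, r2_threshold = 0.5, window = 50L, step = 5L,
                     chrom = NULL) {
  if (window < 2L || window < step) stop("window must be >= 2 and >= step")
  L <- ncol(G)
  if (is.null(chrom)) chrom <- rep("1", L)
  # Standardize once (missing dosages imputed at the variant mean, i.e.
  # contributing zero to the correlation); window correlations then reduce
  # to crossproducts.
  Z <- sweep(G, 2L, colMeans(G, na.rm = TRUE))
  Z[is.na(Z)] <- 0
  sdv <- sqrt(colSums(Z^2) / (nrow(G) - 1L))
  zero_var <- sdv == 0 | is.na(sdv)
  sdv[zero_var] <- 1
  Z <- sweep(Z, 2L, sdv, "/")
  Z[, zero_var] <- 0
  keep <- rep(TRUE, L)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win_live <- win[keep[win]]
      if (length(win_live) >= 2L) {
        r2 <- (crossprod(Z[, win_live, drop = FALSE]) / (nrow(G) - 1L))^2
        for (a in seq_len(length(win_live) - 1L)) {
          if (!keep[win_live[a]]) next
          hit <- which(r2[a, ] > r2_threshold)
          hit <- hit[hit > a]
          for (b in hit) {
            ib <- win_live[b]
            if (keep[ib]) keep[ib] <- FALSE
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  which(keep)
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per variant; each variant is centered
#' by twice its estimated allele frequency and scaled by the binomial
#' standard deviation sqrt(2 p (1 - p)); monomorphic variants are excluded.
#' Coordinates come from the eigendecomposition of the sample covariance of
#' the standardized matrix (computed via SVD). Column signs are fixed by
#' making the entry of largest magnitude in each component positive.
#'
#' @param G n x L genotype dosage matrix.
#' @param n_pcs Number of components to return.
#' @return Object of class `pca_result`: list with `coords` (n x n_pcs),
#'   `eigenvalues` (non-increasing), `variants_used` (indices).
#' @export
genotype_pca <- function(G, n_pcs = 10L) {
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 samples")
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  poly <- which(p_hat > 0 & p_hat < 1 & !is.na(p_hat))
  if (!length(poly)) stop("no polymorphic variants")
  if (n_pcs > min(n - 1L, length(poly)))
    stop("n_pcs exceeds min(n - 1, number of usable variants)")
  X <- G[, poly, drop = FALSE]
  mu <- 2 * p_hat[poly]
  sdv <- sqrt(2 * p_hat[poly] * (1 - p_hat[poly]))
  X <- sweep(X, 2L, mu)
  nas <- which(is.na(X))
  if (length(nas)) X[nas] <- 0          # mean imputation after centering
  X <- sweep(X, 2L, sdv, "/")
  if (ncol(X) > 2L * n) {
    # wide matrix: eigendecompose the n x n Gram matrix instead of a full SVD
    ee <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(ee$values, 0))
    coords <- ee$vectors[, seq_len(n_pcs), drop = FALSE] *
      rep(d[seq_len(n_pcs)], each = n)
  } else {
    sv <- svd(X, nu = n_pcs, nv = 0)
    d <- sv$d
    coords <- sv$u * rep(d[seq_len(n_pcs)], each = n)
  }
  for (j in seq_len(n_pcs)) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  eig <- d^2 / (n - 1)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  rownames(coords) <- rownames(G)
  structure(list(coords = coords, eigenvalues = eig[seq_len(n_pcs)],
                 variants_used = poly),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pv <- x$eigenvalues / sum(x$eigenvalues)
  cat("genotype PCA:", nrow(x$coords), "samples,", length(x$variants_used),
      "variants\n  leading eigenvalue shares:",
      paste(sprintf("%.3f", utils::head(pv, 5)), collapse = " "), "\n")
  invisible(x)
}
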