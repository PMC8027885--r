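#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly-upper-triangle entries, with a
#' one-sided permutation null built by jointly permuting the rows and
#' columns of `D2`. The p-value uses the add-one estimator
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1), so p >= 1/(n_perm + 1).
#'
#' @param D1,D2 Symmetric matrices with matching dimnames (or matching
#'   order if unnamed).
#' @param n_perm Number of permutations (default 9999); ignored when
#'   `exact = TRUE`.
#' @param seed Optional seed.
#' @param exact Enumerate all n! label permutations instead of sampling
#'   (feasible for small n only, n <= 8); the p-value is then the exact
#'   fraction of permutations (identity included) with r at least as
#'   large as observed.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `r_perm` (the permutation distribution).
#' @export
mantel_test <- function(D1, D2, n_perm = 9999L, seed = NULL, exact = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (n < 3L) stop("need at least 3 labels")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2)))
      stop("distance matrices have mismatched labels")
    D2 <- D2[rownames(D1), rownames(D1)]
  } else if (!all(dim(D1) == dim(D2))) stop("dimension mismatch")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(D1)
  r_obs <- stats::cor(D1[ut], D2[ut])
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, function(pm)
      stats::cor(D1[ut], D2[pm, pm][ut]))
    p <- mean(r_perm >= r_obs - 1e-12)
    return(structure(list(r = r_obs, p = p, n_perm = nrow(perms),
                          r_perm = r_perm),
                     class = "mantel_result"))
  }
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    r_perm[b] <- stats::cor(D1[ut], D2[pm, pm][ut])
  }
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = n_perm, r_perm = r_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Procrustes superimposition test of two 2-D configurations
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' orthogonal transform (rotation, optionally with reflection) and scaling
#' minimizing the residual sum of squares m2 are found from the SVD of the
#' cross-product matrix. The association statistic is r = sqrt(1 - m2).
#' Significance comes from permuting the rows of `Y` (one-sided, add-one
#' estimator, as in the Mantel test).
#'
#' @param X,Y Numeric matrices with the same number of rows (>= 3), 2
#'   columns each (e.g. PC1-PC2 versus lon/lat).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional seed.
#' @param allow_reflection Include improper rotations (default TRUE); when
#'   the optimum is ambiguous the proper rotation (det = +1) is preferred.
#' @return List of class `procrustes_result`: `m2`, `r`, `r2`, `p`,
#'   `n_perm`, `rotation`, `scale`.
#' @export
procrustes_test <- function(X, Y, n_perm = 9999L, seed = NULL,
                            allow_reflection = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("row count mismatch")
  if (nrow(X) < 3L) stop("need at least 3 rows")
  if (!is.null(seed)) set.seed(seed)
  fit <- procrustes_m2(X, Y, allow_reflection)
  m2_perm <- numeric(n_perm)
  for (b in seq_len(n_perm))
    m2_perm[b] <- procrustes_m2(X, Y[sample.int(nrow(Y)), , drop = FALSE],
                                allow_reflection)$m2
  p <- (1 + sum(m2_perm <= fit$m2)) / (n_perm + 1)
  structure(list(m2 = fit$m2, r = sqrt(max(0, 1 - fit$m2)),
                 r2 = max(0, 1 - fit$m2), p = p, n_perm = n_perm,
                 rotation = fit$rotation, scale = fit$scale),
            class = "procrustes_result")
}

procrustes_m2 <- function(X, Y, allow_reflection = TRUE) {
  std <- function(M) {
    M <- sweep(M, 2L, colMeans(M))
    ss <- sum(M^2)
    if (ss <= 0) {
      warning("rank-deficient (constant) configuration")
      return(M)
    }
    M / sqrt(ss)
  }
  Xs <- std(X); Ys <- std(Y)
  sv <- svd(crossprod(Xs, Ys))
  d <- sv$d
  R <- sv$v %*% t(sv$u)
  if (!allow_reflection && det(R) < 0) {
    # restrict to proper rotations: flip the smallest singular direction
    sgn <- diag(c(rep(1, length(d) - 1L), -1))
    R <- sv$v %*% sgn %*% t(sv$u)
    d[length(d)] <- -d[length(d)]
  }
  s <- sum(d)                      # optimal scaling (unit-ss configurations)
  m2 <- max(0, 1 - s^2)
  list(m2 = m2, rotation = R, scale = s)
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4f, r = %.4f, r2 = %.4f, p = %.4g (%d permutations)\n",
              x$m2, x$r, x$r2, x$p, x$n_perm))
  invisible(x)
}
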