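#' Weir-Cockerham F_ST between two populations
#'
#' Per-locus variance components of Weir & Cockerham (1984) for r = 2
#' populations: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), computed from per-population
#' sample sizes, allele frequencies and observed heterozygote frequencies.
#' The overall estimate is the ratio of averages
#' theta = sum(a) / sum(a + b + c); loci where the denominator is zero or
#' undefined are skipped. Missing genotypes are excluded per locus.
#'
#' @param G n x L genotype dosage matrix (0/1/2, NA = missing).
#' @param labels Length-n population labels.
#' @param popA,popB The two population labels to compare.
#' @return List with `theta` (overall), `components` (L x 3 matrix of a, b,
#'   c; NA where skipped), `per_locus` (a / (a+b+c) per locus), `n_loci`
#'   used.
#' @export
weir_cockerham_fst <- function(G, labels, popA, popB) {
  rows <- list(which(labels == popA), which(labels == popB))
  if (any(lengths(rows) < 2L)) stop("need >= 2 samples per population")
  L <- ncol(G)
  comp <- matrix(NA_real_, L, 3L, dimnames = list(NULL, c("a", "b", "c")))
  r <- 2
  for (l in seq_len(L)) {
    n_i <- p_i <- h_i <- numeric(r)
    ok <- TRUE
    for (j in 1:2) {
      g <- G[rows[[j]], l]
      g <- g[!is.na(g)]
      if (length(g) < 2L) { ok <- FALSE; break }
      n_i[j] <- length(g)
      p_i[j] <- mean(g) / 2
      h_i[j] <- mean(g == 1L)
    }
    if (!ok) next
    n_bar <- mean(n_i)
    n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    p_bar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / sum(n_i)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    comp[l, ] <- c(a, b, cc)
  }
  denom <- rowSums(comp)
  use <- which(!is.na(denom) & denom != 0)
  if (!length(use)) stop("no locus with a defined F_ST denominator")
  theta <- sum(comp[use, "a"]) / sum(denom[use])
  per_locus <- comp[, "a"] / denom
  per_locus[!is.finite(per_locus)] <- NA_real_
  list(theta = theta, components = comp, per_locus = per_locus,
       n_loci = length(use))
}

#' Pairwise F_ST distance matrix over groups
#'
#' Entry (i, j) is the overall Weir-Cockerham theta for the pair. The
#' matrix used as a distance floors negative estimates at zero; the raw
#' (possibly negative) values are kept in the `raw` attribute.
#'
#' @param G Genotype matrix.
#' @param labels Group labels per sample.
#' @return Symmetric matrix with zero diagonal and group dimnames;
#'   attribute `raw` holds unfloored values.
#' @export
pairwise_fst_matrix <- function(G, labels) {
  grp <- unique(labels)
  if (length(grp) < 2L) stop("need at least two groups")
  k <- length(grp)
  D <- matrix(0, k, k, dimnames = list(grp, grp))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    th <- weir_cockerham_fst(G, labels, grp[i], grp[j])$theta
    D[i, j] <- D[j, i] <- th
  }
  raw <- D
  D[D < 0] <- 0
  attr(D, "raw") <- raw
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration: repeatedly merge the closest pair of
#' clusters, with inter-cluster distance the size-weighted average of
#' member distances. Node heights are half the merge distance, so the tree
#' is ultrametric. Ties are broken by the lexicographically smallest pair
#' of cluster labels.
#'
#' @param D Symmetric distance matrix with dimnames (zero diagonal);
#'   asymmetric input (beyond 1e-8) is an error.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
upgma_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least two labels")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  labs <- rownames(D)
  if (is.null(labs)) labs <- colnames(D) <- rownames(D) <- paste0("t", seq_len(nrow(D)))
  active <- labs
  newick <- stats::setNames(labs, labs)       # partial newick per cluster
  height <- stats::setNames(numeric(length(labs)), labs)
  size <- stats::setNames(rep(1L, length(labs)), labs)
  min_leaf <- stats::setNames(labs, labs)     # for child ordering in output
  Dw <- D
  while (length(active) >= 2L) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      pair <- sort(c(active[i], active[j]))
      d <- Dw[active[i], active[j]]
      if (is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(d = d, a = active[i], b = active[j], pair = pair)
      }
    }
    h <- best$d / 2
    new_lab <- paste0("(", best$a, "|", best$b, ")")
    kids <- c(best$a, best$b)
    kids <- kids[order(min_leaf[kids])]       # stable child order
    newick[new_lab] <- paste0("(", newick[kids[1]], ":",
                              format(h - height[kids[1]], digits = 12), ",",
                              newick[kids[2]], ":",
                              format(h - height[kids[2]], digits = 12), ")")
    height[new_lab] <- h
    size[new_lab] <- size[best$a] + size[best$b]
    min_leaf[new_lab] <- min(min_leaf[kids])
    others <- setdiff(active, c(best$a, best$b))
    Dnew <- matrix(0, length(others) + 1L, length(others) + 1L,
                   dimnames = list(c(others, new_lab), c(others, new_lab)))
    if (length(others)) {
      Dnew[others, others] <- Dw[others, others]
      dm <- (size[best$a] * Dw[others, best$a] +
               size[best$b] * Dw[others, best$b]) /
        (size[best$a] + size[best$b])
      Dnew[others, new_lab] <- Dnew[new_lab, others] <- dm
    }
    Dw <- Dnew
    active <- c(others, new_lab)
    if (length(active) == 1L) break
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Ultrametricity check for a rooted tree
#' @param tree An `ape::phylo`.
#' @param tol Tolerance on root-to-leaf path-length differences.
#' @return TRUE/FALSE.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol
}
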