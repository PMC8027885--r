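test_that("LD pruning drops duplicates and matches a brute-force scan", {
  set.seed(1)
  G <- matrix(rbinom(100 * 30, 2, 0.4), 100, 30)
  G <- cbind(G[, 1:3], G[, 3], G[, 4:30])  # duplicate adjacent to column 3
  kept <- ld_prune(G, window = 10, step = 2)
  expect_true(3 %in% kept)
  expect_false(4 %in% kept)

  # independent variants: nothing pruned
  set.seed(2)
  Gi <- matrix(rbinom(200 * 40, 2, 0.3), 200, 40)
  expect_equal(ld_prune(Gi), seq_len(40))

  # oracle equivalence on a correlated 200-SNP panel
  set.seed(3)
  n <- 150
  base <- matrix(rbinom(n * 200, 2, 0.5), n, 200)
  for (j in seq(2, 200, by = 3)) {  # plant strong LD with the previous SNP
    base[, j] <- ifelse(stats::runif(n) < 0.9, base[, j - 1], base[, j])
  }
  brute <- function(G, r2 = 0.5, window = 50, step = 5) {
    keep <- rep(TRUE, ncol(G))
    start <- 1
    repeat {
      win <- start:min(start + window - 1, ncol(G))
      for (a in win) for (b in win) {
        if (b <= a || !keep[a] || !keep[b]) next
        Z <- G
        Z[is.na(Z)] <- NA
        r <- suppressWarnings(stats::cor(G[, a], G[, b]))
        if (!is.na(r) && r^2 > r2) keep[b] <- FALSE
      }
      if (start + window - 1 >= ncol(G)) break
      start <- start + step
    }
    which(keep)
  }
  expect_equal(ld_prune(base), brute(base))
})

test_that("genotype PCA matches an SVD oracle and separates clusters", {
  set.seed(5)
  # two clusters of duplicated genotype rows
  r1 <- rbinom(60, 2, 0.5); r2 <- rbinom(60, 2, 0.5)
  G2 <- rbind(matrix(rep(r1, 10), 10, byrow = TRUE),
              matrix(rep(r2, 10), 10, byrow = TRUE))
  pc <- genotype_pca(G2, 2)
  s1 <- pc$coords[1:10, 1]; s2 <- pc$coords[11:20, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))

  # SVD oracle (independently standardized)
  set.seed(6)
  G <- matrix(rbinom(40 * 300, 2, stats::runif(300, 0.1, 0.9)),
              40, 300, byrow = TRUE)
  pc <- genotype_pca(G, 5)
  p_hat <- colMeans(G) / 2
  use <- p_hat > 0 & p_hat < 1
  X <- sweep(G[, use], 2, 2 * p_hat[use])
  X <- sweep(X, 2, sqrt(2 * p_hat[use] * (1 - p_hat[use])), "/")
  sv <- svd(X)
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  for (j in 1:5) {
    expect_true(max(abs(pc$coords[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(pc$coords[, j] + oracle[, j])) < 1e-8)
  }
  expect_equal(pc$eigenvalues, (sv$d[1:5])^2 / (nrow(G) - 1),
               tolerance = 1e-10)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))

  # monomorphic variants are excluded, not fatal
  Gm <- cbind(G, 0L)
  pcm <- genotype_pca(Gm, 3)
  expect_equal(abs(pcm$coords), abs(genotype_pca(G, 3)$coords),
               tolerance = 1e-10)
})

test_that("Weir-Cockerham components match hand-evaluated formulas", {
  # 10-individual toy data, two loci; frozen values from an independent
  # step-by-step evaluation of the published variance components
  G <- rbind(matrix(c(0, 1, 1, 2, 2,  1, 2, 0, 1, 2), 5),
             matrix(c(0, 0, 1, 0, 1,  0, 1, 0, 0, 0), 5))
  labels <- rep(c("A", "B"), each = 5)
  res <- weir_cockerham_fst(G, labels, "A", "B")
  expect_equal(unname(res$components[1, ]), c(0.055, 0.025, 0.200),
               tolerance = 1e-12)
  expect_equal(unname(res$components[2, ]), c(0.1025, 0.0375, 0.150),
               tolerance = 1e-12)
  expect_equal(res$theta, 0.276315789474, tolerance = 1e-9)

  # same numbers from the in-suite hand oracle
  for (l in 1:2) {
    expect_equal(unname(res$components[l, ]),
                 unname(wc_hand(G[1:5, l], G[6:10, l])), tolerance = 1e-12)
  }
})

test_that("F_ST hits its boundary cases", {
  # complete differentiation
  G <- rbind(matrix(2L, 10, 20), matrix(0L, 10, 20))
  labels <- rep(c("A", "B"), each = 10)
  expect_equal(weir_cockerham_fst(G, labels, "A", "B")$theta, 1)
  # popB an exact copy of popA's genotype multiset
  set.seed(8)
  GA <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50)
  expect_lte(weir_cockerham_fst(rbind(GA, GA), labels, "A", "B")$theta, 0.01)
})

test_that("pairwise F_ST matrix is consistent and recovers drift F", {
  cfg <- two_group_config(q_ks = c(0.1, 0.1), n = c(40L, 40L), L = 600L,
                          drift = 0.05, seed = 13)
  co <- simulate_genotypes(cfg, keep_ancestry = FALSE)
  G <- co$dataset$G
  labels <- co$dataset$samples$group
  D <- pairwise_fst_matrix(G, labels)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  raw <- attr(D, "raw")
  expect_equal(raw["G1", "G2"],
               weir_cockerham_fst(G, labels, "G1", "G2")$theta)
  expect_error(pairwise_fst_matrix(G, rep("A", nrow(G))), "two groups")
})

test_that("UPGMA reproduces the 3-taxon closed form and stays ultrametric", {
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(D)
  expect_equal(ape::write.tree(tr), "((A:0.5,B:0.5):1.5,C:2);")
  expect_true(is_ultrametric_tree(tr))

  # oracle equivalence on random matrices: same topology and heights as
  # average-linkage agglomeration in stats::hclust
  for (s in 1:5) {
    set.seed(s)
    M <- matrix(stats::runif(36), 6)
    D6 <- as.matrix(stats::dist(M))
    dimnames(D6) <- list(letters[1:6], letters[1:6])
    tr6 <- upgma_tree(D6)
    hc <- stats::hclust(stats::as.dist(D6), method = "average")
    tr_hc <- ape::as.phylo(hc)
    expect_true(ape::all.equal.phylo(tr6, tr_hc, use.edge.length = FALSE))
    co_a <- ape::cophenetic.phylo(tr6)
    co_b <- ape::cophenetic.phylo(tr_hc)
    expect_equal(co_a[rownames(co_b), colnames(co_b)], co_b,
                 tolerance = 1e-9)
    expect_true(is_ultrametric_tree(tr6))
  }
  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("Weiszfeld geometric median matches a grid-search oracle", {
  p0 <- data.frame(lat = rep(-26.2, 4), lon = rep(28.0, 4))
  expect_equal(geometric_median(p0), c(lat = -26.2, lon = 28.0),
               tolerance = 1e-7)

  # equilateral-ish triangle about the equator: symmetric -> centroid
  tri <- data.frame(lat = c(0, 0, sqrt(3) / 2), lon = c(-0.5, 0.5, 0))
  gm <- geometric_median(tri)
  expect_equal(unname(gm["lon"]), 0, tolerance = 1e-6)
  expect_equal(unname(gm["lat"]), sqrt(3) / 6, tolerance = 1e-3)

  pts <- data.frame(lat = c(-25, -29, -33, -26), lon = c(28, 26, 19, 32))
  w <- c(3, 1, 1, 2)
  gm <- geometric_median(pts, w)
  lat_grid <- seq(-33, -25, by = 1e-3)
  lon_grid <- seq(19, 32, by = 1e-3)
  obj <- function(lat, lon) {
    lat0 <- sum(w * pts$lat) / sum(w)
    sx <- cos(lat0 * pi / 180)
    sum(w * sqrt(((pts$lon - lon) * sx)^2 + (pts$lat - lat)^2))
  }
  # localized grid around the returned optimum (full grid is wasteful)
  lat_g <- lat_grid[abs(lat_grid - gm["lat"]) < 0.05]
  lon_g <- lon_grid[abs(lon_grid - gm["lon"]) < 0.05]
  vals <- outer(lat_g, lon_g, Vectorize(obj))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(lat_g[best[1]] - gm["lat"]), 2e-3)
  expect_lt(abs(lon_g[best[2]] - gm["lon"]), 2e-3)
  expect_error(geometric_median(pts, c(0, 0, 0, 0)), "weights")
})

test_that("great-circle distances match the spherical closed forms", {
  p <- c(lat = -26, lon = 28)
  expect_equal(great_circle_distance(p, p), 0)
  expect_equal(great_circle_distance(c(lat = 0, lon = 0),
                                     c(lat = 0, lon = 180)),
               pi * 6371, tolerance = 1e-6)
  expect_equal(great_circle_distance(c(lat = 0, lon = 0),
                                     c(lat = 0, lon = 90)),
               pi * 6371 / 2, tolerance = 1e-6)
})

test_that("Mantel test: affine invariance, exact enumeration, p floor", {
  set.seed(17)
  D1 <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5)))
  D2 <- 2 * D1 + 3
  diag(D2) <- 0
  mt <- mantel_test(D1, D2, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_gte(mt$p, 1 / 100)

  # exhaustive enumeration over all 24 permutations of a 4x4 problem
  set.seed(18)
  A <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
  B <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
  ex <- mantel_test(A, B, exact = TRUE)
  perms <- rbind(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- as.matrix(perms[apply(perms, 1, function(x) length(unique(x)) == 4), ])
  ut <- upper.tri(A)
  r_obs <- stats::cor(A[ut], B[ut])
  r_all <- apply(perms, 1, function(pm) stats::cor(A[ut], B[pm, pm][ut]))
  expect_equal(ex$p, mean(r_all >= r_obs - 1e-12))
  expect_equal(ex$r, r_obs)
})

test_that("Mantel statistic agrees with vegan and null p is calibrated", {
  skip_if_not_installed("vegan")
  set.seed(19)
  D1 <- as.matrix(stats::dist(matrix(stats::rnorm(14), 7)))
  D2 <- as.matrix(stats::dist(matrix(stats::rnorm(14), 7)))
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 3)
  vg <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                      permutations = 999)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)

  # null calibration: p roughly uniform over replicates
  ps <- replicate(200, {
    X <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6)))
    Y <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6)))
    mantel_test(X, Y, n_perm = 199)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Procrustes test recognizes superposable and rotated configurations", {
  set.seed(23)
  X <- matrix(stats::rnorm(18), 9, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3.2 * X %*% R
  pr <- procrustes_test(X, Y, n_perm = 499, seed = 4)
  expect_equal(pr$m2, 0, tolerance = 1e-12)
  expect_equal(pr$r, 1, tolerance = 1e-9)
  expect_equal(pr$p, 1 / 500)

  # invariance of the statistic under a global rotation of X
  Y2 <- matrix(stats::rnorm(18), 9, 2)
  a <- procrustes_test(X, Y2, n_perm = 49, seed = 5)
  b <- procrustes_test(X %*% R, Y2, n_perm = 49, seed = 5)
  expect_equal(a$m2, b$m2, tolerance = 1e-12)

  # rotation-grid oracle: best m2 over a fine sweep of rotation angles
  std <- function(M) { M <- sweep(M, 2, colMeans(M)); M / sqrt(sum(M^2)) }
  Xs <- std(X); Ys <- std(Y2)
  angles <- seq(0, 2 * pi, by = 1e-4)
  best <- Inf
  for (flip in list(diag(2), diag(c(1, -1)))) {
    Yf <- Ys %*% flip
    cp <- crossprod(Xs, Yf)
    # optimal scale for a given rotation: s = trace(R' X'Y); m2 = 1 - s^2
    s_vals <- cp[1, 1] * cos(angles) + cp[2, 2] * cos(angles) +
      (cp[2, 1] - cp[1, 2]) * sin(angles)
    best <- min(best, 1 - max(s_vals)^2)
  }
  expect_equal(a$m2, best, tolerance = 1e-6)
})

test_that("PCA-vs-geography Procrustes correlation rises as noise falls", {
  skip_if_not_installed("vegan")
  set.seed(29)
  geo <- cbind(lon = stats::runif(8, 18, 32), lat = stats::runif(8, -34, -22))
  r2_at <- function(noise) {
    Y <- geo + matrix(stats::rnorm(16, sd = noise), 8, 2)
    procrustes_test(geo, Y, n_perm = 49, seed = 6)$r2
  }
  r2s <- vapply(c(5, 1, 0.1, 0.001), r2_at, 1)
  expect_true(all(diff(r2s) > 0))
  expect_gt(r2s[4], 0.999)

  # statistic agrees with vegan::protest on the same configurations
  Y <- geo + matrix(stats::rnorm(16, sd = 1), 8, 2)
  ours <- procrustes_test(geo, Y, n_perm = 199, seed = 7)
  vg <- vegan::protest(geo, Y, permutations = 199)
  expect_equal(ours$r, unname(vg$t0), tolerance = 1e-10)
})
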