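test_that("QC filter applies missingness, MAF and HWE rules", {
  set.seed(1)
  n <- 100
  ok <- rbinom(n, 2, 0.3)
  mono <- rep(0L, n)                                  # MAF = 0
  hwe_bad <- rep(c(0L, 2L), each = n / 2)             # no hets at p = 0.5
  missing_heavy <- ok
  missing_heavy[1:10] <- NA                           # 10% missing
  G <- cbind(ok, mono, hwe_bad, missing_heavy)
  keep <- qc_filter(G)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE, FALSE))

  # hand-checked HWE chi-square for (50, 0, 50): expected (25, 50, 25)
  stat <- (50 - 25)^2 / 25 * 2 + 50
  expect_equal(unname(stratsim:::hwe_chisq_p(50, 0, 50)),
               stats::pchisq(stat, 1, lower.tail = FALSE))
  # defaults follow standard array QC
  f <- formals(qc_filter)
  expect_equal(f$miss_max, 0.05)
  expect_equal(f$maf_min, 0.01)
  expect_equal(f$hwe_p_min, 1e-4)
  expect_error(qc_filter(cbind(mono)), "all variants")
})

test_that("trait-label assignment respects all four scheme contracts", {
  set.seed(2)
  meta <- data.frame(
    id = sprintf("S%04d", 1:3000),
    site = sample(c("AGT", "DKG", "SWT"), 3000, TRUE),
    group = sample(c("Tswana", "Tsonga", "Zulu"), 3000, TRUE))
  n_min <- min(table(meta$site))
  n <- as.integer(n_min - 10)

  a1 <- assign_trait_labels(meta, "category1",
                            list(site_case = "AGT", site_control = "SWT",
                                 n = n), seed = 3)
  expect_length(a1$case, n)
  expect_length(a1$control, n)
  expect_length(intersect(a1$case, a1$control), 0)
  expect_true(all(meta$site[match(a1$case, meta$id)] == "AGT"))
  expect_true(all(meta$site[match(a1$control, meta$id)] == "SWT"))

  a2 <- assign_trait_labels(meta, "category2",
                            list(site_a = "AGT", site_b = "SWT",
                                 mix_fraction = 0.375, n = 400L), seed = 4)
  case_sites <- meta$site[match(a2$case, meta$id)]
  expect_equal(sum(case_sites == "AGT"), round(0.375 * 400))
  expect_true(all(meta$site[match(a2$control, meta$id)] == "SWT"))
  expect_length(intersect(a2$case, a2$control), 0)

  a3 <- assign_trait_labels(meta, "category3",
                            list(site = "SWT", excluded_group = "Tswana",
                                 n = 300L), seed = 5)
  expect_false(any(meta$group[match(a3$case, meta$id)] == "Tswana"))
  expect_gt(sum(meta$group[match(a3$control, meta$id)] == "Tswana"), 0)

  a4 <- assign_trait_labels(meta, "category4",
                            list(site = "DKG", n_case = 200L,
                                 n_control = 200L), seed = 6)
  expect_true(all(meta$site[match(c(a4$case, a4$control), meta$id)] == "DKG"))

  # reproducibility and infeasibility
  expect_identical(assign_trait_labels(meta, "category1",
                                       list(site_case = "AGT",
                                            site_control = "SWT", n = n),
                                       seed = 3), a1)
  expect_error(assign_trait_labels(meta, "category1",
                                   list(site_case = "AGT",
                                        site_control = "SWT", n = 5000L),
                                   seed = 7), "insufficient")
})

test_that("allelic chi-square matches hand-computed 2x2 values", {
  # cases: 50 het + 50 hom-alt (150 alt / 50 ref); controls: 100 het
  G <- rbind(matrix(c(rep(1, 50), rep(2, 50))),
             matrix(rep(1, 100)))
  G <- cbind(c(rep(1, 50), rep(2, 50), rep(1, 100)))
  rownames(G) <- sprintf("S%03d", 1:200)
  asn <- structure(list(case = rownames(G)[1:100],
                        control = rownames(G)[101:200],
                        scheme = "manual", params = list(), seed = NULL),
                   class = "trait_assignment")
  tab <- assoc_test(G, asn, method = "allelic")
  expect_equal(tab$stat, 400 * (150 * 100 - 50 * 100)^2 /
                 (200 * 200 * 250 * 150))
  expect_equal(tab$stat, 26.6667, tolerance = 1e-4)

  # equal allele frequencies (controls an exact copy of the case multiset)
  block <- rep(c(0L, 1L, 2L, 1L), 25)
  G0 <- cbind(c(block, block))
  rownames(G0) <- rownames(G)
  tab0 <- assoc_test(G0, asn, method = "allelic")
  expect_equal(tab0$stat, 0)
  expect_equal(tab0$p, 1)
})

test_that("logistic Wald statistics match an independent IRLS oracle", {
  set.seed(8)
  n <- 50
  G <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  rownames(G) <- sprintf("S%03d", 1:n)
  cov1 <- stats::rnorm(n)
  asn <- structure(list(case = rownames(G)[1:25],
                        control = rownames(G)[26:50],
                        scheme = "manual", params = list(), seed = NULL),
                   class = "trait_assignment")
  tab <- assoc_test(G, asn, covariates = cbind(cov1), method = "logistic")
  y <- as.integer(rownames(G) %in% asn$case)
  for (l in 1:6) {
    or <- stats::glm(y ~ cov1 + G[, l], family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12))
    z_or <- summary(or)$coefficients["G[, l]", "z value"]
    expect_equal(tab$stat[l], z_or^2, tolerance = 1e-6)
    expect_equal(tab$beta[l], unname(stats::coef(or)["G[, l]"]),
                 tolerance = 1e-6)
  }
})

test_that("Firth fallback yields finite, converged fits under separation", {
  set.seed(9)
  x <- c(stats::rnorm(40, 3), stats::rnorm(40, -3))   # complete separation
  y <- rep(1:0, each = 40)
  g <- rbinom(80, 2, 0.4)
  f <- firth_logistic(cbind(1, x = x, g = g), y)
  expect_true(f$converged)
  expect_true(all(is.finite(f$beta)))
  expect_true(all(is.finite(f$se)))

  # on well-behaved data the penalized fit is close to plain ML
  set.seed(10)
  x2 <- stats::rnorm(300)
  y2 <- rbinom(300, 1, stats::plogis(0.3 + 0.8 * x2))
  fm <- firth_logistic(cbind(1, x = x2), y2)
  ml <- stats::glm(y2 ~ x2, family = stats::binomial())
  expect_equal(unname(fm$beta[2]), unname(stats::coef(ml)[2]),
               tolerance = 0.05)
})

test_that("genomic inflation factor follows the median definition", {
  tab <- data.frame(p = rep(0.5, 100), valid = TRUE)
  expect_equal(genomic_inflation(tab), 1)

  # scale equivariance: doubling every chi-square doubles lambda
  set.seed(11)
  x <- stats::rchisq(2000, 1)
  t1 <- data.frame(p = stats::pchisq(x, 1, lower.tail = FALSE), valid = TRUE)
  t2 <- data.frame(p = stats::pchisq(2 * x, 1, lower.tail = FALSE),
                   valid = TRUE)
  expect_equal(genomic_inflation(t2), 2 * genomic_inflation(t1),
               tolerance = 1e-9)

  # null calibration on uniform p-values
  set.seed(12)
  tu <- data.frame(p = stats::runif(1e5), valid = TRUE)
  expect_gt(genomic_inflation(tu), 0.98)
  expect_lt(genomic_inflation(tu), 1.02)
})

test_that("genomic control deflates exactly when lambda exceeds 1", {
  tab <- data.frame(variant = 1:3, stat = c(29.72, 5, 1), df = 1,
                    p = stats::pchisq(c(29.72, 5, 1), 1, lower.tail = FALSE),
                    beta = NA_real_, valid = TRUE)
  corr <- gc_correct(tab, lambda = 2)
  expect_equal(corr$stat[1], 14.86)
  expect_equal(corr$p[1], stats::pchisq(14.86, 1, lower.tail = FALSE))

  # lambda <= 1 leaves the table untouched
  expect_identical(gc_correct(tab, lambda = 0.9)$p, tab$p)

  # corrected table has lambda exactly 1; correction is idempotent there
  set.seed(13)
  infl <- data.frame(p = stats::pchisq(2.2 * stats::rchisq(5000, 1), 1,
                                       lower.tail = FALSE), valid = TRUE)
  infl$stat <- stats::qchisq(infl$p, 1, lower.tail = FALSE)
  infl$variant <- seq_len(nrow(infl)); infl$df <- 1; infl$beta <- NA
  g1 <- gc_correct(infl)
  expect_equal(genomic_inflation(g1), 1, tolerance = 1e-12)
  g2 <- gc_correct(g1)
  expect_equal(g2$p, g1$p)
})

test_that("significance tallies count below-threshold valid variants", {
  empty <- data.frame(p = numeric(), valid = logical())
  expect_equal(unname(tally_significant(empty)), c(0L, 0L))
  expect_equal(names(tally_significant(empty)), c("genomewide", "suggestive"))
  f <- formals(tally_significant)
  expect_equal(eval(f$thresholds), c(genomewide = 5e-8, suggestive = 1e-5))

  set.seed(14)
  p <- c(1e-9, 2e-6, 0.5, NA, 1e-10)
  tab <- data.frame(p = p, valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(tally_significant(tab)), c(sum(p[1] < 5e-8),
                                                 sum(p[1:2] < 1e-5)))
})

test_that("allelic and covariate-free logistic p-values agree in rank", {
  cfg <- two_group_config(q_ks = c(0.25, 0.02), n = c(120L, 120L),
                          L = 400L, seed = 15)
  co <- simulate_genotypes(cfg, keep_ancestry = FALSE)
  G <- co$dataset$G
  rownames(G) <- co$dataset$samples$id
  maf <- pmin(colMeans(G, na.rm = TRUE) / 2,
              1 - colMeans(G, na.rm = TRUE) / 2)
  G <- G[, maf > 0.05]
  asn <- assign_trait_labels(co$dataset$samples, "category1",
                             list(site_case = "S1", site_control = "S2",
                                  n = 100L), seed = 16)
  al <- assoc_test(G, asn, method = "allelic")
  lo <- assoc_test(G, asn, method = "logistic")
  ok <- al$valid & lo$valid
  expect_gt(stats::cor(al$p[ok], lo$p[ok], method = "spearman"), 0.99)
})

test_that("PC correction collapses to plain logistic when n_pcs = 0", {
  set.seed(17)
  G <- matrix(rbinom(150 * 60, 2, 0.4), 150, 60)
  rownames(G) <- sprintf("S%03d", 1:150)
  asn <- structure(list(case = rownames(G)[1:75],
                        control = rownames(G)[76:150],
                        scheme = "manual", params = list(), seed = NULL),
                   class = "trait_assignment")
  pc0 <- pc_corrected_assoc(G, asn, n_pcs = 0)
  plain <- assoc_test(G, asn, method = "logistic")
  expect_equal(pc0$stat, plain$stat, tolerance = 1e-12)
})

test_that("the GWAS suite is reproducible and calibrated under the null", {
  cfg <- homogeneous_config(n = 240L, L = 1500L, seed = 18)
  co <- simulate_genotypes(cfg, keep_ancestry = FALSE)
  scen <- list(list(name = "null", scheme = "category4",
                    params = list(site = "S", n_case = 120L,
                                  n_control = 120L)))
  s1 <- run_gwas_suite(co$dataset, scen, n_iter = 3, seed = 19)
  s2 <- run_gwas_suite(co$dataset, scen, n_iter = 3, seed = 19)
  expect_identical(s1$summary, s2$summary)
  expect_equal(median(s1$summary$lambda_raw), 1, tolerance = 0.12)
  expect_true(all(s1$summary$gw_raw == 0))
})
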