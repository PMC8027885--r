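#' Draw ancestral allele frequencies under the Balding-Nichols model
#'
#' For each locus a shared base frequency p is drawn uniformly from
#' `base_freq_range`; each ancestral component k then receives a frequency
#' f_k ~ Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k), so that
#' E[f_k] = p and Var[f_k] = F_k p (1 - p). Frequencies are clipped to
#' [0.001, 0.999] to avoid fixed loci that break downstream estimators.
#'
#' @param K Number of ancestral components.
#' @param L Number of loci.
#' @param F_anc Differentiation parameter(s) in (0,1); recycled to length K.
#' @param base_freq_range Range for the uniform base-frequency draw.
#' @param map Optional variant map (data frame with `chrom`, `bp`, `cM`);
#'   defaults to a single uniform-map chromosome.
#' @param seed Optional integer seed.
#' @param ancestry_names Optional row labels.
#' @return Object of class `ancestral_freqs`: list with `freq` (K x L
#'   matrix), `base` (length-L), `map`, `F_anc`.
#' @export
draw_ancestral_frequencies <- function(K, L, F_anc,
                                       base_freq_range = c(0.05, 0.95),
                                       map = NULL, seed = NULL,
                                       ancestry_names = NULL) {
  if (K < 1L || L < 1L) stop("K and L must be >= 1")
  if (length(F_anc) == 1L) F_anc <- rep(F_anc, K)
  if (any(F_anc <= 0 | F_anc >= 1)) stop("F_anc must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(L, base_freq_range[1], base_freq_range[2])
  freq <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    lam <- (1 - F_anc[k]) / F_anc[k]
    freq[k, ] <- stats::rbeta(L, p * lam, (1 - p) * lam)
  }
  freq <- pmin(pmax(freq, 0.001), 0.999)
  if (is.null(map))
    map <- data.frame(chrom = "1", bp = seq_len(L), cM = seq_len(L) * 1e-6)
  if (!is.null(ancestry_names)) rownames(freq) <- ancestry_names
  structure(list(freq = freq, base = p, map = map, F_anc = F_anc),
            class = "ancestral_freqs")
}

# Second Balding-Nichols layer: drift each ancestry's frequencies within a
# group by F_g around the ancestral value.
drift_frequencies <- function(freq, F_g) {
  if (F_g <= 0) return(freq)
  lam <- (1 - F_g) / F_g
  out <- matrix(stats::rbeta(length(freq), freq * lam, (1 - freq) * lam),
                nrow(freq), ncol(freq))
  pmin(pmax(out, 0.001), 0.999)
}

# Ancestry of one haplotype along one chromosome. Switch points form a
# Poisson process of rate g per Morgan; ancestry at the chromosome start and
# after each switch is drawn iid from q (silent same-ancestry switches
# allowed). `pos_M` are variant positions in Morgans.
hap_ancestry_chrom <- function(q, g, morgans, pos_M) {
  n_sw <- stats::rpois(1L, g * morgans)
  K <- length(q)
  if (n_sw == 0L) return(rep(sample.int(K, 1L, prob = q), length(pos_M)))
  breaks <- sort(stats::runif(n_sw, 0, morgans))
  anc <- sample.int(K, n_sw + 1L, replace = TRUE, prob = q)
  anc[findInterval(pos_M, breaks) + 1L]
}

#' Simulate local-ancestry tracts for a set of haplotypes
#'
#' Each haplotype's ancestry along each chromosome is a piecewise-constant
#' process: switch points are Poisson with rate `g` per Morgan and ancestry
#' is redrawn iid from `q` at the chromosome start and at every switch
#' point. Truth posteriors are 1 unless degraded via `posterior_noise`.
#'
#' @param q Length-K ancestry simplex (shared by all haplotypes), or an
#'   `n_haplotypes` x K matrix of per-haplotype proportions.
#' @param g Generations since admixture (switch rate per Morgan).
#' @param chromosomes Data frame with `name`, `bp_length`, `morgans` (and
#'   optionally `is_x`), as in [default_chromosomes()].
#' @param n_haplotypes Number of haplotypes.
#' @param L Number of variants (allocated across chromosomes proportional to
#'   physical length); ignored when `map` is supplied.
#' @param map Optional variant map (`chrom`, `bp`, `cM`).
#' @param seed Optional integer seed.
#' @param posterior_noise If > 0, posteriors are drawn from
#'   Beta(1/noise, 1) instead of being exactly 1.
#' @return Object of class `local_ancestry`: list with integer matrix `A`
#'   (haplotypes x variants, 1-based ancestry indices), posterior matrix
#'   `P`, variant `map`, and `haplotype` metadata.
#' @export
simulate_local_ancestry <- function(q, g, chromosomes = default_chromosomes(),
                                    n_haplotypes = 2L, L = 1000L, map = NULL,
                                    seed = NULL, posterior_noise = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(q))) {
    check_simplex(q, "q")
    qmat <- matrix(q, n_haplotypes, length(q), byrow = TRUE)
  } else {
    qmat <- as.matrix(q)
    n_haplotypes <- nrow(qmat)
    apply(qmat, 1L, check_simplex, what = "q")
  }
  if (g < 1) stop("g must be >= 1")
  if (is.null(map)) map <- build_variant_map(chromosomes, L)
  L <- nrow(map)
  A <- matrix(NA_integer_, n_haplotypes, L)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cr <- chromosomes[chromosomes$name == ch, ]
    pos_M <- map$cM[idx] / 100
    for (h in seq_len(n_haplotypes))
      A[h, idx] <- hap_ancestry_chrom(qmat[h, ], g, cr$morgans, pos_M)
  }
  P <- matrix(1, n_haplotypes, L)
  if (posterior_noise > 0)
    P[] <- stats::rbeta(length(P), 1 / posterior_noise, 1)
  structure(list(A = A, P = P, map = map,
                 haplotype = data.frame(sample = ceiling(seq_len(n_haplotypes) / 2),
                                        hap = rep(1:2, length.out = n_haplotypes))),
            class = "local_ancestry")
}

# Allocate L variants over chromosomes proportional to bp length; positions
# are sorted uniform draws, genetic positions interpolate the chromosome's
# total Morgan length (uniform map within chromosome). 1-based inclusive bp.
build_variant_map <- function(chromosomes, L) {
  w <- chromosomes$bp_length / sum(chromosomes$bp_length)
  n_per <- floor(L * w)
  rem <- L - sum(n_per)
  if (rem > 0) {
    extra <- order(L * w - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  pieces <- lapply(seq_len(nrow(chromosomes)), function(i) {
    n_i <- n_per[i]
    if (n_i == 0L) return(NULL)
    bp <- sort(sample.int(chromosomes$bp_length[i], n_i))
    data.frame(chrom = chromosomes$name[i], bp = bp,
               cM = bp / chromosomes$bp_length[i] * chromosomes$morgans[i] * 100,
               is_x = isTRUE(chromosomes$is_x[i]))
  })
  do.call(rbind, pieces)
}

#' Simulate an admixed, multi-site genotype cohort
#'
#' The full generator: draws ancestral frequencies (one Balding-Nichols
#' layer, `F_anc`), adds group-specific drift (second layer, `drift`),
#' simulates per-haplotype local-ancestry tracts (Poisson switches at rate
#' `g` per Morgan), and emits genotypes by drawing each haplotype's allele
#' from the frequency of its local ancestry in its group. Autosomal
#' haplotypes use the group's `q`; X haplotypes use the single-pulse
#' equilibrium expectation H_X = (2 s_f + s_m) / 3, and males carry one X
#' haplotype. Sample metadata includes site (sampled from the group's site
#' fractions), sex, self-reported ethnicity (the group) and six relative
#' ethnicities (2 parents + 4 grandparents) with independent mismatch
#' probability `ethnicity_mismatch_rate`.
#'
#' @param config A [sim_config()].
#' @param keep_ancestry Keep the haplotype-level local-ancestry matrix
#'   (memory: 2n x L integers). Set `FALSE` for large association-study
#'   simulations where only genotypes and realized ancestry are needed.
#' @param ethnicity_mismatch_rate Per-relative probability that a relative's
#'   ethnicity differs from the sample's group (default 0.2, under which
#'   about a third of samples have two or more mismatching relatives).
#' @return Object of class `sim_cohort`: list with `dataset` (a
#'   `genotype_dataset`), `ancestry` (a `local_ancestry` or `NULL`),
#'   `Q_auto` and `Q_X` (realized ancestry-dosage matrices, class
#'   `admix_proportions`), and the `config`.
#' @export
simulate_genotypes <- function(config, keep_ancestry = TRUE,
                               ethnicity_mismatch_rate = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$K
  map <- build_variant_map(config$chromosomes, config$L)
  L <- nrow(map)
  auto_idx <- which(!map$is_x)
  x_idx <- which(map$is_x)

  anc <- draw_ancestral_frequencies(K, L, config$F_anc,
                                    config$base_freq_range, map = map,
                                    ancestry_names = config$ancestry_names)

  groups <- config$groups
  n_total <- sum(vapply(groups, function(g) g$n, 1L))
  if (n_total == 0L) stop("no samples requested")

  G <- matrix(NA_integer_, n_total, L)
  A <- if (keep_ancestry) matrix(NA_integer_, 2L * n_total, L) else NULL
  Q_auto <- matrix(0, n_total, K)
  Q_X <- matrix(NA_real_, n_total, K)
  sample_group <- character(n_total)
  sample_site <- character(n_total)
  sample_sex <- character(n_total)
  chroms <- config$chromosomes
  auto_chroms <- chroms[!chroms$is_x, , drop = FALSE]
  x_chrom <- chroms[chroms$is_x, , drop = FALSE]

  row0 <- 0L
  for (gr in groups) {
    if (gr$n == 0L) next
    f_g <- drift_frequencies(anc$freq, gr$drift)
    q_X <- (2 * gr$s_f + gr$s_m) / 3
    sites_g <- sample(names(gr$site_fractions), gr$n, replace = TRUE,
                      prob = gr$site_fractions)
    sexes_g <- sample(c("F", "M"), gr$n, replace = TRUE)
    for (i in seq_len(gr$n)) {
      r <- row0 + i
      sample_group[r] <- gr$name
      sample_site[r] <- sites_g[i]
      sample_sex[r] <- sexes_g[i]
      dos <- integer(L)
      n_x_hap <- if (sexes_g[i] == "M") 1L else 2L
      for (h in 1:2) {
        hap_anc <- integer(L)
        for (ci in seq_len(nrow(auto_chroms))) {
          ch <- auto_chroms$name[ci]
          idx <- which(map$chrom == ch)
          hap_anc[idx] <- hap_ancestry_chrom(gr$q, gr$g, auto_chroms$morgans[ci],
                                             map$cM[idx] / 100)
        }
        has_x <- length(x_idx) && h <= n_x_hap
        if (has_x) {
          hap_anc[x_idx] <- hap_ancestry_chrom(q_X, gr$g, x_chrom$morgans[1],
                                               map$cM[x_idx] / 100)
        }
        live <- if (h <= n_x_hap) seq_len(L) else auto_idx
        pf <- f_g[cbind(hap_anc[live], live)]
        allele <- as.integer(stats::runif(length(live)) < pf)
        dos[live] <- dos[live] + allele
        if (keep_ancestry) {
          arow <- 2L * (r - 1L) + h
          A[arow, live] <- hap_anc[live]
        }
        Q_auto[r, ] <- Q_auto[r, ] +
          tabulate(hap_anc[auto_idx], K) / (2 * length(auto_idx))
        if (has_x) {
          qx <- tabulate(hap_anc[x_idx], K) / (n_x_hap * length(x_idx))
          Q_X[r, ] <- if (anyNA(Q_X[r, ])) qx else Q_X[r, ] + qx
        }
      }
      G[r, ] <- dos
      if (sexes_g[i] == "M" && length(x_idx)) G[r, x_idx] <- pmin(G[r, x_idx], 1L)
    }
    row0 <- row0 + gr$n
  }

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(G)) < config$missing_rate
    G[miss] <- NA_integer_
  }

  ids <- sprintf("S%04d", seq_len(n_total))
  pool <- vapply(groups, function(g) g$name, "")
  # a single-group cohort has no alternative labels to mismatch to
  rel <- generate_pedigree_ethnicities(
    sample_group, if (length(pool) > 1L) ethnicity_mismatch_rate else 0,
    group_pool = pool)
  samples <- data.frame(id = ids, group = sample_group, site = sample_site,
                        sex = sample_sex, self_ethnicity = sample_group,
                        rel, stringsAsFactors = FALSE)
  variants <- cbind(map,
                    data.frame(ref = "A", alt = "G", stringsAsFactors = FALSE))
  ds <- structure(list(G = G, variants = variants, samples = samples),
                  class = "genotype_dataset")
  la <- NULL
  if (keep_ancestry) {
    la <- structure(list(A = A, P = matrix(1, nrow(A), L), map = variants,
                         haplotype = data.frame(sample = rep(ids, each = 2),
                                                hap = rep(1:2, n_total))),
                    class = "local_ancestry")
  }
  rownames(Q_auto) <- ids
  rownames(Q_X) <- ids
  colnames(Q_auto) <- colnames(Q_X) <- config$ancestry_names
  structure(list(dataset = ds, ancestry = la,
                 Q_auto = admix_proportions(Q_auto, scope = "autosomal"),
                 Q_X = admix_proportions(Q_X, scope = "X"),
                 freqs = anc, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated admixed cohort\n")
  cat("  samples:  ", nrow(x$dataset$G), " (",
      length(unique(x$dataset$samples$group)), " groups, ",
      length(unique(x$dataset$samples$site)), " sites)\n", sep = "")
  cat("  variants: ", ncol(x$dataset$G), " (",
      sum(x$dataset$variants$is_x), " on X)\n", sep = "")
  cat("  ancestries:", paste(colnames(x$Q_auto$Q), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$G), "samples x", ncol(x$G), "variants;",
      sum(is.na(x$G)), "missing calls\n")
  invisible(x)
}

#' Spike local-ancestry enrichment into genomic regions
#'
#' Fixture generator for enrichment-scan testing: inside each region,
#' haplotypes are reassigned so that the mean dosage of `ancestry_index`
#' equals `target_dosage` (a fixed count of haplotypes carries the focal
#' ancestry across the whole region; the remainder are redrawn uniformly
#' from the other ancestries). Variants outside the regions are untouched.
#'
#' @param la A `local_ancestry` object.
#' @param regions Data frame with `chrom`, `start_bp`, `end_bp` (1-based,
#'   inclusive). Empty data frame is a no-op.
#' @param ancestry_index Focal ancestry (1-based index).
#' @param target_dosage Desired mean dosage in [0, 1].
#' @param K Total number of ancestries (default: max index observed).
#' @param seed Optional seed.
#' @return A modified `local_ancestry`.
#' @export
spike_enrichment <- function(la, regions, ancestry_index, target_dosage,
                             K = max(la$A, na.rm = TRUE), seed = NULL) {
  stopifnot(inherits(la, "local_ancestry"))
  if (target_dosage < 0 || target_dosage > 1)
    stop("target_dosage must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(regions)) return(la)
  A <- la$A
  for (ri in seq_len(nrow(regions))) {
    cols <- which(la$map$chrom == regions$chrom[ri] &
                    la$map$bp >= regions$start_bp[ri] &
                    la$map$bp <= regions$end_bp[ri])
    if (!length(cols))
      stop("region ", ri, " covers no variants in the map")
    live <- which(!is.na(A[, cols[1]]))
    H <- length(live)
    n_carrier <- round(target_dosage * H)
    carriers <- live[sample.int(H, n_carrier)]
    others <- setdiff(live, carriers)
    A[carriers, cols] <- ancestry_index
    if (length(others) && K > 1L) {
      pool <- setdiff(seq_len(K), ancestry_index)
      block <- A[others, cols, drop = FALSE]
      hit <- which(block == ancestry_index)
      if (length(hit))
        block[hit] <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
      A[others, cols] <- block
    }
  }
  la$A <- A
  la
}
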