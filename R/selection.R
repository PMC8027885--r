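#' Population branch statistic (PBS)
#'
#' Converts per-variant pairwise F_ST values into branch lengths
#' T = -log(1 - F_ST) (F_ST floored at 0 first, so T >= 0) and computes the
#' focal population A's branch length in the three-population tree:
#' PBS_A = (T_AB + T_AC - T_BC) / 2. Variants with F_ST = 1 on a focal pair
#' give infinite T; they are flagged and excluded from ranking.
#'
#' @param fst_ab,fst_ac,fst_bc Aligned numeric vectors of per-variant F_ST
#'   between populations (A,B), (A,C), (B,C).
#' @return Data frame of class `pbs_result` with `T_ab`, `T_ac`, `T_bc`,
#'   `pbs`, and logical `valid` (finite PBS).
#' @export
pbs_scores <- function(fst_ab, fst_ac, fst_bc) {
  n <- length(fst_ab)
  if (length(fst_ac) != n || length(fst_bc) != n)
    stop("the three F_ST vectors must be aligned (equal length)")
  Tfun <- function(f) -log(1 - pmax(f, 0))
  T_ab <- Tfun(fst_ab); T_ac <- Tfun(fst_ac); T_bc <- Tfun(fst_bc)
  pbs <- (T_ab + T_ac - T_bc) / 2
  out <- data.frame(T_ab = T_ab, T_ac = T_ac, T_bc = T_bc, pbs = pbs,
                    valid = is.finite(pbs))
  class(out) <- c("pbs_result", "data.frame")
  out
}

#' Scan for local-ancestry enrichment (preferential gene-flow regions)
#'
#' Per-variant mean dosage of the focal ancestry is computed across
#' haplotype calls whose posterior exceeds `posterior_min`; variants within
#' `excl_bp` of chromosome ends or the centromere are removed. Variants
#' whose dosage deviates from the genome-wide mean by more than
#' `sd_mult` genome-wide standard deviations (high tail by default; both
#' tails with `tail = "both"`) are flagged, consecutive flagged variants
#' are merged, and runs of at least `min_snps` variants become candidate
#' regions.
#'
#' @param la A `local_ancestry` object.
#' @param ancestry_index Focal ancestry (1-based).
#' @param annotation Data frame with `name`, `bp_length`, `centromere_bp`
#'   per chromosome (e.g. [default_chromosomes()]).
#' @param posterior_min Posterior cutoff; calls with posterior <= this are
#'   dropped (default 0.8).
#' @param sd_mult SD multiplier (default 3).
#' @param min_snps Minimum variants per region (default 3).
#' @param excl_bp Exclusion margin around centromeres/telomeres (default
#'   2e6).
#' @param tail `"high"` (default) or `"both"`.
#' @return Data frame of class `enrichment_regions`: `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `mean_dosage`, `z`; attributes `genome_mean` and
#'   `genome_sd`.
#' @export
khoesan_enrichment_scan <- function(la, ancestry_index = 2L,
                                    annotation = default_chromosomes(),
                                    posterior_min = 0.8, sd_mult = 3,
                                    min_snps = 3L, excl_bp = 2e6,
                                    tail = c("high", "both")) {
  tail <- match.arg(tail)
  stopifnot(inherits(la, "local_ancestry"))
  map <- la$map
  ann <- annotation[match(map$chrom, annotation$name), ]
  near_end <- map$bp <= excl_bp | map$bp > ann$bp_length - excl_bp
  near_cen <- !is.na(ann$centromere_bp) &
    abs(map$bp - ann$centromere_bp) <= excl_bp
  keep_var <- which(!near_end & !near_cen)
  if (!length(keep_var)) stop("no variants retained after the exclusion mask")
  is_focal <- (la$A == ancestry_index)
  use <- la$P > posterior_min & !is.na(la$A)
  num <- colSums(is_focal & use, na.rm = TRUE)
  den <- colSums(use)
  dosage <- num / den
  dosage <- dosage[keep_var]
  ok <- is.finite(dosage)
  if (!any(ok)) stop("no variants with retained haplotype calls")
  mu <- mean(dosage[ok])
  sigma <- stats::sd(dosage[ok])
  if (is.na(sigma) || sigma == 0) {
    flags <- rep(FALSE, length(dosage))
  } else if (tail == "high") {
    flags <- ok & dosage > mu + sd_mult * sigma
  } else {
    flags <- ok & abs(dosage - mu) > sd_mult * sigma
  }
  out <- data.frame(chrom = character(), start_bp = numeric(),
                    end_bp = numeric(), n_snps = integer(),
                    mean_dosage = numeric(), z = numeric(),
                    stringsAsFactors = FALSE)
  if (any(flags)) {
    vm <- map[keep_var, ]
    run <- rle(paste0(vm$chrom, "/", flags))
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in seq_along(run$lengths)) {
      if (!endsWith(run$values[k], "TRUE")) next
      if (run$lengths[k] < min_snps) next
      span <- starts[k]:ends[k]
      md <- mean(dosage[span])
      out <- rbind(out, data.frame(
        chrom = vm$chrom[starts[k]], start_bp = vm$bp[starts[k]],
        end_bp = vm$bp[ends[k]], n_snps = length(span),
        mean_dosage = md, z = (md - mu) / sigma, stringsAsFactors = FALSE))
    }
  }
  attr(out, "genome_mean") <- mu
  attr(out, "genome_sd") <- sigma
  class(out) <- c("enrichment_regions", "data.frame")
  out
}

#' Write enrichment regions as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions An `enrichment_regions` data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start_bp) - 1L,
                    end = as.integer(regions$end_bp),
                    name = sprintf("region%03d", seq_len(nrow(regions))),
                    score = round(regions$z, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Allele-frequency fold-change scan between groups
#'
#' For every variant and every pair of groups, the fold difference is
#' max(f_i / f_j, f_j / f_i) on the alternate-allele frequencies. Pairs
#' where either frequency is exactly zero are reported separately as
#' unbounded and excluded from the ranked table. Bootstrap standard errors
#' of each group's frequency come from `n_boot` subsamples of size
#' `subsample` (defaults 50 and 30). Groups smaller than `subsample` are
#' dropped with a notice.
#'
#' @param G Genotype matrix.
#' @param labels Group labels per sample.
#' @param fold_min Minimum fold difference to retain (default 3).
#' @param n_boot,subsample Bootstrap settings.
#' @param seed Optional seed.
#' @return List of class `freq_scan`: `table` (ranked data frame with
#'   `variant`, `group1`, `group2`, `f1`, `f2`, `se1`, `se2`, `fold`),
#'   `unbounded` (same columns, zero-frequency pairs), `groups` used.
#' @export
allele_frequency_scan <- function(G, labels, fold_min = 3, n_boot = 50L,
                                  subsample = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- unique(labels)
  sizes <- vapply(grp, function(g) sum(labels == g), 1L)
  small <- grp[sizes < subsample]
  if (length(small)) {
    message("dropping groups smaller than the bootstrap subsample: ",
            paste(small, collapse = ", "))
    grp <- setdiff(grp, small)
  }
  if (length(grp) < 2L) stop("need >= 2 groups of at least subsample samples")
  freq <- se <- matrix(NA_real_, length(grp), ncol(G),
                       dimnames = list(grp, NULL))
  for (g in grp) {
    rows <- which(labels == g)
    freq[g, ] <- colMeans(G[rows, , drop = FALSE], na.rm = TRUE) / 2
    bf <- matrix(NA_real_, n_boot, ncol(G))
    for (b in seq_len(n_boot)) {
      bs <- sample(rows, subsample)
      bf[b, ] <- colMeans(G[bs, , drop = FALSE], na.rm = TRUE) / 2
    }
    se[g, ] <- apply(bf, 2L, stats::sd)
  }
  ranked <- unbounded <- list()
  for (i in seq_len(length(grp) - 1L)) for (j in (i + 1L):length(grp)) {
    f1 <- freq[grp[i], ]; f2 <- freq[grp[j], ]
    zero <- (f1 == 0 | f2 == 0) & (f1 != f2)
    fold <- pmax(f1 / f2, f2 / f1)
    hit <- which(!zero & is.finite(fold) & fold >= fold_min)
    if (length(hit))
      ranked[[length(ranked) + 1L]] <- data.frame(
        variant = hit, group1 = grp[i], group2 = grp[j],
        f1 = f1[hit], f2 = f2[hit],
        se1 = se[grp[i], hit], se2 = se[grp[j], hit],
        fold = fold[hit], stringsAsFactors = FALSE)
    zhit <- which(zero)
    if (length(zhit))
      unbounded[[length(unbounded) + 1L]] <- data.frame(
        variant = zhit, group1 = grp[i], group2 = grp[j],
        f1 = f1[zhit], f2 = f2[zhit],
        se1 = se[grp[i], zhit], se2 = se[grp[j], zhit],
        fold = NA_real_, stringsAsFactors = FALSE)
  }
  tab <- if (length(ranked)) do.call(rbind, ranked) else
    data.frame(variant = integer(), group1 = character(),
               group2 = character(), f1 = numeric(), f2 = numeric(),
               se1 = numeric(), se2 = numeric(), fold = numeric(),
               stringsAsFactors = FALSE)
  tab <- tab[order(-tab$fold), , drop = FALSE]
  rownames(tab) <- NULL
  ub <- if (length(unbounded)) do.call(rbind, unbounded) else tab[0, ]
  structure(list(table = tab, unbounded = ub, groups = grp),
            class = "freq_scan")
}

#' @export
print.freq_scan <- function(x, ...) {
  cat("allele-frequency fold-change scan:", nrow(x$table),
      "ranked pairs,", nrow(x$unbounded), "unbounded (zero-frequency)\n")
  if (nrow(x$table)) print(utils::head(x$table, 5))
  invisible(x)
}
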