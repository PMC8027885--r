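#' X-versus-autosome admixture difference ratio (sex-bias statistic)
#'
#' For each ancestry k the statistic is the relative excess of X-chromosome
#' over autosomal ancestry in the group means:
#' DeltaAdmix_k = (Qbar_X,k - Qbar_A,k) / Qbar_A,k. Because the X spends
#' two-thirds of its history in females, a positive value indicates a
#' female-biased (maternal) contribution of ancestry k, a negative value a
#' male-biased one. Ancestries with zero autosomal mean are reported NA.
#'
#' @param Q_auto,Q_X `admix_proportions` (or bare matrices) on the same
#'   samples.
#' @param subset Optional logical/integer subset of samples (e.g. one
#'   group).
#' @return Named numeric vector of per-ancestry estimates.
#' @export
delta_admix <- function(Q_auto, Q_X, subset = NULL) {
  QA <- if (inherits(Q_auto, "admix_proportions")) Q_auto$Q else as.matrix(Q_auto)
  QX <- if (inherits(Q_X, "admix_proportions")) Q_X$Q else as.matrix(Q_X)
  if (!all(dim(QA) == dim(QX))) stop("Q_auto and Q_X must match in shape")
  if (!is.null(subset)) {
    QA <- QA[subset, , drop = FALSE]
    QX <- QX[subset, , drop = FALSE]
  }
  if (!nrow(QA)) stop("empty sample subset")
  mA <- colMeans(QA, na.rm = TRUE)
  mX <- colMeans(QX, na.rm = TRUE)
  out <- (mX - mA) / mA
  out[mA == 0] <- NA_real_
  out
}

#' Bootstrap the DeltaAdmix statistic within a group
#'
#' Resamples `subsample` individuals (without replacement) from the group
#' `n_boot` times, recomputing the statistic each time. The reported SE is
#' the standard deviation of the bootstrap estimates, with a percentile 95%
#' confidence interval. Defaults (50 iterations of 20 samples) follow the
#' study design this package emulates.
#'
#' @param Q_auto,Q_X `admix_proportions` on the same samples.
#' @param group_idx Logical or integer index of the group's samples.
#' @param n_boot Number of bootstrap iterations (default 50).
#' @param subsample Resample size (default 20); must not exceed group size.
#' @param seed Optional seed.
#' @return List of class `delta_admix_boot`: `estimate` (point estimate on
#'   the full group), `se`, `ci` (2.5%/97.5% percentile, K x 2), `boot`
#'   (n_boot x K draws), `n_boot`, `subsample`.
#' @export
bootstrap_delta_admix <- function(Q_auto, Q_X, group_idx, n_boot = 50L,
                                  subsample = 20L, seed = NULL) {
  idx <- if (is.logical(group_idx)) which(group_idx) else group_idx
  if (subsample > length(idx))
    stop("subsample exceeds group size (", length(idx), ")")
  if (!is.null(seed)) set.seed(seed)
  est <- delta_admix(Q_auto, Q_X, idx)
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot))
    boot[b, ] <- delta_admix(Q_auto, Q_X, sample(idx, subsample))
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  structure(list(estimate = est, se = apply(boot, 2L, stats::sd), ci = ci,
                 boot = boot, n_boot = n_boot, subsample = subsample),
            class = "delta_admix_boot")
}

#' @export
print.delta_admix_boot <- function(x, ...) {
  cat("DeltaAdmix (X vs autosome; positive = maternal bias)\n")
  tab <- cbind(estimate = x$estimate, se = x$se, x$ci)
  print(round(tab, 4))
  cat(sprintf("(%d bootstrap iterations of %d samples)\n",
              x$n_boot, x$subsample))
  invisible(x)
}

#' Wilcoxon rank-sum test (normal approximation with ties)
#'
#' Rank-sum statistic with midranks for ties; two-sided p-value from the
#' normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `W` (rank-sum statistic of `x`, Mann-Whitney form) and
#'   `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(W = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Compare an ancestry proportion across study sites within a group
#'
#' Welch two-sample t-tests on one ancestry component (by default the
#' Khoe-San-related one) between every pair of sites for samples of one
#' group. Site pairs where either site has fewer than two samples are
#' skipped with a notice.
#'
#' @param Q `admix_proportions` (or matrix).
#' @param metadata Data frame with `group` and `site` per sample (same
#'   order as `Q`).
#' @param group Group label to analyse.
#' @param ancestry Column (index or name) of the ancestry to compare.
#' @return Data frame with `site1`, `site2`, `n1`, `n2`, `t`, `df`, `p`
#'   (zero rows when fewer than two usable sites).
#' @export
compare_ancestry_by_site <- function(Q, metadata, group, ancestry = 2L) {
  Qm <- if (inherits(Q, "admix_proportions")) Q$Q else as.matrix(Q)
  rows <- which(metadata$group == group)
  val <- Qm[rows, ancestry]
  site <- metadata$site[rows]
  sites <- sort(unique(site))
  out <- data.frame(site1 = character(), site2 = character(),
                    n1 = integer(), n2 = integer(), t = numeric(),
                    df = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (length(sites) < 2L) return(out)
  for (i in seq_len(length(sites) - 1L)) for (j in (i + 1L):length(sites)) {
    v1 <- val[site == sites[i]]
    v2 <- val[site == sites[j]]
    if (length(v1) < 2L || length(v2) < 2L) {
      message("skipping site pair ", sites[i], "-", sites[j],
              ": fewer than 2 samples in a site")
      next
    }
    tt <- stats::t.test(v1, v2)
    out <- rbind(out, data.frame(site1 = sites[i], site2 = sites[j],
                                 n1 = length(v1), n2 = length(v2),
                                 t = unname(tt$statistic),
                                 df = unname(tt$parameter),
                                 p = tt$p.value, stringsAsFactors = FALSE))
  }
  out
}

#' Invert autosomal and X ancestry into sex-specific contributions
#'
#' Under the single-pulse equilibrium model H_A = (s_f + s_m) / 2 and
#' H_X = (2 s_f + s_m) / 3, so the female and male contribution fractions
#' of an ancestry are recovered as s_f = 3 H_X - 2 H_A and
#' s_m = 4 H_A - 3 H_X. Solutions outside [-0.02, 1.02] signal a violation
#' of the model; values within that slack are clipped to [0, 1].
#'
#' @param H_A,H_X Autosomal and X mean ancestry fractions in [0, 1]
#'   (vectorised).
#' @return List with `s_f` and `s_m`.
#' @export
invert_sex_contributions <- function(H_A, H_X) {
  if (any(H_A < 0 | H_A > 1 | H_X < 0 | H_X > 1))
    stop("H_A and H_X must lie in [0, 1]")
  s_f <- 3 * H_X - 2 * H_A
  s_m <- 4 * H_A - 3 * H_X
  if (any(s_f < -0.02 | s_f > 1.02 | s_m < -0.02 | s_m > 1.02))
    stop("implied sex-specific contributions outside [0, 1] beyond slack: ",
         "single-pulse model violated")
  list(s_f = pmin(pmax(s_f, 0), 1), s_m = pmin(pmax(s_m, 0), 1))
}
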