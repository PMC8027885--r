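#' Generate relative (parent/grandparent) ethnicity labels
#'
#' Each sample receives six relative labels (2 parents + 4 grandparents).
#' Independently, each label equals the sample's own group with probability
#' `1 - mismatch_rate`, otherwise it is drawn uniformly from the other
#' groups in `group_pool`.
#'
#' @param sample_groups Character vector of the samples' own groups.
#' @param mismatch_rate Probability in [0, 1] that a relative's label
#'   differs from the sample's group.
#' @param group_pool Character vector of all group labels.
#' @param seed Optional seed.
#' @return Data frame with columns `rel1`..`rel6`.
#' @export
generate_pedigree_ethnicities <- function(sample_groups, mismatch_rate = 0.2,
                                          group_pool = unique(sample_groups),
                                          seed = NULL) {
  if (mismatch_rate < 0 || mismatch_rate > 1)
    stop("mismatch_rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(sample_groups)
  out <- matrix(rep(sample_groups, 6L), n, 6L)
  if (mismatch_rate > 0) {
    for (j in 1:6) {
      flip <- stats::runif(n) < mismatch_rate
      if (any(flip)) {
        out[flip, j] <- vapply(sample_groups[flip], function(g) {
          others <- setdiff(group_pool, g)
          if (!length(others))
            stop("group_pool has no alternative group for mismatches")
          others[sample.int(length(others), 1L)]
        }, "")
      }
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- paste0("rel", 1:6)
  out
}

#' Ethno-linguistic concordance (EC) of samples
#'
#' A sample is ethno-linguistically concordant when at least five of its six
#' parent/grandparent ethnicity labels equal its self-reported ethnicity.
#'
#' @param samples A `genotype_dataset`, or a data frame with columns
#'   `self_ethnicity` and `rel1`..`rel6`.
#' @return Logical vector, one entry per sample.
#' @export
ec_concordant <- function(samples) {
  if (inherits(samples, "genotype_dataset")) samples <- samples$samples
  rel_cols <- paste0("rel", 1:6)
  if (!all(c("self_ethnicity", rel_cols) %in% names(samples)))
    stop("samples must carry self_ethnicity and rel1..rel6")
  rel <- as.matrix(samples[rel_cols])
  if (anyNA(rel) || anyNA(samples$self_ethnicity))
    stop("missing ethnicity labels")
  matches <- rowSums(rel == samples$self_ethnicity)
  matches >= 5L
}

#' Restrict a dataset (and companions) to EC samples
#'
#' @param cohort A `sim_cohort`.
#' @return The cohort with non-EC samples dropped from the genotype
#'   dataset, local ancestry, and ancestry-proportion matrices.
#' @export
filter_ec <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  keep <- ec_concordant(cohort$dataset)
  cohort$dataset$G <- cohort$dataset$G[keep, , drop = FALSE]
  cohort$dataset$samples <- cohort$dataset$samples[keep, , drop = FALSE]
  if (!is.null(cohort$ancestry)) {
    hap_keep <- rep(keep, each = 2L)
    cohort$ancestry$A <- cohort$ancestry$A[hap_keep, , drop = FALSE]
    cohort$ancestry$P <- cohort$ancestry$P[hap_keep, , drop = FALSE]
    cohort$ancestry$haplotype <- cohort$ancestry$haplotype[hap_keep, , drop = FALSE]
  }
  cohort$Q_auto$Q <- cohort$Q_auto$Q[keep, , drop = FALSE]
  cohort$Q_X$Q <- cohort$Q_X$Q[keep, , drop = FALSE]
  cohort
}
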