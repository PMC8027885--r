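#' Export a dataset to VCF + TSV files
#'
#' Writes genotypes as VCF v4.2 (diploid calls `0/0`, `0/1`, `1/1`,
#' missing `./.`; hemizygous male X calls as haploid `0` / `1`, missing
#' `.`), sample metadata as TSV (`id`, `group`, `site`, `sex`,
#' `self_ethnicity`, `rel1`..`rel6`), and (optionally) local ancestry as a
#' long TSV (`haplotype`, `chrom`, `pos`, `ancestry`, `posterior`). The
#' genetic-map position is stored per variant in the INFO field (`CM=`), so
#' [import_dataset()] round-trips losslessly.
#'
#' @param dataset A `genotype_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param ancestry Optional `local_ancestry` to export.
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Named character vector of written paths.
#' @export
export_dataset <- function(dataset, out_dir, ancestry = NULL,
                           prefix = "cohort") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf_path <- file.path(out_dir, paste0(prefix, ".vcf"))
  meta_path <- file.path(out_dir, paste0(prefix, ".samples.tsv"))
  v <- dataset$variants
  s <- dataset$samples
  G <- dataset$G
  male <- s$sex == "M"

  con <- file(vcf_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=stratsim",
               paste0("##contig=<ID=", unique(v$chrom), ">"),
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position (cM)\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s$id), collapse = "\t")), con)
  dip_codes <- c("0/0", "0/1", "1/1")
  hap_codes <- c("0", "1")
  n <- nrow(G)
  for (l in seq_len(ncol(G))) {
    g <- G[, l]
    gt <- character(n)
    if (v$is_x[l]) {
      gt[male] <- ifelse(is.na(g[male]), ".", hap_codes[g[male] + 1L])
      gt[!male] <- ifelse(is.na(g[!male]), "./.", dip_codes[g[!male] + 1L])
    } else {
      gt <- ifelse(is.na(g), "./.", dip_codes[g + 1L])
    }
    writeLines(paste(c(v$chrom[l], v$bp[l], sprintf("var%06d", l),
                       v$ref[l], v$alt[l], ".", "PASS",
                       sprintf("CM=%.6f", v$cM[l]), "GT", gt),
                     collapse = "\t"), con)
  }
  utils::write.table(s, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(vcf = vcf_path, metadata = meta_path)
  if (!is.null(ancestry)) {
    anc_path <- file.path(out_dir, paste0(prefix, ".ancestry.tsv"))
    H <- nrow(ancestry$A)
    hap_id <- paste0(ancestry$haplotype$sample, "_h", ancestry$haplotype$hap)
    long <- data.frame(
      haplotype = rep(hap_id, times = ncol(ancestry$A)),
      chrom = rep(ancestry$map$chrom, each = H),
      pos = rep(ancestry$map$bp, each = H),
      ancestry = as.vector(ancestry$A),
      posterior = as.vector(ancestry$P))
    long <- long[!is.na(long$ancestry), ]
    utils::write.table(long, anc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, ancestry = anc_path)
  }
  paths
}

#' Import a dataset written by [export_dataset()] (or any VCF + metadata)
#'
#' @param vcf_path VCF file (v4.2; `GT` field; haploid or diploid calls).
#' @param metadata_path Sample-metadata TSV with an `id` column matching
#'   the VCF sample columns.
#' @return A `genotype_dataset`.
#' @export
import_dataset <- function(vcf_path, metadata_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  alt_count <- function(x) {
    alleles <- strsplit(x, "[/|]")
    vapply(alleles, function(a) {
      if (!length(a) || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, 1L)
  }
  gt[is.na(gt)] <- "."
  G <- t(apply(gt, 1L, alt_count))
  G <- t(G)                                  # samples x variants
  storage.mode(G) <- "integer"
  info <- vcf@fix[, "INFO"]
  cm <- suppressWarnings(as.numeric(sub(".*CM=([0-9.eE+-]+).*", "\\1", info)))
  variants <- data.frame(chrom = fix[, "CHROM"],
                         bp = as.integer(fix[, "POS"]),
                         cM = cm,
                         is_x = fix[, "CHROM"] %in% c("X", "chrX", "23"),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  samples <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  samples <- samples[match(colnames(gt), samples$id), , drop = FALSE]
  rownames(G) <- samples$id
  structure(list(G = G, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' Import a local-ancestry TSV written by [export_dataset()]
#'
#' @param path Long-format TSV (`haplotype`, `chrom`, `pos`, `ancestry`,
#'   `posterior`).
#' @return A `local_ancestry`.
#' @export
import_local_ancestry <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  hap_ids <- unique(long$haplotype)
  key <- paste(long$chrom, long$pos)
  var_keys <- unique(key)
  H <- length(hap_ids)
  L <- length(var_keys)
  A <- matrix(NA_integer_, H, L)
  P <- matrix(NA_real_, H, L)
  hi <- match(long$haplotype, hap_ids)
  vi <- match(key, var_keys)
  A[cbind(hi, vi)] <- long$ancestry
  P[cbind(hi, vi)] <- long$posterior
  first <- !duplicated(key)
  map <- data.frame(chrom = long$chrom[first], bp = long$pos[first])
  sample_id <- sub("_h[12]$", "", hap_ids)
  hap_no <- as.integer(sub("^.*_h", "", hap_ids))
  structure(list(A = A, P = P, map = map,
                 haplotype = data.frame(sample = sample_id, hap = hap_no)),
            class = "local_ancestry")
}
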