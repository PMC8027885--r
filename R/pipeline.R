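#' Default pipeline configuration
#'
#' The full default configuration tree used by [load_config()]; values not
#' present in a user's YAML file are filled from here.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "stratsim_run",
    log_level = "info",
    ec_filter = FALSE,
    stages = c("simulate", "structure", "ancestry", "gwas"),
    simulate = list(preset = "seb", n_scale = 1, L = 5000L,
                    missing_rate = 0.002, ks_maternal_bias = 0.4,
                    ethnicity_mismatch_rate = 0.2),
    import = list(vcf = "", metadata = ""),
    structure = list(n_pcs = 10L, ld_r2 = 0.5, ld_window = 50L,
                     ld_step = 5L, n_perm = 9999L),
    ancestry = list(n_boot = 50L, subsample = 20L, posterior_min = 0.8,
                    sd_mult = 3, min_snps = 3L, excl_bp = 2e6,
                    fold_min = 3, freq_n_boot = 50L, freq_subsample = 30L),
    gwas = list(n_iter = 5L, maf_min = 0.05, n_pcs = 3L,
                suggestive = 1e-5, scenarios = list())
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills missing keys from [default_config()], and
#' rejects unknown keys (typo guard) at the top level and within each
#' stage block.
#'
#' @param path YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- default_config()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("simulate", "import", "structure", "ancestry", "gwas")) {
    if (!is.null(user[[blk]])) {
      bad <- setdiff(names(user[[blk]]), names(defs[[blk]]))
      if (length(bad))
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(defs, user)
  cfg$seed <- as.integer(cfg$seed)
  bad_stage <- setdiff(cfg$stages, c("simulate", "structure", "ancestry", "gwas"))
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Serialize a configuration back to YAML
#' @param config A `run_config` (or plain list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Feasible default GWAS scenarios for whatever cohort was simulated:
# a two-site contrast (category1 analog) and a within-site null
# (category4 analog), sized to the available samples.
default_scenarios <- function(metadata) {
  site_n <- sort(table(metadata$site), decreasing = TRUE)
  sites <- names(site_n)
  scen <- list()
  if (length(sites) >= 2L) {
    n <- min(site_n[1], site_n[2])
    n <- max(2L, floor(0.9 * n))
    scen[[length(scen) + 1L]] <- list(
      name = paste0("site_contrast_", sites[1], "_vs_", sites[2]),
      scheme = "category1",
      params = list(site_case = sites[1], site_control = sites[2], n = n))
  }
  n4 <- max(2L, floor(site_n[1] / 2))
  scen[[length(scen) + 1L]] <- list(
    name = paste0("within_site_null_", sites[1]),
    scheme = "category4",
    params = list(site = sites[1], n_case = n4, n_control = site_n[[1]] - n4))
  scen
}

#' Run the full simulation-to-GWAS pipeline
#'
#' Executes the enabled stages in order (simulate, structure, ancestry,
#' gwas), writing each stage's artifacts under `out_dir` and a JSON run
#' manifest at the end. Stage sub-seeds derive deterministically from the
#' global seed, so identical configurations reproduce identical outputs.
#' With `ec_filter = TRUE`, downstream stages see only ethno-linguistically
#' concordant samples (at least 5 of 6 relatives matching).
#'
#' @param config A `run_config` (from [load_config()]) or a nested list in
#'   the same layout.
#' @param dry_run List the planned stages without computing or writing.
#' @return The run manifest (list of class `run_manifest`), invisibly for
#'   normal runs.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (!inherits(config, "run_config"))
    config <- utils::modifyList(default_config(), config)
  stages <- config$stages
  if (dry_run) {
    cat("planned stages:", paste(stages, collapse = " -> "), "\n")
    return(invisible(stages))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("stratsim")),
                   config_hash = config_hash(config),
                   seed = config$seed, stages = list())
  log_msg <- function(...) {
    if (!identical(config$log_level, "quiet")) message("[stratsim] ", ...)
  }
  cohort <- NULL
  status <- function(name, ok, outputs = character(), reason = NULL) {
    manifest$stages[[name]] <<- list(status = if (ok) "ok" else "failed",
                                     outputs = as.list(outputs),
                                     reason = reason)
  }

  if ("simulate" %in% stages) {
    log_msg("simulate: generating cohort")
    sp <- config$simulate
    sim_cfg <- seb_cohort_config(n_scale = sp$n_scale, L = sp$L,
                                 missing_rate = sp$missing_rate,
                                 seed = derive_seed(config$seed, "simulate"),
                                 ks_maternal_bias = sp$ks_maternal_bias)
    cohort <- simulate_genotypes(sim_cfg,
                                 ethnicity_mismatch_rate = sp$ethnicity_mismatch_rate)
    if (isTRUE(config$ec_filter)) cohort <- filter_ec(cohort)
    paths <- export_dataset(cohort$dataset, file.path(out_dir, "simulate"),
                            ancestry = cohort$ancestry)
    save_config(config, file.path(out_dir, "simulate", "config.yaml"))
    status("simulate", TRUE, c(paths,
                               config = file.path(out_dir, "simulate", "config.yaml")))
  }
  if (is.null(cohort) && nzchar(config$import$vcf %||% "")) {
    log_msg("import: reading dataset from VCF + metadata")
    ds_in <- import_dataset(config$import$vcf, config$import$metadata)
    cohort <- list(dataset = ds_in, ancestry = NULL, Q_auto = NULL,
                   Q_X = NULL, config = NULL)
    status("import", TRUE, c(config$import$vcf, config$import$metadata))
  }
  if (is.null(cohort)) {
    for (st in setdiff(stages, "simulate"))
      status(st, FALSE, reason = "no cohort available (simulate disabled, no import)")
    return(write_manifest(manifest, out_dir))
  }

  ds <- cohort$dataset
  G <- ds$G
  rownames(G) <- ds$samples$id
  groups <- unique(ds$samples$group)

  if ("structure" %in% stages) {
    log_msg("structure: PCA, F_ST, tree, geography")
    sdir <- file.path(out_dir, "structure")
    dir.create(sdir, showWarnings = FALSE)
    st <- config$structure
    res <- tryCatch({
      kept <- ld_prune(G, st$ld_r2, st$ld_window, st$ld_step,
                       chrom = ds$variants$chrom)
      pca <- genotype_pca(G[, kept, drop = FALSE],
                          n_pcs = min(st$n_pcs, nrow(G) - 1L))
      utils::write.table(
        data.frame(id = ds$samples$id, group = ds$samples$group,
                   site = ds$samples$site, pca$coords),
        file.path(sdir, "pca.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      fst <- pairwise_fst_matrix(G, ds$samples$group)
      utils::write.table(as.data.frame(fst),
                         file.path(sdir, "fst_matrix.tsv"),
                         sep = "\t", quote = FALSE)
      tree <- upgma_tree(fst)
      ape::write.tree(tree, file.path(sdir, "upgma.nwk"))
      geo <- group_geo_points(cohort$config)
      stats_block <- list(seed = derive_seed(config$seed, "structure"))
      if (!is.null(geo) && nrow(geo) >= 3L) {
        Dg <- geo_distance_matrix(geo)
        common <- intersect(rownames(fst), rownames(Dg))
        mt <- mantel_test(fst[common, common], Dg[common, common],
                          n_perm = st$n_perm, seed = stats_block$seed)
        pc_means <- group_means(pca$coords[, 1:2, drop = FALSE],
                                ds$samples$group)[common, , drop = FALSE]
        pt <- procrustes_test(cbind(geo[common, "lon"], geo[common, "lat"]),
                              pc_means, n_perm = st$n_perm,
                              seed = stats_block$seed)
        stats_block$mantel <- list(r = mt$r, p = mt$p, n_perm = mt$n_perm)
        stats_block$procrustes <- list(m2 = pt$m2, r = pt$r, r2 = pt$r2,
                                       p = pt$p, n_perm = pt$n_perm)
      }
      jsonlite::write_json(stats_block, file.path(sdir, "structure_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) status("structure", FALSE, reason = conditionMessage(res))
    else status("structure", TRUE,
                file.path(sdir, c("pca.tsv", "fst_matrix.tsv", "upgma.nwk",
                                  "structure_stats.json")))
  }

  if ("ancestry" %in% stages) {
    log_msg("ancestry: sex bias, enrichment, frequency scan")
    adir <- file.path(out_dir, "ancestry")
    dir.create(adir, showWarnings = FALSE)
    ap <- config$ancestry
    res <- tryCatch({
      seed_a <- derive_seed(config$seed, "ancestry")
      da <- list()
      if (!is.null(cohort$Q_auto)) for (g in groups) {
        idx <- which(ds$samples$group == g)
        if (length(idx) < ap$subsample) next
        bt <- bootstrap_delta_admix(cohort$Q_auto, cohort$Q_X, idx,
                                    n_boot = ap$n_boot,
                                    subsample = ap$subsample,
                                    seed = derive_seed(seed_a, g))
        da[[g]] <- list(estimate = as.list(bt$estimate),
                        se = as.list(bt$se),
                        n_boot = bt$n_boot, subsample = bt$subsample)
      }
      jsonlite::write_json(list(seed = seed_a, delta_admix = da),
                           file.path(adir, "delta_admix.json"),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(cohort$ancestry)) {
        regions <- khoesan_enrichment_scan(
          cohort$ancestry, ancestry_index = 2L,
          annotation = cohort$config$chromosomes,
          posterior_min = ap$posterior_min, sd_mult = ap$sd_mult,
          min_snps = ap$min_snps, excl_bp = ap$excl_bp)
        write_regions_bed(regions, file.path(adir, "ks_enrichment.bed"))
      }
      grp_sizes <- table(ds$samples$group)
      if (sum(grp_sizes >= ap$freq_subsample) >= 2L) {
        fs <- allele_frequency_scan(G, ds$samples$group,
                                    fold_min = ap$fold_min,
                                    n_boot = ap$freq_n_boot,
                                    subsample = ap$freq_subsample,
                                    seed = derive_seed(seed_a, "freq"))
        utils::write.table(fs$table, file.path(adir, "freq_scan.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        log_msg("ancestry: frequency scan skipped ",
                "(fewer than 2 groups reach the bootstrap subsample size)")
      }
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) status("ancestry", FALSE, reason = conditionMessage(res))
    else status("ancestry", TRUE, list.files(adir, full.names = TRUE))
  }

  if ("gwas" %in% stages) {
    log_msg("gwas: simulated-trait association suite")
    gdir <- file.path(out_dir, "gwas")
    dir.create(gdir, showWarnings = FALSE)
    gp <- config$gwas
    res <- tryCatch({
      scen <- if (length(gp$scenarios)) gp$scenarios else default_scenarios(ds$samples)
      suite <- run_gwas_suite(ds, scen, n_iter = gp$n_iter,
                              seed = derive_seed(config$seed, "gwas"),
                              maf_min = gp$maf_min, n_pcs = gp$n_pcs,
                              suggestive = gp$suggestive)
      utils::write.table(suite$summary,
                         file.path(gdir, "inflation_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        lapply(suite$reports, function(r)
          list(scenario = r$scenario, iteration = r$iteration,
               lambda_raw = r$lambda_raw, lambda_gc = r$lambda_gc,
               lambda_pc = r$lambda_pc, seed = r$seed,
               counts = as.data.frame(r$counts))),
        file.path(gdir, "inflation_reports.json"),
        auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) status("gwas", FALSE, reason = conditionMessage(res))
    else status("gwas", TRUE,
                file.path(gdir, c("inflation_summary.tsv",
                                  "inflation_reports.json")))
  }

  write_manifest(manifest, out_dir)
}

group_geo_points <- function(sim_cfg) {
  if (is.null(sim_cfg)) return(NULL)
  geo <- do.call(rbind, lapply(sim_cfg$groups, function(g)
    data.frame(lat = g$geo[["lat"]], lon = g$geo[["lon"]])))
  rownames(geo) <- vapply(sim_cfg$groups, function(g) g$name, "")
  geo <- geo[stats::complete.cases(geo), , drop = FALSE]
  if (!nrow(geo)) NULL else geo
}

group_means <- function(M, labels) {
  out <- rowsum(M, labels) / as.vector(table(labels)[sort(unique(labels))])
  out[sort(unique(labels)), , drop = FALSE]
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  u <- utf8ToInt(s)
  sprintf("%08x", sum(u * (seq_along(u) %% 8191)) %% 4294967291)
}

# Manifest written atomically: temp file then rename.
write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  manifest <- structure(manifest, class = "run_manifest")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("stratsim run manifest (seed ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
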