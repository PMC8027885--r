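#' Specification of one admixed group
#'
#' A group is an ethno-linguistic population with its own admixture profile:
#' autosomal ancestry proportions `q` over the K ancestral components,
#' sex-specific contribution fractions `s_f` (female) and `s_m` (male) that
#' must average to `q`, a within-group drift parameter, generations since
#' admixture, a geographic anchor (the geometric median of the group's
#' language majority area) and the fractions of the group sampled at each
#' study site.
#'
#' Under a single-pulse admixture model the expected autosomal ancestry is
#' H_A = (s_f + s_m) / 2 and the expected X-chromosome ancestry is
#' H_X = (2 s_f + s_m) / 3, so unequal `s_f` and `s_m` induce an
#' X-versus-autosome ancestry difference (sex-biased gene flow).
#'
#' @param name Group label.
#' @param n Number of sampled individuals (>= 0).
#' @param q Numeric length-K simplex of autosomal ancestry proportions.
#' @param s_f,s_m Female/male per-ancestry contribution fractions; each a
#'   length-K simplex with `(s_f + s_m) / 2 == q` elementwise. Default: no
#'   sex bias (`s_f = s_m = q`).
#' @param drift Within-group Balding-Nichols drift parameter F_g >= 0.
#' @param g Generations since admixture (integer >= 1); sets the ancestry
#'   switch rate (per Morgan) of local-ancestry tracts.
#' @param geo Length-2 numeric `c(lat, lon)` in decimal degrees.
#' @param site_fractions Named numeric vector of sampling fractions over
#'   sites; must sum to 1.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n, q, s_f = NULL, s_m = NULL, drift = 0.005,
                       g = 28L, geo = c(NA_real_, NA_real_),
                       site_fractions = c(site1 = 1)) {
  q <- as.numeric(q)
  check_simplex(q, "q")
  if (is.null(s_f) && is.null(s_m)) {
    s_f <- q
    s_m <- q
  }
  s_f <- as.numeric(s_f)
  s_m <- as.numeric(s_m)
  check_simplex(s_f, "s_f")
  check_simplex(s_m, "s_m")
  if (max(abs((s_f + s_m) / 2 - q)) > 1e-9)
    stop("(s_f + s_m)/2 must equal q elementwise (within 1e-9)")
  if (n < 0) stop("group sample size must be >= 0")
  if (drift < 0) stop("drift must be >= 0")
  if (g < 1) stop("g (generations since admixture) must be >= 1")
  if (abs(sum(site_fractions) - 1) > 1e-9)
    stop("site_fractions must sum to 1")
  if (any(site_fractions < 0)) stop("site_fractions must be non-negative")
  structure(list(name = as.character(name), n = as.integer(n), q = q,
                 s_f = s_f, s_m = s_m, drift = drift, g = as.integer(g),
                 geo = c(lat = geo[[1]], lon = geo[[2]]),
                 site_fractions = site_fractions),
            class = "group_spec")
}

check_simplex <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " entries must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop(what, " must sum to 1 (simplex)")
  invisible(x)
}

#' Build sex-biased contribution fractions from autosomal proportions
#'
#' Convenience constructor: given autosomal proportions `q` and a vector of
#' per-ancestry female excesses `delta`, returns `s_f = q + delta` and
#' `s_m = q - delta` renormalised onto the simplex pairwise-consistently
#' (deltas must sum to 0 so that both remain simplexes).
#'
#' @param q Length-K simplex.
#' @param delta Length-K numeric summing to 0; positive entries give a
#'   female-biased (maternal) contribution for that ancestry.
#' @return List with components `s_f` and `s_m`.
#' @export
sex_biased_contributions <- function(q, delta) {
  if (abs(sum(delta)) > 1e-9) stop("delta must sum to 0")
  s_f <- q + delta
  s_m <- q - delta
  if (any(s_f < 0) || any(s_f > 1) || any(s_m < 0) || any(s_m > 1))
    stop("delta too large: s_f or s_m leaves [0, 1]")
  list(s_f = s_f, s_m = s_m)
}

#' Simulation configuration for an admixed, multi-site cohort
#'
#' Bundles all simulator knobs: the K ancestral components and their
#' divergence from a shared base frequency (`F_anc`, one Balding-Nichols
#' parameter per ancestry), the variant panel (`L` variants over
#' `chromosomes`), the admixed groups, the study sites, and global nuisance
#' parameters (missing-genotype rate, base-frequency range).
#'
#' @param groups List of [group_spec()] objects.
#' @param L Total number of variants.
#' @param K Number of ancestral components (default 3: Bantu-speaker-related,
#'   Khoe-San-related, Eurasian-related).
#' @param ancestry_names Character length-K labels.
#' @param F_anc Numeric length-K in (0,1): per-ancestry differentiation from
#'   the shared base frequency.
#' @param chromosomes Data frame with columns `name`, `bp_length`,
#'   `morgans`, `is_x` (logical; exactly zero or one X). Defaults to two
#'   autosomes of 120 Mb / 1.2 Morgan each plus one 150 Mb / 1.8 Morgan X.
#' @param sites Character vector of site names; must cover every name used
#'   in the groups' `site_fractions`.
#' @param base_freq_range Length-2 range in (0,1) for the shared base
#'   frequency (uniform draw).
#' @param missing_rate Fraction of genotype calls set missing, in [0, 1).
#' @param seed Integer seed; all randomness in [simulate_genotypes()] flows
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups, L = 5000L, K = 3L,
                       ancestry_names = c("BS", "KS", "EUR"),
                       F_anc = c(0.05, 0.20, 0.15),
                       chromosomes = default_chromosomes(),
                       sites = NULL,
                       base_freq_range = c(0.05, 0.95),
                       missing_rate = 0, seed = 1L) {
  if (!length(groups)) stop("at least one group required")
  if (!all(vapply(groups, inherits, TRUE, "group_spec")))
    stop("groups must be a list of group_spec objects")
  K <- as.integer(K)
  if (length(ancestry_names) != K) stop("ancestry_names must have length K")
  if (length(F_anc) == 1L) F_anc <- rep(F_anc, K)
  if (length(F_anc) != K) stop("F_anc must have length K (or 1)")
  if (any(F_anc <= 0 | F_anc >= 1)) stop("F_anc must lie in (0, 1)")
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "bp_length", "morgans", "is_x") %in% names(chromosomes)))
  if (any(chromosomes$morgans <= 0)) stop("Morgan lengths must be > 0")
  if (sum(chromosomes$is_x) > 1L) stop("at most one X chromosome")
  for (gr in groups) {
    if (length(gr$q) != K) stop("group ", gr$name, ": q has wrong length")
  }
  if (is.null(sites))
    sites <- unique(unlist(lapply(groups, function(g) names(g$site_fractions))))
  missing_sites <- setdiff(unlist(lapply(groups, function(g) names(g$site_fractions))), sites)
  if (length(missing_sites))
    stop("site_fractions reference unknown sites: ", paste(missing_sites, collapse = ", "))
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (base_freq_range[1] <= 0 || base_freq_range[2] >= 1 ||
      base_freq_range[1] > base_freq_range[2])
    stop("base_freq_range must be an increasing range inside (0, 1)")
  structure(list(groups = groups, L = as.integer(L), K = K,
                 ancestry_names = ancestry_names, F_anc = F_anc,
                 chromosomes = chromosomes, sites = sites,
                 base_freq_range = base_freq_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default chromosome layout: two autosomes and one X
#'
#' Genetic lengths use a uniform 1 cM/Mb map except the X, which is given a
#' slightly higher per-bp rate as in human female maps.
#' @return Data frame with columns `name`, `bp_length`, `morgans`, `is_x`,
#'   `centromere_bp`.
#' @export
default_chromosomes <- function() {
  data.frame(name = c("1", "2", "X"),
             bp_length = c(120e6, 120e6, 150e6),
             morgans = c(1.2, 1.2, 1.8),
             is_x = c(FALSE, FALSE, TRUE),
             centromere_bp = c(60e6, 60e6, 60e6),
             stringsAsFactors = FALSE)
}

#' Preset cohort emulating the South-Eastern Bantu-speaker study design
#'
#' Eight admixed groups with three ancestral components at the study's
#' reported mean proportions, sampled at three sites (Agincourt, Dikgale,
#' Soweto) with mixed group composition, Khoe-San-maternal sex bias, and
#' geographic anchors at each group's language-majority-area median.
#' Group sizes follow the downsized ethno-linguistically concordant design
#' (80-individual cap per group). Proportions are the K = 3 means
#' (Bantu-related, Khoe-San-related, Eurasian-related), renormalised.
#'
#' @param n_scale Multiplier applied to the default group sizes.
#' @param L,missing_rate,seed Passed to [sim_config()].
#' @param ks_maternal_bias Fraction of each group's Khoe-San ancestry added
#'   to the female contribution (and removed from the male), emulating
#'   maternally biased Khoe-San gene flow. 0 disables sex bias.
#' @return A `sim_config`.
#' @export
seb_cohort_config <- function(n_scale = 1, L = 5000L, missing_rate = 0.002,
                              seed = 1L, ks_maternal_bias = 0.4) {
  tab <- seb_group_table()
  groups <- lapply(seq_len(nrow(tab)), function(i) {
    q <- c(tab$bs[i], tab$ks[i], tab$eur[i])
    q <- q / sum(q)
    d_ks <- ks_maternal_bias * q[2]
    delta <- c(-d_ks, d_ks, 0)
    s <- sex_biased_contributions(q, delta)
    group_spec(name = tab$group[i],
               n = max(0L, as.integer(round(tab$n[i] * n_scale))),
               q = q, s_f = s$s_f, s_m = s$s_m,
               drift = 0.005, g = tab$g[i],
               geo = c(tab$lat[i], tab$lon[i]),
               site_fractions = c(AGT = tab$agt[i], DKG = tab$dkg[i],
                                  SWT = tab$swt[i]))
  })
  sim_config(groups = groups, L = L, sites = c("AGT", "DKG", "SWT"),
             missing_rate = missing_rate, seed = seed)
}

# Mean K=3 ancestry percentages per group, downsized-EC sample sizes,
# approximate site composition, generations since admixture, and
# language-majority-area medians (lat/lon, decimal degrees).
seb_group_table <- function() {
  data.frame(
    group = c("Pedi", "Sotho", "Tswana", "Swazi", "Xhosa", "Zulu", "Tsonga", "Venda"),
    bs  = c(88.28, 84.17, 78.19, 90.43, 80.24, 84.64, 97.80, 91.31) / 100,
    ks  = c(10.61, 14.65, 20.49,  8.69, 17.62, 13.58,  1.56,  6.45) / 100,
    eur = c( 1.12,  1.18,  1.32,  0.87,  2.14,  1.78,  0.65,  2.24) / 100,
    n   = c(80L, 45L, 70L, 30L, 59L, 80L, 80L, 23L),
    g   = c(28L, 25L, 24L, 30L, 26L, 30L, 45L, 45L),
    agt = c(0.12, 0.20, 0.05, 0.60, 0.10, 0.25, 0.85, 0.10),
    dkg = c(0.75, 0.05, 0.10, 0.05, 0.02, 0.05, 0.05, 0.20),
    swt = c(0.13, 0.75, 0.85, 0.35, 0.88, 0.70, 0.10, 0.70),
    lat = c(-24.3, -29.1, -26.0, -26.2, -32.0, -28.5, -23.5, -22.9),
    lon = c( 29.5,  27.5,  25.0,  31.0,  27.0,  31.0,  31.2,  30.5),
    stringsAsFactors = FALSE)
}
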