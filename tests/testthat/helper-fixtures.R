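# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# Two-group admixed cohort on autosomes only (no X), each group at its own
# site unless site fractions are given.
two_group_config <- function(q_ks = c(0.15, 0.02), n = c(100L, 100L),
                             L = 2000L, drift = 0.005, g = 28L,
                             site_frac = NULL, seed = 1L,
                             missing_rate = 0) {
  chroms <- data.frame(name = c("1", "2"), bp_length = c(120e6, 120e6),
                       morgans = c(1.2, 1.2), is_x = FALSE,
                       centromere_bp = 60e6)
  mk <- function(i) {
    fr <- if (is.null(site_frac)) stats::setNames(1, paste0("S", i))
          else site_frac[[i]]
    group_spec(paste0("G", i), n[i],
               q = c(1 - q_ks[i] - 0.01, q_ks[i], 0.01),
               drift = drift, g = g, site_fractions = fr)
  }
  sim_config(list(mk(1L), mk(2L)), L = L, chromosomes = chroms,
             sites = if (is.null(site_frac)) c("S1", "S2")
                     else unique(unlist(lapply(site_frac, names))),
             missing_rate = missing_rate, seed = seed)
}

# Homogeneous single-population cohort (one group, one site, no X).
homogeneous_config <- function(n = 200L, L = 2000L, seed = 1L,
                               base_freq_range = c(0.1, 0.9)) {
  chroms <- data.frame(name = c("1", "2"), bp_length = c(120e6, 120e6),
                       morgans = c(1.2, 1.2), is_x = FALSE,
                       centromere_bp = 60e6)
  gr <- group_spec("POP", n, q = 1, drift = 0, g = 1L,
                   site_fractions = c(S = 1))
  sim_config(list(gr), L = L, K = 1L, ancestry_names = "ANC",
             F_anc = 1e-4, chromosomes = chroms, sites = "S",
             base_freq_range = base_freq_range, seed = seed)
}

# Independent hand evaluation of the published Weir-Cockerham (1984)
# variance components for one locus, r = 2 (used as the test oracle).
wc_hand <- function(dosA, dosB) {
  r <- 2
  ns <- c(length(dosA), length(dosB))
  ps <- c(sum(dosA) / (2 * ns[1]), sum(dosB) / (2 * ns[2]))
  hs <- c(mean(dosA == 1), mean(dosB == 1))
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  pbar <- sum(ns * ps) / sum(ns)
  s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ns * hs) / sum(ns)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}
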