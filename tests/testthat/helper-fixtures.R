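# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small but complete synthetic herd (6 sires x 5 dams, ~45 progeny,
# 3 time points of OTU tables at depth 10,000).
small_herd <- function() {
  if (is.null(.fixture_env$herd)) {
    cfg <- herdqg::sim_config(n_sires = 6, dams_per_sire = 5, seed = 3)
    .fixture_env$herd <- suppressMessages(herdqg::simulate_herd(cfg))
  }
  .fixture_env$herd
}

# Genus-level two-cluster count table with known labels, independent of
# the herd generator (used by enterotype tests).
planted_genus_table <- function(n = 120, n_genera = 40, depth = 2000,
                                seed = 11, k = 2, conc = 60,
                                boost = 40) {
  set.seed(seed)
  base <- 0.9^seq_len(n_genera)
  markers <- seq_len(k)
  templates <- lapply(markers, function(m) {
    x <- base
    x[m] <- x[m] * boost
    x / sum(x)
  })
  lab <- sample(seq_len(k), n, replace = TRUE)
  P <- do.call(rbind, templates)[lab, , drop = FALSE]
  G <- rdirich(n, rep(1, n_genera))
  G <- matrix(stats::rgamma(n * n_genera, shape = as.vector(P) * conc),
              nrow = n)
  G <- G / rowSums(G)
  counts <- t(apply(G, 1, function(p) stats::rmultinom(1, depth, p)))
  dimnames(counts) <- list(paste0("s", seq_len(n)),
                           paste0("g", seq_len(n_genera)))
  list(counts = counts, labels = lab)
}

# Half-sib phenotype simulation for REML tests: builds a config whose
# traits carry the requested variance fractions, all mutually independent.
grid_herd <- function(n_sires, dams_per_sire, progeny_per_dam,
                      cells, seed, var_p = 1) {
  stopifnot(is.data.frame(cells))
  tr <- data.frame(
    trait = cells$trait, mean = 0, var_p = var_p,
    h2 = cells$h2, c2_litter = cells$c2_litter, c2_pen = cells$c2_pen,
    sex_effect = 0.1 * sqrt(var_p), stringsAsFactors = FALSE)
  tr$bs_effects <- I(replicate(nrow(tr), c(0, 0.2, -0.1) * sqrt(var_p),
                               simplify = FALSE))
  tr$dl_effect <- 0
  rownames(tr) <- tr$trait
  R <- diag(nrow(tr)); dimnames(R) <- list(tr$trait, tr$trait)
  cfg <- herdqg::sim_config(n_sires = n_sires, dams_per_sire = dams_per_sire,
                            progeny_per_dam = progeny_per_dam,
                            traits = tr, genetic_corr = R, seed = seed)
  ped <- herdqg::simulate_pedigree(cfg)
  frame <- suppressMessages(herdqg::simulate_design(ped, cfg))
  traits <- herdqg::simulate_traits(ped, frame, cfg)
  list(pedigree = ped, frame = frame, traits = traits, config = cfg)
}
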