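test_that("pedigree simulation respects the design counts and is deterministic", {
  cfg <- sim_config(n_sires = 1, dams_per_sire = 1, progeny_per_dam = 2L,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4)                       # sire, dam, 2 full sibs
  prog <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(prog), 2)
  expect_equal(prog$sire[1], prog$sire[2])
  expect_equal(prog$dam[1], prog$dam[2])

  cfg2 <- sim_config(n_sires = 28, dams_per_sire = 26, seed = 9)
  ped2 <- simulate_pedigree(cfg2)
  n_litters <- length(unique(ped2$dam[!is.na(ped2$dam)]))
  expect_equal(n_litters, 28 * 26)
  expect_gte(sum(!is.na(ped2$sire)), 28 * 26)      # >= 1 progeny per litter

  expect_identical(simulate_pedigree(cfg2), ped2)  # same seed, same records
  expect_error(sim_config(n_sires = 0), "counts")
})

test_that("design keeps pens single-family and single-sex with balanced sexes", {
  herd <- small_herd()
  frame <- herd$frame
  for (p in unique(frame$pen)) {
    rows <- frame[frame$pen == p, ]
    expect_length(unique(rows$family), 1)
    expect_length(unique(rows$sex), 1)
  }
  # litters nested in dams, one per dam
  expect_true(all(frame$litter == frame$dam))
  # alternating sexes keep the overall split near 1:1
  expect_lt(abs(mean(frame$sex == "M") - 0.5), 0.15)
  # each animal appears once per time point in the OTU tables
  for (tp in names(herd$otu$counts)) {
    expect_equal(anyDuplicated(rownames(herd$otu$counts[[tp]])), 0)
    expect_equal(nrow(herd$otu$counts[[tp]]), nrow(frame))
  }
  # determinism of the full generator
  herd2 <- suppressMessages(simulate_herd(herd$config))
  expect_identical(herd2$frame, frame)
  expect_identical(herd2$otu$counts, herd$otu$counts)
  expect_identical(herd2$traits$phenotypes, herd$traits$phenotypes)
})

test_that("null additive variance yields breeding values that are all zero", {
  cells <- data.frame(trait = "null_t", h2 = 0, c2_litter = 0.3, c2_pen = 0)
  g <- grid_herd(10, 6, 2L, cells, seed = 21)
  expect_lt(stats::var(g$traits$tbv$null_t), 1e-20)
  # full-sib phenotypic resemblance then comes only from litter
  ph <- merge(g$frame, g$traits$phenotypes, by = "animal")
  lit_var <- stats::var(stats::ave(ph$null_t, ph$litter) )
  expect_gt(lit_var, 0.05)   # litter effect visible at c2 = 0.3
})

test_that("simulated breeding values match the nominal variance and correlation", {
  cells <- data.frame(trait = c("t1", "t2"), h2 = 0.25, c2_litter = 0,
                      c2_pen = 0)
  tr <- data.frame(trait = cells$trait, mean = 0, var_p = 1, h2 = 0.25,
                   c2_litter = 0, c2_pen = 0, sex_effect = 0,
                   stringsAsFactors = FALSE)
  tr$bs_effects <- I(replicate(2, c(0, 0, 0), simplify = FALSE))
  tr$dl_effect <- 0
  rownames(tr) <- tr$trait
  R <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(tr$trait, tr$trait))
  cfg <- sim_config(n_sires = 100, dams_per_sire = 25, progeny_per_dam = 2L,
                    traits = tr, genetic_corr = R, seed = 31)
  ped <- simulate_pedigree(cfg)
  frame <- suppressMessages(simulate_design(ped, cfg))
  sim <- simulate_traits(ped, frame, cfg)
  u <- sim$tbv
  n <- nrow(u)
  expect_gte(n, 4500)
  # sample variance of true breeding values within 3 MC SE of 0.25
  # (progeny are correlated through sires; allow an inflated SE)
  mc_se <- 0.25 * sqrt(2 / 100)          # conservative: ~100 independent families
  expect_lt(abs(stats::var(u$t1) - 0.25), 3 * mc_se)
  # genetic correlation of the tbv pairs near 0.8
  r <- stats::cor(u$t1, u$t2)
  expect_lt(abs(r - 0.8), 3 * (1 - 0.8^2) / sqrt(100))
})

test_that("OTU tables respect depth exactly and track their templates", {
  herd <- small_herd()
  for (tp in names(herd$otu$counts)) {
    expect_true(all(rowSums(herd$otu$counts[[tp]]) == herd$config$depth))
  }
  # near-infinite concentration pins samples to the template: per-genus
  # proportions within 3 binomial SE of the template mean
  cfg <- sim_config(n_sires = 4, dams_per_sire = 4, concentration = 1e7,
                    depth = 5000, seed = 13)
  ped <- simulate_pedigree(cfg)
  frame <- suppressMessages(simulate_design(ped, cfg))
  otu <- simulate_otu_table(frame, cfg)
  tp <- "weaning"
  lab <- otu$labels[otu$labels$time_point == tp, "enterotype"]
  gen <- aggregate_taxa(otu$counts[[tp]], otu$taxonomy, "genus")
  gen <- gen[, names(cfg$templates[[tp]]$templates$A)]
  idx_a <- which(lab == "A")
  p_hat <- colSums(gen[idx_a, , drop = FALSE]) /
    sum(gen[idx_a, , drop = FALSE])
  tmpl <- cfg$templates[[tp]]$templates$A
  n_reads <- length(idx_a) * 5000
  se <- sqrt(tmpl * (1 - tmpl) / n_reads)
  big <- tmpl > 1e-3
  expect_true(all(abs(p_hat[big] - tmpl[big]) < 3 * se[big] + 1e-4))
})

test_that("template length mismatches and bad variance fractions are rejected", {
  tm <- default_enterotype_templates()
  tm$week15$b <- tm$week15$b[-1]
  expect_error(sim_config(templates = tm), "mismatch")
  tr <- default_trait_params()
  tr$h2[1] <- 0.9; tr$c2_litter[1] <- 0.3
  expect_error(sim_config(traits = tr), "sum to <= 1")
})
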