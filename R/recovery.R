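# Simulation-study harnesses: parameter recovery, LRT calibration/power,
# enterotype recovery, and the Welch power computation. The analysis
# drivers and the acceptance checks all run these.

#' Build a trait parameter table for simulation studies
#'
#' One row per requested trait, with unit phenotypic variance by default
#' and mild fixed effects, suitable for variance-component recovery work.
#'
#' @param trait trait names.
#' @param h2,c2_litter,c2_pen variance fractions (recycled).
#' @param var_p phenotypic variance.
#' @param mean trait mean.
#' @return data.frame in the layout of [default_trait_params()].
#' @export
make_trait_params <- function(trait, h2, c2_litter = 0, c2_pen = 0,
                              var_p = 1, mean = 0) {
  tr <- data.frame(trait = trait, mean = mean, var_p = var_p,
                   h2 = h2, c2_litter = c2_litter, c2_pen = c2_pen,
                   sex_effect = 0.1 * sqrt(var_p), stringsAsFactors = FALSE)
  tr$bs_effects <- I(replicate(nrow(tr), c(0, 0.2, -0.1) * sqrt(var_p[1]),
                               simplify = FALSE))
  tr$dl_effect <- 0
  rownames(tr) <- tr$trait
  tr
}

#' Univariate variance-component recovery over a parameter grid
#'
#' For every (h2, litter, pen) cell, simulates half-sib herds under the
#' animal model and re-estimates the components by REML, fitting every
#' random term regardless of whether its true variance is zero. All cells
#' share each replicate's pedigree and design (the cells enter as
#' independent traits), so one relationship matrix serves every fit.
#'
#' @param h2,litter,pen grids of true variance fractions.
#' @param n_sires,dams_per_sire,progeny_per_dam design (defaults give
#'   n = 5000 records).
#' @param reps replicates per cell.
#' @param seed root seed.
#' @return data.frame per cell: true values, mean estimates, MC standard
#'   errors, and the per-replicate estimates as attribute "draws".
#' @export
recovery_grid_univariate <- function(h2 = c(0.05, 0.15, 0.25, 0.35),
                                     litter = c(0, 0.1), pen = c(0, 0.05),
                                     n_sires = 100, dams_per_sire = 25,
                                     progeny_per_dam = 2L,
                                     reps = 3, seed = 1) {
  cells <- expand.grid(h2 = h2, c2_litter = litter, c2_pen = pen,
                       KEEP.OUT.ATTRS = FALSE)
  cells$trait <- sprintf("t%02d", seq_len(nrow(cells)))
  tr <- make_trait_params(cells$trait, cells$h2, cells$c2_litter, cells$c2_pen)
  R <- diag(nrow(tr)); dimnames(R) <- list(tr$trait, tr$trait)
  seeds <- with_seed(seed, sample.int(2147483646L, reps))
  draws <- array(NA_real_, c(nrow(cells), reps, 2),
                 dimnames = list(cells$trait, NULL, c("h2", "sigma2_a")))
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_sires = n_sires, dams_per_sire = dams_per_sire,
                      progeny_per_dam = progeny_per_dam, traits = tr,
                      genetic_corr = R, seed = seeds[r])
    ped <- simulate_pedigree(cfg)
    frame <- suppressMessages(simulate_design(ped, cfg))
    sim <- simulate_traits(ped, frame, cfg)
    A <- numerator_relationship_matrix(ped)
    dat <- merge(frame, sim$phenotypes, by = "animal")
    for (i in seq_len(nrow(cells))) {
      fit <- reml_univariate(cells$trait[i], dat, A = A,
                             random = c("animal", "litter", "pen"))
      draws[i, r, "h2"] <- heritability(fit)$h2
      draws[i, r, "sigma2_a"] <- fit$theta[["animal"]]
    }
  }
  cells$mean_h2 <- apply(draws[, , "h2", drop = FALSE], 1, mean)
  cells$mcse_h2 <- apply(draws[, , "h2", drop = FALSE], 1,
                         stats::sd) / sqrt(reps)
  cells$mean_sigma2_a <- apply(draws[, , "sigma2_a", drop = FALSE], 1, mean)
  attr(cells, "draws") <- draws
  cells
}

#' Bivariate genetic-correlation recovery
#'
#' Simulates trait pairs with the requested genetic correlations (both
#' traits h2 = 0.2, litter 0.1) and re-estimates r_g by bivariate REML,
#' warm-started from the univariate fits.
#'
#' @param r_g true genetic correlations to plant.
#' @param reps replicates per value.
#' @param n_sires,dams_per_sire,progeny_per_dam design.
#' @param h2,c2_litter true fractions shared by both traits.
#' @param seed root seed.
#' @return data.frame per r_g value: mean estimate, MC SE, and the draws.
#' @export
recovery_bivariate <- function(r_g = c(-0.5, 0, 0.8), reps = 3,
                               n_sires = 100, dams_per_sire = 25,
                               progeny_per_dam = 2L, h2 = 0.2,
                               c2_litter = 0.1, seed = 1) {
  seeds <- with_seed(seed, sample.int(2147483646L, reps * length(r_g)))
  draws <- matrix(NA_real_, length(r_g), reps)
  k <- 0
  for (v in seq_along(r_g)) {
    tr <- make_trait_params(c("x1", "x2"), h2, c2_litter)
    R <- matrix(c(1, r_g[v], r_g[v], 1), 2,
                dimnames = list(tr$trait, tr$trait))
    for (r in seq_len(reps)) {
      k <- k + 1
      cfg <- sim_config(n_sires = n_sires, dams_per_sire = dams_per_sire,
                        progeny_per_dam = progeny_per_dam, traits = tr,
                        genetic_corr = R, seed = seeds[k])
      ped <- simulate_pedigree(cfg)
      frame <- suppressMessages(simulate_design(ped, cfg))
      sim <- simulate_traits(ped, frame, cfg)
      A <- numerator_relationship_matrix(ped)
      dat <- merge(frame, sim$phenotypes, by = "animal")
      u1 <- reml_univariate("x1", dat, A = A, random = c("animal", "litter"))
      u2 <- reml_univariate("x2", dat, A = A, random = c("animal", "litter"))
      init <- c(u1$theta[["animal"]], 0, u2$theta[["animal"]],
                u1$theta[["litter"]], 0, u2$theta[["litter"]],
                u1$theta[["residual"]], 0, u2$theta[["residual"]])
      fit <- reml_bivariate(c("x1", "x2"), dat, A = A,
                            random = c("animal", "litter"), init = init)
      draws[v, r] <- correlations(fit)$r_g
    }
  }
  data.frame(r_g_true = r_g, mean_r_g = rowMeans(draws),
             mcse_r_g = apply(draws, 1, stats::sd) / sqrt(reps),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test calibration and power study
#'
#' Simulates a trait with the given true litter and pen fractions, fits the
#' nested model pair, and returns the mixture p-value per replicate.
#' `comparison = "pen"` tests litter+pen vs litter (model 5 vs 4);
#' `"litter"` tests animal+litter vs animal (model 4 vs 3).
#'
#' @param reps number of replicates.
#' @param c2_litter,c2_pen true variance fractions.
#' @param h2 true heritability.
#' @param comparison which nested pair to compare.
#' @param n_sires,dams_per_sire,progeny_per_dam design.
#' @param seed root seed.
#' @return data.frame with one row per replicate: statistic, p_mixture.
#' @export
lrt_study <- function(reps = 200, c2_litter = 0.1, c2_pen = 0, h2 = 0.2,
                      comparison = c("pen", "litter"),
                      n_sires = 28, dams_per_sire = 6, progeny_per_dam = 2L,
                      seed = 1) {
  comparison <- match.arg(comparison)
  tr <- make_trait_params("y", h2, c2_litter, c2_pen)
  R <- matrix(1, 1, 1, dimnames = list("y", "y"))
  seeds <- with_seed(seed, sample.int(2147483646L, reps))
  out <- data.frame(statistic = numeric(reps), p_mixture = numeric(reps))
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_sires = n_sires, dams_per_sire = dams_per_sire,
                      progeny_per_dam = progeny_per_dam, traits = tr,
                      genetic_corr = R, seed = seeds[r])
    ped <- simulate_pedigree(cfg)
    frame <- suppressMessages(simulate_design(ped, cfg))
    sim <- simulate_traits(ped, frame, cfg)
    A <- numerator_relationship_matrix(ped)
    dat <- merge(frame, sim$phenotypes, by = "animal")
    terms <- if (comparison == "pen") {
      list(reduced = c("animal", "litter"), full = c("animal", "litter", "pen"))
    } else {
      list(reduced = "animal", full = c("animal", "litter"))
    }
    f_red <- reml_univariate("y", dat, A = A, random = terms$reduced)
    f_full <- reml_univariate("y", dat, A = A, random = terms$full)
    lrt <- likelihood_ratio_test(f_red, f_full)
    out$statistic[r] <- lrt$statistic
    out$p_mixture[r] <- lrt$p_mixture
  }
  out
}

#' Enterotype recovery on a synthetic herd
#'
#' Runs the full abundance + enterotyping path (filter, rarefy, genus
#' aggregation, JSD, PAM, CH selection) on a generated herd and scores the
#' chosen cluster number and adjusted Rand index against the planted
#' labels at each time point.
#'
#' @param config a [sim_config()].
#' @param k_range candidate cluster numbers.
#' @param min_total sparse-OTU filter (scaled to the synthetic library
#'   sizes).
#' @return data.frame per time point: chosen_k, ARI, mean silhouette.
#' @export
enterotype_recovery <- function(config, k_range = 2:6, min_total = NULL) {
  herd <- simulate_herd(config)
  if (is.null(min_total)) {
    # same fraction of the total reads as 1200 out of ~1200 x 10000
    min_total <- round(1e-4 * nrow(herd$frame) * config$depth)
  }
  rows <- lapply(names(herd$otu$counts), function(tp) {
    counts <- filter_sparse_otus(herd$otu$counts[[tp]], min_total)
    gen <- aggregate_taxa(counts, herd$otu$taxonomy, "genus")
    rel <- relative_abundance(gen)
    fit <- select_enterotypes(rel, k_range)
    truth <- herd$otu$labels[herd$otu$labels$time_point == tp, "enterotype"]
    data.frame(time_point = tp, n_samples = nrow(rel),
               chosen_k = fit$chosen_k,
               ari = adjusted_rand_index(fit$assignments, truth),
               silhouette = fit$silhouette_by_k[[as.character(fit$chosen_k)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Power of the Welch t-test at given group means and SDs
#'
#' Draws normal samples at the two groups' means and SDs and counts how
#' often the Welch test rejects at the given threshold.
#'
#' @param mean1,sd1,mean2,sd2 group parameters.
#' @param n per-group sample size.
#' @param reps replicates.
#' @param alpha rejection threshold.
#' @param seed seed.
#' @return rejection rate (fraction of replicates with p < alpha).
#' @export
welch_power <- function(mean1 = 3.33, sd1 = 0.67, mean2 = 4.13, sd2 = 0.43,
                        n = 400, reps = 200, alpha = 0.001, seed = 1) {
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      x <- stats::rnorm(n, mean1, sd1)
      y <- stats::rnorm(n, mean2, sd2)
      stats::t.test(x, y)$p.value < alpha
    }, logical(1)))
  })
}
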