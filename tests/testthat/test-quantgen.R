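test_that("pedigree reading sorts, adds missing founders, and rejects bad input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "P1,S,D", "P2,S,D", "X,S,0"), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(ped), 5)                  # S and D added as founders
  expect_true(all(is.na(ped$sire[ped$animal %in% c("S", "D")])))
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  expect_true(pos["S"] < pos["P1"] && pos["D"] < pos["P1"])
  # shuffled rows give the identical sorted pedigree
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "X,S,0", "P2,S,D", "P1,S,D"), f2)
  expect_identical(read_pedigree(f2), ped)
  # self-parentage and cycles are rejected
  expect_error(sort_pedigree(data.frame(animal = "A", sire = "A", dam = NA)),
               "own parent")
  expect_error(sort_pedigree(data.frame(animal = c("A", "B"),
                                        sire = c("B", "A"),
                                        dam = c(NA, NA))), "cycle")
  expect_error(sort_pedigree(data.frame(animal = c("A", "A"),
                                        sire = c(NA, NA), dam = c(NA, NA))),
               "duplicate")
})

test_that("the A matrix reproduces textbook relationships", {
  ped <- data.frame(animal = c("S", "D", "P1", "P2", "H"),
                    sire = c(NA, NA, "S", "S", "S"),
                    dam = c(NA, NA, "D", "D", NA))
  A <- numerator_relationship_matrix(ped)
  expect_equal(unname(A["P1", "P2"]), 0.5)    # full sibs
  expect_equal(unname(A["S", "P1"]), 0.5)     # parent-offspring
  expect_equal(unname(A["P1", "H"]), 0.25)    # half sibs
  expect_equal(unname(diag(A)), rep(1, 5))    # non-inbred
  # unrelated founders give the identity
  founders <- data.frame(animal = letters[1:4], sire = NA, dam = NA)
  expect_equal(unname(numerator_relationship_matrix(founders)), diag(4))
  # sire mated to his own daughter: offspring diagonal 1.25
  ped2 <- data.frame(animal = c("S", "D", "G", "I"),
                     sire = c(NA, NA, "S", "S"),
                     dam = c(NA, NA, "D", "G"))
  A2 <- numerator_relationship_matrix(ped2)
  expect_equal(unname(A2["I", "I"]), 1.25)
})

test_that("the A matrix agrees with gene-dropping IBD estimates", {
  # 10-animal pedigree with inbreeding and collateral relatives
  ped <- data.frame(
    animal = c("F1", "F2", "F3", "F4", "A", "B", "C", "D", "E", "G"),
    sire = c(NA, NA, NA, NA, "F1", "F1", "A", "A", "C", "C"),
    dam = c(NA, NA, NA, NA, "F2", "F3", "F4", "B", "D", "E"))
  A <- numerator_relationship_matrix(ped)
  Ahat <- gene_drop_A(ped, n_drops = 4e4, seed = 2)
  # binomial MC SE for a proportion ~ a/2 estimated from 4e4 drops
  se <- pmax(sqrt(pmax(A / 2 * (1 - A / 2), 1e-4) / 4e4) * 2, 1e-4)
  expect_true(all(abs(A - Ahat) < 3.5 * se + 0.01))
})

test_that("estimates are invariant to record order and id relabeling", {
  cells <- data.frame(trait = "t", h2 = 0.3, c2_litter = 0.1, c2_pen = 0)
  g <- grid_herd(12, 8, 2L, cells, seed = 41)
  A <- numerator_relationship_matrix(g$pedigree)
  dat <- merge(g$frame, g$traits$phenotypes, by = "animal")
  f1 <- reml_univariate("t", dat, A = A, random = c("animal", "litter"))
  perm <- sample(nrow(dat))
  f2 <- reml_univariate("t", dat[perm, ], A = A, random = c("animal", "litter"))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  # relabel ids consistently
  dat3 <- dat
  dat3$animal <- paste0("zz_", dat3$animal)
  A3 <- A
  rownames(A3) <- colnames(A3) <- paste0("zz_", rownames(A))
  f3 <- reml_univariate("t", dat3, A = A3, random = c("animal", "litter"))
  expect_equal(f1$theta, f3$theta, tolerance = 1e-8)
})

test_that("REML equals the ANOVA estimator on a balanced one-way design", {
  set.seed(43)
  ns <- 40; npr <- 20
  g <- factor(rep(seq_len(ns), each = npr))
  y <- 5 + rnorm(ns, 0, sqrt(3))[as.integer(g)] + rnorm(ns * npr, 0, 2)
  Blist <- list(group = Matrix::tcrossprod(herdqg:::.indicator(g)),
                residual = Matrix::Diagonal(length(y)))
  fit <- reml_fit(y, matrix(1, length(y), 1), Blist, var_par = c(TRUE, TRUE))
  oracle <- anova_group_varcomp(y, g)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta["group"]), unname(oracle["group"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$theta["residual"]), unname(oracle["residual"]),
               tolerance = 1e-6)
  # restricted likelihood agrees with lme4 at the optimum
  lmm <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lmm)), tolerance = 1e-4)
})

test_that("a pure-noise trait gives a near-zero heritability estimate", {
  h2s <- numeric(4)
  for (r in 1:4) {
    cells <- data.frame(trait = "noise", h2 = 0, c2_litter = 0, c2_pen = 0)
    g <- grid_herd(25, 10, 2L, cells, seed = 600 + r)
    A <- numerator_relationship_matrix(g$pedigree)
    dat <- merge(g$frame, g$traits$phenotypes, by = "animal")
    fit <- reml_univariate("noise", dat, A = A, random = c("animal", "litter"))
    h2s[r] <- heritability(fit)$h2
  }
  expect_lt(mean(h2s), 0.05)
})

test_that("heritability and correlation arithmetic follow their definitions", {
  fake <- list(theta = c(animal = 1, litter = 0, pen = 0, residual = 3),
               cov_theta = NULL, floor = 1e-8)
  expect_equal(heritability(fake)$h2, 0.25)
  fake0 <- list(theta = c(animal = 0, residual = 2), cov_theta = NULL,
                floor = 1e-8)
  expect_equal(heritability(fake0)$h2, 0)
  bfake <- list(theta = c(animal.v1 = 1, animal.c = 0.8, animal.v2 = 1,
                          residual.v1 = 1, residual.c = 0, residual.v2 = 1),
                cov_theta = NULL, floor = 1e-10)
  cc <- correlations(bfake)
  expect_equal(cc$r_g, 0.8)
  expect_equal(cc$r_p, 0.8 / 2)
  zfake <- bfake
  zfake$theta["animal.c"] <- 0
  expect_equal(correlations(zfake)$r_g, 0)
})

test_that("a trait paired with its jittered copy has genetic correlation near 1", {
  cells <- data.frame(trait = "t", h2 = 0.35, c2_litter = 0.1, c2_pen = 0)
  g <- grid_herd(20, 8, 2L, cells, seed = 51)
  A <- numerator_relationship_matrix(g$pedigree)
  dat <- merge(g$frame, g$traits$phenotypes, by = "animal")
  set.seed(52)
  dat$t2 <- dat$t + rnorm(nrow(dat), 0, 0.05)
  fit <- reml_bivariate(c("t", "t2"), dat, A = A, random = c("animal", "litter"))
  expect_gte(correlations(fit)$r_g, 0.95)
})

test_that("likelihood-ratio tests apply the boundary mixture and nesting checks", {
  a <- list(logLik = -100, random = c("animal", "residual"))
  b <- list(logLik = -95, random = c("animal", "litter", "residual"))
  lrt <- likelihood_ratio_test(a, b)
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$p_naive, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(lrt$p_mixture, 0.5 * pchisq(10, 1, lower.tail = FALSE))
  # identical models: statistic 0; mixture convention gives 0.5
  same <- likelihood_ratio_test(a, list(logLik = -100,
                                        random = c("animal", "pen", "residual")))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_naive, 1)
  expect_equal(same$p_mixture, 0.5 * 1 + 0.5 * 1)
  expect_error(likelihood_ratio_test(b, a), "not nested")
})

test_that("fixed-effect models recover planted effects and the F = t^2 identity", {
  d <- data.frame(sex = rep(c("F", "M"), 30), bs = rep(c("b1", "b2", "b3"), 20))
  d$y <- 1 + 0.2 * (d$sex == "M") + 0.5 * (d$bs == "b2")
  fit <- suppressWarnings(fit_fixed_model("y", d, c("sex", "bs")))
  expect_equal(unname(fit$solutions["sexM"]), 0.2, tolerance = 1e-10)
  set.seed(53)
  d2 <- data.frame(g = rep(c("a", "b"), each = 20))
  d2$y <- rnorm(40) + 0.5 * (d2$g == "b")
  fitF <- fit_fixed_model("y", d2, "g")
  tt <- stats::t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(fitF$anova["g", "F value"], unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("a planted enterotype contrast on back fat is recovered on average", {
  set.seed(54)
  ests <- numeric(10)
  for (r in 1:10) {
    n <- 600
    d <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                    bs = sample(c("b1", "b2", "b3"), n, TRUE),
                    family = sample(paste0("f", 1:20), n, TRUE),
                    days = rnorm(n, 145, 5),
                    enterotype = sample(c("C", "D"), n, TRUE))
    d$BF <- 1.6 + 0.05 * (d$sex == "M") + 0.002 * (d$days - 145) +
      0.10 * (d$enterotype == "D") + rnorm(n, 0, 0.28)
    fit <- fit_fixed_model("BF", d, c("sex", "days", "family", "bs",
                                      "enterotype"))
    ests[r] <- unname(fit$solutions["enterotypeD"])
  }
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.10), 3 * mc_se)
})

test_that("family effect profiles recover limiting cross-age correlations", {
  set.seed(55)
  fams <- paste0("f", 1:28)
  base <- rnorm(28, 0, 0.4)
  mk <- function(eff_by_age) {
    do.call(rbind, lapply(c("w", "m", "o"), function(a) {
      data.frame(family = rep(fams, each = 12), age = a,
                 sex = rep(c("F", "M"), 14 * 12),
                 bs = sample(c("b1", "b2", "b3"), 28 * 12, TRUE),
                 shannon = 4 + rep(eff_by_age[[a]], each = 12) +
                   rnorm(28 * 12, 0, 0.25))
    }))
  }
  d_same <- mk(list(w = base, m = base, o = base))
  pr_same <- family_effect_profile(d_same)
  expect_true(all(pr_same$correlations[upper.tri(pr_same$correlations)] > 0.8))
  d_flip <- mk(list(w = base, m = -base, o = base))
  pr_flip <- family_effect_profile(d_flip)
  expect_lt(pr_flip$correlations["w", "m"], -0.8)
  expect_gt(pr_flip$correlations["w", "o"], 0.8)
})
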