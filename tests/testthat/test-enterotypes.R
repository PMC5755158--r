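test_that("JSD reproduces hand values and its square root is bounded", {
  expect_equal(jsd_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0, tolerance = 1e-12)
  # maximal divergence between disjoint supports: sqrt(ln 2)
  d <- sqrt(jsd_divergence(c(1, 0), c(0, 1)))
  expect_lt(abs(d - sqrt(log(2))), 1e-4)
  # hand evaluation with M = (0.75, 0.25): JSD = 0.75 ln(4/3)
  expect_equal(jsd_divergence(c(0.5, 0.5), c(1, 0)), 0.75 * log(4 / 3),
               tolerance = 1e-4)
  expect_error(jsd_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
})

test_that("the JSD distance matrix is symmetric, zero-diagonal, and matches pairwise calls", {
  set.seed(10)
  m <- rdirich(15, rep(0.6, 12))
  D <- jsd_distance_matrix(m)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D <= sqrt(log(2)) + 1e-9))
  for (pair in list(c(1, 2), c(3, 9), c(14, 15))) {
    expect_equal(D[pair[1], pair[2]],
                 sqrt(jsd_divergence(m[pair[1], ], m[pair[2], ])),
                 tolerance = 1e-10)
  }
})

test_that("sqrt-JSD satisfies the triangle inequality on random triples", {
  set.seed(12)
  m <- rdirich(60, rep(0.4, 20))
  D <- jsd_distance_matrix(m)
  worst <- 0
  for (i in 1:1000) {
    t3 <- sample(60, 3)
    worst <- max(worst, D[t3[1], t3[2]] -
                   (D[t3[1], t3[3]] + D[t3[3], t3[2]]))
  }
  expect_lte(worst, 1e-12)
})

test_that("PAM equals exhaustive k-medoids on small instances", {
  set.seed(14)
  for (rep_ in 1:25) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(pts))
    fit <- pam_cluster(d, k)
    oracle <- exhaustive_kmedoids(d, k)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-10)
  }
})

test_that("PAM recovers planted separation and matches the cluster package objective", {
  # two well-separated point sets
  set.seed(15)
  d <- as.matrix(dist(c(rnorm(4, 0, 0.05), rnorm(4, 10, 0.05))))
  fit <- pam_cluster(d, 2)
  expect_equal(fit$assignments[1:4], rep(fit$assignments[1], 4))
  expect_equal(fit$assignments[5:8], rep(fit$assignments[5], 4))
  expect_false(fit$assignments[1] == fit$assignments[5])
  # k = n - 1 forces the objective to the smallest pairwise distance
  fit_n1 <- pam_cluster(d, 7)
  expect_equal(fit_n1$objective, min(d[upper.tri(d)]), tolerance = 1e-12)
  # independent implementation agreement on larger random instances
  for (s in 1:5) {
    set.seed(100 + s)
    dd <- as.matrix(dist(matrix(rnorm(40 * 3), 40)))
    for (k in c(2, 4)) {
      ours <- pam_cluster(dd, k)$objective
      # cluster::pam reports the average dissimilarity; ours is the sum
      ref <- cluster::pam(stats::as.dist(dd), k)$objective[["swap"]] * nrow(dd)
      expect_equal(ours, ref, tolerance = 1e-8)
    }
  }
  expect_error(pam_cluster(d, 8), "k must be <")
  expect_error(pam_cluster(d, 1), "k must be >")
})

test_that("the PCoA embedding reproduces Euclidean-embeddable distances", {
  set.seed(16)
  pts <- matrix(rnorm(12 * 3), 12)
  d <- as.matrix(dist(pts))
  coords <- pcoa_embed(d)
  d2 <- as.matrix(dist(coords))
  expect_lt(sqrt(sum((d - d2)^2)), 1e-6)
})

test_that("Calinski-Harabasz behaves at degenerate and planted configurations", {
  # two point masses: zero within-cluster spread
  d <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5,
                5, 5, 0, 0,
                5, 5, 0, 0), 4, byrow = TRUE)
  expect_equal(calinski_harabasz(d, c(1, 1, 2, 2)), Inf)
  expect_true(is.na(calinski_harabasz(d, rep(1, 4))))
  # planted 2-cluster data prefer k = 2 over k in 3..6
  wins <- 0
  for (s in 1:20) {
    tab <- planted_genus_table(n = 60, seed = 400 + s, boost = 40)
    rel <- relative_abundance(tab$counts)
    dmat <- jsd_distance_matrix(rel)
    coords <- pcoa_embed(dmat)
    ch <- vapply(2:6, function(k)
      calinski_harabasz(assignments = pam_cluster(dmat, k)$assignments,
                        coords = coords, d = NULL), numeric(1))
    if (which.max(ch) == 1) wins <- wins + 1
  }
  expect_gte(wins, 19)                     # >= 95% of draws
})

test_that("silhouette widths match hand computation and the cluster package", {
  # 4-point worked case on a line: 0, 1, 10, 11; clusters {1,2}, {3,4}
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  s <- silhouette_width(d, c(1, 1, 2, 2))
  # for point 1: a = 1, b = mean(10, 11) = 10.5 -> s = 9.5/10.5
  expect_equal(unname(s$widths[1]), 9.5 / 10.5, tolerance = 1e-12)
  # for point 3 (at 10): a = 1, b = mean(10, 9) = 9.5 -> s = 8.5/9.5
  expect_equal(unname(s$widths[3]), 8.5 / 9.5, tolerance = 1e-12)
  ref <- cluster::silhouette(c(1, 1, 2, 2), stats::as.dist(d))
  expect_equal(unname(s$widths), unname(ref[, "sil_width"]), tolerance = 1e-12)
  # all points equidistant: s = 0 everywhere
  deq <- matrix(1, 5, 5); diag(deq) <- 0
  expect_equal(silhouette_width(deq, c(1, 1, 2, 2, 2))$mean, 0)
  # two tight, far clusters: mean width near 1
  dfar <- as.matrix(dist(c(0, 0.01, 0.02, 100, 100.01, 100.02)))
  expect_gt(silhouette_width(dfar, c(1, 1, 1, 2, 2, 2))$mean, 0.99)
})

test_that("enterotype selection recovers the planted number of clusters", {
  tab2 <- planted_genus_table(n = 120, seed = 11, k = 2, boost = 40)
  fit2 <- select_enterotypes(relative_abundance(tab2$counts), 2:6)
  expect_equal(fit2$chosen_k, 2)
  expect_gt(adjusted_rand_index(fit2$assignments, tab2$labels), 0.95)
  tab3 <- planted_genus_table(n = 120, seed = 19, k = 3, boost = 40)
  fit3 <- select_enterotypes(relative_abundance(tab3$counts), 2:6)
  expect_equal(fit3$chosen_k, 3)
  expect_gt(adjusted_rand_index(fit3$assignments, tab3$labels), 0.95)
  expect_error(select_enterotypes(relative_abundance(tab2$counts),
                                  integer(0)), "empty")
})

test_that("a single-template control raises the weak-structure warning", {
  warned <- 0
  for (s in 1:5) {
    tab <- planted_genus_table(n = 100, seed = 500 + s, k = 1, boost = 1)
    got <- tryCatch({
      select_enterotypes(relative_abundance(tab$counts), 2:6)
      FALSE
    }, warning = function(w) grepl("flat", conditionMessage(w)))
    if (isTRUE(got)) warned <- warned + 1
  }
  expect_gte(warned, 4)
  # and the planted-structure fixture does not warn
  tab2 <- planted_genus_table(n = 100, seed = 11, k = 2, boost = 40)
  expect_no_warning(select_enterotypes(relative_abundance(tab2$counts), 2:6))
})

test_that("LDA effect sizes filter nulls, capture strong shifts, and are antisymmetric", {
  set.seed(21)
  n <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  # genus 1: strong shift (ppm-scale 1e5 vs 1e2); genus 2: null; rest noise
  base <- matrix(rgamma(n * 8, 5, 1), n, 8)
  base[, 1] <- c(rgamma(n / 2, 50, 1), rgamma(n / 2, 0.05, 1)) + 1e-3
  m <- base / rowSums(base)
  colnames(m) <- paste0("g", 1:8)
  res <- lda_effect_size(m, lab, n_boot = 0)
  expect_gt(res$lda_score[1], 2)
  expect_identical(res$enriched_class[1], "A")
  expect_true(res$significant[1])
  # classes with identical per-genus distributions are all excluded by
  # the KW filter (class B rows duplicate class A rows)
  m2 <- rbind(m[1:(n / 2), ], m[1:(n / 2), ])
  res2 <- lda_effect_size(m2, lab, n_boot = 0)
  expect_true(all(is.na(res2$lda_score)))
  # swapping labels negates scores, keeps |score| ranking
  swapped <- lda_effect_size(m, factor(lab, levels = c("B", "A")), n_boot = 0)
  keep <- !is.na(res$lda_score)
  expect_equal(res$lda_score[keep], -swapped$lda_score[keep], tolerance = 1e-9)
  expect_error(lda_effect_size(m, rep("A", n)), "two classes")
})

test_that("LDA scores are monotone in the planted effect size", {
  set.seed(22)
  n <- 80
  lab <- rep(c("A", "B"), each = n / 2)
  shifts <- c(1.5, 2.5, 4, 7, 12, 25, 60, 150)
  base <- matrix(rgamma(n * 10, 8, 1), n, 10)
  for (j in seq_along(shifts)) {
    base[lab == "A", j] <- base[lab == "A", j] * shifts[j]
  }
  m <- base / rowSums(base)
  colnames(m) <- paste0("g", 1:10)
  res <- lda_effect_size(m, lab, n_boot = 30, seed = 1)
  sc <- res$lda_score[seq_along(shifts)]
  expect_gt(stats::cor(sc, shifts, method = "spearman", use = "complete.obs"),
            0.9)
})

test_that("transition tables tally animal movements with rows summing to 100", {
  lab <- rbind(
    data.frame(animal = paste0("a", 1:10), time_point = "weaning",
               enterotype = rep(c("A", "B"), c(4, 6))),
    data.frame(animal = paste0("a", 1:10), time_point = "week15",
               enterotype = c("C", "C", "D", "D", "C", "D", "D", "D", "C", "C")))
  tr <- enterotype_transitions(lab, c("weaning", "week15"))
  tab <- tr[["weaning->week15"]]$counts
  expect_equal(unname(tab["A", "C"]), 2)
  expect_equal(unname(tab["A", "D"]), 2)
  expect_equal(unname(tab["B", "C"]), 3)
  expect_equal(unname(tab["B", "D"]), 3)
  expect_true(all(abs(rowSums(tr[["weaning->week15"]]$percent) - 100) < 1e-9))
  # identical labels give a diagonal table
  lab2 <- lab; lab2$enterotype <- rep(c("A", "B"), c(4, 6))
  tr2 <- enterotype_transitions(lab2, c("weaning", "week15"))
  expect_equal(unname(tr2[["weaning->week15"]]$percent["A", "B"]), 0)
  expect_warning(
    enterotype_transitions(rbind(lab[1:3, ],
                                 data.frame(animal = "zz", time_point = "week15",
                                            enterotype = "C"))),
    "no shared animals")
})

test_that("family-biased enterotype membership is detected with high power", {
  set.seed(23)
  hits <- 0
  for (r in 1:20) {
    fam <- rep(sprintf("f%02d", 1:28), each = 40)
    bias <- rep(stats::runif(28, 0.3, 0.7), each = 40)
    ass <- ifelse(stats::runif(length(fam)) < bias, "A", "B")
    if (enterotype_family_association(ass, fam)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)                    # >= 90% of replicates
})

test_that("family association reproduces the chi-square oracle", {
  ass <- rep(c("A", "B", "A", "B"), c(10, 10, 10, 10))
  fam <- rep(c("f1", "f2"), each = 20)
  res <- enterotype_family_association(ass, fam)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  ass2 <- rep(c("A", "B", "A", "B"), c(30, 10, 10, 30))
  fam2 <- rep(c("f1", "f2"), each = 40)
  res2 <- enterotype_family_association(ass2, fam2)
  tab <- table(fam2, ass2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(res2$df, 1)
})
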