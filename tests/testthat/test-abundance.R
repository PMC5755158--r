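test_that("sparse-OTU filter is inclusive at the threshold and matches a brute-force oracle", {
  counts <- matrix(c(600, 600, 599, 600, 2500, 2500), nrow = 2,
                   dimnames = list(c("a", "b"), c("o1", "o2", "o3")))
  kept <- filter_sparse_otus(counts, 1200)
  expect_identical(colnames(kept), c("o1", "o3"))
  expect_identical(rownames(kept), c("a", "b"))
  expect_identical(filter_sparse_otus(counts, 0), counts)

  set.seed(4)
  big <- matrix(rpois(40 * 30, 20), 40, 30,
                dimnames = list(paste0("s", 1:40), paste0("o", 1:30)))
  for (t in c(0, 400, 700, 820)) {
    expect_identical(colnames(filter_sparse_otus(big, t)),
                     colnames(big)[colSums(big) >= t])
  }
  expect_error(filter_sparse_otus(big, 1e9), "lower the min_total")
})

test_that("rarefaction subsamples without replacement at exact depth", {
  set.seed(7)
  counts <- matrix(rpois(10 * 25, 30), 10, 25,
                   dimnames = list(paste0("s", 1:10), paste0("o", 1:25)))
  depth <- min(rowSums(counts)) - 10
  r <- rarefy_table(counts, depth, seed = 1)
  expect_true(all(rowSums(r) == depth))
  expect_true(all(r <= counts))                         # support preserved
  # a sample whose total equals the depth is passed through unchanged
  exact <- matrix(c(5L, 3L, 2L), 1, dimnames = list("s", c("a", "b", "c")))
  expect_identical(rarefy_table(exact, 10, seed = 1), exact)
  expect_error(rarefy_table(counts, 0), "depth")
  expect_warning(rarefy_table(counts, max(rowSums(counts)), seed = 1),
                 "dropped")
})

test_that("rarefied counts follow hypergeometric moments", {
  # one OTU holds half the reads: its rarefied count has mean depth/2
  counts <- matrix(c(100L, 50L, 50L), 1,
                   dimnames = list("s", c("big", "m1", "m2")))
  depth <- 60
  draws <- vapply(seq_len(1000), function(s)
    rarefy_table(counts, depth, seed = s)[1, "big"], numeric(1))
  m <- 100; ntot <- 200
  mu <- depth * m / ntot
  v <- depth * (m / ntot) * (1 - m / ntot) * (ntot - depth) / (ntot - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 1000))
})

test_that("taxonomic aggregation conserves totals and buckets the unclassified", {
  counts <- matrix(c(3L, 5L, 2L, 8L, 1L, 4L), 2,
                   dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tax <- data.frame(otu_id = c("o1", "o2"),
                    phylum = c("Firmicutes", "Bacteroidetes"),
                    genus = c("Clostridium", "Prevotella"),
                    stringsAsFactors = FALSE)
  ph <- aggregate_taxa(counts, tax, "phylum")
  expect_setequal(colnames(ph), c("Firmicutes", "Bacteroidetes", "unclassified"))
  expect_equal(rowSums(ph), rowSums(counts))
  expect_equal(unname(ph[, "unclassified"]), unname(counts[, "o3"]))
  g <- aggregate_taxa(counts, tax, "genus")
  expect_equal(rowSums(g), rowSums(counts))
  expect_error(aggregate_taxa(counts, tax, "kingdom2"), "valid ranks")
  # two OTUs of the same genus collapse to their sum
  tax2 <- data.frame(otu_id = c("o1", "o2", "o3"),
                     genus = c("g", "g", "h"), stringsAsFactors = FALSE)
  g2 <- aggregate_taxa(counts, tax2, "genus")
  expect_equal(unname(g2[, "g"]), unname(counts[, "o1"] + counts[, "o2"]))
})

test_that("relative abundance normalizes rows and is idempotent", {
  m <- matrix(c(10, 30, 60), 1)
  expect_equal(as.vector(relative_abundance(m)), c(0.1, 0.3, 0.6))
  expect_equal(as.vector(relative_abundance(matrix(5, 1, 1))), 1)
  r <- relative_abundance(m)
  expect_equal(relative_abundance(r), r)
  bad <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("ok", "empty"), NULL))
  expect_error(relative_abundance(bad), "empty")
})

test_that("log-centre transform centres rows and evaluates in closed form", {
  m <- matrix(rep(1 / 3, 3), 1)
  expect_equal(as.vector(log_center_transform(m)), c(0, 0, 0))
  m2 <- matrix(c(0.1, 0.9), 1)
  cc <- mean(log(c(0.1, 0.9)))
  expect_equal(as.vector(log_center_transform(m2)),
               c(log(0.1) - cc, log(0.9) - cc))
  set.seed(2)
  m3 <- relative_abundance(matrix(rpois(60, 5), 5, 12))
  lc <- log_center_transform(m3)
  expect_true(all(abs(rowMeans(lc)) < 1e-9))
  expect_error(log_center_transform(matrix(0, 2, 2)), "all-zero")
})

test_that("Good's coverage reproduces closed-form values", {
  counts <- rbind(c(5L, 3L, 2L), c(1L, 1L, 0L), c(4L, 1L, 0L))
  gc <- goods_coverage(counts)
  expect_equal(unname(gc$coverage), c(1.0, 0.0, 0.8))
  empty <- rbind(c(0L, 0L), c(2L, 1L))
  expect_true(is.na(goods_coverage(empty)$coverage[1]))
})

test_that("Kruskal-Wallis screen matches the rank-formula oracle", {
  g <- factor(rep(c("a", "b"), each = 3))
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  res <- kruskal_wallis_screen(m, g)
  expect_equal(res$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-10)            # = 3.857...
  expect_equal(res$H, kw_H_oracle(m[, 1], g), tolerance = 1e-10)
  # all 2-group splits of 8 values (with ties) equal the oracle
  set.seed(9)
  x <- sample(c(1.5, 2, 2, 3.7, 5, 5, 6, 8))
  splits <- utils::combn(8, 4)
  for (c_ in seq_len(ncol(splits))) {
    gg <- factor(ifelse(seq_len(8) %in% splits[, c_], "a", "b"))
    r <- kruskal_wallis_screen(matrix(x, ncol = 1), gg)
    expect_equal(r$H, kw_H_oracle(x, gg), tolerance = 1e-10)
  }
  # constant taxon: H = 0, p = 1
  res0 <- kruskal_wallis_screen(matrix(1, 6, 1), g)
  expect_equal(res0$H, 0)
  expect_equal(res0$p_raw, 1)
  # Bonferroni is multiplication by the number of taxa, capped at 1
  mm <- matrix(rnorm(6 * 100), 6, 100)
  rr <- kruskal_wallis_screen(mm, g)
  expect_equal(rr$p_adj, pmin(1, rr$p_raw * 100))
})

test_that("composition PCA has normalized contributions and exact small-case eigenvalues", {
  # perfectly collinear two-column data: PC1 explains all variance
  m <- cbind(1:6, 2 * (1:6))
  p <- pca_composition(m)
  expect_equal(p$prop_var[1], 100, tolerance = 1e-8)
  expect_equal(unname(colSums(p$contributions)), rep(100, 2),
               tolerance = 1e-6)
  # 3x2 toy matrix: eigenvalues from the characteristic polynomial of the
  # 2x2 covariance
  m2 <- matrix(c(1, 2, 4, 1, 3, 2), 3, 2)
  S <- stats::cov(m2)
  tr <- sum(diag(S)); dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam <- (tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2
  p2 <- pca_composition(m2)
  expect_equal(p2$sdev^2, lam, tolerance = 1e-10)
  # proportions non-increasing; full reconstruction is exact
  set.seed(3)
  m3 <- log_center_transform(relative_abundance(matrix(rpois(200, 8) + 1, 10, 20)))
  p3 <- pca_composition(m3)
  expect_true(all(diff(p3$prop_var) < 1e-10))
  pc <- stats::prcomp(m3)
  rec <- pc$x %*% t(pc$rotation)
  cent <- scale(m3, center = TRUE, scale = FALSE)
  expect_lt(sqrt(sum((rec - cent)^2)), 1e-8)
  expect_error(pca_composition(m3[1, , drop = FALSE]), "2 samples")
})
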