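# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Gene-dropping estimate of the additive relationship matrix: founders get
# unique alleles, each descendant inherits one random allele per parent,
# and a_ij is estimated as twice the average allele-sharing probability.
gene_drop_A <- function(ped, n_drops = 1e4, seed = 1) {
  ped <- herdqg::sort_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  set.seed(seed)
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s)) {
      al1[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, s], al2[, s])
    }
    if (is.na(d)) {
      al2[, i] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, d], al2[, d])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      f <- (mean(al1[, i] == al1[, j]) + mean(al1[, i] == al2[, j]) +
              mean(al2[, i] == al1[, j]) + mean(al2[, i] == al2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  # a_ii = 2 * f_ii where f_ii = 0.5 (1 + F): the formula above already
  # counts the self allele matches, so the diagonal needs no correction
  A
}

# Exhaustive k-medoids: evaluate every medoid subset, minimal objective,
# lexicographically smallest set on ties.
exhaustive_kmedoids <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  sets <- utils::combn(n, k)
  objs <- apply(sets, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min)))
  best <- which(objs <= min(objs) + 1e-12)[1]
  med <- sets[, best]
  assign <- apply(d[, med, drop = FALSE], 1, which.min)
  list(medoids = med, objective = objs[best], assignments = assign)
}

# Midrank Kruskal-Wallis H with tie correction, straight from the rank
# formula (independent of stats::kruskal.test).
kw_H_oracle <- function(x, g) {
  g <- as.factor(g)
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Balanced one-way random-effects ANOVA estimator of the group variance.
anova_group_varcomp <- function(y, g) {
  ms <- stats::anova(stats::lm(y ~ as.factor(g)))[["Mean Sq"]]
  npr <- length(y) / length(unique(g))
  c(group = (ms[1] - ms[2]) / npr, residual = ms[2])
}

rdirich <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}
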