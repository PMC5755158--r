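#' Jensen-Shannon divergence between two abundance profiles
#'
#' JSD(P, Q) = (KL(P||M) + KL(Q||M)) / 2 with M = (P+Q)/2, natural log.
#' Zeros are replaced by a pseudocount and the profiles renormalized, so
#' the divergence is finite on sparse compositions.
#'
#' @param p,q non-negative vectors (renormalized internally).
#' @param pseudocount replacement for zero entries.
#' @return JSD in nats (bounded by ln 2).
#' @export
jsd_divergence <- function(p, q, pseudocount = 1e-10) {
  if (any(p < 0) || any(q < 0)) stop("negative abundances")
  p[p == 0] <- pseudocount; q[q == 0] <- pseudocount
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  sum(p * log(p / m)) / 2 + sum(q * log(q / m)) / 2
}

#' Square-root JSD distance matrix between samples
#'
#' d(i, j) = sqrt(JSD(P_i, P_j)); the square root of the Jensen-Shannon
#' divergence is a metric, bounded by sqrt(ln 2). Computed via the entropy
#' identity JSD(P, Q) = H((P+Q)/2) - (H(P) + H(Q))/2.
#'
#' @param m relative abundance matrix, samples x taxa (genus rank for
#'   enterotyping).
#' @param pseudocount replacement for zero entries before renormalization.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jsd_distance_matrix <- function(m, pseudocount = 1e-10) {
  if (any(m < 0)) stop("negative abundances")
  P <- m
  P[P == 0] <- pseudocount
  P <- P / rowSums(P)
  n <- nrow(P)
  H <- -rowSums(P * log(P))
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    rows <- (i + 1):n
    Mi <- (P[rows, , drop = FALSE] + rep(P[i, ], each = length(rows))) / 2
    Hm <- -rowSums(Mi * log(Mi))
    jsd <- pmax(Hm - (H[rows] + H[i]) / 2, 0)
    D[i, rows] <- D[rows, i] <- sqrt(jsd)
  }
  D
}

#' Partitioning around medoids (deterministic BUILD + SWAP)
#'
#' Greedy BUILD initialization followed by SWAP steps, accepting the single
#' medoid/non-medoid exchange that most lowers the objective
#' sum_i d(i, medoid(i)) until no exchange improves it. Ties are broken by
#' the lowest sample index, so the fit is deterministic and seed-free.
#' When the medoid search space is tiny (choose(n, k) <= `exact_limit`) the
#' objective is minimized by exact enumeration instead: the swap heuristic
#' (like any single-exchange k-medoids, including the reference cluster
#' package) can stall in a local optimum, and at these sizes the global
#' optimum is affordable.
#'
#' @param d symmetric distance matrix.
#' @param k number of clusters (1 < k < n).
#' @param exact_limit largest number of candidate medoid subsets for which
#'   exact enumeration replaces BUILD+SWAP.
#' @return list with `assignments` (1..k, clusters numbered by ascending
#'   medoid index), `medoids` (sample indices), `objective`, `method`.
#' @export
pam_cluster <- function(d, k, exact_limit = 300) {
  n <- nrow(d)
  if (k <= 1) stop("k must be > 1")
  if (k >= n) stop("k must be < number of samples")
  d <- unname(as.matrix(d))
  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    objs <- apply(sets, 2, function(m)
      sum(apply(d[, m, drop = FALSE], 1, min)))
    med <- sets[, which(objs <= min(objs) + 1e-12)[1]]  # lexicographic ties
    dm <- d[, med, drop = FALSE]
    assignments <- max.col(-dm, ties.method = "first")
    return(list(assignments = assignments, medoids = med,
                objective = sum(dm[cbind(seq_len(n), assignments)]),
                method = "exact"))
  }
  # BUILD
  med <- which.min(colSums(d))
  dnear <- d[, med]
  while (length(med) < k) {
    gains <- colSums(pmax(dnear - d, 0))
    gains[med] <- -Inf
    nxt <- which.max(gains)          # ties -> lowest index
    med <- c(med, nxt)
    dnear <- pmin(dnear, d[, nxt])
  }
  # SWAP
  repeat {
    dm <- d[, med, drop = FALSE]
    near_idx <- max.col(-dm, ties.method = "first")
    dnear <- dm[cbind(seq_len(n), near_idx)]
    objective <- sum(dnear)
    dm2 <- dm
    dm2[cbind(seq_len(n), near_idx)] <- Inf
    dsec <- dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
    delta <- matrix(Inf, length(med), n)
    for (mi in seq_along(med)) {
      alt <- dnear
      own <- near_idx == mi
      alt[own] <- dsec[own]
      delta[mi, ] <- colSums(pmin(d, alt)) - objective
    }
    delta[, med] <- Inf
    best <- min(delta)
    if (best >= -1e-12) break
    hits <- which(delta == best, arr.ind = TRUE)
    hit <- hits[order(hits[, "col"], hits[, "row"])[1], ]   # lowest sample index first
    med[hit["row"]] <- hit["col"]
  }
  med <- sort(med)
  dm <- d[, med, drop = FALSE]
  assignments <- max.col(-dm, ties.method = "first")
  list(assignments = assignments, medoids = med,
       objective = sum(dm[cbind(seq_len(n), assignments)]),
       method = "build-swap")
}

#' Principal-coordinates embedding of a distance matrix
#'
#' Classical multidimensional scaling retaining the positive-eigenvalue
#' axes; used to give the Calinski-Harabasz index the Euclidean coordinates
#' its sum-of-squares form requires.
#'
#' @param d symmetric distance matrix.
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return coordinate matrix (samples x retained axes).
#' @export
pcoa_embed <- function(d, tol = 1e-9) {
  n <- nrow(d)
  # cmdscale warns when fewer than k positive eigenvalues exist; only the
  # positive axes are retained here, so that is the expected situation
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  keep <- mds$eig > tol * max(mds$eig)
  keep <- keep[seq_len(ncol(mds$points))]
  mds$points[, keep, drop = FALSE]
}

#' Calinski-Harabasz index of a partition
#'
#' CH = [B / (k-1)] / [W / (n-k)], with B and W the between- and
#' within-cluster sums of squared Euclidean distances to centroids in a
#' principal-coordinates embedding of the distance matrix. Zero
#' within-cluster spread yields +Inf.
#'
#' @param d symmetric distance matrix (ignored if `coords` given).
#' @param assignments integer cluster labels.
#' @param coords optional precomputed embedding (samples x axes).
#' @return numeric index value (`NA` for a single cluster).
#' @export
calinski_harabasz <- function(d, assignments, coords = NULL) {
  if (is.null(coords)) coords <- pcoa_embed(d)
  k <- length(unique(assignments))
  n <- nrow(coords)
  if (k < 2) return(NA_real_)
  grand <- colMeans(coords)
  tot_ss <- sum(sweep(coords, 2, grand)^2)
  cent <- rowsum(coords, assignments) / as.vector(table(assignments))
  W <- sum((coords - cent[as.character(assignments), , drop = FALSE])^2)
  B <- tot_ss - W
  if (W <= 1e-12 * max(tot_ss, 1)) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette widths of a partition
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a the mean within-cluster
#' distance (excluding self) and b the smallest mean distance to another
#' cluster. Members of singleton clusters get s = 0.
#'
#' @param d symmetric distance matrix.
#' @param assignments integer cluster labels.
#' @return list with `mean` and per-sample `widths`.
#' @export
silhouette_width <- function(d, assignments) {
  d <- as.matrix(d)
  n <- nrow(d)
  f <- as.factor(assignments)
  if (nlevels(f) < 2) stop("need at least 2 clusters")
  sizes <- as.vector(table(f))
  S <- rowsum(d, f)                       # clusters x samples: sums of distances
  own <- as.integer(f)
  a <- (S[cbind(own, seq_len(n))]) / pmax(sizes[own] - 1, 1)
  Sm <- S / sizes
  Sm[cbind(own, seq_len(n))] <- Inf
  b <- apply(Sm, 2, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1] <- 0
  s[!is.finite(s)] <- 0
  list(mean = mean(s), widths = s)
}

#' Discover enterotypes by JSD + PAM with CH-based cluster-number choice
#'
#' Computes the square-root JSD distance matrix at the genus rank, runs PAM
#' for every k in `k_range`, and picks the k maximizing the
#' Calinski-Harabasz index (silhouette reported alongside). Sexes are
#' analyzed combined. A flat CH curve (max below `flat_ratio` times the
#' minimum) triggers a weak-structure warning, since the chosen k is then
#' unstable across data draws.
#'
#' @param m genus-level relative abundance matrix, samples x genera.
#' @param k_range candidate cluster numbers.
#' @param pseudocount zero replacement used in the JSD.
#' @param flat_ratio CH max/min ratio below which the curve is called flat.
#' @return list with `assignments`, `medoids`, `chosen_k`, `ch_by_k`,
#'   `silhouette_by_k`, `distance`, `weak_structure`.
#' @export
select_enterotypes <- function(m, k_range = 2:10, pseudocount = 1e-10,
                               flat_ratio = 2) {
  if (!length(k_range)) stop("empty k_range")
  if (nrow(m) <= max(k_range)) stop("need more samples than max(k_range)")
  d <- jsd_distance_matrix(m, pseudocount)
  coords <- pcoa_embed(d)
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  ch <- vapply(fits, function(f) calinski_harabasz(coords = coords,
                                                   assignments = f$assignments,
                                                   d = NULL), numeric(1))
  sil <- vapply(fits, function(f) silhouette_width(d, f$assignments)$mean,
                numeric(1))
  names(ch) <- names(sil) <- k_range
  best <- which.max(ch)                 # ties -> smallest k
  weak <- is.finite(max(ch)) && max(ch) < flat_ratio * min(ch)
  if (weak)
    warning("flat Calinski-Harabasz curve (max/min < ", flat_ratio,
            "): cluster number is unstable, no strong enterotype structure")
  fit <- fits[[best]]
  list(assignments = fit$assignments, medoids = fit$medoids,
       chosen_k = k_range[best], ch_by_k = ch, silhouette_by_k = sil,
       distance = d, weak_structure = weak)
}

#' LDA effect sizes of genera between two enterotypes (LEfSe-style)
#'
#' Abundances are rescaled per sample to sum 1e6; genera failing a
#' Kruskal-Wallis test at `alpha` are excluded; for each retained genus the
#' effect size is log10 of the absolute average of the raw class-mean
#' difference and the class-mean difference of the genus's component along
#' the unit-norm two-class Fisher discriminant axis (ridge-regularized
#' pooled covariance), averaged over `n_boot` within-class bootstrap
#' resamples (`n_boot = 0` gives a single deterministic fit). The score is
#' signed by the enriched class: positive when the first factor level has
#' the larger mean.
#'
#' @param m abundance matrix, samples x genera.
#' @param labels two-level factor.
#' @param alpha Kruskal-Wallis significance filter (raw p).
#' @param threshold significant set requires |score| > threshold (strict).
#' @param n_boot bootstrap rounds.
#' @param seed seed for the bootstrap.
#' @param ridge ridge added to the pooled covariance, relative to its mean
#'   diagonal.
#' @return data.frame genus, enriched_class, lda_score, kw_p, significant.
#' @export
lda_effect_size <- function(m, labels, alpha = 0.05, threshold = 2.0,
                            n_boot = 30, seed = NULL, ridge = 1e-3) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 2) stop("each class needs >= 2 samples")
  lev <- levels(labels)
  M <- m / rowSums(m) * 1e6
  kw_p <- apply(M, 2, function(x) {
    if (length(unique(x)) == 1L) return(1)
    stats::kruskal.test(x, labels)$p.value
  })
  keep <- which(kw_p < alpha)
  out <- data.frame(genus = colnames(m), enriched_class = NA_character_,
                    lda_score = NA_real_, kw_p = kw_p, significant = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!length(keep)) return(out)
  X <- M[, keep, drop = FALSE]
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  eff_once <- function(a, b) {
    mu1 <- colMeans(X[a, , drop = FALSE]); mu2 <- colMeans(X[b, , drop = FALSE])
    raw <- mu1 - mu2
    S1 <- stats::cov(X[a, , drop = FALSE]); S2 <- stats::cov(X[b, , drop = FALSE])
    Sw <- ((length(a) - 1) * S1 + (length(b) - 1) * S2) /
      (length(a) + length(b) - 2)
    lam <- ridge * mean(diag(Sw))
    if (!is.finite(lam) || lam <= 0) lam <- ridge
    w <- solve(Sw + diag(lam, ncol(Sw)), raw)
    w <- w / sqrt(sum(w^2))
    avg <- (abs(raw) + abs(w * raw)) / 2
    log10(pmax(avg, .Machine$double.eps))
  }
  scores <- if (n_boot > 0) {
    with_seed(seed, {
      reps <- replicate(n_boot, {
        a <- sample(i1, length(i1), replace = TRUE)
        b <- sample(i2, length(i2), replace = TRUE)
        while (length(unique(a)) < 2) a <- sample(i1, length(i1), replace = TRUE)
        while (length(unique(b)) < 2) b <- sample(i2, length(i2), replace = TRUE)
        eff_once(a, b)
      })
      rowMeans(matrix(reps, nrow = length(keep)))
    })
  } else {
    eff_once(i1, i2)
  }
  mu_diff <- colMeans(X[i1, , drop = FALSE]) - colMeans(X[i2, , drop = FALSE])
  sgn <- ifelse(mu_diff >= 0, 1, -1)
  out$lda_score[keep] <- sgn * scores
  out$enriched_class[keep] <- ifelse(sgn > 0, lev[1], lev[2])
  out$significant[keep] <- abs(scores) > threshold & kw_p[keep] < alpha
  out
}

#' Enterotype transition tables between time points
#'
#' For each ordered pair of time points, counts how animals move between
#' enterotype labels, with row percentages summing to 100.
#'
#' @param labels data.frame with `animal`, `time_point`, `enterotype`.
#' @param time_points ordering of time points (defaults to order of
#'   appearance).
#' @return named list (one per ordered pair) of lists with `counts` and
#'   `percent` matrices.
#' @export
enterotype_transitions <- function(labels,
                                   time_points = unique(labels$time_point)) {
  out <- list()
  for (i in seq_along(time_points)) {
    for (j in seq_along(time_points)) {
      if (j <= i) next
      a <- labels[labels$time_point == time_points[i], ]
      b <- labels[labels$time_point == time_points[j], ]
      shared <- intersect(a$animal, b$animal)
      key <- paste(time_points[i], time_points[j], sep = "->")
      if (!length(shared)) {
        warning("no shared animals between ", key)
        out[[key]] <- list(counts = table(character(0), character(0)),
                           percent = NULL)
        next
      }
      tab <- table(source = a$enterotype[match(shared, a$animal)],
                   destination = b$enterotype[match(shared, b$animal)])
      pct <- 100 * tab / rowSums(tab)
      out[[key]] <- list(counts = tab, percent = pct)
    }
  }
  out
}

#' Chi-square test of enterotype membership against sire family
#'
#' Pearson chi-square on the family x enterotype contingency table.
#'
#' @param assignments enterotype label per sample.
#' @param family sire family factor per sample.
#' @return list with `statistic`, `df`, `p`, `table`, and
#'   `expected_lt_1` flag (TRUE when some expected cell < 1).
#' @export
enterotype_family_association <- function(assignments, family) {
  tab <- table(family, assignments)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need >= 2 families and >= 2 enterotypes")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  flag <- any(ct$expected < 1)
  if (flag) warning("expected cell count < 1 in family x enterotype table")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, expected_lt_1 = flag)
}
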