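#' Filter sparse OTUs by total observation count
#'
#' Removes OTUs whose grand total across all samples falls below
#' `min_total` (threshold inclusive: an OTU with exactly `min_total` reads
#' is kept). The sample set is unchanged.
#'
#' @param counts integer matrix, samples x OTUs.
#' @param min_total minimum total observation count for an OTU to be kept.
#' @return filtered count matrix.
#' @export
filter_sparse_otus <- function(counts, min_total = 1200) {
  .check_counts(counts)
  keep <- colSums(counts) >= min_total
  if (!any(keep))
    stop("no OTU reaches a total of ", min_total,
         "; lower the min_total threshold")
  counts[, keep, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Draws `depth` reads per sample without replacement (vegan's `rrarefy`).
#' Samples whose total is below `depth` are dropped with a warning; sampling
#' without replacement is undefined above the available total.
#'
#' @param counts integer matrix, samples x OTUs.
#' @param depth target reads per sample.
#' @param seed optional seed for reproducible subsampling.
#' @return rarefied count matrix (row sums all equal `depth`).
#' @export
rarefy_table <- function(counts, depth = 10000, seed = NULL) {
  .check_counts(counts)
  if (depth <= 0) stop("depth must be > 0")
  tot <- rowSums(counts)
  low <- tot < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth ", depth, " dropped")
    counts <- counts[!low, , drop = FALSE]
    tot <- tot[!low]
  }
  if (!nrow(counts)) stop("no sample reaches the rarefaction depth")
  # vegan warns when the smallest nonzero count exceeds 1, which is routine
  # for tables already filtered of sparse OTUs
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(counts, depth)))
  exact <- tot == depth
  if (any(exact)) out[exact, ] <- counts[exact, ]   # sampling all reads
  storage.mode(out) <- "integer"
  out
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts within rank labels; OTUs missing from the taxonomy map (or
#' with an unclassified entry at that rank) are pooled into an
#' "unclassified" bucket. Per-sample totals are preserved.
#'
#' @param counts integer matrix, samples x OTUs.
#' @param taxonomy data.frame with `otu_id` and rank columns
#'   (kingdom...species).
#' @param rank rank name to aggregate at.
#' @return matrix samples x taxa at the requested rank.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "genus") {
  .check_counts(counts)
  ranks <- setdiff(names(taxonomy), "otu_id")
  if (!rank %in% ranks)
    stop("unknown rank '", rank, "'; valid ranks: ", paste(ranks, collapse = ", "))
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$otu_id)]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  agg <- t(rowsum(t(counts), group = lab))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' @param m numeric matrix, samples x taxa; row sums must be positive.
#' @return matrix with rows summing to 1.
#' @export
relative_abundance <- function(m) {
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    bad <- rownames(m)[tot <= 0] %||% which(tot <= 0)
    stop("zero-sum sample(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  m / tot
}

#' Log-transform and row-centre relative abundances
#'
#' Zeros are replaced per the pseudocount policy (default: half the smallest
#' nonzero value in the matrix), the natural log is applied, and each row is
#' centred to mean zero — the compositional transform used upstream of PCA
#' and the Kruskal-Wallis screen.
#'
#' @param m relative abundance matrix (samples x taxa).
#' @param pseudocount `"half-min"` or a fixed positive number.
#' @return log-centred matrix (row means 0).
#' @export
log_center_transform <- function(m, pseudocount = "half-min") {
  if (all(m == 0)) stop("all-zero matrix")
  eps <- if (identical(pseudocount, "half-min")) {
    min(m[m > 0]) / 2
  } else {
    stopifnot(is.numeric(pseudocount), pseudocount > 0)
    pseudocount
  }
  lm_ <- log(ifelse(m == 0, eps, m))
  lm_ - rowMeans(lm_)
}

#' Good's coverage per sample
#'
#' coverage = 1 - singletons / total reads; the usual estimate of how
#' completely a sample's community was observed at its sequencing depth.
#'
#' @param counts integer matrix, samples x OTUs.
#' @return list with `coverage` (per sample, `NA` for empty samples),
#'   `mean`, `sd`.
#' @export
goods_coverage <- function(counts) {
  .check_counts(counts)
  tot <- rowSums(counts)
  singletons <- rowSums(counts == 1)
  cov <- ifelse(tot > 0, 1 - singletons / tot, NA_real_)
  list(coverage = cov, mean = mean(cov, na.rm = TRUE),
       sd = stats::sd(cov, na.rm = TRUE))
}

#' Kruskal-Wallis screen of taxa between two groups
#'
#' Runs a midrank Kruskal-Wallis test per taxon (tie-corrected H, chi-square
#' p with groups-1 df) and applies Bonferroni correction over the taxa
#' tested. A taxon constant across all samples gets H = 0, p = 1.
#'
#' @param m abundance matrix, samples x taxa.
#' @param groups factor with one level per sample (typically two).
#' @param alpha significance level used for the `significant` flag (applied
#'   to adjusted p).
#' @return data.frame taxon, H, p_raw, p_adj, significant.
#' @export
kruskal_wallis_screen <- function(m, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nrow(m) == length(groups))
  if (min(table(groups)) < 2) stop("need >= 2 observations per group")
  res <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (length(unique(x)) == 1L) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(x, groups)
    c(H = unname(kt$statistic), p = unname(kt$p.value))
  }, numeric(2))
  p_adj <- pmin(1, res["p", ] * ncol(m))
  taxa <- colnames(m) %||% paste0("taxon", seq_len(ncol(m)))
  data.frame(taxon = taxa, H = res["H", ], p_raw = res["p", ],
             p_adj = p_adj, significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA of a log-centred composition matrix
#'
#' Columns are centred internally and the covariance (not correlation)
#' eigendecomposition taken, matching a centred-but-unscaled `prcomp`.
#' Per-taxon contributions to a component are squared loading shares in
#' percent (summing to 100 per component).
#'
#' @param m log-centred abundance matrix, samples x taxa.
#' @param n_components how many components to report contributions for.
#' @return list with `scores`, `prop_var` (percent per component),
#'   `contributions` (taxa x components, percent), `sdev`.
#' @export
pca_composition <- function(m, n_components = 2) {
  if (nrow(m) < 2) stop("need at least 2 samples")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  prop <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  contrib <- 100 * pc$rotation[, seq_len(k), drop = FALSE]^2
  contrib <- sweep(contrib, 2, colSums(contrib), "/") * 100
  list(scores = pc$x, prop_var = prop, contributions = contrib, sdev = pc$sdev)
}

.check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (samples x OTUs)")
  if (any(counts < 0)) stop("negative counts")
  invisible(TRUE)
}
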