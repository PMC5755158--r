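#' Shannon diversity index (nats)
#'
#' H = -sum p_i ln p_i over the nonzero proportional abundances of a
#' sample's OTUs (vegan's definition with the natural log). A single-OTU
#' sample has H = 0.
#'
#' @param counts numeric vector of one sample's OTU counts, or a samples x
#'   OTUs matrix (one value per row).
#' @return numeric vector of Shannon indices in nats.
#' @export
shannon_index <- function(counts) {
  if (is.matrix(counts)) {
    if (any(counts < 0)) stop("negative counts")
    if (any(rowSums(counts) <= 0)) stop("sample with non-positive total")
    return(vegan::diversity(counts, index = "shannon"))
  }
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("sample with non-positive total")
  unname(vegan::diversity(matrix(counts, nrow = 1), index = "shannon"))
}

#' OTU richness: number of OTUs observed
#'
#' @param counts numeric vector or samples x OTUs matrix of (rarefied)
#'   counts.
#' @return integer count(s) of OTUs with count > 0.
#' @export
otu_richness <- function(counts) {
  if (is.matrix(counts)) return(rowSums(counts > 0))
  sum(counts > 0)
}

#' Pre-adjust a trait for a grouping factor
#'
#' value <- value - group mean + grand mean, so every group's adjusted mean
#' equals the grand mean. Used to remove the contemporary-group stratum
#' from week-15 and off-test diversity before genetic analysis. A singleton
#' group's value maps to the grand mean. Idempotent.
#'
#' @param values numeric vector.
#' @param group factor of the same length.
#' @return adjusted numeric vector.
#' @export
pre_adjust_for_group <- function(values, group) {
  stopifnot(length(values) == length(group))
  gm <- mean(values)
  values - stats::ave(values, group) + gm
}

#' Welch t-tests of diversity between two enterotypes within sex
#'
#' @param shannon numeric vector of Shannon indices.
#' @param enterotype two-level factor.
#' @param sex factor of sexes (a test is run within each level).
#' @return data.frame sex, t, df, p, mean per enterotype, n per enterotype.
#' @export
compare_enterotype_diversity <- function(shannon, enterotype, sex) {
  enterotype <- droplevels(as.factor(enterotype))
  lev <- levels(enterotype)
  stopifnot(length(lev) == 2)
  out <- lapply(unique(as.character(sex)), function(sx) {
    i <- sex == sx
    x <- shannon[i & enterotype == lev[1]]
    y <- shannon[i & enterotype == lev[2]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(sex = sx, t = NA_real_, df = NA_real_, p = NA_real_,
                        mean_1 = mean(x), mean_2 = mean(y),
                        n_1 = length(x), n_2 = length(y)))
    }
    tt <- stats::t.test(x, y)   # Welch by default
    data.frame(sex = sx, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_1 = mean(x), mean_2 = mean(y),
               n_1 = length(x), n_2 = length(y))
  })
  do.call(rbind, out)
}

#' Build a diversity phenotype table from rarefied OTU tables
#'
#' Computes Shannon and richness per sample at each time point, and
#' pre-adjusts both for contemporary group at the post-weaning time points
#' (weaning values are left unadjusted).
#'
#' @param counts_by_tp named list of rarefied samples x OTUs matrices; row
#'   names must be `<animal>_<time_point>`.
#' @param frame design frame with `animal` and `cg` columns.
#' @param adjust_time_points time points whose values get the
#'   contemporary-group pre-adjustment.
#' @param adjust_richness also pre-adjust richness (default TRUE).
#' @return data.frame animal, time_point, shannon, richness, shannon_adj,
#'   richness_adj.
#' @export
diversity_phenotypes <- function(counts_by_tp, frame,
                                 adjust_time_points = c("week15", "offtest"),
                                 adjust_richness = TRUE) {
  out <- lapply(names(counts_by_tp), function(tp) {
    m <- counts_by_tp[[tp]]
    animal <- sub(paste0("_", tp, "$"), "", rownames(m))
    d <- data.frame(animal = animal, time_point = tp,
                    shannon = shannon_index(m),
                    richness = otu_richness(m),
                    stringsAsFactors = FALSE)
    cg <- frame$cg[match(animal, frame$animal)]
    if (tp %in% adjust_time_points) {
      d$shannon_adj <- pre_adjust_for_group(d$shannon, cg)
      d$richness_adj <- if (adjust_richness)
        pre_adjust_for_group(d$richness, cg) else d$richness
    } else {
      d$shannon_adj <- d$shannon
      d$richness_adj <- d$richness
    }
    rownames(d) <- NULL
    d
  })
  do.call(rbind, out)
}
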