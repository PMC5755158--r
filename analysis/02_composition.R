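#!/usr/bin/env Rscript
# Stage 2: OTU-table processing and compositional comparison across time
# points: sparse-OTU filter, rarefaction, Good's coverage, genus-level
# Kruskal-Wallis screening between consecutive time points (Bonferroni),
# and PCA of log-centred composition at several taxonomic ranks.

suppressMessages(library(herdqg))

data_dir <- "results/data"
out_dir <- "results/composition"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
time_points <- c("weaning", "week15", "offtest")

tables <- lapply(time_points, function(tp)
  read_otu_table(file.path(data_dir, paste0("otu_", tp, ".tsv"))))
names(tables) <- time_points
taxonomy <- tables$weaning$taxonomy

rarefied <- list()
cov_rows <- list()
for (tp in time_points) {
  counts <- filter_sparse_otus(tables[[tp]]$counts, min_total = 1200)
  depth <- min(10000, min(rowSums(counts)))
  counts <- suppressWarnings(rarefy_table(counts, depth, seed = 1))
  rarefied[[tp]] <- counts
  gc_ <- goods_coverage(counts)
  cov_rows[[tp]] <- data.frame(time_point = tp, depth = depth,
                               mean = gc_$mean, sd = gc_$sd)
  message(sprintf("%s: %d OTUs kept, Good's coverage %.3f +/- %.3f",
                  tp, ncol(counts), gc_$mean, gc_$sd))
}
write.table(do.call(rbind, cov_rows), file.path(out_dir, "goods_coverage.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# rarefied tables are re-derivable from stage 1; persist them for stages 3-5
for (tp in time_points) {
  write_otu_table(rarefied[[tp]],
                  file.path(out_dir, paste0("rarefied_", tp, ".tsv")))
}

# genus-level differential abundance between consecutive time points
genus <- lapply(rarefied, function(m) {
  rel <- relative_abundance(aggregate_taxa(m, taxonomy, "genus"))
  log_center_transform(rel)
})
pairs <- list(c("weaning", "week15"), c("weaning", "offtest"),
              c("week15", "offtest"))
for (pr in pairs) {
  shared <- intersect(colnames(genus[[pr[1]]]), colnames(genus[[pr[2]]]))
  m <- rbind(genus[[pr[1]]][, shared], genus[[pr[2]]][, shared])
  grp <- rep(pr, c(nrow(genus[[pr[1]]]), nrow(genus[[pr[2]]])))
  kw <- kruskal_wallis_screen(m, grp, alpha = 0.01)
  message(sprintf("%s vs %s: %d / %d genera differ (Bonferroni p < 0.01)",
                  pr[1], pr[2], sum(kw$significant), nrow(kw)))
  write.table(kw, file.path(out_dir, sprintf("kw_%s_vs_%s.tsv", pr[1], pr[2])),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# PCA of all samples at six ranks
pca_rows <- list()
for (rank in c("phylum", "class", "order", "family", "genus", "species")) {
  per_tp <- lapply(rarefied, function(m)
    relative_abundance(aggregate_taxa(m, taxonomy, rank)))
  taxa <- sort(unique(unlist(lapply(per_tp, colnames))))
  all_rel <- do.call(rbind, lapply(per_tp, function(m) {
    out <- matrix(0, nrow(m), length(taxa),
                  dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }))
  pca <- pca_composition(log_center_transform(all_rel))
  pca_rows[[rank]] <- data.frame(rank = rank,
                                 pc1 = pca$prop_var[1], pc2 = pca$prop_var[2])
  message(sprintf("%s: PC1 %.1f%%, PC2 %.1f%%", rank,
                  pca$prop_var[1], pca$prop_var[2]))
  top <- head(pca$contributions[order(-pca$contributions[, 1]), , drop = FALSE], 10)
  write.table(data.frame(taxon = rownames(top), top, check.names = FALSE),
              file.path(out_dir, paste0("pca_contrib_", rank, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(do.call(rbind, pca_rows), file.path(out_dir, "pca_by_rank.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
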