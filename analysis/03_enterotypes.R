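#!/usr/bin/env Rscript
# Stage 3: enterotype discovery and characterization at each time point:
# JSD distances at the genus rank, PAM over k = 2..10 with CH selection,
# LDA effect sizes of the discriminating genera, transitions of animals
# between enterotypes over time, sire-family association, and Welch
# t-tests of Shannon diversity between enterotypes within sex.

suppressMessages(library(herdqg))

data_dir <- "results/data"
comp_dir <- "results/composition"
out_dir <- "results/enterotypes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
time_points <- c("weaning", "week15", "offtest")

taxonomy <- read_otu_table(file.path(data_dir, "otu_weaning.tsv"))$taxonomy
meta <- read.delim(file.path(data_dir, "metadata.tsv"),
                   stringsAsFactors = FALSE)
truth <- read.delim(file.path(data_dir, "truth.tsv"), stringsAsFactors = FALSE)

labels <- list()
for (tp in time_points) {
  counts <- read_otu_table(file.path(comp_dir,
                                     paste0("rarefied_", tp, ".tsv")))$counts
  rel <- relative_abundance(aggregate_taxa(counts, taxonomy, "genus"))
  fit <- select_enterotypes(rel, k_range = 2:10)
  message(sprintf("%s: chosen k = %d (CH %.1f, silhouette %.2f)", tp,
                  fit$chosen_k, max(fit$ch_by_k),
                  fit$silhouette_by_k[[as.character(fit$chosen_k)]]))
  write.table(data.frame(k = as.integer(names(fit$ch_by_k)),
                         ch = fit$ch_by_k, silhouette = fit$silhouette_by_k),
              file.path(out_dir, paste0("indices_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(animal = sub(paste0("_", tp, "$"), "", rownames(rel)),
                    time_point = tp,
                    enterotype = paste0("E", fit$assignments),
                    stringsAsFactors = FALSE)
  labels[[tp]] <- lab
  tr_lab <- truth[truth$time_point == tp, ]
  ari <- adjusted_rand_index(lab$enterotype,
                             tr_lab$enterotype[match(lab$animal, tr_lab$animal)])
  message(sprintf("  adjusted Rand vs planted labels: %.3f", ari))

  lda <- lda_effect_size(rel, lab$enterotype, threshold = 2, n_boot = 30,
                         seed = 1)
  sig <- lda[which(lda$significant), ]
  sig <- sig[order(-abs(sig$lda_score)), ]
  message(sprintf("  %d genera with |LDA score| > 2; leaders: %s", nrow(sig),
                  paste(head(sig$genus, 3), collapse = ", ")))
  write.table(lda, file.path(out_dir, paste0("lda_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  fam <- meta$family[match(lab$animal, meta$animal)]
  assoc <- enterotype_family_association(lab$enterotype, fam)
  message(sprintf("  family x enterotype chi-square %.1f (df %d), p = %.2g",
                  assoc$statistic, assoc$df, assoc$p))

  # Shannon between enterotypes within sex
  sh <- shannon_index(counts)
  tt <- compare_enterotype_diversity(sh, lab$enterotype,
                                     meta$sex[match(lab$animal, meta$animal)])
  write.table(tt, file.path(out_dir, paste0("shannon_ttest_", tp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

all_lab <- do.call(rbind, labels)
write.table(all_lab, file.path(out_dir, "assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
trans <- enterotype_transitions(all_lab, time_points)
rows <- do.call(rbind, lapply(names(trans), function(k) {
  pct <- trans[[k]]$percent
  data.frame(pair = k, source = rep(rownames(pct), ncol(pct)),
             destination = rep(colnames(pct), each = nrow(pct)),
             percent = round(as.vector(pct), 2))
}))
write.table(rows, file.path(out_dir, "transitions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("transition tables written for ", length(trans), " time-point pairs")
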