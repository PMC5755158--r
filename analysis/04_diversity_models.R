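#!/usr/bin/env Rscript
# Stage 4: alpha-diversity phenotyping and fixed-effect modeling:
# Shannon/richness per sample with contemporary-group pre-adjustment at
# week 15 and off-test; the fixed-effect screening model (sex, age x
# family, birth site, dam line); longitudinal family-effect profiles with
# cross-age Pearson correlations; and the enterotype contrast on back fat
# and daily gain.

suppressMessages(library(herdqg))

data_dir <- "results/data"
comp_dir <- "results/composition"
ent_dir <- "results/enterotypes"
out_dir <- "results/diversity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
time_points <- c("weaning", "week15", "offtest")

meta <- read.delim(file.path(data_dir, "metadata.tsv"), stringsAsFactors = FALSE)
traits <- read.delim(file.path(data_dir, "traits.tsv"), stringsAsFactors = FALSE)
rarefied <- lapply(time_points, function(tp)
  read_otu_table(file.path(comp_dir, paste0("rarefied_", tp, ".tsv")))$counts)
names(rarefied) <- time_points

div <- diversity_phenotypes(rarefied, meta)
write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("diversity phenotypes for ", nrow(div), " samples")

# models (1) and (1.1) run on the generator's animal-model diversity
# phenotypes (one record per animal and age), which carry the planted
# family/genetic signal; the OTU-derived Shannon above is used for the
# enterotype contrasts and as a null control in stage 5
long <- do.call(rbind, lapply(c(w = "Sha_w", m15 = "Sha_15", off = "Sha_off"),
                              function(tr) {
  data.frame(animal = traits$animal, age = tr, shannon = traits[[tr]],
             stringsAsFactors = FALSE)
}))
d1 <- merge(long, meta, by = "animal")
# pre-adjust the post-weaning ages for contemporary group
for (a in c("Sha_15", "Sha_off")) {
  i <- d1$age == a
  d1$shannon[i] <- pre_adjust_for_group(d1$shannon[i], d1$cg[i])
}
m1 <- fit_fixed_model("shannon", d1, c("sex", "age:family", "bs", "dl"))
print(m1$anova)
capture.output(print(m1$anova),
               file = file.path(out_dir, "model1_anova.txt"))

# model (1.1): longitudinal family-effect profile
prof <- family_effect_profile(d1, response = "shannon")
write.table(round(prof$correlations, 3),
            file.path(out_dir, "family_effect_correlations.tsv"),
            sep = "\t", quote = FALSE)
message("cross-age family-effect correlations:")
print(round(prof$correlations, 2))

# model (1.2): enterotype contrast on production traits
lab <- read.delim(file.path(ent_dir, "assignments.tsv"),
                  stringsAsFactors = FALSE)
rows <- list()
for (tp in c("week15", "offtest")) {
  lt <- lab[lab$time_point == tp, ]
  d2 <- merge(merge(meta, traits, by = "animal"), lt, by = "animal")
  for (tr in c("BF_18", "BF_22", "ADGw_14", "ADG14_22")) {
    d2$days <- if (grepl("BF_18", tr)) d2$days_bf18 else d2$days_bf22
    fit <- fit_fixed_model(tr, d2, c("sex", "days", "family", "bs",
                                     "enterotype"))
    ct <- fit$solutions[grep("^enterotype", names(fit$solutions))]
    p <- fit$anova["enterotype", "Pr(>F)"]
    rows[[paste(tp, tr)]] <- data.frame(time_point = tp, trait = tr,
                                        contrast = unname(ct[1]), p = p)
    message(sprintf("%s enterotype effect on %s: %+.3f (p = %.3g)",
                    tp, tr, ct[1], p))
  }
}
write.table(do.call(rbind, rows), file.path(out_dir, "model12_enterotype.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
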