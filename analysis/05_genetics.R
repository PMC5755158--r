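#!/usr/bin/env Rscript
# Stage 5: pedigree-based quantitative genetics of diversity and
# production: numerator relationship matrix, REML variance components
# under the animal model without litter (model 3), with litter (model 4),
# and with litter + pen (model 5, post-weaning only), likelihood-ratio
# comparisons, and bivariate genetic correlations between week-15
# diversity and production traits, presented as triangular tables.
#
# The phenotypes here are the generator's animal-model diversity traits
# (Sha_w, Sha_15, Sha_off), which carry the planted host-genetic signal.
# The OTU-derived Shannon used in stages 3-4 is generated independently
# of the pedigree, so its heritability is a null control, reported at the
# end.

suppressMessages(library(herdqg))

data_dir <- "results/data"
div_dir <- "results/diversity"
out_dir <- "results/genetics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ped <- read_pedigree(file.path(data_dir, "pedigree.csv"))
meta <- read.delim(file.path(data_dir, "metadata.tsv"), stringsAsFactors = FALSE)
traits <- read.delim(file.path(data_dir, "traits.tsv"), stringsAsFactors = FALSE)
div <- read.delim(file.path(div_dir, "diversity.tsv"), stringsAsFactors = FALSE)

A <- numerator_relationship_matrix(ped)
message("A matrix over ", nrow(A), " animals")

dat <- merge(meta, traits, by = "animal")
# contemporary-group pre-adjustment of the post-weaning diversity traits
for (tr in c("Sha_15", "Sha_off")) {
  dat[[tr]] <- pre_adjust_for_group(dat[[tr]], dat$cg)
}

h2_rows <- list()
lrt_rows <- list()
for (tr in c("Sha_w", "Sha_15", "Sha_off")) {
  post_weaning <- tr != "Sha_w"
  m3 <- reml_univariate(tr, dat, A = A, random = "animal")
  m4 <- reml_univariate(tr, dat, A = A, random = c("animal", "litter"))
  fits <- list("3" = m3, "4" = m4)
  if (post_weaning) {
    fits[["5"]] <- reml_univariate(tr, dat, A = A,
                                   random = c("animal", "litter", "pen"))
  }
  for (mod in names(fits)) {
    h <- heritability(fits[[mod]])
    h2_rows[[paste(tr, mod)]] <- data.frame(
      trait = tr, model = mod, h2 = h$h2, se = h$se,
      logLik = fits[[mod]]$logLik, converged = fits[[mod]]$converged)
    message(sprintf("%s model (%s): h2 = %.2f +/- %.2f", tr, mod, h$h2, h$se))
  }
  l43 <- likelihood_ratio_test(m3, m4)
  lrt_rows[[paste(tr, "4v3")]] <- data.frame(
    trait = tr, comparison = "model4_vs_model3", statistic = l43$statistic,
    p_mixture = l43$p_mixture, p_naive = l43$p_naive)
  if (post_weaning) {
    l54 <- likelihood_ratio_test(m4, fits[["5"]])
    lrt_rows[[paste(tr, "5v4")]] <- data.frame(
      trait = tr, comparison = "model5_vs_model4", statistic = l54$statistic,
      p_mixture = l54$p_mixture, p_naive = l54$p_naive)
  }
}
write.table(do.call(rbind, h2_rows), file.path(out_dir, "heritability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, lrt_rows), file.path(out_dir, "lrt.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# bivariate: week-15 diversity against the production traits (model 4 terms)
pairs <- list(c("Sha_15", "BF_18"), c("Sha_15", "BF_22"),
              c("Sha_15", "ADGw_14"), c("Sha_15", "ADG14_22"))
bv_rows <- list()
for (pr in pairs) {
  fit <- reml_bivariate(pr, dat, A = A, random = c("animal", "litter"))
  cc <- correlations(fit)
  bv_rows[[paste(pr, collapse = "_")]] <- data.frame(
    trait1 = pr[1], trait2 = pr[2],
    r_g = cc$r_g, r_g_se = cc$r_g_se, r_p = cc$r_p, r_p_se = cc$r_p_se,
    h2_1 = cc$h2$trait1$h2, h2_2 = cc$h2$trait2$h2,
    converged = fit$converged, bent = any(fit$bent))
  message(sprintf("%s x %s: r_g = %+.2f +/- %.2f, r_p = %+.2f", pr[1], pr[2],
                  cc$r_g, cc$r_g_se, cc$r_p))
}
bv <- do.call(rbind, bv_rows)
write.table(bv, file.path(out_dir, "bivariate.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("note: 28 sire families support genetic-correlation SEs of ~0.25-0.5,")
message("so single-herd r_g estimates are noisy; unbiasedness at scale is")
message("checked by recovery_bivariate() in the test suite")

# triangular presentation for week-15 diversity x back fat at week 18
sel <- bv[bv$trait2 == "BF_18", ]
h2l <- list(Sha_15 = c(sel$h2_1, NA), BF_18 = c(sel$h2_2, NA))
est_g <- matrix(c(NA, sel$r_g, sel$r_g, NA), 2)
est_p <- matrix(c(NA, sel$r_p, sel$r_p, NA), 2)
M <- triangular_table(c("Sha_15", "BF_18"), h2l,
                      r_g = list(est = est_g, se = matrix(sel$r_g_se, 2, 2)),
                      r_p = list(est = est_p, se = matrix(sel$r_p_se, 2, 2)))
write.table(M, file.path(out_dir, "triangular_sha15_bf18.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
message("triangular table written")

# null control: the OTU-derived Shannon has no planted genetic component
wide <- reshape(div[, c("animal", "time_point", "shannon_adj")],
                idvar = "animal", timevar = "time_point", direction = "wide")
names(wide) <- sub("shannon_adj.", "otu_sha_", names(wide))
dat0 <- merge(meta, wide, by = "animal")
m0 <- reml_univariate("otu_sha_week15", dat0, A = A,
                      random = c("animal", "litter"))
h0 <- heritability(m0)
message(sprintf(
  "null control (measured OTU Shannon, week 15): h2 = %.2f +/- %.2f", h0$h2,
  h0$se))
write.table(data.frame(trait = "otu_sha_week15", h2 = h0$h2, se = h0$se),
            file.path(out_dir, "null_control.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
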