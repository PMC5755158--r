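#!/usr/bin/env Rscript
# Stage 1: generate the synthetic herd the rest of the analysis replays.
# Design: 28 Duroc-style sires x 26 dams (one litter each), 1-2 sampled
# progeny per litter (~1200 pigs), single-sex half-sib pens of 20, 6
# contemporary groups, 3 birth sites, 2 dam lines; fecal OTU tables at
# weaning / week 15 / off-test with a planted two-enterotype mixture; and
# production + diversity traits generated under the animal model.

suppressMessages(library(herdqg))

out_dir <- "results/data"
seed <- 20240915

cfg <- sim_config(seed = seed)
message("simulating herd (seed ", seed, ") ...")
herd <- simulate_herd(cfg)
files <- write_herd(herd, out_dir)

message("pedigree animals: ", nrow(herd$pedigree),
        " (progeny: ", sum(!is.na(herd$pedigree$sire)), ")")
message("litters: ", length(unique(herd$frame$litter)),
        "; pens: ", length(unique(herd$frame$pen)))
for (tp in names(herd$otu$counts)) {
  message(tp, ": ", nrow(herd$otu$counts[[tp]]), " samples x ",
          ncol(herd$otu$counts[[tp]]), " OTUs at depth ", cfg$depth)
}
message("wrote ", length(files), " files under ", out_dir)
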