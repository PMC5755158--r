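#' Reference catalog of swine gut genera
#'
#' A compact catalog of bacterial genera commonly reported in pig fecal
#' 16S surveys, with full seven-rank lineages. It seeds the synthetic OTU
#' generator: enterotype templates are defined over these genera and each
#' genus is expanded into several synthetic OTUs, each carrying a
#' synthetic species label ("<genus>_sp<k>") so that species-level
#' aggregation stays meaningful even though the generator plants its
#' structure at the genus level.
#'
#' @return data.frame with columns `genus`, `family`, `order`, `class`,
#'   `phylum`.
#' @export
genus_catalog <- function() {
  g <- function(genus, family, order, class, phylum) {
    data.frame(genus = genus, family = family, order = order,
               class = class, phylum = phylum, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    g("Clostridium", "Clostridiaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Escherichia", "Enterobacteriaceae", "Enterobacteriales", "Gammaproteobacteria", "Proteobacteria"),
    g("Bacteroides", "Bacteroidaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Prevotella", "Prevotellaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Ruminococcus", "Ruminococcaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Fusobacterium", "Fusobacteriaceae", "Fusobacteriales", "Fusobacteriia", "Fusobacteria"),
    g("Campylobacter", "Campylobacteraceae", "Campylobacterales", "Epsilonproteobacteria", "Proteobacteria"),
    g("Eubacterium", "Eubacteriaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Lactobacillus", "Lactobacillaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    g("Streptococcus", "Streptococcaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    g("Turicibacter", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Enterococcus", "Enterococcaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    g("Blautia", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Coprococcus", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Dorea", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Roseburia", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Lachnospira", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Oribacterium", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Faecalibacterium", "Ruminococcaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Oscillibacter", "Oscillospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Anaerotruncus", "Ruminococcaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Anaerostipes", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Cellulosilyticum", "Lachnospiraceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Sarcina", "Clostridiaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Peptostreptococcus", "Peptostreptococcaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Mogibacterium", "Mogibacteriaceae", "Clostridiales", "Clostridia", "Firmicutes"),
    g("Catenibacterium", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Holdemania", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Solobacterium", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Bulleidia", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Sharpea", "Erysipelotrichaceae", "Erysipelotrichales", "Erysipelotrichia", "Firmicutes"),
    g("Megasphaera", "Veillonellaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Mitsuokella", "Veillonellaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Dialister", "Veillonellaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Selenomonas", "Selenomonadaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Veillonella", "Veillonellaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Acidaminococcus", "Acidaminococcaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Phascolarctobacterium", "Acidaminococcaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Anaerovibrio", "Selenomonadaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Schwartzia", "Selenomonadaceae", "Selenomonadales", "Negativicutes", "Firmicutes"),
    g("Butyricimonas", "Odoribacteraceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Parabacteroides", "Porphyromonadaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Alistipes", "Rikenellaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Porphyromonas", "Porphyromonadaceae", "Bacteroidales", "Bacteroidia", "Bacteroidetes"),
    g("Actinobacillus", "Pasteurellaceae", "Pasteurellales", "Gammaproteobacteria", "Proteobacteria"),
    g("Haemophilus", "Pasteurellaceae", "Pasteurellales", "Gammaproteobacteria", "Proteobacteria"),
    g("Pasteurella", "Pasteurellaceae", "Pasteurellales", "Gammaproteobacteria", "Proteobacteria"),
    g("Succinivibrio", "Succinivibrionaceae", "Aeromonadales", "Gammaproteobacteria", "Proteobacteria"),
    g("Ruminobacter", "Succinivibrionaceae", "Aeromonadales", "Gammaproteobacteria", "Proteobacteria"),
    g("Sutterella", "Sutterellaceae", "Burkholderiales", "Betaproteobacteria", "Proteobacteria"),
    g("Oxalobacter", "Oxalobacteraceae", "Burkholderiales", "Betaproteobacteria", "Proteobacteria"),
    g("Desulfovibrio", "Desulfovibrionaceae", "Desulfovibrionales", "Deltaproteobacteria", "Proteobacteria"),
    g("Helicobacter", "Helicobacteraceae", "Campylobacterales", "Epsilonproteobacteria", "Proteobacteria"),
    g("Treponema", "Spirochaetaceae", "Spirochaetales", "Spirochaetia", "Spirochaetes"),
    g("Fibrobacter", "Fibrobacteraceae", "Fibrobacterales", "Fibrobacteria", "Fibrobacteres"),
    g("Akkermansia", "Akkermansiaceae", "Verrucomicrobiales", "Verrucomicrobiae", "Verrucomicrobia"),
    g("Mucispirillum", "Deferribacteraceae", "Deferribacterales", "Deferribacteres", "Deferribacteres"),
    g("Collinsella", "Coriobacteriaceae", "Coriobacteriales", "Coriobacteriia", "Actinobacteria"),
    g("Olsenella", "Atopobiaceae", "Coriobacteriales", "Coriobacteriia", "Actinobacteria"),
    g("Bifidobacterium", "Bifidobacteriaceae", "Bifidobacteriales", "Actinomycetia", "Actinobacteria")
  ))
}

#' Build a taxonomy map for synthetic OTUs
#'
#' @param otu_ids character OTU ids.
#' @param genera genus label per OTU (must appear in [genus_catalog()]).
#' @return data.frame with `otu_id` and the seven ranks
#'   kingdom/phylum/class/order/family/genus/species.
#' @export
taxonomy_for_otus <- function(otu_ids, genera) {
  stopifnot(length(otu_ids) == length(genera))
  cat_tab <- genus_catalog()
  idx <- match(genera, cat_tab$genus)
  if (anyNA(idx)) stop("unknown genera: ", paste(unique(genera[is.na(idx)]), collapse = ", "))
  within_genus <- stats::ave(seq_along(genera), genera, FUN = seq_along)
  data.frame(
    otu_id = otu_ids,
    kingdom = "Bacteria",
    phylum = cat_tab$phylum[idx],
    class = cat_tab$class[idx],
    order = cat_tab$order[idx],
    family = cat_tab$family[idx],
    genus = genera,
    species = paste0(genera, "_sp", within_genus),
    stringsAsFactors = FALSE
  )
}

.TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
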