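#' Read a classic tab-separated OTU table
#'
#' Expects the QIIME-classic layout: first column OTU ids, one column per
#' sample, optionally a trailing taxonomy column holding a
#' semicolon-delimited lineage. Returns the matrix oriented samples x OTUs
#' (the orientation every function in this package uses).
#'
#' @param path file path.
#' @return list with `counts` (samples x OTUs integer matrix) and
#'   `taxonomy` (data.frame or NULL).
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  otu_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (ncol(df) && tolower(names(df)[ncol(df)]) %in% c("taxonomy", "lineage")) {
    taxonomy <- parse_lineages(otu_ids, df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  counts <- t(as.matrix(df))
  colnames(counts) <- otu_ids
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = taxonomy)
}

#' Write a classic tab-separated OTU table
#'
#' @param counts samples x OTUs integer matrix.
#' @param path output file.
#' @param taxonomy optional taxonomy data.frame (`otu_id` + rank columns);
#'   written as a trailing semicolon-delimited `taxonomy` column.
#' @export
write_otu_table <- function(counts, path, taxonomy = NULL) {
  df <- data.frame(`#OTU ID` = colnames(counts), t(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    ranks <- intersect(.TAX_RANKS, names(taxonomy))
    lin <- apply(taxonomy[match(colnames(counts), taxonomy$otu_id), ranks,
                          drop = FALSE], 1, paste, collapse = "; ")
    df$taxonomy <- lin
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse semicolon-delimited lineages into a rank table
#'
#' Missing trailing ranks propagate as "unclassified".
#'
#' @param otu_ids OTU id per lineage.
#' @param lineages character vector, ranks separated by ";".
#' @return data.frame `otu_id` + seven rank columns.
#' @export
parse_lineages <- function(otu_ids, lineages) {
  parts <- strsplit(as.character(lineages), ";")
  tab <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[kpcofgs]__", "", p)
    p[p == ""] <- "unclassified"
    c(p, rep("unclassified", length(.TAX_RANKS)))[seq_along(.TAX_RANKS)]
  }, character(length(.TAX_RANKS))))
  out <- data.frame(otu_id = otu_ids, tab, stringsAsFactors = FALSE)
  names(out) <- c("otu_id", .TAX_RANKS)
  out
}

#' Read a taxonomy TSV (otu_id, lineage)
#'
#' @param path file with two tab-separated columns: OTU id and a
#'   semicolon-delimited lineage.
#' @return data.frame `otu_id` + rank columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  parse_lineages(df[[1]], df[[2]])
}

#' Read a pedigree CSV (animal,sire,dam)
#'
#' Unknown parents may be coded 0, "", or NA. Parents referenced but never
#' declared as animals are added as founders. The result is topologically
#' sorted (parents before offspring); cycles and self-parentage are
#' rejected.
#'
#' @param path CSV file with header `animal,sire,dam`.
#' @return sorted pedigree data.frame (`animal`, `sire`, `dam`).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  sort_pedigree(df[, c("animal", "sire", "dam")])
}

#' Topologically sort and validate a pedigree
#'
#' @param ped data.frame with `animal`, `sire`, `dam` (unknown = NA/0/"").
#' @return sorted pedigree with unknown parents as NA.
#' @export
sort_pedigree <- function(ped) {
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  animal <- as.character(ped$animal)
  sire <- clean(ped$sire)
  dam <- clean(ped$dam)
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  selfp <- animal == sire | animal == dam
  if (any(selfp, na.rm = TRUE))
    stop("animal listed as its own parent: ",
         paste(animal[which(selfp)], collapse = ", "))
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- idx[sire]; di <- idx[dam]
  # Kahn's algorithm to detect cycles and assign generation depths; the
  # final order (generation, id) is canonical, independent of row order
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  gen <- rep(1L, n)
  queue <- which(indeg == 0)
  n_seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    n_seen <- n_seen + 1L
    for (ch in children[[v]]) {
      gen[ch] <- max(gen[ch], gen[v] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (n_seen < n)
    stop("pedigree cycle involving: ",
         paste(animal[indeg > 0], collapse = ", "))
  ord <- order(gen, animal)
  data.frame(animal = animal[ord], sire = sire[ord],
             dam = dam[ord], stringsAsFactors = FALSE)
}

#' Write synthetic herd outputs as plain-text files
#'
#' Pedigree CSV (unknown parent = 0), metadata TSV, trait TSV, one OTU TSV
#' per time point (with taxonomy column), and a truth TSV of breeding
#' values and enterotype labels.
#'
#' @param herd output of [simulate_herd()].
#' @param dir output directory (created if missing).
#' @return invisible character vector of files written.
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ped <- herd$pedigree
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  f <- file.path(dir, "pedigree.csv")
  utils::write.csv(ped, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "metadata.tsv")
  utils::write.table(herd$frame, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "traits.tsv")
  utils::write.table(herd$traits$phenotypes, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  for (tp in names(herd$otu$counts)) {
    f <- file.path(dir, paste0("otu_", tp, ".tsv"))
    write_otu_table(herd$otu$counts[[tp]], f, herd$otu$taxonomy)
    files <- c(files, f)
  }
  truth <- merge(herd$otu$labels,
                 stats::setNames(herd$traits$tbv,
                                 c("animal", paste0("tbv_", names(herd$traits$tbv)[-1]))),
                 by = "animal")
  f <- file.path(dir, "truth.tsv")
  utils::write.table(truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
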