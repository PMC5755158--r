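#' Configuration for the synthetic herd generator
#'
#' Defaults emulate the study design the pipeline replays: 28 purebred sires
#' each mated to ~26 dams (one litter per dam, ~728 litters), 1-2 sampled
#' progeny per litter (~1200 sampled pigs), pens of 20 paternal half-sibs of
#' one sex, 6 contemporary groups, 3 birth sites, 2 dam lines, fecal samples
#' at three time points (weaning, week 15, off-test) rarefiable to 10,000
#' reads, and production traits (back fat at weeks 18/22, average daily gain)
#' generated under an animal model with pedigree-structured breeding values.
#'
#' @param n_sires number of paternal half-sib families.
#' @param dams_per_sire dams (= litters) mated to each sire.
#' @param progeny_per_dam integer vector of allowed sampled-progeny counts
#'   per litter; each litter draws uniformly from it.
#' @param pen_size pigs per pen; pens are single-sex, single-family.
#' @param n_contemporary_groups,n_birth_sites,n_dam_lines design constants.
#' @param depth reads per sample drawn by the OTU generator.
#' @param concentration Dirichlet concentration of within-enterotype spread
#'   (larger = samples closer to their template).
#' @param traits data.frame of trait generative parameters (see
#'   [default_trait_params()]).
#' @param genetic_corr genetic correlation matrix across traits (bent to the
#'   nearest PSD correlation matrix if needed).
#' @param templates per-time-point enterotype templates (see
#'   [default_enterotype_templates()]).
#' @param seed root seed; all stages derive named substreams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 28L,
                       dams_per_sire = 26L,
                       progeny_per_dam = c(1L, 2L),
                       pen_size = 20L,
                       n_contemporary_groups = 6L,
                       n_birth_sites = 3L,
                       n_dam_lines = 2L,
                       depth = 10000L,
                       concentration = 60,
                       traits = default_trait_params(),
                       genetic_corr = default_genetic_corr(),
                       templates = default_enterotype_templates(),
                       seed = 1L) {
  counts <- c(n_sires, dams_per_sire, pen_size, n_contemporary_groups,
              n_birth_sites, n_dam_lines)
  if (any(counts < 1)) stop("design counts must be >= 1")
  if (any(progeny_per_dam < 1)) stop("progeny_per_dam must be >= 1")
  if (depth <= 0) stop("depth must be > 0")
  stopifnot(nrow(genetic_corr) == nrow(traits),
            all(rownames(genetic_corr) == traits$trait))
  if (any(traits$h2 < 0) || any(traits$c2_litter < 0) || any(traits$c2_pen < 0) ||
      any(traits$h2 + traits$c2_litter + traits$c2_pen > 1))
    stop("variance proportions must be >= 0 and sum to <= 1 per trait")
  genetic_corr <- make_psd_corr(genetic_corr)
  for (tp in names(templates)) {
    tm <- templates[[tp]]
    # normalize the two accepted layouts to templates + mixture weights
    if (!is.null(tm$a)) {
      tm <- list(templates = list(A = tm$a, B = tm$b),
                 mix = c(tm$p_a, 1 - tm$p_a))
    }
    lens <- lengths(tm$templates)
    if (length(unique(lens)) != 1L)
      stop("template length mismatch at time point ", tp)
    if (is.null(names(tm$templates)))
      names(tm$templates) <- LETTERS[seq_along(tm$templates)]
    tm$templates <- lapply(tm$templates, function(x) x / sum(x))
    tm$mix <- tm$mix / sum(tm$mix)
    templates[[tp]] <- tm
  }
  structure(list(
    n_sires = as.integer(n_sires), dams_per_sire = as.integer(dams_per_sire),
    progeny_per_dam = as.integer(progeny_per_dam), pen_size = as.integer(pen_size),
    n_contemporary_groups = as.integer(n_contemporary_groups),
    n_birth_sites = as.integer(n_birth_sites), n_dam_lines = as.integer(n_dam_lines),
    depth = as.integer(depth), concentration = concentration,
    traits = traits, genetic_corr = genetic_corr, templates = templates,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default generative parameters per trait
#'
#' Phenotypic variances and variance proportions chosen to mirror the
#' magnitudes the pipeline is meant to estimate: Shannon diversity lowly
#' heritable at weaning, moderately at week 15/off-test, with litter and
#' (post-weaning) pen effects; back fat moderately heritable; daily gain
#' lowly to moderately heritable. `mean` is the trait mean, `var_p` the
#' phenotypic variance, `h2`/`c2_litter`/`c2_pen` the fractions of `var_p`
#' attributed to additive genetics, litter, and pen; `sex_effect` and
#' `bs_effects` are fixed-effect sizes in trait units.
#'
#' @return data.frame, one row per trait.
#' @export
default_trait_params <- function() {
  tr <- data.frame(
    trait = c("Sha_w", "Sha_15", "Sha_off", "Ric_15",
              "BF_18", "BF_22", "ADGw_14", "ADG14_22"),
    mean  = c(3.85, 4.53, 4.62, 900, 1.60, 2.00, 0.75, 0.95),
    var_p = c(0.45, 0.090, 0.100, 8100, 0.090, 0.120, 0.0064, 0.0100),
    h2        = c(0.04, 0.17, 0.19, 0.24, 0.30, 0.28, 0.09, 0.17),
    c2_litter = c(0.25, 0.10, 0.10, 0.10, 0.10, 0.10, 0.15, 0.10),
    c2_pen    = c(0.00, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    sex_effect = c(0.10, 0.05, 0.05, 15, 0.08, 0.10, 0.02, 0.03),
    stringsAsFactors = FALSE
  )
  tr$bs_effects <- I(lapply(seq_len(nrow(tr)), function(i)
    c(0, 0.5, -0.35) * sqrt(tr$var_p[i]) * 0.3))
  tr$dl_effect <- 0.05 * sqrt(tr$var_p)
  rownames(tr) <- tr$trait
  tr
}

#' Default genetic correlation matrix across simulated traits
#'
#' Moderate negative genetic correlations between week-15 diversity and the
#' production traits, near-zero to weakly negative correlations involving
#' weaning diversity, strong correlation between the two back-fat ages.
#' Bent to the nearest PSD correlation matrix by [sim_config()].
#'
#' @return symmetric matrix with unit diagonal.
#' @export
default_genetic_corr <- function() {
  tr <- c("Sha_w", "Sha_15", "Sha_off", "Ric_15",
          "BF_18", "BF_22", "ADGw_14", "ADG14_22")
  R <- diag(length(tr))
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("Sha_w", "Sha_15", -0.17); set_r("Sha_w", "Sha_off", -0.34)
  set_r("Sha_15", "Sha_off", 0.44); set_r("Sha_15", "Ric_15", 0.70)
  set_r("Sha_w", "Ric_15", -0.10); set_r("Sha_off", "Ric_15", 0.30)
  set_r("Sha_w", "BF_18", 0.38); set_r("Sha_w", "BF_22", 0.40)
  set_r("Sha_w", "ADGw_14", -0.30); set_r("Sha_w", "ADG14_22", 0.30)
  set_r("Sha_15", "BF_18", -0.53); set_r("Sha_15", "BF_22", -0.45)
  set_r("Sha_15", "ADGw_14", -0.53); set_r("Sha_15", "ADG14_22", -0.53)
  set_r("Sha_off", "BF_18", -0.20); set_r("Sha_off", "BF_22", -0.20)
  set_r("Sha_off", "ADGw_14", -0.20); set_r("Sha_off", "ADG14_22", -0.20)
  set_r("Ric_15", "BF_18", -0.35); set_r("Ric_15", "BF_22", -0.30)
  set_r("Ric_15", "ADGw_14", -0.35); set_r("Ric_15", "ADG14_22", -0.35)
  set_r("BF_18", "BF_22", 0.90); set_r("BF_18", "ADGw_14", 0.25)
  set_r("BF_18", "ADG14_22", 0.25); set_r("BF_22", "ADGw_14", 0.20)
  set_r("BF_22", "ADG14_22", 0.25); set_r("ADGw_14", "ADG14_22", 0.30)
  R
}

#' Default two-enterotype genus templates per time point
#'
#' Each time point carries two genus-level mean composition vectors over the
#' genera of [genus_catalog()] plus the mixture proportion of the first
#' type. At weaning the contrast is an Escherichia-led low-diversity type
#' against a Prevotella-led high-diversity type; at week 15 and off-test a
#' Clostridium/Turicibacter-led type against a Lactobacillus/Streptococcus-
#' led type, mirroring the enterotype contrasts the pipeline is built to
#' recover. Base abundances decay geometrically over the catalog so that a
#' realistic long tail of rare genera is present.
#'
#' @return named list with elements `weaning`, `week15`, `offtest`, each a
#'   list `a`, `b` (template proportions) and `p_a` (mixture weight of `a`).
#' @export
default_enterotype_templates <- function() {
  genera <- genus_catalog()$genus
  base <- 0.90^seq_along(genera)
  names(base) <- genera
  boost <- function(x, up) {
    x[names(up)] <- x[names(up)] * up
    x / sum(x)
  }
  list(
    weaning = list(
      a = boost(base, c(Escherichia = 90, Enterococcus = 12, Fusobacterium = 8,
                        Bacteroides = 6, Campylobacter = 5)),
      b = boost(base, c(Prevotella = 16, Ruminococcus = 5, Lactobacillus = 4,
                        Bacteroides = 4, Faecalibacterium = 3, Blautia = 3)),
      p_a = 0.325
    ),
    week15 = list(
      a = boost(base, c(Clostridium = 25, Turicibacter = 10, Sarcina = 4,
                        Peptostreptococcus = 3)),
      b = boost(base, c(Lactobacillus = 18, Streptococcus = 12, Prevotella = 8,
                        Megasphaera = 3)),
      p_a = 0.438
    ),
    offtest = list(
      a = boost(base, c(Clostridium = 22, Turicibacter = 9, Sarcina = 3,
                        Coprococcus = 3)),
      b = boost(base, c(Lactobacillus = 16, Streptococcus = 10, Prevotella = 7,
                        Dialister = 3)),
      p_a = 0.657
    )
  )
}

#' Simulate a paternal half-sib pedigree
#'
#' Base-generation sires and dams have unknown parents; every dam produces
#' one litter by her sire mate, with a per-litter number of sampled progeny
#' drawn from `config$progeny_per_dam`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `animal`, `sire`, `dam` (`NA` for
#'   founders) plus `sex`-free litter bookkeeping in attribute `litters`.
#' @export
simulate_pedigree <- function(config) {
  seeds <- substream_seeds(config$seed)
  with_seed(seeds[["pedigree"]], {
    sires <- sprintf("S%02d", seq_len(config$n_sires))
    dams <- sprintf("D%04d", seq_len(config$n_sires * config$dams_per_sire))
    dam_sire <- rep(sires, each = config$dams_per_sire)
    n_off <- if (length(config$progeny_per_dam) == 1L) {
      rep(config$progeny_per_dam, length(dams))
    } else {
      sample(config$progeny_per_dam, length(dams), replace = TRUE)
    }
    prog <- sprintf("P%05d", seq_len(sum(n_off)))
    ped <- data.frame(
      animal = c(sires, dams, prog),
      sire = c(rep(NA_character_, length(sires) + length(dams)),
               rep(dam_sire, n_off)),
      dam = c(rep(NA_character_, length(sires) + length(dams)),
              rep(dams, n_off)),
      stringsAsFactors = FALSE
    )
    attr(ped, "generation") <- rep(c("founder", "progeny"),
                                   c(length(sires) + length(dams), length(prog)))
    ped
  })
}

#' Assign sexes, litters, pens and design factors to progeny
#'
#' Pens contain paternal half-sibs of one sex only; sexes alternate within
#' litter to balance the design; each dam's litter is one litter effect
#' level; pens rotate through contemporary groups so each family spans all
#' of them; birth site is a property of the litter and dam line of the dam.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return data.frame of animals with design columns (`sex`, `family`,
#'   `litter`, `pen`, `cg`, `bs`, `dl`, ages in days per time point).
#' @export
simulate_design <- function(pedigree, config) {
  seeds <- substream_seeds(config$seed)
  with_seed(seeds[["design"]], {
    prog <- pedigree[!is.na(pedigree$sire), , drop = FALSE]
    n <- nrow(prog)
    frame <- data.frame(
      animal = prog$animal, sire = prog$sire, dam = prog$dam,
      stringsAsFactors = FALSE
    )
    frame$family <- frame$sire
    frame$litter <- frame$dam       # one litter per dam per simulation
    # alternate sexes within litter, random start per litter
    frame <- frame[order(frame$dam, frame$animal), ]
    starts <- sample(0:1, length(unique(frame$dam)), replace = TRUE)
    names(starts) <- unique(frame$dam)
    within_pos <- stats::ave(seq_len(n), frame$dam, FUN = seq_along)
    frame$sex <- ifelse((within_pos + starts[frame$dam]) %% 2 == 0, "M", "F")
    # litter-level factors
    dams <- unique(frame$dam)
    bs_of_dam <- sample(sprintf("BS%d", seq_len(config$n_birth_sites)),
                        length(dams), replace = TRUE)
    dl_of_dam <- sprintf("DL%d", (seq_along(dams) - 1L) %% config$n_dam_lines + 1L)
    names(bs_of_dam) <- names(dl_of_dam) <- dams
    frame$bs <- bs_of_dam[frame$dam]
    frame$dl <- dl_of_dam[frame$dam]
    # pens: fill within family x sex; never mixed-family; last pen may be short
    frame$pen <- NA_character_
    pen_id <- 0L
    short_pens <- 0L
    for (fam in unique(frame$family)) {
      for (sx in c("F", "M")) {
        members <- which(frame$family == fam & frame$sex == sx)
        members <- members[sample.int(length(members))]
        npen <- ceiling(length(members) / config$pen_size)
        for (p in seq_len(npen)) {
          pen_id <- pen_id + 1L
          take <- members[((p - 1L) * config$pen_size + 1L):
                            min(p * config$pen_size, length(members))]
          frame$pen[take] <- sprintf("PEN%04d", pen_id)
          if (length(take) < config$pen_size) short_pens <- short_pens + 1L
        }
      }
    }
    if (short_pens > 0L)
      message("simulate_design: ", short_pens,
              " pens hold fewer than pen_size animals (families not divisible)")
    # contemporary groups rotate over pens within family
    pens <- unique(frame$pen)
    cg_of_pen <- sprintf("CG%d", (seq_along(pens) - 1L) %%
                           config$n_contemporary_groups + 1L)
    names(cg_of_pen) <- pens
    frame$cg <- cg_of_pen[frame$pen]
    # ages in days at sampling / trait recording
    frame$days_weaning <- round(stats::rnorm(n, 18.6, 1.09), 1)
    frame$days_week15 <- round(stats::rnorm(n, 118.2, 1.18), 1)
    frame$days_offtest <- round(stats::rnorm(n, 196.4, 7.86), 1)
    frame$days_bf18 <- frame$days_weaning + 18 * 7
    frame$days_bf22 <- frame$days_weaning + 22 * 7
    rownames(frame) <- NULL
    frame
  })
}

#' Simulate trait phenotypes under the animal model
#'
#' Breeding values for all traits are drawn jointly with covariance
#' A (x) G0, where A is the pedigree numerator relationship matrix
#' (factorized with a small diagonal jitter if numerically semidefinite)
#' and G0 combines per-trait additive variances with the genetic
#' correlation matrix. Litter, pen and residual effects are independent
#' with identity covariance scaled by their components. Phenotype =
#' mean + fixed effects (sex, birth site, dam line) + animal + litter +
#' pen + residual; true effect draws are stored for evaluation.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param frame output of [simulate_design()].
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame animal x trait), `tbv`
#'   (true breeding values, same shape), and `true_effects` (litter/pen
#'   effect draws).
#' @export
simulate_traits <- function(pedigree, frame, config) {
  seeds <- substream_seeds(config$seed)
  with_seed(seeds[["traits"]], {
    tr <- config$traits
    ntr <- nrow(tr)
    sd_a <- sqrt(tr$h2 * tr$var_p)
    G0 <- config$genetic_corr * tcrossprod(sd_a)
    eg <- eigen((G0 + t(G0)) / 2, symmetric = TRUE)
    if (any(eg$values < -1e-8 * max(eg$values))) {
      bad <- which.min(eg$values)
      stop("G0 is not positive semi-definite (most negative eigenvector loads on ",
           paste(tr$trait[order(abs(eg$vectors[, bad]), decreasing = TRUE)[1:2]],
                 collapse = " x "), ")")
    }
    L_G <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), ntr)

    A <- numerator_relationship_matrix(pedigree)
    # sparse Cholesky: half-sib pedigrees make A block diagonal by family
    As <- Matrix::forceSymmetric(.sparsify(A))
    ch <- tryCatch(Matrix::Cholesky(As, LDL = FALSE, perm = TRUE),
                   error = function(e)
                     Matrix::Cholesky(As + Matrix::Diagonal(nrow(A), 1e-8),
                                      LDL = FALSE, perm = TRUE))
    ex <- Matrix::expand(ch)
    Z <- matrix(stats::rnorm(nrow(A) * ntr), nrow(A), ntr)
    U <- as.matrix(Matrix::t(ex$P) %*% (ex$L %*% Z)) %*% t(L_G)  # cov = A (x) G0
    rownames(U) <- rownames(A)
    colnames(U) <- tr$trait

    litters <- unique(frame$litter)
    pens <- unique(frame$pen)
    lit_eff <- matrix(stats::rnorm(length(litters) * ntr), length(litters), ntr) %*%
      diag(sqrt(tr$c2_litter * tr$var_p), ntr)
    pen_eff <- matrix(stats::rnorm(length(pens) * ntr), length(pens), ntr) %*%
      diag(sqrt(tr$c2_pen * tr$var_p), ntr)
    rownames(lit_eff) <- litters; rownames(pen_eff) <- pens
    colnames(lit_eff) <- colnames(pen_eff) <- tr$trait

    n <- nrow(frame)
    res_sd <- sqrt((1 - tr$h2 - tr$c2_litter - tr$c2_pen) * tr$var_p)
    E <- matrix(stats::rnorm(n * ntr), n, ntr) %*% diag(res_sd, ntr)

    Y <- matrix(rep(tr$mean, each = n), n, ntr)
    Y <- Y + outer(as.numeric(frame$sex == "M"), tr$sex_effect)
    bs_idx <- as.integer(factor(frame$bs, levels = sprintf("BS%d", seq_len(config$n_birth_sites))))
    for (j in seq_len(ntr)) {
      Y[, j] <- Y[, j] + tr$bs_effects[[j]][bs_idx] +
        tr$dl_effect[j] * as.numeric(frame$dl == "DL2")
    }
    Y <- Y + U[frame$animal, , drop = FALSE] +
      lit_eff[frame$litter, , drop = FALSE] +
      pen_eff[frame$pen, , drop = FALSE] + E
    colnames(Y) <- tr$trait

    phen <- data.frame(animal = frame$animal, Y, stringsAsFactors = FALSE,
                       check.names = FALSE)
    tbv <- data.frame(animal = frame$animal,
                      U[frame$animal, , drop = FALSE],
                      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(phen) <- rownames(tbv) <- NULL
    list(phenotypes = phen, tbv = tbv,
         true_effects = list(litter = lit_eff, pen = pen_eff, bv_all = U))
  })
}

#' Simulate OTU count tables with planted enterotype structure
#'
#' Every animal contributes one sample per time point. Each sample draws a
#' latent enterotype label from the time point's mixture, then genus-level
#' proportions from a Dirichlet centred on that enterotype's template, then
#' `depth` reads multinomially. Genus proportions are expanded to several
#' OTUs per genus with fixed within-genus weights, so OTU-level and
#' genus-level analyses are both possible. Labels are returned for
#' evaluation only and never consumed by the pipeline.
#'
#' @param frame output of [simulate_design()].
#' @param config a [sim_config()].
#' @param otus_per_genus integer vector recycled over the genus catalog.
#' @return list with `counts` (named list per time point: samples x OTUs
#'   integer matrix), `taxonomy` (data.frame), `labels` (data.frame animal,
#'   time_point, enterotype).
#' @export
simulate_otu_table <- function(frame, config, otus_per_genus = c(6L, 4L, 3L, 2L)) {
  seeds <- substream_seeds(config$seed)
  with_seed(seeds[["otu"]], {
    genera <- names(config$templates[[1]]$templates[[1]])
    k_otu <- rep_len(otus_per_genus, length(genera))
    otu_genus <- rep(genera, k_otu)
    otu_ids <- sprintf("OTU%04d", seq_along(otu_genus))
    taxonomy <- taxonomy_for_otus(otu_ids, otu_genus)
    # fixed within-genus OTU weights (geometric), shared by all samples
    w <- unlist(lapply(k_otu, function(k) {
      v <- 0.6^(seq_len(k) - 1)
      v / sum(v)
    }))
    genus_index <- match(otu_genus, genera)

    counts <- list()
    labels <- list()
    for (tp in names(config$templates)) {
      tm <- config$templates[[tp]]
      n <- nrow(frame)
      classes <- names(tm$templates)
      lab <- classes[sample.int(length(classes), n, replace = TRUE,
                                prob = tm$mix)]
      P_genus <- matrix(NA_real_, n, length(genera))
      for (cl in classes) {
        idx <- which(lab == cl)
        if (!length(idx)) next
        P_genus[idx, ] <- rdirichlet(length(idx),
                                     tm$templates[[cl]] * config$concentration)
      }
      P_otu <- P_genus[, genus_index, drop = FALSE] *
        matrix(w, n, length(otu_ids), byrow = TRUE)
      M <- matrix(0L, n, length(otu_ids),
                  dimnames = list(paste0(frame$animal, "_", tp), otu_ids))
      for (i in seq_len(n)) {
        M[i, ] <- as.integer(stats::rmultinom(1, config$depth, P_otu[i, ]))
      }
      counts[[tp]] <- M
      labels[[tp]] <- data.frame(animal = frame$animal, time_point = tp,
                                 enterotype = lab, stringsAsFactors = FALSE)
    }
    list(counts = counts, taxonomy = taxonomy,
         labels = do.call(rbind, labels))
  })
}

#' Run the full synthetic herd generator
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `frame`, `traits`, `otu` components.
#' @export
simulate_herd <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  frame <- simulate_design(ped, config)
  traits <- simulate_traits(ped, frame, config)
  otu <- simulate_otu_table(frame, config)
  list(pedigree = ped, frame = frame, traits = traits, otu = otu,
       config = config)
}
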