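#' Configuration for the synthetic GeoMx cohort generator
#'
#' The defaults emulate the structure of a rapid-autopsy GeoMx DSP study:
#' 10 patients, 4 circular regions each (40 ROIs), of which 4 are tumor-only,
#' 4 are histologically normal, and the remaining 32 yield paired tumor/TME
#' segments (36 tumor + 32 TME + 4 normal = 72 segments). Three tumor
#' phenotypes are planted: neuroendocrine (NE), hybrid-NE (co-expressing NE
#' and EMT programs at intermediate level) and non-NE. TME cell-type
#' composition covaries with the adjacent tumor phenotype with strength
#' `mixing_link_strength` (0 = independent, 1 = fully phenotype-determined).
#' Two TME segments are planted with low sequencing saturation so that the
#' default QC step removes them (32 -> 30).
#'
#' @param n_patients number of patients.
#' @param regions_per_patient regions per patient; a single count or a
#'   `c(min, max)` range sampled per patient.
#' @param n_genes size of the gene universe (must accommodate the planted
#'   programs and cell-type markers).
#' @param probes_per_gene probes per non-negative gene target.
#' @param n_negative_probes number of negative-control probes.
#' @param phenotype_fractions length-3 simplex vector, sampling weights for
#'   the planted tumor phenotypes, in the order (NE, hybrid, nonNE).
#' @param signature_size_per_phenotype genes per planted phenotype program.
#' @param celltypes character vector of TME cell-type names.
#' @param markers_per_celltype marker genes per cell type.
#' @param mixing_link_strength real in `[0, 1]`; how strongly the TME
#'   composition tracks the tumor phenotype.
#' @param nb_dispersion negative-binomial size parameter for counts
#'   (larger = closer to Poisson).
#' @param lr_pairs_active number of planted active ligand-receptor pairs.
#' @param hazard_ratio_true hazard ratio planted in survival cohorts.
#' @param n_tumor_only,n_normal numbers of tumor-only and normal ROIs.
#' @param n_low_quality number of TME segments planted below the default
#'   saturation QC threshold.
#' @param fold expression fold elevation of the NE program in NE segments
#'   and, scaled by the multipliers below, of the other planted programs.
#' @param nonne_fold_mult multiplier on `fold` for the non-NE program in
#'   non-NE segments; values above 1 let the non-NE centroid dominate the
#'   leading principal axis, as in tumors where the non-NE state is the
#'   transcriptionally most divergent.
#' @param hybrid_ne_fold fold elevation of the NE program in hybrid
#'   segments (intermediate NE differentiation).
#' @param hybrid_emt_mult multiplier on `fold` for the EMT metaprogram in
#'   hybrid segments.
#' @param seed integer seed; a fixed seed yields byte-identical output
#'   (Mersenne-Twister, Inversion normals, Rejection sampling).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 10,
                             regions_per_patient = 4,
                             n_genes = 1000,
                             probes_per_gene = 3,
                             n_negative_probes = 32,
                             phenotype_fractions = c(NE = 1 / 3,
                                                     hybrid = 1 / 3,
                                                     nonNE = 1 / 3),
                             signature_size_per_phenotype = 60,
                             celltypes = c("CAF", "T.cell", "B.cell", "NK",
                                           "Macrophage", "Endothelial",
                                           "Dendritic", "Neutrophil"),
                             markers_per_celltype = 20,
                             mixing_link_strength = 0.8,
                             nb_dispersion = 10,
                             lr_pairs_active = 6,
                             hazard_ratio_true = 2.09,
                             n_tumor_only = 4,
                             n_normal = 4,
                             n_low_quality = 2,
                             fold = 6,
                             nonne_fold_mult = 1.5,
                             hybrid_ne_fold = 1.15,
                             hybrid_emt_mult = 1,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    regions_per_patient = as.integer(regions_per_patient),
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_negative_probes = as.integer(n_negative_probes),
    phenotype_fractions = phenotype_fractions,
    signature_size_per_phenotype = as.integer(signature_size_per_phenotype),
    celltypes = celltypes,
    markers_per_celltype = as.integer(markers_per_celltype),
    mixing_link_strength = mixing_link_strength,
    nb_dispersion = nb_dispersion,
    lr_pairs_active = as.integer(lr_pairs_active),
    hazard_ratio_true = hazard_ratio_true,
    n_tumor_only = as.integer(n_tumor_only),
    n_normal = as.integer(n_normal),
    n_low_quality = as.integer(n_low_quality),
    fold = fold,
    nonne_fold_mult = nonne_fold_mult,
    hybrid_ne_fold = hybrid_ne_fold,
    hybrid_emt_mult = hybrid_emt_mult,
    seed = as.integer(seed)
  )
  if (abs(sum(cfg$phenotype_fractions) - 1) > 1e-9) {
    stop("phenotype_fractions must sum to 1")
  }
  if (length(cfg$phenotype_fractions) != 3) {
    stop("phenotype_fractions must have length 3 (NE, hybrid, nonNE)")
  }
  counts <- c(cfg$n_patients, cfg$regions_per_patient, cfg$n_genes,
              cfg$probes_per_gene, cfg$n_negative_probes,
              cfg$signature_size_per_phenotype, cfg$markers_per_celltype)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$mixing_link_strength < 0 || cfg$mixing_link_strength > 1) {
    stop("mixing_link_strength must lie in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$hazard_ratio_true <= 0) stop("hazard_ratio_true must be positive")
  reserved <- 3L * cfg$signature_size_per_phenotype +
    length(cfg$celltypes) * cfg$markers_per_celltype
  if (cfg$n_genes < reserved + 50L) {
    stop("n_genes too small for the planted programs and markers (need > ",
         reserved + 50L, ")")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# internal: deterministic gene universe, phenotype mean profiles, cell-type
# reference profiles and L/R pair layout shared by generate_segments() and
# generate_reference_assets(). Uses its own seeded stream so both entry
# points see identical structures.
.synth_universe <- function(config) {
  set.seed(config$seed %% 2147480000L + 101L)
  n <- config$n_genes
  s <- config$signature_size_per_phenotype
  genes <- sprintf("G%04d", seq_len(n))
  prog <- list(
    NE = genes[seq_len(s)],
    hybrid = genes[s + seq_len(s)],
    nonNE = genes[2L * s + seq_len(s)]
  )
  mk_start <- 3L * s
  markers <- list()
  for (i in seq_along(config$celltypes)) {
    idx <- mk_start + (i - 1L) * config$markers_per_celltype +
      seq_len(config$markers_per_celltype)
    markers[[config$celltypes[i]]] <- genes[idx]
  }
  background <- genes[(mk_start + length(config$celltypes) *
                         config$markers_per_celltype + 1L):n]

  baseline <- stats::rlnorm(n, meanlog = log(20), sdlog = 0.6)
  names(baseline) <- genes
  fold <- config$fold

  # phenotype mean profiles. The non-NE program is elevated more strongly
  # (1.5x fold) than the other two so the non-NE centroid dominates the
  # leading principal axis, while the NE and hybrid centroids are near-pure
  # program indicators whose mutual contrast falls on the second axis: PC1
  # then captures non-NE and PC2 contrasts NE against hybrid, the geometry
  # in which positive/negative PC contributors recover the planted programs.
  # The hybrid co-expresses the NE program at a mild intermediate elevation
  # on top of its own fully elevated EMT metaprogram.
  mean_pheno <- cbind(NE = baseline, hybrid = baseline, nonNE = baseline)
  rownames(mean_pheno) <- genes
  mean_pheno[prog$NE, "NE"] <- baseline[prog$NE] * fold
  mean_pheno[prog$nonNE, "nonNE"] <- baseline[prog$nonNE] * fold *
    config$nonne_fold_mult
  mean_pheno[prog$NE, "hybrid"] <- baseline[prog$NE] * config$hybrid_ne_fold
  mean_pheno[prog$hybrid, "hybrid"] <- baseline[prog$hybrid] * fold *
    config$hybrid_emt_mult

  # cell-type reference profiles: marker genes elevated, tumor programs low
  ref <- matrix(baseline, nrow = n, ncol = length(config$celltypes),
                dimnames = list(genes, config$celltypes))
  for (ct in config$celltypes) ref[markers[[ct]], ct] <- baseline[markers[[ct]]] * 8
  tumor_genes <- unlist(prog, use.names = FALSE)
  ref[tumor_genes, ] <- ref[tumor_genes, ] * 0.2

  # neutral and phenotype-linked TME compositions
  t0 <- c(CAF = 0.15, T.cell = 0.20, B.cell = 0.10, NK = 0.10,
          Macrophage = 0.20, Endothelial = 0.10, Dendritic = 0.075,
          Neutrophil = 0.075)
  t0 <- t0[config$celltypes]
  t0[is.na(t0)] <- 0.05
  names(t0) <- config$celltypes
  t0 <- t0 / sum(t0)
  t_pheno <- rbind(
    NE = c(0.28, 0.10, 0.04, 0.04, 0.32, 0.10, 0.06, 0.06),
    hybrid = c(0.55, 0.05, 0.03, 0.03, 0.20, 0.08, 0.03, 0.03),
    nonNE = c(0.05, 0.26, 0.20, 0.18, 0.12, 0.07, 0.06, 0.06)
  )[, seq_along(config$celltypes), drop = FALSE]
  t_pheno <- sweep(t_pheno, 1, rowSums(t_pheno), "/")
  colnames(t_pheno) <- config$celltypes

  # ligand-receptor pairs: active pairs couple immune-cell ligands (high in
  # non-NE TME) to non-NE tumor program receptors; decoys use background genes
  imm <- intersect(c("T.cell", "B.cell", "NK"), config$celltypes)
  if (!length(imm)) imm <- config$celltypes[1]
  n_act <- config$lr_pairs_active
  lig_pool <- unlist(markers[imm], use.names = FALSE)
  act_lig <- lig_pool[seq_len(n_act)]
  # make the first two active pairs two-subunit ligands when the pool allows
  extra <- min(2L, n_act, max(0L, length(lig_pool) - n_act))
  if (extra > 0) {
    act_lig[seq_len(extra)] <- paste(act_lig[seq_len(extra)],
                                     lig_pool[n_act + seq_len(extra)],
                                     sep = ";")
  }
  act_rec <- prog$nonNE[seq_len(n_act)]
  act_send <- rep(imm, length.out = n_act)
  active <- data.frame(
    pair_id = sprintf("LR_ACT%02d", seq_len(n_act)),
    ligand_genes = act_lig,
    receptor_genes = act_rec,
    sender_pops = act_send,
    receiver_pops = "Tumor",
    direction = "in",
    stringsAsFactors = FALSE
  )
  n_dec <- 14L
  dec_genes <- sample(background, 2L * n_dec)
  decoy <- data.frame(
    pair_id = sprintf("LR_DEC%02d", seq_len(n_dec)),
    ligand_genes = dec_genes[seq_len(n_dec)],
    receptor_genes = dec_genes[n_dec + seq_len(n_dec)],
    sender_pops = rep(config$celltypes, length.out = n_dec),
    receiver_pops = "Tumor",
    direction = rep(c("in", "out"), length.out = n_dec),
    stringsAsFactors = FALSE
  )
  lr <- rbind(active, decoy)

  list(genes = genes, programs = prog, markers = markers,
       background = background, baseline = baseline,
       mean_pheno = mean_pheno, ref = ref, t0 = t0, t_pheno = t_pheno,
       lr = lr, active_lr = active$pair_id)
}

# internal: Dirichlet sampler via gamma variates
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic GeoMx segment cohort with planted ground truth
#'
#' Draws probe-level negative-binomial counts around phenotype-specific gene
#' means for tumor segments, reference-profile mixtures at planted cell-type
#' proportions for TME segments, and low background means for negative
#' probes. Each paired tumor/TME couple shares a region id.
#'
#' @param config a [synthetic_config].
#' @return A list with elements `probe_counts` ([probe_counts]), `annotation`
#'   (segment annotation data.frame) and `truth` (planted ground truth:
#'   `segment_phenotypes`, `signature_genes`, `true_proportions`,
#'   `true_purity`, `active_lr_pairs`, `hazard_ratio_true`).
#' @export
generate_segments <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  uni <- .synth_universe(config)
  set.seed(config$seed %% 2147480000L + 202L)

  # region bookkeeping
  rpp <- config$regions_per_patient
  regions_per <- if (length(rpp) == 2) {
    sample(rpp[1]:rpp[2], config$n_patients, replace = TRUE)
  } else rep(rpp[1], config$n_patients)
  n_regions <- sum(regions_per)
  if (config$n_tumor_only + config$n_normal >= n_regions) {
    stop("not enough regions for the requested tumor-only and normal ROIs")
  }
  patient <- rep(sprintf("P%02d", seq_len(config$n_patients)), regions_per)
  region <- sprintf("R%03d", seq_len(n_regions))
  role <- rep("paired", n_regions)
  special <- sample(n_regions, config$n_tumor_only + config$n_normal)
  role[special[seq_len(config$n_tumor_only)]] <- "tumor_only"
  role[special[config$n_tumor_only + seq_len(config$n_normal)]] <- "normal"

  # fixed phenotype composition: apportion tumor regions to the three
  # phenotypes by largest remainder, then shuffle the assignment, so every
  # cohort realizes the configured fractions exactly (as a real cohort has
  # one fixed composition) rather than a multinomial draw around them
  phen_names <- c("NE", "hybrid", "nonNE")
  tumor_regions <- which(role != "normal")
  n_tum <- length(tumor_regions)
  quota <- config$phenotype_fractions * n_tum
  n_each <- floor(quota)
  rem <- n_tum - sum(n_each)
  if (rem > 0) {
    top_up <- order(quota - n_each, decreasing = TRUE)[seq_len(rem)]
    n_each[top_up] <- n_each[top_up] + 1
  }
  phenotype <- rep("normal", n_regions)
  phenotype[tumor_regions] <- sample(rep(phen_names, times = n_each))

  # segment table
  seg <- list()
  for (i in seq_len(n_regions)) {
    if (role[i] != "normal") {
      seg[[length(seg) + 1L]] <- data.frame(
        segment_id = sprintf("%s_T", region[i]),
        compartment = if (role[i] == "tumor_only") "tumor_only" else "tumor",
        patient_id = patient[i], region_id = region[i],
        phenotype = phenotype[i], stringsAsFactors = FALSE)
    }
    if (role[i] == "paired") {
      seg[[length(seg) + 1L]] <- data.frame(
        segment_id = sprintf("%s_M", region[i]),
        compartment = "TME", patient_id = patient[i], region_id = region[i],
        phenotype = phenotype[i], stringsAsFactors = FALSE)
    }
    if (role[i] == "normal") {
      seg[[length(seg) + 1L]] <- data.frame(
        segment_id = sprintf("%s_N", region[i]),
        compartment = "normal", patient_id = patient[i], region_id = region[i],
        phenotype = "normal", stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, seg)
  n_seg <- nrow(seg)
  is_tumorish <- seg$compartment %in% c("tumor", "tumor_only")
  is_tme <- seg$compartment == "TME"

  # planted compositions and purities
  lambda <- config$mixing_link_strength
  props <- matrix(NA_real_, nrow = sum(is_tme), ncol = length(config$celltypes),
                  dimnames = list(seg$segment_id[is_tme], config$celltypes))
  tme_idx <- which(is_tme)
  for (j in seq_along(tme_idx)) {
    p <- seg$phenotype[tme_idx[j]]
    m <- (1 - lambda) * uni$t0 + lambda * uni$t_pheno[p, ]
    props[j, ] <- .rdirichlet(m * 40)
  }
  purity <- stats::runif(sum(is_tumorish), 0.92, 0.99)
  names(purity) <- seg$segment_id[is_tumorish]

  # expected gene means per segment
  mu <- matrix(0, nrow = config$n_genes, ncol = n_seg,
               dimnames = list(uni$genes, seg$segment_id))
  generic_tme <- as.numeric(uni$ref %*% uni$t0)
  for (i in seq_len(n_seg)) {
    mu[, i] <- switch(
      seg$compartment[i],
      tumor = ,
      tumor_only = purity[seg$segment_id[i]] *
        uni$mean_pheno[, seg$phenotype[i]] +
        (1 - purity[seg$segment_id[i]]) * generic_tme,
      TME = as.numeric(uni$ref %*% props[seg$segment_id[i], ]),
      normal = generic_tme
    )
  }
  size_factor <- stats::rlnorm(n_seg, 0, 0.15)
  mu <- sweep(mu, 2, size_factor, "*")

  # probe-level counts
  ppg <- config$probes_per_gene
  n_probes <- config$n_genes * ppg
  probe_gene <- rep(uni$genes, each = ppg)
  probe_id <- sprintf("%s_p%d", probe_gene, rep(seq_len(ppg), config$n_genes))
  mu_probe <- mu[probe_gene, , drop = FALSE]
  counts <- matrix(
    stats::rnbinom(n_probes * n_seg, size = config$nb_dispersion,
                   mu = as.numeric(mu_probe)),
    nrow = n_probes, ncol = n_seg,
    dimnames = list(probe_id, seg$segment_id)
  )
  neg <- matrix(
    stats::rnbinom(config$n_negative_probes * n_seg,
                   size = config$nb_dispersion, mu = 3),
    nrow = config$n_negative_probes, ncol = n_seg,
    dimnames = list(sprintf("NEG_p%02d", seq_len(config$n_negative_probes)),
                    seg$segment_id)
  )
  pcm <- probe_counts(
    rbind(counts, neg),
    target_gene = c(probe_gene, rep("NEG", config$n_negative_probes)),
    is_negative = c(rep(FALSE, n_probes),
                    rep(TRUE, config$n_negative_probes))
  )

  # annotation, with planted low-saturation TME segments
  saturation <- stats::runif(n_seg, 0.85, 0.99)
  low <- tme_idx[seq_len(min(config$n_low_quality, length(tme_idx)))]
  saturation[low] <- stats::runif(length(low), 0.40, 0.70)
  sites <- sample(c(rep("liver", 7), "lymph_node", "lymph_node", "adrenal"),
                  config$n_patients, replace = config$n_patients > 10)
  ann <- data.frame(
    segment_id = seg$segment_id,
    compartment = seg$compartment,
    patient_id = seg$patient_id,
    region_id = seg$region_id,
    area = round(stats::runif(n_seg, 150000, 220000)),
    nuclei = stats::rpois(n_seg, ifelse(is_tumorish, 250,
                                        ifelse(is_tme, 120, 150))),
    saturation = saturation,
    site = sites[match(seg$patient_id,
                       sprintf("P%02d", seq_len(config$n_patients)))],
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)

  truth <- list(
    segment_phenotypes = stats::setNames(seg$phenotype, seg$segment_id),
    signature_genes = uni$programs,
    true_proportions = props,
    true_purity = purity,
    active_lr_pairs = uni$active_lr,
    hazard_ratio_true = config$hazard_ratio_true
  )
  list(probe_counts = pcm, annotation = ann, truth = truth)
}

#' Generate reference assets matching a synthetic cohort
#'
#' Produces the auxiliary inputs the downstream modules need, consistent with
#' the planted structure of [generate_segments()] under the same config:
#' a gene-set collection (the three planted phenotype programs, a stromal
#' set, an immune set, and uniform decoy sets), cell-type reference
#' expression profiles, NE / non-NE reference profiles for the NE score,
#' a ligand-receptor annotation table, and purity training triples generated
#' from a known linear relation plus noise.
#'
#' @param config a [synthetic_config].
#' @param n_decoy_sets number of decoy gene sets.
#' @param decoy_size genes per decoy set.
#' @param n_purity_train purity training triples.
#' @param purity_noise_sd Gaussian noise sd on the purity relation (0 gives
#'   exact recovery by OLS).
#' @return list with `gene_sets`, `reference_profiles` (genes x cell types),
#'   `ne_profile`, `nonne_profile`, `lr_annotation`, `purity_training`
#'   (data.frame with attribute `true_coef`).
#' @export
generate_reference_assets <- function(config, n_decoy_sets = 10,
                                      decoy_size = 40,
                                      n_purity_train = 120,
                                      purity_noise_sd = 0.02) {
  stopifnot(inherits(config, "synthetic_config"))
  uni <- .synth_universe(config)
  set.seed(config$seed %% 2147480000L + 303L)

  sets <- list(
    NE_program = uni$programs$NE,
    HYBRID_EMT_program = uni$programs$hybrid,
    NONNE_program = uni$programs$nonNE,
    STROMAL_score = unique(unlist(
      uni$markers[intersect(c("CAF", "Endothelial"), config$celltypes)],
      use.names = FALSE)),
    IMMUNE_score = unique(unlist(
      uni$markers[setdiff(config$celltypes, c("CAF", "Endothelial"))],
      use.names = FALSE))
  )
  for (d in seq_len(n_decoy_sets)) {
    sets[[sprintf("DECOY_%02d", d)]] <- sort(sample(uni$genes, decoy_size))
  }
  gs <- gene_sets(sets)

  sig <- c(uni$programs$NE, uni$programs$nonNE)
  ne_profile <- log2(uni$mean_pheno[sig, "NE"] + 1)
  nonne_profile <- log2(uni$mean_pheno[sig, "nonNE"] + 1)

  true_coef <- c(intercept = 0.98, stromal = -0.40, immune = -0.45)
  stromal <- stats::runif(n_purity_train, 0, 1)
  immune <- stats::runif(n_purity_train, 0, 1)
  purity <- clamp(true_coef["intercept"] + true_coef["stromal"] * stromal +
                    true_coef["immune"] * immune +
                    stats::rnorm(n_purity_train, 0, purity_noise_sd), 0, 1)
  training <- data.frame(stromal = stromal, immune = immune, purity = purity)
  attr(training, "true_coef") <- true_coef

  list(gene_sets = gs, reference_profiles = uni$ref,
       ne_profile = ne_profile, nonne_profile = nonne_profile,
       lr_annotation = uni$lr, purity_training = training)
}

#' Generate a synthetic survival cohort with a planted hazard ratio
#'
#' Event times are exponential; samples with score above the
#' `score_cutoff_quantile` empirical quantile (type-7) have their hazard
#' multiplied by `hr`. Censoring is independent exponential, calibrated so
#' that roughly `censoring_fraction` of samples are censored.
#'
#' @param n cohort size (>= 20).
#' @param hr true hazard ratio of the high-score arm (> 0).
#' @param score_cutoff_quantile quantile defining the high-score arm.
#' @param seed integer seed.
#' @param baseline_median_months median survival of the low-score arm.
#' @param censoring_fraction target censored fraction in `[0, 1)`; a value of
#'   1 would leave no events, making any survival comparison undefined, and
#'   raises an error.
#' @return data.frame with columns `sample`, `time_months`, `event`, `score`,
#'   `true_group`, plus attribute `true_hr`.
#' @export
generate_survival_cohort <- function(n, hr, score_cutoff_quantile = 0.75,
                                     seed = 1L,
                                     baseline_median_months = 12,
                                     censoring_fraction = 0.2) {
  if (n < 20) stop("cohort size must be at least 20")
  if (hr <= 0) stop("hazard ratio must be positive")
  if (censoring_fraction >= 1) {
    stop("censoring fraction 1 leaves no events; log-rank would be undefined")
  }
  if (censoring_fraction < 0) stop("censoring fraction must be in [0, 1)")
  set.seed(as.integer(seed) %% 2147480000L)
  score <- stats::rnorm(n)
  cutoff <- stats::quantile(score, score_cutoff_quantile, type = 7,
                            names = FALSE)
  high <- score > cutoff
  lambda0 <- log(2) / baseline_median_months
  t_event <- stats::rexp(n, rate = lambda0 * ifelse(high, hr, 1))
  if (censoring_fraction > 0) {
    f <- censoring_fraction
    t_cens <- stats::rexp(n, rate = lambda0 * f / (1 - f))
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (sum(event) == 0) stop("no events in generated cohort")
  out <- data.frame(
    sample = sprintf("S%04d", seq_len(n)),
    time_months = time,
    event = event,
    score = score,
    true_group = ifelse(high, "high", "low"),
    stringsAsFactors = FALSE
  )
  attr(out, "true_hr") <- hr
  out
}
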