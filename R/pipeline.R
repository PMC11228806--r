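#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one document-style
#' list (serializable as YAML). Defaults reproduce the standard study
#' conditions: synthetic cohort of 10 patients / 40 ROIs, QC at saturation
#' 0.8, HVG selection, elbow scan to k = 10, ssGSEA alpha 0.25, FDR 5%,
#' survival stratification at the 75th percentile.
#'
#' @param out_dir output directory for stage files.
#' @param seed master seed for every stochastic stage.
#' @param synthetic named list of overrides for [synthetic_config()].
#' @param qc named list of QC threshold overrides (see [qc_segments()]).
#' @param hvg_n number of highly variable genes for clustering.
#' @param k_max elbow scan upper bound.
#' @param kmeans_iterations,kmeans_attempts k-means settings.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param fdr_level FDR level used for reporting significance.
#' @param survival list: `n`, `quantile`, `hr` (NULL = the synthetic truth).
#' @param stages character vector of stages to run (dependency order is
#'   enforced; later stages require earlier ones or `resume = TRUE`).
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("tmeco_run_"),
                            seed = 1L,
                            synthetic = list(),
                            qc = list(),
                            hvg_n = 500,
                            k_max = 10,
                            kmeans_iterations = 50,
                            kmeans_attempts = 200,
                            ssgsea_alpha = 0.25,
                            fdr_level = 0.05,
                            survival = list(n = 81, quantile = 0.75,
                                            hr = NULL),
                            stages = c("simulate", "preprocess", "cluster",
                                       "score", "deconvolve", "communicate",
                                       "survival")) {
  if (hvg_n <= 0 || k_max < 3 || ssgsea_alpha < 0 ||
      fdr_level <= 0 || fdr_level >= 1) {
    stop("threshold outside documented range")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
         qc = qc, hvg_n = hvg_n, k_max = k_max,
         kmeans_iterations = kmeans_iterations,
         kmeans_attempts = kmeans_attempts,
         ssgsea_alpha = ssgsea_alpha, fdr_level = fdr_level,
         survival = survival, stages = stages),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# internal: md5 digests of a set of files
.digest_files <- function(files) {
  md5 <- tools::md5sum(files)
  stats::setNames(as.character(md5), basename(files))
}

#' Run the full segment-analysis pipeline
#'
#' Executes the stages simulate -> preprocess -> cluster -> score ->
#' deconvolve -> communicate -> survival in dependency order, writing each
#' stage's outputs (TSV/CSV/GMT/JSON) under `config$out_dir` and a
#' `run_report.json` with per-stage file digests, parameter echo and timing.
#' Identical config + seed yields identical output digests. With
#' `resume = TRUE`, stages whose output files already exist are re-read
#' instead of recomputed. A stage failure halts the run with the failing
#' stage named; downstream outputs are absent.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @param resume reuse existing stage outputs where present.
#' @return (invisibly) list with `report` and the in-memory stage `objects`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  obj <- new.env(parent = emptyenv())
  fp <- function(...) file.path(config$out_dir, ...)

  run_stage <- function(name, files, compute, reload) {
    t0 <- proc.time()[["elapsed"]]
    paths <- fp(files)
    if (resume && all(file.exists(paths))) {
      reload(paths)
      cached <- TRUE
    } else {
      tryCatch(compute(paths), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      cached <- FALSE
    }
    report[[name]] <<- list(
      files = .digest_files(paths),
      cached = cached,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
    )
  }

  stages <- config$stages

  if ("simulate" %in% stages) run_stage(
    "simulate",
    c("probe_counts.tsv", "annotation.csv", "ground_truth.json",
      "gene_sets.gmt", "reference_profiles.tsv", "lr_annotation.tsv",
      "purity_training.csv", "ne_profiles.tsv"),
    compute = function(paths) {
      scfg <- do.call(synthetic_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$synthetic))
      sim <- generate_segments(scfg)
      assets <- generate_reference_assets(scfg)
      obj$sim <- sim; obj$assets <- assets; obj$scfg <- scfg
      write_probe_counts(sim$probe_counts, paths[1])
      utils::write.csv(sim$annotation, paths[2], row.names = FALSE)
      truth <- sim$truth
      truth$true_proportions <- as.data.frame(truth$true_proportions)
      jsonlite::write_json(truth, paths[3], digits = NA, auto_unbox = TRUE,
                           dataframe = "columns")
      write_gmt(assets$gene_sets, paths[4])
      utils::write.table(
        data.frame(gene = rownames(assets$reference_profiles),
                   assets$reference_profiles, check.names = FALSE),
        paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
      write_lr_annotation(assets$lr_annotation, paths[6])
      utils::write.csv(assets$purity_training, paths[7], row.names = FALSE)
      utils::write.table(
        data.frame(gene = names(assets$ne_profile),
                   ne = assets$ne_profile, nonne = assets$nonne_profile),
        paths[8], sep = "\t", quote = FALSE, row.names = FALSE)
    },
    reload = function(paths) {
      scfg <- do.call(synthetic_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$synthetic))
      obj$scfg <- scfg
      truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
      truth$segment_phenotypes <- unlist(truth$segment_phenotypes)
      obj$sim <- list(probe_counts = read_probe_counts(paths[1]),
                      annotation = read_annotation(paths[2]),
                      truth = truth)
      refp <- utils::read.delim(paths[5], row.names = 1, check.names = FALSE)
      nep <- utils::read.delim(paths[8])
      obj$assets <- list(
        gene_sets = read_gmt(paths[4]),
        reference_profiles = as.matrix(refp),
        lr_annotation = read_lr_annotation(paths[6]),
        purity_training = utils::read.csv(paths[7]),
        ne_profile = stats::setNames(nep$ne, nep$gene),
        nonne_profile = stats::setNames(nep$nonne, nep$gene))
    })

  if ("preprocess" %in% stages) run_stage(
    "preprocess",
    c("expr_q3.tsv", "expr_log2q3.tsv", "qc_report.json"),
    compute = function(paths) {
      raw <- collapse_probes(obj$sim$probe_counts)
      loq <- compute_loq(obj$sim$probe_counts)
      qc <- qc_segments(raw, obj$sim$annotation, loq,
                        thresholds = config$qc)
      q3 <- q3_normalize(qc$expr, loq = loq)
      obj$ann <- qc$annotation
      obj$q3 <- q3
      obj$log2q3 <- log2_transform(q3)
      obj$qc_report <- qc$report
      write_expr_matrix(q3, paths[1])
      write_expr_matrix(obj$log2q3, paths[2])
      jsonlite::write_json(qc$report, paths[3], digits = NA,
                           dataframe = "columns")
    },
    reload = function(paths) {
      obj$q3 <- read_expr_matrix(paths[1])
      obj$log2q3 <- read_expr_matrix(paths[2])
      obj$qc_report <- as.data.frame(
        jsonlite::read_json(paths[3], simplifyVector = TRUE))
      obj$ann <- obj$sim$annotation[
        obj$sim$annotation$segment_id %in% colnames(obj$q3), ]
    })

  if ("cluster" %in% stages) run_stage(
    "cluster",
    c("cluster_labels.csv", "cluster_signatures.gmt", "cluster_markers.csv",
      "wss_per_k.csv"),
    compute = function(paths) {
      tum <- obj$ann$segment_id[obj$ann$compartment %in%
                                  c("tumor", "tumor_only")]
      em_t <- expr_matrix(obj$log2q3[, tum, drop = FALSE], "log2q3")
      hvg <- select_hvg(em_t, min(config$hvg_n, nrow(em_t)))
      elbow <- choose_k_elbow(em_t, k_max = config$k_max,
                              seed = config$seed, genes = hvg)
      ne <- ne_score(em_t, obj$assets$ne_profile, obj$assets$nonne_profile)
      cl <- kmeans_cluster(em_t, k = elbow$k, seed = config$seed,
                           iterations = config$kmeans_iterations,
                           attempts = config$kmeans_attempts,
                           genes = hvg, orient_by = ne)
      pca <- run_pca(em_t, genes = hvg)
      sigs <- extract_pc_signatures(pca, universe = hvg)
      tme_labels <- assign_tme_clusters(cl, obj$ann)
      mk <- cluster_markers(em_t, cl)
      obj$cl <- cl; obj$tme_labels <- tme_labels; obj$signatures <- sigs
      obj$elbow <- elbow; obj$ne_tumor <- ne
      labels_df <- rbind(
        data.frame(segment_id = names(cl$labels), cluster = cl$labels,
                   compartment = "tumor", row.names = NULL),
        data.frame(segment_id = names(tme_labels), cluster = tme_labels,
                   compartment = "TME", row.names = NULL)
      )
      utils::write.csv(labels_df, paths[1], row.names = FALSE)
      write_gmt(gene_sets(list(sig_cluster1 = sigs$sig_cluster1$gene,
                               sig_cluster2 = sigs$sig_cluster2$gene,
                               sig_cluster3 = sigs$sig_cluster3$gene)),
                paths[2])
      utils::write.csv(mk, paths[3], row.names = FALSE)
      utils::write.csv(data.frame(k = as.integer(names(elbow$wss_per_k)),
                                  wss = elbow$wss_per_k,
                                  chosen = as.integer(names(elbow$wss_per_k))
                                  == elbow$k),
                       paths[4], row.names = FALSE)
    },
    reload = function(paths) {
      lab <- utils::read.csv(paths[1])
      tum <- lab[lab$compartment == "tumor", ]
      obj$cl <- structure(list(
        labels = stats::setNames(as.integer(tum$cluster), tum$segment_id),
        k = max(tum$cluster)), class = "cluster_assignment")
      tme <- lab[lab$compartment == "TME", ]
      obj$tme_labels <- stats::setNames(as.integer(tme$cluster),
                                        tme$segment_id)
    })

  if ("score" %in% stages) run_stage(
    "score",
    c("ssgsea_scores.tsv", "ne_scores.csv", "purity.csv"),
    compute = function(paths) {
      sc <- ssgsea(obj$log2q3, obj$assets$gene_sets,
                   alpha = config$ssgsea_alpha)
      ne_all <- ne_score(obj$log2q3, obj$assets$ne_profile,
                         obj$assets$nonne_profile)
      pm <- fit_purity_model(obj$assets$purity_training)
      # stromal/immune ssGSEA scores mapped to the training scale
      rng <- function(x) (x - min(x)) / (max(x) - min(x))
      tum <- intersect(colnames(obj$log2q3),
                       obj$ann$segment_id[obj$ann$compartment %in%
                                            c("tumor", "tumor_only")])
      pur <- predict_purity(pm, list(
        stromal = rng(sc["STROMAL_score", ])[tum],
        immune = rng(sc["IMMUNE_score", ])[tum]))
      pur <- data.frame(segment_id = tum, pur)
      obj$scores <- sc; obj$ne_all <- ne_all; obj$purity <- pur
      utils::write.table(
        data.frame(set = rownames(sc), sc, check.names = FALSE),
        paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.csv(data.frame(segment_id = names(ne_all), ne = ne_all,
                                  row.names = NULL),
                       paths[2], row.names = FALSE)
      utils::write.csv(pur, paths[3], row.names = FALSE)
    },
    reload = function(paths) {
      sc <- utils::read.delim(paths[1], row.names = 1, check.names = FALSE)
      obj$scores <- as.matrix(sc)
      nedf <- utils::read.csv(paths[2])
      obj$ne_all <- stats::setNames(nedf$ne, nedf$segment_id)
      obj$purity <- utils::read.csv(paths[3])
    })

  if ("deconvolve" %in% stages) run_stage(
    "deconvolve",
    c("proportions.tsv", "diversity.csv", "composition_ne_correlation.csv"),
    compute = function(paths) {
      tme <- intersect(colnames(obj$q3),
                       obj$ann$segment_id[obj$ann$compartment == "TME"])
      em_m <- expr_matrix(obj$q3[, tme, drop = FALSE], "q3")
      dec <- deconvolve(em_m, obj$assets$reference_profiles)
      div <- composition_diversity(dec$proportions)
      # pair each TME segment with its tumor segment's NE score
      tme_ann <- obj$ann[match(tme, obj$ann$segment_id), ]
      tum_ann <- obj$ann[obj$ann$compartment %in% c("tumor", "tumor_only"), ]
      tum_seg <- tum_ann$segment_id[match(tme_ann$region_id,
                                          tum_ann$region_id)]
      ne_paired <- stats::setNames(obj$ne_all[tum_seg], tme)
      corr <- correlate_composition_with_ne(dec$proportions, ne_paired)
      obj$deconv <- dec; obj$diversity <- div; obj$comp_ne <- corr
      utils::write.table(
        data.frame(segment_id = rownames(dec$proportions), dec$proportions,
                   residual = dec$residual, check.names = FALSE),
        paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.csv(data.frame(segment_id = names(div), shannon = div,
                                  row.names = NULL),
                       paths[2], row.names = FALSE)
      utils::write.csv(corr, paths[3], row.names = FALSE)
    },
    reload = function(paths) {
      pr <- utils::read.delim(paths[1], check.names = FALSE)
      m <- as.matrix(pr[, setdiff(names(pr), c("segment_id", "residual"))])
      rownames(m) <- pr$segment_id
      obj$deconv <- list(proportions = m, residual = stats::setNames(
        pr$residual, pr$segment_id))
    })

  if ("communicate" %in% stages) run_stage(
    "communicate",
    c("lr_pair_scores.csv", "population_interactions.csv",
      "differential_interactions.csv"),
    compute = function(paths) {
      em_all <- expr_matrix(
        obj$log2q3[, intersect(colnames(obj$log2q3), obj$ann$segment_id),
                   drop = FALSE], "log2q3")
      ps <- score_lr_pairs(em_all, obj$ann, obj$assets$lr_annotation)
      summ <- summarize_population_interactions(ps)
      # ecosystem groups from tumor clusters: cluster 1 (lowest NE) = nonNE
      tum_ann <- obj$ann[obj$ann$compartment == "tumor", ]
      grp <- ifelse(obj$cl$labels[tum_ann$segment_id] == 1,
                    "nonNE", "NE_hybrid")
      names(grp) <- tum_ann$region_id
      grp <- grp[!is.na(grp)]
      di <- differential_interactions(ps[ps$region %in% names(grp), ], grp)
      obj$pair_scores <- ps; obj$pop_summary <- summ; obj$diff_lr <- di
      utils::write.csv(ps, paths[1], row.names = FALSE)
      utils::write.csv(summ, paths[2], row.names = FALSE)
      utils::write.csv(di, paths[3], row.names = FALSE)
    },
    reload = function(paths) {
      obj$pair_scores <- utils::read.csv(paths[1])
      obj$diff_lr <- utils::read.csv(paths[3])
    })

  if ("survival" %in% stages) run_stage(
    "survival",
    "survival.json",
    compute = function(paths) {
      sv <- config$survival
      hr <- if (is.null(sv$hr)) {
        if (!is.null(obj$scfg)) obj$scfg$hazard_ratio_true else 2.09
      } else sv$hr
      cohort <- generate_survival_cohort(
        n = sv$n, hr = hr, score_cutoff_quantile = sv$quantile,
        seed = config$seed)
      strat <- dichotomize_at_quantile(cohort, q = sv$quantile)
      km <- km_logrank(strat)
      cx <- cox_hr(strat)
      obj$survival <- list(cohort = strat, km = km, cox = cx)
      jsonlite::write_json(
        list(n = nrow(strat), n_events = cx$n_events,
             true_hr = hr, hr = cx$hr, ci = cx$ci, wald_p = cx$p,
             logrank_chisq = km$chisq, logrank_p = km$p),
        paths[1], digits = NA, auto_unbox = TRUE)
    },
    reload = function(paths) {
      obj$survival <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
    })

  report_path <- fp("run_report.json")
  jsonlite::write_json(
    list(seed = config$seed,
         parameters = config[setdiff(names(config), "out_dir")],
         stages = report),
    report_path, digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(list(report = report, objects = as.list(obj),
                 report_path = report_path))
}
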