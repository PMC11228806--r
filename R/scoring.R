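#' Single-sample gene set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression in decreasing order (ties
#' broken alphabetically by gene name for cross-platform determinism). With
#' rank values r = N, N-1, ..., 1 from the top and weights |r|^alpha, the
#' enrichment score of a set S is the sum over all positions i of
#' P_in(i) - P_out(i), where P_in is the weighted cumulative in-set frequency
#' and P_out the unweighted cumulative out-of-set frequency. Being rank
#' based, the score is invariant to any strictly monotone transformation of a
#' sample's expression values. With `normalize = TRUE` all scores are divided
#' by the global (max - min) across the matrix.
#'
#' @param em an [expr_matrix] (typically `log2q3`).
#' @param sets a [gene_sets] collection.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide by the global score range.
#' @return matrix sets x segments of class `score_matrix` with attribute
#'   `method = "ssgsea"`. Sets with no overlap give `NA` scores (reported
#'   with a warning); singleton overlaps warn but are scored.
#' @export
ssgsea <- function(em, sets, alpha = 0.25, normalize = FALSE) {
  genes <- rownames(em)
  n <- length(genes)
  overlap <- lapply(sets, intersect, y = genes)
  sizes <- lengths(overlap)
  if (any(sizes == 0)) {
    warning("set(s) with zero overlap reported as NA: ",
            paste(names(sets)[sizes == 0], collapse = ", "))
  }
  if (any(sizes == 1)) {
    warning("singleton-overlap set(s): ",
            paste(names(sets)[sizes == 1], collapse = ", "))
  }
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(em),
                   dimnames = list(names(sets), colnames(em)))
  for (s in seq_len(ncol(em))) {
    ord <- order(-em[, s], genes)          # descending, tie-break by name
    ordered_genes <- genes[ord]
    w <- (n:1)^alpha                        # rank value N at the top
    for (k in seq_along(sets)) {
      if (sizes[k] == 0) next
      ins <- ordered_genes %in% overlap[[k]]
      win <- w * ins
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!ins) / (n - sizes[k])
      scores[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    scores <- scores / (rng[2] - rng[1])
  }
  structure(scores, method = "ssgsea",
            class = c("score_matrix", "matrix", "array"))
}

#' Neuroendocrine (NE) differentiation score
#'
#' For each segment, the score is (rho_NE - rho_nonNE) / 2 where rho_* is the
#' Pearson correlation between the segment's expression over the signature
#' genes and the NE / non-NE reference profiles. The score lies in [-1, 1];
#' positive means NE-like. It is antisymmetric under swapping the two
#' reference profiles.
#'
#' @param em an [expr_matrix] (log2 scale recommended).
#' @param ne_profile,nonne_profile named numeric reference mean profiles over
#'   the signature genes.
#' @return Named numeric score per segment; segments with zero variance over
#'   the signature genes give `NA` with a warning.
#' @export
ne_score <- function(em, ne_profile, nonne_profile) {
  genes <- intersect(intersect(names(ne_profile), names(nonne_profile)),
                     rownames(em))
  if (length(genes) < 3) {
    stop("fewer than 3 signature genes present in the expression matrix")
  }
  x <- unclass(em)[genes, , drop = FALSE]
  np <- ne_profile[genes]
  nn <- nonne_profile[genes]
  out <- vapply(seq_len(ncol(x)), function(i) {
    if (stats::sd(x[, i]) == 0) return(NA_real_)
    (stats::cor(x[, i], np) - stats::cor(x[, i], nn)) / 2
  }, numeric(1))
  names(out) <- colnames(x)
  if (anyNA(out)) {
    warning("zero-variance segment(s) over signature genes: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Fit and apply a linear tumor-purity model
#'
#' Ordinary least squares purity ~ intercept + stromal + immune, trained on
#' triples where purity is known; predictions for new segments are clamped to
#' [0, 1] with a flag.
#'
#' @param training data.frame with columns `stromal`, `immune`, `purity`
#'   (purity in [0, 1], >= 3 rows).
#' @return `fit_purity_model`: list of class `purity_model` with `intercept`,
#'   `beta_stromal`, `beta_immune`, `training_r2`, `fit`.
#' @export
fit_purity_model <- function(training) {
  stopifnot(all(c("stromal", "immune", "purity") %in% names(training)))
  if (nrow(training) < 3) stop("at least 3 training triples required")
  if (any(training$purity < 0 | training$purity > 1)) {
    stop("training purity must lie in [0, 1]")
  }
  X <- cbind(1, training$stromal, training$immune)
  if (kappa(crossprod(X)) > 1e8) {
    stop("collinear stromal/immune predictors (condition number > 1e8)")
  }
  fit <- stats::lm(purity ~ stromal + immune, data = training)
  # noiseless training (e.g. synthetic exact relations) is legitimate;
  # silence summary.lm's perfect-fit warning
  smy <- suppressWarnings(summary(fit))
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         beta_stromal = unname(stats::coef(fit)[2]),
         beta_immune = unname(stats::coef(fit)[3]),
         training_r2 = smy$r.squared,
         fit = fit),
    class = "purity_model"
  )
}

#' @rdname fit_purity_model
#' @param model a `purity_model`.
#' @param scores data.frame (or named list) with `stromal` and `immune`
#'   score vectors for the segments to predict.
#' @return `predict_purity`: data.frame with `purity` (clamped to [0, 1])
#'   and `clamped` flag.
#' @export
predict_purity <- function(model, scores) {
  raw <- model$intercept + model$beta_stromal * scores$stromal +
    model$beta_immune * scores$immune
  data.frame(
    purity = clamp(raw, 0, 1),
    clamped = raw < 0 | raw > 1
  )
}

#' Shannon diversity index
#'
#' H' = -sum(p_i * ln(p_i)) with the convention 0 * ln 0 = 0. Proportions
#' must be non-negative; vectors whose sum deviates from 1 by more than 1e-6
#' are renormalized with a warning.
#'
#' @param p non-negative proportion vector.
#' @return H' (natural-log units); maximal, ln(N), for the uniform
#'   distribution over N categories.
#' @export
shannon_index <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (s == 0) stop("proportions sum to zero")
  if (abs(s - 1) > 1e-6) {
    warning("proportions renormalized (sum was ", format(s), ")")
  }
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' IHC H-score
#'
#' 1 x (% weakly stained) + 2 x (% moderately stained) + 3 x (% strongly
#' stained) nuclei; the result lies in [0, 300].
#'
#' @param pct_weak,pct_moderate,pct_strong staining percentages (>= 0,
#'   summing to at most 100).
#' @return H-score in [0, 300].
#' @export
h_score <- function(pct_weak, pct_moderate, pct_strong) {
  if (any(c(pct_weak, pct_moderate, pct_strong) < 0)) {
    stop("percentages must be non-negative")
  }
  if (pct_weak + pct_moderate + pct_strong > 100 + 1e-9) {
    stop("staining percentages sum to more than 100")
  }
  1 * pct_weak + 2 * pct_moderate + 3 * pct_strong
}

# internal: weighted Kolmogorov-Smirnov enrichment score of a preranked list.
# metric must be sorted decreasing; returns the maximum signed deviation.
.gsea_es <- function(metric_sorted, in_set) {
  w <- abs(metric_sorted) * in_set
  sw <- sum(w)
  # all-zero in-set weights (flat metric): fall back to unweighted steps
  p_hit <- if (sw > 0) cumsum(w) / sw else cumsum(in_set) / sum(in_set)
  p_miss <- cumsum(!in_set) / max(sum(!in_set), 1)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment (weight = |metric|, exponent 1) of
#' each set against a signed ranking metric, with a gene-label permutation
#' null: p is the fraction of same-sign null enrichment scores at least as
#' extreme, and NES = ES / mean |null ES| of matching sign. BH correction is
#' applied across sets.
#'
#' @param ranked named numeric vector: gene -> signed ranking metric (no NA,
#'   no duplicate genes, >= 10 genes).
#' @param sets a [gene_sets] collection.
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame: set, size, es, nes, p, fdr_bh. Sets with no overlap
#'   are skipped with a warning.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, seed = 1L) {
  if (anyNA(ranked)) stop("ranking metric contains NA")
  if (anyDuplicated(names(ranked))) stop("duplicate genes in ranking")
  if (length(ranked) < 10) stop("ranked list must have at least 10 genes")
  if (n_perm < 100) stop("n_perm must be at least 100")
  ord <- order(-ranked, names(ranked))
  metric <- unname(ranked[ord])
  genes <- names(ranked)[ord]
  n <- length(genes)
  set.seed(as.integer(seed) %% 2147480000L)
  res <- lapply(names(sets), function(nm) {
    ov <- intersect(sets[[nm]], genes)
    if (!length(ov)) return(NULL)
    ins <- genes %in% ov
    es <- .gsea_es(metric, ins)
    null_es <- vapply(seq_len(n_perm), function(b) {
      .gsea_es(metric, genes %in% sample(genes, length(ov)))
    }, numeric(1))
    same <- null_es * sign(es) >= 0
    n_same <- sum(same)
    p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + n_same)
    denom <- mean(abs(null_es[same]))
    nes <- if (n_same > 0 && denom > 0) es / denom else NA_real_
    data.frame(set = nm, size = length(ov), es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(res, is.null, logical(1))]
  if (length(skipped)) {
    warning("set(s) with no overlap skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no set overlaps the ranked list")
  out$fdr_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Signed -log10(p) ranking metric from a marker table
#'
#' metric = -log10(p) with sign set positive for fold change > 1 and negative
#' for fold change < 1; p-values of exactly zero are floored at the smallest
#' representable double (flagged with a warning). Ties are broken
#' deterministically by gene name, and the result is invariant to input row
#' order.
#'
#' @param markers data.frame with columns `gene`, `p`, `log2fc` (one row per
#'   gene, e.g. one cluster's slice of [cluster_markers()]).
#' @return Named numeric vector sorted by decreasing metric (gene-name
#'   tie-break).
#' @export
rank_by_signed_logp <- function(markers) {
  stopifnot(all(c("gene", "p", "log2fc") %in% names(markers)))
  if (anyDuplicated(markers$gene)) stop("duplicate genes in marker table")
  p <- markers$p
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of 0 floored at machine precision")
    p[p == 0] <- .Machine$double.xmin
  }
  metric <- -log10(p) * sign(markers$log2fc)
  names(metric) <- markers$gene
  metric[order(-metric, names(metric))]
}

#' Pairwise signature correlation with hierarchical ordering
#'
#' Pearson correlations between score rows of a score matrix, plus an
#' average-linkage hierarchical ordering on the 1 - r distance. Zero-variance
#' score rows are excluded with a warning.
#'
#' @param scores sets x segments score matrix (>= 2 sets, >= 3 segments).
#' @return list with `r` (correlation matrix), `order` (hclust leaf order),
#'   `hclust`, `excluded`.
#' @export
pairwise_signature_correlation <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2 || ncol(scores) < 3) {
    stop("need at least 2 sets and 3 segments")
  }
  v <- apply(scores, 1, stats::var)
  excluded <- rownames(scores)[v == 0 | is.na(v)]
  if (length(excluded)) {
    warning("zero-variance score row(s) excluded: ",
            paste(excluded, collapse = ", "))
    scores <- scores[!(rownames(scores) %in% excluded), , drop = FALSE]
  }
  r <- stats::cor(t(scores))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, order = hc$order, hclust = hc, excluded = excluded)
}
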