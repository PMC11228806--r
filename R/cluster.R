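#' Select highly variable genes
#'
#' Top-n genes by variance across the provided segments, with a deterministic
#' alphabetical tie-break on the gene name.
#'
#' @param em an [expr_matrix] (typically state `log2q3`).
#' @param n number of genes to keep.
#' @return Character vector of gene names, length `n`.
#' @export
select_hvg <- function(em, n) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(em)) stop("n exceeds the number of genes")
  v <- apply(em, 1, stats::var)
  ord <- order(-v, rownames(em))
  rownames(em)[ord][seq_len(n)]
}

#' Principal component analysis of segments
#'
#' PCA on the segments x genes matrix (segments as observations, Euclidean
#' metric, centered, unscaled). Each component is oriented deterministically:
#' the gene with the largest absolute loading on a component has positive
#' loading. This pins down the otherwise arbitrary PCA sign convention so
#' that "positive contributors" is well defined.
#'
#' @param em an [expr_matrix]; rows are genes, columns segments.
#' @param genes optional gene subset (e.g. from [select_hvg()]).
#' @return list of class `geomx_pca`: `loadings` (genes x components,
#'   orthonormal columns), `scores` (segments x components),
#'   `explained_variance_fraction`, `center`.
#' @export
run_pca <- function(em, genes = NULL) {
  x <- t(unclass(em))
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (c in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, c]))
    if (p$rotation[j, c] < 0) {
      p$rotation[, c] <- -p$rotation[, c]
      p$x[, c] <- -p$x[, c]
    }
  }
  evf <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(loadings = p$rotation, scores = p$x,
         explained_variance_fraction = evf, center = p$center),
    class = "geomx_pca"
  )
}

# internal: seeded k-means, best of `attempts` restarts
.run_kmeans <- function(x, k, iterations, attempts) {
  if (k == 1) {
    ctr <- colMeans(x)
    wss <- sum(sweep(x, 2, ctr)^2)
    return(list(cluster = rep(1L, nrow(x)), tot.withinss = wss))
  }
  distinct <- nrow(unique(x))
  if (distinct < k) {
    # degenerate data: fewer distinct points than centers; every distinct
    # point is its own cluster and the within-cluster scatter is zero
    labels <- as.integer(factor(apply(x, 1, paste, collapse = "\r")))
    return(list(cluster = labels, tot.withinss = 0))
  }
  suppressWarnings(
    stats::kmeans(x, centers = k, iter.max = iterations, nstart = attempts)
  )
}

#' Choose the number of clusters by the elbow of the WSS curve
#'
#' Runs k-means for k = 1..k_max and selects k* as the argmax of the second
#' forward difference of the total within-cluster sum of squares over
#' k = 2..k_max-1 — a reproducible automation of the visual elbow. If every
#' WSS is (numerically) zero the data are degenerate and k* = 1 by
#' convention.
#'
#' @param em an [expr_matrix]; columns are the segments to cluster.
#' @param k_max largest k to scan (>= 3).
#' @param seed integer seed.
#' @param genes optional gene subset.
#' @param iterations,attempts k-means settings for the scan.
#' @return list with `k` and `wss_per_k` (named numeric, k = 1..k_max).
#' @export
choose_k_elbow <- function(em, k_max = 10, seed = 1L, genes = NULL,
                           iterations = 50, attempts = 25) {
  if (k_max < 3) stop("k_max must be at least 3")
  x <- t(unclass(em))
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (nrow(x) < k_max) stop("fewer segments than k_max")
  set.seed(as.integer(seed) %% 2147480000L)
  wss <- vapply(seq_len(k_max), function(k) {
    .run_kmeans(x, k, iterations, attempts)$tot.withinss
  }, numeric(1))
  names(wss) <- seq_len(k_max)
  if (all(wss < 1e-12)) {
    return(list(k = 1L, wss_per_k = wss))
  }
  ks <- 2:(k_max - 1)
  d2 <- wss[ks + 1] - 2 * wss[ks] + wss[ks - 1]
  list(k = ks[which.max(d2)], wss_per_k = wss)
}

#' k-means clustering of segments
#'
#' Best-of-`attempts` k-means (lowest WSS, Euclidean distance) on the
#' provided (typically HVG log2-Q3) matrix. When an orienting score is
#' supplied, cluster labels are renumbered by ascending cluster mean of that
#' score, so that with the default NE-score orientation cluster k is the most
#' NE-like and cluster 1 the least.
#'
#' @param em an [expr_matrix]; columns are segments.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param iterations,attempts k-means iteration cap and number of restarts.
#' @param genes optional gene subset.
#' @param orient_by optional named numeric score per segment used to renumber
#'   labels (ascending cluster means).
#' @return list of class `cluster_assignment`: `labels` (named integer),
#'   `k`, `wss`, `seed`, `iterations`, `attempts`.
#' @export
kmeans_cluster <- function(em, k, seed = 1L, iterations = 50, attempts = 200,
                           genes = NULL, orient_by = NULL) {
  x <- t(unclass(em))
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(x)) stop("k exceeds the number of segments")
  set.seed(as.integer(seed) %% 2147480000L)
  fit <- .run_kmeans(x, k, iterations, attempts)
  labels <- stats::setNames(as.integer(fit$cluster), rownames(x))
  if (!is.null(orient_by) && k > 1) {
    sc <- orient_by[names(labels)]
    means <- tapply(sc, labels, mean, na.rm = TRUE)
    ord <- order(means)  # ascending: cluster k = highest orienting score
    remap <- integer(k)
    remap[as.integer(names(means))[ord]] <- seq_len(k)
    labels[] <- remap[labels]
  }
  structure(
    list(labels = labels, k = k, wss = fit$tot.withinss, seed = seed,
         iterations = iterations, attempts = attempts),
    class = "cluster_assignment"
  )
}

#' Extract phenotype signatures from PC contributions
#'
#' The contribution of a gene to a component is its squared loading divided
#' by the column sum of squared loadings (so contributions sum to 1 per
#' component). A gene is a contributor when its contribution exceeds the
#' uniform expectation 1/|universe| on PC1 or PC2; each contributing gene is
#' assigned to the single axis where its contribution is larger. Signature 1
#' collects PC1-assigned genes with positive PC1 loading, signature 2
#' PC2-assigned genes with positive PC2 loading, and signature 3 PC2-assigned
#' genes with negative PC2 loading; single-axis assignment guarantees the
#' three lists are pairwise disjoint.
#'
#' @param pca a `geomx_pca` from [run_pca()] (or any list with a `loadings`
#'   matrix of >= 2 columns).
#' @param universe gene universe (defaults to the loading rownames); the
#'   contributor threshold is 1/length(universe).
#' @return list of class `cluster_signatures` with `sig_cluster1`,
#'   `sig_cluster2`, `sig_cluster3` (data.frames: gene, pc, contribution,
#'   loading) and `threshold`.
#' @export
extract_pc_signatures <- function(pca, universe = NULL) {
  L <- pca$loadings
  if (ncol(L) < 2) stop("at least 2 principal components are required")
  if (all(abs(L[, 1:2]) < 1e-12)) stop("degenerate PCA: zero loadings")
  if (is.null(universe)) universe <- rownames(L)
  thr <- 1 / length(universe)
  contrib <- sweep(L[, 1:2, drop = FALSE]^2, 2,
                   colSums(L[, 1:2, drop = FALSE]^2), "/")
  axis <- ifelse(contrib[, 1] >= contrib[, 2], 1L, 2L)
  is_contrib <- (contrib[, 1] > thr) | (contrib[, 2] > thr)
  pick <- function(ax, sign_dir) {
    sel <- is_contrib & axis == ax &
      (if (sign_dir > 0) L[, ax] > 0 else L[, ax] < 0)
    data.frame(
      gene = rownames(L)[sel],
      pc = rep(ax, sum(sel)),
      contribution = contrib[sel, ax],
      loading = L[sel, ax],
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(sig_cluster1 = pick(1L, +1),
         sig_cluster2 = pick(2L, +1),
         sig_cluster3 = pick(2L, -1),
         threshold = thr),
    class = "cluster_signatures"
  )
}

#' @export
print.cluster_signatures <- function(x, ...) {
  cat(sprintf("cluster_signatures: %d / %d / %d genes (threshold %.2e)\n",
              nrow(x$sig_cluster1), nrow(x$sig_cluster2),
              nrow(x$sig_cluster3), x$threshold))
  invisible(x)
}

#' Assign TME segments the cluster of their paired tumor segment
#'
#' Each TME segment inherits the label of the tumor segment sharing its
#' region id; TME segments whose region has no labeled tumor segment are
#' flagged `NA` (unassigned).
#'
#' @param tumor_labels a `cluster_assignment` (or named integer vector) over
#'   tumor segments.
#' @param ann segment annotation covering both compartments.
#' @return Named integer vector over TME segments (`NA` = unassigned).
#' @export
assign_tme_clusters <- function(tumor_labels, ann) {
  validate_annotation(ann)
  if (inherits(tumor_labels, "cluster_assignment")) {
    tumor_labels <- tumor_labels$labels
  }
  tumor <- ann[ann$compartment %in% c("tumor", "tumor_only"), ]
  tme <- ann[ann$compartment == "TME", ]
  region_label <- stats::setNames(
    tumor_labels[tumor$segment_id], tumor$region_id
  )
  out <- region_label[tme$region_id]
  names(out) <- tme$segment_id
  out
}

#' Cluster marker genes (one-vs-rest Wilcoxon with Q3 fold change)
#'
#' For each gene and cluster: a two-sided Wilcoxon rank-sum p-value (cluster
#' vs all other segments) and the fold change log2(median Q3 in cluster /
#' median Q3 in rest), computed on un-logged q3-scale values. A gene is a
#' marker when p < 0.05 and the linear fold change exceeds 2 in either
#' direction (|log2FC| > 1). A zero median in numerator or denominator gets a
#' pseudo-count of 1 (flagged in the `zero_median` column). BH-adjusted
#' p-values are reported per cluster across genes.
#'
#' @param em an [expr_matrix] in state `log2q3` (un-logged internally for
#'   the fold change) or `q3`.
#' @param labels named cluster labels (or a `cluster_assignment`).
#' @param p_cutoff,fc_cutoff marker thresholds (defaults 0.05 and 2x).
#' @return data.frame: gene, cluster, p, fdr_bh, log2fc, zero_median,
#'   is_marker.
#' @export
cluster_markers <- function(em, labels, p_cutoff = 0.05, fc_cutoff = 2) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- labels[colnames(em)]
  if (any(is.na(labels))) stop("every segment needs a cluster label")
  if (any(table(labels) < 2)) stop("each cluster needs at least 2 segments")
  q3vals <- switch(expr_state(em),
                   log2q3 = 2^unclass(em) - 1,
                   q3 = unclass(em),
                   stop("cluster_markers expects q3 or log2q3 expression"))
  vals <- unclass(em)
  res <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    p <- vapply(seq_len(nrow(vals)), function(i) {
      suppressWarnings(
        stats::wilcox.test(vals[i, in_cl], vals[i, !in_cl],
                           alternative = "two.sided", exact = FALSE)$p.value
      )
    }, numeric(1))
    p[is.na(p)] <- 1  # constant gene across all segments
    med_in <- apply(q3vals[, in_cl, drop = FALSE], 1, stats::median)
    med_out <- apply(q3vals[, !in_cl, drop = FALSE], 1, stats::median)
    zero <- med_in == 0 | med_out == 0
    med_in[med_in == 0] <- 1
    med_out[med_out == 0] <- 1
    l2fc <- log2(med_in / med_out)
    res[[as.character(cl)]] <- data.frame(
      gene = rownames(vals),
      cluster = cl,
      p = p,
      fdr_bh = stats::p.adjust(p, method = "BH"),
      log2fc = l2fc,
      zero_median = zero,
      is_marker = p < p_cutoff & abs(l2fc) > log2(fc_cutoff),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
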