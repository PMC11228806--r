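#' Min-max rescale expression per gene to [0, 10]
#'
#' Ligand-receptor scores are computed on a bounded per-gene scale so that
#' scores are comparable across pairs: each gene is rescaled linearly to
#' [0, 10] over all segments in the run. Constant genes map to 0.
#'
#' @param em an [expr_matrix] (any state; values must be non-negative).
#' @return plain numeric matrix on the [0, 10] scale.
#' @export
rescale_expression <- function(em) {
  x <- unclass(em)
  if (any(x < 0)) stop("negative expression values")
  t(apply(x, 1, function(g) {
    r <- max(g) - min(g)
    if (r == 0) rep(0, length(g)) else (g - min(g)) / r * 10
  }))
}

# internal: split a ';'-joined field
.split_field <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

#' Score a single ligand-receptor pair between two segments
#'
#' Ligand activity is the geometric mean of the ligand-subunit expressions in
#' the sender segment; receptor activity likewise in the receiver; the pair
#' score is sqrt(ligand activity x receptor activity). Computed on per-gene
#' min-max [0, 10]-rescaled expression, so the score is bounded by 10, and
#' symmetric under exchanging (ligand, receptor) together with
#' (sender, receiver). A missing subunit gene yields a missing (NA) score:
#' absence of measurement is not absence of signal.
#'
#' @param sender_expr,receiver_expr named numeric expression vectors on the
#'   [0, 10] rescaled scale (see [rescale_expression()]).
#' @param ligand_genes,receptor_genes character vectors of subunit genes.
#' @return pair score in [0, 10], or NA when a subunit is missing.
#' @export
lr_pair_score <- function(sender_expr, receiver_expr,
                          ligand_genes, receptor_genes) {
  .lr_activities(sender_expr, receiver_expr,
                 ligand_genes, receptor_genes)[["score"]]
}

# internal: ligand activity, receptor activity and pair score
.lr_activities <- function(sender_expr, receiver_expr,
                           ligand_genes, receptor_genes) {
  if (any(c(sender_expr, receiver_expr) < 0, na.rm = TRUE)) {
    stop("negative expression values")
  }
  if (!all(ligand_genes %in% names(sender_expr)) ||
      !all(receptor_genes %in% names(receiver_expr))) {
    return(c(ligand = NA_real_, receptor = NA_real_, score = NA_real_))
  }
  gm <- function(x) if (any(x == 0)) 0 else exp(mean(log(x)))
  lig <- gm(sender_expr[ligand_genes])
  rec <- gm(receiver_expr[receptor_genes])
  c(ligand = lig, receptor = rec, score = sqrt(lig * rec))
}

#' Score all ligand-receptor pairs across paired tumor/TME regions
#'
#' For every region with both a tumor and a TME segment, each annotated pair
#' is scored in its annotated direction: `"in"` = TME sender, tumor receiver;
#' `"out"` = tumor sender, TME receiver.
#'
#' @param em an [expr_matrix] covering tumor and TME segments (linear or log
#'   scale; rescaled internally per gene to [0, 10]).
#' @param ann segment annotation (see [validate_annotation()]).
#' @param lr ligand-receptor annotation data.frame (see
#'   [read_lr_annotation()]).
#' @return data.frame: region, direction, pair_id, sender_pop, receiver_pop,
#'   score (NA when a subunit gene is absent).
#' @export
score_lr_pairs <- function(em, ann, lr) {
  validate_annotation(ann)
  resc <- rescale_expression(em)
  tumor <- ann[ann$compartment == "tumor", ]
  tme <- ann[ann$compartment == "TME", ]
  regions <- intersect(tumor$region_id, tme$region_id)
  regions <- regions[tumor$segment_id[match(regions, tumor$region_id)] %in%
                       colnames(resc) &
                     tme$segment_id[match(regions, tme$region_id)] %in%
                       colnames(resc)]
  if (!length(regions)) stop("no paired tumor/TME regions in the matrix")
  out <- list()
  for (rg in regions) {
    t_seg <- tumor$segment_id[tumor$region_id == rg]
    m_seg <- tme$segment_id[tme$region_id == rg]
    for (i in seq_len(nrow(lr))) {
      dirn <- lr$direction[i]
      sender <- if (dirn == "in") resc[, m_seg] else resc[, t_seg]
      receiver <- if (dirn == "in") resc[, t_seg] else resc[, m_seg]
      act <- .lr_activities(sender, receiver,
                            .split_field(lr$ligand_genes[i]),
                            .split_field(lr$receptor_genes[i]))
      out[[length(out) + 1L]] <- data.frame(
        region = rg, direction = dirn, pair_id = lr$pair_id[i],
        sender_pop = lr$sender_pops[i], receiver_pop = lr$receiver_pops[i],
        ligand_activity = act[["ligand"]],
        receptor_activity = act[["receptor"]],
        score = act[["score"]], stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize pair scores to population-level interactions
#'
#' For each (region, direction, sender population, receiver population), the
#' summary communication score is the maximum pair score over the mapped
#' pairs (the headline aggregator); the cross-check aggregator
#' `"mean_of_min"` assigns each pair the minimum of its ligand and receptor
#' activities and averages over pairs. Since min(l, r) <= sqrt(l x r) <= the
#' maximum pair score, the max aggregator always dominates the mean-of-min.
#'
#' @param pair_scores output of [score_lr_pairs()].
#' @param aggregator `"max"` (default) or `"mean_of_min"`.
#' @return data.frame: region, direction, sender_pop, receiver_pop, summary,
#'   n_pairs. Population mappings whose pair scores are all NA are reported
#'   with `summary = NA`.
#' @export
summarize_population_interactions <- function(pair_scores,
                                              aggregator = c("max",
                                                             "mean_of_min")) {
  aggregator <- match.arg(aggregator)
  key <- interaction(pair_scores$region, pair_scores$direction,
                     pair_scores$sender_pop, pair_scores$receiver_pop,
                     drop = TRUE)
  res <- lapply(split(pair_scores, key), function(df) {
    ok <- !is.na(df$score)
    val <- if (!any(ok)) NA_real_
    else if (aggregator == "max") max(df$score[ok])
    else mean(pmin(df$ligand_activity[ok], df$receptor_activity[ok]))
    data.frame(region = df$region[1], direction = df$direction[1],
               sender_pop = df$sender_pop[1],
               receiver_pop = df$receiver_pop[1],
               summary = val, n_pairs = nrow(df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Differential ligand-receptor interactions between ecosystem groups
#'
#' Two-sided Wilcoxon rank-sum test per pair across regions, comparing the
#' two ecosystem groups (e.g. non-NE vs NE/hybrid), with BH FDR across
#' pairs. The effect size is the difference of group medians
#' (group2 - group1); the direction tag is preserved. Pairs with constant
#' scores get p = 1.
#'
#' @param pair_scores output of [score_lr_pairs()].
#' @param groups named character vector region -> group (exactly 2 groups,
#'   >= 3 regions each).
#' @return data.frame: pair_id, direction, median_diff, p, fdr_bh,
#'   n1, n2.
#' @export
differential_interactions <- function(pair_scores, groups) {
  g <- groups[pair_scores$region]
  if (anyNA(g)) stop("every region needs a group label")
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups are required")
  if (any(table(unique(data.frame(r = pair_scores$region, g = g))$g) < 3)) {
    stop("each group needs at least 3 regions")
  }
  res <- lapply(split(seq_len(nrow(pair_scores)),
                      list(pair_scores$pair_id, pair_scores$direction),
                      drop = TRUE), function(idx) {
    df <- pair_scores[idx, ]
    gg <- groups[df$region]
    x <- df$score[gg == lv[1]]
    y <- df$score[gg == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NULL)
    # exact test when sample sizes and ties permit (matters at region-level
    # n, where the normal approximation is too conservative for BH control)
    p <- if (stats::sd(c(x, y)) == 0) 1 else suppressWarnings(
      stats::wilcox.test(x, y)$p.value
    )
    data.frame(pair_id = df$pair_id[1], direction = df$direction[1],
               median_diff = stats::median(y) - stats::median(x),
               p = p, n1 = length(x), n2 = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out$fdr_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
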