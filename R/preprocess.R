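#' Collapse probes to gene-level expression
#'
#' For each gene in each segment the reported value is the arithmetic mean of
#' that gene's probe counts after removal of outlier probes. A probe is an
#' outlier in a segment when its count falls outside 0.1x - 10x the median of
#' the gene's probes in that segment; the rule is only applied when the gene
#' has at least three probes (with one or two probes no probe is removed).
#' Negative probes are excluded from gene rows but retained by the caller for
#' LOQ computation.
#'
#' @param pcm a [probe_counts] object.
#' @return An [expr_matrix] in state `raw` (genes x segments).
#' @export
collapse_probes <- function(pcm) {
  stopifnot(inherits(pcm, "probe_counts"))
  keep <- !pcm$is_negative
  counts <- pcm$counts[keep, , drop = FALSE]
  gene <- pcm$target_gene[keep]
  if (!length(gene)) stop("no non-negative probes to collapse")
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(counts),
                dimnames = list(genes, colnames(counts)))
  idx <- split(seq_along(gene), gene)
  for (g in genes) {
    rows <- idx[[g]]
    if (!length(rows)) stop("gene '", g, "' has zero probes")
    sub <- counts[rows, , drop = FALSE]
    if (length(rows) < 3) {
      out[g, ] <- colMeans(sub)
    } else {
      med <- apply(sub, 2, stats::median)
      lo <- rep(0.1 * med, each = nrow(sub))
      hi <- rep(10 * med, each = nrow(sub))
      ok <- sub >= matrix(lo, nrow = nrow(sub)) &
        sub <= matrix(hi, nrow = nrow(sub))
      # if the rule would drop everything in a segment, keep all probes there
      none <- colSums(ok) == 0
      if (any(none)) ok[, none] <- TRUE
      out[g, ] <- colSums(sub * ok) / colSums(ok)
    }
  }
  expr_matrix(out, state = "raw")
}

#' Per-segment limit of quantification from negative probes
#'
#' LOQ for a segment is the geometric mean of its negative-probe counts plus
#' `n_sd` standard deviations. Zeros are replaced by a pseudo-count of 1
#' before the geometric mean. By default the standard deviation is the
#' arithmetic sample sd of the (pseudo-counted) negative counts; the
#' multiplicative alternative (`sd_type = "geometric"`) uses
#' geomean x gsd^n_sd, where gsd is the geometric standard deviation.
#'
#' @param pcm a [probe_counts] object with at least two negative probes.
#' @param n_sd number of standard deviations above the geometric mean.
#' @param sd_type `"arithmetic"` (default) or `"geometric"`.
#' @return Named numeric vector, one LOQ per segment.
#' @export
compute_loq <- function(pcm, n_sd = 2, sd_type = c("arithmetic", "geometric")) {
  stopifnot(inherits(pcm, "probe_counts"))
  sd_type <- match.arg(sd_type)
  neg <- pcm$counts[pcm$is_negative, , drop = FALSE]
  if (nrow(neg) < 2) stop("at least 2 negative probes are required")
  apply(neg, 2, function(x) {
    x[x == 0] <- 1
    gm <- exp(mean(log(x)))
    if (sd_type == "arithmetic") {
      gm + n_sd * stats::sd(x)
    } else {
      gsd <- exp(stats::sd(log(x)))
      gm * gsd^n_sd
    }
  })
}

#' Segment quality control
#'
#' Flags and removes segments failing any enabled threshold: sequencing
#' saturation, nuclei count, or fraction of genes detected above the
#' segment's LOQ. Thresholds of 0 disable a check.
#'
#' @param em an [expr_matrix] (state `raw`).
#' @param ann segment annotation (see [validate_annotation()]).
#' @param loq per-segment LOQ vector from [compute_loq()].
#' @param thresholds list with elements `saturation` (default 0.8), `nuclei`
#'   (default 20) and `min_frac_above_loq` (default 0.05).
#' @return list with `report` (per-segment data.frame: saturation, nuclei,
#'   area, frac_above_loq, pass, reasons), `expr` and `annotation` filtered
#'   to passing segments.
#' @export
qc_segments <- function(em, ann, loq,
                        thresholds = list(saturation = 0.8, nuclei = 20,
                                          min_frac_above_loq = 0.05)) {
  validate_annotation(ann)
  th <- utils::modifyList(
    list(saturation = 0.8, nuclei = 20, min_frac_above_loq = 0.05),
    thresholds
  )
  if (th$saturation < 0 || th$saturation > 1 ||
      th$min_frac_above_loq < 0 || th$min_frac_above_loq > 1 ||
      th$nuclei < 0) {
    stop("QC thresholds outside valid ranges")
  }
  segs <- colnames(em)
  if (!all(segs %in% ann$segment_id) || !all(segs %in% names(loq))) {
    stop("segment ids of expression, annotation and LOQ do not match")
  }
  ann <- ann[match(segs, ann$segment_id), ]
  loq <- loq[segs]
  frac_above <- vapply(seq_along(segs),
                       function(i) mean(em[, i] > loq[i]), numeric(1))
  reasons <- vapply(seq_along(segs), function(i) {
    r <- character(0)
    if (ann$saturation[i] < th$saturation) r <- c(r, "saturation")
    if (ann$nuclei[i] < th$nuclei) r <- c(r, "nuclei")
    if (frac_above[i] < th$min_frac_above_loq) r <- c(r, "genes_above_loq")
    paste(r, collapse = ";")
  }, character(1))
  pass <- !nzchar(reasons)
  report <- data.frame(
    segment_id = segs,
    saturation = ann$saturation,
    nuclei = ann$nuclei,
    area = ann$area,
    frac_above_loq = frac_above,
    pass = pass,
    reasons = reasons,
    stringsAsFactors = FALSE
  )
  attr(report, "thresholds") <- th
  attr(report, "loq_note") <- "negative-probe zeros replaced by pseudo-count 1"
  list(
    report = report,
    expr = expr_matrix(em[, pass, drop = FALSE], state = expr_state(em)),
    annotation = ann[pass, , drop = FALSE]
  )
}

#' Third-quartile (Q3) normalization
#'
#' Each segment's Q3 (75th percentile of its above-LOQ genes; all genes when
#' `loq` is NULL) is scaled to the geometric mean of all segments' Q3 values:
#' the scale factor for segment s is geomean(Q3) / Q3_s.
#'
#' @param em an [expr_matrix] in state `raw`.
#' @param loq optional per-segment LOQ vector; Q3 is then computed on genes
#'   above the segment's LOQ only.
#' @return An [expr_matrix] in state `q3` with attributes `q3` (the
#'   per-segment Q3 values) and `scale_factors`.
#' @export
q3_normalize <- function(em, loq = NULL) {
  if (expr_state(em) != "raw") {
    stop("q3_normalize expects a raw matrix; got state '", expr_state(em),
         "' (refusing to double-normalize)")
  }
  q3 <- vapply(seq_len(ncol(em)), function(i) {
    x <- em[, i]
    if (!is.null(loq)) {
      l <- loq[colnames(em)[i]]
      if (is.na(l)) stop("no LOQ for segment ", colnames(em)[i])
      x <- x[x > l]
    }
    if (!length(x)) return(0)
    stats::quantile(x, 0.75, type = 7, names = FALSE)
  }, numeric(1))
  names(q3) <- colnames(em)
  if (any(q3 == 0)) {
    stop("segment(s) with zero Q3: ",
         paste(names(q3)[q3 == 0], collapse = ", "))
  }
  target <- exp(mean(log(q3)))
  factors <- target / q3
  out <- sweep(unclass(em), 2, factors, "*")
  out <- expr_matrix(out, state = "q3")
  attr(out, "q3") <- q3
  attr(out, "scale_factors") <- factors
  out
}

#' Log2 transform of Q3-normalized expression
#'
#' Applies log2(x + 1), moving the state from `q3` to `log2q3`.
#'
#' @param em an [expr_matrix] in state `q3`.
#' @return An [expr_matrix] in state `log2q3`.
#' @export
log2_transform <- function(em) {
  if (expr_state(em) != "q3") {
    stop("log2_transform expects a q3 matrix; got state '",
         expr_state(em), "'")
  }
  expr_matrix(log2(unclass(em) + 1), state = "log2q3")
}
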