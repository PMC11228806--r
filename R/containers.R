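#' Probe-level count container
#'
#' Bundles a probe x segment count matrix with its probe-to-gene mapping and
#' negative-probe flags. Negative probes carry no gene target; they exist only
#' to estimate background and the per-segment limit of quantification (LOQ).
#'
#' @param counts integer-like matrix, probes x segments, non-negative.
#'   Rownames are probe ids.
#' @param target_gene character vector, one gene symbol per probe; negative
#'   probes may use a pool label such as `"NEG"`.
#' @param is_negative logical vector, one flag per probe.
#' @return An object of class `probe_counts`.
#' @export
probe_counts <- function(counts, target_gene, is_negative) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("probe_%05d", seq_len(nrow(counts)))
  }
  if (length(target_gene) != nrow(counts)) {
    stop("'target_gene' must have one entry per probe")
  }
  if (length(is_negative) != nrow(counts)) {
    stop("'is_negative' must have one entry per probe")
  }
  if (any(counts < 0)) stop("probe counts must be non-negative")
  if (!any(is_negative)) stop("at least one negative probe is required")
  structure(
    list(
      counts = counts,
      probe_id = rownames(counts),
      target_gene = as.character(target_gene),
      is_negative = as.logical(is_negative)
    ),
    class = "probe_counts"
  )
}

#' @export
print.probe_counts <- function(x, ...) {
  cat(sprintf(
    "probe_counts: %d probes (%d negative) x %d segments, %d target genes\n",
    nrow(x$counts), sum(x$is_negative), ncol(x$counts),
    length(unique(x$target_gene[!x$is_negative]))
  ))
  invisible(x)
}

#' Expression matrix with an explicit normalization state
#'
#' A genes x segments matrix tagged with one of three states: `raw` (probe
#' means), `q3` (third-quartile normalized, linear scale), or `log2q3`
#' (log2(x + 1) of the q3 values). State transitions are one-way
#' (raw -> q3 -> log2q3) and guarded: re-normalizing raises an error rather
#' than silently double-normalizing.
#'
#' @param values numeric matrix, genes x segments, with dimnames.
#' @param state one of `"raw"`, `"q3"`, `"log2q3"`.
#' @return A numeric matrix of class `expr_matrix` with a `state` attribute.
#' @export
expr_matrix <- function(values, state = c("raw", "q3", "log2q3")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and segment colnames")
  }
  if (state == "raw" && any(values < 0)) {
    stop("raw expression values must be non-negative")
  }
  structure(values, state = state, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_state <- function(x) {
  s <- attr(x, "state")
  if (is.null(s)) stop("matrix has no normalization state tag")
  s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d segments\n",
              expr_state(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Validate a segment annotation table
#'
#' Checks the contract used throughout the pipeline: one row per segment with
#' compartment (`tumor`, `TME`, `normal`, `tumor_only`), patient, region id
#' (shared by a paired tumor/TME couple), area, nuclei and sequencing
#' saturation. A region may link at most one tumor and one TME segment.
#'
#' @param ann data.frame with columns `segment_id`, `compartment`,
#'   `patient_id`, `region_id`, `area`, `nuclei`, `saturation`.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_annotation <- function(ann) {
  needed <- c("segment_id", "compartment", "patient_id", "region_id",
              "area", "nuclei", "saturation")
  missing <- setdiff(needed, names(ann))
  if (length(missing)) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  ok <- c("tumor", "TME", "normal", "tumor_only")
  if (!all(ann$compartment %in% ok)) {
    stop("compartment must be one of: ", paste(ok, collapse = ", "))
  }
  if (anyDuplicated(ann$segment_id)) stop("duplicate segment ids")
  if (any(ann$saturation < 0 | ann$saturation > 1)) {
    stop("saturation must lie in [0, 1]")
  }
  for (comp in c("tumor", "TME")) {
    tab <- table(ann$region_id[ann$compartment == comp])
    if (any(tab > 1)) {
      stop("a region links more than one ", comp, " segment")
    }
  }
  invisible(ann)
}

#' Gene set collection
#'
#' A named list of character vectors. Sets must be non-empty and contain no
#' duplicate genes.
#'
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @return A named list of class `gene_sets`.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (length(g) == 0) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(g)) stop("gene set '", nm, "' has duplicate genes")
  }
  structure(lapply(sets, as.character),
            description = description, class = c("gene_sets", "list"))
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

# internal: geometric mean; zeros replaced by 1 before the log so background
# counts of zero do not annihilate the mean (documented in compute_loq)
geomean <- function(x, zero_pseudo = TRUE) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("geometric mean requires non-negative values")
  if (zero_pseudo) x[x == 0] <- 1
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

# internal: clamp to an interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
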