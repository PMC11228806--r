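#' Reference-based cell-type deconvolution
#'
#' Models each segment's linear-scale (q3) expression as a non-negative
#' mixture of reference cell-type profiles: per segment, solve
#' min ||ref %*% w - expr||^2 subject to w >= 0 (Lawson-Hanson active-set
#' NNLS), then renormalize w onto the simplex. Because mixtures are additive
#' in linear space, deconvolution runs on un-logged values; the simplex
#' renormalization absorbs overall library-size scale, so the result is
#' invariant to multiplying a segment by a positive constant. The
#' `"augmented"` mode instead solves the sum-to-one constraint explicitly by
#' appending a penalty row sqrt(gamma) * 1' to the design.
#'
#' @param em an [expr_matrix] in state `q3` (linear scale).
#' @param ref genes x cell-type reference profile matrix (>= 10 shared
#'   genes).
#' @param mode `"nnls"` (NNLS + renormalization, default) or `"augmented"`
#'   (penalized sum-to-one).
#' @param gamma penalty weight for the augmented mode.
#' @return list with `proportions` (segments x cell types, rows on the
#'   simplex) and `residual` (per-segment relative residual norm
#'   ||ref w - expr|| / ||expr|| at the fitted scale).
#' @export
deconvolve <- function(em, ref, mode = c("nnls", "augmented"), gamma = 1e4) {
  mode <- match.arg(mode)
  if (inherits(em, "expr_matrix") && expr_state(em) == "log2q3") {
    stop("deconvolve expects linear-scale (q3) expression, not log2q3")
  }
  ref <- as.matrix(ref)
  if (any(colSums(ref) == 0)) stop("reference has an all-zero column")
  shared <- intersect(rownames(em), rownames(ref))
  if (length(shared) < 10) {
    stop("fewer than 10 genes shared between expression and reference")
  }
  A <- ref[shared, , drop = FALSE]
  X <- unclass(em)[shared, , drop = FALSE]
  k <- ncol(A)
  props <- matrix(NA_real_, nrow = ncol(X), ncol = k,
                  dimnames = list(colnames(X), colnames(A)))
  resid <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    b <- X[, j]
    if (mode == "nnls") {
      w <- pracma::lsqnonneg(A, b)$x
      b_used <- b
    } else {
      # pre-scale the segment with an unconstrained NNLS fit so that the
      # simplex constraint and the data term are consistent, then solve
      # with a stiff sum-to-one penalty row
      w0 <- pracma::lsqnonneg(A, b)$x
      s <- sum(w0)
      if (s <= 0) s <- 1
      b_used <- b / s
      pen <- sqrt(gamma) * mean(abs(A))
      A2 <- rbind(A, rep(pen, k))
      w <- pracma::lsqnonneg(A2, c(b_used, pen))$x
    }
    if (sum(w) <= 0 || sum(b_used^2) == 0) {
      resid[j] <- 1
      next
    }
    fitted <- as.numeric(A %*% w)
    resid[j] <- sqrt(sum((fitted - b_used)^2)) / sqrt(sum(b_used^2))
    props[j, ] <- w / sum(w)
  }
  list(proportions = props, residual = resid)
}

#' Per-segment composition diversity (Shannon H')
#'
#' Applies [shannon_index()] row-wise to a proportion matrix.
#'
#' @param props segments x cell-type proportion matrix (rows on the simplex).
#' @return Named numeric H' per segment.
#' @export
composition_diversity <- function(props) {
  props <- as.matrix(props)
  out <- apply(props, 1, shannon_index)
  stats::setNames(out, rownames(props))
}

#' Correlate TME composition with tumor NE differentiation
#'
#' Spearman correlation of each cell-type fraction against the paired tumor
#' segment's NE score, with BH-adjusted p-values. Constant fraction columns
#' give a missing rho (reported).
#'
#' @param props segments x cell-type proportion matrix.
#' @param ne_scores named NE score vector aligned to the same segments
#'   (e.g. the paired tumor segment's score, named by TME segment id).
#' @return data.frame: celltype, rho, p, fdr_bh, n.
#' @export
correlate_composition_with_ne <- function(props, ne_scores) {
  props <- as.matrix(props)
  common <- intersect(rownames(props), names(ne_scores))
  if (length(common) < 5) stop("fewer than 5 paired segments")
  props <- props[common, , drop = FALSE]
  ne <- ne_scores[common]
  res <- lapply(colnames(props), function(ct) {
    x <- props[, ct]
    if (stats::sd(x) == 0) {
      return(data.frame(celltype = ct, rho = NA_real_, p = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    }
    ct_test <- suppressWarnings(
      stats::cor.test(x, ne, method = "spearman", exact = FALSE)
    )
    data.frame(celltype = ct, rho = unname(ct_test$estimate),
               p = ct_test$p.value, n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
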