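#' Read and write GMT gene set files
#'
#' The GMT format stores one gene set per line: name, description, then the
#' member genes, all tab-separated.
#'
#' @param path file path.
#' @return `read_gmt` returns a [gene_sets] object.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  names(desc) <- names(sets)
  gene_sets(sets, description = desc)
}

#' @rdname read_gmt
#' @param sets a [gene_sets] object (or plain named list).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write probe-level count tables
#'
#' The on-disk layout is TSV with columns `probe_id`, `target_gene`,
#' `is_negative` followed by one column per segment.
#'
#' @param path file path.
#' @return `read_probe_counts` returns a [probe_counts] object.
#' @export
read_probe_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("probe_id", "target_gene", "is_negative")
  if (!all(meta %in% names(df))) {
    stop("probe count table must have columns: ", paste(meta, collapse = ", "))
  }
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(counts) <- df$probe_id
  probe_counts(counts, df$target_gene, as.logical(df$is_negative))
}

#' @rdname read_probe_counts
#' @param pcm a [probe_counts] object.
#' @export
write_probe_counts <- function(pcm, path) {
  df <- data.frame(
    probe_id = pcm$probe_id,
    target_gene = pcm$target_gene,
    is_negative = pcm$is_negative,
    pcm$counts,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' @param path file path.
#' @param state normalization state recorded in / expected from the file
#'   (stored as a `# state:` comment line).
#' @return `read_expr_matrix` returns an [expr_matrix].
#' @export
read_expr_matrix <- function(path, state = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "# state:")) {
    file_state <- trimws(sub("# state:", "", first, fixed = TRUE))
    if (is.null(state)) state <- file_state
    skip <- 1L
  }
  if (is.null(state)) state <- "raw"
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          row.names = 1L)
  expr_matrix(as.matrix(df), state = state)
}

#' @rdname read_expr_matrix
#' @param em an [expr_matrix].
#' @export
write_expr_matrix <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# state: ", expr_state(em)), con)
  df <- data.frame(gene = rownames(em), unclass(em), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment annotation CSV
#'
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' Read a ligand-receptor annotation TSV
#'
#' Columns: `pair_id`, `ligand_genes`, `receptor_genes`, `sender_pops`,
#' `receiver_pops`, `direction`; multi-entry fields are `;`-joined.
#' `direction` is `"in"` (TME to tumor) or `"out"` (tumor to TME).
#'
#' @param path file path.
#' @return data.frame with list-columns expanded on demand by the scorer.
#' @export
read_lr_annotation <- function(path) {
  lr <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pair_id", "ligand_genes", "receptor_genes",
              "sender_pops", "receiver_pops", "direction")
  missing <- setdiff(needed, names(lr))
  if (length(missing)) {
    stop("L/R annotation missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lr$pair_id)) stop("duplicate L/R pair ids")
  if (any(!nzchar(lr$ligand_genes)) || any(!nzchar(lr$receptor_genes))) {
    stop("empty ligand or receptor gene list")
  }
  lr
}

#' @rdname read_lr_annotation
#' @param lr L/R annotation data.frame.
#' @export
write_lr_annotation <- function(lr, path) {
  utils::write.table(lr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival cohort CSV
#'
#' Expects columns `sample`, `time_months`, `event`, `score`; any further
#' columns are treated as covariates.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample", "time_months", "event", "score")
  missing <- setdiff(needed, names(co))
  if (length(missing)) {
    stop("cohort missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(co$time_months <= 0)) stop("survival times must be positive")
  if (!all(co$event %in% c(0, 1))) stop("event must be 0/1")
  co
}
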