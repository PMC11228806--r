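# small fixtures built in code, shared across test files

# a tiny probe-count object with known structure
tiny_probe_counts <- function() {
  counts <- rbind(
    A_p1 = c(10, 20), A_p2 = c(12, 22), A_p3 = c(14, 24),
    B_p1 = c(7, 7),
    NEG1 = c(1, 2), NEG2 = c(4, 8), NEG3 = c(16, 2)
  )
  colnames(counts) <- c("S1", "S2")
  probe_counts(counts,
               target_gene = c("A", "A", "A", "B", "NEG", "NEG", "NEG"),
               is_negative = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
}

# deterministic expression matrix fixture
rand_expr <- function(n_genes = 30, n_seg = 10, seed = 42, state = "log2q3") {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_genes * n_seg, 2, 1),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_seg))))
  if (state == "log2q3") m <- log2(m + 1)
  expr_matrix(m, state = state)
}

# small synthetic cohort processed through preprocessing, cached per session
small_cohort <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- synthetic_config(seed = seed)
    sim <- generate_segments(cfg)
    assets <- generate_reference_assets(cfg)
    raw <- collapse_probes(sim$probe_counts)
    loq <- compute_loq(sim$probe_counts)
    qc <- qc_segments(raw, sim$annotation, loq)
    q3 <- q3_normalize(qc$expr, loq = loq)
    lg <- log2_transform(q3)
    tum <- qc$annotation$segment_id[
      qc$annotation$compartment %in% c("tumor", "tumor_only")]
    out <- list(cfg = cfg, sim = sim, assets = assets, qc = qc,
                q3 = q3, log2q3 = lg, tumor_segments = tum)
    cache[[key]] <- out
    out
  }
})

# independent brute-force ssGSEA oracle: direct double loop over positions,
# no shared code with the package implementation
ssgsea_oracle <- function(values, genes, set, alpha) {
  ord <- order(-values, genes)
  g <- genes[ord]
  n <- length(g)
  w <- (n:1)^alpha
  es <- 0
  sum_w_in <- 0
  for (i in seq_len(n)) if (g[i] %in% set) sum_w_in <- sum_w_in + w[i]
  n_out <- n - sum(g %in% set)
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (g[i] %in% set) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    es <- es + cum_in / sum_w_in - cum_out / n_out
  }
  es
}
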