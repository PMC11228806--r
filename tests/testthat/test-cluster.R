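make_blobs <- function(k, per = 12, dim = 40, sep = 12, noise = 0.5,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim, sd = sep / sqrt(dim)), nrow = k)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(per * dim, sd = noise), ncol = dim), 2,
          centers[i, ], "+")
  }))
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("g%03d", seq_len(dim))
  list(em = expr_matrix(t(x), "log2q3"),
       labels = rep(seq_len(k), each = per))
}

test_that("HVG selection matches a brute-force variance sort", {
  em <- rand_expr(50, 12, seed = 9)
  v <- apply(em, 1, var)
  oracle <- rownames(em)[order(-v, rownames(em))][1:20]
  expect_equal(select_hvg(em, 20), oracle)
  # constant matrix: alphabetical tie-break
  cm <- expr_matrix(matrix(1, 12, 4,
                           dimnames = list(sprintf("g%02d", c(3, 1, 2, 12,
                                                              4:11)),
                                           paste0("s", 1:4))),
                    "log2q3")
  expect_equal(select_hvg(cm, 3), c("g01", "g02", "g03"))
  # single informative gene
  m <- matrix(0, 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m["g4", ] <- rnorm(6, sd = 3)
  expect_equal(select_hvg(expr_matrix(m, "log2q3"), 1), "g4")
  expect_error(select_hvg(em, 0), "positive")
  expect_error(select_hvg(em, 1e4), "exceeds")
})

test_that("elbow selects the planted number of blobs", {
  b3 <- make_blobs(3, per = 12, seed = 2)
  expect_equal(choose_k_elbow(b3$em, k_max = 8, seed = 1)$k, 3)
  b5 <- make_blobs(5, per = 10, seed = 3)
  expect_equal(choose_k_elbow(b5$em, k_max = 9, seed = 1)$k, 5)
  # identical points: WSS all ~0, k = 1 by convention
  same <- expr_matrix(matrix(2, 8, 12,
                             dimnames = list(paste0("g", 1:8),
                                             paste0("s", 1:12))),
                      "log2q3")
  res <- choose_k_elbow(same, k_max = 4, seed = 1)
  expect_equal(res$k, 1L)
  expect_true(all(res$wss_per_k < 1e-10))
  expect_error(choose_k_elbow(b3$em, k_max = 40, seed = 1), "fewer segments")
  expect_error(choose_k_elbow(b3$em, k_max = 2, seed = 1), "at least 3")
})

test_that("WSS is nonincreasing in k and k-means recovers planted blobs", {
  b <- make_blobs(3, per = 10, seed = 5)
  res <- choose_k_elbow(b$em, k_max = 7, seed = 2)
  expect_true(all(diff(res$wss_per_k) < 1e-8))
  cl <- kmeans_cluster(b$em, 3, seed = 7)
  expect_equal(mclust::adjustedRandIndex(cl$labels, b$labels), 1.0)
  # determinism: same seed twice gives identical labels
  cl2 <- kmeans_cluster(b$em, 3, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  # k = 1: WSS equals the total sum of squares around the centroid
  cl1 <- kmeans_cluster(b$em, 1, seed = 1)
  x <- t(unclass(b$em))
  expect_equal(cl1$wss, sum(sweep(x, 2, colMeans(x))^2))
  expect_error(kmeans_cluster(b$em, 999, seed = 1), "exceeds")
})

test_that("many restarts never do worse than a single restart", {
  b <- make_blobs(4, per = 8, dim = 10, sep = 4, noise = 1.5, seed = 11)
  one <- kmeans_cluster(b$em, 4, seed = 3, attempts = 1)
  many <- kmeans_cluster(b$em, 4, seed = 3, attempts = 200)
  expect_lte(many$wss, one$wss + 1e-8)
})

test_that("orienting score renumbers clusters so the last is highest", {
  b <- make_blobs(3, per = 10, seed = 8)
  score <- stats::setNames(rnorm(30, mean = rep(c(10, 0, 5), each = 10)),
                           colnames(b$em))
  cl <- kmeans_cluster(b$em, 3, seed = 1, orient_by = score)
  means <- tapply(score[names(cl$labels)], cl$labels, mean)
  expect_true(all(diff(means) > 0))
})

test_that("PCA reconstructs the centered matrix and orients loadings", {
  em <- rand_expr(25, 15, seed = 21)
  p <- run_pca(em)
  x <- t(unclass(em))
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, sweep(x, 2, p$center), tolerance = 1e-6,
               ignore_attr = TRUE)
  # orthonormal loading columns, nonincreasing explained variance
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance_fraction) < 1e-12))
  # orientation: largest |loading| gene is positive on each component
  for (c in 1:2) {
    j <- which.max(abs(p$loadings[, c]))
    expect_gt(p$loadings[j, c], 0)
  }
})

test_that("PC signature extraction obeys the axis and sign rules", {
  # identity loadings on 2 genes: gene1 -> sig1, gene2 -> sig2, sig3 empty
  fake <- list(loadings = diag(2))
  rownames(fake$loadings) <- c("gene1", "gene2")
  sigs <- extract_pc_signatures(fake)
  expect_equal(sigs$sig_cluster1$gene, "gene1")
  expect_equal(sigs$sig_cluster2$gene, "gene2")
  expect_equal(nrow(sigs$sig_cluster3), 0)

  # flipping PC2 swaps sig2 and sig3 exactly
  em <- rand_expr(40, 18, seed = 31)
  p <- run_pca(em)
  s1 <- extract_pc_signatures(p)
  p2 <- p
  p2$loadings[, 2] <- -p2$loadings[, 2]
  s2 <- extract_pc_signatures(p2)
  expect_equal(s1$sig_cluster2$gene, s2$sig_cluster3$gene)
  expect_equal(s1$sig_cluster3$gene, s2$sig_cluster2$gene)
  expect_equal(s1$sig_cluster1$gene, s2$sig_cluster1$gene)

  # signatures are pairwise disjoint
  expect_length(intersect(s1$sig_cluster1$gene, s1$sig_cluster2$gene), 0)
  expect_length(intersect(s1$sig_cluster2$gene, s1$sig_cluster3$gene), 0)
  expect_length(intersect(s1$sig_cluster1$gene, s1$sig_cluster3$gene), 0)

  expect_error(extract_pc_signatures(list(loadings = matrix(0, 3, 2))),
               "degenerate")
})

test_that("planted phenotype programs are recovered by PC contributions", {
  co <- small_cohort(1)
  em_t <- expr_matrix(unclass(co$log2q3)[, co$tumor_segments], "log2q3")
  hvg <- select_hvg(em_t, 500)
  pca <- run_pca(em_t, genes = hvg)
  sigs <- extract_pc_signatures(pca, universe = hvg)
  sl <- list(sigs$sig_cluster1$gene, sigs$sig_cluster2$gene,
             sigs$sig_cluster3$gene)
  # signatures matched to programs by maximal overlap (the PCA rotation
  # decides which program lands on which axis/sign cell)
  for (pg in co$sim$truth$signature_genes) {
    rec <- max(vapply(sl, function(x)
      length(intersect(x, pg)) / length(pg), numeric(1)))
    expect_gte(rec, 0.8)
  }
})

test_that("TME segments inherit the paired tumor cluster through regions", {
  co <- small_cohort(1)
  em_t <- expr_matrix(unclass(co$log2q3)[, co$tumor_segments], "log2q3")
  hvg <- select_hvg(em_t, 500)
  ne <- ne_score(em_t, co$assets$ne_profile, co$assets$nonne_profile)
  cl <- kmeans_cluster(em_t, 3, seed = 1, genes = hvg, orient_by = ne)
  tme <- assign_tme_clusters(cl, co$qc$annotation)
  expect_equal(length(tme), 30)
  expect_false(anyNA(tme))
  # inherited label equals the paired tumor's planted phenotype mapping
  ann <- co$qc$annotation
  tme_ann <- ann[ann$compartment == "TME", ]
  tum_ann <- ann[ann$compartment == "tumor", ]
  paired_tumor <- tum_ann$segment_id[match(tme_ann$region_id,
                                           tum_ann$region_id)]
  expect_equal(unname(tme[tme_ann$segment_id]),
               unname(cl$labels[paired_tumor]))

  # a TME segment whose region lacks a labeled tumor is unassigned
  ann2 <- data.frame(
    segment_id = c("t1", "m1", "m2"),
    compartment = c("tumor", "TME", "TME"),
    patient_id = "p1", region_id = c("r1", "r1", "r2"),
    area = 1, nuclei = 10, saturation = 0.9
  )
  labs <- stats::setNames(2L, "t1")
  out <- assign_tme_clusters(labs, ann2)
  expect_equal(unname(out["m1"]), 2L)
  expect_true(is.na(out["m2"]))
})

test_that("cluster markers combine Wilcoxon p with linear fold change", {
  set.seed(17)
  n1 <- 10; n2 <- 20
  base <- matrix(rlnorm(30 * 5, 3, 0.2), nrow = 5)
  m <- base
  m[1, 1:n1] <- m[1, 1:n1] * 4   # planted 4x shift in cluster A
  rownames(m) <- paste0("g", 1:5)
  colnames(m) <- paste0("s", 1:30)
  em <- expr_matrix(log2(m + 1), "log2q3")
  labels <- stats::setNames(rep(c(1, 2), c(n1, n2)), colnames(m))
  mk <- cluster_markers(em, labels)
  g1 <- mk[mk$gene == "g1" & mk$cluster == 1, ]
  expect_true(g1$is_marker)
  expect_equal(g1$log2fc, 2, tolerance = 0.35)
  # identical distributions produce no markers
  b0 <- log2(base + 1)
  dimnames(b0) <- list(paste0("g", 1:5), paste0("s", 1:30))
  em0 <- expr_matrix(b0, "log2q3")
  mk0 <- cluster_markers(em0, labels)
  expect_false(any(mk0$is_marker))
})

test_that("Wilcoxon p matches the exact permutation null at tiny n", {
  # brute-force oracle: enumerate all assignments of 4 vs 4 samples and
  # compare the rank-sum tail probability with the normal-approximation p
  set.seed(23)
  x <- rnorm(4, 2); y <- rnorm(4)
  vals <- c(x, y)
  rank_sum <- sum(rank(vals)[1:4])
  combs <- combn(8, 4)
  null_sums <- apply(combs, 2, function(idx) sum(rank(vals)[idx]))
  exact_p <- mean(abs(null_sums - mean(null_sums)) >=
                    abs(rank_sum - mean(null_sums)) - 1e-12)
  w <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(w, exact_p, tolerance = 1e-10)
})
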