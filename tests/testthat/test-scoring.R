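test_that("ssGSEA worked example: singleton top-gene set scores ES = 2", {
  m <- matrix(c(8, 5, 3, 1), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "s1"))
  em <- expr_matrix(m, "log2q3")
  sc <- suppressWarnings(ssgsea(em, gene_sets(list(top = "a")),
                                alpha = 0.7))
  expect_equal(unname(sc["top", "s1"]), 2.0, tolerance = 1e-12)
})

test_that("ssGSEA matches an independent double-loop oracle", {
  set.seed(12)
  em <- rand_expr(60, 8, seed = 12)
  sets <- gene_sets(lapply(stats::setNames(1:6, paste0("set", 1:6)),
                           function(i) sample(rownames(em), 5 + i)))
  sc <- ssgsea(em, sets, alpha = 0.25)
  for (k in names(sets)) {
    for (s in colnames(em)) {
      expect_equal(sc[k, s],
                   ssgsea_oracle(em[, s], rownames(em), sets[[k]], 0.25),
                   tolerance = 1e-10)
    }
  }
})

test_that("ssGSEA is rank-based: monotone maps and duplicates behave", {
  em <- rand_expr(40, 5, seed = 13)
  sets <- gene_sets(list(s1 = rownames(em)[c(3, 9, 20)],
                         s2 = rownames(em)[c(1, 2, 30, 35)]))
  sc <- ssgsea(em, sets)
  # strictly monotone transformation of each sample leaves scores unchanged
  em2 <- expr_matrix(exp(unclass(em) / 3) + 5, "log2q3")
  expect_equal(unclass(ssgsea(em2, sets)), unclass(sc), tolerance = 1e-12)
  # identical samples give identical columns
  em3 <- expr_matrix(cbind(a = em[, 1], b = em[, 1]), "log2q3")
  sc3 <- ssgsea(em3, sets)
  expect_equal(sc3[, "a"], sc3[, "b"])
  # normalization divides by the global range
  scn <- ssgsea(em, sets, normalize = TRUE)
  rng <- diff(range(sc))
  expect_equal(unclass(scn), unclass(sc) / rng, tolerance = 1e-12)
  # zero-overlap set reported missing with warning
  expect_warning(s0 <- ssgsea(em, gene_sets(list(none = c("zz1", "zz2")))),
                 "zero overlap")
  expect_true(all(is.na(s0["none", ])))
})

test_that("NE score contrasts correlations with the two reference profiles", {
  set.seed(14)
  prof <- stats::setNames(rnorm(20), paste0("g", 1:20))
  m <- cbind(s1 = prof, s2 = rnorm(20))
  em <- expr_matrix(m, "log2q3")
  sc <- ne_score(em, prof, -prof)
  expect_equal(unname(sc["s1"]), 1.0, tolerance = 1e-12)
  # antisymmetry under swapping the profiles
  sc_sw <- ne_score(em, -prof, prof)
  expect_equal(unname(sc_sw), unname(-sc), tolerance = 1e-12)
  # zero-variance segment is NA with warning
  em0 <- expr_matrix(cbind(s1 = prof, s2 = rep(1, 20)), "log2q3")
  expect_warning(sc0 <- ne_score(em0, prof, -prof), "zero-variance")
  expect_true(is.na(sc0["s2"]))
  expect_error(ne_score(em, prof[1:2], -prof[1:2]), "fewer than 3")
})

test_that("planted NE segments outscore non-NE segments across seeds", {
  wins <- vapply(1:10, function(s) {
    co <- small_cohort(s)
    em <- expr_matrix(unclass(co$log2q3)[, co$tumor_segments], "log2q3")
    ne <- ne_score(em, co$assets$ne_profile, co$assets$nonne_profile)
    ph <- co$sim$truth$segment_phenotypes[co$tumor_segments]
    mean(ne[ph == "NE"]) > mean(ne[ph == "nonNE"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("purity model is exact on noiseless data and clamps predictions", {
  set.seed(15)
  st <- runif(50); im <- runif(50)
  pur <- pmin(pmax(0.9 - 0.3 * st - 0.4 * im, 0), 1)
  pm <- fit_purity_model(data.frame(stromal = st, immune = im, purity = pur))
  expect_equal(pm$intercept, 0.9, tolerance = 1e-8)
  expect_equal(pm$beta_stromal, -0.3, tolerance = 1e-8)
  expect_equal(pm$beta_immune, -0.4, tolerance = 1e-8)
  expect_equal(pm$training_r2, 1, tolerance = 1e-8)
  pr <- predict_purity(pm, list(stromal = c(0, 3), immune = c(0, 3)))
  expect_equal(pr$purity[1], 0.9)
  expect_equal(pr$purity[2], 0)       # clamped from below
  expect_true(pr$clamped[2])
  expect_error(fit_purity_model(data.frame(stromal = st, immune = st,
                                           purity = pur)), "collinear")
})

test_that("purity coefficients are nearly unbiased under noise", {
  est <- t(sapply(1:50, function(s) {
    set.seed(s + 1000)
    st <- runif(100); im <- runif(100)
    pur <- pmin(pmax(0.9 - 0.3 * st - 0.4 * im + rnorm(100, 0, 0.05), 0), 1)
    pm <- fit_purity_model(data.frame(stromal = st, immune = im,
                                      purity = pur))
    c(pm$beta_stromal, pm$beta_immune)
  }))
  expect_lt(abs(mean(est[, 1]) + 0.3), 0.02)
  expect_lt(abs(mean(est[, 2]) + 0.4), 0.02)
})

test_that("Shannon index has the textbook values and maxima", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  # uniform maximizes H' over its support
  for (n in 2:10) {
    set.seed(n)
    p <- runif(n); p <- p / sum(p)
    expect_lte(shannon_index(p), log(n) + 1e-12)
  }
  expect_warning(h <- shannon_index(c(2, 2)), "renormalized")
  expect_equal(h, log(2))
  expect_error(shannon_index(c(-0.1, 1.1)), "non-negative")
})

test_that("H-score is the weighted staining sum bounded by 300", {
  expect_equal(h_score(0, 0, 100), 300)
  expect_equal(h_score(0, 0, 0), 0)
  expect_equal(h_score(50, 30, 20), 170)
  expect_error(h_score(60, 30, 20), "more than 100")
  expect_error(h_score(-5, 0, 0), "non-negative")
  set.seed(16)
  for (i in 1:25) {
    x <- diff(c(0, sort(runif(3, 0, 100)))) # random valid triple
    expect_equal(h_score(x[1], x[2], x[3]), x[1] + 2 * x[2] + 3 * x[3])
  }
})

test_that("preranked GSEA ES matches a direct cumulative-sum oracle", {
  set.seed(18)
  metric <- stats::setNames(sort(rnorm(30), decreasing = TRUE),
                            paste0("g", 1:30))
  set <- c("g2", "g5", "g9")
  res <- preranked_gsea(metric, gene_sets(list(s = set)), n_perm = 100,
                        seed = 1)
  # oracle: running weighted hit CDF minus miss CDF, maximum deviation
  ins <- names(metric) %in% set
  p_hit <- cumsum(abs(metric) * ins) / sum(abs(metric) * ins)
  p_miss <- cumsum(!ins) / sum(!ins)
  dev <- p_hit - p_miss
  expect_equal(res$es, dev[which.max(abs(dev))], tolerance = 1e-12,
               ignore_attr = TRUE)
  # fgsea computes the same statistic (independent implementation)
  skip_if_not_installed("fgsea")
  es_fgsea <- fgsea::calcGseaStat(unname(metric),
                                  selectedStats = which(ins),
                                  gseaParam = 1)
  expect_equal(res$es, es_fgsea, tolerance = 1e-10)
})

test_that("top-of-ranking sets maximize ES among same-size sets", {
  set.seed(19)
  metric <- stats::setNames(sort(rexp(12), decreasing = TRUE),
                            letters[1:12])
  sets <- combn(letters[1:12], 3, simplify = FALSE)
  ess <- vapply(sets, function(s) {
    suppressWarnings(
      preranked_gsea(metric, gene_sets(list(x = s)), n_perm = 100,
                     seed = 1)$es)
  }, numeric(1))
  top_idx <- which(vapply(sets, function(s)
    setequal(s, c("a", "b", "c")), logical(1)))
  expect_equal(which.max(ess), top_idx)
  expect_gt(ess[top_idx], 0)
})

test_that("preranked GSEA p-values are calibrated under the null", {
  set.seed(20)
  pvals <- vapply(1:60, function(i) {
    metric <- stats::setNames(rnorm(40), paste0("g", 1:40))
    s <- sample(names(metric), 8)
    preranked_gsea(metric, gene_sets(list(x = s)), n_perm = 200,
                   seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signed log-p ranking is order invariant with floored zeros", {
  mk <- data.frame(gene = c("a", "b", "c"), p = c(0.01, 0.01, 0.5),
                   log2fc = c(1, -1, 0.2))
  r <- rank_by_signed_logp(mk)
  expect_equal(unname(r["a"]), 2)
  expect_equal(unname(r["b"]), -2)
  # permuting rows changes nothing
  r2 <- rank_by_signed_logp(mk[c(3, 1, 2), ])
  expect_identical(r, r2)
  expect_warning(rz <- rank_by_signed_logp(
    data.frame(gene = letters[1:3], p = c(0, 0.5, 1),
               log2fc = c(2, 1, -1))), "floored")
  expect_true(is.finite(rz["a"]))
})

test_that("pairwise signature correlation matches cor() and orders rows", {
  set.seed(22)
  sc <- matrix(rnorm(100), 5, 20,
               dimnames = list(paste0("set", 1:5), paste0("s", 1:20)))
  res <- pairwise_signature_correlation(sc)
  expect_equal(res$r, cor(t(sc)), tolerance = 1e-12)
  # duplicated set: r = 1; negated set: r = -1
  sc2 <- rbind(sc, dup = sc[1, ], neg = -sc[1, ])
  res2 <- pairwise_signature_correlation(sc2)
  expect_equal(res2$r["set1", "dup"], 1)
  expect_equal(res2$r["set1", "neg"], -1)
  # zero-variance rows are excluded with a warning
  sc3 <- rbind(sc, flat = rep(1, 20))
  expect_warning(res3 <- pairwise_signature_correlation(sc3), "flat")
  expect_false("flat" %in% rownames(res3$r))
})
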