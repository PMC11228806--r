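lr_fixture <- function() {
  data.frame(
    pair_id = c("p1", "p2", "p3"),
    ligand_genes = c("L1", "L2a;L2b", "Lmiss"),
    receptor_genes = c("R1", "R2", "R3"),
    sender_pops = c("CAF", "Macrophage", "CAF"),
    receiver_pops = "Tumor",
    direction = c("in", "in", "out"),
    stringsAsFactors = FALSE
  )
}

test_that("pair score is the geometric-mean square root on [0, 10]", {
  sender <- c(L1 = 4, L2a = 2, L2b = 8)
  receiver <- c(R1 = 9, R2 = 5)
  # single-subunit activities (4, 9) -> sqrt(36) = 6
  expect_equal(lr_pair_score(sender, receiver, "L1", "R1"), 6)
  # multi-subunit ligand activity is the geometric mean
  expect_equal(lr_pair_score(sender, receiver, c("L2a", "L2b"), "R2"),
               sqrt(4 * 5))
  # zero activity on either side gives 0
  expect_equal(lr_pair_score(c(L1 = 0), c(R1 = 9), "L1", "R1"), 0)
  # missing subunit yields NA, not 0
  expect_true(is.na(lr_pair_score(sender, receiver, "Lmiss", "R1")))
  expect_error(lr_pair_score(c(L1 = -1), receiver, "L1", "R1"), "negative")
  # symmetry under exchanging roles
  expect_equal(lr_pair_score(sender, receiver, "L1", "R1"),
               lr_pair_score(receiver, sender, "R1", "L1"))
})

test_that("rescaled expression bounds all pair scores by 10", {
  set.seed(41)
  m <- matrix(rlnorm(40, 4, 1), 8, 5,
              dimnames = list(c("L1", "L2a", "L2b", "R1", "R2", "R3",
                                "x1", "x2"), paste0("s", 1:5)))
  resc <- rescale_expression(expr_matrix(m, "q3"))
  expect_true(all(resc >= 0 & resc <= 10))
  expect_equal(max(resc["L1", ]), 10)
  # constant gene maps to zero
  m2 <- m; m2["x1", ] <- 3
  expect_true(all(rescale_expression(expr_matrix(m2, "q3"))["x1", ] == 0))
})

test_that("region pair scores flow tumor/TME directions correctly", {
  co <- small_cohort(1)
  ps <- score_lr_pairs(co$log2q3, co$qc$annotation,
                       co$assets$lr_annotation)
  expect_true(all(c("region", "direction", "pair_id", "score") %in%
                    names(ps)))
  expect_equal(length(unique(ps$region)), 30)  # paired regions post-QC
  expect_true(all(ps$score >= 0 & ps$score <= 10, na.rm = TRUE))
})

test_that("population summary takes the max and dominates mean-of-min", {
  ps <- data.frame(
    region = "r1", direction = "in",
    pair_id = c("a", "b", "c"),
    sender_pop = "CAF", receiver_pop = "Tumor",
    ligand_activity = c(1, 9.8, 4),
    receptor_activity = c(4, 5, 7),
    score = c(2, 7, 5)
  )
  mx <- summarize_population_interactions(ps, "max")
  expect_equal(mx$summary, 7)
  mm <- summarize_population_interactions(ps, "mean_of_min")
  expect_equal(mm$summary, mean(c(1, 5, 4)))
  expect_lte(mm$summary, mx$summary)
  # single mapped pair: summary equals that pair's score
  one <- summarize_population_interactions(ps[1, ], "max")
  expect_equal(one$summary, 2)
  # property on random tables: max >= mean-of-min for every population
  set.seed(43)
  for (i in 1:10) {
    lig <- runif(6, 0, 10); rec <- runif(6, 0, 10)
    tab <- data.frame(region = "r", direction = "in",
                      pair_id = letters[1:6],
                      sender_pop = rep(c("A", "B"), 3),
                      receiver_pop = "Tumor",
                      ligand_activity = lig, receptor_activity = rec,
                      score = sqrt(lig * rec))
    a <- summarize_population_interactions(tab, "max")
    b <- summarize_population_interactions(tab, "mean_of_min")
    expect_true(all(a$summary >= b$summary - 1e-12))
  }
})

test_that("identical groups yield no significant differential pairs", {
  set.seed(44)
  regions <- paste0("r", 1:12)
  ps <- expand.grid(region = regions, pair_id = paste0("p", 1:8),
                    stringsAsFactors = FALSE)
  ps$direction <- "in"; ps$sender_pop <- "CAF"; ps$receiver_pop <- "Tumor"
  ps$ligand_activity <- runif(nrow(ps), 0, 10)
  ps$receptor_activity <- runif(nrow(ps), 0, 10)
  ps$score <- sqrt(ps$ligand_activity * ps$receptor_activity)
  groups <- stats::setNames(rep(c("g1", "g2"), 6), regions)
  di <- differential_interactions(ps, groups)
  expect_false(any(di$fdr_bh < 0.05))
  # constant pair scores get p = 1
  ps2 <- ps; ps2$score[ps2$pair_id == "p1"] <- 5
  di2 <- differential_interactions(ps2, groups)
  expect_equal(di2$p[di2$pair_id == "p1"], 1)
})

test_that("a planted shifted pair is detected and labeled by direction", {
  detect <- vapply(1:10, function(s) {
    set.seed(s + 500)
    regions <- paste0("r", 1:12)
    ps <- expand.grid(region = regions, pair_id = paste0("p", 1:10),
                      stringsAsFactors = FALSE)
    ps$direction <- ifelse(as.integer(sub("p", "", ps$pair_id)) %% 2 == 1,
                           "in", "out")
    ps$sender_pop <- "CAF"; ps$receiver_pop <- "Tumor"
    ps$score <- runif(nrow(ps), 0, 3)
    groups <- stats::setNames(rep(c("nonNE", "NE_hybrid"), each = 6),
                              regions)
    shift <- ps$pair_id == "p1" & groups[ps$region] == "nonNE"
    ps$score[shift] <- ps$score[shift] + 5
    ps$ligand_activity <- ps$score; ps$receptor_activity <- ps$score
    di <- differential_interactions(ps, groups)
    di$fdr_bh[di$pair_id == "p1"] < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.9)
})

test_that("planted active pairs surface as the significant interactions", {
  co <- small_cohort(1)
  ps <- score_lr_pairs(co$log2q3, co$qc$annotation, co$assets$lr_annotation)
  ann <- co$qc$annotation
  tum <- ann[ann$compartment == "tumor", ]
  ph <- co$sim$truth$segment_phenotypes[tum$segment_id]
  groups <- stats::setNames(ifelse(ph == "nonNE", "nonNE", "NE_hybrid"),
                            tum$region_id)
  di <- differential_interactions(ps[ps$region %in% names(groups), ],
                                  groups)
  hits <- di$pair_id[di$fdr_bh < 0.05]
  expect_true(all(co$sim$truth$active_lr_pairs %in% hits))
  # the planted pairs are over-represented in the non-NE ecosystem
  act <- di$pair_id %in% co$sim$truth$active_lr_pairs
  expect_true(all(di$median_diff[act] > 0))
  # and they dominate the significant calls
  expect_gte(mean(hits %in% co$sim$truth$active_lr_pairs), 0.5)
})

test_that("permuting region labels destroys the planted signal", {
  co <- small_cohort(1)
  ps <- score_lr_pairs(co$log2q3, co$qc$annotation, co$assets$lr_annotation)
  ann <- co$qc$annotation
  tum <- ann[ann$compartment == "tumor", ]
  ph <- co$sim$truth$segment_phenotypes[tum$segment_id]
  groups <- stats::setNames(ifelse(ph == "nonNE", "nonNE", "NE_hybrid"),
                            tum$region_id)
  ps <- ps[ps$region %in% names(groups), ]
  set.seed(45)
  n_sig <- vapply(1:20, function(i) {
    perm <- stats::setNames(sample(groups), names(groups))
    sum(differential_interactions(ps, perm)$fdr_bh < 0.05)
  }, numeric(1))
  expect_lt(mean(n_sig > 0), 0.25)
})
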