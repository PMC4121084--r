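test_that("-dCt arithmetic references the per-sample control mean", {
  design <- stage_design(c("MII", "1cell"), 1L, "mouse")
  ct <- make_ct(matrix(c(25, 20, 22, 21,     # MII_1: gene 25, ctrls 20/22, g2 21
                         NA, 20, 22, 21),    # 1cell_1: gene undetected
                       ncol = 2),
                design, assay_ids = c("gene", "Hprt1", "Psmb6", "g2"))
  nd <- neg_delta_ct(ct, c("Hprt1", "Psmb6"))
  expect_equal(nd$neg_delta_ct[nd$assay_id == "gene" & nd$sample == "MII_1"], -4)
  expect_equal(nd$neg_delta_ct[nd$assay_id == "g2" & nd$sample == "MII_1"], 0)
  # undetected cell computed with Ct 40: -(40 - 21) = -19, flagged by `detected`
  und <- nd[nd$assay_id == "gene" & nd$sample == "1cell_1", ]
  expect_equal(und$neg_delta_ct, -19)
  expect_false(und$detected)
})

test_that("-dCt is invariant to per-sample Ct offsets", {
  design <- stage_design(c("MII", "1cell"), 2L, "mouse")
  set.seed(61)
  base <- matrix(runif(16, 20, 30), nrow = 4)
  ct <- make_ct(base, design, c("a", "b", "Hprt1", "Psmb6"))
  shifted <- make_ct(sweep(base, 2, c(1, -2, 5, 0.5), "+"), design,
                     c("a", "b", "Hprt1", "Psmb6"))
  nd1 <- neg_delta_ct(ct, c("Hprt1", "Psmb6"))
  nd2 <- neg_delta_ct(shifted, c("Hprt1", "Psmb6"))
  expect_equal(nd1$neg_delta_ct, nd2$neg_delta_ct, tolerance = 1e-12)
})

test_that("undetected controls are an error naming the sample", {
  design <- stage_design("MII", 1L, "mouse")
  ct <- make_ct(matrix(c(25, NA, 22), ncol = 1), design,
                c("gene", "Hprt1", "Psmb6"))
  expect_error(neg_delta_ct(ct, c("Hprt1", "Psmb6")), "MII_1")
  expect_error(neg_delta_ct(ct, c("Hprt1", "Gapdh")), "Gapdh")
})

test_that("floor imputation uses the lowest detected non-control value", {
  design <- stage_design(c("MII", "1cell"), 1L, "mouse")
  # detected -dCt values: gene1 MII -14.8 (ct 35.8 vs ctrl 21); gene2 -4
  ct <- make_ct(matrix(c(35.8, 25, 20, 22,
                         NA,  25, 20, 22), ncol = 2),
                design, c("g1", "g2", "Hprt1", "Psmb6"))
  nd <- impute_undetected(neg_delta_ct(ct, c("Hprt1", "Psmb6")))
  expect_equal(attr(nd, "floor_value"), -14.8)
  imputed <- nd[nd$assay_id == "g1" & nd$sample == "1cell_1", ]
  expect_true(imputed$imputed)
  expect_equal(imputed$neg_delta_ct, -14.8)
  # after imputation the non-control table minimum equals the floor
  noctrl <- nd[!nd$assay_id %in% c("Hprt1", "Psmb6"), ]
  expect_equal(min(noctrl$neg_delta_ct), -14.8)
  # a table without undetected cells is unchanged
  ct2 <- make_ct(matrix(c(30, 25, 20, 22), ncol = 1),
                 stage_design("MII", 1L, "mouse"),
                 c("g1", "g2", "Hprt1", "Psmb6"))
  nd2 <- neg_delta_ct(ct2, c("Hprt1", "Psmb6"))
  expect_equal(impute_undetected(nd2)$neg_delta_ct, nd2$neg_delta_ct)
})

test_that("plotting averages drop undetected replicates unless all are undetected", {
  design <- stage_design(c("MII", "1cell"), c(3L, 3L), "mouse")
  # gene g: MII replicates -4, -5, undetected; 1cell all undetected
  gene_ct <- c(25, 26, NA, NA, NA, NA)
  ctrl <- rep(21, 6)
  mat <- rbind(gene_ct, ctrl, ctrl, c(30, 30, 30, 30, 30, 6.2))
  ct <- make_ct(mat, design, c("g", "Hprt1", "Psmb6", "low"))
  nd <- impute_undetected(neg_delta_ct(ct, c("Hprt1", "Psmb6")))
  avg <- qpcr_stage_averages(nd)
  g_mii <- avg[avg$assay_id == "g" & avg$stage == "MII", ]
  expect_equal(g_mii$mean_ndct, -4.5)
  expect_equal(g_mii$n_detected, 2)
  g_1c <- avg[avg$assay_id == "g" & avg$stage == "1cell", ]
  expect_true(g_1c$all_undetected)
  expect_equal(g_1c$mean_ndct, attr(nd, "floor_value"))
  full <- avg[avg$assay_id == "low" & avg$stage == "MII", ]
  expect_equal(full$mean_ndct, -9)
})

test_that("stage-pair tests include imputed values but gate on detection", {
  design <- stage_design(c("MII", "1cell"), c(3L, 3L), "mouse")
  ctrl <- rep(20, 6)
  mat <- rbind(
    c(24, 25, 26, 30, 31, 32),   # fully detected, clear decrease
    c(24, 25, NA, 26, 27, 28),   # one undetected at MII: still >= 2 detected
    c(24, NA, NA, 26, 27, 28),   # only one detected at MII: skipped
    ctrl, ctrl
  )
  ct <- make_ct(mat, design, c("clear", "partial", "thin", "Hprt1", "Psmb6"))
  nd <- impute_undetected(neg_delta_ct(ct, c("Hprt1", "Psmb6")))
  res <- stage_pair_tests(nd)
  expect_equal(res$status[res$feature_id == "thin"], "skipped")
  expect_equal(res$status[res$feature_id == "partial"], "tested")
  # oracle: imputed replicate participates at the floor value
  floor <- attr(nd, "floor_value")
  x_mii <- c(-4, -5, floor)
  x_1c <- c(-6, -7, -8)
  tt <- t.test(x_1c, x_mii, var.equal = TRUE)
  row <- res[res$feature_id == "partial", ]
  expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  clear <- res[res$feature_id == "clear", ]
  expect_lt(clear$p_value, 0.01)
  expect_lt(clear$log_fc, 0)
})

test_that("identical stages give p = 1 and strong separation p < 1e-6", {
  design <- stage_design(c("1cell", "2cell"), 3L, "mouse")
  ctrl <- rep(20, 6)
  mat <- rbind(
    c(24, 25, 26, 24, 25, 26),                    # identical -> p = 1
    c(30, 30.1, 29.9, 22, 22.1, 21.9),            # -dCt -10 vs -2
    ctrl, ctrl
  )
  ct <- make_ct(mat, design, c("same", "jump", "Hprt1", "Psmb6"))
  res <- stage_pair_tests(impute_undetected(neg_delta_ct(ct, c("Hprt1", "Psmb6"))))
  expect_equal(res$p_value[res$feature_id == "same"], 1)
  jump <- res[res$feature_id == "jump", ]
  expect_lt(jump$p_value, 1e-6)
  expect_gt(jump$log_fc, 0)
  expect_error(
    stage_pair_tests(impute_undetected(neg_delta_ct(ct, c("Hprt1", "Psmb6"))),
                     pairs = tibble::tibble(earlier = "MII", later = "2cell")),
    "Unknown stage"
  )
})
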