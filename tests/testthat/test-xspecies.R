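# mouse transition evidence builder over the default MII/1c/2c/8c course
mouse_evidence <- function(mouse_gene, sig) {
  tr <- make_transitions(mouse_gene, mouse_design(), sig)
  tr$q_value <- tr$p_value
  tr
}

test_that("ortholog mapping joins, drops and duplicates as specified", {
  calls <- tibble::tibble(gene_id = c("A", "B", "C"),
                          call = c("UP", "DOWN", "UP_DOWN"))
  map <- tibble::tibble(human_gene = c("A", "B", "B"),
                        mouse_gene = c("a1", "b1", "b2"))
  expect_message(pairs <- map_orthologs(calls, map), "1 gene")
  expect_equal(nrow(pairs), 3)                      # B maps to two mouse genes
  expect_equal(sum(pairs$human_gene == "B"), 2)
  expect_identical(attr(pairs, "dropped"), "C")
})

test_that("concordance verdicts follow the per-class rules", {
  pair <- function(cls) tibble::tibble(human_gene = "H", mouse_gene = "m",
                                       human_class = cls)
  verdict <- function(cls, sig, ...) {
    classify_concordance(pair(cls), mouse_evidence("m", sig), ...)$verdict
  }
  # human UP: the 1-cell -> 2-cell upregulation decides
  expect_equal(verdict("UP", c("1cell->2cell" = 2)), "SIMILAR")
  expect_equal(verdict("UP", c("2cell->8cell" = -2)), "DIFFERENT_MATERNAL")
  expect_equal(verdict("UP", c("1cell->2cell" = -2)), "DIFFERENT_MATERNAL")
  expect_equal(verdict("UP", c()), "UNCLASSIFIED")
  # human UP_DOWN: needs both the rise and the fall
  expect_equal(verdict("UP_DOWN", c("1cell->2cell" = 2, "2cell->8cell" = -2)),
               "SIMILAR")
  expect_equal(verdict("UP_DOWN", c("1cell->2cell" = 2)), "UNCLASSIFIED")
  expect_equal(verdict("UP_DOWN", c("1cell->2cell" = 2), relax_updown = TRUE),
               "SIMILAR")
  expect_equal(verdict("UP_DOWN", c("2cell->8cell" = -2)), "DIFFERENT_MATERNAL")
  # human DOWN: any decrease and no increase
  expect_equal(verdict("DOWN", c("1cell->2cell" = -2)), "SIMILAR")
  expect_equal(verdict("DOWN", c("MII->1cell" = -2, "2cell->8cell" = -1)),
               "SIMILAR")
  expect_equal(verdict("DOWN", c("1cell->2cell" = 2, "2cell->8cell" = -2)),
               "DIFFERENT_MATERNAL")
  expect_equal(verdict("DOWN", c()), "UNCLASSIFIED")
})

test_that("a skipped or non-significant ZGA transition never yields SIMILAR for UP", {
  pair <- tibble::tibble(human_gene = "H", mouse_gene = "m", human_class = "UP")
  ev <- mouse_evidence("m", c("1cell->2cell" = 2))
  ev$status[ev$earlier == "1cell"] <- "skipped"
  ev$p_value[ev$earlier == "1cell"] <- NA_real_
  expect_false(classify_concordance(pair, ev)$verdict == "SIMILAR")
  ev2 <- mouse_evidence("m", c())
  ev2$log_fc[ev2$earlier == "1cell"] <- 2   # rises, but p stays 0.8
  expect_false(classify_concordance(pair, ev2)$verdict == "SIMILAR")
  # missing evidence is an error, not a silent verdict
  expect_error(classify_concordance(pair, mouse_evidence("other", c())),
               "No mouse transition evidence")
})

test_that("stage correlations behave at the exact and degenerate limits", {
  a <- tibble::tibble(feature_id = c("x", "y", "z"),
                      MII = c(1, 2, 3), `8cell` = c(3, 1, 2))
  expect_equal(pearson_stage_correlation(a, a)$r, c(1, 1))
  flipped <- a
  flipped$MII <- -a$MII
  expect_equal(pearson_stage_correlation(a, flipped)$r[1], -1)
  const <- a
  const$MII <- c(2, 2, 2)
  expect_warning(r <- pearson_stage_correlation(a, const)$r[1], "Zero variance")
  expect_true(is.na(r))
  expect_error(pearson_stage_correlation(a[1:2, ], a[1:2, ]), ">= 3 matched")
})

test_that("hierarchical clustering recovers planted groups deterministically", {
  design_stagesn <- c("MII", "2cell", "8cell")
  set.seed(71)
  lo <- replicate(5, rnorm(3, -5, 0.1), simplify = FALSE)
  hi <- replicate(5, rnorm(3, 5, 0.1), simplify = FALSE)
  data <- tibble::as_tibble(as.data.frame(do.call(rbind, c(lo, hi))))
  names(data) <- design_stagesn
  data <- tibble::add_column(data, feature_id = sprintf("f%02d", 1:10),
                             .before = 1)
  out <- hierarchical_cluster(data, k = 2)
  expect_equal(length(unique(out$cluster[1:5])), 1)
  expect_equal(length(unique(out$cluster[6:10])), 1)
  expect_false(out$cluster[1] == out$cluster[6])
  # identical rows merge at height zero
  dup <- data
  dup[2, -1] <- dup[1, -1]
  hc <- attr(hierarchical_cluster(dup, k = 2), "hclust")
  expect_equal(min(hc$height), 0)
  # permutation equivariance of the k-cut partition
  perm <- sample(10)
  out_p <- hierarchical_cluster(data[perm, ], k = 2)
  agree <- outer(out$cluster[perm], out$cluster[perm], "==") ==
    outer(out_p$cluster, out_p$cluster, "==")
  expect_true(all(agree))
  expect_error(hierarchical_cluster(data, k = 11), "k exceeds")
})

test_that("concordance recovery tracks the planted fraction on simulated data", {
  study <- simulate_study(sim_config(seed = 81, n_per_archetype = 60,
                                     concordant_fraction = 0.5))
  nd <- impute_undetected(neg_delta_ct(study$mouse_ct, c("Hprt1", "Psmb6")))
  tests <- stage_pair_tests(nd)
  human_class <- c(up = "UP", up_down = "UP_DOWN", down = "DOWN")
  pairs <- tibble::tibble(
    human_gene = study$truth$gene_id,
    mouse_gene = study$truth$mouse_gene,
    human_class = dplyr::coalesce(human_class[study$truth$archetype],
                                  "UNCLASSIFIED")
  )
  verdicts <- classify_concordance(pairs, tests)
  classified <- verdicts$verdict != "UNCLASSIFIED"
  expect_gt(mean(classified), 0.9)
  expect_equal(mean(verdicts$verdict[classified] == "SIMILAR"), 0.5,
               tolerance = 0.12)
  # verdicts agree with the planted truth for the overwhelming majority
  merged <- dplyr::inner_join(verdicts, study$truth,
                              by = c(human_gene = "gene_id"))
  acc <- mean((merged$verdict == "SIMILAR") == merged$concordant)
  expect_gt(acc, 0.9)
})
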