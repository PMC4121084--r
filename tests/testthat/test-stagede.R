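test_that("comparative expression follows the control-referencing formula", {
  design <- stage_design("MII", 1L, "human")
  data <- make_expr(list(400, 100, 300, 200), design,
                    ids = c("gene", "ctrl1", "ctrl2", "avg"))
  out <- comparative_expression(data, c("ctrl1", "ctrl2"))
  expect_equal(out$MII_1[out$feature_id == "gene"], 1.0)   # log2(400/200)
  expect_equal(out$MII_1[out$feature_id == "avg"], 0.0)    # equals control mean
  # per-sample scale invariance
  doubled <- data
  doubled$MII_1 <- 2 * doubled$MII_1
  expect_equal(comparative_expression(doubled, c("ctrl1", "ctrl2"))$MII_1,
               out$MII_1)
  expect_error(comparative_expression(data, "nope"), "nope")
  data$MII_1[1] <- -1
  expect_error(comparative_expression(data, c("ctrl1", "ctrl2")), "positive")
})

test_that("bh_fdr reproduces the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing on sorted input
  set.seed(41)
  p <- sort(runif(100))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

test_that("bh_fdr agrees with brute force and p.adjust on random vectors", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- runif(n)^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    if (i <= 50) expect_equal(q, bh_oracle(p), tolerance = 1e-15)
  }
})

test_that("variance moderation follows the posterior formula and its limits", {
  # plug-in posterior: s^2 = [1, 4], df = 2, d0 = 4, s0^2 = 2
  post <- (4 * 2 + 2 * c(1, 4)) / (4 + 2)
  expect_equal(post, c(1.6667, 2.6667), tolerance = 1e-4)
  # equal sample variances drive d0 to infinity and s_tilde to the common value
  fit <- fit_moderated(rep(2.5, 50), rep(4, 50))
  expect_true(is.infinite(fit$d0))
  expect_equal(fit$s_tilde_sq, rep(2.5, 50), tolerance = 1e-9)
  # s_tilde always lies between s^2 and s0^2
  set.seed(43)
  s2 <- 1.5 * stats::rchisq(200, df = 4) / 4
  fit2 <- fit_moderated(s2, rep(4, 200))
  expect_true(all(fit2$s_tilde_sq >= pmin(s2, fit2$s0_sq) - 1e-12))
  expect_true(all(fit2$s_tilde_sq <= pmax(s2, fit2$s0_sq) + 1e-12))
  expect_warning(fit_moderated(c(0, 1), c(2, 2)), "positive variance")
  expect_error(fit_moderated(1, 0.5), "df")
})

test_that("moderation matches the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(44)
  s2 <- 0.8 * stats::rchisq(500, df = 4) / 4
  fit <- fit_moderated(s2, rep(4, 500))
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(fit$s_tilde_sq, sq$var.post, tolerance = 1e-6)
})

test_that("transition tests handle degenerate and separated features", {
  design <- stage_design(c("MII", "4cell"), 3L, "human")
  data <- make_expr(list(
    c(1, 2, 3, 1, 2, 3),        # identical replicate vectors
    c(0, 0, 0, 10, 10, 10),     # complete separation, zero variance
    c(0, 0.01, -0.01, 10, 10.01, 9.99)  # separation with tiny noise
  ), design, ids = c("same", "shift", "sep"))
  res <- transition_tests(data, design)
  same <- res[res$feature_id == "same", ]
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  shift <- res[res$feature_id == "shift", ]
  expect_equal(shift$log_fc, 10)
  expect_equal(shift$p_value, 0)
  sep <- res[res$feature_id == "sep", ]
  expect_lt(sep$p_value, 1e-6)
  expect_equal(sep$log_fc, 10, tolerance = 1e-2)
})

test_that("features with fewer than two usable replicates are skipped", {
  design <- stage_design(c("MII", "4cell"), c(2L, 3L), "human")
  data <- make_expr(list(c(1, NA, 4, 5, 6), c(1, 2, 4, 5, 6)), design,
                    ids = c("thin", "full"))
  res <- transition_tests(data, design)
  expect_equal(res$status[res$feature_id == "thin"], "skipped")
  expect_true(is.na(res$p_value[res$feature_id == "thin"]))
  expect_equal(res$status[res$feature_id == "full"], "tested")
})

test_that("pooled and Welch statistics match t.test feature by feature", {
  design <- stage_design(c("MII", "4cell"), c(3L, 4L), "human")
  set.seed(45)
  vals <- replicate(20, rnorm(7, sd = runif(1, 0.5, 2)), simplify = FALSE)
  data <- make_expr(vals, design)
  for (w in c(FALSE, TRUE)) {
    res <- transition_tests(data, design, welch = w)
    for (i in c(1, 7, 20)) {
      tt <- t.test(vals[[i]][4:7], vals[[i]][1:3], var.equal = !w)
      row <- res[res$feature_id == sprintf("F%02d", i), ]
      expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-12)
      expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
      expect_equal(row$df, unname(tt$parameter), tolerance = 1e-9)
    }
  }
})

test_that("moderated t with d0 = 0 equals the ordinary t exactly", {
  design <- human_design(3L)
  set.seed(46)
  data <- make_expr(replicate(50, rnorm(12), simplify = FALSE), design)
  ordinary <- transition_tests(data, design, method = "student")
  forced <- transition_tests(data, design, method = "moderated", prior_df = 0)
  expect_equal(forced$t_stat, ordinary$t_stat, tolerance = 1e-9)
  expect_equal(forced$p_value, ordinary$p_value, tolerance = 1e-9)
  expect_equal(forced$df, ordinary$df)
})

test_that("moderated variance shrinks toward the prior as d0 grows", {
  set.seed(47)
  s2 <- 2 * stats::rchisq(100, 4) / 4
  fit <- fit_moderated(s2, rep(4, 100))
  s0 <- fit$s0_sq
  gaps <- vapply(c(0, 1, 4, 16, 64), function(d0) {
    st <- if (d0 == 0) s2 else (d0 * s0 + 4 * s2) / (d0 + 4)
    mean(abs(st - s0))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})
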