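test_that("the induction index is the mean induced-VPC count", {
  expect_equal(induction_index(c(3, 2))$VI, 2.5)
  expect_equal(induction_index(rep(0, 10))$VI, 0.0)
  expect_equal(induction_index(data.frame(induced_vpcs = c(3, 3, 3)))$VI, 3.0)
  expect_error(induction_index(numeric(0)), "empty")
  expect_error(induction_index(c(3, 7)), "\\[0, 6\\]")
  # invariant under record reordering
  set.seed(1)
  v <- sample(0:6, 30, TRUE)
  expect_equal(induction_index(v)$VI_raw, induction_index(rev(v))$VI_raw)
})

test_that("proportion CIs match the closed-form Wilson interval and its boundaries", {
  ci <- proportion_ci(12, 16)
  oracle <- wilson_interval(12, 16)
  expect_equal(ci$p_hat, 0.75)
  expect_equal(ci$lo, unname(oracle["lo"]), tolerance = 1e-6)
  expect_equal(ci$hi, unname(oracle["hi"]), tolerance = 1e-6)

  expect_equal(proportion_ci(16, 16)$hi, 1)
  expect_equal(proportion_ci(0, 16)$lo, 0)
  expect_error(proportion_ci(3, 0), "n must be")
  expect_error(proportion_ci(5, 4), "k must lie")

  # the interval always contains p_hat and narrows with n at fixed p_hat
  widths <- vapply(c(8, 16, 64, 256), function(n) {
    ci <- proportion_ci(round(0.75 * n), n)
    expect_true(ci$lo <= ci$p_hat && ci$p_hat <= ci$hi)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  cp <- proportion_ci(12, 16, method = "clopper-pearson")
  expect_true(cp$lo < ci$lo || cp$hi > ci$hi)  # CP is the wider construction
})

test_that("Welch t matches closed-form arithmetic on a worked example", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- welch_t(x, y)
  # hand computation: means 2 and 5, both variances 1, se = sqrt(2/3),
  # t = -3 / sqrt(2/3), Welch-Satterthwaite df = (2/3)^2 / (2 * (1/9) / 2) = 4
  t_hand <- -3 / sqrt(2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(t_hand, 4), tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(2, 2), c(2, 2)), "degenerate")
})

test_that("Mann-Whitney U handles the exact, tie and extreme cases", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 2 / 6)
  expect_true(res$exact)

  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$exact)
  expect_equal(tied$p, 1)

  extreme <- mann_whitney_u(1:5, 6:10)
  expect_equal(unname(extreme$U), 0)
})

test_that("the variance F-test follows the printed-s.d. arithmetic and its symmetry", {
  scale_to_sd <- function(v, s) v / sd(v) * s
  set.seed(10)
  x <- scale_to_sd(rnorm(113), 1.584)
  y <- scale_to_sd(rnorm(134), 2.380)
  res <- variance_f_test(y, x)
  expect_equal(res$F, (2.380 / 1.584)^2, tolerance = 1e-9)

  sym1 <- variance_f_test(x, y)
  expect_equal(sym1$F, 1 / res$F)
  expect_equal(sym1$p, res$p, tolerance = 1e-9)

  eq <- variance_f_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(eq$F, 1)
  expect_error(variance_f_test(c(1, 2), c(3, 3)), "zero variance")
})

test_that("group summaries are re-derivable by brute-force recounting", {
  set.seed(20)
  tab <- data.frame(genotype = rep(c("ctrl", "mut"), c(12, 15)),
                    delta = c(rnorm(12, 1, 1.5), rnorm(15, 1, 2.5)))
  out <- summarize_groups(tab, "delta", test = "ftest")
  for (g in c("ctrl", "mut")) {
    v <- tab$delta[tab$genotype == g]
    row <- out$summary[out$summary$group == g, ]
    expect_equal(row$n, length(v))
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
    expect_equal(row$median, median(v))
  }
  expect_equal(out$p, var.test(tab$delta[tab$genotype == "ctrl"],
                               tab$delta[tab$genotype == "mut"])$p.value)

  single <- data.frame(genotype = c("a", "a", "b"), m = c(1, 2, 5))
  res <- summarize_groups(single, "m")
  expect_equal(res$summary$sd_flag[res$summary$group == "b"],
               "undefined (n = 1)")
  expect_error(summarize_groups(tab, "nope"), "unknown metric")
})

test_that("star codes follow the legend thresholds", {
  expect_equal(star_code(c(0.2, 0.04, 0.009, 0.0005, 0.00005)),
               c("ns", "*", "**", "***", "****"))
})
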