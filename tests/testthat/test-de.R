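make_null_expr <- function(n_mirnas, n_case = 14, n_ctrl = 2, sd = 1) {
  n <- n_case + n_ctrl
  m <- matrix(rnorm(n_mirnas * n, sd = sd), n_mirnas, n,
              dimnames = list(sprintf("m%04d", seq_len(n_mirnas)),
                              sprintf("s%02d", seq_len(n))))
  groups <- stats::setNames(c(rep("case", n_case), rep("control", n_ctrl)),
                            colnames(m))
  list(expr = m, groups = groups)
}

test_that("degenerate variance dispersion gives a degenerate prior", {
  expect_equal(estimate_prior(rep(0.3, 50), 14), list(d0 = Inf, s0_sq = 0.3))
  expect_equal(estimate_prior(c(1, 1), 4), list(d0 = Inf, s0_sq = 1))
})

test_that("prior moment-matching recovers planted hyperparameters", {
  set.seed(42)
  d0 <- 4; s0 <- 0.05; n <- 5000; dg <- 14
  sigma2 <- s0 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  pr <- estimate_prior(s2, dg)
  expect_lt(abs(pr$d0 - d0) / d0, 0.25)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)
})

test_that("prior estimator agrees with the independent F-distribution fit", {
  set.seed(43)
  s2 <- 0.1 * 6 / rchisq(3000, 6) * rchisq(3000, 10) / 10
  pr <- estimate_prior(s2, 10)
  lim <- limma::fitFDist(s2, df1 = 10)
  expect_equal(pr$d0, lim$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lim$scale, tolerance = 1e-6)
})

test_that("non-positive variances are floored with a warning", {
  expect_warning(pr <- estimate_prior(c(0, 0.5, 0.7, 0.6), 8), "floored")
  expect_true(is.finite(pr$s0_sq))
})

test_that("zero prior df reduces the moderated t to the ordinary pooled t", {
  set.seed(5)
  d <- make_null_expr(40, n_case = 5, n_ctrl = 4)
  res <- moderated_t_test(d$expr, d$groups, params = list(d0 = 0, s0_sq = 1))
  for (i in c(1, 17, 40)) {
    tt <- t.test(d$expr[i, d$groups == "case"], d$expr[i, d$groups == "control"],
                 var.equal = TRUE)
    expect_equal(res$moderated_t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("shrunken variance interpolates between sample and prior variance", {
  set.seed(6)
  d <- make_null_expr(200)
  res <- moderated_t_test(d$expr, d$groups, params = list(d0 = 3, s0_sq = 0.5))
  lo <- pmin(res$sample_variance, 0.5)
  hi <- pmax(res$sample_variance, 0.5)
  expect_true(all(res$shrunken_variance >= lo - 1e-12))
  expect_true(all(res$shrunken_variance <= hi + 1e-12))
})

test_that("infinite prior df limit matches the pooled-prior z statistic", {
  set.seed(7)
  d <- make_null_expr(100)
  n1 <- sum(d$groups == "case"); n2 <- sum(d$groups == "control")
  res_large <- moderated_t_test(d$expr, d$groups,
                                params = list(d0 = 1e12, s0_sq = 0.8))
  lfc <- res_large$log2_fold_change
  z_ref <- lfc / sqrt(0.8 * (1 / n1 + 1 / n2))
  expect_equal(res_large$moderated_t, z_ref, tolerance = 1e-6)
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  set.seed(8)
  d <- make_null_expr(500)
  res <- moderated_t_test(d$expr, d$groups)
  design <- cbind(intercept = 1, case = as.numeric(d$groups == "case"))
  eb <- limma::eBayes(limma::lmFit(d$expr, design))
  expect_equal(res$moderated_t, unname(eb$t[, "case"]), tolerance = 1e-9)
  expect_equal(res$p_value, unname(eb$p.value[, "case"]), tolerance = 1e-9)
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 1e-9)
})

test_that("swapping group labels negates every statistic exactly", {
  set.seed(9)
  d <- make_null_expr(80)
  swapped <- stats::setNames(ifelse(d$groups == "case", "control", "case"),
                             names(d$groups))
  # swapped design has 2 cases / 14 controls: same pooled variance
  r1 <- moderated_t_test(d$expr, d$groups, params = list(d0 = 2, s0_sq = 1))
  r2 <- moderated_t_test(d$expr, swapped, params = list(d0 = 2, s0_sq = 1))
  expect_equal(r1$moderated_t, -r2$moderated_t)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change)
})

test_that("Bonferroni q-values dominate p-values and preserve their order", {
  set.seed(10)
  d <- make_null_expr(300)
  res <- moderated_t_test(d$expr, d$groups)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$q_value <= 1))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= 0))
})

test_that("constant miRNAs yield t = 0 and p = 1 with a warning", {
  d <- make_null_expr(10, n_case = 3, n_ctrl = 3)
  d$expr[4, ] <- 2.5
  expect_warning(res <- moderated_t_test(d$expr, d$groups,
                                         params = list(d0 = 0, s0_sq = 1)),
                 "constant")
  expect_equal(res$moderated_t[4], 0)
  expect_equal(res$p_value[4], 1)
})

test_that("designs with an undersized group are rejected", {
  d <- make_null_expr(10, n_case = 5, n_ctrl = 1)
  expect_error(moderated_t_test(d$expr, d$groups), "at least 2")
})

test_that("direction classification respects the alpha boundary", {
  res <- data.frame(mirna_id = c("a", "b", "c"),
                    log2_fold_change = c(1, 3, -2),
                    q_value = c(0.049, 0.051, 0.01))
  dir <- classify_direction(res, alpha = 0.05)
  expect_equal(dir$over, "a")
  expect_equal(dir$under, "c")
  expect_equal(dir$ns, "b")

  empty <- classify_direction(res[0, ])
  expect_equal(lengths(empty), c(over = 0L, under = 0L, ns = 0L))
})
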