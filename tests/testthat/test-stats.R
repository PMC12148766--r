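score_df <- function(call, location = NULL, method = "arm") {
  data.frame(patient = seq_along(call), method = method, call = call,
             location = location %||% ifelse(call, "RUL", "none"),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("agreement of an arm with itself and with its complement", {
  set.seed(1)
  ref <- score_df(runif(20) < 0.5)
  same <- binary_agreement(ref, ref)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$precision, 1)
  expect_equal(same$specificity, 1)
  expect_equal(same$accuracy, 1)
  flip <- binary_agreement(ref, score_df(!ref$call))
  expect_equal(flip$sensitivity, 0)
  expect_equal(flip$specificity, 0)
})

test_that("hand-counted confusion matrix gives the expected rates", {
  # 10 patients: ref positive 1-5; test positive on 1-4 (TP) and 6-7 (FP)
  ref <- score_df(c(rep(TRUE, 5), rep(FALSE, 5)))
  tst <- score_df(c(rep(TRUE, 4), FALSE, TRUE, TRUE, rep(FALSE, 3)))
  cs <- binary_agreement(ref, tst)
  expect_equal(c(cs$tp, cs$fn, cs$fp, cs$tn), c(4, 1, 2, 3))
  expect_equal(cs$sensitivity, 0.8)
  expect_equal(cs$precision, 4 / 6, tolerance = 1e-12)
  expect_equal(cs$specificity, 0.6)
  expect_equal(cs$accuracy, 0.7)
})

test_that("agreement equals brute-force counting on random score sets", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    r <- runif(n) < 0.5; t <- runif(n) < 0.5
    cs <- binary_agreement(score_df(r), score_df(t))
    expect_identical(c(cs$tp, cs$fp, cs$tn, cs$fn),
                     c(sum(t & r), sum(t & !r), sum(!t & !r), sum(!t & r)))
  }
})

test_that("location mode scores wrong-lobe positives as discordant", {
  ref <- score_df(c(TRUE, TRUE, TRUE, FALSE), c("RUL", "LLL", "RML", "none"))
  tst <- score_df(c(TRUE, TRUE, FALSE, TRUE), c("RUL", "RLL", "none", "LUL"))
  plain <- binary_agreement(ref, tst)
  expect_equal(c(plain$tp, plain$fp, plain$fn, plain$tn), c(2, 1, 1, 0))
  loc <- binary_agreement(ref, tst, use_location = TRUE)
  # patient 2's wrong lobe moves from TP to FP under the stricter reading
  expect_equal(c(loc$tp, loc$fp, loc$fn, loc$tn), c(1, 2, 1, 0))
  expect_error(binary_agreement(ref, tst[1:3, ]), "symmetric difference")
})

test_that("undefined rates are NaN-flagged rather than invented", {
  ref <- score_df(rep(FALSE, 5))
  tst <- score_df(rep(FALSE, 5))
  cs <- binary_agreement(ref, tst)
  expect_true(is.nan(cs$sensitivity))
  expect_true(cs$undefined_rates)
  expect_equal(cs$accuracy, 1)
})

# brute-force distance of every voxel to the nearest tumor voxel (oracle)
dist_to_tumor <- function(dm, sp, tumor) {
  ijk <- arrayInd(seq_len(prod(dm)), dm)
  X <- sweep((ijk - 1), 2, sp, "*")
  tw <- X[which(tumor), , drop = FALSE]
  out <- numeric(prod(dm))
  for (s in seq(1, prod(dm), by = 4096)) {
    e <- min(s + 4095, prod(dm))
    d2 <- outer(rowSums(X[s:e, , drop = FALSE]^2), rowSums(tw^2), "+") -
      2 * X[s:e, , drop = FALSE] %*% t(tw)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  array(out, dm)
}

test_that("heterogeneity criterion measures the peritumoral decrease", {
  dm <- c(24, 24, 24)
  sp <- c(2, 2, 2)
  ijk <- arrayInd(seq_len(prod(dm)), dm)
  X <- sweep((ijk - 1), 2, sp, "*")
  ctr <- c(23, 23, 23)
  r <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  lung <- array(r < 20, dm)
  tumor <- array(r < 6, dm)
  # uniform function: no decrease, criterion fails
  f <- function_image(ifelse(lung, 1, NA), lung, "jacobian", sp)
  hc <- heterogeneity_criterion(f, tumor, lung, shell_mm = 10)
  expect_equal(hc$decrease, 0)
  expect_false(hc$pass)
  # suppressed shell: decrease follows the brute-force mean ratio
  shell_or <- lung & !tumor & dist_to_tumor(dm, sp, tumor) <= 10
  vals <- array(1, dm); vals[shell_or] <- 0.5
  f2 <- function_image(ifelse(lung, vals, NA), lung, "jacobian", sp)
  hc2 <- heterogeneity_criterion(f2, tumor, lung, shell_mm = 10)
  expected <- 1 - mean(vals[shell_or]) / mean(vals[lung & !tumor])
  expect_equal(hc2$decrease, expected, tolerance = 1e-12)
  expect_gt(hc2$decrease, 0.15)
  expect_true(hc2$pass)
  # inclusive boundary: the measured decrease used as threshold still passes
  hc3 <- heterogeneity_criterion(f2, tumor, lung, shell_mm = 10,
                                 threshold = hc2$decrease)
  expect_true(hc3$pass)
  expect_error(heterogeneity_criterion(f, array(FALSE, dm), lung), "empty")
})

test_that("Friedman statistic matches both the closed form and stats::friedman.test", {
  # all methods identical: statistic 0, p 1
  tied <- matrix(rep(c(3, 3, 3), 4), 4, 3, byrow = TRUE)
  ft <- friedman_test(tied)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  # three patients each ranking methods (1, 2, 3): Q = 6
  ranks <- matrix(rep(c(0.1, 0.5, 0.9), 3), 3, 3, byrow = TRUE)
  expect_equal(friedman_test(ranks)$statistic, 6)
  # random matrices against the base-R implementation
  set.seed(19)
  for (i in 1:25) {
    m <- matrix(rnorm(7 * 4), 7, 4)
    a <- friedman_test(m); b <- stats::friedman.test(m)
    expect_equal(a$statistic, unname(b$statistic), tolerance = 1e-12)
    expect_equal(a$p_value, unname(b$p.value), tolerance = 1e-12)
  }
  # rank-based: invariant to within-patient monotone transforms
  m <- matrix(rnorm(6 * 3), 6, 3)
  expect_equal(friedman_test(m)$statistic,
               friedman_test(t(apply(m, 1, function(r) exp(r))))$statistic)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("post-hoc Wilcoxon reproduces exact enumeration and the 0.016 alpha", {
  # n = 6, all positive differences: two-sided p = 2/64
  r <- posthoc_wilcoxon(rep(0, 6), list(a = 1:6), family_alpha = 0.05, m = 3)
  expect_equal(r$a$p_value, 2 / 64)
  expect_equal(r$a$alpha, 0.016)   # 0.05 / 3 truncated, not rounded
  # identical arms: p = 1 with the all-zero flag
  z <- posthoc_wilcoxon(1:8, list(a = 1:8))
  expect_equal(z$a$p_value, 1)
  expect_true(z$a$all_zero)
  # full sign-assignment enumeration oracle for n <= 10
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    d <- rnorm(n)
    p_pkg <- posthoc_wilcoxon(rep(0, n), list(a = d))$a$p_value
    r <- rank(abs(d)); W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- signs %*% r
    p_or <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
    expect_equal(p_pkg, p_or, tolerance = 1e-12)
  }
  expect_error(posthoc_wilcoxon(rep(0, 4), list(a = c(1, 2, 3, 4))),
               "fewer than 5")
})

test_that("large-sample path matches wilcox.test and calibration path matches ours", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(63); y <- rnorm(63)
    p1 <- posthoc_wilcoxon(x, list(a = y))$a$p_value
    p2 <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  # the vectorized null-calibration path uses the identical p-value routine
  set.seed(31)
  d <- rnorm(63)
  expect_equal(vent4d:::signed_rank_p(d)$p,
               posthoc_wilcoxon(rep(0, 63), list(a = d))$a$p_value)
})
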