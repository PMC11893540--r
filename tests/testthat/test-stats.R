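# Assumption gating, paired and multilevel comparisons, Holm correction,
# power simulation.

test_that("assumption checks calibrate and flag as designed", {
  # Shapiro-Wilk type-I calibration: ~95% pass rate under normality
  set.seed(13)
  pass <- mean(vapply(1:1000, function(i)
    isTRUE(check_assumptions(rnorm(30))$normality), NA))
  expect_gt(pass, 0.93)
  expect_lt(pass, 0.97)
  # one extreme difference trips the 3 x IQR rule
  d <- rnorm(30)
  d[1] <- 100 * IQR(d)
  expect_true(check_assumptions(d)$outliers)
  # constant differences are degenerate: normality not assessable
  a <- check_assumptions(rep(2, 10))
  expect_true(is.na(a$normality))
  expect_true(a$degenerate)
  # sphericity only applies to >= 3 levels
  expect_true(is.na(check_assumptions(rnorm(20))$sphericity))
  set.seed(14)
  m <- matrix(rnorm(80), 20, 4)
  expect_false(is.na(check_assumptions(m)$sphericity))
})

test_that("complete separation yields the minimal one-tailed signed-rank p", {
  set.seed(42)
  n <- 10
  a <- rnorm(n)
  b <- a + 3 + runif(n)     # every difference positive, all distinct
  r <- paired_compare(b, a, tail = "greater", force = "wilcoxon")
  expect_match(r$test, "Wilcoxon")
  expect_equal(r$p_raw, 2^-n, tolerance = 1e-12)  # exact: 1 of 2^n signings
  expect_equal(r$effect$value, 1)      # all positive: rank-biserial = 1
  # a constant shift (tied |differences|) routes to the Wilcoxon branch via
  # the degenerate-normality gate and stays overwhelmingly significant
  r2 <- paired_compare(a + 3, a, tail = "greater")
  expect_match(r2$test, "Wilcoxon")
  expect_lt(r2$p_raw, 0.005)
})

test_that("identical samples give the degenerate zero-effect result", {
  a <- rnorm(10)
  r <- paired_compare(a, a)
  expect_equal(r$p_raw, 1)
  expect_equal(r$effect$value, 0)
  expect_true("all_zero_differences" %in% r$flags)
})

test_that("the t branch reports dz with a noncentral-t CI", {
  set.seed(15)
  a <- rnorm(30); b <- a - 0.8 + rnorm(30, sd = 0.9)
  r <- paired_compare(a, b, tail = "greater")
  expect_match(r$test, "t-test")
  d <- a - b
  expect_equal(r$effect$value, mean(d) / sd(d))
  expect_equal(unname(r$statistic), unname(t.test(a, b, paired = TRUE,
                                  alternative = "greater")$statistic))
  # the CI inverts pt(): check both ends against the defining equation
  t_obs <- r$effect$value * sqrt(30)
  expect_equal(pt(t_obs, 29, r$effect$ci95[1] * sqrt(30)), 0.975,
               tolerance = 1e-4)
  expect_equal(pt(t_obs, 29, r$effect$ci95[2] * sqrt(30)), 0.025,
               tolerance = 1e-3)
  # dz of 0 when x == y + pure noise centred at zero has CI covering 0
  set.seed(16)
  r0 <- paired_compare(rnorm(30), rnorm(30))
  expect_lt(r0$effect$ci95[1], 0.5)
  expect_gt(r0$effect$ci95[2], -0.5)
})

test_that("empirical power of the gated comparison matches the noncentral t", {
  closed <- power_t_closed_form(0.7, 30, tail = "greater")
  set.seed(17)
  hits <- mean(vapply(1:2000, function(i) {
    d <- rnorm(30, mean = 0.7)
    paired_compare(d, rep(0, 30), tail = "greater")$p_raw < 0.05
  }, NA))
  # gated branch is nearly always the t-test here; 2000 sims -> se ~ 0.008
  expect_equal(hits, closed, tolerance = 0.03)
})

test_that("multilevel comparison mirrors the wake-versus-sleep pattern", {
  set.seed(18)
  n <- 24
  m <- cbind(W = rnorm(n, 10), N2 = rnorm(n), N3 = rnorm(n),
             REM = rnorm(n))
  r <- multilevel_compare(m)
  expect_lt(r$p_raw, 0.001)
  ph <- r$posthoc
  w_rows <- grepl("W", ph$contrast)
  expect_true(all(ph$p_adjusted[w_rows] < 0.01))
  expect_true(all(ph$p_adjusted[!w_rows] > 0.05))
  # identical levels -> degenerate p = 1 family
  r0 <- multilevel_compare(matrix(rep(rnorm(6), 4), ncol = 4))
  expect_equal(r0$p_raw, 1)
  expect_true(all(r0$posthoc$p_adjusted == 1))
  # missing cells are refused
  m[2, 3] <- NA
  expect_error(multilevel_compare(m), "complete cases")
})

test_that("the Friedman branch matches the hand-computed rank statistic", {
  # printed toy table: 4 subjects x 4 conditions
  m <- rbind(c(1, 2, 3, 4),
             c(2, 1, 4, 3),
             c(1, 3, 2, 4),
             c(1, 2, 4, 3))
  n <- 4; k <- 4
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  r <- multilevel_compare(m, force = "friedman")
  expect_equal(unname(r$statistic), chi2)
  expect_equal(r$effect$kind, "kendall_w")
  expect_equal(r$effect$value, chi2 / (n * (k - 1)))
  expect_true(r$effect$ci95[1] >= 0 && r$effect$ci95[2] <= 1)
})

test_that("Holm adjustment is monotone, capped, and order-invariant", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  p <- c(0.6, 0.7, 0.8)
  adj <- holm_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(sort(adj)) >= 0))
  shuf <- c(2, 3, 1)
  expect_equal(holm_adjust(p[shuf]), adj[shuf])
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("power simulation is calibrated at the null and monotone in n", {
  pw0 <- power_simulation(0, n_grid = 30, n_sims = 20000, seed = 19,
                          test = "t")
  expect_gt(pw0$power, 0.044)   # 20000 sims: se ~ 0.0015
  expect_lt(pw0$power, 0.056)
  pw <- power_simulation(0.7, n_grid = c(10, 20, 30), n_sims = 5000,
                         seed = 20, test = "t")
  expect_true(all(diff(pw$power) > 0))
  closed <- power_t_closed_form(0.7, 30)
  expect_equal(pw$power[3], closed, tolerance = 0.02)
  expect_error(power_simulation(-1), "non-negative")
})
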