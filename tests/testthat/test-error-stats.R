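test_that("error summaries compute the five classical statistics", {
  s <- summarize_errors(c(0, 0, 0))
  expect_equal(unlist(s[c("me_d", "sd_d", "rmse_d", "mae_d", "medae_d")]),
               c(me_d = 0, sd_d = 0, rmse_d = 0, mae_d = 0, medae_d = 0))
  s2 <- summarize_errors(c(0.1, -0.1, 0.3))
  expect_equal(s2$me_d, 0.1, tolerance = 1e-12)
  expect_equal(s2$rmse_d, sqrt(0.11 / 3), tolerance = 1e-12)
  expect_equal(round(s2$rmse_d, 5), 0.19149)
  expect_error(summarize_errors(numeric(0)), "no errors")
})

test_that("summaries respect sign symmetry, permutation invariance and the RMSE identity", {
  set.seed(3)
  for (rep in 1:5) {
    e <- rnorm(50, mean = runif(1, -0.3, 0.3), sd = 0.4)
    s <- summarize_errors(e)
    neg <- summarize_errors(-e)
    expect_equal(neg$me_d, -s$me_d, tolerance = 1e-12)
    expect_equal(neg[c("sd_d", "rmse_d", "mae_d", "medae_d")],
                 s[c("sd_d", "rmse_d", "mae_d", "medae_d")], tolerance = 1e-12)
    expect_equal(summarize_errors(sample(e)), s, tolerance = 1e-12)
    # population identity rmse^2 = me^2 + sd^2 (n-1)/n
    expect_equal(s$rmse_d^2, s$me_d^2 + s$sd_d^2 * (s$n - 1) / s$n,
                 tolerance = 1e-12)
    expect_gte(s$rmse_d, abs(s$me_d))
  }
})

test_that("the zero-mean test gates on normality and detects shifts", {
  set.seed(42)
  e <- rnorm(200, 0, 0.3)
  res <- test_me_nonzero(e)
  expect_identical(res$method, "t")
  expect_gt(res$p_value, 0.05)
  shifted <- test_me_nonzero(e + 5 * 0.3)
  expect_lt(shifted$p_value, 1e-6)
  # heavy-tailed errors drop to the signed-rank branch
  skewed <- test_me_nonzero(rexp(200) - 1)
  expect_identical(skewed$method, "wilcoxon")
  expect_error(test_me_nonzero(rep(0.2, 10)), "identical")
  expect_error(test_me_nonzero(c(0.1, 0.2)), "at least 3")
})

test_that("paired bootstrap RMSE comparison behaves at the boundaries", {
  set.seed(8)
  a <- rnorm(300, 0, 0.3)
  expect_equal(heteroscedastic_rmse_test(a, a, seed = 2)$p_value, 1)
  b <- a + rnorm(300, 0, 0.3 * sqrt(8))  # triples the RMSE
  res <- heteroscedastic_rmse_test(a, b, n_boot = 2000, seed = 2)
  expect_lt(res$p_value, 0.01)
  # swapping the two formulas negates the difference, same two-sided p
  swapped <- heteroscedastic_rmse_test(b, a, n_boot = 2000, seed = 2)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$delta_rmse, -res$delta_rmse)
  # determinism for a given seed, no global RNG disturbance
  before <- .Random.seed
  again <- heteroscedastic_rmse_test(a, b, n_boot = 2000, seed = 2)
  expect_identical(again$p_value, res$p_value)
  expect_identical(before, .Random.seed)
  expect_error(heteroscedastic_rmse_test(a, b[-1]), "paired")
})

test_that("Holm adjustment reproduces hand-worked examples", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.2, 0.2, 0.2)), c(0.6, 0.6, 0.6))
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))  # capped at 1
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("axial-length binning rounds half-up to the bin grid", {
  b <- bin_by_al(c(23.1, 23.2), c(1, 3), 0.5)
  expect_equal(b$bin_center, 23.0)
  expect_equal(b$mean, 2)
  expect_equal(b$n, 2L)
  expect_equal(bin_by_al(23.26, 1, 0.5)$bin_center, 23.5)  # tie-ish, half-up
  expect_equal(bin_by_al(23.25, 1, 0.5)$bin_center, 23.5)  # exact tie, half-up
  # uniform ALs fill the expected bins with the expected counts
  al <- seq(22, 27, by = 0.01)
  b2 <- bin_by_al(al, rep(1, length(al)), 0.5)
  expect_equal(b2$bin_center, seq(22, 27, by = 0.5))
  expect_equal(sum(b2$n), length(al))
  # flagged (NA) values are excluded listwise
  b3 <- bin_by_al(c(23.1, 23.2), c(1, NA), 0.5)
  expect_equal(b3$n, 1L)
})

test_that("ACD subgroups split long eyes at mean +/- 1 SD", {
  set.seed(21)
  cases <- data.frame(al_mm = runif(400, 26.01, 29),
                      acd_mm = rnorm(400, 3.51, 0.27))
  g <- acd_subgroups(cases, 26)
  m <- mean(cases$acd_mm); s <- sd(cases$acd_mm)
  expect_equal(g$boundaries, c(m - s, m + s))
  expect_equal(nrow(g$short) + nrow(g$medium) + nrow(g$long), 400L)
  expect_true(all(g$short$acd_mm < g$boundaries[1]))
  expect_true(all(g$long$acd_mm > g$boundaries[2]))
  # roughly 16/68/16 under normality
  expect_gt(nrow(g$medium) / 400, 0.55)
  expect_lt(nrow(g$medium) / 400, 0.80)
  # degenerate zero spread: everything is medium
  flat <- data.frame(al_mm = rep(27, 5), acd_mm = rep(3.5, 5))
  gf <- acd_subgroups(flat, 26)
  expect_equal(nrow(gf$medium), 5L)
  expect_error(acd_subgroups(data.frame(al_mm = 27, acd_mm = 3.5), 26),
               "fewer than 3")
})
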