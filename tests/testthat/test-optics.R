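test_that("keratometer-to-physical corneal power conversion is the index ratio", {
  expect_equal(corneal_power(43.52), 43.52 * 0.3315 / 0.3375, tolerance = 1e-12)
  expect_equal(round(corneal_power(43.52), 3), 42.746)
  expect_equal(round(corneal_power(45), 3), 44.2)
  # equal indices collapse to the identity
  p <- vergence_params(corneal_index = 1.3375)
  expect_equal(corneal_power(c(40, 44, 48), p), c(40, 44, 48))
  expect_error(vergence_params(corneal_index = 0.9), "indices")
})

test_that("predicted refraction matches the independent vergence-chain oracle", {
  L <- cmal(26.77, 4.31); Dc <- corneal_power(43.52)
  # long-eye worked values
  expect_equal(predict_refraction(L, Dc, 5.63, 11.47),
               oracle_refraction(L, Dc, 5.63, 11.47), tolerance = 1e-9)
  expect_equal(round(predict_refraction(L, Dc, 5.63, 11.47), 2), -0.06)
  expect_equal(round(predict_refraction(L, Dc, 5.28, 11.47), 2), -0.30)
  # lattice agreement
  for (l in c(21, 24.5, 28)) for (dc in c(39, 44, 48)) for (d in c(3.5, 5, 6.5))
    for (p in c(6, 14, 28))
      expect_equal(predict_refraction(l, dc, d, p),
                   oracle_refraction(l, dc, d, p), tolerance = 1e-8)
  expect_error(predict_refraction(24, 43, 25, 20), "anterior to the retina")
})

test_that("refraction is monotone in ELP and IOL power, with power-dependent ELP sensitivity", {
  Dc <- corneal_power(44)
  # deeper ELP -> more hyperopic; more power -> more myopic
  for (L in c(22, 25, 28)) {
    d <- seq(3, 6, by = 0.5)
    se_d <- predict_refraction(L, Dc, d, 20)
    expect_true(all(diff(se_d) > 0))
    p <- seq(6, 30, by = 2)
    se_p <- predict_refraction(L, Dc, 4.8, p)
    expect_true(all(diff(se_p) < 0))
  }
  # |dSE/dELP| grows with IOL power: ELP error matters least for the weak
  # implants of very long eyes
  sens <- function(p) abs(predict_refraction(27, Dc, 5.1, p) -
                            predict_refraction(27, Dc, 4.9, p))
  expect_true(sens(10) < sens(20))
  expect_true(sens(20) < sens(30))
})

test_that("emmetropic power closes the loop and matches a bisection search", {
  cases <- expand.grid(L = c(21.5, 23.68, 26.663, 29),
                       Dc = corneal_power(c(40, 43.43, 47)),
                       d = c(3.2, 4.9, 6.4))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p <- emmetropic_power(L, Dc, d)
      expect_equal(predict_refraction(L, Dc, d, p), 0, tolerance = 1e-9)
      expect_equal(p, oracle_emmetropic_power(L, Dc, d), tolerance = 1e-6)
    })
  }
})

test_that("back-calculated ELP inverts predicted refraction over a 4-D lattice", {
  for (L in c(21, 24, 27, 30)) for (Dc in c(38, 43, 48))
    for (P in c(6, 15, 30)) for (d in c(3, 5, 7)) {
      se <- predict_refraction(L, Dc, d, P)
      got <- suppressWarnings(back_calculate_elp(L, Dc, P, se))
      expect_equal(got, d, tolerance = 1e-6)
      # and the returned root reproduces the refraction
      expect_equal(predict_refraction(L, Dc, got, P), se, tolerance = 1e-6)
    }
})

test_that("back-calculation matches an independent bisection oracle and flags rootless eyes", {
  L <- cmal(26.77, 4.31); Dc <- corneal_power(43.52)
  d <- back_calculate_elp(L, Dc, 11.47, -0.275)
  expect_equal(d, oracle_back_elp(L, Dc, 11.47, -0.275), tolerance = 1e-8)
  expect_equal(round(d, 1), 5.3)
  expect_equal(back_calculate_elp(23.68, corneal_power(43.43), 20.5, 0),
               oracle_back_elp(23.68, corneal_power(43.43), 20.5, 0),
               tolerance = 1e-8)
  # a strongly hyperopic result no anatomic lens position can produce
  expect_warning(flagged <- back_calculate_elp(23, corneal_power(44), 21, 15),
                 "no ELP root")
  expect_true(is.na(flagged))
})

test_that("grid recommendation minimises |predicted SE| with myopic tie-break", {
  L <- cmal(26.77, 4.31); Dc <- corneal_power(43.52)
  elp_cmal <- haigis_elp(haigis_constants(1.556), 3.51, L)
  elp_al <- haigis_elp(haigis_constants(1.523), 3.51, 26.77)
  expect_equal(recommend_iol_power(L, Dc, elp_cmal), 11.5)
  expect_equal(recommend_iol_power(26.77, Dc, elp_al), 11.0)
  # a single-point grid is returned verbatim
  p_emm <- emmetropic_power(25, Dc, 5)
  expect_equal(recommend_iol_power(25, Dc, 5, grid = p_emm), p_emm)
  # exact tie (target midway between the two predicted SEs) goes to the
  # higher power, i.e. the more myopic outcome
  se2 <- predict_refraction(25, Dc, 5, c(18, 19))
  mid <- mean(se2)
  expect_equal(recommend_iol_power(25, Dc, 5, grid = c(18, 19),
                                   target_se_d = mid), 19)
  expect_error(recommend_iol_power(25, Dc, 5, grid = numeric(0)), "empty")
})
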