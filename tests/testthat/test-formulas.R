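test_that("CMAL transform matches the printed coefficients and inverts exactly", {
  expect_equal(cmal(26.77, 4.31), 26.663286, tolerance = 1e-6)
  expect_equal(cmal(23.68, 4.47), 23.692628, tolerance = 1e-6)
  expect_equal(reversed_cmal(cmal(26.77, 4.31), 4.31), 26.77, tolerance = 1e-10)
  # round-trip identity over a lattice
  for (al in seq(21, 30, by = 1.5)) for (lt in c(3.6, 4.5, 5.4)) {
    expect_equal(reversed_cmal(cmal(al, lt), lt), al, tolerance = 1e-10)
    expect_equal(cmal(reversed_cmal(al, lt), lt), al, tolerance = 1e-10)
  }
})

test_that("CMAL is increasing in AL, decreasing in LT, close to AL, and shorter in long eyes", {
  al <- seq(20.5, 30, by = 0.25)
  expect_true(all(diff(cmal(al, 4.47)) > 0))
  lt <- seq(3.4, 5.7, by = 0.1)
  expect_true(all(diff(cmal(24, lt)) < 0))
  eyes <- random_eyes(200, seed = 5)
  expect_true(all(abs(cmal(eyes$al_mm, eyes$lt_mm) - eyes$al_mm) < 0.5))
  long <- eyes$al_mm > 25.5
  expect_true(all(cmal(eyes$al_mm[long], eyes$lt_mm[long]) < eyes$al_mm[long]))
})

test_that("Haigis ELP predictor is the printed linear form", {
  expect_equal(round(haigis_elp(haigis_constants(1.556), 3.51, cmal(26.77, 4.31)), 2),
               5.63)
  expect_equal(haigis_elp(haigis_constants(1.523), 3.51, 26.77), 5.604,
               tolerance = 1e-10)
  expect_equal(haigis_elp(haigis_constants(2.5, 0, 0), 3.1, 27), 2.5)
  expect_error(haigis_constants(1.5, 0.4, -0.1), "non-negative")
  # exact linearity: subgroup mean ELP equals ELP at mean biometry
  eyes <- random_eyes(50, seed = 9)
  cst <- haigis_constants(1.39)
  expect_equal(mean(haigis_elp(cst, eyes$acd_mm, eyes$al_mm)),
               haigis_elp(cst, mean(eyes$acd_mm), mean(eyes$al_mm)),
               tolerance = 1e-12)
})

test_that("classical formulas agree with independent transcriptions of their published forms", {
  eyes <- random_eyes(20, seed = 17)
  consts <- list(srkt = 119.1, hofferq = 5.61, holladay1 = 1.84)
  oracles <- list(srkt = oracle_srkt_power,
                  hofferq = oracle_hofferq_power,
                  holladay1 = oracle_holladay1_power)
  preds <- list(srkt = srkt_predict, hofferq = hofferq_predict,
                holladay1 = holladay1_predict)
  for (f in names(consts)) {
    for (i in seq_len(nrow(eyes))) {
      al <- eyes$al_mm[i]; k <- eyes$k_d[i]
      p_given <- round(oracles[[f]](al, k, consts[[f]], 0) * 2) / 2
      got <- preds[[f]](al, k, consts[[f]], p_given)
      want <- oracle_formula_se(oracles[[f]], al, k, consts[[f]], p_given)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("%s eye %d", f, i))
    }
  }
})

test_that("classical formulas are monotone in IOL power and sane at average biometry", {
  powers <- seq(10, 30, by = 2)
  expect_true(all(diff(srkt_predict(23.68, 44.21, 119.1, powers)) < 0))
  expect_true(all(diff(hofferq_predict(23.68, 44.21, 5.61, powers)) < 0))
  expect_true(all(diff(holladay1_predict(23.68, 44.21, 1.84, powers)) < 0))
  # grid power nearest emmetropia leaves less than half a step of refraction
  p_emm <- uniroot(function(p) srkt_predict(23.68, 44.21, 119.1, p),
                   c(5, 35))$root
  se <- srkt_predict(23.68, 44.21, 119.1, round(p_emm * 2) / 2)
  expect_lt(abs(se), 0.5)
})

test_that("SRK/T and Holladay 1 flag eyes whose corneal-height root is impossible", {
  expect_warning(out <- srkt_predict(30, 60, 119.1, 6), "flagged")
  expect_true(is.na(out))
  expect_warning(out2 <- holladay1_predict(29, 59, 1.84, 6), "flagged")
  expect_true(is.na(out2))
})

test_that("haigis_predict substitutes CMAL wholesale in the CMAL variant", {
  cst <- haigis_constants(1.556)
  got <- haigis_predict(cst, 26.77, 43.52, 3.51, 4.31, 11.47, variant = "cmal")
  al_eff <- cmal(26.77, 4.31)
  want <- predict_refraction(al_eff, corneal_power(43.52),
                             haigis_elp(cst, 3.51, al_eff), 11.47)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(haigis_predict(cst, 26.77, 43.52, 3.51, NULL, 11.47,
                              variant = "cmal"), "lt_mm")
})
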