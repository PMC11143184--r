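# Independent oracles, deliberately coded along different routes than the
# package: the vergence oracle propagates vergences with explicit translation
# operators and root-finds the spectacle refraction; the classical-formula
# oracles transcribe the published power-for-target-refraction forms and
# invert them numerically.

# Spectacle refraction by numeric root-finding over the translated vergence
# chain (cornea -> aqueous translation -> IOL -> image distance on retina).
oracle_refraction <- function(L, Dc, d, P, n = 1.336, vx = 12) {
  # solve in corneal-plane refraction space (free of the vertex-distance
  # pole), then convert the root to the spectacle plane
  mismatch <- function(ref_c) {
    v1 <- Dc + ref_c                # vergence leaving the cornea
    v2 <- n * 1000 / (n * 1000 / v1 - d)  # translated to the IOL plane
    v3 <- v2 + P                    # vergence leaving the IOL
    n * 1000 / v3 - (L - d)         # image distance minus IOL-retina distance
  }
  # scan for a sign change to bracket the root away from the chain's poles
  rc <- seq(-80, 80, by = 0.25)
  f <- suppressWarnings(vapply(rc, function(x) tryCatch(mismatch(x),
                                                        error = function(e) NA_real_),
                               numeric(1)))
  ok <- which(is.finite(f[-length(f)]) & is.finite(f[-1]) &
                f[-length(f)] * f[-1] <= 0 &
                abs(f[-length(f)] - f[-1]) < 50)  # exclude pole crossings
  if (length(ok) == 0) stop("oracle failed to bracket a refraction root")
  root_c <- uniroot(mismatch, c(rc[ok[1]], rc[ok[1] + 1]), tol = 1e-12)$root
  root_c / (1 + root_c * vx / 1000)
}

oracle_back_elp <- function(L, Dc, P, se, n = 1.336, vx = 12) {
  uniroot(function(d) oracle_refraction(L, Dc, d, P, n, vx) - se,
          c(1.0001, min(9.9999, L - 0.2)), tol = 1e-12)$root
}

oracle_emmetropic_power <- function(L, Dc, d, n = 1.336, vx = 12) {
  # power at which the oracle vergence chain returns zero refraction
  uniroot(function(p) oracle_refraction(L, Dc, d, p, n, vx),
          c(-10, 60), tol = 1e-12)$root
}

# ---- published power-for-target-refraction transcriptions ----

oracle_srkt_power <- function(al, k, a_const, ref, v = 12) {
  r <- 337.5 / k
  lcor <- if (al > 24.2) -3.446 + 1.715 * al - 0.0237 * al^2 else al
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  h <- r - sqrt(r^2 - cw^2 / 4)
  elp <- h + (0.62467 * a_const - 68.747) - 3.336
  lopt <- al + 0.65696 - 0.02029 * al
  na <- 1.336; ncm1 <- 0.333
  (1000 * na * (na * r - ncm1 * lopt -
                  0.001 * ref * (v * (na * r - ncm1 * lopt) + lopt * r))) /
    ((lopt - elp) * (na * r - ncm1 * elp -
                       0.001 * ref * (v * (na * r - ncm1 * elp) + elp * r)))
}

oracle_holladay1_power <- function(al, k, sf, ref, v = 12) {
  r <- 337.5 / k
  ag <- min(12.5 * al / 23.45, 13.5)
  elp <- 0.56 + r - sqrt(r^2 - ag^2 / 4) + sf
  alm <- al + 0.2
  na <- 1.336; ncm1 <- 1 / 3
  (1000 * na * (na * r - ncm1 * alm -
                  0.001 * ref * (v * (na * r - ncm1 * alm) + alm * r))) /
    ((alm - elp) * (na * r - ncm1 * elp -
                      0.001 * ref * (v * (na * r - ncm1 * elp) + elp * r)))
}

oracle_hofferq_power <- function(al, k, pacd, ref, v = 12) {
  alc <- min(max(al, 18.5), 31)
  m <- if (alc <= 23) 1 else -1
  g <- if (alc <= 23) 28 else 23.5
  deg <- pi / 180
  elp <- pacd + 0.3 * (alc - 23.5) + tan(k * deg)^2 +
    0.1 * m * (23.5 - alc)^2 * tan(0.1 * (g - alc)^2 * deg) - 0.99166
  rc <- ref / (1 - ref * v / 1000)
  1336 / (al - elp - 0.05) -
    1.336 / (1.336 / (k + rc) - (elp + 0.05) / 1000)
}

# invert any of the power transcriptions numerically for the refraction
oracle_formula_se <- function(power_fn, al, k, const, p_given, ...) {
  uniroot(function(ref) power_fn(al, k, const, ref, ...) - p_given,
          c(-30, 25), tol = 1e-12)$root
}

# small deterministic random-eye factory for property loops
random_eyes <- function(n, seed) {
  set.seed(seed)
  data.frame(al_mm = runif(n, 21, 29),
             k_d = runif(n, 40, 47),
             acd_mm = runif(n, 2.4, 4.2),
             lt_mm = runif(n, 3.8, 5.2))
}
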