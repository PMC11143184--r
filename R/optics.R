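#' Optical constants for the thin-lens pseudophakic eye model
#'
#' Bundles the refractive indices and the spectacle vertex distance used by
#' the vergence engine.  The defaults follow the Haigis convention: aqueous /
#' vitreous index 1.336, keratometer calibration index 1.3375, and a corneal
#' index of 1.3315 used to convert keratometer-scale corneal power into the
#' physical corneal power entered into vergence calculations.  Total
#' keratometry (TK) readings from the biometer are treated as
#' keratometer-scale inputs and pass through the same conversion.
#'
#' @param n_aqueous Refractive index of aqueous and vitreous (dimensionless).
#' @param keratometric_index Index assumed by the keratometer when it
#'   converted corneal radius to dioptres (dimensionless).
#' @param corneal_index Index used to convert keratometer readings to
#'   physical corneal power (dimensionless).
#' @param vertex_mm Spectacle vertex distance in mm.
#' @return An object of class `vergence_params`.
#' @examples
#' vergence_params()
#' @export
vergence_params <- function(n_aqueous = 1.336,
                            keratometric_index = 1.3375,
                            corneal_index = 1.3315,
                            vertex_mm = 12) {
  if (n_aqueous <= 1 || keratometric_index <= 1 || corneal_index <= 1)
    stop("refractive indices must exceed 1", call. = FALSE)
  if (vertex_mm < 0)
    stop("vertex_mm must be non-negative", call. = FALSE)
  structure(list(n_aqueous = n_aqueous,
                 keratometric_index = keratometric_index,
                 corneal_index = corneal_index,
                 vertex_mm = vertex_mm),
            class = "vergence_params")
}

#' Convert keratometer-scale corneal power to physical corneal power
#'
#' Keratometers report corneal power on a calibration index (1.3375 by
#' convention); vergence calculations need the power implied by the model's
#' own corneal index (1.3315 in the Haigis convention).  Since both scales
#' are proportional to curvature, the conversion is a fixed ratio:
#' `D_C = k_d * (corneal_index - 1) / (keratometric_index - 1)`.
#'
#' @param k_d Corneal power on the keratometer scale (D); vectorised.
#' @param params A [vergence_params()] object.
#' @return Physical corneal power in dioptres.
#' @examples
#' corneal_power(43.52)  # 42.746 D
#' @export
corneal_power <- function(k_d, params = vergence_params()) {
  stopifnot(inherits(params, "vergence_params"))
  k_d * (params$corneal_index - 1) / (params$keratometric_index - 1)
}

## spectacle-plane refraction -> corneal-plane vergence and back
.to_corneal_plane <- function(rx_d, vertex_mm) {
  rx_d / (1 - rx_d * vertex_mm / 1000)
}
.to_spectacle_plane <- function(ref_c, vertex_mm) {
  ref_c / (1 + ref_c * vertex_mm / 1000)
}

#' Predicted spectacle refraction of a pseudophakic eye
#'
#' Thin-lens vergence chain: light from a spectacle correction `R_x` at the
#' vertex distance is translated to the corneal plane, refracted by the
#' cornea, translated through aqueous to the IOL plane at depth `elp_mm`,
#' refracted by the IOL, and must focus on the retina at `al_eff_mm`.
#' Solving that chain for `R_x` given an IOL power `iol_power_d` yields the
#' predicted spherical equivalent.  All arguments are vectorised and
#' recycled.
#'
#' @param al_eff_mm Effective axial length entered into the optics (mm);
#'   conventional AL or CMAL depending on the formula variant.
#' @param d_c Physical corneal power (D), e.g. from [corneal_power()].
#' @param elp_mm Effective lens position, cornea to IOL plane (mm).
#' @param iol_power_d IOL power at the IOL plane (D).
#' @param params A [vergence_params()] object.
#' @return Predicted spectacle-plane spherical equivalent (D).
#' @examples
#' predict_refraction(26.663, corneal_power(43.52), 5.63, 11.47)
#' @export
predict_refraction <- function(al_eff_mm, d_c, elp_mm, iol_power_d,
                               params = vergence_params()) {
  stopifnot(inherits(params, "vergence_params"))
  n1000 <- params$n_aqueous * 1000
  if (any(elp_mm >= al_eff_mm))
    stop("invalid optics: ELP must be anterior to the retina (elp_mm < al_eff_mm)",
         call. = FALSE)
  ## n/(L-d) - n/(n/z - d) = D_L, solved for z then for R_x
  a <- n1000 / (al_eff_mm - elp_mm) - iol_power_d
  if (any(!is.finite(a) | abs(a) < 1e-12))
    stop("invalid optics: degenerate vergence (zero denominator)", call. = FALSE)
  z <- n1000 / (n1000 / a + elp_mm)
  ref_c <- z - d_c
  .to_spectacle_plane(ref_c, params$vertex_mm)
}

#' Emmetropic IOL power
#'
#' Closed-form IOL power that makes the eye emmetropic (zero spectacle
#' refraction) for a given effective axial length, corneal power and ELP:
#' `D_L = n/(L - d) - n/(n/D_C - d)` with reduced vergences in dioptres.
#' Inverts [predict_refraction()] at `R_x = 0`.
#'
#' @inheritParams predict_refraction
#' @return IOL power in dioptres (not snapped to any manufacturing grid).
#' @examples
#' emmetropic_power(26.663, corneal_power(43.52), 5.63)
#' @export
emmetropic_power <- function(al_eff_mm, d_c, elp_mm, params = vergence_params()) {
  stopifnot(inherits(params, "vergence_params"))
  n1000 <- params$n_aqueous * 1000
  if (any(elp_mm >= al_eff_mm))
    stop("invalid optics: ELP must be anterior to the retina (elp_mm < al_eff_mm)",
         call. = FALSE)
  denom <- n1000 / d_c - elp_mm
  if (any(abs(denom) < 1e-12))
    stop("invalid optics: degenerate vergence (zero denominator)", call. = FALSE)
  n1000 / (al_eff_mm - elp_mm) - n1000 / denom
}

#' Back-calculate the effective lens position from an observed refraction
#'
#' The reference ("back-calculated") ELP is the lens position at which the
#' thin-lens model reproduces the actually observed postoperative refraction
#' with the actually implanted IOL power.  The vergence chain is a quadratic
#' in the ELP `d`:
#' `D_L d^2 - D_L (L + C) d + D_L L C - n (C - L) = 0`, `C = n / z`,
#' where `z` is the corneal-plane vergence implied by the observed
#' refraction plus corneal power (reduced, dioptres; `n` in mm-dioptre
#' units).  The root inside the anatomic range (1, 10) mm is returned; if
#' both roots fall inside, the smaller (anatomically plausible) root is
#' chosen with a warning.  Eyes with no admissible root return `NA` with a
#' warning, so callers can exclude them listwise.
#'
#' @inheritParams predict_refraction
#' @param iol_power_d Implanted IOL power (D).
#' @param actual_se_d Observed postoperative spherical equivalent at the
#'   spectacle plane (D).
#' @param lower,upper Admissible anatomic range for the ELP root (mm).
#' @return Back-calculated ELP in mm (`NA` for flagged eyes).
#' @examples
#' back_calculate_elp(26.663, corneal_power(43.52), 11.47, -0.275)
#' @export
back_calculate_elp <- function(al_eff_mm, d_c, iol_power_d, actual_se_d,
                               params = vergence_params(),
                               lower = 1, upper = 10) {
  stopifnot(inherits(params, "vergence_params"))
  n1000 <- params$n_aqueous * 1000
  m <- max(length(al_eff_mm), length(d_c), length(iol_power_d), length(actual_se_d))
  L <- rep_len(al_eff_mm, m); Dc <- rep_len(d_c, m)
  P <- rep_len(iol_power_d, m); se <- rep_len(actual_se_d, m)
  z <- Dc + .to_corneal_plane(se, params$vertex_mm)
  C <- n1000 / z
  qa <- P
  qb <- -P * (L + C)
  qc <- P * L * C - n1000 * (C - L)
  disc <- qb^2 - 4 * qa * qc
  out <- rep(NA_real_, m)
  ok <- is.finite(disc) & disc >= 0 & abs(qa) > 1e-12
  r1 <- r2 <- rep(NA_real_, m)
  r1[ok] <- (-qb[ok] - sqrt(disc[ok])) / (2 * qa[ok])
  r2[ok] <- (-qb[ok] + sqrt(disc[ok])) / (2 * qa[ok])
  in1 <- ok & r1 > lower & r1 < upper
  in2 <- ok & r2 > lower & r2 < upper
  both <- in1 & in2
  if (any(both))
    warning(sum(both), " eye(s) with two anatomically plausible ELP roots; ",
            "choosing the smaller root", call. = FALSE)
  out[in1] <- r1[in1]
  out[!in1 & in2] <- r2[!in1 & in2]
  if (anyNA(out))
    warning(sum(is.na(out)), " eye(s) with no ELP root in (", lower, ", ",
            upper, ") mm flagged as NA", call. = FALSE)
  out
}

#' Recommend an IOL power from a manufacturing grid
#'
#' Evaluates [predict_refraction()] over the available powers and returns
#' the one whose predicted spherical equivalent is closest to
#' `target_se_d`.  Exact ties are broken toward the higher power, i.e. the
#' more myopic outcome, which is the usual surgical convention for
#' avoiding a hyperopic surprise.
#'
#' @inheritParams predict_refraction
#' @param grid Available IOL powers (D); default 6.0-30.0 D in 0.5 D steps.
#' @param target_se_d Desired postoperative spherical equivalent (D).
#' @return The recommended grid power (scalar if the biometry inputs are
#'   scalar, otherwise a vector with one power per eye).
#' @examples
#' recommend_iol_power(26.663, corneal_power(43.52), 5.63)
#' @export
recommend_iol_power <- function(al_eff_mm, d_c, elp_mm,
                                grid = seq(6, 30, by = 0.5),
                                target_se_d = 0,
                                params = vergence_params()) {
  if (length(grid) == 0) stop("empty IOL power grid", call. = FALSE)
  grid <- sort(unique(grid), decreasing = TRUE)  # first minimum = higher power
  m <- max(length(al_eff_mm), length(d_c), length(elp_mm), length(target_se_d))
  L <- rep_len(al_eff_mm, m); Dc <- rep_len(d_c, m)
  d <- rep_len(elp_mm, m); tgt <- rep_len(target_se_d, m)
  ## eyes x grid matrix of |predicted SE - target|
  err <- vapply(grid, function(p)
    abs(predict_refraction(L, Dc, d, p, params) - tgt), numeric(m))
  err <- matrix(err, nrow = m)
  grid[max.col(-err, ties.method = "first")]
}
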