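#' Cooke-modified axial length (CMAL)
#'
#' Linear transform of conventional optical-biometer axial length and lens
#' thickness approximating sum-of-segments axial length:
#' `CMAL = 1.23853 + 0.95855 * AL - 0.05467 * LT`.
#' For long eyes with typical lens thickness the CMAL is shorter than the
#' conventional AL, which is the root of the mechanism this package
#' analyses.
#'
#' @param al_mm Conventional axial length (mm); vectorised.
#' @param lt_mm Lens thickness (mm); vectorised.
#' @return Modified axial length (mm).
#' @seealso [reversed_cmal()] for the exact inverse at fixed lens thickness.
#' @examples
#' cmal(26.77, 4.31)  # 26.663
#' @export
cmal <- function(al_mm, lt_mm) {
  1.23853 + 0.95855 * al_mm - 0.05467 * lt_mm
}

#' Reverse the CMAL transform
#'
#' Recovers the conventional axial length from a CMAL value at fixed lens
#' thickness: `AL = (CMAL + 0.05467 * LT - 1.23853) / 0.95855`.  Exact
#' inverse of [cmal()].
#'
#' @param al_like_mm A CMAL-scale axial length (mm).
#' @param lt_mm Lens thickness (mm).
#' @return Conventional axial length (mm).
#' @examples
#' reversed_cmal(cmal(26.77, 4.31), 4.31)  # 26.77
#' @export
reversed_cmal <- function(al_like_mm, lt_mm) {
  (al_like_mm + 0.05467 * lt_mm - 1.23853) / 0.95855
}

#' Effective axial length for a formula variant
#'
#' @param al_mm Conventional axial length (mm).
#' @param lt_mm Lens thickness (mm); only used by the CMAL variant.
#' @param variant `"al"` (conventional) or `"cmal"`.
#' @return Effective axial length (mm).
#' @export
effective_al <- function(al_mm, lt_mm, variant = c("al", "cmal")) {
  variant <- match.arg(variant)
  if (variant == "al") al_mm else cmal(al_mm, lt_mm)
}

#' Haigis ELP predictor constants
#'
#' The Haigis formula predicts the effective lens position linearly from
#' preoperative anterior chamber depth and (effective) axial length:
#' `ELP = a0 + a1 * ACD + a2 * AL`.  `a0` absorbs the lens/surgeon offset
#' (the constant adjusted in single optimization); `a1` and `a2` weight the
#' anterior-segment and axial contributions and default to the classical
#' 0.4 / 0.1.
#'
#' @param a0 Intercept (mm).
#' @param a1 ACD coefficient (dimensionless).
#' @param a2 Axial-length coefficient (dimensionless).
#' @return An object of class `haigis_constants`.
#' @examples
#' haigis_constants(1.523)
#' @export
haigis_constants <- function(a0, a1 = 0.4, a2 = 0.1) {
  stopifnot(is.finite(a0), is.finite(a1), is.finite(a2))
  if (a2 < 0)
    stop("a2 must be non-negative (constrained fits clamp it at 0)", call. = FALSE)
  structure(list(a0 = a0, a1 = a1, a2 = a2), class = "haigis_constants")
}

#' @export
print.haigis_constants <- function(x, ...) {
  cat(sprintf("Haigis constants: a0 = %.4g, a1 = %.4g, a2 = %.4g\n",
              x$a0, x$a1, x$a2))
  invisible(x)
}

#' Haigis predicted effective lens position
#'
#' @param constants A [haigis_constants()] object.
#' @param acd_mm Preoperative anterior chamber depth (mm, epithelium to
#'   anterior lens surface).
#' @param al_eff_mm Effective axial length (mm): conventional AL for the AL
#'   variant, [cmal()] for the CMAL variant.
#' @return Predicted ELP (mm).
#' @examples
#' haigis_elp(haigis_constants(1.556), 3.51, cmal(26.77, 4.31))  # 5.63
#' @export
haigis_elp <- function(constants, acd_mm, al_eff_mm) {
  stopifnot(inherits(constants, "haigis_constants"))
  constants$a0 + constants$a1 * acd_mm + constants$a2 * al_eff_mm
}

#' Haigis predicted refraction
#'
#' Predicts the spectacle-plane spherical equivalent for an eye and an IOL
#' power with the Haigis formula: ELP from [haigis_elp()], corneal power
#' converted by [corneal_power()], refraction from the thin-lens vergence
#' chain.  In the CMAL variant the modified axial length replaces the
#' conventional AL everywhere, in the ELP predictor and in the vergence
#' optics alike.
#'
#' @inheritParams haigis_elp
#' @param al_mm Conventional axial length (mm).
#' @param k_d Keratometer-scale corneal power (D; TK accepted on the same
#'   scale).
#' @param lt_mm Lens thickness (mm); required for the CMAL variant.
#' @param iol_power_d IOL power (D).
#' @param variant `"al"` or `"cmal"`.
#' @param params A [vergence_params()] object.
#' @return Predicted spherical equivalent (D).
#' @export
haigis_predict <- function(constants, al_mm, k_d, acd_mm, lt_mm = NULL,
                           iol_power_d, variant = c("al", "cmal"),
                           params = vergence_params()) {
  variant <- match.arg(variant)
  if (variant == "cmal" && is.null(lt_mm))
    stop("lt_mm is required for the CMAL variant", call. = FALSE)
  al_eff <- effective_al(al_mm, lt_mm, variant)
  elp <- haigis_elp(constants, acd_mm, al_eff)
  predict_refraction(al_eff, corneal_power(k_d, params), elp, iol_power_d, params)
}

## Shared vergence back-solve used by SRK/T and Holladay 1 (both published
## with the same retinal-image structure, differing in corneal index and
## retinal-thickness convention).  All lengths mm, powers D.
.retzlaff_refraction <- function(r, lopt, elp, p, na, ncm1, v) {
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    p * (lopt - elp) * (na * r - ncm1 * elp)
  den <- na * (v * (na * r - ncm1 * lopt) + lopt * r) -
    0.001 * p * (lopt - elp) * (v * (na * r - ncm1 * elp) + elp * r)
  num / den
}

#' SRK/T predicted refraction
#'
#' The published SRK/T formula: regression-corrected axial length (LCOR),
#' corneal width and corneal height give the estimated ELP from the
#' A-constant; the refraction for a given IOL power follows from the
#' theoretic vergence part with retinal-thickness-corrected optical axial
#' length.  Eyes whose corneal-height square root argument is negative are
#' flagged `NA` (the published formula clamps the width term; here the case
#' is reported instead so it can be excluded listwise).
#'
#' @param al_mm Axial length entered into the formula (mm); pass
#'   [cmal()] output for the CMAL variant (wholesale substitution).
#' @param k_d Corneal power, keratometer scale (D).
#' @param a_constant SRK/T A-constant.
#' @param iol_power_d IOL power (D).
#' @param vertex_mm Spectacle vertex distance (mm).
#' @return Predicted spectacle-plane spherical equivalent (D); `NA` for
#'   flagged eyes.
#' @export
srkt_predict <- function(al_mm, k_d, a_constant, iol_power_d, vertex_mm = 12) {
  r <- 337.5 / k_d
  lcor <- ifelse(al_mm > 24.2,
                 -3.446 + 1.715 * al_mm - 0.0237 * al_mm^2,
                 al_mm)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k_d
  arg <- r^2 - cw^2 / 4
  h <- ifelse(arg >= 0, r - sqrt(pmax(arg, 0)), NA_real_)
  if (anyNA(h))
    warning(sum(is.na(h)), " eye(s) with negative corneal-height argument ",
            "flagged as NA", call. = FALSE)
  acd_const <- 0.62467 * a_constant - 68.747
  elp <- h + (acd_const - 3.336)
  lopt <- al_mm + (0.65696 - 0.02029 * al_mm)  # retinal thickness correction
  .retzlaff_refraction(r, lopt, elp, iol_power_d, na = 1.336, ncm1 = 0.333,
                       v = vertex_mm)
}

#' Hoffer Q predicted refraction
#'
#' The published Hoffer Q formula: personalized ACD (pACD) plus axial and
#' tangent keratometric terms give the predicted chamber depth (axial
#' length clamped to 18.5-31 mm inside the ELP model only); refraction for
#' a given IOL power is obtained by algebraically inverting Hoffer's
#' vergence expression for power, with the corneal-plane/spectacle-plane
#' conversion at the stated vertex distance.
#'
#' @inheritParams srkt_predict
#' @param pacd Personalized ACD constant (mm).
#' @return Predicted spectacle-plane spherical equivalent (D).
#' @export
hofferq_predict <- function(al_mm, k_d, pacd, iol_power_d, vertex_mm = 12) {
  alc <- pmin(pmax(al_mm, 18.5), 31)
  m <- ifelse(alc <= 23, 1, -1)
  g <- ifelse(alc <= 23, 28, 23.5)
  deg <- pi / 180  # published tangent terms take their arguments in degrees
  elp <- pacd + 0.3 * (alc - 23.5) + tan(k_d * deg)^2 +
    0.1 * m * (23.5 - alc)^2 * tan(0.1 * (g - alc)^2 * deg) - 0.99166
  t1 <- 1336 / (al_mm - elp - 0.05)
  rc <- 1.336 / ((elp + 0.05) / 1000 + 1.336 / (t1 - iol_power_d)) - k_d
  rc / (1 + rc * vertex_mm / 1000)
}

#' Holladay 1 predicted refraction
#'
#' The published Holladay 1 formula: the anatomical anterior chamber depth
#' follows from corneal radius and the scaled corneal width (AG, capped at
#' 13.5 mm); adding the surgeon factor gives the ELP; refraction for a
#' given IOL power follows from the vergence part with corneal index 4/3
#' and a fixed 0.2 mm retinal-thickness correction.
#'
#' @inheritParams srkt_predict
#' @param sf Surgeon factor (mm).
#' @return Predicted spectacle-plane spherical equivalent (D); `NA` for
#'   eyes whose chamber-depth square root argument is negative.
#' @export
holladay1_predict <- function(al_mm, k_d, sf, iol_power_d, vertex_mm = 12) {
  r <- 337.5 / k_d
  ag <- pmin(12.5 * al_mm / 23.45, 13.5)
  arg <- r^2 - ag^2 / 4
  aacd <- ifelse(arg >= 0, 0.56 + r - sqrt(pmax(arg, 0)), NA_real_)
  if (anyNA(aacd))
    warning(sum(is.na(aacd)), " eye(s) with negative chamber-depth argument ",
            "flagged as NA", call. = FALSE)
  elp <- aacd + sf
  alm <- al_mm + 0.2
  .retzlaff_refraction(r, alm, elp, iol_power_d, na = 1.336, ncm1 = 1 / 3,
                       v = vertex_mm)
}
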