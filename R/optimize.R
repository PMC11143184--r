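.formula_ids <- c("haigis", "srkt", "hofferq", "holladay1")

#' Predicted refraction of every eye in a cohort under one formula
#'
#' Dispatch helper shared by the optimizer and the study pipeline.  For the
#' Haigis formula `constant` may be a full [haigis_constants()] object or a
#' bare `a0` (with `a1 = 0.4`, `a2 = 0.1`); for SRK/T, Hoffer Q and
#' Holladay 1 it is the A-constant, pACD and surgeon factor respectively.
#' The CMAL variant substitutes [cmal()] for the axial length everywhere it
#' appears in the formula.
#'
#' @param formula_id One of `"haigis"`, `"srkt"`, `"hofferq"`, `"holladay1"`.
#' @param cases A cohort `data.frame` (see [generate_cohort()]).
#' @param constant Formula constant as described above.
#' @param variant `"al"` or `"cmal"`.
#' @param params A [vergence_params()] object (Haigis optics only).
#' @return Predicted spherical equivalent per eye (D), `NA` for flagged
#'   eyes.
#' @export
predict_cohort <- function(formula_id, cases, constant,
                           variant = c("al", "cmal"),
                           params = vergence_params()) {
  formula_id <- match.arg(formula_id, .formula_ids)
  variant <- match.arg(variant)
  al_eff <- effective_al(cases$al_mm, cases$lt_mm, variant)
  switch(formula_id,
    haigis = {
      cst <- if (inherits(constant, "haigis_constants")) constant
             else haigis_constants(constant)
      elp <- haigis_elp(cst, cases$acd_mm, al_eff)
      predict_refraction(al_eff, corneal_power(cases$k_d, params), elp,
                         cases$iol_power_d, params)
    },
    srkt = srkt_predict(al_eff, cases$k_d, constant, cases$iol_power_d,
                        params$vertex_mm),
    hofferq = hofferq_predict(al_eff, cases$k_d, constant,
                              cases$iol_power_d, params$vertex_mm),
    holladay1 = holladay1_predict(al_eff, cases$k_d, constant,
                                  cases$iol_power_d, params$vertex_mm))
}

.single_brackets <- list(haigis = c(-5, 10), srkt = c(110, 126),
                         hofferq = c(0, 10), holladay1 = c(-2, 5))

#' Single-constant lens-constant optimization
#'
#' Finds the formula constant (Haigis `a0`, SRK/T A-constant, Hoffer Q
#' pACD, or Holladay 1 surgeon factor) at which the cohort's mean
#' prediction error (actual minus predicted refraction) is zero, by
#' bracketed root-finding; for the Haigis formula `a1` and `a2` are held at
#' their defaults 0.4 and 0.1, so single optimization is purely an
#' intercept shift of the ELP predictor.  Eyes flagged by the formula are
#' excluded listwise.
#'
#' @param formula_id One of `"haigis"`, `"srkt"`, `"hofferq"`, `"holladay1"`.
#' @param cases Cohort `data.frame` with implanted powers and observed
#'   refractions.
#' @param variant `"al"` or `"cmal"`.
#' @param a1,a2 Haigis slope constants held fixed during single
#'   optimization.
#' @param tol Tolerance on the residual mean error (D).
#' @param params A [vergence_params()] object.
#' @return A list of class `elp_optimization` with `formula_id`, `variant`,
#'   `mode = "single"`, `constants` (a [haigis_constants()] for Haigis, a
#'   scalar otherwise), `me_after` and `n_used`.
#' @export
optimize_single <- function(formula_id, cases, variant = c("al", "cmal"),
                            a1 = 0.4, a2 = 0.1, tol = 1e-4,
                            params = vergence_params()) {
  formula_id <- match.arg(formula_id, .formula_ids)
  variant <- match.arg(variant)
  if (nrow(cases) < 2) stop("need at least 2 cases", call. = FALSE)
  me_at <- function(const) {
    cst <- if (formula_id == "haigis") haigis_constants(const, a1, a2) else const
    pred <- predict_cohort(formula_id, cases, cst, variant, params)
    mean(cases$postop_se_d - pred, na.rm = TRUE)
  }
  br <- .single_brackets[[formula_id]]
  f_lo <- me_at(br[1]); f_hi <- me_at(br[2])
  if (!is.finite(f_lo) || !is.finite(f_hi) || sign(f_lo) == sign(f_hi))
    stop("bracket failure: mean error does not change sign over [",
         br[1], ", ", br[2], "] for ", formula_id, call. = FALSE)
  root <- uniroot(me_at, br, f.lower = f_lo, f.upper = f_hi,
                  tol = .Machine$double.eps^0.5)$root
  me_after <- me_at(root)
  if (abs(me_after) > tol)
    stop("single optimization failed to reach |ME| <= ", tol, call. = FALSE)
  cst <- if (formula_id == "haigis") haigis_constants(root, a1, a2) else root
  pred <- predict_cohort(formula_id, cases, cst, variant, params)
  structure(list(formula_id = formula_id, variant = variant,
                 mode = "single", constants = cst,
                 me_after = me_after, n_used = sum(!is.na(pred))),
            class = "elp_optimization")
}

#' Triple-constant optimization of the Haigis formula
#'
#' A complete retraining of the ELP predictor: the reference ELP of every
#' eye is back-calculated from the implanted power and observed refraction
#' (with the variant's effective axial length in the optics), then
#' ordinary least squares regresses the reference ELP on (1, ACD, AL_eff).
#' If the fitted axial coefficient `a2` comes out negative it is clamped to
#' zero and the fit repeated without the axial term (one-constraint
#' active set).  Finally `a0` is shifted by root-finding so the cohort's
#' mean refraction-space prediction error is zero, reconciling the
#' ELP-space fit with the refraction-space optimization convention.
#'
#' @param cases Cohort `data.frame`.
#' @param variant `"al"` or `"cmal"`.
#' @param tol Tolerance on the residual mean error (D).
#' @param params A [vergence_params()] object.
#' @return A list of class `elp_optimization` with `mode = "triple"`,
#'   `constants` a [haigis_constants()], `me_after`, `n_used`, and
#'   `a2_clamped` (logical).
#' @export
optimize_triple_haigis <- function(cases, variant = c("al", "cmal"),
                                   tol = 1e-4, params = vergence_params()) {
  variant <- match.arg(variant)
  al_eff <- effective_al(cases$al_mm, cases$lt_mm, variant)
  d_c <- corneal_power(cases$k_d, params)
  ref_elp <- back_calculate_elp(al_eff, d_c, cases$iol_power_d,
                                cases$postop_se_d, params)
  ok <- !is.na(ref_elp)
  if (sum(ok) < 10)
    stop("need at least 10 cases with a valid back-calculated ELP",
         call. = FALSE)
  acd <- cases$acd_mm[ok]; ale <- al_eff[ok]; y <- ref_elp[ok]
  X <- cbind(1, acd, ale)
  if (qr(X)$rank < 3)
    stop("rank-deficient design: ACD or axial length has no variation",
         call. = FALSE)
  beta <- unname(qr.solve(X, y))
  a2_clamped <- FALSE
  if (beta[3] < 0) {
    a2_clamped <- TRUE
    beta <- c(unname(qr.solve(cbind(1, acd), y)), 0)
  }
  fit <- cases[ok, , drop = FALSE]
  me_at <- function(a0) {
    cst <- haigis_constants(a0, beta[2], beta[3])
    mean(fit$postop_se_d -
           predict_cohort("haigis", fit, cst, variant, params))
  }
  root <- uniroot(me_at, interval = beta[1] + c(-3, 3), extendInt = "yes",
                  tol = .Machine$double.eps^0.5)$root
  me_after <- me_at(root)
  if (abs(me_after) > tol)
    stop("triple optimization failed to reach |ME| <= ", tol, call. = FALSE)
  structure(list(formula_id = "haigis", variant = variant, mode = "triple",
                 constants = haigis_constants(root, beta[2], beta[3]),
                 me_after = me_after, n_used = sum(ok),
                 a2_clamped = a2_clamped),
            class = "elp_optimization")
}

#' @export
print.elp_optimization <- function(x, ...) {
  cat(sprintf("%s optimization of %s (%s variant), n = %d\n",
              x$mode, x$formula_id, toupper(x$variant), x$n_used))
  if (inherits(x$constants, "haigis_constants")) print(x$constants)
  else cat(sprintf("constant: %.4f\n", x$constants))
  cat(sprintf("residual mean error: %.2e D\n", x$me_after))
  invisible(x)
}
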