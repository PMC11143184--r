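#' Run the full lens-position mechanism analysis on a cohort
#'
#' Orchestrates the whole analysis for the four Haigis variants
#' (conventional AL / CMAL, single / triple optimization) and the three
#' older single-constant formulas (SRK/T, Hoffer Q, Holladay 1, each
#' optimized in both axial-length variants):
#' \itemize{
#'   \item `constants_table`: optimized constants with residual mean error;
#'   \item `error_table`: ME/SD/RMSE/MAE/MedAE per formula-variant for the
#'     whole cohort and the long-eye subgroup (`al_mm > long_al_cutoff`);
#'   \item `elp_curves`: per Haigis variant, predicted and back-calculated
#'     reference ELP binned against conventional AL;
#'   \item `acd_curve`: mean ACD binned against conventional AL;
#'   \item `rotation_table`: slope of binned mean error versus AL per older
#'     formula and variant (a clockwise rotation shows as a smaller CMAL
#'     slope), unweighted least squares over bins with at least
#'     `min_bin_n` eyes;
#'   \item `acd_subgroup_me`: mean error within the long-eye ACD subgroups
#'     (mean +/- 1 SD boundaries);
#'   \item `eyemodel`: the worked example at the long-eye mean biometry
#'     using the cohort's single-optimized constants.
#' }
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param bin_width Axial-length bin width (mm).
#' @param long_al_cutoff Long-eye cutoff (mm).
#' @param min_bin_n Minimum per-bin count entering rotation slopes.
#' @param params A [vergence_params()] object.
#' @return A list of class `study_report`.
#' @export
run_study <- function(cohort, bin_width = 0.5, long_al_cutoff = 26,
                      min_bin_n = 5, params = vergence_params()) {
  stopifnot(all(.required_cols %in% names(cohort)))
  long <- cohort$al_mm > long_al_cutoff
  variants <- c("al", "cmal")

  ## ---- Haigis: optimize, per-eye ELPs, error summaries, curves ----
  opts <- list()
  constants_rows <- list()
  error_rows <- list()
  curve_rows <- list()
  for (v in variants) {
    for (mode in c("single", "triple")) {
      opt <- if (mode == "single")
        optimize_single("haigis", cohort, v, params = params)
      else optimize_triple_haigis(cohort, v, params = params)
      key <- paste(v, mode, sep = "_")
      opts[[key]] <- opt
      cst <- opt$constants
      al_eff <- effective_al(cohort$al_mm, cohort$lt_mm, v)
      d_c <- corneal_power(cohort$k_d, params)
      pred_elp <- haigis_elp(cst, cohort$acd_mm, al_eff)
      ref_elp <- back_calculate_elp(al_eff, d_c, cohort$iol_power_d,
                                    cohort$postop_se_d, params)
      err <- cohort$postop_se_d -
        predict_refraction(al_eff, d_c, pred_elp, cohort$iol_power_d, params)
      constants_rows[[key]] <- data.frame(
        formula = "haigis", variant = v, mode = mode,
        a0 = cst$a0, a1 = cst$a1, a2 = cst$a2,
        me_after = opt$me_after, n_used = opt$n_used)
      error_rows[[paste0(key, "_whole")]] <- cbind(
        data.frame(formula = "haigis", variant = v, mode = mode,
                   subgroup = "whole"), summarize_errors(err))
      error_rows[[paste0(key, "_long")]] <- cbind(
        data.frame(formula = "haigis", variant = v, mode = mode,
                   subgroup = "long"), summarize_errors(err[long]))
      pb <- bin_by_al(cohort$al_mm, pred_elp, bin_width)
      rb <- bin_by_al(cohort$al_mm, ref_elp, bin_width)
      mrg <- merge(pb, rb, by = "bin_center", suffixes = c("_predicted", "_reference"))
      curve_rows[[key]] <- cbind(data.frame(variant = v, mode = mode), mrg)
    }
  }

  ## ---- older formulas: single optimization, errors, rotation ----
  older <- c("srkt", "hofferq", "holladay1")
  rotation_rows <- list()
  older_errors <- list()
  for (f in older) {
    for (v in variants) {
      opt <- optimize_single(f, cohort, v, params = params)
      key <- paste(f, v, sep = "_")
      opts[[key]] <- opt
      err <- cohort$postop_se_d -
        predict_cohort(f, cohort, opt$constants, v, params)
      older_errors[[key]] <- err
      constants_rows[[key]] <- data.frame(
        formula = f, variant = v, mode = "single",
        a0 = opt$constants, a1 = NA_real_, a2 = NA_real_,
        me_after = opt$me_after, n_used = opt$n_used)
      error_rows[[paste0(key, "_whole")]] <- cbind(
        data.frame(formula = f, variant = v, mode = "single",
                   subgroup = "whole"), summarize_errors(err))
      error_rows[[paste0(key, "_long")]] <- cbind(
        data.frame(formula = f, variant = v, mode = "single",
                   subgroup = "long"), summarize_errors(err[long]))
      b <- bin_by_al(cohort$al_mm, err, bin_width)
      b <- b[b$n >= min_bin_n, , drop = FALSE]
      slope <- if (nrow(b) >= 2)
        unname(coef(lm(mean ~ bin_center, data = b))[2]) else NA_real_
      rotation_rows[[key]] <- data.frame(formula = f, variant = v,
                                         slope_d_per_mm = slope,
                                         n_bins = nrow(b))
    }
  }

  ## ---- ACD curve and long-eye ACD subgroup mean errors ----
  acd_curve <- bin_by_al(cohort$al_mm, cohort$acd_mm, bin_width)
  groups <- acd_subgroups(cohort, long_al_cutoff)
  subgroup_rows <- list()
  for (v in variants) {
    key <- paste(v, "single", sep = "_")
    cst <- opts[[key]]$constants
    for (g in c("short", "medium", "long")) {
      sub <- groups[[g]]
      if (nrow(sub) == 0) next
      err <- sub$postop_se_d - predict_cohort("haigis", sub, cst, v, params)
      subgroup_rows[[paste(v, g)]] <- data.frame(
        formula = "haigis_single", variant = v, acd_group = g,
        me_d = mean(err, na.rm = TRUE), n = nrow(sub))
    }
  }

  ## ---- worked example at the long-eye mean biometry ----
  long_cases <- cohort[long, , drop = FALSE]
  eyemodel <- NULL
  if (nrow(long_cases) >= 3) {
    eyemodel <- eye_model(
      al_mm = mean(long_cases$al_mm), k_d = mean(long_cases$k_d),
      acd_mm = mean(long_cases$acd_mm), lt_mm = mean(long_cases$lt_mm),
      iol_power_d = mean(long_cases$iol_power_d),
      actual_se_d = mean(long_cases$postop_se_d),
      a0_al = opts[["al_single"]]$constants$a0,
      a0_cmal = opts[["cmal_single"]]$constants$a0,
      params = params)
  }

  structure(list(
    constants_table = do.call(rbind, c(constants_rows, make.row.names = FALSE)),
    error_table = do.call(rbind, c(error_rows, make.row.names = FALSE)),
    elp_curves = do.call(rbind, c(curve_rows, make.row.names = FALSE)),
    acd_curve = acd_curve,
    rotation_table = do.call(rbind, c(rotation_rows, make.row.names = FALSE)),
    acd_subgroup_me = do.call(rbind, c(subgroup_rows, make.row.names = FALSE)),
    acd_boundaries = groups$boundaries,
    eyemodel = eyemodel,
    settings = list(bin_width = bin_width, long_al_cutoff = long_al_cutoff,
                    min_bin_n = min_bin_n),
    n = nrow(cohort), n_long = sum(long)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Lens-position mechanism study: %d eyes (%d with AL > %.1f mm)\n\n",
              x$n, x$n_long, x$settings$long_al_cutoff))
  cat("Optimized constants:\n")
  print(format(x$constants_table, digits = 4), row.names = FALSE)
  cat("\nLong-eye prediction errors (D):\n")
  tab <- x$error_table[x$error_table$subgroup == "long",
                       c("formula", "variant", "mode", "me_d", "sd_d", "rmse_d")]
  print(format(tab, digits = 3), row.names = FALSE)
  if (!is.null(x$eyemodel)) {
    cat("\nWorked example at the long-eye mean biometry:\n")
    print(x$eyemodel)
  }
  invisible(x)
}

#' Worked eye model at a single (typically mean) biometry
#'
#' Reproduces the mechanism on one eye: for the single-optimized AL and
#' CMAL Haigis variants it computes the predicted ELP, the back-calculated
#' reference ELP (from the implanted power and observed refraction), the
#' ELP error (reference minus predicted), the refraction impact of
#' substituting the reference for the predicted ELP at the fixed implanted
#' power, and the grid power each variant would have recommended.  An
#' overestimated ELP yields a higher-powered recommendation and hence a
#' myopic outcome.
#'
#' @param al_mm,k_d,acd_mm,lt_mm Mean biometry (mm, D, mm, mm).
#' @param iol_power_d Implanted IOL power (D).
#' @param actual_se_d Observed postoperative spherical equivalent (D).
#' @param a0_al,a0_cmal Single-optimized `a0` of the AL and CMAL variants.
#' @param a1,a2 Shared Haigis slope constants.
#' @param grid Available IOL powers (D).
#' @param params A [vergence_params()] object.
#' @return A `data.frame` of class `eye_model` with one row per variant:
#'   `variant, al_eff_mm, predicted_elp_mm, reference_elp_mm, elp_error_mm,
#'   predicted_se_d, refraction_impact_d, recommended_power_d`.
#' @examples
#' eye_model(26.77, 43.52, 3.51, 4.31, 11.47, -0.275)
#' @export
eye_model <- function(al_mm, k_d, acd_mm, lt_mm, iol_power_d, actual_se_d,
                      a0_al = 1.523, a0_cmal = 1.556, a1 = 0.4, a2 = 0.1,
                      grid = seq(6, 30, by = 0.5),
                      params = vergence_params()) {
  d_c <- corneal_power(k_d, params)
  rows <- lapply(c("al", "cmal"), function(v) {
    a0 <- if (v == "al") a0_al else a0_cmal
    al_eff <- effective_al(al_mm, lt_mm, v)
    pred_elp <- haigis_elp(haigis_constants(a0, a1, a2), acd_mm, al_eff)
    ref_elp <- back_calculate_elp(al_eff, d_c, iol_power_d, actual_se_d, params)
    pred_se <- predict_refraction(al_eff, d_c, pred_elp, iol_power_d, params)
    impact <- predict_refraction(al_eff, d_c, ref_elp, iol_power_d, params) -
      pred_se
    data.frame(variant = v, al_eff_mm = al_eff,
               predicted_elp_mm = pred_elp, reference_elp_mm = ref_elp,
               elp_error_mm = ref_elp - pred_elp,
               predicted_se_d = pred_se, refraction_impact_d = impact,
               recommended_power_d = recommend_iol_power(
                 al_eff, d_c, pred_elp, grid = grid, params = params))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eye_model", "data.frame")
  out
}

#' @export
print.eye_model <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
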