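#' Configuration of a synthetic surgical cohort
#'
#' Describes the generative model of a synthetic cataract-surgery
#' population: marginal biometry moments, the AL-ACD relationship (an East
#' Asian preset in which chamber deepening plateaus in long eyes, or a
#' Caucasian-like preset in which it keeps rising), a linear generative
#' true-ELP model, and measurement/biological noise on the postoperative
#' refraction.  Defaults emulate a 3100-eye East Asian trifocal-IOL
#' population: AL 23.68 +/- 1.15 mm, K 44.21 +/- 1.40 D, LT 4.47 +/- 0.31 mm,
#' ACD plateauing at 3.5 mm beyond AL 25.5 mm so that long eyes (AL > 26 mm)
#' average ACD ~3.5 mm, and a true-ELP triple (1.304, 0.442, 0.104).
#'
#' The conditional slopes of K and LT on AL (-0.22 D/mm and -0.05 mm/mm)
#' are chosen so the long-eye subgroup means land near 43.5 D and 4.31 mm;
#' the linear ACD trend (slope 0.198 mm/mm) is anchored so that the
#' below-knee line passes through the whole-cohort mean ACD 3.14 mm at mean
#' AL and reaches the 3.5 mm plateau exactly at the knee.
#'
#' @param n Cohort size.
#' @param seed Random seed; the generator draws one stream eye by eye, so a
#'   cohort of size `n` is a prefix of a cohort of size `n + k` at the same
#'   seed.
#' @param al_mean,al_sd Axial length mean and SD (mm).
#' @param al_range Truncation range for AL (mm); sampled by rejection.
#' @param k_mean,k_sd Keratometry marginal mean and SD (D).
#' @param k_al_slope Conditional slope of K on AL (D per mm).
#' @param lt_mean,lt_sd Lens thickness marginal mean and SD (mm).
#' @param lt_al_slope Conditional slope of LT on AL (mm per mm).
#' @param acd_preset `"east_asian_plateau"` or `"caucasian_linear"`.
#' @param acd_base_slope,acd_base_intercept Linear AL-ACD trend (mm/mm, mm);
#'   the default intercept places the plateau level exactly at the knee.
#' @param acd_plateau_mm Plateau level of the East Asian preset (mm).
#' @param acd_knee_mm AL at which the ACD slope flattens (mm).
#' @param acd_noise_sd Residual ACD noise SD (mm).
#' @param elp_true Generative true-ELP model, a [haigis_constants()] object
#'   evaluated on conventional AL.
#' @param refraction_noise_sd SD of postoperative refraction noise (D).
#' @param surgeon_target_d Refraction targeted when choosing the implanted
#'   power (D).
#' @param iol_grid Available IOL powers (D).
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n = 100, seed = 7)
#' @export
cohort_config <- function(n = 3000,
                          seed = 1,
                          al_mean = 23.68, al_sd = 1.15,
                          al_range = c(20.5, 30.0),
                          k_mean = 44.21, k_sd = 1.40, k_al_slope = -0.22,
                          lt_mean = 4.47, lt_sd = 0.31, lt_al_slope = -0.05,
                          acd_preset = c("east_asian_plateau", "caucasian_linear"),
                          acd_base_slope = 0.198,
                          acd_base_intercept = acd_plateau_mm - acd_knee_mm * acd_base_slope,
                          acd_plateau_mm = 3.5,
                          acd_knee_mm = 25.5,
                          acd_noise_sd = 0.22,
                          elp_true = haigis_constants(1.304, 0.442, 0.104),
                          refraction_noise_sd = 0.30,
                          surgeon_target_d = 0,
                          iol_grid = seq(6, 30, by = 0.5)) {
  acd_preset <- match.arg(acd_preset)
  stopifnot(n >= 1, al_sd > 0, k_sd > 0, lt_sd > 0, acd_noise_sd > 0,
            refraction_noise_sd >= 0, length(al_range) == 2,
            al_range[1] < al_range[2], length(iol_grid) >= 1,
            inherits(elp_true, "haigis_constants"))
  if (acd_knee_mm <= al_range[1] || acd_knee_mm >= al_range[2])
    stop("acd_knee_mm must lie inside al_range", call. = FALSE)
  if (k_sd^2 <= (k_al_slope * al_sd)^2)
    stop("k_sd too small for the stated k_al_slope", call. = FALSE)
  if (lt_sd^2 <= (lt_al_slope * al_sd)^2)
    stop("lt_sd too small for the stated lt_al_slope", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 al_mean = al_mean, al_sd = al_sd, al_range = al_range,
                 k_mean = k_mean, k_sd = k_sd, k_al_slope = k_al_slope,
                 lt_mean = lt_mean, lt_sd = lt_sd, lt_al_slope = lt_al_slope,
                 acd_preset = acd_preset,
                 acd_base_slope = acd_base_slope,
                 acd_base_intercept = acd_base_intercept,
                 acd_plateau_mm = acd_plateau_mm,
                 acd_knee_mm = acd_knee_mm,
                 acd_noise_sd = acd_noise_sd,
                 elp_true = elp_true,
                 refraction_noise_sd = refraction_noise_sd,
                 surgeon_target_d = surgeon_target_d,
                 iol_grid = iol_grid),
            class = "cohort_config")
}

#' Expected anterior chamber depth at a given axial length
#'
#' The East Asian preset follows the linear AL-ACD trend below the knee and
#' is capped at the plateau level beyond it, with a 0.5 mm-half-width
#' quadratic blend across the knee so binned curves show no slope
#' discontinuity.  The Caucasian-like preset keeps the uninterrupted linear
#' trend.  Both presets coincide below the blend region.
#'
#' @param al_mm Axial length (mm); vectorised.
#' @param config A [cohort_config()] object.
#' @return Expected ACD (mm).
#' @examples
#' acd_mean_curve(27, cohort_config())  # 3.5 (plateau)
#' @export
acd_mean_curve <- function(al_mm, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  base <- config$acd_base_intercept + config$acd_base_slope * al_mm
  if (config$acd_preset == "caucasian_linear") return(base)
  h <- 0.5
  s <- config$acd_base_slope
  plateau <- config$acd_plateau_mm
  t <- al_mm - config$acd_knee_mm
  ## quadratic joins value and slope of the line at t = -h and of the
  ## plateau at t = +h
  blend <- plateau - s / (4 * h) * t^2 + s / 2 * t - s * h / 4
  ifelse(t <= -h, base, ifelse(t >= h, plateau, blend))
}

.required_cols <- c("eye_id", "al_mm", "k_d", "acd_mm", "lt_mm",
                    "iol_power_d", "postop_se_d")
.optional_cols <- c("cct_um", "wtw_mm")

#' Generate a synthetic surgical cohort
#'
#' Draws eyes one at a time from a single RNG stream: AL from a truncated
#' normal (rejection sampling), K and LT from conditional normals whose
#' residual SDs are set so the configured marginal SDs hold, ACD as the
#' preset mean curve plus noise.  Each eye's true ELP is the linear model
#' `a0 + a1 * ACD + a2 * AL` from `config$elp_true`; the implanted power is
#' the grid power whose thin-lens prediction (conventional AL, true ELP) is
#' closest to the surgeon's target; the observed postoperative spherical
#' equivalent is that prediction plus Gaussian noise.  Conventional AL is
#' treated as the optically true length, so the AL-variant Haigis formula
#' is well-specified on these cohorts and any CMAL-variant bias arises
#' purely from the lens-position mechanism.
#'
#' Biometry invariants (30 < K < 60, 1 < ACD < 6, 2 < LT < 8) are enforced
#' by per-variable redraw, which at the default noise levels essentially
#' never triggers.
#'
#' @param config A [cohort_config()] object.
#' @param params A [vergence_params()] object for the optics.
#' @return A `data.frame` with columns `eye_id, al_mm, k_d, acd_mm, lt_mm,
#'   iol_power_d, postop_se_d, elp_true_mm` (the last records the
#'   generative truth for recovery checks).
#' @examples
#' head(generate_cohort(cohort_config(n = 5, seed = 1)))
#' @export
generate_cohort <- function(config = cohort_config(),
                            params = vergence_params()) {
  stopifnot(inherits(config, "cohort_config"))
  k_res_sd <- sqrt(config$k_sd^2 - (config$k_al_slope * config$al_sd)^2)
  lt_res_sd <- sqrt(config$lt_sd^2 - (config$lt_al_slope * config$al_sd)^2)
  n <- config$n
  al <- k <- lt <- acd <- eps <- numeric(n)
  set.seed(config$seed)
  draw_trunc <- function(mean, sd, lo, hi) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > lo && x < hi) return(x)
    }
  }
  for (i in seq_len(n)) {
    al[i] <- draw_trunc(config$al_mean, config$al_sd,
                        config$al_range[1], config$al_range[2])
    k[i] <- draw_trunc(config$k_mean + config$k_al_slope * (al[i] - config$al_mean),
                       k_res_sd, 30, 60)
    lt[i] <- draw_trunc(config$lt_mean + config$lt_al_slope * (al[i] - config$al_mean),
                        lt_res_sd, 2, 8)
    acd[i] <- draw_trunc(acd_mean_curve(al[i], config), config$acd_noise_sd, 1, 6)
    eps[i] <- if (config$refraction_noise_sd > 0)
      rnorm(1, 0, config$refraction_noise_sd) else 0
  }
  elp_true <- haigis_elp(config$elp_true, acd, al)
  d_c <- corneal_power(k, params)
  iol <- recommend_iol_power(al, d_c, elp_true, grid = config$iol_grid,
                             target_se_d = config$surgeon_target_d,
                             params = params)
  se <- predict_refraction(al, d_c, elp_true, iol, params) + eps
  data.frame(eye_id = seq_len(n), al_mm = al, k_d = k, acd_mm = acd,
             lt_mm = lt, iol_power_d = iol, postop_se_d = se,
             elp_true_mm = elp_true)
}

#' Write a cohort to CSV
#'
#' Writes the canonical cohort schema (`eye_id, al_mm, k_d, acd_mm, lt_mm,
#' iol_power_d, postop_se_d` plus any optional columns present) as UTF-8
#' CSV with a header and '.' decimal separator.
#'
#' @param cases A cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cases, path) {
  missing_cols <- setdiff(.required_cols, names(cases))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- c(.required_cols,
            intersect(c(.optional_cols, "elp_true_mm"), names(cases)))
  utils::write.csv(cases[keep], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the canonical schema: all required columns present and
#' numeric, no missing values in required columns.  Absent optional
#' columns (`cct_um`, `wtw_mm`) are filled with `NA` and noted via
#' `message()`.  Violations raise an error naming the offending column and
#' row.
#'
#' @param path CSV file path.
#' @return A cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.required_cols, names(x))
  if (length(missing_cols) > 0)
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in .required_cols) {
    if (cl == "eye_id") next
    if (!is.numeric(x[[cl]]))
      stop("cohort column '", cl, "' is not numeric", call. = FALSE)
    if (anyNA(x[[cl]]))
      stop("cohort column '", cl, "' has missing values (first at row ",
           which(is.na(x[[cl]]))[1], ")", call. = FALSE)
  }
  for (cl in .optional_cols) {
    if (!cl %in% names(x)) {
      message("optional column '", cl, "' absent; filled with NA")
      x[[cl]] <- NA_real_
    }
  }
  bad <- x$al_mm <= 15 | x$al_mm >= 40 | x$k_d <= 30 | x$k_d >= 60 |
    x$acd_mm <= 1 | x$acd_mm >= 6 | x$lt_mm <= 2 | x$lt_mm >= 8
  if (any(bad))
    stop("biometry out of plausible bounds at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  x
}
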