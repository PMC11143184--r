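#' Summary statistics of refractive prediction errors
#'
#' Prediction error is actual minus predicted refraction (D), so negative
#' means a myopic outcome.  Returns the mean numerical error (ME), sample
#' standard deviation, root mean square error of the signed errors
#' (`sqrt(mean(e^2))`, n denominator), mean absolute error and median
#' absolute error.  The population identity
#' `RMSE^2 = ME^2 + SD^2 * (n - 1) / n` holds exactly.
#'
#' @param errors Numeric vector of signed prediction errors (D).
#' @return A one-row `data.frame` with columns
#'   `me_d, sd_d, rmse_d, mae_d, medae_d, n`.
#' @examples
#' summarize_errors(c(0.1, -0.1, 0.3))
#' @export
summarize_errors <- function(errors) {
  errors <- errors[!is.na(errors)]
  n <- length(errors)
  if (n < 1) stop("no errors to summarize", call. = FALSE)
  data.frame(me_d = mean(errors),
             sd_d = if (n > 1) sd(errors) else 0,
             rmse_d = sqrt(mean(errors^2)),
             mae_d = mean(abs(errors)),
             medae_d = median(abs(errors)),
             n = n)
}

#' Test whether the mean prediction error differs from zero
#'
#' Normality of the errors is assessed with the Shapiro-Wilk test at
#' alpha = 0.05; normal samples are tested with Student's one-sample
#' t-test, non-normal samples with the Wilcoxon signed-rank test against
#' zero.  Shapiro-Wilk accepts at most 5000 observations, so larger
#' samples are assessed on a deterministic seeded subsample of 5000.
#'
#' @param errors Numeric vector of signed prediction errors (D), n >= 3.
#' @param shapiro_alpha Normality threshold used to select the test.
#' @return A list with `p_value`, `method` (`"t"` or `"wilcoxon"`) and
#'   `shapiro_p`.
#' @export
test_me_nonzero <- function(errors, shapiro_alpha = 0.05) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 3) stop("need at least 3 errors", call. = FALSE)
  if (diff(range(errors)) == 0)
    stop("degenerate sample: all errors identical", call. = FALSE)
  sw_sample <- errors
  if (length(sw_sample) > 5000)
    sw_sample <- .with_local_rng(1L, sample(errors, 5000))
  sw <- shapiro.test(sw_sample)$p.value
  if (sw > shapiro_alpha) {
    list(p_value = t.test(errors, mu = 0)$p.value, method = "t",
         shapiro_p = sw)
  } else {
    list(p_value = wilcox.test(errors, mu = 0, exact = FALSE)$p.value,
         method = "wilcoxon", shapiro_p = sw)
  }
}

## run `expr` under a private RNG stream without disturbing the caller's
.with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compare the RMSE of two formulas on paired eyes
#'
#' Accounts for both systematic and random error by comparing root mean
#' square errors with a paired nonparametric bootstrap: eyes are resampled
#' with replacement, the RMSE difference is recomputed on each resample,
#' and the two-sided p-value is twice the smaller tail probability of the
#' resampled differences crossing zero.  Deterministic for a given seed.
#'
#' @param errors_a,errors_b Signed prediction errors of the two formulas,
#'   paired by eye (equal length).
#' @param n_boot Number of bootstrap resamples (>= 2000 recommended).
#' @param seed Seed for the private bootstrap RNG stream.
#' @return A list with `p_value`, `delta_rmse` (RMSE a - RMSE b) and
#'   `n_boot`.
#' @export
heteroscedastic_rmse_test <- function(errors_a, errors_b, n_boot = 2000,
                                      seed = 1) {
  if (length(errors_a) != length(errors_b))
    stop("errors_a and errors_b must be paired (equal length)", call. = FALSE)
  n <- length(errors_a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rmse <- function(e) sqrt(mean(e^2))
  delta <- rmse(errors_a) - rmse(errors_b)
  deltas <- .with_local_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rmse(errors_a[idx]) - rmse(errors_b[idx])
    }, numeric(1))
  })
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(p_value = p, delta_rmse = delta, n_boot = n_boot)
}

#' Holm step-down adjustment of p-values
#'
#' Validated wrapper over [stats::p.adjust()] with `method = "holm"`
#' (step-down Bonferroni with monotonicity enforcement, capped at 1).
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "holm")
}

#' Bin a per-eye quantity by axial length
#'
#' Bin centres are the axial lengths rounded to the nearest multiple of
#' `width_mm`, with ties rounded half-up (away from zero), matching the
#' usual presentation of biometry curves.  Eyes with `NA` values (flagged
#' cases) are excluded listwise.
#'
#' @param al_mm Conventional axial lengths (mm).
#' @param values Per-eye quantity to average within bins.
#' @param width_mm Bin width (mm); 0.5 and 0.25 are the usual choices.
#' @return A `data.frame` with `bin_center`, `mean`, `n`, ordered by bin.
#' @examples
#' bin_by_al(c(23.1, 23.2, 23.26), c(1, 2, 3), 0.5)
#' @export
bin_by_al <- function(al_mm, values, width_mm = 0.5) {
  stopifnot(width_mm > 0, length(al_mm) == length(values))
  keep <- !is.na(al_mm) & !is.na(values)
  al_mm <- al_mm[keep]; values <- values[keep]
  centre <- floor(al_mm / width_mm + 0.5) * width_mm  # half-up
  agg <- tapply(values, centre, mean)
  cnt <- tapply(values, centre, length)
  data.frame(bin_center = as.numeric(names(agg)),
             mean = as.numeric(agg),
             n = as.integer(cnt),
             row.names = NULL)
}

#' Split long eyes into ACD subgroups
#'
#' Selects the long-eye subgroup (`al_mm > al_cutoff_mm`), then partitions
#' it at the subgroup's mean ACD plus/minus one SD: short (< mean - SD),
#' medium (within one SD, boundaries inclusive), long (> mean + SD).  With
#' zero ACD spread everything falls in the medium group.
#'
#' @param cases A cohort `data.frame` with `al_mm` and `acd_mm` columns.
#' @param al_cutoff_mm Long-eye cutoff (mm); 26 mm by convention.
#' @return A list with `short`, `medium`, `long` (row subsets of `cases`)
#'   and `boundaries` (mean - SD, mean + SD).
#' @export
acd_subgroups <- function(cases, al_cutoff_mm = 26) {
  stopifnot(all(c("al_mm", "acd_mm") %in% names(cases)))
  sub <- cases[cases$al_mm > al_cutoff_mm, , drop = FALSE]
  if (nrow(sub) < 3)
    stop("fewer than 3 eyes with AL > ", al_cutoff_mm, " mm", call. = FALSE)
  m <- mean(sub$acd_mm); s <- sd(sub$acd_mm)
  lo <- m - s; hi <- m + s
  list(short = sub[sub$acd_mm < lo, , drop = FALSE],
       medium = sub[sub$acd_mm >= lo & sub$acd_mm <= hi, , drop = FALSE],
       long = sub[sub$acd_mm > hi, , drop = FALSE],
       boundaries = c(lo, hi))
}
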