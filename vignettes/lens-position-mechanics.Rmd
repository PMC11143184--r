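---
title: "Lens-position mechanics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lens-position mechanics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elpmech)
```

## The problem this package models

After cataract surgery the refractive outcome is governed by three numbers:
the eye's axial length (AL), the corneal power, and where the implanted
intraocular lens (IOL) ends up sitting — the effective lens position (ELP).
Power formulas predict the ELP from preoperative biometry; a formula that
*overestimates* the ELP believes the lens will sit more posteriorly than it
does, computes a more hyperopic outcome than reality, and therefore
recommends a stronger implant — a myopic surprise.

Several modern formulas modify the measured AL before use. The
Cooke-modified axial length,

$$\mathrm{CMAL} = 1.23853 + 0.95855\,\mathrm{AL} - 0.05467\,\mathrm{LT},$$

approximates sum-of-segments AL and is *shorter* than conventional AL in
long eyes. In populations whose anterior segment keeps growing with AL this
correction is benign. In East Asian populations the anterior chamber depth
(ACD) stops deepening at roughly 3.5 mm once AL exceeds ~25.5 mm, and the
combination of (i) the shortened effective AL and (ii) an ELP predictor
that keeps rising with AL produces a systematic ELP overestimate in long
eyes, higher-powered recommendations, and myopic outcomes. `elpmech`
implements every ingredient of that argument so it can be demonstrated and
stress-tested on synthetic cohorts.

## The thin-lens vergence engine

All optics are paraxial thin-lens vergence transport with the aqueous /
vitreous index $n = 1.336$ and a spectacle vertex distance of 12 mm.
Corneal powers are entered on the keratometer scale (1.3375 calibration;
biometer "total keratometry" values are accepted on the same scale) and
converted to physical corneal power with the 1.3315 corneal index,
$D_C = K \cdot 331.5/337.5$. This convention is not optional decoration:
with it, the worked long-eye example — predicted ELP 5.63 mm versus a
reference position near 5.3 mm at an 11.47 D implant — closes to within a
hundredth of a dioptre, and without it it does not.

`predict_refraction()` solves the chain for the spectacle refraction;
`emmetropic_power()` is its closed-form inversion at zero refraction;
`back_calculate_elp()` inverts it for the lens position instead, which is a
quadratic in the ELP. Numerical conventions:

* the back-calculation root is the one inside the anatomic range
  1–10 mm; should both roots land inside, the smaller (anatomically
  plausible) one is chosen and a warning is emitted;
* eyes with no admissible root are returned as `NA` and excluded listwise
  from curves and fits — never zero-filled;
* degenerate vergences (lens at the retina, zero denominators) raise
  errors rather than propagate `Inf`.

`recommend_iol_power()` scans a manufacturing grid (default 6.0–30.0 D in
0.5 D steps) for the power minimising the absolute predicted refraction
relative to the target; exact ties go to the higher power, the surgical
convention that prefers a slightly myopic over a slightly hyperopic error.

## Formulas and their variants

The Haigis predictor $\mathrm{ELP} = a_0 + a_1\,\mathrm{ACD} + a_2\,L$ is
the package's analytic workhorse because it is linear and fully published:
its "single-optimized" form (adjust $a_0$ only, $a_1 = 0.4$, $a_2 = 0.1$)
mimics how single-constant formulas are tuned in practice, and its
"CMAL-applied" variant substitutes the CMAL for the AL *everywhere* — in
the ELP predictor and in the vergence optics. SRK/T, Hoffer Q and
Holladay 1 are transcribed from their published closed forms (including
SRK/T's corneal-height and retinal-thickness chains and Hoffer Q's tangent
terms, with the tangent arguments in degrees); their CMAL variants likewise
substitute wholesale, including SRK/T's AL-dependent regression terms.
Where the published SRK/T leaves ambiguous whether an AL modification
should reach the retinal-thickness term, we substitute everywhere, on the
reasoning that an AL-modifying formula has no access to the unmodified
value at evaluation time; the rotation results are insensitive to this
choice. The tests pin each transcription against an independently coded
power-for-target-refraction form of the same publication, inverted
numerically.

## Lens-constant optimization

`optimize_single()` zeroes the cohort's mean prediction error
(actual − predicted refraction) in the formula's own constant by bracketed
root-finding (brackets: $a_0 \in [-5, 10]$, A-constant $[110, 126]$,
pACD $[0, 10]$, SF $[-2, 5]$; residual mean error below $10^{-4}$ D).

`optimize_triple_haigis()` retrains the predictor: it back-calculates every
eye's reference ELP, regresses it on $(1, \mathrm{ACD}, L)$ by ordinary
least squares, clamps a negative axial coefficient to zero with a refit
(one-constraint active set — empirically the constraint activates exactly
on CMAL-applied long-eye populations, where the required ELP stops growing
with AL), and finally shifts $a_0$ so the refraction-space mean error is
zero. Regressing in ELP space and closing with an intercept shift — rather
than minimising refraction error in all three constants jointly — keeps the
fitted constants interpretable as a lens-position model while preserving
the universal "mean error is zero on the training set" convention; on
noiseless cohorts it recovers a generative linear ELP model exactly, so
nothing is lost where both conventions coincide.

## Error statistics

`summarize_errors()` reports ME, sample SD, RMSE (with the $n$ denominator,
so $\mathrm{RMSE}^2 = \mathrm{ME}^2 + \mathrm{SD}^2 (n-1)/n$ holds as an
identity), MAE and median AE. Significance of a nonzero ME is tested with
Student's t when Shapiro–Wilk does not reject normality at $\alpha = 0.05$
and with the Wilcoxon signed-rank test otherwise; Shapiro–Wilk accepts at
most 5000 values, so larger samples are screened on a deterministic seeded
subsample. RMSE pairs are compared with a seed-controlled paired bootstrap
of the RMSE difference (resampling eyes, two-sided p from the tail
crossing); the literature's heteroscedastic comparison is distributed only
inside a closed-source statistics package, so the bootstrap here is a
documented stand-in with the same intent — honouring both systematic and
random error — rather than a transcription. Multiplicity uses Holm's
step-down adjustment via `stats::p.adjust()`. Binned curves round AL to the
nearest multiple of the bin width with half-up ties, the convention used by
biometry figures; ACD subgrouping of long eyes splits at the subgroup mean
±1 SD.

## The synthetic cohort generator

`generate_cohort()` emulates the marginal structure of a large East Asian
trifocal-IOL population with no access to patient data:

| parameter | default | anchor |
|---|---|---|
| AL | N(23.68, 1.15²) truncated to 20.5–30 mm | whole-cohort biometry |
| K | conditional on AL, slope −0.22 D/mm, marginal SD 1.40 D | long-eye mean ≈ 43.5 D |
| LT | conditional on AL, slope −0.05 mm/mm, marginal SD 0.31 mm | long-eye mean ≈ 4.31 mm |
| ACD | preset mean curve + N(0, 0.22²) | see below |
| true ELP | $1.304 + 0.442\,\mathrm{ACD} + 0.104\,\mathrm{AL}$ | triple-fit constants of the emulated population |
| refraction noise | SD 0.30 D | typical postoperative SE spread |

The ACD mean curve rises linearly at 0.198 mm per mm of AL and, in the
`east_asian_plateau` preset, is capped at 3.50 mm beyond the 25.5 mm knee
(with a 0.5 mm-half-width quadratic blend so binned curves show no slope
kink); the `caucasian_linear` preset lets the line continue. The slope and
intercept are jointly anchored so the line passes through the whole-cohort
mean ACD (3.14 mm at mean AL) and reaches the plateau level exactly at the
knee — the population's below-knee AL–ACD slope is not published, so this
anchoring is the package's own choice and both parameters are exposed in
`cohort_config()`.

Each eye's implanted power is the grid power that the *true*-ELP thin-lens
model brings closest to the surgeon's target (default emmetropia), and the
observed refraction is that model's prediction plus noise. Two design
decisions matter for interpretation:

* **Conventional AL is treated as optically true.** No group-refractive-
  index measurement error is simulated, because the emulated population's
  conventional-AL formulas were essentially unbiased. A consequence worth
  stating plainly: the CMAL-variant bias on these cohorts is driven
  overwhelmingly by the CMAL's shortening of the effective optical length
  (roughly 3 mm of required-ELP shift per mm of AL change), while the shape
  of the ACD curve contributes little to the *gap* between the CMAL and AL
  variants — the Haigis predictor reads each eye's measured ACD, so it
  tracks most of any ACD trend under either preset. The presets therefore
  probe the anatomy's effect on the required-ELP curve and on triple-fit
  constants, not a counterfactual "this population would rescue the CMAL
  formula". Reproducing that counterfactual would require simulating the
  biometer's index error that the CMAL exists to correct, which is outside
  this generator's scope.
* **One RNG stream, per-eye draws.** Eye $i$'s draws complete before eye
  $i+1$ begins, so a cohort of size $n$ is a bitwise prefix of a larger
  cohort at the same seed — convenient for scaling experiments.

What passing tests on these cohorts show about real data: that the
*mechanism* — plateau anatomy plus AL modification plus single-constant
tuning ⇒ ELP overestimation ⇒ myopic long-eye errors of roughly a quarter
dioptre, repaired by triple retraining with $a_2 \to 0$ — is a property of
the optics and the population geometry, not of any particular dataset. What
they do not show: magnitudes on real eyes, where measurement error in every
biometric input, non-Gaussian refraction noise, bilateral correlation and
surgeon-specific targeting all intrude.

## Study pipeline and problem sizes

`run_study()` optimizes all four Haigis variants and the six older-formula
variants, bins predicted against back-calculated ELP by conventional AL
(0.5 mm default), summarises errors for the whole cohort and the long-eye
(AL > 26 mm) subgroup, fits rotation slopes to binned mean errors
(unweighted least squares over bins with ≥ 5 eyes, matching how such
figures are drawn), and evaluates the worked eye model at the long-eye mean
biometry. The packaged tests exercise cohorts of 1000–3000 eyes — the scale
at which the long-eye subgroup (~2% of a truncated-normal AL distribution)
still contains enough eyes for stable subgroup means — and the full
simulate-plus-analyze cycle at n = 3000 runs in a few seconds on one core.

## Known limitations

* Thin-lens optics only: no thick-lens or ray-traced model, no toric
  power handling, and proprietary formulas (Barrett, EVO, Kane, PEARL-DGS,
  Hoffer QST) are supported only as externally supplied prediction columns.
* The long-eye tail of a truncated normal underweights very long eyes
  relative to a clinical myopic population, so synthetic long-eye subgroup
  means sit nearer the cutoff than a real cohort's would.
* The bootstrap RMSE comparison is a stand-in for the closed-source
  heteroscedastic test distributed with Holladay's statistics package, as
  documented above.
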