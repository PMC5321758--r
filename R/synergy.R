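# Chou-Talalay median-effect modelling and combination-index computation,
# plus small closed-form assay metrics (two-sample t power, population
# doubling time, tumour volume).
#
# Median-effect equation: fa/fu = (D/Dm)^m, i.e. the median-effect plot
# log10(fa/(1-fa)) vs log10(D) is linear with slope m and x-intercept
# log10(Dm).

#' Fit the median-effect model to a single-drug dose-response curve
#'
#' Ordinary least squares of `y = log10(fa / (1 - fa))` on `x = log10(D)`.
#' Points with `fa` outside (0, 1) are excluded from the fit (their count is
#' reported); a non-positive fitted slope is flagged.
#'
#' @param dr A `DoseResponse` (see [simulate_dose_response()]) or a list
#'   with `doses`, `fa` and optionally `drug`.
#' @return Object of class `MedianEffectFit`: list with `m` (slope), `dm`
#'   (median-effect dose), `r2`, `drug`, `n_used`, `n_excluded`, `flagged`.
#' @export
fit_median_effect <- function(dr) {
  doses <- dr$doses; fa <- dr$fa
  stopifnot(length(doses) == length(fa), all(doses > 0))
  usable <- fa > 0 & fa < 1
  n_excluded <- sum(!usable)
  doses <- doses[usable]; fa <- fa[usable]
  if (length(unique(doses)) < 2)
    stop("insufficient data: need >=2 distinct doses with fa in (0, 1)",
         call. = FALSE)
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  ols <- stats::lm(y ~ x)
  m <- unname(stats::coef(ols)[2])
  intercept <- unname(stats::coef(ols)[1])
  dm <- 10^(-intercept / m)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(ols)^2) / sst else 1
  structure(list(m = m, dm = dm, r2 = r2,
                 drug = if (!is.null(dr$drug)) dr$drug else "drug",
                 n_used = length(doses), n_excluded = n_excluded,
                 flagged = m <= 0),
            class = "MedianEffectFit")
}

#' @export
print.MedianEffectFit <- function(x, ...) {
  cat(sprintf("MedianEffectFit '%s': m=%.4f Dm=%.4g r2=%.4f (n=%d%s)%s\n",
              x$drug, x$m, x$dm, x$r2, x$n_used,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else "",
              if (x$flagged) " [non-positive slope]" else ""))
  invisible(x)
}

#' Effective dose for a target fraction affected
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`: the dose at which the fitted
#' median-effect model predicts effect level `fa`.
#'
#' @param fit A `MedianEffectFit`.
#' @param fa Target fraction affected, strictly inside (0, 1).
#' @return Dose in the units of the fitted curve.
#' @export
effective_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "MedianEffectFit"))
  if (any(fa <= 0 | fa >= 1))
    stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index for a two-drug combination
#'
#' `CI = d1 / Dx1(fa) + d2 / Dx2(fa)` at the observed combined effect level:
#' CI < 1 synergism, CI = 1 additive, CI > 1 antagonism. The categorical
#' call treats `|CI - 1| <= call_tolerance` as additive (reporting
#' convention; default 0.05).
#'
#' @param fit1,fit2 `MedianEffectFit` objects for the two single drugs.
#' @param d1,d2 Combination doses (>= 0, not both zero).
#' @param fa_combo Observed combined fraction affected, in (0, 1).
#' @param call_tolerance Half-width of the additive band around CI = 1.
#' @return Object of class `CombinationResult`: list with `ci`, `call`,
#'   `d1`, `d2`, `fa_combo`, `dx1`, `dx2`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa_combo,
                              call_tolerance = 0.05) {
  stopifnot(inherits(fit1, "MedianEffectFit"), inherits(fit2, "MedianEffectFit"),
            d1 >= 0, d2 >= 0)
  if (d1 == 0 && d2 == 0) stop("both doses are zero", call. = FALSE)
  if (fa_combo <= 0 || fa_combo >= 1)
    stop("fa_combo must lie strictly inside (0, 1)", call. = FALSE)
  dx1 <- effective_dose(fit1, fa_combo)
  dx2 <- effective_dose(fit2, fa_combo)
  ci <- d1 / dx1 + d2 / dx2
  call <- if (abs(ci - 1) <= call_tolerance) "additive"
          else if (ci < 1) "synergism" else "antagonism"
  structure(list(ci = ci, call = call, d1 = d1, d2 = d2,
                 fa_combo = fa_combo, dx1 = dx1, dx2 = dx2),
            class = "CombinationResult")
}

#' @export
print.CombinationResult <- function(x, ...) {
  cat(sprintf("CombinationResult: CI=%.4f (%s) at fa=%.3f (d1=%g, d2=%g)\n",
              x$ci, x$call, x$fa_combo, x$d1, x$d2))
  invisible(x)
}

#' Power of the two-sided two-sample t-test
#'
#' Noncentral-t power with `ncp = (true_diff / sd) * sqrt(n/2)` on
#' `2n - 2` degrees of freedom: `power = P(|T'| > t_crit)`.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param true_diff True mean difference.
#' @param sd Common within-group standard deviation (> 0).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(n_per_group, true_diff, sd, alpha = 0.05) {
  stopifnot(n_per_group >= 2, sd > 0, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- (true_diff / sd) * sqrt(n_per_group / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Population doubling time under exponential growth
#'
#' `PD = hours * log(2) / (log(Nt) - log(N0))`: hours per doubling of the
#' culture.
#'
#' @param n0 Cells seeded.
#' @param nt Cells harvested (> `n0`).
#' @param hours Hours from seeding to harvest (> 0).
#' @return Doubling time in hours.
#' @export
population_doubling_time <- function(n0, nt, hours) {
  stopifnot(hours > 0)
  if (!(nt > n0 && n0 > 0))
    stop("no net growth: need nt > n0 > 0", call. = FALSE)
  hours * log(2) / (log(nt) - log(n0))
}

#' Ellipsoid tumour volume from caliper measurements
#'
#' `V = pi/6 * length * width^2` (mm^3), longest dimension first; swapped
#' inputs are corrected with a warning.
#'
#' @param length Longest tumour dimension (mm).
#' @param width Shortest tumour dimension (mm).
#' @return Volume in mm^3.
#' @export
tumour_volume <- function(length, width) {
  stopifnot(length > 0, width > 0)
  if (width > length) {
    warning("width exceeds length; inputs swapped", call. = FALSE)
    tmp <- length; length <- width; width <- tmp
  }
  pi / 6 * length * width^2
}
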