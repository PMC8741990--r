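#' Fit a power law dose = alpha * Volume^beta
#'
#' Ordinary least squares of log10(dose) on log10(volume), with 95%
#' confidence intervals from the classical t-based formulas and the
#' coefficient of determination of the log-log fit.
#'
#' @param volumes tumor volumes in cm^3 (all > 0, not all equal).
#' @param doses doses in mg (all > 0), same length.
#' @return a [PowerLawFit-class].
#' @examples
#' v <- c(1, 2, 5, 10, 20)
#' fitPowerLaw(v, 10^(-1.8) * v^4)   # exact recovery
#' @export
fitPowerLaw <- function(volumes, doses) {
  if (length(volumes) != length(doses))
    stop("volumes and doses must have the same length")
  if (length(volumes) < 3L)
    stop("at least 3 points are required")
  if (any(!is.finite(volumes)) || any(volumes <= 0) ||
      any(!is.finite(doses)) || any(doses <= 0))
    stop("volumes and doses must be positive and finite")
  if (diff(range(volumes)) == 0)
    stop("all volumes are equal: the exponent is not identifiable")
  lv <- log10(volumes); ld <- log10(doses)
  fit <- stats::lm(ld ~ lv)
  # noiseless inputs trip the "essentially perfect fit" warning; a zero
  # residual is a legitimate outcome here
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  new("PowerLawFit",
      log10_alpha = unname(stats::coef(fit)[1]),
      beta = unname(stats::coef(fit)[2]),
      ci_log10_alpha = unname(ci[1, ]), ci_beta = unname(ci[2, ]),
      r2 = suppressWarnings(summary(fit)$r.squared),
      n_points = length(volumes))
}

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit (n = %d): dose = 10^%.3f * V^%.3f, R^2 = %.3f\n",
              object@n_points, object@log10_alpha, object@beta, object@r2))
  cat(sprintf("  95%% CI log10(alpha): [%.3f, %.3f]   beta: [%.3f, %.3f]\n",
              object@ci_log10_alpha[1], object@ci_log10_alpha[2],
              object@ci_beta[1], object@ci_beta[2]))
})

#' Minimal-dose power laws per injection count
#'
#' For each injection count, computes the minimal effective dose of a
#' sphere surrogate at every volume ([minDose()], median over threshold
#' replicates) and fits the dose-volume power law. The default volume
#' set is the 28 cohort volumes below 40 cm^3, the declared validity
#' range of the power law.
#'
#' @param volumes volumes in cm^3; `NULL` uses the packaged cohort
#'   volumes < 40 cm^3.
#' @param n_list injection counts (default 1:5).
#' @param params a [ModelParams-class].
#' @param n_replicates threshold replicates per volume.
#' @param seed master seed; per-volume, per-count replicate seeds are
#'   derived deterministically from it.
#' @param spacing_mm voxel edge for the sphere surrogates, mm.
#' @return a data.frame with one row per injection count: `n`,
#'   `log10_alpha`, `alpha_ci_lo`, `alpha_ci_hi`, `beta`, `beta_ci_lo`,
#'   `beta_ci_hi`, `r2`, plus the fitted doses as an attribute
#'   `"doses"` (matrix volumes x counts).
#' @export
doseLawTable <- function(volumes = NULL, n_list = 1:5,
                         params = modelParams(), n_replicates = 25L,
                         seed = 1L, spacing_mm = 1) {
  if (is.null(volumes)) {
    rec <- loadCohort()
    volumes <- rec$volume_cm3[rec$volume_cm3 < 40]
  }
  stopifnot(length(volumes) >= 3L, all(volumes > 0))
  doses <- matrix(NA_real_, length(volumes), length(n_list),
                  dimnames = list(NULL, paste0("n", n_list)))
  masks <- lapply(volumes, makeSphereMask, spacing_mm = spacing_mm)
  for (ci in seq_along(n_list)) {
    for (vi in seq_along(volumes)) {
      doses[vi, ci] <- minDose(masks[[vi]], n_list[ci], params,
                               n_replicates,
                               seed = .deriveSeed(seed, vi, n_list[ci]))
    }
  }
  rows <- lapply(seq_along(n_list), function(ci) {
    f <- fitPowerLaw(volumes, doses[, ci])
    data.frame(n = n_list[ci], log10_alpha = f@log10_alpha,
               alpha_ci_lo = f@ci_log10_alpha[1],
               alpha_ci_hi = f@ci_log10_alpha[2],
               beta = f@beta, beta_ci_lo = f@ci_beta[1],
               beta_ci_hi = f@ci_beta[2], r2 = f@r2)
  })
  out <- do.call(rbind, rows)
  attr(out, "doses") <- doses
  attr(out, "volumes") <- volumes
  out
}

#' Dose reduction between two injection strategies
#'
#' Orders of magnitude saved by distributing the dose:
#' `log10(minDose with n_lo injections / minDose with n_hi injections)`
#' for a sphere surrogate of the given volume. The ratio is invariant
#' to the kernel normalization mode.
#'
#' @param volume_cm3 tumor volume in cm^3.
#' @param n_lo,n_hi injection counts, `n_lo < n_hi`.
#' @param params a [ModelParams-class].
#' @param n_replicates threshold replicates.
#' @param seed master seed.
#' @param spacing_mm voxel edge in mm.
#' @return log10 dose ratio (0 when `n_lo == n_hi`).
#' @export
doseReductionOrders <- function(volume_cm3, n_lo, n_hi,
                                params = modelParams(),
                                n_replicates = 25L, seed = 1L,
                                spacing_mm = 1) {
  if (n_lo > n_hi) stop("n_lo must not exceed n_hi")
  if (n_lo == n_hi) return(0)
  mask <- makeSphereMask(volume_cm3, spacing_mm)
  d_lo <- minDose(mask, n_lo, params, n_replicates,
                  seed = .deriveSeed(seed, 1L, n_lo))
  d_hi <- minDose(mask, n_hi, params, n_replicates,
                  seed = .deriveSeed(seed, 1L, n_hi))
  log10(d_lo / d_hi)
}

# deterministic sub-seed, kept well inside 32-bit integer range
.deriveSeed <- function(seed, i, j) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147480000)
}
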