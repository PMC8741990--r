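# restore the caller's RNG state after a seeded draw
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw per-voxel apoptosis thresholds
#'
#' Every occupied voxel receives an independent threshold
#' `phi_t = 10^x`, `x ~ Normal(mu, sigma)` in log10(mg/ml), emulating
#' the heterogeneity of cisplatin IC50 across tumor cell populations.
#' The draw is fully reproducible: the same seed regenerates the field
#' bit-for-bit, and the caller's RNG state is left untouched.
#'
#' @param mask a [TumorMask-class].
#' @param params a [ModelParams-class] (uses `mu`, `sigma`).
#' @param seed integer sampling seed.
#' @return a [ThresholdField-class] in mg/ml.
#' @export
sampleThresholds <- function(mask, params = modelParams(), seed) {
  stopifnot(is(mask, "TumorMask"), is(params, "ModelParams"))
  n <- sum(mask@occupancy)
  vals <- .withSeed(seed, 10^stats::rnorm(n, params@mu, params@sigma))
  new("ThresholdField", values = vals, mask = mask, seed = as.integer(seed))
}

#' Responding volume percentage
#'
#' Percentage of occupied voxels whose asymptotic intracellular
#' concentration reaches their apoptosis threshold.
#'
#' @param field a [ConcentrationField-class].
#' @param thresholds a [ThresholdField-class] on the same mask.
#' @return percent in \[0, 100\].
#' @export
vResponse <- function(field, thresholds) {
  m1 <- field@mask; m2 <- thresholds@mask
  if (!identical(dim(m1@occupancy), dim(m2@occupancy)) ||
      !identical(m1@occupancy, m2@occupancy) ||
      !isTRUE(all.equal(m1@spacing, m2@spacing)))
    stop("field and thresholds are defined on different masks")
  100 * mean(field@values >= thresholds@values)
}

#' Binary response classification
#'
#' A tumor is predicted to respond when at least the response fraction
#' of its volume (66% by default, the spherical equivalent of a 30%
#' diameter reduction) reaches the apoptosis threshold. The boundary is
#' inclusive.
#'
#' @param v_response_pct percent in \[0, 100\].
#' @param params a [ModelParams-class].
#' @return integer 0 or 1.
#' @export
classifyResponse <- function(v_response_pct, params = modelParams()) {
  stopifnot(all(v_response_pct >= 0 & v_response_pct <= 100))
  as.integer(v_response_pct >= 100 * params@response_fraction)
}

#' Predict treatment response for a tumor and injection strategy
#'
#' Plans `n` sites deterministically, splits the dose equally, computes
#' the asymptotic intracellular field once, and evaluates the responding
#' volume against `n_replicates` independent threshold draws (seeds
#' `seed + 1 ... seed + n_replicates`). The mean responding volume over
#' replicates feeds the binary classification.
#'
#' @param mask a [TumorMask-class].
#' @param total_dose injected dose in mg.
#' @param n number of injections.
#' @param params a [ModelParams-class].
#' @param n_replicates threshold replicates (default 25).
#' @param seed master seed.
#' @return a [ResponseResult-class].
#' @examples
#' predictResponse(makeSphereMask(0.95), 40, 4, seed = 1)
#' @export
predictResponse <- function(mask, total_dose, n, params = modelParams(),
                            n_replicates = 25L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  plan <- apportionDose(placeSites(mask, n), total_dose)
  field <- steadyStateField(mask, plan, params)
  reps <- vapply(seq_len(n_replicates), function(r) {
    thr <- sampleThresholds(mask, params, seed = seed + r)
    vResponse(field, thr)
  }, numeric(1))
  v <- mean(reps)
  new("ResponseResult", v_response_pct = v,
      predicted = classifyResponse(v, params), replicates = reps,
      seed = as.integer(seed))
}

setMethod("show", "ResponseResult", function(object) {
  cat(sprintf("ResponseResult: V_response = %.1f%% (%d replicates, seed %d) -> %s\n",
              object@v_response_pct, length(object@replicates), object@seed,
              if (object@predicted == 1L) "predicted responder"
              else "predicted non-responder"))
})

#' Minimal effective dose of a tumor
#'
#' Smallest total dose for which the responding volume reaches the
#' response fraction. Because the field is exactly linear in dose, each
#' replicate reduces to a percentile computation: with unit-dose field
#' `Phi(v)` and thresholds `phi_t(v)`, the per-voxel critical dose is
#' `M_v = phi_t(v) / Phi(v)`, and the replicate's minimal dose is the
#' k-th smallest `M_v` with `k = ceiling(fraction * N_vox)` -- the
#' infimum dose covering at least the required fraction. The median
#' over replicates is returned.
#'
#' @param mask a [TumorMask-class].
#' @param n number of injections.
#' @param params a [ModelParams-class].
#' @param n_replicates threshold replicates (default 25).
#' @param seed master seed.
#' @param details if `TRUE`, return a list with the median and the
#'   per-replicate doses.
#' @return dose in mg (or a list when `details = TRUE`).
#' @examples
#' minDose(makeSphereMask(1), n = 1, seed = 1)
#' @export
minDose <- function(mask, n, params = modelParams(), n_replicates = 25L,
                    seed = 1L, details = FALSE) {
  stopifnot(n_replicates >= 1L)
  plan <- placeSites(mask, n)                  # unit total dose
  Phi <- steadyStateField(mask, plan, params)@values
  nv <- length(Phi)
  k <- ceiling(params@response_fraction * nv)
  reps <- vapply(seq_len(n_replicates), function(r) {
    thr <- sampleThresholds(mask, params, seed = seed + r)@values
    M <- thr / Phi
    sort(M, partial = k)[k]
  }, numeric(1))
  if (details) list(dose_mg = stats::median(reps), replicates = reps)
  else stats::median(reps)
}
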