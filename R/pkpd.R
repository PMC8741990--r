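#' Construct model parameters
#'
#' Returns the full parameter set of the pharmacodynamic model with
#' literature defaults: a cisplatin diffusion coefficient estimated from
#' molecular weight, an intracellular uptake rate from head/neck and
#' gastric carcinoma data, fluid-compartment constants fitted to blood
#' cisplatin kinetics of a monitored patient, and a log-normal IC50
#' distribution fitted to 75 NSCLC cell lines.
#'
#' @param D diffusion coefficient, cm^2/s.
#' @param k_i intracellular uptake rate, 1/s.
#' @param k_f clearance rate to the fluid compartment, 1/s.
#' @param V_f fluid compartment volume, ml.
#' @param k_r renal elimination rate, 1/s (default 0; the asymptotic
#'   response pathway never depends on it because uptake is
#'   irreversible and the fluid compartment does not feed back).
#' @param mu mean of log10(IC50 in mg/ml).
#' @param sigma SD of log10(IC50 in mg/ml).
#' @param response_fraction volume fraction required for a predicted
#'   response.
#' @param greens_mode `"paper"` (printed kernel, no 1/(4 pi)) or
#'   `"physical"` (free-space kernel). Classification and all
#'   slope/ratio-level results are invariant to the choice; absolute
#'   dose intercepts are not.
#' @param mw_cisplatin molecular weight, g/mol.
#' @return a [ModelParams-class].
#' @examples
#' p <- modelParams()
#' decayLength(p)   # ~0.1 cm
#' @export
modelParams <- function(D = 2.47e-6, k_i = 1.05e-4, k_f = 1.46e-4,
                        V_f = 12200, k_r = 0, mu = -2.59, sigma = 0.50,
                        response_fraction = 0.66,
                        greens_mode = c("paper", "physical"),
                        mw_cisplatin = 300.01) {
  greens_mode <- match.arg(greens_mode)
  new("ModelParams", D = D, k_i = k_i, k_f = k_f, V_f = V_f, k_r = k_r,
      mu = mu, sigma = sigma, response_fraction = response_fraction,
      greens_mode = greens_mode, mw_cisplatin = mw_cisplatin)
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams:\n")
  cat(sprintf("  D   = %.3g cm^2/s   k_i = %.3g /s   k_f = %.3g /s\n",
              object@D, object@k_i, object@k_f))
  cat(sprintf("  V_f = %.4g ml       k_r = %.3g /s\n", object@V_f, object@k_r))
  cat(sprintf("  IC50: 10^Normal(mu = %.3g, sigma = %.3g) mg/ml\n",
              object@mu, object@sigma))
  cat(sprintf("  response fraction = %.2f, kernel mode = %s\n",
              object@response_fraction, object@greens_mode))
  cat(sprintf("  decay length = %.4g cm\n", decayLength(object)))
})

#' Characteristic decay length of the steady-state field
#'
#' The point-source field falls off as `exp(-r / L)` with
#' `L = sqrt(D / (k_i + k_f))`, the distance over which diffusion
#' balances the combined uptake and clearance losses (~1 mm at the
#' defaults).
#'
#' @param params a [ModelParams-class].
#' @return length in cm.
#' @export
decayLength <- function(params) {
  stopifnot(is(params, "ModelParams"))
  sqrt(params@D / (params@k_i + params@k_f))
}

#' Asymptotic intracellular concentration field
#'
#' Evaluates the steady-state intracellular cisplatin concentration of
#' every occupied voxel as a superposition of point-source kernels, one
#' per injection site:
#' `phi_i(r) = sum_j C * k_i * m_j / (D * r_eff) * exp(-|r - r_j| / L)`
#' with `L` the [decayLength()], `C = 1` in `"paper"` mode and
#' `C = 1/(4 pi)` in `"physical"` mode. The kernel diverges at the
#' source, so distances are floored at half a voxel edge
#' (`r_eff = max(r, h/2)`), which keeps source voxels finite.
#'
#' @param mask a [TumorMask-class].
#' @param plan an [InjectionPlan-class]; every site must lie on an
#'   occupied voxel.
#' @param params a [ModelParams-class].
#' @return a [ConcentrationField-class] in mg/ml.
#' @examples
#' m <- makeSphereMask(1)
#' pl <- apportionDose(placeSites(m, 2), 40)
#' f <- steadyStateField(m, pl, modelParams())
#' summary(fieldValues(f))
#' @export
steadyStateField <- function(mask, plan, params = modelParams()) {
  stopifnot(is(mask, "TumorMask"), is(plan, "InjectionPlan"),
            is(params, "ModelParams"))
  sites <- plan@sites
  d <- dim(mask@occupancy)
  idx <- .positionToIndex(mask, sites)
  inside <- idx >= 1L & sweep(idx, 2L, d, `<=`)
  ok <- rowSums(inside) == 3L
  ok[ok] <- mask@occupancy[idx[ok, , drop = FALSE]]
  if (!all(ok))
    stop("injection site(s) ", paste(which(!ok), collapse = ", "),
         " fall outside the occupied mask")
  P <- voxelCenters(mask)
  h_cm <- mean(mask@spacing) / 10
  L <- decayLength(params)
  C <- if (params@greens_mode == "physical") 1 / (4 * pi) else 1
  phi <- numeric(nrow(P))
  for (j in seq_len(nrow(sites))) {
    r <- sqrt((P[, 1] - sites[j, 1])^2 + (P[, 2] - sites[j, 2])^2 +
                (P[, 3] - sites[j, 3])^2)
    phi <- phi + C * params@k_i * plan@doses[j] /
      (params@D * pmax(r, h_cm / 2)) * exp(-r / L)
  }
  new("ConcentrationField", values = phi, mask = mask)
}

#' Asymptotic fluid-compartment concentration
#'
#' With no renal elimination, the fraction `k_f / (k_i + k_f)` of the
#' injected dose is eventually cleared to the systemic fluid compartment
#' and diluted in its volume; the remainder is taken up irreversibly by
#' tumor cells.
#'
#' @param params a [ModelParams-class] with `k_r = 0`.
#' @param total_dose injected dose in mg.
#' @return fluid concentration in mg/ml.
#' @export
fluidAsymptote <- function(params, total_dose) {
  stopifnot(is(params, "ModelParams"), total_dose >= 0)
  if (params@k_r > 0)
    stop("the fluid asymptote is only defined without renal elimination ",
         "(k_r = 0); use transientSimulate() for k_r > 0")
  params@k_f / (params@k_i + params@k_f) * total_dose / params@V_f
}

#' @rdname ConcentrationField-class
#' @export
setMethod("fieldValues", "ConcentrationField", function(x) x@values)

#' @rdname ConcentrationField-class
#' @export
setMethod("fieldValues", "ThresholdField", function(x) x@values)

#' @rdname ConcentrationField-class
#' @export
setMethod("fieldMask", "ConcentrationField", function(x) x@mask)

#' @rdname ConcentrationField-class
#' @export
setMethod("fieldMask", "ThresholdField", function(x) x@mask)

setMethod("show", "ConcentrationField", function(object) {
  cat(sprintf("ConcentrationField: %d voxels, range [%.3g, %.3g] mg/ml\n",
              length(object@values), min(object@values), max(object@values)))
})

setMethod("show", "ThresholdField", function(object) {
  cat(sprintf("ThresholdField: %d voxels, seed %d, median %.3g mg/ml\n",
              length(object@values), object@seed, stats::median(object@values)))
})

#' Export a field as a NIfTI volume co-registered with its mask
#'
#' Unoccupied voxels are written as zero.
#'
#' @param field a [ConcentrationField-class] or [ThresholdField-class].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
writeFieldNifti <- function(field, path) {
  mask <- field@mask
  vol <- array(0, dim(mask@occupancy))
  vol[mask@occupancy] <- field@values
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
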