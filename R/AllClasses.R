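#' @import methods
NULL

#' Binary tumor mask on a regular voxel grid
#'
#' A `TumorMask` holds the spatial domain of all concentration and
#' threshold fields: a 3-D logical occupancy grid together with the
#' physical voxel spacing and the physical position of the grid corner.
#' Physical positions follow the voxel-center convention: the center of
#' voxel `(i, j, k)` (1-based indices) lies at
#' `origin + (index - 0.5) * spacing`, in millimetres.
#'
#' @slot occupancy 3-D `logical` array; `TRUE` marks tumor voxels.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), physical offset of the grid corner in mm.
#'
#' @seealso [makeSphereMask()], [maskVolume()], [padDomain()]
#' @export
setClass("TumorMask",
  representation(occupancy = "array", spacing = "numeric", origin = "numeric"),
  prototype(occupancy = array(TRUE, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("TumorMask", function(object) {
  msg <- character()
  if (length(dim(object@occupancy)) != 3L)
    msg <- c(msg, "'occupancy' must be a 3-D array")
  if (!is.logical(object@occupancy))
    msg <- c(msg, "'occupancy' must be logical")
  if (!any(object@occupancy))
    msg <- c(msg, "mask must contain at least one occupied voxel")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Pharmacodynamic model parameters
#'
#' Rate constants, IC50 distribution parameters and mode switches of the
#' intratumoral cisplatin model. Internal units are CGS-derived: cm, s,
#' mg; concentrations in mg/ml (identically mg/cm^3).
#'
#' @slot D diffusion coefficient of cisplatin in tissue, cm^2/s.
#' @slot k_i intracellular uptake rate constant, 1/s. Uptake is
#'   irreversible (cisplatin binds DNA), so intracellular concentration
#'   grows monotonically toward its asymptote.
#' @slot k_f clearance rate from the extracellular space to the systemic
#'   fluid compartment, 1/s.
#' @slot V_f systemic fluid compartment volume, ml.
#' @slot k_r renal elimination rate from the fluid compartment, 1/s.
#' @slot mu mean of log10(IC50 in mg/ml) of the apoptosis-threshold
#'   distribution.
#' @slot sigma standard deviation of log10(IC50 in mg/ml).
#' @slot response_fraction volume fraction that must exceed its
#'   per-voxel threshold for a predicted response (default 0.66,
#'   the spherical-volume equivalent of a 30% diameter reduction).
#' @slot greens_mode `"paper"` evaluates the printed point-source kernel
#'   verbatim; `"physical"` includes the 1/(4*pi) prefactor of the
#'   free-space diffusion Green's function.
#' @slot mw_cisplatin molecular weight of cisplatin, g/mol.
#'
#' @seealso [modelParams()], [decayLength()], [steadyStateField()]
#' @export
setClass("ModelParams",
  representation(D = "numeric", k_i = "numeric", k_f = "numeric",
                 V_f = "numeric", k_r = "numeric", mu = "numeric",
                 sigma = "numeric", response_fraction = "numeric",
                 greens_mode = "character", mw_cisplatin = "numeric"))

setValidity("ModelParams", function(object) {
  msg <- character()
  pos <- c(D = object@D, k_i = object@k_i, k_f = object@k_f, V_f = object@V_f)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("'", bad, "' must be a positive finite number"))
  if (!is.finite(object@k_r) || object@k_r < 0)
    msg <- c(msg, "'k_r' must be >= 0")
  if (!is.finite(object@sigma) || object@sigma < 0)
    msg <- c(msg, "'sigma' must be >= 0")
  if (!is.finite(object@mu))
    msg <- c(msg, "'mu' must be finite")
  if (!is.finite(object@response_fraction) ||
      object@response_fraction <= 0 || object@response_fraction >= 1)
    msg <- c(msg, "'response_fraction' must lie strictly between 0 and 1")
  if (length(object@greens_mode) != 1L ||
      !object@greens_mode %in% c("paper", "physical"))
    msg <- c(msg, "'greens_mode' must be \"paper\" or \"physical\"")
  if (length(msg)) msg else TRUE
})

#' Injection plan: sites and per-site doses
#'
#' Positions of the N injection sites (physical coordinates in cm,
#' snapped to occupied voxel centers) and the dose deposited at each
#' site in mg.
#'
#' @slot sites numeric matrix, N x 3, site positions in cm.
#' @slot doses numeric(N), per-site doses m_j in mg (all > 0).
#'
#' @seealso [placeSites()], [apportionDose()]
#' @export
setClass("InjectionPlan",
  representation(sites = "matrix", doses = "numeric"))

setValidity("InjectionPlan", function(object) {
  msg <- character()
  if (!is.numeric(object@sites) || ncol(object@sites) != 3L)
    msg <- c(msg, "'sites' must be a numeric N x 3 matrix (cm)")
  if (nrow(object@sites) < 1L)
    msg <- c(msg, "plan must contain at least one site")
  if (length(object@doses) != nrow(object@sites))
    msg <- c(msg, "'doses' must have one entry per site")
  if (any(!is.finite(object@doses)) || any(object@doses <= 0))
    msg <- c(msg, "all doses must be positive and finite")
  if (anyDuplicated(round(object@sites, 10)))
    msg <- c(msg, "sites must be distinct voxels")
  if (length(msg)) msg else TRUE
})

#' Per-voxel scalar field aligned to a tumor mask
#'
#' `ConcentrationField` stores the asymptotic intracellular cisplatin
#' concentration (mg/ml) of every occupied voxel; `ThresholdField`
#' stores the per-voxel apoptosis threshold (mg/ml) together with the
#' seed that generated it. Values are ordered by the column-major linear
#' index of the occupied voxels of the underlying mask.
#'
#' @slot values numeric vector over occupied voxels, mg/ml.
#' @slot mask the [TumorMask-class] the field is aligned to.
#'
#' @seealso [steadyStateField()], [sampleThresholds()], [vResponse()]
#' @aliases ThresholdField-class
#' @export
setClass("ConcentrationField",
  representation(values = "numeric", mask = "TumorMask"))

setValidity("ConcentrationField", function(object) {
  msg <- character()
  if (length(object@values) != sum(object@mask@occupancy))
    msg <- c(msg, "'values' must have one entry per occupied voxel")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "field values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ConcentrationField-class
#' @slot seed integer seed that reproduces the threshold draw bit-for-bit.
#' @export
setClass("ThresholdField",
  representation(values = "numeric", mask = "TumorMask", seed = "integer"))

setValidity("ThresholdField", function(object) {
  msg <- character()
  if (length(object@values) != sum(object@mask@occupancy))
    msg <- c(msg, "'values' must have one entry per occupied voxel")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    msg <- c(msg, "thresholds must be finite and > 0")
  if (length(object@seed) != 1L)
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Result of a stochastic response prediction
#'
#' @slot v_response_pct mean percentage of tumor volume at or above its
#'   per-voxel apoptosis threshold, averaged over replicates.
#' @slot predicted integer, 1 if the mean V_response reaches the
#'   response fraction, else 0.
#' @slot replicates per-replicate V_response percentages.
#' @slot seed master seed of the replicate ensemble.
#'
#' @seealso [predictResponse()]
#' @export
setClass("ResponseResult",
  representation(v_response_pct = "numeric", predicted = "integer",
                 replicates = "numeric", seed = "integer"))

setValidity("ResponseResult", function(object) {
  msg <- character()
  if (object@v_response_pct < 0 || object@v_response_pct > 100)
    msg <- c(msg, "'v_response_pct' must lie in [0, 100]")
  if (!object@predicted %in% c(0L, 1L))
    msg <- c(msg, "'predicted' must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' State of the transient compartment solver
#'
#' Final state and mass trajectory of the explicit finite-difference
#' solution of the full transport system on a padded box enclosing the
#' tumor mask.
#'
#' @slot phi_e 3-D array, extracellular concentration on the padded
#'   solver grid, mg/ml.
#' @slot phi_i 3-D array, intracellular concentration, mg/ml.
#' @slot phi_f fluid-compartment concentration, mg/ml.
#' @slot t elapsed time, s.
#' @slot domain the padded [TumorMask-class] the arrays are defined on.
#' @slot trajectory data.frame with columns `t`, `mass_e`, `mass_i`,
#'   `mass_f` (mg) recorded at snapshot times.
#'
#' @seealso [transientSimulate()]
#' @export
setClass("TransientResult",
  representation(phi_e = "array", phi_i = "array", phi_f = "numeric",
                 t = "numeric", domain = "TumorMask",
                 trajectory = "data.frame"))

#' Power-law fit of minimal dose against tumor volume
#'
#' Ordinary least squares of log10(dose) on log10(volume):
#' dose = alpha * Volume^beta.
#'
#' @slot log10_alpha intercept, log10 of alpha (mg * ml^-beta scale).
#' @slot beta exponent of the power law.
#' @slot ci_log10_alpha,ci_beta 95% confidence intervals (length 2).
#' @slot r2 coefficient of determination of the log-log fit.
#' @slot n_points number of (volume, dose) pairs.
#'
#' @seealso [fitPowerLaw()], [doseLawTable()]
#' @export
setClass("PowerLawFit",
  representation(log10_alpha = "numeric", beta = "numeric",
                 ci_log10_alpha = "numeric", ci_beta = "numeric",
                 r2 = "numeric", n_points = "integer"))

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@n_points < 3L) msg <- c(msg, "'n_points' must be >= 3")
  if (object@r2 < 0 || object@r2 > 1) msg <- c(msg, "'r2' must lie in [0, 1]")
  if (object@ci_beta[1] > object@beta || object@ci_beta[2] < object@beta)
    msg <- c(msg, "'ci_beta' must bracket 'beta'")
  if (object@ci_log10_alpha[1] > object@log10_alpha ||
      object@ci_log10_alpha[2] < object@log10_alpha)
    msg <- c(msg, "'ci_log10_alpha' must bracket 'log10_alpha'")
  if (length(msg)) msg else TRUE
})

#' Prediction-versus-outcome tally
#'
#' Counts of true/false positives and negatives of model predictions
#' against clinical outcomes, with percentages of the cohort size.
#'
#' @slot tp,tn,fp,fn integer counts.
#'
#' @seealso [confusionSummary()], [concordance()]
#' @export
setClass("ConfusionSummary",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("ConfusionSummary", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(counts < 0)) "counts must be non-negative" else TRUE
})
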