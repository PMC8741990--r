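#' Transient simulation of the full transport system
#'
#' Integrates the coupled extracellular / intracellular / fluid system
#' explicitly on a padded box enclosing the mask: diffusion with
#' first-order uptake and clearance losses for the extracellular
#' compartment, pure accumulation for the intracellular compartment, and
#' a well-mixed fluid compartment fed by the clearance flux and drained
#' by renal elimination. The dose of each site is loaded into the
#' extracellular compartment of the site's voxel at `t = 0`; the
#' concentration is held at zero on the box faces, so the padded box
#' emulates free space. Coefficients are uniform everywhere (tumor and
#' surround identical), matching the free-space assumption behind the
#' asymptotic kernel.
#'
#' This solver is a verification and diagnostic path: the response
#' pipeline uses [steadyStateField()], to which this solution converges
#' (in `"physical"` kernel mode) as time grows.
#'
#' @param mask a [TumorMask-class].
#' @param plan an [InjectionPlan-class].
#' @param params a [ModelParams-class].
#' @param t_end simulated time in s (> 0).
#' @param pad_mm padding margin in mm; default five decay lengths,
#'   beyond which the field has decayed below 1% of its 1-decay-length
#'   value.
#' @param spacing_mm optional solver voxel edge in mm; defaults to the
#'   mask spacing. The mask is re-rasterized when a finer grid is
#'   requested (only meaningful for sphere surrogates; arbitrary masks
#'   must be supplied at the desired resolution).
#' @param stencil `"isotropic27"` (default) or `"standard7"` Laplacian.
#' @param dt time step in s; defaults to (and must not exceed) the
#'   stability bound `0.9 * h^2 / (6 D)`.
#' @param n_snapshots number of trajectory records (default 50).
#' @return a [TransientResult-class].
#' @examples
#' m <- makeSphereMask(0.3, spacing_mm = 2)
#' pl <- apportionDose(placeSites(m, 1), 10)
#' tr <- transientSimulate(m, pl, modelParams(), t_end = 3600)
#' utils::tail(tr@trajectory, 3)
#' @export
transientSimulate <- function(mask, plan, params = modelParams(), t_end,
                              pad_mm = 50 * decayLength(params),
                              spacing_mm = NULL,
                              stencil = c("isotropic27", "standard7"),
                              dt = NULL, n_snapshots = 50L) {
  stopifnot(is(mask, "TumorMask"), is(plan, "InjectionPlan"),
            is(params, "ModelParams"), t_end > 0)
  stencil <- match.arg(stencil)
  if (!is.null(spacing_mm) && !isTRUE(all.equal(spacing_mm,
                                                mean(mask@spacing)))) {
    mask <- makeSphereMask(maskVolume(mask), spacing_mm)
  }
  dom <- padDomain(mask, pad_mm)
  h <- mean(dom@spacing) / 10                      # cm
  dt_max <- 0.9 * h^2 / (6 * params@D)
  if (is.null(dt)) dt <- dt_max
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %.4g s exceeds the explicit stability bound %.4g s",
                 dt, dt_max))
  if (t_end < dt)
    stop("t_end is shorter than one time step")
  d <- dim(dom@occupancy)
  phe <- array(0, d)
  Vvox <- prod(dom@spacing) / 1000                 # cm^3
  idx <- .positionToIndex(dom, plan@sites)
  inside <- idx >= 1L & sweep(idx, 2L, d, `<=`)
  ok <- rowSums(inside) == 3L
  ok[ok] <- dom@occupancy[idx[ok, , drop = FALSE]]
  if (!all(ok))
    stop("injection site(s) ", paste(which(!ok), collapse = ", "),
         " fall outside the occupied mask")
  for (j in seq_len(nrow(idx)))
    phe[idx[j, 1], idx[j, 2], idx[j, 3]] <-
      phe[idx[j, 1], idx[j, 2], idx[j, 3]] + plan@doses[j] / Vvox
  phi <- array(0, d)
  phf <- 0
  nsteps_total <- ceiling(t_end / dt)
  snap_at <- unique(round(seq(0, nsteps_total, length.out = n_snapshots + 1L)))
  traj <- data.frame(t = 0, mass_e = sum(phe) * Vvox, mass_i = 0, mass_f = 0)
  done <- 0L
  for (s in snap_at[-1]) {
    res <- .fd_integrate(as.vector(phe), as.vector(phi), phf, as.integer(d),
                         params@D, params@k_i, params@k_f, params@k_r,
                         params@V_f, h, dt, as.integer(s - done),
                         stencil == "isotropic27")
    phe <- array(res$phe, d); phi <- array(res$phi, d); phf <- res$phf
    done <- s
    traj <- rbind(traj, data.frame(t = s * dt, mass_e = sum(phe) * Vvox,
                                   mass_i = sum(phi) * Vvox,
                                   mass_f = phf * params@V_f))
  }
  new("TransientResult", phi_e = phe, phi_i = phi, phi_f = phf,
      t = nsteps_total * dt, domain = dom, trajectory = traj)
}

setMethod("show", "TransientResult", function(object) {
  d <- dim(object@phi_e)
  cat(sprintf("TransientResult: %d x %d x %d grid at t = %.4g s\n",
              d[1], d[2], d[3], object@t))
  m <- utils::tail(object@trajectory, 1L)
  cat(sprintf("  mass (mg): extracellular %.4g, intracellular %.4g, fluid %.4g\n",
              m$mass_e, m$mass_i, m$mass_f))
})

#' Write a transient mass trajectory as CSV
#'
#' @param result a [TransientResult-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeTrajectoryCsv <- function(result, path) {
  utils::write.csv(result@trajectory, path, row.names = FALSE)
  invisible(path)
}
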