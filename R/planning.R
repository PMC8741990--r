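#' Choose injection sites inside a tumor mask
#'
#' Deterministic site placement aiming at the most homogeneous
#' superposed concentration pattern: the first seed is the occupied
#' voxel nearest the mask centroid; subsequent seeds are picked by
#' farthest-point selection (maximize the minimum distance to the seeds
#' already chosen, first-index tie-break); the seed set is then refined
#' by Lloyd iterations (assign every occupied voxel to its nearest site,
#' move each site to its cluster centroid snapped to the nearest
#' occupied voxel) until a fixed point or 100 iterations. Equidistant
#' partitioning of the mask minimizes the heterogeneity of a superposed
#' monotonically decaying kernel. There is no randomness: identical
#' inputs give identical plans, and plan geometry never depends on the
#' dose.
#'
#' The returned plan carries unit total dose split equally; use
#' [apportionDose()] to set the actual dose.
#'
#' @param mask a [TumorMask-class].
#' @param n number of sites (1 <= n <= occupied voxels).
#' @param max_iter maximum Lloyd iterations (default 100).
#' @return an [InjectionPlan-class] with unit total dose.
#' @examples
#' placeSites(makeSphereMask(1), 2)
#' @export
placeSites <- function(mask, n, max_iter = 100L) {
  stopifnot(is(mask, "TumorMask"))
  P <- voxelCenters(mask)
  nv <- nrow(P)
  if (n < 1L) stop("n must be at least 1")
  if (n > nv)
    stop(sprintf("n = %d exceeds the %d occupied voxels", n, nv))
  .sq <- function(p) (P[, 1] - p[1])^2 + (P[, 2] - p[2])^2 + (P[, 3] - p[3])^2
  cen <- colMeans(P)
  sites <- which.min(.sq(cen))          # seed 1: nearest the centroid
  mind <- .sq(P[sites, ])
  while (length(sites) < n) {           # farthest-point seeding
    s <- which.max(mind)                # which.max: lowest index on ties
    sites <- c(sites, s)
    mind <- pmin(mind, .sq(P[s, ]))
  }
  if (n > 1L) {
    for (it in seq_len(max_iter)) {     # Lloyd refinement on the voxel set
      dmat <- vapply(sites, function(s) .sq(P[s, ]), numeric(nv))
      assign <- max.col(-dmat, ties.method = "first")
      new_sites <- vapply(seq_along(sites), function(cl) {
        members <- assign == cl
        if (!any(members)) return(sites[cl])
        which.min(.sq(colMeans(P[members, , drop = FALSE])))
      }, integer(1))
      if (all(new_sites == sites)) break
      sites <- new_sites
    }
  }
  new("InjectionPlan", sites = P[sites, , drop = FALSE],
      doses = rep(1 / n, n))
}

#' Apportion a total dose equally among the sites of a plan
#'
#' Equal splitting `m_j = total / N` is the symmetric default; no
#' per-site weighting is applied.
#'
#' @param plan an [InjectionPlan-class].
#' @param total_dose total dose in mg (> 0).
#' @return the plan with doses replaced.
#' @export
apportionDose <- function(plan, total_dose) {
  stopifnot(is(plan, "InjectionPlan"))
  if (!is.finite(total_dose) || total_dose <= 0)
    stop("total_dose must be positive")
  plan@doses <- rep(total_dose / nrow(plan@sites), nrow(plan@sites))
  validObject(plan)
  plan
}

#' Heterogeneity of a concentration field
#'
#' Coefficient of variation (population SD over mean, n in the
#' denominator) of the field over the occupied voxels. Zero for a
#' perfectly uniform field.
#'
#' @param field a [ConcentrationField-class] on at least 2 voxels.
#' @return dimensionless CV.
#' @export
homogeneityCost <- function(field) {
  v <- field@values
  if (length(v) < 2L)
    stop("homogeneity is undefined on a single-voxel field")
  sqrt(mean((v - mean(v))^2)) / mean(v)
}

#' @rdname InjectionPlan-class
#' @export
setMethod("planSites", "InjectionPlan", function(x) x@sites)

#' @rdname InjectionPlan-class
#' @export
setMethod("planDoses", "InjectionPlan", function(x) x@doses)

#' @rdname InjectionPlan-class
#' @export
setMethod("totalDose", "InjectionPlan", function(x) sum(x@doses))

setMethod("show", "InjectionPlan", function(object) {
  cat(sprintf("InjectionPlan: %d site(s), total dose %.4g mg\n",
              nrow(object@sites), sum(object@doses)))
  df <- data.frame(x_mm = object@sites[, 1] * 10,
                   y_mm = object@sites[, 2] * 10,
                   z_mm = object@sites[, 3] * 10,
                   dose_mg = object@doses)
  print(format(df, digits = 4), row.names = FALSE)
})

#' Serialize or load an injection plan as JSON
#'
#' Plans are exchanged with site coordinates in mm and doses in mg, so
#' clinicians' actual site choices can be evaluated against planner
#' output.
#'
#' @param plan an [InjectionPlan-class].
#' @param path JSON file path.
#' @return `writePlanJson` invisibly returns `path`; `readPlanJson`
#'   returns an [InjectionPlan-class].
#' @export
writePlanJson <- function(plan, path) {
  jsonlite::write_json(
    list(sites_mm = unname(plan@sites * 10), doses_mg = plan@doses),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writePlanJson
#' @export
readPlanJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- matrix(as.numeric(obj$sites_mm), ncol = 3L) / 10
  new("InjectionPlan", sites = sites, doses = as.numeric(obj$doses_mg))
}
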