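.cohort_cols <- c("patient_id", "histology", "dose_mg", "n_injections",
                  "volume_cm3", "v_response_printed", "prediction_printed",
                  "outcome")

#' Path of the packaged cohort table
#'
#' The 32 retrospectively evaluated patients (15 adenocarcinoma, 16
#' squamous-cell, 1 large-cell), transcribed verbatim from the published
#' per-patient tables: dose, number of injections, initial tumor volume,
#' printed responding-volume percentage, printed model prediction, and
#' clinical outcome (1 = complete or partial response). Note the printed
#' outcome column sums to 24 responders while the accompanying text
#' reports 25; the table is kept verbatim.
#'
#' @return file path of the CSV fixture.
#' @export
cohortFixture <- function() {
  system.file("extdata", "cohort_tables.csv", package = "TumorDosim",
              mustWork = TRUE)
}

#' Load and validate a cohort table
#'
#' @param path CSV path following the fixture schema
#'   (`patient_id, histology, dose_mg, n_injections, volume_cm3,
#'   v_response_printed, prediction_printed, outcome`); defaults to the
#'   packaged 32-patient table.
#' @return a validated data.frame, one row per patient.
#' @examples
#' rec <- loadCohort()
#' table(rec$histology)
#' @export
loadCohort <- function(path = cohortFixture()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(rec), .cohort_cols))
    stop("cohort header must be exactly: ",
         paste(.cohort_cols, collapse = ", "))
  .bad <- function(col, ok) {
    i <- which(!ok)
    if (length(i))
      stop(sprintf("cohort validation failed at row %d, column '%s'",
                   i[1], col))
  }
  .bad("histology", rec$histology %in% c("ADN", "SQC", "SCLC", "LCC"))
  .bad("dose_mg", is.finite(rec$dose_mg) & rec$dose_mg > 0 &
         rec$dose_mg <= 40)
  .bad("n_injections", rec$n_injections %in% 1:5)
  .bad("volume_cm3", is.finite(rec$volume_cm3) & rec$volume_cm3 > 0)
  .bad("outcome", rec$outcome %in% c(0L, 1L))
  .bad("prediction_printed", is.na(rec$prediction_printed) |
         rec$prediction_printed %in% c(0L, 1L))
  rec
}

.predCol <- function(records, source = c("printed", "regenerated")) {
  source <- match.arg(source)
  col <- if (source == "printed") "prediction_printed" else "prediction_model"
  if (!col %in% names(records) || anyNA(records[[col]]))
    stop("predictions ('", col, "') are missing; ",
         if (source == "regenerated") "run regeneratePredictions() first"
         else "the table carries no printed predictions")
  records[[col]]
}

#' Prediction-outcome concordance
#'
#' Percentage of patients whose model prediction matches the clinical
#' outcome, overall and per histology. Percentages are returned at full
#' precision; published summaries round the overall accuracy to the
#' nearest integer (72 for 23/32) and report subgroup accuracies to one
#' decimal where needed.
#'
#' @param records a cohort data.frame from [loadCohort()] (after
#'   [regeneratePredictions()] for `source = "regenerated"`).
#' @param source use the `"printed"` prediction column or the
#'   `"regenerated"` one.
#' @return a list with `overall`, `by_histology` (named vector) and `n`.
#' @examples
#' concordance(loadCohort())
#' @export
concordance <- function(records, source = c("printed", "regenerated")) {
  pred <- .predCol(records, source)
  hit <- pred == records$outcome
  list(overall = 100 * mean(hit),
       by_histology = vapply(split(hit, records$histology), function(z)
         100 * mean(z), numeric(1)),
       n = nrow(records))
}

#' Confusion tally of predictions against outcomes
#'
#' @inheritParams concordance
#' @return a [ConfusionSummary-class].
#' @examples
#' confusionSummary(loadCohort())
#' @export
confusionSummary <- function(records, source = c("printed", "regenerated")) {
  pred <- .predCol(records, source)
  out <- records$outcome
  new("ConfusionSummary",
      tp = sum(pred == 1L & out == 1L), tn = sum(pred == 0L & out == 0L),
      fp = sum(pred == 1L & out == 0L), fn = sum(pred == 0L & out == 1L))
}

#' @rdname ConfusionSummary-class
#' @param x a `ConfusionSummary`.
#' @return `confusionCounts`: named integer vector; `confusionPct`:
#'   percentages of cohort size; `accuracy`: percent correct.
#' @export
confusionCounts <- function(x) {
  c(tp = x@tp, tn = x@tn, fn = x@fn, fp = x@fp)
}

#' @rdname ConfusionSummary-class
#' @export
confusionPct <- function(x) {
  n <- x@tp + x@tn + x@fp + x@fn
  100 * confusionCounts(x) / n
}

#' @rdname ConfusionSummary-class
#' @export
accuracy <- function(x) {
  n <- x@tp + x@tn + x@fp + x@fn
  100 * (x@tp + x@tn) / n
}

setMethod("show", "ConfusionSummary", function(object) {
  n <- object@tp + object@tn + object@fp + object@fn
  cat(sprintf("ConfusionSummary (n = %d): TP %d  TN %d  FN %d  FP %d  (accuracy %.1f%%)\n",
              n, object@tp, object@tn, object@fn, object@fp,
              accuracy(object)))
})

#' Regenerate model predictions for a cohort on sphere surrogates
#'
#' The published per-patient evaluation used segmented tumor shapes that
#' are not available; only volumes are printed. Each patient is replayed
#' on a sphere surrogate of the recorded volume with the recorded dose
#' and injection count. The printed columns are kept alongside so exact
#' and regenerated evaluations remain distinct.
#'
#' @param records a cohort data.frame.
#' @param params a [ModelParams-class].
#' @param n_replicates threshold replicates per patient.
#' @param seed master seed; per-patient seeds are derived
#'   deterministically.
#' @param spacing_mm sphere surrogate voxel edge, mm.
#' @return the records with columns `v_response_model` and
#'   `prediction_model` appended.
#' @export
regeneratePredictions <- function(records, params = modelParams(),
                                  n_replicates = 25L, seed = 1L,
                                  spacing_mm = 1) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    mask <- makeSphereMask(records$volume_cm3[i], spacing_mm)
    predictResponse(mask, records$dose_mg[i], records$n_injections[i],
                    params, n_replicates, seed = .deriveSeed(seed, i, 0L))
  })
  records$v_response_model <- vapply(res, function(r) r@v_response_pct,
                                     numeric(1))
  records$prediction_model <- vapply(res, function(r) r@predicted,
                                     integer(1))
  records
}

#' Parameter sensitivity of the cohort confusion summary
#'
#' Re-runs the cohort replay with each of `D`, `k_i`, `k_f` and `mu`
#' perturbed by the given factors in turn and tallies the confusion
#' summary per perturbation. Rate constants are multiplied by the
#' factor; for `mu` the factor scales the linear-scale median IC50,
#' i.e. `mu` is shifted by `log10(factor)` (a factor 0.1 lowers every
#' threshold tenfold, which shifts predictions toward more positives).
#' Site geometry is independent of the parameters, so masks, plans and
#' per-site distances are computed once per patient and reused across
#' perturbations.
#'
#' @param records a cohort data.frame.
#' @param params baseline [ModelParams-class].
#' @param factors perturbation factors (default `c(0.1, 10)`).
#' @param n_replicates threshold replicates per patient.
#' @param seed master seed (same derived per-patient seeds for every
#'   perturbation, so threshold draws are shared).
#' @param spacing_mm sphere surrogate voxel edge, mm.
#' @return a data.frame with one row per (parameter, factor): counts
#'   `tp`, `tn`, `fn`, `fp` and the matching percentages; the baseline
#'   (factor 1) is included as the first row.
#' @export
sensitivityAnalysis <- function(records, params = modelParams(),
                                factors = c(0.1, 10), n_replicates = 25L,
                                seed = 1L, spacing_mm = 1) {
  pert <- rbind(data.frame(parameter = "baseline", factor = 1),
                expand.grid(parameter = c("D", "k_i", "k_f", "mu"),
                            factor = factors, stringsAsFactors = FALSE)[
                  order(rep(seq_len(4), length(factors))), ])
  pred <- matrix(NA_integer_, nrow(records), nrow(pert))
  for (i in seq_len(nrow(records))) {
    mask <- makeSphereMask(records$volume_cm3[i], spacing_mm)
    plan <- placeSites(mask, records$n_injections[i])
    P <- voxelCenters(mask)
    h_cm <- mean(mask@spacing) / 10
    nv <- nrow(P)
    dists <- vapply(seq_len(nrow(plan@sites)), function(j)
      sqrt((P[, 1] - plan@sites[j, 1])^2 + (P[, 2] - plan@sites[j, 2])^2 +
             (P[, 3] - plan@sites[j, 3])^2), numeric(nv))
    reff <- pmax(dists, h_cm / 2)
    m_j <- records$dose_mg[i] / ncol(dists)
    seed_i <- .deriveSeed(seed, i, 0L)
    zs <- lapply(seq_len(n_replicates), function(r)
      .withSeed(seed_i + r, stats::rnorm(nv)))
    for (p in seq_len(nrow(pert))) {
      pp <- params
      fac <- pert$factor[p]
      switch(pert$parameter[p],
             D = { pp@D <- pp@D * fac },
             k_i = { pp@k_i <- pp@k_i * fac },
             k_f = { pp@k_f <- pp@k_f * fac },
             mu = { pp@mu <- pp@mu + log10(fac) },
             baseline = {})
      L <- decayLength(pp)
      C <- if (pp@greens_mode == "physical") 1 / (4 * pi) else 1
      phi <- rowSums(C * pp@k_i * m_j / (pp@D * reff) * exp(-dists / L))
      v <- mean(vapply(zs, function(z)
        100 * mean(phi >= 10^(pp@mu + pp@sigma * z)), numeric(1)))
      pred[i, p] <- classifyResponse(v, pp)
    }
  }
  out <- records$outcome
  tab <- cbind(pert, t(apply(pred, 2L, function(pm)
    c(tp = sum(pm == 1L & out == 1L), tn = sum(pm == 0L & out == 0L),
      fn = sum(pm == 0L & out == 1L), fp = sum(pm == 1L & out == 0L)))))
  tab$tp_pct <- 100 * tab$tp / nrow(records)
  tab$tn_pct <- 100 * tab$tn / nrow(records)
  tab$fn_pct <- 100 * tab$fn / nrow(records)
  tab$fp_pct <- 100 * tab$fp / nrow(records)
  rownames(tab) <- NULL
  tab
}

#' Exact two-sided Mann-Whitney rank test
#'
#' Exact p-value by complete enumeration of rank assignments under the
#' null, suitable for the very small samples of the cohort (total size
#' at most 25). The two-sided p doubles the smaller tail of the
#' rank-sum null distribution (capped at 1). Ties across groups are
#' rejected: the exact null assumes continuous data.
#'
#' @param group_a,group_b numeric vectors.
#' @return two-sided p-value.
#' @examples
#' exactRankTest(c(9, 10), c(1:8))
#' @export
exactRankTest <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1L, nb >= 1L)
  if (na + nb > 25L)
    stop("exact enumeration is limited to a total sample size of 25")
  if (anyDuplicated(c(group_a, group_b)))
    stop("ties across groups are not supported by the exact null")
  r <- rank(c(group_a, group_b))
  w_obs <- sum(r[seq_len(na)])
  w_null <- utils::combn(na + nb, na, FUN = function(ix) sum(ix))
  p_lo <- mean(w_null <= w_obs)
  p_hi <- mean(w_null >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}
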