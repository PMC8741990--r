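test_that("threshold sampling is reproducible and degenerate at sigma = 0", {
  m <- makeSphereMask(0.7)
  p0 <- modelParams(sigma = 0)
  thr <- fieldValues(sampleThresholds(m, p0, seed = 7))
  expect_equal(thr, rep(10^-2.59, nOccupied(m)), tolerance = 1e-12)
  expect_equal(10^-2.59, 2.57e-3, tolerance = 1e-3)
  a <- sampleThresholds(m, defaultParams, seed = 11)
  b <- sampleThresholds(m, defaultParams, seed = 11)
  expect_identical(fieldValues(a), fieldValues(b))
  expect_false(identical(fieldValues(a),
                         fieldValues(sampleThresholds(m, defaultParams, 12))))
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(sampleThresholds(m, defaultParams, 5))
  expect_identical(rnorm(3), before)
})

test_that("responding volume counts voxels at or above threshold", {
  m3 <- lineMask(3)
  thr <- new("ThresholdField", values = rep(1, 3), mask = m3, seed = 1L)
  expect_equal(vResponse(fieldOn(m3, c(2, 1, 0.5)), thr), 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(vResponse(fieldOn(m3, c(9, 9, 9)), thr), 100)
  expect_equal(vResponse(fieldOn(m3, c(0, 0, 0)), thr), 0)
  expect_error(vResponse(fieldOn(lineMask(2), c(1, 1)), thr), "different masks")
})

test_that("classification applies the inclusive 66% volume rule", {
  expect_identical(classifyResponse(57), 0L)   # printed non-responder level
  expect_identical(classifyResponse(72), 1L)   # printed responder level
  expect_identical(classifyResponse(66), 1L)   # boundary is inclusive
  expect_identical(classifyResponse(65.9), 0L)
  expect_identical(classifyResponse(c(0, 100)), c(0L, 1L))
})

test_that("a small tumor at the clinical dose saturates; vanishing dose does not", {
  res <- predictResponse(makeSphereMask(0.95), 40, 4, seed = 1)
  expect_equal(res@v_response_pct, 100)
  expect_identical(res@predicted, 1L)
  low <- predictResponse(makeSphereMask(0.95), 1e-9, 4, seed = 1)
  expect_identical(low@predicted, 0L)
  expect_lt(low@v_response_pct, 1)
})

test_that("single-voxel closed form fixes the critical dose exactly", {
  m <- pointMask(2)                     # h = 0.2 cm, floor r_eff = 0.1 cm
  p0 <- modelParams(sigma = 0)
  phi_unit <- defaultParams@k_i / (defaultParams@D * 0.1)
  critical <- 10^-2.59 / phi_unit
  expect_equal(minDose(m, 1, p0, n_replicates = 3, seed = 1), critical,
               tolerance = 1e-12)
  expect_identical(predictResponse(m, critical * 1.01, 1, p0, 3, 1)@predicted, 1L)
  expect_identical(predictResponse(m, critical * 0.99, 1, p0, 3, 1)@predicted, 0L)
})

test_that("the percentile rule picks the k-th smallest critical dose", {
  # 3 voxels, deterministic thresholds: critical doses rank with distance,
  # and k = ceiling(0.66 * 3) = 2 selects the middle voxel
  m <- lineMask(3)
  p0 <- modelParams(sigma = 0)
  Phi <- fieldValues(steadyStateField(m, planAt(m, 1, 1), p0))
  M <- sort(10^-2.59 / Phi)
  expect_equal(minDose(m, 1, p0, n_replicates = 1, seed = 1), M[2],
               tolerance = 1e-12)
  # dose just above/below that quantile flips the classification
  expect_identical(classifyResponse(
    vResponse(fieldOn(m, Phi * M[2] * 1.001),
              sampleThresholds(m, p0, 1))), 1L)
  expect_identical(classifyResponse(
    vResponse(fieldOn(m, Phi * M[2] * 0.999),
              sampleThresholds(m, p0, 1))), 0L)
})

test_that("percentile minimal dose agrees with a bisection oracle per replicate", {
  m <- makeSphereMask(0.8)
  md <- minDose(m, 2, defaultParams, n_replicates = 4, seed = 3,
                details = TRUE)
  field <- steadyStateField(m, placeSites(m, 2), defaultParams)
  for (r in seq_len(4)) {
    thr <- sampleThresholds(m, defaultParams, seed = 3 + r)
    covered <- function(dose)
      vResponse(fieldOn(m, fieldValues(field) * dose), thr) >=
        100 * defaultParams@response_fraction
    lo <- 1e-12; hi <- 1e6
    for (i in 1:80) {
      mid <- sqrt(lo * hi)
      if (covered(mid)) hi <- mid else lo <- mid
    }
    expect_equal(md$replicates[r], hi, tolerance = 1e-3)
  }
})

test_that("doubling every threshold doubles the minimal dose replicate-wise", {
  m <- makeSphereMask(0.8)
  # shifting mu by log10(2) doubles all thresholds for the same seed
  base <- minDose(m, 2, defaultParams, n_replicates = 5, seed = 9,
                  details = TRUE)
  doubled <- minDose(m, 2, modelParams(mu = defaultParams@mu + log10(2)),
                     n_replicates = 5, seed = 9, details = TRUE)
  expect_equal(doubled$replicates, 2 * base$replicates, tolerance = 1e-12)
})

test_that("responding volume is monotone in dose and min dose is positive", {
  m <- makeSphereMask(0.8)
  field <- steadyStateField(m, apportionDose(placeSites(m, 2), 1),
                            defaultParams)
  thr <- sampleThresholds(m, defaultParams, seed = 4)
  vs <- vapply(c(0.01, 0.1, 1, 10, 100), function(d)
    vResponse(fieldOn(m, fieldValues(field) * d), thr), numeric(1))
  expect_true(all(diff(vs) >= 0))
  md <- minDose(m, 2, defaultParams, n_replicates = 2, seed = 4)
  expect_true(is.finite(md) && md > 0)
})

test_that("min dose scales by exactly 4*pi between kernel conventions", {
  m <- makeSphereMask(0.8)
  paper <- minDose(m, 2, defaultParams, n_replicates = 3, seed = 5,
                   details = TRUE)
  phys <- minDose(m, 2, modelParams(greens_mode = "physical"),
                  n_replicates = 3, seed = 5, details = TRUE)
  expect_equal(phys$replicates, 4 * pi * paper$replicates, tolerance = 1e-12)
})
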