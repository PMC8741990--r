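test_that("immobile drug with negligible clearance loads one voxel completely", {
  # D -> 0, k_f -> 0: the site voxel ends at m / V_voxel intracellularly
  m <- pointMask(2)
  p <- modelParams(D = 1e-12, k_f = 1e-15)
  plan <- planAt(m, 1, doses = 5)
  t_end <- 12 / p@k_i                              # ~12 uptake time constants
  tr <- transientSimulate(m, plan, p, t_end = t_end, pad_mm = 2, dt = 1800)
  expect_equal(max(tr@phi_i), 5 / 0.008, tolerance = 1e-3)
})

test_that("mass is conserved within 0.5% without renal elimination", {
  m <- makeSphereMask(0.2)
  plan <- apportionDose(placeSites(m, 2), 10)
  tr <- transientSimulate(m, plan, defaultParams, t_end = 24 * 3600,
                          pad_mm = 10)
  total <- tr@trajectory$mass_e + tr@trajectory$mass_i + tr@trajectory$mass_f
  expect_lt(max(abs(total - 10) / 10), 0.005)
  # intracellular mass grows monotonically (uptake is irreversible)
  expect_true(all(diff(tr@trajectory$mass_i) >= 0))
})

test_that("the limiting intracellular uptake fraction is k_i / (k_i + k_f)", {
  m <- makeSphereMask(0.2)
  plan <- apportionDose(placeSites(m, 1), 10)
  tr <- transientSimulate(m, plan, defaultParams, t_end = 24 * 3600,
                          pad_mm = 10)
  frac <- utils::tail(tr@trajectory$mass_i, 1) / 10
  expect_equal(frac, 1.05e-4 / 2.51e-4, tolerance = 0.005)
  expect_equal(1.05e-4 / 2.51e-4, 0.418, tolerance = 1e-3)
})

test_that("interior solution is insensitive to doubling the default padding", {
  m <- makeSphereMask(0.1)
  plan <- apportionDose(placeSites(m, 1), 10)
  grab <- function(pad) {
    tr <- transientSimulate(m, plan, defaultParams, t_end = 6 * 3600,
                            pad_mm = pad)
    tr@phi_i[occupancy(tr@domain)]
  }
  a <- grab(5)       # the default margin, ~5 decay lengths
  b <- grab(10)
  expect_lt(max(abs(a - b) / b), 0.01)
})

test_that("renal elimination drains the fluid compartment", {
  m <- pointMask(1)
  plan <- planAt(m, 1, doses = 1)
  p0 <- modelParams(k_r = 0)
  p1 <- modelParams(k_r = 5e-4)
  t0 <- transientSimulate(m, plan, p0, t_end = 12 * 3600, pad_mm = 3)
  t1 <- transientSimulate(m, plan, p1, t_end = 12 * 3600, pad_mm = 3)
  expect_lt(t1@phi_f, t0@phi_f)
  total1 <- with(utils::tail(t1@trajectory, 1), mass_e + mass_i + mass_f)
  expect_lt(total1, 1)                             # mass leaves the system
})

test_that("unstable or degenerate step requests are rejected", {
  m <- pointMask(1)
  plan <- planAt(m, 1, doses = 1)
  dt_max <- 0.9 * 0.1^2 / (6 * defaultParams@D)
  expect_error(transientSimulate(m, plan, defaultParams, t_end = 100,
                                 pad_mm = 2, dt = dt_max * 1.5),
               "stability")
  expect_error(transientSimulate(m, plan, defaultParams, t_end = 1,
                                 pad_mm = 2), "shorter than one")
})

test_that("trajectories can be exported as CSV", {
  m <- pointMask(2)
  tr <- transientSimulate(m, planAt(m, 1, 1), defaultParams,
                          t_end = 3600, pad_mm = 2)
  path <- tempfile(fileext = ".csv")
  writeTrajectoryCsv(tr, path)
  back <- read.csv(path)
  expect_identical(names(back), c("t", "mass_e", "mass_i", "mass_f"))
  expect_equal(nrow(back), nrow(tr@trajectory))
  unlink(path)
})

test_that("the isotropic stencil outperforms the 7-point near the source", {
  # lattice anisotropy of the 7-point Laplacian: its Green's function
  # overshoots on-axis at small separations, which the 27-point isotropic
  # stencil corrects by an order of magnitude
  p <- modelParams()
  L <- decayLength(p)
  m <- makeSphereMask(0.113, spacing_mm = 0.5)
  plan <- apportionDose(placeSites(m, 1), 10)
  err <- function(stencil) {
    tr <- transientSimulate(m, plan, p, t_end = 24 * 3600, pad_mm = 3,
                            stencil = stencil)
    dom <- tr@domain
    P <- voxelCenters(dom)
    s <- planSites(plan)[1, ]
    r <- sqrt((P[, 1] - s[1])^2 + (P[, 2] - s[2])^2 + (P[, 3] - s[3])^2)
    h <- mean(voxelSpacing(dom)) / 10
    sel <- r >= 2 * h & r <= 3 * L
    ref <- p@k_i * 10 / (4 * pi * p@D * r[sel]) * exp(-r[sel] / L)
    max(abs(tr@phi_i[occupancy(dom)][sel] - ref) / ref)
  }
  e7 <- err("standard7")
  e27 <- err("isotropic27")
  expect_gt(e7, 0.05)
  expect_lt(e27, e7 / 3)
})
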