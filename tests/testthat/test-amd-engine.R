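test_that("boost potential gates at the threshold and matches hand arithmetic", {
  expect_identical(boostDeltaV(100, 100, 10), 0)
  expect_identical(boostDeltaV(110, 100, 10), 0)
  expect_equal(boostDeltaV(80, 100, 10), 400 / 30, tolerance = 1e-12)
  expect_error(boostDeltaV(80, 100, 0), "positive")
  # continuity and smoothness at V = E
  expect_lt(abs(boostDeltaV(100 - 1e-9, 100, 10)), 1e-12)
  expect_lt(abs(boostFactor(100 - 1e-9, 100, 10) - 1), 1e-8)
})

test_that("boost factor is the derivative of the boosted potential", {
  expect_equal(boostFactor(80, 100, 10), 1 / 9, tolerance = 1e-12)
  expect_identical(boostFactor(105, 100, 10), 1)
  Vgrid <- seq(50, 99, by = 0.5)
  eps <- 1e-5
  numDeriv <- ((Vgrid + eps + boostDeltaV(Vgrid + eps, 100, 10)) -
               (Vgrid - eps + boostDeltaV(Vgrid - eps, 100, 10))) / (2 * eps)
  expect_equal(boostFactor(Vgrid, 100, 10), numDeriv, tolerance = 1e-6)
  # monotone non-increasing as V decreases below E
  expect_true(all(diff(boostFactor(Vgrid, 100, 10)) >= 0))
})

test_that("the boosted surface flattens but never crosses the threshold", {
  Vgrid <- seq(-200, 99.9, by = 0.1)
  Vstar <- Vgrid + boostDeltaV(Vgrid, 100, 10)
  expect_true(all(Vstar < 100))
  expect_true(all(diff(Vstar) > 0))
})

test_that("aMD parameter estimation reproduces the published worked blocks", {
  # methylated complex
  p <- estimateAmdParameters(-68357, 2016, 22552, 162)
  expect_equal(amdParameterTable(p),
               c(eTot = -64749, alphaTot = 4510, eDih = 2583, alphaDih = 113))
  # apo
  p <- estimateAmdParameters(-59185, 1933, 19702, 156)
  expect_equal(amdParameterTable(p),
               c(eTot = -56033, alphaTot = 3940, eDih = 2479, alphaDih = 109))
  # non-methylated complex (dihedral block)
  p <- estimateAmdParameters(-66609, 1949, 22555, 162)
  expect_equal(unname(amdParameterTable(p)[c("alphaTot", "eDih")]),
               c(4511, 2516))
  # double mutant
  p <- estimateAmdParameters(-68088, 2042, 22455, 162)
  expect_equal(unname(amdParameterTable(p)["alphaTot"]), 4491)
  # unit counts expose the coefficients
  p <- estimateAmdParameters(0, 0, 1, 1)
  expect_equal(c(p@eTot, p@alphaTot, p@eDih, p@alphaDih),
               c(0.16, 0.2, 3.5, 0.7), tolerance = 1e-12)
  expect_error(estimateAmdParameters(0, 0, 0, 1), ">= 1")
})

test_that("parameter estimation is exactly linear in system size", {
  base <- estimateAmdParameters(-100, 50, 1000, 20)
  doubled <- estimateAmdParameters(-100, 50, 2000, 40)
  expect_equal(doubled@eTot - (-100), 2 * (base@eTot - (-100)))
  expect_equal(doubled@alphaTot, 2 * base@alphaTot)
  expect_equal(doubled@eDih - 50, 2 * (base@eDih - 50))
  expect_equal(doubled@alphaDih, 2 * base@alphaDih)
})

test_that("dual boost applies the dihedral channel before the total", {
  p <- estimateAmdParameters(-50, 10, 100, 10)
  out <- dualBoostDeltaV(c(-60, -20), c(5, 50), p)
  expect_equal(out$deltaVDih[1], boostDeltaV(5, p@eDih, p@alphaDih))
  expect_equal(out$deltaVTot[1],
               boostDeltaV(-60 + out$deltaVDih[1], p@eTot, p@alphaTot))
  expect_equal(out$deltaVTotal, out$deltaVDih + out$deltaVTot)
  expect_identical(out$deltaVDih[2], 0)   # V_dih above threshold
})

test_that("Langevin runs are deterministic and gate to the unboosted path", {
  sys <- toySystem("double_well", h = 3)
  a <- runLangevin(sys, nSteps = 5000, seed = 9)
  b <- runLangevin(sys, nSteps = 5000, seed = 9)
  expect_identical(a@samples, b@samples)
  expect_identical(a@V, b@V)
  # boost parameters with E below every sampled V: bitwise identical
  low <- new("AMDParameters", eTot = -100, alphaTot = 1, eDih = 0,
             alphaDih = 1, provenance = list())
  c <- runLangevin(sys, nSteps = 5000, seed = 9, params = low)
  expect_identical(c@samples, a@samples)
  expect_true(all(c@deltaV == 0))
  expect_error(runLangevin(sys, nSteps = 100, dt = 1, seed = 1), "dt")
  expect_error(runLangevin(sys, nSteps = 100, seed = 1, guard = 0.5),
               "diverged")
})

test_that("long unboosted sampling reproduces the Boltzmann density", {
  sys <- toySystem("double_well", h = 3)
  bt <- runLangevin(sys, nSteps = 1e8, stride = 100, seed = 21)
  edges <- seq(-1.8, 1.8, length.out = 37)
  fes <- suppressWarnings(freeEnergySurface(bt@samples, breaks = list(edges)))
  tv <- 0.5 * sum(abs(as.vector(fes@weightSums) /
                        sum(fes@weightSums) -
                      quadratureBinProbs(sys, edges)))
  expect_lt(tv, 0.05)
})

test_that("boosted runs cross the barrier more often than unboosted runs", {
  sys <- toySystem("double_well", h = 3)
  p <- new("AMDParameters", eTot = 3, alphaTot = 1, eDih = 0, alphaDih = 1,
           provenance = list())
  for (seed in 1:5) {
    un <- runLangevin(sys, nSteps = 2e5, stride = 10, seed = seed)
    bo <- runLangevin(sys, nSteps = 2e5, stride = 10, seed = seed, params = p)
    expect_gt(sum(diff(bo@samples[, 1] > 0) != 0),
              sum(diff(un@samples[, 1] > 0) != 0))
  }
})

test_that("reweighting recovers closed-form weight ratios", {
  expect_equal(reweightFrames(c(0, 0, 0)), rep(1 / 3, 3))
  kT <- kBoltzmann * 300
  w <- reweightFrames(c(0, kT * log(2)))
  expect_equal(w[2] / w[1], 2, tolerance = 1e-12)
  expect_error(reweightFrames(c(-1, 0)), "non-negative")
  # Maclaurin series converges to the exponential weights
  set.seed(4)
  dV <- runif(200, 0, 5) / thermoBeta(300)   # beta * dV in [0, 5]
  exact <- reweightFrames(dV)
  expect_gt(max(abs(reweightFrames(dV, method = "maclaurin", k = 3) - exact)),
            1e-6)   # low order differs ...
  expect_lt(max(abs(reweightFrames(dV, method = "maclaurin", k = 30) - exact)),
            1e-6)   # ... high order agrees
})

test_that("free-energy surfaces are flat for uniform sampling and zero-shifted", {
  set.seed(2)
  x <- runif(20000, -1, 1)
  fes <- freeEnergySurface(x, breaks = 10)
  expect_equal(min(fes@G), 0)
  expect_lt(max(fes@G) - min(fes@G), 0.1)
  expect_warning(freeEnergySurface(rep(0.5, 10), breaks = list(c(0, 1, 2))),
                 "degenerate")
})

test_that("sampled double-well deltaG matches the quadrature oracle", {
  sys <- toySystem("double_well", h = 3, tilt = 0.8)
  bt <- runLangevin(sys, nSteps = 2e7, stride = 100, seed = 5)
  fes <- suppressWarnings(
    freeEnergySurface(bt@samples, breaks = list(seq(-1.8, 1.8, length.out = 37))))
  basins <- list(a = c(-1.6, -0.4), b = c(0.4, 1.6))
  bb <- basinBarrier(fes, basins$a, basins$b)
  expect_equal(bb$deltaG, quadratureDeltaG(sys, basins$a, basins$b),
               tolerance = 0.3)
  # swapped basins: exact antisymmetry of deltaG
  bb2 <- basinBarrier(fes, basins$b, basins$a)
  expect_equal(bb2$deltaG, -bb$deltaG)
})

test_that("basinBarrier finds the lowest saddle on a 2D surface", {
  # hand-built surface: two basins at (2,3) and (8,3), ridge at x ~ 5 with a
  # notch of height 1.7 at (5,5)
  G <- matrix(5, 10, 7)
  G[2, 3] <- 0; G[8, 3] <- 0.9
  G[3:7, 3] <- c(2, 4, 5, 4, 2)
  G[5, 5] <- 1.7; G[3:4, 5] <- 1; G[6:7, 5] <- 1
  G[2, 4:5] <- 0.5; G[8, 4:5] <- 1
  fes <- new("FreeEnergySurface",
             edges = list(0:10, 0:7), G = G,
             counts = array(1L, dim(G)), weightSums = array(1, dim(G)),
             temperature = 300)
  bb <- basinBarrier(fes, list(c(1, 3), c(2, 3)), list(c(7, 9), c(2, 3)))
  expect_equal(bb$deltaG, 0.9)
  expect_equal(bb$barrier, 1.7)   # through the notch, not over the 5 ridge
})
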