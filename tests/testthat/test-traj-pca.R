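makeCov <- function(M, center = rep(0, nrow(M)), kind = "cartesian") {
  new("CovarianceModel", center = center, matrix = M, kind = kind,
      selection = new("AtomSelection", indices = integer(), label = "x"),
      nFrames = 2L, meta = list())
}

test_that("covariance of identical frames is zero and trace tracks fluctuation", {
  st <- mixedAtomStructure()
  arr <- array(rep(coords(st), each = 5), dim = c(5, nAtoms(st), 3))
  tr <- Trajectory(arr, st)
  sel <- selectAtoms(st, heavy = TRUE)
  cov <- buildCovariance(tr, sel, st)
  expect_lt(max(abs(cov@matrix)), 1e-18)
  # trace identity on a fluctuating trajectory (no fitting, so exact)
  tr2 <- randomTrajectory(st, nFrames = 20L, seed = 2L)
  cov2 <- buildCovariance(tr2, sel, st, fit = FALSE)
  X <- t(vapply(1:20, function(i)
    as.vector(t(coords(tr2, i)[sel@indices, ])), numeric(3 * 7)))
  expect_equal(sum(diag(cov2@matrix)), sum(colMeans(sweep(X, 2, colMeans(X))^2)),
               tolerance = 1e-10)
})

test_that("two opposed frames give a single eigenvalue d^2 (population)", {
  st <- mixedAtomStructure()
  base <- coords(st)
  d <- 1.7
  arr <- array(NA_real_, dim = c(2, nAtoms(st), 3))
  arr[1, , ] <- base; arr[2, , ] <- base
  arr[1, 3, 1] <- base[3, 1] + d
  arr[2, 3, 1] <- base[3, 1] - d
  cov <- buildCovariance(Trajectory(arr, st), selectAtoms(st, heavy = TRUE),
                         st, fit = FALSE)
  pca <- eigenDecompose(cov)
  ev <- eigenvalues(pca)
  expect_equal(ev[1], d^2, tolerance = 1e-10)
  expect_lt(max(abs(ev[-1])), 1e-10)
})

test_that("eigenDecompose is a faithful, sign-fixed spectral decomposition", {
  pca <- eigenDecompose(makeCov(diag(c(3, 1, 0))))
  expect_equal(eigenvalues(pca), c(3, 1, 0))
  expect_equal(abs(eigenvectors(pca)), diag(3), tolerance = 1e-12)
  # reconstruction round trip on a random PSD matrix
  set.seed(10)
  A <- matrix(rnorm(144), 12)
  S <- crossprod(A) / 12
  pca <- eigenDecompose(makeCov(S))
  Q <- eigenvectors(pca)
  expect_lt(max(abs(Q %*% diag(eigenvalues(pca)) %*% t(Q) - S)), 1e-8)
  # sign convention: largest-magnitude component positive
  expect_true(all(apply(Q, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("sample covariance spectrum approaches a known population spectrum", {
  set.seed(33)
  n <- 3000
  sd <- c(3, 1.5, 0.5, 0.2, 0.1, 0.05)    # 2 pseudo-atoms x 3 coords
  X <- sweep(matrix(rnorm(n * 6), n), 2, sd, "*")
  st <- Structure(data.frame(name = c("CA", "CA"), element = c("C", "C"),
                             resno = 1:2, resname = "ALA", chain = "A"),
                  matrix(0, 2, 3))
  arr <- array(NA_real_, dim = c(n, 2, 3))
  arr[, 1, ] <- X[, 1:3]; arr[, 2, ] <- X[, 4:6]
  cov <- buildCovariance(Trajectory(arr, st), 1:2, st, fit = FALSE)
  top <- eigenvalues(eigenDecompose(cov))[1]
  expect_equal(top, 9, tolerance = 0.1 * 9)
})

test_that("contribution fractions are normalized and ranked as constructed", {
  pca <- eigenDecompose(makeCov(diag(c(3, 1, 0, 0))))
  expect_equal(contributionFraction(pca, 1), 0.75)
  expect_equal(sum(vapply(1:4, contributionFraction, numeric(1), pca = pca)), 1)
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  pca2 <- eigenDecompose(buildCovariance(sc$gen$trajectories, sel,
                                         sc$tpl$structure))
  f1 <- contributionFraction(pca2, 1)
  expect_true(all(f1 > vapply(2:10, contributionFraction, numeric(1),
                              pca = pca2)))
})

test_that("projection identities hold on the defining ensemble", {
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  pca <- eigenDecompose(buildCovariance(sc$gen$trajectories, sel,
                                        sc$tpl$structure))
  P <- do.call(rbind, lapply(sc$gen$trajectories, projectTrajectory,
                             pca, 1:3, sc$tpl$structure))
  # population variance of projections equals the eigenvalue
  popVar <- function(x) mean((x - mean(x))^2)
  for (k in 1:3)
    expect_equal(popVar(P[, k]), eigenvalues(pca)[k],
                 tolerance = 1e-8 * eigenvalues(pca)[1])
  # projections of the mean conformation are zero; unit displacement along
  # an eigenvector projects to exactly that amplitude
  n <- length(sel@indices)
  meanFrame <- coords(sc$tpl$structure)
  meanFrame[sel@indices, ] <- matrix(pca@center, ncol = 3, byrow = TRUE)
  dispFrame <- meanFrame
  dispFrame[sel@indices, ] <- dispFrame[sel@indices, ] +
    matrix(eigenvectors(pca)[, 1], ncol = 3, byrow = TRUE) * 2
  arr <- array(NA_real_, dim = c(2, nAtoms(sc$tpl$structure), 3))
  arr[1, , ] <- meanFrame; arr[2, , ] <- dispFrame
  pr <- projectTrajectory(Trajectory(arr, sc$tpl$structure), pca, 1:3,
                          sc$tpl$structure, fit = FALSE)
  expect_equal(unname(pr[1, ]), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(unname(pr[2, ]), c(2, 0, 0), tolerance = 1e-8)
})

test_that("rigid fitting removes at least six degrees of freedom", {
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  pca <- eigenDecompose(buildCovariance(sc$gen$trajectories, sel,
                                        sc$tpl$structure))
  ev <- eigenvalues(pca)
  expect_gte(sum(ev < 1e-6 * ev[1]), 6)
  expect_equal(sum(ev), sum(diag(buildCovariance(
    sc$gen$trajectories, sel, sc$tpl$structure)@matrix)),
    tolerance = 1e-8 * sum(ev))
})

test_that("extreme conformations follow argmin/argmax with low-index ties", {
  proj <- matrix(c(-1, 0, 3), ncol = 1)
  expect_equal(extremeConformations(proj), c(min = 1L, max = 3L))
  expect_equal(extremeConformations(matrix(rep(2, 4), ncol = 1)),
               c(min = 1L, max = 1L))
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  pca <- eigenDecompose(buildCovariance(sc$gen$trajectories, sel,
                                        sc$tpl$structure))
  pr <- projectTrajectory(sc$gen$trajectories[[1]], pca, 1L,
                          sc$tpl$structure)
  ext <- extremeConformations(pr)
  lab <- sc$gen$groundTruth$labels
  s <- lab$state[lab$replica == 1]
  expect_equal(length(unique(s[ext])), 2L)   # opposite ground-truth states
})

test_that("mode arrows reproduce the two-state displacement direction", {
  pcaU <- eigenDecompose(makeCov(diag(c(2, 0, 0, 0, 0, 0))))
  arrows <- modeArrows(pcaU, 1, scale = 1)
  expect_equal(sum(arrows^2), 1, tolerance = 1e-12)
  expect_true(all(modeArrows(pcaU, 1, scale = 0) == 0))
  # noise-free two-state fixture: arrows align with (open - closed)
  tpl <- buildTemplate()
  dyn <- dynamicsSpec(noiseSigma = 0, nFrames = 10L, nReplicas = 1L,
                      seed = 3L)
  gen <- suppressWarnings(generateTrajectories(tpl, dyn, "two_state"))
  sel <- selectAtoms(tpl$structure, name = "CA", class = "protein")
  st <- gen$groundTruth$labels$state
  expect_setequal(unique(st), c(0L, 1L))
  cov <- buildCovariance(gen$trajectories, sel, tpl$structure, fit = FALSE)
  pca <- eigenDecompose(cov)
  arrows <- modeArrows(pca, 1)
  iOpen <- which(st == 1L)[1]; iClosed <- which(st == 0L)[1]
  disp <- coords(gen$trajectories[[1]], iOpen)[sel@indices, ] -
          coords(gen$trajectories[[1]], iClosed)[sel@indices, ]
  cosSim <- abs(sum(arrows * disp)) /
    sqrt(sum(arrows^2) * sum(disp^2))
  expect_gt(cosSim, 0.99)
})

test_that("cross-projection is linear in the projected coordinates", {
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  pca <- eigenDecompose(buildCovariance(sc$gen$trajectories, sel,
                                        sc$tpl$structure))
  base <- coords(sc$tpl$structure)
  d1 <- d2 <- array(0, dim = c(1, nrow(base), 3))
  set.seed(6)
  d1[1, sel@indices, ] <- rnorm(3 * length(sel@indices), sd = 0.1)
  d2[1, sel@indices, ] <- rnorm(3 * length(sel@indices), sd = 0.1)
  mk <- function(d) {
    arr <- d
    arr[1, , ] <- arr[1, , ] + base
    Trajectory(arr, sc$tpl$structure)
  }
  pa <- projectTrajectory(mk(d1), pca, 1:2, sc$tpl$structure, fit = FALSE)
  pb <- projectTrajectory(mk(d2), pca, 1:2, sc$tpl$structure, fit = FALSE)
  pab <- projectTrajectory(mk(d1 + d2), pca, 1:2, sc$tpl$structure,
                           fit = FALSE)
  p0 <- projectTrajectory(mk(d1 * 0), pca, 1:2, sc$tpl$structure,
                          fit = FALSE)
  expect_equal(pab - p0, (pa - p0) + (pb - p0), tolerance = 1e-10)
})

test_that("essential-subspace projections reproduce the conformational-selection pattern", {
  tpl <- buildTemplate()
  dyn <- dynamicsSpec(nFrames = 250L, nReplicas = 2L, seed = 19L)
  apoLike <- generateTrajectories(tpl, dyn, "two_state")
  boundLike <- generateTrajectories(tpl, dyn, "closed_stable")
  partial <- generateTrajectories(tpl, dyn, "partial_opening")
  sel <- selectAtoms(tpl$structure, name = "CA", class = "protein")
  pca <- eigenDecompose(buildCovariance(apoLike$trajectories, sel,
                                        tpl$structure))
  projOf <- function(gen) do.call(rbind, lapply(gen$trajectories,
    projectTrajectory, pca, 1:2, tpl$structure))
  pApo <- projOf(apoLike); pBound <- projOf(boundLike)
  pPartial <- projOf(partial)
  lab <- apoLike$groundTruth$labels$state
  # PC1 midpoint threshold recovers the state labels
  thr <- (max(pApo[, 1]) + min(pApo[, 1])) / 2
  acc <- mean((pApo[, 1] > thr) == (lab == 1))
  acc <- max(acc, 1 - acc)
  expect_gte(acc, 0.95)
  # bound-like ensemble stays inside the closed cluster's 99th-percentile
  # radius; the partial ensemble leaks along PC1 only
  closed <- pApo[lab == 0, , drop = FALSE]
  ctr <- colMeans(closed)
  rad <- stats::quantile(sqrt(rowSums(sweep(closed, 2, ctr)^2)), 0.99)
  distBound <- sqrt(rowSums(sweep(pBound, 2, ctr)^2))
  expect_gte(mean(distBound <= rad), 0.97)   # ~1% outside expected at p99
  leak <- abs(pPartial[, 1] - ctr[1]) > 3 * stats::sd(closed[, 1])
  expect_gt(mean(leak), 0.02)
  expect_lt(mean(abs(pPartial[leak, 2] - ctr[2]) > 3 * stats::sd(closed[, 2])),
            0.05)
})
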