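test_that("readPDB selects the requested model and classifies residues", {
  path <- writeTinyPDB()
  st1 <- readPDB(path, model = 1)
  st2 <- readPDB(path, model = 2)
  expect_equal(nAtoms(st1), 15L)
  expect_equal(coords(st2)[, "x"], coords(st1)[, "x"] + 1, tolerance = 1e-9)
  expect_equal(coords(st2)[, "y"], coords(st1)[, "y"], tolerance = 1e-12)
  rt <- residueTable(st1)
  expect_equal(nrow(rt), 6L)
  expect_equal(sum(rt$moleculeClass == "protein"), 5L)
  expect_equal(rt$moleculeClass[rt$resname == "6MA"], "nucleotide")
  # element fallback: H1' had a blank element column
  expect_false(st1@atoms$isHeavy[st1@atoms$name == "H1'"])
  expect_error(readPDB(path, model = 4), "out of range")
  expect_error(readPDB(tempfile()), "not found")
})

test_that("PDB write/read round-trips coordinates at fixed-point precision", {
  path <- writeTinyPDB()
  st <- readPDB(path, model = 3)
  out <- tempfile(fileext = ".pdb")
  writePDB(st, out)
  st2 <- readPDB(out, model = 1)
  expect_equal(coords(st2), coords(st), tolerance = 1e-9)   # 3-decimal format
  expect_equal(st2@atoms$resno, st@atoms$resno)
  expect_equal(st2@atoms$moleculeClass, st@atoms$moleculeClass)
  # multi-model round trip through a trajectory
  tr <- readPDBTrajectory(path)
  expect_equal(nFrames(tr), 3L)
  out2 <- tempfile(fileext = ".pdb")
  writePDB(tr, out2)
  tr2 <- readPDBTrajectory(out2)
  expect_equal(tr2@coords, tr@coords, tolerance = 1e-9)
})

test_that("coordinate-table trajectory format round-trips", {
  st <- mixedAtomStructure()
  tr <- randomTrajectory(st, nFrames = 4L, seed = 3L)
  path <- tempfile(fileext = ".tab")
  writeCoordTable(tr, path)
  tr2 <- readCoordTable(path, st)
  expect_equal(tr2@coords, tr@coords, tolerance = 1e-12)
  expect_error(readCoordTable(path, buildTemplate()$structure), "dense")
})

test_that("selectAtoms applies conjunctive rules deterministically", {
  path <- writeTinyPDB()
  st <- readPDB(path)
  ca <- selectAtoms(st, name = "CA", class = "protein")
  expect_equal(length(ca@indices), 5L)
  expect_false(is.unsorted(ca@indices, strictly = TRUE))
  mx <- mixedAtomStructure()
  expect_equal(length(selectAtoms(mx, heavy = TRUE)@indices), 7L)
  expect_equal(sort(unique(mx@atoms$resno[selectAtoms(mx, resno = 347)@indices])),
               347L)
  expect_error(selectAtoms(st, name = "ZZ"), "no atoms")
  expect_equal(length(selectAtoms(st, name = "ZZ", allowEmpty = TRUE)@indices),
               0L)
})

test_that("superpose recovers rigid transforms and matches the grid oracle", {
  set.seed(7)
  ref <- matrix(rnorm(12), ncol = 3)
  # identity
  fit <- superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  fit <- superpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  # proper rotation always
  for (seed in 1:5) {
    set.seed(seed)
    mob <- matrix(rnorm(30), ncol = 3)
    rf <- matrix(rnorm(30), ncol = 3)
    fit <- superpose(mob, rf)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_equal(fit$rmsd, oracleFitRMSD(mob, rf), tolerance = 1e-3)
  }
  # independent implementation cross-check (bio3d Kabsch)
  set.seed(42)
  mob <- matrix(rnorm(24), ncol = 3)
  rf <- matrix(rnorm(24), ncol = 3)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(rf)), as.vector(t(mob))))
  bio3dRmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - rf)^2)))
  expect_equal(superpose(mob, rf)$rmsd, bio3dRmsd, tolerance = 1e-6)
  expect_error(superpose(matrix(0, 4, 3), matrix(rnorm(12), 4, 3)),
               "degenerate")
})

test_that("superpose is idempotent", {
  set.seed(8)
  mob <- matrix(rnorm(30), ncol = 3)
  ref <- matrix(rnorm(30), ncol = 3)
  once <- applyTransform(mob, superpose(mob, ref))
  twice <- applyTransform(once, superpose(once, ref))
  expect_lt(max(abs(twice - once)), 1e-8)
})

test_that("rmsdSeries is zero for the reference and rigid copies of it", {
  st <- mixedAtomStructure()
  base <- coords(st)
  arr <- array(NA_real_, dim = c(3, nAtoms(st), 3))
  arr[1, , ] <- base
  arr[2, , ] <- sweep(base, 2, c(2 / sqrt(3), 2 / sqrt(3), 2 / sqrt(3)), "+")
  th <- 0.7
  arr[3, , ] <- base %*% matrix(c(cos(th), sin(th), 0,
                                  -sin(th), cos(th), 0, 0, 0, 1), 3)
  tr <- Trajectory(arr, st)
  expect_equal(rmsdSeries(tr, st), rep(0, 3), tolerance = 1e-8)
})

test_that("rmsdSeries is invariant under rigid transforms of the trajectory", {
  sc <- smallScenario()
  tr <- sc$gen$trajectories[[1]]
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  sub <- Trajectory(tr@coords[1:20, , , drop = FALSE], tr@template)
  r1 <- rmsdSeries(sub, sc$tpl$structure, sel)
  R <- eulerRotation(c(0.4, 1.1, -0.3))
  moved <- sub@coords
  for (i in seq_len(dim(moved)[1]))
    moved[i, , ] <- sweep(moved[i, , ] %*% R, 2, c(3, -2, 7), "+")
  r2 <- rmsdSeries(Trajectory(moved, tr@template), sc$tpl$structure, sel)
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("rmsdSeries separates open from closed loop states", {
  sc <- smallScenario()
  sel <- selectAtoms(sc$tpl$structure, name = "CA", class = "protein")
  lab <- sc$gen$groundTruth$labels
  r <- rmsdSeries(sc$gen$trajectories[[1]], sc$tpl$structure, sel)
  s <- lab$state[lab$replica == 1]
  expect_setequal(unique(s), c(0L, 1L))   # both states present at this seed
  expect_gt(min(r[s == 1]), max(r[s == 0]))
})

test_that("rmsdSeries agrees with the grid-search oracle on small fixtures", {
  st <- mixedAtomStructure()
  tr <- randomTrajectory(st, nFrames = 3L, seed = 5L, sd = 0.8)
  r <- rmsdSeries(tr, st)
  oracle <- vapply(1:3, function(i)
    oracleFitRMSD(coords(tr, i), coords(st)), numeric(1))
  expect_equal(r, oracle, tolerance = 1e-3)
})

test_that("replicaSummary computes per-frame mean and sample std", {
  out <- replicaSummary(list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_equal(out$mean, c(1, 1, 1))
  expect_equal(out$std, c(0, 0, 0))
  expect_equal(attr(out, "nReplicas"), 3L)
  out <- replicaSummary(list(0, 2))
  expect_equal(out$mean, 1)
  expect_equal(out$std, sqrt(2))
  expect_error(replicaSummary(list(1:3)), "2 replicas")
  expect_true(is.na(replicaSummary(list(1:3), allowSingle = TRUE)$std[1]))
  expect_error(replicaSummary(list(1:3, 1:4)), "length")
})
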