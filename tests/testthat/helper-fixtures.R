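# -- text PDB fixture ---------------------------------------------------------

# Hand-formatted 3-model PDB: five protein residues (N + CA each, plus a CB
# and a hydrogen on the first), one 6MA nucleotide with a blank element
# column on H1' to exercise the atom-name fallback. Model m is model 1
# shifted by (m - 1) Angstrom in x.
tinyPDBLines <- function() {
  at <- function(serial, name, resn, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resn, chain, resno, x, y, z, el)
  }
  model <- function(m) {
    dx <- m - 1
    c(sprintf("MODEL     %4d", m),
      at(1, "N", "ALA", "A", 347, 11.104 + dx, 6.134, -6.504, "N"),
      at(2, "CA", "ALA", "A", 347, 11.639 + dx, 6.071, -5.147, "C"),
      at(3, "CB", "ALA", "A", 347, 12.217 + dx, 7.423, -4.712, "C"),
      at(4, "HB1", "ALA", "A", 347, 12.951 + dx, 7.716, -5.464, "H"),
      at(5, "N", "GLY", "A", 348, 10.591 + dx, 5.031, -4.432, "N"),
      at(6, "CA", "GLY", "A", 348, 10.957 + dx, 4.836, -3.027, "C"),
      at(7, "N", "VAL", "A", 349, 9.906 + dx, 4.190, -2.261, "N"),
      at(8, "CA", "VAL", "A", 349, 10.070 + dx, 3.928, -0.828, "C"),
      at(9, "N", "LEU", "A", 350, 8.934 + dx, 3.427, -0.083, "N"),
      at(10, "CA", "LEU", "A", 350, 8.948 + dx, 3.135, 1.352, "C"),
      at(11, "N", "MET", "A", 351, 7.773 + dx, 2.638, 2.003, "N"),
      at(12, "CA", "MET", "A", 351, 7.669 + dx, 2.332, 3.434, "C"),
      at(13, "C1'", "6MA", "B", 3, 9.500 + dx, 6.800, -1.200, "C"),
      at(14, "N9", "6MA", "B", 3, 10.113 + dx, 7.014, 0.108, "N"),
      at(15, "H1'", "6MA", "B", 3, 8.700 + dx, 7.500, -1.400, ""),
      "ENDMDL")
  }
  c(model(1), model(2), model(3), "END")
}

writeTinyPDB <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tinyPDBLines(), path)
  path
}

# -- in-code structure fixtures ----------------------------------------------

# Structure with a controlled mix of heavy atoms and hydrogens.
mixedAtomStructure <- function() {
  atoms <- data.frame(
    name = c("N", "CA", "CB", "HB1", "HB2", "O", "C", "N9", "C1", "H1"),
    element = c("N", "C", "C", "H", "H", "O", "C", "N", "C", "H"),
    resno = c(rep(347L, 7), rep(1L, 3)),
    resname = c(rep("ALA", 7), rep("A", 3)),
    chain = c(rep("A", 7), rep("B", 3)))
  xyz <- rbind(c(0.2, 1.4, -2.1), c(1.8, -0.6, 0.9), c(-1.1, 2.2, 1.5),
               c(2.4, 0.8, -1.7), c(-0.9, -1.3, 2.6), c(1.1, 3.0, 0.4),
               c(-2.2, 0.1, -0.8), c(3.1, -2.4, 1.9), c(0.6, 2.7, 2.8),
               c(-1.6, -2.0, -2.5))
  Structure(atoms, xyz)
}

# Random protein-RNA structure with <= maxAtoms atoms for oracle comparisons.
randomComplexStructure <- function(seed, nProt = 4L, nNuc = 2L, box = 8) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  add <- function(resno, resname, chain, n) {
    el <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
    el[1] <- sample(c("C", "N", "O"), 1)   # at least one heavy atom
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = paste0(el[k], k), element = el[k], resno = resno,
        resname = resname, chain = chain)
      xyz[[length(xyz) + 1L]] <<- runif(3, -box, box)
    }
  }
  for (i in seq_len(nProt)) add(300L + i, "ALA", "A", sample(3:6, 1))
  for (j in seq_len(nNuc)) add(j, "A", "B", sample(3:6, 1))
  st <- Structure(do.call(rbind, rows), do.call(rbind, xyz))
  # guarantee at least one heavy atom per residue for contact analysis
  stopifnot(all(tapply(st@atoms$isHeavy, st@atoms$resno, any)))
  st
}

randomTrajectory <- function(st, nFrames = 3L, seed = 1L, sd = 1.5) {
  set.seed(seed)
  n <- nAtoms(st)
  arr <- array(rnorm(nFrames * n * 3, sd = sd), dim = c(nFrames, n, 3))
  for (k in 1:3) arr[, , k] <- arr[, , k] +
    matrix(coords(st)[, k], nFrames, n, byrow = TRUE)
  Trajectory(arr, st)
}

# -- independent oracles ------------------------------------------------------

rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
rotY <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
eulerRotation <- function(p) rotZ(p[1]) %*% rotY(p[2]) %*% rotZ(p[3])

# Least-squares fit RMSD by coarse Euler-angle grid search plus Nelder-Mead
# refinement; centroids aligned analytically. Independent of the SVD path.
oracleFitRMSD <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) sqrt(mean(rowSums((mc %*% eulerRotation(p) - rc)^2)))
  best <- Inf; bp <- NULL
  for (a in seq(0, 2 * pi, length.out = 13))
    for (b in seq(0, pi, length.out = 7))
      for (cc in seq(0, 2 * pi, length.out = 13)) {
        v <- obj(c(a, b, cc))
        if (v < best) { best <- v; bp <- c(a, b, cc) }
      }
  stats::optim(bp, obj, control = list(reltol = 1e-14, maxit = 5000))$value
}

# All-pairs heavy-atom minimum distance (plain double loop).
bruteMinDist <- function(st, frameCoords, resnoProt, resnoNuc) {
  a <- st@atoms
  ia <- which(a$resno == resnoProt & a$moleculeClass == "protein" & a$isHeavy)
  ib <- which(a$resno == resnoNuc & a$moleculeClass == "nucleotide" & a$isHeavy)
  best <- Inf
  for (i in ia) for (j in ib)
    best <- min(best, sqrt(sum((frameCoords[i, ] - frameCoords[j, ])^2)))
  best
}

bruteResidueCount <- function(st, frameCoords, resnoNuc, cutoff) {
  protRes <- unique(st@atoms$resno[st@atoms$moleculeClass == "protein"])
  sum(vapply(protRes, function(r)
    bruteMinDist(st, frameCoords, r, resnoNuc) <= cutoff, logical(1)))
}

bruteAtomPairCount <- function(st, frameCoords, resnoNuc, cutoff) {
  a <- st@atoms
  ib <- which(a$resno == resnoNuc & a$moleculeClass == "nucleotide" & a$isHeavy)
  ia <- which(a$moleculeClass == "protein" & a$isHeavy)
  n <- 0L
  for (i in ia) for (j in ib)
    if (sqrt(sum((frameCoords[i, ] - frameCoords[j, ])^2)) <= cutoff)
      n <- n + 1L
  n
}

# Basin free-energy difference of a 1D potential by quadrature.
quadratureDeltaG <- function(system, basinA, basinB, temperature = 300) {
  beta <- thermoBeta(temperature)
  z <- function(lim) stats::integrate(function(x)
    exp(-beta * toyPotential(system, x)), lim[1], lim[2])$value
  -log(z(basinB) / z(basinA)) / beta
}

# Boltzmann bin probabilities of a 1D potential by quadrature.
quadratureBinProbs <- function(system, edges, temperature = 300) {
  beta <- thermoBeta(temperature)
  dens <- function(x) exp(-beta * toyPotential(system, x))
  Z <- stats::integrate(dens, edges[1] - 5, edges[length(edges)] + 5)$value
  vapply(seq_len(length(edges) - 1L), function(i)
    stats::integrate(dens, edges[i], edges[i + 1])$value / Z, numeric(1))
}

# Synthetic contact-distance series with a planted breaking block: `b`
# contacts jump by `gap` in the open state, the rest stay; Gaussian noise.
plantedDistanceSeries <- function(seed, nFrames = 200L, p = 12L, b = 6L,
                                  gap = 4, sigma = 0.2) {
  set.seed(seed)
  state <- rbinom(nFrames, 1L, 0.5)
  base <- runif(p, 3, 5.5)
  D <- matrix(rnorm(nFrames * p, sd = sigma), nFrames, p)
  D <- sweep(D, 2, base, "+")
  D[, seq_len(b)] <- D[, seq_len(b)] + state * gap
  pairs <- data.frame(resno = 400L + seq_len(p), resname = "ALA",
                      nucleotide = 3L, nucName = "6MA",
                      nativeDistance = base)
  cs <- new("ContactSet", pairs = pairs, cutoff = 6.0, referenceId = "planted")
  list(series = new("ContactDistanceSeries", distances = D, contacts = cs),
       breaking = pairs$resno[seq_len(b)], state = state)
}

# Small default synthetic scenario shared across tests (cached per session).
smallScenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- buildTemplate()
      dyn <- dynamicsSpec(nFrames = 150L, nReplicas = 2L, seed = 11L)
      cache <<- list(tpl = tpl, dyn = dyn,
                     gen = generateTrajectories(tpl, dyn, "two_state"))
    }
    cache
  }
})
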