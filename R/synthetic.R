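#' Specification of the synthetic protein-RNA complex template
#'
#' Parameters for the pseudo-structure that stands in for a YTH-like
#' protein-RNA complex: a 156-residue protein (author numbering starting at
#' 347, so the recognition-loop block defaults to residues 431-442 and the
#' pocket block to 380-386) and a 6-nucleotide RNA whose third position is
#' the methylated ligand nucleotide. Each residue carries a C-alpha, 2-4
#' pseudo-heavy side atoms and one hydrogen; nucleotides carry 9 heavy atoms.
#'
#' @param nProteinResidues number of protein residues.
#' @param nNucleotides number of nucleotides.
#' @param proteinStart first author residue number.
#' @param loopResidues contiguous recognition-loop residue numbers.
#' @param pocketResidues contiguous binding-pocket residue numbers.
#' @param ligandNucleotide RNA position of the ligand (default 3).
#' @param seed integer seed for the deterministic geometry jitter.
#' @return a `ComplexTemplateSpec` list.
#' @export
complexTemplate <- function(nProteinResidues = 156L, nNucleotides = 6L,
                            proteinStart = 347L, loopResidues = 431:442,
                            pocketResidues = 380:386, ligandNucleotide = 3L,
                            seed = 42L) {
  resnos <- seq(proteinStart, length.out = nProteinResidues)
  if (!all(loopResidues %in% resnos) || !all(pocketResidues %in% resnos))
    stop("loop/pocket residue ranges must lie within the protein")
  if (length(intersect(loopResidues, pocketResidues)))
    stop("loop and pocket ranges must be disjoint")
  if (ligandNucleotide < 1L || ligandNucleotide > nNucleotides)
    stop("ligand nucleotide out of range")
  structure(list(nProteinResidues = as.integer(nProteinResidues),
                 nNucleotides = as.integer(nNucleotides),
                 proteinStart = as.integer(proteinStart),
                 loopResidues = as.integer(loopResidues),
                 pocketResidues = as.integer(pocketResidues),
                 ligandNucleotide = as.integer(ligandNucleotide),
                 seed = as.integer(seed)),
            class = "ComplexTemplateSpec")
}

.unitVector <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Build the synthetic complex structure
#'
#' Deterministically constructs the pseudo-structure defined by a
#' [complexTemplate()] spec: pocket side atoms sit below the ligand
#' nucleotide and loop side atoms above it, both within native-contact range
#' (< 6 Angstrom heavy-atom minimum distance), the remaining protein
#' residues trace a distant helix-like shell, and the RNA runs through the
#' pocket with the ligand at the origin. A fixed opening direction
#' (near +z, with a small seed-derived tilt) is attached: displacing the
#' loop along it by the dynamics amplitude breaks all loop-ligand contacts.
#'
#' @param spec a `ComplexTemplateSpec` from [complexTemplate()].
#' @return a `ComplexTemplate` list with elements `structure`
#'   ([Structure-class]), `spec`, `openDirection` (unit 3-vector),
#'   `loopAtomIndices`, `ligandNucleotide`.
#' @export
buildTemplate <- function(spec = complexTemplate()) {
  stopifnot(inherits(spec, "ComplexTemplateSpec"))
  set.seed(spec$seed)
  resnos <- seq(spec$proteinStart, length.out = spec$nProteinResidues)
  loop <- spec$loopResidues
  pocket <- spec$pocketResidues
  far <- setdiff(resnos, c(loop, pocket))
  aaNames <- c("ALA", "LEU", "VAL", "MET", "TRP", "PRO", "GLY", "SER")

  rows <- list(); xyz <- list()
  addAtom <- function(name, element, resno, resname, chain, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resno = resno, resname = resname,
      chain = chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  sideSpec <- function(k) 2L + (k %% 3L)   # 2-4 pseudo-heavy side atoms

  addResidue <- function(resno, ca, sides, resname) {
    addAtom("CA", "C", resno, resname, "A", ca)
    for (s in seq_len(nrow(sides)))
      addAtom(paste0("CB", s), c("C", "C", "O", "N")[s], resno, resname, "A",
              sides[s, ])
    addAtom("HA", "H", resno, resname, "A", ca + .unitVector(1) * 1.0)
  }

  # binding-pocket residues: ring below the ligand, side atoms reaching in
  for (k in seq_along(pocket)) {
    phi <- 2 * pi * (k - 1) / length(pocket)
    ca <- c(7.5 * cos(phi), 7.5 * sin(phi), -4.5)
    s1 <- c(3.6 * cos(phi), 3.6 * sin(phi), -2.6)
    s2 <- c(4.3 * cos(phi + 0.15), 4.3 * sin(phi + 0.15), -3.2)
    sides <- rbind(s1, s2) + matrix(stats::rnorm(6, 0, 0.08), ncol = 3)
    addResidue(pocket[k], ca, sides, aaNames[(k - 1L) %% 8L + 1L])
  }
  # recognition-loop residues: ring above the ligand
  for (k in seq_along(loop)) {
    phi <- 2 * pi * (k - 1) / length(loop)
    ca <- c(7.5 * cos(phi), 7.5 * sin(phi), 5.0)
    s1 <- c(3.4 * cos(phi), 3.4 * sin(phi), 2.8)
    s2 <- c(4.2 * cos(phi + 0.12), 4.2 * sin(phi + 0.12), 3.4)
    sides <- rbind(s1, s2) + matrix(stats::rnorm(6, 0, 0.08), ncol = 3)
    addResidue(loop[k], ca, sides, aaNames[(k - 1L) %% 8L + 1L])
  }
  # remaining residues: distant helical shell, no ligand contacts
  for (k in seq_along(far)) {
    t <- (k - 1) / max(1L, length(far) - 1L)
    phi <- 4 * pi * t
    ca <- c(29 * cos(phi), 29 * sin(phi), -16 + 32 * t)
    ns <- sideSpec(k)
    sides <- matrix(rep(ca, each = ns), ncol = 3) +
      .unitVector(ns) * stats::runif(ns, 1.6, 2.2)
    addResidue(far[k], ca, sides, aaNames[(k - 1L) %% 8L + 1L])
  }
  # RNA: centers along x, ligand nucleotide at the origin
  ntNames <- rep(c("U", "G", "6MA", "C", "A", "C"),
                 length.out = spec$nNucleotides)
  ntNames[spec$ligandNucleotide] <- "6MA"
  ringEl <- c("C", "C", "N", "O", "C", "N", "C", "O")
  for (i in seq_len(spec$nNucleotides)) {
    ctr <- c(5.5 * (i - spec$ligandNucleotide), 0, 0)
    addAtom("N9", "N", i, ntNames[i], "B", ctr)
    for (k in 1:8) {
      th <- 2 * pi * (k - 1) / 8
      addAtom(paste0("C", k), ringEl[k], i, ntNames[i], "B",
              ctr + c(1.4 * cos(th), 1.4 * sin(th), 0))
    }
  }

  atoms <- do.call(rbind, rows)
  coords <- do.call(rbind, xyz)
  st <- Structure(atoms, coords)
  tilt <- stats::rnorm(2, 0, 0.05)
  dir <- c(tilt, 1); dir <- dir / sqrt(sum(dir^2))
  loopIdx <- which(st@atoms$resno %in% loop & st@atoms$chain == "A")
  structure(list(structure = st, spec = spec, openDirection = dir,
                 loopAtomIndices = loopIdx,
                 ligandNucleotide = spec$ligandNucleotide),
            class = "ComplexTemplate")
}

#' Dynamics parameters for the synthetic loop motion
#'
#' The loop motion is a two-state Markov chain (closed/open) rather than
#' dynamics on a continuous coordinate, so state occupancies have closed-form
#' expectations. Per frame, a closed state opens with probability
#' `2 * transitionRate * p` and an open state closes with probability
#' `2 * transitionRate * (1 - p)`, giving stationary open fraction `p`.
#'
#' @param openAmplitude loop displacement between states, Angstrom.
#' @param transitionRate per-frame switching scale, in (0, 1/2).
#' @param openFraction stationary open-state occupancy target for the
#'   two-state mode.
#' @param noiseSigma isotropic Gaussian thermal noise per atom, Angstrom.
#' @param nFrames frames per replica.
#' @param nReplicas independent replicas (replica r uses `seed + r`).
#' @param seed base integer seed.
#' @return a `DynamicsSpec` list.
#' @export
dynamicsSpec <- function(openAmplitude = 8, transitionRate = 0.1,
                         openFraction = 0.5, noiseSigma = 0.3,
                         nFrames = 1000L, nReplicas = 3L, seed = 1L) {
  if (openAmplitude <= 0) stop("openAmplitude must be positive")
  if (transitionRate <= 0 || transitionRate >= 0.5)
    stop("transitionRate must be in (0, 0.5)")
  if (openFraction <= 0 || openFraction >= 1)
    stop("openFraction must be in (0, 1)")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  structure(list(openAmplitude = openAmplitude,
                 transitionRate = transitionRate,
                 openFraction = openFraction, noiseSigma = noiseSigma,
                 nFrames = as.integer(nFrames),
                 nReplicas = as.integer(nReplicas), seed = as.integer(seed)),
            class = "DynamicsSpec")
}

.markovStates <- function(n, p, rate) {
  if (p <= 0) return(integer(n))
  a <- 2 * rate * p          # closed -> open
  b <- 2 * rate * (1 - p)    # open -> closed
  s <- integer(n)
  u <- stats::runif(n)
  s[1] <- as.integer(u[1] < p)
  if (n < 2L) return(s)
  for (t in 2:n) {
    s[t] <- if (s[t - 1L] == 0L) as.integer(u[t] < a)
            else as.integer(u[t] >= b)
  }
  s
}

#' Generate synthetic two-state loop trajectories with ground truth
#'
#' Emulates the three qualitative regimes of the study systems:
#' `closed_stable` (ligand-bound, methylated-complex-like: the loop stays
#' closed), `two_state` (apo-like: full close-open transitions at the target
#' occupancy) and `partial_opening` (non-methylated-complex-like: reduced
#' open occupancy, 0.3 x `openFraction`). Open frames displace all loop
#' atoms along the template's fixed opening direction by `openAmplitude`;
#' isotropic Gaussian noise is added everywhere. All randomness flows from
#' `seed` (replica r uses `seed + r`).
#'
#' @param template a `ComplexTemplate` from [buildTemplate()].
#' @param dyn a `DynamicsSpec` from [dynamicsSpec()].
#' @param mode `"two_state"`, `"closed_stable"` or `"partial_opening"`.
#' @param contactCutoff Angstrom; used for the feasibility guard and the
#'   planted-contact list.
#' @return list with `trajectories` (list of [Trajectory-class]) and
#'   `groundTruth` (per-frame state labels, planted breaking contacts,
#'   achieved occupancy, parameter echo).
#' @export
generateTrajectories <- function(template, dyn = dynamicsSpec(),
                                 mode = c("two_state", "closed_stable",
                                          "partial_opening"),
                                 contactCutoff = 6.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "ComplexTemplate"),
            inherits(dyn, "DynamicsSpec"))
  if (dyn$openAmplitude < contactCutoff + 2 * dyn$noiseSigma)
    stop("infeasible geometry: openAmplitude ", dyn$openAmplitude,
         " A cannot push contacts past the ", contactCutoff,
         " A cutoff by 2 x noiseSigma")
  p <- switch(mode, two_state = dyn$openFraction, closed_stable = 0,
              partial_opening = 0.3 * dyn$openFraction)
  st <- template$structure
  base <- coords(st)
  n <- nrow(base)
  f <- dyn$nFrames
  shift <- dyn$openAmplitude * template$openDirection
  trajs <- vector("list", dyn$nReplicas)
  labels <- vector("list", dyn$nReplicas)
  for (r in seq_len(dyn$nReplicas)) {
    set.seed(dyn$seed + r)
    s <- .markovStates(f, p, dyn$transitionRate)
    arr <- array(stats::rnorm(f * n * 3, 0, dyn$noiseSigma),
                 dim = c(f, n, 3L))
    open <- which(s == 1L)
    for (k in 1:3) {
      arr[, , k] <- arr[, , k] + matrix(base[, k], f, n, byrow = TRUE)
      if (length(open))
        arr[open, template$loopAtomIndices, k] <-
          arr[open, template$loopAtomIndices, k] + shift[k]
    }
    trajs[[r]] <- Trajectory(arr, st, frameSpacing = 1, replicaId = r)
    labels[[r]] <- s
  }
  achieved <- mean(unlist(labels))
  if (p > 0 && abs(achieved - p) > 0.1)
    warning("achieved open occupancy ", signif(achieved, 3),
            " deviates from target ", p,
            " (transitionRate/nFrames may be too small)")
  planted <- nativeContacts(st, proteinResidues = template$spec$loopResidues,
                            nucleotides = template$ligandNucleotide,
                            cutoff = contactCutoff,
                            referenceId = "synthetic-template")
  gt <- list(labels = data.frame(
               replica = rep(seq_len(dyn$nReplicas), each = f),
               frame = rep(seq_len(f), dyn$nReplicas),
               state = unlist(labels)),
             plantedContacts = contactPairs(planted),
             openDirection = template$openDirection,
             occupancyTarget = p, occupancyAchieved = achieved,
             mode = mode, dynamics = dyn)
  list(trajectories = trajs, groundTruth = gt)
}
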