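#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
kBoltzmann <- 0.0019872041

#' Inverse temperature beta = 1/(kB T)
#'
#' @param temperature Kelvin (default 300, the production temperature).
#' @return beta in mol kcal^-1.
#' @export
thermoBeta <- function(temperature = 300) {
  stopifnot(temperature > 0)
  1 / (kBoltzmann * temperature)
}

#' aMD boost potential
#'
#' The boost added to the potential when it falls below the threshold E:
#' `deltaV = (E - V)^2 / (alpha + E - V)` for `V < E`, and exactly 0 for
#' `V >= E`. The modified potential `V + deltaV` stays below E and flattens
#' the surface; smaller `alpha` boosts more aggressively.
#'
#' @param V potential energy, kcal/mol (vectorized).
#' @param E threshold energy, kcal/mol.
#' @param alpha acceleration factor, kcal/mol, > 0.
#' @return boost energy deltaV >= 0, kcal/mol.
#' @export
boostDeltaV <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  dv <- numeric(length(V))
  low <- V < E
  dv[low] <- (E - V[low])^2 / (alpha + E - V[low])
  dv
}

#' Derivative of the boosted potential w.r.t. the raw potential
#'
#' `d(V + deltaV)/dV`: equals 1 for `V >= E` and
#' `alpha^2 / (alpha + E - V)^2` for `V < E` (continuous at `V = E`). Forces
#' on a boosted surface are the raw forces scaled by this factor, which lies
#' in (0, 1].
#'
#' @inheritParams boostDeltaV
#' @return scaling factor in (0, 1].
#' @export
boostFactor <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  f <- rep(1, length(V))
  low <- V < E
  f[low] <- alpha^2 / (alpha + E - V[low])^2
  f
}

#' Dual-boost evaluation
#'
#' Amber's dual-boost convention: the dihedral boost is evaluated first from
#' the dihedral energy against `(E_dih, alpha_dih)`, then the total boost from
#' the dihedral-boosted total potential `V_tot + deltaV_dih` against
#' `(E_tot, alpha_tot)`.
#'
#' @param vTot,vDih per-frame total and dihedral potential energies, kcal/mol.
#' @param params [AMDParameters-class].
#' @return data.frame with `deltaVDih`, `deltaVTot`, `deltaVTotal` (their
#'   sum), kcal/mol.
#' @export
dualBoostDeltaV <- function(vTot, vDih, params) {
  stopifnot(is(params, "AMDParameters"), length(vTot) == length(vDih))
  dDih <- boostDeltaV(vDih, params@eDih, params@alphaDih)
  dTot <- boostDeltaV(vTot + dDih, params@eTot, params@alphaTot)
  data.frame(deltaVDih = dDih, deltaVTot = dTot, deltaVTotal = dDih + dTot)
}

#' Heuristic coefficients for aMD parameter estimation
#'
#' The standard per-system-size heuristic: the total-potential threshold sits
#' 0.16 kcal/mol per atom above the cMD average total potential with
#' acceleration factor 0.2 kcal/mol per atom; the dihedral threshold sits
#' 3.5 kcal/mol per residue above the average dihedral energy with
#' acceleration factor 0.2 of that per-residue increment.
#'
#' @param perAtomE,perAtomAlpha,perResidueE,dihedralAlphaFraction override the
#'   defaults (all positive).
#' @return named list of the four coefficients.
#' @export
amdCoefficients <- function(perAtomE = 0.16, perAtomAlpha = 0.2,
                            perResidueE = 3.5, dihedralAlphaFraction = 0.2) {
  co <- list(perAtomE = perAtomE, perAtomAlpha = perAtomAlpha,
             perResidueE = perResidueE,
             dihedralAlphaFraction = dihedralAlphaFraction)
  if (any(unlist(co) <= 0)) stop("all coefficients must be positive")
  co
}

#' Estimate dual-boost aMD parameters from cMD averages
#'
#' Linear arithmetic on the conventional-MD energy averages:
#' `E_tot = <V_tot> + perAtomE * nAtoms`, `alpha_tot = perAtomAlpha * nAtoms`,
#' `E_dih = <V_dih> + perResidueE * nResidues`,
#' `alpha_dih = dihedralAlphaFraction * perResidueE * nResidues`.
#' Values are kept at full precision; rounding to the nearest integer happens
#' only at report time ([amdParameterTable()], `show`). The atom count is
#' taken verbatim (solvated-system counts included), as is the residue count
#' (protein residues plus nucleotides).
#'
#' @param meanVTot average total potential energy from cMD, kcal/mol.
#' @param meanVDih average dihedral energy from cMD, kcal/mol.
#' @param nAtoms,nResidues system size counts (>= 1).
#' @param coeffs coefficients from [amdCoefficients()].
#' @return an [AMDParameters-class] with provenance.
#' @export
estimateAmdParameters <- function(meanVTot, meanVDih, nAtoms, nResidues,
                                  coeffs = amdCoefficients()) {
  if (nAtoms < 1 || nResidues < 1) stop("counts must be >= 1")
  new("AMDParameters",
      eTot = meanVTot + coeffs$perAtomE * nAtoms,
      alphaTot = coeffs$perAtomAlpha * nAtoms,
      eDih = meanVDih + coeffs$perResidueE * nResidues,
      alphaDih = coeffs$dihedralAlphaFraction * coeffs$perResidueE * nResidues,
      provenance = list(meanVTot = meanVTot, meanVDih = meanVDih,
                        nAtoms = nAtoms, nResidues = nResidues,
                        coeffs = coeffs))
}

#' Report aMD parameters rounded to the nearest integer
#'
#' @param params [AMDParameters-class].
#' @return named numeric vector `eTot`, `alphaTot`, `eDih`, `alphaDih`
#'   (kcal/mol, nearest integer).
#' @export
amdParameterTable <- function(params) {
  stopifnot(is(params, "AMDParameters"))
  round(c(eTot = params@eTot, alphaTot = params@alphaTot,
          eDih = params@eDih, alphaDih = params@alphaDih))
}
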