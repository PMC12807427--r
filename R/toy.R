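#' Analytic toy system for boost/reweight validation
#'
#' A desk-scale surrogate used to validate the boost/reweighting cycle: a 1D
#' double well `U(x) = h (x^2 - 1)^2 + tilt * x` (minima near x = -1, +1;
#' barrier height h at x = 0 for tilt = 0), or its 2D extension with a
#' harmonic `0.5 * ky * y^2` channel. Energies kcal/mol, coordinates
#' Angstrom. The toy unit system takes mass in kcal/mol ps^2/A^2 so that
#' accelerations are F/m in A/ps^2 without conversion constants.
#'
#' @param potential `"double_well"` (1D) or `"double_basin"` (2D).
#' @param h barrier-height parameter, kcal/mol, > 0.
#' @param tilt linear tilt on x, kcal/mol/A (breaks well symmetry).
#' @param ky harmonic stiffness of the y channel (2D only).
#' @param mass particle mass, toy units.
#' @param friction Langevin collision frequency, ps^-1 (default 1.0).
#' @return a `ToySystem` list.
#' @export
toySystem <- function(potential = c("double_well", "double_basin"), h = 3,
                      tilt = 0, ky = 1, mass = 1, friction = 1) {
  potential <- match.arg(potential)
  if (h <= 0) stop("h must be positive (bounded-below double well)")
  structure(list(potential = potential,
                 id = if (potential == "double_well") 1L else 2L,
                 dimension = if (potential == "double_well") 1L else 2L,
                 h = h, tilt = tilt, ky = ky, mass = mass,
                 friction = friction),
            class = "ToySystem")
}

#' Evaluate a toy potential
#'
#' @param system a `ToySystem` from [toySystem()].
#' @param x numeric vector (1D) or matrix with `dimension` columns.
#' @return potential energies, kcal/mol.
#' @export
toyPotential <- function(system, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = system$dimension)
  u <- system$h * (x[, 1]^2 - 1)^2 + system$tilt * x[, 1]
  if (system$dimension == 2L) u <- u + 0.5 * system$ky * x[, 2]^2
  u
}

#' Langevin dynamics on a toy potential, with optional aMD boost
#'
#' BAOAB-splitting Langevin integration of a [toySystem()]. When
#' `params` (an [AMDParameters-class]) is supplied, the conservative force is
#' scaled by [boostFactor()] evaluated on the total toy potential against
#' `(E_tot, alpha_tot)` -- the analytic toys have no dihedral term, so only
#' the total channel is exercised. Positions, the raw potential V and the
#' boost deltaV are recorded every `stride` steps.
#'
#' @param system a `ToySystem`.
#' @param nSteps number of integration steps.
#' @param dt time step, ps (default 0.002); rejected if too large for the
#'   well stiffness.
#' @param stride record every `stride`-th step.
#' @param seed integer RNG seed (required; all randomness flows from it).
#' @param temperature Kelvin.
#' @param params [AMDParameters-class] for a boosted run, or `NULL`.
#' @param x0 starting position (defaults to the x = -1 well).
#' @param guard abort radius, Angstrom.
#' @return a [BoostedTrajectory-class].
#' @export
runLangevin <- function(system, nSteps, dt = 0.002, stride = 10L, seed,
                        temperature = 300, params = NULL, x0 = NULL,
                        guard = 10) {
  stopifnot(inherits(system, "ToySystem"), nSteps >= stride)
  if (missing(seed)) stop("an explicit integer seed is required")
  omega <- sqrt(8 * system$h / system$mass)   # curvature at the well minima
  if (dt * max(omega, system$friction) > 0.5)
    stop("dt = ", dt, " too large for well stiffness/friction ",
         "(dt * max(omega, friction) must be <= 0.5)")
  if (is.null(x0)) x0 <- c(-1, 0)[seq_len(system$dimension)]
  boost <- !is.null(params)
  if (boost) stopifnot(is(params, "AMDParameters"))
  set.seed(as.integer(seed))
  res <- .langevinBAOAB(as.numeric(x0), as.integer(nSteps), dt,
                        as.integer(stride), system$mass, system$friction,
                        kBoltzmann * temperature, system$id, system$h,
                        system$tilt, system$ky, boost,
                        if (boost) params@eTot else 0,
                        if (boost) params@alphaTot else 1, guard)
  new("BoostedTrajectory", samples = res$samples, V = res$V,
      deltaV = res$deltaV, seed = as.integer(seed),
      params = if (boost) list(params = params) else list())
}
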