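#' @import methods
NULL

#' Molecular structure container
#'
#' Holds one conformation of a molecular system: an atom table and an N x 3
#' coordinate matrix in Angstrom. Residues are kept in author numbering (for
#' the YTH domain of YT521-B that is 347-502) and classified as protein,
#' nucleotide or other; hydrogens are flagged so that heavy-atom-only
#' operations (contact analysis in particular) can filter on `isHeavy`.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `moleculeClass`, `isHeavy`.
#' @slot coords numeric matrix, N x 3, Angstrom.
#'
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resno", "resname", "chain",
            "moleculeClass", "isHeavy")
  if (!all(need %in% names(a)))
    return(paste("atoms table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) != nrow(object@coords))
    return("atom table and coordinate matrix disagree on atom count")
  if (ncol(object@coords) != 3L)
    return("coords must have 3 columns")
  if (nrow(a) > 0L) {
    if (!all(is.finite(object@coords)))
      return("coordinates must be finite")
    if (any(!nzchar(a$element)))
      return("element must be non-empty for every atom")
    if (!identical(a$isHeavy, toupper(a$element) != "H"))
      return("isHeavy inconsistent with element column")
  }
  TRUE
})

#' Coordinate trajectory
#'
#' A stack of conformations of one system: an F x N x 3 array of coordinates
#' (Angstrom) plus the `Structure` that provides the atom template, the frame
#' spacing (default 1 ns, the stride at which conformations were extracted
#' from the underlying simulations) and a replica identifier.
#'
#' @slot coords numeric array, frames x atoms x 3, Angstrom.
#' @slot frameSpacing numeric scalar, time between stored frames (ns).
#' @slot template `Structure` describing the atoms.
#' @slot replicaId integer replica label.
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(coords = "array", frameSpacing = "numeric",
                 template = "Structure", replicaId = "integer"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[1] < 1L) return("trajectory must contain at least one frame")
  if (d[2] != nAtoms(object@template))
    return("atom count differs from template")
  if (!all(is.finite(object@coords)))
    return("coordinates must be finite")
  if (length(object@frameSpacing) != 1L || object@frameSpacing <= 0)
    return("frameSpacing must be a positive scalar")
  TRUE
})

#' Ordered atom selection
#'
#' Integer atom indices (1-based, strictly increasing) into a `Structure`,
#' with a human-readable label such as `"calpha"` or `"heavy"`.
#'
#' @slot indices integer vector, strictly increasing.
#' @slot label character label.
#'
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(indices = "integer", label = "character"))

setValidity("AtomSelection", function(object) {
  i <- object@indices
  if (length(i) && (any(i < 1L) || is.unsorted(i, strictly = TRUE)))
    return("indices must be strictly increasing and >= 1")
  TRUE
})

#' Dual-boost aMD parameters
#'
#' The four accelerated-MD input parameters: threshold energies and
#' acceleration factors for the total-potential and dihedral boosts, all in
#' kcal/mol. The `provenance` list records the inputs they were derived from
#' (mean potential energies, atom and residue counts).
#'
#' @slot eTot,alphaTot total-potential threshold and acceleration factor.
#' @slot eDih,alphaDih dihedral threshold and acceleration factor.
#' @slot provenance list of estimation inputs.
#'
#' @exportClass AMDParameters
setClass("AMDParameters",
  representation(eTot = "numeric", alphaTot = "numeric",
                 eDih = "numeric", alphaDih = "numeric",
                 provenance = "list"))

setValidity("AMDParameters", function(object) {
  v <- c(object@eTot, object@alphaTot, object@eDih, object@alphaDih)
  if (length(v) != 4L || !all(is.finite(v)))
    return("all four parameters must be finite scalars")
  if (object@alphaTot <= 0 || object@alphaDih <= 0)
    return("acceleration factors must be positive")
  TRUE
})

#' Boosted toy-model trajectory
#'
#' Output of the Langevin toy simulator: sampled positions, the unbiased
#' potential V and the boost Delta-V per stored frame (kcal/mol), the seed
#' used, and the `AMDParameters` applied (empty list when unboosted).
#'
#' @slot samples numeric matrix, frames x dimension.
#' @slot V,deltaV numeric per-frame energies, kcal/mol.
#' @slot seed integer RNG seed.
#' @slot params list: either `list()` or `list(params = <AMDParameters>)`.
#'
#' @exportClass BoostedTrajectory
setClass("BoostedTrajectory",
  representation(samples = "matrix", V = "numeric", deltaV = "numeric",
                 seed = "integer", params = "list"))

setValidity("BoostedTrajectory", function(object) {
  f <- nrow(object@samples)
  if (length(object@V) != f || length(object@deltaV) != f)
    return("V and deltaV must have one value per frame")
  if (any(object@deltaV < 0)) return("deltaV must be non-negative")
  TRUE
})

#' Binned free-energy surface
#'
#' G = -kT ln(weighted density) over a 1D or 2D grid, shifted so the occupied
#' minimum is zero; unoccupied bins carry `Inf`.
#'
#' @slot edges list of per-dimension bin-edge vectors.
#' @slot G numeric array of free energies, kcal/mol.
#' @slot counts integer array of raw sample counts per bin.
#' @slot weightSums numeric array of summed normalized weights per bin.
#' @slot temperature numeric, Kelvin.
#'
#' @exportClass FreeEnergySurface
setClass("FreeEnergySurface",
  representation(edges = "list", G = "array", counts = "array",
                 weightSums = "array", temperature = "numeric"))

setValidity("FreeEnergySurface", function(object) {
  occ <- is.finite(object@G)
  if (any(occ) && abs(min(object@G[occ])) > 1e-9)
    return("occupied minimum of G must be shifted to zero")
  TRUE
})

#' Principal component decomposition
#'
#' Eigen-decomposition of a covariance model, either of Cartesian coordinates
#' (`kind = "cartesian"`, variables are the 3N selected coordinates) or of
#' native-contact distances (`kind = "contact"`, variables are contact pairs).
#' Eigenvalues are sorted descending (Angstrom^2); eigenvector columns are
#' orthonormal with the sign fixed so each column's largest-magnitude
#' component is positive.
#'
#' @slot eigenvalues numeric, descending.
#' @slot eigenvectors numeric matrix, orthonormal columns.
#' @slot center numeric mean vector of the variables.
#' @slot kind `"cartesian"` or `"contact"`.
#' @slot selection `AtomSelection` used (cartesian) or empty.
#' @slot meta list (e.g. the contact table for contact PCA, frame count).
#'
#' @exportClass PCAResult
setClass("PCAResult",
  representation(eigenvalues = "numeric", eigenvectors = "matrix",
                 center = "numeric", kind = "character",
                 selection = "AtomSelection", meta = "list"))

setValidity("PCAResult", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  if (length(ev) != ncol(object@eigenvectors))
    return("eigenvalue count must match eigenvector columns")
  if (length(object@center) != nrow(object@eigenvectors))
    return("center length must match eigenvector rows")
  Q <- object@eigenvectors
  if (ncol(Q) && max(abs(crossprod(Q) - diag(ncol(Q)))) > 1e-6)
    return("eigenvector columns must be orthonormal")
  if (!object@kind %in% c("cartesian", "contact"))
    return("kind must be 'cartesian' or 'contact'")
  TRUE
})

#' Native contact set
#'
#' Protein-residue / nucleotide pairs whose minimum heavy-atom distance in a
#' reference structure is below the cutoff (strictly, by default 6.0 A), with
#' that native distance recorded. Pair order (by residue, then nucleotide) is
#' the canonical variable order for distance series and contact PCA.
#'
#' @slot pairs data.frame: `resno`, `resname`, `nucleotide`, `nucName`,
#'   `nativeDistance`.
#' @slot cutoff numeric, Angstrom.
#' @slot referenceId character tag of the defining structure.
#'
#' @exportClass ContactSet
setClass("ContactSet",
  representation(pairs = "data.frame", cutoff = "numeric",
                 referenceId = "character"))

setValidity("ContactSet", function(object) {
  p <- object@pairs
  need <- c("resno", "resname", "nucleotide", "nucName", "nativeDistance")
  if (!all(need %in% names(p)))
    return(paste("pairs table missing columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (anyDuplicated(p[c("resno", "nucleotide")]))
    return("contact pairs must be unique")
  if (nrow(p) && any(p$nativeDistance <= 0))
    return("native distances must be positive")
  if (nrow(p) && any(p$nativeDistance >= object@cutoff))
    return("native distances must be below the cutoff")
  TRUE
})

setClass("ContactDistanceSeries",
  representation(distances = "matrix", contacts = "ContactSet"))

setValidity("ContactDistanceSeries", function(object) {
  if (ncol(object@distances) != nrow(object@contacts@pairs))
    return("distance columns must match contact pairs")
  if (length(object@distances) &&
      (any(!is.finite(object@distances)) || any(object@distances <= 0)))
    return("distances must be finite and positive")
  TRUE
})

#' Per-frame minimum-distance series for a contact set
#'
#' F x P matrix of per-frame minimum heavy-atom distances (Angstrom), one
#' column per `ContactSet` pair, in the contact set's canonical order.
#'
#' @name ContactDistanceSeries-class
#' @exportClass ContactDistanceSeries
NULL
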