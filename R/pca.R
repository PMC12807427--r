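#' Covariance model of selected coordinates or contact distances
#'
#' For Cartesian PCA the variables are the 3N coordinates of the selected
#' atoms after rigid fitting; for contact PCA they are the native-contact
#' minimum distances. The population convention (divide by the number of
#' frames F) is used throughout, so projection variances equal eigenvalues
#' exactly.
#'
#' @slot center variable means (Angstrom).
#' @slot matrix covariance matrix (Angstrom^2).
#' @slot kind `"cartesian"` or `"contact"`.
#' @slot selection [AtomSelection-class] (cartesian) or empty.
#' @slot nFrames frames used.
#' @slot meta list (fit mode, contact table, ...).
#'
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(center = "numeric", matrix = "matrix", kind = "character",
                 selection = "AtomSelection", nFrames = "integer",
                 meta = "list"))

setValidity("CovarianceModel", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("covariance matrix must be square")
  if (length(object@center) != nrow(M))
    return("center length must match matrix dimension")
  scale <- max(abs(M), 1e-12)
  if (max(abs(M - t(M))) > 1e-10 * scale)
    return("covariance matrix must be symmetric")
  TRUE
})

setMethod("show", "CovarianceModel", function(object) {
  cat("CovarianceModel (", object@kind, "): ", nrow(object@matrix), " x ",
      ncol(object@matrix), " from ", object@nFrames, " frames\n", sep = "")
  invisible(object)
})

.asTrajList <- function(trajs) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(all(vapply(trajs, is, logical(1), "Trajectory")))
  trajs
}

# Selected, rigid-fitted frames flattened to an F x 3n matrix with per-atom
# (x, y, z) column order.
.fittedRows <- function(traj, idx, refCoords, fit = TRUE) {
  t(vapply(seq_len(nFrames(traj)), function(i) {
    fr <- coords(traj, i)
    if (fit) fr <- applyTransform(fr, superpose(fr, refCoords, idx))
    as.vector(t(fr[idx, , drop = FALSE]))
  }, numeric(3 * length(idx))))
}

#' Cartesian covariance of a trajectory ensemble
#'
#' Builds the coordinate covariance matrix
#' `sigma_mn = <(r_m - <r_m>)(r_n - <r_n>)>` over the selected atoms
#' (typically protein C-alpha). Replicas are concatenated before averaging,
#' as when the independent aMD runs are combined into one ensemble. Each
#' frame is first rigid-fitted over the selection, by default onto the
#' starting/reference structure (`fitTo = "mean"` instead fits onto the
#' ensemble mean, recomputed once).
#'
#' @param trajs a [Trajectory-class] or list of them (replicas).
#' @param selection [AtomSelection-class] or indices.
#' @param reference [Structure-class] fit target.
#' @param fit rigid-fit frames before averaging (default TRUE).
#' @param fitTo `"reference"` or `"mean"`.
#' @return a [CovarianceModel-class].
#' @export
buildCovariance <- function(trajs, selection, reference, fit = TRUE,
                            fitTo = c("reference", "mean")) {
  fitTo <- match.arg(fitTo)
  trajs <- .asTrajList(trajs)
  n <- nAtoms(trajs[[1]])
  if (!all(vapply(trajs, nAtoms, numeric(1)) == n))
    stop("trajectories disagree on atom count")
  idx <- .selIndices(selection, n)
  refCoords <- coords(reference)
  X <- do.call(rbind, lapply(trajs, .fittedRows, idx, refCoords, fit))
  if (nrow(X) < 2L) stop("need at least 2 frames in total")
  if (fitTo == "mean" && fit) {
    meanRef <- matrix(colMeans(X), ncol = 3L, byrow = TRUE)
    full <- refCoords
    full[idx, ] <- meanRef
    X <- do.call(rbind, lapply(trajs, .fittedRows, idx, full, fit))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(X)          # population convention
  sel <- if (is(selection, "AtomSelection")) selection
         else new("AtomSelection", indices = as.integer(idx), label = "index")
  new("CovarianceModel", center = mu, matrix = C, kind = "cartesian",
      selection = sel, nFrames = nrow(X),
      meta = list(fit = fit, fitTo = fitTo))
}

# Shared eigensolver: descending spectrum, sign fixed so the largest-
# magnitude component of each eigenvector is positive (ties: first index).
.eigenSorted <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  Q <- e$vectors
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  list(values = e$values, vectors = Q)
}

#' Eigen-decomposition of a covariance model
#'
#' Full spectrum in descending order with a deterministic sign convention
#' (largest-magnitude component of each mode positive). For a rigid-fitted
#' Cartesian covariance the six rigid-body freedoms are removed, so at least
#' six near-zero eigenvalues are expected; the modes with the largest
#' eigenvalues span the essential subspace.
#'
#' @param cov a [CovarianceModel-class].
#' @return a [PCAResult-class].
#' @export
eigenDecompose <- function(cov) {
  stopifnot(is(cov, "CovarianceModel"))
  e <- .eigenSorted(cov@matrix)
  new("PCAResult", eigenvalues = e$values, eigenvectors = e$vectors,
      center = cov@center, kind = cov@kind, selection = cov@selection,
      meta = c(cov@meta, list(nFrames = cov@nFrames)))
}

#' Fraction of total fluctuation carried by one mode
#'
#' `eigenvalue(mode) / sum(eigenvalues)` with negative (numerical-noise)
#' eigenvalues clipped to zero.
#'
#' @param pca a [PCAResult-class].
#' @param mode 1-based mode index.
#' @return fraction in `[0, 1]`.
#' @export
contributionFraction <- function(pca, mode) {
  ev <- pmax(eigenvalues(pca), 0)
  if (mode < 1L || mode > length(ev)) stop("mode out of range")
  tot <- sum(ev)
  if (tot <= 0) stop("total variance is zero")
  ev[mode] / tot
}

#' Project a trajectory onto PCA modes
#'
#' Projects frames (rigid-fitted the same way as the covariance build) onto
#' selected modes: `value = (frame - center) . eigenvector`, in Angstrom.
#' The trajectory need not be the one that defined the subspace -- this is
#' the cross-projection used to compare the ligand-bound ensembles on the apo
#' essential subspace.
#'
#' @param traj a [Trajectory-class].
#' @param pca a Cartesian-kind [PCAResult-class].
#' @param modes mode indices (default first two).
#' @param reference [Structure-class]: the same fit target the covariance
#'   used.
#' @param fit rigid-fit frames (default TRUE, matching the build).
#' @return F x k matrix of projections with `modes` attribute.
#' @export
projectTrajectory <- function(traj, pca, modes = 1:2, reference, fit = TRUE) {
  stopifnot(is(pca, "PCAResult"), pca@kind == "cartesian")
  idx <- pca@selection@indices
  if (nAtoms(traj) < max(idx)) stop("trajectory does not cover the selection")
  if (any(modes < 1L) || any(modes > ncol(pca@eigenvectors)))
    stop("mode index out of range")
  X <- .fittedRows(traj, idx, coords(reference), fit)
  P <- sweep(X, 2, pca@center) %*% pca@eigenvectors[, modes, drop = FALSE]
  colnames(P) <- paste0("PC", modes)
  attr(P, "modes") <- modes
  P
}

#' Frames with the most negative / most positive projection
#'
#' @param proj projection matrix from [projectTrajectory()] (or any F x k
#'   matrix).
#' @param mode which column of `proj` (by position among its modes).
#' @return named integer vector `c(min = , max = )` of frame indices; ties
#'   resolved to the lowest frame index.
#' @export
extremeConformations <- function(proj, mode = 1L) {
  if (!nrow(proj)) stop("empty projection set")
  v <- proj[, mode]
  c(min = which.min(v), max = which.max(v))
}

#' Per-atom displacement field of a PCA mode
#'
#' Reshapes a Cartesian eigenvector into per-selected-atom 3-vectors scaled
#' by `scale`, for drawing arrows between extreme conformations in a
#' molecular viewer.
#'
#' @param pca a Cartesian-kind [PCAResult-class].
#' @param mode mode index.
#' @param scale multiplier (Angstrom per unit eigenvector component).
#' @return n x 3 matrix of displacements.
#' @export
modeArrows <- function(pca, mode, scale = 1) {
  stopifnot(is(pca, "PCAResult"), pca@kind == "cartesian")
  if (mode < 1L || mode > ncol(pca@eigenvectors)) stop("mode out of range")
  matrix(pca@eigenvectors[, mode], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("dx", "dy", "dz"))) * scale
}
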