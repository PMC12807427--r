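#' Optimal rigid-body superposition (least-squares fit)
#'
#' Closed-form least-squares rigid fit of a mobile coordinate set onto a
#' reference over a fit selection, with reflection correction so the returned
#' rotation is proper (determinant +1). The transform maps row-vector
#' coordinates as `x %*% rotation + translation`; the reported RMSD is over
#' the fit selection after the transform.
#'
#' @param mobile,reference N x 3 coordinate matrices, Angstrom.
#' @param fitSelection [AtomSelection-class] or integer indices defining the
#'   fit atoms; `NULL` fits on all atoms.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom).
#' @export
superpose <- function(mobile, reference, fitSelection = NULL) {
  idx <- .selIndices(fitSelection, nrow(mobile))
  if (length(idx) < 3L) stop("need at least 3 fit atoms")
  m <- mobile[idx, , drop = FALSE]
  r <- reference[idx, , drop = FALSE]
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  # degenerate fit sets (coincident or collinear points) have rank < 2
  if (qr(mc)$rank < 2L || qr(rc)$rank < 2L)
    stop("degenerate fit atoms: coincident or collinear")
  H <- crossprod(mc, rc)              # 3x3 covariance of the two point sets
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))    # reflection correction
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cr - as.vector(cm %*% R)
  fitted <- sweep(mc %*% R, 2, cr, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - r)^2))))
}

.selIndices <- function(selection, n) {
  if (is.null(selection)) return(seq_len(n))
  if (is(selection, "AtomSelection")) selection <- selection@indices
  sel <- as.integer(selection)
  if (length(sel) && max(sel) > n) stop("selection index out of range")
  sel
}

#' Apply a rigid transform to coordinates
#'
#' @param x N x 3 matrix.
#' @param fit list with `rotation` and `translation` as from [superpose()].
#' @return transformed N x 3 matrix.
#' @export
applyTransform <- function(x, fit) {
  sweep(x %*% fit$rotation, 2, fit$translation, "+")
}

#' RMSD time series against a reference structure
#'
#' For each frame, the frame is rigid-fitted onto the reference over the
#' selection (the universal convention; disable with `fit = FALSE`) and the
#' RMSD over the same selection reported. The default analysis of the study
#' design measures protein C-alpha RMSD with respect to the starting
#' structure.
#'
#' @param traj [Trajectory-class].
#' @param reference [Structure-class] (same atom template).
#' @param selection [AtomSelection-class] or indices; fit set and measurement
#'   set coincide.
#' @param fit superpose each frame first (default `TRUE`).
#' @return numeric vector of per-frame RMSD, Angstrom.
#' @export
rmsdSeries <- function(traj, reference, selection = NULL, fit = TRUE) {
  if (nAtoms(traj) != nAtoms(reference))
    stop("trajectory and reference atom counts differ")
  idx <- .selIndices(selection, nAtoms(traj))
  ref <- coords(reference)
  vapply(seq_len(nFrames(traj)), function(i) {
    fr <- coords(traj, i)
    if (fit) {
      tr <- superpose(fr, ref, idx)
      tr$rmsd
    } else {
      sqrt(mean(rowSums((fr[idx, , drop = FALSE] -
                           ref[idx, , drop = FALSE])^2)))
    }
  }, numeric(1))
}

#' Per-frame mean and standard deviation across replicas
#'
#' Combines per-replica series (e.g. RMSD) frame by frame into an average
#' curve with sample standard deviations, as done over the three independent
#' aMD runs per system.
#'
#' @param seriesList list of equal-length numeric vectors, one per replica.
#' @param allowSingle with one replica, return `NA` std instead of erroring.
#' @return data.frame with columns `frame`, `mean`, `std`; attribute
#'   `nReplicas`.
#' @export
replicaSummary <- function(seriesList, allowSingle = FALSE) {
  stopifnot(is.list(seriesList), length(seriesList) >= 1L)
  len <- lengths(seriesList)
  if (length(unique(len)) != 1L) stop("replica series differ in length")
  if (length(seriesList) < 2L && !allowSingle)
    stop("need >= 2 replicas for a standard deviation ",
         "(set allowSingle = TRUE)")
  m <- do.call(cbind, seriesList)
  out <- data.frame(frame = seq_len(nrow(m)),
                    mean = rowMeans(m),
                    std = if (ncol(m) >= 2L) apply(m, 1, stats::sd)
                          else NA_real_)
  attr(out, "nReplicas") <- ncol(m)
  out
}
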