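#' @title Accessors for amdtools classes
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
#' @param x an amdtools object
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nFrames", "BoostedTrajectory", function(x) nrow(x@samples))

setMethod("coords", "Structure", function(x, ...) x@coords)

#' @param frame integer frame index; `NULL` returns the full array
#' @rdname accessors
setMethod("coords", "Trajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) return(x@coords)
  stopifnot(frame >= 1L, frame <= nFrames(x))
  matrix(x@coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
})

setMethod("atoms", "Structure", function(x) x@atoms)
setMethod("atoms", "Trajectory", function(x) x@template@atoms)

#' Residue table of a structure
#'
#' One row per residue: key, residue number, name, chain, molecule class and
#' the atom index range it occupies.
#'
#' @rdname accessors
setMethod("residueTable", "Structure", function(x) {
  a <- x@atoms
  if (!nrow(a)) {
    return(data.frame(key = character(), resno = integer(),
                      resname = character(), chain = character(),
                      moleculeClass = character(), first = integer(),
                      last = integer(), nAtoms = integer()))
  }
  key <- paste(a$chain, a$resno, sep = ":")
  ord <- !duplicated(key)
  idx <- split(seq_len(nrow(a)), factor(key, levels = key[ord]))
  spans <- t(vapply(idx, range, integer(2)))
  data.frame(key = key[ord], resno = a$resno[ord], resname = a$resname[ord],
             chain = a$chain[ord], moleculeClass = a$moleculeClass[ord],
             first = spans[, 1], last = spans[, 2],
             nAtoms = lengths(idx), row.names = NULL)
})

setMethod("eigenvalues", "PCAResult", function(x) x@eigenvalues)
setMethod("eigenvectors", "PCAResult", function(x) x@eigenvectors)
setMethod("contactPairs", "ContactSet", function(x) x@pairs)
setMethod("contactPairs", "ContactDistanceSeries", function(x) x@contacts@pairs)

setMethod("show", "Structure", function(object) {
  rt <- residueTable(object)
  cat("Structure:", nAtoms(object), "atoms,", nrow(rt), "residues (",
      sum(rt$moleculeClass == "protein"), "protein /",
      sum(rt$moleculeClass == "nucleotide"), "nucleotide )\n")
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", nFrames(object), " frames x ", nAtoms(object),
      " atoms, spacing ", object@frameSpacing, " ns, replica ",
      object@replicaId, "\n", sep = "")
  invisible(object)
})

setMethod("show", "AtomSelection", function(object) {
  cat("AtomSelection '", object@label, "': ", length(object@indices),
      " atoms\n", sep = "")
  invisible(object)
})

setMethod("show", "AMDParameters", function(object) {
  cat("Dual-boost aMD parameters (kcal/mol, reported to nearest integer):\n")
  cat(sprintf("  E_tot     %10.0f\n  alpha_tot %10.0f\n", object@eTot,
              object@alphaTot))
  cat(sprintf("  E_dih     %10.0f\n  alpha_dih %10.0f\n", object@eDih,
              object@alphaDih))
  invisible(object)
})

setMethod("show", "BoostedTrajectory", function(object) {
  boosted <- length(object@params) > 0L
  cat("BoostedTrajectory: ", nrow(object@samples), " frames, dim ",
      ncol(object@samples), ", ", if (boosted) "boosted" else "unboosted",
      ", seed ", object@seed, "\n", sep = "")
  invisible(object)
})

setMethod("show", "FreeEnergySurface", function(object) {
  occ <- sum(is.finite(object@G))
  cat("FreeEnergySurface: ", paste(dim(object@G), collapse = " x "),
      " bins (", occ, " occupied), T = ", object@temperature, " K\n",
      sep = "")
  invisible(object)
})

setMethod("show", "PCAResult", function(object) {
  ev <- object@eigenvalues
  cat("PCAResult (", object@kind, "): ", length(ev), " modes; PC1 ",
      sprintf("%.1f%%", 100 * max(0, ev[1]) / max(sum(pmax(ev, 0)),
                                                  .Machine$double.eps)),
      " of total variance\n", sep = "")
  invisible(object)
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet: ", nrow(object@pairs), " native pairs, cutoff ",
      object@cutoff, " A (strict <)\n", sep = "")
  invisible(object)
})

setMethod("show", "ContactDistanceSeries", function(object) {
  cat("ContactDistanceSeries: ", nrow(object@distances), " frames x ",
      ncol(object@distances), " contacts\n", sep = "")
  invisible(object)
})
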