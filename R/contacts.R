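# Heavy-atom indices grouped by residue for one molecule class.
.heavyByResidue <- function(structure, class, resnos = NULL) {
  a <- structure@atoms
  keep <- a$moleculeClass == class & a$isHeavy
  if (!is.null(resnos)) keep <- keep & a$resno %in% resnos
  idx <- which(keep)
  if (!length(idx)) stop("no heavy ", class, " atoms in the given residues")
  split(idx, a$resno[idx])
}

.minPairDist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Native contacts of a reference structure
#'
#' A protein residue and a nucleotide form a native contact when the minimum
#' distance over their heavy-atom pairs in the reference structure is
#' strictly below the cutoff (6.0 Angstrom by default; `inclusive = TRUE`
#' switches to `<=`). Hydrogens are never counted. Pairs are returned in
#' deterministic (residue, nucleotide) order with their native minimum
#' distances.
#'
#' @param ref a [Structure-class] (e.g. the NMR starting model).
#' @param proteinResidues protein residue numbers to consider (default: all).
#' @param nucleotides nucleotide residue numbers to consider (default: all).
#' @param cutoff Angstrom, > 0.
#' @param inclusive use `<=` instead of the default strict `<`.
#' @param referenceId tag stored on the result.
#' @return a [ContactSet-class].
#' @export
nativeContacts <- function(ref, proteinResidues = NULL, nucleotides = NULL,
                           cutoff = 6.0, inclusive = FALSE,
                           referenceId = "reference") {
  if (cutoff <= 0) stop("cutoff must be positive")
  prot <- .heavyByResidue(ref, "protein", proteinResidues)
  nuc <- .heavyByResidue(ref, "nucleotide", nucleotides)
  a <- ref@atoms
  xyz <- ref@coords
  rows <- list()
  for (rn in names(prot)) {
    xa <- xyz[prot[[rn]], , drop = FALSE]
    for (nn in names(nuc)) {
      d <- .minPairDist(xa, xyz[nuc[[nn]], , drop = FALSE])
      hit <- if (inclusive) d <= cutoff else d < cutoff
      if (hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          resno = as.integer(rn), resname = a$resname[prot[[rn]][1]],
          nucleotide = as.integer(nn), nucName = a$resname[nuc[[nn]][1]],
          nativeDistance = d)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(resno = integer(), resname = character(),
                           nucleotide = integer(), nucName = character(),
                           nativeDistance = numeric())
  pairs <- pairs[order(pairs$resno, pairs$nucleotide), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactSet", pairs = pairs, cutoff = cutoff, referenceId = referenceId)
}

# Per-frame minimum heavy-atom distance between two atom groups, vectorized
# over frames: loops over the (small) atom-pair grid, not over frames.
.minDistOverFrames <- function(tcoords, ia, ib) {
  f <- dim(tcoords)[1]
  best <- rep(Inf, f)
  for (i in ia) {
    dx <- tcoords[, i, 1]; dy <- tcoords[, i, 2]; dz <- tcoords[, i, 3]
    for (j in ib) {
      d2 <- (dx - tcoords[, j, 1])^2 + (dy - tcoords[, j, 2])^2 +
            (dz - tcoords[, j, 3])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Per-frame minimum distances for a set of native contacts
#'
#' For every frame and every contact pair, the minimum heavy-atom distance
#' D_ij between the protein residue and the nucleotide, with no
#' periodic-image handling (analysis trajectories are solute-only).
#'
#' @param traj a [Trajectory-class] whose template carries the residues of
#'   the contact set.
#' @param contacts a [ContactSet-class].
#' @return a [ContactDistanceSeries-class] (frames x pairs).
#' @export
minDistanceSeries <- function(traj, contacts) {
  stopifnot(is(contacts, "ContactSet"))
  tmpl <- traj@template
  prot <- .heavyByResidue(tmpl, "protein")
  nuc <- .heavyByResidue(tmpl, "nucleotide")
  p <- contacts@pairs
  miss <- setdiff(p$resno, as.integer(names(prot)))
  missN <- setdiff(p$nucleotide, as.integer(names(nuc)))
  if (length(miss) || length(missN))
    stop("contact residues not present in trajectory template: ",
         paste(c(miss, missN), collapse = ", "))
  D <- vapply(seq_len(nrow(p)), function(k) {
    .minDistOverFrames(traj@coords, prot[[as.character(p$resno[k])]],
                       nuc[[as.character(p$nucleotide[k])]])
  }, numeric(nFrames(traj)))
  D <- matrix(D, nrow = nFrames(traj))
  colnames(D) <- paste0(p$resname, p$resno, "-", p$nucName, p$nucleotide)
  new("ContactDistanceSeries", distances = D, contacts = contacts)
}

#' Per-frame contact counts between one nucleotide and the protein
#'
#' Counts, for each frame, either the protein residues whose minimum
#' heavy-atom distance to the nucleotide is within the cutoff
#' (`level = "residue"`, inclusive `<=` by default, matching "within
#' 6.0 Angstrom"), or the individual heavy-atom pairs within the cutoff
#' (`level = "atom_pair"`). The per-nucleotide average of these counts is the
#' quantity compared across the methylated and non-methylated complexes.
#'
#' @param traj a [Trajectory-class].
#' @param nucleotide nucleotide residue number.
#' @param proteinResidues protein residue numbers to consider (default all).
#' @param cutoff Angstrom.
#' @param level `"residue"` or `"atom_pair"`.
#' @param inclusive use `<=` (default) or strict `<`.
#' @return list with `counts` (per frame), `mean`, `std`, `level`,
#'   `nucleotide`.
#' @export
contactCountSeries <- function(traj, nucleotide, proteinResidues = NULL,
                               cutoff = 6.0,
                               level = c("residue", "atom_pair"),
                               inclusive = TRUE) {
  level <- match.arg(level)
  if (cutoff <= 0) stop("cutoff must be positive")
  tmpl <- traj@template
  nuc <- .heavyByResidue(tmpl, "nucleotide")
  nn <- as.character(nucleotide)
  if (!nn %in% names(nuc)) stop("unknown nucleotide: ", nucleotide)
  prot <- tryCatch(.heavyByResidue(tmpl, "protein", proteinResidues),
                   error = function(e) list())
  f <- nFrames(traj)
  counts <- rep(0L, f)
  for (ia in prot) {
    if (level == "residue") {
      d <- .minDistOverFrames(traj@coords, ia, nuc[[nn]])
      hit <- if (inclusive) d <= cutoff else d < cutoff
      counts <- counts + hit
    } else {
      for (i in ia) {
        for (j in nuc[[nn]]) {
          d2 <- (traj@coords[, i, 1] - traj@coords[, j, 1])^2 +
                (traj@coords[, i, 2] - traj@coords[, j, 2])^2 +
                (traj@coords[, i, 3] - traj@coords[, j, 3])^2
          hit <- if (inclusive) d2 <= cutoff^2 else d2 < cutoff^2
          counts <- counts + hit
        }
      }
    }
  }
  list(counts = as.integer(counts), mean = mean(counts),
       std = stats::sd(counts), level = level,
       nucleotide = as.integer(nucleotide))
}
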