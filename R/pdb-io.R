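#' @importFrom utils read.table write.table write.csv
NULL

.PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN", "MSE")

#' Residue-name aliases recognized as nucleotides
#'
#' Standard RNA/DNA residue names plus common aliases for N6-methyladenosine
#' and other modified nucleotides, as used to classify residues when reading
#' structures. Extend via the `nucleotideAliases` argument of [readPDB()].
#'
#' @return character vector of residue names.
#' @export
nucleotideResnames <- function() {
  c("A", "U", "G", "C", "RA", "RU", "RG", "RC", "DA", "DT", "DG", "DC",
    "ADE", "URA", "GUA", "CYT", "THY",
    "6MA", "6MZ", "M6A", "MA6", "A2M", "1MA", "N6A")
}

.moleculeClass <- function(resname, nucleotideAliases = nucleotideResnames()) {
  rn <- toupper(trimws(resname))
  ifelse(rn %in% .PROTEIN_RESNAMES, "protein",
         ifelse(rn %in% toupper(nucleotideAliases), "nucleotide", "other"))
}

# Element from PDB element column with atom-name fallback: first non-digit
# character of the atom name ('1HB' -> H, 'CA' -> C).
.inferElement <- function(element, name) {
  el <- toupper(trimws(element))
  bad <- is.na(el) | !nzchar(el)
  if (any(bad)) {
    stripped <- gsub("[0-9'\\*]", "", toupper(trimws(name[bad])))
    el[bad] <- substr(stripped, 1L, 1L)
  }
  el
}

#' Construct a Structure from an atom table and coordinates
#'
#' @param atoms data.frame with at least `name`, `resno`, `resname`; optional
#'   `serial`, `element`, `chain`.
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param nucleotideAliases residue names classified as nucleotides.
#' @return a [Structure-class] object.
#' @export
Structure <- function(atoms, coords, nucleotideAliases = nucleotideResnames()) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")
  n <- nrow(atoms)
  a <- data.frame(
    serial = if (is.null(atoms$serial)) seq_len(n) else as.integer(atoms$serial),
    name = as.character(atoms$name),
    element = .inferElement(
      if (is.null(atoms$element)) rep("", n) else as.character(atoms$element),
      atoms$name),
    resno = as.integer(atoms$resno),
    resname = as.character(atoms$resname),
    chain = if (is.null(atoms$chain)) rep("A", n) else as.character(atoms$chain),
    stringsAsFactors = FALSE)
  a$moleculeClass <- .moleculeClass(a$resname, nucleotideAliases)
  a$isHeavy <- toupper(a$element) != "H"
  new("Structure", atoms = a, coords = coords)
}

#' Construct a Trajectory
#'
#' @param coords frames x atoms x 3 array (or a single N x 3 matrix for a
#'   one-frame trajectory), Angstrom.
#' @param template [Structure-class] providing the atom metadata.
#' @param frameSpacing time between frames, ns (default 1, i.e. conformations
#'   extracted every 1 ns).
#' @param replicaId integer replica label.
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(coords, template, frameSpacing = 1, replicaId = 1L) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  new("Trajectory", coords = coords, frameSpacing = as.numeric(frameSpacing),
      template = template, replicaId = as.integer(replicaId))
}

#' Read one model of a (multi-model) PDB file
#'
#' Parses a PDB file (via bio3d) and returns the requested MODEL as a
#' [Structure-class]. Elements are taken from PDB columns 77-78 when present,
#' falling back to the first non-digit character of the atom name. Residues
#' are classified as protein or nucleotide by residue name; methylated
#' adenosine aliases (6MA, 6MZ, M6A, ...) count as nucleotides. Alternate
#' locations other than blank/'A' are dropped.
#'
#' @param path PDB file path.
#' @param model 1-based model index (NMR ensembles store several).
#' @param nucleotideAliases residue names classified as nucleotides.
#' @return a [Structure-class].
#' @export
readPDB <- function(path, model = 1L, nucleotideAliases = nucleotideResnames()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nModels <- nrow(pdb$xyz)
  if (model < 1L || model > nModels)
    stop("model ", model, " out of range: file has ", nModels, " model(s)")
  keep <- pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM"
  alt <- pdb$atom$alt
  keep <- keep & (is.na(alt) | alt == "" | alt == "A")
  if (!any(keep)) stop("no atoms parsed from ", path)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
  at <- pdb$atom[keep, , drop = FALSE]
  Structure(
    atoms = data.frame(serial = at$eleno, name = at$elety,
                       element = ifelse(is.na(at$elesy), "", at$elesy),
                       resno = at$resno, resname = at$resid,
                       chain = ifelse(is.na(at$chain), "A", at$chain),
                       stringsAsFactors = FALSE),
    coords = xyz, nucleotideAliases = nucleotideAliases)
}

#' Write a Structure or Trajectory as a (multi-model) PDB file
#'
#' A `Structure` is written as a single model; a `Trajectory` as one MODEL
#' per frame. Coordinates use the PDB fixed-point format (3 decimals).
#'
#' @param x a [Structure-class] or [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Structure")) {
    a <- x@atoms
    xyz <- as.vector(t(x@coords))
  } else if (is(x, "Trajectory")) {
    a <- x@template@atoms
    f <- nFrames(x)
    xyz <- t(vapply(seq_len(f),
                    function(i) as.vector(t(coords(x, i))), numeric(3 * nrow(a))))
  } else stop("x must be a Structure or Trajectory")
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' All MODELs become frames; the atom template is taken from the first model.
#'
#' @param path PDB file path.
#' @param frameSpacing,replicaId passed to [Trajectory()].
#' @inheritParams readPDB
#' @return a [Trajectory-class].
#' @export
readPDBTrajectory <- function(path, frameSpacing = 1, replicaId = 1L,
                              nucleotideAliases = nucleotideResnames()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  template <- readPDB(path, model = 1L, nucleotideAliases = nucleotideAliases)
  f <- nrow(pdb$xyz)
  n <- nAtoms(template)
  if (ncol(pdb$xyz) != 3L * n)
    stop("altLoc-filtered atom count does not tile the trajectory")
  arr <- array(NA_real_, dim = c(f, n, 3L))
  for (i in seq_len(f))
    arr[i, , ] <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
  Trajectory(arr, template, frameSpacing, replicaId)
}

#' Read/write the lightweight whitespace trajectory format
#'
#' A plain table with columns `frame`, `atom`, `x`, `y`, `z` (Angstrom),
#' frames and atoms 1-based and dense. This is the package's text trajectory
#' interchange format next to multi-model PDB.
#'
#' @param path table file path.
#' @param template [Structure-class] for the atoms.
#' @param frameSpacing,replicaId passed to [Trajectory()].
#' @return [readCoordTable()]: a [Trajectory-class]; [writeCoordTable()]:
#'   `path`, invisibly.
#' @export
readCoordTable <- function(path, template, frameSpacing = 1, replicaId = 1L) {
  tab <- read.table(path, header = TRUE)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  f <- max(tab$frame)
  n <- nAtoms(template)
  if (nrow(tab) != f * n || max(tab$atom) != n)
    stop("coordinate table is not dense over ", f, " frames x ", n, " atoms")
  arr <- array(NA_real_, dim = c(f, n, 3L))
  idx <- cbind(tab$frame, tab$atom)
  arr[cbind(idx, 1L)] <- tab$x
  arr[cbind(idx, 2L)] <- tab$y
  arr[cbind(idx, 3L)] <- tab$z
  Trajectory(arr, template, frameSpacing, replicaId)
}

#' @param traj [Trajectory-class] to write.
#' @rdname readCoordTable
#' @export
writeCoordTable <- function(traj, path) {
  f <- nFrames(traj); n <- nAtoms(traj)
  tab <- data.frame(
    frame = rep(seq_len(f), each = n),
    atom = rep(seq_len(n), times = f),
    x = as.vector(t(matrix(traj@coords[, , 1], nrow = f))),
    y = as.vector(t(matrix(traj@coords[, , 2], nrow = f))),
    z = as.vector(t(matrix(traj@coords[, , 3], nrow = f))))
  write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select atoms of a structure
#'
#' Deterministic conjunction of simple selection rules, returned in atom-index
#' order: atom `name` equality (e.g. `"CA"`), heavy atoms only, residue-number
#' range or set, and molecule class (`"protein"` / `"nucleotide"`). The
#' recurring selections of the analyses are protein C-alpha atoms (RMSD, PCA)
#' and heavy atoms (contacts).
#'
#' @param structure a [Structure-class].
#' @param name atom name(s) to keep, or `NULL`.
#' @param heavy if `TRUE`, keep heavy (non-hydrogen) atoms only.
#' @param resno residue numbers (author numbering) to keep, or `NULL`.
#' @param class molecule class to keep, or `NULL`.
#' @param allowEmpty if `FALSE` (default), an empty result is an error.
#' @param label selection label; autogenerated when `NULL`.
#' @return an [AtomSelection-class].
#' @export
selectAtoms <- function(structure, name = NULL, heavy = FALSE, resno = NULL,
                        class = NULL, allowEmpty = FALSE, label = NULL) {
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & trimws(a$name) %in% name
  if (heavy) keep <- keep & a$isHeavy
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(class)) keep <- keep & a$moleculeClass %in% class
  idx <- which(keep)
  if (!length(idx) && !allowEmpty)
    stop("selection matched no atoms (set allowEmpty = TRUE to permit)")
  if (is.null(label)) {
    parts <- c(if (!is.null(name)) paste0("name=", paste(name, collapse = "|")),
               if (heavy) "heavy",
               if (!is.null(resno)) "resno-subset",
               if (!is.null(class)) paste(class, collapse = "|"))
    label <- if (length(parts)) paste(parts, collapse = " & ") else "all"
  }
  new("AtomSelection", indices = as.integer(idx), label = label)
}
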