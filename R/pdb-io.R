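#' @include AllClasses.R AllGenerics.R
NULL

# Columns 31-54 of an ATOM/HETATM record hold x, y, z in fixed width.
.checkCoordLines <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (ln in rec) {
    fld <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
             substr(lines[ln], 47, 54))
    num <- suppressWarnings(as.numeric(fld))
    if (any(is.na(num)))
      stop(sprintf("unparseable coordinate line %d: %s", ln,
                   trimws(lines[ln])), call. = FALSE)
  }
  length(rec)
}

#' Read a PDB file as an Ensemble
#'
#' Parses ATOM and HETATM records (metal ions such as the MIDAS Mg are
#' retained); each MODEL becomes one frame, a file without MODEL records
#' gives a single-frame ensemble. Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken in favour of altLoc 'A'.
#' Insertion codes, if present, are kept as distinct residues with a
#' warning.
#'
#' @param path path to a PDB file.
#' @param id identifier for the ensemble (default: file base name).
#' @return an \code{\link{Ensemble}}.
#' @examples
#' pdb <- writePDB(makeIdealPeptide("alpha_helix", 8), tempfile(fileext = ".pdb"))
#' ens <- readPDB(pdb)
#' nFrames(ens)
#' @export
readPDB <- function(path, id = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_rec <- .checkCoordLines(lines)
  if (n_rec == 0) stop("no ATOM/HETATM records in ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)

  # resolve alternate locations: keep highest occupancy, tie -> 'A'
  keep <- rep(TRUE, nrow(at))
  alt <- at$alt
  if (any(!is.na(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    for (k in unique(key[!is.na(alt)])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        occ <- at$o[idx]
        occ[is.na(occ)] <- 1
        best <- idx[order(-occ, ifelse(is.na(alt[idx]), "A", alt[idx]))][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  if (any(!is.na(at$insert) & at$insert != ""))
    warning("insertion codes present; treated as distinct residues")

  at <- at[keep, , drop = FALSE]
  ci <- which(keep)
  xyz_cols <- as.vector(rbind(3 * ci - 2, 3 * ci - 1, 3 * ci))
  xyz <- xyz[, xyz_cols, drop = FALSE]

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), at$elesy),
    hetatm = at$type == "HETATM",
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE)

  nfr <- nrow(xyz)
  nat <- nrow(atoms)
  coords <- array(NA_real_, c(nat, 3, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  atoms$x <- coords[, 1, 1]; atoms$y <- coords[, 2, 1]; atoms$z <- coords[, 3, 1]
  new("Ensemble", atoms = atoms, coords = coords, weights = numeric(0),
      id = id)
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Multi-frame ensembles are written as MODEL/ENDMDL blocks. Coordinates
#' are written at PDB precision (1e-3 Angstrom).
#'
#' @param x a \code{Structure} or \code{Ensemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(x, path) {
  if (is(x, "Structure"))
    x <- asEnsemble(x)
  at <- x@atoms
  nfr <- nFrames(x)
  xyz <- matrix(NA_real_, nfr, 3 * nrow(at))
  for (f in seq_len(nfr))
    xyz[f, ] <- as.vector(t(x@coords[, , f]))
  het <- if (is.null(at$hetatm)) rep(FALSE, nrow(at)) else at$hetatm
  bio3d::write.pdb(
    file = path, xyz = if (nfr == 1) xyz[1, ] else xyz,
    type = ifelse(het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Wrap a Structure as a one-frame Ensemble
#' @param x a \code{Structure}.
#' @return an \code{Ensemble} with one frame.
#' @export
asEnsemble <- function(x) {
  stopifnot(is(x, "Structure"))
  at <- x@atoms
  coords <- array(c(at$x, at$y, at$z), c(nrow(at), 3, 1))
  new("Ensemble", atoms = at, coords = coords, weights = numeric(0),
      id = x@id)
}

#' Build an Ensemble from a list of Structures
#' @param frames list of \code{Structure} sharing one atom layout.
#' @param weights optional per-frame weights (must sum to 1).
#' @param id identifier.
#' @return an \code{Ensemble}.
#' @export
makeEnsemble <- function(frames, weights = numeric(0), id = "ensemble") {
  stopifnot(length(frames) >= 1)
  ref <- frames[[1]]@atoms
  key <- paste(ref$chain, ref$resno, ref$name)
  coords <- array(NA_real_, c(nrow(ref), 3, length(frames)))
  for (f in seq_along(frames)) {
    at <- frames[[f]]@atoms
    if (nrow(at) != nrow(ref) ||
        !identical(paste(at$chain, at$resno, at$name), key))
      stop("frame ", f, " does not share the reference atom layout")
    coords[, , f] <- c(at$x, at$y, at$z)
  }
  new("Ensemble", atoms = ref, coords = coords, weights = weights, id = id)
}

#' Construct a residue selection
#'
#' @param chain chain identifier.
#' @param first,last inclusive author-numbered residue range bounds
#'   (vectors for multiple ranges).
#' @param atoms optional atom-name filter (e.g. "CA").
#' @return a \code{\link{ResidueSelection}}.
#' @export
residueSelection <- function(chain, first, last, atoms = character(0)) {
  new("ResidueSelection", chain = as.character(chain),
      first = as.integer(first), last = as.integer(last),
      atoms = as.character(atoms))
}

#' Parse a selection string "chain:first-last[:atomname]"
#'
#' e.g. \code{"A:256-260:CA"} selects the Calpha atoms of residues 256-260
#' in chain A. A single residue may be written without the dash.
#'
#' @param s selection string.
#' @return a \code{\link{ResidueSelection}}.
#' @export
parseSelection <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3)
    stop("selection must be 'chain:first-last[:atom]': ", s)
  rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  first <- as.integer(rng[1])
  last <- as.integer(if (length(rng) > 1) rng[2] else rng[1])
  if (is.na(first) || is.na(last)) stop("bad residue range in ", s)
  residueSelection(parts[1], first, last,
                   if (length(parts) == 3) parts[3] else character(0))
}

#' Row indices of atoms matched by a selection
#'
#' @param structure a \code{Structure} (or \code{Ensemble} atom layout).
#' @param selection a \code{ResidueSelection}.
#' @return integer row indices into the atom table.
#' @export
matchSelection <- function(structure, selection) {
  at <- if (is(structure, "Structure") || is(structure, "Ensemble"))
    atomTable(structure) else structure
  inRange <- rep(FALSE, nrow(at))
  for (k in seq_along(selection@first))
    inRange <- inRange | (at$resno >= selection@first[k] &
                          at$resno <= selection@last[k])
  hit <- at$chain == selection@chain & inRange
  if (length(selection@atoms))
    hit <- hit & at$name %in% selection@atoms
  idx <- which(hit)
  if (!length(idx))
    stop(sprintf("selection matched no atoms (chain %s, residues %s%s)",
                 selection@chain,
                 paste(sprintf("%d-%d", selection@first, selection@last),
                       collapse = ","),
                 if (length(selection@atoms))
                   paste0(", atoms ", paste(selection@atoms, collapse = "/"))
                 else ""))
  idx
}
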