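# Central S4 containers. Atom tables use PDB author numbering throughout;
# coordinates are Angstrom.

.validAtomTable <- function(atoms) {
  need <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z",
            "element")
  if (!all(need %in% names(atoms)))
    return(paste("atom table lacks columns:",
                 paste(setdiff(need, names(atoms)), collapse = ", ")))
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
        !all(is.finite(atoms$z)))
      return("non-finite atom coordinates")
    key <- paste(atoms$chain, atoms$resno, atoms$name, atoms$insert %||% "")
    if (anyDuplicated(key))
      return("duplicated (chain, resno, name) atom identifiers")
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Protein structure: an ordered atom table
#'
#' A single conformation: one row per atom with PDB-style naming
#' (\code{serial}, \code{name}, \code{resname}, \code{chain}, \code{resno},
#' \code{x}, \code{y}, \code{z}, \code{element}). Residue numbers are PDB
#' author numbering and are preserved exactly from the source file, so
#' residues can be addressed the way the structural literature does
#' (e.g. Phe292, the MIDAS Mg ion).
#'
#' @slot atoms data.frame, one row per atom.
#' @slot id character identifier.
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", id = "character"),
  validity = function(object) .validAtomTable(object@atoms))

#' Conformational ensemble with shared atom layout
#'
#' Ordered frames over one fixed atom table; coordinates are stored as an
#' natoms x 3 x nframes array. Optional per-frame weights must be
#' non-negative and sum to one (within 1e-9); an empty weight vector means
#' uniform weights.
#'
#' @slot atoms data.frame atom layout shared by all frames.
#' @slot coords numeric array natoms x 3 x nframes.
#' @slot weights numeric, length 0 (uniform) or nframes.
#' @slot id character identifier.
#' @exportClass Ensemble
setClass("Ensemble",
  representation(atoms = "data.frame", coords = "array",
                 weights = "numeric", id = "character"),
  validity = function(object) {
    v <- .validAtomTable(object@atoms)
    if (!isTRUE(v)) return(v)
    d <- dim(object@coords)
    if (length(d) != 3 || d[2] != 3)
      return("coords must be an natoms x 3 x nframes array")
    if (d[1] != nrow(object@atoms))
      return("coords first dimension does not match atom table")
    w <- object@weights
    if (length(w)) {
      if (length(w) != d[3]) return("weights length != number of frames")
      if (any(w < 0)) return("negative frame weights")
      if (abs(sum(w) - 1) > 1e-9) return("frame weights do not sum to 1")
    }
    TRUE
  })

#' Residue selection by chain, author-numbered ranges and atom names
#'
#' @slot chain single chain identifier.
#' @slot first,last integer vectors of inclusive range bounds.
#' @slot atoms character vector of atom names to keep, or empty for all.
#' @exportClass ResidueSelection
setClass("ResidueSelection",
  representation(chain = "character", first = "integer", last = "integer",
                 atoms = "character"),
  validity = function(object) {
    if (length(object@first) != length(object@last) ||
        length(object@first) < 1)
      return("need >= 1 residue range")
    if (any(object@first > object@last))
      return("range with first > last")
    TRUE
  })

#' Collective-variable definition
#'
#' Either a dihedral-correlation CV over an ordered list of dihedral angles
#' (phi/psi or chi1), a three-group angle CV (the orientation that a helix
#' forms with the hydrophobic core), or a generic coordinate of a toy
#' system. \code{sigma} is the metadynamics Gaussian width attached to the
#' CV (dimensionless for dihedral correlations; degrees for the angle CV).
#'
#' @slot name character, e.g. "cv1".
#' @slot kind one of "dihedral_correlation", "group_angle",
#'   "generic_coordinate".
#' @slot angles data.frame(chain, resno, label) of dihedral identifiers
#'   (label in phi/psi/chi1), in evaluation order.
#' @slot groups list of 3 \code{ResidueSelection} for group_angle.
#' @slot coordIndex integer coordinate index for generic_coordinate.
#' @slot sigma positive Gaussian width in CV units.
#' @exportClass CVDefinition
setClass("CVDefinition",
  representation(name = "character", kind = "character",
                 angles = "data.frame", groups = "list",
                 coordIndex = "integer", sigma = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("dihedral_correlation", "group_angle",
                            "generic_coordinate"))
      return("unknown CV kind")
    if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
        object@sigma <= 0)
      return("sigma must be a single positive number")
    if (object@kind == "dihedral_correlation" && nrow(object@angles) < 1)
      return("dihedral_correlation needs a non-empty angle list")
    if (object@kind == "group_angle" && length(object@groups) != 3)
      return("group_angle needs exactly 3 residue groups")
    TRUE
  })

#' History-dependent metadynamics bias potential
#'
#' The Gaussian-hill sum V(s, t) = sum_{k tau < t} W exp(-sum_i
#' (s_i - s_i0)^2 / (2 sigma_i^2)). Hills deposited at step k*stride act
#' only strictly after their deposition time.
#'
#' @slot cvNames character, one per biased CV dimension.
#' @slot sigma per-CV Gaussian widths.
#' @slot centers numeric matrix nhills x d of hill centres.
#' @slot heights numeric hill heights W, kJ/mol.
#' @slot times numeric deposition step indices, non-decreasing.
#' @slot stride deposition stride tau in integrator steps.
#' @exportClass BiasPotential
setClass("BiasPotential",
  representation(cvNames = "character", sigma = "numeric",
                 centers = "matrix", heights = "numeric", times = "numeric",
                 stride = "numeric"),
  validity = function(object) {
    d <- length(object@sigma)
    if (any(object@sigma <= 0)) return("sigma must be positive")
    if (ncol(object@centers) != d && nrow(object@centers) > 0)
      return("hill centre dimension != sigma length")
    n <- nrow(object@centers)
    if (length(object@heights) != n || length(object@times) != n)
      return("heights/times length != number of hills")
    if (any(object@heights < 0)) return("negative hill height")
    if (n > 1 && any(diff(object@times) < 0))
      return("hills not ordered by deposition time")
    TRUE
  })

#' Analytic toy potential (sum of Gaussian wells on a confining wall)
#'
#' U(x) = -sum_k A_k exp(-|x - c_k|^2 / (2 w_k^2)) +
#' wallHeight * (|x - wallCenter| / wallScale)^wallPower, in kJ/mol, with
#' analytic gradient. Used as the desk-scale stand-in for an all-atom
#' system in the metadynamics engine.
#'
#' @slot dimension 1 or 2.
#' @slot depths numeric well depths A_k (kJ/mol, positive = attractive).
#' @slot centers numeric matrix nwells x dimension.
#' @slot widths numeric well widths w_k.
#' @slot wallCenter,wallScale,wallPower,wallHeight confinement parameters.
#' @slot descriptor character.
#' @exportClass ToyPotential
setClass("ToyPotential",
  representation(dimension = "integer", depths = "numeric",
                 centers = "matrix", widths = "numeric",
                 wallCenter = "numeric", wallScale = "numeric",
                 wallPower = "numeric", wallHeight = "numeric",
                 descriptor = "character"),
  validity = function(object) {
    d <- object@dimension
    if (!d %in% c(1L, 2L)) return("dimension must be 1 or 2")
    if (ncol(object@centers) != d) return("well centres have wrong dimension")
    n <- nrow(object@centers)
    if (length(object@depths) != n || length(object@widths) != n)
      return("depths/widths length != number of wells")
    if (any(object@widths <= 0)) return("well widths must be positive")
    if (length(object@wallCenter) != d) return("wallCenter wrong length")
    if (object@wallScale <= 0 || object@wallHeight < 0)
      return("bad confinement parameters")
    TRUE
  })

#' Microstates: occupied CV-space bins with per-replica counts
#'
#' @slot centers numeric matrix nmicro x d of bin centres.
#' @slot counts numeric matrix nmicro x nreplicas of post-equilibration
#'   frame counts.
#' @slot binWidths numeric bin widths per CV.
#' @slot cvNames character.
#' @exportClass MicrostateTable
setClass("MicrostateTable",
  representation(centers = "matrix", counts = "matrix",
                 binWidths = "numeric", cvNames = "character"),
  validity = function(object) {
    if (nrow(object@centers) != nrow(object@counts))
      return("centers/counts row mismatch")
    if (any(object@counts < 0)) return("negative counts")
    if (length(object@binWidths) != ncol(object@centers))
      return("binWidths length != CV dimension")
    if (any(object@binWidths <= 0)) return("bin widths must be positive")
    TRUE
  })

#' WHAM free energies over microstates
#'
#' Free energies are gauged so the minimum over microstates with non-zero
#' total count is 0 kJ/mol; empty microstates carry +Inf.
#'
#' @slot F numeric per-microstate free energy, kJ/mol.
#' @slot f numeric per-replica normalisation constants, kJ/mol.
#' @slot temperature Kelvin.
#' @slot iterations integer, self-consistency iterations used.
#' @slot residual final max |delta f_r|.
#' @slot microstates the \code{MicrostateTable} the fit was run on.
#' @exportClass FreeEnergyTable
setClass("FreeEnergyTable",
  representation(F = "numeric", f = "numeric", temperature = "numeric",
                 iterations = "integer", residual = "numeric",
                 microstates = "MicrostateTable"),
  validity = function(object) {
    if (length(object@F) != nrow(object@microstates@centers))
      return("F length != number of microstates")
    vis <- is.finite(object@F)
    if (any(vis) && abs(min(object@F[vis])) > 1e-6)
      return("free energies not gauged to min 0")
    TRUE
  })

#' Projected free-energy surface on a 1D or 2D grid
#'
#' @slot axes list of axis definitions: list(name, unit, edges).
#' @slot F numeric vector (1D) or matrix (2D) of free energies, kJ/mol,
#'   min 0 over visited cells; unvisited cells are +Inf.
#' @slot temperature Kelvin.
#' @exportClass FESGrid
setClass("FESGrid",
  representation(axes = "list", F = "array", temperature = "numeric"),
  validity = function(object) {
    if (!length(object@axes) %in% 1:2) return("1 or 2 axes required")
    vis <- is.finite(object@F)
    if (any(vis) && abs(min(object@F[vis])) > 1e-6)
      return("projected free energies not gauged to min 0")
    TRUE
  })

#' Saupe alignment tensor
#'
#' 3x3 symmetric traceless order matrix describing partial molecular
#' alignment; five independent components.
#'
#' @slot S 3x3 numeric matrix, symmetric, trace < 1e-12.
#' @exportClass AlignmentTensor
setClass("AlignmentTensor",
  representation(S = "matrix"),
  validity = function(object) {
    if (!all(dim(object@S) == c(3, 3))) return("S must be 3x3")
    if (max(abs(object@S - t(object@S))) > 1e-9) return("S not symmetric")
    if (abs(sum(diag(object@S))) > 1e-9) return("S not traceless")
    TRUE
  })

#' Table of experimental observables (chemical shifts)
#'
#' One row per (residue, atom type) with the measured value in ppm; pairs
#' must be unique. The residue and atom-type ranges are properties of the
#' data, never structural constants.
#'
#' @slot entries data.frame(resno, atomType, value).
#' @slot provenance character free-text source tag.
#' @exportClass ObservableTable
setClass("ObservableTable",
  representation(entries = "data.frame", provenance = "character"),
  validity = function(object) {
    e <- object@entries
    if (!all(c("resno", "atomType", "value") %in% names(e)))
      return("entries needs columns resno, atomType, value")
    if (nrow(e) && !all(is.finite(e$value))) return("non-finite shift values")
    if (anyDuplicated(paste(e$resno, e$atomType)))
      return("duplicated (residue, atom type) pairs")
    TRUE
  })

#' Flat-bottom harmonic restraint penalty
#'
#' Per-entry energy 0 when |delta| <= eps, k (|delta| - eps)^2 beyond, with
#' an optional per-term cap. Tolerances are per atom type with a fallback
#' default.
#'
#' @slot k force constant, kJ/mol/ppm^2.
#' @slot eps named numeric of per-atom-type tolerances (ppm); unnamed
#'   single value = uniform.
#' @slot cap optional per-term maximum energy (Inf = none).
#' @exportClass PenaltyForm
setClass("PenaltyForm",
  representation(k = "numeric", eps = "numeric", cap = "numeric"),
  validity = function(object) {
    if (object@k < 0) return("k must be >= 0")
    if (any(object@eps < 0)) return("tolerances must be >= 0")
    TRUE
  })

#' Linear forward model for toy-system observables
#'
#' Predicts observables delta = A x + b from a replica's coordinate vector;
#' the analytic stand-in for a chemical-shift predictor, with known
#' derivatives so restraint forces can be validated exactly. An arbitrary
#' external predictor can be supplied as a plain R function via
#' \code{\link{restraintEnergy}} helpers.
#'
#' @slot A numeric matrix nobs x d.
#' @slot b numeric intercepts, length nobs.
#' @slot descriptor character.
#' @exportClass LinearShiftModel
setClass("LinearShiftModel",
  representation(A = "matrix", b = "numeric", descriptor = "character"),
  validity = function(object) {
    if (length(object@b) != nrow(object@A)) return("b length != nrow(A)")
    TRUE
  })

#' Bias-exchange metadynamics simulation log
#'
#' @slot cvTraj list, one numeric matrix per replica (recorded step, CV
#'   value(s)); column 1 is the step index.
#' @slot hills list of \code{BiasPotential}, one per replica.
#' @slot exchanges data.frame(step, i, j, accepted).
#' @slot restraintEnergy numeric series (kJ/mol) or length 0.
#' @slot params list of run parameters (dt, temperature, friction, strides,
#'   hill height, seed).
#' @exportClass BemetaLog
setClass("BemetaLog",
  representation(cvTraj = "list", hills = "list", exchanges = "data.frame",
                 restraintEnergy = "numeric", params = "list"))
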