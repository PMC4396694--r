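#' @include AllClasses.R
NULL

#' Number of frames in an ensemble
#' @param x an \code{Ensemble}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])

#' Atom table accessor
#' @param x a \code{Structure} or \code{Ensemble}.
#' @return data.frame of atoms.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "Structure", function(x) x@atoms)

#' @rdname atomTable
#' @export
setMethod("atomTable", "Ensemble", function(x) x@atoms)

#' Extract a single frame of an ensemble as a Structure
#' @param x an \code{Ensemble}.
#' @param i frame index.
#' @return a \code{Structure}.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "Ensemble", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nFrames(x))
  at <- x@atoms
  at$x <- x@coords[, 1, i]
  at$y <- x@coords[, 2, i]
  at$z <- x@coords[, 3, i]
  new("Structure", atoms = at, id = sprintf("%s.frame%d", x@id, i))
})

#' Per-frame weights of an ensemble (uniform if unset)
#' @param x an \code{Ensemble}.
#' @return numeric weights summing to 1.
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))

#' @rdname frameWeights
#' @export
setMethod("frameWeights", "Ensemble", function(x) {
  n <- nFrames(x)
  if (length(x@weights)) x@weights else rep(1 / n, n)
})

#' Potential energy of a toy potential
#' @param object a \code{ToyPotential}.
#' @param x numeric vector (one point) or matrix (points in rows).
#' @return energy value(s), kJ/mol.
#' @export
setGeneric("potentialEnergy",
           function(object, x) standardGeneric("potentialEnergy"))

#' Analytic gradient of a toy potential
#' @param object a \code{ToyPotential}.
#' @param x numeric vector (one point) or matrix (points in rows).
#' @return gradient vector, or matrix of gradients in rows.
#' @export
setGeneric("potentialGradient",
           function(object, x) standardGeneric("potentialGradient"))

#' Saupe matrix accessor
#' @param x an \code{AlignmentTensor}.
#' @return 3x3 numeric matrix.
#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))

#' @rdname saupeMatrix
#' @export
setMethod("saupeMatrix", "AlignmentTensor", function(x) x@S)

#' Number of hills in a bias potential
#' @param x a \code{BiasPotential}.
#' @return integer.
#' @export
setGeneric("nHills", function(x) standardGeneric("nHills"))

#' @rdname nHills
#' @export
setMethod("nHills", "BiasPotential", function(x) nrow(x@centers))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure", sQuote(object@id), "with", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble", sQuote(object@id), "with", nFrames(object), "frames x",
      nrow(object@atoms), "atoms;",
      if (length(object@weights)) "weighted" else "uniform weights", "\n")
})

setMethod("show", "BiasPotential", function(object) {
  cat("BiasPotential on", paste(object@cvNames, collapse = ", "), "with",
      nHills(object), "hills (sigma =",
      paste(signif(object@sigma, 3), collapse = ", "),
      ", stride =", object@stride, ")\n")
})

setMethod("show", "ToyPotential", function(object) {
  cat(sprintf("ToyPotential [%dD] %s: %d wells, depths %s kJ/mol\n",
              object@dimension, object@descriptor, nrow(object@centers),
              paste(signif(object@depths, 3), collapse = "/")))
})

setMethod("show", "MicrostateTable", function(object) {
  cat("MicrostateTable:", nrow(object@centers), "occupied bins in",
      ncol(object@centers), "CV dimension(s);",
      ncol(object@counts), "replica(s), ", sum(object@counts),
      "frames total\n")
})

setMethod("show", "FreeEnergyTable", function(object) {
  cat(sprintf(
    "FreeEnergyTable: %d microstates at T = %g K (WHAM, %d iterations, residual %.2e)\n",
    length(object@F), object@temperature, object@iterations,
    object@residual))
})

setMethod("show", "FESGrid", function(object) {
  dims <- vapply(object@axes, function(a) length(a$edges) - 1L, integer(1))
  cat("FESGrid:", paste(dims, collapse = " x "), "cells on",
      paste(vapply(object@axes, `[[`, "", "name"), collapse = " x "),
      sprintf("; %d visited\n", sum(is.finite(object@F))))
})

setMethod("show", "AlignmentTensor", function(object) {
  ev <- eigen(object@S, symmetric = TRUE)$values
  cat("AlignmentTensor: eigenvalues",
      paste(signif(sort(ev), 4), collapse = ", "), "\n")
})

setMethod("show", "ObservableTable", function(object) {
  cat("ObservableTable:", nrow(object@entries), "observables (",
      paste(unique(object@entries$atomType), collapse = ", "), ") from",
      object@provenance, "\n")
})

setMethod("show", "BemetaLog", function(object) {
  cat("BemetaLog:", length(object@cvTraj), "replica(s),",
      sum(vapply(object@hills, nHills, integer(1))), "hills,",
      nrow(object@exchanges), "exchange attempts\n")
})
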