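#' @include AllClasses.R
NULL

#' Build an observable table
#' @param resno integer residue numbers.
#' @param atomType character atom types (e.g. "HA", "HN", "N", "CA", "CB",
#'   "C").
#' @param value numeric observed values, ppm.
#' @param provenance free-text source tag.
#' @return an \code{\link{ObservableTable}}.
#' @export
observableTable <- function(resno, atomType, value, provenance = "user") {
  new("ObservableTable",
      entries = data.frame(resno = as.integer(resno),
                           atomType = as.character(atomType),
                           value = as.numeric(value)),
      provenance = provenance)
}

#' Read a chemical-shift table from TSV
#'
#' Expected columns: residue_number, residue_name, atom_type, shift_ppm
#' (header required; extra columns ignored). NMR-STAR-style exports that
#' contain these columns under the names Seq_ID / Atom_ID / Val are also
#' accepted.
#'
#' @param path TSV file.
#' @return an \code{\link{ObservableTable}}.
#' @export
readShiftTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    stop("shift table lacks a column named one of: ",
         paste(c(...), collapse = ", "))
  }
  observableTable(pick("residue_number", "Seq_ID"),
                  pick("atom_type", "Atom_ID"),
                  pick("shift_ppm", "Val"),
                  provenance = path)
}

#' Flat-bottom harmonic penalty form
#'
#' Per-entry energy E(delta) = 0 for |delta| <= eps, k (|delta| - eps)^2
#' beyond, optionally capped. Default tolerances follow common
#' chemical-shift restraint practice: 0.3 ppm for proton types, 1.0 ppm
#' for nitrogen/carbon.
#'
#' @param k force constant, kJ/mol/ppm^2.
#' @param eps named per-atom-type tolerances (ppm), or a single number.
#' @param cap optional per-term energy cap, kJ/mol.
#' @return a \code{\link{PenaltyForm}}.
#' @export
flatBottomPenalty <- function(k = 2,
                              eps = c(HA = 0.3, HN = 0.3, N = 1.0,
                                      CA = 1.0, CB = 1.0, C = 1.0),
                              cap = Inf) {
  new("PenaltyForm", k = k, eps = eps, cap = cap)
}

.epsFor <- function(penalty, atomType) {
  eps <- penalty@eps
  if (is.null(names(eps)) || length(eps) == 1)
    return(rep(eps[[1]], length(atomType)))
  out <- unname(eps[atomType])
  out[is.na(out)] <- min(eps)  # unknown types: strictest tolerance
  out
}

#' Average predicted observables over replicas
#'
#' @param predictions numeric matrix, one row per replica, or a list of
#'   equal-length vectors.
#' @return arithmetic mean per observable.
#' @export
replicaAverage <- function(predictions) {
  if (is.list(predictions)) {
    len <- unique(lengths(predictions))
    if (length(len) != 1) stop("replica prediction length mismatch")
    predictions <- do.call(rbind, predictions)
  }
  colMeans(predictions)
}

#' Replica-averaged restraint energy
#'
#' The chemical-shift restraint energy: a sum over table entries of a
#' flat-bottom harmonic penalty on the deviation of the replica-averaged
#' calculated value from the experimental one,
#' E = sum_ij E_ij(delta_calc_avg - delta_exp). Zero iff every deviation
#' is inside its tolerance; always >= 0.
#'
#' @param delta_calc_avg numeric vector aligned with the table entries
#'   (the replica-averaged predictions).
#' @param table an \code{\link{ObservableTable}}.
#' @param penalty a \code{\link{PenaltyForm}}.
#' @return energy in kJ/mol.
#' @export
restraintEnergy <- function(delta_calc_avg, table, penalty = flatBottomPenalty()) {
  e <- table@entries
  if (length(delta_calc_avg) != nrow(e))
    stop("prediction vector not aligned with observable table (",
         length(delta_calc_avg), " vs ", nrow(e), ")")
  dev <- abs(delta_calc_avg - e$value)
  eps <- .epsFor(penalty, e$atomType)
  excess <- pmax(dev - eps, 0)
  sum(pmin(penalty@k * excess^2, penalty@cap))
}

# dE/d(delta_avg): 2 k sign(delta) (|delta| - eps)_+ with cap plateau
.penaltyGrad <- function(delta_calc_avg, table, penalty) {
  e <- table@entries
  diffv <- delta_calc_avg - e$value
  eps <- .epsFor(penalty, e$atomType)
  excess <- pmax(abs(diffv) - eps, 0)
  g <- 2 * penalty@k * excess * sign(diffv)
  capped <- penalty@k * excess^2 >= penalty@cap
  g[capped] <- 0
  g
}

#' Linear forward model delta = A x + b
#'
#' @param A numeric matrix (n_obs x d) mapping coordinates to observables.
#' @param b numeric intercepts.
#' @param descriptor free text.
#' @return a \code{\link{LinearShiftModel}}.
#' @export
linearShiftModel <- function(A, b = rep(0, nrow(A)),
                             descriptor = "linear toy shift model") {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1)
  new("LinearShiftModel", A = A, b = b, descriptor = descriptor)
}

#' Predict observables with a forward model
#' @param model a \code{\link{LinearShiftModel}} or a function(x) ->
#'   numeric vector.
#' @param x coordinate vector of one replica.
#' @return numeric predictions aligned with the observable table.
#' @export
predictObservables <- function(model, x) {
  if (is.function(model)) return(model(x))
  drop(model@A %*% x) + model@b
}

#' Restraint force on one replica
#'
#' Negative gradient of the replica-averaged restraint energy with respect
#' to the coordinates of replica \code{replica_index}. The chain rule
#' through the average gives each replica 1/n_replicas of the sensitivity,
#' so adding identical replicas halves the per-replica force while the
#' total restraint on the average is unchanged. For a
#' \code{LinearShiftModel} the gradient is analytic; for a plain function
#' model a central finite difference is used.
#'
#' @param replica_index which replica the force acts on.
#' @param configurations list (or matrix rows) of per-replica coordinate
#'   vectors.
#' @param table an \code{\link{ObservableTable}}.
#' @param penalty a \code{\link{PenaltyForm}}.
#' @param model forward model (see \code{\link{predictObservables}}).
#' @param h finite-difference step for function models.
#' @return numeric force vector (same length as the replica coordinates).
#' @export
restraintForce <- function(replica_index, configurations, table,
                           penalty = flatBottomPenalty(), model, h = 1e-6) {
  if (is.matrix(configurations))
    configurations <- lapply(seq_len(nrow(configurations)),
                             function(i) configurations[i, ])
  nrep <- length(configurations)
  preds <- lapply(configurations, function(x) predictObservables(model, x))
  avg <- replicaAverage(preds)
  gE <- .penaltyGrad(avg, table, penalty)  # dE/d(avg)
  x <- configurations[[replica_index]]
  if (is(model, "LinearShiftModel")) {
    force <- -drop(crossprod(model@A, gE)) / nrep
  } else {
    force <- vapply(seq_along(x), function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      dpred <- (predictObservables(model, xp) -
                predictObservables(model, xm)) / (2 * h)
      -sum(gE * dpred) / nrep
    }, numeric(1))
  }
  if (!all(is.finite(force)))
    stop("non-finite restraint force (entries ",
         paste(which(!is.finite(force)), collapse = ","), ")")
  force
}
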