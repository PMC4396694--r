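#' @include pdb-io.R geometry.R
NULL

#' Read an RDC table from TSV
#'
#' Columns: residue_number, atom1, atom2, D_obs_Hz, and optionally
#' segment.
#'
#' @param path TSV file with header.
#' @return data.frame(resno, atom1, atom2, D_obs, segment).
#' @export
readRDCTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(resno = as.integer(df$residue_number),
                    atom1 = df$atom1, atom2 = df$atom2,
                    D_obs = as.numeric(df$D_obs_Hz),
                    segment = if ("segment" %in% names(df)) df$segment
                              else NA_character_)
  if (anyDuplicated(paste(out$resno, out$atom1, out$atom2)))
    stop("duplicate (residue, atom pair) records")
  if (!all(is.finite(out$D_obs))) stop("non-finite D_obs")
  out
}

#' Construct an amide hydrogen at ideal geometry
#'
#' Places H 1.02 Angstrom from the backbone N along the in-plane bisector
#' opposite the C(i-1)-N-CA angle, the standard construction when crystal
#' structures lack amide protons.
#'
#' @param structure a \code{Structure}.
#' @param chain,resno the residue to protonate.
#' @return numeric 3-vector: the H position, or NULL when the flanking
#'   atoms are missing.
#' @export
constructAmideH <- function(structure, chain, resno) {
  at <- atomTable(structure)
  iN <- .atomIndex(at, chain, resno, "N")
  iCA <- .atomIndex(at, chain, resno, "CA")
  resnos <- unique(at$resno[at$chain == chain])
  prev <- resnos[match(resno, resnos) - 1]
  iC <- if (length(prev) && !is.na(prev)) .atomIndex(at, chain, prev, "C")
        else NA_integer_
  if (anyNA(c(iN, iCA, iC))) return(NULL)
  N <- .atomXYZ(at, iN); CA <- .atomXYZ(at, iCA); C <- .atomXYZ(at, iC)
  u1 <- (C - N) / sqrt(sum((C - N)^2))
  u2 <- (CA - N) / sqrt(sum((CA - N)^2))
  bis <- -(u1 + u2)
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-9) return(NULL)
  N + 1.02 * bis / nb
}

#' N-H (or general) bond unit vectors for RDC records
#'
#' For each record, the unit vector from atom1 to atom2 of that residue.
#' Missing amide hydrogens are constructed at ideal geometry when
#' \code{buildH} is TRUE; records whose atoms cannot be resolved are
#' skipped with a warning.
#'
#' @param structure a \code{Structure}.
#' @param records RDC data.frame (see \code{\link{readRDCTable}}).
#' @param chain chain identifier.
#' @param buildH construct missing amide H atoms (default TRUE).
#' @return list(vectors = n x 3 unit matrix, used = logical per record).
#' @export
bondUnitVectors <- function(structure, records, chain = "A",
                            buildH = TRUE) {
  at <- atomTable(structure)
  n <- nrow(records)
  vec <- matrix(NA_real_, n, 3)
  used <- rep(FALSE, n)
  skipped <- integer(0)
  for (k in seq_len(n)) {
    r <- records$resno[k]
    i1 <- .atomIndex(at, chain, r, records$atom1[k])
    p1 <- if (!is.na(i1)) .atomXYZ(at, i1) else NULL
    i2 <- .atomIndex(at, chain, r, records$atom2[k])
    p2 <- if (!is.na(i2)) .atomXYZ(at, i2) else
      if (buildH && records$atom2[k] %in% c("H", "HN"))
        constructAmideH(structure, chain, r) else NULL
    if (is.null(p1) || is.null(p2)) {
      skipped <- c(skipped, k)
      next
    }
    v <- p2 - p1
    vec[k, ] <- v / sqrt(sum(v^2))
    used[k] <- TRUE
  }
  if (length(skipped))
    warning("skipped RDC records with unresolvable atoms: residues ",
            paste(records$resno[skipped], collapse = ", "))
  list(vectors = vec, used = used)
}

# N x 5 design matrix of direction cosines for the traceless symmetric
# Saupe parameterisation (Syy, Szz, Sxy, Sxz, Syz), with
# Sxx = -Syy - Szz absorbed
.rdcDesign <- function(vectors) {
  cx <- vectors[, 1]; cy <- vectors[, 2]; cz <- vectors[, 3]
  cbind(cy^2 - cx^2, cz^2 - cx^2, 2 * cx * cy, 2 * cx * cz, 2 * cy * cz)
}

.saupeFromParams <- function(p) {
  S <- matrix(c(-p[1] - p[2], p[3], p[4],
                p[3], p[1], p[5],
                p[4], p[5], p[2]), 3, 3)
  new("AlignmentTensor", S = S)
}

#' Fit a Saupe alignment tensor by singular value decomposition
#'
#' Least-squares solution of D = D_max sum_kl S_kl c_k c_l over the five
#' independent components of the traceless symmetric order matrix, via the
#' standard N x 5 direction-cosine design matrix and its SVD
#' pseudo-inverse. At least five records with non-degenerate orientations
#' are required.
#'
#' @param vectors n x 3 matrix of unit bond vectors.
#' @param D_obs numeric observed couplings, Hz.
#' @param D_max overall dipolar scale (default 1: the scale is absorbed
#'   into S, making the fit scale-invariant).
#' @param condLimit condition-number limit for a usable fit.
#' @return an \code{\link{AlignmentTensor}}.
#' @export
fitAlignmentTensorSVD <- function(vectors, D_obs, D_max = 1,
                                  condLimit = 1e8) {
  if (nrow(vectors) != length(D_obs)) stop("vectors/D_obs length mismatch")
  if (nrow(vectors) < 5)
    stop("degenerate fit: need >= 5 RDC records, got ", nrow(vectors))
  A <- .rdcDesign(vectors) * D_max
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[5]
  if (!is.finite(cond) || cond > condLimit)
    stop(sprintf("degenerate fit: design matrix condition number %.3g",
                 cond))
  p <- sv$v %*% (crossprod(sv$u, D_obs) / sv$d)
  .saupeFromParams(drop(p))
}

#' Back-calculate RDCs from an alignment tensor
#'
#' D_calc = D_max sum_kl S_kl c_k c_l per bond vector.
#'
#' @param tensor an \code{\link{AlignmentTensor}}.
#' @param vectors n x 3 matrix of unit bond vectors.
#' @param D_max overall dipolar scale.
#' @return numeric couplings, Hz.
#' @export
backcalcRDC <- function(tensor, vectors, D_max = 1) {
  S <- saupeMatrix(tensor)
  D_max * rowSums((vectors %*% S) * vectors)
}

#' RDC quality factor
#'
#' Q = sqrt(sum (D_calc - D_obs)^2 / sum D_obs^2): the normalised rms
#' discrepancy between observed and back-calculated couplings (lower is
#' better; 0 for perfect agreement, 1 for D_calc = 0). Invariant under a
#' common rescaling of both vectors.
#'
#' @param D_obs,D_calc aligned numeric vectors, Hz.
#' @return dimensionless Q.
#' @export
qFactor <- function(D_obs, D_calc) {
  if (!length(D_obs) || length(D_obs) != length(D_calc))
    stop("D_obs and D_calc must be aligned, non-empty")
  denom <- sum(D_obs^2)
  if (denom == 0) stop("undefined Q: all observed couplings are zero")
  sqrt(sum((D_calc - D_obs)^2) / denom)
}

#' Axial component and rhombicity of an alignment tensor
#' @param tensor an \code{\link{AlignmentTensor}}.
#' @return list(Da, rhombicity, eigenvalues, principalAxes).
#' @export
tensorAnisotropy <- function(tensor) {
  e <- eigen(saupeMatrix(tensor), symmetric = TRUE)
  ord <- order(abs(e$values))  # |Sxx'| <= |Syy'| <= |Szz'|
  ev <- e$values[ord]
  Da <- ev[3] / 2
  Rh <- (ev[1] - ev[2]) / (1.5 * ev[3])
  list(Da = Da, rhombicity = Rh, eigenvalues = ev,
       principalAxes = e$vectors[, ord])
}

#' Ensemble RDC validation: tensor fit, back-calculation and Q factors
#'
#' The tensor is fitted on a subset of records (typically the rigid
#' beta-strand core); couplings of the remaining records are
#' back-calculated and scored. Two ensemble modes: "per_frame_tensor"
#' fits one tensor per frame, back-calculates per frame and averages
#' D_calc over frames with the frame weights before scoring (the standard
#' practice for ensemble RDC validation); "single_tensor" fits one tensor
#' to the weighted-average direction-cosine products. Per-segment Q
#' factors restrict the sums to each segment label.
#'
#' @param ensemble an \code{\link{Ensemble}} (a \code{Structure} is
#'   treated as one frame).
#' @param records RDC data.frame (resno, atom1, atom2, D_obs, segment).
#' @param fitSelection logical or integer index of records used for the
#'   tensor fit (e.g. beta-strand residues).
#' @param mode "per_frame_tensor" or "single_tensor".
#' @param chain chain identifier.
#' @param includeFitInQ score fit records too (default FALSE: Q is
#'   computed on held-out records only).
#' @param D_max overall dipolar scale.
#' @return list(Q, Qsegments, D_calc, tensor(s), fitRecords,
#'   scoredRecords).
#' @export
ensembleQ <- function(ensemble, records, fitSelection,
                      mode = c("per_frame_tensor", "single_tensor"),
                      chain = "A", includeFitInQ = FALSE, D_max = 1) {
  mode <- match.arg(mode)
  if (is(ensemble, "Structure")) ensemble <- asEnsemble(ensemble)
  nfr <- nFrames(ensemble)
  w <- frameWeights(ensemble)
  n <- nrow(records)
  fit <- rep(FALSE, n)
  fit[fitSelection] <- TRUE

  vecs <- vector("list", nfr)
  usedAll <- rep(TRUE, n)
  for (f in seq_len(nfr)) {
    bv <- bondUnitVectors(getFrame(ensemble, f), records, chain)
    vecs[[f]] <- bv$vectors
    usedAll <- usedAll & bv$used
  }
  if (!any(usedAll & fit)) stop("no usable fit records")

  if (mode == "per_frame_tensor") {
    Dmat <- matrix(NA_real_, nfr, n)
    tensors <- vector("list", nfr)
    for (f in seq_len(nfr)) {
      tensors[[f]] <- fitAlignmentTensorSVD(
        vecs[[f]][usedAll & fit, , drop = FALSE],
        records$D_obs[usedAll & fit], D_max)
      Dmat[f, usedAll] <- backcalcRDC(tensors[[f]],
                                      vecs[[f]][usedAll, , drop = FALSE],
                                      D_max)
    }
    D_calc <- colSums(Dmat * w)
  } else {
    # weighted-average direction-cosine products enter the design matrix
    Abar <- matrix(0, n, 5)
    for (f in seq_len(nfr))
      Abar <- Abar + w[f] * .rdcDesign(vecs[[f]])
    sv <- svd(Abar[usedAll & fit, , drop = FALSE] * D_max)
    if (sv$d[5] <= 0 || sv$d[1] / sv$d[5] > 1e8)
      stop("degenerate single-tensor fit")
    p <- drop(sv$v %*% (crossprod(sv$u, records$D_obs[usedAll & fit]) /
                          sv$d))
    tensors <- .saupeFromParams(p)
    D_calc <- rep(NA_real_, n)
    D_calc[usedAll] <- D_max * (Abar[usedAll, , drop = FALSE] %*% p)
  }

  score <- usedAll & (includeFitInQ | !fit)
  if (!any(score)) stop("no records left to score")
  Q <- qFactor(records$D_obs[score], D_calc[score])
  segs <- unique(stats::na.omit(records$segment))
  Qseg <- list()
  for (sg in segs) {
    sel <- score & records$segment %in% sg
    if (!any(sel)) {
      warning("segment ", sg, " contains no scored records; no Q computed")
      next
    }
    Qseg[[sg]] <- qFactor(records$D_obs[sel], D_calc[sel])
  }
  list(Q = Q, Qsegments = unlist(Qseg), D_calc = D_calc,
       tensor = tensors, fitRecords = which(fit & usedAll),
       scoredRecords = which(score))
}
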