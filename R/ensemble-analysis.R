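#' @include rdc.R
NULL

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between donor
# amide (N, H) and acceptor carbonyl (C, O); bond if E < -0.5 kcal/mol.
.ksEnergy <- function(N, H, C, O) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N)) * 332
}

# backbone geometry per residue of one chain: N, CA, C, O coordinates and
# constructed amide H
.backboneFrame <- function(structure, chain) {
  at <- atomTable(structure)
  het <- if (is.null(at$hetatm)) rep(FALSE, nrow(at)) else at$hetatm
  resnos <- unique(at$resno[at$chain == chain & !het])
  get <- function(r, nm) {
    i <- .atomIndex(at, chain, r, nm)
    if (is.na(i)) NULL else .atomXYZ(at, i)
  }
  res <- lapply(seq_along(resnos), function(k) {
    r <- resnos[k]
    H <- get(r, "H")
    if (is.null(H)) H <- constructAmideH(structure, chain, r)
    list(resno = r, N = get(r, "N"), CA = get(r, "CA"), C = get(r, "C"),
         O = get(r, "O"), H = H,
         pro = any(at$chain == chain & at$resno == r & at$resname == "PRO"))
  })
  res
}

#' Assign secondary structure (simplified Kabsch-Sander)
#'
#' A compact reimplementation of the DSSP assignment: backbone H-bonds by
#' the Kabsch-Sander electrostatic energy (bond if E < -0.5 kcal/mol,
#' amide H constructed at ideal geometry when absent), alpha-helix (H)
#' from consecutive i -> i+4 turns, 3-10 helix (G) from consecutive
#' i -> i+3 turns, strand (E) from parallel/antiparallel bridge patterns.
#' Residues left unassigned are labelled P when their (phi, psi) falls in
#' the polyproline-II window (phi in [-110, -50], psi in [120, 180]
#' degrees; an approximation, PPII is not an H-bond class), else C.
#' Residues with incomplete backbones are labelled C with a warning.
#'
#' @param structure a \code{Structure}.
#' @param chain chain identifier.
#' @return data.frame(resno, label) with label in H, G, E, P, C.
#' @export
assignSecondaryStructure <- function(structure, chain = "A") {
  bb <- .backboneFrame(structure, chain)
  n <- length(bb)
  resnos <- vapply(bb, `[[`, numeric(1), "resno")
  complete <- vapply(bb, function(b)
    !is.null(b$N) && !is.null(b$CA) && !is.null(b$C) && !is.null(b$O),
    logical(1))
  if (any(!complete))
    warning("residues with incomplete backbone labelled C: ",
            paste(resnos[!complete], collapse = ", "))

  # hb[i, j]: N-H of residue i donates to C=O of residue j
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    bi <- bb[[i]]
    if (is.null(bi$N) || is.null(bi$H) || bi$pro) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      bj <- bb[[j]]
      if (!complete[j]) next
      if (sum((bi$N - bj$O)^2) > 49) next  # 7 A screen
      hb[i, j] <- .ksEnergy(bi$N, bi$H, bj$C, bj$O) < -0.5
    }
  }

  turn <- function(nlen) {
    v <- rep(FALSE, n)
    idx <- seq_len(n - nlen)
    v[idx] <- hb[cbind(idx + nlen, idx)]
    v
  }
  t4 <- turn(4); t3 <- turn(3)
  lab <- rep(NA_character_, n)

  for (i in 2:max(n - 4, 2))
    if (i >= 2 && i + 3 <= n && t4[i - 1] && t4[i])
      lab[i:(i + 3)] <- "H"

  # bridges
  isE <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    par <- (i > 1 && i < n && hb[j, i - 1] && hb[i + 1, j]) ||
           (j > 1 && j < n && hb[i, j - 1] && hb[j + 1, i])
    anti <- (hb[i, j] && hb[j, i]) ||
            (i > 1 && j < n && i + 1 <= n && j - 1 >= 1 &&
             hb[j + 1, i - 1] && hb[i + 1, j - 1])
    if (par || anti) isE[c(i, j)] <- TRUE
  }
  lab[isE & is.na(lab)] <- "E"

  for (i in 2:max(n - 3, 2))
    if (i >= 2 && i + 2 <= n && t3[i - 1] && t3[i] &&
        all(is.na(lab[i:(i + 2)])))
      lab[i:(i + 2)] <- "G"

  # PPII window on otherwise-unassigned residues
  dih <- suppressWarnings(
    enumerateBackboneDihedrals(structure, chain, compute = TRUE))
  for (i in which(is.na(lab))) {
    r <- resnos[i]
    phi <- dih$value[dih$resno == r & dih$label == "phi"] * 180 / pi
    psi <- dih$value[dih$resno == r & dih$label == "psi"] * 180 / pi
    if (length(phi) == 1 && length(psi) == 1 &&
        phi >= -110 && phi <= -50 && psi >= 120 && psi <= 180)
      lab[i] <- "P"
  }
  lab[is.na(lab)] <- "C"
  lab[!complete] <- "C"
  data.frame(resno = resnos, label = lab)
}

#' Per-residue secondary-structure populations of an ensemble
#'
#' Weighted fraction of frames in each class (H, G, E, P, C) per residue;
#' fractions sum to 1 for every residue.
#'
#' @param ensemble an \code{\link{Ensemble}}.
#' @param chain chain identifier.
#' @return data.frame(resno, H, G, E, P, C).
#' @export
secondaryStructurePopulations <- function(ensemble, chain = "A") {
  w <- frameWeights(ensemble)
  classes <- c("H", "G", "E", "P", "C")
  acc <- NULL
  for (f in seq_len(nFrames(ensemble))) {
    ss <- assignSecondaryStructure(getFrame(ensemble, f), chain)
    m <- outer(ss$label, classes, "==") * w[f]
    if (is.null(acc)) {
      acc <- m
      resnos <- ss$resno
    } else {
      if (!identical(ss$resno, resnos))
        stop("frames disagree on residue set")
      acc <- acc + m
    }
  }
  out <- data.frame(resno = resnos)
  acc <- acc / rowSums(acc)
  for (k in seq_along(classes)) out[[classes[k]]] <- acc[, k]
  out
}

#' RMS deviation between two secondary-structure population profiles
#'
#' sqrt(mean over residues of (fraction_a - fraction_b)^2) for one class.
#'
#' @param pops_a,pops_b data.frames from
#'   \code{\link{secondaryStructurePopulations}} (or any with resno +
#'   class columns) over the same residues.
#' @param ss_class class column to compare (e.g. "H", "E").
#' @return dimensionless rmsd.
#' @export
populationRMSD <- function(pops_a, pops_b, ss_class) {
  if (!identical(pops_a$resno, pops_b$resno))
    stop("population tables cover different residues")
  if (!ss_class %in% names(pops_a) || !ss_class %in% names(pops_b))
    stop("unknown class ", ss_class)
  sqrt(mean((pops_a[[ss_class]] - pops_b[[ss_class]])^2))
}

#' Distance distribution over an ensemble
#'
#' Per-frame distance between two uniquely selected atoms with a weighted
#' histogram and weighted mean/sd.
#'
#' @param ensemble an \code{\link{Ensemble}}.
#' @param atom_a,atom_b single-atom selections (strings like
#'   "A:292:CZ" or \code{ResidueSelection}s).
#' @param breaks histogram bin edges (default: 30 bins over the range).
#' @return list(values, mean, sd, histogram = data.frame(lower, upper,
#'   weight)).
#' @export
distanceDistribution <- function(ensemble, atom_a, atom_b, breaks = NULL) {
  w <- frameWeights(ensemble)
  vals <- vapply(seq_len(nFrames(ensemble)), function(f)
    atomDistance(getFrame(ensemble, f), atom_a, atom_b), numeric(1))
  m <- sum(w * vals)
  s <- sqrt(max(sum(w * (vals - m)^2), 0))
  if (is.null(breaks))
    breaks <- seq(min(vals), max(vals) + 1e-9, length.out = 31)
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE)
  hw <- vapply(seq_len(length(breaks) - 1), function(b)
    sum(w[bin == b]), numeric(1))
  list(values = vals, mean = m, sd = s,
       histogram = data.frame(lower = head(breaks, -1),
                              upper = tail(breaks, -1), weight = hw))
}

#' Detect a salt bridge between an acidic and a basic side chain
#'
#' TRUE iff the minimum distance over carboxylate-O / basic-N atom pairs
#' is below the cutoff. Glu uses OE1/OE2, Asp OD1/OD2; Lys uses NZ, Arg
#' NE/NH1/NH2, His ND1/NE2. Missing side-chain atoms give an
#' indeterminate (NA) result, never FALSE.
#'
#' @param structure a \code{Structure}.
#' @param acidic,basic c(chain, resno) of the two residues.
#' @param cutoff Angstrom (default 4.0).
#' @return list(formed (TRUE/FALSE/NA), minDistance).
#' @export
detectSaltBridge <- function(structure, acidic, basic, cutoff = 4.0) {
  at <- atomTable(structure)
  sideAtoms <- function(spec, names) {
    idx <- which(at$chain == spec[1] & at$resno == as.integer(spec[2]) &
                 at$name %in% names)
    idx
  }
  rn <- function(spec) unique(at$resname[at$chain == spec[1] &
                                         at$resno == as.integer(spec[2])])
  aNames <- switch(rn(acidic)[1], GLU = c("OE1", "OE2"),
                   ASP = c("OD1", "OD2"), c("OE1", "OE2", "OD1", "OD2"))
  bNames <- switch(rn(basic)[1], LYS = "NZ",
                   ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"), "NZ")
  ia <- sideAtoms(acidic, aNames)
  ib <- sideAtoms(basic, bNames)
  if (!length(ia) || !length(ib)) {
    warning("missing side-chain atoms; salt bridge indeterminate")
    return(list(formed = NA, minDistance = NA_real_))
  }
  dmin <- min(outer(ia, ib, Vectorize(function(i, j)
    sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
         (at$z[i] - at$z[j])^2))))
  list(formed = dmin < cutoff, minDistance = dmin)
}

#' Classify conformational substates from theta and the ratchet distance
#'
#' Decision rule for the three I-domain-like substates: a frame is
#' IA-like when the aromatic side chain is displaced from the ratchet
#' pocket (d >= d_IA_min, default 10 Angstrom, the midpoint between the
#' buried ~8 A and displaced ~11.8 A means); otherwise LA-like when the
#' helix angle theta is below \code{theta_split}, else AI-like.
#'
#' @param theta numeric helix-orientation angle(s), degrees.
#' @param d numeric ratchet distance(s), Angstrom.
#' @param theta_split LA/AI split angle, degrees (no universal default:
#'   calibrate on the system at hand).
#' @param d_IA_min IA displacement threshold, Angstrom.
#' @return character vector in "LA_like", "AI_like", "IA_like".
#' @export
classifyState <- function(theta, d, theta_split, d_IA_min = 10.0) {
  stopifnot(length(theta) == length(d))
  ifelse(d >= d_IA_min, "IA_like",
         ifelse(theta < theta_split, "LA_like", "AI_like"))
}
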