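#' @include metadynamics.R rdc.R
NULL

#' Basin free energies of a toy potential by numerical quadrature
#'
#' Partitions the confined domain into basins by nearest well centre and
#' integrates exp(-U/RT) on a fine grid (trapezoid rule; 1D or 2D).
#' Returns free-energy offsets gauged to the deepest basin.
#'
#' @param potential a \code{\link{ToyPotential}}.
#' @param temperature Kelvin.
#' @param ngrid grid points per dimension.
#' @return numeric deltaG per well, kJ/mol, min 0.
#' @export
quadratureBasinDeltaG <- function(potential, temperature = 300,
                                  ngrid = 2001) {
  kT <- .R_GAS * temperature
  d <- potential@dimension
  lo <- potential@wallCenter - potential@wallScale * 1.3
  hi <- potential@wallCenter + potential@wallScale * 1.3
  if (d == 1) {
    x <- seq(lo, hi, length.out = ngrid)
    w <- exp(-potentialEnergy(potential, matrix(x, ncol = 1)) / kT)
    basin <- apply(abs(outer(x, potential@centers[, 1], "-")), 1,
                   which.min)
    Z <- tapply(w, basin, sum)  # common dx cancels in ratios
  } else {
    ng <- min(ngrid, 401)
    x <- seq(lo[1], hi[1], length.out = ng)
    y <- seq(lo[2], hi[2], length.out = ng)
    pts <- as.matrix(expand.grid(x = x, y = y))
    w <- exp(-potentialEnergy(potential, pts) / kT)
    d2 <- vapply(seq_len(nrow(potential@centers)), function(k)
      rowSums((pts - matrix(potential@centers[k, ], nrow(pts), 2,
                            byrow = TRUE))^2), numeric(nrow(pts)))
    basin <- max.col(-d2)
    Z <- tapply(w, basin, sum)
  }
  Zfull <- numeric(nrow(potential@centers))
  Zfull[as.integer(names(Z))] <- as.numeric(Z)
  Fk <- -kT * log(Zfull)
  Fk - min(Fk)
}

#' Construct a calibrated multi-basin toy potential
#'
#' Builds a smooth analytic potential (inverted Gaussians on a steep
#' confining wall) whose basin free energies at the stated temperature,
#' computed by numerical quadrature, match the requested offsets within
#' \code{tol}. Well depths are calibrated by fixed-point iteration on the
#' quadrature free energies; construction fails loudly when the tolerance
#' cannot be reached.
#'
#' @param deltaG target basin free-energy offsets, kJ/mol (one 0; default
#'   the three-substate values 0, 0.7, 2.8).
#' @param barrier approximate barrier height above the deepest minimum,
#'   kJ/mol (> max(deltaG)).
#' @param centers well centres: numeric vector (1D) or matrix (2D).
#' @param widths well widths (recycled).
#' @param temperature calibration temperature, K.
#' @param tol calibration tolerance, kJ/mol (default 0.01; the
#'   constructor contract is 0.05).
#' @param maxIter calibration iterations.
#' @return a \code{\link{ToyPotential}} with attribute
#'   \code{"calibratedDeltaG"}.
#' @examples
#' pot <- makeTripleWell()
#' attr(pot, "calibratedDeltaG")  # ~ 0, 0.7, 2.8
#' @export
makeTripleWell <- function(deltaG = c(0, 0.7, 2.8), barrier = 6,
                           centers = seq(-2, 2,
                                         length.out = length(deltaG)),
                           widths = 0.35, temperature = 300, tol = 0.01,
                           maxIter = 100) {
  if (min(deltaG) != 0) stop("one basin must have deltaG = 0")
  if (any(deltaG < 0)) stop("deltaG must be >= 0")
  if (barrier <= max(deltaG)) stop("barrier must exceed max(deltaG)")
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = 1)
  d <- ncol(centers)
  nw <- nrow(centers)
  if (length(deltaG) != nw) stop("one deltaG per well required")
  widths <- rep(widths, length.out = nw)
  span <- apply(centers, 2, function(cc) diff(range(cc)))
  wallCenter <- colMeans(centers)
  wallScale <- max(span) / 2 + 2 * max(widths)
  depths <- barrier + max(deltaG) - deltaG
  pot <- NULL
  for (it in seq_len(maxIter)) {
    pot <- new("ToyPotential", dimension = as.integer(d), depths = depths,
               centers = centers, widths = widths, wallCenter = wallCenter,
               wallScale = wallScale, wallPower = 8, wallHeight = 60,
               descriptor = sprintf("%d-well calibrated potential", nw))
    cur <- quadratureBasinDeltaG(pot, temperature)
    err <- cur - deltaG
    if (max(abs(err)) < tol) {
      attr(pot, "calibratedDeltaG") <- cur
      return(pot)
    }
    depths <- depths + err - err[which.min(deltaG)]
    # keep every well substantial relative to the confining plateau: a
    # uniform depth shift preserves the targets while restoring reach
    if (min(depths) < barrier / 2)
      depths <- depths + (barrier / 2 - min(depths))
  }
  stop(sprintf(
    "calibration did not reach %.3g kJ/mol in %d iterations (residual %.3g)",
    tol, maxIter, max(abs(err))))
}

# NeRF atom placement: position D given A-B-C, bond length r (C-D), bond
# angle theta (B-C-D, radians) and dihedral phi (A-B-C-D, radians)
.placeAtom <- function(A, B, C, r, theta, phi) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  C + r * (-cos(theta) * bc + sin(theta) * cos(phi) * m +
             sin(theta) * sin(phi) * n)
}

.BB <- list(rNCA = 1.458, rCAC = 1.525, rCN = 1.329, rCO = 1.231,
            aNCAC = 111.2 * pi / 180, aCACN = 116.2 * pi / 180,
            aCNCA = 121.7 * pi / 180, aCACO = 120.8 * pi / 180)

# build a poly-Ala backbone (N, CA, C, O) from per-residue (phi, psi)
.buildBackbone <- function(phi, psi, chain = "A", firstResno = 1L,
                           resnames = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  g <- .BB
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$rNCA, 0, 0)
  C[1, ] <- .placeAtom(c(0, 1, 0), N[1, ], CA[1, ], g$rCAC, g$aNCAC, pi / 3)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$rCN, g$aCACN,
                               psi[i])
      CA[i + 1, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1, ], g$rNCA,
                                g$aCNCA, pi)  # trans omega
      C[i + 1, ] <- .placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ], g$rCAC,
                               g$aNCAC, phi[i + 1])
      O[i, ] <- .placeAtom(N[i + 1, ], CA[i, ], C[i, ], g$rCO, g$aCACO, pi)
    } else {
      O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$rCO, g$aCACO,
                           psi[i] + pi)
    }
  }
  if (is.null(resnames)) resnames <- rep("ALA", n)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      serial = 0L,
      name = c("N", "CA", "C", "O"),
      resname = resnames[i], chain = chain,
      resno = firstResno + i - 1L,
      x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
      element = c("N", "C", "C", "O"),
      hetatm = FALSE, insert = "", stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  new("Structure", atoms = atoms, id = "built-peptide")
}

#' Build an ideal poly-Ala peptide
#'
#' Canonical backbone dihedrals: alpha helix (-57, -47), extended
#' (-135, 135), polyproline II (-75, 145); "hairpin" builds two
#' antiparallel strands joined by a tight two-residue turn. Geometry is
#' internally consistent (standard bond lengths/angles, trans peptide
#' bonds), so dihedrals measured back from the coordinates reproduce the
#' targets.
#'
#' @param kind "alpha_helix", "extended", "ppii", "hairpin" or "coil"
#'   (random backbone dihedrals, seeded; useful when orientationally
#'   diverse bond vectors are needed).
#' @param n_res number of residues (>= 4).
#' @param chain chain id.
#' @param firstResno first residue number.
#' @param seed RNG seed for "coil".
#' @return a \code{\link{Structure}}.
#' @export
makeIdealPeptide <- function(kind = c("alpha_helix", "extended", "ppii",
                                      "hairpin", "coil"),
                             n_res = 15, chain = "A", firstResno = 1L,
                             seed = 1) {
  kind <- match.arg(kind)
  if (n_res < 4) stop("n_res must be >= 4")
  deg <- pi / 180
  if (kind == "coil") {
    set.seed(seed)
    phi <- stats::runif(n_res, -180, 180) * deg
    psi <- stats::runif(n_res, -180, 180) * deg
  } else if (kind == "hairpin") {
    half <- (n_res - 2) %/% 2
    phi <- c(rep(-139, half), 45, 110,
             rep(-139, n_res - half - 2)) * deg
    psi <- c(rep(135, half), 45, 0,
             rep(135, n_res - half - 2)) * deg
    phi <- phi[seq_len(n_res)]
    psi <- psi[seq_len(n_res)]
  } else {
    pp <- switch(kind, alpha_helix = c(-57, -47), extended = c(-135, 135),
                 ppii = c(-75, 145))
    phi <- rep(pp[1] * deg, n_res)
    psi <- rep(pp[2] * deg, n_res)
  }
  s <- .buildBackbone(phi, psi, chain = chain, firstResno = firstResno)
  s@id <- paste0("ideal-", kind)
  s
}

#' Synthetic I-domain-sized backbone (stand-in structure)
#'
#' A complete 188-residue poly-Ala backbone with author numbering
#' 128-315, the construct length for which the backbone phi/psi
#' enumeration yields 374 dihedrals. This is a synthetic stand-in used to
#' exercise structure I/O and dihedral counting at realistic size; it is
#' not a model of any deposited structure.
#'
#' @param n_res residues (default 188).
#' @param firstResno first author residue number (default 128).
#' @param chain chain id.
#' @return a \code{\link{Structure}}.
#' @export
makeSyntheticIDomainBackbone <- function(n_res = 188L, firstResno = 128L,
                                         chain = "A") {
  s <- makeIdealPeptide("alpha_helix", n_res, chain = chain,
                        firstResno = firstResno)
  s@id <- "synthetic-idomain-backbone"
  s
}

#' Generate a labelled three-state marker ensemble
#'
#' Frames carry marker atoms placed so that the helix-orientation angle
#' theta and the ratchet distance d computed by the geometry module
#' reproduce per-frame values sampled from per-state normal
#' distributions. State labels are drawn from \code{fractions}; defaults
#' mirror a three-substate system with populations 0.48/0.36/0.16 and
#' ratchet distances 8.0/8.0/11.8 Angstrom. Marker layout: Calpha atoms
#' at residues 258 (arm 1), 291 (vertex) and 310 (arm 2) encode theta;
#' the aromatic CZ of residue 292 and a HETATM Mg ion encode d.
#'
#' @param n_frames frames to generate.
#' @param fractions state fractions (LA, AI, IA), sum 1.
#' @param theta_mean,theta_sd per-state theta parameters, degrees.
#' @param d_mean,d_sd per-state ratchet-distance parameters, Angstrom.
#' @param seed RNG seed.
#' @return list(ensemble, labels, theta, d).
#' @export
makeStateEnsemble <- function(n_frames = 1000,
                              fractions = c(LA_like = 0.48,
                                            AI_like = 0.36,
                                            IA_like = 0.16),
                              theta_mean = c(20, 40, 30),
                              theta_sd = c(3, 3, 3),
                              d_mean = c(8.0, 8.0, 11.8),
                              d_sd = c(0.5, 0.5, 0.5),
                              seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(theta_sd > 0),
            all(d_sd > 0))
  set.seed(seed)
  states <- sample.int(3, n_frames, replace = TRUE, prob = fractions)
  theta <- stats::rnorm(n_frames, theta_mean[states], theta_sd[states])
  theta <- pmin(pmax(theta, 0.1), 179.9)
  d <- pmax(stats::rnorm(n_frames, d_mean[states], d_sd[states]), 0.1)

  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", "CA", "CA", "CZ", "MG"),
    resname = c("ALA", "ALA", "ALA", "PHE", "MG"),
    chain = "A",
    resno = c(258L, 291L, 310L, 292L, 400L),
    x = 0, y = 0, z = 0,
    element = c("C", "C", "C", "C", "MG"),
    hetatm = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    insert = "", stringsAsFactors = FALSE)
  coords <- array(0, c(5, 3, n_frames))
  arm <- 10
  for (f in seq_len(n_frames)) {
    th <- theta[f] * pi / 180
    coords[1, , f] <- c(arm, 0, 0)              # arm 1
    coords[2, , f] <- c(0, 0, 0)                # vertex
    coords[3, , f] <- arm * c(cos(th), sin(th), 0)  # arm 2
    coords[4, , f] <- c(20, 20, 20)             # Phe CZ
    coords[5, , f] <- c(20, 20, 20 + d[f])      # Mg
  }
  ens <- new("Ensemble", atoms = atoms, coords = coords,
             weights = numeric(0), id = "synthetic-three-state")
  list(ensemble = ens,
       labels = c("LA_like", "AI_like", "IA_like")[states],
       theta = theta, d = d)
}

#' Random traceless symmetric Saupe tensor
#' @param magnitude scale of the components.
#' @param seed RNG seed (NULL: use current RNG state).
#' @return an \code{\link{AlignmentTensor}}.
#' @export
randomSaupeTensor <- function(magnitude = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::rnorm(5, sd = magnitude)
  .saupeFromParams(p)
}

#' Generate synthetic RDC records from a known alignment tensor
#'
#' D_obs = backcalc(true tensor) + Normal(0, noise_sd), either on the
#' N-H bond vectors of a supplied structure or on random unit vectors.
#'
#' @param tensor the true \code{\link{AlignmentTensor}}.
#' @param structure optional \code{Structure}; its residues' N-H vectors
#'   are used (amide H constructed when missing).
#' @param n_records number of random-orientation records when no
#'   structure is given.
#' @param noise_sd Gaussian noise, Hz.
#' @param D_max overall dipolar scale.
#' @param seed RNG seed.
#' @param chain chain id for structure mode.
#' @return list(records (data.frame resno, atom1, atom2, D_obs, segment),
#'   vectors, tensor, D_true).
#' @export
makeSyntheticRDC <- function(tensor, structure = NULL, n_records = 40,
                             noise_sd = 0, D_max = 1, seed = 1,
                             chain = "A") {
  set.seed(seed)
  if (!is.null(structure)) {
    at <- atomTable(structure)
    het <- if (is.null(at$hetatm)) rep(FALSE, nrow(at)) else at$hetatm
    resnos <- unique(at$resno[at$chain == chain & !het])
    records <- data.frame(resno = resnos, atom1 = "N", atom2 = "H",
                          D_obs = NA_real_, segment = NA_character_)
    # unresolvable records (e.g. the N-terminal amide) are dropped from
    # the generated set, so the skip warning is expected here
    bv <- suppressWarnings(bondUnitVectors(structure, records, chain))
    records <- records[bv$used, , drop = FALSE]
    vectors <- bv$vectors[bv$used, , drop = FALSE]
  } else {
    v <- matrix(stats::rnorm(3 * n_records), n_records, 3)
    vectors <- v / sqrt(rowSums(v^2))
    records <- data.frame(resno = seq_len(n_records), atom1 = "N",
                          atom2 = "H", D_obs = NA_real_,
                          segment = NA_character_)
  }
  D_true <- backcalcRDC(tensor, vectors, D_max)
  records$D_obs <- D_true + stats::rnorm(nrow(records), sd = noise_sd)
  list(records = records, vectors = vectors, tensor = tensor,
       D_true = D_true)
}

#' Generate a linear toy observable system for restraint tests
#'
#' Observables delta_e(x) = slope_e x + intercept_e evaluated at known
#' true coordinates; the returned table and model make the restraint
#' energy exactly zero at the truth.
#'
#' @param n_obs number of observables (>= 1).
#' @param slope slopes (recycled; default random standard normal).
#' @param intercept intercepts (recycled).
#' @param x_true true coordinate vector (default 0.5, 1D).
#' @param seed RNG seed.
#' @return list(model = \code{\link{LinearShiftModel}},
#'   table = \code{\link{ObservableTable}}, x_true).
#' @export
makeLinearShiftSystem <- function(n_obs = 6, slope = NULL, intercept = 0,
                                  x_true = 0.5, seed = 1) {
  stopifnot(n_obs >= 1)
  set.seed(seed)
  d <- length(x_true)
  if (is.null(slope)) slope <- stats::rnorm(n_obs * d)
  A <- matrix(rep_len(slope, n_obs * d), n_obs, d)
  b <- rep_len(intercept, n_obs)
  model <- linearShiftModel(A, b)
  types <- rep_len(c("HA", "HN", "N", "CA", "CB", "C"), n_obs)
  tab <- observableTable(seq_len(n_obs), types,
                         predictObservables(model, x_true),
                         provenance = "synthetic linear system")
  list(model = model, table = tab, x_true = x_true)
}
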