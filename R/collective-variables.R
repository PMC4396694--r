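#' @include geometry.R
NULL

# residue types whose chi1 participates in the side-chain CVs; all seven
# use CG as the gamma atom
.HEAVY_CHI1 <- c("PHE", "HIS", "TYR", "TRP", "ARG", "LYS", "MET")

#' Dihedral-correlation collective variable
#'
#' The consecutive-pair dihedral correlation
#' sum_{k=1}^{n-1} (1 + cos(a_k - a_{k+1})) / 2, dimensionless and bounded
#' by [0, n-1]; it is maximal when adjacent dihedrals agree and 0 when they
#' alternate by pi. Invariant to shifting any angle by 2 pi.
#'
#' @param angles ordered numeric vector of >= 2 angles, radians.
#' @return dimensionless correlation value.
#' @examples
#' dihedralCorrelation(rep(1, 5))   # 4
#' dihedralCorrelation(c(0, pi, 0)) # 0
#' @export
dihedralCorrelation <- function(angles) {
  if (length(angles) < 2) stop("dihedral correlation needs >= 2 angles")
  sum((1 + cos(diff(angles))) / 2)
}

#' Construct a CV definition
#'
#' @param name CV name, e.g. "cv1".
#' @param kind "dihedral_correlation", "group_angle" or
#'   "generic_coordinate".
#' @param angles data.frame(chain, resno, label) of dihedrals in order
#'   (label in "phi","psi","chi1"); for dihedral_correlation.
#' @param groups list of 3 \code{ResidueSelection}; for group_angle.
#' @param coordIndex coordinate index; for generic_coordinate.
#' @param sigma metadynamics Gaussian width in CV units.
#' @return a \code{\link{CVDefinition}}.
#' @export
cvDefinition <- function(name, kind, angles = data.frame(), groups = list(),
                         coordIndex = 1L, sigma = 0.1) {
  new("CVDefinition", name = name, kind = kind, angles = angles,
      groups = groups, coordIndex = as.integer(coordIndex), sigma = sigma)
}

# ordered angle values (radians) for a dihedral list
.dihedralValues <- function(structure, angles) {
  at <- atomTable(structure)
  vapply(seq_len(nrow(angles)), function(k) {
    ch <- angles$chain[k]; r <- angles$resno[k]; lab <- angles$label[k]
    quad <- switch(lab,
      phi  = list(c(ch, r - 1, "C"), c(ch, r, "N"), c(ch, r, "CA"),
                  c(ch, r, "C")),
      psi  = list(c(ch, r, "N"), c(ch, r, "CA"), c(ch, r, "C"),
                  c(ch, r + 1, "N")),
      chi1 = list(c(ch, r, "N"), c(ch, r, "CA"), c(ch, r, "CB"),
                  c(ch, r, "CG")),
      stop("unknown dihedral label ", lab))
    idx <- vapply(quad, function(q)
      .atomIndex(at, q[1], as.integer(q[2]), q[3]), integer(1))
    if (anyNA(idx))
      stop(sprintf("missing atoms for %s of residue %s:%s", lab, ch, r))
    dihedralAngle(.atomXYZ(at, idx[1]), .atomXYZ(at, idx[2]),
                  .atomXYZ(at, idx[3]), .atomXYZ(at, idx[4]))
  }, numeric(1))
}

#' Helix-orientation angle CV
#'
#' The angle theta that the C-terminal helix forms with the hydrophobic
#' core, defined by the Calpha centroids of three residue groups with the
#' middle group (the helix anchor loop, the geometric hinge between core
#' and helix) as the vertex. Degrees in [0, 180]; invariant under rigid
#' transforms.
#'
#' @param structure a \code{Structure}.
#' @param groups list of exactly 3 \code{ResidueSelection} (or selection
#'   strings); default: the I-domain groups Arg256-Gly260, Asp290-Phe292
#'   (vertex), Leu305-Ile316 on chain A.
#' @return theta in degrees.
#' @export
thetaCV <- function(structure,
                    groups = list("A:256-260:CA", "A:290-292:CA",
                                  "A:305-316:CA")) {
  if (length(groups) != 3) stop("theta needs exactly 3 residue groups")
  groups <- lapply(groups, function(g)
    if (is.character(g)) parseSelection(g) else g)
  cents <- lapply(groups, function(g) groupCentroid(structure, g))
  interGroupAngle(cents[[1]], cents[[2]], cents[[3]])
}

# residues (chain, resno) of the structure whose type has a heavy chi1
.heavyChi1Residues <- function(structure) {
  at <- atomTable(structure)
  het <- if (is.null(at$hetatm)) rep(FALSE, nrow(at)) else at$hetatm
  res <- unique(at[!het, c("chain", "resno", "resname")])
  res[res$resname %in% .HEAVY_CHI1, c("chain", "resno"), drop = FALSE]
}

#' Build the standard four-CV set for an I-domain-like protein
#'
#' cv1: dihedral correlation over all backbone phi/psi (sigma 0.1);
#' cv2: dihedral correlation over chi1 of the heavy side chains (Phe, His,
#' Tyr, Trp, Arg, Lys, Met) outside helices 1 and 7 (sigma 0.1);
#' cv3: the same chi1 set inside those two helices (sigma 0.1);
#' cv4: the helix-orientation angle theta (sigma 0.05).
#' The cv2/cv3 angle lists partition the full heavy-chi1 set.
#'
#' @param structure a \code{Structure}.
#' @param chain chain identifier (default "A").
#' @param helix1,helix7 inclusive residue ranges c(first, last) for
#'   helices 1 and 7; the defaults (142-156 and 287-305) can and should be
#'   overridden when the true boundaries are known.
#' @param thetaGroups passed to \code{\link{thetaCV}}.
#' @return named list of 4 \code{\link{CVDefinition}}s.
#' @export
buildCVSet <- function(structure, chain = "A",
                       helix1 = c(142L, 156L), helix7 = c(287L, 305L),
                       thetaGroups = list("A:256-260:CA", "A:290-292:CA",
                                          "A:305-316:CA")) {
  if (max(helix1[1], helix7[1]) <= min(helix1[2], helix7[2]))
    stop("helix 1 and helix 7 ranges overlap")
  bb <- enumerateBackboneDihedrals(structure, chain, compute = FALSE)
  cv1 <- cvDefinition("cv1", "dihedral_correlation",
                      angles = data.frame(chain = chain, resno = bb$resno,
                                          label = bb$label), sigma = 0.1)
  chi <- .heavyChi1Residues(structure)
  chi <- chi[chi$chain == chain, , drop = FALSE]
  inHel <- (chi$resno >= helix1[1] & chi$resno <= helix1[2]) |
           (chi$resno >= helix7[1] & chi$resno <= helix7[2])
  mk <- function(rows, name) {
    if (nrow(rows) < 1)
      stop(name, ": empty heavy-chi1 set for its residue ranges; ",
           "adjust the helix ranges")
    cvDefinition(name, "dihedral_correlation",
                 angles = data.frame(chain = rows$chain, resno = rows$resno,
                                     label = "chi1"), sigma = 0.1)
  }
  cv2 <- mk(chi[!inHel, , drop = FALSE], "cv2")
  cv3 <- mk(chi[inHel, , drop = FALSE], "cv3")
  cv4 <- cvDefinition("cv4", "group_angle",
                      groups = lapply(thetaGroups, function(g)
                        if (is.character(g)) parseSelection(g) else g),
                      sigma = 0.05)
  list(cv1 = cv1, cv2 = cv2, cv3 = cv3, cv4 = cv4)
}

#' Evaluate a CV on a structure or coordinate vector
#'
#' @param cv a \code{\link{CVDefinition}}.
#' @param x a \code{Structure} (dihedral_correlation, group_angle) or a
#'   numeric coordinate vector (generic_coordinate).
#' @return the CV value.
#' @export
evalCV <- function(cv, x) {
  switch(cv@kind,
    dihedral_correlation = dihedralCorrelation(.dihedralValues(x, cv@angles)),
    group_angle = thetaCV(x, cv@groups),
    generic_coordinate = {
      stopifnot(is.numeric(x))
      x[cv@coordIndex]
    })
}

#' Serialize a CV set to a YAML config file
#' @param cvs named list of \code{CVDefinition}s.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeCVSet <- function(cvs, path) {
  lst <- lapply(cvs, function(cv) {
    out <- list(kind = cv@kind, sigma = cv@sigma)
    if (cv@kind == "dihedral_correlation")
      out$angles <- lapply(seq_len(nrow(cv@angles)), function(k)
        list(chain = cv@angles$chain[k], resno = cv@angles$resno[k],
             label = cv@angles$label[k]))
    if (cv@kind == "group_angle")
      out$groups <- lapply(cv@groups, function(g)
        sprintf("%s:%d-%d%s", g@chain, g@first[1], g@last[1],
                if (length(g@atoms)) paste0(":", g@atoms[1]) else ""))
    if (cv@kind == "generic_coordinate") out$coordIndex <- cv@coordIndex
    out
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a CV set from a YAML config file
#' @param path YAML file written by \code{\link{writeCVSet}}.
#' @return named list of \code{CVDefinition}s.
#' @export
readCVSet <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- lapply(names(lst), function(nm) {
    e <- lst[[nm]]
    ang <- if (!is.null(e$angles))
      do.call(rbind, lapply(e$angles, as.data.frame)) else data.frame()
    grp <- if (!is.null(e$groups)) lapply(e$groups, parseSelection)
           else list()
    cvDefinition(nm, e$kind, angles = ang, groups = grp,
                 coordIndex = e$coordIndex %||% 1L, sigma = e$sigma)
  })
  names(out) <- names(lst)
  out
}
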