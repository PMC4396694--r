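#' @include pdb-io.R
NULL

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = pi; the angle is the rotation of
#' the p3->p4 bond relative to the p1->p2 bond, viewed along p2->p3,
#' positive clockwise. Result in radians in (-pi, pi].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in radians.
#' @examples
#' dihedralAngle(c(0,1,0), c(0,0,0), c(1,0,0), c(1,-1,0))  # pi (trans)
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20)
    stop("coincident consecutive points in dihedral")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined dihedral: colinear points")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# index lookup (chain, resno, name) -> atom row; NA when absent
.atomIndex <- function(atoms, chain, resno, name) {
  idx <- which(atoms$chain == chain & atoms$resno == resno &
               atoms$name == name)
  if (length(idx) == 1) idx else NA_integer_
}

.atomXYZ <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

#' Enumerate backbone phi/psi dihedrals of a chain
#'
#' Lists, in N- to C-terminal order with phi before psi within a residue,
#' every backbone dihedral that the chain's atoms define: phi for each
#' residue with a preceding residue, psi for each residue with a following
#' one, so a complete chain of N residues yields 2(N-1) angles. An angle
#' whose four atoms are not all present is omitted with a warning, never
#' silently mis-measured.
#'
#' @param structure a \code{Structure}.
#' @param chain chain identifier.
#' @param compute if TRUE (default) also return the angle values (radians).
#' @return data.frame(resno, label, value) with label "phi"/"psi"; value
#'   column only when \code{compute} is TRUE.
#' @export
enumerateBackboneDihedrals <- function(structure, chain, compute = TRUE) {
  at <- atomTable(structure)
  het <- if (is.null(at$hetatm)) rep(FALSE, nrow(at)) else at$hetatm
  at <- at[at$chain == chain & !het, , drop = FALSE]
  resnos <- unique(at$resno)  # list order = chain order
  if (length(resnos) < 2)
    stop("chain ", chain, " has fewer than 2 residues")
  out <- list()
  miss <- character(0)
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    prev <- if (k > 1) resnos[k - 1] else NA
    nxt <- if (k < length(resnos)) resnos[k + 1] else NA
    # phi: C(i-1) - N(i) - CA(i) - C(i)
    if (!is.na(prev)) {
      idx <- c(.atomIndex(at, chain, prev, "C"), .atomIndex(at, chain, r, "N"),
               .atomIndex(at, chain, r, "CA"), .atomIndex(at, chain, r, "C"))
      if (anyNA(idx)) {
        miss <- c(miss, sprintf("phi %d", r))
      } else {
        v <- if (compute)
          dihedralAngle(.atomXYZ(at, idx[1]), .atomXYZ(at, idx[2]),
                        .atomXYZ(at, idx[3]), .atomXYZ(at, idx[4]))
        else NA_real_
        out[[length(out) + 1]] <- list(resno = r, label = "phi", value = v)
      }
    }
    # psi: N(i) - CA(i) - C(i) - N(i+1)
    if (!is.na(nxt)) {
      idx <- c(.atomIndex(at, chain, r, "N"), .atomIndex(at, chain, r, "CA"),
               .atomIndex(at, chain, r, "C"), .atomIndex(at, chain, nxt, "N"))
      if (anyNA(idx)) {
        miss <- c(miss, sprintf("psi %d", r))
      } else {
        v <- if (compute)
          dihedralAngle(.atomXYZ(at, idx[1]), .atomXYZ(at, idx[2]),
                        .atomXYZ(at, idx[3]), .atomXYZ(at, idx[4]))
        else NA_real_
        out[[length(out) + 1]] <- list(resno = r, label = "psi", value = v)
      }
    }
  }
  if (length(miss))
    warning("omitted dihedrals with missing backbone atoms: ",
            paste(miss, collapse = ", "))
  df <- do.call(rbind, lapply(out, as.data.frame))
  # chain order with phi before psi within a residue
  ord <- order(match(df$resno, resnos), match(df$label, c("phi", "psi")))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!compute) df$value <- NULL
  df
}

#' Unweighted centroid of the Calpha atoms matched by a selection
#'
#' All Calpha atoms carry the same mass, so the unweighted centroid equals
#' the centre of mass of the group.
#'
#' @param structure a \code{Structure}.
#' @param selection a \code{ResidueSelection}; restricted to CA atoms if no
#'   atom filter given.
#' @return numeric 3-vector, Angstrom.
#' @export
groupCentroid <- function(structure, selection) {
  if (!length(selection@atoms))
    selection@atoms <- "CA"
  idx <- matchSelection(structure, selection)
  at <- atomTable(structure)
  c(mean(at$x[idx]), mean(at$y[idx]), mean(at$z[idx]))
}

#' Angle at a vertex between three points
#'
#' Returns the angle at vertex \code{c2} between the arms c2->c1 and
#' c2->c3, in degrees in [0, 180]. Symmetric in its outer arguments.
#'
#' @param c1,c2,c3 numeric 3-vectors.
#' @return angle in degrees.
#' @export
interGroupAngle <- function(c1, c2, c3) {
  u <- c1 - c2
  v <- c3 - c2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate angle: zero-length arm")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Distance between two uniquely selected atoms
#'
#' @param structure a \code{Structure}.
#' @param sel_a,sel_b \code{ResidueSelection}s that each resolve to exactly
#'   one atom (selection strings are accepted).
#' @return Euclidean distance, Angstrom.
#' @export
atomDistance <- function(structure, sel_a, sel_b) {
  one <- function(sel) {
    if (is.character(sel)) sel <- parseSelection(sel)
    idx <- matchSelection(structure, sel)
    if (length(idx) != 1)
      stop("ambiguous selection: ", length(idx), " atoms matched")
    idx
  }
  at <- atomTable(structure)
  ia <- one(sel_a); ib <- one(sel_b)
  sqrt((at$x[ia] - at$x[ib])^2 + (at$y[ia] - at$y[ib])^2 +
       (at$z[ia] - at$z[ib])^2)
}
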