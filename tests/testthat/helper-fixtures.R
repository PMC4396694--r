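# shared fixtures and small independent oracles used across test files

kT300 <- 0.0083145 * 300

# exactly harmonic 1D potential U = 0.5 * kappa * x^2 (quadratic wall,
# no wells)
harmonicPotential <- function(kappa = 1) {
  new("ToyPotential", dimension = 1L, depths = numeric(0),
      centers = matrix(numeric(0), 0, 1), widths = numeric(0),
      wallCenter = 0, wallScale = 1, wallPower = 2,
      wallHeight = kappa / 2, descriptor = "harmonic well")
}

# random proper rotation matrix
randomRotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3])
}

# rigid-transform a Structure
transformStructure <- function(s, R = randomRotation(),
                               shift = stats::runif(3, -10, 10)) {
  at <- s@atoms
  xyz <- t(R %*% t(as.matrix(at[, c("x", "y", "z")]))) +
    matrix(shift, nrow(at), 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  new("Structure", atoms = at, id = s@id)
}

# static bias made of a few fixed hills
staticBias <- function(centers, heights, sigma = 0.35) {
  b <- biasPotential("x", sigma = sigma, stride = 1)
  for (i in seq_along(centers))
    b <- depositHill(b, centers[i], heights[i], 0)
  b
}

# Metropolis random walk on a discrete grid of energies (exact MCMC for
# the binned system); independent of the package's samplers
gridMCMC <- function(E, n, i0, kT = kT300, maxJump = 4) {
  out <- integer(n)
  i <- i0
  m <- length(E)
  for (k in seq_len(n)) {
    j <- i + sample(c(-maxJump:-1, 1:maxJump), 1)
    if (j >= 1 && j <= m && log(stats::runif(1)) < (E[i] - E[j]) / kT)
      i <- j
    out[k] <- i
  }
  out
}

# build a Structure directly from an atom table skeleton
structureFromAtoms <- function(name, resname, chain, resno, xyz,
                               hetatm = FALSE, id = "test") {
  n <- length(name)
  atoms <- data.frame(
    serial = seq_len(n), name = name, resname = resname, chain = chain,
    resno = as.integer(resno), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = substr(name, 1, 1), hetatm = rep_len(hetatm, n),
    insert = "", stringsAsFactors = FALSE)
  new("Structure", atoms = atoms, id = id)
}
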