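test_that("microstate assignment bins frames and conserves counts", {
  tr <- list(cbind(step = 1:4, cv = rep(0.25, 4)))
  ms <- assignMicrostates(tr, 0, 0.5)
  expect_equal(nrow(ms@centers), 1)
  expect_equal(sum(ms@counts), 4)
  tr2 <- list(cbind(step = 1:2, cv = c(0.1, 0.9)))
  expect_equal(nrow(assignMicrostates(tr2, 0, 0.5)@centers), 2)
  # 2D uniform points: total count conserved after t_eq
  set.seed(6)
  n <- 5000
  tr3 <- list(cbind(step = 1:n, u = stats::runif(n), v = stats::runif(n)),
              cbind(step = 1:n, u = stats::runif(n), v = stats::runif(n)))
  teq <- 2000
  ms3 <- assignMicrostates(tr3, teq, c(0.1, 0.1))
  expect_equal(colSums(ms3@counts), c(n - teq, n - teq))
  expect_error(assignMicrostates(tr2, 10, 0.5), "no frames")
  expect_error(assignMicrostates(tr2, 0, -1), "positive")
})

test_that("single-replica zero-bias WHAM reduces to -kT log counts", {
  set.seed(3)
  n <- c(700, 200, 100)
  tr <- list(cbind(step = seq_len(sum(n)),
                   cv = rep(c(0.5, 1.5, 2.5), n)))
  ms <- assignMicrostates(tr, 0, 1)
  fet <- whamFreeEnergies(ms, matrix(0, 3, 1))
  expected <- -kT300 * log(n / sum(n))
  expect_equal(fet@F, expected - min(expected), tolerance = 1e-6)
})

test_that("two replicas with identical bias match pooled single-replica WHAM", {
  set.seed(4)
  x1 <- stats::rnorm(2000); x2 <- stats::rnorm(2000)
  tr2 <- list(cbind(step = 1:2000, cv = x1),
              cbind(step = 1:2000, cv = x2))
  trPooled <- list(cbind(step = 1:4000, cv = c(x1, x2)))
  b <- staticBias(0, 3, sigma = 1)
  ms2 <- assignMicrostates(tr2, 0, 0.25)
  msP <- assignMicrostates(trPooled, 0, 0.25)
  B2 <- biasOnMicrostates(ms2, list(b, b))
  BP <- biasOnMicrostates(msP, list(b))
  f2 <- whamFreeEnergies(ms2, B2)
  fP <- whamFreeEnergies(msP, BP)
  expect_equal(f2@F, fP@F, tolerance = 1e-6)
})

test_that("WHAM is invariant (up to gauge) to constant bias offsets", {
  set.seed(9)
  tr <- list(cbind(step = 1:3000, cv = stats::rnorm(3000)),
             cbind(step = 1:3000, cv = stats::rnorm(3000, 0.5)))
  ms <- assignMicrostates(tr, 0, 0.25)
  b1 <- staticBias(-0.5, 2, 0.7)
  b2 <- staticBias(0.8, 2, 0.7)
  B <- biasOnMicrostates(ms, list(b1, b2))
  f0 <- whamFreeEnergies(ms, B)
  f1 <- whamFreeEnergies(ms, B + matrix(c(5, -3), nrow(B), 2,
                                        byrow = TRUE))
  expect_equal(f0@F, f1@F, tolerance = 1e-6)
})

test_that("WHAM recovers quadrature truth from exact MCMC under static biases", {
  pot <- makeTripleWell()
  set.seed(77)
  centers <- seq(-3.05, 3.05, by = 0.1)
  U <- potentialEnergy(pot, matrix(centers))
  # known static umbrella biases: near-cancelling and half-cancelling
  # copies of the well depths, fixed before any sampling
  biases <- list(staticBias(c(-2, 0, 2), 0.9 * pot@depths),
                 staticBias(c(-2, 0, 2), 0.45 * pot@depths))
  traj <- lapply(biases, function(b) {
    V <- vapply(centers, function(x) evaluateBias(b, x, 1), numeric(1))
    idx <- gridMCMC(U + V, 1e5, which.min(abs(centers)))
    cbind(step = 1:1e5, cv = centers[idx])
  })
  ms <- assignMicrostates(traj, 0, 0.1)
  fet <- whamFreeEnergies(ms, biasOnMicrostates(ms, biases))
  bt <- basinThermodynamics(fet, min_barrier = 1)
  truth <- sort(quadratureBasinDeltaG(pot, 300))
  expect_equal(nrow(bt), 3)
  expect_lt(max(abs(bt$deltaG - truth)), 0.3)
})

test_that("FES projection Boltzmann-sums microstates and conserves probability", {
  set.seed(12)
  nm <- 40
  Fvals <- stats::runif(nm, 0, 8)
  Fvals[1] <- 0
  ms <- new("MicrostateTable",
            centers = matrix((seq_len(nm) - 0.5) * 0.1, ncol = 1),
            counts = matrix(rep(10, nm), ncol = 1), binWidths = 0.1,
            cvNames = "cv1")
  fet <- new("FreeEnergyTable", F = Fvals, f = 0, temperature = 300,
             iterations = 1L, residual = 0, microstates = ms)
  # identity projection: same F up to gauge
  fes <- microstateFES(fet)
  expect_equal(as.numeric(fes@F), Fvals, tolerance = 1e-9)
  # two microstates with equal F collapsing into one cell lower the cell
  # free energy by kT log 2 relative to a lone microstate of the same F
  ms2 <- new("MicrostateTable", centers = matrix(c(0.05, 0.15, 1.05),
                                                 ncol = 1),
             counts = matrix(c(1, 1, 1), ncol = 1), binWidths = 0.1,
             cvNames = "cv1")
  fet2 <- new("FreeEnergyTable", F = c(2, 2, 0), f = 0, temperature = 300,
              iterations = 1L, residual = 0, microstates = ms2)
  grid <- list(list(name = "x", unit = "u", edges = c(0, 1, 2)))
  pr2 <- projectFES(fet2, ms2@centers[, 1], grid)
  expect_equal(pr2@F[1] - pr2@F[2], 2 - kT300 * log(2), tolerance = 1e-9)
  # probability conservation: cell probabilities equal the direct
  # Boltzmann marginalisation of the microstates (summation oracle)
  grid2 <- list(list(name = "x", unit = "u", edges = c(0, 2, 4)))
  fes2 <- projectFES(fet, ms@centers[, 1], grid2)
  pcell <- exp(-fes2@F / kT300) / sum(exp(-fes2@F / kT300))
  pr <- tapply(exp(-Fvals / kT300),
               findInterval(ms@centers[, 1], c(0, 2, 4)), sum)
  expect_equal(as.numeric(pcell), as.numeric(pr / sum(pr)),
               tolerance = 1e-9)
})

test_that("basin finding: single minimum, calibrated triple well, merging", {
  mkfes <- function(F, width = 0.1) {
    new("FESGrid",
        axes = list(list(name = "x", unit = "u",
                         edges = seq(0, by = width,
                                     length.out = length(F) + 1))),
        F = array(F - min(F)), temperature = 300)
  }
  x <- seq(-2, 2, length.out = 81)
  parab <- mkfes(x^2)
  b1 <- findBasins(parab, 1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$deltaG, 0)
  # analytic triple well with point minima 0 / 0.7 / 2.8 and ~6 kJ/mol
  # barriers
  wells <- -8.8 * exp(-(x + 1.5)^2 / 0.045) -
    8.1 * exp(-x^2 / 0.045) - 6 * exp(-(x - 1.5)^2 / 0.045)
  F <- wells - min(wells)
  fes <- mkfes(F)
  b3 <- findBasins(fes, 1)
  expect_equal(nrow(b3), 3)
  expect_equal(b3$deltaG, c(0, 0.7, 2.8), tolerance = 0.05)
  # a merge threshold above every barrier collapses all basins into one
  expect_equal(nrow(findBasins(fes, 100)), 1)
})

test_that("Boltzmann populations reproduce the three-state 48/36/16 split", {
  p <- boltzmannPopulations(c(0, 0.7, 2.8), 300)
  expect_equal(round(p$population, 2), c(0.48, 0.36, 0.16))
  expect_equal(sum(p$population), 1, tolerance = 1e-12)
  expect_equal(boltzmannPopulations(c(0, 0), 300)$population,
               c(0.5, 0.5))
  expect_equal(boltzmannPopulations(0, 300)$population, 1)
  expect_error(boltzmannPopulations(c(0, 1), -3), "temperature")
  expect_error(boltzmannPopulations(c(-0.2, 1), 300), ">= 0")
})

test_that("free-energy tables serialize with metadata; FES exports as text", {
  set.seed(2)
  tr <- list(cbind(step = 1:500, cv = stats::rnorm(500)))
  ms <- assignMicrostates(tr, 0, 0.5)
  fet <- whamFreeEnergies(ms, matrix(0, nrow(ms@centers), 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFreeEnergyTable(fet, f)
  lines <- readLines(f)
  expect_match(lines[1], "WHAM")
  redo <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(redo$F_kJmol, fet@F, tolerance = 1e-6)
  g <- withr::local_tempfile(fileext = ".dat")
  writeFESGrid(microstateFES(fet), g)
  expect_gt(length(readLines(g)), nrow(ms@centers))
})

test_that("end-to-end landscape recovery: bemeta, WHAM, basins, populations", {
  # the central parameter-recovery property: simulate the calibrated
  # three-basin system with two biased replicas, reconstruct, and recover
  # the 0 / 0.7 / 2.8 kJ/mol offsets and 48/36/16 populations
  pot <- makeTripleWell()
  target <- sort(attr(pot, "calibratedDeltaG"))
  popTarget <- boltzmannPopulations(target, 300)$population
  passes <- 0L
  for (seed in 1:5) {
    log <- runBemeta(pot, cvIndex = c(1L, 1L), nSteps = 6e5, seed = seed,
                     params = list(dt = 0.02, hillHeight = 0.2,
                                   hillStride = 500, sigma = 0.1,
                                   recordStride = 20))
    teq <- 3e5
    ms <- assignMicrostates(log, teq, 0.1)
    B <- biasOnMicrostates(ms, log@hills, t_from = teq, t_to = 6e5)
    fet <- whamFreeEnergies(ms, B)
    bt <- basinThermodynamics(fet, min_barrier = 1)
    ok <- nrow(bt) == 3 &&
      max(abs(bt$deltaG - target)) < 0.3 &&
      max(abs(bt$population - popTarget)) < 0.05
    passes <- passes + ok
  }
  expect_gte(passes, 3)  # majority of 5 seeds
})
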