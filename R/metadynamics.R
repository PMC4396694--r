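#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname potentialEnergy
#' @export
setMethod("potentialEnergy", "ToyPotential", function(object, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = object@dimension)
  stopifnot(ncol(x) == object@dimension)
  e <- rep(0, nrow(x))
  for (k in seq_len(nrow(object@centers))) {
    d2 <- rowSums((x - matrix(object@centers[k, ], nrow(x),
                              object@dimension, byrow = TRUE))^2)
    e <- e - object@depths[k] * exp(-d2 / (2 * object@widths[k]^2))
  }
  r <- sqrt(rowSums((x - matrix(object@wallCenter, nrow(x),
                                object@dimension, byrow = TRUE))^2))
  e + object@wallHeight * (r / object@wallScale)^object@wallPower
})

#' @rdname potentialGradient
#' @export
setMethod("potentialGradient", "ToyPotential", function(object, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = object@dimension)
  g <- matrix(0, nrow(x), object@dimension)
  for (k in seq_len(nrow(object@centers))) {
    dx <- x - matrix(object@centers[k, ], nrow(x), object@dimension,
                     byrow = TRUE)
    w2 <- object@widths[k]^2
    e <- object@depths[k] * exp(-rowSums(dx^2) / (2 * w2))
    g <- g + dx * (e / w2)
  }
  dxw <- x - matrix(object@wallCenter, nrow(x), object@dimension,
                    byrow = TRUE)
  r <- sqrt(rowSums(dxw^2))
  pos <- r > 1e-300
  if (any(pos)) {
    pref <- object@wallHeight * object@wallPower *
      (r[pos] / object@wallScale)^(object@wallPower - 1) /
      (object@wallScale * r[pos])
    g[pos, ] <- g[pos, , drop = FALSE] + dxw[pos, , drop = FALSE] * pref
  }
  if (vec) drop(g) else g
})

#' Construct an empty bias potential
#'
#' @param cvNames names of the biased CVs (one per dimension).
#' @param sigma Gaussian widths per CV.
#' @param stride hill deposition stride tau, integrator steps.
#' @return a \code{\link{BiasPotential}} with no hills.
#' @export
biasPotential <- function(cvNames, sigma, stride = 500) {
  d <- length(sigma)
  new("BiasPotential", cvNames = as.character(cvNames), sigma = sigma,
      centers = matrix(numeric(0), 0, d), heights = numeric(0),
      times = numeric(0), stride = stride)
}

#' Evaluate a metadynamics bias potential
#'
#' V(s, t) = sum over hills deposited strictly before step t of
#' W exp(-sum_i (s_i - s_i0)^2 / (2 sigma_i^2)). A hill does not act at
#' its own deposition instant.
#'
#' @param bias a \code{\link{BiasPotential}}.
#' @param s CV point (length = bias dimension).
#' @param t evaluation step (default Inf: all hills act).
#' @return bias energy, kJ/mol.
#' @export
evaluateBias <- function(bias, s, t = Inf) {
  if (length(s) != length(bias@sigma))
    stop("CV point dimension != bias dimension")
  act <- bias@times < t
  if (!any(act)) return(0)
  dc <- bias@centers[act, , drop = FALSE] -
    matrix(s, sum(act), length(s), byrow = TRUE)
  z <- rowSums(sweep(dc^2, 2, 2 * bias@sigma^2, "/"))
  sum(bias@heights[act] * exp(-z))
}

#' Analytic gradient of the bias with respect to the CVs
#'
#' @inheritParams evaluateBias
#' @return numeric gradient, one component per CV.
#' @export
biasGradient <- function(bias, s, t = Inf) {
  if (length(s) != length(bias@sigma))
    stop("CV point dimension != bias dimension")
  act <- bias@times < t
  g <- numeric(length(s))
  if (!any(act)) return(g)
  dc <- matrix(s, sum(act), length(s), byrow = TRUE) -
    bias@centers[act, , drop = FALSE]
  z <- rowSums(sweep(dc^2, 2, 2 * bias@sigma^2, "/"))
  w <- bias@heights[act] * exp(-z)
  -drop(crossprod(dc, w)) / bias@sigma^2
}

#' Deposit a Gaussian hill
#'
#' Appends a hill of constant height W (plain, non-well-tempered
#' metadynamics) at the current CV position; the hill only acts at steps
#' strictly after \code{t}.
#'
#' @param bias a \code{\link{BiasPotential}}.
#' @param s current CV position.
#' @param W hill height, kJ/mol (>= 0).
#' @param t deposition step; must be a multiple of the bias stride.
#' @return the updated \code{BiasPotential}.
#' @export
depositHill <- function(bias, s, W, t) {
  if (W < 0) stop("hill height must be >= 0")
  if (t %% bias@stride != 0)
    stop("deposition time ", t, " not aligned with stride ", bias@stride)
  bias@centers <- rbind(bias@centers, matrix(s, 1))
  bias@heights <- c(bias@heights, W)
  bias@times <- c(bias@times, t)
  bias
}

#' One BAOAB Langevin step
#'
#' Underdamped Langevin integrator (BAOAB splitting) at unit mass, in
#' kJ/mol energy units with k_B T = R T. The total force is the negative
#' gradient of the toy potential, minus the bias gradient chained through
#' the CV, minus any external restraint force. Deterministic given the R
#' RNG state.
#'
#' @param state list(x, v): coordinates and velocities.
#' @param potential a \code{\link{ToyPotential}}.
#' @param bias optional \code{BiasPotential} acting on coordinate
#'   \code{cvIndex}.
#' @param cvIndex coordinate index the bias acts on.
#' @param extraForce optional numeric force vector added to the total.
#' @param dt time step; \code{temperature} Kelvin; \code{friction} 1/time.
#' @param temperature temperature in K.
#' @param friction Langevin friction coefficient.
#' @param t current step index (for hill activation).
#' @return updated state list(x, v).
#' @export
langevinStep <- function(state, potential, bias = NULL, cvIndex = 1L,
                         extraForce = NULL, dt = 0.01, temperature = 300,
                         friction = 1, t = Inf) {
  kT <- .R_GAS * temperature
  force <- function(x) {
    f <- -potentialGradient(potential, x)
    if (!is.null(bias) && nHills(bias) > 0) {
      g <- biasGradient(bias, x[cvIndex], t)
      f[cvIndex] <- f[cvIndex] - g
    }
    if (!is.null(extraForce)) f <- f + extraForce
    if (!all(is.finite(f))) stop("non-finite force at x = ",
                                 paste(signif(x, 4), collapse = ", "))
    f
  }
  x <- state$x; v <- state$v
  v <- v + 0.5 * dt * force(x)          # B
  x <- x + 0.5 * dt * v                 # A
  c1 <- exp(-friction * dt)             # O
  v <- c1 * v + sqrt(kT * (1 - c1^2)) * stats::rnorm(length(v))
  x <- x + 0.5 * dt * v                 # A
  v <- v + 0.5 * dt * force(x)          # B
  list(x = x, v = v)
}

#' Metropolis exchange attempt between two biased replicas
#'
#' Bias-exchange swap at a common temperature: with s_a = cv_a(x_a) etc.,
#' Delta = [V_a(s_a(x_a)) + V_b(s_b(x_b)) - V_a(s_a(x_b)) - V_b(s_b(x_a))]
#' / k_B T and the swap is accepted with probability min(1, exp(Delta)),
#' so swaps that lower the total bias energy are always accepted. On
#' acceptance the two replicas exchange coordinates (and velocities); the
#' configuration multiset is preserved.
#'
#' @param replica_a,replica_b lists with elements \code{x}, \code{v},
#'   \code{bias} (a \code{BiasPotential}), \code{cvIndex}.
#' @param temperature Kelvin.
#' @param t current step (hills deposited at or after t do not act).
#' @return list(accepted, replica_a, replica_b).
#' @export
attemptExchange <- function(replica_a, replica_b, temperature = 300,
                            t = Inf) {
  kT <- .R_GAS * temperature
  va_a <- evaluateBias(replica_a$bias, replica_a$x[replica_a$cvIndex], t)
  vb_b <- evaluateBias(replica_b$bias, replica_b$x[replica_b$cvIndex], t)
  va_b <- evaluateBias(replica_a$bias, replica_b$x[replica_a$cvIndex], t)
  vb_a <- evaluateBias(replica_b$bias, replica_a$x[replica_b$cvIndex], t)
  delta <- (va_a + vb_b - va_b - vb_a) / kT
  accepted <- delta >= 0 || stats::runif(1) < exp(delta)
  if (accepted) {
    tmp <- replica_a[c("x", "v")]
    replica_a$x <- replica_b$x; replica_a$v <- replica_b$v
    replica_b$x <- tmp$x; replica_b$v <- tmp$v
  }
  list(accepted = accepted, replica_a = replica_a, replica_b = replica_b)
}

#' Run bias-exchange metadynamics on a toy potential
#'
#' Each replica carries its own history-dependent Gaussian bias acting on
#' one coordinate of the toy system; replicas evolve by BAOAB Langevin
#' dynamics at a common temperature, deposit constant-height hills at a
#' fixed stride, and attempt Metropolis exchanges of configurations at the
#' exchange stride. Optionally a replica-averaged flat-bottom restraint on
#' observables from a linear forward model couples the replicas
#' synchronously. Fully reproducible given \code{seed}.
#'
#' @param potential a \code{\link{ToyPotential}}.
#' @param cvIndex integer vector: the coordinate biased by each replica.
#' @param nSteps total integrator steps.
#' @param seed RNG seed.
#' @param params list overriding defaults: dt (0.01), temperature (300 K),
#'   friction (1), hillHeight (0.2 kJ/mol), hillStride (500),
#'   exchangeStride (2000), recordStride (10), sigma (per-replica Gaussian
#'   width, default 0.1), x0 (initial coordinates, one row per replica).
#' @param restraint optional list(model = \code{LinearShiftModel},
#'   table = \code{ObservableTable}, penalty = \code{PenaltyForm}).
#' @return a \code{\link{BemetaLog}}.
#' @export
runBemeta <- function(potential, cvIndex, nSteps, seed,
                      params = list(), restraint = NULL) {
  p <- modifyList(list(dt = 0.01, temperature = 300, friction = 1,
                       hillHeight = 0.2, hillStride = 500,
                       exchangeStride = 2000, recordStride = 10,
                       sigma = 0.1, x0 = NULL), params)
  nrep <- length(cvIndex)
  d <- potential@dimension
  sigma <- rep(p$sigma, length.out = nrep)
  set.seed(seed)
  X <- p$x0
  if (is.null(X)) {
    start <- if (nrow(potential@centers)) {
      potential@centers[which.max(potential@depths), ]
    } else potential@wallCenter
    X <- matrix(rep(start, each = nrep), nrep, d)
  } else if (!is.matrix(X)) X <- matrix(X, nrep, d, byrow = TRUE)
  V <- matrix(stats::rnorm(nrep * d,
                           sd = sqrt(.R_GAS * p$temperature)), nrep, d)

  hasRes <- !is.null(restraint)
  resA <- if (hasRes) restraint$model@A else matrix(0, 0, d)
  resB <- if (hasRes) restraint$model@b else numeric(0)
  pen <- if (hasRes) restraint$penalty %||% flatBottomPenalty()
         else flatBottomPenalty()
  resVal <- if (hasRes) restraint$table@entries$value else numeric(0)
  resEps <- if (hasRes) .epsFor(pen, restraint$table@entries$atomType)
            else numeric(0)

  hillC <- replicate(nrep, numeric(0), simplify = FALSE)
  hillT <- replicate(nrep, numeric(0), simplify = FALSE)
  hillH <- replicate(nrep, numeric(0), simplify = FALSE)
  traj <- vector("list", nrep)
  resE <- numeric(0)
  exch <- list()

  nChunks <- ceiling(nSteps / p$exchangeStride)
  stepAt <- 0
  for (chunk in seq_len(nChunks)) {
    nsub <- min(p$exchangeStride, nSteps - stepAt)
    out <- bemeta_chunk_cpp(
      X, V, cvIndex - 1L,
      potential@depths, potential@centers, potential@widths,
      potential@wallCenter, potential@wallScale, potential@wallPower,
      potential@wallHeight,
      hillC, hillT, sigma, p$hillHeight, p$hillStride,
      p$dt, .R_GAS * p$temperature, p$friction,
      stepAt, nsub, p$recordStride,
      hasRes, resA, resB, resVal, resEps, pen@k)
    X <- out$X; V <- out$V
    hillC <- out$hillCenters; hillT <- out$hillTimes
    hillH <- out$hillHeights
    for (r in seq_len(nrep))
      traj[[r]] <- rbind(traj[[r]], out$traj[[r]])
    if (hasRes) resE <- c(resE, out$restraintEnergy)
    stepAt <- stepAt + nsub

    if (nrep >= 2 && stepAt < nSteps) {
      pair <- sample.int(nrep, 2)
      i <- pair[1]; j <- pair[2]
      mkrep <- function(r) list(
        x = X[r, ], v = V[r, ], cvIndex = cvIndex[r],
        bias = .hillsToBias(hillC[[r]], hillT[[r]], hillH[[r]], sigma[r],
                            p$hillStride, cvIndex[r]))
      res <- attemptExchange(mkrep(i), mkrep(j), p$temperature, t = stepAt)
      if (res$accepted) {
        X[c(i, j), ] <- X[c(j, i), , drop = FALSE]
        V[c(i, j), ] <- V[c(j, i), , drop = FALSE]
      }
      exch[[length(exch) + 1]] <-
        data.frame(step = stepAt, i = i, j = j, accepted = res$accepted)
    }
  }

  biases <- lapply(seq_len(nrep), function(r)
    .hillsToBias(hillC[[r]], hillT[[r]], hillH[[r]], sigma[r],
                 p$hillStride, cvIndex[r]))
  for (r in seq_len(nrep))
    colnames(traj[[r]]) <- c("step", "cv")
  new("BemetaLog", cvTraj = traj, hills = biases,
      exchanges = if (length(exch)) do.call(rbind, exch) else
        data.frame(step = numeric(0), i = integer(0), j = integer(0),
                   accepted = logical(0)),
      restraintEnergy = resE,
      params = c(p, list(cvIndex = cvIndex, seed = seed, nSteps = nSteps)))
}

.hillsToBias <- function(centers, times, heights, sigma, stride, cvIndex) {
  new("BiasPotential", cvNames = paste0("x", cvIndex), sigma = sigma,
      centers = matrix(centers, ncol = 1), heights = heights,
      times = times, stride = stride)
}

#' Convergence diagnostic for metadynamics hill histories
#'
#' Plain metadynamics converges when newly added hills fill CV space
#' uniformly, so the shape of the bias profile stops changing even though
#' its mean keeps growing. For each replica the hills are split into
#' windows of \code{window} depositions; the rate of a window is the
#' spatial standard deviation, over a grid covering the visited CV range,
#' of the bias added during that window, divided by the number of hills in
#' it. The replica is flagged stationary when the trailing rate falls
#' below \code{fraction} of the first window's rate. With constant-height
#' hills the trailing rate has a nonzero fluctuation floor (hills keep
#' being added after the well is filled), so the default threshold is a
#' substantial fraction of the initial rate rather than zero.
#'
#' @param log a \code{\link{BemetaLog}}.
#' @param window hills per window (default 50).
#' @param fraction stationarity threshold relative to the initial rate.
#' @param ngrid grid points for profile evaluation.
#' @return data.frame(replica, initialRate, trailingRate, stationary).
#' @export
convergenceDiagnostic <- function(log, window = 50, fraction = 0.5,
                                  ngrid = 200) {
  out <- lapply(seq_along(log@hills), function(r) {
    b <- log@hills[[r]]
    n <- nHills(b)
    if (n == 0)
      return(data.frame(replica = r, initialRate = 0, trailingRate = 0,
                        stationary = TRUE))
    if (n < 2 * window)
      stop("window too long: replica ", r, " has only ", n, " hills")
    rng <- range(b@centers[, 1])
    grid <- seq(rng[1] - 2 * b@sigma, rng[2] + 2 * b@sigma,
                length.out = ngrid)
    addedSd <- function(idx) {
      dc <- outer(grid, b@centers[idx, 1], "-")
      v <- drop(exp(-(dc^2) / (2 * b@sigma^2)) %*% b@heights[idx])
      stats::sd(v) / length(idx)
    }
    first <- addedSd(seq_len(window))
    last <- addedSd((n - window + 1):n)
    data.frame(replica = r, initialRate = first, trailingRate = last,
               stationary = last < fraction * first)
  })
  do.call(rbind, out)
}

#' Write hill histories in a PLUMED-style HILLS text format
#'
#' Columns: time (step index), centre per CV, sigma per CV, height.
#'
#' @param bias a \code{\link{BiasPotential}}.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeHills <- function(bias, path) {
  d <- length(bias@sigma)
  hdr <- paste("#! FIELDS time",
               paste(bias@cvNames, collapse = " "),
               paste(paste0("sigma_", bias@cvNames), collapse = " "),
               "height")
  rows <- vapply(seq_len(nHills(bias)), function(k)
    paste(format(bias@times[k]),
          paste(format(bias@centers[k, ], digits = 10), collapse = " "),
          paste(format(bias@sigma, digits = 10), collapse = " "),
          format(bias@heights[k], digits = 10)), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a HILLS-style text file back into a BiasPotential
#' @param path file written by \code{\link{writeHills}} (or PLUMED).
#' @param stride deposition stride to record.
#' @return a \code{\link{BiasPotential}}.
#' @export
readHills <- function(path, stride = 500) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#! FIELDS ", "", lines[1]), " +")[[1]]
  dat <- utils::read.table(text = lines[-1])
  names(dat) <- hdr
  cvn <- hdr[!(hdr %in% c("time", "height")) & !grepl("^sigma_", hdr)]
  centers <- as.matrix(dat[, cvn, drop = FALSE])
  sig <- as.numeric(dat[1, paste0("sigma_", cvn)])
  new("BiasPotential", cvNames = cvn, sigma = sig, centers = centers,
      heights = dat$height, times = dat$time, stride = stride)
}
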