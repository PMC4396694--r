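#' @include AllClasses.R metadynamics.R
NULL

#' Bin post-equilibration CV trajectories into microstates
#'
#' Regular-grid binning in CV space: every frame recorded after
#' \code{t_eq} is assigned to exactly one bin; only occupied bins are
#' stored, with per-replica frame counts.
#'
#' @param cvTraj list of per-replica trajectories: numeric matrices whose
#'   first column is the step index and remaining column(s) the CV
#'   value(s) (a \code{\link{BemetaLog}} \code{cvTraj} slot works
#'   directly). All replicas must report the same CV dimensions.
#' @param t_eq equilibration time (step index); only frames with
#'   step > t_eq are counted.
#' @param binWidths numeric bin widths per CV dimension.
#' @param cvNames optional CV names.
#' @return a \code{\link{MicrostateTable}}.
#' @export
assignMicrostates <- function(cvTraj, t_eq, binWidths,
                              cvNames = paste0("cv", seq_along(binWidths))) {
  if (is(cvTraj, "BemetaLog")) cvTraj <- cvTraj@cvTraj
  if (any(binWidths <= 0)) stop("bin widths must be positive")
  nrep <- length(cvTraj)
  d <- length(binWidths)
  keys <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    tr <- cvTraj[[r]]
    tr <- tr[tr[, 1] > t_eq, , drop = FALSE]
    if (nrow(tr) == 0)
      stop("no frames after t_eq = ", t_eq, " in replica ", r)
    s <- tr[, -1, drop = FALSE]
    if (ncol(s) != d) stop("CV dimension mismatch in replica ", r)
    idx <- floor(sweep(s, 2, binWidths, "/"))
    keys[[r]] <- apply(idx, 1, paste, collapse = "_")
  }
  allKeys <- sort(unique(unlist(keys)))
  counts <- matrix(0, length(allKeys), nrep)
  for (r in seq_len(nrep)) {
    tab <- table(keys[[r]])
    counts[match(names(tab), allKeys), r] <- as.numeric(tab)
  }
  centers <- matrix(unlist(lapply(strsplit(allKeys, "_", fixed = TRUE),
                                  function(p)
                                    (as.numeric(p) + 0.5) * binWidths)),
                    ncol = d, byrow = TRUE)
  new("MicrostateTable", centers = centers, counts = counts,
      binWidths = binWidths, cvNames = cvNames)
}

#' WHAM free energies over microstates
#'
#' Solves the weighted-histogram equations for microstate probabilities
#' under per-replica static bias potentials:
#' p_a = sum_r n_ra / sum_r N_r exp((f_r - V_r(s_a)) / k_B T), with
#' exp(-f_r / k_B T) = sum_a p_a exp(-V_r(s_a) / k_B T), iterated until
#' the normalisation constants are self-consistent. Free energies
#' F_a = -k_B T log p_a are gauged so the visited minimum is 0; empty
#' microstates get +Inf. Log-sum-exp stabilisation is used throughout.
#'
#' @param table a \code{\link{MicrostateTable}}.
#' @param biasAtCenter numeric matrix nmicro x nreplica of bias energies
#'   V_r(s_a), kJ/mol (e.g. from \code{\link{biasOnMicrostates}}).
#' @param temperature Kelvin.
#' @param tol convergence tolerance on max |delta f_r|, kJ/mol.
#' @param maxIter iteration cap.
#' @return a \code{\link{FreeEnergyTable}}.
#' @export
whamFreeEnergies <- function(table, biasAtCenter, temperature = 300,
                             tol = 1e-8, maxIter = 1e5) {
  counts <- table@counts
  nmicro <- nrow(counts); nrep <- ncol(counts)
  if (!all(dim(biasAtCenter) == c(nmicro, nrep)))
    stop("biasAtCenter must be nmicro x nreplicas")
  if (!all(is.finite(biasAtCenter))) stop("non-finite bias values")
  kT <- .R_GAS * temperature
  nTot <- rowSums(counts)
  Nr <- colSums(counts)
  vis <- nTot > 0
  f <- numeric(nrep)
  logsumexp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    # log p_a (unnormalised)
    denom <- vapply(seq_len(nmicro), function(a) {
      logsumexp(log(Nr) + (f - biasAtCenter[a, ]) / kT)
    }, numeric(1))
    logp <- ifelse(vis, log(nTot) - denom, -Inf)
    logp <- logp - logsumexp(logp[vis])
    fNew <- vapply(seq_len(nrep), function(r)
      -kT * logsumexp(logp[vis] - biasAtCenter[vis, r] / kT), numeric(1))
    fNew <- fNew - fNew[1]  # gauge: f_1 = 0
    resid <- max(abs(fNew - f))
    f <- fNew
    if (resid < tol) break
    if (it >= maxIter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3e)",
                   it, resid))
  }
  Fa <- -kT * logp
  Fa[vis] <- Fa[vis] - min(Fa[vis])
  Fa[!vis] <- Inf
  new("FreeEnergyTable", F = Fa, f = f, temperature = temperature,
      iterations = it, residual = resid, microstates = table)
}

#' Bias energies of replica hill sums at microstate centres
#'
#' Evaluates each replica's (optionally time-averaged) bias at every
#' microstate centre. In quasi-stationary metadynamics the bias after
#' equilibration grows uniformly; averaging V(s, t) over deposition times
#' in the window [t_from, t_to] gives the static bias WHAM assumes.
#'
#' @param table a \code{\link{MicrostateTable}} whose CV dimensions match
#'   the biased CV of each replica (1D per replica: column r is replica
#'   r's biased CV).
#' @param biases list of \code{\link{BiasPotential}}, one per replica.
#' @param cvColumn integer vector: which microstate CV column each
#'   replica's bias acts on (default: replica r on column r, capped to the
#'   table dimension).
#' @param t_from,t_to averaging window over hill deposition times
#'   (defaults: final bias, no averaging).
#' @param nAvg number of time points in the averaging window.
#' @return numeric matrix nmicro x nreplicas, kJ/mol.
#' @export
biasOnMicrostates <- function(table, biases, cvColumn = NULL,
                              t_from = Inf, t_to = Inf, nAvg = 11) {
  nrep <- length(biases)
  d <- ncol(table@centers)
  if (is.null(cvColumn)) cvColumn <- pmin(seq_len(nrep), d)
  out <- matrix(0, nrow(table@centers), nrep)
  for (r in seq_len(nrep)) {
    b <- biases[[r]]
    s <- table@centers[, cvColumn[r]]
    if (is.finite(t_from) && t_from < t_to) {
      ts <- seq(t_from, t_to, length.out = nAvg)
      acc <- matrix(0, length(s), length(ts))
      for (j in seq_along(ts))
        acc[, j] <- vapply(s, function(si) evaluateBias(b, si, ts[j]),
                           numeric(1))
      out[, r] <- rowMeans(acc)
    } else {
      out[, r] <- vapply(s, function(si) evaluateBias(b, si), numeric(1))
    }
  }
  out
}

#' Project microstate free energies onto a 1D or 2D grid
#'
#' Boltzmann-sums microstate weights into grid cells:
#' F(cell) = -k_B T log sum_{a in cell} exp(-F_a / k_B T), re-gauged to a
#' minimum of 0 over visited cells. Total probability is conserved.
#'
#' @param fet a \code{\link{FreeEnergyTable}}.
#' @param projection numeric vector (1D) or matrix with one row per
#'   microstate (2D): the projection coordinate(s) of each microstate.
#' @param grid list of axis definitions: list(name, unit, edges), one per
#'   projection dimension.
#' @return a \code{\link{FESGrid}}.
#' @export
projectFES <- function(fet, projection, grid) {
  if (!is.matrix(projection)) projection <- matrix(projection, ncol = 1)
  nmicro <- length(fet@F)
  if (nrow(projection) != nmicro)
    stop("projection rows != number of microstates")
  if (nmicro == 0 || all(!is.finite(fet@F))) stop("empty projection")
  kT <- .R_GAS * fet@temperature
  ndim <- length(grid)
  cellIdx <- vapply(seq_len(ndim), function(j) {
    i <- findInterval(projection[, j], grid[[j]]$edges,
                      rightmost.closed = TRUE)
    if (any(i < 1 | i >= length(grid[[j]]$edges)))
      stop("projection values outside grid on axis ", grid[[j]]$name)
    i
  }, integer(nmicro))
  if (!is.matrix(cellIdx)) cellIdx <- matrix(cellIdx, ncol = ndim)
  dims <- vapply(grid, function(a) length(a$edges) - 1L, integer(1))
  Fcell <- array(Inf, dims)
  lin <- if (ndim == 1) cellIdx[, 1] else
    cellIdx[, 1] + (cellIdx[, 2] - 1) * dims[1]
  w <- exp(-fet@F / kT)
  sums <- tapply(w, lin, sum)
  Fcell[as.integer(names(sums))] <- -kT * log(as.numeric(sums))
  vis <- is.finite(Fcell)
  Fcell[vis] <- Fcell[vis] - min(Fcell[vis])
  new("FESGrid", axes = grid, F = Fcell, temperature = fet@temperature)
}

#' Identity-projection FES over the microstate bins themselves
#'
#' Builds the 1D or 2D free-energy surface on a grid aligned with the
#' microstate binning (so every microstate maps to its own cell), which
#' is the natural input for \code{\link{findBasins}} when the CVs are the
#' projection coordinates.
#'
#' @param fet a \code{\link{FreeEnergyTable}}.
#' @param cvColumns which CV columns to project on (1 or 2 of them).
#' @return a \code{\link{FESGrid}}; attribute \code{"cellOfMicrostate"}
#'   gives each microstate's linear cell index.
#' @export
microstateFES <- function(fet, cvColumns = 1L) {
  ms <- fet@microstates
  w <- ms@binWidths[cvColumns]
  cent <- ms@centers[, cvColumns, drop = FALSE]
  grid <- lapply(seq_along(cvColumns), function(j) {
    idx <- round(cent[, j] / w[j] - 0.5)
    list(name = ms@cvNames[cvColumns[j]], unit = "CV units",
         edges = seq(min(idx), max(idx) + 1) * w[j])
  })
  fes <- projectFES(fet, cent, grid)
  dims <- vapply(grid, function(a) length(a$edges) - 1L, integer(1))
  cellIdx <- vapply(seq_along(cvColumns), function(j)
    findInterval(cent[, j], grid[[j]]$edges, rightmost.closed = TRUE),
    integer(nrow(cent)))
  if (!is.matrix(cellIdx)) cellIdx <- matrix(cellIdx, ncol = length(cvColumns))
  lin <- if (length(cvColumns) == 1) cellIdx[, 1] else
    cellIdx[, 1] + (cellIdx[, 2] - 1) * dims[1]
  attr(fes, "cellOfMicrostate") <- lin
  fes
}

#' Basin free energies and populations from a reconstructed landscape
#'
#' Convenience wrapper: identity-projected FES over the microstate bins,
#' watershed basin detection, and per-basin free energies from
#' basin-restricted partition sums, Delta G_k = -k_B T log(p_k / p_1).
#'
#' @param fet a \code{\link{FreeEnergyTable}}.
#' @param min_barrier basin merge threshold, kJ/mol.
#' @param cvColumns projection CV columns.
#' @return data.frame(label, deltaG, population), basins by ascending
#'   deltaG.
#' @export
basinThermodynamics <- function(fet, min_barrier = 1, cvColumns = 1L) {
  fes <- microstateFES(fet, cvColumns)
  bas <- findBasins(fes, min_barrier)
  mem <- attr(bas, "membership")
  cellOf <- attr(fes, "cellOfMicrostate")
  basOf <- mem[as.character(cellOf)]
  pops <- boltzmannPopulations(NULL, fet@temperature, fet = fet,
                               cellOfMicrostate = basOf)
  kT <- .R_GAS * fet@temperature
  dg <- -kT * log(pops$population)
  ord <- order(dg)
  data.frame(label = pops$label[ord], deltaG = dg[ord] - min(dg),
             population = pops$population[ord])
}

#' Find basins of a free-energy surface by steepest-descent watershed
#'
#' Every visited grid cell is walked downhill to its local minimum
#' (8-neighbourhood in 2D, 2-neighbourhood in 1D); cells draining to the
#' same minimum form a basin. Basins whose separating barrier (the lowest
#' saddle on their shared boundary, relative to the higher minimum) is
#' below \code{min_barrier} are merged. Basins are reported by ascending
#' free-energy offset from the global minimum.
#'
#' @param fes a \code{\link{FESGrid}}.
#' @param min_barrier merge threshold, kJ/mol.
#' @return data.frame(label, minimum (location of the minimum cell
#'   centre), Fmin, deltaG, nCells) with one row per basin, plus a
#'   \code{"membership"} attribute mapping each visited cell (linear
#'   index) to a basin label.
#' @export
findBasins <- function(fes, min_barrier = 1) {
  Fv <- fes@F
  dims <- dim(Fv) %||% length(Fv)
  if (length(dims) == 1 || is.null(dim(Fv))) {
    dims <- c(length(Fv), 1L)
    Fv <- matrix(Fv, ncol = 1)
  }
  nx <- dims[1]; ny <- dims[2]
  vis <- which(is.finite(Fv))
  if (!length(vis)) stop("no visited cells")
  neigh <- function(i) {
    x <- (i - 1) %% nx + 1; y <- (i - 1) %/% nx + 1
    dx <- rep(-1:1, 3); dy <- rep(-1:1, each = 3)
    xx <- x + dx; yy <- y + dy
    ok <- xx >= 1 & xx <= nx & yy >= 1 & yy <= ny & !(dx == 0 & dy == 0)
    (yy[ok] - 1) * nx + xx[ok]
  }
  # steepest descent with memoised assignment
  assign <- rep(NA_integer_, nx * ny)
  for (i in vis) {
    path <- integer(0)
    cur <- i
    while (is.na(assign[cur])) {
      path <- c(path, cur)
      nb <- neigh(cur)
      nb <- nb[is.finite(Fv[nb])]
      if (!length(nb) || min(Fv[nb]) >= Fv[cur]) break
      cur <- nb[which.min(Fv[nb])]
    }
    root <- if (is.na(assign[cur])) cur else assign[cur]
    assign[c(path, cur)] <- root
  }
  mins <- sort(unique(assign[vis]))
  # saddle heights between basin pairs along shared boundaries
  repeat {
    if (length(mins) <= 1) break
    saddle <- matrix(Inf, length(mins), length(mins))
    for (i in vis) {
      bi <- match(assign[i], mins)
      for (j in neigh(i)) {
        if (!is.finite(Fv[j])) next
        bj <- match(assign[j], mins)
        if (bi == bj) next
        s <- max(Fv[i], Fv[j])
        if (s < saddle[bi, bj]) saddle[bi, bj] <- saddle[bj, bi] <- s
      }
    }
    # barrier relative to the shallower (higher-F) of the two minima
    bar <- saddle
    for (a in seq_along(mins)) for (b in seq_along(mins))
      if (is.finite(saddle[a, b]))
        bar[a, b] <- saddle[a, b] - max(Fv[mins[a]], Fv[mins[b]])
    low <- which(bar == min(bar), arr.ind = TRUE)[1, ]
    if (!is.finite(bar[low[1], low[2]]) ||
        bar[low[1], low[2]] >= min_barrier) break
    # merge the shallower basin into the deeper one
    a <- mins[low[1]]; b <- mins[low[2]]
    keep <- if (Fv[a] <= Fv[b]) a else b
    drop <- setdiff(c(a, b), keep)
    assign[assign == drop] <- keep
    mins <- sort(unique(assign[vis]))
  }
  Fmins <- Fv[mins]
  ord <- order(Fmins)
  mins <- mins[ord]; Fmins <- Fmins[ord]
  loc <- function(i) {
    x <- (i - 1) %% nx + 1; y <- (i - 1) %/% nx + 1
    ax <- fes@axes
    cx <- (ax[[1]]$edges[x] + ax[[1]]$edges[x + 1]) / 2
    if (length(ax) == 2)
      c(cx, (ax[[2]]$edges[y] + ax[[2]]$edges[y + 1]) / 2)
    else cx
  }
  out <- data.frame(
    label = paste0("basin", seq_along(mins)),
    Fmin = Fmins,
    deltaG = Fmins - Fmins[1],
    nCells = vapply(mins, function(m) sum(assign[vis] == m), integer(1)))
  out$minimum <- I(lapply(mins, loc))
  attr(out, "membership") <- setNames(
    paste0("basin", match(assign[vis], mins)), vis)
  out
}

#' Boltzmann populations of basins
#'
#' From basin free-energy offsets: p_k = exp(-dG_k / RT) / sum_l
#' exp(-dG_l / RT) with R = 0.0083145 kJ/mol/K ("minima" mode). When a
#' \code{FreeEnergyTable} and basin membership are supplied, populations
#' are instead basin-restricted partition sums over microstates
#' ("partition_sum" mode); the mode used is recorded in the result.
#'
#' @param deltaG numeric basin free-energy offsets (kJ/mol, >= 0), or the
#'   data.frame from \code{\link{findBasins}}.
#' @param temperature Kelvin (> 0).
#' @param fet optional \code{\link{FreeEnergyTable}} for partition-sum
#'   mode.
#' @param cellOfMicrostate optional character: basin label per microstate,
#'   required with \code{fet}.
#' @return data.frame(label, population) with attribute "mode" and
#'   "temperature"; populations sum to 1.
#' @examples
#' boltzmannPopulations(c(0, 0.7, 2.8), 300)  # 0.48 / 0.36 / 0.16
#' @export
boltzmannPopulations <- function(deltaG, temperature = 300, fet = NULL,
                                 cellOfMicrostate = NULL) {
  if (temperature <= 0) stop("temperature must be > 0")
  kT <- .R_GAS * temperature
  if (!is.null(fet)) {
    stopifnot(!is.null(cellOfMicrostate),
              length(cellOfMicrostate) == length(fet@F))
    w <- exp(-fet@F / kT)
    agg <- tapply(w, cellOfMicrostate, sum)
    pops <- as.numeric(agg) / sum(agg)
    out <- data.frame(label = names(agg), population = pops)
    attr(out, "mode") <- "partition_sum"
  } else {
    if (is.data.frame(deltaG)) {
      labels <- deltaG$label
      deltaG <- deltaG$deltaG
    } else labels <- paste0("basin", seq_along(deltaG))
    if (any(deltaG < 0)) stop("deltaG must be >= 0")
    w <- exp(-deltaG / kT)
    out <- data.frame(label = labels, population = w / sum(w))
    attr(out, "mode") <- "minima"
  }
  attr(out, "temperature") <- temperature
  stopifnot(abs(sum(out$population) - 1) < 1e-12)
  out
}

#' Export a FES grid as gnuplot-style columns
#' @param fes a \code{\link{FESGrid}}.
#' @param path output text file (coordinate column(s), free energy;
#'   unvisited cells written as "inf").
#' @return path, invisibly.
#' @export
writeFESGrid <- function(fes, path) {
  ax <- fes@axes
  mid <- function(a) (head(a$edges, -1) + tail(a$edges, -1)) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(vapply(ax, function(a)
    paste0(a$name, " (", a$unit, ")"), character(1)), collapse = " x "),
    "; F kJ/mol"), con)
  if (length(ax) == 1) {
    x <- mid(ax[[1]])
    writeLines(sprintf("%g %s", x, ifelse(is.finite(fes@F),
                                          sprintf("%.6f", fes@F), "inf")),
               con)
  } else {
    x <- mid(ax[[1]]); y <- mid(ax[[2]])
    for (j in seq_along(y)) {
      writeLines(sprintf("%g %g %s", x, y[j],
                         ifelse(is.finite(fes@F[, j]),
                                sprintf("%.6f", fes@F[, j]), "inf")), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Serialize a microstate table (with free energies) to TSV
#' @param fet a \code{\link{FreeEnergyTable}}.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeFreeEnergyTable <- function(fet, path) {
  ms <- fet@microstates
  df <- data.frame(id = seq_len(nrow(ms@centers)))
  for (j in seq_len(ncol(ms@centers)))
    df[[ms@cvNames[j]]] <- ms@centers[, j]
  df$F_kJmol <- fet@F
  for (r in seq_len(ncol(ms@counts)))
    df[[paste0("n_rep", r)]] <- ms@counts[, r]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# WHAM free energies; T = %g K; iterations = %d; residual = %.3e",
                     fet@temperature, fet@iterations, fet@residual), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}
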