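test_that("bond unit vectors are unit-norm; missing H handled", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.02))
  s <- structureFromAtoms(c("N", "H"), "ALA", "A", c(5, 5), xyz)
  bv <- bondUnitVectors(s, data.frame(resno = 5, atom1 = "N", atom2 = "H",
                                      D_obs = 1, segment = NA), "A",
                        buildH = FALSE)
  expect_equal(bv$vectors[1, ], c(0, 0, 1))
  # random-coil structure: all constructed N-H vectors unit norm
  coil <- makeIdealPeptide("coil", 12, seed = 3)
  recs <- data.frame(resno = 2:12, atom1 = "N", atom2 = "H", D_obs = 1,
                     segment = NA)
  bv2 <- bondUnitVectors(coil, recs, "A")
  expect_true(all(abs(sqrt(rowSums(bv2$vectors[bv2$used, ]^2)) - 1) <
                    1e-12))
  # residue 1 has no preceding carbonyl: skipped with a warning
  recs1 <- rbind(data.frame(resno = 1, atom1 = "N", atom2 = "H",
                            D_obs = 1, segment = NA), recs)
  expect_warning(bv3 <- bondUnitVectors(coil, recs1, "A"), "skipped")
  expect_false(bv3$used[1])
})

test_that("constructed amide H sits 1.02 A from N on the in-plane bisector", {
  coil <- makeIdealPeptide("coil", 8, seed = 5)
  at <- atomTable(coil)
  H <- constructAmideH(coil, "A", 4)
  N <- unlist(at[at$resno == 4 & at$name == "N", c("x", "y", "z")])
  CA <- unlist(at[at$resno == 4 & at$name == "CA", c("x", "y", "z")])
  C <- unlist(at[at$resno == 3 & at$name == "C", c("x", "y", "z")])
  expect_equal(sqrt(sum((H - N)^2)), 1.02, tolerance = 1e-9)
  # geometric construction oracle: N->H is antiparallel to the bisector
  # of the two N->neighbour unit vectors, hence coplanar and symmetric
  u1 <- (C - N) / sqrt(sum((C - N)^2))
  u2 <- (CA - N) / sqrt(sum((CA - N)^2))
  nh <- (H - N) / 1.02
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  expect_equal(nh, bis, tolerance = 1e-9)
})

test_that("SVD tensor fit: exact recovery, noise propagation, rank guards", {
  S <- randomSaupeTensor(1e-3, seed = 4)
  syn <- makeSyntheticRDC(S, n_records = 20, noise_sd = 0, seed = 2)
  fit <- fitAlignmentTensorSVD(syn$vectors, syn$records$D_obs)
  expect_lt(max(abs(saupeMatrix(fit) - saupeMatrix(S))), 1e-10)
  expect_lt(abs(sum(diag(saupeMatrix(fit)))), 1e-12)
  # Gaussian noise: residual rms ~ noise sd within a factor 1.3
  syn2 <- makeSyntheticRDC(S, n_records = 200, noise_sd = 0.5, seed = 3)
  fit2 <- fitAlignmentTensorSVD(syn2$vectors, syn2$records$D_obs)
  rms <- sqrt(mean((backcalcRDC(fit2, syn2$vectors) -
                      syn2$records$D_obs)^2))
  expect_lt(rms, 0.5 * 1.3)
  expect_gt(rms, 0.5 / 1.3)
  expect_error(fitAlignmentTensorSVD(syn$vectors[1:4, ],
                                     syn$records$D_obs[1:4]),
               "degenerate")
  # rank-deficient orientations (all vectors identical)
  same <- matrix(rep(c(0, 0, 1), 10), 10, 3, byrow = TRUE)
  expect_error(fitAlignmentTensorSVD(same, rep(1, 10)),
               "condition number")
})

test_that("back-calculation is the quadratic form in the direction cosines", {
  vecs <- diag(3)
  zero <- new("AlignmentTensor", S = matrix(0, 3, 3))
  expect_equal(backcalcRDC(zero, vecs), c(0, 0, 0))
  a <- 1e-3
  Sdiag <- new("AlignmentTensor", S = diag(c(-a / 2, -a / 2, a)))
  expect_equal(backcalcRDC(Sdiag, matrix(c(0, 0, 1), 1), D_max = 2),
               2 * a)
  # covariance under joint rotation of tensor and vectors
  set.seed(10)
  S <- randomSaupeTensor(1e-3)
  v <- makeSyntheticRDC(S, n_records = 15, seed = 8)$vectors
  for (k in 1:10) {
    R <- randomRotation()
    S2 <- new("AlignmentTensor", S = R %*% saupeMatrix(S) %*% t(R))
    expect_equal(backcalcRDC(S2, v %*% t(R)), backcalcRDC(S, v),
                 tolerance = 1e-12)
  }
})

test_that("Q factor: limits, printed arithmetic, scale invariance", {
  expect_equal(qFactor(c(1, 2, -1), c(1, 2, -1)), 0)
  expect_equal(qFactor(c(1, 2, -1), c(0, 0, 0)), 1)
  expect_equal(qFactor(c(1, -1), c(0.5, -0.5)), 0.5)
  set.seed(2)
  o <- stats::rnorm(20); c0 <- stats::rnorm(20)
  expect_equal(qFactor(3.7 * o, 3.7 * c0), qFactor(o, c0))
  expect_error(qFactor(c(0, 0), c(1, 1)), "undefined")
})

test_that("fitted tensor is locally optimal in Q on the fit subset", {
  S <- randomSaupeTensor(1e-3, seed = 6)
  syn <- makeSyntheticRDC(S, n_records = 30, noise_sd = 0.3, seed = 7)
  fit <- fitAlignmentTensorSVD(syn$vectors, syn$records$D_obs)
  q0 <- qFactor(syn$records$D_obs, backcalcRDC(fit, syn$vectors))
  set.seed(8)
  for (k in 1:25) {
    pert <- saupeMatrix(fit) + 1e-4 * {
      m <- matrix(stats::rnorm(9), 3); m <- (m + t(m)) / 2
      m - diag(rep(sum(diag(m)) / 3, 3))
    }
    qp <- qFactor(syn$records$D_obs,
                  backcalcRDC(new("AlignmentTensor", S = pert),
                              syn$vectors))
    expect_gte(qp, q0)
  }
})

test_that("tensor anisotropy returns consistent eigen decomposition", {
  a <- 2e-3
  S <- new("AlignmentTensor", S = diag(c(-a / 2, -a / 2, a)))
  an <- tensorAnisotropy(S)
  expect_equal(an$Da, a / 2)
  expect_equal(an$rhombicity, 0)
})

test_that("ensemble Q: identical frames equal the single-structure result", {
  coil <- makeIdealPeptide("coil", 20, seed = 9)
  S <- randomSaupeTensor(1e-3, seed = 10)
  syn <- makeSyntheticRDC(S, structure = coil, noise_sd = 0, seed = 11)
  recs <- syn$records
  recs$segment <- rep(c("s1", "s2"), length.out = nrow(recs))
  fitSel <- seq_len(10)
  ens <- makeEnsemble(list(coil, coil, coil))
  for (mode in c("per_frame_tensor", "single_tensor")) {
    r1 <- ensembleQ(coil, recs, fitSel, mode = mode)
    r3 <- ensembleQ(ens, recs, fitSel, mode = mode)
    expect_equal(r3$Q, r1$Q, tolerance = 1e-9)
    expect_equal(r3$D_calc, r1$D_calc, tolerance = 1e-9)
  }
  # noiseless self-consistent data: Q ~ 0 on held-out records
  r <- ensembleQ(coil, recs, fitSel)
  expect_lt(r$Q, 1e-8)
  expect_named(r$Qsegments, c("s1", "s2"), ignore.order = TRUE)
})

test_that("two-state ensemble Q is minimised at the true state weights", {
  s1 <- makeIdealPeptide("coil", 20, seed = 21)
  s2 <- makeIdealPeptide("coil", 20, seed = 22)
  S <- randomSaupeTensor(1e-3, seed = 23)
  recs <- data.frame(resno = 2:20, atom1 = "N", atom2 = "H",
                     D_obs = NA_real_, segment = NA_character_)
  v1 <- bondUnitVectors(s1, recs, "A")$vectors
  v2 <- bondUnitVectors(s2, recs, "A")$vectors
  # observations are the 60/40 population average of the exact RDCs
  recs$D_obs <- 0.6 * backcalcRDC(S, v1) + 0.4 * backcalcRDC(S, v2)
  fitSel <- seq_len(8)
  qAt <- function(w) {
    ens <- makeEnsemble(list(s1, s2), weights = c(w, 1 - w))
    ensembleQ(ens, recs, fitSel, mode = "single_tensor")$Q
  }
  expect_lt(qAt(0.6), 0.02)
  expect_gt(qAt(1.0), qAt(0.6))
  expect_gt(qAt(0.0), qAt(0.6))
})

test_that("ensemble Q is permutation-invariant over frames; fit-only segments warn", {
  s1 <- makeIdealPeptide("coil", 16, seed = 31)
  s2 <- makeIdealPeptide("coil", 16, seed = 32)
  s3 <- makeIdealPeptide("coil", 16, seed = 33)
  S <- randomSaupeTensor(1e-3, seed = 34)
  syn <- makeSyntheticRDC(S, structure = s1, noise_sd = 0.2, seed = 35)
  recs <- syn$records
  a <- ensembleQ(makeEnsemble(list(s1, s2, s3)), recs, 1:8)
  b <- ensembleQ(makeEnsemble(list(s3, s1, s2)), recs, 1:8)
  expect_equal(a$Q, b$Q, tolerance = 1e-9)
  recs$segment <- NA_character_
  recs$segment[1:8] <- "fitonly"
  expect_warning(r <- ensembleQ(makeEnsemble(list(s1, s2)), recs, 1:8),
                 "fitonly")
  expect_false("fitonly" %in% names(r$Qsegments))
})

test_that("RDC tables read from TSV with segment labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tatom1\tatom2\tD_obs_Hz\tsegment",
               "130\tN\tH\t5.2\tbeta1", "131\tN\tH\t-3.1\tbeta1"), f)
  r <- readRDCTable(f)
  expect_equal(r$D_obs, c(5.2, -3.1))
  expect_equal(r$segment, c("beta1", "beta1"))
})
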