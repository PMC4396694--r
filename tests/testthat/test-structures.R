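test_that("PDB round trip preserves coordinates and atom identity", {
  s <- makeIdealPeptide("alpha_helix", 10)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f1)
  ens <- readPDB(f1)
  expect_equal(nFrames(ens), 1)
  at0 <- atomTable(s)
  at1 <- atomTable(ens)
  expect_identical(paste(at1$chain, at1$resno, at1$name),
                   paste(at0$chain, at0$resno, at0$name))
  expect_lt(max(abs(as.matrix(at1[, c("x", "y", "z")]) -
                    as.matrix(at0[, c("x", "y", "z")]))), 1e-3)
})

test_that("multi-model files become multi-frame ensembles; HETATMs kept", {
  se <- makeStateEnsemble(n_frames = 3, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(se$ensemble, f)
  ens <- readPDB(f)
  expect_equal(nFrames(ens), 3)
  expect_true("MG" %in% atomTable(ens)$name)
  # identical atom layout across frames is enforced by the class
  expect_true(validObject(ens))
})

test_that("parser errors on malformed coordinates and empty files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.4xx   0.000   0.000  1.00  0.00           C"),
    f)
  expect_error(readPDB(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(readPDB(f2), "no ATOM")
  expect_error(readPDB(file.path(tempdir(), "absent-file.pdb")),
               "not found")
})

test_that("alternate locations resolve to highest occupancy, tie to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       8.000   0.000   0.000  0.50  0.00           C"),
    f)
  ens <- readPDB(f)
  at <- atomTable(ens)
  expect_equal(nrow(at), 2)
  expect_equal(at$x[at$name == "N"], 9.0)   # higher occupancy wins
  expect_equal(at$x[at$name == "CA"], 1.0)  # tie -> altLoc A
})

test_that("dihedral angle follows the IUPAC convention", {
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, -1, 0)), pi)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0)
  # rotating the cis reference by +60 deg about the p2->p3 axis gives
  # +pi/3 (rotation-matrix oracle)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  p4 <- drop(Rx(pi / 3) %*% c(1, 1, 0))
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), p4),
               pi / 3, tolerance = 1e-12)
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), "coincident")
  expect_error(dihedralAngle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(2, 0, 0)), "colinear")
})

test_that("dihedral angle is invariant under rigid transforms", {
  set.seed(42)
  pts <- list(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0.3, 0.8))
  a0 <- do.call(dihedralAngle, pts)
  for (k in 1:20) {
    R <- randomRotation()
    tr <- stats::runif(3, -5, 5)
    a1 <- do.call(dihedralAngle, lapply(pts, function(p) drop(R %*% p) + tr))
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("backbone dihedral enumeration yields 2(N-1) ordered angles", {
  for (n in c(4, 7, 12)) {
    s <- makeIdealPeptide("extended", n)
    d <- enumerateBackboneDihedrals(s, "A")
    expect_equal(nrow(d), 2 * (n - 1))
  }
  # complete tripeptide: trim a 4-mer to residues 1-3
  s4 <- makeIdealPeptide("alpha_helix", 4)
  s <- new("Structure", atoms = s4@atoms[s4@atoms$resno <= 3, ],
           id = "tripeptide")
  d <- enumerateBackboneDihedrals(s, "A")
  expect_equal(nrow(d), 4)
  # psi1, phi2, psi2, phi3 in chain order
  expect_equal(d$label, c("psi", "phi", "psi", "phi"))
  expect_equal(d$resno, c(1, 2, 2, 3))
})

test_that("missing backbone atoms omit angles with a warning", {
  s <- makeIdealPeptide("extended", 8)
  at <- s@atoms
  at <- at[!(at$resno == 5 & at$name == "C"), ]
  s2 <- new("Structure", atoms = at, id = "broken")
  expect_warning(d <- enumerateBackboneDihedrals(s2, "A"), "psi 5")
  expect_false(any(d$resno == 5 & d$label == "psi"))
  expect_false(any(d$resno == 6 & d$label == "phi"))
  # phi5 also needs C5, so it is omitted too; psi4 needs N5 only
  expect_true(any(d$resno == 4 & d$label == "psi"))
})

test_that("group centroid is the unweighted Calpha mean", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  s <- structureFromAtoms(c("CA", "CA"), "ALA", "A", 1:2, xyz)
  expect_equal(groupCentroid(s, residueSelection("A", 1, 2)), c(1, 0, 0))
  expect_equal(groupCentroid(s, residueSelection("A", 2, 2)), c(2, 0, 0))
  # 5-residue helix: equals independent arithmetic mean
  h <- makeIdealPeptide("alpha_helix", 5)
  at <- atomTable(h)
  ca <- at[at$name == "CA", ]
  expect_equal(groupCentroid(h, residueSelection("A", 1, 5)),
               c(mean(ca$x), mean(ca$y), mean(ca$z)))
  expect_error(groupCentroid(h, residueSelection("A", 100, 120)),
               "matched no atoms")
})

test_that("inter-group angle is the vertex angle, symmetric in its arms", {
  expect_equal(interGroupAngle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(interGroupAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(interGroupAngle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  set.seed(1)
  for (k in 1:10) {
    p <- matrix(stats::rnorm(9), 3)
    expect_equal(interGroupAngle(p[1, ], p[2, ], p[3, ]),
                 interGroupAngle(p[3, ], p[2, ], p[1, ]))
  }
  expect_error(interGroupAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
})

test_that("atom distance resolves unique selections", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  s <- structureFromAtoms(c("CZ", "MG"), c("PHE", "MG"), "A",
                          c(292, 400), xyz, hetatm = c(FALSE, TRUE))
  expect_equal(atomDistance(s, "A:292:CZ", "A:400:MG"), 5)
  expect_equal(atomDistance(s, "A:292:CZ", "A:292:CZ"), 0)
  s2 <- structureFromAtoms(c("CA", "CA"), "ALA", "A", 1:2,
                           rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(atomDistance(s2, "A:1-2:CA", "A:1:CA"), "ambiguous")
})

test_that("selection strings parse chain, ranges and atom filters", {
  sel <- parseSelection("A:256-260:CA")
  expect_equal(sel@chain, "A")
  expect_equal(c(sel@first, sel@last), c(256L, 260L))
  expect_equal(sel@atoms, "CA")
  expect_equal(parseSelection("B:42")@first, 42L)
  expect_error(parseSelection("nonsense"), "selection")
})
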