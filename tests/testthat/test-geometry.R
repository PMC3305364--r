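# Rigid-body operations: translations, rotations, tether alignment.

test_that("translation is exact, invertible and preserves bonds", {
  m <- buildFixture("methane")
  expect_equal(coords(translateMol(m, c(0, 0, 0))), coords(m))
  shifted <- translateMol(m, c(1, 2, 3))
  expect_equal(coords(shifted)[1, ] - coords(m)[1, ], c(x = 1, y = 2, z = 3))
  expect_identical(bonds(shifted), bonds(m))
  back <- translateMol(shifted, -c(1, 2, 3))
  expect_lt(max(abs(coords(back) - coords(m))), 1e-12)
})

test_that("setAtomLocation is a pure translation", {
  m <- buildFixture("methane")
  moved <- setAtomLocation(m, 1, c(0, 0, 0))
  expect_equal(unname(coords(moved)[1, ]), c(0, 0, 0))
  m2 <- randomCloudMolecule(20, seed = 3)
  before <- ClickMol:::.pairwiseDists(coords(m2))
  after <- ClickMol:::.pairwiseDists(coords(setAtomLocation(m2, 7, c(4, -2, 9))))
  expect_lt(max(abs(before - after)), 1e-9)
  expect_error(setAtomLocation(m, 99, c(0, 0, 0)), "invalid atom index")
})

test_that("axis rotations follow the right-handed closed form", {
  m <- ClickMol:::.newMolecule("C", matrix(c(1, 0, 0), ncol = 3))
  quarter <- rotateAboutLine(m, c(0, 0, 0), c(0, 0, 1), pi / 2)
  expect_lt(max(abs(coords(quarter) - c(0, 1, 0))), 1e-9)
  full <- rotateAboutLine(m, c(0, 0, 0), c(0, 0, 1), 2 * pi)
  expect_lt(max(abs(coords(full) - coords(m))), 1e-9)
  expect_error(rotateAboutLine(m, c(0, 0, 0), c(0, 0, 1e-9), 1),
               "degenerate")
  # two quarter turns compose to a half turn
  two <- rotateAboutPivot(rotateAboutPivot(m, c(0, 0, 0), c(0, 0, 1), pi / 2),
                          c(0, 0, 0), c(0, 0, 1), pi / 2)
  half <- rotateAboutPivot(m, c(0, 0, 0), c(0, 0, 1), pi)
  expect_lt(max(abs(coords(two) - coords(half))), 1e-9)
  expect_error(rotateAboutPivot(m, c(0, 0, 0), c(0, 0, 0), 1), "zero")
})

test_that("bond rotation fixes the axis atoms and respects C3 symmetry", {
  eth <- buildFixture("ethane")
  rot <- rotateAboutBond(eth, 1, 2, 1.234)
  expect_lt(max(abs(coords(rot)[1:2, ] - coords(eth)[1:2, ])), 1e-9)
  expect_equal(coords(rotateAboutBond(eth, 1, 2, 0)), coords(eth))
  # rotating by 120 degrees maps the methyl hydrogens onto each other
  rot3 <- rotateAboutBond(eth, 1, 2, 2 * pi / 3)
  hIdx <- which(elements(eth) == "H")
  d <- ClickMol:::.pairwiseDists(rbind(coords(rot3)[hIdx, ],
                                       coords(eth)[hIdx, ]))
  cross <- d[seq_along(hIdx), seq_along(hIdx) + length(hIdx)]
  expect_lt(max(apply(cross, 1, min)), 1e-6)
  expect_error(rotateAboutBond(eth, 1, 1, 1), "distinct")
})

test_that("every rigid operation preserves intramolecular distances", {
  for (seed in 1:25) {
    m <- randomCloudMolecule(15, seed = seed)
    before <- ClickMol:::.pairwiseDists(coords(m))
    ops <- list(
      translateMol(m, c(3.3, -1, 0.5)),
      setAtomLocation(m, 3, c(-2, 7, 1)),
      rotateAboutLine(m, c(0, 0, 0), c(1, 1, 1), 1.1),
      rotateAboutBond(m, 1, 2, 2.2),
      rotateAboutPivot(m, c(1, 2, 3), c(0, 1, 0), -0.7),
      alignByTethers(m, randomCloudMolecule(15, seed = seed + 100),
                     cbind(1:5, 1:5))$molecule)
    for (res in ops) {
      expect_lt(max(abs(ClickMol:::.pairwiseDists(coords(res)) - before)),
                1e-9)
    }
  }
})

test_that("tether alignment recovers known rigid transforms", {
  m <- buildFixture("methane")
  # identity when aligning a copy onto itself
  out <- alignByTethers(m, m, cbind(1:5, 1:5))
  expect_lt(out$residual, 1e-18)
  expect_lt(max(abs(coords(out$molecule) - coords(m))), 1e-9)
  # a single tether becomes a zero-length translation
  far <- translateMol(m, c(9, 9, 9))
  one <- alignByTethers(far, m, cbind(2L, 2L))
  expect_lt(sqrt(sum((coords(one$molecule)[2, ] - coords(m)[2, ])^2)), 1e-12)
  # self-recovery from seeded random rigid transforms
  ref <- randomCloudMolecule(5, seed = 17)
  for (seed in 1:40) {
    moved <- randomRigidTransform(ref, seed)
    got <- alignByTethers(moved, ref, cbind(1:5, 1:5))
    expect_lt(max(abs(coords(got$molecule) - coords(ref))), 1e-6)
    expect_lt(got$residual, 1e-10)
  }
})

test_that("aligned poses are locally optimal in squared tether length", {
  sqsum <- function(mob, ref, t) {
    sum((coords(mob)[t[, 1], , drop = FALSE] -
           coords(ref)[t[, 2], , drop = FALSE])^2)
  }
  for (seed in 1:20) {
    mob <- randomCloudMolecule(8, seed = seed)
    ref <- randomCloudMolecule(8, seed = seed + 500)
    t <- cbind(1:8, sample(8))
    out <- alignByTethers(mob, ref, t)
    base <- sqsum(out$molecule, ref, t)
    set.seed(seed)
    for (k in 1:20) {
      pert <- rotateAboutPivot(out$molecule, colMeans(coords(out$molecule)),
                               rnorm(3), runif(1, -0.05, 0.05))
      pert <- translateMol(pert, runif(3, -0.02, 0.02))
      expect_gte(sqsum(pert, ref, t), base - 1e-9)
    }
  }
})

test_that("merging concatenates atoms and shifts bond indices", {
  a <- buildFixture("methane")
  b <- translateMol(buildFixture("ethanol"), c(10, 0, 0))
  m <- mergeMolecules(a, b)
  expect_equal(natoms(m), natoms(a) + natoms(b))
  expect_equal(nrow(bonds(m)), nrow(bonds(a)) + nrow(bonds(b)))
  expect_equal(coords(m), rbind(coords(a), coords(b)))
  expect_equal(coords(mergeMolecules(a, ClickMol:::.emptyMolecule())),
               coords(a))
})

test_that("minimum intermolecular distance matches the brute-force oracle", {
  a <- ClickMol:::.newMolecule("C", matrix(c(0, 0, 0), ncol = 3))
  b <- ClickMol:::.newMolecule("C", matrix(c(3, 0, 0), ncol = 3))
  expect_equal(minInterMolDist(a, b), 3)
  expect_equal(minInterMolDist(a, a), 0)
  x <- randomCloudMolecule(50, seed = 5)
  y <- translateMol(randomCloudMolecule(50, seed = 6), c(25, 0, 0))
  brute <- min(as.vector(outer(seq_len(50), seq_len(50), Vectorize(
    function(i, j) sqrt(sum((coords(x)[i, ] - coords(y)[j, ])^2))))))
  expect_equal(minInterMolDist(x, y), brute, tolerance = 1e-12)
  expect_error(minInterMolDist(a, ClickMol:::.emptyMolecule()), "non-empty")
})
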