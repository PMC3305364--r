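# Bond inference, connectivity queries, hybridization, rings, branches.

test_that("bond perception follows covalent radii plus tolerance", {
  twoC <- ClickMol:::.newMolecule(c("C", "C"),
                                  rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(bonds(inferBonds(twoC))), 0L)
  expect_equal(nrow(bonds(buildFixture("ethane"))), 7L)
  expect_equal(nrow(bonds(buildFixture("benzene"))), 12L)
  # fixture connectivity audit across the whole panel
  declared <- c(methane = 4, ethane = 7, ethene = 5, ethyne = 3,
                benzene = 12, methylamine = 6, acetamide = 8,
                acetic_acid = 7, acetyl_chloride = 6, ethanethiol = 8,
                ethanol = 8, ethylene_oxide = 7, propylene_oxide = 10,
                methyl_azide = 6, benzyl_azide = 17, propyne = 6,
                phenylacetylene = 14, butyne2 = 9, benzyl_bromide = 15,
                glucose = 23, butane = 13)
  for (nm in names(declared)) {
    expect_equal(nrow(bonds(buildFixture(nm))), unname(declared[[nm]]),
                 info = nm)
  }
  # existing CONECT bonds survive as a union
  pre <- twoC
  bonds(pre) <- cbind(1L, 2L)
  expect_equal(nrow(bonds(inferBonds(pre))), 1L)
})

test_that("hydrogens are capped at one bond, keeping the shortest", {
  m <- ClickMol:::.newMolecule(c("C", "H", "C"),
                               rbind(c(0, 0, 0), c(1.1, 0, 0), c(2.3, 0, 0)))
  b <- bonds(inferBonds(m))
  hRows <- b[b[, 1] == 2 | b[, 2] == 2, , drop = FALSE]
  expect_equal(nrow(hRows), 1L)
  expect_true(all(hRows == c(1L, 2L)))
})

test_that("bond perception is invariant to atom permutation", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- buildFixture(sample(fixtureNames(), 1))
    p <- sample(natoms(m))
    atoms <- m@atoms[p, ]; rownames(atoms) <- NULL
    perm <- ClickMol:::.newMolecule(atoms$element,
                                    as.matrix(atoms[, c("x", "y", "z")]))
    bp <- bonds(inferBonds(perm))
    inv <- order(p)  # map permuted indices back
    bpBack <- t(apply(bp, 1, function(r) sort(p[r])))
    expect_identical(ClickMol:::.normalizeBonds(bpBack, natoms(m)),
                     bonds(m))
  }
})

test_that("neighbor queries count and locate bonded elements", {
  m <- buildFixture("methane")
  expect_equal(neighborsOfElement(m, 1, "H"), 4L)
  expect_equal(neighborsOfElement(m, 1, "N"), 0L)
  expect_equal(firstNeighborOfElement(m, 1, "H"),
               min(which(elements(m) == "H")))
  expect_true(is.na(firstNeighborOfElement(m, 1, "O")))
  az <- buildFixture("methyl_azide")
  medial <- matchRoles(detectGroups(az)[[1]])[["medial_N"]]
  expect_equal(neighborsOfElement(az, medial, "N"), 2L)
  expect_error(neighborsOfElement(m, 0, "H"), "invalid atom index")
})

test_that("hybridization classifies idealized geometries", {
  ethyne <- buildFixture("ethyne")
  expect_equal(hybridization(ethyne, 1), "sp")
  ethene <- buildFixture("ethene")
  expect_equal(hybridization(ethene, 1), "sp2")
  methane <- buildFixture("methane")
  expect_equal(hybridization(methane, 1), "sp3")
  lone <- ClickMol:::.newMolecule("C", matrix(0, ncol = 3, nrow = 1))
  expect_equal(hybridization(lone, 1), "other")
  # every benzene carbon is trigonal planar
  benz <- buildFixture("benzene")
  for (i in which(elements(benz) == "C"))
    expect_equal(hybridization(benz, i), "sp2")
})

test_that("ring membership matches the exhaustive cycle oracle", {
  benz <- buildFixture("benzene")
  cIdx <- which(elements(benz) == "C")
  expect_true(inSameRing(benz, cIdx[1], cIdx[4]))
  h1 <- ClickMol:::.neighborsOf(benz, cIdx[1])
  h1 <- h1[elements(benz)[h1] == "H"]
  expect_false(inSameRing(benz, cIdx[1], h1))
  for (seed in 1:40) {
    g <- randomGraphMolecule(seed)
    n <- natoms(g)
    set.seed(seed + 1000)
    for (k in 1:5) {
      ab <- sample(n, 2)
      expect_identical(inSameRing(g, ab[1], ab[2]),
                       bruteSameRing(g, ab[1], ab[2]),
                       info = sprintf("seed %d pair %d-%d", seed,
                                      ab[1], ab[2]))
    }
  }
})

test_that("branch cutting partitions the molecule cleanly", {
  eth <- buildFixture("ethanol")
  cI <- which(elements(eth) == "C")[2]  # carbinol carbon
  oI <- which(elements(eth) == "O")
  br <- getBranch(eth, anchor = cI, direction = oI)
  expect_equal(natoms(br), 2L)
  expect_setequal(elements(br), c("O", "H"))

  but <- buildFixture("butane")
  b1 <- getBranch(but, anchor = 2, direction = 3)
  b2 <- getBranch(but, anchor = 3, direction = 2)
  expect_equal(natoms(b1), 7L)
  expect_equal(natoms(b2), 7L)
  expect_setequal(c(b1@metadata$provenance, b2@metadata$provenance),
                  seq_len(natoms(but)))
  expect_length(intersect(b1@metadata$provenance,
                          b2@metadata$provenance), 0)

  benz <- buildFixture("benzene")
  ring <- which(elements(benz) == "C")[1:2]
  expect_error(getBranch(benz, ring[1], ring[2]), "ring bonds")
  expect_error(getBranch(eth, 1, oI), "not bonded")
})
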