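# Functional-group perception and alkyne symmetry.

test_that("the fixture panel detects exactly the expected groups", {
  expected <- list(
    methane = character(), ethane = character(), butane = character(),
    benzene = character(),
    ethene = "alkene", ethyne = "terminal_alkyne",
    methylamine = "primary_amine", acetamide = character(),
    acetic_acid = "carboxylic_acid", acetyl_chloride = "acyl_halide",
    ethanethiol = "thiol", ethanol = "alcohol",
    ethylene_oxide = "epoxide", propylene_oxide = "epoxide",
    methyl_azide = "azide", benzyl_azide = "azide",
    propyne = "terminal_alkyne", phenylacetylene = "terminal_alkyne",
    butyne2 = "internal_alkyne", benzyl_bromide = "alkyl_halide",
    glucose = rep("alcohol", 5))
  for (nm in names(expected)) {
    got <- vapply(detectGroups(buildFixture(nm)), matchKind, character(1))
    expect_identical(sort(got), sort(expected[[nm]]), info = nm)
  }
})

test_that("azide roles are labelled proximal to distal", {
  az <- buildFixture("methyl_azide")
  m <- detectGroups(az)[[1]]
  r <- matchRoles(m)
  expect_setequal(names(r),
                  c("proximal_N", "medial_N", "distal_N", "attach_C"))
  deg <- lengths(ClickMol:::.adjacency(az))
  expect_equal(deg[[r[["distal_N"]]]], 1L)
  expect_equal(deg[[r[["medial_N"]]]], 2L)
  expect_equal(elements(az)[r[["attach_C"]]], "C")
  # the proximal nitrogen is bonded to the attachment carbon
  expect_equal(neighborsOfElement(az, r[["proximal_N"]], "C"), 1L)
})

test_that("amide nitrogens and carboxyl oxygens are excluded", {
  expect_length(detectGroups(buildFixture("acetamide"),
                             kinds = "primary_amine"), 0)
  expect_length(detectGroups(buildFixture("acetic_acid"),
                             kinds = "alcohol"), 0)
  # detection requires a bond graph
  raw <- ClickMol:::.newMolecule(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_error(detectGroups(raw), "inferBonds")
})

test_that("no two matches of one kind share an atom", {
  for (nm in c("glucose", "benzyl_azide", "propylene_oxide")) {
    ms <- detectGroups(buildFixture(nm))
    byKind <- split(ms, vapply(ms, matchKind, character(1)))
    for (grp in byKind) {
      atoms <- unlist(lapply(grp, matchRoles))
      expect_equal(anyDuplicated(atoms), 0L, info = nm)
    }
  }
})

test_that("detection is invariant to atom-order permutation", {
  for (nm in c("methyl_azide", "acetic_acid", "propylene_oxide",
               "phenylacetylene")) {
    m <- buildFixture(nm)
    set.seed(11)
    p <- sample(natoms(m))
    atoms <- m@atoms[p, ]; rownames(atoms) <- NULL
    perm <- inferBonds(ClickMol:::.newMolecule(
      atoms$element, as.matrix(atoms[, c("x", "y", "z")])))
    orig <- lapply(detectGroups(m), function(x)
      sort(unname(matchRoles(x))))
    back <- lapply(detectGroups(perm), function(x)
      sort(p[unname(matchRoles(x))]))
    expect_setequal(lapply(back, paste, collapse = "-"),
                    lapply(orig, paste, collapse = "-"))
  }
})

test_that("alkyne symmetry agrees with brute-force branch isomorphism", {
  b2 <- buildFixture("butyne2")
  expect_true(isSymmetricAlkyne(b2, detectGroups(b2)[[1]]))
  pr <- buildFixture("propyne")
  expect_false(isSymmetricAlkyne(pr, detectGroups(pr)[[1]]))
  ey <- buildFixture("ethyne")
  expect_true(isSymmetricAlkyne(ey, detectGroups(ey)[[1]]))
  # the package's VF2 route equals exhaustive permutation on small branches
  cases <- list(buildFixture("butyne2"), buildFixture("propyne"),
                symmetricAlkyne(2), buildFixture("phenylacetylene"))
  for (mol in cases) {
    match <- detectGroups(mol)[[1]]
    cpair <- ClickMol:::.alkyneCarbons(match)
    b1 <- getBranch(mol, anchor = cpair[2], direction = cpair[1])
    b2 <- getBranch(mol, anchor = cpair[1], direction = cpair[2])
    s1 <- ClickMol:::.dropAtoms(b1, match(cpair[1], b1@metadata$provenance))
    s2 <- ClickMol:::.dropAtoms(b2, match(cpair[2], b2@metadata$provenance))
    if (natoms(s1) <= 7 && natoms(s2) <= 7) {
      expect_identical(isSymmetricAlkyne(mol, match),
                       bruteIsomorphic(s1, s2), info = molLabel(mol))
    }
  }
  # random labelled graphs: VF2 wrapper vs exhaustive permutations
  for (seed in 1:15) {
    set.seed(seed)
    g1 <- randomGraphMolecule(seed, maxN = 6)
    perm <- sample(natoms(g1))
    atoms <- g1@atoms[perm, ]; rownames(atoms) <- NULL
    g2 <- ClickMol:::.newMolecule(atoms$element,
                                  as.matrix(atoms[, c("x", "y", "z")]))
    inv <- order(perm)
    bp <- t(apply(bonds(g1), 1, function(r) sort(inv[r])))
    bonds(g2) <- bp
    expect_true(ClickMol:::.molIsomorphic(g1, g2))
    expect_true(bruteIsomorphic(g1, g2))
    g3 <- randomGraphMolecule(seed + 333, maxN = 6)
    expect_identical(ClickMol:::.molIsomorphic(g1, g3),
                     bruteIsomorphic(g1, g3))
  }
})
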