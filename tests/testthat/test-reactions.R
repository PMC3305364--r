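# Reaction engine: assembly, stoichiometry, regio rules, steric relief.

azF <- function() buildFixture("methyl_azide")
firstMatch <- function(m, kind = NULL) {
  gs <- detectGroups(m)
  if (!is.null(kind))
    gs <- Filter(function(x) matchKind(x) %in% kind, gs)
  gs[[1]]
}

test_that("Huisgen cycloaddition builds both triazole regioisomers", {
  az <- azF(); alk <- buildFixture("propyne")
  prods <- huisgenCycloaddition(az, firstMatch(az), alk, firstMatch(alk))
  expect_length(prods, 2)
  expect_setequal(vapply(prods, productRegio, character(1)),
                  c("1,4", "1,5"))
  for (p in prods) {
    m <- productMolecule(p)
    expect_identical(formulaString(molecularFormula(m)),
                     formulaSum(molecularFormula(az),
                                molecularFormula(alk)))  # C4H7N3
    expect_equal(natoms(m), 14L)
    ring <- ClickMol:::.findTriazoleRing(m)
    expect_length(ring, 5)
    expect_setequal(elements(m)[ring], c("N", "N", "N", "C", "C"))
    # all five ring atoms share one ring
    expect_true(inSameRing(m, ring[1], ring[4]))
    expect_true(geometrySanity(m)$pass)
    expect_length(productFlags(p), 0)
    # closure: the ring consumed the azide and the alkyne
    kinds <- vapply(detectGroups(m), matchKind, character(1))
    expect_false(any(kinds %in% c("azide", "terminal_alkyne",
                                  "internal_alkyne")))
  }
})

test_that("symmetric alkynes collapse to a single cycloaddition product", {
  az <- azF()
  b2 <- buildFixture("butyne2")
  expect_length(huisgenCycloaddition(az, firstMatch(az), b2, firstMatch(b2)),
                1)
  ey <- buildFixture("ethyne")
  expect_length(huisgenCycloaddition(az, firstMatch(az), ey, firstMatch(ey)),
                1)
  # explicit regio request yields exactly that isomer
  pr <- buildFixture("propyne")
  one <- huisgenCycloaddition(az, firstMatch(az), pr, firstMatch(pr),
                              regio = "1,5")
  expect_length(one, 1)
  expect_identical(productRegio(one[[1]]), "1,5")
})

test_that("halide-to-azide conversion swaps X for a linear N3 unit", {
  bb <- buildFixture("benzyl_bromide")
  rec <- halideToAzide(bb, firstMatch(bb))
  m <- productMolecule(rec)
  expect_identical(formulaString(molecularFormula(m)), "C7H7N3")
  expect_equal(sum(elements(m) != "H"), 10L)  # 7 C + 3 N heavy atoms
  az <- firstMatch(m, "azide")
  r <- matchRoles(az)
  xyz <- coords(m)
  v1 <- xyz[r[["proximal_N"]], ] - xyz[r[["medial_N"]], ]
  v2 <- xyz[r[["distal_N"]], ] - xyz[r[["medial_N"]], ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 172, tolerance = 2)
  expect_true(geometrySanity(m)$pass)

  # bromoethane route: heavy atoms 2 C + 3 N
  bld <- ClickMol:::.newBuilder()
  ClickMol:::.addAtom(bld, "Br", c(-1.94, 0, 0))
  ClickMol:::.buildChainScaffold(bld, c(0, 0, 0), c(-1, 0, 0), 2, 0, FALSE)
  bre <- ClickMol:::.finishMolecule(bld, "bromoethane")
  m2 <- productMolecule(halideToAzide(bre, firstMatch(bre)))
  expect_identical(formulaString(molecularFormula(m2)), "C2H5N3")
  expect_equal(sum(elements(m2) != "H"), 5L)
})

test_that("amine-to-azide conversion closes back to a detectable azide", {
  ma <- buildFixture("methylamine")
  rec <- amineToAzide(ma, firstMatch(ma))
  m <- productMolecule(rec)
  expect_identical(formulaString(molecularFormula(m)), "CH3N3")
  kinds <- vapply(detectGroups(m), matchKind, character(1))
  expect_equal(sum(kinds == "azide"), 1L)
  expect_true(geometrySanity(m)$pass)
})

test_that("epoxide opening forms the anti alcohol and dedups symmetry", {
  eo <- buildFixture("ethylene_oxide")
  ma <- buildFixture("methylamine")
  recs <- epoxideOpening(eo, firstMatch(eo), ma, firstMatch(ma))
  expect_length(recs, 1)  # symmetric epoxide deduplicated
  m <- productMolecule(recs[[1]])
  expect_identical(formulaString(molecularFormula(m)), "C3H9NO")
  kinds <- vapply(detectGroups(m), matchKind, character(1))
  expect_equal(sum(kinds == "alcohol"), 1L)
  expect_equal(sum(kinds == "epoxide"), 0L)

  po <- buildFixture("propylene_oxide")
  et <- buildFixture("ethanethiol")
  recs2 <- epoxideOpening(po, firstMatch(po), et, firstMatch(et))
  expect_length(recs2, 2)
  expect_setequal(vapply(recs2, productRegio, character(1)),
                  c("attack_C1", "attack_C2"))
  for (p in recs2) {
    m2 <- productMolecule(p)
    expect_identical(formulaString(molecularFormula(m2)),
                     formulaSum(molecularFormula(po),
                                molecularFormula(et)))
    k2 <- vapply(detectGroups(m2), matchKind, character(1))
    expect_equal(sum(k2 == "alcohol"), 1L)
    expect_equal(sum(k2 == "epoxide"), 0L)
    expect_true(geometrySanity(m2)$pass)
  }
  expect_error(epoxideOpening(po, firstMatch(po), buildFixture("ethanol"),
                              firstMatch(buildFixture("ethanol"))),
               "unsupported nucleophile")
})

test_that("amide formation condenses acid or acyl halide with amine", {
  ma <- buildFixture("methylamine")
  for (acidName in c("acetic_acid", "acetyl_chloride")) {
    acid <- buildFixture(acidName)
    rec <- amideFormation(acid, firstMatch(acid), ma, firstMatch(ma))
    m <- productMolecule(rec)
    expect_identical(formulaString(molecularFormula(m)), "C3H7NO",
                     info = acidName)
    kinds <- vapply(detectGroups(m), matchKind, character(1))
    expect_false(any(kinds %in% c("primary_amine", "secondary_amine")),
                 info = acidName)
    expect_true(geometrySanity(m)$pass, info = acidName)
  }
})

test_that("alkene epoxidation inserts a ring oxygen at template geometry", {
  ev <- buildFixture("ethene")
  rec <- alkeneEpoxidation(ev, firstMatch(ev))
  m <- productMolecule(rec)
  expect_identical(formulaString(molecularFormula(m)), "C2H4O")
  kinds <- vapply(detectGroups(m), matchKind, character(1))
  expect_equal(sum(kinds == "epoxide"), 1L)
  ep <- firstMatch(m, "epoxide")
  r <- matchRoles(ep)
  xyz <- coords(m)
  for (cc in c(r[["C1"]], r[["C2"]])) {
    d <- sqrt(sum((xyz[cc, ] - xyz[r[["O"]], ])^2))
    expect_equal(d, 1.43, tolerance = 0.05)
  }
})

test_that("steric relief never worsens the minimum cross distance", {
  # two well-separated fragments: the zero rotation is retained
  a <- buildFixture("methane")
  b <- translateMol(buildFixture("methane"), c(8, 0, 0))
  m <- mergeMolecules(a, b)
  bonds(m) <- rbind(bonds(m), c(1L, 6L))
  out <- stericRelief(m, moving = 6:10, bond = c(1L, 6L))
  expect_equal(out$angle, 0)
  expect_equal(coords(out$molecule), coords(m))

  # a constructed eclipsed clash must strictly improve
  bld <- ClickMol:::.newBuilder()
  ClickMol:::.addAtom(bld, "C", c(0, 0, 0))
  ClickMol:::.addAtom(bld, "C", c(1.54, 0, 0))
  clash <- ClickMol:::.finishMolecule(bld, "axis")
  arm <- function(base, sign) {
    ph <- translateMol(buildFixture("benzene"), base + c(0, sign * 2.6, 0))
    ph
  }
  m2 <- mergeMolecules(mergeMolecules(clash, arm(c(0, 0, 0), 1)),
                       arm(c(1.54, 0, 0), 1))
  bonds(m2) <- rbind(bonds(m2), c(1L, 3L), c(2L, 15L))
  pre <- ClickMol:::.minCrossDist(coords(m2)[3:14, ], coords(m2)[15:26, ])
  out2 <- stericRelief(m2, moving = 15:26, bond = c(2L, 15L))
  expect_gt(out2$minDist, pre)

  # property: scanning from any pose never returns less than the start
  for (seed in 1:10) {
    set.seed(seed)
    start <- rotateAboutBond(m2, 2, 15, runif(1, 0, 2 * pi))
    p0 <- ClickMol:::.minCrossDist(coords(start)[15:26, ],
                                   coords(start)[c(1:14), ])
    res <- stericRelief(start, moving = 15:26, bond = c(2L, 15L))
    expect_gte(res$minDist + 1e-9, p0)
  }
})

test_that("relief matches a fine-grid oracle within one coarse step", {
  for (seed in 1:8) {
    set.seed(seed)
    bld <- ClickMol:::.newBuilder()
    ClickMol:::.addAtom(bld, "C", c(0, 0, 0))
    ClickMol:::.addAtom(bld, "C", c(1.54, 0, 0))
    base <- ClickMol:::.finishMolecule(bld, "ax")
    blob <- translateMol(randomCloudMolecule(8, seed = seed, box = 4),
                         c(2.6, -2, -2))
    fixed <- translateMol(randomCloudMolecule(8, seed = seed + 50, box = 4),
                          c(-4.2, -2, -2))
    m <- mergeMolecules(mergeMolecules(base, fixed), blob)
    bonds(m) <- rbind(bonds(m), c(1L, 3L), c(2L, 11L))
    coarse <- stericRelief(m, 11:18, c(2L, 11L), stepDeg = 10)
    # oracle mirrors the relief objective: atoms beyond the bond rotate,
    # axis atoms excluded from both sides
    f <- vapply(seq(0, 359) * pi / 180, function(a) {
      xyz <- coords(m)
      rot <- ClickMol:::.rotateCoords(xyz[12:18, , drop = FALSE],
                                      xyz[2, ], xyz[11, ], a)
      ClickMol:::.minCrossDist(rot, xyz[c(1, 3:10), , drop = FALSE])
    }, numeric(1))
    oracleBest <- max(f)
    # worst possible drop of the objective across one 10-degree window
    worstDrop <- max(vapply(seq(0, 359), function(k) {
      win <- f[(k + seq(0, 9)) %% 360 + 1]
      max(win) - min(win)
    }, numeric(1)))
    expect_gte(coarse$minDist + 1e-9, oracleBest - worstDrop)
    expect_gte(coarse$minDist, f[1] - 1e-9)
  }
})

test_that("geometry sanity flags clashes and stretched bonds", {
  expect_true(geometrySanity(buildFixture("ethanol"))$pass)
  tight <- ClickMol:::.newMolecule(c("C", "C"),
                                   rbind(c(0, 0, 0), c(0.1, 0, 0)))
  rep <- geometrySanity(tight)
  expect_false(rep$pass)
  expect_match(rep$violations, "non-bonded", all = FALSE)
  stretched <- graphMolecule(2, list(c(1, 2)))
  expect_false(geometrySanity(stretched)$pass)
})

test_that("applicable reactions cross detected groups with the registry", {
  az <- azF(); pr <- buildFixture("propyne")
  ents <- applicableReactions(az, pr)
  expect_length(ents, 1)
  expect_identical(ents[[1]]$reaction, "huisgen_cycloaddition")
  bb <- buildFixture("benzyl_bromide")
  uni <- applicableReactions(bb)
  expect_identical(vapply(uni, `[[`, character(1), "reaction"),
                   "halide_to_azide")
  expect_length(applicableReactions(buildFixture("methane"),
                                    buildFixture("methane")), 0)
  # orientation swap: alkyne as molA, azide as molB
  sw <- applicableReactions(pr, az)
  expect_length(sw, 1)
  expect_true(sw[[1]]$swap)
  prods <- runReaction(sw[[1]], pr, az)
  expect_length(prods, 2)
})

test_that("identical inputs produce byte-identical product files", {
  az <- azF(); pr <- buildFixture("propyne")
  build <- function() {
    p <- huisgenCycloaddition(az, firstMatch(az), pr, firstMatch(pr))
    lapply(p, function(x) writePDB(productMolecule(x),
                                   withr::local_tempfile(fileext = ".pdb")))
  }
  expect_identical(build(), build())
})
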