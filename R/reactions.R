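# Template-based geometric assembly of click-chemistry products.
#
# Every bimolecular builder follows the same six steps: fragment the
# reactants at the reacting bond, superimpose each fragment onto the
# idealized product core by two-point tether alignment (handle atom ->
# core position, handle-adjacent atom -> exocyclic direction point),
# relieve steric clashes by a discrete dihedral scan about the exocyclic
# single bonds, delete the superseded core scaffold, merge, and form the
# new bonds.

# --- 1,2,3-triazole template ----------------------------------------------

# Planar five-ring, uniform ring bond length 1.36 A, exocyclic direction
# points 1.45 A radially outward from N1, C4 and C5. Idealized values,
# not fit to any crystal structure. Ring order N1-N2-N3-C4-C5.
.triazoleTemplate <- function() {
  side <- 1.36
  R <- side / (2 * sin(pi / 5))
  roles <- c("N1", "N2", "N3", "C4", "C5")
  ang <- pi / 2 + (0:4) * 2 * pi / 5
  ring <- cbind(R * cos(ang), R * sin(ang), 0)
  exo <- ring * (R + 1.45) / R
  core <- data.frame(
    element = c("N", "N", "N", "C", "C", "*", "*", "*"),
    role = c(roles, "N1_exo", "C4_exo", "C5_exo"),
    x = c(ring[, 1L], exo[c(1L, 4L, 5L), 1L]),
    y = c(ring[, 2L], exo[c(1L, 4L, 5L), 2L]),
    z = 0, stringsAsFactors = FALSE)
  new("ReactionTemplate", name = "huisgen_cycloaddition", core = core,
      doomed = roles,
      newBonds = cbind(c("N1", "N2", "N3", "C4", "C5"),
                       c("N2", "N3", "C4", "C5", "N1")))
}

.templatePoint <- function(tpl, role) {
  i <- match(role, tpl@core$role)
  c(tpl@core$x[i], tpl@core$y[i], tpl@core$z[i])
}

# Pseudo-molecule carrying template coordinates so alignByTethers can
# target them (elements are placeholders; it is never emitted).
.templateMolecule <- function(tpl) {
  core <- tpl@core
  .newMolecule(ifelse(core$element == "*", "C", core$element),
               as.matrix(core[, c("x", "y", "z")]),
               label = paste0("template:", tpl@name))
}

# --- steric relief ---------------------------------------------------------

#' Relieve steric clashes by dihedral scanning
#'
#' Rotates one side of a freely rotatable bond in fixed angular steps
#' over [0, 360) degrees and keeps the angle that maximizes the minimum
#' cross-fragment interatomic distance; ties are broken by the smallest
#' rotation, so an already-clash-free pose is retained unchanged. The
#' returned minimum cross distance is therefore never smaller than the
#' unrotated one.
#'
#' @param product the assembled \code{\linkS4class{Molecule}}.
#' @param moving integer vector of atom indices rotated about the bond
#'   (one of the two fragment sides); all other atoms are held fixed.
#' @param bond length-2 integer vector (a, b): the rotation axis runs
#'   through these two atoms. Must not be a ring bond.
#' @param stepDeg scan step in degrees (default 10, i.e. 36 poses).
#' @return list with \code{molecule}, \code{angle} (radians applied) and
#'   \code{minDist} (final minimum cross-fragment distance, A).
#' @export
stericRelief <- function(product, moving, bond, stepDeg = 10) {
  a <- bond[1L]; b <- bond[2L]
  if (.isRingBond(product, a, b)) {
    warning("steric relief skipped: ring bond")
    xyz <- coords(product)
    fixedIdx <- setdiff(seq_len(natoms(product)), moving)
    return(list(molecule = product, angle = 0,
                minDist = .minCrossDist(xyz[moving, , drop = FALSE],
                                        xyz[fixedIdx, , drop = FALSE])))
  }
  xyz <- coords(product)
  moving <- setdiff(as.integer(moving), c(a, b))
  fixedIdx <- setdiff(seq_len(natoms(product)), c(moving, a, b))
  if (length(moving) == 0L || length(fixedIdx) == 0L)
    return(list(molecule = product, angle = 0, minDist = Inf))
  p1 <- xyz[a, ]; p2 <- xyz[b, ]
  angles <- seq(0, 2 * pi - 1e-9, by = stepDeg * pi / 180)
  fixedXyz <- xyz[fixedIdx, , drop = FALSE]
  best <- -Inf; bestAngle <- 0
  for (ang in angles) {
    rot <- if (ang == 0) xyz[moving, , drop = FALSE] else
      .rotateCoords(xyz[moving, , drop = FALSE], p1, p2, ang)
    d <- .minCrossDist(rot, fixedXyz)
    if (d > best + 1e-12) { best <- d; bestAngle <- ang }
  }
  if (bestAngle != 0)
    xyz[moving, ] <- .rotateCoords(xyz[moving, , drop = FALSE], p1, p2,
                                   bestAngle)
  coords(product) <- xyz
  list(molecule = product, angle = bestAngle, minDist = best)
}

# --- geometry sanity -------------------------------------------------------

#' Geometric sanity report for a built model
#'
#' Checks that no two non-bonded atoms are closer than 0.7 A, that every
#' bonded pair lies within 0.7 A and an element-aware upper limit
#' (max(1.9, rcov_i + rcov_j + 0.25) A, so long single bonds such as
#' C-Br are admitted), and, when the molecule contains a 1,2,3-triazole
#' ring, that the ring atoms deviate at most 0.1 A from their best-fit
#' plane.
#'
#' @param product a bonded \code{\linkS4class{Molecule}}.
#' @return list with \code{pass} (logical) and \code{violations}
#'   (character vector describing each failure).
#' @export
geometrySanity <- function(product) {
  viol <- character()
  n <- natoms(product)
  if (n >= 2L) {
    xyz <- coords(product)
    D <- .pairwiseDists(xyz)
    bonded <- matrix(FALSE, n, n)
    b <- product@bonds
    if (nrow(b)) {
      bonded[b] <- TRUE
      bonded[b[, 2:1, drop = FALSE]] <- TRUE
    }
    close <- D < 0.7 & upper.tri(D) & !bonded
    if (any(close)) {
      idx <- which(close, arr.ind = TRUE)
      viol <- c(viol, sprintf("non-bonded atoms %d-%d at %.2f A",
                              idx[, 1L], idx[, 2L], D[close]))
    }
    if (nrow(b)) {
      r <- .covalentRadius(elements(product))
      for (k in seq_len(nrow(b))) {
        i <- b[k, 1L]; j <- b[k, 2L]
        hi <- max(1.9, r[i] + r[j] + 0.25)
        if (D[i, j] < 0.7 || D[i, j] > hi)
          viol <- c(viol, sprintf("bond %d-%d length %.2f A outside [0.7, %.2f]",
                                  i, j, D[i, j], hi))
      }
    }
    ring <- .findTriazoleRing(product)
    if (!is.null(ring)) {
      dev <- .planeDeviation(xyz[ring, , drop = FALSE])
      if (dev > 0.1)
        viol <- c(viol, sprintf("triazole ring planarity %.3f A > 0.1 A", dev))
    }
  }
  list(pass = length(viol) == 0L, violations = viol)
}

# locate an N-N-N-C-C five-ring, if any (NULL otherwise)
.findTriazoleRing <- function(mol) {
  el <- elements(mol)
  adj <- .adjacency(mol)
  for (n2 in which(el == "N")) {
    nbN <- adj[[n2]][el[adj[[n2]]] == "N"]
    if (length(nbN) < 2L) next
    for (i in seq_along(nbN)) for (j in seq_along(nbN)) {
      if (i == j) next
      n1 <- nbN[i]; n3 <- nbN[j]
      c5s <- adj[[n1]][el[adj[[n1]]] == "C"]
      c4s <- adj[[n3]][el[adj[[n3]]] == "C"]
      for (c5 in c5s) for (c4 in c4s) {
        if (c4 != c5 && any(adj[[c4]] == c5))
          return(c(n1, n2, n3, c4, c5))
      }
    }
  }
  NULL
}

# max distance of points from their least-squares plane
.planeDeviation <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr, "-"))
  normal <- sv$v[, 3L]
  max(abs(sweep(pts, 2L, ctr, "-") %*% normal))
}

# --- assembly helpers ------------------------------------------------------

# fragment of `mol` on the `direction` side of the anchor-direction bond,
# with the fragment-local indices of the listed role atoms
.takeFragment <- function(mol, anchor, direction, roleAtoms) {
  frag <- getBranch(mol, anchor = anchor, direction = direction)
  prov <- frag@metadata$provenance
  local <- vapply(roleAtoms, function(i) match(i, prov), integer(1L))
  if (anyNA(local)) stop("internal: role atom missing from fragment")
  list(mol = frag, local = local)
}

# greedy sequential relief about exocyclic bonds, in formation order
.reliefPass <- function(product, exoBonds, stepDeg) {
  for (eb in exoBonds) {
    if (.isRingBond(product, eb[1L], eb[2L])) next
    branch <- getBranch(product, anchor = eb[1L], direction = eb[2L])
    moving <- branch@metadata$provenance
    if (length(setdiff(moving, eb)) == 0L) next
    product <- stericRelief(product, moving, eb, stepDeg)$molecule
  }
  product
}

.productFlags <- function(product) {
  rep <- geometrySanity(product)
  if (any(grepl("^non-bonded", rep$violations))) "clash" else character()
}

# --- Huisgen cycloaddition -------------------------------------------------

#' Azide-alkyne Huisgen cycloaddition in silico
#'
#' Builds 3D models of the 1,2,3-triazole product(s) of an azide and an
#' alkyne: the alkyne is fragmented along its triple bond and the azide
#' along the proximal-medial N-N bond; each fragment keeps a handle atom
#' (the former alkyne carbons, the proximal azide nitrogen) that is
#' superimposed onto the corresponding atom of an idealized planar
#' triazole core by two-tether least-squares alignment (handle -> ring
#' position, handle-adjacent atom -> exocyclic direction point); the
#' substituents are then rotated about the exocyclic single bonds to
#' relieve steric strain, the superseded core scaffold is deleted, and
#' the fragments are merged with the five ring bonds formed.
#'
#' Non-symmetric alkynes give both regioisomers ("1,4": the larger
#' alkyne branch sits para-like across the ring from the azide
#' substituent, i.e. on ring carbon C4; "1,5": on C5); symmetric alkynes
#' give a single product. Cycloaddition conserves all atoms, so the
#' product formula is the sum of the reactant formulas. A product whose
#' fragments could not be separated beyond 0.7 A is flagged
#' \code{"clash"}, never dropped.
#'
#' @param azideMol,azideMatch the azide-bearing molecule and its
#'   \code{azide} \code{\linkS4class{FGMatch}}.
#' @param alkyneMol,alkyneMatch the alkyne-bearing molecule and its
#'   alkyne match.
#' @param regio \code{"both"} (default), \code{"1,4"} or \code{"1,5"}.
#' @param stepDeg steric-relief scan step in degrees.
#' @return list of \code{\linkS4class{ProductRecord}} objects (two for a
#'   non-symmetric alkyne with \code{regio = "both"}, else one).
#' @examples
#' az <- buildFixture("methyl_azide"); alk <- buildFixture("propyne")
#' prods <- huisgenCycloaddition(az, detectGroups(az)[[1]],
#'                               alk, detectGroups(alk)[[1]])
#' length(prods)  # 2 regioisomers
#' @export
huisgenCycloaddition <- function(azideMol, azideMatch, alkyneMol,
                                 alkyneMatch, regio = c("both", "1,4", "1,5"),
                                 stepDeg = 10) {
  regio <- match.arg(regio)
  stopifnot(azideMatch@kind == "azide",
            alkyneMatch@kind %in% c("terminal_alkyne", "internal_alkyne"))
  r <- azideMatch@roles
  if (.isRingBond(azideMol, r[["proximal_N"]], r[["medial_N"]]))
    stop("azide N-N bond lies in a ring; fragmentation impossible")
  cpair <- .alkyneCarbons(alkyneMatch)
  if (.isRingBond(alkyneMol, cpair[1L], cpair[2L]))
    stop("alkyne triple bond lies in a ring; fragmentation impossible")

  # azide fragments
  fOrg <- .takeFragment(azideMol, anchor = r[["medial_N"]],
                        direction = r[["proximal_N"]],
                        roleAtoms = c(N = r[["proximal_N"]],
                                      C = r[["attach_C"]]))
  fNN <- .takeFragment(azideMol, anchor = r[["proximal_N"]],
                       direction = r[["medial_N"]],
                       roleAtoms = c(N2 = r[["medial_N"]],
                                     N3 = r[["distal_N"]]))
  # alkyne fragments: `sub` carries the larger substituent branch
  sub_C <- .alkyneSubstCarbon(alkyneMol, alkyneMatch)
  other_C <- setdiff(cpair, sub_C)
  fSub <- .alkyneFragment(alkyneMol, keepC = sub_C, dropC = other_C)
  fOth <- .alkyneFragment(alkyneMol, keepC = other_C, dropC = sub_C)

  wanted <- if (regio == "both") {
    if (isSymmetricAlkyne(alkyneMol, alkyneMatch)) "1,4" else c("1,4", "1,5")
  } else regio
  lapply(wanted, function(rg) {
    .assembleTriazole(fOrg, fNN, fSub, fOth, rg, stepDeg,
                      parents = c(azideMol@label, alkyneMol@label))
  })
}

# the alkyne carbon holding the larger substituent branch (ties broken by
# the lower atom index); for terminal alkynes this is the non-H carbon
.alkyneSubstCarbon <- function(mol, match) {
  if (match@kind == "terminal_alkyne") return(match@roles[["subst_C"]])
  cpair <- .alkyneCarbons(match)
  n1 <- natoms(getBranch(mol, anchor = cpair[2L], direction = cpair[1L]))
  n2 <- natoms(getBranch(mol, anchor = cpair[1L], direction = cpair[2L]))
  if (n2 > n1) cpair[2L] else cpair[1L]
}

.alkyneFragment <- function(mol, keepC, dropC) {
  frag <- getBranch(mol, anchor = dropC, direction = keepC)
  prov <- frag@metadata$provenance
  handle <- match(keepC, prov)
  adjLocal <- .neighborsOf(frag, handle)
  if (length(adjLocal) != 1L)
    stop("internal: alkyne carbon should keep exactly one neighbor")
  list(mol = frag, local = c(C = handle, adj = adjLocal))
}

.assembleTriazole <- function(fOrg, fNN, fSub, fOth, regioLabel, stepDeg,
                              parents) {
  tpl <- .triazoleTemplate()
  ref <- .templateMolecule(tpl)
  roleIdx <- function(role) match(role, tpl@core$role)
  subRing <- if (regioLabel == "1,4") "C4" else "C5"
  othRing <- if (regioLabel == "1,4") "C5" else "C4"

  aOrg <- alignByTethers(fOrg$mol, ref,
    cbind(fOrg$local, c(roleIdx("N1"), roleIdx("N1_exo"))))$molecule
  aNN <- alignByTethers(fNN$mol, ref,
    cbind(fNN$local, c(roleIdx("N2"), roleIdx("N3"))))$molecule
  aSub <- alignByTethers(fSub$mol, ref,
    cbind(fSub$local, c(roleIdx(subRing), roleIdx(paste0(subRing, "_exo")))))$molecule
  aOth <- alignByTethers(fOth$mol, ref,
    cbind(fOth$local, c(roleIdx(othRing), roleIdx(paste0(othRing, "_exo")))))$molecule

  # merge in fixed order; record handle indices in the merged product
  off <- cumsum(c(0L, natoms(aOrg), natoms(aNN), natoms(aSub)))
  prod <- mergeMolecules(mergeMolecules(aOrg, aNN),
                         mergeMolecules(aSub, aOth))
  h <- c(N1 = fOrg$local[[1L]],
         N2 = off[2L] + fNN$local[[1L]], N3 = off[2L] + fNN$local[[2L]],
         SUB = off[3L] + fSub$local[[1L]], OTH = off[4L] + fOth$local[[1L]])
  ringBonds <- rbind(c(h[["N1"]], h[["N2"]]), c(h[["N2"]], h[["N3"]]),
                     if (regioLabel == "1,4")
                       rbind(c(h[["N3"]], h[["SUB"]]), c(h[["SUB"]], h[["OTH"]]),
                             c(h[["OTH"]], h[["N1"]]))
                     else
                       rbind(c(h[["N3"]], h[["OTH"]]), c(h[["OTH"]], h[["SUB"]]),
                             c(h[["SUB"]], h[["N1"]])))
  bonds(prod) <- rbind(prod@bonds, ringBonds)

  # steric relief about the exocyclic single bonds, in formation order
  exo <- list(c(h[["N1"]], fOrg$local[[2L]]),
              c(h[["SUB"]], off[3L] + fSub$local[[2L]]),
              c(h[["OTH"]], off[4L] + fOth$local[[2L]]))
  prod <- .reliefPass(prod, exo, stepDeg)
  prod@label <- paste(parents, collapse = "__")
  new("ProductRecord", molecule = prod, reaction = "huisgen_cycloaddition",
      parents = parents, regio = regioLabel, flags = .productFlags(prod))
}

# --- azide formation -------------------------------------------------------

#' Convert an alkyl halide to the corresponding azide
#'
#' The halogen is deleted and a linear azide unit is grown along the
#' former C-X vector with template geometry (C-N 1.47 A, N-N 1.24/1.13 A,
#' C-N-N 115 degrees, N-N-N 172 degrees), followed by a dihedral relief
#' scan about the new C-N bond. Formula change: -X, +N3.
#'
#' @param mol the halide-bearing \code{\linkS4class{Molecule}}.
#' @param match its \code{alkyl_halide} match.
#' @param stepDeg steric-relief scan step in degrees.
#' @return a \code{\linkS4class{ProductRecord}} (regio \code{"-"}).
#' @export
halideToAzide <- function(mol, match, stepDeg = 10) {
  stopifnot(match@kind == "alkyl_halide")
  cI <- match@roles[["C"]]; xI <- match@roles[["X"]]
  xyz <- coords(mol)
  u <- .unitv(xyz[xI, ] - xyz[cI, ])
  base <- .dropAtoms(mol, xI)
  cNew <- match(cI, base@metadata$provenance)
  prod <- .growAzide(base, attachC = cNew, u = u, stepDeg = stepDeg)
  prod@label <- paste0(mol@label, "_azide")
  new("ProductRecord", molecule = prod, reaction = "halide_to_azide",
      parents = mol@label, regio = "-", flags = .productFlags(prod))
}

#' Convert a primary amine to the corresponding azide
#'
#' Both amine hydrogens are deleted and two nitrogens are appended,
#' continuing from the amine nitrogen with the azide template geometry.
#' Formula change: -H2, +N2.
#'
#' @param mol the amine-bearing \code{\linkS4class{Molecule}}.
#' @param match its \code{primary_amine} match.
#' @param stepDeg steric-relief scan step in degrees.
#' @return a \code{\linkS4class{ProductRecord}}.
#' @export
amineToAzide <- function(mol, match, stepDeg = 10) {
  stopifnot(match@kind == "primary_amine")
  r <- match@roles
  base <- .dropAtoms(mol, c(r[["H1"]], r[["H2"]]))
  prov <- base@metadata$provenance
  n1 <- match(r[["N"]], prov); cA <- match(r[["C1"]], prov)
  xyz <- coords(base)
  u <- .unitv(xyz[n1, ] - xyz[cA, ])
  bld <- .newBuilder()
  nn <- .addAzideTail(bld, xyz[n1, ], u)
  tail <- .newMolecule(bld$element, bld$xyz, label = "")
  prod <- mergeMolecules(base, tail)
  nOld <- natoms(base)
  bonds(prod) <- rbind(prod@bonds, c(n1, nOld + 1L), c(nOld + 1L, nOld + 2L))
  prod <- .reliefPass(prod, list(c(cA, n1)), stepDeg)
  prod@label <- paste0(mol@label, "_azide")
  new("ProductRecord", molecule = prod, reaction = "amine_to_azide",
      parents = mol@label, regio = "-", flags = .productFlags(prod))
}

# medial+distal N positions continuing from an existing proximal N at
# `n1pos` reached along unit vector u (from the attached heavy atom)
.addAzideTail <- function(bld, n1pos, u) {
  pb <- .perpBasis(u)
  th <- 115 * pi / 180
  d12 <- cos(th) * (-u) + sin(th) * pb$e1
  n2pos <- n1pos + .BL[["N=N"]] * d12
  .addAtom(bld, "N", n2pos)
  ax <- .crossv(u, pb$e1)
  d23 <- as.numeric(.rotationMatrix(ax, (180 - 172) * pi / 180) %*% d12)
  .addAtom(bld, "N", n2pos + .BL[["N#N"]] * d23)
  invisible(bld)
}

# shared by halideToAzide: grow proximal+medial+distal N from attachC
.growAzide <- function(base, attachC, u, stepDeg) {
  xyz <- coords(base)
  n1pos <- xyz[attachC, ] + .BL[["CN"]] * u
  bld <- .newBuilder()
  .addAtom(bld, "N", n1pos)
  .addAzideTail(bld, n1pos, u)
  tail <- .newMolecule(bld$element, bld$xyz, label = "")
  prod <- mergeMolecules(base, tail)
  nOld <- natoms(base)
  bonds(prod) <- rbind(prod@bonds,
                       c(attachC, nOld + 1L), c(nOld + 1L, nOld + 2L),
                       c(nOld + 2L, nOld + 3L))
  .reliefPass(prod, list(c(attachC, nOld + 1L)), stepDeg)
}

# --- epoxide opening -------------------------------------------------------

#' Nucleophilic epoxide ring opening
#'
#' Opens a C-C-O epoxide with an amine, thiol or azide nucleophile. For
#' each attacked carbon the ring C-O bond is broken, the ring oxygen
#' becomes a hydroxyl (gaining the hydrogen lost by an amine or thiol
#' nucleophile; an azide nucleophile donates no hydrogen, so the oxygen
#' is left as an alkoxide to conserve atoms exactly), and the nucleophile
#' is bonded to the attacked carbon anti to the former C-O bond. Two
#' regio products ("attack_C1", "attack_C2") are produced; when they are
#' graph-isomorphic (symmetric epoxide) only one is emitted. The formula
#' is the exact sum of the reactant formulas.
#'
#' @param epoxMol,epMatch the epoxide-bearing molecule and its match.
#' @param nuMol,nuMatch the nucleophile molecule and its match (kind
#'   \code{primary_amine}, \code{secondary_amine}, \code{thiol}, or
#'   \code{azide}).
#' @param stepDeg steric-relief scan step in degrees.
#' @return list of \code{\linkS4class{ProductRecord}} objects.
#' @export
epoxideOpening <- function(epoxMol, epMatch, nuMol, nuMatch, stepDeg = 10) {
  stopifnot(epMatch@kind == "epoxide")
  if (!nuMatch@kind %in% c("primary_amine", "secondary_amine", "thiol",
                           "azide"))
    stop("unsupported nucleophile kind: ", nuMatch@kind)
  recs <- lapply(c("attack_C1", "attack_C2"), function(site) {
    .openEpoxideAt(epoxMol, epMatch, nuMol, nuMatch, site, stepDeg)
  })
  if (.molIsomorphic(recs[[1L]]@molecule, recs[[2L]]@molecule))
    recs <- recs[1L]
  recs
}

.openEpoxideAt <- function(epoxMol, epMatch, nuMol, nuMatch, site, stepDeg) {
  r <- epMatch@roles
  ca <- if (site == "attack_C1") r[["C1"]] else r[["C2"]]
  cb <- if (site == "attack_C1") r[["C2"]] else r[["C1"]]
  oI <- r[["O"]]
  xyz <- coords(epoxMol)
  dAttack <- .unitv(xyz[ca, ] - xyz[oI, ])  # anti to the broken C-O bond

  # break the ring bond, protonate the oxygen (unless azide nucleophile)
  ep <- epoxMol
  keep <- !((ep@bonds[, 1L] == ca & ep@bonds[, 2L] == oI) |
            (ep@bonds[, 1L] == oI & ep@bonds[, 2L] == ca))
  ep@bonds <- ep@bonds[keep, , drop = FALSE]
  nuInfo <- .nucleophileInfo(nuMol, nuMatch)
  if (nuInfo$donatesH) {
    hdirs <- .sp3Fill(matrix(.unitv(xyz[cb, ] - xyz[oI, ]), nrow = 1L))
    k <- .pickFarthest(sweep(hdirs * .BL[["OH"]], 2L, xyz[oI, ], "+"),
                       coords(ep))
    bld <- .newBuilder()
    .addAtom(bld, "H", xyz[oI, ] + .BL[["OH"]] * hdirs[k, ])
    hmol <- .newMolecule(bld$element, bld$xyz, label = "")
    nEp <- natoms(ep)
    ep <- mergeMolecules(ep, hmol)
    bonds(ep) <- rbind(ep@bonds, c(oI, nEp + 1L))
  }

  # prepare the nucleophile: drop one H (amine/thiol), align onto the
  # attack vector with a two-point tether (nucleophilic atom + its
  # heavy-atom neighbor)
  nu <- nuInfo$mol
  nuAtom <- nuInfo$atom; nuAdj <- nuInfo$adj
  L <- nuInfo$bondLength
  P1 <- xyz[ca, ] + L * dAttack
  e <- .coneDirs(-dAttack, 109.471, 3L)[1L, ]
  P2 <- P1 + 1.47 * e
  tgt <- .newMolecule(c("C", "C"), rbind(P1, P2), label = "")
  nu <- alignByTethers(nu, tgt, cbind(c(nuAtom, nuAdj), c(1L, 2L)))$molecule

  nEp <- natoms(ep)
  prod <- mergeMolecules(ep, nu)
  bonds(prod) <- rbind(prod@bonds, c(ca, nEp + nuAtom))
  prod <- .reliefPass(prod, list(c(ca, nEp + nuAtom)), stepDeg)
  prod@label <- paste(c(epoxMol@label, nuMol@label), collapse = "__")
  new("ProductRecord", molecule = prod, reaction = "epoxide_opening",
      parents = c(epoxMol@label, nuMol@label), regio = site,
      flags = .productFlags(prod))
}

# nucleophile bookkeeping: attacking atom, its heavy neighbor, whether a
# hydrogen is transferred, and the new bond length to carbon
.nucleophileInfo <- function(nuMol, nuMatch) {
  r <- nuMatch@roles
  if (nuMatch@kind %in% c("primary_amine", "secondary_amine")) {
    dropH <- r[[grep("^H", names(r))[1L]]]
    base <- .dropAtoms(nuMol, dropH)
    prov <- base@metadata$provenance
    list(mol = base, atom = match(r[["N"]], prov),
         adj = match(r[[grep("^C", names(r))[1L]]], prov),
         donatesH = TRUE, bondLength = .BL[["CN"]])
  } else if (nuMatch@kind == "thiol") {
    base <- .dropAtoms(nuMol, r[["H"]])
    prov <- base@metadata$provenance
    list(mol = base, atom = match(r[["S"]], prov),
         adj = match(r[["C"]], prov),
         donatesH = TRUE, bondLength = .BL[["CS"]])
  } else {
    list(mol = nuMol, atom = r[["proximal_N"]], adj = r[["attach_C"]],
         donatesH = FALSE, bondLength = .BL[["CN"]])
  }
}

# --- amide formation -------------------------------------------------------

#' Amide bond formation (condensation)
#'
#' A carboxylic acid (losing its OH) or acyl halide (losing X) is
#' condensed with a primary or secondary amine (losing one H); the new
#' C-N bond is formed with planar amide geometry (C-N 1.35 A, the
#' nitrogen placed 120 degrees from the carbonyl oxygen in the acyl
#' plane). Formula: sum of reactants minus H2O (acid route) or HX
#' (halide route).
#'
#' @param acidMol,acidMatch the acyl-donor molecule and its
#'   \code{carboxylic_acid} or \code{acyl_halide} match.
#' @param amineMol,amineMatch the amine molecule and its match.
#' @param stepDeg steric-relief scan step in degrees.
#' @return a \code{\linkS4class{ProductRecord}}.
#' @export
amideFormation <- function(acidMol, acidMatch, amineMol, amineMatch,
                           stepDeg = 10) {
  stopifnot(acidMatch@kind %in% c("carboxylic_acid", "acyl_halide"),
            amineMatch@kind %in% c("primary_amine", "secondary_amine"))
  r <- acidMatch@roles
  drop <- if (acidMatch@kind == "carboxylic_acid")
    c(r[["hydroxyl_O"]], r[["hydroxyl_H"]]) else r[["X"]]
  leavingAtom <- if (acidMatch@kind == "carboxylic_acid")
    r[["hydroxyl_O"]] else r[["X"]]
  xyz <- coords(acidMol)
  dN <- .unitv(xyz[leavingAtom, ] - xyz[r[["C"]], ])
  acyl <- .dropAtoms(acidMol, drop)
  prov <- acyl@metadata$provenance
  cI <- match(r[["C"]], prov)
  nPos <- coords(acyl)[cI, ] + .BL[["C-Nam"]] * dN

  # amide plane: defined by the carbonyl group; the amine carbon goes
  # 120 degrees onward within that plane, anti to the carbonyl oxygen
  oI <- match(r[["carbonyl_O"]], prov)
  planeN <- .crossv(dN, .unitv(coords(acyl)[oI, ] - coords(acyl)[cI, ]))
  planeN <- .unitv(planeN)
  backDir <- -dN
  cand <- rbind(
    as.numeric(.rotationMatrix(planeN, 2 * pi / 3) %*% backDir),
    as.numeric(.rotationMatrix(planeN, -2 * pi / 3) %*% backDir))
  pick <- .pickFarthest(sweep(cand * 1.47, 2L, nPos, "+"),
                        coords(acyl)[oI, , drop = FALSE])
  P2 <- nPos + 1.47 * cand[pick, ]

  ra <- amineMatch@roles
  dropH <- ra[[grep("^H", names(ra))[1L]]]
  am <- .dropAtoms(amineMol, dropH)
  prova <- am@metadata$provenance
  nI <- match(ra[["N"]], prova)
  cAdj <- match(ra[[grep("^C", names(ra))[1L]]], prova)
  tgt <- .newMolecule(c("C", "C"), rbind(nPos, P2), label = "")
  am <- alignByTethers(am, tgt, cbind(c(nI, cAdj), c(1L, 2L)))$molecule

  nAcyl <- natoms(acyl)
  prod <- mergeMolecules(acyl, am)
  bonds(prod) <- rbind(prod@bonds, c(cI, nAcyl + nI))
  prod <- .reliefPass(prod, list(c(cI, nAcyl + nI)), stepDeg)
  prod@label <- paste(c(acidMol@label, amineMol@label), collapse = "__")
  new("ProductRecord", molecule = prod, reaction = "amide_formation",
      parents = c(acidMol@label, amineMol@label), regio = "-",
      flags = .productFlags(prod))
}

# --- alkene epoxidation ----------------------------------------------------

#' Epoxidize an alkene
#'
#' Inserts an oxygen above the C=C midpoint (along the normal of the sp2
#' plane) forming a three-ring with template C-O distances of about
#' 1.43 A. Formula change: +O.
#'
#' @param mol the alkene-bearing \code{\linkS4class{Molecule}}.
#' @param match its \code{alkene} match.
#' @return a \code{\linkS4class{ProductRecord}}.
#' @export
alkeneEpoxidation <- function(mol, match) {
  stopifnot(match@kind == "alkene")
  c1 <- match@roles[["C1"]]; c2 <- match@roles[["C2"]]
  xyz <- coords(mol)
  mid <- (xyz[c1, ] + xyz[c2, ]) / 2
  others <- setdiff(.neighborsOf(mol, c1), c2)
  normal <- if (length(others) >= 1L) {
    .unitv(.crossv(xyz[others[1L], ] - xyz[c1, ], xyz[c2, ] - xyz[c1, ]))
  } else .perpBasis(.unitv(xyz[c2, ] - xyz[c1, ]))$e1
  half <- sqrt(sum((xyz[c2, ] - xyz[c1, ])^2)) / 2
  h <- sqrt(max(.BL[["CO"]]^2 - half^2, 0.25))
  bld <- .newBuilder()
  .addAtom(bld, "O", mid + h * normal)
  omol <- .newMolecule(bld$element, bld$xyz, label = "")
  nOld <- natoms(mol)
  prod <- mergeMolecules(mol, omol)
  bonds(prod) <- rbind(prod@bonds, c(c1, nOld + 1L), c(c2, nOld + 1L))
  prod@label <- paste0(mol@label, "_epoxide")
  new("ProductRecord", molecule = prod, reaction = "alkene_epoxidation",
      parents = mol@label, regio = "-", flags = .productFlags(prod))
}

# --- reaction registry -----------------------------------------------------

# Ordered registry of the implemented core reaction set. Additional
# click reactions plug in as new entries without engine changes.
.reactionRegistry <- list(
  list(name = "huisgen_cycloaddition", arity = 2L,
       kindsA = "azide", kindsB = c("terminal_alkyne", "internal_alkyne")),
  list(name = "epoxide_opening", arity = 2L,
       kindsA = "epoxide",
       kindsB = c("primary_amine", "secondary_amine", "thiol", "azide")),
  list(name = "amide_formation", arity = 2L,
       kindsA = c("carboxylic_acid", "acyl_halide"),
       kindsB = c("primary_amine", "secondary_amine")),
  list(name = "halide_to_azide", arity = 1L, kindsA = "alkyl_halide"),
  list(name = "amine_to_azide", arity = 1L, kindsA = "primary_amine"),
  list(name = "alkene_epoxidation", arity = 1L, kindsA = "alkene")
)

#' The reaction registry
#' @return list of registry entries (name, arity, reacting kinds).
#' @export
reactionRegistry <- function() .reactionRegistry

#' Enumerate the applicable reactions for one or two reactants
#'
#' Crosses the functional groups detected in the reactant(s) against the
#' reaction registry. With a single molecule only unimolecular
#' conversions (halide/amine to azide, alkene epoxidation) are returned;
#' with two molecules each bimolecular registry entry is tried in both
#' orientations. Order is deterministic: registry order, then role-atom
#' index.
#'
#' @param molA a bonded \code{\linkS4class{Molecule}}.
#' @param molB optional second bonded molecule.
#' @return list of entries with elements \code{reaction}, \code{matchA},
#'   \code{matchB} (NULL for unimolecular), \code{swap} (TRUE when the
#'   first reacting group was found in \code{molB}).
#' @export
applicableReactions <- function(molA, molB = NULL) {
  gA <- detectGroups(molA)
  gB <- if (is.null(molB)) list() else detectGroups(molB)
  out <- list()
  for (entry in .reactionRegistry) {
    if (is.null(molB)) {
      if (entry$arity != 1L) next
      for (m in gA) {
        if (m@kind %in% entry$kindsA)
          out[[length(out) + 1L]] <- list(reaction = entry$name,
                                          matchA = m, matchB = NULL,
                                          swap = FALSE)
      }
    } else {
      if (entry$arity != 2L) next
      for (sw in c(FALSE, TRUE)) {
        g1 <- if (sw) gB else gA
        g2 <- if (sw) gA else gB
        for (m1 in g1) {
          if (!m1@kind %in% entry$kindsA) next
          for (m2 in g2) {
            if (!m2@kind %in% entry$kindsB) next
            out[[length(out) + 1L]] <- list(reaction = entry$name,
                                            matchA = m1, matchB = m2,
                                            swap = sw)
          }
        }
      }
    }
  }
  out
}

#' Run one registry reaction on matched reactants
#'
#' Dispatch helper used by the library enumerator and the command-line
#' interface: takes one entry produced by
#' \code{\link{applicableReactions}} plus the parent molecules and
#' returns the list of \code{\linkS4class{ProductRecord}}s.
#'
#' @param entry one element of the \code{\link{applicableReactions}} list.
#' @param molA,molB the parent molecules passed to
#'   \code{applicableReactions}.
#' @param regio regio policy for the cycloaddition.
#' @param stepDeg steric-relief scan step in degrees.
#' @return list of \code{\linkS4class{ProductRecord}} objects.
#' @export
runReaction <- function(entry, molA, molB = NULL,
                        regio = c("both", "1,4", "1,5"), stepDeg = 10) {
  regio <- match.arg(regio)
  m1mol <- if (isTRUE(entry$swap)) molB else molA
  m2mol <- if (isTRUE(entry$swap)) molA else molB
  switch(entry$reaction,
    huisgen_cycloaddition =
      huisgenCycloaddition(m1mol, entry$matchA, m2mol, entry$matchB,
                           regio = regio, stepDeg = stepDeg),
    epoxide_opening =
      epoxideOpening(m1mol, entry$matchA, m2mol, entry$matchB,
                     stepDeg = stepDeg),
    amide_formation =
      list(amideFormation(m1mol, entry$matchA, m2mol, entry$matchB,
                          stepDeg = stepDeg)),
    halide_to_azide = list(halideToAzide(m1mol, entry$matchA,
                                         stepDeg = stepDeg)),
    amine_to_azide = list(amineToAzide(m1mol, entry$matchA,
                                       stepDeg = stepDeg)),
    alkene_epoxidation = list(alkeneEpoxidation(m1mol, entry$matchA)),
    stop("unknown reaction: ", entry$reaction)
  )
}
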