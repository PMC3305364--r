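# Programmatic generation of idealized 3D reactant models.
#
# All geometry is built from an in-code table of idealized bond lengths
# and ideal sp3/sp2/sp angles; hydrogens are always explicit. These
# models stand in for real reactant libraries so that every test and
# acceptance run is download-free.

.BL <- c(CH = 1.09, CC = 1.54, "C=C" = 1.34, "C#C" = 1.20,
         CarCar = 1.39, CarH = 1.08, CarC = 1.51, CarCsp = 1.43,
         CspC = 1.46, CspH = 1.06,
         CN = 1.47, NH = 1.01, "N=N" = 1.24, "N#N" = 1.13, "C-Nam" = 1.35,
         "C=O" = 1.22, CO = 1.43, "CO2H" = 1.36, OH = 0.96,
         CS = 1.82, SH = 1.34, CCl = 1.79, CBr = 1.94,
         epoxCC = 1.47)

# --- incremental molecule assembler ---------------------------------------

.newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character()
  env$xyz <- matrix(numeric(), ncol = 3L)
  env
}

.addAtom <- function(bld, element, pos) {
  bld$element <- c(bld$element, element)
  bld$xyz <- rbind(bld$xyz, as.numeric(pos))
  length(bld$element)
}

# add k hydrogens on `center` along the remaining sp3 directions implied
# by the unit vectors `us` toward already-placed neighbors
.addSp3H <- function(bld, center, us, k = NULL, bl = .BL[["CH"]],
                     element = "H", phaseDeg = 0) {
  dirs <- .sp3Fill(us, phaseDeg)
  if (!is.null(k)) dirs <- dirs[seq_len(k), , drop = FALSE]
  for (i in seq_len(nrow(dirs)))
    .addAtom(bld, element, center + bl * dirs[i, ])
  invisible(bld)
}

# methyl hydrogens with the torsion phase (deterministically) chosen to
# maximize the minimum distance to all atoms placed so far
.addMethylH <- function(bld, center, u) {
  phases <- seq(0, 110, by = 10)
  score <- vapply(phases, function(ph) {
    dirs <- .coneDirs(u, 109.471, 3L, ph)
    pts <- sweep(dirs * .BL[["CH"]], 2L, center, "+")
    min(apply(pts, 1L, function(p) {
      min(sqrt(colSums((t(bld$xyz) - p)^2)))
    }))
  }, numeric(1L))
  .addSp3H(bld, center, u, phaseDeg = phases[which.max(score)])
  invisible(bld)
}

# choose, among candidate unit directions, the one whose endpoint is
# farthest from all existing atoms (deterministic clash avoidance)
.bestDir <- function(bld, center, dirs, bl) {
  pts <- sweep(dirs * bl, 2L, center, "+")
  pts <- matrix(pts, ncol = 3L)
  k <- .pickFarthest(pts, bld$xyz)
  dirs[k, ]
}

.finishMolecule <- function(bld, label, tolerance = 0.4) {
  mol <- .newMolecule(bld$element, bld$xyz, label = label)
  inferBonds(mol, tolerance)
}

# zig-zag carbon backbone in the xy-plane; returns n x 3 positions
.zigzag <- function(n, bl = .BL[["CC"]]) {
  alpha <- (180 - 109.471) / 2 * pi / 180
  dirs <- t(vapply(seq_len(max(n - 1L, 0L)), function(k) {
    c(cos(alpha), if (k %% 2L == 1L) sin(alpha) else -sin(alpha), 0)
  }, numeric(3L)))
  pos <- matrix(0, nrow = n, ncol = 3L)
  for (k in seq_len(n - 1L))
    pos[k + 1L, ] <- pos[k, ] + bl * dirs[k, ]
  pos
}

# attach a phenyl ring (6 C + 5 H) whose ipso carbon sits at
# attach + bl * dir; the ring plane contains dir, with the azimuth
# chosen deterministically to maximize clearance from existing atoms
.addPhenyl <- function(bld, attach, dir, bl = .BL[["CarC"]]) {
  d <- .unitv(dir)
  ipso <- attach + bl * d
  ctr <- ipso + .BL[["CarCar"]] * d
  pb <- .perpBasis(d)
  ringAt <- function(e) {
    pos <- matrix(0, nrow = 11L, ncol = 3L)
    row <- 1L
    for (k in 0:5) {
      ang <- k * pi / 3
      u <- cos(ang) * (-d) + sin(ang) * e
      pos[row, ] <- ctr + .BL[["CarCar"]] * u
      row <- row + 1L
      if (k > 0L) {
        pos[row, ] <- ctr + (.BL[["CarCar"]] + .BL[["CarH"]]) * u
        row <- row + 1L
      }
    }
    pos
  }
  es <- lapply(seq(0, 85, by = 5) * pi / 180, function(a) {
    cos(a) * pb$e1 + sin(a) * pb$e2
  })
  if (nrow(bld$xyz) > 0L) {
    score <- vapply(es, function(e) {
      pts <- ringAt(e)
      min(apply(pts, 1L, function(p) {
        min(sqrt(colSums((t(bld$xyz) - p)^2)))
      }))
    }, numeric(1L))
    e <- es[[which.max(score)]]
  } else e <- es[[1L]]
  pos <- ringAt(e)
  idx <- integer(6L)
  row <- 1L
  for (k in 0:5) {
    idx[k + 1L] <- .addAtom(bld, "C", pos[row, ])
    row <- row + 1L
    if (k > 0L) { .addAtom(bld, "H", pos[row, ]); row <- row + 1L }
  }
  idx[1L]  # ipso carbon index
}

# append an azide unit (-N=N=N) continuing from atom at `from` whose
# bond direction arrives along unit vector `u` (from parent to `from`);
# when `withProximal`, a new proximal N is created at from + 1.47 u.
# Template geometry: C-N 1.47, N=N 1.24, N#N 1.13, C-N-N 115 deg,
# N-N-N 172 deg, planar.
.addAzide <- function(bld, from, u, withProximal = TRUE) {
  u <- .unitv(u)
  if (withProximal) {
    n1pos <- from + .BL[["CN"]] * u
    n1 <- .addAtom(bld, "N", n1pos)
  } else {
    n1pos <- from
    n1 <- nrow(bld$xyz)
  }
  pb <- .perpBasis(u)
  # N2 direction makes 115 deg with the N1->parent direction (-u)
  th <- 115 * pi / 180
  d12 <- cos(th) * (-u) + sin(th) * pb$e1
  n2pos <- n1pos + .BL[["N=N"]] * d12
  n2 <- .addAtom(bld, "N", n2pos)
  # N3 nearly linear: N-N-N = 172 deg, bend kept in the same plane
  ax <- .crossv(u, pb$e1)  # plane normal
  d23 <- as.numeric(.rotationMatrix(ax, (180 - 172) * pi / 180) %*% d12)
  n3pos <- n2pos + .BL[["N#N"]] * d23
  n3 <- .addAtom(bld, "N", n3pos)
  c(proximal = n1, medial = n2, distal = n3)
}

#' Build a canonical idealized fixture molecule
#'
#' Constructs one of a fixed panel of explicit-hydrogen, idealized 3D
#' models (bond lengths and angles from an in-code table), with bonds
#' perceived by \code{\link{inferBonds}}. Available names:
#' methane, ethane, ethene, ethyne, benzene, methylamine, acetamide,
#' acetic_acid, acetyl_chloride, ethanethiol, ethanol, ethylene_oxide,
#' propylene_oxide, methyl_azide, benzyl_azide, propyne, phenylacetylene,
#' butyne2 (2-butyne), benzyl_bromide, glucose (open-chain), butane.
#'
#' @param name fixture name (see list above).
#' @return a bonded \code{\linkS4class{Molecule}}.
#' @examples
#' formulaString(molecularFormula(buildFixture("methyl_azide")))  # CH3N3
#' @export
buildFixture <- function(name) {
  bld <- .newBuilder()
  CH <- .BL[["CH"]]; CC <- .BL[["CC"]]
  switch(name,
    methane = {
      c1 <- .addAtom(bld, "C", c(0, 0, 0))
      for (d in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
        .addAtom(bld, "H", CH * .unitv(d))
    },
    ethane = {
      .addAtom(bld, "C", c(0, 0, 0))
      .addAtom(bld, "C", c(CC, 0, 0))
      .addSp3H(bld, c(0, 0, 0), c(1, 0, 0))
      .addSp3H(bld, c(CC, 0, 0), c(-1, 0, 0), phaseDeg = 60)
    },
    ethene = {
      b <- .BL[["C=C"]]
      .addAtom(bld, "C", c(0, 0, 0))
      .addAtom(bld, "C", c(b, 0, 0))
      for (s in c(1, -1)) {
        .addAtom(bld, "H", CH * c(cos(2 * pi / 3), s * sin(2 * pi / 3), 0))
        .addAtom(bld, "H", c(b, 0, 0) +
                   CH * c(cos(pi / 3), s * sin(2 * pi / 3), 0))
      }
    },
    ethyne = {
      b <- .BL[["C#C"]]; ch <- .BL[["CspH"]]
      .addAtom(bld, "C", c(0, 0, 0))
      .addAtom(bld, "C", c(b, 0, 0))
      .addAtom(bld, "H", c(-ch, 0, 0))
      .addAtom(bld, "H", c(b + ch, 0, 0))
    },
    benzene = {
      r <- .BL[["CarCar"]]
      for (k in 0:5) {
        ang <- k * pi / 3
        .addAtom(bld, "C", r * c(cos(ang), sin(ang), 0))
        .addAtom(bld, "H", (r + .BL[["CarH"]]) * c(cos(ang), sin(ang), 0))
      }
    },
    methylamine = {
      cn <- .BL[["CN"]]
      .addAtom(bld, "C", c(0, 0, 0))
      .addAtom(bld, "N", c(cn, 0, 0))
      .addSp3H(bld, c(0, 0, 0), c(1, 0, 0))
      .addSp3H(bld, c(cn, 0, 0), c(-1, 0, 0), k = 2L, bl = .BL[["NH"]],
               phaseDeg = 60)
    },
    acetamide = .buildAcyl(bld, tail = "NH2"),
    acetic_acid = .buildAcyl(bld, tail = "OH"),
    acetyl_chloride = .buildAcyl(bld, tail = "Cl"),
    ethanethiol = .buildHetChain(bld, hetero = "S",
                                 blCX = .BL[["CS"]], blXH = .BL[["SH"]]),
    ethanol = .buildHetChain(bld, hetero = "O",
                             blCX = .BL[["CO"]], blXH = .BL[["OH"]]),
    ethylene_oxide = .buildEpoxide(bld, methyl = FALSE),
    propylene_oxide = .buildEpoxide(bld, methyl = TRUE),
    methyl_azide = {
      c1 <- .addAtom(bld, "C", c(0, 0, 0))
      .addAzide(bld, c(0, 0, 0), c(1, 0, 0))
      .addSp3H(bld, c(0, 0, 0), c(1, 0, 0))
    },
    benzyl_azide = {
      ch2 <- c(0, 0, 0)
      c7 <- .addAtom(bld, "C", ch2)
      ipso <- .addPhenyl(bld, ch2, c(-1, 0, 0))
      uring <- .unitv(bld$xyz[ipso, ] - ch2)
      dirs <- .sp3Fill(matrix(uring, nrow = 1L))
      .addAzide(bld, ch2, dirs[1L, ])
      un <- dirs[1L, ]
      hdirs <- .sp3Fill(rbind(uring, un))
      for (i in 1:2) .addAtom(bld, "H", ch2 + CH * hdirs[i, ])
    },
    propyne = {
      csp <- .BL[["CspC"]]; cc <- .BL[["C#C"]]
      .addAtom(bld, "C", c(0, 0, 0))                 # methyl C
      .addAtom(bld, "C", c(csp, 0, 0))
      .addAtom(bld, "C", c(csp + cc, 0, 0))
      .addAtom(bld, "H", c(csp + cc + .BL[["CspH"]], 0, 0))
      .addSp3H(bld, c(0, 0, 0), c(1, 0, 0))
    },
    phenylacetylene = {
      # ipso carbon at (-1.43, 0, 0), sp carbons along +x from origin
      ipso <- .addPhenyl(bld, c(0, 0, 0), c(-1, 0, 0),
                         bl = .BL[["CarCsp"]])
      ip <- bld$xyz[ipso, ]
      .addAtom(bld, "C", ip + .BL[["CarCsp"]] * c(1, 0, 0))
      .addAtom(bld, "C", ip + (.BL[["CarCsp"]] + .BL[["C#C"]]) *
                 c(1, 0, 0))
      .addAtom(bld, "H", ip + (.BL[["CarCsp"]] + .BL[["C#C"]] +
                                 .BL[["CspH"]]) * c(1, 0, 0))
    },
    butyne2 = {
      csp <- .BL[["CspC"]]; cc <- .BL[["C#C"]]
      .addAtom(bld, "C", c(0, 0, 0))
      .addAtom(bld, "C", c(csp, 0, 0))
      .addAtom(bld, "C", c(csp + cc, 0, 0))
      .addAtom(bld, "C", c(2 * csp + cc, 0, 0))
      .addSp3H(bld, c(0, 0, 0), c(1, 0, 0))
      .addSp3H(bld, c(2 * csp + cc, 0, 0), c(-1, 0, 0), phaseDeg = 60)
    },
    benzyl_bromide = {
      ch2 <- c(0, 0, 0)
      c7 <- .addAtom(bld, "C", ch2)
      ipso <- .addPhenyl(bld, ch2, c(-1, 0, 0))
      uring <- .unitv(bld$xyz[ipso, ] - ch2)
      dirs <- .sp3Fill(matrix(uring, nrow = 1L))
      .addAtom(bld, "Br", ch2 + .BL[["CBr"]] * dirs[1L, ])
      hdirs <- .sp3Fill(rbind(uring, dirs[1L, ]))
      for (i in 1:2) .addAtom(bld, "H", ch2 + CH * hdirs[i, ])
    },
    glucose = .buildGlucose(bld),
    butane = {
      pos <- .zigzag(4L)
      for (k in 1:4) .addAtom(bld, "C", pos[k, ])
      .addSp3H(bld, pos[1L, ], .unitv(pos[2L, ] - pos[1L, ]))
      .addSp3H(bld, pos[4L, ], .unitv(pos[3L, ] - pos[4L, ]))
      for (k in 2:3) {
        us <- rbind(.unitv(pos[k - 1L, ] - pos[k, ]),
                    .unitv(pos[k + 1L, ] - pos[k, ]))
        .addSp3H(bld, pos[k, ], us)
      }
    },
    stop("unknown fixture name: ", name)
  )
  .finishMolecule(bld, label = name)
}

# CH3-C(=O)-tail with tail one of NH2 / OH / Cl (planar acyl group)
.buildAcyl <- function(bld, tail) {
  cc <- .BL[["CarC"]]
  c2 <- .addAtom(bld, "C", c(0, 0, 0))                   # carbonyl C
  c1pos <- c(-1.50, 0, 0)
  c1 <- .addAtom(bld, "C", c1pos)                        # methyl C
  opos <- .BL[["C=O"]] * c(cos(pi / 3), sin(pi / 3), 0)
  .addAtom(bld, "O", opos)
  tdir <- c(cos(pi / 3), -sin(pi / 3), 0)
  if (tail == "NH2") {
    npos <- .BL[["C-Nam"]] * tdir
    .addAtom(bld, "N", npos)
    # planar amide N-H's at 120 deg in the xy-plane
    un <- .unitv(c(0, 0, 0) - npos)
    for (s in c(1, -1)) {
      R <- .rotationMatrix(c(0, 0, 1), s * 2 * pi / 3)
      .addAtom(bld, "H", npos + .BL[["NH"]] * as.numeric(R %*% un))
    }
  } else if (tail == "OH") {
    opos2 <- .BL[["CO2H"]] * tdir
    o2 <- .addAtom(bld, "O", opos2)
    uo <- .unitv(c(0, 0, 0) - opos2)
    # O-H roughly tetrahedral, anti to the carbonyl oxygen
    R <- .rotationMatrix(c(0, 0, 1), -109.471 * pi / 180)
    .addAtom(bld, "H", opos2 + .BL[["OH"]] * as.numeric(R %*% uo))
  } else if (tail == "Cl") {
    .addAtom(bld, "Cl", .BL[["CCl"]] * tdir)
  }
  .addSp3H(bld, c1pos, .unitv(c(0, 0, 0) - c1pos))
  invisible(bld)
}

# CH3-CH2-X-H with X = O or S
.buildHetChain <- function(bld, hetero, blCX, blXH) {
  pos <- .zigzag(2L)
  .addAtom(bld, "C", pos[1L, ])
  .addAtom(bld, "C", pos[2L, ])
  u21 <- .unitv(pos[1L, ] - pos[2L, ])
  xdir <- .sp3Fill(matrix(u21, nrow = 1L))[1L, ]
  xpos <- pos[2L, ] + blCX * xdir
  .addAtom(bld, hetero, xpos)
  .addSp3H(bld, pos[1L, ], .unitv(pos[2L, ] - pos[1L, ]))
  .addSp3H(bld, pos[2L, ], rbind(u21, xdir))
  hdirs <- .sp3Fill(matrix(.unitv(pos[2L, ] - xpos), nrow = 1L))
  .addAtom(bld, "H", xpos + blXH * .bestDir(bld, xpos, hdirs, blXH))
  invisible(bld)
}

.buildEpoxide <- function(bld, methyl) {
  b <- .BL[["epoxCC"]]; co <- .BL[["CO"]]
  p1 <- c(0, 0, 0); p2 <- c(b, 0, 0)
  h <- sqrt(co^2 - (b / 2)^2)
  po <- c(b / 2, h, 0)
  c1 <- .addAtom(bld, "C", p1)
  c2 <- .addAtom(bld, "C", p2)
  .addAtom(bld, "O", po)
  d1 <- .sp3Fill(rbind(.unitv(p2 - p1), .unitv(po - p1)))
  d2 <- .sp3Fill(rbind(.unitv(p1 - p2), .unitv(po - p2)))
  .addAtom(bld, "H", p1 + .BL[["CH"]] * d1[1L, ])
  .addAtom(bld, "H", p1 + .BL[["CH"]] * d1[2L, ])
  .addAtom(bld, "H", p2 + .BL[["CH"]] * d2[1L, ])
  if (methyl) {
    mpos <- p2 + .BL[["CC"]] * d2[2L, ]
    .addAtom(bld, "C", mpos)
    .addSp3H(bld, mpos, .unitv(p2 - mpos))
  } else {
    .addAtom(bld, "H", p2 + .BL[["CH"]] * d2[2L, ])
  }
  invisible(bld)
}

# open-chain (aldehyde) glucose: OHC-(CHOH)4-CH2OH
.buildGlucose <- function(bld) {
  pos <- .zigzag(6L)
  for (k in 1:6) .addAtom(bld, "C", pos[k, ])
  # C1: aldehyde, planar sp2 in a plane containing the C1->C2 bond
  u12 <- .unitv(pos[2L, ] - pos[1L, ])
  pb <- .perpBasis(u12)
  dO <- cos(2 * pi / 3) * u12 + sin(2 * pi / 3) * pb$e1
  dH <- cos(2 * pi / 3) * u12 - sin(2 * pi / 3) * pb$e1
  .addAtom(bld, "O", pos[1L, ] + .BL[["C=O"]] * dO)
  .addAtom(bld, "H", pos[1L, ] + .BL[["CH"]] * dH)
  # C2..C5: one OH + one H each, OH side alternating
  for (k in 2:5) {
    us <- rbind(.unitv(pos[k - 1L, ] - pos[k, ]),
                .unitv(pos[k + 1L, ] - pos[k, ]))
    dirs <- .sp3Fill(us)
    oi <- if (k %% 2L == 0L) 1L else 2L
    opos <- pos[k, ] + .BL[["CO"]] * dirs[oi, ]
    .addAtom(bld, "O", opos)
    .addAtom(bld, "H", pos[k, ] + .BL[["CH"]] * dirs[3L - oi, ])
    hdirs <- .sp3Fill(matrix(.unitv(pos[k, ] - opos), nrow = 1L))
    .addAtom(bld, "H", opos + .BL[["OH"]] *
               .bestDir(bld, opos, hdirs, .BL[["OH"]]))
  }
  # C6: terminal CH2OH
  u65 <- .unitv(pos[5L, ] - pos[6L, ])
  dirs <- .coneDirs(u65, 109.471, 3L)
  opos <- pos[6L, ] + .BL[["CO"]] * dirs[1L, ]
  .addAtom(bld, "O", opos)
  for (i in 2:3) .addAtom(bld, "H", pos[6L, ] + .BL[["CH"]] * dirs[i, ])
  hdirs <- .sp3Fill(matrix(.unitv(pos[6L, ] - opos), nrow = 1L))
  .addAtom(bld, "H", opos + .BL[["OH"]] *
             .bestDir(bld, opos, hdirs, .BL[["OH"]]))
  invisible(bld)
}

#' Names of the canonical fixture panel
#' @return character vector accepted by \code{\link{buildFixture}}.
#' @export
fixtureNames <- function() {
  c("methane", "ethane", "ethene", "ethyne", "benzene", "methylamine",
    "acetamide", "acetic_acid", "acetyl_chloride", "ethanethiol",
    "ethanol", "ethylene_oxide", "propylene_oxide", "methyl_azide",
    "benzyl_azide", "propyne", "phenylacetylene", "butyne2",
    "benzyl_bromide", "glucose", "butane")
}

# --- seeded reactant-set generation ---------------------------------------

# scaffold catalogue: (chain length, methyl-branch bitmask over interior
# carbons, phenyl terminus flag), enumerated deterministically
.scaffoldCatalogue <- function(maxLen = 12L) {
  out <- list()
  for (len in seq_len(maxLen)) {
    nInterior <- max(len - 2L, 0L)
    for (mask in 0:(2^nInterior - 1L)) {
      for (ph in c(FALSE, TRUE)) {
        out[[length(out) + 1L]] <- list(len = len, mask = mask, phenyl = ph)
      }
    }
  }
  out
}

# Build an alkyl chain of `len` carbons from `origin` along the zig-zag,
# with methyl branches per bitmask and an optional terminal phenyl.
# `headDirs`: unit vector(s) from C1 to already-placed neighbors (the
# functional head). Returns builder side effects only.
.buildChainScaffold <- function(bld, origin, headU, len, mask, phenyl) {
  alpha <- (180 - 109.471) / 2 * pi / 180
  pos <- matrix(0, nrow = len, ncol = 3L)
  pos[1L, ] <- origin
  idx <- integer(len)
  idx[1L] <- .addAtom(bld, "C", origin)
  if (len > 1L) {
    # chain continues opposite the head, zig-zagging in the head plane
    pb <- .perpBasis(headU)
    dirAlt <- function(k) {
      s <- if (k %% 2L == 1L) 1 else -1
      cos(alpha) * (-headU) + s * sin(alpha) * pb$e1
    }
    for (k in 2:len) {
      pos[k, ] <- pos[k - 1L, ] + .BL[["CC"]] * dirAlt(k - 1L)
      idx[k] <- .addAtom(bld, "C", pos[k, ])
    }
  }
  # hydrogens/branches; branch methyls alternate sides of the chain
  # plane (fixed reference normal, so the side does not flip with the
  # zig-zag parity of the local bond cross product)
  nref <- .crossv(headU, .perpBasis(headU)$e1)
  for (k in seq_len(len)) {
    us <- NULL
    if (k == 1L) us <- rbind(us, headU)
    if (k > 1L) us <- rbind(us, .unitv(pos[k - 1L, ] - pos[k, ]))
    if (k < len) us <- rbind(us, .unitv(pos[k + 1L, ] - pos[k, ]))
    dirs <- .sp3Fill(us)
    branchHere <- k > 1L && k < len &&
      bitwAnd(mask, bitwShiftL(1L, k - 2L)) > 0L
    phenylHere <- phenyl && k == len
    if (branchHere) {
      wantSign <- if (k %% 2L == 0L) 1 else -1
      side <- which.max(wantSign * as.numeric(dirs %*% nref))
      mpos <- pos[k, ] + .BL[["CC"]] * dirs[side, ]
      .addAtom(bld, "C", mpos)
      .addMethylH(bld, mpos, .unitv(pos[k, ] - mpos))
      dirs <- dirs[-side, , drop = FALSE]
    }
    if (phenylHere) {
      .addPhenyl(bld, pos[k, ], dirs[1L, ])
      dirs <- dirs[-1L, , drop = FALSE]
    }
    for (i in seq_len(nrow(dirs)))
      .addAtom(bld, "H", pos[k, ] + .BL[["CH"]] * dirs[i, ])
  }
  idx[1L]
}

#' Generate a seeded set of structurally distinct reactants
#'
#' Emits \code{n} distinct molecules of the requested functional kind by
#' decorating alkyl/aryl scaffolds (chain length 1-12, optional methyl
#' branches and phenyl terminus) with the reactive head group. The
#' scaffold catalogue is enumerated deterministically and shuffled by
#' \code{seed}, so equal seeds give identical sets and different seeds
#' different orderings. Every member carries exactly one match of the
#' requested kind; terminal alkynes are all non-symmetric (the far branch
#' is never a lone hydrogen).
#'
#' @param kind one of \code{"azide"}, \code{"terminal_alkyne"},
#'   \code{"alkyl_bromide"}.
#' @param n number of molecules (at most the catalogue size, 4096).
#' @param seed integer seed controlling the scaffold selection.
#' @return list of bonded \code{\linkS4class{Molecule}} objects labelled
#'   \code{<kind>_<i>}.
#' @export
generateReactantSet <- function(kind, n, seed = 1L) {
  kind <- match.arg(kind, c("azide", "terminal_alkyne", "alkyl_bromide"))
  stopifnot(n >= 1L)
  cat <- .scaffoldCatalogue()
  if (n > length(cat))
    stop("at most ", length(cat), " distinct scaffolds available")
  ord <- .seededSample(length(cat), n, seed)
  lapply(seq_len(n), function(i) {
    sc <- cat[[ord[i]]]
    .buildReactant(kind, sc, label = sprintf("%s_%04d", kind, i))
  })
}

# seeded sample without touching the caller's RNG state
.seededSample <- function(total, n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(total, n)
}

.buildReactant <- function(kind, sc, label) {
  bld <- .newBuilder()
  if (kind == "azide") {
    origin <- c(0, 0, 0)
    # azide head built first pointing along -x; chain continues along +x
    .addAzide(bld, origin, c(-1, 0, 0), withProximal = TRUE)
    .buildChainScaffold(bld, origin, c(-1, 0, 0),
                        sc$len, sc$mask, sc$phenyl)
  } else if (kind == "terminal_alkyne") {
    ch <- .BL[["CspH"]]; cc <- .BL[["C#C"]]; csp <- .BL[["CspC"]]
    .addAtom(bld, "H", c(-ch, 0, 0))
    .addAtom(bld, "C", c(0, 0, 0))
    c2pos <- c(cc, 0, 0)
    .addAtom(bld, "C", c2pos)
    origin <- c2pos + csp * c(1, 0, 0)
    .buildChainScaffold(bld, origin, c(-1, 0, 0), sc$len, sc$mask, sc$phenyl)
  } else {
    origin <- c(0, 0, 0)
    .addAtom(bld, "Br", origin + .BL[["CBr"]] * c(-1, 0, 0))
    .buildChainScaffold(bld, origin, c(-1, 0, 0), sc$len, sc$mask, sc$phenyl)
  }
  .finishMolecule(bld, label = label)
}
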