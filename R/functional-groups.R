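#' Detect click-reactive functional groups
#'
#' Scans a bonded molecular graph for the functional groups that drive
#' the reaction registry, returning role-labelled matches. Patterns are
#' graph rules over elements, degrees and hybridization:
#' \describe{
#'   \item{azide}{N1-N2-N3 chain: medial N2 of degree exactly 2 (both
#'     neighbors N), distal N3 of degree 1, proximal N1 bonded to exactly
#'     one carbon (\code{attach_C}).}
#'   \item{terminal_alkyne / internal_alkyne}{two mutually bonded sp
#'     carbons, each of degree 2; terminal when one carbon's other
#'     neighbor is a hydrogen.}
#'   \item{alkyl_halide}{sp3 carbon bonded to exactly one of Cl/Br/I.}
#'   \item{primary_amine}{N with exactly two H and one C neighbor, where
#'     that carbon has no degree-1 oxygen neighbor (amide exclusion);
#'     \code{secondary_amine} analogously with one H and two C, both
#'     carbons passing the amide exclusion.}
#'   \item{epoxide}{a C-C-O three-ring.}
#'   \item{carboxylic_acid}{C bonded to two O, one of degree 1 (carbonyl)
#'     and one bearing an H; \code{acyl_halide}: C bonded to one degree-1
#'     O and one halogen.}
#'   \item{thiol}{S with one H and one C; \code{alcohol}: O with one H
#'     and one C whose carbon is not a carboxyl carbon.}
#'   \item{alkene}{two mutually bonded sp2 carbons, excluding pairs that
#'     sit together in a six-ring whose members are all sp2 carbons (a
#'     deliberate crude aromaticity guard, so benzene is never
#'     "epoxidized" in library mode).}
#' }
#'
#' Matches are maximal and non-overlapping within a kind; across kinds
#' the more specific pattern wins by the precedence order azide,
#' terminal_alkyne, internal_alkyne, epoxide, carboxylic_acid,
#' acyl_halide, alkyl_halide, primary_amine, secondary_amine, thiol,
#' alcohol, alkene.
#'
#' @param mol a \code{\linkS4class{Molecule}} with bonds populated and
#'   explicit hydrogens.
#' @param kinds optional character vector restricting the kinds searched.
#' @return list of \code{\linkS4class{FGMatch}} objects, ordered by kind
#'   precedence then lowest role atom index.
#' @examples
#' detectGroups(buildFixture("methyl_azide"))
#' @export
detectGroups <- function(mol, kinds = NULL) {
  if (natoms(mol) > 1L && nrow(mol@bonds) == 0L)
    stop("detectGroups: molecule has no bonds; run inferBonds() first")
  precedence <- c("azide", "terminal_alkyne", "internal_alkyne", "epoxide",
                  "carboxylic_acid", "acyl_halide", "alkyl_halide",
                  "primary_amine", "secondary_amine", "thiol", "alcohol",
                  "alkene")
  wanted <- if (is.null(kinds)) precedence else intersect(precedence, kinds)

  el <- elements(mol)
  adj <- .adjacency(mol)
  deg <- lengths(adj)
  hyb <- vapply(seq_along(el), function(i) {
    if (el[i] %in% c("C", "N", "O", "S") && deg[i] > 0L)
      hybridization(mol, i) else "other"
  }, character(1L))
  nbEl <- function(i, e) adj[[i]][el[adj[[i]]] == e]

  found <- list()     # all candidate matches in precedence order
  claimed <- integer()

  addMatch <- function(kind, roles) {
    # cross-kind overlap: first (more specific) claim wins
    if (any(roles %in% claimed)) return(invisible())
    claimed <<- c(claimed, unname(roles))
    found[[length(found) + 1L]] <<-
      new("FGMatch", kind = kind,
          roles = stats::setNames(as.integer(roles), names(roles)),
          label = mol@label)
    invisible()
  }

  for (kind in precedence) {
    if (!kind %in% wanted && !kind %in% precedence) next
    collect <- switch(kind,
      azide = {
        for (n2 in which(el == "N" & deg == 2L)) {
          nb <- adj[[n2]]
          if (!all(el[nb] == "N")) next
          for (n3 in nb) {
            n1 <- setdiff(nb, n3)
            if (deg[n3] != 1L) next
            cs <- nbEl(n1, "C")
            if (length(cs) != 1L) next
            if (kind %in% wanted)
              addMatch("azide", c(proximal_N = n1, medial_N = n2,
                                  distal_N = n3, attach_C = cs))
          }
        }
      },
      terminal_alkyne = ,
      internal_alkyne = {
        if (kind == "internal_alkyne") next_done <- TRUE # handled below
      },
      NULL)
    if (kind == "terminal_alkyne") {
      spC <- which(el == "C" & deg == 2L & hyb == "sp")
      for (c1 in spC) {
        for (c2 in adj[[c1]]) {
          if (c2 <= c1) next
          if (!(c2 %in% spC)) next
          o1 <- setdiff(adj[[c1]], c2)
          o2 <- setdiff(adj[[c2]], c1)
          h1 <- length(o1) == 1L && el[o1] == "H"
          h2 <- length(o2) == 1L && el[o2] == "H"
          if (h1 || h2) {
            if (!"terminal_alkyne" %in% wanted) next
            term <- if (h1) c1 else c2
            subst <- if (h1) c2 else c1
            addMatch("terminal_alkyne",
                     c(terminal_C = term, subst_C = subst,
                       terminal_H = if (h1) o1 else o2))
          }
        }
      }
    }
    if (kind == "internal_alkyne") {
      spC <- which(el == "C" & deg == 2L & hyb == "sp")
      for (c1 in spC) {
        for (c2 in adj[[c1]]) {
          if (c2 <= c1) next
          if (!(c2 %in% spC)) next
          o1 <- setdiff(adj[[c1]], c2)
          o2 <- setdiff(adj[[c2]], c1)
          h1 <- length(o1) == 1L && el[o1] == "H"
          h2 <- length(o2) == 1L && el[o2] == "H"
          if (!h1 && !h2 && "internal_alkyne" %in% wanted)
            addMatch("internal_alkyne", c(c1 = c1, c2 = c2))
        }
      }
    }
    if (kind == "epoxide") {
      for (o in which(el == "O" & deg == 2L)) {
        cs <- nbEl(o, "C")
        if (length(cs) != 2L) next
        if (any(adj[[cs[1L]]] == cs[2L]) && "epoxide" %in% wanted)
          addMatch("epoxide", c(C1 = cs[1L], C2 = cs[2L], O = o))
      }
    }
    if (kind == "carboxylic_acid") {
      for (cc in which(el == "C")) {
        os <- nbEl(cc, "O")
        if (length(os) != 2L) next
        carbonyl <- os[deg[os] == 1L]
        hydroxyl <- os[deg[os] == 2L &
                       vapply(os, function(o) length(nbEl(o, "H")) == 1L,
                              logical(1L))]
        if (length(carbonyl) == 1L && length(hydroxyl) == 1L &&
            "carboxylic_acid" %in% wanted)
          addMatch("carboxylic_acid",
                   c(C = cc, carbonyl_O = carbonyl, hydroxyl_O = hydroxyl,
                     hydroxyl_H = nbEl(hydroxyl, "H")[1L]))
      }
    }
    if (kind == "acyl_halide") {
      for (cc in which(el == "C")) {
        os <- nbEl(cc, "O")
        xs <- adj[[cc]][el[adj[[cc]]] %in% .HALOGENS]
        if (length(os) == 1L && deg[os] == 1L && length(xs) == 1L &&
            "acyl_halide" %in% wanted)
          addMatch("acyl_halide", c(C = cc, carbonyl_O = os, X = xs))
      }
    }
    if (kind == "alkyl_halide") {
      for (cc in which(el == "C" & hyb == "sp3")) {
        xs <- adj[[cc]][el[adj[[cc]]] %in% .HALOGENS]
        if (length(xs) == 1L && "alkyl_halide" %in% wanted)
          addMatch("alkyl_halide", c(C = cc, X = xs))
      }
    }
    if (kind %in% c("primary_amine", "secondary_amine")) {
      wantH <- if (kind == "primary_amine") 2L else 1L
      wantC <- if (kind == "primary_amine") 1L else 2L
      for (nn in which(el == "N")) {
        hs <- nbEl(nn, "H"); cs <- nbEl(nn, "C")
        if (length(hs) != wantH || length(cs) != wantC ||
            deg[nn] != wantH + wantC) next
        amide <- any(vapply(cs, function(cc) {
          os <- nbEl(cc, "O"); any(deg[os] == 1L)
        }, logical(1L)))
        if (amide || !kind %in% wanted) next
        roles <- c(N = nn,
                   stats::setNames(hs, paste0("H", seq_along(hs))),
                   stats::setNames(cs, paste0("C", seq_along(cs))))
        addMatch(kind, roles)
      }
    }
    if (kind == "thiol") {
      for (ss in which(el == "S" & deg == 2L)) {
        hs <- nbEl(ss, "H"); cs <- nbEl(ss, "C")
        if (length(hs) == 1L && length(cs) == 1L && "thiol" %in% wanted)
          addMatch("thiol", c(S = ss, H = hs, C = cs))
      }
    }
    if (kind == "alcohol") {
      for (o in which(el == "O" & deg == 2L)) {
        hs <- nbEl(o, "H"); cs <- nbEl(o, "C")
        if (length(hs) != 1L || length(cs) != 1L) next
        # carboxyl carbon: the attached C carries another degree-1 oxygen
        otherO <- setdiff(nbEl(cs, "O"), o)
        if (any(deg[otherO] == 1L)) next
        if ("alcohol" %in% wanted)
          addMatch("alcohol", c(O = o, H = hs, C = cs))
      }
    }
    if (kind == "alkene") {
      sp2C <- which(el == "C" & hyb == "sp2")
      for (c1 in sp2C) {
        for (c2 in adj[[c1]]) {
          if (c2 <= c1) next
          if (!(c2 %in% sp2C)) next
          if (.inAromaticSixRing(mol, c1, c2, el, hyb)) next
          if ("alkene" %in% wanted)
            addMatch("alkene", c(C1 = c1, C2 = c2))
        }
      }
    }
  }

  keepKinds <- vapply(found, function(m) m@kind %in% wanted, logical(1L))
  found[keepKinds]
}

# Crude aromaticity guard: c1 and c2 share a six-ring whose members are
# all sp2 carbons.
.inAromaticSixRing <- function(mol, c1, c2, el, hyb) {
  adj <- .adjacency(mol)
  paths <- .simplePaths(adj, c1, c2, maxEdges = 5L)
  for (i in seq_along(paths)) {
    for (j in seq_along(paths)) {
      if (i >= j) next
      p1 <- paths[[i]]; p2 <- paths[[j]]
      if ((length(p1) - 1L) + (length(p2) - 1L) != 6L) next
      if (length(intersect(setdiff(p1, c(c1, c2)),
                           setdiff(p2, c(c1, c2)))) > 0L) next
      ring <- union(p1, p2)
      if (length(ring) == 6L && all(el[ring] == "C") &&
          all(hyb[ring] == "sp2"))
        return(TRUE)
    }
  }
  FALSE
}

# Element-coloured igraph over a set of atom indices of `mol`.
.branchGraph <- function(mol) {
  el <- elements(mol)
  g <- igraph::make_empty_graph(n = natoms(mol), directed = FALSE)
  if (nrow(mol@bonds))
    g <- igraph::add_edges(g, t(mol@bonds))
  igraph::V(g)$color <- match(el, .ELEMENT_TABLE$symbol)
  g
}

# Labelled-graph isomorphism of two molecules (element colours, VF2).
.molIsomorphic <- function(a, b) {
  if (natoms(a) != natoms(b)) return(FALSE)
  fa <- molecularFormula(a); fb <- molecularFormula(b)
  if (!identical(fa, fb)) return(FALSE)
  igraph::isomorphic(.branchGraph(a), .branchGraph(b), method = "vf2")
}

#' Is an alkyne symmetric?
#'
#' An alkyne is symmetric when the two substituent branches obtained by
#' cutting the triple bond (\code{\link{getBranch}} from each alkyne
#' carbon) are isomorphic as element-labelled graphs. A terminal alkyne
#' is symmetric only when the other branch is also a lone hydrogen (i.e.
#' ethyne itself). Symmetric alkynes give a single Huisgen cycloaddition
#' product; non-symmetric alkynes give both regioisomers.
#'
#' @param mol the alkyne-bearing \code{\linkS4class{Molecule}}.
#' @param match an alkyne \code{\linkS4class{FGMatch}} from
#'   \code{\link{detectGroups}}.
#' @return logical scalar.
#' @export
isSymmetricAlkyne <- function(mol, match) {
  stopifnot(is(match, "FGMatch"))
  if (!match@kind %in% c("terminal_alkyne", "internal_alkyne"))
    stop("isSymmetricAlkyne expects an alkyne match")
  cpair <- .alkyneCarbons(match)
  b1 <- getBranch(mol, anchor = cpair[2L], direction = cpair[1L])
  b2 <- getBranch(mol, anchor = cpair[1L], direction = cpair[2L])
  # compare substituent branches (alkyne carbon excluded from each side)
  s1 <- .dropAtoms(b1, match(cpair[1L], b1@metadata$provenance))
  s2 <- .dropAtoms(b2, match(cpair[2L], b2@metadata$provenance))
  .molIsomorphic(s1, s2)
}

.alkyneCarbons <- function(match) {
  r <- match@roles
  if (match@kind == "terminal_alkyne") {
    c(r[["terminal_C"]], r[["subst_C"]])
  } else {
    c(r[["c1"]], r[["c2"]])
  }
}

.dropAtoms <- function(mol, drop) {
  keep <- setdiff(seq_len(natoms(mol)), drop)
  prov <- mol@metadata$provenance
  sub <- .subMolecule(mol, keep)
  if (!is.null(prov)) sub@metadata$provenance <- prov[keep]
  sub
}
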