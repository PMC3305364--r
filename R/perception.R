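#' Infer covalent bonds from interatomic distances
#'
#' PDB files of small molecules rarely carry trustworthy connectivity, so
#' bonds are perceived geometrically: atoms \code{i} and \code{j} are
#' bonded iff \code{dist(i,j) <= rcov(i) + rcov(j) + tolerance} and
#' \code{dist(i,j) >= 0.4} A, using tabulated single-bond covalent radii
#' (H 0.31, C 0.76, N 0.71, O 0.66, S 1.05, Cl 1.02, Br 1.20, I 1.39 A).
#' Bonds already present (e.g. from CONECT records) are kept (union).
#' Hydrogens are capped at one bond, keeping the shortest. No bond orders
#' are stored; multiplicity is inferred contextually by the detectors
#' (e.g. an alkyne is two bonded sp carbons).
#'
#' @param mol a \code{\linkS4class{Molecule}} with finite coordinates.
#' @param tolerance distance slack in Angstrom (default 0.4).
#' @return the molecule with its bond slot populated.
#' @examples
#' eth <- buildFixture("ethane")
#' nrow(bonds(eth))  # 7: one C-C and six C-H
#' @export
inferBonds <- function(mol, tolerance = 0.4) {
  n <- natoms(mol)
  if (n == 0L) return(mol)
  el <- elements(mol)
  r <- .covalentRadius(el)  # errors on missing entries
  xyz <- coords(mol)
  D <- .pairwiseDists(xyz)
  thr <- outer(r, r, "+") + tolerance
  hit <- D <= thr & D >= 0.4
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  b <- .normalizeBonds(rbind(mol@bonds, idx), n)
  # cap hydrogens at one bond (keep the shortest partner)
  if (nrow(b)) {
    isH <- el == "H"
    repeat {
      deg <- tabulate(c(b[, 1L], b[, 2L]), nbins = n)
      over <- which(isH & deg > 1L)
      if (!length(over)) break
      h <- over[1L]
      rows <- which(b[, 1L] == h | b[, 2L] == h)
      partner <- ifelse(b[rows, 1L] == h, b[rows, 2L], b[rows, 1L])
      keep <- rows[which.min(D[cbind(rep(h, length(rows)), partner)])]
      b <- b[-setdiff(rows, keep), , drop = FALSE]
    }
  }
  mol@bonds <- b
  validObject(mol)
  mol
}

.requireBonds <- function(mol, caller) {
  if (nrow(mol@bonds) == 0L && natoms(mol) > 1L)
    stop(caller, ": molecule has no bonds; run inferBonds() first")
}

#' Count bonded neighbors of a given element
#'
#' @param mol a \code{\linkS4class{Molecule}} with bonds populated.
#' @param atom atom index of interest.
#' @param element element symbol to count among the bonded neighbors.
#' @return non-negative integer count.
#' @export
neighborsOfElement <- function(mol, atom, element) {
  .checkIndex(mol, atom)
  nb <- .neighborsOf(mol, atom)
  sum(elements(mol)[nb] == element)
}

#' First bonded neighbor of a given element
#'
#' @inheritParams neighborsOfElement
#' @return the lowest matching neighbor atom index, or \code{NA_integer_}
#'   when no bonded neighbor has that element.
#' @export
firstNeighborOfElement <- function(mol, atom, element) {
  .checkIndex(mol, atom)
  nb <- .neighborsOf(mol, atom)
  nb <- nb[elements(mol)[nb] == element]
  if (length(nb)) min(nb) else NA_integer_
}

.checkIndex <- function(mol, atom) {
  if (!(is.numeric(atom) && length(atom) == 1L &&
        atom >= 1L && atom <= natoms(mol)))
    stop("invalid atom index: ", atom)
}

.neighborsOf <- function(mol, atom) {
  b <- mol@bonds
  sort(c(b[b[, 1L] == atom, 2L], b[b[, 2L] == atom, 1L]))
}

#' Orbital hybridization of an atom
#'
#' Classified from connectivity and bond angles: a carbon with two
#' neighbors subtending >= 155 degrees is sp; an atom with three
#' neighbors whose angle sum is >= 350 degrees is sp2; a carbon with two
#' neighbors and a mean angle in [115, 128] degrees is sp2; any other
#' centre of degree <= 4 is sp3. Elements other than C/N/O/S, isolated
#' atoms, and hypervalent centres return \code{"other"}. The angular
#' thresholds classify idealized geometries with a wide (>= 25 degree)
#' margin.
#'
#' @inheritParams neighborsOfElement
#' @return one of \code{"sp"}, \code{"sp2"}, \code{"sp3"}, \code{"other"}.
#' @export
hybridization <- function(mol, atom) {
  .checkIndex(mol, atom)
  el <- elements(mol)[atom]
  if (!el %in% c("C", "N", "O", "S")) return("other")
  nb <- .neighborsOf(mol, atom)
  deg <- length(nb)
  if (deg == 0L) return("other")
  if (deg > 4L) return("other")
  if (deg == 1L) return("sp3")
  xyz <- coords(mol)
  angles <- utils::combn(nb, 2L, function(p) {
    u <- .unitv(xyz[p[1L], ] - xyz[atom, ])
    v <- .unitv(xyz[p[2L], ] - xyz[atom, ])
    acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  })
  if (el == "C" && deg == 2L && max(angles) >= 155) return("sp")
  if (deg == 3L && sum(angles) >= 350) return("sp2")
  if (el == "C" && deg == 2L && mean(angles) >= 115 && mean(angles) <= 128)
    return("sp2")
  "sp3"
}

#' Are two atoms in the same ring?
#'
#' True iff some simple cycle of length at most 8 contains both atoms.
#' Ring perception is bounded at size 8: this covers all click-relevant
#' chemistry while avoiding exponential cycle enumeration on pathological
#' graphs (a documented limitation for macrocycles).
#'
#' @param mol a \code{\linkS4class{Molecule}} with bonds populated.
#' @param a,b atom indices.
#' @return logical scalar.
#' @export
inSameRing <- function(mol, a, b) {
  .checkIndex(mol, a); .checkIndex(mol, b)
  if (a == b) {
    # an atom shares a ring with itself iff it lies on some cycle <= 8
    return(.bondInCycle(mol, a, NULL, maxLen = 8L))
  }
  adj <- .adjacency(mol)
  # two internally vertex-disjoint paths a->b with total length <= 8
  paths <- .simplePaths(adj, a, b, maxEdges = 7L)
  if (length(paths) < 2L) return(FALSE)
  for (i in seq_len(length(paths) - 1L)) {
    pi <- paths[[i]]
    inner_i <- setdiff(pi, c(a, b))
    len_i <- length(pi) - 1L
    for (j in seq((i + 1L), length(paths))) {
      pj <- paths[[j]]
      if (len_i + (length(pj) - 1L) > 8L) next
      if (length(intersect(inner_i, setdiff(pj, c(a, b)))) == 0L &&
          !identical(pi, pj))
        return(TRUE)
    }
  }
  FALSE
}

# All simple paths from a to b with <= maxEdges edges (DFS).
.simplePaths <- function(adj, a, b, maxEdges) {
  out <- list()
  rec <- function(path) {
    last <- path[length(path)]
    if (last == b) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    if (length(path) - 1L >= maxEdges) return(invisible())
    for (nx in adj[[last]]) {
      if (!(nx %in% path)) rec(c(path, nx))
    }
  }
  rec(a)
  out
}

# Is atom `a` (or, when b given, the a-b bond) on some cycle <= maxLen?
.bondInCycle <- function(mol, a, b = NULL, maxLen = 8L) {
  adj <- .adjacency(mol)
  if (is.null(b)) {
    for (nb in adj[[a]]) {
      paths <- .simplePaths(adj, a, nb, maxEdges = maxLen - 1L)
      if (any(vapply(paths, function(p) length(p) > 2L, logical(1L))))
        return(TRUE)
    }
    return(FALSE)
  }
  paths <- .simplePaths(adj, a, b, maxEdges = maxLen - 1L)
  any(vapply(paths, function(p) length(p) > 2L, logical(1L)))
}

# Ring-bond test used by getBranch/stericRelief: a bond is a ring bond iff
# the graph stays connected between its endpoints after the bond is cut
# (unbounded, because cutting any cycle's bond leaves the branch undefined).
.isRingBond <- function(mol, a, b) {
  adj <- .adjacency(mol)
  adj[[a]] <- setdiff(adj[[a]], b)
  adj[[b]] <- setdiff(adj[[b]], a)
  seen <- logical(natoms(mol))
  queue <- a; seen[a] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nx in adj[[cur]]) {
      if (nx == b) return(TRUE)
      if (!seen[nx]) { seen[nx] <- TRUE; queue <- c(queue, nx) }
    }
  }
  FALSE
}

#' Cut a molecule along a bond and return one side
#'
#' Partitions the molecule in two by cutting the \code{anchor-direction}
#' bond and returns the sub-molecule reachable from \code{direction}
#' (including \code{direction}, excluding \code{anchor}). Original atom
#' indices are preserved in \code{metadata$provenance}.
#'
#' @param mol a \code{\linkS4class{Molecule}} with bonds populated.
#' @param anchor,direction atom indices of a non-ring bond; the branch on
#'   the \code{direction} side is returned.
#' @return the branch \code{\linkS4class{Molecule}}.
#' @export
getBranch <- function(mol, anchor, direction) {
  .checkIndex(mol, anchor); .checkIndex(mol, direction)
  b <- mol@bonds
  isBond <- any((b[, 1L] == anchor & b[, 2L] == direction) |
                (b[, 1L] == direction & b[, 2L] == anchor))
  if (!isBond) stop("atoms ", anchor, " and ", direction, " are not bonded")
  if (.isRingBond(mol, anchor, direction))
    stop("branch undefined for ring bonds")
  adj <- .adjacency(mol)
  adj[[anchor]] <- setdiff(adj[[anchor]], direction)
  adj[[direction]] <- setdiff(adj[[direction]], anchor)
  seen <- logical(natoms(mol))
  queue <- direction; seen[direction] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nx in adj[[cur]]) {
      if (!seen[nx]) { seen[nx] <- TRUE; queue <- c(queue, nx) }
    }
  }
  keep <- which(seen)
  .subMolecule(mol, keep)
}

# Sub-molecule over atom indices `keep` (sorted); provenance recorded.
.subMolecule <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  atoms <- mol@atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  remap <- match(seq_len(natoms(mol)), keep)
  b <- mol@bonds
  if (nrow(b)) {
    i <- remap[b[, 1L]]; j <- remap[b[, 2L]]
    ok <- !is.na(i) & !is.na(j)
    b <- cbind(i[ok], j[ok])
  }
  new("Molecule", atoms = atoms,
      bonds = .normalizeBonds(b, length(keep)),
      label = mol@label, metadata = list(provenance = keep))
}
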