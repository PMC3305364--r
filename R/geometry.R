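#' Rigid-body molecular geometry operations
#'
#' Translation, rotation about arbitrary axes, tether-based least-squares
#' superposition, merging and intermolecular distances. Every operation
#' except \code{mergeMolecules} is rigid: all intramolecular pairwise
#' distances are preserved.
#'
#' @param mol a \code{\linkS4class{Molecule}}.
#' @param v numeric length-3 translation vector (Angstrom).
#' @return the transformed \code{\linkS4class{Molecule}} (bond set and
#'   atom order unchanged).
#' @name geometry
NULL

#' @rdname geometry
#' @export
translateMol <- function(mol, v) {
  stopifnot(length(v) == 3L, all(is.finite(v)))
  coords(mol) <- sweep(coords(mol), 2L, as.numeric(v), "+")
  mol
}

#' @rdname geometry
#' @param atom atom index (1-based).
#' @param target numeric length-3 coordinate the atom should move to; the
#'   whole molecule is translated rigidly.
#' @export
setAtomLocation <- function(mol, atom, target) {
  n <- natoms(mol)
  if (!(is.numeric(atom) && length(atom) == 1L && atom >= 1L && atom <= n))
    stop("invalid atom index: ", atom)
  translateMol(mol, as.numeric(target) - coords(mol)[atom, ])
}

# Rotation matrix for a right-handed rotation by `angle` about unit axis.
.rotationMatrix <- function(axis, angle) {
  u <- .unitv(axis)
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  matrix(c(
    c + u[1L]^2 * C,            u[1L] * u[2L] * C - u[3L] * s, u[1L] * u[3L] * C + u[2L] * s,
    u[2L] * u[1L] * C + u[3L] * s, c + u[2L]^2 * C,            u[2L] * u[3L] * C - u[1L] * s,
    u[3L] * u[1L] * C - u[2L] * s, u[3L] * u[2L] * C + u[1L] * s, c + u[3L]^2 * C),
    nrow = 3L, byrow = TRUE)
}

# Rotate a coordinate matrix about the line p1->p2 (right-handed).
.rotateCoords <- function(xyz, p1, p2, angle) {
  axis <- p2 - p1
  R <- .rotationMatrix(axis, angle)
  sweep(tcrossprod(sweep(xyz, 2L, p1, "-"), R), 2L, p1, "+")
}

#' @rdname geometry
#' @param p1,p2 two points (length-3) defining the rotation axis
#'   \code{p1 -> p2}; they must be at least 1e-6 A apart.
#' @param angle rotation angle in radians (right-handed about the axis).
#' @export
rotateAboutLine <- function(mol, p1, p2, angle) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (sqrt(sum((p2 - p1)^2)) <= 1e-6)
    stop("degenerate rotation axis: |p2 - p1| <= 1e-6 A")
  coords(mol) <- .rotateCoords(coords(mol), p1, p2, angle)
  mol
}

#' @rdname geometry
#' @param a,b atom indices whose positions define the rotation axis.
#' @export
rotateAboutBond <- function(mol, a, b, angle) {
  n <- natoms(mol)
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  if (a == b) stop("rotation axis needs two distinct atoms")
  xyz <- coords(mol)
  rotateAboutLine(mol, xyz[a, ], xyz[b, ], angle)
}

#' @rdname geometry
#' @param pivot point the rotation axis passes through.
#' @param axis direction of the rotation axis (nonzero).
#' @export
rotateAboutPivot <- function(mol, pivot, axis, angle) {
  axis <- as.numeric(axis)
  if (sqrt(sum(axis^2)) < 1e-12) stop("zero rotation axis")
  pivot <- as.numeric(pivot)
  rotateAboutLine(mol, pivot, pivot + .unitv(axis), angle)
}

#' Align a molecule to a reference by tethers
#'
#' Tethers are declared atom-atom correspondences between a mobile and a
#' reference molecule. The mobile molecule is translated and rotated
#' rigidly to minimize the sum of squared tether lengths (classic
#' least-squares superposition via the Kabsch/SVD solution). With one
#' tether this reduces to the pure translation that zeroes that tether;
#' degenerate tether geometries (collinear targets) leave a rotational
#' degree of freedom that is fixed deterministically by the SVD's
#' canonical sign convention, so results are reproducible.
#'
#' @param mobile the \code{\linkS4class{Molecule}} to move.
#' @param reference the fixed reference \code{\linkS4class{Molecule}}.
#' @param tethers two-column integer matrix; column 1 holds atom indices
#'   into \code{mobile}, column 2 the corresponding indices into
#'   \code{reference}. At least one row.
#' @return list with \code{molecule} (the aligned mobile molecule) and
#'   \code{residual} (the minimized sum of squared tether lengths, A^2).
#' @examples
#' m <- buildFixture("methane")
#' out <- alignByTethers(translateMol(m, c(5, 0, 0)), m,
#'                       cbind(seq_len(natoms(m)), seq_len(natoms(m))))
#' out$residual
#' @export
alignByTethers <- function(mobile, reference, tethers) {
  tethers <- matrix(as.integer(tethers), ncol = 2L)
  if (nrow(tethers) < 1L) stop("at least one tether is required")
  P <- coords(mobile)[tethers[, 1L], , drop = FALSE]   # mobile points
  Q <- coords(reference)[tethers[, 2L], , drop = FALSE] # targets
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, pc, "-"), sweep(Q, 2L, qc, "-"))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xyz <- coords(mobile)
  newXyz <- sweep(tcrossprod(sweep(xyz, 2L, pc, "-"), R), 2L, qc, "+")
  coords(mobile) <- newXyz
  resid <- sum((newXyz[tethers[, 1L], , drop = FALSE] - Q)^2)
  list(molecule = mobile, residual = resid)
}

#' Merge two molecules into one
#'
#' Atoms of \code{a} are followed by atoms of \code{b}; bond indices of
#' \code{b} are shifted by \code{natoms(a)}; coordinates are untouched and
#' labels are concatenated.
#'
#' @param a,b \code{\linkS4class{Molecule}} objects.
#' @return the merged \code{\linkS4class{Molecule}}.
#' @export
mergeMolecules <- function(a, b) {
  if (natoms(a) == 0L) return(b)
  if (natoms(b) == 0L) return(a)
  atoms <- rbind(a@atoms, b@atoms)
  atoms$serial <- seq_len(nrow(atoms))
  bb <- b@bonds
  if (nrow(bb)) bb <- bb + natoms(a)
  lab <- paste(c(a@label, b@label)[nzchar(c(a@label, b@label))],
               collapse = "+")
  new("Molecule", atoms = atoms,
      bonds = .normalizeBonds(rbind(a@bonds, bb), nrow(atoms)),
      label = lab, metadata = list())
}

#' Minimum intermolecular distance
#'
#' @param a,b non-empty \code{\linkS4class{Molecule}} objects.
#' @return smallest Euclidean distance (A) over all cross pairs of atoms.
#' @export
minInterMolDist <- function(a, b) {
  if (natoms(a) == 0L || natoms(b) == 0L)
    stop("minInterMolDist needs two non-empty molecules")
  .minCrossDist(coords(a), coords(b))
}
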