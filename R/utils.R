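# Internal construction and small-vector helpers.

# Canonical bond matrix: integer, i < j, unique rows, sorted.
.normalizeBonds <- function(b, n) {
  if (is.null(b) || length(b) == 0L) return(matrix(integer(), ncol = 2L))
  b <- matrix(as.integer(b), ncol = 2L)
  b <- b[b[, 1L] != b[, 2L], , drop = FALSE]
  b <- cbind(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
  b <- unique(b)
  b[order(b[, 1L], b[, 2L]), , drop = FALSE]
}

# Build a Molecule from element symbols + coordinate matrix (+ bonds).
# Atom names default to element + per-element counter ("C1", "H3", ...).
.newMolecule <- function(element, xyz, bonds = NULL, label = "",
                         name = NULL, het = TRUE, metadata = list()) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  n <- length(element)
  stopifnot(nrow(xyz) == n)
  if (is.null(name)) {
    name <- paste0(element, stats::ave(seq_len(n), element,
                                       FUN = seq_along))
  }
  atoms <- data.frame(
    serial = seq_len(n), name = name, element = element,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    resname = rep("LIG", n), chain = rep("A", n), resno = rep(1L, n),
    occ = rep(1, n), b = rep(0, n), het = rep(het, length.out = n),
    stringsAsFactors = FALSE)
  new("Molecule", atoms = atoms, bonds = .normalizeBonds(bonds, n),
      label = label, metadata = metadata)
}

.emptyMolecule <- function(label = "") {
  .newMolecule(character(), matrix(numeric(), ncol = 3L), label = label)
}

# Adjacency list from a bond matrix.
.adjacency <- function(mol) {
  n <- natoms(mol)
  adj <- vector("list", n)
  b <- mol@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1L]; j <- b[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

.unitv <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a zero vector")
  v / nv
}

.crossv <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Orthonormal pair perpendicular to unit vector u (deterministic choice).
.perpBasis <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unitv(.crossv(u, a))
  e2 <- .crossv(u, e1)
  list(e1 = e1, e2 = e2)
}

# k unit vectors making angleDeg with u, equally spaced in azimuth.
.coneDirs <- function(u, angleDeg, k, phaseDeg = 0) {
  u <- .unitv(u)
  pb <- .perpBasis(u)
  th <- angleDeg * pi / 180
  ph <- (phaseDeg + (seq_len(k) - 1L) * 360 / k) * pi / 180
  t(vapply(ph, function(p) {
    cos(th) * u + sin(th) * (cos(p) * pb$e1 + sin(p) * pb$e2)
  }, numeric(3L)))
}

# Remaining ideal tetrahedral directions given bond unit vectors already
# placed at an sp3 centre (1, 2 or 3 existing bonds).
.sp3Fill <- function(us, phaseDeg = 0) {
  if (is.null(dim(us))) us <- matrix(us, nrow = 1L)
  k <- nrow(us)
  if (k == 1L) return(.coneDirs(us[1L, ], 109.471, 3L, phaseDeg))
  if (k == 2L) {
    b <- .unitv(-(us[1L, ] + us[2L, ]))
    w <- .unitv(.crossv(us[1L, ], us[2L, ]))
    alpha <- 0.57735; beta <- 0.81650  # cos/sin of half H-C-H tetrahedral
    rbind(alpha * b + beta * w, alpha * b - beta * w)
  } else {
    matrix(.unitv(-colSums(us)), nrow = 1L)
  }
}

# Minimum distance from each candidate point to a set of existing points;
# used to pick clash-free hydrogen placements deterministically.
.pickFarthest <- function(candidates, existing) {
  if (nrow(existing) == 0L) return(1L)
  score <- apply(candidates, 1L, function(p) {
    min(sqrt(colSums((t(existing) - p)^2)))
  })
  which.max(score)
}

.pairwiseDists <- function(xyz) as.matrix(stats::dist(xyz))

# Minimum cross distance between two coordinate sets (vectorized).
.minCrossDist <- function(a, b) {
  # a: n x 3, b: m x 3
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}
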