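# Shared fixtures-in-code and independent brute-force oracles.

# random coordinate-cloud molecule (no chemistry implied) with pairwise
# separations large enough to be a valid Molecule
randomCloudMolecule <- function(n, seed, box = 20,
                                els = c("C", "N", "O", "H", "S")) {
  set.seed(seed)
  xyz <- matrix(numeric(), ncol = 3)
  while (nrow(xyz) < n) {
    p <- runif(3, 0, box)
    if (nrow(xyz) == 0 || min(sqrt(colSums((t(xyz) - p)^2))) > 1.0)
      xyz <- rbind(xyz, p)
  }
  ClickMol:::.newMolecule(sample(els, n, replace = TRUE), xyz,
                          label = sprintf("cloud%d", seed))
}

# molecule over an arbitrary abstract graph: atoms on a wide grid so the
# declared bonds are the only structure (coordinates never perceived)
graphMolecule <- function(nNodes, edges, els = rep("C", nNodes)) {
  xyz <- cbind(10 * seq_len(nNodes), (seq_len(nNodes) %% 7) * 9, 0)
  m <- ClickMol:::.newMolecule(els, xyz, label = "graph")
  if (length(edges)) bonds(m) <- matrix(unlist(edges), ncol = 2, byrow = TRUE)
  m
}

randomGraphMolecule <- function(seed, maxN = 12) {
  set.seed(seed)
  n <- sample(4:maxN, 1)
  pEdge <- runif(1, 0.15, 0.4)
  edges <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (runif(1) < pEdge) edges[[length(edges) + 1]] <- c(i, j)
  }
  graphMolecule(n, edges)
}

# brute-force enumeration of all simple cycles of length <= maxLen;
# returns a list of vertex sets
allSimpleCycles <- function(mol, maxLen = 8) {
  b <- bonds(mol)
  n <- natoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  cycles <- list()
  seen <- character()
  dfs <- function(path) {
    last <- path[length(path)]
    for (nx in adj[[last]]) {
      if (nx == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1]] <<- sort(path)
        }
      } else if (!(nx %in% path) && length(path) < maxLen &&
                 nx > path[1]) {  # canonical: start at smallest vertex
        dfs(c(path, nx))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  cycles
}

# oracle: are a and b on a common simple cycle of length <= 8?
bruteSameRing <- function(mol, a, b) {
  cyc <- allSimpleCycles(mol, 8)
  any(vapply(cyc, function(cs) a %in% cs && b %in% cs, logical(1)))
}

# brute-force element-labelled graph isomorphism over all permutations
bruteIsomorphic <- function(molA, molB) {
  nA <- natoms(molA); nB <- natoms(molB)
  if (nA != nB) return(FALSE)
  elA <- elements(molA); elB <- elements(molB)
  adjM <- function(m) {
    A <- matrix(FALSE, natoms(m), natoms(m))
    b <- bonds(m)
    if (nrow(b)) { A[b] <- TRUE; A[b[, 2:1, drop = FALSE]] <- TRUE }
    A
  }
  A <- adjM(molA); B <- adjM(molB)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nA))) {
    if (!all(elA == elB[p])) next
    if (all(A == B[p, p])) return(TRUE)
  }
  FALSE
}

# random rigid transform applied to a molecule (for self-recovery tests)
randomRigidTransform <- function(mol, seed) {
  set.seed(seed)
  ax <- ClickMol:::.unitv(rnorm(3))
  ang <- runif(1, 0, 2 * pi)
  shift <- runif(3, -8, 8)
  m <- rotateAboutPivot(mol, pivot = c(0, 0, 0), axis = ax, angle = ang)
  translateMol(m, shift)
}

expect_sameFormula <- function(got, want) {
  expect_identical(formulaString(molecularFormula(got)),
                   formulaString(molecularFormula(want)))
}

# sum of two formula count vectors, rendered in Hill order
formulaSum <- function(a, b) {
  els <- union(names(a), names(b))
  v <- sapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) +
      (if (e %in% names(b)) b[[e]] else 0L)
  })
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  formulaString(stats::setNames(as.integer(v[ord]), ord))
}

# small symmetric internal alkynes R-C#C-R built with the package's own
# geometry helpers (identical chains on both sides)
symmetricAlkyne <- function(chainLen) {
  bl <- ClickMol:::.BL
  bld <- ClickMol:::.newBuilder()
  c1 <- c(0, 0, 0); c2 <- c(bl[["C#C"]], 0, 0)
  ClickMol:::.addAtom(bld, "C", c1)
  ClickMol:::.addAtom(bld, "C", c2)
  ClickMol:::.buildChainScaffold(bld, c1 - bl[["CspC"]] * c(1, 0, 0),
                                 c(1, 0, 0), chainLen, 0, FALSE)
  ClickMol:::.buildChainScaffold(bld, c2 + bl[["CspC"]] * c(1, 0, 0),
                                 c(-1, 0, 0), chainLen, 0, FALSE)
  ClickMol:::.finishMolecule(bld, label = sprintf("symalkyne%d", chainLen))
}
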