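#' @import methods
NULL

#' Molecule: an ordered set of atoms with an inferred bond graph
#'
#' The central container of the package. Atoms are stored as a data frame
#' (one row per atom, in file order) carrying PDB bookkeeping columns;
#' bonds are an integer matrix of unordered atom-index pairs. Atom indices
#' are 1-based throughout the R interface; PDB serials are renumbered from
#' 1 on output.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{resname},
#'   \code{chain}, \code{resno}, \code{occ}, \code{b}, \code{het}.
#' @slot bonds two-column integer matrix; each row \code{(i, j)} with
#'   \code{i < j} is one covalent bond.
#' @slot label character scalar, usually the source filename stem.
#' @slot metadata list of free-form annotations (e.g. provenance indices
#'   recorded by \code{\link{getBranch}}).
#'
#' @seealso \code{\link{readPDB}}, \code{\link{inferBonds}},
#'   \code{\link{buildFixture}}
#' @export
setClass("Molecule",
  slots = c(atoms = "data.frame", bonds = "matrix",
            label = "character", metadata = "list"),
  prototype = prototype(
    atoms = data.frame(serial = integer(), name = character(),
                       element = character(), x = numeric(), y = numeric(),
                       z = numeric(), resname = character(),
                       chain = character(), resno = integer(),
                       occ = numeric(), b = numeric(), het = logical(),
                       stringsAsFactors = FALSE),
    bonds = matrix(integer(), ncol = 2L), label = "", metadata = list())
)

setValidity("Molecule", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  need <- c("serial", "name", "element", "x", "y", "z",
            "resname", "chain", "resno", "occ", "b", "het")
  if (!all(need %in% names(a))) {
    return(paste("atoms data.frame lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  }
  n <- nrow(a)
  if (n > 0L) {
    if (!all(.knownElement(a$element)))
      msgs <- c(msgs, paste("unknown element symbol:",
                            paste(unique(a$element[!.knownElement(a$element)]),
                                  collapse = ", ")))
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      msgs <- c(msgs, "non-finite atomic coordinates")
    else if (n > 1L) {
      # duplicate-position guard (0.01 A) -- two atoms cannot coincide
      d <- stats::dist(xyz)
      if (any(d < 0.01))
        msgs <- c(msgs, "two atoms closer than 0.01 A (duplicate positions)")
    }
  }
  if (ncol(b) != 2L)
    msgs <- c(msgs, "bonds must have two columns")
  else if (nrow(b) > 0L) {
    if (any(b < 1L) || any(b > n))
      msgs <- c(msgs, "bond indices out of range")
    else if (any(b[, 1L] == b[, 2L]))
      msgs <- c(msgs, "self-bonds are not allowed")
  }
  if (length(object@label) != 1L)
    msgs <- c(msgs, "label must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' FGMatch: one detected functional group
#'
#' @slot kind functional-group tag, one of the kinds listed in
#'   \code{\link{detectGroups}}.
#' @slot roles named integer vector mapping role names (e.g.
#'   \code{proximal_N}, \code{attach_C}) to atom indices in the parent
#'   molecule.
#' @slot label label of the molecule the match was found in.
#' @export
setClass("FGMatch",
  slots = c(kind = "character", roles = "integer", label = "character"))

setValidity("FGMatch", function(object) {
  if (length(object@kind) != 1L) return("kind must be a single string")
  if (is.null(names(object@roles)) || any(!nzchar(names(object@roles))))
    return("roles must be a named integer vector")
  TRUE
})

#' ReactionTemplate: an idealized product core for fragment assembly
#'
#' Holds the idealized 3D coordinates of a product core (e.g. a planar
#' 1,2,3-triazole ring), the handle roles onto which reactant fragment
#' atoms are superimposed, the core atoms superseded by fragment handles
#' ("doomed", deleted after the merge), and the bonds formed between
#' handles in the product.
#'
#' @slot name reaction name.
#' @slot core data.frame with columns \code{element}, \code{role},
#'   \code{x}, \code{y}, \code{z}; rows with \code{element == "*"} are
#'   pure direction markers (exocyclic attachment points), never atoms.
#' @slot doomed character vector of core roles deleted after assembly.
#' @slot newBonds two-column character matrix of handle-role pairs bonded
#'   in the product.
#' @export
setClass("ReactionTemplate",
  slots = c(name = "character", core = "data.frame",
            doomed = "character", newBonds = "matrix"))

setValidity("ReactionTemplate", function(object) {
  core <- object@core
  if (!all(c("element", "role", "x", "y", "z") %in% names(core)))
    return("core needs element/role/x/y/z columns")
  # internal consistency: bonded real core atoms at plausible bond lengths
  real <- core$element != "*"
  if (nrow(object@newBonds) > 0L && ncol(object@newBonds) != 2L)
    return("newBonds must have two columns")
  ok <- vapply(seq_len(nrow(object@newBonds)), function(k) {
    i <- match(object@newBonds[k, 1L], core$role)
    j <- match(object@newBonds[k, 2L], core$role)
    if (is.na(i) || is.na(j)) return(FALSE)
    d <- sqrt(sum((unlist(core[i, c("x", "y", "z")]) -
                   unlist(core[j, c("x", "y", "z")]))^2))
    d >= 1.2 && d <= 1.6
  }, logical(1L))
  if (!all(ok)) return("core bond lengths outside 1.2-1.6 A or bad role")
  if (!all(object@doomed %in% core$role[real]))
    return("doomed roles must name real core atoms")
  TRUE
})

#' ProductRecord: a built product model plus its provenance
#'
#' @slot molecule the product \code{\linkS4class{Molecule}}.
#' @slot reaction reaction name (registry key).
#' @slot parents character vector of parent reactant labels (length 1 for
#'   unimolecular reactions).
#' @slot regio regiochemistry label: \code{"1,4"}, \code{"1,5"},
#'   \code{"attack_C1"}, \code{"attack_C2"}, or \code{"-"}.
#' @slot flags character vector of quality flags (e.g. \code{"clash"} when
#'   steric relief could not separate the fragments beyond 0.7 A; flagged
#'   products are reported, never silently dropped).
#' @export
setClass("ProductRecord",
  slots = c(molecule = "Molecule", reaction = "character",
            parents = "character", regio = "character", flags = "character"))
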