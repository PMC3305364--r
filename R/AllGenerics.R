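#' @include AllClasses.R
NULL

#' Number of atoms in a molecule
#' @param x a \code{\linkS4class{Molecule}}
#' @return integer atom count
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' Element symbols, in atom order
#' @param x a \code{\linkS4class{Molecule}}
#' @return character vector of IUPAC element symbols
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' Atomic coordinates
#' @param x a \code{\linkS4class{Molecule}}
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param value replacement coordinate matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Bond list of a molecule
#' @param x a \code{\linkS4class{Molecule}}
#' @return two-column integer matrix of bonded atom-index pairs (i < j)
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @param value replacement bond matrix
#' @export
setGeneric("bonds<-", function(x, value) standardGeneric("bonds<-"))

#' Label (source name) of a molecule
#' @param x a \code{\linkS4class{Molecule}}
#' @return character scalar
#' @export
setGeneric("molLabel", function(x) standardGeneric("molLabel"))

#' @rdname molLabel
#' @param value replacement label
#' @export
setGeneric("molLabel<-", function(x, value) standardGeneric("molLabel<-"))

setMethod("natoms", "Molecule", function(x) nrow(x@atoms))
setMethod("elements", "Molecule", function(x) x@atoms$element)
setMethod("coords", "Molecule", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})
setReplaceMethod("coords", "Molecule", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == natoms(x), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  validObject(x)
  x
})
setMethod("bonds", "Molecule", function(x) x@bonds)
setReplaceMethod("bonds", "Molecule", function(x, value) {
  x@bonds <- .normalizeBonds(value, natoms(x))
  validObject(x)
  x
})
setMethod("molLabel", "Molecule", function(x) x@label)
setReplaceMethod("molLabel", "Molecule", function(x, value) {
  x@label <- as.character(value)
  x
})

setMethod("show", "Molecule", function(object) {
  f <- formulaString(molecularFormula(object))
  cat("Molecule \"", object@label, "\": ", natoms(object), " atoms (",
      if (nzchar(f)) f else "empty", "), ", nrow(object@bonds),
      " bonds\n", sep = "")
})

setMethod("show", "FGMatch", function(object) {
  cat("FGMatch <", object@kind, "> in \"", object@label, "\": ",
      paste(names(object@roles), object@roles, sep = "=", collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ProductRecord", function(object) {
  cat("ProductRecord: ", object@reaction,
      " [", paste(object@parents, collapse = " + "), "] regio=",
      object@regio, sep = "")
  if (length(object@flags)) cat(" flags:", paste(object@flags, collapse = ","))
  cat("\n  ")
  show(object@molecule)
})

#' Accessors for ProductRecord
#' @param x a \code{\linkS4class{ProductRecord}}
#' @return \code{productMolecule}: the product Molecule;
#'   \code{productRegio}: the regiochemistry label;
#'   \code{productFlags}: character vector of quality flags.
#' @export
setGeneric("productMolecule", function(x) standardGeneric("productMolecule"))
#' @rdname productMolecule
#' @export
setGeneric("productRegio", function(x) standardGeneric("productRegio"))
#' @rdname productMolecule
#' @export
setGeneric("productFlags", function(x) standardGeneric("productFlags"))
setMethod("productMolecule", "ProductRecord", function(x) x@molecule)
setMethod("productRegio", "ProductRecord", function(x) x@regio)
setMethod("productFlags", "ProductRecord", function(x) x@flags)

#' Accessors for FGMatch
#' @param x an \code{\linkS4class{FGMatch}}
#' @return \code{matchKind}: the functional-group tag; \code{matchRoles}:
#'   named integer vector of role atom indices.
#' @export
setGeneric("matchKind", function(x) standardGeneric("matchKind"))
#' @rdname matchKind
#' @export
setGeneric("matchRoles", function(x) standardGeneric("matchRoles"))
setMethod("matchKind", "FGMatch", function(x) x@kind)
setMethod("matchRoles", "FGMatch", function(x) x@roles)
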