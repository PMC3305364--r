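#' Read a small-molecule PDB file
#'
#' Parses fixed-column ATOM/HETATM records into a
#' \code{\linkS4class{Molecule}}, one atom per record in file order. The
#' element is taken from columns 77-78 when present; otherwise it is
#' inferred from the atom-name field (leading spaces and digits stripped,
#' a small set of unambiguous two-letter symbols such as \code{CL}/\code{BR}
#' recognized case-insensitively, everything else resolved to the
#' one-letter element -- so a bare \code{"CA"} name reads as carbon unless
#' columns 77-78 say calcium). CONECT records populate the bond list
#' (deduplicated and symmetrized); bonds may well be empty, since
#' perception normally happens later via \code{\link{inferBonds}}.
#'
#' Only the first MODEL of a multi-model file is read, and alternate
#' locations other than blank/\code{A} are skipped: inputs are expected to
#' be single-conformer small-molecule models with explicit hydrogens.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param label molecule label; defaults to the filename stem.
#' @return a \code{\linkS4class{Molecule}}.
#' @examples
#' m <- buildFixture("methane")
#' f <- tempfile(fileext = ".pdb")
#' writePDB(m, f)
#' readPDB(f)
#' @export
readPDB <- function(source, label = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- sub("\\.[Pp][Dd][Bb]$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(label)) label <- ""
  }
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  rec <- substr(lines, 1L, 6L)
  isAtom <- rec %in% c("ATOM  ", "HETATM") |
    grepl("^(ATOM|HETATM)\\b", lines)
  atomLineIdx <- which(isAtom)
  if (length(atomLineIdx) == 0L)
    stop("empty structure: no ATOM/HETATM records in input")

  parseNum <- function(s, what, lineNo) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    bad <- bad | !nzchar(trimws(s)) & what == "coordinate"
    if (any(bad)) {
      stop("unparseable ", what, " field at line ",
           lineNo[which(bad)[1L]], ": '", trimws(s[which(bad)[1L]]), "'")
    }
    v
  }

  ln <- lines[atomLineIdx]
  altLoc <- substr(ln, 17L, 17L)
  keep <- altLoc %in% c(" ", "", "A")
  ln <- ln[keep]
  lineNo <- atomLineIdx[keep]
  if (length(ln) == 0L)
    stop("empty structure: all ATOM/HETATM records carry skipped altLocs")

  name <- trimws(substr(ln, 13L, 16L))
  x <- parseNum(substr(ln, 31L, 38L), "coordinate", lineNo)
  y <- parseNum(substr(ln, 39L, 46L), "coordinate", lineNo)
  z <- parseNum(substr(ln, 47L, 54L), "coordinate", lineNo)
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(substr(ln, 61L, 66L)))
  bfac[is.na(bfac)] <- 0
  elemCol <- trimws(substr(ln, 77L, 78L))
  element <- .resolveElement(elemCol, name)
  bad <- !.knownElement(element)
  if (any(bad)) {
    stop("unknown element symbol for atom '", name[which(bad)[1L]],
         "' (line ", lineNo[which(bad)[1L]], ")")
  }

  n <- length(ln)
  serial <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  atoms <- data.frame(
    serial = serial, name = name, element = element, x = x, y = y, z = z,
    resname = trimws(substr(ln, 18L, 20L)),
    chain = substr(ln, 22L, 22L),
    resno = {
      r <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
      r[is.na(r)] <- 1L; r
    },
    occ = occ, b = bfac,
    het = grepl("^HETATM", ln),
    stringsAsFactors = FALSE)

  # CONECT: map serials -> indices, dedupe symmetric duplicates
  bmat <- matrix(integer(), ncol = 2L)
  conect <- lines[grepl("^CONECT", lines)]
  if (length(conect)) {
    serialToIdx <- match(seq_len(max(atoms$serial)), atoms$serial)
    prs <- lapply(conect, function(l) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7L, nchar(l))),
                                                "\\s+")[[1L]]))
      f <- f[!is.na(f)]
      if (length(f) < 2L) return(NULL)
      cbind(f[1L], f[-1L])
    })
    prs <- do.call(rbind, prs)
    if (!is.null(prs) && nrow(prs)) {
      i <- serialToIdx[prs[, 1L]]
      j <- serialToIdx[prs[, 2L]]
      ok <- !is.na(i) & !is.na(j)
      bmat <- cbind(i[ok], j[ok])
    }
  }

  mol <- new("Molecule", atoms = atoms,
             bonds = .normalizeBonds(bmat, n), label = label,
             metadata = list())
  validObject(mol)
  mol
}

# Element resolution: columns 77-78 first, then the atom-name fallback.
.resolveElement <- function(elemCol, name) {
  el <- ifelse(nzchar(elemCol),
               paste0(toupper(substr(elemCol, 1L, 1L)),
                      tolower(substr(elemCol, 2L, 2L))),
               NA_character_)
  needInfer <- is.na(el)
  if (any(needInfer)) {
    stripped <- toupper(gsub("^[ 0-9]+", "", name[needInfer]))
    two <- substr(stripped, 1L, 2L)
    one <- substr(stripped, 1L, 1L)
    inferred <- ifelse(two %in% .NAME_INFERABLE_2LETTER,
                       paste0(substr(two, 1L, 1L),
                              tolower(substr(two, 2L, 2L))),
                       one)
    el[needInfer] <- inferred
  }
  el
}

#' Write a molecule as a fixed-column PDB file
#'
#' Serials are renumbered from 1, coordinates are printed with three
#' decimals, the element is right-justified in columns 77-78, a CONECT
#' record pair (both directions) is emitted for every bond, and the file
#' is terminated by \code{END}. Writing then re-reading preserves the
#' element sequence, the bond set, and coordinates to within the printed
#' quantum (0.0005 A).
#'
#' @param mol a non-empty \code{\linkS4class{Molecule}}.
#' @param destination output file path (or connection).
#' @return invisibly, the character vector of lines written.
#' @export
writePDB <- function(mol, destination) {
  stopifnot(is(mol, "Molecule"))
  if (natoms(mol) == 0L) stop("cannot write an empty molecule")
  xyz <- coords(mol)
  if (any(abs(xyz) >= 10000 - 0.0005))
    stop("coordinate magnitude >= 10000 A overflows the PDB field")
  a <- mol@atoms
  n <- nrow(a)
  recname <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom-name column convention: names of <= 3 chars start in column 14
  nm <- ifelse(nchar(a$name) <= 3L,
               sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  lines <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    recname, seq_len(n), nm, " ", substr(a$resname, 1L, 3L),
    a$chain, a$resno, xyz[, 1L], xyz[, 2L], xyz[, 3L], a$occ, a$b,
    a$element)
  b <- mol@bonds
  if (nrow(b)) {
    both <- rbind(b, b[, 2:1, drop = FALSE])
    both <- both[order(both[, 1L], both[, 2L]), , drop = FALSE]
    conect <- sprintf("CONECT%5d%5d", both[, 1L], both[, 2L])
    lines <- c(lines, conect)
  }
  lines <- c(lines, "END")
  writeLines(lines, destination)
  invisible(lines)
}

#' Molecular formula as an element-count table
#'
#' @param mol a \code{\linkS4class{Molecule}}.
#' @return named integer vector of element counts, ordered by the Hill
#'   convention (C first, then H, then the rest alphabetically).
#' @export
molecularFormula <- function(mol) {
  if (natoms(mol) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(elements(mol))
  els <- names(tab)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  stats::setNames(as.integer(tab[ord]), ord)
}

#' @rdname molecularFormula
#' @param formula a named count vector as returned by
#'   \code{molecularFormula}.
#' @return \code{formulaString}: the Hill-notation string (e.g.
#'   \code{"CH3N3"}).
#' @export
formulaString <- function(formula) {
  if (length(formula) == 0L) return("")
  paste0(names(formula), ifelse(formula > 1L, formula, ""), collapse = "")
}

#' Molecular weight in Dalton
#'
#' Sum of standard atomic weights over all atoms (explicit hydrogens
#' included; no implicit-H accounting is ever done in this package).
#'
#' @param mol a \code{\linkS4class{Molecule}}.
#' @return numeric scalar, Da.
#' @export
molecularWeight <- function(mol) {
  if (natoms(mol) == 0L) return(0)
  sum(.atomicWeight(elements(mol)))
}
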