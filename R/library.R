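# Combinatorial virtual-library enumeration over reactant collections.

#' Lipinski rule-of-five report
#'
#' Computes Lipinski's original descriptors: molecular weight from
#' \code{\link{molecularWeight}}; hydrogen-bond donors as the count of
#' O-H and N-H hydrogens; acceptors as the count of N plus O atoms; and
#' a logP \emph{estimate} from a documented per-element contribution
#' table (pluggable via \code{contrib}; the estimate is deliberately
#' crude and used only for drug-likeness screening, never as a reported
#' physicochemical property). The molecule passes when MW <= 500, HBD
#' <= 5, HBA <= 10 and logP <= 5.
#'
#' @param mol a bonded \code{\linkS4class{Molecule}} with explicit
#'   hydrogens.
#' @param contrib named numeric vector of per-element logP contributions.
#' @return list with \code{MW}, \code{HBD}, \code{HBA},
#'   \code{logP_estimate}, \code{passes}.
#' @examples
#' lipinskiReport(buildFixture("glucose"))  # HBD 5, HBA 6
#' @export
lipinskiReport <- function(mol, contrib = .LOGP_CONTRIB) {
  el <- elements(mol)
  hbd <- 0L
  if (nrow(mol@bonds)) {
    b <- mol@bonds
    isH1 <- el[b[, 1L]] == "H" & el[b[, 2L]] %in% c("N", "O")
    isH2 <- el[b[, 2L]] == "H" & el[b[, 1L]] %in% c("N", "O")
    hbd <- sum(isH1) + sum(isH2)
  }
  hba <- sum(el %in% c("N", "O"))
  logp <- sum(contrib[el], na.rm = TRUE)
  mw <- molecularWeight(mol)
  list(MW = mw, HBD = as.integer(hbd), HBA = as.integer(hba),
       logP_estimate = unname(logp),
       passes = mw <= 500 && hbd <= 5L && hba <= 10L && logp <= 5)
}

#' Configuration for a library run
#'
#' @param dirA directory of reactant PDB files (or a list of bonded
#'   \code{\linkS4class{Molecule}} objects) for side A.
#' @param dirB optional directory (or molecule list) for side B; when
#'   omitted only unimolecular conversions run over side A, mirroring
#'   the bromide-to-azide preprocessing of a cycloaddition library.
#' @param out optional output directory; product PDBs, the JSON manifest
#'   and the TSV summary are written there (never in dry-run mode).
#' @param reactions optional character vector restricting the registry.
#' @param regio regio policy for cycloadditions: \code{"both"},
#'   \code{"1,4"} or \code{"1,5"}.
#' @param dryRun count products exactly (including regioisomer
#'   multiplicity) without building any geometry.
#' @param maxProducts cap on the number of product files written.
#' @param lipinski annotate (and count) rule-of-five compliance.
#' @param seed integer seed recorded in the manifest and used for any
#'   subsampling a caller performs.
#' @param stepDeg steric-relief scan step in degrees.
#' @return a \code{LibraryRunConfig} list.
#' @export
libraryConfig <- function(dirA, dirB = NULL, out = NULL, reactions = NULL,
                          regio = c("both", "1,4", "1,5"), dryRun = FALSE,
                          maxProducts = Inf, lipinski = FALSE, seed = 1L,
                          stepDeg = 10) {
  regio <- match.arg(regio)
  stopifnot(maxProducts >= 0)
  if (is.character(dirA) && !dir.exists(dirA))
    stop("dirA does not exist: ", dirA)
  if (!is.null(dirB) && is.character(dirB) && !dir.exists(dirB))
    stop("dirB does not exist: ", dirB)
  structure(list(dirA = dirA, dirB = dirB, out = out,
                 reactions = reactions, regio = regio, dryRun = dryRun,
                 maxProducts = maxProducts, lipinski = lipinski,
                 seed = as.integer(seed), stepDeg = stepDeg),
            class = "LibraryRunConfig")
}

# load a reactant collection: list of bonded molecules, sorted by label;
# unreadable files are skipped with a logged warning, never an abort
.loadCollection <- function(src) {
  if (is.list(src)) {
    labs <- vapply(src, molLabel, character(1L))
    ord <- order(labs)
    return(list(mols = src[ord], skipped = character()))
  }
  files <- sort(list.files(src, pattern = "\\.pdb$", ignore.case = TRUE,
                           full.names = TRUE))
  mols <- list()
  skipped <- character()
  for (f in files) {
    m <- tryCatch(inferBonds(readPDB(f)), error = function(e) {
      warning("skipping unreadable file ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(m)) skipped <- c(skipped, basename(f))
    else mols[[length(mols) + 1L]] <- m
  }
  labs <- vapply(mols, molLabel, character(1L))
  list(mols = mols[order(labs)], skipped = skipped)
}

#' Enumerate a combinatorial reaction library
#'
#' Crosses every reactant of side A against every reactant of side B (in
#' deterministic sorted-label order) under the reaction registry. In
#' dry-run mode exact product counts are computed from the detected
#' functional groups and the regioisomer rules (symmetric alkynes and
#' epoxides contribute one product, non-symmetric two) without building
#' any 3D geometry; a full run builds and optionally writes every
#' product. Counts are identical between the two modes.
#'
#' @param config a \code{\link{libraryConfig}}.
#' @return manifest list with elements \code{totals} (named count per
#'   reaction and grand total), \code{pairs} (data.frame labelA, labelB,
#'   reaction, count), \code{products} (list of
#'   \code{\linkS4class{ProductRecord}}, full runs only), \code{skipped},
#'   \code{lipinskiPass} (when requested), \code{files} (paths written).
#' @export
enumerateLibrary <- function(config) {
  stopifnot(inherits(config, "LibraryRunConfig"))
  collA <- .loadCollection(config$dirA)
  collB <- if (!is.null(config$dirB)) .loadCollection(config$dirB) else NULL
  molsA <- collA$mols
  molsB <- if (is.null(collB)) NULL else collB$mols
  groupsA <- lapply(molsA, detectGroups)
  groupsB <- if (is.null(molsB)) NULL else lapply(molsB, detectGroups)
  wanted <- if (is.null(config$reactions))
    vapply(.reactionRegistry, `[[`, character(1L), "name")
  else config$reactions

  labsA <- vapply(molsA, molLabel, character(1L))
  pairs <- NULL
  products <- list()
  written <- character()
  lipPass <- 0L

  if (is.null(molsB)) {
    # unimolecular mode over side A
    counts <- integer(0)
    labs <- character(0)
    reacts <- character(0)
    for (i in seq_along(molsA)) {
      for (entry in .reactionRegistry) {
        if (entry$arity != 1L || !entry$name %in% wanted) next
        ms <- Filter(function(m) m@kind %in% entry$kindsA, groupsA[[i]])
        if (!length(ms)) next
        labs <- c(labs, labsA[i])
        reacts <- c(reacts, entry$name)
        counts <- c(counts, length(ms))
        if (!config$dryRun) {
          for (m in ms) {
            rec <- runReaction(list(reaction = entry$name, matchA = m,
                                    matchB = NULL, swap = FALSE),
                               molsA[[i]], regio = config$regio,
                               stepDeg = config$stepDeg)
            products <- c(products, rec)
          }
        }
      }
    }
    pairs <- data.frame(labelA = labs, labelB = NA_character_,
                        reaction = reacts, count = counts,
                        stringsAsFactors = FALSE)
  } else {
    labsB <- vapply(molsB, molLabel, character(1L))
    # per-molecule reaction multiplicities (vectorized across pairs)
    pairs <- .bimolecularCounts(molsA, groupsA, labsA,
                                molsB, groupsB, labsB, wanted,
                                config$regio)
    if (!config$dryRun) {
      for (k in seq_len(nrow(pairs))) {
        if (pairs$count[k] == 0L) next
        i <- match(pairs$labelA[k], labsA)
        j <- match(pairs$labelB[k], labsB)
        ents <- applicableReactions(molsA[[i]], molsB[[j]])
        ents <- Filter(function(e) e$reaction == pairs$reaction[k], ents)
        for (e in ents) {
          recs <- runReaction(e, molsA[[i]], molsB[[j]],
                              regio = config$regio,
                              stepDeg = config$stepDeg)
          products <- c(products, recs)
        }
      }
    }
  }

  if (!config$dryRun && length(products)) {
    if (config$lipinski) {
      lipPass <- sum(vapply(products, function(p) {
        isTRUE(lipinskiReport(p@molecule)$passes)
      }, logical(1L)))
    }
    if (!is.null(config$out)) {
      dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
      nWritten <- 0L
      for (p in products) {
        if (nWritten >= config$maxProducts) break
        fn <- sprintf("%s__%s__%s.pdb",
                      paste(p@parents, collapse = "__"), p@reaction,
                      gsub("[^0-9A-Za-z_]+", "-", p@regio))
        path <- file.path(config$out, fn)
        writePDB(p@molecule, path)
        written <- c(written, path)
        nWritten <- nWritten + 1L
      }
    }
  }

  totals <- stats::setNames(
    vapply(wanted, function(rn) sum(pairs$count[pairs$reaction == rn]),
           numeric(1L)), wanted)
  manifest <- list(
    totals = c(totals, total = sum(pairs$count)),
    pairs = pairs,
    products = products,
    skipped = c(collA$skipped, if (!is.null(collB)) collB$skipped),
    seed = config$seed, regio = config$regio, dryRun = config$dryRun,
    lipinskiPass = if (config$lipinski) lipPass else NA_integer_,
    files = written)
  if (!is.null(config$out) && !config$dryRun) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    json <- manifest[c("totals", "skipped", "seed", "regio", "dryRun",
                       "lipinskiPass")]
    json$files <- basename(written)
    jsonlite::write_json(json, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(pairs, file.path(config$out, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}

# exact per-pair product counts without geometry construction
.bimolecularCounts <- function(molsA, groupsA, labsA, molsB, groupsB,
                               labsB, wanted, regio) {
  kindCount <- function(groups, kinds) {
    vapply(groups, function(gs) {
      sum(vapply(gs, function(m) m@kind %in% kinds, logical(1L)))
    }, integer(1L))
  }
  # per-molecule cycloaddition multiplicity of each alkyne group
  alkyneMult <- function(mols, groups) {
    both <- regio == "both"
    vapply(seq_along(mols), function(i) {
      s <- 0L
      for (m in groups[[i]]) {
        if (m@kind %in% c("terminal_alkyne", "internal_alkyne"))
          s <- s + if (both && !isSymmetricAlkyne(mols[[i]], m)) 2L else 1L
      }
      s
    }, integer(1L))
  }
  epoxideMult <- function(mols, groups) {
    vapply(seq_along(mols), function(i) {
      s <- 0L
      for (m in groups[[i]]) {
        if (m@kind == "epoxide")
          s <- s + if (.isSymmetricEpoxide(mols[[i]], m)) 1L else 2L
      }
      s
    }, integer(1L))
  }
  out <- list()
  addBlock <- function(reaction, perA, perB) {
    cnt <- outer(perA, perB)
    nz <- which(cnt > 0L, arr.ind = TRUE)
    if (nrow(nz) == 0L) return(invisible())
    out[[length(out) + 1L]] <<- data.frame(
      labelA = labsA[nz[, 1L]], labelB = labsB[nz[, 2L]],
      reaction = reaction, count = as.integer(cnt[nz]),
      stringsAsFactors = FALSE)
    invisible()
  }
  for (entry in .reactionRegistry) {
    if (entry$arity != 2L || !entry$name %in% wanted) next
    if (entry$name == "huisgen_cycloaddition") {
      addBlock(entry$name, kindCount(groupsA, "azide"),
               alkyneMult(molsB, groupsB))
      # reverse orientation: azides in B, alkynes in A
      revA <- alkyneMult(molsA, groupsA)
      revB <- kindCount(groupsB, "azide")
      cnt <- outer(revA, revB)
      nz <- which(cnt > 0L, arr.ind = TRUE)
      if (nrow(nz)) {
        out[[length(out) + 1L]] <- data.frame(
          labelA = labsA[nz[, 1L]], labelB = labsB[nz[, 2L]],
          reaction = entry$name, count = as.integer(cnt[nz]),
          stringsAsFactors = FALSE)
      }
    } else if (entry$name == "epoxide_opening") {
      nuKinds <- entry$kindsB
      addBlock(entry$name, epoxideMult(molsA, groupsA),
               kindCount(groupsB, nuKinds))
      cnt <- outer(kindCount(groupsA, nuKinds), epoxideMult(molsB, groupsB))
      nz <- which(cnt > 0L, arr.ind = TRUE)
      if (nrow(nz)) {
        out[[length(out) + 1L]] <- data.frame(
          labelA = labsA[nz[, 1L]], labelB = labsB[nz[, 2L]],
          reaction = entry$name, count = as.integer(cnt[nz]),
          stringsAsFactors = FALSE)
      }
    } else if (entry$name == "amide_formation") {
      addBlock(entry$name, kindCount(groupsA, entry$kindsA),
               kindCount(groupsB, entry$kindsB))
      cnt <- outer(kindCount(groupsA, entry$kindsB),
                   kindCount(groupsB, entry$kindsA))
      nz <- which(cnt > 0L, arr.ind = TRUE)
      if (nrow(nz)) {
        out[[length(out) + 1L]] <- data.frame(
          labelA = labsA[nz[, 1L]], labelB = labsB[nz[, 2L]],
          reaction = entry$name, count = as.integer(cnt[nz]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(labelA = character(), labelB = character(),
                      reaction = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # aggregate duplicates (same pair+reaction found via both orientations
  # never happens for distinct kinds, but keep the invariant)
  agg <- stats::aggregate(count ~ labelA + labelB + reaction, data = res,
                          FUN = sum)
  agg <- agg[order(agg$reaction, agg$labelA, agg$labelB), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("labelA", "labelB", "reaction", "count")]
}

# epoxide symmetry: the substituent sets of the two ring carbons are
# isomorphic as labelled branch graphs
.isSymmetricEpoxide <- function(mol, match) {
  r <- match@roles
  b1 <- .epoxideSide(mol, r[["C1"]], r[["C2"]], r[["O"]])
  b2 <- .epoxideSide(mol, r[["C2"]], r[["C1"]], r[["O"]])
  .molIsomorphic(b1, b2)
}

# sub-molecule reachable from carbon `ca` without crossing the ring
# bonds to `cb` or the epoxide oxygen (includes ca)
.epoxideSide <- function(mol, ca, cb, o) {
  adj <- .adjacency(mol)
  blocked <- c(cb, o)
  seen <- logical(natoms(mol))
  seen[ca] <- TRUE
  queue <- ca
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nx in adj[[cur]]) {
      if (nx %in% blocked && cur == ca) next
      if (!seen[nx] && !(nx %in% blocked)) {
        seen[nx] <- TRUE; queue <- c(queue, nx)
      }
    }
  }
  .subMolecule(mol, which(seen))
}
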