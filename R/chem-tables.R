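# Internal periodic-table data used across the package.
#
# Covalent radii (Angstrom) are the Cordero et al. (2008) single-bond
# consensus values; atomic weights are the 2021 IUPAC conventional values.
# Both tables cover the elements that occur in click-chemistry reactants;
# an element outside the table is rejected at parse time.

.ELEMENT_TABLE <- data.frame(
  symbol = c("H",    "B",    "C",    "N",    "O",    "F",
             "Na",   "Mg",   "Si",   "P",    "S",    "Cl",
             "K",    "Ca",   "Fe",   "Zn",   "Se",   "Br",  "I"),
  weight = c(1.008,  10.81,  12.011, 14.007, 15.999, 18.998,
             22.990, 24.305, 28.085, 30.974, 32.06,  35.45,
             39.098, 40.078, 55.845, 65.38,  78.971, 79.904, 126.904),
  rcov   = c(0.31,   0.84,   0.76,   0.71,   0.66,   0.57,
             1.66,   1.41,   1.11,   1.07,   1.05,   1.02,
             2.03,   1.76,   1.32,   1.22,   1.20,   1.20,  1.39),
  stringsAsFactors = FALSE
)
rownames(.ELEMENT_TABLE) <- .ELEMENT_TABLE$symbol

.HALOGENS <- c("F", "Cl", "Br", "I")

# Two-letter element symbols that may safely be inferred from a PDB atom
# NAME when the element column (77-78) is blank.  Deliberately excludes
# ambiguous names such as "CA" (C-alpha vs calcium), "CD", "NA", "NB":
# those resolve to their one-letter element unless columns 77-78 say
# otherwise.  Ligand atom names like "CL1"/"BR2" are common in small-
# molecule PDB files and are what this list is for.
.NAME_INFERABLE_2LETTER <- c("CL", "BR", "SI", "SE")

# Atom-contribution logP estimate (crude Crippen-flavoured per-element
# scheme, documented in the vignette).  This is an *estimate* used only
# for rule-of-five screening; it is pluggable in lipinskiReport().
.LOGP_CONTRIB <- c(C = 0.27, H = 0.12, N = -0.60, O = -0.41, S = 0.25,
                   F = 0.22, Cl = 0.59, Br = 0.77, I = 1.10, P = -0.50,
                   B = 0.10, Si = 0.20)

.knownElement <- function(el) el %in% .ELEMENT_TABLE$symbol

.atomicWeight <- function(el) {
  w <- .ELEMENT_TABLE[el, "weight"]
  if (anyNA(w)) {
    stop("no atomic weight tabulated for element(s): ",
         paste(unique(el[is.na(w)]), collapse = ", "))
  }
  w
}

.covalentRadius <- function(el) {
  r <- .ELEMENT_TABLE[el, "rcov"]
  if (anyNA(r)) {
    stop("no covalent radius tabulated for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  }
  r
}
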