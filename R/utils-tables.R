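# Element property tables used across the package. Heavy atoms only:
# crystal structures generally lack hydrogens, and every derived quantity
# (molecular weight, bond inference, SASA) is documented as heavy-atom-only.

#' Standard atomic masses (Da) for elements seen in protein/ligand heavy atoms
#' @keywords internal
.atomicMasses <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
  B = 10.81, H = 1.008
)

#' Covalent radii (Angstrom), Cordero consensus values
#' @keywords internal
.covalentRadii <- c(
  C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84, H = 0.31
)

#' Van der Waals radii (Angstrom) for SASA
#'
#' Fixed table (C 1.70, N 1.55, O 1.52, S 1.80); hydrogens are ignored
#' throughout.
#' @keywords internal
.vdwRadii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92
)

# Waters and common crystallization additives excluded from ligand candidacy.
.defaultLigandDenylist <- c(
  "HOH", "DOD", "WAT", "SO4", "PO4", "GOL", "EDO", "PEG", "ACT", "DMS",
  "MPD", "TRS", "EPE", "MES", "FMT", "CIT", "NO3", "CO3", "BME", "IMD",
  "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "NI", "CU", "CD", "IOD", "BR"
)

#' Look up a per-element table, erroring on unknown elements
#' @keywords internal
.elementLookup <- function(table, elements, what = "property") {
  idx <- toupper(elements)
  vals <- table[idx]
  if (anyNA(vals)) {
    bad <- unique(idx[is.na(vals)])
    stop("unknown element(s) for ", what, ": ", paste(bad, collapse = ", "))
  }
  unname(vals)
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column (PDB columns 77-78) is blank. Digits and
#' primes are stripped; a leading two-letter symbol is recognised for the
#' common heteroatoms, otherwise the first alphabetic character is taken.
#' @keywords internal
.elementFromName <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN"),
         two, substr(nm, 1, 1))
}
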