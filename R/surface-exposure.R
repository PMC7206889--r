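#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a water-sized probe: each atom's accessible sphere
#' of radius vdW + probe is sampled on a deterministic Fibonacci lattice
#' (no RNG, bit-reproducible) and the accessible fraction of test points
#' scaled by the sphere area 4 pi (r + probe)^2. Hydrogens are ignored by
#' the vdW table (heavy-atom crystal structures).
#'
#' @param xyz n x 3 coordinate matrix
#' @param elements element symbols (length n); unknown elements error
#' @param probe probe radius in Angstrom (default 1.4, water)
#' @param nPoints test points per atom (default 960)
#' @param radii named vdW radius table
#' @return numeric vector of per-atom SASA in square Angstrom
#' @examples
#' sasaAtoms(matrix(0, 1, 3), "C")  # lone carbon: 4*pi*3.1^2
#' @export
sasaAtoms <- function(xyz, elements, probe = 1.4, nPoints = 960L,
                      radii = .vdwRadii) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(probe > 0, length(elements) == n)
  r <- .elementLookup(radii, elements, "vdW radius")
  if (n > 1) {
    dm <- stats::dist(xyz)
    if (min(dm) < 1e-6)
      stop("degenerate input: coincident atom centers")
    dm <- as.matrix(dm)
  }
  pts <- .fibonacciSphere(nPoints)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- r[i] + probe
    test <- sweep(pts * Ri, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    if (n > 1) {
      nb <- which(dm[i, ] < Ri + r + probe & seq_len(n) != i)
      for (j in nb) {
        Rj <- r[j] + probe
        dx <- test[, 1] - xyz[j, 1]
        dy <- test[, 2] - xyz[j, 2]
        dz <- test[, 3] - xyz[j, 3]
        acc <- acc & (dx * dx + dy * dy + dz * dz >= Rj * Rj)
        if (!any(acc)) break
      }
    }
    out[i] <- 4 * pi * Ri^2 * sum(acc) / nPoints
  }
  out
}

# Deterministic, near-uniform unit-sphere lattice.
#' @keywords internal
.fibonacciSphere <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - 2 * (k + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Backbone atom names excluded from the side chain.
.backboneNames <- c("N", "CA", "C", "O", "OXT")

#' Side-chain exposure ratios in three structural contexts
#'
#' For each requested residue, the side-chain SASA is computed in three
#' contexts: alone (\code{iSASA}), within its own protein monomer
#' (\code{eSASA}) and within the entire complex including ligands and the
#' partner protein (\code{nSASA}); whence the two exposure ratios
#' \deqn{\%Exposed = 100\, eSASA / iSASA}
#' \deqn{\%inContact = 100\,(eSASA - nSASA) / eSASA}
#' The side chain is the atoms beyond and including CB (configurable);
#' glycines are skipped. The monomer context is the residue's own polymer
#' chain for two-chain (PP) complexes and the whole protein for
#' protein-drug complexes, so the contact ratio isolates partner-induced
#' burial. Hetero atoms never enter iSASA/eSASA and enter only nSASA.
#'
#' @param x a \linkS4class{ComplexStructure} (altLocs resolved)
#' @param residues data.frame with columns chain, resno, insert; default
#'   all Phe/Tyr/Trp/His residues
#' @param monomer \code{"protein"} (all polymer chains) or \code{"chain"}
#'   (own chain only)
#' @param probe,nPoints see \code{\link{sasaAtoms}}
#' @param includeCB count CB as part of the side chain (default TRUE)
#' @return data.frame: chain, resno, insert, resid, iSASA, eSASA, nSASA,
#'   pct_exposed, pct_in_contact (NA where eSASA = 0)
#' @export
exposureTable <- function(x, residues = NULL,
                          monomer = c("protein", "chain"),
                          probe = 1.4, nPoints = 960L, includeCB = TRUE) {
  monomer <- match.arg(monomer)
  a <- atoms(x)
  if (is.null(residues)) {
    sel <- !a$het & a$resid %in% c("PHE", "TYR", "TRP", "HIS")
    residues <- unique(a[sel, c("chain", "resno", "insert")])
  }
  if (!nrow(residues))
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      iSASA = numeric(), eSASA = numeric(),
                      nSASA = numeric(), pct_exposed = numeric(),
                      pct_in_contact = numeric()))
  # one full-complex and one per-monomer SASA evaluation, reused per residue
  allSasa <- sasaAtoms(as.matrix(a[, c("x", "y", "z")]), a$elem,
                       probe, nPoints)
  polyIdx <- which(!a$het)
  monoSasa <- rep(NA_real_, nrow(a))
  if (monomer == "protein") {
    monoSasa[polyIdx] <- sasaAtoms(as.matrix(a[polyIdx, c("x", "y", "z")]),
                                   a$elem[polyIdx], probe, nPoints)
  } else {
    for (ch in unique(a$chain[polyIdx])) {
      idx <- polyIdx[a$chain[polyIdx] == ch]
      monoSasa[idx] <- sasaAtoms(as.matrix(a[idx, c("x", "y", "z")]),
                                 a$elem[idx], probe, nPoints)
    }
  }
  drop <- .backboneNames
  if (!includeCB) drop <- c(drop, "CB")
  rows <- list()
  for (k in seq_len(nrow(residues))) {
    ridx <- which(!a$het & a$chain == residues$chain[k] &
                  a$resno == residues$resno[k] &
                  a$insert == residues$insert[k])
    side <- ridx[!(a$name[ridx] %in% drop)]
    if (!length(side)) next  # glycine or backbone-only residue
    iS <- sum(sasaAtoms(as.matrix(a[side, c("x", "y", "z")]),
                        a$elem[side], probe, nPoints))
    eS <- sum(monoSasa[side])
    nS <- sum(allSasa[side])
    rows[[length(rows) + 1L]] <- data.frame(
      chain = residues$chain[k], resno = residues$resno[k],
      insert = residues$insert[k], resid = a$resid[ridx[1]],
      iSASA = iS, eSASA = eS, nSASA = nS,
      pct_exposed = if (iS > 0) 100 * eS / iS else NA_real_,
      pct_in_contact = if (eS > 0) 100 * (eS - nS) / eS else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
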