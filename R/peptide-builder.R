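# Ideal poly-alanine backbone construction from internal coordinates,
# used by the synthetic fixtures that exercise secondary-structure
# assignment and SASA. Bond lengths and angles are standard values
# (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; tau angles
# 111.2 / 116.2 / 121.7 degrees, omega fixed trans).

# Place atom D from reference atoms a-b-c with bond length r (c-D),
# bond angle theta (b-c-D, degrees) and dihedral tor (a-b-c-D, degrees).
#' @keywords internal
.placeAtom <- function(a, b, c, r, theta, tor) {
  th <- theta * pi / 180; ph <- tor * pi / 180
  bc <- .unit(c - b)
  nrm <- .unit(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  c + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * nrm))
}

#' Build an ideal poly-alanine peptide from backbone torsions
#'
#' Constructs N, CA, C, O and CB for each residue by sequential internal
#' coordinate placement with trans peptide bonds. An alpha-helix uses
#' phi = -57, psi = -47; an extended strand phi = -139, psi = 135.
#'
#' @param nres number of residues
#' @param phi,psi backbone torsions in degrees (scalars or length-nres)
#' @param chain chain id
#' @param startResno first residue number
#' @return data.frame of atoms in fixture-writer layout (record, serial,
#'   name, resn, chain, resno, x, y, z, elem)
#' @export
buildPeptide <- function(nres, phi = -57, psi = -47, chain = "A",
                         startResno = 1L) {
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- .placeAtom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, phi[1])
  for (i in seq_len(nres)) {
    if (i > 1) {
      N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi[i - 1])
      CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psi[i] + 180)
    CB[i, ] <- .placeAtom(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, -122.6)
  }
  rows <- list()
  serial <- 1L
  for (i in seq_len(nres)) {
    nm <- c("N", "CA", "C", "O", "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ])
    rows[[i]] <- data.frame(record = "ATOM",
                            serial = serial + seq_along(nm) - 1,
                            name = nm, resn = "ALA", chain = chain,
                            resno = startResno + i - 1L,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            elem = substr(nm, 1, 1),
                            stringsAsFactors = FALSE)
    serial <- serial + length(nm)
  }
  do.call(rbind, rows)
}

#' @keywords internal
.transformAtoms <- function(df, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

# Count Kabsch-Sander H-bonds between the residues of two atom tables
# when concatenated; used to select the sheet-pairing offset.
#' @keywords internal
.interStrandHbonds <- function(df1, df2) {
  poly <- rbind(df1, df2)
  poly$het <- FALSE; poly$insert <- ""
  res <- .backboneTable(poly)
  hb <- .ksHbonds(res)
  n1 <- length(unique(df1$resno))
  idx1 <- seq_len(n1); idx2 <- seq_len(res$n)[-idx1]
  sum(hb[idx1, idx2]) + sum(hb[idx2, idx1])
}

#' Write an ideal two-strand antiparallel beta fixture
#'
#' Builds one flat pleated strand, generates its antiparallel partner by
#' a 180-degree rotation, and scans the lateral and longitudinal offsets
#' for the placement that maximizes the number of inter-strand
#' Kabsch-Sander hydrogen bonds before writing the pair as PDB text.
#' The default torsions (-138.3, 135.7) are the canonical antiparallel
#' values adjusted so the residue-to-residue transform is an exact
#' two-fold screw under the builder's bond geometry, i.e. the strand has
#' no net twist and every residue can pair.
#'
#' @param nres residues per strand (default 8)
#' @param path output PDB path
#' @param chain chain id (the two strands get separated residue ranges)
#' @param phi,psi strand torsions in degrees
#' @return \code{path}, invisibly
#' @export
makeSheetFixture <- function(nres = 8L, path = tempfile(fileext = ".pdb"),
                             chain = "A", phi = -138.2689, psi = 135.6964) {
  s1 <- buildPeptide(nres, phi = phi, psi = psi, chain = chain,
                     startResno = 1L)
  # canonical frame: strand axis along +x, carbonyls in the xy-plane.
  # The axis is taken over an even residue span: the strand repeat is a
  # two-fold screw, so only even spans are pure translations.
  ca <- as.matrix(s1[s1$name == "CA", c("x", "y", "z")])
  iEven <- nres - (nres + 1) %% 2
  u <- .unit(ca[iEven, ] - ca[1, ])
  co <- as.matrix(s1[s1$name == "O", c("x", "y", "z")]) -
        as.matrix(s1[s1$name == "C", c("x", "y", "z")])
  v <- colMeans(co * rep_len(c(-1, 1), nres))  # alternating carbonyls
  v <- .unit(v - sum(v * u) * u)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  B <- cbind(u, v, w)
  s1 <- .transformAtoms(s1, t(B), c(0, 0, 0))
  ctr <- colMeans(as.matrix(s1[s1$name == "CA", c("x", "y", "z")]))
  s1 <- .transformAtoms(s1, diag(3), -ctr)
  s2base <- s1
  s2base$resno <- s2base$resno + nres + 10L
  R <- diag(c(-1, 1, -1))  # reverse the chain direction, keep y
  best <- NULL; bestScore <- -1L
  for (dy in seq(4.2, 5.6, by = 0.2)) {
    for (dx in seq(-7, 7, by = 0.25)) {
      for (dz in c(-0.5, 0, 0.5)) {
        s2 <- .transformAtoms(s2base, R, c(dx, dy, dz))
        if (.minInterDist(s1, s2) < 2.2) next
        sc <- .interStrandHbonds(s1, s2)
        if (sc > bestScore) { bestScore <- sc; best <- s2 }
      }
    }
  }
  out <- rbind(s1, best)
  out$serial <- seq_len(nrow(out))
  writeFixturePDB(out, path, resolution = 2.0)
}

#' @keywords internal
.minInterDist <- function(df1, df2) {
  a <- as.matrix(df1[, c("x", "y", "z")])
  b <- as.matrix(df2[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Write the synthetic reference protein fixture
#'
#' A small single-chain protein with the three secondary-structure
#' classes: a 14-residue ideal alpha-helix, then (after a chain break) an
#' antiparallel two-strand beta pair, all poly-alanine. Used as the
#' common input for comparing the internal secondary-structure
#' approximation against an external reference assignment.
#'
#' @param path output PDB path
#' @return \code{path}, invisibly
#' @export
makeReferenceProtein <- function(path = tempfile(fileext = ".pdb")) {
  helix <- buildPeptide(14L, phi = -57, psi = -47, chain = "A",
                        startResno = 1L)
  sheetPath <- tempfile(fileext = ".pdb")
  makeSheetFixture(8L, sheetPath, chain = "A")
  sheet <- atoms(readStructure(sheetPath))
  sheetDf <- data.frame(record = "ATOM", serial = 0L, name = sheet$name,
                        resn = sheet$resid, chain = "A",
                        resno = sheet$resno + 20L,
                        x = sheet$x, y = sheet$y + 40, z = sheet$z,
                        elem = sheet$elem, stringsAsFactors = FALSE)
  out <- rbind(helix, sheetDf)
  out$serial <- seq_len(nrow(out))
  writeFixturePDB(out, path, resolution = 2.0)
}
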