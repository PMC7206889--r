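# Synthetic-fixture generators: toy PDB complexes with exactly controlled
# aromatic ring geometry. Fixtures are written as standard PDB text so
# every test exercises the full parsing path, and ligands always carry
# CONECT records.

#' Coordinates of an ideal aromatic ring
#'
#' A regular planar polygon (6 atoms for benzene, 5 for the five-membered
#' heterocycles) in the plane through \code{center} perpendicular to
#' \code{normal}. The default circumradius 1.39 Angstrom makes benzene
#' C-C bonds 1.39 Angstrom (hexagon chord = circumradius).
#'
#' @param type "benzene", "pyrrole" or "imidazole"
#' @param center length-3 ring center
#' @param normal plane normal (any nonzero length)
#' @param radius circumradius in Angstrom
#' @param phase rotation of the first vertex within the plane (radians)
#' @return n x 3 coordinate matrix, vertices in cycle order
#' @export
makeRing <- function(type = c("benzene", "pyrrole", "imidazole"),
                     center = c(0, 0, 0), normal = c(0, 0, 1),
                     radius = 1.39, phase = 0) {
  type <- match.arg(type)
  if (sqrt(sum(normal^2)) < 1e-12) stop("zero-length normal")
  nv <- if (type == "benzene") 6L else 5L
  b <- .planeBasis(normal)
  ang <- phase + 2 * pi * (seq_len(nv) - 1) / nv
  t(vapply(ang, function(a)
    center + radius * (cos(a) * b$e1 + sin(a) * b$e2), numeric(3)))
}

# --- PDB text writer -------------------------------------------------------

#' @keywords internal
.pdbAtomLine <- function(record, serial, name, resn, chain, resno, xyz,
                         occ = 1.0, b = 0.0, elem) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, "", resn, chain, resno, "",
          xyz[1], xyz[2], xyz[3], occ, b, elem)
}

#' Write an atom table plus CONECT records as PDB text
#'
#' @param atomsDf data.frame: record, serial, name, resn, chain, resno,
#'   x, y, z, elem (occ/b optional)
#' @param path output file
#' @param conect two-column matrix of bonded atom serials
#' @param resolution optional REMARK 2 resolution (Angstrom)
#' @return \code{path}, invisibly
#' @export
writeFixturePDB <- function(atomsDf, path, conect = NULL, resolution = NULL) {
  lines <- character()
  if (!is.null(resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              resolution))
  occ <- if ("occ" %in% names(atomsDf)) atomsDf$occ else rep(1, nrow(atomsDf))
  bf <- if ("b" %in% names(atomsDf)) atomsDf$b else rep(0, nrow(atomsDf))
  for (k in seq_len(nrow(atomsDf))) {
    lines <- c(lines, .pdbAtomLine(
      atomsDf$record[k], atomsDf$serial[k], atomsDf$name[k], atomsDf$resn[k],
      atomsDf$chain[k], atomsDf$resno[k],
      c(atomsDf$x[k], atomsDf$y[k], atomsDf$z[k]), occ[k], bf[k],
      atomsDf$elem[k]))
  }
  if (!is.null(conect) && nrow(conect)) {
    for (s in sort(unique(c(conect)))) {
      nb <- sort(unique(c(conect[conect[, 1] == s, 2],
                          conect[conect[, 2] == s, 1])))
      while (length(nb)) {
        take <- utils::head(nb, 4)
        nb <- nb[-seq_along(take)]
        lines <- c(lines, paste0("CONECT",
                                 paste0(sprintf("%5d", c(s, take)),
                                        collapse = "")))
      }
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# --- rigid aromatic units --------------------------------------------------

# A PHE residue reduced to its essential atoms: the benzene ring at the
# requested center/normal plus a short stub of backbone (CB, CA, N, C, O)
# on the -normal side, pointing away from `awayFrom` when given.
#' @keywords internal
.pheUnit <- function(center, normal, chain, resno, serial0, awayFrom = NULL) {
  n <- .unit(normal)
  b <- .planeBasis(n)
  u <- b$e1
  if (!is.null(awayFrom)) {
    dir <- center - awayFrom
    dirP <- dir - sum(dir * n) * n
    if (sqrt(sum(dirP^2)) > 1e-6) u <- .unit(dirP)
  }
  e2 <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
          n[1] * u[2] - n[2] * u[1])
  ang <- 2 * pi * (0:5) / 6
  ringNames <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ring <- t(vapply(ang, function(a)
    center + 1.39 * (cos(a) * u + sin(a) * e2), numeric(3)))
  cg <- ring[1, ]
  cb <- cg + 1.50 * u
  ca <- cb + 1.53 * .unit(0.55 * u - 0.835 * n)
  nn <- ca + 1.46 * .unit(0.7 * e2 - 0.7 * n)
  cc <- ca + 1.53 * .unit(-0.7 * e2 - 0.7 * n)
  oo <- cc + 1.23 * .unit(-0.6 * e2 - 0.8 * n)
  nm <- c("N", "CA", "C", "O", "CB", ringNames)
  xyz <- unname(rbind(nn, ca, cc, oo, cb, ring))
  data.frame(record = "ATOM", serial = serial0 + seq_along(nm) - 1,
             name = nm, resn = "PHE", chain = unname(chain),
             resno = unname(resno),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             elem = substr(nm, 1, 1), stringsAsFactors = FALSE)
}

# A benzene HETATM ligand with its 6 ring bonds.
#' @keywords internal
.benzeneLigand <- function(center, normal, chain, resno, serial0,
                           comp = "BNZ") {
  ring <- makeRing("benzene", center, normal)
  nm <- paste0("C", 1:6)
  df <- data.frame(record = "HETATM", serial = serial0 + 0:5, name = nm,
                   resn = comp, chain = chain, resno = resno,
                   x = ring[, 1], y = ring[, 2], z = ring[, 3],
                   elem = "C", stringsAsFactors = FALSE)
  conect <- cbind(df$serial, df$serial[c(2:6, 1)])
  list(atoms = df, conect = conect)
}

#' Write a two-ring fixture with exact interaction descriptors
#'
#' One PHE residue (ring A, center at the origin, normal +z) and one
#' HETATM benzene (ring B) placed so the measured descriptors equal the
#' request: the center-center vector makes angle \code{theta} with ring
#' A's normal, and ring B's normal is tilted by \code{alpha} in the
#' perpendicular plane, which guarantees ring B's own orientational angle
#' is never smaller than ring A's — so the min-rule theta is exactly the
#' requested value. Round-trip through the written file agrees to PDB
#' fixed-width precision (1e-3 Angstrom).
#'
#' @param d center-center distance (Angstrom, > 0)
#' @param alpha planar angle (degrees, 0-90)
#' @param theta orientational angle (degrees, 0-90)
#' @param path output PDB path
#' @param resolution header resolution
#' @return \code{path}, invisibly
#' @examples
#' pdb <- makeDimer(3.75, 0, 0)
#' @export
makeDimer <- function(d, alpha, theta, path = tempfile(fileext = ".pdb"),
                      resolution = 2.0) {
  stopifnot(d > 0, alpha >= 0, alpha <= 90, theta >= 0, theta <= 90)
  tr <- theta * pi / 180; ar <- alpha * pi / 180
  centerB <- d * c(sin(tr), 0, cos(tr))
  normalB <- c(0, sin(ar), cos(ar))
  phe <- .pheUnit(c(0, 0, 0), c(0, 0, 1), "A", 1L, 1L, awayFrom = centerB)
  lig <- .benzeneLigand(centerB, normalB, "A", 101L, serial0 = 12L)
  writeFixturePDB(rbind(phe, lig$atoms), path, conect = lig$conect,
                  resolution = resolution)
}

#' Write a three-PHE trimer fixture
#'
#' \code{Sym}: ring centers on an equilateral triangle of side
#' \code{spacing} (default 5.0 Angstrom, all pairs within the 7.0 cutoff,
#' giving 3 edges). \code{Lad}: collinear centers spaced \code{spacing},
#' so the two end rings sit \code{2 * spacing} apart (beyond the cutoff
#' at the default, giving the 2-edge ladder). All normals +z.
#'
#' @param motif "Sym" or "Lad"
#' @param spacing center-center spacing (Angstrom)
#' @param path output PDB path
#' @return \code{path}, invisibly
#' @export
makeTrimer <- function(motif = c("Sym", "Lad"), spacing = 5.0,
                       path = tempfile(fileext = ".pdb")) {
  motif <- match.arg(motif)
  centers <- if (motif == "Sym") {
    rbind(c(0, 0, 0), c(spacing, 0, 0),
          c(spacing / 2, spacing * sqrt(3) / 2, 0))
  } else {
    rbind(c(0, 0, 0), c(spacing, 0, 0), c(2 * spacing, 0, 0))
  }
  centroid <- colMeans(centers)
  units <- list()
  for (k in 1:3)
    units[[k]] <- .pheUnit(centers[k, ], c(0, 0, 1), "A", k,
                           serial0 = (k - 1) * 11 + 1, awayFrom = centroid)
  writeFixturePDB(do.call(rbind, units), path, resolution = 2.0)
}

#' Write a protein-drug or protein-protein complex fixture
#'
#' Places rigid aromatic units at requested ring centers/normals:
#' protein rings as PHE stub residues on the requested chains, ligand
#' rings as HETATM benzenes with CONECT records. PP fixtures must name
#' exactly two chains and carry no ligand. Non-bonded atoms of different
#' units closer than \code{clashTol} abort generation.
#'
#' @param kind "PD" or "PP"
#' @param proteinRings list of lists with \code{chain}, \code{center},
#'   \code{normal}
#' @param ligandRings list of lists with \code{center}, \code{normal}
#'   (PD only)
#' @param path output PDB path
#' @param resolution header resolution
#' @param clashTol minimum allowed inter-unit atom distance (Angstrom)
#' @return \code{path}, invisibly
#' @export
makeComplexFixture <- function(kind = c("PD", "PP"), proteinRings,
                               ligandRings = list(),
                               path = tempfile(fileext = ".pdb"),
                               resolution = 2.0, clashTol = 1.5) {
  kind <- match.arg(kind)
  chains <- unique(vapply(proteinRings, `[[`, "", "chain"))
  if (kind == "PP" && (length(chains) != 2 || length(ligandRings)))
    stop("a PP fixture needs exactly two chains and no ligand")
  if (kind == "PD" && !length(ligandRings))
    stop("a PD fixture needs at least one ligand ring")
  allCenters <- do.call(rbind, c(lapply(proteinRings, `[[`, "center"),
                                 lapply(ligandRings, `[[`, "center")))
  centroid <- colMeans(allCenters)
  parts <- list(); conect <- NULL; serial <- 1L
  resnoByChain <- stats::setNames(rep(0L, length(chains)), chains)
  placed <- NULL
  for (pr in proteinRings) {
    resnoByChain[pr$chain] <- resnoByChain[pr$chain] + 1L
    unit <- .pheUnit(pr$center, pr$normal, pr$chain,
                     resnoByChain[pr$chain], serial, awayFrom = centroid)
    .checkClash(placed, unit, clashTol)
    placed <- rbind(placed, unit)
    parts[[length(parts) + 1L]] <- unit
    serial <- serial + nrow(unit)
  }
  ligno <- 100L
  for (lr in ligandRings) {
    ligno <- ligno + 1L
    lig <- .benzeneLigand(lr$center, lr$normal, chains[1], ligno, serial)
    .checkClash(placed, lig$atoms, clashTol)
    placed <- rbind(placed, lig$atoms)
    parts[[length(parts) + 1L]] <- lig$atoms
    conect <- rbind(conect, lig$conect)
    serial <- serial + nrow(lig$atoms)
  }
  writeFixturePDB(do.call(rbind, parts), path, conect = conect,
                  resolution = resolution)
}

#' @keywords internal
.checkClash <- function(placed, unit, clashTol) {
  if (is.null(placed) || !nrow(placed)) return(invisible())
  a <- as.matrix(placed[, c("x", "y", "z")])
  b <- as.matrix(unit[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  if (min(d2) < clashTol^2)
    stop("unsatisfiable geometry: inter-unit clash below ", clashTol,
         " Angstrom")
  invisible()
}

#' Sample (d, alpha) pairs from a mixture of interaction modes
#'
#' Gaussian mixture over distance and planar angle, emulating the
#' empirical two-mode geometry of aromatic contacts (broad T-shape mode
#' near d = 5 Angstrom / alpha = 75 degrees and a narrow stacking mode
#' near d = 3.75 / alpha = 0). Angles are folded into [0, 90] by
#' reflection; non-positive distances are redrawn. Reproducible given
#' (components, n, seed).
#'
#' @param components list of lists: \code{d}, \code{alpha}, \code{weight},
#'   \code{sd_d}, \code{sd_alpha}
#' @param n number of samples
#' @param seed RNG seed
#' @return data.frame with columns d, alpha, component
#' @export
sampleEnsemble <- function(components, n, seed) {
  w <- vapply(components, `[[`, 0, "weight")
  stopifnot(abs(sum(w) - 1) < 1e-9, n >= 1)
  set.seed(seed)
  comp <- sample.int(length(components), n, replace = TRUE, prob = w)
  d <- numeric(n); alpha <- numeric(n)
  for (k in seq_along(components)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    ck <- components[[k]]
    dk <- stats::rnorm(length(idx), ck$d, ck$sd_d)
    while (any(dk <= 0))
      dk[dk <= 0] <- stats::rnorm(sum(dk <= 0), ck$d, ck$sd_d)
    ak <- stats::rnorm(length(idx), ck$alpha, ck$sd_alpha)
    ak <- abs(ak) %% 180
    ak <- ifelse(ak > 90, 180 - ak, ak)
    d[idx] <- dk; alpha[idx] <- ak
  }
  data.frame(d = d, alpha = alpha, component = comp)
}
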