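# Aromatic ring templates for the four aromatic amino acids. Phe/Tyr carry
# one benzene; His one imidazole; Trp an indole counted as two rings
# (pyrrole + benzene) sharing the CD2-CE2 edge.
.proteinRingTemplates <- list(
  PHE = list(list(type = "benzene",
                  atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  TYR = list(list(type = "benzene",
                  atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  HIS = list(list(type = "imidazole",
                  atoms = c("CG", "ND1", "CD2", "CE1", "NE2"))),
  TRP = list(list(type = "pyrrole",
                  atoms = c("CG", "CD1", "NE1", "CE2", "CD2")),
             list(type = "benzene",
                  atoms = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))
)

#' Detect aromatic rings in protein residues
#'
#' Template-based: Phe and Tyr contribute one benzene ring each, His one
#' imidazole, and Trp two rings (pyrrole and benzene of the indole system,
#' counted individually). Residues with incomplete ring templates are
#' skipped with a warning. AltLocs must be resolved first
#' (\code{\link{resolveAltLoc}}).
#'
#' @param x a \linkS4class{ComplexStructure}
#' @return an \linkS4class{AromaticRingSet} of source class \code{"R"}
#' @export
detectProteinRings <- function(x) {
  a <- atoms(x)
  out <- list()
  poly <- which(!a$het & a$resid %in% names(.proteinRingTemplates))
  if (length(poly)) {
    key <- paste(a$chain[poly], a$resno[poly], a$insert[poly], a$resid[poly],
                 sep = "\r")
    for (idx in split(poly, key)[unique(key)]) {
      resid <- a$resid[idx[1]]
      for (tmpl in .proteinRingTemplates[[resid]]) {
        pos <- idx[match(tmpl$atoms, a$name[idx])]
        if (anyNA(pos)) {
          warning("incomplete ", tmpl$type, " ring in ", resid, " ",
                  a$chain[idx[1]], a$resno[idx[1]], "; skipped")
          next
        }
        out[[length(out) + 1L]] <- list(
          source = "R", type = tmpl$type, chain = a$chain[idx[1]],
          resno = a$resno[idx[1]], insert = a$insert[idx[1]],
          resname = resid, atomIdx = pos)
      }
    }
  }
  .buildRingSet(x, out)
}

#' @keywords internal
.buildRingSet <- function(x, ringList) {
  a <- atoms(x)
  n <- length(ringList)
  if (n == 0) {
    return(new("AromaticRingSet",
               rings = data.frame(ring_id = character(), source = character(),
                                  type = character(), chain = character(),
                                  resno = integer(), insert = character(),
                                  resname = character(), rms_dev = numeric()),
               atomIdx = list(), centers = matrix(0, 0, 3),
               normals = matrix(0, 0, 3), structureId = x@id))
  }
  centers <- matrix(0, n, 3); normals <- matrix(0, n, 3)
  rms <- numeric(n)
  for (k in seq_len(n)) {
    fit <- planeFit(as.matrix(a[ringList[[k]]$atomIdx, c("x", "y", "z")]))
    centers[k, ] <- fit$center; normals[k, ] <- fit$normal
    rms[k] <- fit$rms_dev
  }
  df <- data.frame(
    ring_id = vapply(seq_len(n), function(k) {
      r <- ringList[[k]]
      paste0(r$source, ":", r$chain, r$resno, r$insert, ":", r$resname,
             ":", r$type, ":", k)
    }, ""),
    source = vapply(ringList, `[[`, "", "source"),
    type = vapply(ringList, `[[`, "", "type"),
    chain = vapply(ringList, `[[`, "", "chain"),
    resno = vapply(ringList, function(r) as.integer(r$resno), 0L),
    insert = vapply(ringList, `[[`, "", "insert"),
    resname = vapply(ringList, `[[`, "", "resname"),
    rms_dev = rms, stringsAsFactors = FALSE)
  new("AromaticRingSet", rings = df,
      atomIdx = lapply(ringList, `[[`, "atomIdx"),
      centers = centers, normals = normals, structureId = x@id)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two heavy atoms are bonded iff their distance is at most the sum of
#' their covalent radii plus 0.40 Angstrom tolerance.
#'
#' @param atomsDf data.frame with columns elem, x, y, z
#' @return two-column integer matrix of bonded row pairs (i < j)
#' @export
inferBonds <- function(atomsDf) {
  keep <- which(toupper(atomsDf$elem) != "H")
  if (length(keep) < 2) return(matrix(integer(), ncol = 2))
  xyz <- as.matrix(atomsDf[keep, c("x", "y", "z")])
  r <- .elementLookup(.covalentRadii, atomsDf$elem[keep], "covalent radius")
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + 0.40
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  cbind(keep[hit[, 1]], keep[hit[, 2]])
}

#' Detect aromatic rings in a ligand instance
#'
#' Graph-based perception: enumerates the smallest rings of the heavy-atom
#' bond graph (per-edge shortest cycles, deduplicated — the minimum-cycle
#' set for the fused systems found in drug-like molecules) and keeps rings
#' of size 5-6 whose atoms are all C/N/O/S with at most 3 heavy-atom
#' neighbours and whose least-squares plane fit has rms deviation
#' <= \code{planarityTol}. Each ring of a fused system is emitted
#' individually. Ring chemical type is assigned by composition: an all-C
#' 6-ring is benzene, a 5-ring with one N pyrrole-like, with two N
#' imidazole-like, anything else other-aromatic.
#'
#' An override table (component id -> list of atom-name vectors) injects
#' externally perceived rings verbatim, bypassing the heuristic.
#'
#' @param x the parent \linkS4class{ComplexStructure}
#' @param ligand one element of \code{\link{ligandInstances}(x)}
#' @param planarityTol rms out-of-plane tolerance in Angstrom (default 0.10)
#' @param overrides optional named list: comp_id -> list of character
#'   vectors of ring atom names
#' @return list of internal ring descriptors (see \code{\link{detectRings}}
#'   for the user-facing entry point)
#' @export
detectLigandRings <- function(x, ligand, planarityTol = 0.10,
                              overrides = NULL) {
  a <- atoms(x)
  idx <- ligand$atomIdx
  if (!is.null(overrides) && !is.null(overrides[[ligand$comp_id]])) {
    out <- list()
    for (nm in overrides[[ligand$comp_id]]) {
      pos <- idx[match(nm, a$name[idx])]
      if (anyNA(pos)) {
        warning("override ring atoms missing in ", ligand$comp_id, "; skipped")
        next
      }
      out[[length(out) + 1L]] <- .ligandRingEntry(a, ligand, pos)
    }
    return(out)
  }
  bnd <- ligand$bonds
  if (is.null(bnd) || nrow(bnd) == 0)
    bnd <- inferBonds(a[idx, , drop = FALSE])
  if (nrow(bnd) == 0)
    stop("no bonds derivable for ligand ", ligand$comp_id,
         ": supply CONECT records or a ring template override")
  cycles <- .smallestRings(length(idx), bnd, sizes = 5:6)
  deg <- tabulate(c(bnd[, 1], bnd[, 2]), nbins = length(idx))
  out <- list()
  for (cyc in cycles) {
    pos <- idx[cyc]
    if (!all(toupper(a$elem[pos]) %in% c("C", "N", "O", "S"))) next
    if (any(deg[cyc] > 3)) next
    fit <- tryCatch(planeFit(as.matrix(a[pos, c("x", "y", "z")])),
                    error = function(e) NULL)
    if (is.null(fit) || fit$rms_dev > planarityTol) next
    out[[length(out) + 1L]] <- .ligandRingEntry(a, ligand, pos)
  }
  out
}

#' @keywords internal
.ligandRingEntry <- function(a, ligand, pos) {
  elems <- toupper(a$elem[pos])
  type <- if (length(pos) == 6 && all(elems == "C")) "benzene"
          else if (length(pos) == 5 && sum(elems == "N") == 1) "pyrrole"
          else if (length(pos) == 5 && sum(elems == "N") == 2) "imidazole"
          else "other-aromatic"
  list(source = "D", type = type, chain = ligand$chain,
       resno = ligand$resno, insert = ligand$insert,
       resname = ligand$comp_id, atomIdx = pos)
}

# Smallest rings of a bond graph: for every edge, the shortest cycle
# through it (edge + shortest path in the graph with the edge removed),
# restricted to the requested sizes and deduplicated on the atom set.
#' @keywords internal
.smallestRings <- function(nAtoms, bondPairs, sizes = 5:6) {
  g <- igraph::graph_from_edgelist(cbind(bondPairs[, 1], bondPairs[, 2]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nAtoms)
    g <- igraph::add_vertices(g, nAtoms - igraph::vcount(g))
  seen <- character()
  out <- list()
  for (e in seq_len(nrow(bondPairs))) {
    u <- bondPairs[e, 1]; v <- bondPairs[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = u, to = v, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 2) next
    if (!length(path) %in% sizes) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- path
  }
  out
}

#' Detect all aromatic rings in a structure
#'
#' Combines template-based protein rings (\code{\link{detectProteinRings}})
#' with graph-perceived ligand rings (\code{\link{detectLigandRings}}) for
#' every ligand instance surviving the deny-list.
#'
#' @param x a \linkS4class{ComplexStructure} (altLocs resolved)
#' @param ligands optionally a pre-filtered list from
#'   \code{\link{ligandInstances}} / \code{\link{filterDrugLike}}; default
#'   all deny-list survivors
#' @param planarityTol,overrides passed to \code{\link{detectLigandRings}}
#' @return an \linkS4class{AromaticRingSet} with mixed R and D rings
#' @examples
#' s <- readStructure(makeDimer(3.75, 0, 0))
#' detectRings(s)
#' @export
detectRings <- function(x, ligands = NULL, planarityTol = 0.10,
                        overrides = NULL) {
  prot <- detectProteinRings(x)
  if (is.null(ligands)) ligands <- ligandInstances(x)
  lig <- list()
  for (lg in ligands)
    lig <- c(lig, detectLigandRings(x, lg, planarityTol, overrides))
  if (!length(lig)) return(prot)
  a <- atoms(x)
  all <- c(.ringSetAsList(prot), lig)
  .buildRingSet(x, all)
}

#' @keywords internal
.ringSetAsList <- function(rs) {
  df <- rings(rs)
  lapply(seq_len(nrow(df)), function(k)
    list(source = df$source[k], type = df$type[k], chain = df$chain[k],
         resno = df$resno[k], insert = df$insert[k],
         resname = df$resname[k], atomIdx = rs@atomIdx[[k]]))
}
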