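#' @import methods
NULL

#' ComplexStructure: a parsed protein(-ligand) coordinate model
#'
#' Container for one model of a PDB entry: a flat atom table (polymer and
#' hetero atoms, waters removed), CONECT-derived bonds between hetero atoms,
#' the crystallographic resolution when the header states one, and any
#' HELIX/SHEET header annotation.
#'
#' @slot id structure identifier (file stem unless overridden)
#' @slot atoms data.frame with one row per atom: serial, name, elem, x, y, z,
#'   occ, alt, chain, resno, insert, resid, het (logical)
#' @slot bonds data.frame of CONECT bonds: columns i, j (row indices into
#'   \code{atoms})
#' @slot resolution numeric scalar (Angstrom) or NA
#' @slot helixRanges,sheetRanges data.frames of header secondary-structure
#'   ranges (chain, start, end), possibly empty
#'
#' @export
setClass("ComplexStructure",
  representation(
    id = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    resolution = "numeric",
    helixRanges = "data.frame",
    sheetRanges = "data.frame"
  ),
  prototype(
    id = NA_character_,
    bonds = data.frame(i = integer(), j = integer()),
    resolution = NA_real_,
    helixRanges = data.frame(chain = character(), start = integer(), end = integer()),
    sheetRanges = data.frame(chain = character(), start = integer(), end = integer())
  )
)

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "elem", "x", "y", "z", "occ", "alt",
            "chain", "resno", "insert", "resid", "het")
  if (!all(need %in% names(a)))
    return(paste("atoms missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) && !all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite atom coordinates")
  if (nrow(a) && any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  b <- object@bonds
  if (nrow(b) && (any(b$i < 1 | b$i > nrow(a)) || any(b$j < 1 | b$j > nrow(a))))
    return("bond indices outside atom table")
  if (length(object@resolution) == 1 && !is.na(object@resolution) &&
      object@resolution <= 0)
    return("resolution must be positive")
  TRUE
})

#' AromaticRingSet: typed aromatic rings with fitted planes
#'
#' One row per ring: protein-residue rings (source class \code{"R"}) come
#' from the fixed Phe/Tyr/Trp/His templates, ligand rings (\code{"D"}) from
#' graph-based perception. Centers are arithmetic means of the member heavy
#' atoms; normals are unit least-squares plane normals with a canonical sign
#' (z >= 0, ties broken on y then x).
#'
#' @slot rings data.frame: ring_id, source, type, chain, resno, insert,
#'   resname, rms_dev
#' @slot atomIdx list of integer vectors (rows of the parent structure's
#'   atom table) per ring
#' @slot centers,normals numeric matrices, one row per ring
#' @slot structureId id of the parent ComplexStructure
#' @export
setClass("AromaticRingSet",
  representation(
    rings = "data.frame",
    atomIdx = "list",
    centers = "matrix",
    normals = "matrix",
    structureId = "character"
  ),
  prototype(structureId = NA_character_)
)

setValidity("AromaticRingSet", function(object) {
  n <- nrow(object@rings)
  if (length(object@atomIdx) != n) return("atomIdx length != ring count")
  if (n == 0) return(TRUE)
  if (nrow(object@centers) != n || nrow(object@normals) != n)
    return("centers/normals row count != ring count")
  nrm <- sqrt(rowSums(object@normals^2))
  if (any(abs(nrm - 1) > 1e-9)) return("normals are not unit vectors")
  sz <- lengths(object@atomIdx)
  if (any(sz < 5 | sz > 6)) return("ring size outside 5..6")
  if (!all(object@rings$source %in% c("R", "D")))
    return("ring source must be R or D")
  TRUE
})

#' RingInteractionSet: pairwise aromatic interactions
#'
#' One row per detected ring pair within the distance cutoff: descriptors
#' d (Angstrom), alpha and theta (degrees, folded to [0, 90]), the per-ring
#' orientational angles theta_a/theta_b, a conformation class and a context
#' class (drug-residue, inter-chain or intra-chain residue-residue).
#'
#' @slot pairs data.frame: ring_a, ring_b (indices into the ring set),
#'   d, alpha, theta, theta_a, theta_b, conformation, context
#' @slot cutoff detection distance cutoff (Angstrom)
#' @slot thresholds named numeric vector of conformation-class boundaries
#' @export
setClass("RingInteractionSet",
  representation(pairs = "data.frame", cutoff = "numeric",
                 thresholds = "numeric"),
  prototype(cutoff = 7.0)
)

setValidity("RingInteractionSet", function(object) {
  p <- object@pairs
  if (nrow(p) == 0) return(TRUE)
  if (any(p$ring_a == p$ring_b)) return("self-interaction present")
  if (any(p$d > object@cutoff + 1e-9)) return("pair beyond cutoff")
  if (any(p$alpha < -1e-9 | p$alpha > 90 + 1e-9)) return("alpha outside [0, 90]")
  if (any(p$theta < -1e-9 | p$theta > 90 + 1e-9)) return("theta outside [0, 90]")
  TRUE
})

#' AromaticClusterSet: connected components of the interaction graph
#'
#' Clusters enumerated under a context-specific detection edge rule
#' (\code{mode}), with both the detection edges (used for connectivity) and
#' the counting edges (used for interaction totals) retained. Three-ring
#' clusters carry a trimer motif: Sym (triangle, 3 counting edges) or Lad
#' (path, 2).
#'
#' @slot clusters data.frame: cluster_id, size, n_detection, n_counting, motif
#' @slot members list of integer ring indices per cluster
#' @slot detectionEdges,countingEdges list of integer row indices into the
#'   interaction set per cluster
#' @slot mode "PD", "PP" or "intra"
#' @export
setClass("AromaticClusterSet",
  representation(
    clusters = "data.frame",
    members = "list",
    detectionEdges = "list",
    countingEdges = "list",
    mode = "character"
  )
)

setValidity("AromaticClusterSet", function(object) {
  n <- nrow(object@clusters)
  if (length(object@members) != n || length(object@detectionEdges) != n ||
      length(object@countingEdges) != n)
    return("per-cluster list lengths differ from cluster count")
  if (!object@mode %in% c("PD", "PP", "intra")) return("unknown mode")
  if (n == 0) return(TRUE)
  if (any(object@clusters$size < 2)) return("singleton cluster present")
  for (k in seq_len(n)) {
    if (!all(object@detectionEdges[[k]] %in% object@countingEdges[[k]]))
      return("detection edges not a subset of counting edges")
  }
  bad <- object@clusters$size == 3 & !object@clusters$motif %in% c("Sym", "Lad")
  bad <- bad | (object@clusters$size != 3 & !is.na(object@clusters$motif))
  if (any(bad)) return("trimer motif defined iff size == 3")
  TRUE
})
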