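#' Enumerate aromatic clusters as connected components
#'
#' Clusters are the connected components of the ring-interaction graph
#' under a context-specific detection edge rule; singleton rings are not
#' clusters. The edges used to count interactions may be a superset of
#' those used to detect connectivity:
#' \describe{
#'   \item{PD}{detection on drug-residue plus all residue-residue edges;
#'     only components containing at least one drug (D) ring are kept.
#'     Counting edges are the same edge set restricted to members.}
#'   \item{PP}{detection on inter-chain residue-residue edges only; all
#'     components kept. Counting adds intra-chain residue-residue edges
#'     among member rings to the detection edges.}
#'   \item{intra}{detection and counting on intra-chain residue-residue
#'     edges only.}
#' }
#' Three-ring clusters are classified by motif: \code{Sym} (triangle,
#' three counting edges) or \code{Lad} (path, two).
#'
#' @param ringSet an \linkS4class{AromaticRingSet}
#' @param interactionSet a \linkS4class{RingInteractionSet} over the same
#'   rings
#' @param mode \code{"PD"}, \code{"PP"} or \code{"intra"}
#' @return an \linkS4class{AromaticClusterSet}
#' @examples
#' s <- readStructure(makeTrimer("Sym"))
#' rs <- detectRings(s)
#' enumerateClusters(rs, detectInteractions(rs), mode = "intra")
#' @export
enumerateClusters <- function(ringSet, interactionSet,
                              mode = c("PD", "PP", "intra")) {
  mode <- match.arg(mode)
  p <- interactions(interactionSet)
  df <- rings(ringSet)
  n <- nrow(df)
  det <- switch(mode,
    PD = which(p$context %in% c("drug-residue", "intra-chain", "inter-chain")),
    PP = which(p$context == "inter-chain"),
    intra = which(p$context == "intra-chain"))
  cnt_pool <- switch(mode,
    PD = det,
    PP = which(p$context %in% c("inter-chain", "intra-chain")),
    intra = det)

  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(det))
    g <- igraph::add_edges(g, rbind(p$ring_a[det], p$ring_b[det]))
  comp <- igraph::components(g)
  memb <- comp$membership

  keep <- which(comp$csize >= 2)
  if (mode == "PD" && length(keep)) {
    hasD <- vapply(keep, function(cid)
      any(df$source[memb == cid] == "D"), TRUE)
    keep <- keep[hasD]
  }
  members <- detE <- cntE <- list()
  rows <- list()
  for (cid in keep) {
    mem <- which(memb == cid)
    de <- det[p$ring_a[det] %in% mem & p$ring_b[det] %in% mem]
    ce <- cnt_pool[p$ring_a[cnt_pool] %in% mem & p$ring_b[cnt_pool] %in% mem]
    ce <- sort(unique(c(de, ce)))
    k <- length(rows) + 1L
    motif <- if (length(mem) == 3) trimerMotif(length(ce)) else NA_character_
    rows[[k]] <- data.frame(
      cluster_id = k, size = length(mem), n_detection = length(de),
      n_counting = length(ce), motif = motif, stringsAsFactors = FALSE)
    members[[k]] <- mem; detE[[k]] <- de; cntE[[k]] <- ce
  }
  cl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), size = integer(),
               n_detection = integer(), n_counting = integer(),
               motif = character(), stringsAsFactors = FALSE)
  new("AromaticClusterSet", clusters = cl, members = members,
      detectionEdges = detE, countingEdges = cntE, mode = mode)
}

#' Classify a trimer motif from its counting-edge count
#'
#' The only connected graphs on three nodes are the path (2 edges) and the
#' triangle (3 edges), hence three-ring clusters fall into exactly two
#' spatial motifs: \code{Lad} (ladder) and \code{Sym} (symmetric, which
#' maximizes the interaction count at 3 for 3 rings).
#'
#' @param nCountingEdges number of counting edges among the three rings
#' @return \code{"Sym"} or \code{"Lad"}
#' @export
trimerMotif <- function(nCountingEdges) {
  if (nCountingEdges == 3) "Sym"
  else if (nCountingEdges == 2) "Lad"
  else stop("a connected 3-ring cluster has 2 or 3 edges, got ",
            nCountingEdges)
}

#' Summary statistics from dataset totals
#'
#' The ratio definitions behind a Table-1-style dataset summary:
#' clusters per complex is averaged over complexes with at least one
#' cluster, and interactions per cluster over all clusters.
#'
#' @param nComplexesWithCluster complexes having >= 1 aromatic cluster
#' @param nClusters total clusters
#' @param nInteractions total counting-edge interactions
#' @param nComplexesTotal optionally, all complexes surveyed (enables the
#'   percentage with a cluster)
#' @return list with \code{avg_clusters_per_complex},
#'   \code{avg_interactions_per_cluster} and \code{pct_with_cluster}
#' @export
summaryFromCounts <- function(nComplexesWithCluster, nClusters,
                              nInteractions, nComplexesTotal = NA) {
  list(
    avg_clusters_per_complex =
      if (nComplexesWithCluster > 0) nClusters / nComplexesWithCluster else 0,
    avg_interactions_per_cluster =
      if (nClusters > 0) nInteractions / nClusters else 0,
    pct_with_cluster =
      if (!is.na(nComplexesTotal) && nComplexesTotal > 0)
        100 * nComplexesWithCluster / nComplexesTotal else NA_real_
  )
}

#' Dataset-level summary over per-complex cluster results
#'
#' Aggregates one analysis mode over many complexes into the Table-1
#' schema: cluster and interaction counts with their averages, the residue
#' composition of interacting aromatic residues (each residue counted once
#' per cluster membership; a Trp contributes one residue though it carries
#' two rings), secondary-structure fractions and mean percent exposure
#' when per-residue assignments are supplied.
#'
#' @param results named list, one element per complex: each a list with
#'   \code{rings} (\linkS4class{AromaticRingSet}) and \code{clusters}
#'   (\linkS4class{AromaticClusterSet})
#' @param ss optional named character vector residue key
#'   ("chain:resno:insert") -> class in Helix/Sheet/Loop, pooled over
#'   complexes as "complexId|chain:resno:insert"
#' @param exposure optional named numeric vector, same keys, percent
#'   exposed
#' @param perRing count composition per ring instead of per residue
#' @return list: counts, averages, residue_composition (fractions over
#'   PHE/TYR/TRP/HIS), ss_fractions, mean_pct_exposed
#' @export
summarizeDataset <- function(results, ss = NULL, exposure = NULL,
                             perRing = FALSE) {
  nComplexes <- length(results)
  nWith <- 0L; nClusters <- 0L; nInteractions <- 0L
  resCount <- c(PHE = 0, TYR = 0, TRP = 0, HIS = 0)
  ssCount <- c(Loop = 0, Sheet = 0, Helix = 0)
  expo <- numeric()
  for (nm in names(results)) {
    res <- results[[nm]]
    cs <- res$clusters
    cl <- clusters(cs)
    if (nrow(cl) == 0) next
    nWith <- nWith + 1L
    nClusters <- nClusters + nrow(cl)
    nInteractions <- nInteractions + sum(cl$n_counting)
    rdf <- rings(res$rings)
    for (mem in clusterMembers(cs)) {
      rsub <- rdf[mem, , drop = FALSE]
      rsub <- rsub[rsub$source == "R", , drop = FALSE]
      if (!perRing)
        rsub <- rsub[!duplicated(paste(rsub$chain, rsub$resno, rsub$insert)), ,
                     drop = FALSE]
      for (k in seq_len(nrow(rsub))) {
        rn <- rsub$resname[k]
        if (rn %in% names(resCount)) resCount[rn] <- resCount[rn] + 1
        key <- paste0(nm, "|", rsub$chain[k], ":", rsub$resno[k], ":",
                      rsub$insert[k])
        if (!is.null(ss) && !is.na(ss[key]) && ss[key] %in% names(ssCount))
          ssCount[ss[key]] <- ssCount[ss[key]] + 1
        if (!is.null(exposure) && !is.na(exposure[key]))
          expo <- c(expo, exposure[key])
      }
    }
  }
  avg <- summaryFromCounts(nWith, nClusters, nInteractions, nComplexes)
  list(
    counts = list(n_complexes = nComplexes, n_complexes_with_cluster = nWith,
                  n_clusters = nClusters, n_interactions = nInteractions),
    averages = avg,
    residue_composition = if (sum(resCount) > 0) resCount / sum(resCount)
                          else resCount,
    ss_fractions = if (sum(ssCount) > 0) ssCount / sum(ssCount) else ssCount,
    mean_pct_exposed = if (length(expo)) mean(expo) else NA_real_
  )
}
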