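#' Accessors for aroclust S4 containers
#'
#' \code{atoms}, \code{bonds}, \code{resolution}, \code{rings},
#' \code{ringCenters}, \code{ringNormals}, \code{interactions} and
#' \code{clusters} return the underlying tables of the corresponding
#' container; slots are never accessed directly by user code.
#'
#' @param x an aroclust object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setGeneric("rings", function(x) standardGeneric("rings"))
#' @rdname accessors
#' @export
setGeneric("ringCenters", function(x) standardGeneric("ringCenters"))
#' @rdname accessors
#' @export
setGeneric("ringNormals", function(x) standardGeneric("ringNormals"))
#' @rdname accessors
#' @export
setGeneric("ringAtomIndices", function(x) standardGeneric("ringAtomIndices"))
#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setMethod("atoms", "ComplexStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "ComplexStructure", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("resolution", "ComplexStructure", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("rings", "AromaticRingSet", function(x) x@rings)
#' @rdname accessors
#' @export
setMethod("ringCenters", "AromaticRingSet", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("ringNormals", "AromaticRingSet", function(x) x@normals)
#' @rdname accessors
#' @export
setMethod("ringAtomIndices", "AromaticRingSet", function(x) x@atomIdx)
#' @rdname accessors
#' @export
setMethod("interactions", "RingInteractionSet", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("clusters", "AromaticClusterSet", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("clusterMembers", "AromaticClusterSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("length", "AromaticRingSet", function(x) nrow(x@rings))
#' @rdname accessors
#' @export
setMethod("length", "RingInteractionSet", function(x) nrow(x@pairs))
#' @rdname accessors
#' @export
setMethod("length", "AromaticClusterSet", function(x) nrow(x@clusters))

setMethod("show", "ComplexStructure", function(object) {
  a <- object@atoms
  nchain <- length(unique(a$chain[!a$het]))
  cat("ComplexStructure", object@id, "\n")
  cat("  ", sum(!a$het), "polymer atoms in", nchain, "chain(s);",
      sum(a$het), "hetero atoms;", nrow(object@bonds), "CONECT bonds\n")
  cat("   resolution:",
      if (is.na(object@resolution)) "unknown" else
        paste0(format(object@resolution, nsmall = 2), " A"), "\n")
})

setMethod("show", "AromaticRingSet", function(object) {
  cat("AromaticRingSet with", nrow(object@rings), "ring(s)\n")
  if (nrow(object@rings)) {
    tab <- table(object@rings$source, object@rings$type)
    print(tab)
  }
})

setMethod("show", "RingInteractionSet", function(object) {
  cat("RingInteractionSet with", nrow(object@pairs),
      "interaction(s), cutoff", object@cutoff, "A\n")
  if (nrow(object@pairs)) print(table(object@pairs$conformation))
})

setMethod("show", "AromaticClusterSet", function(object) {
  cat("AromaticClusterSet (", object@mode, " mode) with ",
      nrow(object@clusters), " cluster(s)\n", sep = "")
  if (nrow(object@clusters)) {
    cat("   sizes:", paste(object@clusters$size, collapse = ", "), "\n")
  }
})
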