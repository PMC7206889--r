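#' Geometric descriptors of an aromatic ring pair
#'
#' Computes the three descriptors of an aromatic-aromatic contact:
#' \itemize{
#'   \item \code{d}: Euclidean distance between ring centers (Angstrom);
#'   \item \code{alpha}: planar angle between the two ring normals, folded
#'     to [0, 90] degrees;
#'   \item \code{theta}: orientational angle between a ring normal and the
#'     center-to-center vector, folded to [0, 90] degrees. The two rings
#'     give two values (\code{theta_a}, \code{theta_b}); \code{theta} is
#'     their minimum, which makes the descriptor symmetric in the pair.
#' }
#'
#' @param centerA,centerB ring centers (length-3)
#' @param normalA,normalB unit ring normals
#' @return named list d, alpha, theta, theta_a, theta_b
#' @export
pairDescriptors <- function(centerA, normalA, centerB, normalB) {
  v <- centerB - centerA
  d <- sqrt(sum(v^2))
  if (d < 1e-9) stop("coincident ring centers")
  alpha <- .foldedAngle(normalA, normalB)
  ta <- .foldedAngle(normalA, v)
  tb <- .foldedAngle(normalB, v)
  list(d = d, alpha = alpha, theta = min(ta, tb), theta_a = ta, theta_b = tb)
}

#' Classify an interaction conformation from its angles
#'
#' Near-parallel rings (\code{alpha <= alphaParallelMax}) are face-to-face
#' when the center line stays near a ring normal (\code{theta <= thetaFtfMax})
#' and edge-to-edge otherwise; near-perpendicular rings
#' (\code{alpha >= alphaTshapeMin}) are edge-to-face (the T-shape);
#' intermediate tilts are oblique. The default boundaries (30/45/60 degrees)
#' bracket the empirical density maxima of stacking (alpha near 0) and
#' T-shape (alpha near 75) geometries with a wide margin.
#'
#' @param alpha,theta degrees in [0, 90] (vectorized)
#' @param alphaParallelMax,thetaFtfMax,alphaTshapeMin class boundaries
#' @return character vector of conformation classes
#' @export
classifyConformation <- function(alpha, theta, alphaParallelMax = 30,
                                 thetaFtfMax = 45, alphaTshapeMin = 60) {
  stopifnot(all(alpha >= 0 & alpha <= 90), all(theta >= 0 & theta <= 90))
  out <- rep("oblique", length(alpha))
  out[alpha <= alphaParallelMax & theta <= thetaFtfMax] <- "face-to-face"
  out[alpha <= alphaParallelMax & theta > thetaFtfMax] <- "edge-to-edge"
  out[alpha >= alphaTshapeMin] <- "edge-to-face"
  out
}

#' Detect aromatic interactions among a set of rings
#'
#' Emits an interaction for every ring pair whose center distance is at
#' most \code{cutoff} (7.0 Angstrom by default). Detection is on distance
#' only; the angles are descriptive. Pairs sharing any atom (fused rings)
#' or belonging to the same residue/ligand instance are excluded — a fused
#' system is one chemical unit — and drug-drug pairs are not interactions
#' in this analysis.
#'
#' Context labels: \code{"drug-residue"} for D-R pairs, and
#' \code{"intra-chain"} / \code{"inter-chain"} for R-R pairs on the same /
#' different polymer chains.
#'
#' @param ringSet an \linkS4class{AromaticRingSet}
#' @param cutoff center-center distance cutoff in Angstrom
#' @param alphaParallelMax,thetaFtfMax,alphaTshapeMin conformation-class
#'   boundaries, see \code{\link{classifyConformation}}
#' @return a \linkS4class{RingInteractionSet}
#' @examples
#' s <- readStructure(makeDimer(5.0, 75, 10))
#' detectInteractions(detectRings(s))
#' @export
detectInteractions <- function(ringSet, cutoff = 7.0, alphaParallelMax = 30,
                               thetaFtfMax = 45, alphaTshapeMin = 60) {
  df <- rings(ringSet)
  n <- nrow(df)
  thresholds <- c(alphaParallelMax = alphaParallelMax,
                  thetaFtfMax = thetaFtfMax, alphaTshapeMin = alphaTshapeMin)
  empty <- data.frame(ring_a = integer(), ring_b = integer(), d = numeric(),
                      alpha = numeric(), theta = numeric(),
                      theta_a = numeric(), theta_b = numeric(),
                      conformation = character(), context = character(),
                      stringsAsFactors = FALSE)
  if (n < 2)
    return(new("RingInteractionSet", pairs = empty, cutoff = cutoff,
               thresholds = thresholds))
  ctr <- ringCenters(ringSet)
  nrm <- ringNormals(ringSet)
  dm <- as.matrix(stats::dist(ctr))
  cand <- which(dm <= cutoff & upper.tri(dm), arr.ind = TRUE)
  rows <- list()
  resKey <- paste(df$source, df$chain, df$resno, df$insert, sep = "\r")
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (df$source[i] == "D" && df$source[j] == "D") next
    if (resKey[i] == resKey[j]) next
    if (length(intersect(ringSet@atomIdx[[i]], ringSet@atomIdx[[j]]))) next
    desc <- pairDescriptors(ctr[i, ], nrm[i, ], ctr[j, ], nrm[j, ])
    ctx <- if (df$source[i] != df$source[j]) "drug-residue"
           else if (df$chain[i] == df$chain[j]) "intra-chain"
           else "inter-chain"
    rows[[length(rows) + 1L]] <- data.frame(
      ring_a = i, ring_b = j, d = desc$d, alpha = desc$alpha,
      theta = desc$theta, theta_a = desc$theta_a, theta_b = desc$theta_b,
      conformation = classifyConformation(desc$alpha, desc$theta,
                                          alphaParallelMax, thetaFtfMax,
                                          alphaTshapeMin),
      context = ctx, stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(pairs) <- NULL
  new("RingInteractionSet", pairs = pairs, cutoff = cutoff,
      thresholds = thresholds)
}
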