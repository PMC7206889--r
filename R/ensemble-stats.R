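#' Radial distribution function of ring-ring distances
#'
#' Histogram of center-center distances on bins of width \code{binWidth}
#' up to \code{rMax}. \code{"frequency"} normalization (the default)
#' renormalizes the counts to sum to 1 so curves from datasets of
#' different size are comparable densities; \code{"shell"} first divides
#' each bin by its spherical-shell volume 4 pi r^2 dr and then
#' renormalizes to mean 1, so uniform-in-volume points give a flat g(r).
#'
#' @param distances numeric vector in (0, rMax]
#' @param binWidth bin width in Angstrom (default 0.1)
#' @param rMax maximum distance (default 7.0, the detection cutoff)
#' @param normalization "frequency" or "shell"
#' @return data.frame with columns r (bin centers) and g
#' @export
rdf <- function(distances, binWidth = 0.1, rMax = 7.0,
                normalization = c("frequency", "shell")) {
  normalization <- match.arg(normalization)
  if (!length(distances)) stop("empty distance set")
  stopifnot(all(distances > 0), all(distances <= rMax + 1e-9))
  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  r <- h$mids
  g <- if (normalization == "frequency") {
    h$counts / sum(h$counts)
  } else {
    w <- h$counts / (4 * pi * r^2 * diff(breaks))
    w / mean(w)
  }
  data.frame(r = r, g = g)
}

#' Boltzmann-inverted free-energy map over (d, alpha)
#'
#' Bins the (distance, planar angle) samples on a regular grid and
#' converts bin populations to relative free energies by Boltzmann
#' inversion,
#' \deqn{\Delta G(bin) = -RT \ln(N_{bin} / N_{max})}
#' with R = 1.987e-3 kcal/(mol K). The most populated bin is the
#' reference (dG = 0); empty bins are NA. dG depends on population
#' ratios only, so duplicating the sample set leaves the map unchanged.
#'
#' @param d,alpha sample vectors (Angstrom / degrees)
#' @param temperature Kelvin (default 298)
#' @param dBin,alphaBin bin widths (default 0.25 Angstrom / 5 degrees)
#' @param dMax,alphaMax grid extents (default 7 Angstrom / 90 degrees)
#' @return list: dMids, alphaMids, counts (matrix d x alpha), dG (same
#'   shape, kcal/mol), temperature
#' @export
energyMap <- function(d, alpha, temperature = 298, dBin = 0.25,
                      alphaBin = 5, dMax = 7.0, alphaMax = 90) {
  stopifnot(length(d) == length(alpha), length(d) >= 1)
  keep <- d > 0 & d <= dMax & alpha >= 0 & alpha <= alphaMax
  d <- d[keep]; alpha <- alpha[keep]
  dBreaks <- seq(0, dMax, by = dBin)
  aBreaks <- seq(0, alphaMax, by = alphaBin)
  di <- findInterval(d, dBreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ai <- findInterval(alpha, aBreaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, length(dBreaks) - 1, length(aBreaks) - 1)
  for (k in seq_along(di))
    counts[di[k], ai[k]] <- counts[di[k], ai[k]] + 1L
  R <- 1.987e-3
  nmax <- max(counts)
  dG <- matrix(NA_real_, nrow(counts), ncol(counts))
  pos <- counts > 0
  dG[pos] <- -R * temperature * log(counts[pos] / nmax)
  list(dMids = dBreaks[-1] - dBin / 2, alphaMids = aBreaks[-1] - alphaBin / 2,
       counts = counts, dG = dG, temperature = temperature)
}

#' Ingest a binding-affinity table to molar Ki
#'
#' Reads a CSV/TSV with an id column and a Ki column; units are taken
#' from a units column or from a unit suffix in the Ki field (nM, uM,
#' mM, M; default molar). Duplicate ids are resolved by geometric mean
#' (with a message); non-positive or unparseable values are skipped with
#' a warning.
#'
#' @param path CSV or TSV file; first column id, a column named ki/Ki
#'   (case-insensitive), optional units column
#' @return named numeric vector, id -> Ki in molar
#' @export
kiIngest <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  kiCol <- grep("^ki$", names(tab), ignore.case = TRUE)
  if (!length(kiCol)) stop("missing Ki column in ", path)
  unitCol <- grep("^units?$", names(tab), ignore.case = TRUE)
  mult <- c(M = 1, MM = 1e-3, UM = 1e-6, NM = 1e-9, PM = 1e-12)
  raw <- as.character(tab[[kiCol[1]]])
  num <- suppressWarnings(as.numeric(sub("^\\s*([-0-9.eE+]+).*$", "\\1", raw)))
  unit <- toupper(gsub("[^a-zA-Z]", "", sub("^\\s*[-0-9.eE+]+", "", raw)))
  if (length(unitCol))
    unit <- ifelse(nzchar(unit), unit, toupper(trimws(tab[[unitCol[1]]])))
  unit <- sub("^µ", "U", unit)
  fac <- mult[ifelse(nzchar(unit), unit, "M")]
  ki <- num * fac
  id <- as.character(tab[[1]])
  bad <- is.na(ki) | ki <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive or unparseable Ki skipped")
    ki <- ki[!bad]; id <- id[!bad]
  }
  if (anyDuplicated(id)) {
    message("duplicate ids resolved by geometric mean")
    ki <- vapply(split(ki, id), function(v) exp(mean(log(v))), 0)
    return(ki)
  }
  stats::setNames(ki, id)
}

#' Stratify binding affinity by aromatic-cluster properties
#'
#' Groups protein-drug complexes by (number of clusters in {1, 2}) x
#' (interaction bins 2-3, 4-5, >= 6), and separately by side-chain
#' exposure of the contacted residues (> 20 percent vs <= 20, strict) and
#' by their secondary-structure class. Per group, reports n, median Ki
#' and geometric-mean Ki; named group pairs are compared with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test on log Ki. Complexes
#' with more than 2 clusters are reported but excluded from the
#' 1-vs-2-cluster comparison; empty groups are reported with n = 0 and
#' no test.
#'
#' @param records data.frame with columns id, ki (molar), n_clusters,
#'   n_interactions, and optionally max_exposure (percent) and ss_class
#' @param exposureThreshold percent (default 20)
#' @return list with \code{groups}, \code{exposure}, \code{ss} summary
#'   data.frames and \code{tests} (pairwise rank-sum p-values)
#' @export
affinityStratify <- function(records, exposureThreshold = 20) {
  stopifnot(all(c("id", "ki", "n_clusters", "n_interactions") %in%
                names(records)))
  stopifnot(all(records$ki > 0))
  ibin <- function(k) ifelse(k >= 6, ">5", ifelse(k >= 4, "4-5",
                      ifelse(k >= 2, "2-3", "<2")))
  rec <- records
  rec$ibin <- ibin(rec$n_interactions)
  inScope <- rec$n_clusters %in% c(1, 2) & rec$ibin != "<2"
  outOfRange <- rec[!inScope, , drop = FALSE]
  gsum <- function(v) c(n = length(v),
                        median_ki = if (length(v)) stats::median(v) else NA,
                        geomean_ki = if (length(v)) exp(mean(log(v))) else NA)
  groups <- expand.grid(n_clusters = c(1, 2), ibin = c("2-3", "4-5", ">5"),
                        stringsAsFactors = FALSE)
  gstats <- t(apply(groups, 1, function(g) {
    v <- rec$ki[inScope & rec$n_clusters == as.numeric(g[["n_clusters"]]) &
                rec$ibin == g[["ibin"]]]
    gsum(v)
  }))
  groups <- cbind(groups, as.data.frame(gstats))
  tests <- list()
  for (b in c("2-3", "4-5", ">5")) {
    k1 <- rec$ki[inScope & rec$n_clusters == 1 & rec$ibin == b]
    k2 <- rec$ki[inScope & rec$n_clusters == 2 & rec$ibin == b]
    if (length(k1) && length(k2))
      tests[[paste0("1cl_vs_2cl_", b)]] <-
        stats::wilcox.test(log(k1), log(k2), exact = FALSE)$p.value
  }
  expoDf <- ssDf <- NULL
  if ("max_exposure" %in% names(records)) {
    hi <- rec$ki[!is.na(rec$max_exposure) &
                 rec$max_exposure > exposureThreshold]
    lo <- rec$ki[!is.na(rec$max_exposure) &
                 rec$max_exposure <= exposureThreshold]
    expoDf <- data.frame(group = c(paste0(">", exposureThreshold, "%"),
                                   paste0("<=", exposureThreshold, "%")),
                         rbind(gsum(hi), gsum(lo)))
    if (length(hi) && length(lo))
      tests[["exposure"]] <-
        stats::wilcox.test(log(hi), log(lo), exact = FALSE)$p.value
  }
  if ("ss_class" %in% names(records)) {
    cls <- c("Helix", "Sheet", "Loop")
    ssDf <- data.frame(group = cls, t(vapply(cls, function(cl)
      gsum(rec$ki[!is.na(rec$ss_class) & rec$ss_class == cl]), numeric(3))))
    for (pair in list(c("Sheet", "Helix"), c("Sheet", "Loop"),
                      c("Helix", "Loop"))) {
      v1 <- rec$ki[!is.na(rec$ss_class) & rec$ss_class == pair[1]]
      v2 <- rec$ki[!is.na(rec$ss_class) & rec$ss_class == pair[2]]
      if (length(v1) && length(v2))
        tests[[paste(pair, collapse = "_vs_")]] <-
          stats::wilcox.test(log(v1), log(v2), exact = FALSE)$p.value
    }
  }
  list(groups = groups, exposure = expoDf, ss = ssDf, tests = tests,
       out_of_range = outOfRange)
}
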