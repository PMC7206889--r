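# Shared helpers: planar molecule construction for ring-perception tests
# and a brute-force union-find oracle for connected components.

# Regular n-gon with the given side length in the z = 0 plane.
polygonCoords <- function(n, side = 1.39, center = c(0, 0)) {
  r <- side / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), 0)
}

# n-gon sharing the directed edge A -> B (2D points), built on the side
# away from `awayFrom`; returns n vertices starting with A, B.
polygonOnEdge <- function(A, B, n, awayFrom) {
  s <- sqrt(sum((B - A)^2))
  mid <- (A + B) / 2
  dirAB <- (B - A) / s
  nrm <- c(-dirAB[2], dirAB[1])
  ap <- s / (2 * tan(pi / n))
  if (sum((mid + ap * nrm - awayFrom)^2) <
      sum((mid - ap * nrm - awayFrom)^2))
    nrm <- -nrm
  ctr <- mid + ap * nrm
  r <- s / (2 * sin(pi / n))
  a0 <- atan2(A[2] - ctr[2], A[1] - ctr[1])
  for (step in c(2 * pi / n, -2 * pi / n)) {
    ang <- a0 + step * (seq_len(n) - 1)
    v <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    if (sum((v[2, ] - B)^2) < 1e-9) return(cbind(v, 0))
  }
  stop("polygonOnEdge failed")
}

# Write a single-het-ligand PDB with CONECT records and read it back.
hetLigandStructure <- function(coords, elems, bondPairs, comp = "LIG") {
  df <- data.frame(record = "HETATM", serial = seq_len(nrow(coords)),
                   name = paste0(elems, seq_len(nrow(coords))),
                   resn = comp, chain = "A", resno = 101L,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   elem = elems, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".pdb")
  writeFixturePDB(df, path, conect = matrix(df$serial[bondPairs], ncol = 2),
                  resolution = 2.0)
  readStructure(path)
}

cycleBonds <- function(n, offset = 0) {
  cbind(offset + seq_len(n), offset + c(seq_len(n)[-1], 1))
}

# Brute-force union-find connected components; returns a list of sorted
# integer vectors (components with >= 2 nodes), sorted by first member.
ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  findRoot <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ri <- findRoot(parent, edges[k, 1]); rj <- findRoot(parent, edges[k, 2])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), function(i) as.integer(findRoot(parent, i)),
                  0L)
  comps <- split(seq_len(n), roots)
  comps <- Filter(function(v) length(v) >= 2, comps)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, 0L, 1))]
}

# Minimal hand-built ring set (all protein benzenes, one per residue) for
# graph-level tests that do not need real coordinates.
fakeRingSet <- function(n, chain = rep("A", n), source = rep("R", n)) {
  new("AromaticRingSet",
      rings = data.frame(
        ring_id = paste0("r", seq_len(n)), source = source,
        type = "benzene", chain = chain, resno = seq_len(n),
        insert = "", resname = ifelse(source == "R", "PHE", "BNZ"),
        rms_dev = 0, stringsAsFactors = FALSE),
      atomIdx = lapply(seq_len(n), function(k) (k - 1) * 6 + 1:6),
      centers = matrix(0, n, 3) + seq_len(n) * 10,
      normals = matrix(rep(c(0, 0, 1), each = n), n, 3),
      structureId = "fake")
}

# Interaction set over a fake ring set from an explicit edge list with
# per-edge context labels.
fakeInteractions <- function(edges, context, cutoff = 7) {
  n <- if (nrow(edges)) nrow(edges) else 0
  pairs <- data.frame(
    ring_a = edges[, 1], ring_b = edges[, 2],
    d = rep(5, n), alpha = rep(0, n), theta = rep(0, n),
    theta_a = rep(0, n), theta_b = rep(0, n),
    conformation = rep("face-to-face", n),
    context = context, stringsAsFactors = FALSE)
  new("RingInteractionSet", pairs = pairs, cutoff = cutoff,
      thresholds = c(alphaParallelMax = 30, thetaFtfMax = 45,
                     alphaTshapeMin = 60))
}

# Kabsch-Sander H-bond energy evaluated directly from coordinates; the
# independent oracle for the secondary-structure tests.
ksEnergyOracle <- function(Nd, Hd, Ca, Oa) {
  27.888 * (1 / sqrt(sum((Oa - Nd)^2)) + 1 / sqrt(sum((Ca - Hd)^2)) -
            1 / sqrt(sum((Oa - Hd)^2)) - 1 / sqrt(sum((Ca - Nd)^2)))
}
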