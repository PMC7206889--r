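test_that("plane fit recovers exact planar geometry and canonical sign", {
  hex <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 2)))
  fit <- planeFit(hex)
  expect_equal(fit$center, c(0, 0, 2), tolerance = 1e-12)
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit$rms_dev, 0, tolerance = 1e-12)
  expect_error(planeFit(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("plane fit matches an eigendecomposition oracle off-plane", {
  hex <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 2)))
  hex[1, 3] <- hex[1, 3] + 0.1
  fit <- planeFit(hex)
  # independent oracle: smallest eigenvector of the covariance matrix
  x <- sweep(hex, 2, colMeans(hex))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  oracle <- ev$vectors[, 3]
  if (oracle[3] < 0) oracle <- -oracle
  expect_equal(fit$normal, oracle, tolerance = 1e-9)
  expect_equal(fit$rms_dev, sqrt(ev$values[3] / nrow(hex)), tolerance = 1e-9)
})

test_that("plane fit is equivariant under rotation", {
  set.seed(7)
  hex <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
  hex[2, 3] <- 0.05                      # slightly non-planar
  f0 <- planeFit(hex)
  for (rep in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    fr <- planeFit(hex %*% t(R))
    expect_equal(fr$center, as.numeric(R %*% f0$center), tolerance = 1e-9)
    nr <- as.numeric(R %*% f0$normal)
    expect_equal(abs(sum(fr$normal * nr)), 1, tolerance = 1e-9)
    expect_equal(fr$rms_dev, f0$rms_dev, tolerance = 1e-9)
  }
})

test_that("protein ring templates give Trp two rings, Phe/Tyr/His one", {
  tri <- readStructure(makeTrimer("Sym"))
  rs <- detectProteinRings(tri)
  expect_equal(nrow(rings(rs)), 3)
  expect_true(all(rings(rs)$type == "benzene"))
  # normals are unit and centers are member-atom centroids
  expect_equal(sqrt(rowSums(ringNormals(rs)^2)), rep(1, 3), tolerance = 1e-12)
  a <- atoms(tri)
  for (k in 1:3) {
    ctr <- colMeans(as.matrix(a[ringAtomIndices(rs)[[k]], c("x", "y", "z")]))
    expect_equal(as.numeric(ringCenters(rs)[k, ]), as.numeric(ctr),
                 tolerance = 1e-12)
  }
})

test_that("incomplete ring templates are skipped with a warning", {
  path <- makeDimer(4, 0, 0)
  lines <- readLines(path)
  lines <- lines[!grepl("^ATOM.* CZ ", lines)]   # drop PHE CZ
  writeLines(lines, path)
  s <- readStructure(path)
  expect_warning(rs <- detectProteinRings(s), "incomplete")
  expect_equal(nrow(rings(rs)), 0)
})

test_that("bond inference follows covalent radii with 0.4 A tolerance", {
  df <- data.frame(elem = c("C", "C"), x = c(0, 1.39), y = 0, z = 0)
  expect_equal(nrow(inferBonds(df)), 1)          # 1.39 <= 0.76+0.76+0.40
  df$x[2] <- 2.5
  expect_equal(nrow(inferBonds(df)), 0)
  expect_equal(nrow(inferBonds(df[1, , drop = FALSE])), 0)
})

test_that("ligand perception counts rings of fused and linked systems", {
  # biphenyl: two benzenes joined by a single bond -> 2 rings, 13 bonds
  r1 <- polygonCoords(6, 1.39, c(0, 0))
  shift <- 2 * 1.39 + 1.48
  r2 <- polygonCoords(6, 1.39, c(shift, 0))
  coords <- rbind(r1, r2)
  bondsBi <- rbind(cycleBonds(6), cycleBonds(6, 6),
                   c(1, 6 + which.min(r2[, 1] - shift)))
  # link the two closest atoms across rings
  iA <- which.max(r1[, 1]); iB <- 6 + which.min(r2[, 1])
  bondsBi[13, ] <- c(iA, iB)
  s <- hetLigandStructure(coords, rep("C", 12), bondsBi, comp = "BIP")
  li <- ligandInstances(s)[[1]]
  expect_equal(nrow(li$bonds), 13)
  rl <- detectLigandRings(s, li)
  expect_length(rl, 2)
  expect_true(all(vapply(rl, `[[`, "", "type") == "benzene"))

  # indole: fused 6+5 -> 2 rings, counted individually
  hexv <- polygonOnEdge(c(0, 0), c(1.39, 0), 6, awayFrom = c(0.7, 1))
  pentv <- polygonOnEdge(c(1.39, 0), c(0, 0), 5, awayFrom = c(0.7, -1))
  coords <- rbind(hexv, pentv[3:5, ])
  elems <- c(rep("C", 6), "C", "N", "C")
  bondsIn <- rbind(cycleBonds(6),
                   c(2, 7), c(7, 8), c(8, 9), c(9, 1))
  s2 <- hetLigandStructure(coords, elems, bondsIn, comp = "IND")
  rl2 <- detectLigandRings(s2, ligandInstances(s2)[[1]])
  expect_length(rl2, 2)
  expect_setequal(vapply(rl2, `[[`, "", "type"), c("benzene", "pyrrole"))
})

test_that("non-planar rings are rejected by the planarity threshold", {
  # ideal cyclohexane chair: out-of-plane rms 0.25 A > 0.10 A threshold
  q <- 0.25; r <- sqrt(1.54^2 - 4 * q^2)
  ang <- 2 * pi * (0:5) / 6
  chair <- cbind(r * cos(ang), r * sin(ang), q * c(1, -1, 1, -1, 1, -1))
  expect_equal(planeFit(chair)$rms_dev, 0.25, tolerance = 1e-9)
  s <- hetLigandStructure(chair, rep("C", 6), cycleBonds(6), comp = "CHX")
  expect_length(detectLigandRings(s, ligandInstances(s)[[1]]), 0)
})

test_that("perception matches toolkit aromatic-ring counts on the panel", {
  # expected counts frozen from RDKit aromatic-ring perception
  pent <- function(elems, comp) {
    s <- hetLigandStructure(polygonCoords(5, 1.39), elems, cycleBonds(5),
                            comp)
    length(detectLigandRings(s, ligandInstances(s)[[1]]))
  }
  hexa <- function(elems, comp) {
    s <- hetLigandStructure(polygonCoords(6, 1.39), elems, cycleBonds(6),
                            comp)
    length(detectLigandRings(s, ligandInstances(s)[[1]]))
  }
  expect_equal(hexa(rep("C", 6), "BNZ"), 1)                   # benzene
  expect_equal(hexa(c("N", rep("C", 5)), "PYR"), 1)           # pyridine
  expect_equal(hexa(c("N", "C", "N", "C", "C", "C"), "PMD"), 1) # pyrimidine
  expect_equal(pent(c("N", "C", "N", "C", "C"), "IMZ"), 1)    # imidazole
  expect_equal(pent(c("N", rep("C", 4)), "PRL"), 1)           # pyrrole
  expect_equal(pent(c("O", rep("C", 4)), "FUR"), 1)           # furan
  expect_equal(pent(c("S", rep("C", 4)), "THP"), 1)           # thiophene
  # phenol: hydroxyl substituent does not break the ring
  coords <- rbind(polygonCoords(6), c(0, 2.75, 0))
  s <- hetLigandStructure(coords, c(rep("C", 6), "O"),
                          rbind(cycleBonds(6), c(1, 7)), comp = "IPH")
  expect_length(detectLigandRings(s, ligandInstances(s)[[1]]), 1)
  # naphthalene: fused 6+6 -> 2 rings
  hexv <- polygonOnEdge(c(0, 0), c(1.39, 0), 6, awayFrom = c(0.7, 1))
  hex2 <- polygonOnEdge(c(1.39, 0), c(0, 0), 6, awayFrom = c(0.7, -1))
  coords <- rbind(hexv, hex2[3:6, ])
  bondsN <- rbind(cycleBonds(6), c(2, 7), c(7, 8), c(8, 9), c(9, 10),
                  c(10, 1))
  s <- hetLigandStructure(coords, rep("C", 10), bondsN, comp = "NAP")
  expect_length(detectLigandRings(s, ligandInstances(s)[[1]]), 2)
})

test_that("ligand ring enumeration agrees with exhaustive cycle search", {
  # all simple cycles of length 5-6 by DFS, on every panel-sized ligand
  exhaustiveCycles <- function(n, edges) {
    adj <- lapply(seq_len(n), function(i)
      c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
    found <- character()
    path <- integer()
    dfs <- function(v, start, depth) {
      path[depth] <<- v
      for (w in adj[[v]]) {
        if (w == start && depth >= 3) {
          cyc <- sort(path[seq_len(depth)])
          if (length(cyc) %in% 5:6)
            found <<- union(found, paste(cyc, collapse = ","))
        } else if (!(w %in% path[seq_len(depth)]) && depth < 6) {
          dfs(w, start, depth + 1)
        }
      }
    }
    for (v in seq_len(n)) dfs(v, v, 1)
    found
  }
  hexv <- polygonOnEdge(c(0, 0), c(1.39, 0), 6, awayFrom = c(0.7, 1))
  hex2 <- polygonOnEdge(c(1.39, 0), c(0, 0), 6, awayFrom = c(0.7, -1))
  napC <- rbind(hexv, hex2[3:6, ])
  napB <- rbind(cycleBonds(6), c(2, 7), c(7, 8), c(8, 9), c(9, 10), c(10, 1))
  cases <- list(
    list(n = 6, bonds = cycleBonds(6)),
    list(n = 10, bonds = napB),
    list(n = 12, bonds = rbind(cycleBonds(6), cycleBonds(6, 6), c(1, 7))))
  for (cs in cases) {
    mine <- aroclust:::.smallestRings(cs$n, cs$bonds)
    mineKeys <- sort(vapply(mine, function(v) paste(sort(v), collapse = ","),
                            ""))
    expect_equal(mineKeys, sort(exhaustiveCycles(cs$n, cs$bonds)))
  }
})
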