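test_that("ideal helix torsions create i->i+4 H-bonds below threshold", {
  # oracle: evaluate the electrostatic energy directly from coordinates
  p <- buildPeptide(12, phi = -57, psi = -47)
  getXYZ <- function(name, resno)
    as.numeric(p[p$name == name & p$resno == resno, c("x", "y", "z")])
  for (i in 1:7) {
    Ca <- getXYZ("C", i); Oa <- getXYZ("O", i)
    Nd <- getXYZ("N", i + 4)
    Cprev <- getXYZ("C", i + 3); Oprev <- getXYZ("O", i + 3)
    Hd <- Nd + 1.01 * (Cprev - Oprev) / sqrt(sum((Cprev - Oprev)^2))
    expect_lt(ksEnergyOracle(Nd, Hd, Ca, Oa), -0.5)
  }
  path <- tempfile(fileext = ".pdb")
  writeFixturePDB(p, path)
  ss <- assignSS(readStructure(path), "internal")
  expect_true(all(ss[paste0("A:", 3:10, ":")] == "Helix"))
})

test_that("antiparallel strand pair cores are Sheet, lone strand is Loop", {
  ss <- assignSS(readStructure(makeSheetFixture(8)), "internal")
  expect_true(all(ss[paste0("A:", 3:5, ":")] == "Sheet"))
  expect_true(all(ss[paste0("A:", 21:24, ":")] == "Sheet"))
  # an isolated extended strand has no H-bond partner: all Loop
  lone <- tempfile(fileext = ".pdb")
  writeFixturePDB(buildPeptide(8, phi = -139, psi = 135), lone)
  ssLone <- assignSS(readStructure(lone), "internal")
  expect_true(all(ssLone == "Loop"))
})

test_that("residues missing backbone atoms fall back to Loop", {
  p <- buildPeptide(6, phi = -57, psi = -47)
  p <- p[!(p$resno == 3 & p$name == "O"), ]
  path <- tempfile(fileext = ".pdb")
  writeFixturePDB(p, path)
  expect_warning(ss <- assignSS(readStructure(path), "internal"),
                 "missing backbone")
  expect_equal(unname(ss["A:3:"]), "Loop")
})

test_that("DSSP files map 8 states onto 3 classes", {
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N"
  row <- function(i, chain, aa, code)
    sprintf("%5d%5d %s %s  %s", i, i, chain, aa, code)
  lines <- c("==== Secondary Structure Definition ====", hdr,
             row(1, "A", "A", "H"), row(2, "A", "A", "G"),
             row(3, "A", "A", "I"), row(4, "A", "A", "E"),
             row(5, "A", "A", "B"), row(6, "A", "A", "T"),
             row(7, "A", "A", "S"), row(8, "A", "A", " "))
  path <- tempfile(fileext = ".dssp")
  writeLines(lines, path)
  d <- readDSSP(path)
  expect_equal(unname(d[paste0("A:", 1:3, ":")]), rep("Helix", 3))
  expect_equal(unname(d[paste0("A:", 4:5, ":")]), rep("Sheet", 2))
  expect_equal(unname(d[paste0("A:", 6:8, ":")]), rep("Loop", 3))
})

test_that("internal mode reaches 85% agreement with the bundled reference", {
  pdb <- system.file("extdata", "synthetic_ref_protein.pdb",
                     package = "aroclust")
  ref <- utils::read.table(
    system.file("extdata", "synthetic_ref_protein_dssp.tsv",
                package = "aroclust"), header = TRUE, sep = "\t")
  refv <- stats::setNames(ref$class,
                          paste0(ref$chain, ":", ref$resno, ":"))
  ss <- assignSS(readStructure(pdb), "internal")
  common <- intersect(names(ss), names(refv))
  expect_gte(length(common), 25)
  expect_gte(mean(ss[common] == refv[common]), 0.85)
})

test_that("preference log-odds satisfy the independence and ratio anchors", {
  # independence: conditional equals background -> 0 everywhere
  counts <- rbind(ctx1 = c(30, 20, 50), ctx2 = c(60, 40, 100))
  colnames(counts) <- c("Helix", "Sheet", "Loop")
  pt <- preferenceTable(counts)
  expect_equal(unname(pt), matrix(0, 2, 3), tolerance = 1e-12)
  # doubled conditional -> log10 2
  pt2 <- preferenceTable(rbind(a = c(60, 40)),
                         background = c(0.3, 0.7))
  expect_equal(unname(pt2[1, 1]), log10(2), tolerance = 1e-12)
  # direct evaluation of the published example shape
  pt3 <- preferenceTable(rbind(sheet = c(30, 10, 60)),
                         background = c(0.3, 0.2, 0.5))
  expect_equal(unname(pt3[1, 1]), 0, tolerance = 1e-12)
  # enrichment positive, depletion negative
  pt4 <- preferenceTable(rbind(x = c(80, 20)), background = c(0.5, 0.5))
  expect_gt(pt4[1, 1], 0)
  expect_lt(pt4[1, 2], 0)
  # zero cells get Jeffreys smoothing with a message
  expect_message(preferenceTable(rbind(x = c(0, 10))), "Jeffreys")
})

test_that("preference of independent draws shrinks toward zero", {
  set.seed(99)
  bg <- c(Helix = 0.4, Sheet = 0.25, Loop = 0.35)
  maxAbs <- function(n) {
    ctx <- sample(names(bg), n, replace = TRUE, prob = bg)
    prt <- sample(names(bg), n, replace = TRUE, prob = bg)
    counts <- unclass(table(ctx, prt))
    max(abs(preferenceTable(counts, background = bg[colnames(counts)])))
  }
  small <- maxAbs(300)
  large <- maxAbs(30000)
  expect_lt(large, small)
  expect_lt(large, 0.05)
})

test_that("header mode assigns classes from HELIX/SHEET records", {
  p <- buildPeptide(10, phi = -57, psi = -47)
  path <- tempfile(fileext = ".pdb")
  writeFixturePDB(p, path)
  lines <- readLines(path)
  hel <- sprintf("HELIX    1   1 ALA A    2  ALA A    5  1%36d", 4)
  she <- sprintf("SHEET    1   A 1 ALA A   7  ALA A   8  0%s", "")
  writeLines(c(hel, she, lines), path)
  ss <- assignSS(readStructure(path), "header")
  expect_true(all(ss[paste0("A:", 2:5, ":")] == "Helix"))
  expect_true(all(ss[paste0("A:", 7:8, ":")] == "Sheet"))
  expect_equal(unname(ss["A:1:"]), "Loop")
})
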