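test_that("rdf normalizations behave as densities", {
  # point mass: one occupied bin
  r1 <- rdf(rep(3.75, 100))
  expect_equal(sum(r1$g > 0), 1)
  expect_equal(r1$r[r1$g > 0], 3.75, tolerance = 0.05)
  expect_equal(sum(r1$g), 1, tolerance = 1e-9)
  expect_error(rdf(numeric()), "empty")
  # frequency mode always sums to 1
  set.seed(3)
  r2 <- rdf(runif(5000, 1, 7))
  expect_equal(sum(r2$g), 1, tolerance = 1e-9)
})

test_that("shell-normalized rdf of uniform-in-volume points is flat", {
  set.seed(17)
  n <- 1e5
  r <- 7 * runif(n)^(1 / 3)          # uniform density in a ball
  out <- rdf(r, binWidth = 0.5, rMax = 7, normalization = "shell")
  # the estimator divides by 4 pi r_mid^2 dr, not the exact shell volume;
  # fold that discretization factor into the expectation, then compare
  # each bin within ~5 relative MC standard errors
  breaks <- seq(0, 7, 0.5)
  expCount <- n * diff(breaks^3) / 7^3
  shape <- diff(breaks^3) / 3 / (out$r^2 * 0.5)
  gExp <- shape / mean(shape)
  keep <- expCount > 50
  relErr <- abs(out$g[keep] - gExp[keep]) / gExp[keep]
  expect_true(all(relErr < 5 / sqrt(expCount[keep])))
})

test_that("Boltzmann inversion reproduces the closed-form bin ratio", {
  # a 10:1 population ratio at 298 K costs RT ln 10 = 1.363 kcal/mol
  d <- c(rep(3.6, 100), rep(5.1, 10))
  alpha <- c(rep(2, 100), rep(70, 10))
  em <- energyMap(d, alpha)
  expect_equal(min(em$dG, na.rm = TRUE), 0)
  expect_equal(max(em$dG, na.rm = TRUE), 1.987e-3 * 298 * log(10),
               tolerance = 1e-9)
  expect_equal(round(1.987e-3 * 298 * log(10), 3), 1.363)
  # invariance under duplication of the sample set
  em2 <- energyMap(rep(d, 2), rep(alpha, 2))
  expect_equal(em2$dG, em$dG)
})

test_that("energy map recovers the two generator modes", {
  comp <- list(list(d = 5.0, alpha = 75, weight = 0.6, sd_d = 0.3,
                    sd_alpha = 8),
               list(d = 3.75, alpha = 0, weight = 0.4, sd_d = 0.15,
                    sd_alpha = 8))
  sam <- sampleEnsemble(comp, n = 5e4, seed = 20)
  em <- energyMap(sam$d, sam$alpha)
  # global minimum: the denser (stacking) mode
  gmin <- which(em$dG == 0, arr.ind = TRUE)
  expect_lte(abs(em$dMids[gmin[1]] - 3.75), 0.25)
  expect_lte(abs(em$alphaMids[gmin[2]] - 0), 5)
  # second mode: minimum over the d > 4.5 region
  sub <- em$dG[em$dMids > 4.5, , drop = FALSE]
  smin <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lte(abs(em$dMids[em$dMids > 4.5][smin[1]] - 5.0), 0.25)
  expect_lte(abs(em$alphaMids[smin[2]] - 75), 5)
})

test_that("ensemble sampler is reproducible and matches its recipe", {
  comp <- list(list(d = 5.0, alpha = 75, weight = 0.6, sd_d = 0.3,
                    sd_alpha = 8),
               list(d = 3.75, alpha = 0, weight = 0.4, sd_d = 0.15,
                    sd_alpha = 8))
  a <- sampleEnsemble(comp, 1e4, seed = 8)
  b <- sampleEnsemble(comp, 1e4, seed = 8)
  expect_identical(a, b)
  # component counts within 3 binomial SE of 6000/4000
  n1 <- sum(a$component == 1)
  expect_lt(abs(n1 - 6000), 3 * sqrt(1e4 * 0.6 * 0.4))
  # component means within 3 SE (alpha of the folded mode is half-normal;
  # only the unfolded T-shape mode is checked against its mean)
  m1 <- a[a$component == 1, ]
  expect_lt(abs(mean(m1$d) - 5.0), 3 * 0.3 / sqrt(nrow(m1)))
  expect_lt(abs(mean(m1$alpha) - 75), 3 * 8 / sqrt(nrow(m1)))
  expect_true(all(a$alpha >= 0 & a$alpha <= 90))
  expect_true(all(a$d > 0))
})

test_that("Ki ingestion converts units and resolves duplicates", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,ki", "c1,5 nM", "c2,2 uM", "c3,0.001", "c4,1 nM",
               "c4,100 nM"), path)
  expect_message(ki <- kiIngest(path), "geometric mean")
  expect_equal(unname(ki["c1"]), 5e-9)
  expect_equal(unname(ki["c2"]), 2e-6)
  expect_equal(unname(ki["c3"]), 1e-3)    # no unit: molar
  expect_equal(unname(ki["c4"]), 1e-8)    # geomean(1, 100) nM = 10 nM
  # separate units column
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("id,ki,units", "c1,5,nM"), p2)
  expect_equal(unname(kiIngest(p2)["c1"]), 5e-9)
  # bad rows skipped with warning, missing column errors
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("id,ki", "c1,-4", "c2,abc", "c3,1 nM"), p3)
  expect_warning(k3 <- kiIngest(p3), "skipped")
  expect_equal(names(k3), "c3")
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("id,affinity", "c1,5"), p4)
  expect_error(kiIngest(p4), "Ki column")
})

test_that("affinity strata partition records and test group contrasts", {
  rec <- data.frame(
    id = paste0("c", 1:8),
    ki = c(1e-6, 2e-6, 5e-7, 1e-7, 2e-7, 5e-8, 1e-8, 1e-5),
    n_clusters = c(1, 1, 1, 2, 2, 2, 2, 3),
    n_interactions = c(3, 4, 7, 3, 2, 5, 6, 4),
    max_exposure = c(25, 20.0, 15, 30, 10, 50, 18, 22),
    ss_class = c("Loop", "Helix", "Sheet", "Loop", "Helix", "Sheet",
                 "Loop", "Helix"))
  out <- affinityStratify(rec)
  g <- out$groups
  # record with 2 clusters and 3 interactions lands in (2, "2-3")
  expect_equal(g$n[g$n_clusters == 2 & g$ibin == "2-3"], 2)  # c4 and c5
  expect_equal(g$n[g$n_clusters == 1 & g$ibin == ">5"], 1)   # c3 (7)
  # >2 clusters reported out of scope, not silently grouped
  expect_equal(out$out_of_range$id, "c8")
  expect_equal(sum(g$n) + nrow(out$out_of_range), nrow(rec))
  # exposure exactly 20.0 goes to the <= 20 group (strict "more than")
  expect_equal(out$exposure$n[out$exposure$group == ">20%"], 4)
  expect_equal(out$exposure$n[out$exposure$group == "<=20%"], 4)
  # identical Ki sets give rank-sum p = 1
  same <- data.frame(id = paste0("s", 1:6),
                     ki = rep(c(1e-6, 1e-7, 1e-8), 2),
                     n_clusters = rep(c(1, 2), each = 3),
                     n_interactions = rep(3, 6))
  p <- affinityStratify(same)$tests[["1cl_vs_2cl_2-3"]]
  expect_equal(p, 1, tolerance = 0.01)
  # median ordering is invariant to log-scaling of Ki
  expect_equal(order(out$groups$median_ki),
               order(log(out$groups$median_ki)))
})
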