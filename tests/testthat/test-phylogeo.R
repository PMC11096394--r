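test_that("presence matrices are binary with retained counts", {
  hs <- parseVariantString(c(a = "126", b = "239", c = "126"),
                           region = c("TF", "GC", "GC"))
  m <- buildPresenceMatrix(hs)
  expect_setequal(colnames(m), c("TF", "GC"))
  expect_true(all(m %in% 0:1))
  expect_equal(m["16126", "TF"], 1)
  expect_equal(m["16126", "GC"], 1)
  expect_equal(attr(m, "counts")["16126", "GC"], 1L)
  expect_error(buildPresenceMatrix(hs, populations = c("TF", "TF")),
               "duplicate")

  everywhere <- parseVariantString(rep("126", 3), ids = paste0("h", 1:3),
                                   region = c("A", "B", "C"))
  expect_true(all(buildPresenceMatrix(everywhere) == 1))
})

test_that("Venn partitions conserve the number of haplotypes", {
  m <- matrix(c(1, 0, 1, 1,
                0, 1, 1, 0,
                0, 0, 1, 0), ncol = 3,
              dimnames = list(c("h1", "h2", "h3", "h4"),
                              c("EU", "NAf", "SA")))
  v <- vennPartition(m, list(EU = "EU", NAf = "NAf", SA = "SA"))
  expect_equal(sum(v), nrow(m))
  expect_equal(unname(v["EU&NAf&SA"]), 1L)   # h3 present everywhere
  expect_equal(unname(v["EU"]), 2L)          # h1, h4 private to Europe
  expect_equal(unname(v["NAf"]), 1L)
  expect_equal(unname(v["none"]), 0L)

  priv <- matrix(c(1, 1, 0, 0), ncol = 2,
                 dimnames = list(c("a", "b"), c("G1", "G2")))
  vp <- vennPartition(priv, list(G1 = "G1", G2 = "G2"))
  expect_equal(unname(vp["G1"]), 2L)
  expect_equal(unname(vp["G2"]), 0L)
  expect_error(vennPartition(priv, list(G1 = "G1", G2 = character(0))),
               "empty")

  ## a matrix with exactly 14 Europe-only haplotypes reports |EU-only| = 14
  big <- matrix(0L, 20, 3, dimnames = list(paste0("x", 1:20),
                                           c("EU", "NAf", "SA")))
  big[1:14, "EU"] <- 1L
  big[15:20, c("EU", "NAf")] <- 1L
  vb <- vennPartition(big, list(EU = "EU", NAf = "NAf", SA = "SA"))
  expect_equal(unname(vb["EU"]), 14L)
})

test_that("persistence fractions report both denominators", {
  expect_equal(unname(persistenceFraction(c("a", "b"), c("a", "b"))),
               c(1, 1))
  expect_equal(unname(persistenceFraction(c("a", "b"), c("c", "d"))),
               c(0, 0))
  ind <- c("a", "b", "c", "d")
  later <- c("a", "b", paste0("z", 1:6))
  expect_equal(unname(persistenceFraction(ind, later)), c(0.25, 0.5))
  expect_error(persistenceFraction(ind, character(0)), "empty")
})

test_that("exclusive-region labels follow the printed asterisk convention", {
  m3 <- loadMatchCountTable(pkgFile("table3_matches.tsv"))
  pm <- buildPresenceMatrix(m3)
  lab <- exclusiveRegionLabels(pm, list(Europe = c("IP", "FR", "IT"),
                                        NorthAfrica = c("NW", "NA")))
  expect_equal(sum(lab == "Europe"), 7)
  t3 <- utils::read.delim(pkgFile("table3_matches.tsv"))
  ast <- attr(m3, "haplotypes")$key[t3$asterisk == 1]
  expect_true(all(lab[ast] == "Europe"))

  toy <- matrix(c(1, 1, 0,
                  1, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("h1", "h2"), c("IP", "IT", "NW")))
  lt <- exclusiveRegionLabels(toy, list(Europe = c("IP", "IT"),
                                        NorthAfrica = "NW"))
  expect_identical(unname(lt), c("Europe", "shared"))
  none <- matrix(0L, 1, 3, dimnames = list("h", c("IP", "IT", "NW")))
  expect_identical(unname(exclusiveRegionLabels(none,
    list(Europe = c("IP", "IT"), NorthAfrica = "NW"))), "none")
})

test_that("match-based distances behave as a semimetric in both modes", {
  m <- matrix(c(1, 1, 1, 0, 0, 0,
                1, 1, 0, 0, 1, 1,
                1, 1, 1, 1, 0, 0), ncol = 3,
              dimnames = list(paste0("h", 1:6), c("A", "B", "C")))
  ## |A|=3, |B|=4, |A sect B|=2 in a hand-built case
  hand <- matrix(0L, 8, 2, dimnames = list(paste0("h", 1:8), c("P", "Q")))
  hand[1:4, "P"] <- 1L
  hand[3:8, "Q"] <- 1L
  d <- matchDistance(hand)
  expect_equal(d["P", "Q"], 1 - 2 / 8)
  dmin <- matchDistance(hand, method = "min")
  expect_equal(dmin["P", "Q"], 1 - 2 / 4)

  d3 <- matchDistance(m)
  expect_true(isSymmetric(unname(d3)))
  expect_true(all(diag(d3) == 0))
  same <- cbind(m, D = m[, "A"])
  expect_equal(matchDistance(same)["A", "D"], 0)
  expect_error(matchDistance(cbind(m, E = 0L)), "empty")

  ## shared_indigenous mode restricts the rows considered
  ds <- matchDistance(m, mode = "shared_indigenous",
                      indigenousKeys = paste0("h", 1:2))
  expect_equal(ds["A", "B"], 0)
})

test_that("principal coordinates reproduce Euclidean geometry", {
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  fit <- pcoaAnalysis(two, k = 1)
  expect_equal(abs(diff(fit$coordinates[, 1])), 1, tolerance = 1e-12)

  tri <- matrix(1, 3, 3) - diag(3)
  ft <- pcoaAnalysis(tri, k = 2)
  pos <- ft$eigenvalues[ft$eigenvalues > 1e-9]
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  set.seed(9)
  for (rep in 1:5) {
    pts <- matrix(rnorm(2 * 12), ncol = 2)
    d <- as.matrix(dist(pts))
    fit <- pcoaAnalysis(d, k = 2)
    emb <- as.matrix(dist(fit$coordinates))
    expect_lt(max(abs(emb - d)), 1e-9)
    ## eigenvalue sum equals the total centered dispersion
    g <- -0.5 * d^2
    g <- sweep(sweep(g, 1, rowMeans(g)), 2, colMeans(g)) + mean(g)
    expect_equal(sum(fit$eigenvalues), sum(diag(g)), tolerance = 1e-8)
  }
  expect_error(pcoaAnalysis(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("exact tests agree with enumeration oracles and closed forms", {
  expect_lt(fisherExact2x2(matrix(c(0, 25, 25, 0), 2, 2)), 1e-10)
  expect_equal(fisherExact2x2(matrix(1, 2, 2)), 1)
  expect_error(fisherExact2x2(c(-1, 2, 3, 4)), "nonnegative")
  tab <- matrix(c(13, 3, 36, 46), 2, 2)
  expect_equal(fisherExact2x2(tab), fisherOracle(tab), tolerance = 1e-12)

  set.seed(4)
  for (rep in 1:40) {
    t4 <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisherExact2x2(t4), fisherOracle(t4), tolerance = 1e-12)
  }

  expect_equal(signTest(5, 5), 1)
  expect_equal(signTest(10, 0), 2 * 0.5^10)
  for (rep in 1:40) {
    pn <- rpois(2, 8)
    if (sum(pn) == 0) pn <- c(1, 0)
    expect_equal(signTest(pn[1], pn[2]), signOracle(pn[1], pn[2]),
                 tolerance = 1e-12)
  }
})

test_that("the Welch statistic matches an independent implementation", {
  a <- c(2333, 2185, 1600, 1700, 1560)
  b <- c(950, 880, 820)
  ours <- welchTTest(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)

  expect_equal(welchTTest(c(1, 1, 1), c(1, 1))$p.value, 1)
  expect_equal(welchTTest(c(1, 1, 1), c(2, 2))$p.value, 0)
  expect_lt(welchTTest(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))$p.value,
            1e-3)

  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), 0.5)
    expect_equal(welchTTest(x, y)$p.value, stats::t.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})
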