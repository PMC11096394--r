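test_that("simulated motif panels are deterministic with unique motifs", {
  cfg <- simConfig(seed = 5, nHaplogroups = 20)
  p1 <- simulateMotifPanel(cfg)
  p2 <- simulateMotifPanel(cfg)
  expect_identical(privateMotifs(p1), privateMotifs(p2))
  expect_identical(panelParents(p1), panelParents(p2))

  motifs <- vapply(panelLabels(p1), function(hg)
    paste(cumulativeMotif(p1, hg), collapse = " "), character(1))
  expect_false(anyDuplicated(motifs) > 0)

  single <- simulateMotifPanel(simConfig(seed = 1, nHaplogroups = 1))
  expect_equal(length(single), 1L)
  expect_identical(panelRoot(single), "ROOT")

  ## more required variants than positions
  tiny_window <- simConfig(seed = 2, nHaplogroups = 40,
                           window = c(16001L, 16012L))
  expect_error(simulateMotifPanel(tiny_window), "positions")
})

test_that("island populations drift from their founder pools deterministically", {
  cfg <- simConfig(seed = 6, nHaplogroups = 15)
  panel <- simulateMotifPanel(cfg)
  pop1 <- simulateIslandPopulations(panel, cfg)
  pop2 <- simulateIslandPopulations(panel, cfg)
  expect_identical(variantSets(pop1$haplotypes),
                   variantSets(pop2$haplotypes))

  hs <- pop1$haplotypes
  expect_setequal(unique(unname(epochLabels(hs))),
                  c("indigenous", "historic", "current"))
  expect_equal(sum(epochLabels(hs) == "indigenous"),
               sum(cfg@islands$sampleSize))

  ## without immigration, later epochs only contain island haplogroups
  closed <- simConfig(seed = 6, nHaplogroups = 15,
                      historicImmigration = 0, currentImmigration = 0)
  popc <- simulateIslandPopulations(panel, closed)
  for (isl in cfg@islands$name) {
    onisl <- popc$haplotypes[regionLabels(popc$haplotypes) == isl]
    pool <- names(popc$islandFrequencies[[isl]])[
      popc$islandFrequencies[[isl]] > 0]
    expect_true(all(haplogroupLabels(onisl) %in% pool), info = isl)
  }

  ## zero drift generations: island frequencies equal the founder sample
  nodrift <- simConfig(seed = 8, nHaplogroups = 10)
  nodrift@islands$driftGenerations <- 0L
  popn <- simulateIslandPopulations(panel, nodrift)
  f <- popn$islandFrequencies[[1]]
  expect_equal(sum(f), 1)
  ## founder sample of size n: frequencies are multiples of 1/n
  expect_true(all(abs(f * nodrift@islands$founders[1] -
                      round(f * nodrift@islands$founders[1])) < 1e-9))

  ## drift erodes haplotype diversity in expectation
  rich <- function(gens, seed) {
    cfg2 <- simConfig(seed = seed, nHaplogroups = 25)
    cfg2@islands$driftGenerations <- gens
    p <- simulateMotifPanel(cfg2)
    pp <- simulateIslandPopulations(p, cfg2)
    ind <- pp$haplotypes[epochLabels(pp$haplotypes) == "indigenous"]
    length(unique(canonicalKeys(ind)))
  }
  r0 <- mean(vapply(1:3, function(s) rich(0L, s), numeric(1)))
  r60 <- mean(vapply(1:3, function(s) rich(60L, s), numeric(1)))
  expect_gt(r0, r60)
})

test_that("artefact injection records exact truth and respects zero rates", {
  cfg <- simConfig(seed = 9, nHaplogroups = 15)
  panel <- simulateMotifPanel(cfg)
  pop <- simulateIslandPopulations(panel, cfg)
  ind <- pop$haplotypes[epochLabels(pop$haplotypes) == "indigenous"]

  none <- simConfig(seed = 9, chimeraRate = 0, dropoutRate = 0,
                    phantomSites = 0L)
  un <- injectArtifacts(ind, panel, none)
  expect_identical(variantSets(un$haplotypes), variantSets(ind))
  expect_true(all(un$truth$truth == "clean"))

  inj <- injectArtifacts(ind, panel, cfg)
  expect_setequal(inj$truth$id, hapIds(ind))
  expect_true(all(inj$truth$truth %in% c("clean", "chimera", "incomplete",
                                         "phantom")))
  ## every recorded chimera actually carries foreign variants
  chim <- inj$truth$id[inj$truth$truth == "chimera"]
  for (id in chim) {
    i <- match(id, hapIds(ind))
    expect_gt(length(setdiff(variantSets(inj$haplotypes)[[i]],
                             variantSets(ind)[[i]])), 0)
  }
})

test_that("forced chimeras between disjoint motifs decompose at cost zero", {
  panel <- tinyPanel()
  hs <- HaplotypeSet(c("x1", "x2"),
                     list(cumulativeMotif(panel, "A1a"),
                          cumulativeMotif(panel, "C1")))
  n_chim <- 0L; n_full <- 0L
  for (s in 10:40) {
    if (n_full > 0L && n_chim > 2L) break
    cfg <- simConfig(seed = s, chimeraRate = 1, dropoutRate = 0,
                     phantomSites = 0L)
    inj <- injectArtifacts(hs, panel, cfg)
    for (i in which(inj$truth$truth == "chimera")) {
      n_chim <- n_chim + 1L
      h <- assignHaplogroups(inj$haplotypes[i], panel)
      dec <- decomposeChimera(h, panel)
      v <- variantSets(inj$haplotypes)[[i]]
      expect_identical(verdict(dec), "chimera")
      ## decomposition cost always matches the exhaustive oracle; a swap
      ## transplanting the donor's complete motif decomposes at cost 0
      expect_equal(dec@score, bruteDecompose(sort(v), panel))
      if (setequal(v, union(cumulativeMotif(panel, "A1a"),
                            cumulativeMotif(panel, "C1")))) {
        n_full <- n_full + 1L
        expect_equal(dec@score, 0)
      }
    }
  }
  expect_gt(n_chim, 0L)
  expect_gt(n_full, 0L)
})

test_that("star clades follow the Poisson mutation model", {
  z <- simulateClade(0, 10, "star", nSites = 100, seed = 1)
  expect_equal(rhoStatistic(z$clade), 0)

  big <- simulateClade(1400, 10000, "star", nSites = 16000, seed = 2)
  counts <- vapply(big$clade@members, length, integer(1))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 10000))

  a <- simulateClade(1000, 20, "star", nSites = 300, seed = 3)
  b <- simulateClade(1000, 20, "star", nSites = 300, seed = 3)
  expect_identical(a$clade@members, b$clade@members)

  expect_error(simulateClade(1e7, 5, "star", nSites = 100),
               "infinite-sites")
})

test_that("coalescent clades date near but below the star expectation", {
  set.seed(31)
  ages <- vapply(1:30, function(i) {
    sim <- simulateClade(2000, 30, "coalescent", nSites = 2000,
                         seed = 400 + i)
    rhoStatistic(sim$clade) * 1400
  }, numeric(1))
  ## the rescaled Kingman tree is ultrametric with root height T, so
  ## rho*clock is unbiased for T; genealogical correlation only inflates
  ## the variance
  expect_gt(mean(ages), 1600)
  expect_lt(mean(ages), 2400)
})
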