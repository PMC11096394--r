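test_that("rho is the mean founder-to-member mutation count", {
  same <- FounderClade("z", members = rep(list(character(0)), 4),
                       founder = character(0), siteMask = 1:50)
  expect_equal(rhoStatistic(same), 0)

  cl <- FounderClade("m", members = list("1", c("1", "2"),
                                         c("1", "2", "3")),
                     founder = character(0), siteMask = 1:50)
  expect_equal(rhoStatistic(cl), 2)

  ## differences outside the mask are ignored
  masked <- FounderClade("w", members = list(c("1", "40")),
                         founder = character(0), siteMask = 1:10)
  expect_equal(rhoStatistic(masked), 1)

  ## Monte-Carlo star genealogy: rho * 1400 recovers the simulated age
  sim <- simulateClade(2000, 200, "star", nSites = 2000, seed = 77)
  age <- rhoStatistic(sim$clade) * 1400
  se <- sqrt(rhoStatistic(sim$clade) / 200) * 1400
  expect_lt(abs(age - 2000), 3 * se)
})

test_that("the site bootstrap is consistent and degenerates correctly", {
  flat <- FounderClade("f", members = rep(list(character(0)), 5),
                       founder = character(0), siteMask = 1:100)
  bs <- bootstrapRho(flat, B = 50, seed = 1)
  expect_true(all(bs$samples == 0))
  expect_equal(bs$ci, c(0, 0))

  sim <- simulateClade(1000, 40, "star", nSites = 500, seed = 5)
  bs <- bootstrapRho(sim$clade, B = 2000, seed = 2)
  expect_gte(bs$rho, bs$ci[1])
  expect_lte(bs$rho, bs$ci[2])
  ## replicate mean converges to the point rho
  expect_lt(abs(mean(bs$samples) - bs$rho), 0.05)
  b2 <- bootstrapRho(sim$clade, B = 8000, seed = 3)
  expect_lt(abs(mean(b2$samples) - b2$rho),
            abs(mean(bootstrapRho(sim$clade, B = 100, seed = 4)$samples) -
                b2$rho) + 0.05)
})

test_that("age conversion is linear in rho and matches printed arithmetic", {
  clock <- clockModel()
  expect_equal(ageYears(ageFromRho(0)), 0)
  expect_equal(ageYears(ageFromRho(2)), 2800)
  ## inversion of a printed age: rho 1.6664 under the 1400-yr clock
  expect_equal(round(ageYears(ageFromRho(1.6664))), 2333)
  expect_error(ageFromRho(-1), "nonnegative")
  set.seed(8)
  for (rep in 1:5) {
    r <- runif(1, 0, 3); a <- runif(1, 0.1, 4)
    expect_equal(ageYears(ageFromRho(a * r)), a * ageYears(ageFromRho(r)))
  }
  ## clock-CI propagation widens the interval only when asked
  plain <- ageFromRho(1, rhoCI = c(0.8, 1.2))
  wide <- ageFromRho(1, rhoCI = c(0.8, 1.2), propagateClockCI = TRUE)
  expect_equal(ageCI(plain), c(0.8, 1.2) * 1400)
  expect_lt(ageCI(wide)[1], ageCI(plain)[1])
  expect_gt(ageCI(wide)[2], ageCI(plain)[2])
})

test_that("calendar conversion reproduces the period convention", {
  expect_identical(toCalendar(1876), "124 AD")
  expect_identical(toCalendar(570), "1430 AD")
  expect_identical(toCalendar(883), "1117 AD")
  ## an age of 2333 years falls in the fourth century BC
  expect_identical(toCalendar(2333), "334 BC")
  ## round trip on whole years: toCalendar(reference - y) labels year y
  for (y in c(-500, -1, 0, 1, 124, 1430, 1999)) {
    want <- if (y >= 1) paste(y, "AD") else paste(1 - y, "BC")
    expect_identical(toCalendar(2000 - y), want)
  }
})

test_that("wave grouping splits at the largest age gaps", {
  ages <- c(2333, 2185, 1600, 900, 850, 600, 550, 400)
  ## independent oracle: evaluate every contiguous 3-partition and pick the
  ## one whose internal (non-cut) gaps are smallest, i.e. cut at the two
  ## largest gaps
  gaps <- -diff(sort(ages, decreasing = TRUE))
  cuts <- sort(order(-gaps)[1:2])
  oracle <- 1L + findInterval(seq_along(ages) - 1L, cuts)
  gw <- groupWaves(ages, k = 3)
  expect_equal(gw$membership$group, oracle)
  expect_equal(nrow(gw$summary), 3)
  expect_equal(sum(gw$summary$n), length(ages))

  one <- groupWaves(ages, k = 1)
  expect_equal(unique(one$membership$group), 1L)
  expect_equal(one$summary$meanAge, mean(ages))

  all_single <- groupWaves(ages, k = length(ages))
  expect_equal(all_single$summary$meanAge, sort(ages, decreasing = TRUE))
  expect_error(groupWaves(ages, k = 0), "k")
  expect_error(groupWaves(ages, k = 99), "exceeds")
})

test_that("the dating pipeline recovers simulated settlement waves", {
  cfg <- simConfig(seed = 7)
  cs <- simulateCladeSet(cfg)
  dl <- dateLineages(cs$clades, B = 300, seed = 99, k = 3)
  truth <- cs$truth$T_years[match(dl$report$lineage, cs$truth$lineage)]
  ## recovered grouping coincides with the simulated waves
  expect_equal(length(unique(paste(dl$report$group, truth))), 3)
  ## group-1 mean is the arithmetic mean of its member ages
  g1 <- dl$report$age[dl$report$group == 1]
  expect_equal(unique(dl$report$groupMeanAge[dl$report$group == 1]),
               mean(g1))
  ## adjacent-group Welch tests are reported and significant here
  expect_true(all(dl$waves$tests$p < 0.01))

  single <- dateLineages(cs$clades[1], B = 50, seed = 1, k = 1)
  expect_equal(unique(single$report$group), 1L)
})

test_that("clades round-trip through aligned FASTA", {
  sim <- simulateClade(1500, 6, "star", nSites = 120, seed = 12)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  path <- tempfile(fileext = ".fasta")
  writeCladeFasta(sim$clade, path, ref)
  back <- founderCladeFromFasta(path)
  expect_equal(length(back@members), 6)
  expect_equal(rhoStatistic(back), rhoStatistic(sim$clade))
})
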