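test_that("contaminant flagging returns variants foreign to the assigned background", {
  panel <- pkgPanel()
  h <- assignHaplogroups(parseVariantString("126 255 292 294"), panel)
  expect_identical(unname(flagContaminantVariants(h, panel)), "16255")

  ## a haplotype equal to its motif has nothing to flag
  clean <- assignHaplogroups(parseVariantString("145 176G 223 297 311"),
                             panel)
  expect_length(flagContaminantVariants(clean, panel), 0)

  two <- assignHaplogroups(parseVariantString("126 201 255 292 294"), panel)
  expect_setequal(flagContaminantVariants(two, panel), c("16201", "16255"))

  ## a recorded within-haplogroup polymorphism is not contaminant
  hgl <- unname(haplogroupLabels(h))
  poly <- stats::setNames(list("16255"), hgl)
  expect_length(flagContaminantVariants(h, panel, polymorphisms = poly), 0)

  unassigned <- parseVariantString("126")
  expect_error(flagContaminantVariants(unassigned, panel), "assignment")
})

test_that("phantom mutations require independent haplogroup backgrounds", {
  panel <- pkgPanel()
  ## the published pattern: one ambiguous H/HV/U/R carrier and one U6c
  ## carrier of the same rare transition
  hs <- parseVariantString(c(a = "145 213", b = "129 169 172 189 213"))
  ph <- detectPhantoms(hs, panel)
  expect_true("16213" %in% ph$variant)
  expect_gte(ph$nBackgrounds[ph$variant == "16213"], 2)

  ## no repeated novel variant, nothing flagged
  none <- parseVariantString(c(a = "126 201", b = "239 305"))
  expect_equal(nrow(detectPhantoms(none, panel)), 0)

  ## ancestor and descendant backgrounds only: not independent
  rel <- parseVariantString(c(a = "172 219 278 333",
                              b = "172 219 239 278 333"))
  ph2 <- detectPhantoms(rel, panel)
  expect_false("16333" %in% ph2$variant)
})

test_that("incomplete sequences resolve to the minimal completing haplogroup", {
  panel <- pkgPanel()
  a <- applySiteFilter(parseVariantString("(172 219) 239 278"))
  ra <- detectIncomplete(a, panel)
  expect_identical(ra$verdict, "incomplete")
  expect_identical(ra$completingHaplogroup, "U6a1a1")
  expect_setequal(ra$missingSites, c("16172", "16219"))

  ## dropout in the trailing amplicons, no unscored marks
  b <- applySiteFilter(parseVariantString("093 192"))
  rb <- detectIncomplete(b, panel)
  expect_identical(rb$verdict, "incomplete")
  expect_identical(rb$completingHaplogroup, "U5a1b4")

  full <- parseVariantString("145 176G 223 297 311")
  expect_identical(detectIncomplete(full, panel)$verdict, "clean")
})

test_that("chimera decomposition recovers synthetic two-motif chimeras exactly", {
  set.seed(21)
  for (rep in 1:6) {
    cfg <- simConfig(seed = 300 + rep, nHaplogroups = 8, treeDepth = 3)
    panel <- simulateMotifPanel(cfg)
    labs <- setdiff(panelLabels(panel), "ROOT")
    motifs <- lapply(labs, cumulativeMotif, panel = panel)
    names(motifs) <- labs
    ## pick two non-nested clades with disjoint motifs
    pair <- NULL
    for (a in labs) for (b in labs) {
      if (a < b && !isAncestor(panel, a, b) && !isAncestor(panel, b, a) &&
          !length(intersect(motifs[[a]], motifs[[b]])) &&
          length(motifs[[a]]) && length(motifs[[b]]))
        pair <- c(a, b)
    }
    if (is.null(pair)) next
    v <- sort(union(motifs[[pair[1]]], motifs[[pair[2]]]))
    h <- assignHaplogroups(HaplotypeSet("chi", list(v)), panel)
    dec <- decomposeChimera(h, panel)
    expect_identical(verdict(dec), "chimera")
    expect_equal(dec@score, 0)
    expect_setequal(union(dec@primaryVariants, dec@contaminantVariants), v)
    expect_setequal(sort(c(dec@primaryHg, dec@contaminantHg)), pair)
    ## cost agrees with the exhaustive pair/bipartition oracle (kept to
    ## small variant sets: the oracle enumerates 3^|V| assignments)
    if (length(v) <= 6) expect_equal(dec@score, bruteDecompose(v, panel))
  }
})

test_that("decomposition cost matches the brute-force oracle on noisy inputs", {
  set.seed(33)
  for (rep in 1:4) {
    cfg <- simConfig(seed = 500 + rep, nHaplogroups = 7, treeDepth = 3)
    panel <- simulateMotifPanel(cfg)
    labs <- setdiff(panelLabels(panel), "ROOT")
    m1 <- cumulativeMotif(panel, sample(labs, 1))
    m2 <- cumulativeMotif(panel, sample(labs, 1))
    v <- unique(c(m1, sample(m2, min(2, length(m2)))))
    if (length(v) > 6) v <- v[1:6]
    h <- assignHaplogroups(HaplotypeSet("x", list(sort(v))), panel)
    dec <- decomposeChimera(h, panel)
    oracle <- bruteDecompose(sort(v), panel)
    if (is.finite(dec@score)) expect_equal(dec@score, oracle)
  }
})

test_that("the published contaminated-haplotype table is fully flagged", {
  panel <- pkgPanel()
  t1 <- utils::read.delim(pkgFile("table1_detected.tsv"))
  hs <- applySiteFilter(parseVariantString(t1$variants, ids = t1$id))
  cur <- curateDataset(hs, panel)
  expect_equal(sum(cur$report$verdict != "clean"), 10)
  ## verdicts partition the dataset
  expect_equal(sum(cur$summary), length(hs))
  ## the artefactual 16213 transition surfaces as a phantom mutation
  expect_true("16213" %in% cur$phantoms$variant)
})

test_that("clean panels produce no flags and injected chimeras exactly one", {
  panel <- tinyPanel()
  clean <- HaplotypeSet(
    c("c1", "c2", "c3"),
    list(cumulativeMotif(panel, "A1a"), cumulativeMotif(panel, "B1"),
         cumulativeMotif(panel, "C1")))
  cur <- curateDataset(clean, panel)
  expect_equal(unname(cur$summary["clean"]), 3L)
  expect_length(flagContaminantVariants(assignHaplogroups(clean, panel),
                                        panel)[[1]], 0)

  chim <- HaplotypeSet("chi", list(sort(c(cumulativeMotif(panel, "A1a"),
                                          cumulativeMotif(panel, "C1")))))
  cur2 <- curateDataset(chim, panel)
  expect_equal(unname(cur2$summary["chimera"]), 1L)
})
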