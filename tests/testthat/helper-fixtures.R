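## Shared fixtures and independent oracles

pkgPanel <- function() {
  loadMotifPanel(system.file("extdata/motif_panel.tsv", package = "palaeomt"))
}

pkgFile <- function(name) system.file("extdata", name, package = "palaeomt")

## small hand-built panel: two unrelated multi-variant clades, a nested
## chain, a transversion-bearing node
tinyPanel <- function() {
  motifPanel(
    haplogroup = c("ROOT", "A", "A1", "A1a", "B", "B1", "C", "C1", "D", "E"),
    parent = c(NA, "ROOT", "A", "A1", "ROOT", "B", "ROOT", "C", "ROOT",
               "ROOT"),
    private = list(character(0), "16050", "16100", "16150",
                   c("16200", "16210"), "16220", "16300",
                   c("16310", "16320"), "16111A", "16360"))
}

## Brute-force chimera-decomposition oracle: enumerate every haplogroup pair
## and every explicit bipartition of the variant set, scoring exactly from
## first principles. Independent of the package's pruned search.
bruteDecompose <- function(tokens, panel, lo = 16001L, hi = 16400L,
                           uns = integer(0), wU = 2, wM = 1) {
  motifs <- lapply(panelLabels(panel), cumulativeMotif, panel = panel)
  names(motifs) <- panelLabels(panel)
  labs <- panelLabels(panel)
  scored <- function(m, covered) {
    miss <- setdiff(m, covered)
    p <- variantPositions(miss)
    sum(p >= lo & p <= hi & !(p %in% uns))
  }
  best <- Inf
  nv <- length(tokens)
  for (a in labs) for (b in labs) {
    if (a >= b) next
    ma <- motifs[[a]]; mb <- motifs[[b]]
    ## every assignment of each token to component 1, 2 or both
    for (mask in 0:(3^nv - 1)) {
      assign <- integer(nv)
      m <- mask
      for (k in seq_len(nv)) { assign[k] <- m %% 3; m <- m %/% 3 }
      ## assignment code: 0 = both components, 1 = comp2 only, 2 = comp1 only
      v1 <- tokens[assign %in% c(0L, 2L)]
      v2 <- tokens[assign %in% c(0L, 1L)]
      unexp <- tokens[!(tokens %in% ma) & !(tokens %in% mb)]
      if (any(!(setdiff(v1, unexp) %in% ma)) ||
          any(!(setdiff(v2, unexp) %in% mb))) next
      cost <- wU * length(unexp) + wM * (scored(ma, v1) + scored(mb, v2))
      if (cost < best) best <- cost
    }
  }
  best
}

## Exhaustive Fisher oracle via binomial-coefficient products
fisherOracle <- function(tab) {
  tab <- matrix(tab, 2, 2)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x), numeric(1)) / choose(n, c1)
  pobs <- pr[match(tab[1, 1], xs)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

## doubled-tail sign-test oracle by explicit binomial summation
signOracle <- function(pos, neg) {
  n <- pos + neg
  k <- min(pos, neg)
  tail <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail)
}
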