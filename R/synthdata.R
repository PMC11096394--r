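## Synthetic data with known truth -------------------------------------------
##
## Generators emulating the structure of the study data: a haplogroup motif
## tree, continental source pools, island founder populations under strong
## Wright-Fisher drift, sequencing artefacts injected across the seven
## overlapping HVS-I amplicons, and founder clades of known age. Every
## generator is a pure function of its SimConfig / seed. Infinite sites are
## assumed within a run (no recurrent hits), which keeps truth labels exact.

#' Amplicon fragment boundaries
#'
#' Seven (by default) equal intervals tiling the HVS-I window, mirroring the
#' overlapping-fragment amplification design.
#'
#' @param window length-2 integer window.
#' @param nFragments number of fragments.
#' @return integer matrix with columns \code{lo}, \code{hi}.
#' @export
fragmentBoundaries <- function(window = c(16001L, 16400L),
                               nFragments = 7L) {
  cuts <- round(seq(window[1], window[2] + 1L, length.out = nFragments + 1L))
  cbind(lo = cuts[-length(cuts)], hi = cuts[-1] - 1L)
}

#' Simulate a haplogroup motif panel
#'
#' Grows a random rooted tree; every edge acquires at least one private
#' variant at positions drawn by hotspot weight and never reused anywhere in
#' the panel, so all cumulative motifs are unique.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return a \code{\link{MotifPanel}}.
#' @export
simulateMotifPanel <- function(cfg) {
  set.seed(cfg@seed)
  npos <- cfg@window[2] - cfg@window[1] + 1L
  positions <- seq(cfg@window[1], cfg@window[2])
  w <- if (length(cfg@hotspotWeights) == npos) cfg@hotspotWeights
       else stats::rgamma(npos, shape = 0.6)   # heavy-tailed mutability
  n <- cfg@nHaplogroups
  labels <- c("ROOT", sprintf("HG%02d", seq_len(max(0L, n - 1L))))
  parent <- rep(NA_character_, n)
  depth <- integer(n)
  private <- rep(list(character(0)), n)
  avail <- rep(TRUE, npos)
  for (i in seq_len(n)[-1]) {
    ok <- which(depth[seq_len(i - 1L)] < cfg@treeDepth)
    p <- if (length(ok) == 1L) ok else sample(ok, 1L)
    parent[i] <- labels[p]
    depth[i] <- depth[p] + 1L
    npriv <- 1L + stats::rpois(1L, 0.7)
    if (sum(avail) < npriv)
      stop("more required variants than available positions")
    idx <- sample(which(avail), npriv, prob = w[avail])
    avail[idx] <- FALSE
    private[[i]] <- as.character(positions[idx])
  }
  motifPanel(labels, parent, private)
}

## draw a Dirichlet frequency vector
.rdirichlet <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Simulate continental pools and drifted island populations
#'
#' Continental regions receive Dirichlet frequency spectra over the panel
#' motifs; each island starts from a founder sample drawn from a North
#' African source mixture and drifts by multinomial Wright-Fisher resampling
#' for the configured generations. The indigenous epoch samples the
#' post-drift island; historic and current epochs are sequential resamples
#' with European immigration mixed in.
#'
#' @param panel a \code{\link{MotifPanel}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{haplotypes} (a \code{HaplotypeSet} of island
#'   observations across epochs, haplogroup slot holding the true label),
#'   \code{panels} (continental \code{\link{RegionalPanelSet}}) and
#'   \code{islandFrequencies} (post-drift motif frequencies per island).
#' @export
simulateIslandPopulations <- function(panel, cfg) {
  if (length(panel@labels) == 0L) stop("empty panel")
  set.seed(cfg@seed + 1L)
  motifs <- .allMotifs(panel)
  hgs <- panel@labels
  nh <- length(hgs)
  keyOf <- vapply(motifs, paste, character(1), collapse = " ")
  regions <- names(cfg@regionSizes)
  rfreq <- lapply(regions, function(r) .rdirichlet(nh, 0.3))
  names(rfreq) <- regions
  ptab <- do.call(rbind, lapply(regions, function(r) {
    cnt <- as.integer(stats::rmultinom(1L, cfg@regionSizes[[r]],
                                       rfreq[[r]]))
    keep <- cnt > 0L
    data.frame(region = r, key = keyOf[keep], count = cnt[keep],
               stringsAsFactors = FALSE)
  }))
  panels <- new("RegionalPanelSet", table = ptab)

  af_regions <- intersect(c("NW", "NA"), regions)
  eu_regions <- intersect(c("IP", "FR", "IT"), regions)
  source_af <- Reduce(`+`, rfreq[af_regions]) / max(1L, length(af_regions))
  source_eu <- Reduce(`+`, rfreq[eu_regions]) / max(1L, length(eu_regions))

  rows <- list()
  islfreq <- list()
  for (r in seq_len(nrow(cfg@islands))) {
    isl <- cfg@islands[r, ]
    if (isl$founders > sum(cfg@regionSizes))
      stop("founder count exceeds the source pool")
    founders <- sample.int(nh, isl$founders, replace = TRUE,
                           prob = source_af)
    p <- tabulate(founders, nh) / isl$founders
    if (isl$driftGenerations > 0L) {
      for (g in seq_len(isl$driftGenerations))
        p <- as.numeric(stats::rmultinom(1L, isl$popSize, p)) / isl$popSize
    }
    islfreq[[isl$name]] <- stats::setNames(p, hgs)
    draw_epoch <- function(epoch, immigration) {
      n_s <- isl$sampleSize
      fromEU <- stats::runif(n_s) < immigration
      idx <- integer(n_s)
      if (any(!fromEU))
        idx[!fromEU] <- sample.int(nh, sum(!fromEU), replace = TRUE,
                                   prob = p)
      if (any(fromEU))
        idx[fromEU] <- sample.int(nh, sum(fromEU), replace = TRUE,
                                  prob = source_eu)
      data.frame(island = isl$name, epoch = epoch, hg = hgs[idx],
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- draw_epoch("indigenous", 0)
    rows[[length(rows) + 1L]] <- draw_epoch("historic",
                                            cfg@historicImmigration)
    rows[[length(rows) + 1L]] <- draw_epoch("current",
                                            cfg@currentImmigration)
  }
  obs <- do.call(rbind, rows)
  hs <- HaplotypeSet(
    ids = sprintf("%s_%s_%03d", obs$island, obs$epoch,
                  stats::ave(seq_len(nrow(obs)),
                             paste(obs$island, obs$epoch),
                             FUN = seq_along)),
    variants = motifs[obs$hg], range = cfg@window,
    haplogroup = obs$hg, region = obs$island, epoch = obs$epoch)
  list(haplotypes = hs, panels = panels, islandFrequencies = islfreq)
}

#' Inject sequencing artefacts with recorded truth
#'
#' With probability \code{chimeraRate} a haplotype's variants inside a random
#' amplicon fragment are replaced by a donor haplotype's variants there
#' (recorded as a chimera only when at least one foreign variant is actually
#' introduced); alternatively, with probability \code{dropoutRate} a terminal
#' fragment becomes unscored and its variants are lost (recorded as
#' incomplete only when a variant was actually lost). Finally,
#' \code{phantomSites} positions untouched by the motif panel are sprinkled
#' onto \code{phantomCarriers} so-far-clean haplotypes each. Events that
#' leave the observable haplotype unchanged are not labelled artefacts.
#'
#' @param hs a \code{HaplotypeSet} (e.g. the indigenous epoch of
#'   \code{\link{simulateIslandPopulations}}).
#' @param panel the \code{\link{MotifPanel}} the haplotypes derive from.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{haplotypes} (corrupted set) and \code{truth}
#'   (data.frame id, truth in \{clean, chimera, incomplete, phantom\},
#'   donor, detail).
#' @export
injectArtifacts <- function(hs, panel, cfg) {
  set.seed(cfg@seed + 2L)
  frags <- fragmentBoundaries(cfg@window, cfg@nFragments)
  n <- length(hs)
  truth <- data.frame(id = hs@ids, truth = "clean", donor = NA_character_,
                      detail = NA_character_, stringsAsFactors = FALSE)
  inFrag <- function(tokens, f) {
    p <- variantPositions(tokens)
    tokens[p >= frags[f, "lo"] & p <= frags[f, "hi"]]
  }
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (u[i] < cfg@chimeraRate && n > 1L) {
      j <- sample(setdiff(seq_len(n), i), 1L)
      f <- sample.int(nrow(frags), 1L)
      own <- hs@variants[[i]]
      donor_in <- inFrag(hs@variants[[j]], f)
      foreign <- setdiff(donor_in, own)
      if (length(foreign)) {
        hs@variants[[i]] <- .sortTokens(c(setdiff(own, inFrag(own, f)),
                                          donor_in))
        truth$truth[i] <- "chimera"
        truth$donor[i] <- hs@ids[j]
        truth$detail[i] <- paste0("fragment", f)
      }
    } else if (u[i] < cfg@chimeraRate + cfg@dropoutRate) {
      f <- if (stats::runif(1) < 0.5) 1L else nrow(frags)
      own <- hs@variants[[i]]
      lost <- inFrag(own, f)
      hs@unscored[[i]] <- sort(union(hs@unscored[[i]],
                                     seq(frags[f, "lo"], frags[f, "hi"])))
      if (length(lost)) {
        hs@variants[[i]] <- setdiff(own, lost)
        truth$truth[i] <- "incomplete"
        truth$detail[i] <- paste0("fragment", f)
      }
    }
  }
  if (cfg@phantomSites > 0L) {
    used <- unique(variantPositions(unlist(panel@private,
                                           use.names = FALSE)))
    pool <- setdiff(seq(cfg@window[1], cfg@window[2]), used)
    sites <- sample(pool, cfg@phantomSites)
    for (s in sites) {
      clean_idx <- which(truth$truth == "clean")
      carriers <- sample(clean_idx,
                         min(cfg@phantomCarriers, length(clean_idx)))
      for (i in carriers) {
        hs@variants[[i]] <- .sortTokens(c(hs@variants[[i]],
                                          as.character(s)))
        hs@unscored[[i]] <- setdiff(hs@unscored[[i]], s)
        truth$truth[i] <- "phantom"
        truth$detail[i] <- as.character(s)
      }
    }
  }
  validObject(hs)
  list(haplotypes = hs, truth = truth)
}

#' Simulate a founder clade of known age
#'
#' Star mode: every tip accrues \code{Poisson(T / yearsPerMutation)}
#' mutations at distinct random sites. Coalescent mode: a Kingman genealogy
#' (\code{ape::rcoal}) rescaled to TMRCA = T, with Poisson mutations per
#' branch. The founder is the all-reference state; sites are drawn under the
#' infinite-sites approximation.
#'
#' @param T_years true age in years.
#' @param nTips number of sampled lineages.
#' @param genealogy \code{"star"} or \code{"coalescent"}.
#' @param nSites number of masked alignment sites.
#' @param clock a \code{\link{clockModel}}.
#' @param seed optional RNG seed.
#' @return list with \code{clade} (a \code{\link{FounderClade}}) and
#'   \code{truth} (list: T_years, genealogy, expectedRho).
#' @export
simulateClade <- function(T_years, nTips, genealogy = c("star",
                                                        "coalescent"),
                          nSites = 1000L, clock = clockModel(),
                          seed = NULL) {
  genealogy <- match.arg(genealogy)
  stopifnot(T_years >= 0)
  if (!is.null(seed)) set.seed(seed)
  lam <- T_years / clock@yearsPerMutation
  if (lam > nSites)
    stop("expected mutations per lineage exceed the number of sites ",
         "(infinite-sites violation)")
  if (genealogy == "star") {
    members <- lapply(seq_len(nTips), function(i) {
      m <- stats::rpois(1L, lam)
      if (m > nSites) m <- nSites
      as.character(sort(sample.int(nSites, m)))
    })
  } else {
    tr <- ape::rcoal(nTips)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (T_years / depth)
    nmut <- stats::rpois(nrow(tr$edge),
                         tr$edge.length / clock@yearsPerMutation)
    if (sum(nmut) > nSites)
      stop("expected mutations exceed the number of sites ",
           "(infinite-sites violation)")
    sites <- sample.int(nSites, sum(nmut))
    edge_sites <- split(sites, rep(seq_len(nrow(tr$edge)), nmut))
    members <- lapply(seq_len(nTips), function(tip) {
      path_edges <- integer(0)
      node <- tip
      repeat {
        e <- which(tr$edge[, 2] == node)
        if (!length(e)) break
        path_edges <- c(path_edges, e)
        node <- tr$edge[e, 1]
      }
      hits <- unlist(edge_sites[as.character(path_edges)],
                     use.names = FALSE)
      as.character(sort(hits))
    })
  }
  clade <- FounderClade(name = sprintf("sim_T%d", as.integer(T_years)),
                        members = members, founder = character(0),
                        siteMask = seq_len(nSites))
  list(clade = clade, truth = list(T_years = T_years, genealogy = genealogy,
                                   expectedRho = lam))
}

#' Simulate the configured set of founder clades
#'
#' One clade per row of \code{cfg@@cladeSpecs}, with per-clade seeds derived
#' from the config seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{clades} (list of \code{FounderClade}) and
#'   \code{truth} (data.frame lineage, T_years).
#' @export
simulateCladeSet <- function(cfg) {
  specs <- cfg@cladeSpecs
  clades <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sim <- simulateClade(specs$T_years[i], specs$nTips[i],
                         specs$genealogy[i], specs$nSites[i],
                         seed = cfg@seed + 100L + i)
    sim$clade@name <- sprintf("clade%02d_T%d", i,
                              as.integer(specs$T_years[i]))
    clades[[i]] <- sim$clade
  }
  list(clades = clades,
       truth = data.frame(lineage = vapply(clades, function(x) x@name,
                                           character(1)),
                          T_years = specs$T_years))
}

## Clade FASTA round trip -----------------------------------------------------

#' Write / read founder clades as aligned FASTA
#'
#' \code{writeCladeFasta} renders the founder and members onto a reference
#' sequence (transitions flip to the partner base, transversions substitute
#' the recorded base) and writes an aligned FASTA with the founder first.
#' \code{founderCladeFromFasta} reads such a file back, scoring members
#' against the founder record.
#'
#' @param clade a \code{\link{FounderClade}}.
#' @param path FASTA file path.
#' @param reference character string covering the site mask.
#' @return the path, invisibly.
#' @export
writeCladeFasta <- function(clade, path, reference) {
  refv <- strsplit(toupper(as.character(reference)), "")[[1]]
  render <- function(tokens) {
    s <- refv
    pos <- variantPositions(tokens)
    kind <- variantKinds(tokens)
    for (k in seq_along(tokens)) {
      p <- pos[k]
      if (kind[k] == "transition")
        s[p] <- .TRANSITION_PARTNER[[s[p]]]
      else if (kind[k] == "transversion")
        s[p] <- sub("^[0-9]+", "", tokens[k])
    }
    paste(s, collapse = "")
  }
  lines <- c(paste0(">", clade@name, "_founder"), render(clade@founder))
  for (i in seq_along(clade@members))
    lines <- c(lines, paste0(">", clade@name, "_m", i),
               render(clade@members[[i]]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCladeFasta
#' @param name clade name (defaults to the file base name).
#' @param siteMask positions considered (default: full reference length).
#' @return \code{founderCladeFromFasta}: a \code{\link{FounderClade}}.
#' @export
founderCladeFromFasta <- function(path, name = NULL, siteMask = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2L) stop("clade FASTA needs a founder and members")
  ref <- as.character(seqs[[1]])
  members <- lapply(seq_along(seqs)[-1], function(i)
    scoreAgainstReference(as.character(seqs[[i]]), ref))
  if (is.null(siteMask)) siteMask <- seq_len(nchar(ref))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  FounderClade(name = name, members = members, founder = character(0),
               siteMask = siteMask)
}
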