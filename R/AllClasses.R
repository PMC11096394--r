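#' @import methods
NULL

## HaplotypeSet ---------------------------------------------------------------

#' Container for mtDNA control-region haplotypes
#'
#' A vector-like S4 container holding, per haplotype: its variant tokens
#' (differences from the reference, see \code{\link{variantPositions}}), the
#' positions known to be untyped (parenthesized in source tables), the closed
#' interval of sequenced positions, a haplogroup label (or \code{NA} when
#' unassigned) and sampling metadata (island/region and epoch).
#'
#' @slot ids character, unique haplotype identifiers.
#' @slot variants list of character vectors of canonical variant tokens.
#' @slot unscored list of integer vectors of known-untyped positions.
#' @slot range integer matrix with columns \code{lo}, \code{hi}.
#' @slot haplogroup character, label or \code{NA}.
#' @slot region character, island or continental region label.
#' @slot epoch character, one of \code{indigenous}, \code{historic},
#'   \code{current}, \code{continental} (or \code{NA}).
#' @export
setClass("HaplotypeSet",
  representation(ids = "character", variants = "list", unscored = "list",
                 range = "matrix", haplogroup = "character",
                 region = "character", epoch = "character"))

setValidity("HaplotypeSet", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (length(object@variants) != n || length(object@unscored) != n ||
      nrow(object@range) != n || length(object@haplogroup) != n ||
      length(object@region) != n || length(object@epoch) != n)
    msg <- c(msg, "slot lengths differ")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "haplotype ids must be unique")
  for (i in seq_len(n)) {
    pos <- variantPositions(object@variants[[i]])
    if (length(pos) && (any(pos < object@range[i, 1]) ||
                        any(pos > object@range[i, 2])))
      msg <- c(msg, paste0("variants of '", object@ids[i],
                           "' fall outside its sequenced range"))
    if (length(intersect(pos, object@unscored[[i]])))
      msg <- c(msg, paste0("'", object@ids[i],
                           "' has a position both scored and unscored"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#'
#' @param ids character vector of unique identifiers.
#' @param variants list of canonical variant-token vectors (one per haplotype).
#' @param unscored list of integer position vectors (recycled if omitted).
#' @param range integer matrix (n x 2) or length-2 vector of sequenced bounds.
#' @param haplogroup,region,epoch character vectors (recycled).
#' @return a \code{HaplotypeSet}.
#' @export
HaplotypeSet <- function(ids, variants, unscored = NULL,
                         range = c(16001L, 16400L),
                         haplogroup = NA_character_, region = NA_character_,
                         epoch = NA_character_) {
  n <- length(ids)
  if (is.null(unscored)) unscored <- rep(list(integer(0)), n)
  if (!is.matrix(range))
    range <- matrix(rep(as.integer(range), each = n), ncol = 2)
  colnames(range) <- c("lo", "hi")
  variants <- lapply(variants, .sortTokens)
  unscored <- lapply(unscored, function(u) sort(unique(as.integer(u))))
  new("HaplotypeSet", ids = as.character(ids), variants = variants,
      unscored = unscored, range = range,
      haplogroup = rep_len(as.character(haplogroup), n),
      region = rep_len(as.character(region), n),
      epoch = rep_len(as.character(epoch), n))
}

## MotifPanel -----------------------------------------------------------------

#' Haplogroup motif tree
#'
#' A rooted tree of haplogroup labels; each non-root node carries the private
#' diagnostic variants acquired on the edge from its parent. The cumulative
#' motif of a node is the union of private variants along the root path, with
#' back mutations (\code{@pos}) cancelling earlier variants at that position.
#'
#' @slot labels character, node labels (first element is the root).
#' @slot parent named character, parent label per node (\code{NA} for root).
#' @slot private named list of canonical variant-token vectors.
#' @export
setClass("MotifPanel",
  representation(labels = "character", parent = "character",
                 private = "list"))

setValidity("MotifPanel", function(object) {
  msg <- character(0)
  if (length(object@labels) == 0L) return("panel is empty")
  if (anyDuplicated(object@labels)) {
    dup <- object@labels[duplicated(object@labels)][1]
    return(paste0("duplicate node '", dup, "'"))
  }
  roots <- object@labels[is.na(object@parent[object@labels])]
  if (length(roots) != 1L)
    msg <- c(msg, paste0("panel must have exactly one root, found ",
                         length(roots)))
  for (lab in object@labels) {
    p <- object@parent[[lab]]
    if (!is.na(p) && !p %in% object@labels)
      msg <- c(msg, paste0("node '", lab, "' has unknown parent '", p, "'"))
  }
  ## cycle check by walking every root path
  for (lab in object@labels) {
    seen <- character(0)
    cur <- lab
    while (!is.na(cur)) {
      if (cur %in% seen) return(paste0("cycle through node '", cur, "'"))
      seen <- c(seen, cur)
      cur <- if (cur %in% names(object@parent)) object@parent[[cur]] else NA
    }
  }
  if (length(msg)) msg else TRUE
})

## RegionalPanelSet -----------------------------------------------------------

#' Regional haplotype panels for match searching
#'
#' Multisets of canonical haplotype keys with observation counts, one multiset
#' per continental region, standing in for the literature databases screened
#' for exact haplotype matches.
#'
#' @slot table data.frame with columns \code{region}, \code{key} (canonical
#'   haplotype string) and \code{count}.
#' @export
setClass("RegionalPanelSet", representation(table = "data.frame"))

setValidity("RegionalPanelSet", function(object) {
  tb <- object@table
  if (!all(c("region", "key", "count") %in% names(tb)))
    return("table needs columns region, key, count")
  if (any(tb$count < 1)) return("counts must be >= 1")
  TRUE
})

## FounderClade ---------------------------------------------------------------

#' A founder clade, the unit of rho dating
#'
#' @slot name lineage label.
#' @slot founder character vector of canonical variant tokens of the founder
#'   (root) haplotype, relative to the same reference as the members.
#' @slot members list of member variant-token vectors.
#' @slot siteMask integer vector of alignment positions considered.
#' @export
setClass("FounderClade",
  representation(name = "character", founder = "character",
                 members = "list", siteMask = "integer"))

setValidity("FounderClade", function(object) {
  if (length(object@members) < 1L) return("a clade needs at least one member")
  if (length(object@siteMask) == 0L) return("site mask is empty")
  fp <- variantPositions(object@founder)
  if (length(fp) && !all(fp %in% object@siteMask))
    return("founder variants must lie inside the site mask")
  TRUE
})

#' Construct a FounderClade
#'
#' When \code{founder} is \code{NULL} the founder state is reconstructed as
#' the modal state per masked site across members (a token is ancestral when
#' carried by more than half of the members).
#'
#' @param name lineage label.
#' @param members list of member variant-token vectors.
#' @param founder founder variant tokens, or \code{NULL} to reconstruct.
#' @param siteMask integer positions considered (defaults to 1..16569).
#' @return a \code{FounderClade}.
#' @export
FounderClade <- function(name, members, founder = NULL,
                         siteMask = seq_len(16569L)) {
  members <- lapply(members, .sortTokens)
  if (is.null(founder)) {
    all_tok <- unlist(members, use.names = FALSE)
    tab <- table(all_tok)
    founder <- names(tab)[tab > length(members) / 2]
  }
  siteMask <- sort(unique(as.integer(siteMask)))
  founder <- .sortTokens(founder[variantPositions(founder) %in% siteMask])
  new("FounderClade", name = as.character(name), founder = founder,
      members = members, siteMask = siteMask)
}

## MutationClock --------------------------------------------------------------

#' Mutation clock for coalescence dating
#'
#' The fast clock for shallow phylogenies: one mutation per lineage every
#' 1400 years (95\% CI 1261-1539), equivalent to a per-site rate of
#' 4.33e-8 /site/year (95\% CI 3.90-4.82e-8) over the effective sequence
#' length.
#'
#' @slot yearsPerMutation numeric, years per mutation per lineage.
#' @slot ci numeric length 2, 95\% CI of \code{yearsPerMutation}.
#' @slot perSiteRate numeric, mutations/site/year.
#' @slot perSiteCI numeric length 2.
#' @slot effectiveLength integer, sites backing the per-site conversion.
#' @export
setClass("MutationClock",
  representation(yearsPerMutation = "numeric", ci = "numeric",
                 perSiteRate = "numeric", perSiteCI = "numeric",
                 effectiveLength = "integer"))

setValidity("MutationClock", function(object) {
  if (object@yearsPerMutation <= 0) return("yearsPerMutation must be > 0")
  if (length(object@ci) == 2 &&
      (object@ci[1] > object@yearsPerMutation ||
       object@ci[2] < object@yearsPerMutation))
    return("ci must bracket yearsPerMutation")
  TRUE
})

#' @rdname MutationClock-class
#' @param yearsPerMutation,ci,perSiteRate,perSiteCI,effectiveLength see slots.
#'   The default effective length is the one implied by the printed pair of
#'   1400 years/mutation and 4.33e-8 /site/year.
#' @return a \code{MutationClock}.
#' @export
clockModel <- function(yearsPerMutation = 1400, ci = c(1261, 1539),
                       perSiteRate = 4.33e-8,
                       perSiteCI = c(3.90e-8, 4.82e-8),
                       effectiveLength = round(1 / (yearsPerMutation *
                                                    perSiteRate))) {
  new("MutationClock", yearsPerMutation = yearsPerMutation, ci = ci,
      perSiteRate = perSiteRate, perSiteCI = perSiteCI,
      effectiveLength = as.integer(effectiveLength))
}

## Decomposition --------------------------------------------------------------

#' Curation verdict for one haplotype
#'
#' @slot id input haplotype identifier.
#' @slot verdict one of \code{clean}, \code{incomplete}, \code{chimera},
#'   \code{phantom_bearing}.
#' @slot primaryVariants,primaryHg most probable (primary) component.
#' @slot contaminantVariants,contaminantHg contaminating component, or empty.
#' @slot unexplained variant tokens explained by neither component.
#' @slot score numeric decomposition cost (lower is better).
#' @export
setClass("Decomposition",
  representation(id = "character", verdict = "character",
                 primaryVariants = "character", primaryHg = "character",
                 contaminantVariants = "character",
                 contaminantHg = "character",
                 unexplained = "character", score = "numeric"))

setValidity("Decomposition", function(object) {
  if (!object@verdict %in% c("clean", "incomplete", "chimera",
                             "phantom_bearing"))
    return("unknown verdict")
  if (object@verdict == "clean" &&
      (length(object@contaminantVariants) || length(object@unexplained)))
    return("a clean verdict cannot carry a contaminant or residue")
  TRUE
})

## SimConfig ------------------------------------------------------------------

#' Configuration of the synthetic-data generators
#'
#' All generators are pure functions of this object: identical seed, identical
#' output. Defaults emulate the study conditions: 288 HVS-I indigenous
#' haplotypes plus 48 mitogenome-backed clade members, regional screening
#' panels of 3246 northern African and 10,960 European sequences, seven
#' islands with strong founder drift, HVS-I amplified in seven overlapping
#' fragments, and founder clades evolving at one mutation per 1400 years.
#'
#' @slot seed integer RNG seed.
#' @slot nHaplogroups number of motif-tree nodes.
#' @slot treeDepth maximum tree depth.
#' @slot window integer length 2, HVS-I window.
#' @slot hotspotWeights per-position relative mutability (or empty for
#'   gamma-distributed weights drawn from the seed).
#' @slot islands data.frame: name, founders, driftGenerations, popSize,
#'   sampleSize.
#' @slot chimeraRate,dropoutRate probabilities per haplotype.
#' @slot phantomSites number of phantom positions; \code{phantomCarriers}
#'   haplotypes each.
#' @slot phantomCarriers carriers per phantom site.
#' @slot nFragments number of overlapping amplicons tiling the window.
#' @slot regionSizes named integer, continental panel sizes.
#' @slot historicImmigration,currentImmigration continental admixture entering
#'   the post-indigenous epochs.
#' @slot cladeSpecs data.frame: T_years, nTips, genealogy, nSites.
#' @export
setClass("SimConfig",
  representation(seed = "integer", nHaplogroups = "integer",
                 treeDepth = "integer", window = "integer",
                 hotspotWeights = "numeric", islands = "data.frame",
                 chimeraRate = "numeric", dropoutRate = "numeric",
                 phantomSites = "integer", phantomCarriers = "integer",
                 nFragments = "integer", regionSizes = "integer",
                 historicImmigration = "numeric",
                 currentImmigration = "numeric", cladeSpecs = "data.frame"))

setValidity("SimConfig", function(object) {
  if (object@chimeraRate < 0 || object@chimeraRate > 1 ||
      object@dropoutRate < 0 || object@dropoutRate > 1)
    return("rates must lie in [0, 1]")
  if (object@nHaplogroups < 1L) return("need at least one haplogroup")
  TRUE
})

#' @rdname SimConfig-class
#' @param seed,nHaplogroups,treeDepth,window,hotspotWeights,islands see slots.
#' @param chimeraRate,dropoutRate,phantomSites,phantomCarriers,nFragments
#'   artefact-injection parameters.
#' @param regionSizes,historicImmigration,currentImmigration,cladeSpecs see
#'   slots.
#' @return a \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nHaplogroups = 30L, treeDepth = 6L,
                      window = c(16001L, 16400L), hotspotWeights = numeric(0),
                      islands = NULL, chimeraRate = 0.1, dropoutRate = 0.1,
                      phantomSites = 2L, phantomCarriers = 5L,
                      nFragments = 7L,
                      regionSizes = c(NW = 1623L, "NA" = 1623L, IP = 5480L,
                                      FR = 2740L, IT = 2740L),
                      historicImmigration = 0.5, currentImmigration = 0.7,
                      cladeSpecs = NULL) {
  if (is.null(islands))
    islands <- data.frame(
      name = c("TF", "GC", "LP", "LG", "EH", "LZ", "FU"),
      founders = c(40L, 40L, 25L, 20L, 15L, 15L, 15L),
      driftGenerations = c(40L, 40L, 40L, 40L, 40L, 40L, 40L),
      popSize = c(300L, 300L, 150L, 100L, 80L, 80L, 80L),
      sampleSize = c(80L, 80L, 40L, 40L, 20L, 14L, 14L))
  if (is.null(cladeSpecs))
    cladeSpecs <- data.frame(
      T_years = c(rep(1900, 5), rep(900, 4), rep(500, 6)),
      nTips = 150L, genealogy = "star", nSites = 1000L)
  new("SimConfig", seed = as.integer(seed),
      nHaplogroups = as.integer(nHaplogroups),
      treeDepth = as.integer(treeDepth), window = as.integer(window),
      hotspotWeights = hotspotWeights, islands = islands,
      chimeraRate = chimeraRate, dropoutRate = dropoutRate,
      phantomSites = as.integer(phantomSites),
      phantomCarriers = as.integer(phantomCarriers),
      nFragments = as.integer(nFragments),
      regionSizes = stats::setNames(as.integer(regionSizes),
                                    names(regionSizes)),
      historicImmigration = historicImmigration,
      currentImmigration = currentImmigration, cladeSpecs = cladeSpecs)
}
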