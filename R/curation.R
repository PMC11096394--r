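## Curation: contaminants, phantoms, incomplete sequences, chimeras ----------
##
## Rule set, following the published curation procedure:
##  * variants never before seen on the assigned haplogroup background are
##    putative contaminant mutations;
##  * rare novel variants recurring on phylogenetically independent
##    (non-ancestor/descendant) backgrounds are phantom (sequencing-artefact)
##    mutations;
##  * a haplotype whose variants are a proper subset of some cumulative motif,
##    with every missing site untyped or in a terminal segment of the
##    sequenced window, is an incomplete sequence (amplicon dropout: HVS-I was
##    amplified in seven overlapping fragments);
##  * otherwise a minimum-cost two-haplogroup decomposition is searched, and
##    the haplotype is a chimera when splitting it beats declaring its novel
##    variants unexplained.

.scoredMissing <- function(motif, v, lo, hi, uns) {
  missing <- setdiff(motif, v)
  mp <- variantPositions(missing)
  missing[mp >= lo & mp <= hi & !(mp %in% uns)]
}

#' Flag putative contaminant variants
#'
#' Returns the variants of each haplotype that are absent from the cumulative
#' motif of its assigned haplogroup and from any recorded within-haplogroup
#' polymorphism list.
#'
#' @param x a \code{HaplotypeSet} with haplogroups assigned (see
#'   \code{\link{assignHaplogroups}}).
#' @param panel a \code{MotifPanel}.
#' @param polymorphisms optional named list: haplogroup -> tokens known to
#'   segregate within it without being diagnostic.
#' @return named list of token vectors (single vector for one haplotype).
#' @export
flagContaminantVariants <- function(x, panel, polymorphisms = list()) {
  if (any(is.na(x@haplogroup)))
    stop("haplotype(s) without haplogroup assignment: ",
         paste(x@ids[is.na(x@haplogroup)], collapse = ", "))
  motifs <- .allMotifs(panel)
  out <- lapply(seq_len(length(x)), function(i) {
    hg <- x@haplogroup[i]
    if (!hg %in% panel@labels) stop("unknown haplogroup '", hg, "'")
    known <- c(motifs[[hg]], unlist(polymorphisms[[hg]], use.names = FALSE))
    setdiff(x@variants[[i]], known)
  })
  names(out) <- x@ids
  if (length(out) == 1L) out[[1]] else out
}

#' Detect phantom mutations across a collection
#'
#' A novel variant is flagged as a phantom mutation when it recurs on at
#' least \code{minBackgrounds} phylogenetically independent haplogroup
#' backgrounds. Because HVS-I often cannot separate shallow haplogroups, each
#' occurrence contributes its full set of top-scoring classification
#' candidates, and independence holds when representatives can be chosen that
#' are pairwise neither ancestor nor descendant.
#'
#' @param x a \code{HaplotypeSet}.
#' @param panel a \code{MotifPanel}.
#' @param minBackgrounds minimum number of independent backgrounds (default 2).
#' @return data.frame with columns \code{variant}, \code{nBackgrounds},
#'   \code{backgrounds} (comma-separated), \code{carriers}.
#' @export
detectPhantoms <- function(x, panel, minBackgrounds = 2L) {
  motifs <- .allMotifs(panel)
  occ <- list()     # token -> list of candidate-label sets
  bkg <- list()     # token -> list of carrier variant backgrounds
  carriers <- list()
  for (i in seq_len(length(x))) {
    r <- classifyHaplotype(x[i], panel, motifs = motifs)
    cand <- r$haplogroup[r$score == r$score[1]]
    novel <- r$extra[[1]]
    for (tok in novel) {
      occ[[tok]] <- c(occ[[tok]], list(cand))
      bkg[[tok]] <- c(bkg[[tok]], list(setdiff(x@variants[[i]], tok)))
      carriers[[tok]] <- c(carriers[[tok]], x@ids[i])
    }
  }
  ## nested carrier haplotypes are plausibly one lineage observed at two
  ## resolutions and never count as separate backgrounds
  nested <- function(v1, v2) all(v1 %in% v2) || all(v2 %in% v1)
  depths <- panelDepths(panel)
  rows <- list()
  for (tok in names(occ)) {
    sets <- occ[[tok]]
    if (length(sets) < minBackgrounds) next
    ## greedy, preferring the most specific (deepest) candidate of each
    ## occurrence: deep nodes are the most likely to be mutually independent
    vb <- bkg[[tok]]
    chosen <- character(0)
    chosen_bkg <- list()
    for (o in seq_along(sets)) {
      cand <- sets[[o]]
      cand <- cand[order(-depths[cand])]
      sep <- vapply(seq_along(chosen), function(k)
        !nested(vb[[o]], chosen_bkg[[k]]), logical(1))
      if (length(sep) && !all(sep)) next
      ok <- cand[vapply(cand, function(cc)
        all(vapply(chosen, function(ch)
          independentBackgrounds(panel, cc, ch), logical(1))),
        logical(1))]
      if (length(ok)) {
        chosen <- c(chosen, ok[1])
        chosen_bkg <- c(chosen_bkg, list(vb[[o]]))
      }
    }
    ## exact fallback for the pairwise case the greedy pass can miss
    if (length(chosen) < 2L && minBackgrounds <= 2L && length(sets) >= 2L) {
      found <- NULL
      for (i in seq_len(length(sets) - 1L)) {
        for (j in seq(i + 1L, length(sets))) {
          if (nested(vb[[i]], vb[[j]])) next
          for (a in sets[[i]]) for (b in sets[[j]])
            if (independentBackgrounds(panel, a, b)) {
              found <- c(a, b); break
            }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) chosen <- found
    }
    if (length(chosen) >= minBackgrounds)
      rows[[tok]] <- data.frame(
        variant = tok, nBackgrounds = length(chosen),
        backgrounds = paste(chosen, collapse = ","),
        carriers = paste(carriers[[tok]], collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(variant = character(0), nBackgrounds = integer(0),
                      backgrounds = character(0), carriers = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect an incomplete sequence
#'
#' A haplotype is incomplete when its variants form a proper subset of some
#' haplogroup's cumulative motif and every missing motif site is either among
#' the unscored positions or in a terminal segment of the sequenced window
#' (outside the span of the observed variants), consistent with amplicon
#' dropout. The minimal-missing completing haplogroup is returned.
#'
#' @param x a single-haplotype \code{HaplotypeSet}.
#' @param panel a \code{MotifPanel}.
#' @return list with \code{verdict} (\code{clean}, \code{incomplete} or
#'   \code{unresolved}), \code{completingHaplogroup} and \code{missingSites}.
#' @export
detectIncomplete <- function(x, panel) {
  stopifnot(length(x) == 1L)
  motifs <- .allMotifs(panel)
  v <- x@variants[[1]]
  uns <- x@unscored[[1]]
  depths <- panelDepths(panel)
  exact <- names(motifs)[vapply(motifs, function(m) setequal(m, v),
                                logical(1))]
  span <- if (length(v)) range(variantPositions(v)) else c(NA_real_, NA_real_)
  ## completion candidates in two tiers: missing sites all among the
  ## unscored positions (strong dropout evidence), or additionally in the
  ## terminal segments outside the span of the observed variants
  best_unscored <- NULL
  best_terminal <- NULL
  for (hg in panel@labels) {
    m <- motifs[[hg]]
    if (!all(v %in% m) || length(m) == length(v)) next
    missing <- setdiff(m, v)
    mp <- variantPositions(missing)
    in_uns <- mp %in% uns
    eligible <- in_uns | (length(v) > 0L & (mp < span[1] | mp > span[2]))
    if (!all(eligible)) next
    cand <- list(hg = hg, missing = missing, n = length(missing),
                 depth = depths[[hg]])
    better <- function(cand, best) is.null(best) || cand$n < best$n ||
      (cand$n == best$n && (cand$depth < best$depth ||
       (cand$depth == best$depth && cand$hg < best$hg)))
    if (all(in_uns) && better(cand, best_unscored)) best_unscored <- cand
    if (better(cand, best_terminal)) best_terminal <- cand
  }
  if (length(exact)) {
    ## an exact motif match is clean unless a deeper motif completes it
    ## entirely within positions that were never typed
    if (!is.null(best_unscored))
      return(list(verdict = "incomplete",
                  completingHaplogroup = best_unscored$hg,
                  missingSites = best_unscored$missing))
    exact <- exact[order(depths[exact], exact)]
    return(list(verdict = "clean", completingHaplogroup = exact[1],
                missingSites = character(0)))
  }
  if (is.null(best_terminal))
    return(list(verdict = "unresolved",
                completingHaplogroup = NA_character_,
                missingSites = character(0)))
  list(verdict = "incomplete", completingHaplogroup = best_terminal$hg,
       missingSites = best_terminal$missing)
}

#' Decompose a putative chimeric haplotype
#'
#' Searches haplogroup pairs \code{(h1, h2)} whose cumulative motifs jointly
#' explain the observed variants (shared ancestral variants may belong to
#' both components) and minimises
#' \code{cost = wUnexplained * |variants explained by neither motif| +
#' wMissing * (scored motif sites of h1 absent + same for h2)}, with scored
#' restricted to the sequenced range minus the unscored positions. Ties break
#' towards the pair whose primary component has the higher regional-panel
#' frequency, then lexicographically. The search is pruned to haplogroups
#' whose motif shares at least one variant with the input.
#'
#' @param x a single-haplotype \code{HaplotypeSet}, classified (haplogroup
#'   set) and with a nonempty novel-variant set.
#' @param panel a \code{MotifPanel}.
#' @param wUnexplained,wMissing cost weights (defaults 2 and 1: a chimera
#'   explanation is preferred over declaring many novel variants).
#' @param panels optional \code{\link{RegionalPanelSet}} for tie-breaking.
#' @return a \code{\link{Decomposition}}.
#' @export
decomposeChimera <- function(x, panel, wUnexplained = 2, wMissing = 1,
                             panels = NULL) {
  stopifnot(length(x) == 1L)
  if (length(panel@labels) == 0L) stop("empty motif panel")
  motifs <- .allMotifs(panel)
  v <- x@variants[[1]]
  uns <- x@unscored[[1]]
  lo <- x@range[1, 1]; hi <- x@range[1, 2]
  assigned <- x@haplogroup[1]
  novel <- if (!is.na(assigned) && assigned %in% panel@labels)
    setdiff(v, motifs[[assigned]]) else v

  freq <- function(hg) {
    if (is.null(panels)) return(0)
    key <- paste(.sortTokens(intersect(v, motifs[[hg]])), collapse = " ")
    sum(panels@table$count[panels@table$key == key])
  }
  cands <- panel@labels[vapply(motifs, function(m)
    length(intersect(m, v)) > 0L, logical(1))]
  cands <- unique(c(cands, assigned[!is.na(assigned)]))

  phantom <- function() new("Decomposition",
    id = x@ids[1], verdict = "phantom_bearing",
    primaryVariants = if (!is.na(assigned))
      intersect(v, motifs[[assigned]]) else character(0),
    primaryHg = if (is.na(assigned)) NA_character_ else assigned,
    contaminantVariants = character(0), contaminantHg = NA_character_,
    unexplained = novel, score = Inf)

  if (length(cands) < 2L) return(phantom())

  best <- NULL
  for (ai in seq_len(length(cands) - 1L)) {
    for (bi in seq((ai + 1L), length(cands))) {
      a <- cands[ai]; b <- cands[bi]
      ma <- motifs[[a]]; mb <- motifs[[b]]
      unexp <- setdiff(v, union(ma, mb))
      cost <- wUnexplained * length(unexp) +
        wMissing * (length(.scoredMissing(ma, v, lo, hi, uns)) +
                    length(.scoredMissing(mb, v, lo, hi, uns)))
      ## orient: primary is the assigned haplogroup if present, else the
      ## component explaining more variants
      if (!is.na(assigned) && b == assigned) { tmp <- a; a2 <- b; b2 <- tmp }
      else if (!is.na(assigned) && a == assigned) { a2 <- a; b2 <- b }
      else if (length(intersect(v, mb)) > length(intersect(v, ma))) {
        a2 <- b; b2 <- a
      } else { a2 <- a; b2 <- b }
      cand <- list(primary = a2, contam = b2, cost = cost, unexp = unexp)
      ## equal cost: prefer full coverage (fewer unexplained), then the
      ## primary with higher panel frequency, then lexicographic
      if (is.null(best) || cand$cost < best$cost ||
          (cand$cost == best$cost &&
           (length(cand$unexp) < length(best$unexp) ||
            (length(cand$unexp) == length(best$unexp) &&
             (freq(cand$primary) > freq(best$primary) ||
              (freq(cand$primary) == freq(best$primary) &&
               paste(cand$primary, cand$contam) <
               paste(best$primary, best$contam)))))))
        best <- cand
    }
  }
  contamVars <- intersect(v, motifs[[best$contam]])
  ## the contaminant must actually account for novel variants, otherwise the
  ## decomposition adds nothing over the single-haplogroup reading
  if (!length(intersect(novel, contamVars))) return(phantom())
  new("Decomposition", id = x@ids[1], verdict = "chimera",
      primaryVariants = intersect(v, motifs[[best$primary]]),
      primaryHg = best$primary, contaminantVariants = contamVars,
      contaminantHg = best$contam, unexplained = best$unexp,
      score = best$cost)
}

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition of '%s': %s\n", object@id, object@verdict))
  cat("  primary   :", object@primaryHg, "|",
      paste(object@primaryVariants, collapse = " "), "\n")
  if (length(object@contaminantVariants))
    cat("  contaminant:", object@contaminantHg, "|",
        paste(object@contaminantVariants, collapse = " "), "\n")
  if (length(object@unexplained))
    cat("  unexplained:", paste(object@unexplained, collapse = " "), "\n")
})

#' @rdname Decomposition-class
#' @param x a \code{Decomposition}.
#' @export
verdict <- function(x) x@verdict

#' Curate a haplotype dataset
#'
#' Runs the full curation procedure on every haplotype: classification,
#' exact-motif (clean) check, incomplete-sequence detection, chimera
#' decomposition versus the single-haplogroup reading, and dataset-wide
#' phantom-mutation detection. Verdicts partition the dataset.
#'
#' @param x a \code{HaplotypeSet} (filtered).
#' @param panel a \code{MotifPanel}.
#' @param panels optional \code{\link{RegionalPanelSet}} for decomposition
#'   tie-breaks.
#' @param wUnexplained,wMissing chimera cost weights.
#' @param minBackgrounds for \code{\link{detectPhantoms}}.
#' @return a list with \code{decompositions} (list of
#'   \code{\link{Decomposition}}), \code{report} (one row per haplotype,
#'   mirroring the detected/most-probable/contaminator table layout),
#'   \code{summary} (verdict counts) and \code{phantoms}.
#' @export
curateDataset <- function(x, panel, panels = NULL, wUnexplained = 2,
                          wMissing = 1, minBackgrounds = 2L) {
  motifs <- .allMotifs(panel)
  decomps <- vector("list", length(x))
  names(decomps) <- x@ids
  for (i in seq_len(length(x))) {
    h <- x[i]
    r <- classifyHaplotype(h, panel, motifs = motifs)
    assigned <- r$haplogroup[1]
    h@haplogroup[1] <- assigned
    inc <- detectIncomplete(h, panel)
    if (inc$verdict == "clean") {
      decomps[[i]] <- new("Decomposition", id = h@ids[1], verdict = "clean",
        primaryVariants = h@variants[[1]],
        primaryHg = inc$completingHaplogroup,
        contaminantVariants = character(0), contaminantHg = NA_character_,
        unexplained = character(0), score = 0)
      next
    }
    if (inc$verdict == "incomplete") {
      decomps[[i]] <- new("Decomposition", id = h@ids[1],
        verdict = "incomplete", primaryVariants = h@variants[[1]],
        primaryHg = inc$completingHaplogroup,
        contaminantVariants = character(0), contaminantHg = NA_character_,
        unexplained = character(0),
        score = length(inc$missingSites))
      next
    }
    novel <- setdiff(h@variants[[1]], motifs[[assigned]])
    if (!length(novel)) {
      ## all variants on the assigned background but interior motif sites
      ## absent: best read as an incompletely recovered sequence
      decomps[[i]] <- new("Decomposition", id = h@ids[1],
        verdict = "incomplete", primaryVariants = h@variants[[1]],
        primaryHg = assigned, contaminantVariants = character(0),
        contaminantHg = NA_character_, unexplained = character(0),
        score = r$nMissing[1])
      next
    }
    c1 <- wUnexplained * length(novel) + wMissing * r$nMissing[1]
    dec <- decomposeChimera(h, panel, wUnexplained, wMissing, panels)
    decomps[[i]] <- if (dec@verdict == "chimera" && dec@score < c1) dec
    else new("Decomposition", id = h@ids[1], verdict = "phantom_bearing",
             primaryVariants = intersect(h@variants[[1]], motifs[[assigned]]),
             primaryHg = assigned, contaminantVariants = character(0),
             contaminantHg = NA_character_, unexplained = novel, score = c1)
  }
  phantoms <- detectPhantoms(x, panel, minBackgrounds)
  report <- do.call(rbind, lapply(decomps, function(d) data.frame(
    id = d@id, verdict = d@verdict,
    detected = formatVariantString(
      x@variants[[match(d@id, x@ids)]], x@unscored[[match(d@id, x@ids)]]),
    most_probable = paste(d@primaryVariants, collapse = " "),
    hg_primary = d@primaryHg,
    contaminator = paste(d@contaminantVariants, collapse = " "),
    hg_contaminator = d@contaminantHg,
    unexplained = paste(d@unexplained, collapse = " "),
    score = if (is.finite(d@score)) d@score else NA_real_,
    stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  list(decompositions = decomps, report = report,
       summary = table(factor(vapply(decomps, verdict, character(1)),
                              levels = c("clean", "incomplete", "chimera",
                                         "phantom_bearing"))),
       phantoms = phantoms)
}

#' Write a curation report as TSV
#'
#' @param curation result of \code{\link{curateDataset}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCurationReport <- function(curation, path) {
  utils::write.table(curation$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
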