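## MotifPanel methods ---------------------------------------------------------

#' @describeIn MotifPanel-class number of nodes.
#' @param x a \code{MotifPanel}.
#' @export
setMethod("length", "MotifPanel", function(x) length(x@labels))

setMethod("show", "MotifPanel", function(object) {
  cat(sprintf("MotifPanel with %d haplogroups, root '%s', depth %d\n",
              length(object@labels), panelRoot(object),
              max(panelDepths(object))))
})

#' @rdname MotifPanel-class
#' @param x a \code{MotifPanel}.
#' @export
panelLabels <- function(x) x@labels

#' @rdname MotifPanel-class
#' @export
panelRoot <- function(x) x@labels[is.na(x@parent[x@labels])]

#' @rdname MotifPanel-class
#' @export
panelParents <- function(x) x@parent

#' @rdname MotifPanel-class
#' @export
privateMotifs <- function(x) x@private

#' Depth of every node (root = 0)
#' @param x a \code{MotifPanel}.
#' @return named integer vector.
#' @export
panelDepths <- function(x) {
  vapply(x@labels, function(lab) {
    d <- 0L
    cur <- x@parent[[lab]]
    while (!is.na(cur)) {
      d <- d + 1L
      cur <- x@parent[[cur]]
    }
    d
  }, integer(1))
}

## root path, root first
.rootPath <- function(panel, hg) {
  path <- character(0)
  cur <- hg
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- panel@parent[[cur]]
  }
  path
}

#' Is one haplogroup an ancestor of another?
#'
#' @param panel a \code{MotifPanel}.
#' @param a,b node labels. A node is considered an ancestor of itself only
#'   when \code{a == b} and \code{strict = FALSE}.
#' @param strict drop the reflexive case.
#' @return logical.
#' @export
isAncestor <- function(panel, a, b, strict = TRUE) {
  path <- .rootPath(panel, b)
  if (strict) path <- path[path != b]
  a %in% path
}

#' Phylogenetic independence of two haplogroup backgrounds
#'
#' Two backgrounds are independent when neither is an ancestor of the other
#' in the motif tree.
#'
#' @param panel a \code{MotifPanel}.
#' @param a,b node labels.
#' @return logical.
#' @export
independentBackgrounds <- function(panel, a, b) {
  a != b && !isAncestor(panel, a, b) && !isAncestor(panel, b, a)
}

#' Load a motif panel from TSV
#'
#' Dialect: tab-separated columns \code{haplogroup}, \code{parent} (empty for
#' the root) and \code{motif}, the space-separated private diagnostic
#' variants acquired on the edge from the parent (minus-16000 HVS-I shorthand
#' allowed; positions >= 1000 are taken as-is, so coding-region diagnostics
#' can be mixed in).
#'
#' @param path TSV file.
#' @param offset added to positions below 1000 (default 16000).
#' @return a validated \code{\link{MotifPanel}}.
#' @export
loadMotifPanel <- function(path, offset = 16000L) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "")
  if (nrow(tb) == 0L) stop("motif panel file is empty")
  if (!all(c("haplogroup", "parent", "motif") %in% names(tb)))
    stop("motif panel needs columns haplogroup, parent, motif")
  tb$motif[is.na(tb$motif)] <- ""
  private <- lapply(tb$motif, function(s)
    .tokenizeVariantString(s, offset)$variants)
  names(private) <- tb$haplogroup
  panel <- new("MotifPanel", labels = tb$haplogroup,
               parent = stats::setNames(tb$parent, tb$haplogroup),
               private = private)
  validObject(panel)
  panel
}

#' Build a motif panel in code
#'
#' @param haplogroup,parent character vectors (parent \code{NA} for root).
#' @param private list of canonical variant-token vectors.
#' @return a validated \code{\link{MotifPanel}}.
#' @export
motifPanel <- function(haplogroup, parent, private) {
  names(private) <- haplogroup
  panel <- new("MotifPanel", labels = haplogroup,
               parent = stats::setNames(as.character(parent), haplogroup),
               private = lapply(private, .sortTokens))
  validObject(panel)
  panel
}

#' Cumulative motif of a haplogroup
#'
#' Union of the private variants along the root path; a back-mutation token
#' (\code{@@pos}) cancels any earlier variant at that position (and is itself
#' not part of the cumulative motif).
#'
#' @param panel a \code{MotifPanel}.
#' @param hg node label.
#' @return character vector of canonical variant tokens.
#' @export
cumulativeMotif <- function(panel, hg) {
  if (!hg %in% panel@labels) stop("unknown haplogroup '", hg, "'")
  motif <- character(0)
  for (node in .rootPath(panel, hg)) {
    for (tok in panel@private[[node]]) {
      if (startsWith(tok, "@")) {
        pos <- variantPositions(tok)
        motif <- motif[variantPositions(motif) != pos]
      } else {
        motif <- c(motif, tok)
      }
    }
  }
  .sortTokens(motif)
}

## cache all cumulative motifs of a panel
.allMotifs <- function(panel) {
  stats::setNames(lapply(panel@labels, cumulativeMotif, panel = panel),
                  panel@labels)
}

## Classification -------------------------------------------------------------

#' Classify a haplotype on the motif tree
#'
#' Ranks every panel haplogroup by
#' \code{score = |shared| - wMiss * |missing sites that were actually
#' sequenced and scored| - wExtra * |extra|}, where \emph{shared} are the
#' haplotype variants found in the cumulative motif, \emph{missing} are motif
#' variants absent from the haplotype (motif sites outside the sequenced
#' range or among the unscored positions are not penalized), and \emph{extra}
#' are haplotype variants beyond the motif. Ties break towards shallower tree
#' depth, then lexicographic label.
#'
#' @param x a \code{HaplotypeSet} (filtered; see
#'   \code{\link{applySiteFilter}}).
#' @param panel a \code{MotifPanel}.
#' @param wMiss,wExtra penalty weights (both default 1).
#' @param motifs optional precomputed motif cache (internal use).
#' @return for a single haplotype, a data.frame with columns
#'   \code{haplogroup}, \code{score}, \code{nShared}, \code{nMissing},
#'   \code{nExtra}, \code{depth} and list-columns \code{shared},
#'   \code{missing}, \code{extra}, ranked best first; for several haplotypes,
#'   a named list of such data.frames.
#' @export
classifyHaplotype <- function(x, panel, wMiss = 1, wExtra = 1,
                              motifs = NULL) {
  if (length(panel@labels) == 0L) stop("empty motif panel")
  if (is.null(motifs)) motifs <- .allMotifs(panel)
  depths <- panelDepths(panel)
  one <- function(i) {
    v <- x@variants[[i]]
    uns <- x@unscored[[i]]
    lo <- x@range[i, 1]; hi <- x@range[i, 2]
    nlab <- length(panel@labels)
    shared <- missing <- extra <- vector("list", nlab)
    for (j in seq_len(nlab)) {
      m <- motifs[[panel@labels[j]]]
      shared[[j]] <- intersect(v, m)
      miss <- setdiff(m, v)
      mp <- variantPositions(miss)
      missing[[j]] <- miss[mp >= lo & mp <= hi & !(mp %in% uns)]
      extra[[j]] <- setdiff(v, m)
    }
    ns <- lengths(shared); nm <- lengths(missing); ne <- lengths(extra)
    out <- data.frame(haplogroup = panel@labels,
                      score = ns - wMiss * nm - wExtra * ne,
                      nShared = ns, nMissing = nm, nExtra = ne,
                      depth = unname(depths[panel@labels]),
                      shared = I(shared), missing = I(missing),
                      extra = I(extra), stringsAsFactors = FALSE)
    out[order(-out$score, out$depth, out$haplogroup), , drop = FALSE]
  }
  res <- lapply(seq_len(length(x)), one)
  names(res) <- x@ids
  if (length(res) == 1L) res[[1]] else res
}

#' Assign top-ranked haplogroup labels to a haplotype set
#'
#' @param x a \code{HaplotypeSet}.
#' @param panel a \code{MotifPanel}.
#' @param ... passed to \code{\link{classifyHaplotype}}.
#' @return \code{x} with the \code{haplogroup} slot filled.
#' @export
assignHaplogroups <- function(x, panel, ...) {
  motifs <- .allMotifs(panel)
  for (i in seq_len(length(x))) {
    r <- classifyHaplotype(x[i], panel, motifs = motifs, ...)
    x@haplogroup[i] <- r$haplogroup[1]
  }
  x
}
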