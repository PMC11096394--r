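## HaplotypeSet methods and operations ---------------------------------------

#' @describeIn HaplotypeSet-class number of haplotypes.
#' @param x a \code{HaplotypeSet}.
#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@ids))

#' @describeIn HaplotypeSet-class subset by index, logical or id.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("HaplotypeSet", ids = x@ids[i], variants = x@variants[i],
      unscored = x@unscored[i], range = x@range[i, , drop = FALSE],
      haplogroup = x@haplogroup[i], region = x@region[i],
      epoch = x@epoch[i])
})

setMethod("show", "HaplotypeSet", function(object) {
  n <- length(object)
  cat("HaplotypeSet with", n, "haplotypes\n")
  k <- min(n, 5L)
  for (i in seq_len(k)) {
    cat(sprintf("  %s [%s|%s|%s]: %s\n", object@ids[i],
                object@haplogroup[i], object@region[i], object@epoch[i],
                formatVariantString(object@variants[[i]],
                                    object@unscored[[i]])))
  }
  if (n > k) cat("  ...", n - k, "more\n")
})

#' @rdname HaplotypeSet-class
#' @param x a \code{HaplotypeSet}.
#' @export
hapIds <- function(x) x@ids

#' @rdname HaplotypeSet-class
#' @export
variantSets <- function(x) stats::setNames(x@variants, x@ids)

#' @rdname HaplotypeSet-class
#' @export
unscoredSites <- function(x) stats::setNames(x@unscored, x@ids)

#' @rdname HaplotypeSet-class
#' @export
seqRanges <- function(x) x@range

#' @rdname HaplotypeSet-class
#' @export
haplogroupLabels <- function(x) stats::setNames(x@haplogroup, x@ids)

#' @rdname HaplotypeSet-class
#' @export
regionLabels <- function(x) stats::setNames(x@region, x@ids)

#' @rdname HaplotypeSet-class
#' @export
epochLabels <- function(x) stats::setNames(x@epoch, x@ids)

#' Parse HVS-I variant strings
#'
#' Parses whitespace-separated variant strings in the minus-16000 table
#' notation into a \code{\link{HaplotypeSet}}. Bare numeric tokens are
#' transitions, a base-letter suffix marks the derived base (transversion),
#' \code{@@} prefixes back mutations, \code{d} suffixes deletions,
#' \code{pos.kB} denotes insertions, and parenthesized tokens are recorded as
#' unscored positions. Positions below 1000 get \code{offset} added.
#'
#' @param text character vector of variant strings (may be empty strings).
#' @param offset integer added to positions below 1000 (default 16000; use 0
#'   for whole-molecule variant lists).
#' @param ids haplotype identifiers (defaults to names or \code{hap<i>}).
#' @param range sequenced interval; defaults to
#'   \code{c(offset + 1, offset + 400)} for HVS-I input, whole molecule when
#'   \code{offset = 0}.
#' @param haplogroup,region,epoch metadata, recycled.
#' @return a \code{HaplotypeSet}.
#' @examples
#' parseVariantString("093 192")
#' parseVariantString("(172 219) 239 278")
#' @export
parseVariantString <- function(text, offset = 16000L, ids = NULL,
                               range = NULL, haplogroup = NA_character_,
                               region = NA_character_,
                               epoch = NA_character_) {
  if (is.null(ids))
    ids <- if (!is.null(names(text))) names(text)
           else paste0("hap", seq_along(text))
  if (is.null(range))
    range <- if (offset > 0L) c(offset + 1L, offset + 400L)
             else c(1L, .MT_LEN)
  parsed <- lapply(text, .tokenizeVariantString, offset = offset)
  ## widen the sequenced interval when tokens fall outside the nominal
  ## window (e.g. the 16519 hotspot quoted alongside HVS-I strings)
  allpos <- c(unlist(lapply(parsed, function(p)
    variantPositions(p$variants))), range)
  range <- c(min(range[1], allpos), max(range[2], allpos))
  HaplotypeSet(ids = ids,
               variants = lapply(parsed, `[[`, "variants"),
               unscored = lapply(parsed, `[[`, "unscored"),
               range = range, haplogroup = haplogroup, region = region,
               epoch = epoch)
}

## Site filter ----------------------------------------------------------------

#' Site filter for hypervariable and indel-prone positions
#'
#' Positions excluded from trees and statistics: the 16519 hotspot and indel
#' variants around positions 309, 522, 573 and 16193. Substitutions at the
#' indel anchors are kept; only insertion/deletion variants within
#' \code{radius} of an anchor are dropped. Filtering is idempotent.
#'
#' @param excludedPositions integer positions removed outright.
#' @param indelAnchors centres of indel-prone neighbourhoods.
#' @param radius half-width of each neighbourhood in positions.
#' @return a list of class \code{siteFilter}.
#' @export
siteFilter <- function(excludedPositions = 16519L,
                       indelAnchors = c(309L, 522L, 573L, 16193L),
                       radius = 3L) {
  structure(list(excludedPositions = as.integer(excludedPositions),
                 indelAnchors = as.integer(indelAnchors),
                 radius = as.integer(radius)),
            class = "siteFilter")
}

.filterTokens <- function(tokens, f) {
  if (length(tokens) == 0L) return(tokens)
  pos <- variantPositions(tokens)
  kind <- variantKinds(tokens)
  drop <- pos %in% f$excludedPositions
  indel <- kind %in% c("insertion", "deletion")
  if (any(indel) && length(f$indelAnchors)) {
    near <- vapply(pos, function(p)
      any(abs(p - f$indelAnchors) <= f$radius), logical(1))
    drop <- drop | (indel & near)
  }
  tokens[!drop]
}

#' Apply a site filter to a haplotype set
#'
#' Removes the excluded positions from both the variant and unscored sets of
#' every haplotype. All downstream statistics consume filtered haplotypes.
#'
#' @param x a \code{HaplotypeSet}.
#' @param filter a \code{\link{siteFilter}} (default filter when omitted).
#' @return a filtered \code{HaplotypeSet}.
#' @export
applySiteFilter <- function(x, filter = siteFilter()) {
  x@variants <- lapply(x@variants, .filterTokens, f = filter)
  x@unscored <- lapply(x@unscored, function(u)
    u[!u %in% filter$excludedPositions])
  validObject(x)
  x
}

#' Restrict haplotypes to a coordinate window
#'
#' Drops variants and unscored positions outside \code{[lo, hi]} and
#' intersects each sequenced range with the window.
#'
#' @param x a \code{HaplotypeSet}.
#' @param lo,hi closed window bounds (default HVS-I, 16001-16400).
#' @return a windowed \code{HaplotypeSet}.
#' @export
restrictToWindow <- function(x, lo = 16001L, hi = 16400L) {
  stopifnot(lo <= hi)
  x@variants <- lapply(x@variants, function(v) {
    p <- variantPositions(v)
    v[p >= lo & p <= hi]
  })
  x@unscored <- lapply(x@unscored, function(u) u[u >= lo & u <= hi])
  x@range[, 1] <- pmax(x@range[, 1], lo)
  x@range[, 2] <- pmin(x@range[, 2], hi)
  validObject(x)
  x
}

#' Canonical identity keys of haplotypes
#'
#' The canonical identity of a haplotype is its filtered variant set within
#' the comparison window, rendered as a sorted token string; unscored
#' positions never contribute to identity.
#'
#' @param x a \code{HaplotypeSet}.
#' @param filter a \code{\link{siteFilter}}, or \code{NULL} to skip.
#' @param window length-2 window, or \code{NULL} to skip windowing.
#' @return named character vector of keys.
#' @export
canonicalKeys <- function(x, filter = siteFilter(),
                          window = c(16001L, 16400L)) {
  if (!is.null(filter)) x <- applySiteFilter(x, filter)
  if (!is.null(window)) x <- restrictToWindow(x, window[1], window[2])
  vapply(stats::setNames(x@variants, x@ids),
         function(v) paste(v, collapse = " "), character(1))
}

## Table IO -------------------------------------------------------------------

#' Read / write haplotype tables
#'
#' Tab-separated tables with columns \code{id}, \code{variants} (a variant
#' string, parenthesized unscored tokens allowed inline), and optional
#' \code{haplogroup}, \code{region}, \code{epoch}.
#'
#' @param path file path.
#' @param offset passed to \code{\link{parseVariantString}}.
#' @return \code{readHaplotypeTable}: a \code{HaplotypeSet}.
#' @export
readHaplotypeTable <- function(path, offset = 16000L) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "")
  if (!all(c("id", "variants") %in% names(tb)))
    stop("haplotype table needs columns 'id' and 'variants'")
  tb$variants[is.na(tb$variants)] <- ""
  get <- function(col) if (col %in% names(tb)) tb[[col]] else NA_character_
  parseVariantString(tb$variants, offset = offset, ids = tb$id,
                     haplogroup = get("haplogroup"), region = get("region"),
                     epoch = get("epoch"))
}

#' @rdname readHaplotypeTable
#' @param x a \code{HaplotypeSet}.
#' @return \code{writeHaplotypeTable}: the path, invisibly.
#' @export
writeHaplotypeTable <- function(x, path, offset = 16000L) {
  tb <- data.frame(
    id = x@ids,
    variants = mapply(formatVariantString, x@variants, x@unscored,
                      MoreArgs = list(offset = offset)),
    haplogroup = x@haplogroup, region = x@region, epoch = x@epoch,
    stringsAsFactors = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned FASTA sequences as haplotypes
#'
#' Scores every sequence of an aligned FASTA file against a reference
#' sequence (the first record by default) and returns the differences as a
#' \code{HaplotypeSet} in reference coordinates.
#'
#' @param path FASTA file of pre-aligned sequences.
#' @param reference reference id within the file, or a sequence string; by
#'   default the first record is the reference and is dropped from the output.
#' @return a \code{HaplotypeSet} spanning the full reference length.
#' @export
readFastaHaplotypes <- function(path, reference = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  if (is.null(reference)) {
    ref <- as.character(seqs[[1]])
    seqs <- seqs[-1]
  } else if (length(reference) == 1L && reference %in% nm) {
    ref <- as.character(seqs[[reference]])
    seqs <- seqs[nm != reference]
  } else {
    ref <- as.character(reference)
  }
  vars <- lapply(seq_along(seqs), function(i)
    scoreAgainstReference(as.character(seqs[[i]]), ref))
  reflen <- nchar(gsub("-", "", ref))
  HaplotypeSet(ids = names(seqs), variants = vars,
               range = c(1L, as.integer(reflen)))
}
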