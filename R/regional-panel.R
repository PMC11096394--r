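## Regional panels & match search --------------------------------------------

setMethod("show", "RegionalPanelSet", function(object) {
  tb <- object@table
  per <- tapply(tb$count, tb$region, sum)
  cat("RegionalPanelSet:",
      paste(sprintf("%s=%d", names(per), as.integer(per)), collapse = ", "),
      "\n")
})

#' @rdname RegionalPanelSet-class
#' @param x a \code{RegionalPanelSet}.
#' @export
panelTable <- function(x) x@table

#' @rdname RegionalPanelSet-class
#' @export
panelRegions <- function(x) unique(x@table$region)

#' Build regional panels
#'
#' \code{regionalPanels} builds panels from a \code{HaplotypeSet} (one panel
#' per region label); \code{loadRegionalPanels} reads a TSV with columns
#' \code{region}, \code{variants} and optional \code{count} (default 1).
#' Haplotypes are canonicalized (site filter + window) before keying so that
#' matching is on filtered identity.
#'
#' @param x a \code{HaplotypeSet}.
#' @param filter,window passed to \code{\link{canonicalKeys}}.
#' @return a \code{\link{RegionalPanelSet}}.
#' @export
regionalPanels <- function(x, filter = siteFilter(),
                           window = c(16001L, 16400L)) {
  keys <- canonicalKeys(x, filter, window)
  tb <- as.data.frame(table(region = x@region, key = keys),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, ]
  new("RegionalPanelSet",
      table = data.frame(region = tb$region, key = tb$key,
                         count = as.integer(tb$Freq),
                         stringsAsFactors = FALSE))
}

#' @rdname regionalPanels
#' @param path TSV file.
#' @param offset passed to \code{\link{parseVariantString}}.
#' @export
loadRegionalPanels <- function(path, offset = 16000L,
                               filter = siteFilter(),
                               window = c(16001L, 16400L)) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "")
  if (!all(c("region", "variants") %in% names(tb)))
    stop("regional panel needs columns region, variants")
  tb$variants[is.na(tb$variants)] <- ""
  if (!"count" %in% names(tb)) tb$count <- 1L
  hs <- parseVariantString(tb$variants, offset = offset,
                           ids = paste0("p", seq_len(nrow(tb))))
  keys <- canonicalKeys(hs, filter, window)
  agg <- stats::aggregate(count ~ region + key,
                          data = data.frame(region = tb$region, key = keys,
                                            count = as.integer(tb$count)),
                          FUN = sum)
  new("RegionalPanelSet", table = agg)
}

#' Count exact haplotype matches per region
#'
#' Matching is exact equality of the canonical (filtered, window-restricted)
#' variant set; counts are the number of panel observations carrying the
#' identical haplotype, aggregated per region. With \code{mode = "nearest"},
#' the minimal symmetric-difference size to any panel haplotype of each
#' region is reported instead (0 for an exact match, \code{NA} for an empty
#' region), supporting "closest counterpart" statements.
#'
#' @param x a \code{HaplotypeSet} of query haplotypes.
#' @param panels a \code{\link{RegionalPanelSet}}.
#' @param filter,window canonicalization, as in \code{\link{canonicalKeys}}.
#' @param mode \code{"exact"} (default) or \code{"nearest"}.
#' @return integer matrix, haplotypes x regions.
#' @export
findMatches <- function(x, panels, filter = siteFilter(),
                        window = c(16001L, 16400L), mode = "exact") {
  mode <- match.arg(mode, c("exact", "nearest"))
  keys <- canonicalKeys(x, filter, window)
  tb <- panels@table
  regions <- unique(tb$region)
  out <- matrix(0L, nrow = length(keys), ncol = length(regions),
                dimnames = list(x@ids, regions))
  if (mode == "exact") {
    for (r in regions) {
      sub <- tb[tb$region == r, ]
      m <- match(keys, sub$key)
      out[, r] <- ifelse(is.na(m), 0L, sub$count[m])
    }
  } else {
    split_keys <- strsplit(tb$key, " ", fixed = TRUE)
    qsets <- strsplit(unname(keys), " ", fixed = TRUE)
    qsets <- lapply(qsets, function(v) v[nzchar(v)])
    for (r in regions) {
      idx <- which(tb$region == r)
      if (!length(idx)) { out[, r] <- NA_integer_; next }
      psets <- lapply(split_keys[idx], function(v) v[nzchar(v)])
      out[, r] <- vapply(qsets, function(q)
        min(vapply(psets, function(p)
          length(setdiff(q, p)) + length(setdiff(p, q)), integer(1))),
        integer(1))
    }
  }
  out
}

#' Load a wide per-region match-count table
#'
#' Reads a TSV whose first columns are \code{haplotype} (a variant string)
#' and \code{haplogroup}, followed by one count column per region (extra
#' non-numeric annotation columns such as \code{other} or marker flags are
#' ignored), and melts it into a \code{\link{RegionalPanelSet}}. This is the
#' layout of published per-region match tables.
#'
#' @param path TSV file.
#' @param regions which columns to treat as regions (default: all integer
#'   columns after the first two).
#' @param offset passed to \code{\link{parseVariantString}}.
#' @param filter,window canonicalization, as in \code{\link{canonicalKeys}}.
#' @return a \code{\link{RegionalPanelSet}}; the haplotype strings and
#'   haplogroups are kept in the \code{"haplotypes"} attribute.
#' @export
loadMatchCountTable <- function(path, regions = NULL, offset = 16000L,
                                filter = siteFilter(),
                                window = c(16001L, 16400L)) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "")
  if (!"haplotype" %in% names(tb))
    stop("match-count table needs a 'haplotype' column")
  if (is.null(regions)) {
    cand <- setdiff(names(tb), c("haplotype", "haplogroup", "other",
                                 "asterisk"))
    regions <- cand[vapply(tb[cand], is.numeric, logical(1))]
  }
  hs <- parseVariantString(tb$haplotype, offset = offset,
                           ids = paste0("r", seq_len(nrow(tb))))
  keys <- unname(canonicalKeys(hs, filter, window))
  rows <- list()
  for (r in regions) {
    keep <- !is.na(tb[[r]]) & tb[[r]] > 0
    if (any(keep))
      rows[[r]] <- data.frame(region = r, key = keys[keep],
                              count = as.integer(tb[[r]][keep]),
                              stringsAsFactors = FALSE)
  }
  out <- new("RegionalPanelSet", table = do.call(rbind, c(rows,
             list(make.row.names = FALSE))))
  attr(out, "haplotypes") <- data.frame(
    key = keys, haplotype = tb$haplotype,
    haplogroup = if ("haplogroup" %in% names(tb)) tb$haplogroup
                 else NA_character_, stringsAsFactors = FALSE)
  out
}
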