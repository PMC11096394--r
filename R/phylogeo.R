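## Haplotype-sharing phylogeography ------------------------------------------

#' Build a binary presence matrix
#'
#' Rows are canonical haplotypes, columns are population labels (islands,
#' continental regions, epochs); a cell is 1 when the haplotype was observed
#' in that population. Observation counts are kept in the \code{"counts"}
#' attribute.
#'
#' @param x a \code{HaplotypeSet} whose \code{region} slot holds the
#'   population label of each observation, or a \code{RegionalPanelSet}.
#' @param populations optional column order/subset; duplicates are an error.
#' @param filter,window canonicalization, as in \code{\link{canonicalKeys}}.
#' @return binary integer matrix with haplotype keys as rownames.
#' @export
buildPresenceMatrix <- function(x, populations = NULL,
                                filter = siteFilter(),
                                window = c(16001L, 16400L)) {
  if (is(x, "RegionalPanelSet")) {
    tb <- x@table
  } else {
    tb <- data.frame(region = x@region,
                     key = unname(canonicalKeys(x, filter, window)),
                     count = 1L, stringsAsFactors = FALSE)
  }
  if (is.null(populations)) populations <- unique(tb$region)
  if (anyDuplicated(populations)) stop("duplicate population label")
  tb <- tb[tb$region %in% populations, , drop = FALSE]
  keys <- unique(tb$key)
  counts <- matrix(0L, length(keys), length(populations),
                   dimnames = list(keys, populations))
  ## positional indexing: the reference-type haplotype has the empty key ""
  ri <- match(tb$key, keys)
  ci <- match(tb$region, populations)
  for (r in seq_len(nrow(tb)))
    counts[ri[r], ci[r]] <- counts[ri[r], ci[r]] + tb$count[r]
  m <- (counts > 0L) + 0L
  attr(m, "counts") <- counts
  m
}

#' Venn partition of haplotype presence
#'
#' For 2 or 3 groups of populations, counts the haplotypes present in
#' exactly each nonempty subset of groups, plus the haplotypes present in
#' none.
#'
#' @param m a presence matrix (\code{\link{buildPresenceMatrix}}).
#' @param groups named list of 2-3 character vectors of column labels;
#'   groups may overlap, but none may be empty.
#' @return named integer vector; cell names are group names joined by
#'   \code{&}, plus \code{none}. Cells sum to \code{nrow(m)}.
#' @export
vennPartition <- function(m, groups) {
  if (length(groups) < 2L || length(groups) > 3L)
    stop("vennPartition needs 2 or 3 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("empty group definition")
  miss <- setdiff(unlist(groups), colnames(m))
  if (length(miss))
    stop("unknown population(s): ", paste(miss, collapse = ", "))
  ing <- vapply(groups, function(g)
    rowSums(m[, g, drop = FALSE]) > 0, logical(nrow(m)))
  if (is.null(dim(ing))) ing <- matrix(ing, nrow = 1)
  gnames <- names(groups)
  out <- integer(0)
  for (k in rev(seq_along(groups))) {
    for (sel in utils::combn(seq_along(groups), k, simplify = FALSE)) {
      inside <- rowSums(ing[, sel, drop = FALSE]) == length(sel) &
        rowSums(ing[, -sel, drop = FALSE]) == 0
      out[paste(gnames[sel], collapse = "&")] <- sum(inside)
    }
  }
  out["none"] <- sum(rowSums(ing) == 0)
  out
}

#' Persistence of an earlier haplotype pool in a later one
#'
#' Reports both readings of persistence: the share of the later pool that is
#' of indigenous type, \code{|indigenous sect later| / |later|}, and the
#' survival share of the indigenous pool,
#' \code{|indigenous sect later| / |indigenous|}.
#'
#' @param indigenous,later character vectors of canonical haplotype keys
#'   (or \code{HaplotypeSet}s, canonicalized with defaults).
#' @return named numeric vector \code{c(shareOfLater, survivalShare)}.
#' @export
persistenceFraction <- function(indigenous, later) {
  if (is(indigenous, "HaplotypeSet")) indigenous <- canonicalKeys(indigenous)
  if (is(later, "HaplotypeSet")) later <- canonicalKeys(later)
  indigenous <- unique(indigenous)
  later <- unique(later)
  if (!length(later)) stop("later haplotype set is empty")
  if (!length(indigenous)) stop("indigenous haplotype set is empty")
  both <- length(intersect(indigenous, later))
  c(shareOfLater = both / length(later),
    survivalShare = both / length(indigenous))
}

#' Exclusive-region labels for haplotypes
#'
#' For every row of a presence matrix, considers only the columns belonging
#' to the given region groups and returns the name of the single group that
#' contains all of the haplotype's presences, \code{"shared"} when presences
#' span several groups, or \code{"none"} when there are none.
#'
#' @param m a presence matrix.
#' @param regionGroups named list of column-label vectors, e.g.
#'   \code{list(Europe = c("IP","FR","IT"), NorthAfrica = c("NW","NA"))}.
#' @return named character vector, one label per row of \code{m}.
#' @export
exclusiveRegionLabels <- function(m, regionGroups) {
  cols <- unlist(regionGroups)
  miss <- setdiff(cols, colnames(m))
  if (length(miss))
    stop("unknown population(s): ", paste(miss, collapse = ", "))
  ing <- vapply(regionGroups, function(g)
    rowSums(m[, g, drop = FALSE]) > 0, logical(nrow(m)))
  if (is.null(dim(ing))) ing <- matrix(ing, nrow = 1,
                                       dimnames = list(NULL,
                                                       names(regionGroups)))
  lab <- apply(ing, 1, function(row) {
    hit <- names(regionGroups)[row]
    if (length(hit) == 0L) "none"
    else if (length(hit) == 1L) hit
    else "shared"
  })
  stats::setNames(lab, rownames(m))
}

#' Match-based distances between populations
#'
#' Population dissimilarity computed from shared versus unshared haplotype
#' presence rather than haplotype frequencies, which is robust to
#' drift-inflated frequency differences. Default is the Jaccard
#' dissimilarity \code{D(A,B) = 1 - |A sect B| / |A union B|} on the
#' presence sets; \code{method = "min"} uses
#' \code{1 - |A sect B| / min(|A|, |B|)}. In \code{mode =
#' "shared_indigenous"} the rows are restricted to a reference (indigenous)
#' haplotype set so that populations are compared by their sharing of those
#' haplotypes alone; \code{mode = "own_pool"} compares full haplotype pools.
#'
#' @param m a presence matrix.
#' @param mode \code{"own_pool"} (default) or \code{"shared_indigenous"}.
#' @param method \code{"jaccard"} (default) or \code{"min"}.
#' @param indigenousKeys row names to restrict to when
#'   \code{mode = "shared_indigenous"}.
#' @return symmetric \code{dist}-able matrix with zero diagonal.
#' @export
matchDistance <- function(m, mode = c("own_pool", "shared_indigenous"),
                          method = c("jaccard", "min"),
                          indigenousKeys = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "shared_indigenous") {
    if (is.null(indigenousKeys))
      stop("mode 'shared_indigenous' needs indigenousKeys")
    m <- m[rownames(m) %in% indigenousKeys, , drop = FALSE]
  }
  sizes <- colSums(m)
  if (any(sizes == 0))
    stop("population(s) with empty haplotype set: ",
         paste(colnames(m)[sizes == 0], collapse = ", "))
  p <- ncol(m)
  d <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  inter <- crossprod(m)          # |A sect B|
  for (a in seq_len(p)) for (b in seq_len(p)) {
    if (a == b) next
    i <- inter[a, b]
    d[a, b] <- if (method == "jaccard")
      1 - i / (sizes[a] + sizes[b] - i)
    else 1 - i / min(sizes[a], sizes[b])
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower double-centering of \code{-d^2/2}, eigendecomposition, and
#' coordinates scaled by the square root of the top-k positive eigenvalues.
#' Negative eigenvalues are reported but not used; optional Cailliez or
#' Lingoes corrections make the matrix Euclidean first.
#'
#' @param d symmetric distance matrix (zero diagonal) or \code{dist}.
#' @param k number of coordinate axes (default 2, capped at the number of
#'   positive eigenvalues).
#' @param correction \code{"none"} (default), \code{"cailliez"} or
#'   \code{"lingoes"}.
#' @return list with \code{coordinates} (n x k), \code{eigenvalues},
#'   \code{varianceFractions} (per positive eigenvalue) and
#'   \code{negativeEigenvalues}.
#' @export
pcoaAnalysis <- function(d, k = 2L, correction = c("none", "cailliez",
                                                   "lingoes")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (correction == "lingoes") {
    cst <- max(0, -min(eigen(.gower(d), symmetric = TRUE,
                             only.values = TRUE)$values))
    off <- row(d) != col(d)
    d[off] <- sqrt(d[off]^2 + 2 * cst)
  }
  fit <- stats::cmdscale(d, k = min(k, nrow(d) - 1L), eig = TRUE,
                         add = (correction == "cailliez"))
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  kk <- min(k, length(pos))
  coords <- fit$points[, seq_len(kk), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(kk))
  list(coordinates = coords, eigenvalues = eig,
       varianceFractions = if (length(pos)) pos / sum(pos) else numeric(0),
       negativeEigenvalues = eig[eig < -1e-12])
}

.gower <- function(d) {
  a <- -0.5 * d^2
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}
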