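## Rho-statistic coalescence dating ------------------------------------------

setMethod("show", "FounderClade", function(object) {
  cat(sprintf("FounderClade '%s': %d members, %d masked sites, rho = %.3f\n",
              object@name, length(object@members), length(object@siteMask),
              rhoStatistic(object)))
})

setMethod("show", "MutationClock", function(object) {
  cat(sprintf(paste0("MutationClock: 1 mutation / %.0f yr (95%% CI %.0f-",
                     "%.0f); %.3g /site/yr over %d sites\n"),
              object@yearsPerMutation, object@ci[1], object@ci[2],
              object@perSiteRate, object@effectiveLength))
})

## per-member mutation counts against the founder, restricted to the mask
.memberDiffs <- function(clade) {
  mask <- clade@siteMask
  f <- clade@founder[variantPositions(clade@founder) %in% mask]
  vapply(clade@members, function(m) {
    m <- m[variantPositions(m) %in% mask]
    length(setdiff(m, f)) + length(setdiff(f, m))
  }, integer(1))
}

#' Rho statistic of a founder clade
#'
#' Mean number of masked-site mutational differences between the founder
#' haplotype and its members: \code{rho = sum(d_i) / n}.
#'
#' @param clade a \code{\link{FounderClade}}.
#' @return numeric rho.
#' @export
rhoStatistic <- function(clade) {
  if (length(clade@members) == 0L) stop("empty clade")
  mean(.memberDiffs(clade))
}

#' Site bootstrap of the rho statistic
#'
#' Each replicate resamples the masked alignment columns with replacement,
#' recomputes the per-member difference counts and rho; the confidence
#' interval is the (2.5, 97.5) percentile interval of the replicate values.
#'
#' @param clade a \code{\link{FounderClade}}.
#' @param B number of bootstrap replicates (default 3600).
#' @param seed optional RNG seed.
#' @return list with \code{rho}, \code{samples} (length B) and \code{ci}.
#' @export
bootstrapRho <- function(clade, B = 3600L, seed = NULL) {
  stopifnot(B >= 1L)
  L <- length(clade@siteMask)
  if (L == 0L) stop("clade has a zero-width site mask")
  if (!is.null(seed)) set.seed(seed)
  n <- length(clade@members)
  mask <- clade@siteMask
  f <- clade@founder[variantPositions(clade@founder) %in% mask]
  ## difference indicator per member at each position that differs anywhere
  bypos <- lapply(clade@members, function(m) {
    m <- m[variantPositions(m) %in% mask]
    d <- c(setdiff(m, f), setdiff(f, m))
    unique(variantPositions(d))
  })
  active <- sort(unique(unlist(bypos)))
  if (length(active) == 0L) {
    samples <- rep(0, B)
    return(list(rho = 0, samples = samples, ci = c(0, 0)))
  }
  M <- vapply(seq_along(active), function(j)
    vapply(bypos, function(p) active[j] %in% p, logical(1)),
    logical(n))
  if (is.null(dim(M))) M <- matrix(M, nrow = n)
  storage.mode(M) <- "double"
  ## multinomial column weights; inactive columns pooled into a rest bucket
  probs <- c(rep(1 / L, length(active)), (L - length(active)) / L)
  W <- stats::rmultinom(B, size = L, prob = probs)
  W <- W[seq_along(active), , drop = FALSE]
  samples <- colMeans(M %*% W)
  list(rho = mean(.memberDiffs(clade)), samples = samples,
       ci = unname(stats::quantile(samples, c(0.025, 0.975))))
}

## AgeEstimate ----------------------------------------------------------------

#' Coalescence age of a lineage
#'
#' @slot rho mean mutation count.
#' @slot n number of members.
#' @slot ageYears \code{rho * yearsPerMutation}.
#' @slot ciYears 95\% interval in years.
#' @slot replicates bootstrap replicates behind the interval (0 if none).
#' @export
setClass("AgeEstimate",
  representation(rho = "numeric", n = "integer", ageYears = "numeric",
                 ciYears = "numeric", replicates = "integer"))

setValidity("AgeEstimate", function(object) {
  if (object@rho < 0) return("rho must be nonnegative")
  if (object@replicates > 0L && length(object@ciYears) == 2L &&
      !is.na(object@ciYears[1]) &&
      (object@ciYears[1] > object@ageYears + 1e-9 ||
       object@ciYears[2] < object@ageYears - 1e-9))
    return("interval must bracket the age")
  TRUE
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf("AgeEstimate: rho = %.3f (n = %d) -> %.0f ya [%s]\n",
              object@rho, object@n, object@ageYears,
              if (length(object@ciYears) == 2L && !anyNA(object@ciYears))
                sprintf("95%% CI %.0f-%.0f", object@ciYears[1],
                        object@ciYears[2]) else "no CI"))
})

#' @rdname AgeEstimate-class
#' @param x an \code{AgeEstimate}.
#' @export
ageYears <- function(x) x@ageYears

#' @rdname AgeEstimate-class
#' @export
ageCI <- function(x) x@ciYears

#' Convert rho to an age estimate
#'
#' \code{age = rho * yearsPerMutation}, exactly linear in rho. By default
#' the interval propagates the rho bootstrap uncertainty only; clock
#' uncertainty can be propagated in addition (multiplying the lower/upper
#' rho bounds by the lower/upper clock bounds).
#'
#' @param rho nonnegative rho value.
#' @param rhoCI optional length-2 rho interval (e.g. from
#'   \code{\link{bootstrapRho}}).
#' @param clock a \code{\link{clockModel}}.
#' @param propagateClockCI also propagate the clock's own interval
#'   (default \code{FALSE}).
#' @param n,replicates bookkeeping fields of the estimate.
#' @return an \code{\link{AgeEstimate}}.
#' @export
ageFromRho <- function(rho, rhoCI = NULL, clock = clockModel(),
                       propagateClockCI = FALSE, n = NA_integer_,
                       replicates = 0L) {
  if (rho < 0) stop("rho must be nonnegative")
  ypm <- clock@yearsPerMutation
  ci <- if (is.null(rhoCI)) c(NA_real_, NA_real_)
        else if (propagateClockCI) c(rhoCI[1] * clock@ci[1],
                                     rhoCI[2] * clock@ci[2])
        else rhoCI * ypm
  new("AgeEstimate", rho = rho, n = as.integer(n), ageYears = rho * ypm,
      ciYears = ci, replicates = as.integer(replicates))
}

#' Calendar label of an age
#'
#' Astronomical year \code{y = referenceYear - age}; labelled
#' \code{"<y> AD"} when \code{y >= 1}, else \code{"<1-y> BC"}.
#'
#' @param ageYears nonnegative age(s) in years.
#' @param referenceYear calendar year that "age 0" corresponds to
#'   (default 2000).
#' @return character vector of period labels.
#' @export
toCalendar <- function(ageYears, referenceYear = 2000) {
  stopifnot(all(ageYears >= 0))
  y <- floor(referenceYear - ageYears)
  ifelse(y >= 1, paste(y, "AD"), paste(1 - y, "BC"))
}

#' Group lineages into settlement waves
#'
#' One-dimensional partition of lineage ages at the \code{k - 1} largest
#' gaps between consecutive sorted ages. Groups are ordered old to young;
#' each gets its mean age, a t-interval across member ages, and the calendar
#' period of the mean. Welch t-tests between adjacent groups are reported.
#'
#' @param ages named numeric vector of ages in years (names = lineages), or
#'   a list of \code{\link{AgeEstimate}}s.
#' @param k number of waves (1 <= k <= number of lineages).
#' @param referenceYear for \code{\link{toCalendar}}.
#' @param conf confidence level of the group intervals.
#' @return list with \code{membership} (data.frame lineage/age/group),
#'   \code{summary} (per-group n, meanAge, ciLo, ciHi, period) and
#'   \code{tests} (Welch p between adjacent groups).
#' @export
groupWaves <- function(ages, k = 3L, referenceYear = 2000, conf = 0.95) {
  if (is.list(ages))
    ages <- vapply(ages, ageYears, numeric(1))
  if (is.null(names(ages))) names(ages) <- paste0("lineage", seq_along(ages))
  if (k < 1L) stop("k must be >= 1")
  if (k > length(ages)) stop("k exceeds the number of lineages")
  ord <- order(-ages)
  sorted <- ages[ord]
  grp <- rep(1L, length(sorted))
  if (k > 1L) {
    gaps <- -diff(sorted)                      # age drop between neighbours
    cut_after <- sort(order(-gaps)[seq_len(k - 1L)])
    grp <- 1L + findInterval(seq_along(sorted) - 1L, cut_after)
  }
  membership <- data.frame(lineage = names(sorted), age = unname(sorted),
                           group = grp, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(membership$age, membership$group),
    function(a) {
      n <- length(a)
      if (n >= 2L) {
        se <- stats::sd(a) / sqrt(n)
        tq <- stats::qt(1 - (1 - conf) / 2, n - 1L)
        lo <- mean(a) - tq * se; hi <- mean(a) + tq * se
      } else lo <- hi <- NA_real_
      data.frame(n = n, meanAge = mean(a), ciLo = lo, ciHi = hi,
                 period = toCalendar(mean(a), referenceYear))
    }))
  summ <- cbind(group = as.integer(rownames(summ)), summ)
  rownames(summ) <- NULL
  tests <- NULL
  if (k > 1L) {
    tests <- do.call(rbind, lapply(seq_len(k - 1L), function(g) {
      a <- membership$age[membership$group == g]
      b <- membership$age[membership$group == g + 1L]
      p <- if (length(a) >= 2L && length(b) >= 2L)
        welchTTest(a, b)$p.value else NA_real_
      data.frame(comparison = paste0("group", g, " vs group", g + 1L),
                 p = p, stringsAsFactors = FALSE)
    }))
  }
  list(membership = membership, summary = summ, tests = tests)
}

#' Date a set of founder lineages
#'
#' Per-lineage rho, site-bootstrap interval and age under the clock, then
#' wave grouping with per-group period labels: the full dating pipeline,
#' emitted as one report table.
#'
#' @param clades list of \code{\link{FounderClade}}s.
#' @param clock a \code{\link{clockModel}}.
#' @param B bootstrap replicates per clade.
#' @param seed RNG seed (one stream across clades).
#' @param k number of waves.
#' @param referenceYear for calendar labels.
#' @return list with \code{ages} (list of \code{AgeEstimate}), \code{waves}
#'   (see \code{\link{groupWaves}}) and \code{report} (one row per lineage:
#'   lineage, n, rho, age, ciLo, ciHi, group, groupMeanAge, period).
#' @export
dateLineages <- function(clades, clock = clockModel(), B = 3600L,
                         seed = NULL, k = 3L, referenceYear = 2000) {
  if (!is.null(seed)) set.seed(seed)
  names(clades) <- vapply(clades, function(cl) cl@name, character(1))
  ests <- lapply(clades, function(cl) {
    bs <- bootstrapRho(cl, B = B)
    ageFromRho(bs$rho, rhoCI = bs$ci, clock = clock,
               n = length(cl@members), replicates = B)
  })
  ages <- vapply(ests, ageYears, numeric(1))
  waves <- groupWaves(ages, k = min(k, length(ages)),
                      referenceYear = referenceYear)
  mem <- waves$membership
  summ <- waves$summary
  report <- data.frame(
    lineage = mem$lineage,
    n = vapply(ests[mem$lineage], function(e) e@n, integer(1)),
    rho = vapply(ests[mem$lineage], function(e) e@rho, numeric(1)),
    age = mem$age,
    ciLo = vapply(ests[mem$lineage], function(e) e@ciYears[1], numeric(1)),
    ciHi = vapply(ests[mem$lineage], function(e) e@ciYears[2], numeric(1)),
    group = mem$group,
    groupMeanAge = summ$meanAge[mem$group],
    period = summ$period[mem$group],
    stringsAsFactors = FALSE)
  list(ages = ests, waves = waves, report = report)
}
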