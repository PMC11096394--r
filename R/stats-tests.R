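## Exact and classical tests used in the sharing analyses --------------------

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities not exceeding that of
#' the observed table.
#'
#' @param tab 2x2 matrix (or length-4 vector, filled by row) of nonnegative
#'   integer counts.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2, byrow = !is.matrix(tab))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 + r2 == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Exact two-sided sign test
#'
#' Binomial test of positive against negative matches at theta = 0.5;
#' two-sided by doubling the smaller tail, capped at 1.
#'
#' @param pos,neg nonnegative counts, \code{pos + neg >= 1}.
#' @return two-sided p-value.
#' @export
signTest <- function(pos, neg) {
  stopifnot(pos >= 0, neg >= 0, pos + neg >= 1)
  n <- pos + neg
  min(1, 2 * stats::pbinom(min(pos, neg), n, 0.5))
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom, computed directly:
#' \code{t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)} with
#' \code{df = (va/na + vb/nb)^2 / ((va/na)^2/(na-1) + (vb/nb)^2/(nb-1))}.
#' Degenerate zero-variance samples return p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param a,b numeric samples of size >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
welchTTest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (equal) 0 else Inf, df = NA_real_,
                p.value = if (equal) 1 else 0))
  }
  sa <- va / length(a); sb <- vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}
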