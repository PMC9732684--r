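#' Spearman rank correlation with mid-ranks for ties
#'
#' Thin wrapper over [stats::cor.test] (`method = "spearman"`, asymptotic
#' p so that ties are handled with mid-ranks throughout).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho` and two-sided `p`, plus `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom, via [stats::kruskal.test].
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups), or a
#'   numeric vector with `g` giving group membership.
#' @param g optional grouping factor when `groups` is a vector.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(groups, g)
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    # all observations tied: no evidence of any location difference
    return(list(H = 0, df = length(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}
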