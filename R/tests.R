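# Per-marker two-group tests.
#
# Both tests are two-sided.  Degenerate cells -- a genotype class with
# fewer than `min_class` non-missing observations -- return NA, never 0
# or 1: balanced class frequencies hold for a real backcross-style panel
# but cannot be assumed for arbitrary input.

#' Wilcoxon rank-sum test for a mean shift between two genotype classes
#'
#' Default mode is the tie-corrected normal approximation with a 0.5
#' continuity correction; `exact = TRUE` switches to exhaustive
#' enumeration of all label assignments (intended as a small-sample
#' oracle; feasible only while `choose(n, n1)` is modest).  Complete
#' ties are defined to return p = 1 (an uninformative, not invalid,
#' marker).
#'
#' @param values numeric vector of phenotype values (NA allowed).
#' @param groups vector of 0/1 genotype codes, same length (NA allowed);
#'   pairs with a missing value or genotype are dropped.
#' @param exact logical; exhaustive enumeration instead of the normal
#'   approximation.
#' @param continuity apply the 0.5 continuity correction (approximate
#'   mode only).
#' @param min_class minimum observations required per genotype class;
#'   below it the result is degenerate (`NA`).
#' @return list with `statistic` (rank sum of group 1), `p`, `n0`, `n1`.
#' @examples
#' wilcoxon_test(c(1.2, 2.3, 3.1, 4.8, 5.5, 6.0), c(0, 0, 0, 1, 1, 1), exact = TRUE)
#' @export
wilcoxon_test <- function(values, groups, exact = FALSE, continuity = TRUE,
                          min_class = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  y <- as.numeric(values[keep])
  g <- as.integer(groups[keep])
  if (any(!g %in% c(0L, 1L))) stop("groups must be coded 0/1")
  n0 <- sum(g == 0L); n1 <- sum(g == 1L)
  if (n0 < min_class || n1 < min_class)
    return(list(statistic = NA_real_, p = NA_real_, n0 = n0, n1 = n1))
  r <- rank(y)
  W1 <- sum(r[g == 1L])
  if (exact) {
    p <- .wilcoxon_exact_p(r, n1, W1)
    return(list(statistic = W1, p = p, n0 = n0, n1 = n1))
  }
  n <- n0 + n1
  ties <- rle(sort(y))$lengths
  sigma2 <- n0 * n1 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0)  # complete ties: defined limit p = 1
    return(list(statistic = W1, p = 1, n0 = n0, n1 = n1))
  dev <- W1 - n1 * (n + 1) / 2
  z <- if (continuity) sign(dev) * max(abs(dev) - 0.5, 0) / sqrt(sigma2)
       else dev / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W1, p = p, n0 = n0, n1 = n1)
}

# exact two-sided p by full enumeration of label assignments:
# P(|W - E(W)| >= |W_obs - E(W)|) over all choose(n, n1) equally likely
# assignments of the group-1 labels.  Works on the observed (midranked)
# ranks, so ties are handled for free.
.wilcoxon_exact_p <- function(r, n1, W_obs) {
  n <- length(r)
  if (choose(n, n1) > 2e5) stop("exact mode infeasible for this sample size")
  mu <- n1 * (n + 1) / 2
  sets <- utils::combn(n, n1)
  sums <- colSums(matrix(r[sets], nrow = n1))
  eps <- 1e-9
  mean(abs(sums - mu) >= abs(W_obs - mu) - eps)
}

#' Brown-Forsythe test for variance heterogeneity between two classes
#'
#' Levene-type test on absolute deviations from the class medians,
#' assessed by the one-way ANOVA F statistic on 1 and N - 2 degrees of
#' freedom: with z_ij = |y_ij - median_j|,
#' F = (N - 2) * sum_j n_j (zbar_j - zbar)^2 / sum_ij (z_ij - zbar_j)^2.
#'
#' If the within-class deviations are all zero while the between-class
#' term is not (F infinite), p is reported as the smallest representable
#' positive double and flagged; if every deviation is zero the marker is
#' uninformative and the result is `NA`.
#'
#' @inheritParams wilcoxon_test
#' @return list with `statistic` (F), `p`, `n0`, `n1`, `flag`
#'   (`"ok"`, `"infinite_F"` or `"degenerate"`).
#' @examples
#' brown_forsythe_test(c(0, 1, 2, 0, 2, 4), c(0, 0, 0, 1, 1, 1))
#' @export
brown_forsythe_test <- function(values, groups, min_class = 2L) {
  keep <- !is.na(values) & !is.na(groups)
  y <- as.numeric(values[keep])
  g <- as.integer(groups[keep])
  if (any(!g %in% c(0L, 1L))) stop("groups must be coded 0/1")
  n0 <- sum(g == 0L); n1 <- sum(g == 1L)
  if (n0 < min_class || n1 < min_class)
    return(list(statistic = NA_real_, p = NA_real_, n0 = n0, n1 = n1,
                flag = "degenerate"))
  y0 <- y[g == 0L]; y1 <- y[g == 1L]
  z0 <- abs(y0 - stats::median(y0)); z1 <- abs(y1 - stats::median(y1))
  m0 <- mean(z0); m1 <- mean(z1)
  n <- n0 + n1
  gm <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- sum((z0 - m0)^2) + sum((z1 - m1)^2)
  if (ssw <= 0 && ssb <= 0)
    return(list(statistic = NA_real_, p = NA_real_, n0 = n0, n1 = n1,
                flag = "degenerate"))
  if (ssw <= 0)
    return(list(statistic = Inf, p = .Machine$double.xmin, n0 = n0, n1 = n1,
                flag = "infinite_F"))
  F <- (n - 2) * ssb / ssw
  list(statistic = F, p = stats::pf(F, 1, n - 2, lower.tail = FALSE),
       n0 = n0, n1 = n1, flag = "ok")
}
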