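# Whole-matrix genome scans: every phenotype against every marker.
#
# When neither panel contains missing values the scan runs a vectorized
# path (per marker, all phenotypes at once); otherwise it falls back to
# per-cell calls of the scalar tests with pairwise-complete
# observations.  Both paths are required (and tested) to agree with a
# cell-by-cell loop of the single-test functions.

#' Genome scan of an expression panel against a genotype panel
#'
#' Applies [wilcoxon_test()] (mean shifts, GWAS) or
#' [brown_forsythe_test()] (variance heterogeneity, vGWAS) to every
#' phenotype x marker pair, using pairwise-complete observations.
#'
#' @param e an [expression_panel()], sample-aligned with `g` (see
#'   [align_samples()]).
#' @param g a [genotype_panel()].
#' @param test `"wilcoxon"` or `"brown_forsythe"`.
#' @param min_class minimum genotype-class size after missing-data
#'   removal; smaller cells yield `NA` (2 by default; 8 is a sensible
#'   choice for variance tests).
#' @return An object of class `"genome_scan"`: list with `test`,
#'   `treatment`, `p`, `statistic`, `n0`, `n1` (phenotype x marker
#'   matrices), `markers` and `phenotypes` data.frames.
#' @export
genome_scan <- function(e, g, test = c("wilcoxon", "brown_forsythe"),
                        min_class = 2L) {
  test <- match.arg(test)
  stopifnot(inherits(e, "expression_panel"), inherits(g, "genotype_panel"))
  if (nrow(e$values) != nrow(g$calls) ||
      !identical(e$segregants, g$segregants))
    stop("panels are not sample-aligned; run align_samples() first")
  Y <- e$values
  G <- g$calls
  P <- ncol(Y); M <- ncol(G)
  pmat <- stat <- matrix(NA_real_, P, M,
                         dimnames = list(e$phenotypes$phenotype, g$markers$marker))
  n0m <- n1m <- matrix(NA_integer_, P, M, dimnames = dimnames(pmat))
  fast <- !anyNA(Y) && !anyNA(G)
  if (fast && test == "wilcoxon") {
    n <- nrow(Y)
    R <- apply(Y, 2L, rank)
    tiesum <- apply(Y, 2L, function(y) {
      t <- rle(sort(y))$lengths; sum(t^3 - t)
    })
    for (m in seq_len(M)) {
      idx1 <- which(G[, m] == 1L)
      n1 <- length(idx1); n0 <- n - n1
      n0m[, m] <- n0; n1m[, m] <- n1
      if (n0 < min_class || n1 < min_class) next
      W1 <- if (n1 == 1L) R[idx1, ] else colSums(R[idx1, , drop = FALSE])
      sigma2 <- n0 * n1 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
      dev <- W1 - n1 * (n + 1) / 2
      z <- ifelse(sigma2 <= 0, 0,
                  sign(dev) * pmax(abs(dev) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.xmin)))
      p <- pmin(1, 2 * stats::pnorm(-abs(z)))
      p[sigma2 <= 0] <- 1     # complete ties
      stat[, m] <- W1
      pmat[, m] <- p
    }
  } else if (fast && test == "brown_forsythe") {
    n <- nrow(Y)
    for (m in seq_len(M)) {
      i1 <- G[, m] == 1L
      n1 <- sum(i1); n0 <- n - n1
      n0m[, m] <- n0; n1m[, m] <- n1
      if (n0 < min_class || n1 < min_class) next
      y0 <- Y[!i1, , drop = FALSE]; y1 <- Y[i1, , drop = FALSE]
      z0 <- abs(sweep(y0, 2L, col_medians(y0)))
      z1 <- abs(sweep(y1, 2L, col_medians(y1)))
      m0 <- colMeans(z0); m1 <- colMeans(z1)
      gm <- (n0 * m0 + n1 * m1) / n
      ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
      ssw <- colSums(z0^2) - n0 * m0^2 + colSums(z1^2) - n1 * m1^2
      ssw <- pmax(ssw, 0)   # guard tiny negative rounding
      F <- (n - 2) * ssb / ssw
      p <- stats::pf(F, 1, n - 2, lower.tail = FALSE)
      inf <- ssw <= 0 & ssb > 0
      dgn <- ssw <= 0 & ssb <= 0
      F[inf] <- Inf; p[inf] <- .Machine$double.xmin
      F[dgn] <- NA_real_; p[dgn] <- NA_real_
      stat[, m] <- F
      pmat[, m] <- p
    }
  } else {
    fun <- if (test == "wilcoxon") {
      function(y, gg) wilcoxon_test(y, gg, min_class = min_class)
    } else {
      function(y, gg) brown_forsythe_test(y, gg, min_class = min_class)
    }
    for (m in seq_len(M)) {
      gv <- G[, m]
      for (j in seq_len(P)) {
        res <- fun(Y[, j], gv)
        stat[j, m] <- res$statistic
        pmat[j, m] <- res$p
        n0m[j, m] <- res$n0
        n1m[j, m] <- res$n1
      }
    }
  }
  structure(list(test = test, treatment = e$treatment,
                 p = pmat, statistic = stat, n0 = n0m, n1 = n1m,
                 markers = g$markers, phenotypes = e$phenotypes,
                 min_class = min_class),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat(sprintf("Genome scan (%s, %s): %d phenotypes x %d markers\n",
              x$test, x$treatment, nrow(x$p), ncol(x$p)))
  ok <- !is.na(x$p)
  cat(sprintf("  tested cells: %d (%.1f%%), min p = %.3g\n",
              sum(ok), 100 * mean(ok), suppressWarnings(min(x$p, na.rm = TRUE))))
  invisible(x)
}

#' Summarize a genome scan
#'
#' @param object a `genome_scan`.
#' @param threshold significance threshold on the p-value.
#' @param ... unused.
#' @return data.frame of significant phenotype/marker cells, ordered by p.
#' @export
summary.genome_scan <- function(object, threshold = 1e-5, ...) {
  hit <- which(!is.na(object$p) & object$p <= threshold, arr.ind = TRUE)
  out <- data.frame(
    phenotype = object$phenotypes$phenotype[hit[, 1L]],
    marker = object$markers$marker[hit[, 2L]],
    chrom = object$markers$chrom[hit[, 2L]],
    pos = object$markers$pos[hit[, 2L]],
    statistic = object$statistic[hit],
    p = object$p[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "test") <- object$test
  attr(out, "treatment") <- object$treatment
  attr(out, "threshold") <- threshold
  out
}

#' Manhattan plot of one phenotype's scan
#'
#' @param x a `genome_scan`.
#' @param phenotype phenotype id (default: first).
#' @param threshold optional p-value threshold drawn as a dashed line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.genome_scan <- function(x, phenotype = NULL, threshold = NULL, ...) {
  phenotype <- phenotype %||% x$phenotypes$phenotype[1L]
  j <- match(phenotype, x$phenotypes$phenotype)
  if (is.na(j)) stop("unknown phenotype: ", phenotype)
  mk <- x$markers
  chroms <- unique(mk$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc) max(mk$pos[mk$chrom == cc]),
                             numeric(1L))))
  xpos <- mk$pos + offs[match(mk$chrom, chroms)]
  lp <- -log10(pmax(x$p[j, ], 1e-300))
  graphics::plot(xpos, lp, pch = 16, cex = 0.5,
                 col = (match(mk$chrom, chroms) %% 2L) + 1L,
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = expression(-log[10](p)),
                 main = sprintf("%s | %s (%s)", phenotype, x$test, x$treatment),
                 ...)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2)
  invisible(x)
}
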