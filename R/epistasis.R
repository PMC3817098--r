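# vQTL-anchored epistasis screen: multi-locus genotype-phenotype maps,
# interaction contrasts, conditional scans within an anchor genotype,
# and candidate-gene lookup around peaks.

#' Multi-locus genotype-phenotype map
#'
#' Per-class summary statistics (n, mean, SD, SE) of one phenotype over
#' the 2^k genotype classes of k = 2 or 3 marker loci, computed on
#' pairwise-complete observations.  Empty classes are reported with
#' n = 0 and missing statistics, never dropped.
#'
#' @param e an [expression_panel()], sample-aligned with `g`.
#' @param g a [genotype_panel()].
#' @param phenotype phenotype id.
#' @param loci character vector of 2 or 3 marker ids.
#' @return Object of class `"gp_map"`: a data.frame with one row per
#'   genotype class (columns `<locus>` = 0/1 codes, `class` =
#'   "BY,RM"-style label, `n`, `mean`, `sd`, `se`), with attributes
#'   `phenotype`, `loci`, `treatment`.
#' @export
gp_map <- function(e, g, phenotype, loci) {
  stopifnot(inherits(e, "expression_panel"), inherits(g, "genotype_panel"))
  if (!identical(e$segregants, g$segregants))
    stop("panels are not sample-aligned; run align_samples() first")
  k <- length(loci)
  if (k < 2L || k > 3L) stop("loci must name 2 or 3 markers")
  mi <- match(loci, g$markers$marker)
  if (anyNA(mi)) stop("unknown marker id(s): ",
                      paste(loci[is.na(mi)], collapse = ", "))
  j <- match(phenotype, e$phenotypes$phenotype)
  if (is.na(j)) stop("unknown phenotype: ", phenotype)
  y <- e$values[, j]
  gm <- g$calls[, mi, drop = FALSE]
  keep <- !is.na(y) & stats::complete.cases(gm)
  y <- y[keep]; gm <- gm[keep, , drop = FALSE]
  classes <- expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE]
  names(classes) <- rev(loci)   # undone by the [, k:1] flip below
  classes <- classes[, k:1, drop = FALSE]
  names(classes) <- loci
  code <- apply(gm, 1L, paste, collapse = "")
  want <- apply(classes, 1L, paste, collapse = "")
  stats_rows <- lapply(seq_along(want), function(i) {
    yy <- y[code == want[i]]
    n <- length(yy)
    data.frame(n = n,
               mean = if (n) mean(yy) else NA_real_,
               sd = if (n > 1L) stats::sd(yy) else NA_real_,
               se = if (n > 1L) stats::sd(yy) / sqrt(n) else NA_real_)
  })
  out <- cbind(classes,
               class = apply(classes, 1L, function(x)
                 paste(c("BY", "RM")[x + 1L], collapse = ",")),
               do.call(rbind, stats_rows))
  rownames(out) <- NULL
  structure(out, phenotype = phenotype, loci = loci,
            treatment = e$treatment, class = c("gp_map", "data.frame"))
}

#' Interaction contrast of a genotype-phenotype map
#'
#' For a two-locus map the non-additivity contrast is
#' `delta = (m11 - m10) - (m01 - m00)`; for three loci the three-way
#' alternating sum over the genotype cube.  `delta` is missing unless
#' every class has n >= 2.  The flag marks `|delta| > 2 SE(delta)`
#' (SE from the per-class standard errors, classes independent).
#' Per-locus marginal variance ratios (class RM over class BY, from the
#' pooled class moments) quantify the variance heterogeneity each
#' margin would show in a one-dimensional scan.
#'
#' @param map a [gp_map()].
#' @return Object of class `"interaction_summary"`: list with `loci`,
#'   `delta`, `se`, `flag`, `variance_ratio` (named per locus),
#'   `phenotype`, `treatment`.
#' @export
interaction_contrast <- function(map) {
  stopifnot(inherits(map, "gp_map"))
  loci <- attr(map, "loci")
  k <- length(loci)
  codes <- as.matrix(map[, loci, drop = FALSE])
  # alternating-sum weights: +1 when the number of BY (0) alleles is even
  w <- (-1)^(k - rowSums(codes))
  ok <- all(map$n >= 2L)
  delta <- if (ok) sum(w * map$mean) else NA_real_
  se <- if (ok) sqrt(sum(map$se^2)) else NA_real_
  vr <- vapply(loci, function(l) {
    v <- vapply(c(0L, 1L), function(a) {
      sel <- map[, l] == a & map$n > 0L
      n <- map$n[sel]; mu <- map$mean[sel]; s2 <- map$sd[sel]^2
      s2[is.na(s2)] <- 0
      N <- sum(n)
      if (N < 2L) return(NA_real_)
      mbar <- sum(n * mu) / N
      (sum((n - 1L) * s2) + sum(n * (mu - mbar)^2)) / (N - 1L)
    }, numeric(1L))
    v[2L] / v[1L]
  }, numeric(1L))
  structure(list(loci = loci, delta = delta, se = se,
                 flag = isTRUE(ok && abs(delta) > 2 * se),
                 variance_ratio = vr,
                 phenotype = attr(map, "phenotype"),
                 treatment = attr(map, "treatment")),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("Interaction contrast for %s (%s): loci %s\n", x$phenotype,
              x$treatment, paste(x$loci, collapse = " x ")))
  cat(sprintf("  delta = %.4g (SE %.3g)%s\n", x$delta, x$se,
              if (isTRUE(x$flag)) "  [flagged: |delta| > 2 SE]" else ""))
  cat("  marginal variance ratios (RM/BY): ",
      paste(sprintf("%s = %.3g", names(x$variance_ratio), x$variance_ratio),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Conditional scan within an anchor genotype
#'
#' Restricts the panel to segregants carrying `anchor_genotype` at
#' `anchor_marker`, runs a mean-effect scan of one phenotype against all
#' markers in that subset, and estimates a permutation FDR threshold
#' from `perm_R` value-permutations of the subset phenotype.
#'
#' @inheritParams genome_scan
#' @param phenotype phenotype id to scan.
#' @param anchor_marker marker id of the anchoring (usually vQTL) locus.
#' @param anchor_genotype `0`/`"BY"` or `1`/`"RM"`.
#' @param perm_R permutations for the subset threshold (default 500).
#' @param target_fdr FDR target for the reported threshold (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return Object of class `"conditional_scan"`: list with `scan` (the
#'   subset `genome_scan`), `threshold` (p-value at `target_fdr`),
#'   `null` (the [permutation_null()]), `anchor_marker`,
#'   `anchor_genotype`, `n_subset`.
#' @export
conditional_scan <- function(e, g, phenotype, anchor_marker, anchor_genotype,
                             test = "wilcoxon", perm_R = 500L,
                             target_fdr = 0.05, seed = NULL, min_class = 2L) {
  stopifnot(inherits(e, "expression_panel"), inherits(g, "genotype_panel"))
  if (!identical(e$segregants, g$segregants))
    stop("panels are not sample-aligned; run align_samples() first")
  if (is.character(anchor_genotype))
    anchor_genotype <- match(toupper(anchor_genotype), c("BY", "RM")) - 1L
  if (!anchor_genotype %in% c(0L, 1L)) stop("anchor_genotype must be BY/RM (0/1)")
  mi <- match(anchor_marker, g$markers$marker)
  if (is.na(mi)) stop("unknown anchor marker: ", anchor_marker)
  carriers <- which(!is.na(g$calls[, mi]) & g$calls[, mi] == anchor_genotype)
  if (length(carriers) == 0L) stop("no segregants carry the anchor genotype")
  if (length(carriers) < 2L * min_class)
    stop(sprintf("anchor subset too small (%d < %d)", length(carriers),
                 2L * min_class))
  j <- match(phenotype, e$phenotypes$phenotype)
  if (is.na(j)) stop("unknown phenotype: ", phenotype)
  es <- expression_panel(e$values[carriers, j, drop = FALSE],
                         segregant_ids = e$segregants[carriers],
                         phenotype_ids = phenotype, treatment = e$treatment,
                         gene_chrom = e$phenotypes$chrom[j],
                         gene_pos = e$phenotypes$pos[j])
  gs <- g
  gs$calls <- g$calls[carriers, , drop = FALSE]
  gs$segregants <- g$segregants[carriers]
  scan <- genome_scan(es, gs, test = test, min_class = min_class)
  null <- build_null(es, gs, test = test, P_s = 1L, R = perm_R, seed = seed,
                     min_class = min_class)
  thr <- threshold_for_fdr(null, scan, target_fdr, P_total = 1L)
  structure(list(scan = scan, threshold = thr, null = null,
                 anchor_marker = anchor_marker,
                 anchor_genotype = anchor_genotype,
                 n_subset = length(carriers), target_fdr = target_fdr),
            class = "conditional_scan")
}

#' @export
print.conditional_scan <- function(x, ...) {
  cat(sprintf("Conditional scan within %s = %s (n = %d)\n", x$anchor_marker,
              c("BY", "RM")[x$anchor_genotype + 1L], x$n_subset))
  cat(sprintf("  %d%% FDR threshold: %.3g; top marker p = %.3g\n",
              round(100 * x$target_fdr), x$threshold,
              suppressWarnings(min(x$scan$p, na.rm = TRUE))))
  invisible(x)
}

#' Genes within a window of a peak center
#'
#' Lists all annotated genes whose span intersects
#' `[center - window_bp, center + window_bp]` (span taken as annotated
#' start/end, inclusive; intersection, not containment).
#'
#' @param peak one-row `peak_set` slice, or a list/data.frame with
#'   `chrom` and `center_pos`.
#' @param annotation gene table from [read_gene_annotation()] (columns
#'   `gene`, `chrom`, `start`, `end`).
#' @param window_bp half-width of the window (default 10,000 bp).
#' @return data.frame of intersecting genes (possibly empty); a
#'   chromosome absent from the annotation yields an empty result with a
#'   warning.
#' @export
candidate_genes <- function(peak, annotation, window_bp = 10000L) {
  chrom <- as.character(peak$chrom[1L] %||% peak$chrom)
  center <- as.integer(peak$center_pos[1L] %||% peak$center_pos)
  if (nrow(annotation) == 0L || !chrom %in% annotation$chrom) {
    if (nrow(annotation) > 0L)
      warning("chromosome ", chrom, " absent from annotation")
    return(annotation[integer(0L), , drop = FALSE])
  }
  sel <- annotation$chrom == chrom &
    annotation$end >= center - window_bp &
    annotation$start <= center + window_bp
  out <- annotation[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen vQTL-affected phenotypes for pairwise epistasis
#'
#' For every phenotype with at least one vQTL peak, builds two-locus
#' genotype-phenotype maps for all (vQTL x other-peak) center pairs and
#' computes the interaction contrast; replaces the visual GP-map
#' inspection step with a numeric flag at `|delta| > 2 SE`.
#'
#' @param peaks a `peak_set` (or list of them) holding both QTL
#'   (`wilcoxon`) and vQTL (`brown_forsythe`) peaks of one treatment.
#' @param e,g sample-aligned panels matching the peaks' treatment.
#' @param min_n minimum per-class n for a pair to be evaluated.
#' @return data.frame with one row per evaluated pair: `phenotype`,
#'   `locus1` (vQTL center), `locus2`, `delta`, `se`, `flag`,
#'   `vr1`, `vr2` (marginal variance ratios).
#' @export
epistasis_screen <- function(peaks, e, g, min_n = 2L) {
  if (!inherits(peaks, "peak_set")) peaks <- do.call(rbind, lapply(peaks, as.data.frame))
  tab <- as.data.frame(peaks)
  tab <- tab[tab$treatment == e$treatment, , drop = FALSE]
  out <- list()
  for (ph in unique(tab$phenotype[tab$test == "brown_forsythe"])) {
    sub <- tab[tab$phenotype == ph, , drop = FALSE]
    vq <- sub$center_marker[sub$test == "brown_forsythe"]
    others <- unique(sub$center_marker)
    for (a in vq) for (b in setdiff(others, a)) {
      key <- paste(ph, paste(sort(c(a, b)), collapse = "|"), sep = "::")
      if (key %in% names(out)) next
      mp <- gp_map(e, g, ph, c(a, b))
      ic <- interaction_contrast(mp)
      out[[key]] <- data.frame(phenotype = ph, locus1 = a, locus2 = b,
                               delta = ic$delta, se = ic$se,
                               flag = ic$flag,
                               vr1 = unname(ic$variance_ratio[1L]),
                               vr2 = unname(ic$variance_ratio[2L]),
                               stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(phenotype = character(), locus1 = character(),
               locus2 = character(), delta = numeric(), se = numeric(),
               flag = logical(), vr1 = numeric(), vr2 = numeric())
  rownames(res) <- NULL
  res
}

#' Bar plot of a genotype-phenotype map
#'
#' Class means with +/- 1 SE whiskers.
#'
#' @param x a [gp_map()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gp_map <- function(x, ...) {
  mids <- graphics::barplot(x$mean, names.arg = x$class, las = 2,
                            ylab = "mean expression (log2)",
                            main = sprintf("%s (%s)", attr(x, "phenotype"),
                                           attr(x, "treatment")), ...)
  ok <- !is.na(x$se)
  if (any(ok))
    graphics::arrows(mids[ok], x$mean[ok] - x$se[ok],
                     mids[ok], x$mean[ok] + x$se[ok],
                     angle = 90, code = 3, length = 0.04)
  invisible(x)
}
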