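# Hotspot intervals and enrichment tests.
#
# Hotspot boundaries are an input (the study identified them visually),
# never inferred here.  Interval membership uses 1-based inclusive
# coordinates: a peak exactly on a boundary is inside.

#' Construct a hotspot interval set
#'
#' @param chrom,start,end,label interval coordinates (1-based inclusive)
#'   and labels.
#' @param genome named vector of chromosome lengths in bp.
#' @return Object of class `"hotspot_set"`: list with `intervals`
#'   (data.frame) and `genome`; overlapping intervals on a chromosome
#'   are merged with a warning.  `covered_fraction(x)` is the summed
#'   interval width over the genome size.
#' @export
hotspot_set <- function(chrom, start, end, label = NULL, genome) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(end >= start), !is.null(names(genome)))
  label <- label %||% sprintf("hotspot%d", seq_along(chrom))
  iv <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  iv <- iv[order(factor(iv$chrom, levels = unique(iv$chrom)), iv$start), ,
           drop = FALSE]
  merged <- list(); dropped <- FALSE
  for (i in seq_len(nrow(iv))) {
    k <- length(merged)
    if (k && merged[[k]]$chrom == iv$chrom[i] &&
        iv$start[i] <= merged[[k]]$end + 1L) {
      merged[[k]]$end <- max(merged[[k]]$end, iv$end[i])
      dropped <- TRUE
    } else merged[[k + 1L]] <- as.list(iv[i, ])
  }
  if (dropped) warning("overlapping/adjacent hotspot intervals merged")
  iv <- if (length(merged)) do.call(rbind, lapply(merged, as.data.frame)) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  rownames(iv) <- NULL
  bad <- !iv$chrom %in% names(genome)
  if (any(bad)) stop("hotspot chromosome(s) absent from genome: ",
                     paste(unique(iv$chrom[bad]), collapse = ", "))
  structure(list(intervals = iv, genome = genome), class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Hotspot set: %d interval(s), %.1f%% of the genome\n",
              nrow(x$intervals), 100 * covered_fraction(x)))
  invisible(x)
}

#' Fraction of the genome covered by the hotspot intervals
#' @param hotspots a [hotspot_set()].
#' @return Numeric in \[0, 1\].
#' @export
covered_fraction <- function(hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  sum(hotspots$intervals$end - hotspots$intervals$start + 1) /
    sum(as.numeric(hotspots$genome))
}

#' Count peaks inside each hotspot
#'
#' Membership is decided by the peak center position, 1-based inclusive
#' (a center exactly on a boundary is inside).  Typically called on the
#' trans-labelled subset of a peak set.
#'
#' @param peaks a `peak_set`.
#' @param hotspots a [hotspot_set()].
#' @return list with `per_hotspot` (counts by hotspot x test x
#'   treatment), `totals` (in/out counts by test x treatment) and
#'   `assignment` (hotspot label per peak, `NA` = outside).
#' @export
count_in_hotspots <- function(peaks, hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  iv <- hotspots$intervals
  assignment <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(iv))) {
    hit <- peaks$chrom == iv$chrom[i] &
      peaks$center_pos >= iv$start[i] & peaks$center_pos <= iv$end[i]
    assignment[hit & is.na(assignment)] <- iv$label[i]
  }
  combos <- unique(as.data.frame(peaks)[, c("test", "treatment")])
  per <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    do.call(rbind, lapply(seq_len(max(nrow(combos), 0L)), function(k) {
      sel <- assignment == iv$label[i] & !is.na(assignment) &
        peaks$test == combos$test[k] & peaks$treatment == combos$treatment[k]
      data.frame(hotspot = iv$label[i], chrom = iv$chrom[i],
                 start = iv$start[i], end = iv$end[i],
                 test = combos$test[k], treatment = combos$treatment[k],
                 n_peaks = sum(sel), stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(per))
    per <- data.frame(hotspot = character(), chrom = character(),
                      start = integer(), end = integer(), test = character(),
                      treatment = character(), n_peaks = integer())
  totals <- do.call(rbind, lapply(seq_len(max(nrow(combos), 0L)), function(k) {
    sel <- peaks$test == combos$test[k] & peaks$treatment == combos$treatment[k]
    data.frame(test = combos$test[k], treatment = combos$treatment[k],
               inside = sum(sel & !is.na(assignment)),
               outside = sum(sel & is.na(assignment)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(totals))
    totals <- data.frame(test = character(), treatment = character(),
                         inside = integer(), outside = integer())
  list(per_hotspot = per, totals = totals, assignment = assignment)
}

#' Goodness-of-fit test against uniform peak placement
#'
#' Tests the observed in/out split of peaks against the split expected
#' if peaks fell uniformly on the genome, i.e. expected counts
#' `(N f, N (1 - f))` where `f` is the hotspot-covered genome fraction.
#' One-degree-of-freedom Pearson chi-square.
#'
#' @param in_count,out_count observed peak counts inside / outside.
#' @param covered_fraction hotspot-covered fraction of the genome, in (0, 1).
#' @return Object of class `"enrichment_result"`: list with `table`,
#'   `statistic`, `df`, `p`, `direction` (`"enriched"` or `"depleted"`).
#' @export
uniformity_chisq <- function(in_count, out_count, covered_fraction) {
  stopifnot(covered_fraction > 0, covered_fraction < 1)
  N <- in_count + out_count
  if (N == 0) stop("no peaks to test")
  ct <- suppressWarnings(
    stats::chisq.test(c(in_count, out_count),
                      p = c(covered_fraction, 1 - covered_fraction)))
  structure(list(table = matrix(c(in_count, out_count), 1L,
                                dimnames = list(NULL, c("inside", "outside"))),
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value,
                 direction = if (in_count >= N * covered_fraction) "enriched"
                             else "depleted"),
            class = "enrichment_result")
}

#' Chi-square test for differential hotspot occupancy of QTL vs vQTL
#'
#' Pearson chi-square (1 df, no continuity correction by default) on a
#' 2x2 table of peak class (QTL/vQTL) by location (inside/outside
#' hotspots).
#'
#' @param table 2x2 matrix of counts; all margins must be positive.
#' @param yates apply the Yates continuity correction.
#' @return An `"enrichment_result"` (see [uniformity_chisq()]).
#' @export
qtl_vs_vqtl_chisq <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins of the 2x2 table must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(table = table, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 direction = NA_character_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Chi-square = %.4g on %d df, p = %.3g", x$statistic, x$df, x$p))
  if (!is.na(x$direction)) cat(sprintf(" (%s)", x$direction))
  cat("\n")
  invisible(x)
}
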