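# Greedy peak calling and cis/trans classification.
#
# Rule: among unassigned significant SNPs pick the one with the lowest
# p-value (ties broken leftmost by chromosome order, then bp); assign
# every unassigned significant SNP on the same chromosome within
# +/- 25 kb of it to that peak; repeat until no significant SNP remains.
# Every significant SNP therefore belongs to exactly one peak, peaks
# never span chromosomes, and centers of distinct peaks obtained in
# different rounds are the "SNP peaks separated by 50 kb" of the
# two-peak convention.

#' Collapse significant SNPs into association peaks
#'
#' @param scan a [genome_scan()] result.
#' @param threshold p-value significance threshold in (0, 1); a SNP is
#'   significant when `p <= threshold`.
#' @param phenotype optional character vector restricting the call to
#'   some phenotypes (default: all).
#' @param window_bp half-width of the peak assignment window around the
#'   center SNP (default 25,000 bp).
#' @param cis_bp cis/trans distance bound passed to
#'   [classify_cis_trans()] (default 150,000 bp).
#' @param classify classify peaks cis/trans using the scan's gene
#'   positions (default `TRUE`; phenotypes with unknown position get
#'   `"unknown"`).
#' @return An object of class `"peak_set"` (a data.frame, one row per
#'   peak) with columns `phenotype`, `treatment`, `test`, `chrom`,
#'   `center_marker`, `center_pos`, `center_p`, `n_snps`, `span_start`,
#'   `span_end`, `members` (comma-joined marker ids), `cis_trans`.
#' @export
call_peaks <- function(scan, threshold, phenotype = NULL,
                       window_bp = 25000L, cis_bp = 150000L,
                       classify = TRUE) {
  stopifnot(inherits(scan, "genome_scan"), threshold > 0, threshold < 1)
  phen <- phenotype %||% scan$phenotypes$phenotype
  mk <- scan$markers
  chrom_rank <- match(mk$chrom, unique(mk$chrom))
  rows <- list()
  for (ph in phen) {
    j <- match(ph, scan$phenotypes$phenotype)
    if (is.na(j)) stop("unknown phenotype: ", ph)
    p <- scan$p[j, ]
    sig <- which(!is.na(p) & p <= threshold)
    while (length(sig)) {
      # lowest p; ties -> leftmost (chrom order, then position)
      o <- order(p[sig], chrom_rank[sig], mk$pos[sig])
      ctr <- sig[o[1L]]
      memb <- sig[mk$chrom[sig] == mk$chrom[ctr] &
                    abs(mk$pos[sig] - mk$pos[ctr]) <= window_bp]
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, treatment = scan$treatment, test = scan$test,
        chrom = mk$chrom[ctr], center_marker = mk$marker[ctr],
        center_pos = mk$pos[ctr], center_p = p[ctr],
        n_snps = length(memb),
        span_start = min(mk$pos[memb]), span_end = max(mk$pos[memb]),
        members = paste(mk$marker[memb], collapse = ","),
        stringsAsFactors = FALSE)
      sig <- setdiff(sig, memb)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phenotype = character(), treatment = character(),
               test = character(), chrom = character(),
               center_marker = character(), center_pos = integer(),
               center_p = numeric(), n_snps = integer(),
               span_start = integer(), span_end = integer(),
               members = character(), stringsAsFactors = FALSE)
  if (classify) {
    idx <- match(out$phenotype, scan$phenotypes$phenotype)
    out$cis_trans <- classify_cis_trans(out,
                                        gene_chrom = scan$phenotypes$chrom[idx],
                                        gene_pos = scan$phenotypes$pos[idx],
                                        max_dist = cis_bp)
  } else out$cis_trans <- rep("unknown", nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "window_bp") <- window_bp
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Classify peaks as cis or trans
#'
#' A peak is cis when it lies on the same chromosome as the gene whose
#' expression it affects and its center is within `max_dist` bp of the
#' gene position (the bound is inclusive at exactly `max_dist`); trans
#' otherwise; unknown when the gene position is missing.
#'
#' @param peaks a `peak_set` (or data.frame with `chrom`, `center_pos`).
#' @param gene_chrom,gene_pos gene position per peak (recycled if length 1).
#' @param max_dist cis distance bound in bp (default 150,000).
#' @return Character vector in `{"cis", "trans", "unknown"}`.
#' @export
classify_cis_trans <- function(peaks, gene_chrom, gene_pos,
                               max_dist = 150000L) {
  n <- nrow(peaks)
  if (length(gene_chrom) == 1L) gene_chrom <- rep(gene_chrom, n)
  if (length(gene_pos) == 1L) gene_pos <- rep(gene_pos, n)
  out <- rep("unknown", n)
  known <- !is.na(gene_chrom) & !is.na(gene_pos)
  same <- known & peaks$chrom == gene_chrom
  out[known & !same] <- "trans"
  out[same] <- ifelse(abs(peaks$center_pos[same] - gene_pos[same]) <= max_dist,
                      "cis", "trans")
  out
}

#' Count peaks by test, treatment and cis/trans status
#'
#' @param peaks a `peak_set` or a list of them (they are concatenated).
#' @return data.frame with one row per test x treatment: `cis`, `trans`,
#'   `unknown`, `total` counts, plus a per-test `prop_trans` =
#'   trans / (cis + trans) pooled over treatments (peaks with unknown
#'   gene position count toward totals only).
#' @export
summarize_counts <- function(peaks) {
  if (inherits(peaks, "peak_set")) peaks <- list(peaks)
  tab <- do.call(rbind, lapply(peaks, as.data.frame))
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(test = character(), treatment = character(),
                      cis = integer(), trans = integer(),
                      unknown = integer(), total = integer(),
                      prop_trans = numeric()))
  combos <- unique(tab[, c("test", "treatment")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- tab$test == combos$test[i] & tab$treatment == combos$treatment[i]
    ct <- table(factor(tab$cis_trans[sel], levels = c("cis", "trans", "unknown")))
    data.frame(test = combos$test[i], treatment = combos$treatment[i],
               cis = as.integer(ct["cis"]), trans = as.integer(ct["trans"]),
               unknown = as.integer(ct["unknown"]), total = sum(sel),
               stringsAsFactors = FALSE)
  }))
  # proportion trans pooled over treatments, per test
  pool <- tapply(seq_len(nrow(out)), out$test, function(i) {
    tr <- sum(out$trans[i]); ci <- sum(out$cis[i])
    if (tr + ci == 0) NA_real_ else tr / (tr + ci)
  })
  out$prop_trans <- as.numeric(pool[out$test])
  rownames(out) <- NULL
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s)", nrow(x)))
  thr <- attr(x, "threshold")
  if (!is.null(thr)) cat(sprintf(" at p <= %.3g", thr))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x)[,
    c("phenotype", "test", "treatment", "chrom", "center_pos", "center_p",
      "n_snps", "cis_trans")], 10L))
  invisible(x)
}

#' Peak-position versus gene-position map
#'
#' Scatter of peak centers against the position of the affected gene
#' (both on a genome-concatenated axis); cis peaks fall on the diagonal.
#'
#' @param peaks a `peak_set` (classified; peaks with unknown gene
#'   position are skipped).
#' @param gene_pos data.frame with `phenotype`, `chrom`, `pos` giving
#'   gene positions (e.g. the `phenotypes` table of a scan).
#' @param genome named chromosome lengths (bp), defining the axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot_peak_map <- function(peaks, gene_pos, genome, ...) {
  offs <- c(0, cumsum(as.numeric(genome)))
  names(offs) <- c(names(genome), "end")
  gcoord <- function(chrom, pos) offs[as.character(chrom)] + pos
  idx <- match(peaks$phenotype, gene_pos$phenotype)
  ok <- !is.na(idx) & !is.na(gene_pos$chrom[idx]) & !is.na(gene_pos$pos[idx])
  graphics::plot(NA, xlim = c(0, sum(as.numeric(genome))),
                 ylim = c(0, sum(as.numeric(genome))),
                 xlab = "peak position (bp)", ylab = "gene position (bp)", ...)
  graphics::abline(v = offs, h = offs, col = "grey85")
  if (any(ok)) {
    x <- gcoord(peaks$chrom[ok], peaks$center_pos[ok])
    y <- gcoord(gene_pos$chrom[idx[ok]], gene_pos$pos[idx[ok]])
    graphics::points(x, y, pch = ifelse(peaks$test[ok] == "wilcoxon", 16, 4),
                     col = ifelse(peaks$treatment[ok] == "glucose", 2, 4),
                     cex = 0.6)
  }
  invisible(peaks)
}
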