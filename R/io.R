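# Readers/writers for the pipeline's tabular formats.
#
# Genotype TSV: header "marker chrom pos <segregant ids...>"; one row per
# marker; calls coded BY/RM/0/1 with NA, "" or "-" for missing.
# Expression TSV: header "phenotype chrom pos <segregant ids...>"; one
# row per phenotype; chrom/pos may be NA (unknown gene position).
# Coordinates are 1-based inclusive internally; BED export is 0-based
# half-open (start = pos - 1), per the BED standard.

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = .MISSING_CODES, comment.char = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a genotype panel from TSV
#'
#' @param path path to a tab-separated file with columns `marker`,
#'   `chrom`, `pos`, then one column per segregant.  Calls may be coded
#'   `BY`/`RM` or `0`/`1` (BY = 0, RM = 1); `NA`, empty and `-` are
#'   treated as missing.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path) {
  tab <- .read_tsv(path)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(tab)[1:3]))
    stop("genotype file must start with columns marker, chrom, pos")
  seg_ids <- names(tab)[-(1:3)]
  raw <- as.matrix(tab[, -(1:3), drop = FALSE])
  calls <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw))
  chr <- toupper(trimws(as.character(raw)))
  code <- ifelse(chr %in% c("BY", "0"), 0L,
                 ifelse(chr %in% c("RM", "1"), 1L, NA_integer_))
  bad <- !is.na(raw) & is.na(code)
  if (any(bad)) {
    idx <- which(bad)[1L]
    m <- (idx - 1L) %% nrow(raw) + 1L
    s <- (idx - 1L) %/% nrow(raw) + 1L
    stop(sprintf("non-biallelic genotype code '%s' at marker '%s', segregant '%s'",
                 raw[idx], tab$marker[m], seg_ids[s]))
  }
  calls[] <- code
  # rows are markers -> transpose to segregant x marker
  genotype_panel(t(calls), segregant_ids = seg_ids,
                 marker_ids = tab$marker, marker_chrom = tab$chrom,
                 marker_pos = tab$pos)
}

#' Write a genotype panel to TSV
#'
#' @param g a [genotype_panel()].
#' @param path output file.
#' @param coding `"numeric"` writes 0/1, `"parental"` writes BY/RM.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, coding = c("numeric", "parental")) {
  coding <- match.arg(coding)
  m <- t(g$calls)
  out <- if (coding == "parental") {
    matrix(c("BY", "RM")[m + 1L], nrow = nrow(m), dimnames = dimnames(m))
  } else m
  tab <- data.frame(marker = g$markers$marker, chrom = g$markers$chrom,
                    pos = g$markers$pos, out, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[-(1:3)] <- g$segregants
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression panel from TSV
#'
#' @param path tab-separated file with columns `phenotype`, `chrom`,
#'   `pos`, then one numeric column per segregant; `chrom`/`pos` equal to
#'   `NA` flag a phenotype with unknown genome position.
#' @param treatment treatment label attached to the panel.
#' @return An [expression_panel()].
#' @export
read_expression <- function(path, treatment = "other") {
  tab <- .read_tsv(path)
  if (!all(c("phenotype", "chrom", "pos") %in% names(tab)[1:3]))
    stop("expression file must start with columns phenotype, chrom, pos")
  seg_ids <- names(tab)[-(1:3)]
  if (length(seg_ids) < 1L) stop("expression file has no segregant columns")
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  expression_panel(t(vals), segregant_ids = seg_ids,
                   phenotype_ids = tab$phenotype, treatment = treatment,
                   gene_chrom = tab$chrom, gene_pos = tab$pos)
}

#' Write an expression panel to TSV
#' @param e an [expression_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(e, path) {
  tab <- data.frame(phenotype = e$phenotypes$phenotype,
                    chrom = e$phenotypes$chrom, pos = e$phenotypes$pos,
                    t(e$values), check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[-(1:3)] <- e$segregants
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a peak set to TSV (and companion BED6)
#'
#' The TSV carries one row per peak with columns `phenotype`,
#' `treatment`, `test`, `chrom`, `center_pos`, `center_p`, `n_snps`,
#' `cis_trans`, `span_start`, `span_end`, `members`.  The BED6 companion
#' (same path with extension `.bed`) holds the peak spans in 0-based
#' half-open coordinates with `-log10(center_p)` (capped at 1000) as the
#' score.
#'
#' @param peaks a [call_peaks()] result.
#' @param path output TSV path.
#' @param bed_path output BED path (default: `path` with `.bed`).
#' @return Character vector of the two paths, invisibly.
#' @export
write_peaks <- function(peaks, path, bed_path = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.null(bed_path))
    bed_path <- paste0(tools::file_path_sans_ext(path), ".bed")
  cols <- c("phenotype", "treatment", "test", "chrom", "center_pos",
            "center_p", "n_snps", "cis_trans", "span_start", "span_end",
            "members")
  tab <- as.data.frame(peaks)[, cols, drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = tab$chrom,
                    start = tab$span_start - 1L,   # 1-based -> 0-based half-open
                    end = tab$span_end,
                    name = paste(tab$phenotype, tab$test, tab$treatment, sep = "|"),
                    score = pmin(round(-log10(pmax(tab$center_p, 1e-300))), 1000),
                    strand = rep(".", nrow(tab)))
  # header-less BED6; written directly because the table is already laid out
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = path, bed = bed_path))
}

#' Read a peak set written by [write_peaks()]
#' @param path TSV path.
#' @return A `peak_set` data.frame.
#' @export
read_peaks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          cis_trans = "character",
                                          members = "character"))
  if (nrow(tab)) {
    tab$chrom <- as.character(tab$chrom)
    tab$members <- as.character(tab$members)
  }
  class(tab) <- c("peak_set", "data.frame")
  tab
}

#' Read hotspot intervals from a BED file
#'
#' Overlapping intervals are merged with a warning.  BED's 0-based
#' half-open coordinates are converted to the package's 1-based
#' inclusive convention on import.
#'
#' @param path BED file (>= 3 columns; column 4, if present, is the label).
#' @param genome named vector of chromosome lengths in bp (used for the
#'   covered fraction).
#' @return A [hotspot_set()].
#' @export
read_hotspots <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- gr$name
  if (is.null(lab) || all(is.na(lab))) lab <- paste0("hotspot", seq_along(gr))
  hotspot_set(chrom = as.character(GenomicRanges::seqnames(gr)),
              start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
              label = lab, genome = genome)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 file.
#' @param feature feature type(s) to keep (default `"gene"`).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(gr$type)) gr <- gr[as.character(gr$type) %in% feature]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids <- ifelse(is.na(ids) & !is.null(gr$Name), gr$Name, ids)
  data.frame(gene = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
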