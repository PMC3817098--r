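#' Genotype panel of haploid segregants
#'
#' Container for a segregant-by-marker matrix of parental-origin calls
#' together with the marker map.  Calls are coded `0` for the BY allele,
#' `1` for the RM allele, `NA` for missing.  Markers are stored sorted by
#' (chromosome, position); positions are 1-based inclusive.
#'
#' @param calls integer/numeric matrix, segregants in rows, markers in
#'   columns, values in `{0, 1, NA}`.
#' @param segregant_ids character vector of row labels.
#' @param marker_ids character vector of column labels.
#' @param marker_chrom chromosome label per marker.
#' @param marker_pos 1-based bp coordinate per marker; must be strictly
#'   increasing within each chromosome (duplicates raise a warning and
#'   are kept).
#' @return An object of class `"genotype_panel"`: a list with elements
#'   `calls` (matrix), `markers` (data.frame with `marker`, `chrom`,
#'   `pos`) and `segregants`.
#' @seealso [read_genotypes()], [simulate_genotypes()]
#' @export
genotype_panel <- function(calls, segregant_ids, marker_ids, marker_chrom, marker_pos) {
  calls <- as.matrix(calls)
  if (nrow(calls) < 2L) stop("a genotype panel needs at least 2 segregants")
  if (length(segregant_ids) != nrow(calls)) stop("segregant_ids length != nrow(calls)")
  if (length(marker_ids) != ncol(calls)) stop("marker_ids length != ncol(calls)")
  if (length(marker_chrom) != ncol(calls) || length(marker_pos) != ncol(calls))
    stop("marker map length != number of markers")
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf("non-biallelic genotype code %s at segregant '%s', marker '%s'",
                 deparse(calls[idx]),
                 segregant_ids[(idx - 1L) %% nrow(calls) + 1L],
                 marker_ids[(idx - 1L) %/% nrow(calls) + 1L]))
  }
  storage.mode(calls) <- "integer"
  markers <- data.frame(marker = as.character(marker_ids),
                        chrom = as.character(marker_chrom),
                        pos = as.integer(marker_pos),
                        stringsAsFactors = FALSE)
  ord <- order(factor(markers$chrom, levels = unique(markers$chrom)), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(markers) <- NULL
  dup <- stats::ave(markers$pos, markers$chrom,
                    FUN = function(p) duplicated(p)) > 0
  if (any(dup))
    warning(sprintf("%d duplicated marker position(s); keeping both", sum(dup)))
  dimnames(calls) <- list(as.character(segregant_ids), markers$marker)
  structure(list(calls = calls, markers = markers,
                 segregants = as.character(segregant_ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d segregants x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$markers$chrom))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Expression panel
#'
#' Container for a segregant-by-phenotype matrix of log2 expression
#' values for one treatment, with optional gene positions per phenotype.
#' Phenotypes whose genome position is unknown are flagged, not dropped.
#'
#' @param values numeric matrix, segregants in rows, phenotypes in
#'   columns (log2 scale; `NA` allowed, infinities are not).
#' @param segregant_ids,phenotype_ids row / column labels.
#' @param treatment treatment label (e.g. `"glucose"`, `"ethanol"`).
#' @param gene_chrom,gene_pos optional position of the gene behind each
#'   phenotype; `NA` marks an unknown position.
#' @return An object of class `"expression_panel"`: list with `values`,
#'   `phenotypes` (data.frame with `phenotype`, `chrom`, `pos`,
#'   `unknown_position`), `segregants`, `treatment`.
#' @seealso [read_expression()], [simulate_expression()]
#' @export
expression_panel <- function(values, segregant_ids, phenotype_ids,
                             treatment = "other",
                             gene_chrom = NULL, gene_pos = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(segregant_ids) != nrow(values)) stop("segregant_ids length != nrow(values)")
  if (length(phenotype_ids) != ncol(values)) stop("phenotype_ids length != ncol(values)")
  if (any(is.infinite(values))) stop("expression values must be finite where present")
  if (is.null(gene_chrom)) gene_chrom <- rep(NA_character_, ncol(values))
  if (is.null(gene_pos)) gene_pos <- rep(NA_integer_, ncol(values))
  phen <- data.frame(phenotype = as.character(phenotype_ids),
                     chrom = as.character(gene_chrom),
                     pos = as.integer(gene_pos),
                     stringsAsFactors = FALSE)
  phen$unknown_position <- is.na(phen$chrom) | is.na(phen$pos)
  dimnames(values) <- list(as.character(segregant_ids), phen$phenotype)
  structure(list(values = values, phenotypes = phen,
                 segregants = as.character(segregant_ids),
                 treatment = as.character(treatment)),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel (%s): %d segregants x %d phenotypes\n",
              x$treatment, nrow(x$values), ncol(x$values)))
  if (any(x$phenotypes$unknown_position))
    cat(sprintf("  %d phenotype(s) with unknown genome position\n",
                sum(x$phenotypes$unknown_position)))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Restrict genotype and expression panels to their common segregants
#'
#' Both panels are subset, in identical order, to the intersection of
#' their segregant IDs (in the genotype panel's order).  Dropped IDs are
#' reported via `message()`.  The operation is idempotent.
#'
#' @param g a [genotype_panel()].
#' @param e an [expression_panel()].
#' @return A list with elements `genotypes` and `expression`.
#' @export
align_samples <- function(g, e) {
  stopifnot(inherits(g, "genotype_panel"), inherits(e, "expression_panel"))
  common <- intersect(g$segregants, e$segregants)
  if (length(common) == 0L) stop("no segregants shared between the two panels")
  drop_g <- setdiff(g$segregants, common)
  drop_e <- setdiff(e$segregants, common)
  if (length(drop_g))
    vq_message("align_samples: dropping from genotypes: ",
               paste(drop_g, collapse = ", "))
  if (length(drop_e))
    vq_message("align_samples: dropping from expression: ",
               paste(drop_e, collapse = ", "))
  gi <- match(common, g$segregants)
  ei <- match(common, e$segregants)
  g$calls <- g$calls[gi, , drop = FALSE]
  g$segregants <- common
  e$values <- e$values[ei, , drop = FALSE]
  e$segregants <- common
  list(genotypes = g, expression = e)
}
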