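# End-to-end orchestration: scan -> threshold -> peaks -> classification
# -> hotspots -> epistasis screen, from a single configuration, with a
# machine-readable run manifest.

#' Assemble a pipeline configuration
#'
#' @param genotypes path to the genotype TSV, or a [genotype_panel()].
#' @param expression named list (by treatment) of expression TSV paths
#'   or [expression_panel()] objects.
#' @param tests scan tests to run.
#' @param threshold fixed p-value significance threshold; set to `NULL`
#'   to derive one per test x treatment set from the permutation null at
#'   `target_fdr`.
#' @param target_fdr FDR target used when `threshold` is `NULL`.
#' @param perm_P_s,perm_R phenotypes sampled / permutations per
#'   phenotype for [build_null()] (the study design uses 200 x 100).
#' @param peak_window_bp,cis_bp,candidate_window_bp peak assignment
#'   half-window, cis distance bound, candidate-gene half-window (bp).
#' @param min_class minimum genotype-class size per test cell.
#' @param hotspots optional [hotspot_set()] or BED path.
#' @param genome named chromosome lengths (needed with a hotspot BED).
#' @param annotation optional gene table ([read_gene_annotation()]) or
#'   GFF3 path, for candidate-gene lists.
#' @param seed integer seed for all randomized stages.
#' @param out_dir optional output directory; when given, peak tables
#'   (TSV + BED), count tables and the run manifest (JSON) are written.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(genotypes, expression,
                            tests = c("wilcoxon", "brown_forsythe"),
                            threshold = 1e-5, target_fdr = 0.05,
                            perm_P_s = 200L, perm_R = 100L,
                            peak_window_bp = 25000L, cis_bp = 150000L,
                            candidate_window_bp = 10000L, min_class = 2L,
                            hotspots = NULL, genome = NULL,
                            annotation = NULL, seed = 1L, out_dir = NULL) {
  if (!is.null(threshold))
    stopifnot(threshold > 0, threshold < 1)
  stopifnot(peak_window_bp > 0, cis_bp > 0, candidate_window_bp > 0)
  structure(list(genotypes = genotypes, expression = expression,
                 tests = match.arg(tests, several.ok = TRUE),
                 threshold = threshold, target_fdr = target_fdr,
                 perm_P_s = as.integer(perm_P_s), perm_R = as.integer(perm_R),
                 peak_window_bp = peak_window_bp, cis_bp = cis_bp,
                 candidate_window_bp = candidate_window_bp,
                 min_class = as.integer(min_class), hotspots = hotspots,
                 genome = genome, annotation = annotation,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# stable fingerprint of the scalar parameters of a config
config_hash <- function(cfg) {
  keep <- cfg[c("tests", "threshold", "target_fdr", "perm_P_s", "perm_R",
                "peak_window_bp", "cis_bp", "candidate_window_bp",
                "min_class", "seed")]
  fnv1a_hash(paste(deparse(keep), collapse = ""))
}

#' Run the full analysis pipeline
#'
#' Stages: input loading and sample alignment; genome scans per test x
#' treatment; significance thresholds (fixed, or permutation-FDR
#' derived); peak calling with cis/trans classification; count tables;
#' hotspot counting and enrichment chi-squares (when hotspots are
#' supplied); the vQTL-anchored epistasis screen; candidate genes for
#' flagged pairs (when an annotation is supplied).  Deterministic given
#' the configuration seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `"vqtl_pipeline"` with elements `scans`,
#'   `thresholds`, `fdr_at_threshold`, `peaks`, `counts`, `hotspot`
#'   (or NULL), `epistasis`, `candidates` (or NULL), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fail <- function(stage, e) stop(sprintf("pipeline stage '%s' failed: %s",
                                          stage, conditionMessage(e)), call. = FALSE)
  g <- tryCatch({
    if (inherits(cfg$genotypes, "genotype_panel")) cfg$genotypes
    else read_genotypes(cfg$genotypes)
  }, error = function(e) fail("read_genotypes", e))
  panels <- tryCatch({
    lapply(setNames(names(cfg$expression), names(cfg$expression)), function(tr) {
      e <- cfg$expression[[tr]]
      if (inherits(e, "expression_panel")) e else read_expression(e, treatment = tr)
    })
  }, error = function(e) fail("read_expression", e))

  scans <- list(); nulls <- list(); thresholds <- list(); fdrs <- list()
  peak_sets <- list()
  seed_i <- cfg$seed
  for (tr in names(panels)) {
    al <- tryCatch(align_samples(g, panels[[tr]]),
                   error = function(e) fail("align_samples", e))
    for (tst in cfg$tests) {
      key <- paste(tst, tr, sep = ".")
      vq_message(sprintf("pipeline: scanning %s / %s (%d x %d)", tst, tr,
                         ncol(al$expression$values), ncol(al$genotypes$calls)))
      sc <- tryCatch(genome_scan(al$expression, al$genotypes, test = tst,
                                 min_class = cfg$min_class),
                     error = function(e) fail("genome_scan", e))
      scans[[key]] <- sc
      seed_i <- seed_i + 1L
      nul <- tryCatch(build_null(al$expression, al$genotypes, test = tst,
                                 P_s = min(cfg$perm_P_s, ncol(al$expression$values)),
                                 R = cfg$perm_R, seed = seed_i,
                                 min_class = cfg$min_class),
                      error = function(e) fail("build_null", e))
      nulls[[key]] <- nul
      thr <- if (!is.null(cfg$threshold)) cfg$threshold else
        tryCatch(threshold_for_fdr(nul, sc, cfg$target_fdr),
                 error = function(e) fail("threshold_for_fdr", e))
      thresholds[[key]] <- thr
      fdrs[[key]] <- if (is.na(thr)) NA else
        estimate_fdr(nul, sc, thr)$fdr
      if (!is.na(thr))
        peak_sets[[key]] <- tryCatch(
          call_peaks(sc, thr, window_bp = cfg$peak_window_bp,
                     cis_bp = cfg$cis_bp),
          error = function(e) fail("call_peaks", e))
    }
  }
  counts <- tryCatch(summarize_counts(peak_sets),
                     error = function(e) fail("summarize_counts", e))

  hotspot_res <- NULL
  hs <- cfg$hotspots
  if (!is.null(hs)) {
    hotspot_res <- tryCatch({
      if (!inherits(hs, "hotspot_set")) hs <- read_hotspots(hs, cfg$genome)
      all_peaks <- do.call(rbind, lapply(peak_sets, as.data.frame))
      trans <- all_peaks[all_peaks$cis_trans == "trans", , drop = FALSE]
      class(trans) <- c("peak_set", "data.frame")
      cnt <- count_in_hotspots(trans, hs)
      f <- covered_fraction(hs)
      unif <- if (sum(cnt$totals$inside, cnt$totals$outside) > 0)
        uniformity_chisq(sum(cnt$totals$inside), sum(cnt$totals$outside), f)
      else NULL
      qv <- NULL
      tt <- cnt$totals
      if (all(c("wilcoxon", "brown_forsythe") %in% tt$test)) {
        m <- rbind(QTL = c(sum(tt$inside[tt$test == "wilcoxon"]),
                           sum(tt$outside[tt$test == "wilcoxon"])),
                   vQTL = c(sum(tt$inside[tt$test == "brown_forsythe"]),
                            sum(tt$outside[tt$test == "brown_forsythe"])))
        colnames(m) <- c("inside", "outside")
        if (all(rowSums(m) > 0) && all(colSums(m) > 0))
          qv <- qtl_vs_vqtl_chisq(m)
      }
      list(hotspots = hs, counts = cnt, covered_fraction = f,
           uniformity = unif, qtl_vs_vqtl = qv)
    }, error = function(e) fail("hotspot_analysis", e))
  }

  epi <- tryCatch({
    res <- list()
    for (tr in names(panels)) {
      al <- align_samples(g, panels[[tr]])
      sets <- peak_sets[grepl(paste0("\\.", tr, "$"), names(peak_sets))]
      if (length(sets))
        res[[tr]] <- epistasis_screen(sets, al$expression, al$genotypes,
                                      min_n = cfg$min_class)
    }
    do.call(rbind, res)
  }, error = function(e) fail("epistasis_screen", e))

  candidates <- NULL
  if (!is.null(cfg$annotation)) {
    candidates <- tryCatch({
      ann <- if (is.character(cfg$annotation))
        read_gene_annotation(cfg$annotation) else cfg$annotation
      all_peaks <- do.call(rbind, lapply(peak_sets, as.data.frame))
      if (!is.null(all_peaks) && nrow(all_peaks)) {
        lst <- lapply(seq_len(nrow(all_peaks)), function(i)
          candidate_genes(all_peaks[i, ], ann,
                          window_bp = cfg$candidate_window_bp))
        names(lst) <- paste(all_peaks$phenotype, all_peaks$center_marker,
                            sep = "@")
        lst
      } else list()
    }, error = function(e) fail("candidate_genes", e))
  }

  manifest <- list(package = "vqtlscan",
                   version = as.character(utils::packageVersion("vqtlscan")),
                   r_version = as.character(getRversion()),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   threshold_mode = if (is.null(cfg$threshold)) "target_fdr"
                                    else "fixed",
                   threshold = if (is.null(cfg$threshold))
                     unlist(thresholds) else cfg$threshold,
                   target_fdr = cfg$target_fdr,
                   tests = cfg$tests, treatments = names(panels),
                   n_segregants = nrow(g$calls), n_markers = ncol(g$calls))

  out <- structure(list(scans = scans, nulls = nulls, thresholds = thresholds,
                        fdr_at_threshold = fdrs, peaks = peak_sets,
                        counts = counts, hotspot = hotspot_res,
                        epistasis = epi, candidates = candidates,
                        manifest = manifest, config = cfg),
                   class = "vqtl_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' Peak tables (TSV + BED), the count table, the epistasis screen table
#' and the JSON run manifest.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(bundle, dir) {
  stopifnot(inherits(bundle, "vqtl_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(bundle$peaks))
    write_peaks(bundle$peaks[[key]],
                file.path(dir, sprintf("peaks_%s.tsv", key)))
  utils::write.table(bundle$counts, file.path(dir, "peak_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$epistasis))
    utils::write.table(bundle$epistasis, file.path(dir, "epistasis_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.vqtl_pipeline <- function(x, ...) {
  cat("vqtlscan pipeline run\n")
  cat(sprintf("  scans: %s\n", paste(names(x$scans), collapse = ", ")))
  cat(sprintf("  peaks called: %d\n",
              sum(vapply(x$peaks, nrow, integer(1L)))))
  cat(sprintf("  config hash: %s, seed: %d\n", x$manifest$config_hash,
              x$manifest$seed))
  invisible(x)
}

#' Render the pipeline's standard figures to PDF
#'
#' Peak-position vs gene-position map, a Manhattan plot per phenotype
#' with a peak (capped), and GP-map bar plots for flagged epistatic
#' pairs.  Purely presentational.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory.
#' @param genome named chromosome lengths for the peak map (default:
#'   inferred from the scan marker map extents).
#' @param max_manhattan cap on the number of Manhattan plots.
#' @return The directory, invisibly.
#' @export
plot_outputs <- function(bundle, dir, genome = NULL, max_manhattan = 12L) {
  stopifnot(inherits(bundle, "vqtl_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc1 <- bundle$scans[[1L]]
  if (is.null(genome))
    genome <- tapply(sc1$markers$pos, factor(sc1$markers$chrom,
                                             levels = unique(sc1$markers$chrom)),
                     max)
  all_peaks <- do.call(rbind, lapply(bundle$peaks, as.data.frame))
  grDevices::pdf(file.path(dir, "peak_map.pdf"), width = 6, height = 6)
  if (is.null(all_peaks) || nrow(all_peaks) == 0L) {
    pk <- data.frame(phenotype = character(), chrom = character(),
                     center_pos = integer(), test = character(),
                     treatment = character())
    class(pk) <- c("peak_set", "data.frame")
    plot_peak_map(pk, sc1$phenotypes, genome, main = "QTL/vQTL map (empty)")
  } else {
    class(all_peaks) <- c("peak_set", "data.frame")
    plot_peak_map(all_peaks, sc1$phenotypes, genome, main = "QTL/vQTL map")
  }
  grDevices::dev.off()
  if (!is.null(all_peaks) && nrow(all_peaks)) {
    phs <- utils::head(unique(all_peaks$phenotype), max_manhattan)
    grDevices::pdf(file.path(dir, "manhattan.pdf"), width = 8, height = 4)
    for (ph in phs) {
      key <- paste(all_peaks$test[all_peaks$phenotype == ph][1L],
                   all_peaks$treatment[all_peaks$phenotype == ph][1L],
                   sep = ".")
      plot(bundle$scans[[key]], phenotype = ph,
           threshold = bundle$thresholds[[key]])
    }
    grDevices::dev.off()
  }
  epi <- bundle$epistasis
  if (!is.null(epi) && nrow(epi) && any(epi$flag)) {
    flagged <- epi[epi$flag, , drop = FALSE]
    grDevices::pdf(file.path(dir, "gp_maps.pdf"), width = 5, height = 4)
    g <- if (inherits(bundle$config$genotypes, "genotype_panel"))
      bundle$config$genotypes else read_genotypes(bundle$config$genotypes)
    for (i in seq_len(nrow(flagged))) {
      for (tr in unique(vapply(bundle$scans, `[[`, "", "treatment"))) {
        e <- bundle$config$expression[[tr]]
        if (!inherits(e, "expression_panel")) e <- read_expression(e, tr)
        al <- align_samples(g, e)
        mp <- try(gp_map(al$expression, al$genotypes, flagged$phenotype[i],
                         c(flagged$locus1[i], flagged$locus2[i])), silent = TRUE)
        if (!inherits(mp, "try-error")) plot(mp)
      }
    }
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same fields as [pipeline_config()]: `genotypes`
#' (TSV path), `expression` (mapping treatment -> TSV path), scalar
#' parameters, optionally `hotspots` (BED path) with `genome` (mapping
#' chromosome -> length in bp) and `annotation` (GFF3 path).  Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  args <- list(
    genotypes = resolve(raw$genotypes),
    expression = lapply(raw$expression, resolve),
    hotspots = resolve(raw$hotspots),
    annotation = resolve(raw$annotation))
  if (!is.null(raw$genome)) args$genome <- unlist(raw$genome)
  for (f in c("tests", "threshold", "target_fdr", "perm_P_s", "perm_R",
              "peak_window_bp", "cis_bp", "candidate_window_bp",
              "min_class", "seed", "out_dir"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(pipeline_config, args)
}
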