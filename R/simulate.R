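# Synthetic segregant studies with known truth.
#
# Genotypes: each segregant's chromosome is a two-state Markov chain
# along the marker map; the first marker is Bernoulli(0.5) and the
# recombination probability between adjacent markers is the Haldane map
# function r = 0.5 * (1 - exp(-2 d / 100)) with d the inter-marker
# distance in cM (d = spacing_kb * cM_per_kb; no interference).
#
# Expression: y = mu + sum additive e * x
#                 + sum AND-epistasis e * x_A * x_B
#                 - duplicate-factor d * prod(1 - x)
#                 + N(0, sigma_class^2),
# on the log2 scale, with sigma_class genotype-dependent only for the
# direct-vQTL architecture.  Treatments receive independent noise and,
# optionally, treatment-specific effects.

#' S. cerevisiae nuclear chromosome lengths (bp, sacCer3 assembly)
#'
#' Named integer vector used as the default genome for the simulator.
#' @export
yeast_chrom_lengths <- c(
  chr01 = 230218L,  chr02 = 813184L,  chr03 = 316620L,  chr04 = 1531933L,
  chr05 = 576874L,  chr06 = 270161L,  chr07 = 1090940L, chr08 = 562643L,
  chr09 = 439888L,  chr10 = 745751L,  chr11 = 666816L,  chr12 = 1078177L,
  chr13 = 924431L,  chr14 = 784333L,  chr15 = 1091291L, chr16 = 948066L)

#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: 109 haploid
#' segregants of a BY x RM cross, 2956 markers (about one per 4.1 kb)
#' on the 16 yeast chromosomes, a yeast-like map density of 0.35 cM/kb,
#' and Gaussian noise on the log2 scale.
#'
#' @param n_segregants number of haploid segregants.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_markers total marker count, allocated to chromosomes
#'   proportionally to length (largest-remainder rounding) and spaced
#'   evenly within each chromosome.
#' @param cm_per_kb map density in cM per kb (Haldane map function,
#'   no interference).
#' @param noise_sd residual SD of log2 expression.
#' @param seed integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_segregants = 109L,
                       chrom_lengths = yeast_chrom_lengths,
                       n_markers = 2956L, cm_per_kb = 0.35,
                       noise_sd = 0.25, seed = 1L) {
  stopifnot(n_segregants >= 2, all(chrom_lengths > 0), n_markers >= 1,
            cm_per_kb >= 0, noise_sd >= 0, !is.null(names(chrom_lengths)))
  structure(list(n_segregants = as.integer(n_segregants),
                 chrom_lengths = chrom_lengths,
                 n_markers = as.integer(n_markers),
                 cm_per_kb = cm_per_kb, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# allocate n markers to chromosomes proportionally (largest remainder)
.allocate_markers <- function(lengths, n) {
  q <- n * as.numeric(lengths) / sum(as.numeric(lengths))
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  pmax(as.integer(base), 1L)
}

#' Simulate a haploid segregant genotype panel
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_panel()] with markers evenly spaced within each
#'   chromosome; allele frequencies are 0.5 in expectation at every
#'   marker, and linkage decays with distance per the Haldane map.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    counts <- .allocate_markers(cfg$chrom_lengths, cfg$n_markers)
    n <- cfg$n_segregants
    seg_ids <- sprintf("seg%03d", seq_len(n))
    blocks <- vector("list", length(counts))
    map <- vector("list", length(counts))
    for (ci in seq_along(counts)) {
      m <- counts[ci]
      len <- cfg$chrom_lengths[ci]
      pos <- as.integer(round((seq_len(m) - 0.5) * len / m))
      pos <- pmin(pmax(pos, 1L), as.integer(len))
      calls <- matrix(0L, n, m)
      calls[, 1L] <- stats::rbinom(n, 1L, 0.5)
      if (m > 1L) {
        d_cm <- diff(pos) / 1000 * cfg$cm_per_kb
        r <- 0.5 * (1 - exp(-2 * d_cm / 100))
        flips <- matrix(stats::runif(n * (m - 1L)), n, m - 1L) <
          matrix(r, n, m - 1L, byrow = TRUE)
        # cumulative XOR along the chromosome
        states <- t(apply(cbind(calls[, 1L], flips), 1L, cumsum)) %% 2L
        calls <- states
      }
      blocks[[ci]] <- calls
      map[[ci]] <- data.frame(
        marker = sprintf("%s_m%04d", names(cfg$chrom_lengths)[ci], seq_len(m)),
        chrom = names(cfg$chrom_lengths)[ci], pos = pos,
        stringsAsFactors = FALSE)
    }
    mapdf <- do.call(rbind, map)
    genotype_panel(do.call(cbind, blocks), segregant_ids = seg_ids,
                   marker_ids = mapdf$marker, marker_chrom = mapdf$chrom,
                   marker_pos = mapdf$pos)
  })
}

#' Default genetic architectures for a synthetic study
#'
#' One entry per planted phenotype class, mirroring the architecture
#' types the analysis is meant to recover: additive cis and trans
#' effects, a hotspot shared by many phenotypes, AND-type two-locus
#' epistasis, three-locus duplicate-factor epistasis, and a direct
#' variance effect.
#'
#' @param effect additive/epistatic effect size (log2 units).
#' @param n_hotspot_members phenotypes sharing the hotspot regulator.
#' @param sd_ratio residual-SD ratio (RM over BY) of the direct vQTL.
#' @return list of architecture descriptors for [simulate_expression()].
#' @export
default_architectures <- function(effect = 1, n_hotspot_members = 10L,
                                  sd_ratio = 2) {
  list(
    list(type = "cis_additive", effect = effect),
    list(type = "cis_additive", effect = effect),
    list(type = "trans_additive", effect = effect),
    list(type = "trans_additive", effect = effect),
    list(type = "hotspot_member", effect = effect,
         n_phenotypes = n_hotspot_members),
    list(type = "and_epistasis", effect = effect),
    list(type = "duplicate_factor_3locus", depth = effect),
    list(type = "direct_vqtl", sd_ratio = sd_ratio))
}

#' Simulate expression phenotypes over a genotype panel
#'
#' @param g a [genotype_panel()] (typically from [simulate_genotypes()]).
#' @param cfg the [sim_config()] used for `g`.
#' @param architectures list of architecture descriptors; each is a list
#'   with `type` in `cis_additive`, `trans_additive`, `hotspot_member`,
#'   `and_epistasis`, `duplicate_factor_3locus`, `direct_vqtl` plus
#'   type-specific fields (`effect`, `depth`, `sd_ratio`,
#'   `n_phenotypes`, optional `loci` marker ids, optional `treatment`
#'   in `both`/`glucose`/`ethanol`).  See [default_architectures()].
#' @param n_null additional pure-noise phenotypes.
#' @param treatments treatment labels (independent noise per treatment).
#' @return list with one [expression_panel()] per treatment and `truth`,
#'   a data.frame of planted loci and effects per phenotype.
#' @export
simulate_expression <- function(g, cfg, architectures = default_architectures(),
                                n_null = 20L,
                                treatments = c("glucose", "ethanol")) {
  stopifnot(inherits(g, "genotype_panel"), inherits(cfg, "sim_config"))
  types1 <- c("cis_additive", "trans_additive", "and_epistasis",
              "duplicate_factor_3locus", "direct_vqtl")
  for (a in architectures)
    if (!a$type %in% c(types1, "hotspot_member"))
      stop("unknown architecture type: ", a$type)
  with_seed(cfg$seed + 1L, {
    n <- nrow(g$calls); M <- ncol(g$calls)
    mk <- g$markers
    pick_marker <- function(k = 1L) sample.int(M, k)
    # hotspot regulator marker shared by all hotspot_member phenotypes
    hot_idx <- NULL
    specs <- list()
    for (a in architectures) {
      reps <- if (identical(a$type, "hotspot_member")) a$n_phenotypes %||% 5L else 1L
      for (r in seq_len(reps)) specs[[length(specs) + 1L]] <- a
    }
    for (r in seq_len(n_null)) specs[[length(specs) + 1L]] <- list(type = "null")
    P <- length(specs)
    truth <- vector("list", P)
    sig_base <- cfg$noise_sd
    values <- lapply(treatments, function(tr) matrix(NA_real_, n, P))
    names(values) <- treatments
    gene_chrom <- character(P); gene_pos <- integer(P)
    for (j in seq_len(P)) {
      a <- specs[[j]]
      nl <- switch(a$type, cis_additive = 1L, trans_additive = 1L,
                   hotspot_member = 1L, and_epistasis = 2L,
                   duplicate_factor_3locus = 3L, direct_vqtl = 1L, null = 0L)
      if (!is.null(a$loci)) {
        li <- match(a$loci, mk$marker)
        if (anyNA(li)) stop("architecture names unknown loci: ",
                            paste(a$loci[is.na(li)], collapse = ", "))
      } else if (identical(a$type, "hotspot_member")) {
        if (is.null(hot_idx)) hot_idx <- pick_marker()
        li <- hot_idx
      } else li <- pick_marker(nl)
      # gene position: near the causal locus for cis, elsewhere otherwise
      if (identical(a$type, "cis_additive")) {
        gene_chrom[j] <- mk$chrom[li[1L]]
        gene_pos[j] <- pmax(1L, mk$pos[li[1L]] + sample(-5000:5000, 1L))
      } else {
        gi <- pick_marker()
        if (nl > 0L && identical(a$type, "trans_additive")) {
          while (mk$chrom[gi] == mk$chrom[li[1L]]) gi <- pick_marker()
        }
        gene_chrom[j] <- mk$chrom[gi]
        gene_pos[j] <- mk$pos[gi]
      }
      arch_tr <- a$treatment %||% "both"
      for (tr in treatments) {
        on <- arch_tr == "both" || arch_tr == tr
        mu <- numeric(n)
        sdv <- rep(sig_base, n)
        if (on && nl > 0L) {
          x <- g$calls[, li, drop = FALSE]
          mu <- switch(a$type,
            cis_additive = ,
            trans_additive = ,
            hotspot_member = (a$effect %||% 1) * x[, 1L],
            and_epistasis = (a$effect %||% 1) * x[, 1L] * x[, 2L],
            duplicate_factor_3locus =
              -(a$depth %||% 1) * (1 - x[, 1L]) * (1 - x[, 2L]) * (1 - x[, 3L]),
            direct_vqtl = numeric(n))
          if (identical(a$type, "direct_vqtl"))
            sdv <- sig_base * ifelse(x[, 1L] == 1L, a$sd_ratio %||% 2, 1)
        }
        values[[tr]][, j] <- mu + stats::rnorm(n, 0, sdv)
      }
      truth[[j]] <- data.frame(
        phenotype = sprintf("pheno%03d", j), type = a$type,
        loci = if (nl > 0L) paste(mk$marker[li], collapse = ",") else "",
        effect = switch(a$type, duplicate_factor_3locus = a$depth %||% 1,
                        direct_vqtl = a$sd_ratio %||% 2, null = 0,
                        a$effect %||% 1),
        stringsAsFactors = FALSE)
    }
    phen_ids <- sprintf("pheno%03d", seq_len(P))
    panels <- lapply(treatments, function(tr)
      expression_panel(values[[tr]], segregant_ids = g$segregants,
                       phenotype_ids = phen_ids, treatment = tr,
                       gene_chrom = gene_chrom, gene_pos = gene_pos))
    names(panels) <- treatments
    c(panels, list(truth = do.call(rbind, truth)))
  })
}

#' Write a synthetic study to disk
#'
#' Emits the genotype TSV, one expression TSV per treatment, and a truth
#' TSV; reading the files back reproduces the in-memory objects.
#'
#' @param g a [genotype_panel()].
#' @param panels named list of [expression_panel()]s (one per treatment).
#' @param truth truth data.frame from [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(g, panels, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"))
  write_genotypes(g, paths[["genotypes"]])
  for (tr in names(panels)) {
    p <- file.path(dir, sprintf("expression_%s.tsv", tr))
    write_expression(panels[[tr]], p)
    paths[[paste0("expression_", tr)]] <- p
  }
  paths[["truth"]] <- file.path(dir, "truth.tsv")
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
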