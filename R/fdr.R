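# Permutation-based FDR.
#
# The null is built from randomly sampled phenotypes whose values are
# permuted across segregants (the multiset of values is preserved) and
# re-scanned against all markers.  The counting unit for both the
# expected and the observed side is significant SNP tests.  With
# P_total study phenotypes, P_s sampled phenotypes and R permutations
# each:
#   E(t)  = (P_total / P_s) * (1 / R) * #( null p <= t )
#   FDR(t) = E(t) / #( observed p <= t )
# The P_total / P_s scaling (and the counting unit) are configurable.

#' Construct a permutation-null object
#'
#' Normally produced by [build_null()]; the constructor is exported so
#' that nulls can be assembled from pre-computed p-values (e.g. in
#' worked examples and tests).
#'
#' @param p_values numeric vector of all null-scan p-values (NA for
#'   degenerate cells allowed; they are kept but never counted).
#' @param P_s number of sampled phenotypes.
#' @param R permutations per phenotype.
#' @param test,treatment labels carried for compatibility checks.
#' @param n_markers markers per scan.
#' @param sampled_phenotypes ids of the sampled phenotypes.
#' @param seed RNG seed used (if any).
#' @return An object of class `"permutation_null"`.
#' @export
permutation_null <- function(p_values, P_s, R, test = "wilcoxon",
                             treatment = "other", n_markers = NA_integer_,
                             sampled_phenotypes = NULL, seed = NULL) {
  stopifnot(P_s >= 1, R >= 1)
  structure(list(p_values = as.numeric(p_values), P_s = as.integer(P_s),
                 R = as.integer(R), test = test, treatment = treatment,
                 n_markers = n_markers,
                 sampled_phenotypes = sampled_phenotypes, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null (%s, %s): %d phenotypes x %d permutations = %d scans\n",
              x$test, x$treatment, x$P_s, x$R, x$P_s * x$R))
  cat(sprintf("  null p-values stored: %d (min %.3g)\n", length(x$p_values),
              suppressWarnings(min(x$p_values, na.rm = TRUE))))
  invisible(x)
}

#' Build the permutation null for a scan
#'
#' Samples `P_s` phenotypes without replacement, permutes each one's
#' values across segregants `R` times (preserving the value multiset)
#' and scans every permuted copy against all markers.
#'
#' @inheritParams genome_scan
#' @param P_s number of phenotypes to sample (without replacement).
#' @param R permutations per sampled phenotype.
#' @param seed integer seed; the null is reproducible given the seed.
#' @return A [permutation_null()] holding all `P_s * R * n_markers` null
#'   p-values.
#' @export
build_null <- function(e, g, test = c("wilcoxon", "brown_forsythe"),
                       P_s = 200L, R = 100L, seed = NULL, min_class = 2L) {
  test <- match.arg(test)
  if (P_s < 1 || R < 1) stop("P_s and R must be >= 1")
  if (P_s > ncol(e$values)) stop("P_s exceeds the number of phenotypes")
  with_seed(seed, {
    picked <- sort(sample.int(ncol(e$values), P_s))
    n <- nrow(e$values)
    pvals <- vector("list", P_s)
    for (k in seq_len(P_s)) {
      y <- e$values[, picked[k]]
      perm <- matrix(NA_real_, n, R)
      for (r in seq_len(R)) perm[, r] <- y[sample.int(n)]
      ep <- expression_panel(perm, segregant_ids = e$segregants,
                             phenotype_ids = sprintf("perm%03d", seq_len(R)),
                             treatment = e$treatment)
      sc <- genome_scan(ep, g, test = test, min_class = min_class)
      pvals[[k]] <- as.numeric(sc$p)
    }
    permutation_null(unlist(pvals), P_s = P_s, R = R, test = test,
                     treatment = e$treatment, n_markers = ncol(g$calls),
                     sampled_phenotypes = e$phenotypes$phenotype[picked],
                     seed = seed)
  })
}

#' Estimate the FDR at a p-value threshold
#'
#' @param null a [permutation_null()].
#' @param observed a `genome_scan` (or any object with a `p` matrix)
#'   sharing test, treatment and marker set with the null.
#' @param t p-value threshold.
#' @param P_total total number of phenotypes in the study (default:
#'   taken from `observed`); the null counts are scaled by
#'   `P_total / P_s`.
#' @param scale_to_study if `FALSE`, the `P_total / P_s` scaling is
#'   skipped and the FDR refers to the sampled phenotypes only.
#' @return An object of class `"fdr_estimate"`: list with `threshold`,
#'   `expected_false`, `observed_positives`, `fdr`.
#' @export
estimate_fdr <- function(null, observed, t, P_total = NULL,
                         scale_to_study = TRUE) {
  stopifnot(inherits(null, "permutation_null"))
  obs_p <- if (inherits(observed, "genome_scan")) observed$p else observed
  if (inherits(observed, "genome_scan")) {
    if (!identical(observed$test, null$test))
      stop("null and observed scans use different tests")
    if (!identical(observed$treatment, null$treatment))
      stop("null and observed scans use different treatments")
  }
  P_total <- P_total %||% (if (is.matrix(obs_p)) nrow(obs_p) else length(obs_p))
  scale <- if (scale_to_study) P_total / null$P_s else 1
  E <- scale * sum(null$p_values <= t, na.rm = TRUE) / null$R
  O <- sum(obs_p <= t, na.rm = TRUE)
  if (O == 0L) {
    warning("no observed positives at this threshold; FDR is +Inf")
    fdr <- Inf
  } else fdr <- E / O
  structure(list(threshold = t, expected_false = E, observed_positives = O,
                 fdr = fdr), class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("FDR at p <= %.3g: %.4g  (E = %.3g expected false / %d observed)\n",
              x$threshold, x$fdr, x$expected_false, x$observed_positives))
  invisible(x)
}

#' Invert the FDR estimate: threshold for a target FDR
#'
#' Scans the grid of observed p-values from the largest down and returns
#' the largest threshold whose estimated FDR does not exceed the target.
#'
#' @inheritParams estimate_fdr
#' @param target_fdr target FDR in (0, 1).
#' @return The threshold (a p-value), or `NA` if no threshold on the
#'   observed grid achieves the target.
#' @export
threshold_for_fdr <- function(null, observed, target_fdr, P_total = NULL,
                              scale_to_study = TRUE) {
  stopifnot(target_fdr > 0, target_fdr < 1)
  obs_p <- if (inherits(observed, "genome_scan")) observed$p else observed
  obs_p <- sort(as.numeric(obs_p[!is.na(obs_p)]))
  if (length(obs_p) == 0L) stop("no observed p-values to threshold")
  P_total <- P_total %||% (if (inherits(observed, "genome_scan")) nrow(observed$p)
                           else NA_integer_)
  if (is.na(P_total)) P_total <- null$P_s
  scale <- if (scale_to_study) P_total / null$P_s else 1
  nullp <- sort(null$p_values[!is.na(null$p_values)])
  # at t = obs_p[i]: O = i, E = scale/R * #(null <= t)
  Ecount <- findInterval(obs_p, nullp)
  fdr <- scale * Ecount / null$R / seq_along(obs_p)
  ok <- which(fdr <= target_fdr)
  if (length(ok) == 0L) return(NA_real_)
  obs_p[max(ok)]
}

#' Benjamini-Hochberg cross-check
#'
#' Analytical FDR control via [stats::p.adjust()], provided only as a
#' cross-check for the permutation procedure.
#'
#' @param observed a `genome_scan` or numeric vector/matrix of p-values.
#' @param target_fdr target FDR.
#' @return Largest p-value declared significant by BH at `target_fdr`
#'   (`NA` if none).
#' @export
bh_threshold <- function(observed, target_fdr = 0.05) {
  p <- if (inherits(observed, "genome_scan")) observed$p else observed
  p <- as.numeric(p[!is.na(p)])
  adj <- stats::p.adjust(p, method = "BH")
  if (!any(adj <= target_fdr)) return(NA_real_)
  max(p[adj <= target_fdr])
}
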