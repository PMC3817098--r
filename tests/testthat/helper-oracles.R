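# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by brute force / via base
# modelling functions, never through the package's own code paths.

options(vqtlscan.verbose = FALSE)

# exact two-sided Wilcoxon p by enumerating every assignment of the
# group-1 labels and comparing rank-sum deviations from the null mean
oracle_wilcoxon_exact <- function(y, g) {
  r <- rank(y)
  n <- length(y); n1 <- sum(g == 1)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[g == 1]) - mu)
  sets <- combn(n, n1)
  sums <- colSums(matrix(r[sets], nrow = n1))
  mean(abs(sums - mu) >= obs - 1e-9)
}

# Brown-Forsythe as one-way ANOVA on |deviation from the group median|
oracle_bf <- function(y, g) {
  z <- abs(y - ave(y, g, FUN = median))
  fit <- anova(aov(z ~ factor(g)))
  list(F = fit[["F value"]][1L], p = fit[["Pr(>F)"]][1L])
}

# independent greedy peak caller: returns a list of member-position sets
oracle_peaks <- function(chrom, pos, p, threshold, window = 25000) {
  sig <- which(!is.na(p) & p <= threshold)
  out <- list()
  while (length(sig)) {
    ord <- sig[order(p[sig], chrom[sig], pos[sig])]
    ctr <- ord[1L]
    memb <- sig[chrom[sig] == chrom[ctr] & abs(pos[sig] - pos[ctr]) <= window]
    out[[length(out) + 1L]] <- list(center = pos[ctr], chrom = chrom[ctr],
                                    members = sort(pos[memb]))
    sig <- setdiff(sig, memb)
  }
  out
}

# tiny deterministic panels for unit fixtures
make_tiny_genotypes <- function() {
  genotype_panel(rbind(c(0, 1, 0), c(1, 1, NA)),
                 segregant_ids = c("s1", "s2"),
                 marker_ids = c("m1", "m2", "m3"),
                 marker_chrom = c("chr01", "chr01", "chr02"),
                 marker_pos = c(100, 200, 100))
}

make_small_study <- function(n = 60, seed = 42, noise_sd = 0.5,
                             architectures = default_architectures(),
                             n_null = 5) {
  cfg <- sim_config(n_segregants = n,
                    chrom_lengths = c(chr01 = 4e5, chr02 = 4e5,
                                      chr03 = 4e5, chr04 = 4e5),
                    n_markers = 80, noise_sd = noise_sd, seed = seed)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg, architectures = architectures,
                             n_null = n_null)
  list(cfg = cfg, g = g, sim = sim)
}

# marker index lookup by id
marker_index <- function(g, id) match(id, g$markers$marker)

truth_loci <- function(truth, phenotype) {
  strsplit(truth$loci[truth$phenotype == phenotype], ",")[[1]]
}
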