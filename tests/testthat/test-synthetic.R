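test_that("genotype simulation is seed-deterministic and shaped by the config", {
  cfg <- sim_config(seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$calls, g2$calls)
  # default study shape: 109 segregants x 2956 markers on 16 chromosomes
  expect_identical(dim(g1$calls), c(109L, 2956L))
  expect_identical(length(unique(g1$markers$chrom)), 16L)
  # positions strictly increasing within chromosomes
  for (cc in unique(g1$markers$chrom))
    expect_true(all(diff(g1$markers$pos[g1$markers$chrom == cc]) > 0))

  g3 <- simulate_genotypes(sim_config(seed = 6))
  expect_false(identical(g1$calls, g3$calls))
})

test_that("zero map density yields one parental block per chromosome", {
  cfg <- sim_config(n_segregants = 20, cm_per_kb = 0,
                    chrom_lengths = c(chr01 = 5e5, chr02 = 5e5),
                    n_markers = 100, seed = 8)
  g <- simulate_genotypes(cfg)
  for (cc in unique(g$markers$chrom)) {
    block <- g$calls[, g$markers$chrom == cc, drop = FALSE]
    expect_true(all(apply(block, 1, function(x) length(unique(x)) == 1L)))
  }
})

test_that("allele frequencies are balanced and recombination follows Haldane", {
  cfg <- sim_config(n_segregants = 500,
                    chrom_lengths = c(chr01 = 410000),
                    n_markers = 100, cm_per_kb = 0.35, seed = 10)
  g <- simulate_genotypes(cfg)
  # 99% binomial CI around 0.5 at n = 500
  f <- colMeans(g$calls)
  ci <- qnorm(0.995) * sqrt(0.25 / 500)
  expect_true(all(abs(f - 0.5) <= ci + 0.03))

  # adjacent-marker recombinant fraction ~ r(d) within 3 MC SEs
  d_cm <- diff(g$markers$pos) / 1000 * 0.35
  r_theory <- 0.5 * (1 - exp(-2 * d_cm / 100))
  rec <- colMeans(g$calls[, -1] != g$calls[, -ncol(g$calls)])
  se <- sqrt(r_theory * (1 - r_theory) / 500)
  expect_true(all(abs(rec - r_theory) <= 3 * se + 1e-6))

  # linkage decays with distance; across chromosomes ~ 0
  cfg2 <- sim_config(n_segregants = 400,
                     chrom_lengths = c(chr01 = 1e6, chr02 = 1e6),
                     n_markers = 40, seed = 11)
  g2 <- simulate_genotypes(cfg2)
  on1 <- which(g2$markers$chrom == "chr01")
  first <- g2$calls[, on1[1]]
  cors <- vapply(on1[-1], function(m) cor(first, g2$calls[, m]), numeric(1))
  # smoothed monotone decay: correlation with the 2nd marker exceeds the 20th
  expect_gt(cors[1], cors[length(cors)])
  expect_gt(cors[1], 0.5)
  off <- which(g2$markers$chrom == "chr02")
  expect_lt(abs(cor(first, g2$calls[, off[10]])), 0.2)
})

test_that("expression simulation is deterministic and plants what it reports", {
  st1 <- make_small_study(seed = 21)
  st2 <- make_small_study(seed = 21)
  expect_identical(st1$sim$glucose$values, st2$sim$glucose$values)
  expect_identical(st1$sim$ethanol$values, st2$sim$ethanol$values)
  expect_false(identical(st1$sim$glucose$values, st1$sim$ethanol$values))

  truth <- st1$sim$truth
  # every causal locus is a real marker id
  loci <- unlist(strsplit(truth$loci[truth$loci != ""], ","))
  expect_true(all(loci %in% st1$g$markers$marker))
  # hotspot members share one causal marker
  hot <- truth$loci[truth$type == "hotspot_member"]
  expect_identical(length(unique(hot)), 1L)
  # cis phenotypes sit near their causal marker
  cis <- truth[truth$type == "cis_additive", ]
  for (i in seq_len(nrow(cis))) {
    mi <- marker_index(st1$g, cis$loci[i])
    ph <- st1$sim$glucose$phenotypes
    pi <- match(cis$phenotype[i], ph$phenotype)
    expect_identical(ph$chrom[pi], st1$g$markers$chrom[mi])
    expect_lte(abs(ph$pos[pi] - st1$g$markers$pos[mi]), 5000)
  }
  expect_error(simulate_expression(st1$g, st1$cfg,
                                   architectures = list(list(type = "nope"))),
               "unknown architecture")
})

test_that("pure-noise studies scan uniform; planted effects separate the tests", {
  cfg <- sim_config(n_segregants = 109,
                    chrom_lengths = setNames(rep(4e5, 8), paste0("chr0", 1:8)),
                    n_markers = 24, noise_sd = 1, seed = 41)
  g <- simulate_genotypes(cfg)
  nul <- simulate_expression(g, cfg, architectures = list(), n_null = 100)
  p <- as.numeric(genome_scan(nul$glucose, g, "brown_forsythe")$p)
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.05)

  # direct vQTL: variance signal without mean signal
  target <- g$markers$marker[5]
  sim <- simulate_expression(
    g, cfg, architectures = list(list(type = "direct_vqtl", sd_ratio = 3,
                                      loci = target)), n_null = 0)
  y <- sim$glucose$values[, 1]
  x <- g$calls[, 5]
  expect_lt(brown_forsythe_test(y, x)$p, 1e-4)
  expect_gt(wilcoxon_test(y, x)$p, 0.001)
})

test_that("written studies read back identically, with referential integrity", {
  st <- make_small_study(n = 25, seed = 33)
  dir <- withr::local_tempdir()
  paths <- write_study(st$g, st$sim[c("glucose", "ethanol")], st$sim$truth, dir)
  g2 <- read_genotypes(paths[["genotypes"]])
  expect_identical(g2$calls, st$g$calls)
  expect_identical(g2$markers, st$g$markers)
  e2 <- read_expression(paths[["expression_glucose"]], "glucose")
  expect_equal(e2$values, st$sim$glucose$values, tolerance = 1e-12)
  expect_identical(e2$phenotypes$phenotype, st$sim$glucose$phenotypes$phenotype)
  tr2 <- read.table(paths[["truth"]], header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  loci <- unlist(strsplit(tr2$loci[!is.na(tr2$loci) & tr2$loci != ""], ","))
  expect_true(all(loci %in% g2$markers$marker))
})

test_that("AND epistasis induces the predicted marginal variance ratio", {
  # var(y | A = RM) / var(y | A = BY) = 1 + e^2 / (4 sigma^2) = 2 at e/sigma = 2
  cfg <- sim_config(n_segregants = 2000,
                    chrom_lengths = c(chr01 = 2e5, chr02 = 2e5),
                    n_markers = 4, noise_sd = 1, seed = 51)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(
    g, cfg, architectures = list(list(type = "and_epistasis", effect = 2,
                                      loci = c("chr01_m0001", "chr02_m0001"))),
    n_null = 0)
  y <- sim$glucose$values[, 1]
  a <- g$calls[, "chr01_m0001"]
  ratio <- var(y[a == 1]) / var(y[a == 0])
  expect_equal(ratio, 2, tolerance = 0.2)
})
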