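# deterministic two-locus panel: every genotype combination represented
make_two_locus_panel <- function(n_per_class = 5, effect = 2, noise = 0,
                                 model = c("and", "additive"), seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  classes <- expand.grid(a = 0:1, b = 0:1)
  a <- rep(classes$a, each = n_per_class)
  b <- rep(classes$b, each = n_per_class)
  n <- length(a)
  calls <- cbind(a, b, rbinom(n, 1, 0.5))
  g <- genotype_panel(calls, sprintf("s%02d", 1:n), c("mA", "mB", "mC"),
                      c("chr01", "chr02", "chr03"), c(1000, 1000, 1000))
  mu <- if (model == "and") effect * a * b else effect * (a + b)
  y <- mu + rnorm(n, 0, noise)
  e <- expression_panel(matrix(y, n), sprintf("s%02d", 1:n), "ph1",
                        treatment = "glucose")
  list(g = g, e = e, a = a, b = b, y = y)
}

test_that("GP maps recover class means, counts and the AND pattern", {
  px <- make_two_locus_panel(effect = 1.5, noise = 0)
  mp <- gp_map(px$e, px$g, "ph1", c("mA", "mB"))
  expect_identical(nrow(mp), 4L)
  expect_identical(sum(mp$n), 20L)           # conservation, no missing data
  # zero-noise AND model: only (RM,RM) is shifted
  m <- setNames(mp$mean, mp$class)
  expect_equal(unname(m[c("BY,BY", "RM,BY", "BY,RM")]), rep(0, 3))
  expect_equal(unname(m["RM,RM"]), 1.5)
  expect_equal(mp$sd[mp$n > 1], rep(0, 4), tolerance = 1e-12)

  # empty class reported with n = 0, statistics missing
  keep <- !(px$a == 1 & px$b == 1)
  g2 <- px$g; g2$calls <- g2$calls[keep, ]; g2$segregants <- g2$segregants[keep]
  e2 <- px$e; e2$values <- e2$values[keep, , drop = FALSE]
  e2$segregants <- e2$segregants[keep]
  mp2 <- gp_map(e2, g2, "ph1", c("mA", "mB"))
  expect_identical(mp2$n[mp2$class == "RM,RM"], 0L)
  expect_true(is.na(mp2$mean[mp2$class == "RM,RM"]))
})

test_that("the interaction contrast separates additive from epistatic maps", {
  # purely additive, zero noise -> delta exactly 0
  add <- make_two_locus_panel(effect = 2, noise = 0, model = "additive")
  ic_add <- interaction_contrast(gp_map(add$e, add$g, "ph1", c("mA", "mB")))
  expect_equal(ic_add$delta, 0, tolerance = 1e-12)

  # AND model with effect e, zero noise -> delta = e
  andm <- make_two_locus_panel(effect = 2, noise = 0, model = "and")
  ic_and <- interaction_contrast(gp_map(andm$e, andm$g, "ph1", c("mA", "mB")))
  expect_equal(ic_and$delta, 2, tolerance = 1e-12)

  # shift invariance; flipping ONE locus coding flips the sign;
  # flipping BOTH codings returns the original contrast
  e_shift <- andm$e; e_shift$values <- e_shift$values + 7
  expect_equal(interaction_contrast(gp_map(e_shift, andm$g, "ph1",
                                           c("mA", "mB")))$delta,
               2, tolerance = 1e-12)
  g_flip1 <- andm$g; g_flip1$calls[, "mA"] <- 1L - g_flip1$calls[, "mA"]
  expect_equal(interaction_contrast(gp_map(andm$e, g_flip1, "ph1",
                                           c("mA", "mB")))$delta,
               -2, tolerance = 1e-12)
  g_flip2 <- g_flip1; g_flip2$calls[, "mB"] <- 1L - g_flip2$calls[, "mB"]
  expect_equal(interaction_contrast(gp_map(andm$e, g_flip2, "ph1",
                                           c("mA", "mB")))$delta,
               2, tolerance = 1e-12)
})

test_that("three-locus duplicate-factor maps give the alternating-sum depth", {
  # depth-d down-shift only in the all-BY class
  set.seed(2)
  combos <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  calls <- combos[rep(1:8, each = 3), ]
  n <- nrow(calls)
  g <- genotype_panel(calls, sprintf("s%02d", 1:n), c("mA", "mB", "mC"),
                      paste0("chr0", 1:3), rep(1000, 3))
  d <- 1.8
  y <- -d * (calls[, 1] == 0) * (calls[, 2] == 0) * (calls[, 3] == 0)
  e <- expression_panel(matrix(y, n), sprintf("s%02d", 1:n), "ph1")
  ic <- interaction_contrast(gp_map(e, g, "ph1", c("mA", "mB", "mC")))
  expect_equal(ic$delta, d, tolerance = 1e-12)
})

test_that("marginal variance ratios reflect planted variance heterogeneity", {
  # AND model: var(y | A=RM) / var(y | A=BY) -> 1 + e^2/(4 sigma^2)
  set.seed(31)
  n <- 4000
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y <- 2 * a * b + rnorm(n, 0, 1)
  g <- genotype_panel(cbind(a, b), sprintf("s%04d", 1:n), c("mA", "mB"),
                      c("chr01", "chr02"), c(1000, 1000))
  e <- expression_panel(matrix(y, n), sprintf("s%04d", 1:n), "ph1")
  ic <- interaction_contrast(gp_map(e, g, "ph1", c("mA", "mB")))
  expect_equal(unname(ic$variance_ratio["mA"]), 2, tolerance = 0.15)
  # contrast recovers the effect within Monte-Carlo error
  expect_equal(ic$delta, 2, tolerance = 5 * ic$se)
})

test_that("gp_map class means recombine to the full-sample mean", {
  st <- make_small_study(n = 50, seed = 17)
  e <- st$sim$glucose; g <- st$g
  mp <- gp_map(e, g, "pheno001", g$markers$marker[c(1, 30)])
  expect_equal(sum(mp$n * mp$mean) / sum(mp$n), mean(e$values[, "pheno001"]),
               tolerance = 1e-12)
})

test_that("conditional scans recover a planted modifier and validate inputs", {
  set.seed(55)
  cfg <- sim_config(n_segregants = 109,
                    chrom_lengths = c(chr01 = 3e5, chr02 = 3e5),
                    n_markers = 30, noise_sd = 1, seed = 66)
  g <- simulate_genotypes(cfg)
  anchor <- "chr01_m0008"; modifier <- "chr02_m0007"
  sim <- simulate_expression(
    g, cfg, architectures = list(list(type = "and_epistasis", effect = 2,
                                      loci = c(anchor, modifier))),
    n_null = 0)
  cs <- conditional_scan(sim$glucose, g, "pheno001", anchor, "RM",
                         perm_R = 100, seed = 12)
  expect_false(is.na(cs$threshold))
  best <- which.min(cs$scan$p[1, ])
  expect_identical(cs$scan$markers$chrom[best], "chr02")
  expect_lte(abs(cs$scan$markers$pos[best] -
                   g$markers$pos[marker_index(g, modifier)]), 25000)
  expect_lt(min(cs$scan$p, na.rm = TRUE), cs$threshold)

  # anchor genotype nobody carries / too-small subsets error out
  g2 <- g; g2$calls[, 1] <- 0L
  expect_error(conditional_scan(sim$glucose, g2, "pheno001",
                                g$markers$marker[1], "RM"),
               "no segregants carry")
  expect_error(conditional_scan(sim$glucose, g, "pheno001", anchor, "RM",
                                min_class = 60), "too small")
})

test_that("candidate genes are selected by span intersection with the window", {
  ann <- data.frame(gene = c("G1", "G2"), chrom = "chr01",
                    start = c(5000L, 25000L), end = c(8000L, 30000L),
                    stringsAsFactors = FALSE)
  peak <- list(chrom = "chr01", center_pos = 12000L)
  expect_identical(candidate_genes(peak, ann, 10000)$gene, "G1")
  # window 0: only genes overlapping the center position itself
  expect_identical(nrow(candidate_genes(peak, ann, 0)), 0L)
  expect_identical(candidate_genes(list(chrom = "chr01", center_pos = 6000L),
                                   ann, 0)$gene, "G1")
  # absent chromosome: empty with warning
  expect_warning(res <- candidate_genes(list(chrom = "chrX", center_pos = 1L), ann),
                 "absent")
  expect_identical(nrow(res), 0L)
  # empty annotation: empty, no warning
  expect_silent(res0 <- candidate_genes(peak, ann[0, ]))
  expect_identical(nrow(res0), 0L)
})

test_that("the epistasis screen flags a planted AND pair from its peaks", {
  set.seed(91)
  cfg <- sim_config(n_segregants = 109,
                    chrom_lengths = c(chr01 = 3e5, chr02 = 3e5),
                    n_markers = 30, noise_sd = 0.5, seed = 14)
  g <- simulate_genotypes(cfg)
  a <- "chr01_m0005"; b <- "chr02_m0010"
  sim <- simulate_expression(
    g, cfg, architectures = list(list(type = "and_epistasis", effect = 2,
                                      loci = c(a, b))), n_null = 2)
  scw <- genome_scan(sim$glucose, g, "wilcoxon")
  scb <- genome_scan(sim$glucose, g, "brown_forsythe")
  pks <- list(call_peaks(scw, 1e-4), call_peaks(scb, 1e-3))
  res <- epistasis_screen(pks, sim$glucose, g)
  expect_gt(nrow(res), 0)
  hit <- res[res$phenotype == "pheno001", ]
  expect_true(any(hit$flag))
  # the flagged pair's contrast approximates the planted effect
  expect_lt(min(abs(hit$delta[hit$flag] - 2)), 1)
})
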