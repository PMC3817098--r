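# helper: wrap a hand-built p-value row into a scan object
make_scan <- function(chrom, pos, p, phenotype = "ph1",
                      gene_chrom = NA, gene_pos = NA,
                      test = "wilcoxon", treatment = "glucose") {
  pm <- matrix(p, nrow = 1,
               dimnames = list(phenotype, paste0("m", seq_along(p))))
  structure(list(test = test, treatment = treatment, p = pm,
                 statistic = pm, n0 = pm, n1 = pm,
                 markers = data.frame(marker = colnames(pm), chrom = chrom,
                                      pos = as.integer(pos),
                                      stringsAsFactors = FALSE),
                 phenotypes = data.frame(phenotype = phenotype,
                                         chrom = gene_chrom,
                                         pos = gene_pos,
                                         unknown_position = is.na(gene_chrom),
                                         stringsAsFactors = FALSE)),
            class = "genome_scan")
}

test_that("the worked three-SNP example yields exactly two peaks", {
  sc <- make_scan(rep("chr01", 3), c(100000, 110000, 170000),
                  c(1e-8, 1e-6, 1e-7))
  pk <- call_peaks(sc, 1e-5)
  expect_identical(nrow(pk), 2L)
  expect_identical(pk$center_pos, c(100000L, 170000L))
  expect_identical(pk$n_snps, c(2L, 1L))
  expect_identical(strsplit(pk$members[1], ",")[[1]], c("m1", "m2"))
})

test_that("no significant SNP gives an empty set; 60 kb separation gives two peaks", {
  sc <- make_scan(rep("chr01", 3), c(1e5, 1.1e5, 1.7e5), c(1e-3, 1e-2, 1e-3))
  expect_identical(nrow(call_peaks(sc, 1e-5)), 0L)

  sc2 <- make_scan(rep("chr01", 2), c(100000, 160000), c(1e-8, 1e-7))
  pk2 <- call_peaks(sc2, 1e-5)
  expect_identical(nrow(pk2), 2L)
})

test_that("peaks partition the significant SNPs and never span chromosomes", {
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(10:50, 1)
    chrom <- sort(sample(paste0("chr0", 1:3), m, replace = TRUE))
    pos <- unlist(tapply(seq_len(m), chrom, function(i)
      sort(sample.int(3e5, length(i)))), use.names = FALSE)
    p <- 10^-runif(m, 0, 10)
    sc <- make_scan(chrom, pos, p)
    pk <- call_peaks(sc, 1e-4)
    members <- unlist(strsplit(pk$members, ","))
    sig <- sc$markers$marker[p <= 1e-4]
    expect_setequal(members, sig)             # every significant SNP in a peak
    expect_identical(anyDuplicated(members), 0L)  # ... exactly one peak
    for (i in seq_len(nrow(pk))) {
      mi <- match(strsplit(pk$members[i], ",")[[1]], sc$markers$marker)
      expect_true(all(sc$markers$chrom[mi] == pk$chrom[i]))
      expect_true(all(abs(sc$markers$pos[mi] - pk$center_pos[i]) <= 25000))
    }
    expect_equal(pk$center_p, vapply(seq_len(nrow(pk)), function(i) {
      mi <- match(strsplit(pk$members[i], ",")[[1]], sc$markers$marker)
      min(p[mi])
    }, numeric(1)))
  }
})

test_that("greedy calling matches an independent brute-force implementation", {
  set.seed(77)
  for (rep in 1:60) {
    m <- sample(5:50, 1)
    chrom <- sort(sample(paste0("chr0", 1:2), m, replace = TRUE))
    pos <- unlist(tapply(seq_len(m), chrom, function(i)
      sort(sample.int(2e5, length(i)))), use.names = FALSE)
    p <- signif(10^-runif(m, 0, 8), 2)   # rounding induces occasional ties
    sc <- make_scan(chrom, pos, p)
    pk <- call_peaks(sc, 1e-3)
    ref <- oracle_peaks(chrom, pos, p, 1e-3)
    expect_identical(nrow(pk), length(ref))
    for (i in seq_along(ref)) {
      expect_identical(pk$center_pos[i], as.integer(ref[[i]]$center))
      mi <- match(strsplit(pk$members[i], ",")[[1]], sc$markers$marker)
      expect_identical(sort(pos[mi]), ref[[i]]$members)
    }
  }
})

test_that("peak calling is invariant to marker input order", {
  set.seed(13)
  m <- 30
  chrom <- rep("chr01", m)
  pos <- sort(sample.int(4e5, m))
  p <- 10^-runif(m, 0, 8)
  sc <- make_scan(chrom, pos, p)
  pk <- call_peaks(sc, 1e-3)
  perm <- sample(m)
  # the genotype-panel constructor re-sorts markers, and call_peaks works
  # off the sorted map, so shuffled input yields identical peaks
  sc2 <- make_scan(chrom[perm], pos[perm], p[perm])
  ord <- order(sc2$markers$pos)
  sc2$markers <- sc2$markers[ord, ]
  sc2$p <- sc2$p[, ord, drop = FALSE]
  sc2$markers$marker <- paste0("m", seq_len(m))  # relabel after sort
  colnames(sc2$p) <- sc2$markers$marker
  pk2 <- call_peaks(sc2, 1e-3)
  expect_identical(pk2$center_pos, pk$center_pos)
  expect_identical(pk2$n_snps, pk$n_snps)
})

test_that("stricter thresholds never grow a surviving peak's membership", {
  set.seed(19)
  m <- 40
  sc <- make_scan(rep("chr01", m), sort(sample.int(5e5, m)), 10^-runif(m, 0, 8))
  pk_loose <- call_peaks(sc, 1e-3)
  pk_strict <- call_peaks(sc, 1e-5)
  loose_members <- strsplit(pk_loose$members, ",")
  names(loose_members) <- pk_loose$center_marker
  for (i in seq_len(nrow(pk_strict))) {
    ctr <- pk_strict$center_marker[i]
    if (ctr %in% names(loose_members))
      expect_true(all(strsplit(pk_strict$members[i], ",")[[1]] %in%
                        loose_members[[ctr]]))
  }
})

test_that("cis/trans classification respects the inclusive 150 kb boundary", {
  pk <- data.frame(chrom = rep("chr05", 4),
                   center_pos = c(200000, 200000, 200000, 200000))
  expect_identical(
    classify_cis_trans(pk,
                       gene_chrom = rep("chr05", 4),
                       gene_pos = c(200000 - 149999, 200000 - 150000,
                                    200000 - 150001, 200000 + 150001)),
    c("cis", "cis", "trans", "trans"))
  # different chromosome: always trans, whatever the bp distance
  expect_identical(classify_cis_trans(pk[1, ], "chr06", 200000), "trans")
  # missing gene position: unknown
  expect_identical(classify_cis_trans(pk[1, ], NA, NA), "unknown")
})

test_that("count tables include unknowns in totals but not cis/trans sums", {
  pk <- data.frame(
    phenotype = sprintf("p%d", 1:10), treatment = "glucose", test = "wilcoxon",
    chrom = "chr01", center_marker = sprintf("m%d", 1:10),
    center_pos = 1:10 * 1000L, center_p = 1e-8, n_snps = 1L,
    span_start = 1:10 * 1000L, span_end = 1:10 * 1000L, members = "m",
    cis_trans = c(rep("cis", 3), rep("trans", 6), "unknown"),
    stringsAsFactors = FALSE)
  class(pk) <- c("peak_set", "data.frame")
  ct <- summarize_counts(pk)
  expect_identical(ct$cis, 3L)
  expect_identical(ct$trans, 6L)
  expect_identical(ct$unknown, 1L)
  expect_identical(ct$total, 10L)
  expect_equal(ct$prop_trans, 6 / 9, tolerance = 1e-12)

  expect_identical(nrow(summarize_counts(list())), 0L)
})
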