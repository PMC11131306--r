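test_that("gene means weight windows by overlap and respect refinement", {
  gene <- list(chrom = "11", start = 100001, end = 200000)
  w1 <- data.frame(chrom = "11", start = 1, end = 300000, value = 0.8)
  expect_equal(gene_weighted_mean(gene, w1), 0.8)
  # 30 kb at 1.0 and 70 kb at 2.0 -> 1.7
  w2 <- data.frame(chrom = "11", start = c(70001, 130001),
                   end = c(130000, 200000), value = c(1, 2))
  expect_equal(gene_weighted_mean(gene, w2), 1.7)
  # splitting a window into equal-valued halves changes nothing
  w3 <- data.frame(chrom = "11", start = c(70001, 100001, 130001),
                   end = c(100000, 130000, 200000), value = c(1, 1, 2))
  expect_equal(gene_weighted_mean(gene, w3), 1.7)
  expect_warning(v <- gene_weighted_mean(list(chrom = "11", start = 1,
                                              end = 10),
                                         w2), "no window")
  expect_true(is.na(v))
})

test_that("length matching uses inclusive bounds", {
  genes <- data.frame(gene = c("A", "B", "C"), chrom = "1",
                      start = c(1, 1, 1),
                      end = c(116690, 116689, 156690))
  hit <- length_matched_genes(genes, 136690, 20000)
  expect_equal(hit$gene, c("A", "C"))
  # synthetic 50-gene table with known in-tolerance subset
  set.seed(5)
  lens <- c(rep(136690, 6), sample(c(110000:116000, 157000:190000), 44))
  lens[7:12] <- 136690 + sample(c(-20000:20000), 6)
  g50 <- data.frame(gene = sprintf("G%02d", 1:50), chrom = "1", start = 1,
                    end = lens)
  expected <- g50$gene[abs(lens - 136690) <= 20000]
  expect_equal(length_matched_genes(g50, 136690, 20000)$gene, expected)
  expect_equal(length(expected), 12)
  # the focal gene is excluded from its own background
  expect_false("G01" %in%
                 length_matched_genes(g50, 136690, 20000,
                                      exclude = "G01")$gene)
  expect_error(length_matched_genes(genes, 1e7, 10), "no genes")
})

test_that("standardization returns z-scores and strict quantiles", {
  bg <- 0:99
  at_mean <- standardize_statistic(mean(bg), bg)
  expect_equal(at_mean$z, 0)
  expect_equal(standardize_statistic(99, bg)$quantile, 0.99)
  # affine invariance of z
  z1 <- standardize_statistic(80, bg)$z
  z2 <- standardize_statistic(80 * 3 + 7, bg * 3 + 7)$z
  expect_equal(z1, z2)
  expect_error(standardize_statistic(1, rep(2, 40)), "zero background")
  expect_error(standardize_statistic(1, 1:10), ">= 30")
})

test_that("empirical window p-values count strictly greater windows", {
  expect_equal(empirical_window_pvalue(10, 1:9), 0)
  expect_equal(empirical_window_pvalue(1, 1:10), 0.9)
  expect_equal(empirical_window_pvalue(5, c(1, 5, 5, 9)), 0.25)  # ties excluded
  obs <- seq(0, 10, by = 0.5)
  p <- vapply(obs, empirical_window_pvalue, numeric(1),
              window_values = runif(50, 0, 10))
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("nucleotide diversity matches formula and pairwise oracle", {
  # n=4 haplotypes, ALT counts {1,2}, span 10
  hap <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0))
  m <- toy_matrix(hap = hap, arc = cbind(c(0, 0)), pos = c(1, 10))
  expect_equal(nucleotide_diversity(m, span_bp = 10), (0.5 + 2 / 3) / 10)
  # monomorphic data
  m0 <- toy_matrix(hap = matrix(0, 2, 4), arc = cbind(c(0, 0)))
  expect_equal(nucleotide_diversity(m0, span_bp = 10), 0)
  # pairwise Hamming oracle on random fixtures
  set.seed(6)
  for (rep in 1:3) {
    h <- matrix(rbinom(30 * 8, 1, runif(1, 0.2, 0.8)), 30, 8)
    mr <- toy_matrix(hap = h, arc = cbind(rep(0, 30)),
                     pos = seq(10, by = 7, length.out = 30))
    expect_equal(nucleotide_diversity(mr, span_bp = 1000),
                 brute_force_pi(h, 1000), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(m, span_bp = 0), "positive")
})

test_that("Fay and Wu's H matches the hand-computed SFS values", {
  # n=4, one site with derived count 3: theta_pi=0.5, theta_H=1.5, H=-1
  m <- toy_matrix(hap = rbind(c(1, 1, 1, 0)), arc = cbind(0), aa = "A")
  expect_equal(fay_wu_h(m), -1)
  # folded-symmetric SFS S_1=S_3=1: H = 1 - 5/3
  m2 <- toy_matrix(hap = rbind(c(1, 0, 0, 0), c(1, 1, 1, 0)),
                   arc = cbind(c(0, 0)))
  expect_equal(fay_wu_h(m2), 1 - 2 * (1 + 9) / 12)
  # monomorphic: 0
  m0 <- toy_matrix(hap = rbind(c(0, 0, 0, 0)), arc = cbind(0))
  expect_equal(fay_wu_h(m0), 0)
  # derived coding respected: AA=ALT flips the count
  m3 <- toy_matrix(hap = rbind(c(1, 1, 1, 0)), arc = cbind(0), aa = "G")
  expect_equal(fay_wu_h(m3), 0.5 - 2 * 1 / 12)  # derived count 1
  # unpolarized matrix aborts
  m4 <- toy_matrix(hap = rbind(c(1, 0)), arc = cbind(0), aa = "N")
  expect_error(fay_wu_h(m4), "polarized")
})

test_that("the gene scan produces a complete z table for projection", {
  sim <- simulate_locus(simulation_config(seed = 13, n_populations = 3,
                                          n_per_pop = 12))
  td <- tempfile()
  write_bundle(sim, td)
  windows <- read_window_stats(file.path(td, "windows.tsv"))
  genes <- local({
    b <- read.table(file.path(td, "genes.bed"), sep = "\t")
    data.frame(gene = b$V4, chrom = as.character(b$V1), start = b$V2 + 1,
               end = b$V3)
  })
  scan <- standardize_gene_scan(windows, genes, "FOCAL")
  expect_equal(rownames(scan$z), c("POP1", "POP2", "POP3"))
  expect_false(anyNA(scan$z))
  expect_gte(scan$n_background, 30)
  ord <- project_populations(scan$z, k = 2)
  expect_equal(nrow(ord$points), 3)
  expect_lt(ord$stress1, 1e-6)
})
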