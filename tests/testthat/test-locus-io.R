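region <- locus_region("11", 1, 100000)

test_that("modern VCF reading keeps biallelic SNVs and expands haplotypes", {
  # 3 samples, 2 biallelic SNVs, 1 multiallelic, 1 indel
  f <- write_test_vcf(tempfile(fileext = ".vcf"), chrom = "11",
                      pos = c(100, 200, 300, 400),
                      ref = c("A", "G", "C", "AT"),
                      alt = c("G", "T,C", "T", "A"),
                      aa = c("g", "G", "C", "A"),
                      gt = c("0|1", "0|0", "1|1",
                             "0|1", "0|0", "0|0",
                             "0|0", "0|1", "1|0",
                             "0|0", "0|0", "0|0"),
                      samples = c("S1", "S2", "S3"))
  r <- read_modern_vcf(f, region)
  expect_equal(nrow(r$sites), 2)          # multiallelic + indel excluded
  expect_equal(r$sites$pos, c(100, 300))
  expect_equal(ncol(r$hap), 6)
  # hand transcription of the fixture GT fields
  expect_equal(unname(r$hap[1, ]), c(0L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(unname(r$hap[2, ]), c(0L, 0L, 0L, 1L, 1L, 0L))
  # lowercase AA=g with REF=A, ALT=G: polarized, derived is REF
  expect_true(r$sites$polarized[1])
  expect_false(r$sites$derived_is_alt[1])
  # AA=C equal to REF at site 300: derived is ALT
  expect_true(r$sites$derived_is_alt[2])
})

test_that("unphased modern genotypes abort with site and sample named", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), chrom = "11", pos = 500,
                      ref = "A", alt = "G", aa = "A",
                      gt = c("0|1", "0/1"), samples = c("S1", "S2"))
  expect_error(read_modern_vcf(f, region), "11:500.*S2")
})

test_that("AA values outside {ref, alt} leave sites unpolarized", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), chrom = "11",
                      pos = c(10, 20, 30), ref = c("A", "A", "A"),
                      alt = c("G", "G", "G"), aa = c("N", ".", "-"),
                      gt = rep("0|1", 3), samples = "S1")
  r <- read_modern_vcf(f, region)
  expect_equal(r$sites$polarized, c(FALSE, FALSE, FALSE))
})

test_that("archaic dosages are 0/1/2 with uncalled sites flagged", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), chrom = "11",
                      pos = c(10, 20, 30, 40), ref = rep("A", 4),
                      alt = rep("G", 4), aa = rep("A", 4),
                      gt = c("0/0", "0/1", "1/1", "./."), samples = "Altai")
  r <- read_archaic_vcf(f, region)
  expect_equal(unname(r$dosage), c(0L, 1L, 2L, NA))
  expect_equal(r$meta$kind, "archaic")
})

test_that("multi-sample archaic VCFs are rejected", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"), chrom = "11", pos = 10,
                      ref = "A", alt = "G", gt = c("0/0", "0/1"),
                      samples = c("A1", "A2"))
  expect_error(read_archaic_vcf(f, region), "single-sample")
})

make_merge_inputs <- function(n_sites = 10, uncalled_at = integer(0)) {
  pos <- seq(100, by = 100, length.out = n_sites)
  fm <- write_test_vcf(tempfile(fileext = ".vcf"), "11", pos,
                       rep("A", n_sites), rep("G", n_sites),
                       aa = rep("A", n_sites),
                       gt = rep(c("0|1", "1|0"), n_sites),
                       samples = c("S1", "S2"))
  gts <- rep("0/1", n_sites)
  gts[uncalled_at] <- "./."
  fa <- write_test_vcf(tempfile(fileext = ".vcf"), "11", pos,
                       rep("A", n_sites), rep("G", n_sites),
                       aa = rep("A", n_sites), gt = gts, samples = "Altai")
  fa2 <- write_test_vcf(tempfile(fileext = ".vcf"), "11", pos,
                        rep("A", n_sites), rep("G", n_sites),
                        aa = rep("A", n_sites), gt = rep("1/1", n_sites),
                        samples = "Denisova")
  list(modern = read_modern_vcf(fm, region),
       a1 = read_archaic_vcf(fa, region),
       a2 = read_archaic_vcf(fa2, region))
}

test_that("merge drops sites uncalled or absent in any input", {
  inp <- make_merge_inputs(10, uncalled_at = c(2, 5, 9))
  m <- merge_datasets(inp$modern, list(inp$a1, inp$a2))
  expect_equal(nrow(m$sites), 7)
  expect_false(anyNA(m$hap))
  expect_false(anyNA(m$arc))
  # identical site lists and all called: everything retained
  inp2 <- make_merge_inputs(10)
  m2 <- merge_datasets(inp2$modern, list(inp2$a1, inp2$a2))
  expect_equal(nrow(m2$sites), 10)
  # sites absent from one archaic are dropped
  inp3 <- make_merge_inputs(10)
  inp3$a1$sites <- inp3$a1$sites[-c(1, 4), ]
  inp3$a1$dosage <- inp3$a1$dosage[-c(1, 4)]
  m3 <- merge_datasets(inp3$modern, list(inp3$a1, inp3$a2))
  expect_equal(nrow(m3$sites), 8)
})

test_that("merge is order-independent in the archaic list", {
  inp <- make_merge_inputs(10, uncalled_at = 3)
  m12 <- merge_datasets(inp$modern, list(inp$a1, inp$a2))
  m21 <- merge_datasets(inp$modern, list(inp$a2, inp$a1))
  expect_identical(m12$sites, m21$sites)
  expect_identical(m12$hap, m21$hap)
  expect_identical(m12$arc[, colnames(m21$arc)], m21$arc[, colnames(m21$arc)])
})

test_that("REF/ALT mismatches at a shared position abort", {
  inp <- make_merge_inputs(5)
  inp$a1$sites$alt[3] <- "T"
  expect_error(merge_datasets(inp$modern, list(inp$a1, inp$a2)),
               "mismatch")
})

test_that("merged matrices round-trip through VCF exactly", {
  sim <- simulate_locus(simulation_config(seed = 11, n_shared = 40,
                                          n_emh = 20, n_arc = 20,
                                          n_per_pop = 5, n_introgressed = 1))
  d <- tempfile()
  write_merged(sim$matrix, d)
  m2 <- read_merged(d)
  expect_identical(m2$sites, sim$matrix$sites)
  expect_identical(m2$hap, sim$matrix$hap)
  expect_identical(m2$arc, sim$matrix$arc)
})

test_that("polarization flips derived dosage where ancestral is ALT", {
  # site 1: AA=REF (derived = ALT); site 2: AA=ALT (derived = REF)
  m <- toy_matrix(hap = rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)),
                  arc = rbind(c(2, 1), c(2, 1)),
                  aa = c("A", "G"))
  dh <- derived_haplotypes(m)
  dg <- derived_dosages(m)
  expect_equal(unname(dh[1, ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(dh[2, ]), c(0L, 1L, 0L, 1L))
  expect_equal(unname(dg[1, ]), c(2L, 1L))
  expect_equal(unname(dg[2, ]), c(0L, 1L))
  # unpolarizable site is excluded from the derived views
  m3 <- toy_matrix(hap = rbind(c(1, 0), c(0, 1)), arc = cbind(c(1, 1)),
                   aa = c("N", "A"))
  expect_equal(nrow(derived_haplotypes(m3)), 1)
  expect_equal(attr(derived_haplotypes(m3), "site_index"), 2L)
})
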